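# Independent oracles used across the suite. These are written against the
# shared cost model (gap of length L costs open + L*extend; identity =
# matches/columns) but share no code with the package kernels.

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

rc_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# full three-state affine dynamic program over explicit matrices
oracle_align_score <- function(q, r, match, mismatch, gap_open, gap_extend) {
  qv <- strsplit(q, "")[[1]]; rv <- strsplit(r, "")[[1]]
  n <- length(qv); m <- length(rv)
  NEG <- -1e9
  M <- X <- Y <- matrix(NEG, n + 1, m + 1)
  M[1, 1] <- 0
  if (m > 0) for (j in seq_len(m)) X[1, j + 1] <- -(gap_open + j * gap_extend)
  if (n > 0) for (i in seq_len(n)) Y[i + 1, 1] <- -(gap_open + i * gap_extend)
  go <- gap_open + gap_extend
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- if (qv[i] == rv[j]) match else mismatch
      M[i + 1, j + 1] <- max(M[i, j], X[i, j], Y[i, j]) + s
      X[i + 1, j + 1] <- max(M[i + 1, j] - go, Y[i + 1, j] - go,
                             X[i + 1, j] - gap_extend)
      Y[i + 1, j + 1] <- max(M[i, j + 1] - go, X[i, j + 1] - go,
                             Y[i, j + 1] - gap_extend)
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# exhaustive sliding-window seed off-target scan over every NGG site
oracle_offtargets <- function(guide, subjects, max_seed_mm = 1,
                              seed_len = 12) {
  proto <- strsplit(guide$protospacer, "")[[1]]
  seed_idx <- (20 - seed_len + 1):20
  res <- list()
  for (nm in names(subjects)) {
    s0 <- subjects[[nm]]
    L <- nchar(s0)
    if (L < 23) next
    for (strand in c("+", "-")) {
      s <- if (strand == "+") s0 else rc_chr(s0)
      for (a in 1:(L - 22)) {
        site <- substr(s, a, a + 22)
        if (substr(site, 22, 23) != "GG") next
        pv <- strsplit(substr(site, 1, 20), "")[[1]]
        mm <- pv != proto
        if (!any(mm)) next
        sd <- sum(mm[seed_idx])
        if (sd > max_seed_mm) next
        pos <- if (strand == "+") a - 1L else L - (a - 1L) - 23L
        res[[length(res) + 1L]] <- data.frame(
          sequence = nm, position = pos, strand = strand,
          seed_mismatches = sd, total_mismatches = sum(mm))
      }
    }
  }
  if (!length(res))
    return(data.frame(sequence = character(), position = integer(),
                      strand = character(), seed_mismatches = integer(),
                      total_mismatches = integer()))
  out <- do.call(rbind, res)
  out <- out[order(out$sequence, out$position, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}
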