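# Paired-end amplicon read simulation from allele mixtures.

#' Mixture specification for read simulation
#'
#' @param components named numeric vector of mixture fractions (names are
#'   allele labels); fractions must sum to 1 within 1e-9.
#' @param read_pairs number of read pairs to generate.
#' @param error_rate per-base substitution probability in `[0, 0.05]`.
#' @param read_length read length in nt (default 300, i.e. PE300).
#' @param seed integer seed; together with the parameters it fully determines
#'   the output.
#' @return object of class `mixture_spec`.
#' @export
mixture_spec <- function(components, read_pairs, error_rate = 0,
                         read_length = 300, seed = NULL) {
  if (is.null(names(components)) || anyDuplicated(names(components)))
    stop("invalid mixture: component labels must be unique and named",
         call. = FALSE)
  if (abs(sum(components) - 1) > 1e-9)
    stop("invalid mixture: fractions must sum to 1", call. = FALSE)
  if (any(components < 0))
    stop("invalid mixture: negative fraction", call. = FALSE)
  if (error_rate < 0 || error_rate > 0.05)
    stop("error_rate must lie in [0, 0.05]", call. = FALSE)
  structure(list(components = components, read_pairs = as.integer(read_pairs),
                 error_rate = error_rate, read_length = as.integer(read_length),
                 seed = seed),
            class = "mixture_spec")
}

#' Simulate paired-end amplicon reads from an allele mixture
#'
#' Each read pair is drawn from the mixture; R1 is the first `read_length` nt
#' of the allele sequence and R2 the reverse complement of the last
#' `read_length` nt (for alleles shorter than the read length both reads cover
#' the whole molecule). Independent substitution errors are applied at
#' `error_rate`; qualities are a constant symbol (`"I"`, Phred+33 Q40).
#'
#' @param amplicon an [amplicon()] (used only for label `"wt"` defaulting).
#' @param pair a [guide_pair()] (unused in read generation, kept so mixtures
#'   resolve against a reference set).
#' @param mix a [mixture_spec()].
#' @param alleles named list of [build_allele()] results; every mixture label
#'   must resolve here, except `"wt"` which defaults to the wild-type
#'   amplicon.
#' @return list of class `read_set` with data.frames `r1`, `r2`
#'   (columns `id`, `seq`, `qual`) and `truth` (columns `read_id`,
#'   `allele_label`).
#' @export
simulate_reads <- function(amplicon, pair, mix, alleles = list()) {
  stopifnot(inherits(mix, "mixture_spec"))
  labels <- names(mix$components)
  seqs <- vapply(labels, function(lab) {
    if (!is.null(alleles[[lab]])) {
      a <- alleles[[lab]]
      if (inherits(a, "allele")) a$sequence else as.character(a)
    } else if (lab == "wt") {
      amplicon$sequence
    } else {
      stop("invalid mixture: unknown allele label '", lab, "'", call. = FALSE)
    }
  }, character(1))

  L <- mix$read_length
  r1_tpl <- substr(seqs, 1L, pmin(nchar(seqs), L))
  r2_tpl <- rc(substr(seqs, pmax(1L, nchar(seqs) - L + 1L), nchar(seqs)))

  n <- mix$read_pairs
  ids <- sprintf("read_%06d", seq_len(n))
  if (n == 0L) {
    empty <- data.frame(id = character(), seq = character(),
                        qual = character())
    return(structure(list(r1 = empty, r2 = empty,
                          truth = data.frame(read_id = character(),
                                             allele_label = character())),
                     class = "read_set"))
  }

  with_seed_opt(mix$seed, {
    draw <- sample(seq_along(labels), n, replace = TRUE,
                   prob = mix$components)
    r1 <- add_errors(r1_tpl[draw], mix$error_rate)
    r2 <- add_errors(r2_tpl[draw], mix$error_rate)
  })

  structure(list(
    r1 = data.frame(id = ids, seq = r1, qual = strrep("I", nchar(r1))),
    r2 = data.frame(id = ids, seq = r2, qual = strrep("I", nchar(r2))),
    truth = data.frame(read_id = ids, allele_label = labels[draw])),
    class = "read_set")
}

# iid substitution errors at rate e; vectorized over reads, looping only over
# the (few) reads that actually receive an error
add_errors <- function(seqs, e) {
  if (e <= 0) return(seqs)
  k <- rbinom(length(seqs), nchar(seqs), e)
  hit <- which(k > 0L)
  for (i in hit) {
    pos <- sample.int(nchar(seqs[i]), k[i])
    for (p in pos) {
      old <- substr(seqs[i], p, p)
      substr(seqs[i], p, p) <- sample(setdiff(DNA_BASES, old), 1L)
    }
  }
  seqs
}

#' FASTQ input/output
#'
#' Plain 4-line FASTQ records with Phred+33 qualities. `read_fastq` validates
#' the record structure and reports the first offending line on malformed
#' input; `write_fastq` followed by `read_fastq` is the identity on
#' (id, seq, qual).
#'
#' @param reads data.frame with columns `id`, `seq`, `qual`.
#' @param path file path.
#' @return `read_fastq` returns a data.frame with columns `id`, `seq`,
#'   `qual`.
#' @export
write_fastq <- function(reads, path) {
  if (nrow(reads) == 0L) {
    writeLines(character(), path)
    return(invisible(path))
  }
  lines <- as.vector(rbind(paste0("@", reads$id), reads$seq, "+", reads$qual))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_fastq
#' @export
read_fastq <- function(path) {
  lines <- readLines(path)
  n <- length(lines)
  if (n %% 4L != 0L)
    stop(sprintf("FASTQ parse error: truncated record at line %d of %s",
                 (n %/% 4L) * 4L + 1L, path), call. = FALSE)
  if (n == 0L)
    return(data.frame(id = character(), seq = character(), qual = character()))
  idl <- seq(1L, n, by = 4L)
  bad <- idl[!startsWith(lines[idl], "@")]
  if (length(bad))
    stop(sprintf("FASTQ parse error: expected '@' header at line %d of %s",
                 bad[1], path), call. = FALSE)
  plus <- idl + 2L
  bad <- plus[!startsWith(lines[plus], "+")]
  if (length(bad))
    stop(sprintf("FASTQ parse error: expected '+' separator at line %d of %s",
                 bad[1], path), call. = FALSE)
  seqs <- lines[idl + 1L]; quals <- lines[idl + 3L]
  bad <- which(nchar(seqs) != nchar(quals))
  if (length(bad))
    stop(sprintf("FASTQ parse error: sequence/quality length mismatch at line %d of %s",
                 idl[bad[1]] + 3L, path), call. = FALSE)
  data.frame(id = sub("^@", "", sub("\\s.*$", "", lines[idl])),
             seq = seqs, qual = quals)
}

#' Write a simulation truth table
#' @param truth data.frame (`read_id`, `allele_label`).
#' @param path output TSV path.
#' @export
write_truth <- function(truth, path) {
  write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Build the allele set implied by simple component descriptions
#'
#' Convenience used by the run layer and tests: turns short component
#' descriptors into [build_allele()] results. Supported `kind`s:
#' `wt`, `segment_deletion`, `segment_inversion`, `insertion` (size, cut),
#' `deletion` (size, cut), `substitution` (a transition planted at the first
#' base 3' of the chosen cut — in the study spectrum a T->C).
#'
#' @param ref a `reference_set`.
#' @param components list of lists with fields `label`, `kind` and optional
#'   `cut` (1 or 2), `size`, `bases`.
#' @return named list of `allele` objects (wild type included as `"wt"`).
#' @export
alleles_from_components <- function(ref, components) {
  amp <- ref$amplicon; pair <- ref$pair
  out <- list()
  for (comp in components) {
    lab <- comp$label
    cut_name <- if (!is.null(comp$cut) && comp$cut == 2) "cut2" else "cut1"
    cut_pos <- if (cut_name == "cut1") pair$cut1 else pair$cut2
    edits <- switch(comp$kind,
      wt = list(),
      segment_deletion = list(edit_segment_deletion()),
      segment_inversion = list(edit_segment_inversion()),
      insertion = {
        bases <- comp$bases
        if (is.null(bases)) {
          # avoid extending a homopolymer so the insertion stays anchored
          nb <- c(sub0(amp$sequence, cut_pos - 1L, cut_pos),
                  sub0(amp$sequence, cut_pos, cut_pos + 1L))
          bases <- strrep(setdiff(DNA_BASES, nb)[1],
                          if (is.null(comp$size)) 1L else comp$size)
        }
        list(edit_insertion(cut_name, bases))
      },
      deletion = list(edit_deletion(cut_name, comp$size)),
      substitution = {
        p <- cut_pos
        old <- sub0(amp$sequence, p, p + 1L)
        list(edit_substitution(p, transition_base(old)))
      },
      stop("unknown component kind: ", comp$kind, call. = FALSE))
    out[[lab]] <- build_allele(amp, pair, edits, name = lab)
  }
  if (is.null(out[["wt"]]))
    out[["wt"]] <- build_allele(amp, pair, list(), name = "wt")
  out
}
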