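# Reference amplicon geometry: primers, guides, cut sites.

#' Annotated reference amplicon
#'
#' Container for the PCR amplicon spanning both guide targets. All coordinates
#' are 0-based, half-open. `rev_primer` is the annealing site of the reverse
#' primer *on the forward strand*; the primer oligo itself is the reverse
#' complement of that slice.
#'
#' @param name sample/locus label.
#' @param sequence uppercase A/C/G/T string.
#' @param fwd_primer,rev_primer integer length-2 vectors `c(start, end)`,
#'   0-based half-open; the forward primer must end before the reverse primer
#'   site starts.
#' @param cds_frame_offset reading-frame phase of position 0 within the target
#'   CDS (`0`, `1`, `2`), or `NA` when the amplicon is not annotated as coding.
#' @return an object of class `amplicon`.
#' @examples
#' amp <- amplicon("toy", strrep("ACGT", 25), c(0, 18), c(82, 100))
#' @export
amplicon <- function(name, sequence, fwd_primer, rev_primer,
                     cds_frame_offset = NA_integer_) {
  assert_dna(sequence, "amplicon sequence")
  len <- nchar(sequence)
  chk_iv <- function(iv, what) {
    if (length(iv) != 2L || any(is.na(iv)) || iv[1] < 0 || iv[2] > len ||
        iv[1] >= iv[2])
      stop(what, " must be a 0-based half-open interval within the amplicon",
           call. = FALSE)
    as.integer(iv)
  }
  fwd_primer <- chk_iv(fwd_primer, "fwd_primer")
  rev_primer <- chk_iv(rev_primer, "rev_primer")
  if (fwd_primer[2] > rev_primer[1])
    stop("fwd_primer must end before rev_primer starts", call. = FALSE)
  if (!is.na(cds_frame_offset) && !cds_frame_offset %in% 0:2)
    stop("cds_frame_offset must be 0, 1, 2 or NA", call. = FALSE)
  structure(
    list(name = as.character(name), sequence = sequence,
         fwd_primer = fwd_primer, rev_primer = rev_primer,
         cds_frame_offset = as.integer(cds_frame_offset)),
    class = "amplicon")
}

#' @export
print.amplicon <- function(x, ...) {
  cat(sprintf("<amplicon> %s: %d bp, primers [%d,%d)/[%d,%d), frame %s\n",
              x$name, nchar(x$sequence), x$fwd_primer[1], x$fwd_primer[2],
              x$rev_primer[1], x$rev_primer[2],
              ifelse(is.na(x$cds_frame_offset), "-", x$cds_frame_offset)))
  invisible(x)
}

#' Single guide RNA specification
#'
#' @param name guide label.
#' @param protospacer 20 nt A/C/G/T target sequence, written 5'->3' on the
#'   guide's strand.
#' @param strand `"+"` or `"-"` relative to the amplicon's forward strand.
#' @param pam 3 nt NGG motif on the guide's strand.
#' @return object of class `guide_spec`.
#' @export
guide_spec <- function(name, protospacer, strand = c("+", "-"), pam) {
  strand <- match.arg(strand)
  assert_dna(protospacer, "protospacer")
  assert_dna(pam, "pam")
  if (nchar(protospacer) != 20L) stop("protospacer must be 20 nt", call. = FALSE)
  if (nchar(pam) != 3L || substr(pam, 2, 3) != "GG")
    stop("pam must be a 3 nt NGG motif", call. = FALSE)
  structure(list(name = as.character(name), protospacer = protospacer,
                 strand = strand, pam = pam),
            class = "guide_spec")
}

#' @export
print.guide_spec <- function(x, ...) {
  cat(sprintf("<guide_spec> %s (%s) %s|%s\n", x$name, x$strand,
              x$protospacer, x$pam))
  invisible(x)
}

# forward-strand representation of protospacer+PAM and the offset of the cut
# within it: SpCas9 cuts bluntly 3 nt 5' of the PAM.
guide_site_pattern <- function(guide) {
  if (guide$strand == "+")
    list(pattern = paste0(guide$protospacer, guide$pam), cut_offset = 17L)
  else
    list(pattern = rc(paste0(guide$protospacer, guide$pam)), cut_offset = 6L)
}

# 0-based starts of exact forward-strand occurrences of a pattern
pattern_starts <- function(pattern, sequence) {
  m <- Biostrings::matchPattern(pattern, Biostrings::DNAString(sequence))
  start(m) - 1L
}

#' Blunt Cas9 cut coordinate of a guide on an amplicon
#'
#' The protospacer+PAM must occur exactly once on the stated strand. The cut
#' coordinate `c` means the double-strand break falls between positions `c-1`
#' and `c` (0-based), 3 nt 5' of the PAM.
#'
#' @param guide a [guide_spec()].
#' @param amplicon an [amplicon()].
#' @return integer cut coordinate.
#' @export
compute_cut_site <- function(guide, amplicon) {
  gp <- guide_site_pattern(guide)
  hits <- pattern_starts(gp$pattern, amplicon$sequence)
  if (length(hits) != 1L)
    stop(sprintf("ambiguous target: %s occurs %d times on strand %s",
                 guide$name, length(hits), guide$strand), call. = FALSE)
  hits + gp$cut_offset
}

#' Pair of guides and the inter-cut segment they delimit
#'
#' Guides are stored in cut-coordinate order, so `cut1 < cut2` always holds;
#' the inter-cut segment is `[cut1, cut2)`.
#'
#' @param guide1,guide2 [guide_spec()] objects.
#' @param amplicon an [amplicon()].
#' @return object of class `guide_pair` with fields `guide1`, `guide2`,
#'   `cut1`, `cut2`, `intercut` (interval) and `intercut_length`.
#' @export
guide_pair <- function(guide1, guide2, amplicon) {
  c1 <- compute_cut_site(guide1, amplicon)
  c2 <- compute_cut_site(guide2, amplicon)
  if (c1 == c2) stop("guides share a cut site", call. = FALSE)
  if (c1 > c2) { tmp <- guide1; guide1 <- guide2; guide2 <- tmp
                 tmp <- c1; c1 <- c2; c2 <- tmp }
  structure(
    list(guide1 = guide1, guide2 = guide2, cut1 = c1, cut2 = c2,
         intercut = c(c1, c2), intercut_length = c2 - c1),
    class = "guide_pair")
}

#' @export
print.guide_pair <- function(x, ...) {
  cat(sprintf("<guide_pair> %s/%s cuts %d|%d (inter-cut %d bp)\n",
              x$guide1$name, x$guide2$name, x$cut1, x$cut2,
              x$intercut_length))
  invisible(x)
}

# 0-based half-open interval of a guide's protospacer+PAM on the fwd strand,
# or NULL when absent/duplicated
guide_annotation <- function(guide, amplicon) {
  gp <- guide_site_pattern(guide)
  hits <- pattern_starts(gp$pattern, amplicon$sequence)
  if (length(hits) != 1L) return(NULL)
  c(hits, hits + nchar(gp$pattern))
}

#' Validate a guide pair against design rules
#'
#' Checks that each protospacer+PAM occurs exactly once on its stated strand
#' and that the two guide annotations are no further apart than `max_spacing`
#' (the gap between the protospacer+PAM intervals, the quantity a designer
#' reads off the locus annotation; the inter-cut length is reported
#' independently).
#'
#' @param pair a [guide_pair()], or `NULL` to validate from `guide1`/`guide2`.
#' @param amplicon an [amplicon()].
#' @param max_spacing maximum allowed annotation gap in nt (default 300).
#' @param guide1,guide2 used when `pair` construction itself may fail.
#' @return list with `pass` (logical), `reasons` (character), `spacing`,
#'   `intercut_length`, `orientations`.
#' @export
validate_guide_pair <- function(pair = NULL, amplicon, max_spacing = 300,
                                guide1 = NULL, guide2 = NULL) {
  if (is.null(pair)) {
    guides <- list(guide1, guide2)
  } else {
    guides <- list(pair$guide1, pair$guide2)
  }
  reasons <- character()
  anns <- vector("list", 2L)
  for (i in 1:2) {
    g <- guides[[i]]
    gp <- guide_site_pattern(g)
    hits <- pattern_starts(gp$pattern, amplicon$sequence)
    if (length(hits) == 0L)
      reasons <- c(reasons, sprintf("target not found: %s", g$name))
    else if (length(hits) > 1L)
      reasons <- c(reasons, sprintf("ambiguous target: %s", g$name))
    else anns[[i]] <- c(hits, hits + 23L)
  }
  spacing <- NA_integer_
  intercut <- NA_integer_
  if (!any(vapply(anns, is.null, logical(1)))) {
    iv <- anns[order(vapply(anns, `[`, integer(1), 1L))]
    spacing <- iv[[2]][1] - iv[[1]][2]
    cuts <- sort(vapply(guides, compute_cut_site, integer(1),
                        amplicon = amplicon))
    intercut <- cuts[2] - cuts[1]
    if (spacing > max_spacing)
      reasons <- c(reasons, sprintf("spacing exceeds limit: %d > %d bp",
                                    spacing, max_spacing))
  }
  list(pass = length(reasons) == 0L, reasons = reasons,
       spacing = spacing, intercut_length = intercut,
       orientations = vapply(guides, `[[`, character(1), "strand"))
}

#' Scan sequences for seed-region off-target sites
#'
#' Enumerates every NGG-adjacent 20 nt site on both strands of the subject
#' sequences and reports those whose mismatch count to the guide within the
#' seed region (the `seed_length` PAM-proximal protospacer nucleotides,
#' conventionally 12) does not exceed `max_seed_mismatch`. Exact full-length
#' matches (the on-target site) are excluded.
#'
#' @param guide a [guide_spec()].
#' @param subjects named character vector of A/C/G/T sequences.
#' @param max_seed_mismatch maximum seed mismatches to report (default 1).
#' @param seed_length seed-region size in nt (default 12).
#' @return data.frame with columns `sequence`, `position` (0-based start of
#'   the protospacer+PAM site on the forward strand), `strand`,
#'   `seed_mismatches`, `total_mismatches`, ordered by (sequence, position,
#'   strand).
#' @export
scan_seed_offtargets <- function(guide, subjects, max_seed_mismatch = 1,
                                 seed_length = 12) {
  if (length(subjects) == 0L)
    return(data.frame(sequence = character(), position = integer(),
                      strand = character(), seed_mismatches = integer(),
                      total_mismatches = integer()))
  if (is.null(names(subjects)))
    names(subjects) <- paste0("subject", seq_along(subjects))
  proto <- guide$protospacer
  seed_idx <- (20 - seed_length + 1):20  # PAM-proximal end of the protospacer
  proto_v <- strsplit(proto, "")[[1]]

  scan_one <- function(seqname, seqchr) {
    out <- list()
    L <- nchar(seqchr)
    for (strand in c("+", "-")) {
      s <- if (strand == "+") seqchr else rc(seqchr)
      # NGG PAMs with a full 20 nt protospacer upstream
      gg <- gregexpr("(?=GG)", s, perl = TRUE)[[1]]
      gg <- gg[gg > 0]
      pam_start <- gg - 2L          # 1-based position of N
      pam_start <- pam_start[pam_start >= 21L & pam_start + 2L <= nchar(s)]
      if (length(pam_start) == 0L) next
      proto_start <- pam_start - 20L
      cand <- substring(s, proto_start, pam_start - 1L)
      for (i in seq_along(cand)) {
        cv <- strsplit(cand[i], "")[[1]]
        mm_total <- sum(cv != proto_v)
        if (mm_total == 0L) next   # on-target
        mm_seed <- sum(cv[seed_idx] != proto_v[seed_idx])
        if (mm_seed > max_seed_mismatch) next
        # 0-based forward-strand start of the 23-mer site
        a <- proto_start[i] - 1L   # 0-based on strand s
        pos <- if (strand == "+") a else L - (a + 23L)
        out[[length(out) + 1L]] <- data.frame(
          sequence = seqname, position = pos, strand = strand,
          seed_mismatches = mm_seed, total_mismatches = mm_total)
      }
    }
    if (length(out)) do.call(rbind, out) else NULL
  }

  res <- do.call(rbind, Map(scan_one, names(subjects), unname(subjects)))
  if (is.null(res))
    return(data.frame(sequence = character(), position = integer(),
                      strand = character(), seed_mismatches = integer(),
                      total_mismatches = integer()))
  res <- res[order(res$sequence, res$position, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  res
}
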