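# Caller parameters and the global affine-gap aligner.

#' Read-caller parameters
#'
#' @param min_homology minimum identity (matches / alignment columns) for a
#'   read to be considered aligned to its best template. The default 0.60
#'   mirrors the usual amplicon-caller setting; 0.30 is the permissive legacy
#'   alternative that lets structurally rearranged reads through.
#' @param quantification_window number of nt on each side of each cut whose
#'   indels/substitutions count as editing at that cut (default 1).
#' @param match,mismatch,gap_open,gap_extend integer alignment scores; a gap
#'   of length L costs `gap_open + L * gap_extend`. The defaults are
#'   edit-distance-like with strongly discouraged gaps, so identity measures
#'   positional homology: gaps appear only where a length difference forces
#'   them or where a true indel rescues long exact runs, never to harvest
#'   shuffled matches from unrelated sequence.
#' @param min_overlap minimum read-pair overlap for merging (default 20 nt).
#' @param max_overlap_mismatch maximum mismatch fraction tolerated in the
#'   overlap (default 0.1).
#' @param split_flank_min_identity minimum flank / middle identity used by the
#'   split-mode classifier (default 0.9).
#' @param fast_path_identity ungapped screening threshold: an equal-length
#'   template whose Hamming identity reaches this value wins without gapped
#'   alignment. Set above 1 to force full alignment everywhere.
#' @return list of class `caller_params`.
#' @export
caller_params <- function(min_homology = 0.60, quantification_window = 1,
                          match = 1, mismatch = -1, gap_open = 40,
                          gap_extend = 5, min_overlap = 20,
                          max_overlap_mismatch = 0.1,
                          split_flank_min_identity = 0.9,
                          fast_path_identity = 0.95) {
  stopifnot(min_homology > 0, min_homology <= 1, quantification_window >= 0)
  structure(list(min_homology = min_homology,
                 quantification_window = as.integer(quantification_window),
                 match = as.integer(match), mismatch = as.integer(mismatch),
                 gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend),
                 min_overlap = as.integer(min_overlap),
                 max_overlap_mismatch = max_overlap_mismatch,
                 split_flank_min_identity = split_flank_min_identity,
                 fast_path_identity = fast_path_identity),
            class = "caller_params")
}

#' Optimal global alignment under affine-gap scoring
#'
#' Needleman–Wunsch/Gotoh alignment of `query` against `template`. Identity is
#' defined as matches divided by alignment columns, gap columns included.
#'
#' @param query,template A/C/G/T strings.
#' @param params a [caller_params()] (scoring fields are used).
#' @return list with `score`, `query_aln`, `template_aln`, `matches`,
#'   `columns`, `identity`.
#' @examples
#' align_global("ACGTACGT", "ACGTTACGT", caller_params())$identity
#' @export
align_global <- function(query, template, params = caller_params()) {
  if (nchar(query) == 0L || nchar(template) == 0L)
    stop("empty sequence", call. = FALSE)
  a <- gotoh_batch_cpp(query, template, params$match, params$mismatch,
                       params$gap_open, params$gap_extend)
  p <- aln_profile_cpp(a$query_aln, a$template_aln, integer(), 0L)
  list(score = a$score[1], query_aln = a$query_aln[1],
       template_aln = a$template_aln[1], matches = p$matches[1],
       columns = p$columns[1], identity = p$matches[1] / p$columns[1])
}

# pairwise identity of two sequences: ungapped when lengths agree and the
# ungapped comparison is already conclusive, gapped otherwise
seq_identity <- function(a, b, params) {
  if (nchar(a) == nchar(b)) {
    if (nchar(a) == 0L) return(1)
    h <- hamming_profile_cpp(a, b, integer(), 0L)
    ungapped <- 1 - h$mism[1] / nchar(a)
    if (ungapped >= params$split_flank_min_identity) return(ungapped)
  }
  if (nchar(a) == 0L || nchar(b) == 0L) return(0)
  max(align_global(a, b, params)$identity,
      if (nchar(a) == nchar(b)) 1 - hamming_profile_cpp(a, b, integer(), 0L)$mism[1] / nchar(a) else 0)
}
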