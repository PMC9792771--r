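# Synthetic reference amplicons with a valid dual-guide geometry.

#' Generate a reference amplicon and guide pair
#'
#' Builds a random amplicon carrying a forward and reverse primer site, two
#' same-orientation protospacer+PAM sites whose blunt cut sites are exactly
#' `intercut_length` apart, and a clean reading frame. The background is drawn
#' codon-wise from non-stop codons (frame offset 0) so the wild-type amplicon
#' translates like the interior of a real CDS; the two PAM `GG` dinucleotides
#' are then planted (this cannot create a stop codon) and the guide
#' protospacers are read off the final sequence.
#'
#' Flank lengths left and right of the cut sites default to an even split of
#' `total_length - intercut_length` and can be overridden with `left_flank`.
#'
#' @param total_length amplicon length in nt (study geometry: 380).
#' @param intercut_length distance between the two cut sites in nt (study
#'   geometry: 252).
#' @param primer_length length of each primer annealing site (default 20).
#' @param seed integer seed; identical seeds give byte-identical output.
#' @param left_flank cut1 coordinate; default `floor((total-intercut)/2)`.
#' @return list of class `reference_set` with elements `amplicon` (an
#'   [amplicon()]) and `pair` (a [guide_pair()]).
#' @examples
#' ref <- make_reference(380, 252, seed = 1)
#' ref$pair$intercut_length
#' @export
make_reference <- function(total_length = 380, intercut_length = 252,
                           primer_length = 20, seed = NULL,
                           left_flank = NULL) {
  total_length <- as.integer(total_length)
  intercut_length <- as.integer(intercut_length)
  primer_length <- as.integer(primer_length)
  if (is.null(left_flank))
    left_flank <- (total_length - intercut_length) %/% 2L
  cut1 <- as.integer(left_flank)
  cut2 <- cut1 + intercut_length
  s1 <- cut1 - 17L                       # protospacer1 start
  # feasibility: primers, protospacer+PAM sites and segment must fit without
  # functional-element overlap
  if (intercut_length < 23L || s1 < primer_length ||
      cut2 + 6L > total_length - primer_length)
    stop("geometry infeasible", call. = FALSE)

  with_seed_opt(seed, {
    for (attempt in 1:25) {
      seq <- random_orf_sequence(total_length)
      # plant the two NGG PAMs: GG at positions cut+4, cut+5 (0-based)
      for (cc in c(cut1, cut2)) {
        substr(seq, cc + 5L, cc + 6L) <- "GG"
      }
      amp <- amplicon("synthetic_amplicon", seq,
                      fwd_primer = c(0L, primer_length),
                      rev_primer = c(total_length - primer_length, total_length),
                      cds_frame_offset = 0L)
      g1 <- guide_spec("sgRNA1", sub0(seq, s1, s1 + 20L), "+",
                       sub0(seq, s1 + 20L, s1 + 23L))
      g2 <- guide_spec("sgRNA2", sub0(seq, cut2 - 17L, cut2 + 3L), "+",
                       sub0(seq, cut2 + 3L, cut2 + 6L))
      ok <- validate_guide_pair(guide1 = g1, guide2 = g2, amplicon = amp)
      # primer sites must also be unique for unambiguous in-silico PCR
      fwd <- sub0(seq, 0L, primer_length)
      rev <- sub0(seq, total_length - primer_length, total_length)
      uniq <- count_occurrences(fwd, seq) == 1L &&
        count_occurrences(rc(fwd), seq) == 0L &&
        count_occurrences(rev, seq) == 1L &&
        count_occurrences(rc(rev), seq) == 0L
      if (ok$pass && uniq) {
        pair <- guide_pair(g1, g2, amp)
        stopifnot(pair$cut1 == cut1, pair$cut2 == cut2)
        return(structure(list(amplicon = amp, pair = pair),
                         class = "reference_set"))
      }
    }
    stop("geometry infeasible: could not realize a unique-site amplicon",
         call. = FALSE)
  })
}

# random in-frame sequence with no stop codon in frame 0
random_orf_sequence <- function(len) {
  codons <- apply(expand.grid(DNA_BASES, DNA_BASES, DNA_BASES), 1, paste,
                  collapse = "")
  codons <- setdiff(codons, c("TAA", "TAG", "TGA"))
  n_codon <- ceiling(len / 3)
  s <- paste(sample(codons, n_codon, replace = TRUE), collapse = "")
  substr(s, 1, len)
}

#' @export
print.reference_set <- function(x, ...) {
  print(x$amplicon); print(x$pair)
  invisible(x)
}

#' Write / read a reference set on disk
#'
#' The amplicon goes to FASTA; primers, guides and cut sites go to a YAML
#' annotation file (coordinates 0-based, half-open).
#'
#' @param ref a `reference_set` (from [make_reference()]).
#' @param fasta,annotation output/input paths.
#' @return `write_reference` returns the paths invisibly; `read_reference`
#'   returns a `reference_set`.
#' @export
write_reference <- function(ref, fasta, annotation) {
  seqs <- Biostrings::DNAStringSet(ref$amplicon$sequence)
  names(seqs) <- ref$amplicon$name
  Biostrings::writeXStringSet(seqs, fasta)
  g <- function(gd) list(name = gd$name, protospacer = gd$protospacer,
                         strand = gd$strand, pam = gd$pam)
  ann <- list(
    coordinates = "0-based, half-open",
    amplicon = list(name = ref$amplicon$name,
                    fwd_primer = as.integer(ref$amplicon$fwd_primer),
                    rev_primer = as.integer(ref$amplicon$rev_primer),
                    cds_frame_offset = ref$amplicon$cds_frame_offset),
    guides = list(g(ref$pair$guide1), g(ref$pair$guide2)))
  yaml::write_yaml(ann, annotation)
  invisible(c(fasta = fasta, annotation = annotation))
}

#' @rdname write_reference
#' @export
read_reference <- function(fasta, annotation) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  ann <- yaml::read_yaml(annotation)
  fo <- ann$amplicon$cds_frame_offset
  amp <- amplicon(ann$amplicon$name, as.character(seqs[[1]]),
                  unlist(ann$amplicon$fwd_primer),
                  unlist(ann$amplicon$rev_primer),
                  if (is.null(fo)) NA_integer_ else fo)
  gs <- lapply(ann$guides, function(g)
    guide_spec(g$name, g$protospacer, g$strand, g$pam))
  structure(list(amplicon = amp, pair = guide_pair(gs[[1]], gs[[2]], amp)),
            class = "reference_set")
}

#' Primer set for the deletion and inversion assays
#'
#' Derives the outer (del_Fw/del_Rev) primers from the amplicon's primer
#' annotations and places two internal (inv_Fw/inv_Rev) primers inside the
#' inter-cut segment, as used to confirm segment inversions by PCR.
#'
#' @param ref a `reference_set`.
#' @param inner_length internal primer length (default 20).
#' @return named list of four [primer_spec()] objects.
#' @export
design_assay_primers <- function(ref, inner_length = 20) {
  amp <- ref$amplicon; pair <- ref$pair
  seq <- amp$sequence
  seg_len <- pair$intercut_length
  if (seg_len < 2 * inner_length + 2)
    stop("inter-cut segment too short for internal primers", call. = FALSE)
  # forward internal primer in the first third, reverse in the last third
  a <- pair$cut1 + seg_len %/% 5L
  b <- pair$cut2 - seg_len %/% 5L - inner_length
  list(
    del_Fw = primer_spec("del_Fw", sub0(seq, amp$fwd_primer[1], amp$fwd_primer[2])),
    del_Rev = primer_spec("del_Rev", rc(sub0(seq, amp$rev_primer[1], amp$rev_primer[2]))),
    inv_Fw = primer_spec("inv_Fw", sub0(seq, a, a + inner_length)),
    inv_Rev = primer_spec("inv_Rev", rc(sub0(seq, b, b + inner_length))))
}
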