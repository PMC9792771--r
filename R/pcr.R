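# In-silico PCR: product prediction, gel profiles, the four-combination
# inversion assay.

#' Primer specification
#' @param name primer label.
#' @param sequence oligo sequence 5'->3' (A/C/G/T, typically 18-30 nt).
#' @return object of class `primer_spec`.
#' @export
primer_spec <- function(name, sequence) {
  assert_dna(sequence, "primer sequence")
  structure(list(name = as.character(name), sequence = sequence),
            class = "primer_spec")
}

primer_seq <- function(p) if (inherits(p, "primer_spec")) p$sequence else p

#' Predict PCR product lengths on an allele
#'
#' Annealing is exact full-length matching on both strands. A product
#' requires a plus-strand annealing site (3' end pointing right) upstream of
#' a minus-strand site (3' end pointing left); its length is the
#' outer-coordinate span. All convergent placements of the supplied primers
#' (including a primer pairing with itself) within `max_product` are
#' reported in ascending order.
#'
#' @param allele an `allele`, `amplicon`, or bare sequence string.
#' @param primers list of [primer_spec()] (usually two).
#' @param max_product maximum product length reported (default 5000).
#' @return integer vector of product lengths (empty when no product forms).
#' @examples
#' # a 40 bp template amplified end-to-end
#' tpl <- strrep("ACGTTGCA", 5)
#' predict_products(tpl, list(primer_spec("f", substr(tpl, 1, 18)),
#'                            primer_spec("r", substr(tpl, 23, 40))))
#' @export
predict_products <- function(allele, primers, max_product = 5000) {
  seq <- if (inherits(allele, "allele") || inherits(allele, "amplicon"))
    allele$sequence else allele
  subj <- Biostrings::DNAString(seq)
  plus <- integer(); minus <- integer()
  for (p in primers) {
    s <- primer_seq(p)
    fw <- Biostrings::matchPattern(s, subj)
    plus <- c(plus, start(fw) - 1L)                 # 0-based starts
    rv <- Biostrings::matchPattern(rc(s), subj)
    minus <- c(minus, end(rv))                      # 0-based ends (half-open)
  }
  if (!length(plus) || !length(minus)) return(integer())
  spans <- outer(minus, plus, `-`)
  lens <- sort(spans[spans > 0 & spans <= max_product])
  as.integer(lens)
}

#' Classify a gel profile from del-primer product lengths
#'
#' Band calls use a +/- `tolerance` nt window to emulate gel resolution:
#' only wild-type-sized bands give profile I, only deletion-sized bands
#' profile II, both sizes profile III, and any other band profile IV.
#'
#' @param lengths integer product lengths from the del primer pair.
#' @param expected_wt,expected_del expected band sizes (study geometry: 380
#'   and 128).
#' @param tolerance band-size tolerance in nt (default 5).
#' @return one of `"I"`, `"II"`, `"III"`, `"IV"`, `"no_amplification"`.
#' @export
gel_profile <- function(lengths, expected_wt = 380, expected_del = 128,
                        tolerance = 5) {
  if (!length(lengths)) return("no_amplification")
  is_wt <- abs(lengths - expected_wt) <= tolerance
  is_del <- abs(lengths - expected_del) <= tolerance
  if (any(!is_wt & !is_del)) return("IV")
  if (any(is_wt) && any(is_del)) return("III")
  if (any(is_wt)) return("I")
  "II"
}

#' Four-combination inversion PCR assay
#'
#' Couples each outer primer (del_Fw, del_Rev) with each internal primer
#' (inv_Fw, inv_Rev placed inside the invertible inter-cut segment) and
#' predicts products per allele. On the wild type an internal primer yields a
#' product only with the outer primer it points toward; after inversion the
#' internal primer's orientation flips, so the productive combinations swap —
#' the presence/absence patterns of the wild-type and inversion alleles are
#' complementary.
#'
#' @param alleles named list of alleles (or sequences); typically wild type
#'   plus candidates.
#' @param del_fw,del_rev,inv_fw,inv_rev [primer_spec()] objects.
#' @param ref the `reference_set` (used to check that the internal primers
#'   anneal within the inter-cut segment of the wild type).
#' @param max_product see [predict_products()].
#' @return object of class `inversion_assay`: list with `lengths` (list
#'   matrix combination x allele) and `presence` (logical matrix).
#' @export
inversion_assay <- function(alleles, del_fw, del_rev, inv_fw, inv_rev, ref,
                            max_product = 5000) {
  wtseq <- ref$amplicon$sequence
  seg <- c(ref$pair$cut1, ref$pair$cut2)
  for (p in list(inv_fw, inv_rev)) {
    s <- primer_seq(p)
    hit_f <- pattern_starts(s, wtseq)
    hit_r <- pattern_starts(rc(s), wtseq)
    iv <- c(hit_f, hit_r)
    if (length(iv) != 1L || iv < seg[1] || iv + nchar(s) > seg[2])
      stop("not an internal primer: ",
           if (inherits(p, "primer_spec")) p$name else s, call. = FALSE)
  }
  combos <- list(`del_Fw+inv_Fw` = list(del_fw, inv_fw),
                 `del_Fw+inv_Rev` = list(del_fw, inv_rev),
                 `del_Rev+inv_Fw` = list(del_rev, inv_fw),
                 `del_Rev+inv_Rev` = list(del_rev, inv_rev))
  if (is.null(names(alleles)))
    names(alleles) <- paste0("allele", seq_along(alleles))
  lens <- matrix(vector("list", length(combos) * length(alleles)),
                 nrow = length(combos),
                 dimnames = list(names(combos), names(alleles)))
  for (ci in seq_along(combos))
    for (ai in seq_along(alleles))
      lens[[ci, ai]] <- predict_products(alleles[[ai]], combos[[ci]],
                                         max_product)
  presence <- matrix(vapply(lens, function(z) length(z) > 0, logical(1)),
                     nrow = length(combos),
                     dimnames = dimnames(lens))
  structure(list(lengths = lens, presence = presence),
            class = "inversion_assay")
}

#' @export
print.inversion_assay <- function(x, ...) {
  cat("<inversion_assay> products by combination x allele:\n")
  m <- matrix(vapply(x$lengths, function(z)
    if (length(z)) paste(z, collapse = ",") else "-", character(1)),
    nrow = nrow(x$presence), dimnames = dimnames(x$presence))
  print(m, quote = FALSE)
  invisible(x)
}

#' Write an inversion assay as a TSV matrix
#' @param assay an `inversion_assay`.
#' @param path output path.
#' @export
write_inversion_assay <- function(assay, path) {
  m <- matrix(vapply(assay$lengths, function(z)
    if (length(z)) paste(z, collapse = ",") else "", character(1)),
    nrow = nrow(assay$presence), dimnames = dimnames(assay$presence))
  df <- data.frame(combination = rownames(m), m, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
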