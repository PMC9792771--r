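# Sample-level biology: editing status, protein consequence, transformation
# efficiency.

#' Summarise an allele table into a sample report
#'
#' Editing status follows the mutated-read fraction (1 - wild-type fraction
#' over classified reads): at least `full` (default 0.995, i.e. no wild-type
#' allele detectable above sequencing error) is a full knockout; between
#' `partial` (default 0.10) and `full` is partial editing, the signature of a
#' heterozygous or chimeric regenerant; below `partial` the sample is called
#' not edited. Dominant alleles are the distinct variants covering at least
#' `dominant` (default 0.2) of classified reads.
#'
#' @param table an `allele_table` from [call_sample()].
#' @param sample_id sample label.
#' @param thresholds list with elements `full`, `partial`, `dominant`.
#' @return object of class `sample_report`.
#' @export
summarize_sample <- function(table, sample_id = "sample",
                             thresholds = list(full = 0.995, partial = 0.10,
                                               dominant = 0.2)) {
  stopifnot(inherits(table, "allele_table"))
  if (table$classified == 0L)
    stop("no classified reads", call. = FALSE)
  mutated <- 1 - table$fractions[["wt"]]
  status <- if (mutated >= thresholds$full) "edited_full"
    else if (mutated >= thresholds$partial) "edited_partial"
    else "not_edited"
  dom <- table$variants[table$variants$fraction >= thresholds$dominant, ,
                        drop = FALSE]

  guide_frac <- function(cut) {
    cl <- table$calls[table$calls$category != "unclassified", , drop = FALSE]
    structural <- cl$category %in% c("large_deletion", "inversion", "complex")
    ind <- if (cut == 1) cl$cut1_indel else cl$cut2_indel
    sb <- if (cut == 1) cl$cut1_subs else cl$cut2_subs
    site <- !is.na(ind) & (ind != 0L | (cl$category == "substitution_only" &
                                          sb > 0L))
    sum(structural | site) / table$classified
  }
  g1 <- guide_frac(1); g2 <- guide_frac(2)

  structure(list(
    sample_id = sample_id,
    mutated_fraction = mutated,
    status = status,
    dominant_alleles = dom,
    guide_edited = c(guide1 = g1 >= thresholds$partial,
                     guide2 = g2 >= thresholds$partial),
    guide_edited_fraction = c(guide1 = g1, guide2 = g2),
    total = table$total, classified = table$classified,
    thresholds = thresholds),
    class = "sample_report")
}

#' @export
print.sample_report <- function(x, ...) {
  cat(sprintf("<sample_report> %s: %s (%.1f%% mutated reads, %d classified)\n",
              x$sample_id, x$status, 100 * x$mutated_fraction, x$classified))
  if (nrow(x$dominant_alleles))
    cat("  dominant:", paste(sprintf("%s (%.0f%%)",
                                     x$dominant_alleles$variant,
                                     100 * x$dominant_alleles$fraction),
                             collapse = ", "), "\n")
  invisible(x)
}

#' Mechanical protein consequence of an allele
#'
#' Requires the amplicon's `cds_frame_offset`. The net indel size decides the
#' frameshift; the edited sequence is translated in the annotated frame and
#' any stop codon appearing earlier than the first wild-type in-frame stop
#' (or anywhere, when the wild-type amplicon frame is stop-free, as in the
#' interior of a CDS) is reported as a premature stop. A deletion whose net
#' size is a multiple of 3 — notably the inter-cut segment deletion — is
#' reported as an in-frame deletion of `size/3` codons.
#'
#' @param allele an `allele` from [build_allele()].
#' @param amplicon the wild-type [amplicon()].
#' @return list: `frameshift`, `premature_stop`, `in_frame_deletion_codons`,
#'   `net_indel`.
#' @export
protein_consequence <- function(allele, amplicon) {
  if (is.na(amplicon$cds_frame_offset))
    stop("amplicon carries no cds_frame_offset annotation", call. = FALSE)
  pair_len <- nchar(allele$sequence) - nchar(amplicon$sequence)
  net <- pair_len                       # net length change = net indel
  frameshift <- (net %% 3L) != 0L

  first_stop <- function(seq) {
    off <- amplicon$cds_frame_offset
    s <- substr(seq, off + 1L, nchar(seq))
    s <- substr(s, 1L, (nchar(s) %/% 3L) * 3L)
    if (nchar(s) < 3L) return(Inf)
    aa <- as.character(Biostrings::translate(Biostrings::DNAString(s)))
    p <- regexpr("*", aa, fixed = TRUE)
    if (p < 0) Inf else as.integer(p)
  }
  wt_stop <- first_stop(amplicon$sequence)
  ed_stop <- first_stop(allele$sequence)
  premature <- is.finite(ed_stop) && ed_stop < wt_stop

  in_frame_codons <- if (!frameshift && net < 0L) abs(net) %/% 3L else 0L
  list(frameshift = frameshift, premature_stop = premature,
       in_frame_deletion_codons = as.integer(in_frame_codons),
       net_indel = as.integer(net))
}

#' Transformation record and efficiency
#'
#' Transformation efficiency (TE) is the number of regenerants PCR-positive
#' for the selection (nptII) and nuclease (Cas9) genes divided by the number
#' of infected explants, as a percent, rounded half-up to the requested
#' number of decimal places.
#'
#' @param variety variety name.
#' @param infected number of infected explants (> 0).
#' @param resistant number of antibiotic-resistant regenerants.
#' @param tested number of regenerants tested by PCR.
#' @param positive number positive for both transgenes.
#' @return `transformation_record` returns a record object;
#'   `transformation_efficiency` a numeric percentage.
#' @export
transformation_record <- function(variety, infected, resistant = NA_integer_,
                                  tested = NA_integer_, positive) {
  infected <- as.integer(infected); positive <- as.integer(positive)
  if (is.na(infected) || infected < 0 || is.na(positive) || positive < 0)
    stop("counts must be non-negative", call. = FALSE)
  if (!is.na(tested) && positive > tested)
    stop("positives cannot exceed regenerants tested", call. = FALSE)
  structure(list(variety = as.character(variety), infected = infected,
                 resistant = as.integer(resistant),
                 tested = as.integer(tested), positive = positive),
            class = "transformation_record")
}

round_half_up <- function(x, digits) {
  f <- 10^digits
  floor(x * f + 0.5) / f
}

#' @rdname transformation_record
#' @param record a `transformation_record`.
#' @param digits decimal places of the reported percentage (default 1).
#' @export
transformation_efficiency <- function(record, digits = 1) {
  if (record$infected == 0L)
    stop("zero infected explants", call. = FALSE)
  round_half_up(100 * record$positive / record$infected, digits)
}

#' Recompute a transformation-efficiency table
#'
#' Takes a data.frame of transformation records (columns `variety`,
#' `infected`, `positive`, optional `resistant`, `tested`, and optionally
#' `reported_te` with `digits`), recomputes TE per row and, where a reported
#' value is provided, warns when the recomputed value disagrees with it.
#'
#' @param records data.frame, one row per variety.
#' @return the input with a `te` column appended.
#' @export
te_table <- function(records) {
  digits <- if ("digits" %in% names(records)) records$digits
    else rep(1L, nrow(records))
  te <- numeric(nrow(records))
  for (i in seq_len(nrow(records))) {
    rec <- transformation_record(records$variety[i], records$infected[i],
                                 positive = records$positive[i])
    te[i] <- transformation_efficiency(rec, digits[i])
    if ("reported_te" %in% names(records) && !is.na(records$reported_te[i]) &&
        te[i] != records$reported_te[i])
      warning(sprintf("TE rounding mismatch for %s: computed %s, reported %s",
                      records$variety[i], format(te[i]),
                      format(records$reported_te[i])), call. = FALSE)
  }
  records$te <- te
  records
}

#' Write a sample report
#' @param report a `sample_report`.
#' @param tsv_path,json_path output paths (either may be `NULL`).
#' @export
write_sample_report <- function(report, tsv_path = NULL, json_path = NULL) {
  row <- data.frame(sample_id = report$sample_id,
                    status = report$status,
                    mutated_fraction = report$mutated_fraction,
                    classified = report$classified,
                    total = report$total,
                    guide1_edited = report$guide_edited[["guide1"]],
                    guide2_edited = report$guide_edited[["guide2"]],
                    dominant_alleles = paste(report$dominant_alleles$variant,
                                             collapse = ","))
  if (!is.null(tsv_path))
    write.table(row, tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(
      list(sample_id = report$sample_id, status = report$status,
           mutated_fraction = report$mutated_fraction,
           classified = report$classified, total = report$total,
           guide_edited = as.list(report$guide_edited),
           dominant_alleles = report$dominant_alleles),
      json_path, auto_unbox = TRUE, digits = NA)
  invisible(report)
}
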