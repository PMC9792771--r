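# Orchestration layer: simulate -> call -> summarize -> pcr. Each run writes
# its outputs plus a machine-readable copy of the resolved configuration and
# a manifest, so a single seed reproduces a whole run byte-identically.

default_config <- function() {
  list(
    seed = 1L,
    geometry = list(total_length = 380L, intercut_length = 252L,
                    primer_length = 20L),
    mixture = list(
      read_pairs = 24000L, error_rate = 0.001, read_length = 300L,
      components = list(
        list(label = "wt", kind = "wt", fraction = 0.4),
        list(label = "del", kind = "segment_deletion", fraction = 0.2),
        list(label = "inv", kind = "segment_inversion", fraction = 0.2),
        list(label = "ins1_cut1", kind = "insertion", size = 1L, cut = 1L,
             fraction = 0.1),
        list(label = "del5_cut2", kind = "deletion", size = 5L, cut = 2L,
             fraction = 0.1))),
    caller = list(min_homology = 0.60, quantification_window = 1L,
                  mode = "template",
                  templates = c("wt", "large_deletion", "inversion")),
    thresholds = list(full = 0.995, partial = 0.10, dominant = 0.2))
}

load_config <- function(config) {
  base <- default_config()
  if (is.null(config)) return(base)
  if (is.character(config)) config <- yaml::read_yaml(config)
  merged <- modifyList(base, config)
  # unnamed lists must be replaced wholesale, not merged elementwise
  if (!is.null(config$mixture$components))
    merged$mixture$components <- config$mixture$components
  if (!is.null(config$caller$templates))
    merged$caller$templates <- config$caller$templates
  merged
}

write_manifest <- function(out_dir, step, paths, seed) {
  jsonlite::write_json(list(step = step, seed = seed, paths = as.list(paths)),
                       file.path(out_dir, paste0(step, "_manifest.json")),
                       auto_unbox = TRUE, digits = NA)
}

resolve_caller_params <- function(cfg) {
  keep <- intersect(names(cfg$caller), names(formals(caller_params)))
  do.call(caller_params, cfg$caller[keep])
}

#' Run the simulation stage
#'
#' Generates a reference set and paired-end reads from the configured allele
#' mixture, writing the reference FASTA + annotation, both FASTQ files, the
#' truth table, the resolved configuration and a manifest into `out_dir`.
#'
#' @param config `NULL` (defaults), a YAML path, or a nested list; fields
#'   missing from the configuration fall back to the defaults.
#' @param out_dir output directory (created if needed).
#' @return invisibly, a named vector of output paths.
#' @export
run_simulate <- function(config = NULL, out_dir = ".") {
  cfg <- load_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  g <- cfg$geometry
  ref <- make_reference(g$total_length, g$intercut_length, g$primer_length,
                        seed = cfg$seed)
  alleles <- alleles_from_components(ref, cfg$mixture$components)
  fracs <- vapply(cfg$mixture$components, `[[`, numeric(1), "fraction")
  names(fracs) <- vapply(cfg$mixture$components, `[[`, character(1), "label")
  mix <- mixture_spec(fracs, cfg$mixture$read_pairs, cfg$mixture$error_rate,
                      cfg$mixture$read_length, seed = cfg$seed + 1L)
  rs <- simulate_reads(ref$amplicon, ref$pair, mix, alleles)

  paths <- c(reference = file.path(out_dir, "reference.fasta"),
             annotation = file.path(out_dir, "reference.yaml"),
             r1 = file.path(out_dir, "reads_R1.fastq"),
             r2 = file.path(out_dir, "reads_R2.fastq"),
             truth = file.path(out_dir, "truth.tsv"),
             config = file.path(out_dir, "simulate_config.yaml"))
  write_reference(ref, paths[["reference"]], paths[["annotation"]])
  write_fastq(rs$r1, paths[["r1"]])
  write_fastq(rs$r2, paths[["r2"]])
  write_truth(rs$truth, paths[["truth"]])
  yaml::write_yaml(cfg, paths[["config"]])
  write_manifest(out_dir, "simulate", paths, cfg$seed)
  invisible(paths)
}

#' Run the read-calling stage
#'
#' Reads the reference and FASTQ pair produced by [run_simulate()] (or any
#' files in the same layout), classifies every read pair and writes per-read
#' calls (TSV) plus the allele table (JSON).
#'
#' @inheritParams run_simulate
#' @param in_dir directory holding `reference.fasta`, `reference.yaml`,
#'   `reads_R1.fastq`, `reads_R2.fastq`.
#' @return invisibly, the `allele_table`.
#' @export
run_call <- function(config = NULL, in_dir = ".", out_dir = in_dir) {
  cfg <- load_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ref <- read_reference(file.path(in_dir, "reference.fasta"),
                        file.path(in_dir, "reference.yaml"))
  r1 <- read_fastq(file.path(in_dir, "reads_R1.fastq"))
  r2 <- read_fastq(file.path(in_dir, "reads_R2.fastq"))
  params <- resolve_caller_params(cfg)
  tab <- call_sample(r1, r2 = r2, amplicon = ref$amplicon, pair = ref$pair,
                     params = params, mode = cfg$caller$mode,
                     templates = unlist(cfg$caller$templates))
  paths <- c(calls = file.path(out_dir, "read_calls.tsv"),
             table = file.path(out_dir, "allele_table.json"),
             config = file.path(out_dir, "call_config.yaml"))
  write_read_calls(tab, paths[["calls"]])
  write_allele_table(tab, paths[["table"]])
  yaml::write_yaml(cfg, paths[["config"]])
  write_manifest(out_dir, "call", paths, cfg$seed)
  mutated <- if (tab$classified > 0) 1 - tab$fractions[["wt"]] else NA
  message(sprintf("call: %d pairs, %d classified, mutated fraction %.4f",
                  tab$total, tab$classified, mutated))
  invisible(tab)
}

#' Run the summary stage
#'
#' Builds a sample report from a called allele table and, when a
#' transformation-record TSV is supplied, recomputes the
#' transformation-efficiency table.
#'
#' @inheritParams run_call
#' @param sample_id sample label for the report.
#' @param te_records optional TSV path with columns `variety`, `infected`,
#'   `positive` and optionally `reported_te`, `digits`.
#' @return invisibly, the `sample_report` (or `NULL` when only a TE table was
#'   requested).
#' @export
run_summarize <- function(config = NULL, in_dir = ".", out_dir = in_dir,
                          sample_id = "sample", te_records = NULL) {
  cfg <- load_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- NULL
  table_path <- file.path(in_dir, "read_calls.tsv")
  if (file.exists(table_path)) {
    calls <- read.delim(table_path, colClasses = c(
      read_id = "character", category = "character", template = "character",
      cut1_indel = "integer", cut2_indel = "integer",
      cut1_subs = "integer", cut2_subs = "integer", identity = "numeric"))
    tab <- allele_table(calls)
    report <- summarize_sample(tab, sample_id, cfg$thresholds)
    write_sample_report(report,
                        tsv_path = file.path(out_dir, "sample_report.tsv"),
                        json_path = file.path(out_dir, "sample_report.json"))
  }
  if (!is.null(te_records)) {
    rec <- read.delim(te_records)
    out <- te_table(rec)
    write.table(out, file.path(out_dir, "te_table.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  invisible(report)
}

#' Run the in-silico PCR stage
#'
#' Regenerates the standard allele panel (wild type, inter-cut deletion,
#' inter-cut inversion) from the stored reference, predicts del-primer
#' products and gel profiles per allele, and writes the four-combination
#' inversion assay matrix.
#'
#' @inheritParams run_call
#' @return invisibly, a list with `products`, `profiles` and the
#'   `inversion_assay`.
#' @export
run_pcr <- function(config = NULL, in_dir = ".", out_dir = in_dir) {
  cfg <- load_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ref <- read_reference(file.path(in_dir, "reference.fasta"),
                        file.path(in_dir, "reference.yaml"))
  primers <- design_assay_primers(ref)
  alleles <- list(
    wt = build_allele(ref$amplicon, ref$pair, list(), name = "wt"),
    del = build_allele(ref$amplicon, ref$pair, list(edit_segment_deletion()),
                       name = "del"),
    inv = build_allele(ref$amplicon, ref$pair, list(edit_segment_inversion()),
                       name = "inv"))
  del_pair <- list(primers$del_Fw, primers$del_Rev)
  products <- lapply(alleles, predict_products, primers = del_pair)
  wt_len <- nchar(ref$amplicon$sequence)
  del_len <- wt_len - ref$pair$intercut_length
  profiles <- vapply(products, gel_profile, character(1),
                     expected_wt = wt_len, expected_del = del_len)
  assay <- inversion_assay(alleles, primers$del_Fw, primers$del_Rev,
                           primers$inv_Fw, primers$inv_Rev, ref)
  prod_df <- data.frame(
    allele = names(products),
    products = vapply(products, function(z)
      if (length(z)) paste(z, collapse = ",") else "", character(1)),
    profile = profiles)
  write.table(prod_df, file.path(out_dir, "pcr_products.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_inversion_assay(assay, file.path(out_dir, "inversion_assay.tsv"))
  invisible(list(products = products, profiles = profiles,
                 inversion_assay = assay))
}
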