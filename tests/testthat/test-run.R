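# The run layer ties simulate -> call -> summarize -> pcr together on disk.

small_cfg <- function(seed = 2) {
  list(seed = seed,
       mixture = list(read_pairs = 300L, error_rate = 0.001,
                      components = list(
                        list(label = "wt", kind = "wt", fraction = 0.5),
                        list(label = "del", kind = "segment_deletion",
                             fraction = 0.25),
                        list(label = "inv", kind = "segment_inversion",
                             fraction = 0.25))))
}

test_that("simulate runs are reproducible byte for byte", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  p1 <- run_simulate(small_cfg(), d1)
  p2 <- run_simulate(small_cfg(), d2)
  for (f in c("reference.fasta", "reads_R1.fastq", "reads_R2.fastq",
              "truth.tsv"))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  expect_true(file.exists(file.path(d1, "simulate_manifest.json")))
})

test_that("zero-read simulations still produce a valid run directory", {
  d <- withr::local_tempdir()
  cfg <- small_cfg(); cfg$mixture$read_pairs <- 0L
  run_simulate(cfg, d)
  expect_identical(nrow(read_fastq(file.path(d, "reads_R1.fastq"))), 0L)
  expect_true(file.exists(file.path(d, "simulate_manifest.json")))
})

test_that("simulate -> call -> summarize recovers the sample biology", {
  d <- withr::local_tempdir()
  run_simulate(small_cfg(), d)
  tab <- suppressMessages(run_call(NULL, in_dir = d))
  expect_identical(tab$total, 300L)
  expect_gt(tab$fractions[["large_deletion"]], 0.1)
  expect_gt(tab$fractions[["inversion"]], 0.1)

  rep <- run_summarize(NULL, in_dir = d, sample_id = "plantlet_1")
  expect_identical(rep$status, "edited_partial")
  expect_true(file.exists(file.path(d, "sample_report.json")))

  # a wild-type-only run is called not edited with wt fraction 1
  d2 <- withr::local_tempdir()
  cfg <- small_cfg()
  cfg$mixture$error_rate <- 0
  cfg$mixture$components <- list(list(label = "wt", kind = "wt",
                                      fraction = 1.0))
  run_simulate(cfg, d2)
  tab2 <- suppressMessages(run_call(NULL, in_dir = d2))
  expect_identical(tab2$fractions[["wt"]], 1)
})

test_that("the TE table stage reproduces printed percentages with warnings", {
  d <- withr::local_tempdir()
  rec <- data.frame(
    variety = c("Doppio sanguigno", "Vaccaro", "Bud blood", "Tarocco TDV",
                "Tarocco Lempso", "Carrizo"),
    infected = c(510L, 260L, 400L, 300L, 160L, 210L),
    positive = c(66L, 5L, 9L, 8L, 2L, 149L),
    reported_te = c(12, 2, 2.5, 2.7, 1.3, 70),
    digits = c(0L, 0L, 1L, 1L, 1L, 0L))
  tsv <- file.path(d, "records.tsv")
  write.table(rec, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  w <- testthat::capture_warnings(
    run_summarize(NULL, in_dir = d, out_dir = d, te_records = tsv))
  # three printed values disagree with half-up rounding of their quotients
  expect_length(w, 3)
  expect_match(w, "rounding mismatch", all = TRUE)
  out <- read.delim(file.path(d, "te_table.tsv"))
  expect_identical(out$te[out$variety == "Tarocco TDV"], 2.7)
  expect_identical(out$te[out$variety == "Tarocco Lempso"], 1.3)
  expect_identical(out$te[out$variety == "Vaccaro"], 2)
})

test_that("the pcr stage labels the standard alleles I and II", {
  d <- withr::local_tempdir()
  run_simulate(small_cfg(), d)
  res <- run_pcr(NULL, in_dir = d)
  expect_identical(res$profiles[["wt"]], "I")
  expect_identical(res$profiles[["del"]], "II")
  expect_identical(res$profiles[["inv"]], "I")  # same length as wild type
  expect_identical(res$inversion_assay$presence[, "inv"],
                   !res$inversion_assay$presence[, "wt"])
  expect_true(file.exists(file.path(d, "inversion_assay.tsv")))
})

test_that("the command-line front-end ships with the package", {
  cli <- system.file("cli", "dualguide.R", package = "dualguide")
  expect_true(nzchar(cli))
  expect_match(readLines(cli, n = 1), "Rscript")
})
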