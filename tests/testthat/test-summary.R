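amp <- ref_380$amplicon
pair <- ref_380$pair

fake_calls <- function(n_wt, n_del = 0, n_ins = 0) {
  n <- n_wt + n_del + n_ins
  data.frame(
    read_id = sprintf("r%04d", seq_len(n)),
    category = c(rep("wt", n_wt), rep("large_deletion", n_del),
                 rep("indel", n_ins)),
    cut1_indel = c(rep(0L, n_wt + n_del), rep(1L, n_ins)),
    cut2_indel = rep(0L, n), cut1_subs = rep(0L, n), cut2_subs = rep(0L, n),
    identity = rep(1, n), template = rep("wt", n))
}

test_that("editing status follows the mutated-read fraction", {
  full <- summarize_sample(allele_table(fake_calls(0, n_del = 200)), "a")
  expect_identical(full$status, "edited_full")
  expect_identical(full$mutated_fraction, 1)

  half <- summarize_sample(allele_table(fake_calls(100, n_del = 100)), "b")
  expect_identical(half$status, "edited_partial")
  expect_identical(half$mutated_fraction, 0.5)

  none <- summarize_sample(allele_table(fake_calls(200)), "c")
  expect_identical(none$status, "not_edited")
  expect_identical(none$mutated_fraction, 0)

  # the chimeric band starts at the configured lower bound
  low <- summarize_sample(allele_table(fake_calls(95, n_del = 5)), "d")
  expect_identical(low$status, "not_edited")
  lo2 <- summarize_sample(allele_table(fake_calls(89, n_del = 11)), "e")
  expect_identical(lo2$status, "edited_partial")
})

test_that("summaries are scale-invariant and need classified reads", {
  calls <- fake_calls(60, n_del = 30, n_ins = 10)
  r1 <- summarize_sample(allele_table(calls), "x")
  calls3 <- calls[rep(seq_len(nrow(calls)), 3), ]
  calls3$read_id <- sprintf("r%04d", seq_len(nrow(calls3)))
  r3 <- summarize_sample(allele_table(calls3), "x")
  expect_identical(r1$mutated_fraction, r3$mutated_fraction)
  expect_identical(r1$status, r3$status)
  expect_identical(r1$dominant_alleles$variant, r3$dominant_alleles$variant)
  expect_identical(r1$guide_edited, r3$guide_edited)

  empty <- allele_table(fake_calls(0))
  expect_error(summarize_sample(empty), "no classified reads")
})

test_that("dominant alleles and per-guide flags reflect the variant mix", {
  rep <- summarize_sample(allele_table(fake_calls(10, n_del = 60, n_ins = 30)))
  expect_true("large_deletion" %in% rep$dominant_alleles$variant)
  expect_true("indel:cut1+1" %in% rep$dominant_alleles$variant)
  expect_false("wt" %in% rep$dominant_alleles$variant)  # 10% < 20%
  expect_true(rep$guide_edited[["guide1"]])
  expect_true(rep$guide_edited[["guide2"]])  # structural events span both
})

test_that("protein consequences follow frame arithmetic and translation", {
  ins1 <- build_allele(amp, pair, list(edit_insertion("cut1", "T")))
  pc <- protein_consequence(ins1, amp)
  expect_true(pc$frameshift)
  # independent oracle: translate the edited frame directly
  n3 <- (nchar(ins1$sequence) %/% 3L) * 3L
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(
    substr(ins1$sequence, 1, n3))))
  expect_identical(pc$premature_stop, grepl("*", aa, fixed = TRUE))

  del3 <- build_allele(amp, pair, list(edit_deletion("cut1", 3)))
  pc3 <- protein_consequence(del3, amp)
  expect_false(pc3$frameshift)
  expect_identical(pc3$in_frame_deletion_codons, 1L)

  seg <- build_allele(amp, pair, list(edit_segment_deletion()))
  pcs <- protein_consequence(seg, amp)
  expect_false(pcs$frameshift)
  expect_identical(pcs$in_frame_deletion_codons, 84L)

  amp_nf <- amplicon("nf", amp$sequence, amp$fwd_primer, amp$rev_primer)
  expect_error(protein_consequence(ins1, amp_nf), "cds_frame_offset")
})

test_that("transformation efficiency uses exact half-up rounding", {
  expect_identical(
    transformation_efficiency(transformation_record("TDV", 300,
                                                    positive = 8), 1), 2.7)
  expect_identical(
    transformation_efficiency(transformation_record("Lempso", 160,
                                                    positive = 2), 1), 1.3)
  expect_identical(
    transformation_efficiency(transformation_record("x", 260,
                                                    positive = 5), 0), 2)
  expect_identical(
    transformation_efficiency(transformation_record("none", 100,
                                                    positive = 0), 1), 0)
  # 2/160 = 1.25: banker's rounding would give 1.2, half-up must give 1.3
  expect_identical(round(1.25, 1), 1.2)

  expect_error(transformation_efficiency(
    transformation_record("zero", 0, positive = 0)), "zero infected")
  expect_error(transformation_record("bad", 10, tested = 5, positive = 7),
               "exceed")
})

test_that("te_table surfaces reported-value rounding mismatches as warnings", {
  rec <- data.frame(
    variety = c("A", "B"),
    infected = c(300L, 510L),
    positive = c(8L, 66L),
    reported_te = c(2.7, 12),
    digits = c(1L, 0L))
  expect_warning(out <- te_table(rec), "rounding mismatch for B")
  expect_identical(out$te[1], 2.7)
  expect_identical(out$te[2], 13)   # 66/510 = 12.94 -> 13, not the printed 12
})
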