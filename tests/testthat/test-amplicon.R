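test_that("amplicon constructor enforces its invariants", {
  expect_error(amplicon("x", "ACGU", c(0, 2), c(2, 4)), "A/C/G/T")
  expect_error(amplicon("x", strrep("ACGT", 10), c(0, 20), c(10, 30)),
               "end before")
  expect_error(amplicon("x", strrep("ACGT", 10), c(0, 10), c(30, 45)),
               "interval")
  expect_error(amplicon("x", strrep("ACGT", 10), c(0, 10), c(30, 40),
                        cds_frame_offset = 5), "cds_frame_offset")
  amp <- amplicon("x", strrep("ACGT", 10), c(0, 10), c(30, 40), 2L)
  expect_s3_class(amp, "amplicon")
})

test_that("blunt cut sites fall 3 nt 5' of the PAM on both strands", {
  # plus strand: protospacer [10,30), PAM [30,33) -> cut at 27
  withr::with_seed(11, {
    bg <- random_dna(60)
    proto <- random_dna(20)
    pam <- paste0("A", "GG")
    seq <- paste0(substr(bg, 1, 10), proto, pam, substr(bg, 34, 60))
  })
  amp <- amplicon("plus", seq, c(0, 8), c(50, 60))
  g <- guide_spec("g", proto, "+", pam)
  expect_identical(compute_cut_site(g, amp), 27L)

  # minus strand: PAM at forward [10,13), protospacer [13,33) -> cut at 16
  seq2 <- paste0(substr(bg, 1, 10), rc_chr(paste0(proto, pam)),
                 substr(bg, 34, 60))
  amp2 <- amplicon("minus", seq2, c(0, 8), c(50, 60))
  g2 <- guide_spec("g", proto, "-", pam)
  expect_identical(compute_cut_site(g2, amp2), 16L)
})

test_that("absent or duplicated targets are rejected as ambiguous", {
  withr::with_seed(12, {
    proto <- random_dna(20)
    site <- paste0(proto, "TGG")
    seq <- paste0(random_dna(30), site, random_dna(10), site, random_dna(30))
  })
  amp <- amplicon("dup", seq, c(0, 10), c(nchar(seq) - 10, nchar(seq)))
  g <- guide_spec("g", proto, "+", "TGG")
  expect_error(compute_cut_site(g, amp), "ambiguous target")
  g_absent <- guide_spec("g", chartr("ACGT", "TGCA", proto), "+", "TGG")
  expect_error(compute_cut_site(g_absent, amp), "ambiguous target")
})

test_that("the generated pair has the study geometry and passes validation", {
  pair <- ref_380$pair
  expect_lt(pair$cut1, pair$cut2)
  expect_identical(pair$intercut_length, 252L)
  rep <- validate_guide_pair(pair, ref_380$amplicon)
  expect_true(rep$pass)
  expect_identical(rep$intercut_length, 252L)
  expect_identical(rep$orientations, c("+", "+"))
  expect_true(rep$spacing <= 300)
})

test_that("guide-pair validation reports spacing and missing targets", {
  rep <- validate_guide_pair(ref_380$pair, ref_380$amplicon,
                             max_spacing = 100)
  expect_false(rep$pass)
  expect_match(rep$reasons, "spacing exceeds limit", all = FALSE)

  bad <- guide_spec("bad", strrep("A", 20), "+", "AGG")
  rep2 <- validate_guide_pair(amplicon = ref_380$amplicon,
                              guide1 = bad, guide2 = ref_380$pair$guide2)
  expect_false(rep2$pass)
  expect_match(rep2$reasons, "target not found", all = FALSE)
})

test_that("seed off-target scan matches a brute-force enumeration", {
  g <- ref_380$pair$guide1
  # the guide's own site is excluded
  own <- scan_seed_offtargets(g, c(amp = ref_380$amplicon$sequence))
  expect_identical(nrow(own[own$total_mismatches == 0, ]), 0L)

  # a planted single-seed-mismatch site is recovered
  withr::with_seed(13, {
    proto_mm <- g$protospacer
    substr(proto_mm, 15, 15) <- setdiff(c("A", "C", "G", "T"),
                                        substr(proto_mm, 15, 15))[1]
    subj <- paste0(random_dna(40), proto_mm, "TGG", random_dna(40))
  })
  hits <- scan_seed_offtargets(g, c(planted = subj), max_seed_mismatch = 1)
  expect_identical(nrow(hits), 1L)
  expect_identical(hits$position, 40L)
  expect_identical(hits$seed_mismatches, 1L)

  # random 10 kb subject: identical hit set to the sliding-window oracle
  withr::with_seed(14, subj10k <- random_dna(10000))
  got <- scan_seed_offtargets(g, c(s = subj10k), max_seed_mismatch = 2)
  want <- oracle_offtargets(g, c(s = subj10k), max_seed_mm = 2)
  expect_equal(got, want)

  expect_identical(nrow(scan_seed_offtargets(g, character())), 0L)
})
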