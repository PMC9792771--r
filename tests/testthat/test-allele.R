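amp <- ref_380$amplicon
pair <- ref_380$pair

test_that("segment and site edits realize the expected sequences", {
  del <- build_allele(amp, pair, list(edit_segment_deletion()), "del")
  expect_identical(nchar(del$sequence), 128L)

  inv <- build_allele(amp, pair, list(edit_segment_inversion()), "inv")
  expect_identical(nchar(inv$sequence), 380L)
  expect_identical(substr(inv$sequence, pair$cut1 + 1, pair$cut2),
                   rc_chr(substr(amp$sequence, pair$cut1 + 1, pair$cut2)))
  # flanks untouched
  expect_identical(substr(inv$sequence, 1, pair$cut1),
                   substr(amp$sequence, 1, pair$cut1))

  ins <- build_allele(amp, pair, list(edit_insertion("cut1", "T")), "ins")
  expect_identical(nchar(ins$sequence), 381L)

  # odd deletion removes ceiling(s/2) left of the cut, floor(s/2) right
  d5 <- build_allele(amp, pair, list(edit_deletion("cut1", 5)), "d5")
  expect_identical(
    d5$sequence,
    paste0(substr(amp$sequence, 1, pair$cut1 - 3),
           substr(amp$sequence, pair$cut1 + 3, 380)))
})

test_that("allele length accounting holds for random edit combinations", {
  withr::with_seed(21, {
    for (i in 1:25) {
      edits <- list()
      seg <- sample(c("none", "del", "inv"), 1)
      if (seg == "del") edits <- c(edits, list(edit_segment_deletion()))
      if (seg == "inv") edits <- c(edits, list(edit_segment_inversion()))
      expected <- 380L - if (seg == "del") 252L else 0L
      # site indels at cut1/cut2 are only legal outside a deleted segment;
      # deletions centered on a cut stay within the flank for sizes <= 40
      if (seg == "none" && runif(1) < 0.8) {
        sz <- sample(c(1, 2, 3, 7, 25, 39), 1)
        if (runif(1) < 0.5) {
          edits <- c(edits, list(edit_deletion("cut1", sz)))
          expected <- expected - as.integer(sz)
        } else {
          ins <- strrep("A", sz)
          edits <- c(edits, list(edit_insertion("cut2", ins)))
          expected <- expected + as.integer(sz)
        }
      }
      a <- build_allele(amp, pair, edits)
      expect_identical(nchar(a$sequence), expected)
    }
  })
})

test_that("segment inversion is an involution", {
  inv <- build_allele(amp, pair, list(edit_segment_inversion()), "inv")
  amp_inv <- amplicon("inv", inv$sequence, amp$fwd_primer, amp$rev_primer,
                      amp$cds_frame_offset)
  back <- build_allele(amp_inv, pair, list(edit_segment_inversion()), "back")
  expect_identical(back$sequence, amp$sequence)
})

test_that("incompatible edit sets are rejected", {
  expect_error(build_allele(amp, pair, list(edit_segment_deletion(),
                                            edit_segment_inversion())),
               "conflicting edits")
  expect_error(build_allele(amp, pair, list(edit_deletion("cut1", 10),
                                            edit_deletion("cut1", 4))),
               "conflicting edits")
  # an indel strictly inside a deleted segment is meaningless
  expect_error(build_allele(amp, pair,
                            list(edit_segment_deletion(),
                                 edit_substitution(pair$cut1 + 50, "A"))),
               "conflicting edits")
})

test_that("re-cutting requires an intact protospacer+PAM", {
  wt <- build_allele(amp, pair, list(), "wt")
  expect_true(all(recut_check(wt, pair)))

  del <- build_allele(amp, pair, list(edit_segment_deletion()))
  expect_false(any(recut_check(del, pair)))
  inv <- build_allele(amp, pair, list(edit_segment_inversion()))
  expect_false(any(recut_check(inv, pair)))

  ins1 <- build_allele(amp, pair, list(edit_insertion("cut1", "T")))
  rc1 <- recut_check(ins1, pair)
  expect_false(rc1[[pair$guide1$name]])
  expect_true(rc1[[pair$guide2$name]])
})
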