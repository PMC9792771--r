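amp <- ref_380$amplicon
pair <- ref_380$pair
alleles <- std_alleles()

test_that("pair merging honors overlap and quality rules", {
  p <- caller_params()
  # error-free fully overlapping pair reconstructs the allele
  r1 <- read_df(substr(amp$sequence, 1, 300))
  r2 <- read_df(rc_chr(substr(amp$sequence, 81, 380)))
  m <- merge_pairs(r1, r2, p)
  expect_true(m$merged)
  expect_identical(m$seq, amp$sequence)

  # a 10 nt overlap is below the default minimum of 20
  a <- substr(amp$sequence, 1, 50)
  b <- substr(amp$sequence, 41, 90)
  m2 <- merge_pairs(read_df(a), read_df(rc_chr(b)), p)
  expect_false(m2$merged)

  # single disagreement at equal quality resolves toward R1
  r1x <- substr(amp$sequence, 1, 300)
  b2 <- substr(amp$sequence, 81, 380)
  pos <- 100L  # inside the overlap on R2's copy
  substr(b2, pos, pos) <- setdiff(c("A", "C", "G", "T"),
                                  substr(b2, pos, pos))[1]
  m3 <- merge_pairs(read_df(r1x), read_df(rc_chr(b2)), p)
  expect_true(m3$merged)
  expect_identical(m3$seq, amp$sequence)

  # ...and toward the higher-quality base when qualities differ
  m4 <- merge_pairs(read_df(r1x, qual = strrep("#", 300)),
                    read_df(rc_chr(b2), qual = strrep("I", 300)), p)
  expect_identical(substr(m4$seq, 80 + pos, 80 + pos), substr(b2, pos, pos))
})

test_that("template competition classifies each allele class correctly", {
  cases <- list(
    wt = c("wt", "wt"),
    del = c("large_deletion", "large_deletion"),
    inv = c("inversion", "inversion"),
    ins1 = c("indel", "wt"),
    del5 = c("indel", "wt"),
    sub = c("substitution_only", "wt"))
  for (lab in names(cases)) {
    cl <- classify_read(merged_read(alleles[[lab]]), amp, pair)
    expect_identical(cl$category, cases[[lab]][1])
    expect_identical(cl$template, cases[[lab]][2])
  }
  ins <- classify_read(merged_read(alleles$ins1), amp, pair)
  expect_identical(ins$cut1_indel, 1L)
  expect_identical(ins$cut2_indel, 0L)
  d5 <- classify_read(merged_read(alleles$del5), amp, pair)
  expect_identical(d5$cut1_indel, 0L)
  expect_identical(d5$cut2_indel, -5L)
})

test_that("split mode recovers structural events from flanks and middle", {
  del_cl <- classify_read_splitmode(merged_read(alleles$del), amp, pair)
  expect_identical(del_cl$category, "large_deletion")
  inv_cl <- classify_read_splitmode(merged_read(alleles$inv), amp, pair)
  expect_identical(inv_cl$category, "inversion")
  ins_cl <- classify_read_splitmode(merged_read(alleles$ins1), amp, pair)
  expect_identical(ins_cl$category, "indel")
  expect_identical(ins_cl$cut1_indel, 1L)
})

test_that("inversion reads mirror the legacy single-template failure mode", {
  inv_read <- merged_read(alleles$inv)
  id <- align_global(inv_read, amp$sequence, caller_params())$identity
  expect_gte(id, 0.30)
  expect_lt(id, 0.60)
  strict <- classify_read(inv_read, amp, pair, templates = "wt")
  expect_identical(strict$category, "unclassified")
  legacy <- classify_read(inv_read, amp, pair,
                          params = caller_params(min_homology = 0.30),
                          templates = "wt")
  expect_false(legacy$category == "unclassified")
})

test_that("lowering min_homology never loses classified reads", {
  mix <- mixture_spec(c(wt = 0.3, del = 0.2, inv = 0.3, ins1 = 0.2), 400,
                      error_rate = 0.005, seed = 41)
  rs <- simulate_reads(amp, pair, mix, alleles)
  classified <- vapply(c(0.9, 0.6, 0.45, 0.3), function(h) {
    tab <- call_sample(rs, amplicon = amp, pair = pair,
                       params = caller_params(min_homology = h),
                       templates = "wt")
    tab$classified
  }, integer(1))
  expect_true(all(diff(classified) >= 0))
})

test_that("category counts always sum to the read-pair count", {
  withr::with_seed(42, {
    for (i in 1:4) {
      fr <- runif(4); fr <- fr / sum(fr); names(fr) <- c("wt", "del", "inv",
                                                         "ins1")
      mix <- mixture_spec(fr, 300, error_rate = 0.002, seed = 100 + i)
      rs <- simulate_reads(amp, pair, mix, alleles)
      tab <- call_sample(rs, amplicon = amp, pair = pair)
      expect_identical(sum(tab$counts), tab$total)
      expect_identical(tab$total, 300L)
      expect_identical(sum(tab$variants$count), tab$classified)
    }
  })
})

test_that("the ungapped fast path matches full alignment", {
  mix <- mixture_spec(c(wt = 0.4, del = 0.2, inv = 0.2, ins1 = 0.1,
                        sub = 0.1), 300, error_rate = 0.01, seed = 43)
  rs <- simulate_reads(amp, pair, mix, alleles)
  fast <- call_sample(rs, amplicon = amp, pair = pair)
  slow <- call_sample(rs, amplicon = amp, pair = pair,
                      params = caller_params(fast_path_identity = 2))
  expect_identical(fast$calls$category, slow$calls$category)
  expect_identical(fast$calls$template, slow$calls$template)
})

test_that("empty input and pure wild-type samples tabulate correctly", {
  empty <- call_sample(read_df(character()), r2 = read_df(character()),
                       amplicon = amp, pair = pair)
  expect_identical(empty$total, 0L)

  mix <- mixture_spec(c(wt = 1), 1000, error_rate = 0, seed = 44)
  rs <- simulate_reads(amp, pair, mix)
  tab <- call_sample(rs, amplicon = amp, pair = pair)
  expect_identical(tab$fractions[["wt"]], 1)
  expect_identical(tab$classified, 1000L)
})

test_that("calls and tables serialize to TSV/JSON", {
  dir <- withr::local_tempdir()
  mix <- mixture_spec(c(wt = 0.5, del = 0.5), 50, error_rate = 0, seed = 45)
  rs <- simulate_reads(amp, pair, mix, alleles)
  tab <- call_sample(rs, amplicon = amp, pair = pair)
  tsv <- file.path(dir, "calls.tsv"); js <- file.path(dir, "tab.json")
  write_read_calls(tab, tsv)
  write_allele_table(tab, js)
  back <- read.delim(tsv)
  expect_identical(nrow(back), 50L)
  j <- jsonlite::read_json(js)
  expect_identical(j$total, 50L)
  expect_identical(j$counts$large_deletion,
                   as.integer(tab$counts[["large_deletion"]]))
})
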