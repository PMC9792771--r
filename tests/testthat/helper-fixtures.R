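# Shared fixtures, built once per test run.

ref_380 <- make_reference(380, 252, 20, seed = 1)

std_alleles <- function(ref = ref_380) {
  alleles_from_components(ref, list(
    list(label = "wt", kind = "wt"),
    list(label = "del", kind = "segment_deletion"),
    list(label = "inv", kind = "segment_inversion"),
    list(label = "ins1", kind = "insertion", size = 1, cut = 1),
    list(label = "del5", kind = "deletion", size = 5, cut = 2),
    list(label = "sub", kind = "substitution", cut = 1)))
}

# one-pair read data.frames for hand-built sequences
read_df <- function(seqs, qual = NULL) {
  data.frame(id = sprintf("r%03d", seq_along(seqs)), seq = seqs,
             qual = if (is.null(qual)) strrep("I", nchar(seqs)) else qual)
}

# error-free merged read of an allele under PE geometry (R1 covers the
# molecule start, R2 the end); for alleles shorter than 2x read length the
# merged read is the whole allele sequence
merged_read <- function(allele) {
  if (inherits(allele, "allele")) allele$sequence else allele
}
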