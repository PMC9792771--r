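---
title: "Calling editing outcomes in dual-guide CRISPR amplicon sequencing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling editing outcomes in dual-guide CRISPR amplicon sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dualguide)
```

## The experimental design this package models

When a gene is targeted by two SpCas9 guides at once — a strategy used, for
example, to knock out fruit-pigmentation genes such as the fruit-specific
lycopene β-cyclase in citrus — the two simultaneous double-strand breaks open
repair routes that a single guide cannot produce. Besides the familiar small
indels at either cut site, the cell can rejoin the outer ends and drop the
whole inter-cut segment (a large deletion), or reinsert that segment
flipped (an inversion). Amplicon deep sequencing of the target region, PCR
genotyping on a gel, and a four-primer inversion assay are the standard
read-outs, and `dualguide` implements all three *in silico*, together with a
paired-end read simulator so the whole pipeline is testable without deposited
sequencing data.

The geometry is held by two objects. An `amplicon()` records the reference
sequence with the two primer annealing sites and optionally the reading-frame
phase of position 0 (`cds_frame_offset`). A `guide_pair()` derives each
guide's blunt cut site — 3 nt 5′ of the NGG PAM, the SpCas9 default; no
staggered-cut option is offered — and the inter-cut segment `[cut1, cut2)`.
All coordinates are 0-based and half-open, and a cut coordinate `c` means
"between positions `c − 1` and `c`", which keeps segment arithmetic free of
off-by-one ambiguity. In the study geometry the amplicon is 380 bp, the cut
sites are 252 bp apart, and the deletion allele is therefore 128 bp.

Guide-design rules are checked by `validate_guide_pair()` (unique
protospacer+PAM occurrence, annotation spacing ≤ 300 bp) and
`scan_seed_offtargets()`, which enumerates NGG-adjacent sites whose
PAM-proximal *seed* region matches the guide closely. The seed is taken as
the 12 PAM-proximal nucleotides — the conventional choice, configurable,
since "seed region" has no single canonical length. Guide spacing (the gap
between the two annotations) and inter-cut length are reported as
independent quantities: they differ by construction (the cuts sit inside the
protospacers), and conflating them is a common source of off-by-20 errors.

## Alleles and their consequences

`build_allele()` realizes an edited sequence from descriptors: insertions at
a cut, deletions centred on a cut, the segment deletion, the segment
inversion, and single-base substitutions. Deletions of odd size remove
⌈s/2⌉ nt left of the cut and ⌊s/2⌋ right — assays report only total sizes,
so a convention is required for simulation, and this one keeps the deletion
centred. Incompatible descriptor sets (two segment-level edits, overlapping
footprints, a site edit inside a deleted segment) are rejected rather than
silently reordered.

`recut_check()` asks whether Cas9 can cut again: a guide is cuttable iff its
intact protospacer+PAM occurs in the allele on either strand. Both
structural events abolish both sites — the inversion in particular flips the
PAMs out of register — which is why inversion and large-deletion alleles are
stable end points while wild-type alleles in partially edited plants remain
substrates.

`protein_consequence()` reports the mechanical translation effect: a net
indel not divisible by 3 is a frameshift; the edited frame is translated
(Biostrings) and a stop codon appearing earlier than the first wild-type
in-frame stop is flagged premature; the 252 bp segment deletion is an
in-frame loss of 84 codons. Whether a junction creates a stop codon depends
on the actual sequence, so the function reports only what translation shows.

## The read simulator: what it emulates and what it does not

`simulate_reads()` draws each read pair from an allele mixture
(multinomial), takes R1 as the first `read_length` nt of the allele and R2
as the reverse complement of the last `read_length` nt, and applies
independent substitution errors. Defaults mirror the study conditions:
PE300 reads, per-sample depths around 24,000 pairs, mixture fractions
spanning 0–100 % mutated reads, and a substitution error rate of 0.001 —
a realistic MiSeq scale where substitutions dominate. Qualities are a
constant symbol because the pipeline uses quality only to break overlap
disagreements. Sequencing *indel* errors, quality decay along the read,
PCR chimeras and adapter read-through are deliberately not modelled: the
simulator's job is to give the caller reads whose true origin is known
exactly, so tests can measure recovery, not to reproduce instrument
artefacts. Passing tests therefore demonstrate correctness of the calling
logic under substitution noise, not robustness to every failure mode of
real libraries. A truth table (read id → allele label) accompanies every
simulated set, and `(seed, parameters)` determine all outputs exactly.

`make_reference()` generates the synthetic locus: a random background drawn
codon-wise from non-stop codons (so the wild-type frame translates like a
CDS interior), planted PAM dinucleotides, and guides read off the final
sequence; uniqueness of every functional site is enforced with a retry
loop. The real locus's primer-to-cut distances are not printed anywhere, so
flank lengths default to an even split of `total − intercut` and are
parameters, not constants.

## The read caller

`merge_pairs()` merges each pair by the best ungapped overlap (≥ 20 nt,
mismatch fraction ≤ 0.1), resolving disagreements toward the higher-quality
base with ties to R1. Merged reads are deduplicated before classification —
amplicon data collapse heavily, which is where most of the speed comes
from.

### Template competition

`classify_read()` aligns the read to three realized templates — wild type,
segment-deletion allele, segment-inversion allele — and the best-identity
template wins, provided it reaches `min_homology` (default 0.60; 0.30 is
the permissive legacy setting). Ties break conservatively toward
wild type, then large deletion, then inversion: a structural call requires
positive evidence. Within the winning template, indels and substitutions
inside a quantification window of ±1 nt around each cut (the usual
amplicon-caller default, configurable) refine the category: `indel`,
`substitution_only`, or plain `wt`; junction-window indels on a structural
template mark the read `complex`.

Identity is defined as matches divided by alignment columns, gap columns
included — the strictest common convention. The aligner is a Gotoh
affine-gap global aligner (in C++, with full traceback); a gap of length L
costs `gap_open + L·gap_extend`. The default scores (match +1, mismatch −1,
gap open 40, gap extend 5) are deliberately edit-distance-like with harshly
priced gaps: against an *unrelated* 252 bp stretch (which is exactly what
the inverted middle looks like to the wild-type template) a permissive
scoring scheme lets the dynamic program harvest shuffled, common-subsequence
matches and inflate identity well above what positional homology supports.
With gaps priced out, gaps appear only where a length difference forces them
or where a true indel rescues long exact runs, and the identity of an
inversion read against wild type settles at ≈ 0.5 — below the default 0.60
threshold (the read is rejected, reproducing the failure mode of
single-template callers) and above the 0.30 legacy threshold (the read
aligns, as a heavily mutated profile). Lowering `min_homology` can only
add classified reads, never remove them.

Two numerical details matter for correct indel placement. First, every gap
is normalized: a deletion or insertion inside a repeat can be placed at
several equivalent coordinates, so its reachable placement range is computed
(the standard left/right slide over equal bases) and an indel counts toward
a cut if *any* equivalent placement touches the window. Without this, a −1
deletion beside a homopolymer would drift out of the window and be called
wild type. Second, equal-length templates are screened ungapped first: a
template whose Hamming identity reaches `fast_path_identity` (0.95) wins
immediately. No two default templates are within 5 % of each other, so at
most one template can pass the screen, and a property test checks the fast
path agrees with full alignment.

### Split mode

`classify_read_splitmode()` is the in-package analog of the diagnostic that
first revealed inversions: realigning reads with a spliced aligner and
inspecting soft-clips. The read is globally aligned to wild type only; the
flanks outside the cuts must anchor (identity ≥ 0.9 per flank). A deletion
event of exactly the inter-cut length whose normalized placement covers the
junction is the splice-junction signature → large deletion. Otherwise the
unanchored middle is compared to the inter-cut segment: matching its
reverse complement is the soft-clip signature → inversion; matching the
forward segment routes to the ordinary wt/indel path; matching neither is
`complex`. Reads whose flanks fail to anchor fall back to the wt/indel
path, which is what rescues large site deletions (−74 eats half a flank).
On error-free reads from any constructible allele the two modes agree — the
suite checks this class by class.

`call_sample()` tabulates calls into an `allele_table`: counts per
category, fractions over classified reads (unclassified reads — unmerged
pairs and sub-threshold alignments — are reported separately, never in the
denominator), and the distinct-variant spectrum.

## Sample summaries

`summarize_sample()` turns a table into the sample-level biology. The
mutated fraction is 1 − wild-type fraction over classified reads. At or
above 0.995 the sample is a full knockout — the cut-off is 0.995 rather
than literal 1.0 because substitution errors in the cut windows make a
literal 100 % unattainable at realistic depths; "100 % edited" is read as
"no wild-type allele detectable". Between 0.10 and 0.995 the sample is
partially edited, the signature of a heterozygous or (more likely, in
regenerated plantlets) chimeric individual — observed chimeric ranges start
around 11 %, and 0.10 is the configurable default. Dominant alleles are
variants covering ≥ 20 % of classified reads. `transformation_efficiency()`
is exact rational arithmetic, 100·positives/infected, rounded half-up —
`te_table()` recomputes whole tables and *warns* where a printed value
disagrees with half-up rounding of its own quotient, because published
tables do contain such rows and silently "correcting" either side would be
worse.

## In-silico PCR

`predict_products()` anneals primers by exact full-length match on both
strands and reports every convergent placement's outer span. Exactness is a
deliberate choice: the genotyping assay is qualitative, and a
mismatch-tolerant annealing model would buy realism at the price of
nondeterministic product lists. `gel_profile()` reproduces the four-profile
taxonomy (wild-type band only / deletion band only / both / anything else)
with a ±5 nt band tolerance emulating gel resolution. `inversion_assay()`
runs the four outer×inner primer combinations; because inversion flips the
internal primers' orientation, the productive combinations of the wild type
and of the inversion allele are exact complements — a presence/absence
property that holds for any generated reference, which is how the assay is
validated (the study's own four product lengths are shown only graphically,
so there are no printed numbers to compare).

## Problem sizes, determinism, limitations

The test suite exercises the caller at the study's depth: 24,000 pairs per
sample across 20 mixtures spanning mutated fractions 0.1–1.0 at error rate
0.001, plus ≥ 1,000 error-free reads per allele class for the two-classifier
agreement check; these sizes keep a full run within a couple of minutes on
one core while leaving the binomial tolerances meaningful. All randomness
flows from explicit integer seeds (`withr::with_seed` scoping), and the run
layer derives per-stage seeds from one global seed so a single integer
reproduces a whole simulate → call → summarize → pcr run byte for byte.

Known limitations: the caller assumes amplicon-local reads (it is not a
genome aligner and will not place reads spanning novel junctions outside
the amplicon); per-read classification cannot distinguish a true
single-base substitution inside a cut window from a sequencing error
landing there — at error 0.001 about 0.4 % of wild-type reads carry such an
error and are counted `substitution_only`, a known, quantifiable leak;
complex/hybrid alleles (e.g. a segment deletion plus a junction indel) are
flagged `complex` by template competition but may be absorbed as
large deletions by split mode's junction rule; and the simulator's error
model is substitution-only by design, so indel-error robustness is
untested by construction.
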