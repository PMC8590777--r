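---
title: "Genotyping repeat expansions and haplotype-resolved CpG methylation from long reads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genotyping repeat expansions and haplotype-resolved CpG methylation from long reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(replongmeth)
library(dplyr)
```

## The problem

Short tandem-repeat expansions such as the GGC expansion in the
*NOTCH2NLC* 5′-UTR cause neuronal intranuclear inclusion disease when
the allele falls in a disease-causing range of roughly 41–300 repeat
copies. Far longer expansions — many hundreds of copies — can be carried
without symptoms: such alleles are hypermethylated en bloc across a
~2.2 kb region spanning ~700 bp upstream of the repeat, the repeat
itself, and ~1,000 bp downstream, which silences the toxic allele. The
normal allele shows the mirror-image profile: that same region is
unmethylated, flanked by bilateral *transitional zones* whose CpGs are
methylated on some molecules and not on others, with fully methylated
DNA beyond them.

Resolving this biology needs single-molecule, haplotype-resolved
measurements: per-read repeat copy numbers (alleles differ by hundreds
of copies and vary read-to-read through somatic mosaicism), per-read
CpG methylation states (a hypermethylated and an unmethylated allele
coexist in one genome, and a fraction of expanded molecules escape
methylation — epigenetic mosaicism), and, on SMRT data, polymerase
kinetics that slow over methylated tracts. `replongmeth` implements
that workflow as a tested library: every stage takes and returns
tibbles so analyses compose with ordinary dplyr pipelines.

## Data model

A long read is one row of a tibble: placement (`chrom`, 0-based
`ref_start`, `strand`, CIGAR), the stored (reference-orientation)
sequence, and list-columns of per-cytosine modification scores and
optional kinetics arrays. All internal coordinates are 0-based
half-open; user-facing reports and `chrom:start-end` strings are
1-based inclusive, matching genome-browser conventions.

Modification scores are basecaller likelihoods of 5-methylcytosine on
an integer 0–255 scale: a score $s$ means a likelihood of $s/255$, so
192 is 75% and 255 is 100%. A base is **modified** when $s > 128$,
strictly — 128 itself is canonical. Both the scale and the threshold
are configuration constants with these defaults.

Score offsets index the read in its *original basecall orientation*
(the MM/ML tag convention), so for a reverse-strand read offset $k$
addresses stored position $L-1-k$; reverse-strand cytosines therefore
sit under stored Gs. Files round-trip through either plain-text SAM
with MM/ML (and fi/fp/ri/rp kinetics) tags or a documented TSV dialect
that keeps the toolkit testable without any binary alignment
dependency.

## Projecting scores onto reference CpGs

`project_read()` walks the CIGAR: a scored cytosine that lands on a
match/mismatch column whose *reference* context is CpG on the read's
strand yields one observation; insertions contribute nothing, and
scored cytosines over deletions or clips are dropped. Three choices
here were genuinely open and are fixed as follows:

* **CpG context is defined on the reference, not the read**, so
  positions are comparable across reads. By default only *scored*
  cytosines are reported; `include_unscored = TRUE` additionally counts
  covered reference-CpG columns without a score as canonical
  (score 0), which treats mismatched or uncalled bases as unmethylated
  evidence.
* Each observation carries a `cpg_anchor` — the forward-strand C of its
  CpG — so the two strands of a dinucleotide can be combined
  (`combine_strands = TRUE` in `methyl_pileup()`). Combining is off by
  default; the strand-split view remains available for read-level
  displays sorted by strand.
* Cytosines outside CpG context are discarded; CHG/CHH methylation is
  out of scope.

Projection against an expansion-allele consensus
(`project_against_consensus()`) uses identical logic with allele
coordinates; reads placed on decoy contigs (homologous regions added to
absorb mismapping) are excluded and counted.

## Methylation calling

`methyl_pileup()` tallies modified (score > 128) versus canonical
observations per site; `call_methylation()` then supports two modes:

* **rate** — the percent methylation score
  $n_\mathrm{mod} / (n_\mathrm{mod} + n_\mathrm{canon})$ against a
  cutoff, default 20%. The comparison is *inclusive*: 20% is the
  smallest accepted value, so the boundary is deterministic.
* **fisher** — a one-sided Fisher's exact test of the site's counts
  against a pseudo-count null population of `null_n = 1000`
  observations with error floor `null_error = 0.05`. A literal null of
  "zero chance of methylation" makes any exact test degenerate (a
  single modified observation would be infinitely surprising); the
  error floor encodes the basecaller's false-positive rate. Sites with
  $p < 0.01$ are called methylated. The p-values are verified against
  an independent hypergeometric enumeration to $10^{-9}$ for all
  tables with coverage ≤ 30.

Default minimum coverage for per-site reporting is 10, aligned with
common practice for the downstream per-base format. That format
(`export_methylkit()`) is the tab-separated
`chrBase chr base strand coverage freqC freqT` dialect with `freqC` the
percent methylated, so standard bisulfite tooling can consume long-read
calls directly.

## In-silico bisulfite view

For browser display, `convert_reads()` rewrites each read as its
bisulfite image: cytosines with score ≤ 128 become T on forward reads
and A (in the reference-oriented sequence) on reverse reads, while
methylcytosines are untouched. Unscored cytosines in read-sense CpG
context default to "converted" — absence of a call is evidence of
canonical C under the basecaller's output contract — and this is
configurable (`convert_unscored`). Non-CpG cytosines without scores
are never touched. Only positions currently holding the expected base
are substituted, which makes conversion idempotent, and the original
sequence travels in an `XO` auxiliary tag so the SAM output is
lossless.

## Repeat genotyping, phasing and composition

Copy-number genotyping follows the tandem-genotypes idea: for a read
spanning the locus plus a `flank_margin` (default 100 bp) on both
sides, the net inserted-minus-deleted base count within the
margin-expanded tract, divided by the unit length and rounded
half-away-from-zero (symmetric for expansions and contractions), is the
relative copy-number change; adding the reference copy count (13 at
the GGC locus this workflow was built around) gives absolute copies.
Soft-clipped bases never enter the sum, and non-spanning reads are
rejected and counted rather than silently dropped — contractions and
expansions must be measured on spanning evidence only.

Phasing assigns reads with relative calls < 50 to the non-expanded and
≥ 50 to the expanded allele; the split is exhaustive, disjoint and
monotone. `allele_summary()` reports median (midpoint rule), sample SD
(zero with a flag for singletons) and linear-interpolation IQR per
group, and `classify_disease_range()` brackets absolute copies against
the 41–300 disease-causing range.

`decompose_repeat()` renders a tract as ordered motif runs for
waterfall plots using a greedy left-to-right scan. Priority is named
insertion strings (longest first), then the unit, then interruption
motifs, with unmatched bases as single-base runs; the greedy scan was
chosen over optimal segmentation because it is deterministic, linear,
and matches how waterfall figures are read. Decomposition is lossless
by construction — concatenating the runs reproduces the input — and
this identity is property-tested on random strings.

## Polymerase kinetics

The replication cycle time of a base is the sum of its inter-pulse
duration and pulse width, in sequencer frames, taken per strand (fi/fp
forward, ri/rp reverse). `kinetics_track()` averages cycle times by
allele position across reads pre-assigned to an allele;
`cumulative_cycle_time()` accumulates them (positions without coverage
are imputed as 0 frames, with a count, so the curve stays defined);
`replication_rate()` converts a window's total cycle time into
bases/second. The frame rate is a required argument with *no default*:
rates in physical units are only as honest as the instrument constant,
which the package refuses to invent. Tracks are reported in frames and
converted to seconds only when a frame rate is supplied.

## Multi-sample comparison

`build_percent_matrix()` assembles sites × samples percent methylation
(union of sites; cells need coverage ≥ 10). All downstream analyses
are complete-case — no imputation, since missingness here reflects
coverage, not biology. Pairwise similarity is the Pearson correlation
with a simple regression line; sample structure comes from PCA
(centered, not variance-scaled — percent scales are already
commensurate) with a deterministic sign convention, and from Ward
hierarchical clustering (`ward.D2` on Euclidean distances, samples
pre-sorted by name so ties resolve identically everywhere).

Per-base differential methylation is a two-sided Fisher's exact test
on the two samples' modified/canonical counts. Multiple testing is
controlled by Benjamini–Hochberg q-values with the significance cutoff
kept at q < 0.01; BH replaces the sliding-linear-model q-value method
used historically in this workflow because it is transparent,
assumption-light and directly testable. `annotate_features()` places
differential sites in annotation context (BED 0-based half-open,
half-open overlap; ties between equidistant TSSs break by
lexicographic gene name).

## The synthetic trio generator

No patient sequencing data ships with the package; `simulate_trio()`
generates the study conditions instead, and its defaults *are* those
conditions:

* **Mother**: two non-expanded alleles of ~13 copies (SD 0.7).
* **Father**: one non-expanded allele and one extremely long expansion
  (median 520 copies, SD 170 — the asymptomatic-carrier scale, far
  beyond the 41–300 range), hypermethylated en bloc over the repeat
  ±(700, 1,000) bp, with 10% of expanded molecules left unmethylated
  (epigenetic mosaicism). An optional bimodal mode draws copies from a
  50/50 mixture at ~230/~580 to emulate two somatic cell populations.
* **Patient**: the maternal non-expanded allele plus a contracted,
  disease-range expansion (median 93, SD 10 — contracted alleles are
  far more stable than the paternal expansion) with the normal,
  unmethylated profile. Father and patient share 2 GGA interruption
  units placed as a fixed block at the 3′ end of the pure-GGC stretch,
  constant across reads of a haplotype; a named insertion motif can be
  appended to the tract.

Reference flanks are CG-free backgrounds with CpGs planted every
~45 bp distally and ~25 bp over the differential block (a CpG-island
scale density); the last 4 planted CpGs upstream and first 8
downstream of the block are transitional, methylated per read with
probability 0.5 on normal-pattern alleles and fully methylated on the
hypermethylated allele. Score emission draws >128 with probability
0.95 for methylated and ≤128 with probability 0.95 for unmethylated
CpGs, uniform within each side. Sequencing errors (3% substitution,
2% insertion, 2% deletion) are injected *after* composition, so truth
is defined pre-error. Copy-number instability is a truncated normal
over per-read copies; the true noise shape in real data is unknown, so
the distribution is a parameter, not an assertion.

Kinetics fixtures are generated separately at each allele's consensus
length (mirroring per-allele consensus averaging on SMRT data):
Poisson cycle times around 50 frames/base, multiplied by 2.2 over the
methylated repeat tract, with a 100 frames/s frame-rate convention —
giving ~2.0 bases/s on the non-expanded and ~0.9 bases/s on the
expanded allele.

A fixed seed fully determines every output. The default trio is 560
reads (80 + 80, 100 + 100, 100 + 100 per haplotype) — large enough
that end-to-end recovery is sharp (haplotype assignment ≥ 99%, group
median copies within ±2, block boundaries within ±1 CpG) yet small
enough that the whole suite runs in about two minutes; unit tests use
a further-scaled 140-read trio.

What the generator does **not** emulate: signal-level data, realistic
platform error profiles (errors are i.i.d. per base), mappability or
enrichment artefacts, and alignment itself (reads are emitted with
known CIGARs; basecalling and alignment are out of scope throughout).
Passing tests therefore demonstrate the correctness of the
*computational* pipeline under the stated statistical structure, not
robustness to every property of real sequencing runs.

## Worked example

```{r example, eval = FALSE}
sim <- simulate_trio(trio_config(seed = 1))

calls <- genotype_repeats(sim$reads, sim$locus) |>
  phase_alleles()
allele_summary(calls |> semi_join(
  filter(sim$truth$reads, sample == "father"), by = "read_id"))

obs <- sim$reads |>
  filter(sample == "father") |>
  project_sample(sim$reference)
meth <- methyl_pileup(obs, min_coverage = 10, combine_strands = TRUE) |>
  call_methylation(mode = "rate")
plot_methylation_profile(meth)
```

## Known limitations

* The Fisher-mode null construction is this package's explicit
  substitute for an unspecified historical procedure; rate mode is the
  primary calling path.
* Genotyping requires reads spanning both flanks; single-flank
  evidence is not used.
* Differential methylation is per-base only; no tiling windows,
  logistic-regression models or overdispersion corrections.
* The in-silico bisulfite conversion restricts itself to CpG-context
  plus scored cytosines; genome browsers will render non-CpG cytosines
  as methylated under their bisulfite modes.
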