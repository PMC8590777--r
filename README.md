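# replongmeth

Tandem-repeat expansion genotyping and haplotype-resolved CpG
methylation from long reads, in R.

## The problem

GGC-repeat expansions in the *NOTCH2NLC* 5′-UTR cause neuronal
intranuclear inclusion disease when the allele carries roughly 41–300
repeat copies — yet far longer expansions (hundreds of copies) can be
carried asymptomatically because they are hypermethylated en bloc over
a ~2.2 kb region (repeat ± ~700/1,000 bp) and silenced. Dissecting
this requires single-molecule resolution: per-read repeat copy
numbers, per-read CpG methylation states on each haplotype, and (on
SMRT data) polymerase kinetics that slow over methylated DNA.

`replongmeth` implements that workflow end to end for long reads that
carry per-base 5-mC modification likelihoods (MM/ML-style tags or a
documented TSV dialect):

* **Score model** — scores are 0–255 scaled likelihoods
  (`s/255`; 192 → 75%, 255 → 100%); a base is modified iff `s > 128`,
  strictly.
* **Projection** (`project_read`, `project_sample`,
  `project_against_consensus`) — CIGAR walk assigning scored read
  cytosines to reference positions, restricted to reference-CpG
  context, strand-aware via a shared CpG anchor.
* **Calling** (`methyl_pileup`, `call_methylation`,
  `export_methylkit`) — per-site percent methylation
  `n_mod / (n_mod + n_canon)` with an inclusive 20% cutoff, or a
  one-sided exact test against a pseudo-count null; export in the
  methylKit per-base dialect.
* **Bisulfite view** (`convert_reads`, `write_converted`) — in-silico
  bisulfite conversion (score ≤ 128 → T on forward / A on reverse
  reads) for genome-browser bisulfite modes; idempotent and lossless.
* **Repeat genotyping** (`genotype_repeats`, `phase_alleles`,
  `allele_summary`, `decompose_repeat`, `waterfall_table`) —
  tandem-genotypes-style relative copy number
  `round((ins − del) / |unit|)` from spanning reads, allele phasing at
  a relative call of 50, disease-range classification (41–300), and
  lossless greedy motif-run decomposition for waterfall plots.
* **Kinetics** (`kinetics_track`, `cumulative_cycle_time`,
  `replication_rate`) — per-position replication cycle time
  (IPD + pulse width, frames), cumulative curves, bases/second over a
  window.
* **Multi-sample comparison** (`build_percent_matrix`,
  `pairwise_pearson`, `pca_samples`, `ward_clustering`,
  `diff_methyl`, `annotate_features`) — Pearson similarity, centered
  PCA, Ward (ward.D2) clustering, per-base Fisher tests with
  Benjamini–Hochberg q-values (q < 0.01), feature-context summaries.
* **Synthetic trio** (`trio_config`, `simulate_trio`, `write_trio`) —
  a seeded generator emulating a mother (~13 copies), an asymptomatic
  father (median ~520-copy mosaic hypermethylated expansion, 10%
  epigenetic mosaicism) and a patient (median ~93-copy unmethylated
  expansion), with transitional-zone CpGs, sequencing errors and
  kinetics — so the whole pipeline is testable without sequencing
  data.

Everything is tibble-in / tibble-out and composes with dplyr; fitted
comparison objects have `tidy()` / `glance()` methods and
`autoplot()` / `plot_*()` ggplot2 graphics. A thin command-line
wrapper ships at `inst/scripts/replongmeth`.

## Worked example

```r
library(replongmeth)
library(dplyr)

sim <- simulate_trio(trio_config(seed = 1))

# genotype + phase the father's reads
calls <- genotype_repeats(sim$reads, sim$locus) |> phase_alleles()
calls |>
  semi_join(filter(sim$truth$reads, sample == "father"),
            by = "read_id") |>
  allele_summary()
#> # A tibble: 2 × 6
#>   allele       n_reads median     sd   iqr sd_defined
#>   <chr>          <int>  <dbl>  <dbl> <dbl> <lgl>
#> 1 expanded         100   508. 173.    232. TRUE
#> 2 non-expanded     100    13    1.24    2  TRUE

classify_disease_range(c(13, 93, 508))
#> [1] "normal"  "disease-causing range"  "beyond range"
```

The father carries a non-expanded allele (13 copies, the reference
count) and a highly variable expansion (median ~508 copies, SD ~173 —
somatic mosaicism) beyond the disease-causing range; the patient's
expansion (~93 copies) falls inside it.

```r
# per-CpG methylation of the father's sample
meth <- sim$reads |>
  filter(sample == "father") |>
  project_sample(sim$reference) |>
  methyl_pileup(min_coverage = 10, combine_strands = TRUE) |>
  call_methylation(mode = "rate")
head(meth, 3)
#> # A tibble: 3 × 10
#>   chrom    pos strand cpg_anchor n_mod n_canon coverage percent p_value status
#> 1 chrSim    20 *              20   182       9      191   0.953      NA methylated
#> 2 chrSim    65 *              65   169      22      191   0.885      NA methylated
#> 3 chrSim   110 *             110   173      13      186   0.930      NA methylated

# multi-sample similarity
counts <- lapply(split(sim$reads, sim$reads$sample), function(r)
  methyl_pileup(project_sample(r, sim$reference),
                min_coverage = 10, combine_strands = TRUE))
pm <- build_percent_matrix(counts)
pairwise_pearson(pm, "mother", "patient")
#> Pairwise methylation correlation: mother vs patient
#>   Pearson's r = 0.998, p-value < 2.2e-16, n = 130 sites
pca_samples(pm)
#> PCA of 3 methylation profiles over 130 CpG sites
#>   variance explained (%): 99.5, 0.5, 0.0
```

Mother and patient share the normal methylation profile (r = 0.998);
the father's heterozygous gain of methylation over the block separates
him on PC1 and in the first Ward bipartition
(`cut_samples(ward_clustering(pm), 2)`).

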