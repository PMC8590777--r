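test_that("identical seeds give identical simulations", {
  cfg <- trio_config(seed = 3,
                     n_reads = c(mother_a1 = 5, mother_a2 = 5,
                                 father_normal = 5, father_expanded = 5,
                                 patient_normal = 5, patient_expanded = 5))
  s1 <- simulate_trio(cfg)
  s2 <- simulate_trio(cfg)
  expect_equal(s1$reads, s2$reads)
  expect_equal(s1$reference, s2$reference)
  expect_equal(s1$truth$reads, s2$truth$reads)
  s3 <- simulate_trio(trio_config(seed = 4, n_reads = cfg$n_reads))
  expect_false(identical(s1$reads$seq, s3$reads$seq))
})

test_that("config validation names the offending field", {
  expect_error(trio_config(p_hi = 1.2), "p_hi",
               class = "replong_validation_error")
  expect_error(trio_config(mosaic_fraction = -0.1), "mosaic_fraction",
               class = "replong_validation_error")
  expect_error(trio_config(n_reads = c(mother_a1 = 5)), "n_reads",
               class = "replong_validation_error")
})

test_that("zero mosaicism leaves every expanded father read hypermethylated", {
  cfg <- trio_config(seed = 5, mosaic_fraction = 0,
                     n_reads = c(mother_a1 = 0, mother_a2 = 0,
                                 father_normal = 0, father_expanded = 30,
                                 patient_normal = 0, patient_expanded = 0))
  sim <- simulate_trio(cfg)
  expect_true(all(sim$truth$reads$pattern == "hyper"))
  expect_false(any(sim$truth$reads$mosaic))
})

test_that("the father's copy distribution reproduces its median at n = 200", {
  cfg <- trio_config(seed = 6,
                     n_reads = c(mother_a1 = 0, mother_a2 = 0,
                                 father_normal = 0, father_expanded = 200,
                                 patient_normal = 0, patient_expanded = 0))
  sim <- simulate_trio(cfg)
  med <- median(sim$truth$reads$true_copies)
  expect_gt(med, 520 - 40)
  expect_lt(med, 520 + 40)
})

test_that("score emission respects its fidelity parameters", {
  withr::local_seed(30)
  all_hi <- emit_mod_scores(rep(TRUE, 200), p_hi = 1)
  expect_true(all(all_hi > 128))
  all_lo <- emit_mod_scores(rep(FALSE, 200), p_lo = 1)
  expect_true(all(all_lo <= 128))
  many <- emit_mod_scores(rep(TRUE, 10000), p_hi = 0.95)
  frac <- mean(many > 128)
  expect_gt(frac, 0.94)
  expect_lt(frac, 0.96)
  expect_equal(emit_mod_scores(logical()), integer())
})

test_that("emitted fixtures parse with the package loaders", {
  sim <- small_trio()
  dir <- withr::local_tempdir()
  write_trio(sim, dir)
  for (person in c("mother", "father", "patient")) {
    tsv <- load_alignments(file.path(dir, paste0(person, ".tsv")))
    sam <- load_alignments(file.path(dir, paste0(person, ".sam")))
    expect_equal(nrow(tsv), sum(sim$reads$sample == person))
    expect_equal(tsv$seq, sam$seq)
    expect_equal(tsv$mod_offsets, sam$mod_offsets)
  }
  ref <- read_reference(file.path(dir, "reference.fa"))
  expect_equal(ref, sim$reference)
  bed <- readr::read_tsv(file.path(dir, "annotations.bed"),
                         col_names = c("chrom", "start", "end", "name"),
                         col_types = "ciic", progress = FALSE)
  expect_setequal(bed$name, c("repeat", "hypermeth_block",
                              "transition_up", "transition_down"))
})

test_that("simulated truth places alleles in the expected disease bands", {
  sim <- small_trio()
  tr <- sim$truth$reads
  pat <- tr$true_copies[tr$sample == "patient" & tr$expanded]
  fat <- tr$true_copies[tr$sample == "father" & tr$expanded]
  expect_equal(unique(classify_disease_range(median(pat))),
               "disease-causing range")
  expect_equal(classify_disease_range(median(fat)), "beyond range")
  mo <- tr$true_copies[tr$sample == "mother"]
  expect_true(all(classify_disease_range(mo) == "normal"))
})

test_that("the scaled trio pipeline recovers phasing and methylation truth", {
  sim <- small_trio()
  calls <- suppressMessages(genotype_repeats(sim$reads, sim$locus))
  ph <- phase_alleles(calls)
  tr <- dplyr::inner_join(ph, sim$truth$reads, by = "read_id")
  expect_gte(mean((tr$allele == "expanded") == tr$expanded), 0.99)
  med <- tr |>
    dplyr::group_by(.data$sample, .data$haplotype) |>
    dplyr::summarise(est = median(.data$abs_copies),
                     truth = median(.data$true_copies), .groups = "drop")
  # the father's broadly mosaic expansion gets a wider band at this
  # reduced read depth (order-statistic gaps scale with SD / n)
  tol <- ifelse(med$sample == "father" & med$haplotype == "expanded",
                5, 2)
  expect_true(all(abs(med$est - med$truth) <= tol))

  # rate calls inside the hypermethylated block on the father's
  # expanded allele agree with per-site truth
  exp_ids <- tr$read_id[tr$sample == "father" & tr$expanded]
  obs <- suppressMessages(project_sample(
    sim$reads[sim$reads$read_id %in% exp_ids, ], sim$reference))
  counts <- methyl_pileup(obs, min_coverage = 20, combine_strands = TRUE)
  mc <- call_methylation(counts, mode = "rate")
  block <- sim$truth$block
  core <- mc[mc$cpg_anchor >= block$first_cpg &
               mc$cpg_anchor <= block$last_cpg, ]
  expect_gte(mean(core$status == "methylated"), 0.99)
})
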