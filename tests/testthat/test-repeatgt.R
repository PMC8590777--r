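# a 340-bp reference with a 39-bp (13-copy) GGC tract at 150..189
rg_ref <- function() {
  withr::with_seed(8, {
    up <- paste(sample(c("A", "T", "G"), 150, replace = TRUE),
                collapse = "")
    down <- paste(sample(c("A", "T", "G"), 151, replace = TRUE),
                  collapse = "")
    setNames(paste0(up, strrep("GGC", 13), down), "rg")
  })
}

rg_locus <- function() repeat_locus("rg", 150, 189, "GGC", 13,
                                    flank_margin = 100)

spanning_read <- function(id, cigar, seq) {
  aligned_reads(id, "rg", 0L, "+", cigar, seq)
}

test_that("copy-number change follows insertion/deletion arithmetic", {
  ref <- rg_ref()
  refseq <- ref[[1]]
  # perfectly reference-matching spanning read
  perfect <- spanning_read("perfect", "340M", refseq)
  # single 240-base insertion inside the tract: +80 copies
  ins_seq <- paste0(substr(refseq, 1, 189), strrep("GGC", 80),
                    substr(refseq, 190, 340))
  ins <- spanning_read("ins240", "189M240I151M", ins_seq)
  # 9-base deletion in the repeat: -3 copies
  del_seq <- paste0(substr(refseq, 1, 160), substr(refseq, 170, 340))
  del <- spanning_read("del9", "160M9D171M", del_seq)
  calls <- genotype_repeats(dplyr::bind_rows(perfect, ins, del),
                            rg_locus())
  expect_equal(calls$rel_change, c(0L, 80L, -3L))
  expect_equal(calls$abs_copies, c(13L, 93L, 10L))
})

test_that("non-spanning reads are rejected and counted", {
  ref <- rg_ref()
  refseq <- ref[[1]]
  short <- aligned_reads("short", "rg", 100L, "+", "60M",
                         substr(refseq, 101, 160))
  full <- spanning_read("full", "340M", refseq)
  expect_message(
    calls <- genotype_repeats(dplyr::bind_rows(short, full), rg_locus()),
    "1 read")
  expect_equal(calls$read_id, "full")
  expect_equal(attr(calls, "n_nonspanning"), 1L)
})

test_that("indels outside the margin window do not count", {
  refseq <- rg_ref()[[1]]
  # 30-base insertion at position 10, far upstream of the margin window
  far_seq <- paste0(substr(refseq, 1, 10), strrep("A", 30),
                    substr(refseq, 11, 340))
  far <- spanning_read("far", "10M30I330M", far_seq)
  calls <- genotype_repeats(far, rg_locus())
  expect_equal(calls$rel_change, 0L)
})

test_that("phasing splits at 50 and is monotone", {
  calls <- tibble::tibble(read_id = paste0("r", 1:6),
                          rel_change = c(49L, 50L, 0L, 0L, 80L, 120L),
                          abs_copies = c(62L, 63L, 13L, 13L, 93L, 133L))
  ph <- phase_alleles(calls)
  expect_equal(ph$allele[1:2], c("non-expanded", "expanded"))
  expect_equal(sum(ph$allele == "expanded"), 3)
  expect_equal(sum(ph$allele == "non-expanded"), 3)
  # all below threshold: expanded group empty
  low <- phase_alleles(dplyr::filter(calls, rel_change < 50))
  expect_equal(unique(low$allele), "non-expanded")
  # monotone: raising a call never moves it out of the expanded group
  for (d in c(1L, 10L, 100L)) {
    up <- phase_alleles(dplyr::mutate(calls, rel_change = rel_change + d))
    expect_true(all(!(ph$allele == "expanded" & up$allele ==
                        "non-expanded")))
  }
  expect_error(phase_alleles(calls[0, ]),
               class = "replong_parameter_error")
})

test_that("allele summaries match closed forms and a brute-force oracle", {
  single <- tibble::tibble(read_id = "a", allele = "expanded",
                           abs_copies = 93L)
  s1 <- allele_summary(single)
  expect_equal(s1$median, 93)
  expect_equal(s1$sd, 0)
  expect_false(s1$sd_defined)
  expect_equal(s1$iqr, 0)

  four <- tibble::tibble(read_id = letters[1:4], allele = "x",
                         abs_copies = c(1, 2, 3, 4))
  s4 <- allele_summary(four)
  expect_equal(s4$median, 2.5)
  expect_equal(s4$sd, sqrt(sum((1:4 - 2.5)^2) / 3))
  expect_equal(s4$iqr, 1.5)

  same <- tibble::tibble(read_id = letters[1:5], allele = "x",
                         abs_copies = rep(7, 5))
  s5 <- allele_summary(same)
  expect_equal(s5$sd, 0)
  expect_equal(s5$iqr, 0)

  withr::local_seed(21)
  for (i in 1:20) {
    vals <- sample(0:700, sample(2:100, 1), replace = TRUE)
    got <- allele_summary(tibble::tibble(
      read_id = as.character(seq_along(vals)), allele = "x",
      abs_copies = vals))
    sv <- sort(vals)
    n <- length(sv)
    med <- if (n %% 2) sv[(n + 1) / 2] else (sv[n / 2] + sv[n / 2 + 1]) / 2
    expect_equal(got$median, med, tolerance = 1e-9)
    expect_equal(got$sd, sqrt(sum((vals - mean(vals))^2) / (n - 1)),
                 tolerance = 1e-9)
    expect_equal(got$iqr,
                 diff(stats::quantile(vals, c(0.25, 0.75), names = FALSE)),
                 tolerance = 1e-9)
  }
  expect_error(allele_summary(single[0, ]),
               class = "replong_parameter_error")
})

test_that("disease-range classification brackets 41-300 inclusively", {
  expect_equal(classify_disease_range(c(13, 40, 41, 140, 300, 301, 522)),
               c("normal", "normal", "disease-causing range",
                 "disease-causing range", "disease-causing range",
                 "beyond range", "beyond range"))
})

test_that("repeat decomposition is greedy, prioritised and lossless", {
  d1 <- decompose_repeat("GGCGGCGGA")
  expect_equal(d1$motif, c("GGC", "GGA"))
  expect_equal(d1$count, c(2L, 1L))
  d2 <- decompose_repeat("GGCGGCGGCGGC")
  expect_equal(d2$motif, "GGC")
  expect_equal(d2$count, 4L)
  ins <- "ACCGAGAAGATGCCCGCCCTGC"
  d3 <- decompose_repeat(paste0("GGC", ins, "GGC"), insertions = ins)
  expect_equal(d3$class, c("unit", "insertion", "unit"))
  expect_equal(d3$motif[2], ins)
  expect_equal(d3$start, c(0L, 3L, 25L))
  # reconstruction identity on random strings
  withr::local_seed(13)
  for (i in 1:500) {
    s <- paste(sample(c("A", "C", "G", "T"), sample(1:60, 1),
                      replace = TRUE), collapse = "")
    d <- decompose_repeat(s, insertions = ins)
    expect_equal(paste(strrep(d$motif, d$count), collapse = ""), s)
    expect_equal(sum(d$length), nchar(s))
  }
  expect_error(decompose_repeat(""), class = "replong_parameter_error")
})

test_that("waterfall tables sort by tract length with correct offsets", {
  seqs <- c(long = strrep("GGC", 100), short = paste0(strrep("GGC", 8),
                                                      "GGA", "GGC"))
  comps <- repeat_compositions(seqs)
  wt <- waterfall_table(comps)
  expect_equal(unique(wt$read_id), c("long", "short"))
  expect_equal(wt$rank[wt$read_id == "long"][1], 1L)
  # offsets are cumulative sums of preceding segment lengths
  short <- wt[wt$read_id == "short", ]
  expect_equal(short$start, c(0L, cumsum(short$length)[-nrow(short)]))
  expect_equal(nrow(waterfall_table(comps[0, ])), 0)
  # the plot builds
  expect_s3_class(plot_waterfall(wt), "ggplot")
})
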