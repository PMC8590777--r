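counts_tbl <- function(n_mod, n_canon, pos = seq_along(n_mod)) {
  tibble::tibble(chrom = "c", pos = as.integer(pos), strand = "*",
                 cpg_anchor = as.integer(pos),
                 n_mod = as.integer(n_mod), n_canon = as.integer(n_canon),
                 coverage = as.integer(n_mod + n_canon))
}

test_that("percent matrix takes the site union and masks low coverage", {
  a <- counts_tbl(c(5, 5, 5, 5, 5, 9), rep(5, 6))
  b <- counts_tbl(c(0, 1, 2, 3, 4), rep(10, 5))
  pm <- build_percent_matrix(list(s1 = a, s2 = b), min_coverage = 10)
  expect_equal(nrow(pm), 6)
  expect_equal(sum(!pm$complete), 1)
  # a cell below min coverage is missing
  low <- counts_tbl(4, 5)
  pm2 <- build_percent_matrix(list(s1 = a, s2 = low), min_coverage = 10)
  expect_true(all(is.na(pm2$s2)))
  # identical inputs produce identical columns
  pm3 <- build_percent_matrix(list(x = a, y = a))
  expect_equal(pm3$x, pm3$y)
  expect_error(build_percent_matrix(list(a)),
               class = "replong_parameter_error")
  expect_error(build_percent_matrix(setNames(list(a, a), c("s", "s"))),
               class = "replong_parameter_error")
})

test_that("pairwise Pearson matches the textbook formula", {
  a <- counts_tbl(c(0, 5, 10, 2), 10 - c(0, 5, 10, 2))
  b <- counts_tbl(c(1, 6, 9, 4), 10 - c(1, 6, 9, 4))
  pm <- build_percent_matrix(list(A = a, B = b), min_coverage = 5)
  mc <- pairwise_pearson(pm, "A", "B")
  x <- 100 * c(0, 5, 10, 2) / 10
  y <- 100 * c(1, 6, 9, 4) / 10
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(mc$estimate, r_hand, tolerance = 1e-12)
  expect_equal(mc$slope,
               sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2))
  # identity and antisymmetry
  expect_equal(pairwise_pearson(pm, "A", "A")$estimate, 1)
  anti_a <- counts_tbl(c(0, 5, 10), c(10, 5, 0))
  anti_b <- counts_tbl(c(10, 5, 0), c(0, 5, 10))
  pm2 <- build_percent_matrix(list(A = anti_a, B = anti_b),
                              min_coverage = 5)
  expect_equal(pairwise_pearson(pm2, "A", "B")$estimate, -1)
  # degenerate inputs error
  flat <- counts_tbl(rep(5, 4), rep(5, 4))
  pmf <- build_percent_matrix(list(A = a, B = flat), min_coverage = 5)
  expect_error(pairwise_pearson(pmf, "A", "B"),
               class = "replong_parameter_error")
  # tidies
  td <- tidy(mc)
  expect_equal(td$estimate, mc$estimate)
  expect_s3_class(autoplot(mc), "ggplot")
})

test_that("PCA separates duplicated sample groups deterministically", {
  withr::local_seed(4)
  hi <- pmin(30L, pmax(0L, as.integer(rnorm(40, 27, 2))))
  lo <- pmin(30L, pmax(0L, as.integer(rnorm(40, 3, 2))))
  grp1 <- counts_tbl(hi, 30 - hi)
  grp2 <- counts_tbl(lo, 30 - lo)
  pm <- build_percent_matrix(
    list(a1 = grp1, a2 = grp1, b1 = grp2, b2 = grp2), min_coverage = 10)
  pc <- pca_samples(pm)
  s <- pc$scores
  expect_lt(max(abs(s$PC1[s$sample %in% c("a1", "a2")] -
                      s$PC1[s$sample == "a1"])), 1e-6)
  gap <- abs(mean(s$PC1[s$sample %in% c("a1", "a2")]) -
               mean(s$PC1[s$sample %in% c("b1", "b2")]))
  expect_gt(gap, 10 * max(abs(s$PC2)))
  expect_lte(sum(pc$var_explained), 100 + 1e-8)
  # identical samples collapse to the origin
  pm_id <- build_percent_matrix(list(x = grp1, y = grp1, z = grp1),
                                min_coverage = 10)
  pc_id <- pca_samples(pm_id)
  expect_lt(max(abs(pc_id$scores$PC1)), 1e-9)
  expect_s3_class(autoplot(pc), "ggplot")
  expect_equal(nrow(tidy(pc)), 4)
})

test_that("Ward clustering has the n = 2 closed form and splits groups", {
  a <- counts_tbl(c(0, 10, 0), c(10, 0, 10))
  b <- counts_tbl(c(10, 0, 10), c(0, 10, 0))
  pm <- build_percent_matrix(list(A = a, B = b), min_coverage = 5)
  mw <- ward_clustering(pm)
  d <- sqrt(sum((c(0, 100, 0) - c(100, 0, 100))^2))
  expect_equal(mw$hclust$height, d)
  # father-like hypermethylated sample separates first
  withr::local_seed(9)
  hi <- counts_tbl(rep(28, 30), rep(2, 30))
  lo <- counts_tbl(rep(2, 30), rep(28, 30))
  pm2 <- build_percent_matrix(
    list(father = hi, mother = lo, patient = lo), min_coverage = 10)
  cl <- cut_samples(ward_clustering(pm2), 2)
  expect_true(cl$cluster[cl$sample == "mother"] ==
                cl$cluster[cl$sample == "patient"])
  expect_false(cl$cluster[cl$sample == "father"] ==
                 cl$cluster[cl$sample == "mother"])
  # identical samples merge at height zero
  pm3 <- build_percent_matrix(list(x = a, y = a, z = a), min_coverage = 5)
  expect_equal(max(ward_clustering(pm3)$hclust$height), 0)
})

test_that("differential bases match the enumeration oracle and BH control", {
  a <- counts_tbl(c(10, 5, 9), c(0, 5, 1))
  b <- counts_tbl(c(0, 5, 8), c(10, 5, 2))
  db <- diff_methyl(a, b, min_coverage = 10)
  expect_equal(db$p_value[2], 1)
  expect_equal(db$p_value[1], enum_fisher(10, 0, 0, 10, "two.sided"),
               tolerance = 1e-9)
  expect_equal(db$p_value[1], 2 / choose(20, 10), tolerance = 1e-9)
  expect_equal(db$meth_diff[1], 100)
  expect_true(all(db$q_value >= db$p_value - 1e-12))
  # q-values are monotone in p-values
  ord <- order(db$p_value)
  expect_true(all(diff(db$q_value[ord]) >= -1e-12))
  expect_error(diff_methyl(a, counts_tbl(1, 1, pos = 99),
                           min_coverage = 10),
               class = "replong_parameter_error")

  # simulated null family: expected false positives at q < 0.01 is <= 1
  withr::local_seed(17)
  n_sites <- 100
  ma <- rbinom(n_sites, 30, 0.3)
  mb <- rbinom(n_sites, 30, 0.3)
  null_db <- diff_methyl(counts_tbl(ma, 30 - ma),
                         counts_tbl(mb, 30 - mb), min_coverage = 10)
  expect_lte(sum(null_db$significant), 1)
})

test_that("feature annotation assigns classes, TSS distance and ties", {
  diffs <- tibble::tibble(
    chrom = "c", pos = c(10L, 30L, 70L), strand = "*",
    cpg_anchor = c(10L, 30L, 70L),
    meth_diff = c(50, -20, 0), p_value = c(1e-5, 0.2, 0.9),
    q_value = c(3e-5, 0.3, 0.9),
    significant = c(TRUE, FALSE, FALSE))
  features <- tibble::tibble(chrom = "c",
                             start = c(0L, 25L), end = c(20L, 40L),
                             name = c("SINE", "LINE"))
  tss <- tibble::tibble(gene = c("B", "A"), chrom = "c",
                        pos1 = c(21L, 41L), strand = c("+", "-"))
  ann <- annotate_features(diffs, features, tss)
  expect_equal(ann$feature_class, c("SINE", "LINE", "none"))
  # site 10 (base 11): distance to B(21,+) = -10; to A(41,-) = -30
  expect_equal(ann$tss_gene[1], "B")
  expect_equal(ann$tss_dist[1], -10)
  # site 30 (base 31): equidistant (10) to both; lexicographic tie -> A
  expect_equal(ann$tss_gene[2], "A")
  expect_equal(ann$tss_dist[2], 10)
  fs <- feature_summary(ann)
  expect_setequal(fs$feature_class, c("SINE", "LINE", "none"))
  expect_equal(fs$n_significant[fs$feature_class == "SINE"], 1L)
})
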