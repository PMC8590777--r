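#' Build a sites-by-samples percent-methylation matrix
#'
#' Takes per-sample site-count tables (from [methyl_pileup()]) and
#' assembles the union of sites with one percent-methylation column per
#' sample (0-100 scale; `NA` where a sample's coverage falls below
#' `min_coverage`). Downstream analyses are complete-case: the
#' `complete` column marks sites observed at sufficient coverage in
#' every sample.
#'
#' @param samples Named list of site-count tibbles (>= 2 samples,
#'   unique names).
#' @param min_coverage Minimum per-sample coverage for a cell
#'   (default 10).
#' @return Tibble: `chrom`, `pos`, `strand`, `cpg_anchor`, one percent
#'   column per sample, `complete`.
#' @export
build_percent_matrix <- function(samples, min_coverage = 10) {
  if (length(samples) < 2) {
    abort("need at least two samples", class = "replong_parameter_error")
  }
  ids <- names(samples)
  if (is.null(ids) || anyDuplicated(ids) || any(!nzchar(ids))) {
    abort("samples must carry unique non-empty names",
          class = "replong_parameter_error")
  }
  long <- bind_rows(lapply(ids, function(id) {
    samples[[id]] |>
      filter(.data$coverage >= min_coverage) |>
      mutate(sample = id,
             percent = 100 * .data$n_mod / .data$coverage) |>
      select("sample", "chrom", "pos", "strand", "cpg_anchor", "percent")
  }))
  wide <- tidyr::pivot_wider(long, names_from = "sample",
                             values_from = "percent") |>
    arrange(.data$chrom, .data$cpg_anchor, .data$pos)
  for (id in setdiff(ids, names(wide))) wide[[id]] <- NA_real_
  wide$complete <- complete.cases(wide[, ids, drop = FALSE])
  attr(wide, "samples") <- ids
  wide
}

matrix_samples <- function(mat) {
  attr(mat, "samples") %||%
    setdiff(names(mat), c("chrom", "pos", "strand", "cpg_anchor",
                          "complete"))
}

complete_matrix <- function(mat) {
  ids <- matrix_samples(mat)
  m <- as.matrix(mat[mat$complete, ids, drop = FALSE])
  if (!nrow(m)) {
    abort("no complete-case sites", class = "replong_parameter_error")
  }
  m
}

#' Pearson correlation of percent methylation between two samples
#'
#' Product-moment correlation over complete-case sites for the pair,
#' with the simple linear-regression line of B on A, the standard
#' pairwise view of sample similarity in methylation profiles.
#'
#' @param mat Percent matrix from [build_percent_matrix()].
#' @param sample_a,sample_b Sample names (columns of `mat`).
#' @return A `methyl_cor` object; see [tidy()][generics::tidy] and
#'   [glance()][generics::glance].
#' @export
pairwise_pearson <- function(mat, sample_a, sample_b) {
  x <- mat[[sample_a]]
  y <- mat[[sample_b]]
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]
  y <- y[keep]
  if (length(x) < 3) {
    abort("need at least 3 complete sites for the pair",
          class = "replong_parameter_error")
  }
  if (sd(x) == 0 || sd(y) == 0) {
    abort("zero variance in a sample; correlation undefined",
          class = "replong_parameter_error")
  }
  ct <- cor.test(x, y, method = "pearson")
  fit <- lm(y ~ x)
  structure(list(sample_a = sample_a, sample_b = sample_b,
                 estimate = unname(ct$estimate), p_value = ct$p.value,
                 n = length(x), intercept = unname(coef(fit)[1]),
                 slope = unname(coef(fit)[2]), x = x, y = y),
            class = "methyl_cor")
}

#' @export
print.methyl_cor <- function(x, ...) {
  cat("Pairwise methylation correlation: ", x$sample_a, " vs ",
      x$sample_b, "\n", sep = "")
  cat(sprintf("  Pearson's r = %.3f, p-value %s, n = %d sites\n",
              x$estimate,
              if (x$p_value < 2.2e-16) "< 2.2e-16"
              else format(x$p_value, digits = 3), x$n))
  cat(sprintf("  regression line: y = %.3f + %.3f x\n",
              x$intercept, x$slope))
  invisible(x)
}

#' @export
tidy.methyl_cor <- function(x, ...) {
  tibble(sample_a = x$sample_a, sample_b = x$sample_b,
         estimate = x$estimate, p.value = x$p_value,
         intercept = x$intercept, slope = x$slope, n = x$n)
}

#' @export
glance.methyl_cor <- function(x, ...) tidy.methyl_cor(x)

#' Principal component analysis of sample methylation profiles
#'
#' Centered (not variance-scaled; percent scales are commensurate) PCA
#' over the complete-case site-by-sample matrix, with samples as
#' observations. Component signs follow a deterministic convention: the
#' largest-magnitude loading of each component is positive.
#'
#' @param mat Percent matrix from [build_percent_matrix()].
#' @return A `methyl_pca` object with `$scores` (tibble: sample,
#'   PC coordinates), `$var_explained` (percent per component) and
#'   `$n_sites`.
#' @export
pca_samples <- function(mat) {
  ids <- matrix_samples(mat)
  if (length(ids) < 3) {
    abort("PCA needs at least 3 samples", class = "replong_parameter_error")
  }
  m <- complete_matrix(mat)
  if (nrow(m) < 2) {
    abort("PCA needs at least 2 complete sites",
          class = "replong_parameter_error")
  }
  pc <- prcomp(t(m), center = TRUE, scale. = FALSE)
  for (k in seq_len(ncol(pc$rotation))) {
    top <- which.max(abs(pc$rotation[, k]))
    if (pc$rotation[top, k] < 0) {
      pc$rotation[, k] <- -pc$rotation[, k]
      pc$x[, k] <- -pc$x[, k]
    }
  }
  tot <- sum(pc$sdev^2)
  ve <- if (tot > 0) 100 * pc$sdev^2 / tot else rep(0, length(pc$sdev))
  scores <- as_tibble(pc$x, .name_repair = "minimal")
  scores <- mutate(scores, sample = ids, .before = 1)
  structure(list(scores = scores, var_explained = ve, n_sites = nrow(m)),
            class = "methyl_pca")
}

#' @export
print.methyl_pca <- function(x, ...) {
  cat("PCA of", nrow(x$scores), "methylation profiles over", x$n_sites,
      "CpG sites\n")
  cat("  variance explained (%):",
      paste(sprintf("%.1f", head(x$var_explained, 4)), collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
tidy.methyl_pca <- function(x, ...) x$scores

#' @export
glance.methyl_pca <- function(x, ...) {
  tibble(n_samples = nrow(x$scores), n_sites = x$n_sites,
         pc1_var = x$var_explained[1],
         pc2_var = if (length(x$var_explained) > 1) x$var_explained[2]
                   else NA_real_)
}

#' Ward hierarchical clustering of sample methylation profiles
#'
#' Agglomerative clustering with the Ward criterion (`ward.D2` on
#' Euclidean distances) over complete-case percent vectors. Samples are
#' ordered by name before clustering so ties resolve deterministically.
#'
#' @param mat Percent matrix from [build_percent_matrix()].
#' @return A `methyl_ward` object wrapping the `hclust` fit.
#' @export
ward_clustering <- function(mat) {
  ids <- sort(matrix_samples(mat))
  if (length(ids) < 2) {
    abort("clustering needs at least 2 samples",
          class = "replong_parameter_error")
  }
  m <- t(complete_matrix(mat))[ids, , drop = FALSE]
  hc <- hclust(dist(m), method = "ward.D2")
  structure(list(hclust = hc, labels = ids), class = "methyl_ward")
}

#' @export
print.methyl_ward <- function(x, ...) {
  cat("Ward clustering of", length(x$labels), "methylation profiles\n")
  cat("  merge heights:",
      paste(sprintf("%.2f", x$hclust$height), collapse = ", "), "\n")
  invisible(x)
}

#' @export
tidy.methyl_ward <- function(x, ...) {
  tibble(step = seq_along(x$hclust$height),
         height = x$hclust$height,
         merge1 = x$hclust$merge[, 1], merge2 = x$hclust$merge[, 2])
}

#' Cut a Ward tree into k groups
#'
#' @param x `methyl_ward` object.
#' @param k Number of groups (default 2, the first bipartition).
#' @return Tibble: `sample`, `cluster`.
#' @export
cut_samples <- function(x, k = 2) {
  cl <- cutree(x$hclust, k = k)
  tibble(sample = x$labels, cluster = unname(cl[x$labels]))
}

#' Per-base differential methylation between two samples
#'
#' For every site covered at `min_coverage` in both samples, a
#' two-sided Fisher's exact test on the 2x2 table of modified/canonical
#' counts, Benjamini-Hochberg q-values across the tested family, and
#' the percent-methylation difference `percent_a - percent_b`.
#'
#' @param counts_a,counts_b Site-count tibbles from [methyl_pileup()].
#' @param min_coverage Per-sample coverage floor (default 10).
#' @param q_cutoff Significance cutoff on the q-value (default 0.01).
#' @return Tibble per shared site: counts, `percent_a`, `percent_b`,
#'   `meth_diff` (percent points), `p_value`, `q_value`, `significant`.
#' @export
diff_methyl <- function(counts_a, counts_b, min_coverage = 10,
                        q_cutoff = 0.01) {
  key <- c("chrom", "pos", "strand", "cpg_anchor")
  a <- filter(counts_a, .data$coverage >= min_coverage)
  b <- filter(counts_b, .data$coverage >= min_coverage)
  shared <- inner_join(a, b, by = key, suffix = c("_a", "_b"))
  if (!nrow(shared)) {
    abort("no shared sites at the required coverage",
          class = "replong_parameter_error")
  }
  p <- map_dbl(seq_len(nrow(shared)), function(i) {
    fisher.test(matrix(c(shared$n_mod_a[i], shared$n_canon_a[i],
                         shared$n_mod_b[i], shared$n_canon_b[i]),
                       nrow = 2, byrow = TRUE))$p.value
  })
  shared |>
    mutate(percent_a = 100 * .data$n_mod_a / .data$coverage_a,
           percent_b = 100 * .data$n_mod_b / .data$coverage_b,
           meth_diff = .data$percent_a - .data$percent_b,
           p_value = p,
           q_value = p.adjust(p, method = "BH"),
           significant = .data$q_value < q_cutoff) |>
    select(dplyr::all_of(key), "n_mod_a", "n_canon_a", "n_mod_b",
           "n_canon_b", "percent_a", "percent_b", "meth_diff",
           "p_value", "q_value", "significant")
}

#' Annotate differential-methylation sites with feature context
#'
#' Assigns each site its covering annotation feature(s) (BED-style
#' 0-based half-open intervals with a class label, e.g. RepeatMasker
#' classes), `"none"` when uncovered, and optionally the signed
#' distance to the nearest transcription start site (negative =
#' upstream of the TSS on the gene's strand; equidistant ties break by
#' lexicographic gene name).
#'
#' @param diffs Tibble from [diff_methyl()].
#' @param features Tibble: `chrom`, `start`, `end`, `name` (class).
#' @param tss Optional tibble: `gene`, `chrom`, `pos1` (1-based TSS),
#'   `strand`.
#' @return `diffs` with `feature_class` (one row per covering feature)
#'   and, when `tss` is given, `tss_gene` and `tss_dist`.
#' @export
annotate_features <- function(diffs, features, tss = NULL) {
  if (!all(c("chrom", "start", "end", "name") %in% names(features))) {
    abort("features must have chrom, start, end, name columns",
          class = "replong_format_error")
  }
  rows <- lapply(seq_len(nrow(diffs)), function(i) {
    pos <- diffs$cpg_anchor[i]
    hit <- features$name[features$chrom == diffs$chrom[i] &
                           features$start <= pos & pos < features$end]
    if (!length(hit)) hit <- "none"
    mutate(diffs[i, ], feature_class = list(hit))
  })
  out <- tidyr::unnest(bind_rows(rows), "feature_class")
  if (!is.null(tss) && nrow(tss)) {
    near <- lapply(seq_len(nrow(out)), function(i) {
      cand <- tss[tss$chrom == out$chrom[i], , drop = FALSE]
      if (!nrow(cand)) {
        return(tibble(tss_gene = NA_character_, tss_dist = NA_real_))
      }
      pos1 <- out$cpg_anchor[i] + 1
      d <- ifelse(cand$strand == "-", cand$pos1 - pos1, pos1 - cand$pos1)
      best <- which(abs(d) == min(abs(d)))
      best <- best[order(cand$gene[best])][1]
      tibble(tss_gene = cand$gene[best], tss_dist = d[best])
    })
    out <- dplyr::bind_cols(out, bind_rows(near))
  }
  out
}

#' Summarise differential methylation per feature class
#'
#' @param annotated Output of [annotate_features()].
#' @return One row per `feature_class`: `n_sites`, `mean_meth_diff`,
#'   `n_significant`.
#' @export
feature_summary <- function(annotated) {
  annotated |>
    group_by(.data$feature_class) |>
    summarise(n_sites = n(),
              mean_meth_diff = mean(.data$meth_diff),
              n_significant = sum(.data$significant),
              .groups = "drop")
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
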