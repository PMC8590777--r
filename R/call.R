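#' Pile CpG observations into per-site modified/canonical counts
#'
#' Each observation is classified with [is_modified()] (score strictly
#' above 128 by default) and tallied per site. Sites are CpG anchors when
#' `combine_strands = TRUE`, otherwise per-strand cytosine positions.
#'
#' @param observations Observation tibble from [project_sample()].
#' @param min_coverage Sites with fewer observations are dropped.
#' @param combine_strands Merge the two strands of a CpG onto its
#'   forward-strand anchor. Default `FALSE` (strand-split).
#' @param threshold Modification-score threshold passed to
#'   [is_modified()].
#' @return Tibble of site counts: `chrom`, `pos` (0-based), `strand`
#'   (`"*"` when combined), `cpg_anchor`, `n_mod`, `n_canon`, `coverage`.
#' @export
methyl_pileup <- function(observations, min_coverage = 1,
                          combine_strands = FALSE,
                          threshold = MOD_THRESHOLD) {
  obs <- mutate(observations, modified = is_modified(.data$score, threshold))
  if (combine_strands) {
    obs <- mutate(obs, pos = .data$cpg_anchor, strand = "*")
  }
  out <- obs |>
    group_by(.data$chrom, .data$pos, .data$strand, .data$cpg_anchor) |>
    summarise(n_mod = sum(.data$modified),
              n_canon = sum(!.data$modified), .groups = "drop") |>
    mutate(coverage = .data$n_mod + .data$n_canon) |>
    filter(.data$coverage >= min_coverage) |>
    arrange(.data$chrom, .data$cpg_anchor, .data$pos)
  out
}

#' Call per-site methylation status
#'
#' Two modes mirror the two calling strategies of the workflow:
#'
#' * `"rate"`: the percent methylation score `n_mod / coverage` is
#'   compared against a cutoff (default 20%); sites at or above the
#'   cutoff are called methylated (the cutoff is the smallest accepted
#'   value). No p-value is produced.
#' * `"fisher"`: a one-sided Fisher's exact test of the site's counts
#'   against a pseudo-count null population with a small error floor
#'   (`null_error` of `null_n` observations modified), encoding the
#'   basecaller's false-positive rate under the null of an unmethylated
#'   site. Sites with `p < alpha` are called methylated.
#'
#' @param counts Site-count tibble from [methyl_pileup()].
#' @param mode `"rate"` or `"fisher"`.
#' @param cutoff Rate-mode percent-methylation cutoff as a fraction
#'   (default 0.20), inclusive.
#' @param null_error,null_n Fisher-mode null population: fraction of
#'   modified observations and its size. Defaults 0.05 and 1000.
#' @param alpha Fisher-mode significance level (default 0.01).
#' @return `counts` with `percent` (fraction, 4 decimals), `p_value`
#'   (`NA` in rate mode) and `status` (`"methylated"`/`"unmethylated"`).
#' @export
call_methylation <- function(counts, mode = c("rate", "fisher"),
                             cutoff = RATE_CUTOFF, null_error = 0.05,
                             null_n = 1000, alpha = 0.01) {
  mode <- match.arg(mode)
  if (any(counts$coverage < 1)) {
    abort("site with zero coverage cannot be called",
          class = "replong_parameter_error")
  }
  out <- mutate(counts,
                percent = round(.data$n_mod / .data$coverage, 4))
  if (mode == "rate") {
    out <- mutate(out,
                  p_value = NA_real_,
                  status = if_else(.data$percent >= cutoff,
                                   "methylated", "unmethylated"))
  } else {
    if (null_error < 0 || null_error >= 1) {
      abort("null_error must lie in [0, 1)",
            class = "replong_parameter_error")
    }
    null_mod <- round(null_error * null_n)
    p <- map_dbl(seq_len(nrow(out)), function(i) {
      tab <- matrix(c(out$n_mod[i], out$n_canon[i],
                      null_mod, null_n - null_mod),
                    nrow = 2, byrow = TRUE)
      fisher.test(tab, alternative = "greater")$p.value
    })
    out <- mutate(out, p_value = p,
                  status = if_else(p < alpha, "methylated", "unmethylated"))
  }
  out
}

#' Export methylation calls in the methylKit per-base dialect
#'
#' Writes the tab-separated per-base format methylKit reads natively:
#' `chrBase chr base strand coverage freqC freqT`, with 1-based
#' positions, strand `F`/`R` (`F` for strand-combined anchors), and
#' `freqC` the percent methylated (`100 * percent`) in fixed 2-decimal
#' format; `freqC + freqT == 100.00` on every row.
#'
#' @param calls Call tibble from [call_methylation()].
#' @param sample_id Sample label (recorded as a comment convention only;
#'   the methylKit format itself is per-file).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
export_methylkit <- function(calls, sample_id, path) {
  con <- tryCatch(file(path, "w"),
                  error = function(e) abort(
                    paste0("cannot write '", path, "'"),
                    class = "replong_io_error"))
  on.exit(close(con))
  writeLines(paste(c("chrBase", "chr", "base", "strand", "coverage",
                     "freqC", "freqT"), collapse = "\t"), con)
  if (nrow(calls)) {
    base1 <- calls$pos + 1L
    freq_c <- round(100 * calls$n_mod / calls$coverage, 2)
    rows <- paste(paste0(calls$chrom, ".", base1), calls$chrom, base1,
                  if_else(calls$strand == "-", "R", "F"),
                  calls$coverage,
                  formatC(freq_c, format = "f", digits = 2),
                  formatC(100 - freq_c, format = "f", digits = 2),
                  sep = "\t")
    writeLines(rows, con)
  }
  invisible(path)
}
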