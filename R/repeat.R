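#' Describe a tandem-repeat locus
#'
#' @param chrom Contig name.
#' @param start,end 0-based half-open reference span of the repeat tract.
#' @param unit Repeat unit motif (default `"GGC"`).
#' @param ref_copies Copies of the unit in the reference (13 at the
#'   GGC locus this workflow was built around).
#' @param flank_margin Bases on either side of the tract within which
#'   alignment indels are attributed to the repeat (default 100).
#' @return One-row locus tibble.
#' @export
repeat_locus <- function(chrom, start, end, unit = "GGC", ref_copies,
                         flank_margin = 100) {
  if (nchar(unit) < 1 || (end - start) < nchar(unit)) {
    abort("locus must span at least one repeat unit",
          class = "replong_parameter_error")
  }
  tibble(chrom = chrom, start = as.integer(start), end = as.integer(end),
         unit = unit, ref_copies = as.integer(ref_copies),
         flank_margin = as.integer(flank_margin))
}

round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Genotype repeat copy number from spanning alignments
#'
#' For each read spanning the locus (including the flank margin on both
#' sides), the net inserted-minus-deleted base count within the
#' margin-expanded tract is divided by the unit length and rounded
#' half-away-from-zero, giving the copy-number change relative to the
#' reference (`rel_change`, the tandem-genotypes-style call) and the
#' absolute copies `abs_copies = rel_change + ref_copies`. Soft-clipped
#' bases never enter the indel sum; non-spanning reads are excluded and
#' counted in the `n_nonspanning` attribute.
#'
#' @param reads Reads tibble.
#' @param locus Locus tibble from [repeat_locus()].
#' @return Tibble with `read_id`, `rel_change`, `abs_copies`.
#' @export
genotype_repeats <- function(reads, locus) {
  w_lo <- locus$start[1] - locus$flank_margin[1]
  w_hi <- locus$end[1] + locus$flank_margin[1]
  unit_len <- nchar(locus$unit[1])
  rows <- vector("list", nrow(reads))
  n_nonspanning <- 0L
  for (i in seq_len(nrow(reads))) {
    if (reads$chrom[i] != locus$chrom[1]) {
      n_nonspanning <- n_nonspanning + 1L
      next
    }
    cig <- parse_cigar(reads$cigar[i])
    rstart <- reads$ref_start[i]
    rend <- rstart + cigar_ref_len(cig)
    if (rstart > w_lo || rend < w_hi) {
      n_nonspanning <- n_nonspanning + 1L
      next
    }
    ins <- 0L
    del <- 0L
    rpos <- rstart
    for (k in seq_along(cig$op)) {
      len <- cig$len[k]
      if (cig$op[k] == "M") {
        rpos <- rpos + len
      } else if (cig$op[k] == "I") {
        if (rpos >= w_lo && rpos <= w_hi) ins <- ins + len
      } else if (cig$op[k] == "D") {
        del <- del + max(0L, min(rpos + len, w_hi) - max(rpos, w_lo))
        rpos <- rpos + len
      }
    }
    rel <- as.integer(round_half_away((ins - del) / unit_len))
    rows[[i]] <- tibble(read_id = reads$read_id[i], rel_change = rel,
                        abs_copies = rel + locus$ref_copies[1])
  }
  if (n_nonspanning > 0) {
    inform(paste0(n_nonspanning,
                  " read(s) do not span the locus and were excluded"))
  }
  out <- bind_rows(rows)
  if (!nrow(out)) {
    out <- tibble(read_id = character(), rel_change = integer(),
                  abs_copies = integer())
  }
  attr(out, "n_nonspanning") <- n_nonspanning
  out
}

#' Phase repeat calls into non-expanded and expanded allele groups
#'
#' Reads with a relative copy-number call below the threshold form the
#' non-expanded group; calls at or above it form the expanded group
#' (`< 50` / `>= 50` under the default), so 50 is the smallest call
#' assigned to the expanded allele.
#'
#' @param calls Tibble from [genotype_repeats()].
#' @param threshold Relative copy-number phasing threshold (default 50).
#' @return `calls` with an `allele` column
#'   (`"non-expanded"`/`"expanded"`).
#' @export
phase_alleles <- function(calls, threshold = PHASE_THRESHOLD) {
  if (!nrow(calls)) {
    abort("no repeat calls to phase", class = "replong_parameter_error")
  }
  mutate(calls, allele = if_else(.data$rel_change >= threshold,
                                 "expanded", "non-expanded"))
}

#' Summarise absolute copy numbers per allele group
#'
#' Median uses the midpoint rule for even n; SD is the sample standard
#' deviation (n - 1 denominator), reported as 0 with `sd_defined =
#' FALSE` for singleton groups; IQR uses linear-interpolation quartiles.
#'
#' @param calls Phased call tibble (needs `allele` and `abs_copies`).
#' @return One row per allele group: `allele`, `n_reads`, `median`,
#'   `sd`, `iqr`, `sd_defined`.
#' @export
allele_summary <- function(calls) {
  if (!nrow(calls)) {
    abort("cannot summarise an empty group",
          class = "replong_parameter_error")
  }
  calls |>
    group_by(.data$allele) |>
    summarise(n_reads = n(),
              median = median(.data$abs_copies),
              sd = if (n() > 1) sd(.data$abs_copies) else 0,
              iqr = IQR(.data$abs_copies),
              sd_defined = n() > 1,
              .groups = "drop")
}

#' Classify an absolute copy number against the disease-causing range
#'
#' Expansions of 41-300 repeat copies are the disease-causing range;
#' shorter alleles are normal and longer ones (the asymptomatic-carrier
#' scale) lie beyond the range.
#'
#' @param abs_copies Integer vector of absolute copy numbers.
#' @param lo,hi Range bounds, inclusive (defaults 41 and 300).
#' @return Character vector: `"normal"`, `"disease-causing range"` or
#'   `"beyond range"`.
#' @export
classify_disease_range <- function(abs_copies, lo = 41, hi = 300) {
  dplyr::case_when(abs_copies < lo ~ "normal",
                   abs_copies <= hi ~ "disease-causing range",
                   TRUE ~ "beyond range")
}

#' Decompose a repeat tract into ordered motif runs
#'
#' Greedy left-to-right scan with category priority: named insertion
#' strings first (longest first), then the repeat unit, then
#' interruption motifs (longest first); anything else becomes a
#' single-base run. Adjacent runs of the same motif are merged, and
#' concatenating the runs reproduces the input exactly (lossless).
#'
#' @param seq Repeat-tract sequence.
#' @param unit Repeat unit motif.
#' @param interruptions Character vector of interruption motifs.
#' @param insertions Character vector of named insertion strings.
#' @return Tibble of runs: `motif`, `class` (`unit`, `interruption`,
#'   `insertion`, `other`), `count`, `start` (0-based base offset),
#'   `length` (bases); attribute `total_len`.
#' @export
decompose_repeat <- function(seq, unit = "GGC", interruptions = c("GGA"),
                             insertions = character()) {
  if (!nzchar(seq)) {
    abort("cannot decompose an empty sequence",
          class = "replong_parameter_error")
  }
  insertions <- insertions[order(-nchar(insertions))]
  interruptions <- interruptions[order(-nchar(interruptions))]
  candidates <- c(insertions, unit, interruptions)
  classes <- c(rep("insertion", length(insertions)), "unit",
               rep("interruption", length(interruptions)))
  lens <- nchar(candidates)
  n <- nchar(seq)
  motif <- character(0)
  class <- character(0)
  count <- integer(0)
  i <- 1L
  while (i <= n) {
    hit <- 0L
    for (k in seq_along(candidates)) {
      if (i + lens[k] - 1L <= n &&
          substr(seq, i, i + lens[k] - 1L) == candidates[k]) {
        hit <- k
        break
      }
    }
    if (hit) {
      m <- candidates[hit]
      cl <- classes[hit]
      step <- lens[hit]
    } else {
      m <- substr(seq, i, i)
      cl <- "other"
      step <- 1L
    }
    j <- length(motif)
    if (j && motif[j] == m && class[j] == cl) {
      count[j] <- count[j] + 1L
    } else {
      motif <- c(motif, m)
      class <- c(class, cl)
      count <- c(count, 1L)
    }
    i <- i + step
  }
  length_b <- count * nchar(motif)
  out <- tibble(motif = motif, class = class, count = count,
                start = c(0L, cumsum(length_b)[-length(length_b)]),
                length = length_b)
  attr(out, "total_len") <- n
  out
}

#' Decompose many repeat tracts
#'
#' @param seqs Named character vector of repeat-tract sequences.
#' @inheritParams decompose_repeat
#' @return Long tibble of runs with `read_id` and `total_len` columns.
#' @export
repeat_compositions <- function(seqs, unit = "GGC",
                                interruptions = c("GGA"),
                                insertions = character()) {
  ids <- names(seqs) %||% as.character(seq_along(seqs))
  bind_rows(lapply(seq_along(seqs), function(i) {
    d <- decompose_repeat(seqs[[i]], unit, interruptions, insertions)
    mutate(d, read_id = ids[i], total_len = attr(d, "total_len"),
           .before = 1)
  }))
}

#' Order repeat compositions for waterfall rendering
#'
#' Rows are sorted by total tract length, longest first, and each run
#' keeps its base offset and length so segments can be drawn as
#' horizontal bars.
#'
#' @param compositions Long tibble from [repeat_compositions()].
#' @return Tibble with a per-read `rank` (1 = longest) plus the run
#'   columns; empty input yields an empty table.
#' @export
waterfall_table <- function(compositions) {
  if (!nrow(compositions)) {
    return(tibble(read_id = character(), rank = integer(),
                  motif = character(), class = character(),
                  start = integer(), length = integer(),
                  total_len = integer()))
  }
  order_tbl <- compositions |>
    distinct(.data$read_id, .data$total_len) |>
    arrange(dplyr::desc(.data$total_len), .data$read_id) |>
    mutate(rank = row_number())
  compositions |>
    inner_join(select(order_tbl, "read_id", "rank"), by = "read_id") |>
    arrange(.data$rank, .data$start) |>
    select("read_id", "rank", "motif", "class", "start", "length",
           "total_len")
}
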