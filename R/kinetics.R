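#' Per-position average replication cycle time for an allele group
#'
#' The replication cycle time of a base is the sum of its inter-pulse
#' duration (IPD) and pulse width, in sequencer frames; slow
#' incorporation over methylated tracts shows up as long cycle times.
#' Reads are expected pre-assigned to an allele (see [phase_alleles()]),
#' with kinetics arrays aligned to allele coordinates: `ipd_fwd`/`pw_fwd`
#' (fi/fp tags) for the forward strand (st = 0), `ipd_rev`/`pw_rev`
#' (ri/rp tags) for the reverse strand (st = 1).
#'
#' @param reads Reads tibble carrying kinetics arrays of length
#'   `allele_len` for the requested strand; reads without arrays for
#'   that strand are ignored.
#' @param allele_len Allele length L in bases.
#' @param strand `"forward"` or `"reverse"`.
#' @param allele Optional allele label recorded in the output.
#' @return Tibble: `allele`, `strand`, `pos` (1..L), `n_reads`,
#'   `cycle_time` (mean IPD + PW in frames; `NA` where no read
#'   contributes), `missing`.
#' @export
kinetics_track <- function(reads, allele_len, strand = c("forward", "reverse"),
                           allele = NA_character_) {
  strand <- match.arg(strand)
  cols <- if (strand == "forward") c("ipd_fwd", "pw_fwd")
          else c("ipd_rev", "pw_rev")
  total <- numeric(allele_len)
  n_used <- 0L
  for (i in seq_len(nrow(reads))) {
    ipd <- reads[[cols[1]]][[i]]
    pw <- reads[[cols[2]]][[i]]
    if (!length(ipd) && !length(pw)) next
    if (length(ipd) != allele_len || length(pw) != allele_len) {
      abort(paste0("read '", reads$read_id[i], "': kinetics arrays have ",
                   "length ", length(ipd), "/", length(pw),
                   ", expected ", allele_len),
            class = "replong_format_error")
    }
    total <- total + ipd + pw
    n_used <- n_used + 1L
  }
  tibble(allele = allele, strand = strand, pos = seq_len(allele_len),
         n_reads = n_used,
         cycle_time = if (n_used) total / n_used else rep(NA_real_,
                                                          allele_len),
         missing = n_used == 0L)
}

#' Cumulative replication cycle time along an allele
#'
#' The cumulative curve at position i is the running sum of the
#' per-position mean cycle times up to i; missing positions are imputed
#' as 0 (the count is reported) so the curve stays defined and
#' non-decreasing.
#'
#' @param track Tibble from [kinetics_track()].
#' @return `track` with a `cumulative` column (frames).
#' @export
cumulative_cycle_time <- function(track) {
  ct <- track$cycle_time
  n_missing <- sum(is.na(ct))
  if (n_missing > 0) {
    warn(paste0(n_missing,
                " position(s) without coverage imputed as 0 frames"))
    ct[is.na(ct)] <- 0
  }
  mutate(track, cumulative = cumsum(ct))
}

#' Estimate the replication rate over an allele window
#'
#' `rate = window bases / (total cycle time in the window / frame_rate)`,
#' in bases per second. The frame rate (frames per second) is a required
#' instrument constant; no default is asserted.
#'
#' @param track Tibble from [kinetics_track()].
#' @param frame_rate Sequencer frame rate in frames/second (> 0).
#' @param window Length-2 vector: 1-based inclusive allele positions.
#' @return Replication rate in bases/second.
#' @export
replication_rate <- function(track, frame_rate, window) {
  if (frame_rate <= 0) {
    abort("frame_rate must be positive", class = "replong_parameter_error")
  }
  if (length(window) != 2 || window[1] > window[2] ||
      window[1] < 1 || window[2] > nrow(track)) {
    abort("window must be an increasing pair within 1..L",
          class = "replong_parameter_error")
  }
  ct <- track$cycle_time[window[1]:window[2]]
  total <- sum(ct, na.rm = TRUE)
  if (total <= 0) {
    abort("total cycle time in window is zero; rate undefined",
          class = "replong_parameter_error")
  }
  (window[2] - window[1] + 1) / (total / frame_rate)
}
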