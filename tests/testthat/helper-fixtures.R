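# Shared miniature fixtures, built once per test run.

# A scaled-down trio for unit tests; the acceptance suite exercises the
# full default configuration.
small_trio <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_trio(trio_config(
        seed = 11,
        n_reads = c(mother_a1 = 20, mother_a2 = 20, father_normal = 25,
                    father_expanded = 25, patient_normal = 25,
                    patient_expanded = 25)))
    }
    cache
  }
})

# A tiny handmade read set over a 12-bp reference with one CpG per strand
hand_reads <- function() {
  aligned_reads(
    read_id = c("fwd1", "fwd2", "rev1"),
    chrom = "mini", ref_start = c(0L, 2L, 0L),
    strand = c("+", "+", "-"),
    cigar = c("12M", "10M", "12M"),
    seq = c("AACGTTAACGTT", "CGTTAACGTT", "AACGTTAACGTT"),
    mod_offsets = list(c(2L, 8L), c(0L, 6L), c(2L, 8L)),
    mod_scores = list(c(200L, 10L), c(255L, 0L), c(50L, 129L)))
}

mini_ref <- function() c(mini = "AACGTTAACGTT")
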