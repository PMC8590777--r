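#' Rewrite reads as in-silico bisulfite conversions
#'
#' Mimics bisulfite chemistry on basecalled long reads so a genome
#' browser's bisulfite mode renders methylation directly: a cytosine
#' whose 5-mC score is 128 or lower is "converted" — written as T for
#' forward reads and (in the reference-oriented stored sequence) as A
#' for reverse reads — while scored methylcytosines (score > 128) are
#' left untouched. Unscored cytosines in read-sense CpG context are
#' treated as score 0 and converted; cytosines outside CpG context and
#' without a score are never touched. Only positions currently holding
#' the expected base are substituted, which makes the operation
#' idempotent.
#'
#' @param reads Reads tibble.
#' @param threshold Scores strictly above this survive conversion.
#' @param convert_unscored Convert unscored read-sense CpG cytosines
#'   (treated as score 0). Default `TRUE`.
#' @return The reads tibble with `seq` replaced by the converted
#'   sequence, the original sequence in `orig_seq`, and a
#'   `conversion_count` column.
#' @export
convert_reads <- function(reads, threshold = MOD_THRESHOLD,
                          convert_unscored = TRUE) {
  out <- reads
  out$orig_seq <- if ("orig_seq" %in% names(reads)) reads$orig_seq
                  else reads$seq
  out$conversion_count <- integer(nrow(reads))
  for (i in seq_len(nrow(reads))) {
    seq <- reads$seq[i]
    L <- nchar(seq)
    strand <- reads$strand[i]
    rs <- read_sense_seq(seq, strand)
    rs_chars <- strsplit(rs, "")[[1]]
    off <- reads$mod_offsets[[i]]
    sco <- reads$mod_scores[[i]]
    convert <- off[sco <= threshold]
    if (convert_unscored) {
      cpg_c <- find_cpg_anchors(rs)
      convert <- union(convert, setdiff(cpg_c, off))
    }
    # substitute only where the read-sense base still is C (idempotence)
    convert <- convert[rs_chars[convert + 1L] == "C"]
    if (length(convert)) {
      stored <- stored_offset(convert, L, strand)
      chars <- strsplit(seq, "")[[1]]
      chars[stored + 1L] <- if (strand == "-") "A" else "T"
      out$seq[i] <- paste(chars, collapse = "")
    }
    out$conversion_count[i] <- length(convert)
  }
  out
}

#' Write converted reads as SAM for browser bisulfite display
#'
#' Emits SAM-dialect records preserving placement and alignment
#' operations. The pre-conversion sequence is retained in the `XO:Z:`
#' auxiliary tag, so the original read is recoverable exactly;
#' modification tags are omitted (the conversion itself now carries the
#' methylation signal).
#'
#' @param converted Output of [convert_reads()].
#' @param path Output `.sam` path.
#' @param ref_lengths Optional named contig lengths for the header.
#' @return `path`, invisibly.
#' @export
write_converted <- function(converted, path, ref_lengths = NULL) {
  stripped <- converted
  stripped$mod_offsets <- rep(list(integer()), nrow(converted))
  stripped$mod_scores <- rep(list(integer()), nrow(converted))
  attr(stripped, "sam_extra_tags") <-
    if (nrow(converted)) paste0("XO:Z:", converted$orig_seq) else character()
  write_sam_file(stripped, path, ref_lengths)
}

#' Recover original sequences from a converted SAM file
#'
#' @param path SAM file written by [write_converted()].
#' @return Reads tibble with `orig_seq` restored from the `XO` tag.
#' @export
load_converted <- function(path) {
  reads <- load_alignments(path)
  extra <- attr(reads, "sam_extra_tags") %||% character(nrow(reads))
  reads$orig_seq <- ifelse(startsWith(extra, "XO:Z:"),
                           sub("^XO:Z:", "", extra), reads$seq)
  reads
}
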