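#' Project one read's modification scores onto reference CpG positions
#'
#' Walks the alignment and emits one observation per scored read-sense
#' cytosine that lands on a match/mismatch column whose *reference*
#' context is CpG on the read's strand. Insertions contribute nothing;
#' scored cytosines aligned over deletions or soft clips are dropped.
#' Reverse-strand cytosines sit opposite a reference G; their observation
#' position is that G's coordinate and the `cpg_anchor` is the
#' forward-strand C one base to the left, so both strands of a CpG share
#' an anchor.
#'
#' @param read One-row reads tibble (see [aligned_reads()]).
#' @param ref Named character vector of reference sequences.
#' @param include_unscored Also emit score-0 observations for reference
#'   CpG match columns the read covers but carries no score for (so a
#'   mismatching or uncalled read base counts as canonical C). Default
#'   `FALSE`: only scored cytosines are reported.
#' @return Tibble of observations: `chrom`, `pos` (0-based, the C on its
#'   own strand), `strand`, `cpg_anchor` (0-based forward-strand C),
#'   `score`, `read_id`, ordered by position.
#' @export
project_read <- function(read, ref, include_unscored = FALSE) {
  chrom <- read$chrom[1]
  if (!chrom %in% names(ref)) {
    abort(paste0("read '", read$read_id[1], "': contig '", chrom,
                 "' not present in reference"),
          class = "replong_alignment_error")
  }
  refseq <- ref[[chrom]]
  refchars <- strsplit(refseq, "")[[1]]
  reflen <- length(refchars)
  cig <- parse_cigar(read$cigar[1])
  if (read$ref_start[1] + cigar_ref_len(cig) > reflen) {
    abort(paste0("read '", read$read_id[1],
                 "': alignment extends past the end of '", chrom, "'"),
          class = "replong_alignment_error")
  }
  refmap <- cigar_ref_map(read$cigar[1], read$ref_start[1])
  L <- nchar(read$seq[1])
  strand <- read$strand[1]

  off <- read$mod_offsets[[1]]
  sco <- read$mod_scores[[1]]
  if (include_unscored) {
    stored_scored <- stored_offset(off, L, strand)
    covered <- which(!is.na(refmap)) - 1L
    unscored <- setdiff(covered, stored_scored)
    # back to read-sense offsets, keeping only read-sense Cs' columns:
    # on the reference the relevant base is C (forward) / G (reverse)
    off <- c(off, stored_offset(unscored, L, strand))
    sco <- c(sco, rep(0L, length(unscored)))
  }
  if (!length(off)) return(empty_observations())

  js <- stored_offset(off, L, strand)
  pos <- refmap[js + 1L]
  keep <- !is.na(pos)
  pos <- pos[keep]
  sco <- sco[keep]
  if (!length(pos)) return(empty_observations())

  if (strand == "+") {
    ok <- refchars[pos + 1L] == "C" & pos + 2L <= reflen &
      refchars[pos + 2L] == "G"
    anchor <- pos
  } else {
    ok <- refchars[pos + 1L] == "G" & pos >= 1L &
      refchars[pmax(pos, 1L)] == "C"
    anchor <- pos - 1L
  }
  out <- tibble(chrom = chrom, pos = pos[ok], strand = strand,
                cpg_anchor = anchor[ok], score = as.integer(sco[ok]),
                read_id = read$read_id[1])
  arrange(out, .data$pos)
}

empty_observations <- function() {
  tibble(chrom = character(), pos = integer(), strand = character(),
         cpg_anchor = integer(), score = integer(), read_id = character())
}

#' Project a sample's reads onto reference CpG positions
#'
#' Concatenates [project_read()] over all reads, optionally clipped to a
#' region. Per-read alignment failures are downgraded to warnings and
#' counted in the `n_failed` attribute.
#'
#' @param reads Reads tibble.
#' @param ref Named character vector of reference sequences.
#' @param region Optional interval tibble; observations with `pos`
#'   outside `[start, end)` are dropped.
#' @inheritParams project_read
#' @return Observation tibble ordered by read, then position.
#' @export
project_sample <- function(reads, ref, region = NULL,
                           include_unscored = FALSE) {
  n_failed <- 0L
  obs <- vector("list", nrow(reads))
  for (i in seq_len(nrow(reads))) {
    obs[[i]] <- tryCatch(
      project_read(reads[i, ], ref, include_unscored = include_unscored),
      replong_alignment_error = function(e) {
        warn(conditionMessage(e))
        n_failed <<- n_failed + 1L
        empty_observations()
      })
  }
  out <- if (length(obs)) bind_rows(obs) else empty_observations()
  if (n_failed > 0) inform(paste0(n_failed, " read(s) failed projection"))
  if (!is.null(region)) {
    out <- filter(out, .data$chrom == region$chrom[1],
                  .data$pos >= region$start[1], .data$pos < region$end[1])
  }
  attr(out, "n_failed") <- n_failed
  out
}

#' Project reads re-aligned against an expansion-allele consensus
#'
#' Identical projection logic with an allele consensus as the reference;
#' reads placed on decoy contigs (homologous regions added to soak up
#' mismapping) are excluded and counted in the `n_decoy` attribute.
#'
#' @param reads Reads tibble already aligned to the consensus + decoys.
#' @param consensus Named length-1 character vector: the allele consensus
#'   sequence (coordinates are allele positions).
#' @param decoys Named character vector of decoy sequences.
#' @inheritParams project_read
#' @return Observation tibble in consensus coordinates.
#' @export
project_against_consensus <- function(reads, consensus,
                                      decoys = character(),
                                      include_unscored = FALSE) {
  if (is.null(names(consensus)) || !nzchar(names(consensus)[1])) {
    names(consensus) <- "consensus"
  }
  cons_name <- names(consensus)[1]
  if (!length(find_cpg_anchors(consensus[[1]]))) {
    warn("consensus sequence contains no CpG; nothing to project")
    out <- empty_observations()
    attr(out, "n_decoy") <- sum(reads$chrom %in% names(decoys))
    return(out)
  }
  n_decoy <- sum(reads$chrom %in% names(decoys))
  on_target <- filter(reads, .data$chrom == cons_name)
  out <- project_sample(on_target, c(consensus, decoys),
                        include_unscored = include_unscored)
  attr(out, "n_decoy") <- n_decoy
  out
}

#' Find CpG anchor coordinates in a sequence
#'
#' @param seq A DNA sequence string.
#' @return 0-based positions of the C of every CpG dinucleotide.
#' @export
find_cpg_anchors <- function(seq) {
  hits <- gregexpr("CG", seq, fixed = TRUE)[[1]]
  if (hits[1] == -1L) integer() else as.integer(hits) - 1L
}
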