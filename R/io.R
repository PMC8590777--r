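#' Convert a modification score to a likelihood fraction
#'
#' Basecallers emit per-cytosine 5-mC likelihoods as integers on a 0-255
#' scale; a score `s` encodes a likelihood of `s/255`. Scores of 255 and
#' 192 correspond to likelihoods of 100% and 75%.
#'
#' @param score Integer vector of modification scores in `[0, 255]`.
#' @return Numeric vector of likelihood fractions in `[0, 1]`.
#' @examples
#' score_to_likelihood(c(0, 192, 255))
#' @export
score_to_likelihood <- function(score) {
  check_mod_score(score)
  score / MOD_SCORE_MAX
}

#' Classify modification scores as modified (5-mC) or canonical
#'
#' A base is called modified when its score is strictly greater than the
#' threshold (default 128, the midpoint of the 0-255 likelihood scale),
#' so 128 itself is the largest score classified canonical.
#'
#' @param score Integer vector of modification scores in `[0, 255]`.
#' @param threshold Scores strictly above this are modified. Default 128.
#' @return Logical vector: `TRUE` for modified (5-mC).
#' @examples
#' is_modified(c(128, 129, 255))
#' @export
is_modified <- function(score, threshold = MOD_THRESHOLD) {
  check_mod_score(score)
  score > threshold
}

check_mod_score <- function(score) {
  if (length(score) && (any(score < 0L | score > MOD_SCORE_MAX, na.rm = TRUE))) {
    abort("modification scores must lie in [0, 255]",
          class = "replong_parameter_error")
  }
  invisible(score)
}

#' Describe a genomic interval
#'
#' Intervals are 0-based half-open internally; user-facing reports and the
#' `chrom:start-end` string form are 1-based inclusive.
#'
#' @param chrom Chromosome / contig name.
#' @param start 0-based inclusive start.
#' @param end Exclusive end; must exceed `start`.
#' @param name Optional label.
#' @return A one-row tibble with columns `chrom`, `start`, `end`, `name`.
#' @examples
#' genomic_interval("chr1", 149389496, 149393469)
#' @export
genomic_interval <- function(chrom, start, end, name = NA_character_) {
  if (any(start >= end)) {
    abort("interval start must be < end", class = "replong_parameter_error")
  }
  tibble(chrom = chrom, start = as.integer(start), end = as.integer(end),
         name = name)
}

#' Parse a 1-based `chrom:start-end` region string
#'
#' @param region String such as `"chr1:149389497-149393469"` (1-based
#'   inclusive, the UCSC convention).
#' @return A one-row interval tibble (0-based half-open).
#' @export
parse_region <- function(region) {
  m <- stringr::str_match(region, "^([^:]+):([0-9,]+)-([0-9,]+)$")
  if (any(is.na(m[, 1]))) {
    abort(paste0("cannot parse region '", region, "'"),
          class = "replong_format_error")
  }
  s <- as.numeric(gsub(",", "", m[, 3]))
  e <- as.numeric(gsub(",", "", m[, 4]))
  genomic_interval(m[, 2], s - 1, e)
}

# ---- CIGAR -----------------------------------------------------------------

parse_cigar <- function(cigar) {
  ops <- stringr::str_match_all(cigar, "([0-9]+)([MIDS=X])")[[1]]
  if (nrow(ops) == 0 || paste0(ops[, 1], collapse = "") != cigar) {
    abort(paste0("malformed CIGAR '", cigar, "'"),
          class = "replong_format_error")
  }
  op <- ops[, 3]
  op[op %in% c("=", "X")] <- "M"
  list(op = op, len = as.integer(ops[, 2]))
}

cigar_read_len <- function(cig) sum(cig$len[cig$op %in% c("M", "I", "S")])
cigar_ref_len <- function(cig) sum(cig$len[cig$op %in% c("M", "D")])

# Per stored-sequence offset (0-based, soft clips included), the 0-based
# reference position it aligns to, or NA for clips and insertions.
cigar_ref_map <- function(cigar, ref_start, read_id = "?") {
  cig <- parse_cigar(cigar)
  out <- rep(NA_integer_, cigar_read_len(cig))
  qpos <- 0L
  rpos <- as.integer(ref_start)
  for (i in seq_along(cig$op)) {
    len <- cig$len[i]
    switch(cig$op[i],
      M = {
        out[qpos + seq_len(len)] <- rpos + seq_len(len) - 1L
        qpos <- qpos + len
        rpos <- rpos + len
      },
      I = , S = {
        qpos <- qpos + len
      },
      D = {
        rpos <- rpos + len
      })
  }
  out
}

# ---- reads tibble ----------------------------------------------------------

KINETICS_COLS <- c("ipd_fwd", "pw_fwd", "ipd_rev", "pw_rev")

empty_reads <- function() {
  tibble(read_id = character(), chrom = character(), ref_start = integer(),
         strand = character(), cigar = character(), seq = character(),
         mod_offsets = list(), mod_scores = list(),
         ipd_fwd = list(), pw_fwd = list(), ipd_rev = list(), pw_rev = list())
}

#' Assemble an alignment table from per-read fields
#'
#' The central container is a tibble with one row per aligned read:
#' placement (`chrom`, 0-based `ref_start`, `strand`, `cigar`), the stored
#' (aligned-orientation) sequence, and list-columns holding read-sense
#' cytosine offsets with their 0-255 modification scores plus optional
#' per-base kinetics arrays (`ipd_fwd`, `pw_fwd`, `ipd_rev`, `pw_rev`,
#' in frames). Modification offsets index the read in its original
#' (basecall) orientation, so for reverse-strand reads offset `k`
#' addresses stored position `length(seq) - 1 - k`.
#'
#' @param read_id,chrom,ref_start,strand,cigar,seq Per-read scalars
#'   (vectorised); `strand` is `"+"` or `"-"`.
#' @param mod_offsets,mod_scores Lists of integer vectors (same lengths
#'   within a read).
#' @param ipd_fwd,pw_fwd,ipd_rev,pw_rev Optional lists of integer arrays,
#'   each of sequence length when present.
#' @return A validated reads tibble.
#' @export
aligned_reads <- function(read_id, chrom, ref_start, strand, cigar, seq,
                          mod_offsets = NULL, mod_scores = NULL,
                          ipd_fwd = NULL, pw_fwd = NULL,
                          ipd_rev = NULL, pw_rev = NULL) {
  n <- length(read_id)
  fill <- function(x) if (is.null(x)) rep(list(integer()), n) else x
  reads <- tibble(
    read_id = read_id, chrom = chrom, ref_start = as.integer(ref_start),
    strand = strand, cigar = cigar, seq = toupper(seq),
    mod_offsets = fill(mod_offsets), mod_scores = fill(mod_scores),
    ipd_fwd = fill(ipd_fwd), pw_fwd = fill(pw_fwd),
    ipd_rev = fill(ipd_rev), pw_rev = fill(pw_rev))
  validate_reads(reads)
}

validate_reads <- function(reads) {
  for (i in seq_len(nrow(reads))) {
    id <- reads$read_id[i]
    cig <- parse_cigar(reads$cigar[i])
    L <- nchar(reads$seq[i])
    if (cigar_read_len(cig) != L) {
      abort(paste0("read '", id, "': CIGAR-consumed length ",
                   cigar_read_len(cig), " != sequence length ", L),
            class = "replong_format_error")
    }
    off <- reads$mod_offsets[[i]]
    sco <- reads$mod_scores[[i]]
    if (length(off) != length(sco)) {
      abort(paste0("read '", id, "': ", length(off),
                   " modification offsets but ", length(sco), " scores"),
            class = "replong_format_error")
    }
    if (length(off)) {
      check_mod_score(sco)
      rs <- read_sense_seq(reads$seq[i], reads$strand[i])
      if (any(off < 0L | off >= L) ||
          any(substring(rs, off + 1L, off + 1L) != "C")) {
        abort(paste0("read '", id,
                     "': modification offset does not address a read-sense C"),
              class = "replong_format_error")
      }
    }
    for (k in KINETICS_COLS) {
      arr <- reads[[k]][[i]]
      if (length(arr) && length(arr) != L) {
        abort(paste0("read '", id, "': kinetics array ", k, " has length ",
                     length(arr), ", expected ", L),
              class = "replong_format_error")
      }
    }
  }
  reads
}

revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(s)))
}

read_sense_seq <- function(seq, strand) {
  if (strand == "-") revcomp(seq) else seq
}

# stored-sequence offset for a read-sense offset
stored_offset <- function(read_sense_off, seq_len, strand) {
  if (strand == "-") seq_len - 1L - read_sense_off else read_sense_off
}

reads_overlap <- function(reads, region) {
  if (is.null(region) || !nrow(reads)) return(reads)
  span <- map_int(reads$cigar, function(cg) cigar_ref_len(parse_cigar(cg)))
  keep <- reads$chrom == region$chrom[1] &
    reads$ref_start < region$end[1] &
    (reads$ref_start + span) > region$start[1]
  reads[keep, , drop = FALSE]
}

# ---- package TSV dialect ---------------------------------------------------

pack_ints <- function(x) map_chr(x, function(v) paste(v, collapse = ","))
unpack_ints <- function(x) {
  map(x, function(v) {
    if (is.na(v) || !nzchar(v)) integer() else as.integer(strsplit(v, ",")[[1]])
  })
}

#' Load aligned reads with modification scores
#'
#' Reads either the package TSV dialect (`.tsv`) or plain-text SAM with
#' MM/ML-style base-modification tags and optional fi/fp/ri/rp kinetics
#' arrays (`.sam`). Unmapped records are skipped; their count is attached
#' as attribute `n_unmapped` and reported via a message.
#'
#' @param path Input file.
#' @param region Optional interval tibble (see [genomic_interval()]);
#'   only reads overlapping it are returned.
#' @return A reads tibble (see [aligned_reads()]).
#' @export
load_alignments <- function(path, region = NULL) {
  if (!file.exists(path)) {
    abort(paste0("cannot read '", path, "'"), class = "replong_io_error")
  }
  reads <- if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    read_sam_file(path)
  } else {
    read_dialect_tsv(path)
  }
  n_unmapped <- attr(reads, "n_unmapped") %||% 0L
  if (n_unmapped > 0) {
    inform(paste0("skipped ", n_unmapped, " unmapped read(s)"))
  }
  out <- reads_overlap(validate_reads(reads), region)
  attr(out, "n_unmapped") <- n_unmapped
  out
}

read_dialect_tsv <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  needed <- c("read_id", "chrom", "ref_start", "strand", "cigar", "seq",
              "mod_offsets", "mod_scores")
  missing <- setdiff(needed, names(tab))
  if (length(missing)) {
    abort(paste0("TSV dialect lacks column(s): ",
                 paste(missing, collapse = ", ")),
          class = "replong_format_error")
  }
  unmapped <- tab$chrom == "*" | is.na(tab$chrom)
  n_unmapped <- sum(unmapped)
  tab <- tab[!unmapped, , drop = FALSE]
  kin <- lapply(KINETICS_COLS, function(k) {
    if (k %in% names(tab)) unpack_ints(tab[[k]])
    else rep(list(integer()), nrow(tab))
  })
  names(kin) <- KINETICS_COLS
  out <- tibble(
    read_id = tab$read_id, chrom = tab$chrom,
    ref_start = as.integer(tab$ref_start), strand = tab$strand,
    cigar = tab$cigar, seq = toupper(tab$seq),
    mod_offsets = unpack_ints(tab$mod_offsets),
    mod_scores = unpack_ints(tab$mod_scores),
    ipd_fwd = kin$ipd_fwd, pw_fwd = kin$pw_fwd,
    ipd_rev = kin$ipd_rev, pw_rev = kin$pw_rev)
  attr(out, "n_unmapped") <- n_unmapped
  out
}

#' Write aligned reads to the package TSV dialect or SAM
#'
#' Format follows the file extension: `.sam` emits SAM-dialect records
#' with MM/ML modification tags (and fi/fp/ri/rp kinetics arrays when
#' present), anything else the package TSV dialect. Round-trips through
#' [load_alignments()] are lossless field-by-field.
#'
#' @param reads Reads tibble.
#' @param path Output file.
#' @param ref_lengths Named integer vector of contig lengths for the SAM
#'   header; inferred from read spans when omitted.
#' @return `path`, invisibly.
#' @export
write_alignments <- function(reads, path, ref_lengths = NULL) {
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    return(write_sam_file(reads, path, ref_lengths))
  }
  tab <- tibble(
    read_id = reads$read_id, chrom = reads$chrom,
    ref_start = reads$ref_start, strand = reads$strand,
    cigar = reads$cigar, seq = reads$seq,
    mod_offsets = pack_ints(reads$mod_offsets),
    mod_scores = pack_ints(reads$mod_scores),
    ipd_fwd = pack_ints(reads$ipd_fwd), pw_fwd = pack_ints(reads$pw_fwd),
    ipd_rev = pack_ints(reads$ipd_rev), pw_rev = pack_ints(reads$pw_rev))
  readr::write_tsv(tab, path, progress = FALSE)
  invisible(path)
}

# ---- SAM dialect -----------------------------------------------------------

# MM tag: delta-encoded count of skipped read-sense Cs between scored Cs.
encode_mm <- function(seq, strand, mod_offsets) {
  rs <- read_sense_seq(seq, strand)
  cpos <- which(strsplit(rs, "")[[1]] == "C") - 1L
  idx <- match(sort(mod_offsets), cpos)
  deltas <- diff(c(-1L, idx - 1L)) - 1L
  paste0("C+m,", paste(deltas, collapse = ","), ";")
}

decode_mm <- function(mm, ml, seq, strand, read_id) {
  m <- stringr::str_match(mm, "^C\\+m[.?]?,([0-9,]*);?$")
  if (is.na(m[1, 1])) {
    abort(paste0("read '", read_id, "': unsupported MM tag '", mm, "'"),
          class = "replong_format_error")
  }
  deltas <- if (nzchar(m[1, 2])) as.integer(strsplit(m[1, 2], ",")[[1]])
            else integer()
  if (length(deltas) != length(ml)) {
    abort(paste0("read '", read_id, "': MM lists ", length(deltas),
                 " positions but ML carries ", length(ml), " scores"),
          class = "replong_format_error")
  }
  rs <- read_sense_seq(seq, strand)
  cpos <- which(strsplit(rs, "")[[1]] == "C") - 1L
  idx <- cumsum(deltas + 1L)
  if (length(idx) && max(idx) > length(cpos)) {
    abort(paste0("read '", read_id, "': MM tag addresses more Cs than ",
                 "the read contains"),
          class = "replong_format_error")
  }
  cpos[idx]
}

sam_b_tag <- function(tag, values, type = "S") {
  paste0(tag, ":B:", type, ",", paste(values, collapse = ","))
}

write_sam_file <- function(reads, path, ref_lengths = NULL) {
  if (is.null(ref_lengths)) {
    ref_lengths <- integer()
    for (i in seq_len(nrow(reads))) {
      cg <- parse_cigar(reads$cigar[i])
      end <- reads$ref_start[i] + cigar_ref_len(cg)
      cur <- ref_lengths[reads$chrom[i]]
      if (is.na(cur) || is.null(cur) || !length(cur) || cur < end) {
        ref_lengths[reads$chrom[i]] <- end
      }
    }
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unsorted", con)
  for (nm in names(ref_lengths)) {
    writeLines(paste0("@SQ\tSN:", nm, "\tLN:", ref_lengths[[nm]]), con)
  }
  for (i in seq_len(nrow(reads))) {
    flag <- if (reads$strand[i] == "-") 16L else 0L
    fields <- c(reads$read_id[i], flag, reads$chrom[i],
                reads$ref_start[i] + 1L, 60L, reads$cigar[i],
                "*", 0L, 0L, reads$seq[i], "*")
    off <- reads$mod_offsets[[i]]
    if (length(off)) {
      ord <- order(off)
      fields <- c(fields,
                  paste0("MM:Z:", encode_mm(reads$seq[i], reads$strand[i], off)),
                  sam_b_tag("ML", reads$mod_scores[[i]][ord], "C"))
    }
    kin_tag <- c(ipd_fwd = "fi", pw_fwd = "fp", ipd_rev = "ri", pw_rev = "rp")
    for (k in names(kin_tag)) {
      arr <- reads[[k]][[i]]
      if (length(arr)) fields <- c(fields, sam_b_tag(kin_tag[[k]], arr, "S"))
    }
    extra <- attr(reads, "sam_extra_tags")
    if (!is.null(extra) && nzchar(extra[i])) fields <- c(fields, extra[i])
    writeLines(paste(fields, collapse = "\t"), con)
  }
  invisible(path)
}

read_sam_file <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  rows <- vector("list", length(lines))
  extra <- character(length(lines))
  n_unmapped <- 0L
  j <- 0L
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 11) {
      abort("SAM record with fewer than 11 fields",
            class = "replong_format_error")
    }
    flag <- as.integer(f[2])
    if (bitwAnd(flag, 4L) == 4L || f[3] == "*") {
      n_unmapped <- n_unmapped + 1L
      next
    }
    strand <- if (bitwAnd(flag, 16L) == 16L) "-" else "+"
    tags <- if (length(f) > 11) f[12:length(f)] else character()
    get_tag <- function(tag) {
      hit <- tags[startsWith(tags, paste0(tag, ":"))]
      if (length(hit)) sub("^..:[^:]+:", "", hit[1]) else NA_character_
    }
    seq <- toupper(f[10])
    ml_raw <- get_tag("ML")
    ml <- if (is.na(ml_raw)) integer()
          else as.integer(strsplit(sub("^C,", "", ml_raw), ",")[[1]])
    mm_raw <- get_tag("MM")
    off <- integer()
    if (!is.na(mm_raw)) {
      off <- decode_mm(mm_raw, ml, seq, strand, f[1])
    } else if (length(ml)) {
      abort(paste0("read '", f[1], "': ML tag without MM tag"),
            class = "replong_format_error")
    }
    kin <- lapply(c(ipd_fwd = "fi", pw_fwd = "fp",
                    ipd_rev = "ri", pw_rev = "rp"), function(tg) {
      raw <- get_tag(tg)
      if (is.na(raw)) integer()
      else as.integer(strsplit(sub("^[cCsSiIf],", "", raw), ",")[[1]])
    })
    orig <- tags[startsWith(tags, "XO:Z:")]
    j <- j + 1L
    extra[j] <- if (length(orig)) orig[1] else ""
    rows[[j]] <- tibble(
      read_id = f[1], chrom = f[3], ref_start = as.integer(f[4]) - 1L,
      strand = strand, cigar = f[6], seq = seq,
      mod_offsets = list(off), mod_scores = list(ml),
      ipd_fwd = list(kin$ipd_fwd), pw_fwd = list(kin$pw_fwd),
      ipd_rev = list(kin$ipd_rev), pw_rev = list(kin$pw_rev))
  }
  out <- if (j) bind_rows(rows[seq_len(j)]) else empty_reads()
  attr(out, "n_unmapped") <- n_unmapped
  attr(out, "sam_extra_tags") <- extra[seq_len(j)]
  out
}

# ---- reference and annotations --------------------------------------------

#' Read a FASTA reference into a named character vector
#'
#' @param path FASTA file.
#' @return Named character vector of upper-case sequences.
#' @export
read_reference <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("cannot read '", path, "'"), class = "replong_io_error")
  }
  ss <- Biostrings::readDNAStringSet(path)
  setNames(toupper(as.character(ss)),
           sub("\\s.*$", "", names(ss)))
}

#' Write named sequences to FASTA
#'
#' @param seqs Named character vector.
#' @param path Output file.
#' @export
write_reference <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Read a BED annotation file as a tibble
#'
#' BED is 0-based half-open; coordinates are kept that way. Requires the
#' rtracklayer package.
#'
#' @param path BED file.
#' @return Tibble with `chrom`, `start`, `end`, `name` (feature class).
#' @export
read_bed <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    abort("read_bed() requires the rtracklayer package",
          class = "replong_io_error")
  }
  gr <- as.data.frame(rtracklayer::import(path, format = "BED"))
  tibble(chrom = as.character(gr$seqnames),
         start = as.integer(gr$start) - 1L,
         end = as.integer(gr$end),
         name = if ("name" %in% names(gr)) gr$name else NA_character_)
}
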