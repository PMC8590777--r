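# Independent oracles the implementation is checked against.

# Brute-force projection: explicitly renders the read-to-reference column
# map one base at a time, then scans scored read-sense cytosines for
# reference CpG context. Shares no code with project_read().
brute_project <- function(read, ref) {
  refchars <- strsplit(ref[[read$chrom]], "")[[1]]
  ops <- regmatches(read$cigar, gregexpr("[0-9]+[MIDS=X]", read$cigar))[[1]]
  L <- nchar(read$seq)
  col <- rep(NA_integer_, L)
  qp <- 0L
  rp <- read$ref_start
  for (o in ops) {
    len <- as.integer(sub("[MIDS=X]", "", o))
    type <- sub("[0-9]+", "", o)
    for (k in seq_len(len)) {
      if (type %in% c("M", "=", "X")) {
        col[qp + 1L] <- rp
        qp <- qp + 1L
        rp <- rp + 1L
      } else if (type %in% c("I", "S")) {
        qp <- qp + 1L
      } else {
        rp <- rp + 1L
      }
    }
  }
  rows <- list()
  off <- read$mod_offsets[[1]]
  sco <- read$mod_scores[[1]]
  for (i in seq_along(off)) {
    j <- if (read$strand == "-") L - 1L - off[i] else off[i]
    r <- col[j + 1L]
    if (is.na(r)) next
    if (read$strand == "+") {
      if (refchars[r + 1L] == "C" && r + 2L <= length(refchars) &&
          refchars[r + 2L] == "G") {
        rows[[length(rows) + 1L]] <-
          data.frame(pos = r, cpg_anchor = r, score = sco[i])
      }
    } else {
      if (refchars[r + 1L] == "G" && r >= 1L && refchars[r] == "C") {
        rows[[length(rows) + 1L]] <-
          data.frame(pos = r, cpg_anchor = r - 1L, score = sco[i])
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows)
         else data.frame(pos = integer(), cpg_anchor = integer(),
                         score = integer())
  out[order(out$pos, out$score), , drop = FALSE]
}

# Exact hypergeometric tail / two-sided probability by direct enumeration
# over the 2x2 table support, using log-binomial coefficients only.
enum_fisher <- function(a, b, c, d, alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  row1 <- a + b
  row2 <- c + d
  col1 <- a + c
  n <- row1 + row2
  support <- max(0L, col1 - row2):min(row1, col1)
  logp <- lchoose(row1, support) + lchoose(row2, col1 - support) -
    lchoose(n, col1)
  p <- exp(logp)
  if (alternative == "greater") {
    sum(p[support >= a])
  } else {
    p_obs <- p[support == a]
    sum(p[p <= p_obs * (1 + 1e-7)])
  }
}

# Random toy alignment over a small reference; returns a one-row reads
# tibble with a consistent sequence for its CIGAR.
random_toy_read <- function(ref, chrom = names(ref)[1], id = "toy") {
  refchars <- strsplit(ref[[chrom]], "")[[1]]
  reflen <- length(refchars)
  start <- sample(0:(reflen - 15L), 1)
  ops <- c("M")
  lens <- c(sample(3:6, 1))
  rp <- start + lens[1]
  while (rp < reflen - 6L && length(ops) < 8L && runif(1) < 0.75) {
    op <- sample(c("M", "I", "D"), 1, prob = c(0.6, 0.2, 0.2))
    if (op == ops[length(ops)]) op <- "M"
    len <- sample(1:4, 1)
    if (op != "I") {
      len <- min(len, reflen - 6L - rp)
      if (len < 1L) break
      rp <- rp + len
    }
    ops <- c(ops, op)
    lens <- c(lens, len)
  }
  if (ops[length(ops)] != "M") {
    ops <- c(ops, "M")
    lens <- c(lens, sample(2:5, 1))
    rp <- rp + lens[length(lens)]
  }
  if (rp > reflen) {
    lens[length(lens)] <- lens[length(lens)] - (rp - reflen)
    rp <- reflen
  }
  if (runif(1) < 0.3) {
    ops <- c("S", ops)
    lens <- c(sample(1:3, 1), lens)
  }
  if (runif(1) < 0.3) {
    ops <- c(ops, "S")
    lens <- c(lens, sample(1:3, 1))
  }
  seq_chars <- character(0)
  rp <- start
  for (k in seq_along(ops)) {
    if (ops[k] == "M") {
      chunk <- refchars[rp + seq_len(lens[k])]
      mism <- runif(lens[k]) < 0.1
      chunk[mism] <- sample(c("A", "C", "G", "T"), sum(mism),
                            replace = TRUE)
      seq_chars <- c(seq_chars, chunk)
      rp <- rp + lens[k]
    } else if (ops[k] %in% c("I", "S")) {
      seq_chars <- c(seq_chars, sample(c("A", "C", "G", "T"), lens[k],
                                       replace = TRUE))
    } else {
      rp <- rp + lens[k]
    }
  }
  seq <- paste(seq_chars, collapse = "")
  strand <- sample(c("+", "-"), 1)
  rs <- if (strand == "-") {
    paste(rev(chartr("ACGT", "TGCA", seq_chars)), collapse = "")
  } else {
    seq
  }
  cpos <- which(strsplit(rs, "")[[1]] == "C") - 1L
  n_score <- min(length(cpos), sample(0:4, 1))
  off <- sort(cpos[sample.int(length(cpos), n_score)])
  aligned_reads(id, chrom, start, strand,
                paste0(lens, ops, collapse = ""), seq,
                mod_offsets = list(as.integer(off)),
                mod_scores = list(sample(0:255, n_score, replace = TRUE)))
}

toy_reference <- function(len = 50, seed = NULL) {
  chars <- sample(c("A", "C", "G", "T"), len, replace = TRUE,
                  prob = c(0.2, 0.3, 0.3, 0.2))
  setNames(paste(chars, collapse = ""), "toyref")
}
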