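#' Configure a synthetic patient-parents trio
#'
#' The generator emulates the study conditions at a GGC-repeat locus:
#' a mother with two non-expanded alleles (~13 copies, the reference
#' count), a father carrying one non-expanded allele and one extremely
#' long, somatically unstable expansion (median ~520 copies, SD ~170)
#' that is hypermethylated en bloc over the repeat plus ~700 bp upstream
#' and ~1,000 bp downstream, with a fraction of expanded molecules left
#' unmethylated (epigenetic mosaicism), and a patient who inherited a
#' contracted, disease-range expansion (median ~93 copies, SD ~10) that
#' keeps the normal, unmethylated profile. Normal-pattern alleles are
#' methylated distally, unmethylated over the block, and mosaic
#' (per-read Bernoulli) at bilateral transitional-zone CpGs (4 upstream,
#' 8 downstream). GGA interruption units sit as a fixed block at the 3'
#' end of the pure-GGC stretch, constant across reads of a haplotype.
#'
#' @param seed Integer seed; fully determines the simulation.
#' @param flank_len Reference flank on each side of the repeat (bp).
#' @param core_up,core_down Extent of the differential methylation block
#'   upstream/downstream of the repeat tract (bp).
#' @param n_transition_up,n_transition_down Transitional-zone CpG counts
#'   just outside the block.
#' @param transition_p Per-read methylation probability at transitional
#'   CpGs on normal-pattern alleles.
#' @param p_hi,p_lo Score-emission fidelities: probability that a
#'   methylated (resp. unmethylated) CpG draws a score above (resp. at
#'   or below) 128.
#' @param sub_rate,ins_rate,del_rate Per-base read error rates.
#' @param mosaic_fraction Fraction of the father's expanded reads left
#'   unmethylated.
#' @param father_bimodal Model the father's expansion as a 50/50 mixture
#'   of ~230 and ~580 copy populations instead of one truncated normal.
#' @param n_reads Named vector: reads per haplotype for
#'   `mother_a1/a2`, `father_normal/expanded`, `patient_normal/expanded`.
#' @param insertion Optional named insertion motif placed at the 3' end
#'   of the patient+father repeat tract (e.g.
#'   `"ACCGAGAAGATGCCCGCCCTGC"`); `NULL` for none.
#' @param kin_baseline,kin_slowdown,kin_frame_rate,kin_reads Kinetics:
#'   baseline replication cycle time (frames/base), its multiplier over
#'   the methylated repeat tract, the frame rate (frames/s) and reads
#'   per allele for the kinetics fixture.
#' @return A `trio_config` list.
#' @export
trio_config <- function(seed = 1,
                        flank_len = 2000,
                        core_up = 700, core_down = 1000,
                        n_transition_up = 4, n_transition_down = 8,
                        transition_p = 0.5,
                        p_hi = 0.95, p_lo = 0.95,
                        sub_rate = 0.03, ins_rate = 0.02, del_rate = 0.02,
                        mosaic_fraction = 0.1,
                        father_bimodal = FALSE,
                        n_reads = c(mother_a1 = 80, mother_a2 = 80,
                                    father_normal = 100,
                                    father_expanded = 100,
                                    patient_normal = 100,
                                    patient_expanded = 100),
                        insertion = NULL,
                        kin_baseline = 50, kin_slowdown = 2.2,
                        kin_frame_rate = 100, kin_reads = 25) {
  cfg <- list(seed = as.integer(seed), chrom = "chrSim",
              unit = "GGC", ref_copies = 13L,
              flank_len = flank_len, core_up = core_up,
              core_down = core_down,
              n_transition_up = n_transition_up,
              n_transition_down = n_transition_down,
              transition_p = transition_p,
              p_hi = p_hi, p_lo = p_lo,
              sub_rate = sub_rate, ins_rate = ins_rate,
              del_rate = del_rate,
              mosaic_fraction = mosaic_fraction,
              father_bimodal = father_bimodal,
              n_reads = n_reads, insertion = insertion,
              kin_baseline = kin_baseline, kin_slowdown = kin_slowdown,
              kin_frame_rate = kin_frame_rate, kin_reads = kin_reads,
              haplotypes = tibble(
                person = c("mother", "mother", "father", "father",
                           "patient", "patient"),
                haplotype = c("a1", "a2", "normal", "expanded",
                              "normal", "expanded"),
                copies_median = c(13, 13, 13, 520, 13, 93),
                copies_sd = c(0.7, 0.7, 0.7, 170, 0.7, 10),
                pattern = c("normal", "normal", "normal", "hyper",
                            "normal", "normal"),
                gga_units = c(0L, 0L, 0L, 2L, 0L, 2L)))
  validate_trio_config(cfg)
}

validate_trio_config <- function(cfg) {
  probs <- c(transition_p = cfg$transition_p, p_hi = cfg$p_hi,
             p_lo = cfg$p_lo, sub_rate = cfg$sub_rate,
             ins_rate = cfg$ins_rate, del_rate = cfg$del_rate,
             mosaic_fraction = cfg$mosaic_fraction)
  bad <- names(probs)[probs < 0 | probs > 1]
  if (length(bad)) {
    abort(paste0("config field(s) out of [0, 1]: ",
                 paste(bad, collapse = ", ")),
          class = "replong_validation_error")
  }
  expected <- c("mother_a1", "mother_a2", "father_normal",
                "father_expanded", "patient_normal", "patient_expanded")
  if (!all(expected %in% names(cfg$n_reads)) || any(cfg$n_reads < 0)) {
    abort("config field n_reads must name all six haplotypes with ≥ 0",
          class = "replong_validation_error")
  }
  if (any(cfg$haplotypes$copies_sd < 0) ||
      any(cfg$haplotypes$copies_median < 0)) {
    abort("config field haplotypes: copy distributions must be ≥ 0",
          class = "replong_validation_error")
  }
  structure(cfg, class = "trio_config")
}

#' Draw modification scores for CpG methylation states
#'
#' Methylated CpGs emit scores above 128 with probability `p_hi`
#' (uniform over 129-255), unmethylated CpGs scores at or below 128
#' with probability `p_lo` (uniform over 0-128); the remainder are
#' emission errors on the opposite side of the threshold.
#'
#' @param state Logical vector: `TRUE` = methylated.
#' @param p_hi,p_lo Emission fidelities (default 0.95 each).
#' @return Integer vector of scores in `[0, 255]`.
#' @export
emit_mod_scores <- function(state, p_hi = 0.95, p_lo = 0.95) {
  n <- length(state)
  if (!n) return(integer())
  draw_hi <- ifelse(state, runif(n) < p_hi, runif(n) >= p_lo)
  ifelse(draw_hi,
         sample(129:255, n, replace = TRUE),
         sample(0:128, n, replace = TRUE))
}

# CG-free random background sequence
random_backbone <- function(n) {
  s <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  idx <- which(s[-n] == "C" & s[-1] == "G")
  if (length(idx)) s[idx + 1L] <- "A"
  s
}

build_reference <- function(cfg) {
  fl <- cfg$flank_len
  rep_len <- 3L * cfg$ref_copies
  up <- random_backbone(fl)
  down <- random_backbone(fl)
  # plant CpGs: sparse distal, dense over the differential block
  plant <- function(chars, positions) {
    chars[positions + 1L] <- "C"
    chars[positions + 2L] <- "G"
    chars
  }
  up_distal <- seq(20L, fl - cfg$core_up - 30L, by = 45L)
  up_core <- seq(fl - cfg$core_up + 10L, fl - 20L, by = 25L)
  up <- plant(up, c(up_distal, up_core))
  down_core <- seq(15L, cfg$core_down - 20L, by = 25L)
  down_distal <- seq(cfg$core_down + 10L, fl - 20L, by = 45L)
  down <- plant(down, c(down_core, down_distal))
  refseq <- paste0(paste(up, collapse = ""),
                   strrep(cfg$unit, cfg$ref_copies),
                   paste(down, collapse = ""))
  repeat_start <- fl
  repeat_end <- fl + rep_len
  core_start <- repeat_start - cfg$core_up
  core_end <- repeat_end + cfg$core_down
  anchors <- find_cpg_anchors(refseq)
  up_trans <- tail(anchors[anchors < core_start], cfg$n_transition_up)
  down_trans <- head(anchors[anchors >= core_end], cfg$n_transition_down)
  zone <- dplyr::case_when(
    anchors %in% up_trans ~ "transition_up",
    anchors %in% down_trans ~ "transition_down",
    anchors >= repeat_start & anchors < repeat_end ~ "repeat",
    anchors >= core_start & anchors < core_end ~ "core",
    TRUE ~ "distal")
  list(refseq = refseq,
       cpgs = tibble(anchor = anchors, zone = zone),
       repeat_start = repeat_start, repeat_end = repeat_end,
       core_start = core_start, core_end = core_end)
}

zone_lookup <- function(ref) {
  z <- setNames(ref$cpgs$zone, as.character(ref$cpgs$anchor))
  function(anchor) unname(z[as.character(anchor)])
}

# methylation truth per CpG zone for one read
zone_state <- function(zones, pattern, transition_p) {
  if (pattern == "hyper") return(rep(TRUE, length(zones)))
  ifelse(zones == "distal", TRUE,
         ifelse(zones %in% c("transition_up", "transition_down"),
                runif(length(zones)) < transition_p,
                FALSE))
}

# one simulated read: error-injected sequence, CIGAR, scored CpGs
simulate_read <- function(cfg, ref, tract, pattern, read_id, strand) {
  fl <- cfg$flank_len
  rep_ref_len <- 3L * cfg$ref_copies
  tract_len <- nchar(tract)
  allele <- paste0(substr(ref$refseq, 1, fl), tract,
                   substr(ref$refseq, fl + rep_ref_len + 1,
                          nchar(ref$refseq)))
  La <- nchar(allele)
  chars <- strsplit(allele, "")[[1]]
  m_in_tract <- min(tract_len, rep_ref_len)
  op_allele <- c(rep("M", fl), rep("M", m_in_tract),
                 rep("I", max(0L, tract_len - rep_ref_len)),
                 rep("M", fl))
  shift <- tract_len - rep_ref_len

  del <- runif(La) < cfg$del_rate
  kept <- !del
  sub <- kept & (runif(La) < cfg$sub_rate)
  ins <- runif(La) < cfg$ins_rate
  read_chars <- chars
  if (any(sub)) {
    read_chars[sub] <- vapply(chars[sub], function(b) {
      sample(setdiff(c("A", "C", "G", "T"), b), 1)
    }, "")
  }
  read_chars[del] <- NA_character_
  ins_chars <- ifelse(ins, sample(c("A", "C", "G", "T"), La,
                                  replace = TRUE), NA_character_)
  interleaved <- as.vector(rbind(read_chars, ins_chars))
  read_seq <- paste(interleaved[!is.na(interleaved)], collapse = "")

  base_ops <- ifelse(del, ifelse(op_allele == "M", "D", NA_character_),
                     op_allele)
  ins_ops <- ifelse(ins, "I", NA_character_)
  ops <- as.vector(rbind(base_ops, ins_ops))
  if (tract_len < rep_ref_len) {
    # contracted tract: unaligned reference repeat bases are a deletion
    at <- 2L * (fl + m_in_tract)
    ops <- append(ops, rep("D", rep_ref_len - tract_len), after = at)
  }
  ops <- ops[!is.na(ops)]
  ref_start <- 0L
  while (length(ops) && ops[1] == "D") {
    ref_start <- ref_start + 1L
    ops <- ops[-1]
  }
  while (length(ops) && ops[length(ops)] == "D") ops <- ops[-length(ops)]
  r <- rle(ops)
  cigar <- paste0(r$lengths, r$values, collapse = "")

  # read offset of each surviving allele base (0-based, stored orientation)
  contrib <- as.integer(kept) + as.integer(ins)
  before <- c(0L, cumsum(contrib)[-La])
  off_of <- ifelse(kept, before, NA_integer_)

  # scored CpGs: forward reads score the C, reverse reads the opposite-
  # strand C (the stored G one base right of the anchor)
  cpg <- find_cpg_anchors(allele)
  zones <- ifelse(cpg < fl, zone_lookup_vec(ref, cpg),
                  ifelse(cpg < fl + tract_len, "repeat",
                         zone_lookup_vec(ref, cpg - shift)))
  zones[is.na(zones)] <- "core"  # boundary CpGs created by the tract edge
  state <- zone_state(zones, pattern, cfg$transition_p)
  target <- if (strand == "+") cpg else cpg + 1L
  want_base <- if (strand == "+") "C" else "G"
  valid <- target < La & kept[target + 1L] & !sub[target + 1L] &
    chars[target + 1L] == want_base
  stored_off <- off_of[target[valid] + 1L]
  scores <- emit_mod_scores(state[valid], cfg$p_hi, cfg$p_lo)
  L_read <- nchar(read_seq)
  mod_off <- if (strand == "+") stored_off else L_read - 1L - stored_off
  ord <- order(mod_off)

  list(read = tibble(read_id = read_id, chrom = cfg$chrom,
                     ref_start = ref_start, strand = strand,
                     cigar = cigar, seq = read_seq,
                     mod_offsets = list(as.integer(mod_off[ord])),
                     mod_scores = list(as.integer(scores[ord])),
                     ipd_fwd = list(integer()), pw_fwd = list(integer()),
                     ipd_rev = list(integer()), pw_rev = list(integer())),
       truth_cpg = tibble(read_id = read_id,
                          allele_anchor = cpg, zone = zones,
                          methylated = state))
}

zone_lookup_vec <- function(ref, anchors) {
  z <- setNames(ref$cpgs$zone, as.character(ref$cpgs$anchor))
  unname(z[as.character(anchors)])
}

draw_copies <- function(cfg, hap, n) {
  if (hap$person == "father" && hap$haplotype == "expanded" &&
      cfg$father_bimodal) {
    comp <- sample(c(230, 580), n, replace = TRUE)
    return(pmax(0L, as.integer(round(rnorm(n, comp, 40)))))
  }
  pmax(0L, as.integer(round(rnorm(n, hap$copies_median, hap$copies_sd))))
}

build_tract <- function(cfg, copies, gga_units, with_insertion) {
  gga <- min(gga_units, copies)
  tract <- paste0(strrep("GGC", copies - gga), strrep("GGA", gga))
  if (with_insertion && !is.null(cfg$insertion)) {
    tract <- paste0(tract, cfg$insertion)
  }
  tract
}

simulate_kinetics <- function(cfg, ref) {
  haps <- list(
    `non-expanded` = cfg$ref_copies,
    expanded = cfg$haplotypes$copies_median[
      cfg$haplotypes$person == "father" &
        cfg$haplotypes$haplotype == "expanded"])
  out <- vector("list", 0)
  alleles <- vector("list", 0)
  for (lab in names(haps)) {
    copies <- haps[[lab]]
    tract_len <- 3L * copies
    L <- 2L * cfg$flank_len + tract_len
    mean_cycle <- rep(cfg$kin_baseline, L)
    if (lab == "expanded") {
      idx <- cfg$flank_len + seq_len(tract_len)
      mean_cycle[idx] <- cfg$kin_baseline * cfg$kin_slowdown
    }
    rows <- lapply(seq_len(cfg$kin_reads), function(i) {
      strand <- if (i %% 2 == 0) "-" else "+"
      ipd <- stats::rpois(L, 0.7 * mean_cycle)
      pw <- stats::rpois(L, 0.3 * mean_cycle)
      tibble(read_id = paste0("kin_", lab, "_", i),
             allele = lab, chrom = paste0("allele_", lab),
             ref_start = 0L, strand = strand,
             cigar = paste0(L, "M"), seq = strrep("N", L),
             mod_offsets = list(integer()), mod_scores = list(integer()),
             ipd_fwd = list(if (strand == "+") ipd else integer()),
             pw_fwd = list(if (strand == "+") pw else integer()),
             ipd_rev = list(if (strand == "-") ipd else integer()),
             pw_rev = list(if (strand == "-") pw else integer()))
    })
    out[[lab]] <- bind_rows(rows)
    alleles[[lab]] <- tibble(allele = lab, length = L,
                             repeat_start = cfg$flank_len,
                             repeat_end = cfg$flank_len + tract_len)
  }
  list(reads = bind_rows(out), alleles = bind_rows(alleles))
}

#' Simulate a full trio fixture
#'
#' Deterministically (per seed) generates the synthetic reference, the
#' six haplotypes' reads with emission-model modification scores and
#' alignment errors, a PacBio-style kinetics fixture per allele, BED
#' annotations of the locus, and the ground-truth tables every stage of
#' the pipeline can be scored against.
#'
#' @param config A [trio_config()].
#' @return A `trio_sim` list: `reads` (tibble with `sample` column),
#'   `reference` (named character), `locus`, `truth` (per-read table,
#'   reference CpG zones, per-read CpG states, block coordinates),
#'   `kinetics`, `annotations` (BED-style tibble), `tss`, `config`.
#' @export
simulate_trio <- function(config) {
  if (!inherits(config, "trio_config")) config <- validate_trio_config(config)
  withr::with_seed(config$seed, {
    ref <- build_reference(config)
    hap_key <- c(mother_a1 = 1, mother_a2 = 2, father_normal = 3,
                 father_expanded = 4, patient_normal = 5,
                 patient_expanded = 6)
    reads <- vector("list", 0)
    truth_reads <- vector("list", 0)
    truth_cpgs <- vector("list", 0)
    for (nm in names(hap_key)) {
      hap <- config$haplotypes[hap_key[[nm]], ]
      n <- config$n_reads[[nm]]
      if (n == 0) next
      copies <- draw_copies(config, hap, n)
      with_ins <- !is.null(config$insertion) && hap$haplotype == "expanded"
      for (i in seq_len(n)) {
        pattern <- hap$pattern
        mosaic <- FALSE
        if (pattern == "hyper" && runif(1) < config$mosaic_fraction) {
          pattern <- "normal"
          mosaic <- TRUE
        }
        tract <- build_tract(config, copies[i], hap$gga_units, with_ins)
        strand <- if (runif(1) < 0.5) "+" else "-"
        rid <- paste0(hap$person, "_", hap$haplotype, "_", i)
        sim <- simulate_read(config, ref, tract, pattern, rid, strand)
        reads[[rid]] <- mutate(sim$read, sample = hap$person)
        truth_reads[[rid]] <- tibble(
          read_id = rid, sample = hap$person, haplotype = hap$haplotype,
          true_copies = copies[i],
          expanded = hap$haplotype == "expanded",
          pattern = pattern, mosaic = mosaic)
        truth_cpgs[[rid]] <- sim$truth_cpg
      }
    }
    kinetics <- simulate_kinetics(config, ref)
    fl <- config$flank_len
    annotations <- tibble(
      chrom = config$chrom,
      start = c(ref$repeat_start, ref$core_start,
                min(ref$cpgs$anchor[ref$cpgs$zone == "transition_up"]),
                min(ref$cpgs$anchor[ref$cpgs$zone == "transition_down"])),
      end = c(ref$repeat_end, ref$core_end,
              max(ref$cpgs$anchor[ref$cpgs$zone == "transition_up"]) + 2L,
              max(ref$cpgs$anchor[ref$cpgs$zone == "transition_down"]) + 2L),
      name = c("repeat", "hypermeth_block", "transition_up",
               "transition_down"))
    truth <- list(
      reads = bind_rows(truth_reads),
      ref_cpgs = ref$cpgs,
      read_cpgs = bind_rows(truth_cpgs),
      block = tibble(start = ref$core_start, end = ref$core_end,
                     first_cpg = min(ref$cpgs$anchor[
                       ref$cpgs$zone %in% c("core", "repeat")]),
                     last_cpg = max(ref$cpgs$anchor[
                       ref$cpgs$zone %in% c("core", "repeat")])))
    structure(list(
      reads = bind_rows(reads),
      reference = setNames(ref$refseq, config$chrom),
      locus = repeat_locus(config$chrom, ref$repeat_start, ref$repeat_end,
                           config$unit, config$ref_copies),
      truth = truth, kinetics = kinetics, annotations = annotations,
      tss = tibble(gene = "SIMGENE", chrom = config$chrom,
                   pos1 = ref$core_start + 1L, strand = "+"),
      config = config), class = "trio_sim")
  })
}

#' Write a simulated trio to fixture files
#'
#' Emits, under `dir`: one TSV-dialect and one SAM alignment file per
#' sample, the reference FASTA, BED annotations, the locus definition
#' TSV and the per-read truth table.
#'
#' @param sim A `trio_sim` from [simulate_trio()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_trio <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ref_len <- setNames(nchar(sim$reference), names(sim$reference))
  for (person in unique(sim$reads$sample)) {
    sub <- filter(sim$reads, .data$sample == person)
    sub <- select(sub, -"sample")
    write_alignments(sub, file.path(dir, paste0(person, ".tsv")))
    write_alignments(sub, file.path(dir, paste0(person, ".sam")),
                     ref_lengths = ref_len)
  }
  write_reference(sim$reference, file.path(dir, "reference.fa"))
  readr::write_tsv(sim$annotations[, c("chrom", "start", "end", "name")],
                   file.path(dir, "annotations.bed"), col_names = FALSE,
                   progress = FALSE)
  readr::write_tsv(mutate(sim$locus, start1 = .data$start + 1L,
                          end1 = .data$end),
                   file.path(dir, "locus.tsv"), progress = FALSE)
  readr::write_tsv(sim$truth$reads, file.path(dir, "truth_reads.tsv"),
                   progress = FALSE)
  readr::write_tsv(sim$truth$ref_cpgs, file.path(dir, "truth_cpgs.tsv"),
                   progress = FALSE)
  invisible(dir)
}
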