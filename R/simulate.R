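# Ground-truthed synthetic small RNA library generator.  Emulates the
# statistical structure of a hairpin-derived small RNA sequencing library:
# reads drawn from annotated mature arms with a configurable length
# distribution, 5' start offsets, mono/di 3' nontemplated tails with a
# configurable nucleotide mix, uniform per-base substitution error, a 3'
# sequencing adapter and exogenous spike-in reads.  Every read carries a
# truth record, so classification and parameter recovery can be scored
# exactly.

#' Simulation configuration
#'
#' Defaults describe the library structure assumed throughout the test
#' suite: canonical 22 nt matures, most reads at the 22 nt length class,
#' 7% of reads tailed (mostly mono additions dominated by U, then A),
#' a 0.1% per-base substitution error and a small spike-in component.
#'
#' @param seed Integer seed (mandatory; the generator is fully
#'   deterministic given the seed).
#' @param n_hairpins Number of reference hairpins.
#' @param hairpin_len Length range (min, max) of the random hairpins.
#' @param n_reads Number of reads to emit.
#' @param length_weights Named weights over templated core lengths (nt),
#'   summing to 1.
#' @param offset5_weights Named weights over 5' start offsets.
#' @param tail_rate Fraction of non-spike reads receiving a 3' tail.
#' @param tail_len_weights Named weights over tail lengths `{1, 2}`.
#' @param tail_nt_weights Named weights over tail nucleotides
#'   `U`, `A`, `C`, `G`.
#' @param error_rate Per-base substitution probability on the insert.
#' @param adapter 3' adapter appended to every read (`NULL` for none).
#' @param spike_fraction Fraction of reads drawn from spike-ins.
#' @param n_spikes Number of distinct spike-in sequences.
#' @param guide_star_ratio Expected guide:star read ratio.
#' @param mature_len Length of each annotated mature product.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(seed,
                       n_hairpins = 20L,
                       hairpin_len = c(60L, 90L),
                       n_reads = 50000L,
                       length_weights = c("20" = 0.05, "21" = 0.10,
                                          "22" = 0.70, "23" = 0.10,
                                          "24" = 0.05),
                       offset5_weights = c("-2" = 0.02, "-1" = 0.08,
                                           "0" = 0.80, "1" = 0.08,
                                           "2" = 0.02),
                       tail_rate = 0.07,
                       tail_len_weights = c("1" = 0.9, "2" = 0.1),
                       tail_nt_weights = c(U = 0.55, A = 0.30,
                                           C = 0.10, G = 0.05),
                       error_rate = 0.001,
                       adapter = "TGGAATTCTCGGGTGCCAAGG",
                       spike_fraction = 0.02,
                       n_spikes = 6L,
                       guide_star_ratio = 9,
                       mature_len = 22L) {
  if (missing(seed) || is.null(seed) || is.na(seed)) {
    stop_validation("sim_config: seed is mandatory")
  }
  for (w in list(length_weights, offset5_weights, tail_len_weights,
                 tail_nt_weights)) {
    if (abs(sum(w) - 1) > 1e-9) {
      stop_validation("sim_config: weight maps must sum to 1")
    }
  }
  for (r in c(tail_rate, error_rate, spike_fraction)) {
    if (r < 0 || r > 1) stop_validation("sim_config: rates must lie in [0, 1]")
  }
  max_off <- max(abs(as.integer(names(offset5_weights))))
  max_core <- max(as.integer(names(length_weights)))
  need <- 4L + mature_len + 4L + max_off + max_core
  if (hairpin_len[1] < need) {
    stop_validation(sprintf(
      "sim_config: hairpins of length %d cannot host two %d nt arms with the configured offsets and lengths (need >= %d)",
      hairpin_len[1], mature_len, need
    ))
  }
  structure(
    list(seed = as.integer(seed), n_hairpins = as.integer(n_hairpins),
         hairpin_len = as.integer(hairpin_len),
         n_reads = as.integer(n_reads),
         length_weights = length_weights,
         offset5_weights = offset5_weights, tail_rate = tail_rate,
         tail_len_weights = tail_len_weights,
         tail_nt_weights = tail_nt_weights, error_rate = error_rate,
         adapter = if (is.null(adapter)) NULL else .to_dna(adapter),
         spike_fraction = spike_fraction, n_spikes = as.integer(n_spikes),
         guide_star_ratio = guide_star_ratio,
         mature_len = as.integer(mature_len)),
    class = "sim_config"
  )
}

.random_seq <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

#' Generate a random reference (hairpins, annotations, spike-ins)
#'
#' Each hairpin carries one 5'-arm and one 3'-arm mature; the guide arm is
#' drawn at random per hairpin and recorded in the annotation's
#' `is_guide` column (ground truth; the pipeline re-derives its own guide
#' flags from read counts).  Arm placement leaves enough 3' template for
#' the largest configured templated window, so every templated read the
#' generator emits exists verbatim on its hairpin.
#'
#' @param cfg A [sim_config()].
#' @return A list: `hairpins` (named character), `annotations` (data
#'   frame), `spikes` (`spikein_set`), `config`.
#' @export
make_reference <- function(cfg) {
  set.seed(cfg$seed)
  max_off <- max(abs(as.integer(names(cfg$offset5_weights))))
  max_core <- max(as.integer(names(cfg$length_weights)))
  lens <- sample(cfg$hairpin_len[1]:cfg$hairpin_len[2], cfg$n_hairpins,
                 replace = TRUE)
  hp_ids <- sprintf("hp%03d", seq_len(cfg$n_hairpins))
  hairpins <- stats::setNames(
    vapply(lens, .random_seq, character(1)), hp_ids
  )
  start5 <- rep(4L, cfg$n_hairpins)
  start3 <- lens - max_off - max_core
  guide_arm <- sample(c("5p", "3p"), cfg$n_hairpins, replace = TRUE)
  annotations <- data.frame(
    mature_id = as.vector(rbind(paste0(hp_ids, "-5p"),
                                paste0(hp_ids, "-3p"))),
    hairpin_id = rep(hp_ids, each = 2L),
    start = as.vector(rbind(start5, start3)),
    end = as.vector(rbind(start5 + cfg$mature_len,
                          start3 + cfg$mature_len)),
    is_guide = as.vector(rbind(guide_arm == "5p", guide_arm == "3p")),
    stringsAsFactors = FALSE
  )
  validate_annotations(annotations, hairpins)
  spike_seqs <- character(0)
  while (length(unique(spike_seqs)) < cfg$n_spikes) {
    spike_seqs <- unique(c(spike_seqs, .random_seq(22L)))
  }
  spikes <- spikein_set(stats::setNames(
    spike_seqs[seq_len(cfg$n_spikes)],
    sprintf("spike%02d", seq_len(cfg$n_spikes))
  ))
  list(hairpins = hairpins, annotations = annotations, spikes = spikes,
       config = cfg)
}

#' Generate a synthetic read library with ground truth
#'
#' Each non-spike read is a templated hairpin window (sampled length and
#' 5' offset) plus an optional nontemplated tail and per-base substitution
#' errors, with the 3' adapter appended; spike-in reads are interleaved at
#' `spike_fraction`.  Reads whose tail's final base coincides with the
#' templated hairpin base are truth-flagged `tail_indistinguishable`: by
#' the genome-mismatch definition of a nontemplated addition they are
#' (correctly) classified as templated extensions.
#'
#' The truth table's `sequence` column holds the adapter-free insert after
#' errors — the sequence the pipeline should recover by trimming.
#'
#' @param cfg A [sim_config()].
#' @param reference Output of [make_reference()].
#' @param out_dir Optional directory; when given, writes `hairpins.fa`,
#'   `mature.tsv`, `spikes.fa`, `reads.fastq` and `truth.tsv`.
#' @return A list: `reads` (FASTQ data frame), `truth` (data frame, one
#'   row per read, with the `sim_config` attached as attribute
#'   `"config"`).
#' @export
generate_library <- function(cfg, reference, out_dir = NULL) {
  set.seed(cfg$seed + 1L)
  n <- cfg$n_reads
  if (n == 0L) {
    reads <- data.frame(id = character(0), sequence = character(0),
                        quality = character(0), stringsAsFactors = FALSE)
    truth <- data.frame(read_id = character(0), is_spike = logical(0),
                        mature_id = character(0),
                        true_length_class = integer(0),
                        true_offset5 = integer(0),
                        true_tail_seq = character(0),
                        tail_indistinguishable = logical(0),
                        true_error_positions = character(0),
                        sequence = character(0), stringsAsFactors = FALSE)
    attr(truth, "config") <- cfg
    return(list(reads = reads, truth = truth))
  }
  ann <- reference$annotations
  hairpins <- reference$hairpins
  bases <- c("A", "C", "G", "T")

  is_spike <- stats::runif(n) < cfg$spike_fraction
  n_hp <- cfg$n_hairpins
  hp_idx <- sample.int(n_hp, n, replace = TRUE)
  p_guide <- cfg$guide_star_ratio / (1 + cfg$guide_star_ratio)
  use_guide <- stats::runif(n) < p_guide
  # annotation row index: rows come in (5p, 3p) pairs per hairpin
  guide_is_5p <- ann$is_guide[2L * hp_idx - 1L]
  take_5p <- ifelse(use_guide, guide_is_5p, !guide_is_5p)
  ann_row <- ifelse(take_5p, 2L * hp_idx - 1L, 2L * hp_idx)

  core_lens <- as.integer(names(cfg$length_weights))
  ell <- sample(core_lens, n, replace = TRUE, prob = cfg$length_weights)
  offs <- as.integer(names(cfg$offset5_weights))
  off <- sample(offs, n, replace = TRUE, prob = cfg$offset5_weights)

  tailed <- stats::runif(n) < cfg$tail_rate
  tail_len <- integer(n)
  tail_len[tailed] <- sample(as.integer(names(cfg$tail_len_weights)),
                             sum(tailed), replace = TRUE,
                             prob = cfg$tail_len_weights)
  n_tail_nt <- sum(tail_len)
  tail_nt_rna <- sample(names(cfg$tail_nt_weights), n_tail_nt,
                        replace = TRUE, prob = cfg$tail_nt_weights)
  tail_of <- rep.int(seq_len(n), tail_len)
  tail_rna <- stats::setNames(rep("", n), NULL)
  if (n_tail_nt > 0L) {
    agg <- vapply(split(tail_nt_rna, factor(tail_of, levels = seq_len(n))),
                  paste, character(1), collapse = "")
    tail_rna <- unname(agg)
  }
  tail_dna <- .to_dna(tail_rna)

  win_start <- ann$start[ann_row] + off            # 0-based
  hp_seq <- unname(hairpins[ann$hairpin_id[ann_row]])
  core <- substr(hp_seq, win_start + 1L, win_start + ell)
  insert <- paste0(core, tail_dna)

  # a tail is indistinguishable from templated extension when its final
  # base matches the hairpin base aligned to the read's last position
  last_pos <- win_start + ell + tail_len           # 1-based hairpin index
  tmpl_last <- substr(hp_seq, last_pos, last_pos)
  last_tail_base <- substr(tail_dna, tail_len, tail_len)
  tail_indist <- tailed & nzchar(tmpl_last) & tmpl_last == last_tail_base

  # spike reads replace the templated construction
  spike_seqs <- reference$spikes$records$sequence
  if (any(is_spike)) {
    insert[is_spike] <- sample(spike_seqs, sum(is_spike), replace = TRUE)
    tailed[is_spike] <- FALSE
    tail_len[is_spike] <- 0L
    tail_dna[is_spike] <- ""
    tail_rna[is_spike] <- ""
    tail_indist[is_spike] <- FALSE
  }

  # uniform per-base substitution error on the insert
  err_str <- rep("", n)
  if (cfg$error_rate > 0) {
    ilen <- nchar(insert)
    tot <- sum(ilen)
    hit <- which(stats::runif(tot) < cfg$error_rate)
    if (length(hit)) {
      read_of <- rep.int(seq_len(n), ilen)
      first_of <- cumsum(c(0L, ilen[-n]))
      for (h in hit) {
        r <- read_of[h]
        p <- h - first_of[r]
        old <- substr(insert[r], p, p)
        substr(insert[r], p, p) <- sample(setdiff(bases, old), 1L)
      }
      by_read <- split(hit - first_of[read_of[hit]], read_of[hit])
      err_str[as.integer(names(by_read))] <-
        vapply(by_read, paste, character(1), collapse = ",")
    }
  }

  read_id <- sprintf("sim%07d", seq_len(n))
  fq_seq <- if (is.null(cfg$adapter)) insert else paste0(insert, cfg$adapter)
  reads <- data.frame(
    id = read_id, sequence = fq_seq,
    quality = strrep("I", nchar(fq_seq)), stringsAsFactors = FALSE
  )
  truth <- data.frame(
    read_id = read_id,
    is_spike = is_spike,
    mature_id = ifelse(is_spike, NA_character_, ann$mature_id[ann_row]),
    true_length_class = ifelse(is_spike, NA_integer_, ell),
    true_offset5 = ifelse(is_spike, NA_integer_, off),
    true_tail_seq = .to_rna(tail_dna),
    tail_indistinguishable = tail_indist,
    true_error_positions = err_str,
    sequence = insert,
    stringsAsFactors = FALSE
  )
  attr(truth, "config") <- cfg

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_fasta(data.frame(id = names(hairpins), sequence = unname(hairpins)),
                file.path(out_dir, "hairpins.fa"))
    utils::write.table(ann[c("mature_id", "hairpin_id", "start", "end")],
                       file.path(out_dir, "mature.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    write_fasta(data.frame(id = reference$spikes$records$spike_id,
                           sequence = spike_seqs),
                file.path(out_dir, "spikes.fa"))
    write_fastq(reads, file.path(out_dir, "reads.fastq"))
    utils::write.table(truth, file.path(out_dir, "truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  list(reads = reads, truth = truth)
}

#' Score classification against simulator ground truth
#'
#' Joins per-read truth records to the collapsed-read call table and
#' reports a category confusion matrix, NTA precision/recall, and the
#' recovered generator parameters (tail incidence, tail nucleotide mix,
#' templated length weights).  Reads truth-flagged
#' `tail_indistinguishable` are excluded from NTA scoring and from the
#' parameter estimates: their tails are templated by the genome-mismatch
#' definition of a nontemplated addition, so they measure the definition
#' rather than the classifier.
#'
#' @param truth Truth data frame from [generate_library()].
#' @param calls Call table from [classify_library()].
#' @param reads Collapsed read data frame used for classification (maps
#'   call `read_id`s back to sequences).
#' @param cfg The `sim_config` (defaults to the one attached to `truth`).
#' @return A list of class `recovery_report`.
#' @export
score_recovery <- function(truth, calls, reads,
                           cfg = attr(truth, "config")) {
  if (nrow(truth) == 0L) {
    return(structure(list(confusion = table(character(0), character(0)),
                          nta_precision = NA_real_, nta_recall = NA_real_,
                          estimated = list(), truth_values = list(),
                          n_scored = 0L),
                     class = "recovery_report"))
  }
  calls2 <- calls
  calls2$sequence <- reads$sequence[match(calls2$read_id, reads$read_id)]
  if (anyNA(calls2$sequence)) {
    stop_validation("score_recovery: call read_ids missing from the read table")
  }
  # prefer the call made on the read's true mature; fall back to any call
  key_call <- paste(calls2$sequence, calls2$mature_id)
  key_truth <- paste(truth$sequence, truth$mature_id)
  m <- match(key_truth, key_call)
  m2 <- match(truth$sequence, calls2$sequence)
  m[is.na(m)] <- m2[is.na(m)]
  if (anyNA(m)) {
    stop_validation("score_recovery: truth reads missing from the call table")
  }
  called <- calls2$category[m]
  called_tail <- calls2$tail_seq[m]
  called_len <- calls2$read_length[m]

  true_cat <- ifelse(truth$is_spike, "SPIKEIN",
                     ifelse(nzchar(truth$true_tail_seq) &
                              !truth$tail_indistinguishable, "NTA",
                            "TEMPLATED"))
  confusion <- table(truth = true_cat, called = called)

  eligible <- !truth$is_spike & !truth$tail_indistinguishable
  tailed <- nzchar(truth$true_tail_seq)
  tp <- sum(eligible & tailed & called == "NTA")
  recall <- if (any(eligible & tailed)) tp / sum(eligible & tailed) else NA_real_
  called_nta <- eligible & called == "NTA"
  precision <- if (any(called_nta)) {
    sum(called_nta & tailed) / sum(called_nta)
  } else NA_real_

  # raw NTA incidence underestimates the generator's tail rate by the
  # fraction of tails whose final base coincides with the template (those
  # are templated by definition); rescale by the truth-observed
  # distinguishability rate.
  tailed_all <- tailed & !truth$is_spike
  p_dist <- if (any(tailed_all)) {
    mean(!truth$tail_indistinguishable[tailed_all])
  } else NA_real_
  raw_rate <- sum(called == "NTA" & !truth$is_spike) / sum(!truth$is_spike)
  est_tail_rate <- if (!is.na(p_dist) && p_dist > 0) {
    raw_rate / p_dist
  } else raw_rate

  # per-nucleotide distinguishability among truth mono tails: a finite
  # reference makes the template base at the dominant tail positions
  # non-uniform, so each nucleotide's tails are pruned into "templated"
  # at its own rate; the mix estimate divides each observed share by
  # that rate before renormalising
  mono_truth <- tailed_all & nchar(truth$true_tail_seq) == 1L
  p_dist_nt <- vapply(c("U", "A", "C", "G"), function(nt) {
    sel <- mono_truth & truth$true_tail_seq == nt
    if (any(sel)) mean(!truth$tail_indistinguishable[sel]) else p_dist
  }, numeric(1))
  p_dist_nt[is.na(p_dist_nt) | p_dist_nt == 0] <- 1
  mono <- called_nta & nchar(called_tail) == 1L
  nts <- c("U", "A", "C", "G")
  est_mix <- if (any(mono)) {
    tab <- as.numeric(table(factor(called_tail[mono], levels = nts)))
    adj <- tab / p_dist_nt[nts]
    adj / sum(adj)
  } else rep(NA_real_, 4L)
  names(est_mix) <- nts

  core_lens <- as.integer(names(cfg$length_weights))
  tmpl <- eligible & called == "TEMPLATED"
  est_lw <- if (any(tmpl)) {
    tab <- table(factor(called_len[tmpl], levels = core_lens))
    as.numeric(tab) / sum(tab)
  } else rep(NA_real_, length(core_lens))
  names(est_lw) <- core_lens

  structure(
    list(confusion = confusion,
         nta_precision = precision, nta_recall = recall,
         estimated = list(tail_rate = est_tail_rate,
                          tail_nt_weights = est_mix,
                          length_weights = est_lw),
         truth_values = list(tail_rate = cfg$tail_rate,
                             tail_nt_weights = cfg$tail_nt_weights,
                             length_weights = cfg$length_weights),
         n_scored = nrow(truth), n_eligible = sum(eligible),
         counts = list(templated_called = sum(tmpl),
                       mono_nta = sum(mono),
                       nonspike = sum(!truth$is_spike))),
    class = "recovery_report"
  )
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("Simulator recovery report:", x$n_scored, "reads scored\n")
  if (x$n_scored == 0L) return(invisible(x))
  cat(sprintf("  NTA precision %.4f, recall %.4f (distinguishable tails)\n",
              x$nta_precision, x$nta_recall))
  cat(sprintf("  tail incidence: estimated %.4f, true %.4f\n",
              x$estimated$tail_rate, x$truth_values$tail_rate))
  cat("  tail mix (U/A/C/G): estimated",
      paste(sprintf("%.3f", x$estimated$tail_nt_weights), collapse = "/"),
      "true",
      paste(sprintf("%.3f", x$truth_values$tail_nt_weights), collapse = "/"),
      "\n")
  invisible(x)
}
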