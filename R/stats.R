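# Aggregation of read calls into the summary statistics of the analysis:
# guide selection, isoform length spectra, tail nucleotide composition by
# position, spike-in normalisation and the terminal-vs-internal mismatch
# fold used to exclude sequencing artefacts.

#' Guide read-count filter
#'
#' @param min_guide_count Guides with a templated read count strictly
#'   above this value are retained ("above 50" read strictly; a count of
#'   exactly 50 is excluded).  Default 50.
#' @return An object of class `guide_filter`.
#' @export
guide_filter <- function(min_guide_count = 50L) {
  stopifnot(min_guide_count >= 0L)
  structure(list(min_guide_count = as.integer(min_guide_count)),
            class = "guide_filter")
}

.stats_calls <- function(calls, unique_only = FALSE) {
  if (unique_only) calls[calls$multimap_n == 1L, , drop = FALSE] else calls
}

#' Select guide miRNAs
#'
#' For each hairpin the mature with the larger templated read count is the
#' guide (ties broken toward the 5' arm, i.e. the smaller start).  Guides
#' whose templated count exceeds the filter cutoff are retained for the
#' downstream modification statistics.
#'
#' @param calls Call table from [classify_library()].
#' @param annotations Mature annotation data frame.
#' @param filter A [guide_filter()].
#' @param unique_only Drop multimapping calls before counting.
#' @return A data frame per mature: `mature_id`, `hairpin_id`, `start`,
#'   `templated_count`, `is_guide`, `retained`.  The retained guide ids
#'   are `$mature_id[$retained]`.
#' @export
select_guides <- function(calls, annotations, filter = guide_filter(),
                          unique_only = FALSE) {
  calls <- .stats_calls(calls, unique_only)
  tc <- calls[calls$category == "TEMPLATED", , drop = FALSE]
  counts <- tapply(tc$count, tc$mature_id, sum)
  out <- data.frame(
    mature_id = annotations$mature_id,
    hairpin_id = annotations$hairpin_id,
    start = annotations$start,
    templated_count = as.numeric(counts[annotations$mature_id]),
    stringsAsFactors = FALSE
  )
  out$templated_count[is.na(out$templated_count)] <- 0
  out$is_guide <- FALSE
  for (h in unique(out$hairpin_id)) {
    i <- which(out$hairpin_id == h)
    if (all(out$templated_count[i] == 0)) next  # hairpin unseen: no guide
    best <- i[order(-out$templated_count[i], out$start[i])][1L]
    out$is_guide[best] <- TRUE
  }
  out$retained <- out$is_guide &
    out$templated_count > filter$min_guide_count
  out
}

#' Isoform length spectrum of one miRNA
#'
#' Counts of templated calls by read length across the tabulation window
#' (default 18-24 nt) and the corresponding fractions of their total.
#' Only mismatch-free (templated) reads enter the spectrum.
#'
#' @param calls Call table.
#' @param mature_id Mature id to tabulate.
#' @param cfg A [map_config()] supplying the length window.
#' @param unique_only Drop multimapping calls.
#' @return A list of class `isoform_spectrum`: `mature_id`, `counts`
#'   (named by length), `fractions`, `total`.
#' @export
isoform_spectrum <- function(calls, mature_id, cfg = map_config(),
                             unique_only = FALSE) {
  calls <- .stats_calls(calls, unique_only)
  lens <- cfg$min_len:cfg$max_len
  sel <- calls$category == "TEMPLATED" &
    !is.na(calls$mature_id) & calls$mature_id == mature_id &
    calls$read_length >= cfg$min_len & calls$read_length <= cfg$max_len
  counts <- stats::setNames(numeric(length(lens)), lens)
  if (any(sel)) {
    agg <- tapply(calls$count[sel], calls$read_length[sel], sum)
    counts[names(agg)] <- agg
  }
  total <- sum(counts)
  fractions <- if (total > 0) counts / total else counts * NA_real_
  structure(list(mature_id = mature_id, counts = counts,
                 fractions = fractions, total = total),
            class = "isoform_spectrum")
}

#' 3' nontemplated addition profile
#'
#' Tabulates mono-addition (single-nucleotide tail) calls by the read
#' position of the added base (default positions 21-24, i.e. read lengths
#' 21-24) and the added nucleotide (U, A, C, G), with per-position
#' percentage shares.  With `mature_id = NULL` the counts are pooled over
#' all supplied matures (sum counts first, then shares).
#'
#' @param calls Call table.
#' @param mature_id One mature id, or `NULL` to pool.
#' @param positions 1-based read positions of the added nucleotide
#'   tabulated (default `21:24`).
#' @param unique_only Drop multimapping calls.
#' @return A list of class `nta_profile`: `mature_id`, `counts`
#'   (position x nucleotide matrix), `percentages` (per-position rows
#'   summing to 100, `NA` where a position has no calls).
#' @export
nta_profile <- function(calls, mature_id = NULL, positions = 21:24,
                        unique_only = FALSE) {
  calls <- .stats_calls(calls, unique_only)
  nts <- c("U", "A", "C", "G")
  sel <- calls$category == "NTA" & nchar(calls$tail_seq) == 1L &
    calls$read_length %in% positions
  if (!is.null(mature_id)) {
    sel <- sel & !is.na(calls$mature_id) & calls$mature_id == mature_id
  }
  counts <- matrix(0, length(positions), length(nts),
                   dimnames = list(positions, nts))
  if (any(sel)) {
    agg <- tapply(calls$count[sel],
                  list(factor(calls$read_length[sel], levels = positions),
                       factor(calls$tail_seq[sel], levels = nts)),
                  sum)
    agg[is.na(agg)] <- 0
    counts[] <- agg
  }
  totals <- rowSums(counts)
  percentages <- counts / totals * 100
  percentages[totals == 0, ] <- NA_real_
  structure(list(mature_id = mature_id, counts = counts,
                 percentages = percentages),
            class = "nta_profile")
}

#' Spike-in normalisation
#'
#' Scales counts to per-million units using the spike-in matched total
#' as the anchor; when no spike-in reads were seen, the supplied fallback
#' total (classified non-spike reads) is used instead.  Normalisation is
#' a global rescaling, so it never changes a fraction or percentage.
#'
#' @param counts Numeric counts (vector or matrix).
#' @param spike_matched Total read count matching spike-ins.
#' @param fallback_total Total used when `spike_matched` is 0.
#' @return Counts multiplied by `1e6 / anchor`.
#' @export
normalize_counts <- function(counts, spike_matched, fallback_total = 0) {
  anchor <- if (spike_matched > 0) spike_matched else fallback_total
  if (anchor <= 0) {
    stop_validation("nothing to normalize by: no spike-in matches and no fallback total")
  }
  counts * (1e6 / anchor)
}

#' Terminal-vs-internal mismatch fold
#'
#' The artefact-exclusion contrast: the summed count of mono-addition
#' calls whose added base sits at the focal read position (default 23) is
#' divided by the mean, over internal positions 1..focal-1, of the summed
#' counts of single-mismatch internal calls at each position.  A genuine
#' 3' tailing signal stands tens of fold above the uniform background a
#' sequencing-error artefact would produce.
#'
#' @param calls Call table.
#' @param mature_id One mature id, or `NULL` to pool over all matures.
#' @param focal_position 1-based read position of the terminal addition
#'   (default 23).
#' @param exclude_internal Internal positions to drop from the background
#'   mean (default none).
#' @param unique_only Drop multimapping calls.
#' @return A list of class `fold_report`: `mature_id`, `terminal_count`,
#'   `internal_mean`, `fold` (`NA` when the internal mean is 0),
#'   `internal_counts` (per-position background).
#' @export
terminal_internal_fold <- function(calls, mature_id = NULL,
                                   focal_position = 23L,
                                   exclude_internal = integer(0),
                                   unique_only = FALSE) {
  calls <- .stats_calls(calls, unique_only)
  if (!is.null(mature_id)) {
    calls <- calls[!is.na(calls$mature_id) & calls$mature_id == mature_id, ,
                   drop = FALSE]
  }
  terminal_count <- sum(calls$count[
    calls$category == "NTA" & nchar(calls$tail_seq) == 1L &
      calls$read_length == focal_position
  ])
  internal_positions <- setdiff(seq_len(focal_position - 1L),
                                exclude_internal)
  internal_counts <- stats::setNames(numeric(length(internal_positions)),
                                     internal_positions)
  imm <- calls[calls$category == "INTERNAL_MM" &
                 !grepl(",", calls$mismatch_positions_1based), , drop = FALSE]
  if (nrow(imm)) {
    pos <- as.integer(imm$mismatch_positions_1based)
    ok <- pos %in% internal_positions
    if (any(ok)) {
      agg <- tapply(imm$count[ok], pos[ok], sum)
      internal_counts[names(agg)] <- agg
    }
  }
  internal_mean <- mean(internal_counts)
  fold <- if (internal_mean > 0) terminal_count / internal_mean else NA_real_
  structure(list(mature_id = mature_id, terminal_count = terminal_count,
                 internal_mean = internal_mean, fold = fold,
                 internal_counts = internal_counts),
            class = "fold_report")
}

#' Isoform fraction matrix across samples
#'
#' Assembles per-sample isoform spectra into the matrix behind the
#' heat-map display: rows are matures, columns are (sample, length)
#' pairs, cells are fractions.  Matures absent from a sample get `NA`
#' cells; row order is deterministic (descending total count over all
#' samples, ties by id).
#'
#' @param spectra_by_sample Named list (one entry per sample) of lists of
#'   `isoform_spectrum` objects.
#' @return A numeric matrix; columns named `sample.length`.
#' @export
heatmap_matrix <- function(spectra_by_sample) {
  stopifnot(length(spectra_by_sample) >= 1L)
  samples <- names(spectra_by_sample)
  if (is.null(samples)) {
    samples <- sprintf("sample%d", seq_along(spectra_by_sample))
  }
  all_sp <- unlist(spectra_by_sample, recursive = FALSE)
  matures <- unique(vapply(all_sp, `[[`, character(1), "mature_id"))
  totals <- stats::setNames(numeric(length(matures)), matures)
  for (sp in all_sp) totals[[sp$mature_id]] <- totals[[sp$mature_id]] + sp$total
  matures <- matures[order(-totals[matures], matures, method = "radix")]
  lens <- names(all_sp[[1L]]$fractions)
  cols <- as.vector(t(outer(samples, lens, paste, sep = ".")))
  m <- matrix(NA_real_, length(matures), length(cols),
              dimnames = list(matures, cols))
  for (si in seq_along(samples)) {
    for (sp in spectra_by_sample[[si]]) {
      m[sp$mature_id, paste(samples[si], lens, sep = ".")] <- sp$fractions
    }
  }
  m
}
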