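# The central user-facing surface: one call that takes a raw read library
# plus an annotated hairpin reference and returns a classed fit object
# holding the per-read calls and every downstream summary, with the usual
# accessor methods.

#' Fit the isoform/tailing model to a small RNA library
#'
#' Runs the full analysis: adapter trimming and length filtering,
#' collapsing, hairpin-anchored classification (templated isoform /
#' 3' nontemplated addition / internal mismatch / spike-in), guide
#' selection, per-guide isoform length spectra, tail nucleotide profiles
#' (per guide and pooled), and the terminal-vs-internal mismatch fold.
#'
#' @param reads One of: a path to a FASTQ/FASTA file; a character vector
#'   of raw read sequences; a FASTQ data frame (`sequence` column); or an
#'   already-preprocessed collapsed data frame (`read_id`, `sequence`,
#'   `count`), which skips trimming and filtering.
#' @param hairpins Named character vector of hairpin sequences, or a
#'   FASTA path.
#' @param annotations Mature annotation data frame, or a TSV path.
#' @param spikes Optional `spikein_set` or FASTA path.
#' @param trim A [trim_config()], or `NULL` to skip adapter trimming
#'   (length filtering still applies at `min_length`).
#' @param map A [map_config()].
#' @param guide A [guide_filter()].
#' @param focal_position Terminal position for the fold statistic
#'   (default 23).
#' @param min_length Minimum read length kept when `trim` is `NULL`.
#' @param unique_only Drop multimapping calls from all summaries.
#' @return An object of class `mirtail_fit`.
#' @seealso [coef.mirtail_fit()], [summary.mirtail_fit()],
#'   [plot.mirtail_fit()], [simulate.mirtail_fit()]
#' @export
mirtail_fit <- function(reads, hairpins, annotations, spikes = NULL,
                        trim = trim_config(), map = map_config(),
                        guide = guide_filter(), focal_position = 23L,
                        min_length = 18L, unique_only = FALSE) {
  if (is.character(hairpins) && length(hairpins) == 1L &&
      file.exists(hairpins)) {
    hairpins <- read_hairpins(hairpins)
  }
  if (is.character(annotations)) {
    annotations <- read_annotation_tsv(annotations, hairpins)
  }
  if (is.character(spikes)) spikes <- read_spikes(spikes)

  preprocessed <- FALSE
  if (is.data.frame(reads) && all(c("sequence", "count") %in% names(reads))) {
    collapsed <- reads
    n_input <- sum(reads$count)
    n_discarded <- 0L
    preprocessed <- TRUE
  } else {
    if (is.character(reads) && length(reads) == 1L && file.exists(reads)) {
      reads <- if (grepl("\\.(fq|fastq)(\\.gz)?$", reads)) {
        read_fastq(reads)$sequence
      } else {
        read_fasta(reads)$sequence
      }
    } else if (is.data.frame(reads)) {
      reads <- reads$sequence
    }
    pp <- preprocess_reads(reads, cfg = trim, min_length = min_length)
    collapsed <- pp$reads
    n_input <- pp$n_input
    n_discarded <- pp$n_discarded
  }

  calls <- classify_library(collapsed, hairpins, annotations, spikes, map)
  spike_matched <- attr(calls, "spike_matched")
  guides <- select_guides(calls, annotations, guide,
                          unique_only = unique_only)
  retained <- guides$mature_id[guides$retained]

  spectra <- lapply(retained, function(mid) {
    isoform_spectrum(calls, mid, map, unique_only = unique_only)
  })
  names(spectra) <- retained
  guide_calls <- calls[!is.na(calls$mature_id) &
                         calls$mature_id %in% retained, , drop = FALSE]
  nta <- lapply(retained, function(mid) {
    nta_profile(calls, mid, unique_only = unique_only)
  })
  names(nta) <- retained
  nta_pooled <- nta_profile(guide_calls, NULL, unique_only = unique_only)
  fold <- terminal_internal_fold(guide_calls, NULL,
                                 focal_position = focal_position,
                                 unique_only = unique_only)
  fold_by_guide <- lapply(retained, function(mid) {
    terminal_internal_fold(calls, mid, focal_position = focal_position,
                           unique_only = unique_only)
  })
  names(fold_by_guide) <- retained

  structure(
    list(calls = calls, reads = collapsed, guides = guides,
         spectra = spectra, nta = nta, nta_pooled = nta_pooled,
         fold = fold, fold_by_guide = fold_by_guide,
         spike_matched = spike_matched,
         n_input = n_input, n_discarded = n_discarded,
         preprocessed_input = preprocessed,
         trim = trim, map = map, guide_filter = guide,
         focal_position = as.integer(focal_position),
         unique_only = unique_only),
    class = "mirtail_fit"
  )
}

#' @export
print.mirtail_fit <- function(x, ...) {
  cat("mirtail fit\n")
  cat(sprintf("  input reads: %d (%d discarded as < %d nt)\n",
              x$n_input, x$n_discarded,
              if (is.null(x$trim)) 18L else x$trim$min_length))
  first <- !duplicated(x$calls$read_id)  # count each read once
  tot <- tapply(x$calls$count[first], x$calls$category[first], sum)
  cat("  calls by category:",
      paste(sprintf("%s=%d", names(tot), as.integer(tot)), collapse = ", "),
      "\n")
  cat(sprintf("  spike-in matched reads: %d\n", x$spike_matched))
  cat(sprintf("  guides retained (templated count > %d): %d of %d matures\n",
              x$guide_filter$min_guide_count, sum(x$guides$retained),
              nrow(x$guides)))
  invisible(x)
}

#' Summarise a mirtail fit
#'
#' @param object A `mirtail_fit`.
#' @param ... Unused.
#' @return The fit, invisibly; prints the guide table, pooled tail
#'   composition and the fold statistic.
#' @export
summary.mirtail_fit <- function(object, ...) {
  print(object)
  cat("\nGuide table:\n")
  print(object$guides)
  cat("\nPooled 3' addition percentages (position x nucleotide):\n")
  print(round(object$nta_pooled$percentages, 2))
  cat(sprintf(
    "\nTerminal (pos %d) vs internal single-mismatch fold: %s (terminal %g, internal mean %g)\n",
    object$focal_position,
    ifelse(is.na(object$fold$fold), "NA",
           sprintf("%.1f", object$fold$fold)),
    object$fold$terminal_count, object$fold$internal_mean
  ))
  invisible(object)
}

#' Extract the fitted proportions
#'
#' @param object A `mirtail_fit`.
#' @param ... Unused.
#' @return Named numeric vector: pooled templated length fractions
#'   (`frac_len*`), pooled tail nucleotide shares over mono additions
#'   (`tail_share_*`), the tail incidence among guide-assigned reads
#'   (`tail_incidence`), and the terminal/internal fold
#'   (`fold_terminal_internal`).
#' @export
coef.mirtail_fit <- function(object, ...) {
  lens <- object$map$min_len:object$map$max_len
  counts <- stats::setNames(numeric(length(lens)), lens)
  for (sp in object$spectra) counts <- counts + sp$counts
  fracs <- if (sum(counts) > 0) counts / sum(counts) else counts * NA_real_
  nt_counts <- colSums(object$nta_pooled$counts)
  shares <- if (sum(nt_counts) > 0) nt_counts / sum(nt_counts) else
    nt_counts * NA_real_
  retained <- object$guides$mature_id[object$guides$retained]
  gcalls <- object$calls[!is.na(object$calls$mature_id) &
                           object$calls$mature_id %in% retained, ,
                         drop = FALSE]
  assigned_total <- sum(gcalls$count)
  nta_total <- sum(gcalls$count[gcalls$category == "NTA"])
  incidence <- if (assigned_total > 0) nta_total / assigned_total else
    NA_real_
  c(stats::setNames(as.numeric(fracs), paste0("frac_len", lens)),
    stats::setNames(as.numeric(shares),
                    paste0("tail_share_", names(nt_counts))),
    tail_incidence = incidence,
    fold_terminal_internal = object$fold$fold)
}

#' Heat-map style display of isoform length fractions
#'
#' Renders the per-guide isoform fraction matrix (rows: guides ordered by
#' total count; columns: read lengths) with base graphics.  The matrix
#' itself is available via [heatmap_matrix()].
#'
#' @param x A `mirtail_fit`.
#' @param main Plot title.
#' @param ... Passed to [graphics::image()].
#' @export
plot.mirtail_fit <- function(x, main = "miRNA isoform length fractions",
                             ...) {
  if (length(x$spectra) == 0L) {
    stop_validation("no retained guides to plot")
  }
  m <- heatmap_matrix(list(library = x$spectra))
  lens <- x$map$min_len:x$map$max_len
  z <- t(m[rev(seq_len(nrow(m))), , drop = FALSE])
  graphics::image(
    x = seq_along(lens), y = seq_len(nrow(m)), z = z,
    col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE),
    xlab = "read length (nt)", ylab = "", axes = FALSE, main = main, ...
  )
  graphics::axis(1, at = seq_along(lens), labels = lens)
  graphics::axis(2, at = seq_len(nrow(m)), labels = rev(rownames(m)),
                 las = 2, cex.axis = 0.7)
  invisible(m)
}

#' Simulate libraries from a fitted model
#'
#' Draws synthetic libraries whose length distribution, tail incidence
#' and tail nucleotide mix are the fitted proportions, using the
#' package's ground-truthed generator on a fresh random reference.
#'
#' @param object A `mirtail_fit`.
#' @param nsim Number of libraries.
#' @param seed Integer seed (mandatory).
#' @param n_reads Reads per library (default: input size of the fit).
#' @param ... Unused.
#' @return A list of `nsim` libraries as returned by
#'   [generate_library()], each with its `reference` attached.
#' @export
simulate.mirtail_fit <- function(object, nsim = 1, seed, n_reads = NULL,
                                 ...) {
  co <- coef(object)
  lens <- object$map$min_len:object$map$max_len
  lw <- co[paste0("frac_len", lens)]
  lw <- lw[!is.na(lw) & lw > 0]
  names(lw) <- sub("frac_len", "", names(lw))
  lw <- lw / sum(lw)
  mix <- co[paste0("tail_share_", c("U", "A", "C", "G"))]
  if (anyNA(mix) || sum(mix) == 0) {
    mix <- c(U = 0.25, A = 0.25, C = 0.25, G = 0.25)
  } else {
    names(mix) <- c("U", "A", "C", "G")
    mix <- mix / sum(mix)
  }
  out <- vector("list", nsim)
  for (i in seq_len(nsim)) {
    cfg <- sim_config(
      seed = as.integer(seed) + (i - 1L) * 2L,
      n_reads = if (is.null(n_reads)) object$n_input else n_reads,
      length_weights = lw,
      tail_rate = min(1, max(0, unname(co["tail_incidence"]))),
      tail_nt_weights = mix
    )
    ref <- make_reference(cfg)
    lib <- generate_library(cfg, ref)
    lib$reference <- ref
    out[[i]] <- lib
  }
  out
}
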