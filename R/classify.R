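# Library-scale classification: every collapsed read against every
# (hairpin, mature) pair, spike-ins first.  The per-pair alignment is a
# vectorised implementation of the same placement-and-classification rule
# as align_anchored(); agreement between the two paths is asserted in the
# test suite.

# align all reads of one length group against one annotation.
# mat: n x L character matrix; seqs/ids/counts parallel to rows.
.align_pair_group <- function(mat, seqs, ids, hp_chars, m, cfg) {
  n <- nrow(mat)
  L <- ncol(mat)
  starts <- (m$start - cfg$anchor_window):(m$start + cfg$anchor_window)
  starts <- starts[starts >= 0L & starts < length(hp_chars)]
  k <- length(starts)
  if (k == 0L || n == 0L) return(NULL)

  tmpl_for <- function(s) {
    tmpl <- rep("-", L)
    take <- seq_len(max(0L, min(L, length(hp_chars) - s)))
    if (length(take)) tmpl[take] <- hp_chars[s + take]
    tmpl
  }

  NM <- matrix(0, n, k)
  for (j in seq_len(k)) {
    tm <- matrix(tmpl_for(starts[j]), n, L, byrow = TRUE)
    mm <- mat != tm | mat == "N" | tm == "N"
    NM[, j] <- rowSums(mm)
  }
  # lexicographic (mismatches, |offset|, start); candidates ascend in start
  offabs <- abs(starts - m$start)
  score <- sweep(NM * 10000, 2, offabs * 100 + seq_len(k), "+")
  bestj <- max.col(-score, ties.method = "first")
  bestnm <- NM[cbind(seq_len(n), bestj)]
  keep <- which(bestnm <= cfg$max_mismatches)
  if (length(keep) == 0L) return(NULL)

  category <- character(length(keep))
  tail_seq <- character(length(keep))
  tpl_len <- rep(NA_integer_, length(keep))
  mm_str <- character(length(keep))
  drop <- logical(length(keep))

  exact <- bestnm[keep] == 0
  category[exact] <- "TEMPLATED"
  tail_seq[exact] <- ""
  tpl_len[exact] <- L
  mm_str[exact] <- ""

  for (ii in which(!exact)) {
    row <- keep[ii]
    tmpl <- tmpl_for(starts[bestj[row]])
    rc <- mat[row, ]
    mmpos <- which(rc != tmpl | rc == "N" | tmpl == "N")
    cl <- .classify_mm(seqs[row], mmpos, cfg)
    if (cl$category == "UNASSIGNED") {
      drop[ii] <- TRUE
      next
    }
    category[ii] <- cl$category
    tail_seq[ii] <- .to_rna(cl$tail_seq)
    tpl_len[ii] <- cl$templated_prefix_len
    mm_str[ii] <- paste(cl$mismatch_positions, collapse = ",")
  }
  keep <- keep[!drop]
  if (length(keep) == 0L) return(NULL)
  sel <- !drop
  data.frame(
    read_id = ids[keep],
    hairpin_id = m$hairpin_id,
    mature_id = m$mature_id,
    category = category[sel],
    offset5 = starts[bestj[keep]] - m$start,
    read_length = L,
    templated_prefix_len = tpl_len[sel],
    tail_seq = tail_seq[sel],
    mismatch_positions_1based = mm_str[sel],
    stringsAsFactors = FALSE
  )
}

#' Classify a collapsed read library against annotated hairpins
#'
#' Reads exactly matching a spike-in sequence are called `SPIKEIN`; every
#' remaining read is aligned to every (hairpin, mature) pair with
#' [align_anchored()] semantics.  A read assigned to k > 1 matures
#' receives k calls, each flagged `multimap_n = k`; a read matching
#' nothing receives a single `UNASSIGNED` call.  Output is deterministic
#' given deterministic input.
#'
#' @param reads Collapsed read data frame (`read_id`, `sequence`,
#'   `count`) or a character vector of sequences (collapsed internally).
#' @param hairpins Named character vector of hairpin sequences.
#' @param annotations Mature annotation data frame (0-based half-open).
#' @param spikes Optional `spikein_set`.
#' @param cfg A [map_config()].
#' @return A data frame of read calls with the per-read `count` joined on;
#'   the total read count matching a spike-in is available as
#'   `attr(, "spike_matched")`.
#' @export
classify_library <- function(reads, hairpins, annotations, spikes = NULL,
                             cfg = map_config()) {
  if (is.character(reads)) reads <- collapse_reads(reads)
  if (anyDuplicated(annotations$mature_id)) {
    stop_validation(sprintf(
      "duplicate mature_ids: %s",
      paste(unique(annotations$mature_id[duplicated(annotations$mature_id)]),
            collapse = ", ")
    ))
  }
  validate_annotations(annotations, hairpins)
  reads$sequence <- .to_dna(reads$sequence)

  spike_rows <- NULL
  is_spike <- rep(FALSE, nrow(reads))
  spike_matched <- 0L
  if (!is.null(spikes)) {
    is_spike <- reads$sequence %in% spikes$records$sequence
    spike_matched <- sum(reads$count[is_spike])
    if (any(is_spike)) {
      spike_rows <- data.frame(
        read_id = reads$read_id[is_spike],
        hairpin_id = NA_character_, mature_id = NA_character_,
        category = "SPIKEIN", offset5 = NA_integer_,
        read_length = nchar(reads$sequence[is_spike]),
        templated_prefix_len = NA_integer_, tail_seq = "",
        mismatch_positions_1based = "", stringsAsFactors = FALSE
      )
    }
  }

  q <- reads[!is_spike, , drop = FALSE]
  pair_calls <- list()
  if (nrow(q) > 0L) {
    lens <- nchar(q$sequence)
    hp_chars <- lapply(hairpins, function(s) strsplit(s, "", fixed = TRUE)[[1]])
    for (L in sort(unique(lens))) {
      grp <- which(lens == L)
      mat <- matrix(unlist(strsplit(q$sequence[grp], "", fixed = TRUE),
                           use.names = FALSE),
                    nrow = length(grp), ncol = L, byrow = TRUE)
      for (a in seq_len(nrow(annotations))) {
        m <- annotations[a, ]
        res <- .align_pair_group(mat, q$sequence[grp], q$read_id[grp],
                                 hp_chars[[m$hairpin_id]], m, cfg)
        if (!is.null(res)) pair_calls[[length(pair_calls) + 1L]] <- res
      }
    }
  }

  assigned <- if (length(pair_calls)) do.call(rbind, pair_calls) else NULL
  unmatched <- setdiff(q$read_id, if (is.null(assigned)) character(0)
                       else assigned$read_id)
  un_rows <- NULL
  if (length(unmatched)) {
    ri <- match(unmatched, reads$read_id)
    un_rows <- data.frame(
      read_id = unmatched, hairpin_id = NA_character_,
      mature_id = NA_character_, category = "UNASSIGNED",
      offset5 = NA_integer_, read_length = nchar(reads$sequence[ri]),
      templated_prefix_len = NA_integer_, tail_seq = "",
      mismatch_positions_1based = "", stringsAsFactors = FALSE
    )
  }

  calls <- do.call(rbind, Filter(Negate(is.null),
                                 list(assigned, un_rows, spike_rows)))
  # multimap flag: number of matures each read was assigned to
  n_assigned <- table(if (is.null(assigned)) character(0) else assigned$read_id)
  calls$multimap_n <- 1L
  hit <- calls$category %in% c("TEMPLATED", "NTA", "INTERNAL_MM")
  calls$multimap_n[hit] <- as.integer(n_assigned[calls$read_id[hit]])
  calls$count <- reads$count[match(calls$read_id, reads$read_id)]
  # deterministic order: input read order, then annotation order
  ord <- order(match(calls$read_id, reads$read_id),
               match(calls$mature_id, annotations$mature_id),
               method = "radix")
  calls <- calls[ord, , drop = FALSE]
  rownames(calls) <- NULL
  attr(calls, "spike_matched") <- spike_matched
  calls
}

#' Write a per-read call table as TSV
#'
#' @param calls Call table from [classify_library()].
#' @param path Output path.
#' @export
write_call_table <- function(calls, path) {
  cols <- c("read_id", "count", "hairpin_id", "mature_id", "category",
            "offset5", "read_length", "templated_prefix_len", "tail_seq",
            "mismatch_positions_1based", "multimap_n")
  utils::write.table(calls[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}
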