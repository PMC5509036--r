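# Anchored comparison of a read against a hairpin around an annotated
# mature 5' start, and the mutually exclusive classification of the result
# into templated isoform / 3' nontemplated addition (NTA) / internal
# mismatch / unassigned.
#
# Comparison is substitution-only (no indels).  Read positions extending
# past the hairpin 3' end count as mismatches: there is no template there,
# so they are nontemplated by construction.  N never matches anything.

#' Mapping and classification configuration
#'
#' @param max_mismatches Maximum total mismatches for a read to be
#'   classified at all (default 2, matching the mismatch allowance used
#'   for NTA detection in small RNA studies).
#' @param anchor_window Maximum absolute offset of the read 5' start from
#'   the annotated mature 5' start, in nt (default 3).
#' @param min_len,max_len Read-length window tabulated in isoform spectra
#'   (defaults 18 and 24).
#' @param tail_max Maximum length of a terminal nontemplated run called as
#'   a tail (default 2: mono and di additions).
#' @return An object of class `map_config`.
#' @export
map_config <- function(max_mismatches = 2L, anchor_window = 3L,
                       min_len = 18L, max_len = 24L, tail_max = 2L) {
  stopifnot(max_mismatches >= 0L, anchor_window >= 0L, tail_max >= 0L,
            min_len <= max_len)
  structure(
    list(max_mismatches = as.integer(max_mismatches),
         anchor_window = as.integer(anchor_window),
         min_len = as.integer(min_len),
         max_len = as.integer(max_len),
         tail_max = as.integer(tail_max)),
    class = "map_config"
  )
}

# mismatch positions (1-based, on the read) of read `rr` (raw vector)
# placed at 0-based hairpin offset `s`; `hp` is the hairpin raw vector.
.mismatch_positions <- function(rr, hp, s) {
  L <- length(rr)
  idx <- s + seq_len(L)
  inb <- idx <= length(hp)
  tmpl <- raw(L)                      # 0x00 never equals a base
  tmpl[inb] <- hp[idx[inb]]
  rawN <- as.raw(78L)                 # "N"
  which(tmpl != rr | rr == rawN | tmpl == rawN)
}

# classify a placed read from its mismatch positions; returns a list with
# category / tail / templated prefix length.  A terminal mismatch run of
# length <= tail_max containing ALL mismatches is a tail; anything else
# with at least one strictly internal mismatch (and total within budget)
# is an internal mismatch call.
.classify_mm <- function(read_seq, mmpos, cfg) {
  L <- nchar(read_seq)
  n_mm <- length(mmpos)
  if (n_mm == 0L) {
    return(list(category = "TEMPLATED", tail_seq = "",
                templated_prefix_len = L, mismatch_positions = integer(0)))
  }
  # length of the contiguous mismatch run ending at the last read position
  run <- 0L
  while (run < n_mm && mmpos[n_mm - run] == L - run) run <- run + 1L
  if (n_mm <= cfg$max_mismatches && run == n_mm && run <= cfg$tail_max) {
    return(list(category = "NTA",
                tail_seq = substr(read_seq, L - run + 1L, L),
                templated_prefix_len = L - run,
                mismatch_positions = mmpos))
  }
  if (n_mm <= cfg$max_mismatches && any(mmpos < L)) {
    return(list(category = "INTERNAL_MM", tail_seq = "",
                templated_prefix_len = NA_integer_,
                mismatch_positions = mmpos))
  }
  list(category = "UNASSIGNED", tail_seq = "",
       templated_prefix_len = NA_integer_,
       mismatch_positions = mmpos)
}

.read_call <- function(read_id, hairpin_id, mature_id, category,
                       offset5 = NA_integer_, read_length = NA_integer_,
                       templated_prefix_len = NA_integer_, tail_seq = "",
                       mismatch_positions = integer(0), multimap_n = 1L) {
  data.frame(
    read_id = read_id, hairpin_id = hairpin_id, mature_id = mature_id,
    category = category, offset5 = offset5, read_length = read_length,
    templated_prefix_len = templated_prefix_len,
    tail_seq = .to_rna(tail_seq),
    mismatch_positions_1based = paste(mismatch_positions, collapse = ","),
    multimap_n = multimap_n, stringsAsFactors = FALSE
  )
}

#' Align one read to one annotated mature product
#'
#' Compares the read against the hairpin at every candidate 5' start
#' within `anchor_window` of the annotated mature start, position by
#' position.  The candidate minimising (mismatch count, |5' offset|,
#' start) wins, and the winning placement is classified:
#' `TEMPLATED` (no mismatches), `NTA` (all mismatches form a terminal
#' suffix of length at most `tail_max`), `INTERNAL_MM` (any mismatch
#' before the last position, total within `max_mismatches`), otherwise
#' `UNASSIGNED`.  A 3' nucleotide that matches the hairpin is templated
#' extension, never a tail.
#'
#' @param read_seq Read sequence (DNA).
#' @param hairpin_seq Hairpin sequence (DNA).
#' @param mature One annotation row (list or data frame row with
#'   `mature_id`, `hairpin_id`, `start`, `end`; 0-based half-open).
#' @param cfg A [map_config()].
#' @param read_id Read id carried into the call (default `"read"`).
#' @return A one-row data frame (a read call).
#' @export
align_anchored <- function(read_seq, hairpin_seq, mature, cfg = map_config(),
                           read_id = "read") {
  read_seq <- .to_dna(read_seq)
  hairpin_seq <- .to_dna(hairpin_seq)
  rr <- charToRaw(read_seq)
  hp <- charToRaw(hairpin_seq)
  starts <- (mature$start - cfg$anchor_window):(mature$start + cfg$anchor_window)
  starts <- starts[starts >= 0L & starts < length(hp)]
  if (length(starts) == 0L) {
    return(.read_call(read_id, mature$hairpin_id, mature$mature_id,
                      "UNASSIGNED", read_length = length(rr)))
  }
  best <- NULL
  for (s in starts) {
    mmpos <- .mismatch_positions(rr, hp, s)
    key <- c(length(mmpos), abs(s - mature$start), s)
    if (is.null(best) ||
        key[1] < best$key[1] ||
        (key[1] == best$key[1] && key[2] < best$key[2]) ||
        (key[1] == best$key[1] && key[2] == best$key[2] && key[3] < best$key[3])) {
      best <- list(s = s, mmpos = mmpos, key = key)
    }
  }
  cl <- .classify_mm(read_seq, best$mmpos, cfg)
  if (cl$category == "UNASSIGNED") {
    return(.read_call(read_id, mature$hairpin_id, mature$mature_id,
                      "UNASSIGNED", read_length = length(rr)))
  }
  .read_call(read_id, mature$hairpin_id, mature$mature_id, cl$category,
             offset5 = best$s - mature$start, read_length = length(rr),
             templated_prefix_len = cl$templated_prefix_len,
             tail_seq = cl$tail_seq,
             mismatch_positions = cl$mismatch_positions)
}

#' Exhaustive placement oracle
#'
#' Literal re-enumeration of every start position on the hairpin (or,
#' when `mature` and a finite `window` are given, every start inside the
#' anchor window) with a character-by-character mismatch recount.  Used in
#' tests to certify [align_anchored()]; deliberately implemented on a
#' different code path (character vectors, not raw bytes).
#'
#' @inheritParams align_anchored
#' @param mature Optional annotation row; when given, offsets are relative
#'   to its start and ties prefer smaller |offset|.
#' @param window Anchor window restriction (`Inf` = scan the whole
#'   hairpin).
#' @return A one-row data frame (a read call).
#' @export
brute_force_oracle <- function(read_seq, hairpin_seq, mature = NULL,
                               cfg = map_config(), window = Inf,
                               read_id = "read") {
  read_seq <- .to_dna(read_seq)
  hairpin_seq <- .to_dna(hairpin_seq)
  rc <- strsplit(read_seq, "", fixed = TRUE)[[1]]
  hc <- strsplit(hairpin_seq, "", fixed = TRUE)[[1]]
  L <- length(rc)
  anchor <- if (is.null(mature)) 0L else mature$start
  starts <- 0:(length(hc) - 1L)
  if (is.finite(window)) starts <- starts[abs(starts - anchor) <= window]
  mature_id <- if (is.null(mature)) NA_character_ else mature$mature_id
  hairpin_id <- if (is.null(mature)) NA_character_ else mature$hairpin_id
  if (length(starts) == 0L) {
    return(.read_call(read_id, hairpin_id, mature_id, "UNASSIGNED",
                      read_length = L))
  }
  score <- lapply(starts, function(s) {
    tmpl <- rep("-", L)
    take <- seq_len(min(L, length(hc) - s))
    tmpl[take] <- hc[s + take]
    mm <- which(tmpl != rc | rc == "N" | tmpl == "N")
    list(s = s, mm = mm)
  })
  nmm <- vapply(score, function(x) length(x$mm), integer(1))
  offs <- abs(starts - anchor)
  ord <- order(nmm, offs, starts)
  bst <- score[[ord[1L]]]
  cl <- .classify_mm(read_seq, bst$mm, cfg)
  if (cl$category == "UNASSIGNED") {
    return(.read_call(read_id, hairpin_id, mature_id, "UNASSIGNED",
                      read_length = L))
  }
  .read_call(read_id, hairpin_id, mature_id, cl$category,
             offset5 = bst$s - anchor, read_length = L,
             templated_prefix_len = cl$templated_prefix_len,
             tail_seq = cl$tail_seq,
             mismatch_positions = cl$mismatch_positions)
}
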