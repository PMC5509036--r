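# Adapter trimming and minimum-length filtering — the Cutadapt-style
# preprocessing stage for raw small RNA reads.

#' Adapter trimming configuration
#'
#' Parameters for 3' adapter removal.  Semantics follow the standard
#' leftmost-match rule for 3' adapters: the read is cut at the first
#' position from which its remainder aligns to a prefix of the adapter
#' with at most `floor(rate * overlap)` mismatches and overlap at least
#' `min_overlap`.
#'
#' @param adapter 3' adapter sequence (DNA; U accepted and converted).
#'   Default is the Illumina TruSeq small RNA 3' adapter.
#' @param max_adapter_mismatch_rate Allowed mismatch fraction of the
#'   aligned overlap, in `[0, 1]`.  Default 0.1.
#' @param min_overlap Minimum read/adapter overlap to call a match
#'   (default 5, minimum 3).
#' @param min_length Reads shorter than this after trimming are discarded
#'   (default 18; a read of exactly `min_length` is kept).
#' @return An object of class `trim_config`.
#' @export
trim_config <- function(adapter = "TGGAATTCTCGGGTGCCAAGG",
                        max_adapter_mismatch_rate = 0.1,
                        min_overlap = 5L,
                        min_length = 18L) {
  adapter <- .to_dna(adapter)
  if (!nzchar(adapter)) stop_validation("adapter must be non-empty")
  if (max_adapter_mismatch_rate < 0 || max_adapter_mismatch_rate > 1) {
    stop_validation("max_adapter_mismatch_rate must lie in [0, 1]")
  }
  if (min_overlap < 3L) stop_validation("min_overlap must be >= 3")
  structure(
    list(adapter = adapter,
         max_adapter_mismatch_rate = max_adapter_mismatch_rate,
         min_overlap = as.integer(min_overlap),
         min_length = as.integer(min_length)),
    class = "trim_config"
  )
}

#' Trim a 3' adapter from one read
#'
#' Pure function: returns the read prefix before the leftmost adapter
#' match, or the read unchanged when no position qualifies.  The returned
#' sequence is always a prefix of the input, so trimming is idempotent.
#'
#' @param read_seq Read sequence (DNA).
#' @param cfg A [trim_config()].
#' @return The trimmed sequence (possibly empty, possibly unchanged).
#' @export
trim_adapter <- function(read_seq, cfg) {
  read_seq <- .to_dna(read_seq)
  n <- nchar(read_seq)
  ad <- charToRaw(cfg$adapter)
  rr <- charToRaw(read_seq)
  la <- length(ad)
  if (n < cfg$min_overlap) return(read_seq)
  for (i in 0:(n - cfg$min_overlap)) {
    ov <- min(n - i, la)
    mm <- sum(rr[(i + 1L):(i + ov)] != ad[seq_len(ov)])
    if (mm <= floor(cfg$max_adapter_mismatch_rate * ov)) {
      return(substr(read_seq, 1L, i))
    }
  }
  read_seq
}

#' Filter reads by minimum length
#'
#' Reads of length `>= min_length` are kept ("shorter than `min_length`"
#' is discarded, so the boundary length itself passes).
#'
#' @param sequences Character vector of read sequences.
#' @param min_length Minimum length kept.
#' @return A list: `kept` (character vector) and `n_discarded`.
#' @export
length_filter <- function(sequences, min_length = 18L) {
  keep <- nchar(sequences) >= min_length
  list(kept = sequences[keep], n_discarded = sum(!keep))
}

#' Preprocess a raw read library
#'
#' Collapses identical raw reads, trims the 3' adapter from each unique
#' sequence, applies the minimum-length filter and re-collapses.  Total
#' read counts are conserved: `sum(collapsed count) + n_discarded` equals
#' the number of input reads.
#'
#' @param sequences Character vector of raw read sequences.
#' @param cfg A [trim_config()], or `NULL` to skip adapter trimming.
#' @param min_length Minimum post-trim length kept (taken from `cfg` when
#'   one is given).
#' @return A list: `reads` (collapsed data frame), `n_input`,
#'   `n_discarded`.
#' @export
preprocess_reads <- function(sequences, cfg = trim_config(),
                             min_length = 18L) {
  n_input <- length(sequences)
  if (!is.null(cfg)) min_length <- cfg$min_length
  raw_collapsed <- collapse_reads(.to_dna(sequences))
  trimmed <- raw_collapsed$sequence
  if (!is.null(cfg)) {
    trimmed <- vapply(trimmed, trim_adapter, character(1), cfg = cfg,
                      USE.NAMES = FALSE)
  }
  keep <- nchar(trimmed) >= min_length
  n_discarded <- sum(raw_collapsed$count[!keep])
  kept_seq <- rep.int(trimmed[keep], raw_collapsed$count[keep])
  reads <- collapse_reads(kept_seq)
  list(reads = reads, n_input = n_input, n_discarded = n_discarded)
}
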