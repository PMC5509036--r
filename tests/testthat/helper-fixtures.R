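# Shared fixtures: the worked hairpin example, small random references and
# an invariant checker applied to every classified corpus.

# 31 nt hairpin whose first 22 nt are the annotated mature product;
# position 23 (1-based) is G, so a 3' G is templated extension while
# U/A/C additions are nontemplated.
tiny_hairpin <- "TGAGGTAGTAGGTTGTATAGTTGGGATCCAA"
tiny_mature <- list(mature_id = "m1", hairpin_id = "h1",
                    start = 0L, end = 22L)
tiny_mature_seq <- substr(tiny_hairpin, 1, 22)

rand_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

write_tmp <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# independent adapter-scan oracle: enumerate every cut position with
# plain substring comparisons (no shared code with trim_adapter)
oracle_trim <- function(read, adapter, rate = 0.1, min_overlap = 5L) {
  n <- nchar(read)
  for (i in 0:(n - min_overlap)) {
    ov <- min(n - i, nchar(adapter))
    a <- substr(read, i + 1, i + ov)
    b <- substr(adapter, 1, ov)
    mm <- sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
    if (mm <= floor(rate * ov)) return(substr(read, 1, i))
  }
  read
}

split1 <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

# assert the category invariants of every call in a table; `rows` limits
# the per-call detail loop (global checks always run on the full table)
check_call_invariants <- function(calls, reads, hairpins, cfg,
                                  rows = seq_len(nrow(calls))) {
  seqs <- reads$sequence[match(calls$read_id, reads$read_id)]
  expect_true(all(calls$category %in%
                    c("TEMPLATED", "NTA", "INTERNAL_MM", "SPIKEIN",
                      "UNASSIGNED")))
  # every read receives at least one call
  expect_true(all(reads$read_id %in% calls$read_id))
  # at most one call per (read, mature)
  assigned <- calls[!is.na(calls$mature_id), , drop = FALSE]
  expect_false(anyDuplicated(paste(assigned$read_id,
                                   assigned$mature_id)) > 0)
  for (i in rows) {
    cat_i <- calls$category[i]
    L <- calls$read_length[i]
    mm <- calls$mismatch_positions_1based[i]
    mmpos <- if (nzchar(mm)) as.integer(strsplit(mm, ",")[[1]]) else integer(0)
    if (cat_i == "TEMPLATED") {
      expect_identical(mmpos, integer(0))
      expect_identical(calls$tail_seq[i], "")
      expect_identical(calls$templated_prefix_len[i], L)
      expect_true(grepl(seqs[i], hairpins[[calls$hairpin_id[i]]],
                        fixed = TRUE))
    } else if (cat_i == "NTA") {
      tl <- nchar(calls$tail_seq[i])
      expect_true(tl >= 1L && tl <= cfg$tail_max)
      expect_true(length(mmpos) <= cfg$max_mismatches)
      expect_identical(mmpos, seq.int(L - tl + 1L, L))
      expect_identical(calls$templated_prefix_len[i], L - tl)
    } else if (cat_i == "INTERNAL_MM") {
      expect_true(length(mmpos) >= 1L &&
                    length(mmpos) <= cfg$max_mismatches)
      expect_true(any(mmpos < L))
    }
  }
  invisible(TRUE)
}
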