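# Helpers to fabricate call tables directly (category semantics are
# covered by the alignment tests; here we exercise the aggregation).
mk_calls <- function(category, count, mature_id = "m1", read_length = 22L,
                     tail_seq = "", mismatch = "", multimap_n = 1L) {
  n <- max(lengths(list(category, count, mature_id, read_length, tail_seq,
                        mismatch)))
  data.frame(
    read_id = sprintf("r%d", seq_len(n)), hairpin_id = "h1",
    mature_id = mature_id, category = category, offset5 = 0L,
    read_length = read_length, templated_prefix_len = read_length,
    tail_seq = tail_seq, mismatch_positions_1based = mismatch,
    multimap_n = multimap_n, count = count, stringsAsFactors = FALSE
  )
}

test_that("guide selection follows the strict 'above 50' cutoff", {
  ann <- data.frame(mature_id = c("m1", "m1s"), hairpin_id = "h1",
                    start = c(4L, 40L), end = c(26L, 62L),
                    stringsAsFactors = FALSE)
  calls <- mk_calls("TEMPLATED", c(500L, 30L), c("m1", "m1s"))
  g <- select_guides(calls, ann)
  expect_identical(g$mature_id[g$retained], "m1")
  expect_true(g$is_guide[g$mature_id == "m1"])
  expect_false(g$is_guide[g$mature_id == "m1s"])

  # count exactly 50 excluded, 51 included
  g50 <- select_guides(mk_calls("TEMPLATED", c(50L, 3L), c("m1", "m1s")), ann)
  expect_identical(sum(g50$retained), 0L)
  expect_true(g50$is_guide[1])
  g51 <- select_guides(mk_calls("TEMPLATED", c(51L, 3L), c("m1", "m1s")), ann)
  expect_identical(g51$mature_id[g51$retained], "m1")

  # tied arms resolve toward the 5' arm (smaller start)
  gt <- select_guides(mk_calls("TEMPLATED", c(100L, 100L), c("m1s", "m1"),
                               read_length = 22L), ann)
  expect_true(gt$is_guide[gt$mature_id == "m1"])
  expect_false(gt$is_guide[gt$mature_id == "m1s"])
})

test_that("isoform spectra count only templated reads and normalise", {
  calls <- mk_calls(c("TEMPLATED", "TEMPLATED", "TEMPLATED", "NTA"),
                    c(10L, 80L, 10L, 99L), "m1",
                    read_length = c(21L, 22L, 23L, 23L),
                    tail_seq = c("", "", "", "U"))
  sp <- isoform_spectrum(calls, "m1")
  expect_identical(unname(sp$counts[c("21", "22", "23")]), c(10, 80, 10))
  expect_equal(unname(sp$fractions[c("21", "22", "23")]), c(0.1, 0.8, 0.1))
  expect_equal(sum(sp$fractions), 1)

  single <- isoform_spectrum(mk_calls("TEMPLATED", 5L), "m1")
  expect_equal(unname(single$fractions[["22"]]), 1)
  empty <- isoform_spectrum(mk_calls("NTA", 5L, tail_seq = "U"), "m1")
  expect_identical(empty$total, 0)
  expect_true(all(is.na(empty$fractions)))
})

test_that("NTA profiles tabulate mono additions with per-position shares", {
  calls <- mk_calls(rep("NTA", 4), c(60L, 30L, 5L, 5L), "m1",
                    read_length = 23L, tail_seq = c("U", "A", "C", "G"))
  pr <- nta_profile(calls, "m1")
  expect_equal(unname(pr$percentages["23", ]), c(60, 30, 5, 5),
               ignore_attr = TRUE)
  expect_equal(sum(pr$percentages["23", ]), 100)
  expect_true(all(is.na(pr$percentages["21", ])))

  none <- nta_profile(mk_calls("TEMPLATED", 10L), "m1")
  expect_true(all(is.na(none$percentages)))
  expect_identical(sum(none$counts), 0)

  # di-nucleotide tails are excluded from the mono profile
  di <- mk_calls("NTA", 10L, read_length = 23L, tail_seq = "UU")
  expect_identical(sum(nta_profile(di, "m1")$counts), 0)
})

test_that("spike-in normalisation scales counts and preserves fractions", {
  expect_equal(normalize_counts(50, 2000), 25000)
  expect_equal(normalize_counts(c(10, 20), 0, fallback_total = 1e6),
               c(10, 20))
  expect_error(normalize_counts(5, 0, 0), class = "mirtail_validation_error")

  set.seed(31)
  for (i in 1:10) {
    counts <- stats::rpois(7, 100) + 1
    anchor <- sample(100:5000, 1)
    norm <- normalize_counts(counts, anchor)
    expect_equal(norm / sum(norm), counts / sum(counts))
  }
})

test_that("the terminal/internal fold follows its definition", {
  internal <- mk_calls(rep("INTERNAL_MM", 22), rep(10L, 22),
                       read_length = 22L,
                       mismatch = as.character(1:22))
  terminal <- mk_calls("NTA", 700L, read_length = 23L, tail_seq = "U")
  terminal$read_id <- "rt"
  fr <- terminal_internal_fold(rbind(internal, terminal))
  expect_equal(fr$terminal_count, 700)
  expect_equal(fr$internal_mean, 10)
  expect_equal(fr$fold, 70)

  # no internal mismatches: fold undefined
  fr2 <- terminal_internal_fold(terminal)
  expect_true(is.na(fr2$fold))

  # multi-mismatch internal calls are not single-mismatch background
  multi <- mk_calls("INTERNAL_MM", 50L, mismatch = "3,7")
  fr3 <- terminal_internal_fold(rbind(terminal, multi))
  expect_true(is.na(fr3$fold))
})

test_that("the heat-map matrix assembles spectra across samples", {
  calls_a <- mk_calls(c("TEMPLATED", "TEMPLATED"), c(80L, 20L),
                      c("m1", "m1"), read_length = c(22L, 23L))
  calls_a2 <- mk_calls("TEMPLATED", 40L, "m2")
  sp_a <- list(isoform_spectrum(calls_a, "m1"),
               isoform_spectrum(calls_a2, "m2"))
  sp_b <- list(isoform_spectrum(calls_a, "m1"))
  m <- heatmap_matrix(list(sampleA = sp_a, sampleB = sp_b))
  expect_identical(rownames(m), c("m1", "m2"))  # descending total
  expect_equal(sum(m["m1", grepl("sampleA", colnames(m))]), 1)
  expect_true(all(is.na(m["m2", grepl("sampleB", colnames(m))])))

  p1 <- tempfile(fileext = ".tsv")
  p2 <- tempfile(fileext = ".tsv")
  write_count_table(m, p1)
  write_count_table(read_count_table(p1), p2)
  expect_identical(readLines(p1), readLines(p2))
})
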