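# Hairpin: first 22 nt are the mature; position 23 (1-based) is G.

test_that("anchored alignment reproduces the canonical worked examples", {
  cfg <- map_config()
  # exact mature sequence -> templated, length 22, no offset
  c1 <- align_anchored(tiny_mature_seq, tiny_hairpin, tiny_mature, cfg)
  expect_identical(c1$category, "TEMPLATED")
  expect_identical(c1$read_length, 22L)
  expect_identical(c1$offset5, 0L)
  expect_identical(c1$templated_prefix_len, 22L)

  # 3' T where the hairpin has G: mono-U nontemplated addition
  c2 <- align_anchored(paste0(tiny_mature_seq, "T"), tiny_hairpin,
                       tiny_mature, cfg)
  expect_identical(c2$category, "NTA")
  expect_identical(c2$tail_seq, "U")
  expect_identical(c2$templated_prefix_len, 22L)
  expect_identical(c2$read_length, 23L)

  # substitution at read position 11: internal mismatch
  r3 <- tiny_mature_seq
  substr(r3, 11, 11) <- "C"
  c3 <- align_anchored(r3, tiny_hairpin, tiny_mature, cfg)
  expect_identical(c3$category, "INTERNAL_MM")
  expect_identical(c3$mismatch_positions_1based, "11")

  # 3' G matches the hairpin: templated length-23 isoform, never a tail
  c4 <- align_anchored(paste0(tiny_mature_seq, "G"), tiny_hairpin,
                       tiny_mature, cfg)
  expect_identical(c4$category, "TEMPLATED")
  expect_identical(c4$read_length, 23L)
  expect_identical(c4$tail_seq, "")
})

test_that("reads overhanging the hairpin 3' end are tailed by construction", {
  cfg <- map_config()
  hp <- substr(tiny_hairpin, 1, 23)  # hairpin ends right after position 23
  m <- list(mature_id = "m1", hairpin_id = "h1", start = 0L, end = 22L)
  cl <- align_anchored(paste0(substr(hp, 1, 23), "A"), hp, m, cfg)
  expect_identical(cl$category, "NTA")
  expect_identical(cl$tail_seq, "A")
})

test_that("N never matches any reference base", {
  cfg <- map_config()
  r <- tiny_mature_seq
  substr(r, 5, 5) <- "N"
  cl <- align_anchored(r, tiny_hairpin, tiny_mature, cfg)
  expect_identical(cl$category, "INTERNAL_MM")
  expect_identical(cl$mismatch_positions_1based, "5")
})

test_that("anchored alignment agrees with the exhaustive oracle in-window", {
  cfg <- map_config()
  set.seed(101)
  n_trials <- 2000
  for (i in seq_len(n_trials)) {
    hp <- rand_seq(sample(60:90, 1))
    start <- sample(4:30, 1)
    m <- list(mature_id = "m", hairpin_id = "h", start = start,
              end = start + 22L)
    L <- sample(18:24, 1)
    off <- sample(-3:3, 1)
    read <- substr(hp, start + off + 1, start + off + L)
    # random mutations: tails, internal substitutions, or none
    k <- sample(0:3, 1)
    if (k > 0) {
      pos <- sample(nchar(read), k)
      for (p in pos) {
        substr(read, p, p) <- sample(c("A", "C", "G", "T"), 1)
      }
    }
    a <- align_anchored(read, hp, m, cfg)
    b <- brute_force_oracle(read, hp, m, cfg, window = cfg$anchor_window)
    expect_identical(a$category, b$category)
    expect_identical(a$offset5, b$offset5)
    expect_identical(a$tail_seq, b$tail_seq)
    expect_identical(a$mismatch_positions_1based,
                     b$mismatch_positions_1based)
  }
})

test_that("reads placed outside the anchor window are unassigned", {
  cfg <- map_config(anchor_window = 3)
  hp <- rand_seq(80)
  m <- list(mature_id = "m", hairpin_id = "h", start = 10L, end = 32L)
  read <- substr(hp, 31, 52)  # true start 30, |offset| = 20
  inwin <- align_anchored(read, hp, m, cfg)
  free <- brute_force_oracle(read, hp, cfg = cfg)
  expect_identical(inwin$category, "UNASSIGNED")
  expect_identical(free$category, "TEMPLATED")
})

test_that("increasing max_mismatches never loses assignments", {
  set.seed(103)
  hp <- c(h1 = rand_seq(80))
  ann <- data.frame(mature_id = "m1", hairpin_id = "h1", start = 10L,
                    end = 32L, stringsAsFactors = FALSE)
  reads <- vapply(1:300, function(i) {
    r <- substr(hp[[1]], 11, 11 + sample(18:24, 1) - 1)
    k <- sample(0:4, 1)
    if (k > 0) {
      for (p in sample(nchar(r), k)) {
        substr(r, p, p) <- sample(c("A", "C", "G", "T"), 1)
      }
    }
    r
  }, character(1))
  n_assigned <- vapply(0:4, function(mm) {
    calls <- classify_library(reads, hp, ann,
                              cfg = map_config(max_mismatches = mm))
    sum(calls$category != "UNASSIGNED")
  }, numeric(1))
  expect_false(is.unsorted(n_assigned))
})

test_that("a terminal base matching the next hairpin base is never a tail", {
  cfg <- map_config()
  set.seed(107)
  for (i in 1:200) {
    hp <- rand_seq(70)
    start <- sample(4:30, 1)
    L <- sample(18:23, 1)
    m <- list(mature_id = "m", hairpin_id = "h", start = start,
              end = start + 22L)
    read <- substr(hp, start + 1, start + L + 1)  # extended by one
    cl <- align_anchored(read, hp, m, cfg)
    expect_identical(cl$category, "TEMPLATED")
  }
})

test_that("the vectorised library engine equals the scalar aligner", {
  cfg <- map_config()
  set.seed(109)
  hp <- c(h1 = rand_seq(70), h2 = rand_seq(85))
  ann <- data.frame(
    mature_id = c("h1-5p", "h1-3p", "h2-5p", "h2-3p"),
    hairpin_id = c("h1", "h1", "h2", "h2"),
    start = c(4L, 42L, 4L, 57L), end = c(26L, 64L, 26L, 79L),
    stringsAsFactors = FALSE
  )
  reads <- vapply(1:400, function(i) {
    a <- ann[sample(4, 1), ]
    off <- sample(-3:3, 1)
    L <- sample(18:25, 1)
    r <- substr(hp[[a$hairpin_id]], a$start + off + 1, a$start + off + L)
    k <- sample(0:3, 1)
    if (k > 0) {
      for (p in sample(nchar(r), k)) {
        substr(r, p, p) <- sample(c("A", "C", "G", "T", "N"), 1)
      }
    }
    r
  }, character(1))
  col <- collapse_reads(reads)
  calls <- classify_library(col, hp, ann, cfg = cfg)
  assigned <- calls[!is.na(calls$mature_id), , drop = FALSE]
  for (i in seq_len(nrow(assigned))) {
    a <- ann[ann$mature_id == assigned$mature_id[i], ]
    sc <- align_anchored(
      col$sequence[match(assigned$read_id[i], col$read_id)],
      hp[[a$hairpin_id]], as.list(a), cfg
    )
    expect_identical(assigned$category[i], sc$category)
    expect_identical(assigned$offset5[i], sc$offset5)
    expect_identical(assigned$tail_seq[i], sc$tail_seq)
    expect_identical(assigned$mismatch_positions_1based[i],
                     sc$mismatch_positions_1based)
  }
  check_call_invariants(calls, col, hp, cfg)
})

test_that("spike-ins, multimapping and duplicate ids behave as specified", {
  cfg <- map_config()
  hp <- c(h1 = tiny_hairpin, h2 = tiny_hairpin)  # identical hairpins
  ann <- data.frame(mature_id = c("m1", "m2"), hairpin_id = c("h1", "h2"),
                    start = 0L, end = 22L, stringsAsFactors = FALSE)
  spikes <- spikein_set(c(sp1 = "ACGTACGTACGTACGTACGTAC"))
  reads <- data.frame(
    read_id = c("r1", "r2"),
    sequence = c(tiny_mature_seq, "ACGTACGTACGTACGTACGTAC"),
    count = c(3L, 7L), stringsAsFactors = FALSE
  )
  calls <- classify_library(reads, hp, ann, spikes, cfg)
  r1 <- calls[calls$read_id == "r1", ]
  expect_identical(nrow(r1), 2L)
  expect_identical(unique(r1$multimap_n), 2L)
  expect_identical(unique(r1$category), "TEMPLATED")
  expect_identical(calls$category[calls$read_id == "r2"], "SPIKEIN")
  expect_identical(attr(calls, "spike_matched"), 7L)

  bad_ann <- data.frame(mature_id = c("m1", "m1"),
                        hairpin_id = c("h1", "h2"),
                        start = 0L, end = 22L, stringsAsFactors = FALSE)
  expect_error(classify_library(reads, hp, bad_ann, cfg = cfg),
               class = "mirtail_validation_error")
})

test_that("unmatched reads receive exactly one UNASSIGNED call", {
  hp <- c(h1 = tiny_hairpin)
  ann <- data.frame(mature_id = "m1", hairpin_id = "h1", start = 0L,
                    end = 22L, stringsAsFactors = FALSE)
  calls <- classify_library(c("GGGGGGGGGGGGGGGGGGGGGG"), hp, ann)
  expect_identical(calls$category, "UNASSIGNED")
  expect_identical(nrow(calls), 1L)
})
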