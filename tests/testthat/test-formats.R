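test_that("read_fasta normalises case and U->T, preserves order", {
  p <- write_tmp(c(">h1", "ugagGUAG", ">h2", "ACGT", "acgt"), ".fa")
  fa <- read_fasta(p)
  expect_identical(fa$id, c("h1", "h2"))
  expect_identical(fa$sequence, c("TGAGGTAG", "ACGTACGT"))

  empty <- write_tmp(character(0), ".fa")
  expect_identical(nrow(read_fasta(empty)), 0L)
})

test_that("read_fasta rejects bad input with line-numbered parse errors", {
  p <- write_tmp(c(">h1", "ACGT$"), ".fa")
  err <- tryCatch(read_fasta(p), error = identity)
  expect_s3_class(err, "mirtail_parse_error")
  expect_identical(err$line, 2L)

  expect_error(read_fasta(write_tmp(c(">h1", ">h2", "ACGT"), ".fa")),
               class = "mirtail_parse_error")
  expect_error(read_fasta(write_tmp(c("ACGT"), ".fa")),
               class = "mirtail_parse_error")

  # permissive maps IUPAC ambiguity codes to N; strict refuses
  p2 <- write_tmp(c(">h1", "ACGRY"), ".fa")
  expect_error(read_fasta(p2, "strict"), class = "mirtail_parse_error")
  expect_identical(read_fasta(p2, "permissive")$sequence, "ACGNN")
})

test_that("FASTA round-trip preserves content and _xN counts are parsed", {
  set.seed(11)
  df <- data.frame(id = sprintf("r%d_x%d", 1:5, c(3L, 1L, 7L, 2L, 1L)),
                   sequence = vapply(rep(24, 5), rand_seq, character(1)))
  p <- tempfile(fileext = ".fa")
  write_fasta(df, p)
  back <- read_fasta(p)
  expect_identical(back$sequence, df$sequence)
  col <- read_collapsed_fasta(p)
  expect_identical(col$count, c(3L, 1L, 7L, 2L, 1L))
})

test_that("read_fastq parses records, validates lengths, handles gzip", {
  p <- write_tmp(c("@r1", "ACGT", "+", "IIII"), ".fq")
  fq <- read_fastq(p)
  expect_identical(nrow(fq), 1L)
  expect_identical(fq$sequence, "ACGT")

  bad <- write_tmp(c("@r1", "ACGT", "+", "III"), ".fq")
  err <- tryCatch(read_fastq(bad), error = identity)
  expect_s3_class(err, "mirtail_parse_error")
  expect_identical(err$record, 1L)

  expect_error(read_fastq(write_tmp(c("@r1", "ACGT", "+"), ".fq")),
               class = "mirtail_parse_error")

  # gzipped 3-record file round-trips in order
  df <- data.frame(id = c("a", "b", "c"),
                   sequence = c("ACGT", "GGTT", "TTAA"),
                   quality = c("IIII", "IIII", "IIII"))
  gz <- tempfile(fileext = ".fastq.gz")
  write_fastq(df, gz)
  expect_identical(read_fastq(gz)$id, c("a", "b", "c"))
})

test_that("collapse_reads counts distinct sequences deterministically", {
  col <- collapse_reads(c("AC", "AC", "GT"))
  expect_identical(col$sequence, c("AC", "GT"))
  expect_identical(col$count, c(2L, 1L))
  expect_identical(nrow(collapse_reads(character(0))), 0L)

  # conservation over random multisets
  set.seed(7)
  for (rep in 1:20) {
    pool <- vapply(rep(20, 4), rand_seq, character(1))
    n <- sample(50:1000, 1)
    reads <- sample(pool, n, replace = TRUE)
    col <- collapse_reads(reads)
    expect_identical(sum(col$count), n)
    expect_false(is.unsorted(rev(col$count)))
  }
})

test_that("annotation TSV validation enforces coordinates and references", {
  hp <- c(h1 = tiny_hairpin)
  ok <- write_tmp(c("mature_id\thairpin_id\tstart\tend", "m1\th1\t0\t22"),
                  ".tsv")
  ann <- read_annotation_tsv(ok, hp)
  expect_identical(ann$start, 0L)
  expect_identical(ann$end, 22L)

  bad1 <- write_tmp(c("mature_id\thairpin_id\tstart\tend", "m1\th1\t25\t20"),
                    ".tsv")
  expect_error(read_annotation_tsv(bad1, hp), "start >= end",
               class = "mirtail_validation_error")

  bad2 <- write_tmp(c("mature_id\thairpin_id\tstart\tend",
                      "m1\th_missing\t0\t22"), ".tsv")
  expect_error(read_annotation_tsv(bad2, hp), "h_missing",
               class = "mirtail_validation_error")
})

test_that("count tables serialise deterministically and round-trip", {
  m <- matrix(c(0.1, 0.8, 0.1, 1 / 3, 1 / 3, 1 / 3), nrow = 2, byrow = TRUE,
              dimnames = list(c("m1", "m2"), c("a", "b", "c")))
  p1 <- tempfile(fileext = ".tsv")
  write_count_table(m, p1)
  expect_identical(length(readLines(p1)), 3L)

  # parse and re-serialise: byte-identical
  p2 <- tempfile(fileext = ".tsv")
  write_count_table(read_count_table(p1), p2)
  expect_identical(readLines(p1), readLines(p2))

  p3 <- tempfile(fileext = ".tsv")
  write_count_table(matrix(numeric(0), 0, 3,
                           dimnames = list(NULL, c("a", "b", "c"))), p3)
  expect_identical(readLines(p3), "id\ta\tb\tc")
})

test_that("spike-in sets require pairwise distinct sequences", {
  expect_error(spikein_set(c(s1 = "ACGT", s2 = "ACGT")),
               class = "mirtail_validation_error")
  ss <- spikein_set(c(s1 = "ACGTACGT", s2 = "TTGGCCAA"))
  expect_identical(ss$matched_count, 0L)
})
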