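# Readers and writers for the external formats the pipeline touches:
# FASTA (plain or gzip, optionally count-collapsed), FASTQ, the mature
# annotation TSV and the labelled count tables written by the stats stage.
#
# Every sequence entering the package is normalised to the internal DNA
# convention: uppercase, U converted to T.  All coordinates are 0-based
# half-open; 1-based values appear only in report columns suffixed "_1based".

#' Read a FASTA file
#'
#' Parses a (possibly gzipped) FASTA file into a data frame of records.
#' Sequences are uppercased and U is converted to T (internal DNA
#' convention).  In `strict` mode any character outside A/C/G/T/N raises a
#' parse error naming the offending line; in `permissive` mode IUPAC
#' ambiguity codes are mapped to N.
#'
#' @param path Path to a FASTA file (`.gz` accepted).
#' @param alphabet_policy `"strict"` (default) or `"permissive"`.
#' @return A data frame with columns `id` and `sequence`, in file order.
#' @export
read_fasta <- function(path, alphabet_policy = c("strict", "permissive")) {
  alphabet_policy <- match.arg(alphabet_policy)
  .check_file(path, "FASTA file")
  con <- .open_text(path)
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)

  ids <- character(0)
  seqs <- character(0)
  cur_id <- NULL
  cur_seq <- character(0)
  header_line <- NA_integer_

  flush_record <- function() {
    if (is.null(cur_id)) return(invisible(NULL))
    s <- paste0(cur_seq, collapse = "")
    if (!nzchar(s)) {
      stop_parse(sprintf("empty sequence for record '%s'", cur_id),
                 line = header_line)
    }
    ids[[length(ids) + 1L]] <<- cur_id
    seqs[[length(seqs) + 1L]] <<- s
    invisible(NULL)
  }

  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    if (!nzchar(trimws(ln))) next
    if (startsWith(ln, ">")) {
      flush_record()
      id <- trimws(sub("^>", "", ln))
      id <- sub("\\s.*$", "", id)  # first token only
      if (!nzchar(id)) stop_parse("malformed FASTA header (empty id)", line = i)
      cur_id <- id
      cur_seq <- character(0)
      header_line <- i
    } else {
      if (is.null(cur_id)) {
        stop_parse("sequence data before first FASTA header", line = i)
      }
      s <- .to_dna(trimws(ln))
      bad <- gsub("[ACGTN]", "", s)
      if (nzchar(bad)) {
        if (alphabet_policy == "permissive" &&
            !nzchar(gsub(paste0("[", paste(.IUPAC_AMBIG, collapse = ""), "]"),
                         "", bad))) {
          s <- gsub(paste0("[", paste(.IUPAC_AMBIG, collapse = ""), "]"), "N", s)
        } else {
          stop_parse(
            sprintf("disallowed character '%s' in sequence",
                    substr(bad, 1L, 1L)),
            line = i
          )
        }
      }
      cur_seq[[length(cur_seq) + 1L]] <- s
    }
  }
  flush_record()

  data.frame(id = ids, sequence = seqs, stringsAsFactors = FALSE)
}

#' Read a reference hairpin set
#'
#' Wraps [read_fasta()] and enforces the hairpin invariants: non-empty
#' sequences and unique ids.
#'
#' @inheritParams read_fasta
#' @return A named character vector of hairpin sequences (names = ids).
#' @export
read_hairpins <- function(path, alphabet_policy = c("strict", "permissive")) {
  fa <- read_fasta(path, alphabet_policy)
  if (anyDuplicated(fa$id)) {
    stop_validation(sprintf(
      "duplicate hairpin ids: %s",
      paste(unique(fa$id[duplicated(fa$id)]), collapse = ", ")
    ))
  }
  stats::setNames(fa$sequence, fa$id)
}

#' Read a collapsed FASTA file
#'
#' Accepts the common small-RNA collapsing convention where the read count
#' is carried in the header as an `_xCOUNT` suffix (e.g. `>seq1_x42`).
#' Records without the suffix get count 1.
#'
#' @inheritParams read_fasta
#' @return A data frame of collapsed reads: `read_id`, `sequence`, `count`.
#' @export
read_collapsed_fasta <- function(path,
                                 alphabet_policy = c("strict", "permissive")) {
  fa <- read_fasta(path, alphabet_policy)
  count <- rep(1L, nrow(fa))
  has <- grepl("_x[0-9]+$", fa$id)
  count[has] <- as.integer(sub("^.*_x([0-9]+)$", "\\1", fa$id[has]))
  data.frame(read_id = fa$id, sequence = fa$sequence, count = count,
             stringsAsFactors = FALSE)
}

#' Write a FASTA file
#'
#' @param records Data frame with columns `id` and `sequence` (or
#'   `read_id`/`sequence`).
#' @param path Output path.
#' @export
write_fasta <- function(records, path) {
  id_col <- if ("id" %in% names(records)) "id" else "read_id"
  writeLines(
    as.vector(rbind(paste0(">", records[[id_col]]), records$sequence)),
    path
  )
  invisible(path)
}

#' Read a FASTQ file
#'
#' Parses 4-line FASTQ records (gzip accepted by extension).  Sequence and
#' quality lengths must agree; truncated files raise a parse error carrying
#' the record index.
#'
#' @param path Path to a FASTQ file.
#' @return Data frame with columns `id`, `sequence`, `quality`, file order.
#' @export
read_fastq <- function(path) {
  .check_file(path, "FASTQ file")
  con <- .open_text(path)
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  if (length(lines) %% 4L != 0L) {
    stop_parse(
      sprintf("truncated FASTQ file: %d lines is not a multiple of 4",
              length(lines)),
      record = length(lines) %/% 4L + 1L
    )
  }
  n <- length(lines) %/% 4L
  if (n == 0L) {
    return(data.frame(id = character(0), sequence = character(0),
                      quality = character(0), stringsAsFactors = FALSE))
  }
  hdr <- lines[seq(1L, by = 4L, length.out = n)]
  seq <- lines[seq(2L, by = 4L, length.out = n)]
  plus <- lines[seq(3L, by = 4L, length.out = n)]
  qual <- lines[seq(4L, by = 4L, length.out = n)]

  bad_hdr <- which(!startsWith(hdr, "@"))
  if (length(bad_hdr)) {
    stop_parse("FASTQ header does not start with '@'", record = bad_hdr[1L])
  }
  bad_plus <- which(!startsWith(plus, "+"))
  if (length(bad_plus)) {
    stop_parse("FASTQ separator does not start with '+'",
               record = bad_plus[1L])
  }
  mism <- which(nchar(seq) != nchar(qual))
  if (length(mism)) {
    stop_parse(
      sprintf("sequence/quality length mismatch in record %d", mism[1L]),
      record = mism[1L]
    )
  }
  id <- sub("\\s.*$", "", sub("^@", "", hdr))
  data.frame(id = id, sequence = .to_dna(seq), quality = qual,
             stringsAsFactors = FALSE)
}

#' Write a FASTQ file
#'
#' @param records Data frame with columns `id`, `sequence`, `quality`.
#' @param path Output path; a `.gz` extension writes gzip.
#' @export
write_fastq <- function(records, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  writeLines(
    as.vector(rbind(paste0("@", records$id), records$sequence, "+",
                    records$quality)),
    con
  )
  invisible(path)
}

#' Collapse reads to unique sequences with counts
#'
#' One entry per distinct sequence; counts sum to the number of input
#' reads.  Output order is deterministic: descending count, then
#' lexicographic sequence.
#'
#' @param sequences Character vector of read sequences.
#' @return Data frame of collapsed reads: `read_id`, `sequence`, `count`.
#' @export
collapse_reads <- function(sequences) {
  if (length(sequences) == 0L) {
    return(data.frame(read_id = character(0), sequence = character(0),
                      count = integer(0), stringsAsFactors = FALSE))
  }
  tab <- table(sequences)
  seqs <- names(tab)
  counts <- as.integer(tab)
  ord <- order(-counts, seqs, method = "radix")
  seqs <- seqs[ord]
  counts <- counts[ord]
  data.frame(
    read_id = sprintf("s%d_x%d", seq_along(seqs), counts),
    sequence = seqs,
    count = counts,
    stringsAsFactors = FALSE
  )
}

#' Read a mature-miRNA annotation TSV
#'
#' Expects a header `mature_id  hairpin_id  start  end` with 0-based
#' half-open coordinates locating each mature product on its hairpin.
#' All invariants are validated against the supplied hairpin set; every
#' offending row is reported.
#'
#' @param path Path to the TSV.
#' @param hairpins Named character vector of hairpin sequences.
#' @return Data frame `mature_id`, `hairpin_id`, `start`, `end`, `is_guide`
#'   (`NA` until set by [select_guides()]).
#' @export
read_annotation_tsv <- function(path, hairpins) {
  .check_file(path, "annotation TSV")
  ann <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = c(mature_id = "character",
                                          hairpin_id = "character"))
  required <- c("mature_id", "hairpin_id", "start", "end")
  if (!all(required %in% names(ann))) {
    stop_parse(sprintf(
      "annotation TSV must carry columns: %s", paste(required, collapse = ", ")
    ))
  }
  ann <- ann[required]
  ann$start <- as.integer(ann$start)
  ann$end <- as.integer(ann$end)
  ann$is_guide <- NA
  validate_annotations(ann, hairpins)
  ann
}

#' Validate mature annotations against a hairpin set
#'
#' @param annotations Annotation data frame (see [read_annotation_tsv()]).
#' @param hairpins Named character vector of hairpin sequences.
#' @return The annotations, invisibly, if valid; otherwise a validation
#'   error listing every offending row.
#' @export
validate_annotations <- function(annotations, hairpins) {
  problems <- character(0)
  note <- function(i, why) {
    problems[[length(problems) + 1L]] <<-
      sprintf("row %d (%s): %s", i, annotations$mature_id[i], why)
  }
  if (anyDuplicated(annotations$mature_id)) {
    dups <- unique(annotations$mature_id[duplicated(annotations$mature_id)])
    problems <- c(problems, sprintf("duplicate mature_id: %s",
                                    paste(dups, collapse = ", ")))
  }
  for (i in seq_len(nrow(annotations))) {
    hid <- annotations$hairpin_id[i]
    if (!hid %in% names(hairpins)) {
      note(i, sprintf("unknown hairpin_id '%s'", hid))
      next
    }
    s <- annotations$start[i]
    e <- annotations$end[i]
    if (is.na(s) || is.na(e) || s >= e) {
      note(i, "start >= end")
      next
    }
    if (s < 0L || e > nchar(hairpins[[hid]])) {
      note(i, "mature window exceeds hairpin bounds")
      next
    }
    len <- e - s
    if (len < 16L || len > 28L) {
      note(i, sprintf("mature length %d outside [16, 28]", len))
    }
  }
  if (length(problems)) {
    stop_validation(paste(c("invalid mature annotations:", problems),
                          collapse = "\n  "))
  }
  invisible(annotations)
}

#' Read a spike-in reference set
#'
#' @inheritParams read_fasta
#' @return A list of class `spikein_set`: `records` (data frame `spike_id`,
#'   `sequence`) and `matched_count` (reads exactly matching any spike-in;
#'   0 until a library is classified).
#' @export
read_spikes <- function(path, alphabet_policy = c("strict", "permissive")) {
  fa <- read_fasta(path, alphabet_policy)
  spikein_set(stats::setNames(fa$sequence, fa$id))
}

#' Construct a spike-in set from sequences
#'
#' @param sequences Named character vector of spike-in sequences.
#' @return A `spikein_set` list.
#' @export
spikein_set <- function(sequences) {
  sequences <- .to_dna(sequences)
  if (anyDuplicated(sequences)) {
    stop_validation("spike-in sequences must be pairwise distinct")
  }
  if (is.null(names(sequences))) {
    names(sequences) <- sprintf("spike%d", seq_along(sequences))
  }
  structure(
    list(records = data.frame(spike_id = names(sequences),
                              sequence = unname(sequences),
                              stringsAsFactors = FALSE),
         matched_count = 0L),
    class = "spikein_set"
  )
}

#' Write a labelled count/fraction matrix as TSV
#'
#' Row labels go in the first column; numeric cells are rendered at 6
#' significant digits so identical input yields a byte-identical file.
#'
#' @param mat Matrix (or data frame) with row and column names.
#' @param path Output path.
#' @param label Name for the row-label column (default `"id"`).
#' @export
write_count_table <- function(mat, path, label = "id") {
  mat <- as.matrix(mat)
  header <- paste(c(label, colnames(mat)), collapse = "\t")
  if (nrow(mat) == 0L) {
    writeLines(header, path)
    return(invisible(path))
  }
  body <- vapply(seq_len(nrow(mat)), function(i) {
    paste(c(rownames(mat)[i], .fmt_num(as.numeric(mat[i, ]))),
          collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read back a count table written by [write_count_table()]
#'
#' @param path Path to the TSV.
#' @return A numeric matrix with row and column names.
#' @export
read_count_table <- function(path) {
  .check_file(path, "count table")
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(df) == 0L) {
    m <- matrix(numeric(0), nrow = 0, ncol = ncol(df) - 1L)
    colnames(m) <- names(df)[-1L]
    return(m)
  }
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- as.character(df[[1L]])
  m
}
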