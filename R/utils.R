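# Internal helpers shared across modules.

# Internal sequence convention: DNA alphabet (A/C/G/T/N), uppercase.
# Reports render tail nucleotides in the RNA alphabet (U for T).

.to_dna <- function(x) chartr("U", "T", toupper(x))
.to_rna <- function(x) chartr("T", "U", x)

.IUPAC_AMBIG <- c("R", "Y", "S", "W", "K", "M", "B", "D", "H", "V")

#' @noRd
mirtail_error <- function(subclass, message, ...) {
  structure(
    class = c(subclass, "mirtail_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  )
}

stop_parse <- function(message, line = NA_integer_, record = NA_integer_) {
  stop(mirtail_error("mirtail_parse_error", message, line = line, record = record))
}

stop_validation <- function(message, ...) {
  stop(mirtail_error("mirtail_validation_error", message, ...))
}

# open a text connection, transparently handling .gz by extension
.open_text <- function(path) {
  if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
}

.check_file <- function(path, what = "input file") {
  if (!is.character(path) || length(path) != 1L || !file.exists(path)) {
    stop(mirtail_error(
      "mirtail_usage_error",
      sprintf("%s not found: %s", what, as.character(path)[1L])
    ))
  }
  invisible(path)
}

# deterministic numeric formatting for output tables: 6 significant digits
.fmt_num <- function(x) {
  out <- character(length(x))
  out[is.na(x)] <- "NA"
  ok <- !is.na(x)
  out[ok] <- sprintf("%.6g", x[ok])
  out
}
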