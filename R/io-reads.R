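#' Read FASTQ files into a read tibble
#'
#' Reads one (single-end) or two (paired-end) FASTQ files, optionally
#' gzipped. Paired mates are linked through the `mate_of` column by file
#' position; any `/1`, `/2` or space-comment suffix is stripped from ids.
#'
#' @param path FASTQ path (R1 for paired data).
#' @param path2 Optional mate FASTQ (R2).
#' @param sample_id Sample label stored on every record.
#' @return Tibble with columns `read_id`, `sequence`, `quality`, `mate_of`,
#'   `sample_id`.
#' @export
read_fastq <- function(path, path2 = NULL, sample_id = "sample") {
  r1 <- read_one_fastq(path)
  if (is.null(path2)) {
    return(tibble(read_id = r1$id, sequence = r1$seq, quality = r1$qual,
                  mate_of = NA_character_, sample_id = sample_id))
  }
  r2 <- read_one_fastq(path2)
  if (length(r1$id) != length(r2$id)) {
    abort(sprintf("Paired FASTQ files differ in record count (%d vs %d)",
                  length(r1$id), length(r2$id)))
  }
  id1 <- paste0(r1$id, "/1")
  id2 <- paste0(r2$id, "/2")
  tibble(read_id = c(id1, id2),
         sequence = c(r1$seq, r2$seq),
         quality = c(r1$qual, r2$qual),
         mate_of = c(id2, id1),
         sample_id = sample_id)
}

#' @noRd
read_one_fastq <- function(path) {
  if (!file.exists(path)) abort(sprintf("FASTQ file not found: %s", path))
  validate_fastq_structure(path)
  x <- tryCatch(
    Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE),
    error = function(e) diagnose_fastq(path, conditionMessage(e)))
  ids <- sub("\\s.*$", "", names(x))
  ids <- sub("/[12]$", "", ids)
  list(id = ids, seq = unname(as.character(x)),
       qual = unname(as.character(S4Vectors::mcols(x)$qualities)))
}

# Structural validation (4-line records, matching sequence/quality lengths)
# with record-level error messages; the heavy parsing itself stays with the
# Biostrings reader.
#' @noRd
validate_fastq_structure <- function(path) {
  con <- gzfile(path, "r")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  n <- length(lines)
  n_rec <- n %/% 4L
  if (n %% 4L != 0L) {
    id <- if (n_rec * 4L + 1L <= n) lines[n_rec * 4L + 1L] else "<missing header>"
    abort(sprintf("Truncated FASTQ '%s': record %d (starting at line offset %d, id %s) is incomplete",
                  path, n_rec + 1L, n_rec * 4L + 1L, id))
  }
  hdr <- lines[seq(1L, n, by = 4L)]
  sep <- lines[seq(3L, n, by = 4L)]
  sq <- lines[seq(2L, n, by = 4L)]
  ql <- lines[seq(4L, n, by = 4L)]
  bad_hdr <- which(!startsWith(hdr, "@") | !startsWith(sep, "+"))
  if (length(bad_hdr)) {
    abort(sprintf("Malformed FASTQ '%s': record %d (id %s) has bad header/separator lines",
                  path, bad_hdr[1], hdr[bad_hdr[1]]))
  }
  bad_len <- which(nchar(sq) != nchar(ql))
  if (length(bad_len)) {
    i <- bad_len[1]
    abort(sprintf("Malformed FASTQ '%s': record %d (id %s) sequence length %d != quality length %d",
                  path, i, sub("^@", "", hdr[i]), nchar(sq[i]), nchar(ql[i])))
  }
  invisible(TRUE)
}

# Error path only: re-scan a FASTQ that the parser rejected.
#' @noRd
diagnose_fastq <- function(path, parser_msg) {
  abort(sprintf("Malformed FASTQ '%s': %s", path, parser_msg))
}

#' Write a read tibble as FASTQ
#'
#' @param reads Read tibble as produced by [read_fastq()] or the simulator.
#' @param path Output path; a `.gz` suffix enables compression.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(all(nchar(reads$sequence) == nchar(reads$quality)))
  x <- Biostrings::DNAStringSet(reads$sequence)
  names(x) <- reads$read_id
  Biostrings::writeXStringSet(x, path, format = "fastq",
                              qualities = Biostrings::BStringSet(reads$quality),
                              compress = grepl("\\.gz$", path))
  invisible(path)
}
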