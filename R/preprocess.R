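# Read cleanup, in the fixed order adapters/quality -> poly-A -> duplicates.
# Every stage records its attrition counts as attributes so the run log can
# report counts in == counts out + dropped.

#' Trim adapters and low-quality 3' bases
#'
#' Removes an adapter suffix when at least 10nt of the adapter overlap the
#' read 3' end with at most 1 mismatch, then trims trailing bases below
#' `min_qual`, and drops reads shorter than `min_len` (default 2x the 22nt
#' end length, the minimum on which split mapping is possible).
#'
#' @param reads Read tibble.
#' @param adapter Adapter sequence.
#' @param min_qual Phred threshold for 3' quality trimming.
#' @param min_len Minimum retained read length.
#' @param min_overlap Minimum adapter overlap (nt).
#' @return Filtered read tibble; attributes `n_in`, `n_adapter`, `n_dropped`.
#' @export
trim_adapters_and_quality <- function(reads, adapter = "AGATCGGAAGAGC",
                                      min_qual = 20L, min_len = 44L,
                                      min_overlap = 10L) {
  n_in <- nrow(reads)
  seqs <- reads$sequence
  quals <- reads$quality

  cut <- find_adapter_cut(seqs, adapter, min_overlap)
  trimmed_adapter <- !is.na(cut)
  keep_len <- ifelse(trimmed_adapter, cut, nchar(seqs))
  seqs <- substr(seqs, 1L, keep_len)
  quals <- substr(quals, 1L, keep_len)

  if (min_qual > 0L) {
    # trailing run of bases below min_qual (phred+33)
    low_class <- sprintf("[\\x21-\\x%x]+$", 32L + min_qual)
    quals2 <- sub(low_class, "", quals, perl = TRUE, useBytes = TRUE)
    seqs <- substr(seqs, 1L, nchar(quals2))
    quals <- quals2
  }

  out <- reads
  out$sequence <- seqs
  out$quality <- quals
  keep <- nchar(out$sequence) >= min_len
  res <- out[keep, , drop = FALSE]
  attr(res, "n_in") <- n_in
  attr(res, "n_adapter") <- sum(trimmed_adapter)
  attr(res, "n_dropped") <- sum(!keep)
  res
}

# 1-based position at which the adapter begins in each read, minus one
# (i.e. the retained length), or NA when no adapter is found. Overlap of at
# least `min_overlap` nt with <= 1 mismatch; candidate sites come from exact
# matches of one half of the adapter's first `min_overlap` nt (pigeonhole
# for a single mismatch).
#' @noRd
find_adapter_cut <- function(seqs, adapter, min_overlap = 10L) {
  half <- min_overlap %/% 2L
  seed_a <- substr(adapter, 1L, half)
  seed_b <- substr(adapter, half + 1L, min_overlap)
  cut <- rep(NA_integer_, length(seqs))
  cand_idx <- which(stringr::str_detect(seqs, stringr::fixed(seed_a)) |
                      stringr::str_detect(seqs, stringr::fixed(seed_b)))
  for (i in cand_idx) {
    s <- seqs[i]
    w <- nchar(s)
    pos_a <- stringr::str_locate_all(s, stringr::fixed(seed_a))[[1]][, 1]
    pos_b <- stringr::str_locate_all(s, stringr::fixed(seed_b))[[1]][, 1] - half
    starts <- sort(unique(c(pos_a, pos_b)))
    starts <- starts[starts >= 1L & (w - starts + 1L) >= min_overlap]
    for (p in starts) {
      ov <- min(w - p + 1L, nchar(adapter))
      mm <- hamming_n(substr(s, p, p + ov - 1L), substr(adapter, 1L, ov))
      if (mm <= 1L) { cut[i] <- p - 1L; break }
    }
  }
  cut
}

#' Trim terminal poly-A / leading poly-T runs
#'
#' Removes a 3' A-run of at least `run_min` nt (the appended poly-A tail) and
#' a 5' T-run of at least `run_min` nt (the reverse-complement read-through
#' of a tail). Internal runs are left untouched. Reads falling below
#' `min_len` afterwards are dropped.
#'
#' @inheritParams trim_adapters_and_quality
#' @param run_min Minimum terminal homopolymer length trimmed (>= 10).
#' @return Filtered read tibble; attributes `n_in`, `n_trimmed`, `n_dropped`.
#' @export
trim_polya <- function(reads, run_min = 10L, min_len = 44L) {
  stopifnot(run_min >= 10L)
  n_in <- nrow(reads)
  seqs <- reads$sequence
  quals <- reads$quality

  tail_re <- sprintf("A{%d,}$", run_min)
  head_re <- sprintf("^T{%d,}", run_min)
  s1 <- sub(tail_re, "", seqs)
  quals <- substr(quals, 1L, nchar(s1))
  lead_n <- nchar(s1) - nchar(sub(head_re, "", s1))
  s2 <- substr(s1, lead_n + 1L, nchar(s1))
  quals <- substr(quals, lead_n + 1L, nchar(quals) + lead_n)  # keep in step
  quals <- substr(quals, 1L, nchar(s2))

  out <- reads
  out$sequence <- s2
  out$quality <- quals
  keep <- nchar(out$sequence) >= min_len
  res <- out[keep, , drop = FALSE]
  attr(res, "n_in") <- n_in
  attr(res, "n_trimmed") <- sum(nchar(s2) < nchar(seqs))
  attr(res, "n_dropped") <- sum(!keep)
  res
}

#' Collapse exact duplicate reads
#'
#' Exact-sequence deduplication, keeping the first occurrence. For paired
#' reads the key is the ordered pair of mate sequences, so a pair is only a
#' duplicate of another whole pair. Idempotent.
#'
#' @param reads Read tibble.
#' @return Deduplicated read tibble; attribute `n_removed`.
#' @export
deduplicate_reads <- function(reads) {
  n_in <- nrow(reads)
  if (n_in == 0 || !"mate_of" %in% names(reads) || all(is.na(reads$mate_of))) {
    res <- reads[!duplicated(reads$sequence), , drop = FALSE]
  } else {
    # pair-aware: a record is a duplicate only if its whole (ordered) pair
    # of sequences has been seen before
    mate_seq <- reads$sequence[match(reads$mate_of, reads$read_id)]
    unit_id <- ifelse(is.na(reads$mate_of), reads$read_id,
                      pmin(reads$read_id, reads$mate_of))
    key <- ifelse(is.na(mate_seq), reads$sequence,
                  paste(pmin(reads$sequence, mate_seq),
                        pmax(reads$sequence, mate_seq), sep = "|"))
    first_units <- unit_id[!duplicated(unit_id)]
    unit_key <- key[match(first_units, unit_id)]
    keep_units <- first_units[!duplicated(unit_key)]
    res <- reads[unit_id %in% keep_units, , drop = FALSE]
  }
  attr(res, "n_removed") <- n_in - nrow(res)
  res
}

#' Run the full preprocessing stage
#'
#' Fixed order: adapter/quality trimming, then poly-A/poly-T trimming (RNA
#' mode only), then exact deduplication.
#'
#' @param reads Read tibble.
#' @param config A [pipeline_config()].
#' @param mode `"rnaseq"` (default) or `"wgs"`; WGS input skips poly-A
#'   trimming since genomic libraries carry no tails.
#' @return Preprocessed read tibble with a `preprocess_log` attribute
#'   (named list of per-stage counts).
#' @export
preprocess_reads <- function(reads, config = pipeline_config(),
                             mode = c("rnaseq", "wgs")) {
  mode <- match.arg(mode)
  log <- list(n_input = nrow(reads))
  r <- trim_adapters_and_quality(reads, adapter = config$adapter,
                                 min_qual = config$min_qual,
                                 min_len = config$min_len)
  log$n_adapter_trimmed <- attr(r, "n_adapter")
  log$n_dropped_short <- attr(r, "n_dropped")
  if (mode == "rnaseq") {
    r <- trim_polya(r, run_min = config$polyA_run_min, min_len = config$min_len)
    log$n_polya_trimmed <- attr(r, "n_trimmed")
    log$n_dropped_short <- log$n_dropped_short + attr(r, "n_dropped")
  }
  r <- deduplicate_reads(r)
  log$n_duplicates <- attr(r, "n_removed")
  log$n_output <- nrow(r)
  attr(r, "preprocess_log") <- log
  r
}
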