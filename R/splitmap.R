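# Split mapping: reference subtraction, contaminant screening, terminal-end
# extraction and mapping, and assembly of split evidence (one genome-unique
# end plus one TE/IGE element end per read).

#' Remove reads that align end-to-end to the reference genome
#'
#' Reads mapping end-to-end to the (masked) genome with at most `max_mm`
#' mismatches carry no novel junction and are removed; everything else
#' (including reads spanning splice junctions or TE insertions) is kept.
#' The removed reads' alignments are retained on the result as attribute
#' `genome_alignments` (`read_id`, `chrom`, `start`, `end`, `strand`); the
#' coverage-ratio denominator is computed from them.
#'
#' @param reads Read tibble.
#' @param bundle A [reference_bundle()].
#' @param max_mm Maximum mismatches for a full-length alignment.
#' @return Kept reads; attributes `genome_alignments` and `n_removed`.
#' @export
subtract_reference_mappers <- function(reads, bundle, max_mm = 3L) {
  hits <- find_end_to_end_hits(reads, bundle$genome, max_mm = max_mm)
  mapped <- unique(hits$read_id)
  kept <- reads[!reads$read_id %in% mapped, , drop = FALSE]
  best <- hits |>
    group_by(.data$read_id) |>
    slice_min(.data$mismatches, n = 1, with_ties = FALSE) |>
    ungroup() |>
    transmute(read_id = .data$read_id, chrom = .data$target_name,
              start = .data$target_pos, end = .data$target_pos + .data$width,
              strand = .data$strand)
  attr(kept, "genome_alignments") <- best
  attr(kept, "n_removed") <- length(mapped)
  kept
}

#' Screen out contaminant- and TE-consensus-internal reads
#'
#' Reads aligning end-to-end to any contaminant sequence (viral/structural
#' RNA, repeat library) or to a TE consensus are removed; junction-spanning
#' reads survive because only one of their ends matches the element. Reads
#' removed by an end-to-end TE-consensus hit are tallied per family
#' (attribute `te_consensus_counts`), which is the autonomy analysis's
#' consensus expression measure.
#'
#' @inheritParams subtract_reference_mappers
#' @return Kept reads; attributes `te_consensus_counts` (tibble
#'   `element_name`, `n_reads`, one row per TE family) and `n_removed`.
#' @export
screen_contaminants <- function(reads, bundle, max_mm = 3L) {
  te_names <- names(bundle$te_library)
  targets <- c(bundle$contaminants, bundle$te_library)
  if (length(targets) == 0) {
    counts <- tibble(element_name = te_names %||% character(0),
                     n_reads = integer(length(te_names)))
    attr(reads, "te_consensus_counts") <- counts
    attr(reads, "n_removed") <- 0L
    return(reads)
  }
  hits <- find_end_to_end_hits(reads, targets, max_mm = max_mm)
  mapped <- unique(hits$read_id)
  kept <- reads[!reads$read_id %in% mapped, , drop = FALSE]
  te_hits <- hits |>
    filter(.data$target_name %in% te_names) |>
    distinct(.data$read_id, .data$target_name)
  counts <- tibble(element_name = te_names) |>
    left_join(count(te_hits, .data$target_name, name = "n_reads"),
              by = c(element_name = "target_name")) |>
    mutate(n_reads = coalesce(.data$n_reads, 0L))
  attr(kept, "te_consensus_counts") <- counts
  attr(kept, "n_removed") <- length(mapped)
  kept
}

#' Extract the terminal ends of each read
#'
#' Takes the first and last `end_length` bases of every read long enough to
#' carry two non-overlapping ends; shorter reads are skipped and counted.
#'
#' @param reads Read tibble.
#' @param end_length End length in nt (22 by default throughout).
#' @return Tibble `read_id`, `end` (`"FIVE_PRIME"`/`"THREE_PRIME"`),
#'   `end_id`, `seq`, `read_length`; attribute `n_skipped`.
#' @export
extract_ends <- function(reads, end_length = 22L) {
  w <- nchar(reads$sequence)
  ok <- w >= 2L * end_length
  r <- reads[ok, , drop = FALSE]
  w <- w[ok]
  out <- bind_rows(
    tibble(read_id = r$read_id, end = "FIVE_PRIME",
           seq = substr(r$sequence, 1L, end_length), read_length = w),
    tibble(read_id = r$read_id, end = "THREE_PRIME",
           seq = substr(r$sequence, w - end_length + 1L, w), read_length = w)) |>
    mutate(end_id = paste(.data$read_id, .data$end, sep = "::"), .after = "end") |>
    arrange(.data$read_id, .data$end)
  attr(out, "n_skipped") <- sum(!ok)
  out
}

#' Map both read ends against genome, TE library and IGE set
#'
#' Returns the best-mismatch stratum of [map_end()] for every end against
#' each database (exact hits are found for all ends in a single multi-
#' pattern pass; only ends without an exact hit fall back to the exhaustive
#' mismatch scan). Downstream evidence assembly only consumes best-stratum
#' hits and their `n_equal_best_hits` counts, which are identical between
#' the two routes.
#'
#' @param ends End tibble from [extract_ends()].
#' @param bundle A [reference_bundle()].
#' @param max_mm Maximum mismatches per end.
#' @return Alignment tibble (`read_id`, `end`, `end_id`, `target_db`,
#'   `target_name`, `target_pos`, `strand`, `mismatches`,
#'   `n_equal_best_hits`, `read_length`).
#' @export
map_read_ends <- function(ends, bundle, max_mm = 3L) {
  dbs <- list(GENOME = bundle$genome, TE = bundle$te_library,
              IGE = bundle$ige_set)
  res <- list()
  for (db in names(dbs)) {
    tg <- dbs[[db]]
    if (is.null(tg) || length(tg) == 0) next
    subject <- build_block_subject(tg)
    hits <- fast_best_hits(ends$seq, subject, max_mm)
    if (nrow(hits) == 0) next
    res[[db]] <- ends |>
      select("read_id", "end", "end_id", "seq", "read_length") |>
      inner_join(hits, by = "seq", relationship = "many-to-many") |>
      mutate(target_db = db, .after = "end_id") |>
      select(-"seq")
  }
  out <- bind_rows(res)
  if (nrow(out) == 0) {
    return(tibble(read_id = character(0), end = character(0), end_id = character(0),
                  target_db = character(0), target_name = character(0),
                  target_pos = integer(0), strand = character(0),
                  mismatches = integer(0), n_equal_best_hits = integer(0),
                  read_length = integer(0)))
  }
  out |> arrange(.data$read_id, .data$end, .data$target_db, .data$mismatches)
}

#' Assemble split evidence from mapped read ends
#'
#' A read yields one piece of split evidence when one end maps uniquely to
#' the genome (exactly one best-stratum hit genome-wide) and the other end
#' maps to a TE consensus or an IGE control. When both assignments would be
#' possible the TE-element assignment wins (IGEs are the control class), and
#' otherwise the 5'-anchored assignment is taken, so each read contributes at
#' most one evidence row.
#'
#' The junction coordinate is refined by seed-and-extend: the 22nt genome
#' anchor is extended base-by-base along the read (stopping at the first
#' mismatch) and the junction is the genome coordinate immediately beyond
#' the extended anchor on the element side (0-based). `side` records whether
#' the anchor lies upstream or downstream of the junction.
#'
#' @param reads Read tibble (sequences are needed for anchor extension).
#' @param end_alignments Output of [map_read_ends()].
#' @param bundle A [reference_bundle()].
#' @param config A [pipeline_config()].
#' @return Evidence tibble, one row per qualifying read: `read_id`, `chrom`,
#'   `genome_strand`, `anchor_start`, `anchor_end`, `genome_mm`,
#'   `genome_end_seq`, `junction_pos`, `side`, `element_db`, `element_name`,
#'   `element_pos`, `element_strand`, `element_mm`, `element_end_seq`,
#'   `sample_id`. Attribute `n_unassigned` counts non-qualifying reads.
#' @export
assemble_split_evidence <- function(reads, end_alignments, bundle,
                                    config = pipeline_config()) {
  el <- config$end_length
  genome_chr <- bundle$genome

  al <- as_tibble(end_alignments)
  gen_best <- al |>
    filter(.data$target_db == "GENOME") |>
    group_by(.data$read_id, .data$end) |>
    slice_min(.data$mismatches, n = 1, with_ties = FALSE) |>
    ungroup() |>
    filter(.data$n_equal_best_hits == 1L)
  elem_best <- al |>
    filter(.data$target_db %in% c("TE", "IGE")) |>
    mutate(db_rank = ifelse(.data$target_db == "TE", 1L, 2L)) |>
    group_by(.data$read_id, .data$end) |>
    arrange(.data$db_rank, .data$mismatches, .data$target_name, .data$target_pos,
            .by_group = TRUE) |>
    slice_head(n = 1) |>
    ungroup()

  other_end <- c(FIVE_PRIME = "THREE_PRIME", THREE_PRIME = "FIVE_PRIME")
  cand <- gen_best |>
    transmute(read_id = .data$read_id, genome_end = .data$end,
              chrom = .data$target_name, anchor_pos = .data$target_pos,
              genome_strand = .data$strand, genome_mm = .data$mismatches,
              read_length = .data$read_length,
              elem_end = unname(other_end[.data$end])) |>
    inner_join(elem_best |>
                 transmute(read_id = .data$read_id, elem_end = .data$end,
                           element_db = .data$target_db,
                           element_name = .data$target_name,
                           element_pos = .data$target_pos,
                           element_strand = .data$strand,
                           element_mm = .data$mismatches),
               by = c("read_id", "elem_end"))

  n_candidate_reads <- sum(nchar(reads$sequence) >= 2L * el)
  if (nrow(cand) == 0) {
    out <- empty_evidence()
    attr(out, "n_unassigned") <- n_candidate_reads
    return(out)
  }

  # one evidence per read: TE element beats IGE, then 5'-anchored assignment
  cand <- cand |>
    mutate(pref = ifelse(.data$element_db == "TE", 0L, 2L) +
             ifelse(.data$genome_end == "FIVE_PRIME", 0L, 1L)) |>
    group_by(.data$read_id) |>
    slice_min(.data$pref, n = 1, with_ties = FALSE) |>
    ungroup()

  seqs <- setNames(reads$sequence, reads$read_id)
  samp <- if ("sample_id" %in% names(reads)) setNames(reads$sample_id, reads$read_id) else NULL

  res <- cand
  res$junction_pos <- NA_integer_
  res$side <- NA_character_
  for (i in seq_len(nrow(res))) {
    geo <- anchor_geometry(seq = unname(seqs[res$read_id[i]]),
                           chrom_seq = genome_chr[[res$chrom[i]]],
                           anchor_pos = res$anchor_pos[i],
                           strand = res$genome_strand[i],
                           end = res$genome_end[i],
                           end_length = el)
    res$junction_pos[i] <- geo$junction
    res$side[i] <- geo$side
  }

  read_seq <- unname(seqs[res$read_id])
  w <- nchar(read_seq)
  genome_end_seq <- ifelse(res$genome_end == "FIVE_PRIME",
                           substr(read_seq, 1L, el),
                           substr(read_seq, w - el + 1L, w))
  element_end_seq <- ifelse(res$elem_end == "FIVE_PRIME",
                            substr(read_seq, 1L, el),
                            substr(read_seq, w - el + 1L, w))

  out <- res |>
    transmute(read_id = .data$read_id,
              chrom = .data$chrom,
              genome_strand = .data$genome_strand,
              anchor_start = .data$anchor_pos,
              anchor_end = .data$anchor_pos + el,
              genome_mm = .data$genome_mm,
              genome_end_seq = genome_end_seq,
              junction_pos = .data$junction_pos,
              side = .data$side,
              element_db = .data$element_db,
              element_name = .data$element_name,
              element_pos = .data$element_pos,
              element_strand = .data$element_strand,
              element_mm = .data$element_mm,
              element_end_seq = element_end_seq,
              sample_id = if (is.null(samp)) NA_character_ else unname(samp[.data$read_id]))
  attr(out, "n_unassigned") <- n_candidate_reads - nrow(out)
  out
}

#' @noRd
empty_evidence <- function() {
  tibble(read_id = character(0), chrom = character(0), genome_strand = character(0),
         anchor_start = integer(0), anchor_end = integer(0), genome_mm = integer(0),
         genome_end_seq = character(0), junction_pos = integer(0), side = character(0),
         element_db = character(0), element_name = character(0), element_pos = integer(0),
         element_strand = character(0), element_mm = integer(0),
         element_end_seq = character(0), sample_id = character(0))
}

# Junction geometry for one anchored genome end. `anchor_pos` is the 0-based
# forward-strand start of the 22nt anchor; the anchor is extended through the
# read's inner sequence (up to read_length - 2*end_length bases, stopping at
# the first mismatching base) and the junction is the coordinate immediately
# past the extended anchor on the element side.
#' @noRd
anchor_geometry <- function(seq, chrom_seq, anchor_pos, strand, end, end_length) {
  w <- nchar(seq)
  max_ext <- w - 2L * end_length
  s1 <- anchor_pos + 1L  # 1-based anchor start on forward strand
  clen <- nchar(chrom_seq)
  element_right <- (end == "FIVE_PRIME") == (strand == "+")

  read_inner <- function(from_left) {
    # inner read bases adjacent to the anchor, in extension order
    if (from_left) substr(seq, end_length + 1L, end_length + max_ext)
    else paste(rev(strsplit(substr(seq, w - end_length - max_ext + 1L,
                                   w - end_length), "", fixed = TRUE)[[1]]),
               collapse = "")
  }
  ext_len <- function(inner, genomic) {
    n <- min(nchar(inner), nchar(genomic))
    if (n == 0) return(0L)
    a <- charToRaw(substr(inner, 1L, n)); b <- charToRaw(substr(genomic, 1L, n))
    rn <- charToRaw("N")
    bad <- which(a != b | a == rn | b == rn)
    if (length(bad) == 0) n else bad[1] - 1L
  }

  if (max_ext < 0) max_ext <- 0L
  if (element_right) {
    # anchor sits upstream (left) of the junction on the forward strand
    inner <- if (end == "FIVE_PRIME") read_inner(TRUE) else read_inner(FALSE)
    g_from <- s1 + end_length
    g_to <- min(g_from + max_ext - 1L, clen)
    genomic <- if (g_from <= g_to) substr(chrom_seq, g_from, g_to) else ""
    if (strand == "-") genomic <- chartr("ACGT", "TGCA", genomic)  # complement, not reversed
    ext <- ext_len(inner, genomic)
    list(junction = anchor_pos + end_length + ext, side = "UPSTREAM")
  } else {
    inner <- if (end == "FIVE_PRIME") read_inner(TRUE) else read_inner(FALSE)
    g_to <- s1 - 1L
    g_from <- max(g_to - max_ext + 1L, 1L)
    genomic <- if (g_from <= g_to) substr(chrom_seq, g_from, g_to) else ""
    # extension order walks away from the anchor, i.e. right-to-left
    genomic <- paste(rev(strsplit(genomic, "", fixed = TRUE)[[1]]), collapse = "")
    if (strand == "-") genomic <- chartr("ACGT", "TGCA", genomic)
    ext <- ext_len(inner, genomic)
    list(junction = anchor_pos - ext, side = "DOWNSTREAM")
  }
}
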