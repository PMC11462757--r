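# Mismatch-tolerant matching kernels.
#
# Two code paths, both with the same contract ("every locus with at most
# max_mm mismatches, N never counts as a match"):
#
#   * map_end(): exhaustive scan of short fixed-length read ends against a
#     target collection, via Biostrings C kernels on a spacer-concatenated
#     subject. Used for the 22nt terminal ends where exhaustiveness is the
#     contract.
#   * find_end_to_end_hits(): pigeonhole seed-and-verify for full-length
#     reads (reference subtraction, contaminant screening). With max_mm
#     mismatches over a read of length w, at least one of max_mm + 1 disjoint
#     seeds of length floor(w / (max_mm + 1)) is exact; seed hits come from a
#     data.table k-mer index and candidates are verified by raw-byte Hamming
#     comparison.

SPACER_LEN <- 60L

# Concatenate a named sequence collection into one subject with N spacers.
# Returns the subject (DNAString), its raw bytes, and 1-based block offsets.
#' @noRd
build_block_subject <- function(targets) {
  targets <- as_named_character(targets, "target sequences")
  if (length(targets) == 0) return(NULL)
  spacer <- strrep("N", SPACER_LEN)
  concat <- paste(targets, collapse = spacer)
  lens <- unname(nchar(targets))
  cstart <- cumsum(c(1L, head(lens + SPACER_LEN, -1L)))
  list(dna = Biostrings::DNAString(concat),
       raw = charToRaw(concat),
       blocks = tibble(name = names(targets), len = unname(lens),
                       cstart = unname(cstart), cend = unname(cstart + lens - 1L)))
}

# Locate concatenated-subject hits inside their blocks; drop hits that jut
# into a spacer or across a block boundary. `starts` are 1-based concat
# coordinates; returns block name and 0-based in-block position.
#' @noRd
localise_hits <- function(starts, width, blocks) {
  if (length(starts) == 0) {
    return(tibble(target_name = character(0), target_pos = integer(0), keep = logical(0)))
  }
  idx <- findInterval(starts, blocks$cstart)
  idx[idx < 1L] <- 1L
  keep <- starts >= blocks$cstart[idx] & (starts + width - 1L) <= blocks$cend[idx]
  tibble(target_name = blocks$name[idx],
         target_pos = as.integer(starts - blocks$cstart[idx]),
         keep = keep)
}

# All hits of one query (both strands) on a block subject. The reverse-strand
# search matches the reverse complement of the query against the forward
# subject, so reported positions are always forward-strand 0-based starts.
#' @noRd
scan_query <- function(query, subject, max_mm) {
  w <- nchar(query)
  has_n <- grepl("N", query, fixed = TRUE)
  one_strand <- function(q, strand) {
    pat <- Biostrings::DNAString(q)
    m <- Biostrings::matchPattern(pat, subject$dna, max.mismatch = max_mm,
                                  with.indels = FALSE, fixed = TRUE)
    starts <- BiocGenerics::start(m)
    if (length(starts) == 0) return(NULL)
    mm <- Biostrings::neditStartingAt(pat, subject$dna, starting.at = starts,
                                      with.indels = FALSE, fixed = TRUE)
    loc <- localise_hits(starts, w, subject$blocks)
    out <- tibble(target_name = loc$target_name, target_pos = loc$target_pos,
                  strand = strand, mismatches = as.integer(mm))[loc$keep, ]
    if (has_n && nrow(out) > 0) {
      # fixed=TRUE scores N-vs-N as a match; re-score those columns as
      # mismatches (an N never counts as a match on either side)
      qraw <- charToRaw(q)
      rn <- charToRaw("N")
      extra <- vapply(seq_len(nrow(out)), function(i) {
        s <- which(subject$blocks$name == out$target_name[i])
        at <- subject$blocks$cstart[s] + out$target_pos[i]
        seg <- subject$raw[at:(at + w - 1L)]
        sum(seg == rn & qraw == rn)
      }, integer(1))
      out$mismatches <- out$mismatches + extra
      out <- out[out$mismatches <= max_mm, ]
    }
    out
  }
  fw <- one_strand(query, "+")
  rv <- one_strand(revcomp(query), "-")
  bind_rows(fw, rv)
}

#' Map a read end against a target collection
#'
#' Finds every locus where the end aligns with at most `max_mismatches`
#' mismatches (no indels), on either strand. Hits are returned best-mismatch
#' stratum first, and each row carries `n_equal_best_hits`, the number of
#' hits in its end's best stratum across the whole collection (1 means the
#' end is uniquely mapped).
#'
#' @param ends Named character vector of end sequences (names are end ids),
#'   or a tibble with columns `end_id` and `seq`.
#' @param targets Named character vector or `DNAStringSet` to search.
#' @param target_db Label stored in the `target_db` column (e.g. "GENOME",
#'   "TE", "IGE", "CONTAMINANT").
#' @param max_mismatches Maximum mismatches per end.
#' @return Tibble with columns `end_id`, `target_db`, `target_name`,
#'   `target_pos` (0-based), `strand`, `mismatches`, `n_equal_best_hits`.
#' @export
map_end <- function(ends, targets, target_db = "GENOME", max_mismatches = 3L) {
  if (is.data.frame(ends)) {
    end_tbl <- tibble(end_id = ends$end_id, seq = ends$seq)
  } else {
    if (is.null(names(ends))) names(ends) <- paste0("end", seq_along(ends))
    end_tbl <- tibble(end_id = names(ends), seq = unname(ends))
  }
  empty <- tibble(end_id = character(0), target_db = character(0),
                  target_name = character(0), target_pos = integer(0),
                  strand = character(0), mismatches = integer(0),
                  n_equal_best_hits = integer(0))
  subject <- build_block_subject(targets)
  if (is.null(subject) || nrow(end_tbl) == 0) return(empty)

  uniq <- unique(end_tbl$seq)
  hit_list <- lapply(uniq, scan_query, subject = subject, max_mm = max_mismatches)
  names(hit_list) <- uniq
  res <- end_tbl |>
    mutate(hits = hit_list[.data$seq]) |>
    select("end_id", "hits") |>
    unnest("hits")
  if (nrow(res) == 0) return(empty)
  res |>
    mutate(target_db = target_db, .after = "end_id") |>
    group_by(.data$end_id) |>
    mutate(n_equal_best_hits = sum(.data$mismatches == min(.data$mismatches))) |>
    ungroup() |>
    arrange(.data$end_id, .data$mismatches, .data$target_name, .data$target_pos)
}

# Best-stratum hits for many same-width queries: one exact-matching pass
# over all queries at once (Aho-Corasick via PDict), then the exhaustive
# per-query scan only for queries without an exact hit. Produces exactly the
# best-mismatch stratum of map_end() with the same n_equal_best_hits.
#' @noRd
fast_best_hits <- function(queries, subject, max_mm) {
  uniq <- unique(queries)
  safe <- !grepl("N", uniq, fixed = TRUE) & nchar(uniq) == nchar(uniq[1])
  exact <- vector("list", length(uniq))
  names(exact) <- uniq
  if (any(safe)) {
    for (strand in c("+", "-")) {
      pats <- if (strand == "+") uniq[safe] else revcomp(uniq[safe])
      pd <- Biostrings::PDict(Biostrings::DNAStringSet(pats))
      mi <- Biostrings::matchPDict(pd, subject$dna)
      sl <- Biostrings::startIndex(mi)
      for (i in seq_along(sl)) {
        if (length(sl[[i]]) == 0) next
        q <- uniq[safe][i]
        loc <- localise_hits(sl[[i]], nchar(q), subject$blocks)
        if (!any(loc$keep)) next
        exact[[q]] <- bind_rows(exact[[q]],
                                tibble(target_name = loc$target_name[loc$keep],
                                       target_pos = loc$target_pos[loc$keep],
                                       strand = strand, mismatches = 0L))
      }
    }
  }
  need_scan <- uniq[vapply(exact, is.null, logical(1))]
  scanned <- list()
  if (length(need_scan)) {
    all_hits <- scan_many_fixed(need_scan, subject, max_mm)
    scanned <- lapply(split(all_hits, all_hits$seq), function(h) {
      h[h$mismatches == min(h$mismatches), setdiff(names(h), "seq"), drop = FALSE]
    })
  }
  hits <- c(exact[!vapply(exact, is.null, logical(1))], scanned[!vapply(scanned, is.null, logical(1))])
  if (length(hits) == 0) {
    return(tibble(seq = character(0), target_name = character(0),
                  target_pos = integer(0), strand = character(0),
                  mismatches = integer(0), n_equal_best_hits = integer(0)))
  }
  out <- bind_rows(hits, .id = "seq")
  out |>
    group_by(.data$seq) |>
    mutate(n_equal_best_hits = n()) |>
    ungroup()
}

# Exhaustive hits (<= max_mm mismatches, both strands) of many SAME-WIDTH
# queries against a block subject, by pigeonhole seed-and-verify batched
# across every query at once: with max_mm mismatches over max_mm + 1
# disjoint seeds, at least one seed matches exactly; seed hits come from a
# k-mer table join and all candidate (query, position) pairs are verified
# together, one vectorised pass per within-window offset.
#' @noRd
scan_many_fixed <- function(queries, subject, max_mm) {
  empty <- tibble(seq = character(0), target_name = character(0),
                  target_pos = integer(0), strand = character(0),
                  mismatches = integer(0))
  if (length(queries) == 0) return(empty)
  w <- nchar(queries[1])
  stopifnot(all(nchar(queries) == w))
  n_seeds <- max_mm + 1L
  k <- w %/% n_seeds
  if (k < 3L) {
    # seeds too short to be selective; fall back to per-query scans
    out <- lapply(queries, function(q) {
      h <- scan_query(q, subject, max_mm)
      if (nrow(h)) h$seq <- q
      h
    })
    res <- bind_rows(out)
    return(if (nrow(res)) res[, names(empty)] else empty)
  }

  sraw <- subject$raw
  L <- length(sraw)
  sstr <- rawToChar(sraw)
  idx <- data.table::data.table(kmer = substring(sstr, 1:(L - k + 1L), k:L),
                                pos = 1:(L - k + 1L))
  data.table::setkey(idx, kmer)

  # query variants: forward and reverse complement
  qv <- c(queries, revcomp(queries))
  strands <- rep(c("+", "-"), each = length(queries))
  offs <- (seq_len(n_seeds) - 1L) * k + 1L
  seed_dt <- data.table::data.table(
    qi = rep(seq_along(qv), each = n_seeds),
    off = rep(offs, length(qv)),
    kmer = substring(rep(qv, each = n_seeds), rep(offs, length(qv)),
                     rep(offs, length(qv)) + k - 1L))
  cand <- idx[seed_dt, on = "kmer", allow.cartesian = TRUE, nomatch = NULL]
  if (nrow(cand) == 0) return(empty)
  cand[, start := pos - off + 1L]
  cand <- unique(cand[start >= 1L & start + w - 1L <= L, list(qi, start)])
  if (nrow(cand) == 0) return(empty)

  # vectorised verification across all candidate pairs
  tq <- matrix(unlist(lapply(qv, charToRaw)), nrow = w)
  rn <- charToRaw("N")
  mm <- integer(nrow(cand))
  qi_vec <- cand$qi; st_vec <- cand$start
  for (off in 0:(w - 1L)) {
    sb <- sraw[st_vec + off]
    qb <- tq[off + 1L, qi_vec]
    mm <- mm + as.integer(sb != qb | sb == rn | qb == rn)
  }
  keep <- mm <= max_mm
  if (!any(keep)) return(empty)
  qi_vec <- qi_vec[keep]; st_vec <- st_vec[keep]; mm <- mm[keep]
  loc <- localise_hits(st_vec, w, subject$blocks)
  ok <- loc$keep
  orig <- rep(queries, 2L)
  tibble(seq = orig[qi_vec[ok]], target_name = loc$target_name[ok],
         target_pos = loc$target_pos[ok],
         strand = strands[qi_vec[ok]], mismatches = mm[ok]) |>
    distinct()
}

# Batch scan of many same-width queries against a SMALL subject: position-
# by-position vectorised Hamming over a query matrix (with the N rule).
# Returns the best mismatch count per query (NA when above max_mm).
#' @noRd
batch_best_mismatch <- function(queries, targets, max_mm) {
  best <- rep(NA_integer_, length(queries))
  if (length(queries) == 0 || length(targets) == 0) return(best)
  w <- nchar(queries[1])
  stopifnot(all(nchar(queries) == w))
  rn <- charToRaw("N")
  # queries as a w x n matrix so the subject window recycles down columns
  tq <- matrix(unlist(lapply(queries, charToRaw)), nrow = w)
  tq_is_n <- tq == rn
  subj <- paste(unname(as_named_character(setNames(targets, names(targets) %||%
                                                     paste0("t", seq_along(targets))),
                                          "targets")),
                collapse = strrep("N", w))
  for (s in c(subj, revcomp(subj))) {
    sraw <- charToRaw(s)
    L <- length(sraw)
    if (L < w) next
    for (p in seq_len(L - w + 1L)) {
      seg <- sraw[p:(p + w - 1L)]
      neq <- (tq != seg) | tq_is_n | (seg == rn)
      rs <- as.integer(colSums(neq))
      upd <- is.na(best) | rs < best
      best[upd] <- rs[upd]
    }
  }
  best[!is.na(best) & best > max_mm] <- NA_integer_
  best
}

#' End-to-end hits of full reads against a target collection
#'
#' Pigeonhole seed-and-verify search for complete (ungapped) read alignments
#' with at most `max_mm` mismatches on either strand. Used for reference
#' subtraction and contaminant screening, where only the existence and
#' location of an end-to-end alignment matter.
#'
#' @param reads Read tibble (`read_id`, `sequence`).
#' @param targets Named character vector or `DNAStringSet`.
#' @param max_mm Maximum mismatches for a full-length alignment.
#' @return Tibble `read_id`, `target_name`, `target_pos` (0-based start),
#'   `strand`, `mismatches`, `width`.
#' @export
find_end_to_end_hits <- function(reads, targets, max_mm = 3L) {
  empty <- tibble(read_id = character(0), target_name = character(0),
                  target_pos = integer(0), strand = character(0),
                  mismatches = integer(0), width = integer(0))
  subject <- build_block_subject(targets)
  if (is.null(subject) || nrow(reads) == 0) return(empty)
  concat <- subject$raw
  L <- length(concat)

  widths <- unname(nchar(reads$sequence))
  n_seeds <- max_mm + 1L
  k <- max(min(floor(min(widths) / n_seeds), 16L), 4L)
  short <- widths < n_seeds * k

  # query table: forward and reverse-complement orientation of each read
  q <- tibble(read_id = rep(reads$read_id, 2L),
              strand = rep(c("+", "-"), each = nrow(reads)),
              seq = c(reads$sequence, revcomp(reads$sequence)),
              width = rep(widths, 2L),
              is_short = rep(short, 2L))

  out <- list()

  main <- q[!q$is_short, ]
  if (nrow(main) > 0) {
    idx_dt <- data.table::data.table(
      kmer = substring(rawToChar(concat), 1:(L - k + 1L), k:L),
      pos = 1:(L - k + 1L))
    data.table::setkey(idx_dt, kmer)

    offs <- lapply(main$width, function(w) as.integer(floor((0:max_mm) * w / n_seeds)) + 1L)
    seed_dt <- data.table::data.table(
      qi = rep(seq_len(nrow(main)), each = n_seeds),
      off = unlist(offs),
      kmer = substring(rep(main$seq, each = n_seeds), unlist(offs),
                       unlist(offs) + k - 1L))
    cand <- idx_dt[seed_dt, on = "kmer", allow.cartesian = TRUE, nomatch = NULL]
    if (nrow(cand) > 0) {
      cand[, start := pos - off + 1L]
      cand <- unique(cand[, list(qi, start)])
      cand <- cand[start >= 1L]
      # verify candidates by raw-byte Hamming with the N rule
      rn <- charToRaw("N")
      qi_vec <- cand$qi; st_vec <- cand$start
      qraw_cache <- lapply(main$seq, charToRaw)
      keep_mm <- integer(length(qi_vec)); keep <- logical(length(qi_vec))
      for (i in seq_along(qi_vec)) {
        w <- main$width[qi_vec[i]]
        en <- st_vec[i] + w - 1L
        if (en > L) next
        seg <- concat[st_vec[i]:en]
        qraw <- qraw_cache[[qi_vec[i]]]
        mm <- sum(seg != qraw | seg == rn | qraw == rn)
        if (mm <= max_mm) { keep[i] <- TRUE; keep_mm[i] <- mm }
      }
      if (any(keep)) {
        hits <- tibble(qi = qi_vec[keep], start = st_vec[keep], mismatches = keep_mm[keep])
        loc <- localise_hits(hits$start, main$width[hits$qi], subject$blocks)
        hits <- hits[loc$keep, ]
        loc <- loc[loc$keep, ]
        out$main <- tibble(read_id = main$read_id[hits$qi],
                           target_name = loc$target_name,
                           target_pos = loc$target_pos,
                           strand = main$strand[hits$qi],
                           mismatches = as.integer(hits$mismatches),
                           width = main$width[hits$qi])
      }
    }
  }

  rest <- q[q$is_short, ]
  if (nrow(rest) > 0) {   # fallback: exhaustive scan for unusually short reads
    sub_res <- lapply(seq_len(nrow(rest)), function(i) {
      h <- scan_query(rest$seq[i], subject, max_mm)
      h <- h[h$strand == "+", , drop = FALSE]  # orientation handled by q
      if (nrow(h) == 0) return(NULL)
      tibble(read_id = rest$read_id[i], target_name = h$target_name,
             target_pos = h$target_pos, strand = rest$strand[i],
             mismatches = h$mismatches, width = rest$width[i])
    })
    out$rest <- list_rbind(sub_res)
  }

  res <- bind_rows(out)
  if (nrow(res) == 0) return(empty)
  res |> distinct() |> arrange(.data$read_id, .data$target_name, .data$target_pos)
}
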