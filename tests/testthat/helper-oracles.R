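# Independent oracles, deliberately implemented without any of the
# package's matching or correlation machinery.

# All loci (both strands) where `query` aligns to any target with at most
# max_mm mismatches; plain Hamming scan over every position. N never counts
# as a match.
brute_force_hits <- function(query, targets, max_mm) {
  w <- nchar(query)
  rc <- function(s) chartr("ACGTN", "TGCAN", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  out <- list()
  for (tn in names(targets)) {
    subj <- strsplit(targets[[tn]], "")[[1]]
    L <- length(subj)
    if (L < w) next
    for (strand in c("+", "-")) {
      q <- if (strand == "+") query else rc(query)
      qc <- strsplit(q, "")[[1]]
      mm <- integer(L - w + 1L)
      for (off in seq_len(w)) {
        sc <- subj[off:(L - w + off)]
        mm <- mm + as.integer(sc != qc[off] | sc == "N" | qc[off] == "N")
      }
      hit <- which(mm <= max_mm)
      if (length(hit)) {
        out[[length(out) + 1L]] <- data.frame(
          target_name = tn, target_pos = hit - 1L, strand = strand,
          mismatches = mm[hit], stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(target_name = character(0), target_pos = integer(0),
                      strand = character(0), mismatches = integer(0)))
  }
  res <- do.call(rbind, out)
  res[order(res$target_name, res$target_pos, res$strand), , drop = FALSE]
}

# Spearman rho from first principles: O(n^2) average ranks, then the
# Pearson product-moment formula written out longhand.
brute_force_spearman <- function(x, y) {
  n <- length(x)
  rank_of <- function(v) {
    vapply(seq_len(n), function(i) {
      less <- 0; equal <- 0
      for (j in seq_len(n)) {
        if (v[j] < v[i]) less <- less + 1
        if (v[j] == v[i]) equal <- equal + 1
      }
      less + (equal + 1) / 2
    }, numeric(1))
  }
  rx <- rank_of(x); ry <- rank_of(y)
  mx <- sum(rx) / n; my <- sum(ry) / n
  num <- 0; dx <- 0; dy <- 0
  for (i in seq_len(n)) {
    num <- num + (rx[i] - mx) * (ry[i] - my)
    dx <- dx + (rx[i] - mx)^2
    dy <- dy + (ry[i] - my)^2
  }
  num / sqrt(dx * dy)
}

random_seq <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

mutate_bases <- function(seq, positions, seed = 99) {
  set.seed(seed)
  chars <- strsplit(seq, "")[[1]]
  for (p in positions) {
    chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1)
  }
  paste(chars, collapse = "")
}

rc_chr <- function(s) chartr("ACGTN", "TGCAN", vapply(strsplit(s, ""), function(x)
  paste(rev(x), collapse = ""), character(1)))
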