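# Small sequence helpers shared across modules. All coordinates in this
# package are 0-based half-open unless a function says otherwise.

DNA_BASES <- c("A", "C", "G", "T")

random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

# Uniform integers in [lo, hi]; safe when lo == hi (unlike sample(lo:hi)).
sample_range <- function(lo, hi, n = 1L) {
  lo + sample.int(hi - lo + 1L, n, replace = TRUE) - 1L
}

revcomp <- function(x) {
  if (length(x) == 0) return(character(0))
  out <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
  unname(out)
}

#' @noRd
# Longest single-nucleotide run in each sequence.
max_homopolymer_run <- function(x) {
  vapply(x, function(s) {
    if (!nzchar(s)) return(0L)
    r <- rle(strsplit(s, "", fixed = TRUE)[[1]])
    max(r$lengths)
  }, integer(1), USE.NAMES = FALSE)
}

#' @noRd
# Highest mono-nucleotide fraction in each sequence.
max_mono_fraction <- function(x) {
  vapply(x, function(s) {
    n <- nchar(s)
    if (n == 0) return(0)
    tab <- table(strsplit(s, "", fixed = TRUE)[[1]])
    max(tab) / n
  }, numeric(1), USE.NAMES = FALSE)
}

#' @noRd
# Homopolymer intervals (0-based half-open) of at least `min_run` bases.
homopolymer_regions <- function(seq, min_run = 20L) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  r <- rle(chars)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$lengths >= min_run
  tibble(base = r$values[keep], start = starts[keep], end = ends[keep])
}

# Hamming distance between equal-length strings where 'N' on either side
# never counts as a match.
hamming_n <- function(a, b) {
  ra <- charToRaw(a)
  rb <- charToRaw(b)
  stopifnot(length(ra) == length(rb))
  rn <- charToRaw("N")
  sum(ra != rb | ra == rn | rb == rn)
}

as_named_character <- function(x, what = "sequences") {
  if (inherits(x, "DNAStringSet") || inherits(x, "XStringSet")) {
    out <- as.character(x)
  } else if (is.character(x)) {
    out <- x
  } else {
    abort(sprintf("Cannot interpret %s of class '%s'", what, class(x)[1]))
  }
  if (length(out) > 0 && (is.null(names(out)) || anyNA(names(out)) || any(!nzchar(names(out))))) {
    abort(sprintf("All %s must be named", what))
  }
  if (anyDuplicated(names(out))) {
    abort(sprintf("Duplicate names in %s: %s", what,
                  paste(unique(names(out)[duplicated(names(out))]), collapse = ", ")))
  }
  out
}
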