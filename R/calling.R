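# Clustering of split evidence into candidate calls and the quality filters:
# support, spread window, anchor span, locus identity, repeat identity,
# low-complexity poly-T, symmetry score, coverage ratio and zygosity.

#' Cluster split evidence into candidate calls
#'
#' Single-linkage clustering of evidence sharing an element and chromosome:
#' two junctions link when they lie within `cluster_range` nt (300 by
#' default). Deterministic given the input, which is sorted internally by
#' (element, chromosome, junction).
#'
#' @param evidence Evidence tibble from [assemble_split_evidence()].
#' @param cluster_range Link distance in nt.
#' @return Cluster tibble: `cluster_id`, `element_db`, `element_name`,
#'   `chrom`, `position` (median member junction, ties to the smaller
#'   coordinate), `n_support`, `n_upstream`, `n_downstream`, `width`
#'   (junction spread in nt), `span` (genome-anchor extent in nt),
#'   `strand_of_element`, and a nested `members` list-column holding the
#'   member evidence.
#' @export
cluster_evidence <- function(evidence, cluster_range = 300L) {
  ev <- as_tibble(evidence) |>
    arrange(.data$element_name, .data$chrom, .data$junction_pos)
  if (nrow(ev) == 0) {
    return(tibble(cluster_id = character(0), element_db = character(0),
                  element_name = character(0), chrom = character(0),
                  position = integer(0), n_support = integer(0),
                  n_upstream = integer(0), n_downstream = integer(0),
                  width = integer(0), span = integer(0),
                  strand_of_element = character(0), members = list()))
  }
  ev <- ev |>
    group_by(.data$element_name, .data$chrom) |>
    mutate(.new = c(TRUE, diff(.data$junction_pos) > cluster_range),
           .sub = cumsum(.data$.new)) |>
    ungroup() |>
    mutate(cluster_id = paste(.data$element_name, .data$chrom, .data$.sub, sep = "@")) |>
    select(-".new", -".sub")

  ev |>
    group_by(.data$cluster_id, .data$element_db, .data$element_name, .data$chrom) |>
    summarise(position = median_low(.data$junction_pos),
              n_support = n(),
              n_upstream = sum(.data$side == "UPSTREAM"),
              n_downstream = sum(.data$side == "DOWNSTREAM"),
              width = max(.data$junction_pos) - min(.data$junction_pos),
              span = max(.data$anchor_end) - min(.data$anchor_start),
              strand_of_element = majority_strand(.data$element_strand),
              members = list(pick(everything())),
              .groups = "drop") |>
    arrange(.data$chrom, .data$position, .data$element_name)
}

# Median with ties resolved to the smaller coordinate.
#' @noRd
median_low <- function(x) {
  s <- sort(x)
  s[floor((length(s) + 1) / 2)]
}

#' @noRd
majority_strand <- function(strands) {
  np <- sum(strands == "+"); nm <- sum(strands == "-")
  if (np > nm) "+" else if (nm > np) "-" else "unknown"
}

#' Support and spread filters
#'
#' Flags `MIN_SUPPORT` when a cluster has fewer than `min_support` reads,
#' `WINDOW` when its junction spread (`width`) exceeds `window_multiplier`
#' times the read length (supporting reads must lie within the defined
#' window around one breakpoint), and `SPAN` when the genome-anchor extent
#' (`span`) is below `read_length / 2 - end_length` (reads stacked on one
#' spot rather than spread out).
#'
#' @param clusters Cluster tibble from [cluster_evidence()].
#' @param config A [pipeline_config()].
#' @param read_length Read length in nt (sets both window and span bounds).
#' @return `clusters` with logical columns `flag_min_support`, `flag_window`,
#'   `flag_span`.
#' @export
support_and_spread_filter <- function(clusters, config = pipeline_config(),
                                      read_length = 100L) {
  clusters |>
    mutate(flag_min_support = .data$n_support < config$min_support,
           flag_window = .data$width > config$window_multiplier * read_length,
           flag_span = .data$span < span_min(config, read_length))
}

#' Locus-identity and repeat-identity filters
#'
#' `identity_score` is the mean fraction of genome-anchor bases matching at
#' the called locus over the member reads; clusters below
#' `identity_keep_min` (50%) are flagged `LOW_IDENTITY`. `repeat_identity`
#' is the best fraction of any member's genome end matching a TE-library
#' sequence; clusters above `repeat_identity_discard` (83%) are flagged
#' `REPETITIVE` — their "genomic" anchor is itself repeat-derived.
#'
#' @param clusters Cluster tibble.
#' @param bundle A [reference_bundle()] (for the repeat library).
#' @param config A [pipeline_config()].
#' @return `clusters` with `identity_score`, `repeat_identity`,
#'   `flag_low_identity`, `flag_repetitive` columns.
#' @export
identity_filter <- function(clusters, bundle, config = pipeline_config()) {
  el <- config$end_length
  ident <- map_dbl(clusters$members, function(m) mean(1 - m$genome_mm / el))

  # deepest mismatch stratum still informative about the 83% cutoff
  mm_cap <- min(el - 1L, ceiling(el * (1 - config$repeat_identity_discard)) + 1L)
  all_seqs <- unique(unlist(lapply(clusters$members, function(m) m$genome_end_seq)))
  rep_id_of <- if (length(all_seqs) && length(bundle$te_library)) {
    best <- batch_best_mismatch(all_seqs, bundle$te_library, mm_cap)
    setNames(1 - best / el, all_seqs)
  } else {
    setNames(numeric(0), character(0))
  }
  rep_ident <- map_dbl(clusters$members, function(m) {
    v <- rep_id_of[m$genome_end_seq]
    if (all(is.na(v))) 0 else max(v, na.rm = TRUE)
  })

  clusters |>
    mutate(identity_score = ident,
           repeat_identity = rep_ident,
           flag_low_identity = .data$identity_score < config$identity_keep_min,
           flag_repetitive = .data$repeat_identity > config$repeat_identity_discard)
}

#' Low-complexity (poly-T) filter
#'
#' Flags `POLY_T` when any member's element end carries a single-nucleotide
#' run of at least `polyT_run_min` nt or a mono-nucleotide fraction of at
#' least `polyT_fraction_min`, or when the element-end alignment falls
#' entirely inside a homopolymer tract (>= 20nt) of the element consensus —
#' the hopper/M4DM poly-T artifact signature of reverse-transcribed poly-A
#' tails.
#'
#' @param clusters Cluster tibble.
#' @param config A [pipeline_config()].
#' @param bundle Optional [reference_bundle()]; when given, element
#'   homopolymer tracts are screened as well.
#' @return `clusters` with a logical `flag_polyT` column.
#' @export
low_complexity_filter <- function(clusters, config = pipeline_config(),
                                  bundle = NULL) {
  tracts <- if (!is.null(bundle)) {
    lapply(bundle$te_library, homopolymer_regions, min_run = 20L)
  } else {
    NULL
  }
  el <- config$end_length
  flag <- vapply(seq_len(nrow(clusters)), function(ci) {
    m <- clusters$members[[ci]]
    runs <- max_homopolymer_run(m$element_end_seq)
    fracs <- max_mono_fraction(m$element_end_seq)
    if (any(runs >= config$polyT_run_min | fracs >= config$polyT_fraction_min)) {
      return(TRUE)
    }
    tr <- if (!is.null(tracts)) tracts[[clusters$element_name[ci]]] else NULL
    if (!is.null(tr) && nrow(tr) > 0) {
      p0 <- m$element_pos
      if (any(outer(p0, tr$start, ">=") & outer(p0 + el, tr$end, "<="))) return(TRUE)
    }
    FALSE
  }, logical(1))
  clusters |> mutate(flag_polyT = flag)
}

#' @noRd
map_lgl_members <- function(members, f) vapply(members, f, logical(1))

#' Symmetry score of a call
#'
#' Percentage of supporting reads on the upstream side of the insertion
#' point, clamped to `[1, 99]`. A score of 50 is ideal symmetry (half the
#' reads on each side); 1 and 99 are fully one-sided.
#'
#' @param n_upstream,n_downstream Supporting reads on each side
#'   (vectorized).
#' @return Numeric score(s) in `[1, 99]`.
#' @export
symmetry_score <- function(n_upstream, n_downstream) {
  n <- n_upstream + n_downstream
  stopifnot(all(n >= 1))
  pmin(pmax(100 * n_upstream / n, 1), 99)
}

#' Coverage ratio and zygosity annotation
#'
#' `CR = n_support / (local_depth + pseudocount)`, where `local_depth` is
#' the number of genome-aligned reads (from the subtraction stage) whose
#' alignment spans the junction point. A homozygous insertion leaves no
#' reference-spanning reads, so its CR is high; calls with CR below
#' `cr_het_max` (1.5) are annotated `het_or_cnv` — a heterozygous insertion
#' or local copy-number flux.
#'
#' @param clusters Cluster tibble.
#' @param genome_alignments Alignments of subtracted reads (attribute
#'   `genome_alignments` of [subtract_reference_mappers()]), or `NULL` for a
#'   zero local depth everywhere.
#' @param config A [pipeline_config()].
#' @return `clusters` with `local_depth`, `coverage_ratio`, `zygosity_label`
#'   columns.
#' @export
coverage_ratio <- function(clusters, genome_alignments = NULL,
                           config = pipeline_config()) {
  depth <- if (is.null(genome_alignments) || nrow(genome_alignments) == 0) {
    integer(nrow(clusters))
  } else {
    ga <- as_tibble(genome_alignments)
    vapply(seq_len(nrow(clusters)), function(i) {
      p <- clusters$position[i]
      sum(ga$chrom == clusters$chrom[i] & ga$start < p & ga$end > p)
    }, integer(1))
  }
  clusters |>
    mutate(local_depth = depth,
           coverage_ratio = .data$n_support / (depth + config$cr_pseudocount),
           zygosity_label = ifelse(.data$coverage_ratio < config$cr_het_max,
                                   "het_or_cnv", "homozygous"))
}

#' Finalize clusters into call records
#'
#' Clusters with no blocking flag become PASS calls; flagged clusters are
#' retained with their filter annotations so artifact classes stay visible
#' in the output tables.
#'
#' @param clusters Cluster tibble carrying all filter columns.
#' @return Call tibble: one row per cluster with `call_id`, scores, a
#'   comma-separated `filter_flags` column and logical `pass`.
#' @export
finalize_calls <- function(clusters) {
  flag_cols <- c(MIN_SUPPORT = "flag_min_support", WINDOW = "flag_window",
                 SPAN = "flag_span", LOW_IDENTITY = "flag_low_identity",
                 REPETITIVE = "flag_repetitive", POLY_T = "flag_polyT")
  present <- flag_cols[flag_cols %in% names(clusters)]
  flags <- vapply(seq_len(nrow(clusters)), function(i) {
    on <- names(present)[vapply(present, function(cn) isTRUE(clusters[[cn]][i]), logical(1))]
    paste(on, collapse = ",")
  }, character(1))
  samp <- map_chr(clusters$members, function(m) {
    s <- unique(m$sample_id)
    if (length(s) == 1) s else paste(sort(s), collapse = ",")
  })
  clusters |>
    mutate(call_id = sprintf("call%04d", row_number()),
           symmetry = symmetry_score(.data$n_upstream, .data$n_downstream),
           filter_flags = flags,
           pass = !nzchar(flags),
           sample_id = samp) |>
    select("call_id", "element_db", "element_name", "chrom", "position",
           "strand_of_element", "n_support", "n_upstream", "n_downstream",
           "symmetry", "width", "span", any_of(c("identity_score", "repeat_identity",
                                        "local_depth", "coverage_ratio",
                                        "zygosity_label")),
           "filter_flags", "pass", "sample_id", "members")
}

#' Cluster evidence and apply every call filter
#'
#' Convenience orchestrator: [cluster_evidence()], then support/spread,
#' identity, low-complexity (optional), symmetry, coverage ratio, and
#' [finalize_calls()].
#'
#' @param evidence Evidence tibble.
#' @param bundle A [reference_bundle()].
#' @param config A [pipeline_config()].
#' @param read_length Representative read length (nt).
#' @param genome_alignments Subtracted-read alignments for the coverage
#'   ratio (may be `NULL`).
#' @param polyT_filter Apply the low-complexity filter (disabled for WGS
#'   input, which is immune to the poly-T artifact)?
#' @return Call tibble from [finalize_calls()].
#' @export
call_insertions <- function(evidence, bundle, config = pipeline_config(),
                            read_length = 100L, genome_alignments = NULL,
                            polyT_filter = TRUE) {
  cl <- cluster_evidence(evidence, cluster_range = config$cluster_range)
  if (nrow(cl) == 0) return(finalize_calls(cl |> mutate(flag_min_support = logical(0))))
  cl <- support_and_spread_filter(cl, config, read_length)
  cl <- identity_filter(cl, bundle, config)
  if (polyT_filter) cl <- low_complexity_filter(cl, config, bundle)
  cl <- coverage_ratio(cl, genome_alignments, config)
  finalize_calls(cl)
}
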