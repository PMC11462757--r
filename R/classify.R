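# Call triage into the three event categories, junction-context resolution
# against gene models, cross-sample recurrence, and the TE-autonomy
# rank-correlation analysis.

#' Classify calls into TE-mRNA fusion, two-mRNA fusion or InDel/splice
#'
#' An element end in the TE library makes a `TE_MRNA_FUSION`. An element end
#' in the IGE control set is an `INDEL_SPLICE` isoform when the IGE is the
#' gene at the genomic locus (within `max_gene_distance`), and a
#' `TWO_MRNA_FUSION` (template-switch / shared-sequence artifact) when it is
#' a different gene. For TE-mRNA fusions the junction context against the
#' gene models is added: `INTRON_RETENTION` (junction inside an intron),
#' `EXON_JUNCTION` (junction within `exon_boundary_tol` of an exon edge —
#' seamless exonization), `EXONIC_INSERTION` (inside an exon/UTR) or
#' `INTERGENIC`.
#'
#' @param calls Call tibble from [finalize_calls()].
#' @param bundle A [reference_bundle()].
#' @param config A [pipeline_config()].
#' @param max_gene_distance Genomic distance bounding the "same gene" test
#'   for InDel/splice classification (nt).
#' @param exon_boundary_tol Exon-boundary tolerance for `EXON_JUNCTION`
#'   (nt); matches the granularity of 22nt end anchoring.
#' @param annotate_context Add junction context (disabled for WGS input,
#'   where transcript structure is absent)?
#' @return `calls` with `call_class` and `junction_context` columns.
#' @export
classify_calls <- function(calls, bundle, config = pipeline_config(),
                           max_gene_distance = 10000L, exon_boundary_tol = 2L,
                           annotate_context = TRUE) {
  te_names <- names(bundle$te_library)
  ige_names <- names(bundle$ige_set)
  spans <- gene_spans(bundle$gene_models)

  known <- calls$element_name %in% c(te_names, ige_names)
  if (any(!known)) {
    abort(paste0("Unknown element name(s) in calls: ",
                 paste(unique(calls$element_name[!known]), collapse = ", ")))
  }

  gene_at <- function(chrom, pos) {
    cand <- spans[spans$chrom == chrom, , drop = FALSE]
    if (nrow(cand) == 0) return(NA_character_)
    d <- pmax(cand$start - pos, pos - cand$end, 0)
    if (min(d) > max_gene_distance) return(NA_character_)
    cand$gene_id[which.min(d)]
  }

  cls <- character(nrow(calls))
  for (i in seq_len(nrow(calls))) {
    if (calls$element_name[i] %in% te_names) {
      cls[i] <- "TE_MRNA_FUSION"
    } else {
      g <- gene_at(calls$chrom[i], calls$position[i])
      cls[i] <- if (!is.na(g) && g == calls$element_name[i]) "INDEL_SPLICE" else "TWO_MRNA_FUSION"
    }
  }
  out <- calls |> mutate(call_class = cls)
  ctx <- rep(NA_character_, nrow(out))
  if (annotate_context) {
    is_te <- out$call_class == "TE_MRNA_FUSION"
    ctx[is_te] <- junction_context(out$chrom[is_te], out$position[is_te],
                                   bundle$gene_models, tol = exon_boundary_tol)
  }
  out |> mutate(junction_context = ctx)
}

#' Junction context of TE-mRNA fusion positions
#'
#' @param chrom,position Vectors of call coordinates (0-based junctions).
#' @param gene_models Gene-model tibble (exon rows); the union of exonic
#'   bases across isoforms defines "exonic".
#' @param tol Exon-boundary tolerance in nt.
#' @return Character vector: `EXON_JUNCTION`, `EXONIC_INSERTION`,
#'   `INTRON_RETENTION` or `INTERGENIC`.
#' @export
junction_context <- function(chrom, position, gene_models, tol = 2L) {
  gm <- as_tibble(gene_models)
  spans <- gene_spans(gm)
  exon_union <- gm |>
    group_by(.data$chrom) |>
    reframe({
      ir <- IRanges::reduce(IRanges::IRanges(start = .data$start + 1L, end = .data$end))
      tibble(start = BiocGenerics::start(ir) - 1L, end = BiocGenerics::end(ir))
    })
  vapply(seq_along(position), function(i) {
    p <- position[i]
    ex <- exon_union[exon_union$chrom == chrom[i], , drop = FALSE]
    sp <- spans[spans$chrom == chrom[i], , drop = FALSE]
    if (nrow(ex) > 0 && any(abs(p - ex$start) <= tol | abs(p - ex$end) <= tol)) {
      return("EXON_JUNCTION")
    }
    if (nrow(ex) > 0 && any(p > ex$start & p < ex$end)) return("EXONIC_INSERTION")
    if (nrow(sp) > 0 && any(p >= sp$start & p <= sp$end)) return("INTRON_RETENTION")
    "INTERGENIC"
  }, character(1))
}

#' Cross-sample recurrence of calls
#'
#' Merges calls across samples when they share an element and lie within
#' `merge_range` nt (single-linkage, so merging is symmetric and transitive),
#' then counts how many samples support each merged call.
#'
#' @param call_tables A list of call tibbles (one per sample) or one tibble
#'   with a `sample_id` column.
#' @param merge_range Positional merge distance; defaults to the clustering
#'   range (300nt).
#' @param pass_only Restrict to PASS calls?
#' @return List with `calls` (merged-call tibble: element, chromosome,
#'   representative position, `n_samples`, supporting samples) and
#'   `histogram` (tibble `n_samples`, `n_calls`).
#' @export
recurrence_across_samples <- function(call_tables, merge_range = 300L,
                                      pass_only = TRUE) {
  tbl <- if (is.data.frame(call_tables)) as_tibble(call_tables) else bind_rows(call_tables)
  if (!"sample_id" %in% names(tbl)) abort("call tables must carry a sample_id column")
  if (pass_only && "pass" %in% names(tbl)) tbl <- tbl |> filter(.data$pass)
  if (nrow(tbl) == 0) {
    return(list(calls = tibble(element_name = character(0), chrom = character(0),
                               position = integer(0), n_samples = integer(0),
                               samples = character(0)),
                histogram = tibble(n_samples = integer(0), n_calls = integer(0))))
  }
  merged <- tbl |>
    arrange(.data$element_name, .data$chrom, .data$position) |>
    group_by(.data$element_name, .data$chrom) |>
    mutate(.grp = cumsum(c(TRUE, diff(.data$position) > merge_range))) |>
    group_by(.data$element_name, .data$chrom, .data$.grp) |>
    summarise(position = median_low(.data$position),
              n_samples = n_distinct(.data$sample_id),
              samples = paste(sort(unique(.data$sample_id)), collapse = ","),
              .groups = "drop") |>
    select(-".grp")
  hist <- merged |> count(.data$n_samples, name = "n_calls")
  list(calls = merged, histogram = hist)
}

#' Call-category counts and proportions
#'
#' @param calls Classified call tibble.
#' @param pass_only Restrict to PASS calls?
#' @return Tibble with one row per class (`TE_MRNA_FUSION`,
#'   `TWO_MRNA_FUSION`, `INDEL_SPLICE`): `n_calls` and `fraction` (fractions
#'   sum to 1 unless the table is empty, which yields zeros and a warning).
#' @export
category_proportions <- function(calls, pass_only = TRUE) {
  classes <- c("TE_MRNA_FUSION", "TWO_MRNA_FUSION", "INDEL_SPLICE")
  tbl <- as_tibble(calls)
  if (pass_only && "pass" %in% names(tbl)) tbl <- tbl |> filter(.data$pass)
  out <- tibble(call_class = classes) |>
    left_join(count(tbl, .data$call_class, name = "n_calls"), by = "call_class") |>
    mutate(n_calls = coalesce(.data$n_calls, 0L))
  total <- sum(out$n_calls)
  if (total == 0) {
    warn("No classified calls; category fractions are all zero")
    out$fraction <- 0
  } else {
    out$fraction <- out$n_calls / total
  }
  out
}

#' TE autonomy by rank correlation
#'
#' Compares each TE family's consensus-aligned read count (autonomous
#' transcription of the element) with its TE-mRNA fusion support. Both are
#' ranked per library with average ranks for ties (no normalisation or other
#' transformation of the raw counts), and the overall Spearman rho is the
#' Pearson correlation of the two rank vectors. Elements whose fusion rank
#' exceeds their consensus rank sit in the upper-diagonal half of the
#' rank-rank scatter — expression tied to the host gene, `NON_AUTONOMOUS`;
#' elements below the diagonal are `AUTONOMOUS`; exact ties sit
#' `ON_DIAGONAL`.
#'
#' @param consensus_counts Named numeric vector (or tibble
#'   `element_name`/`n_reads`, as produced by [screen_contaminants()]) of
#'   reads aligned end-to-end to each TE consensus.
#' @param fusion_counts Named numeric vector or tibble `element_name`/
#'   `n_support` of TE-mRNA fusion support per element.
#' @return An object of class `te_autonomy`: element tibble plus
#'   `spearman_rho`. At least 3 elements are required.
#' @export
autonomy_correlation <- function(consensus_counts, fusion_counts) {
  cons <- as_count_vector(consensus_counts, c("n_reads", "count", "n"))
  fus <- as_count_vector(fusion_counts, c("n_support", "count", "n"))
  elements <- union(names(cons), names(fus))
  if (length(elements) < 3) {
    abort("autonomy_correlation needs at least 3 elements for a defined rho")
  }
  cc <- unname(cons[elements]); cc[is.na(cc)] <- 0
  ff <- unname(fus[elements]); ff[is.na(ff)] <- 0
  cr <- rank(cc, ties.method = "average")
  fr <- rank(ff, ties.method = "average")
  rho <- cor(cr, fr)
  tbl <- tibble(element_name = elements,
                consensus_reads = cc, fusion_support = ff,
                consensus_rank = cr, fusion_rank = fr,
                label = case_when(fr > cr ~ "NON_AUTONOMOUS",
                                  fr < cr ~ "AUTONOMOUS",
                                  TRUE ~ "ON_DIAGONAL"))
  structure(list(elements = tbl, spearman_rho = rho, n = length(elements)),
            class = "te_autonomy")
}

#' @noRd
as_count_vector <- function(x, value_cols) {
  if (is.data.frame(x)) {
    vc <- intersect(value_cols, names(x))
    if (length(vc) == 0) abort("count table needs one of the expected count columns")
    return(setNames(as.numeric(x[[vc[1]]]), x$element_name))
  }
  if (is.null(names(x))) abort("count vectors must be named by element")
  setNames(as.numeric(x), names(x))
}

#' @export
print.te_autonomy <- function(x, ...) {
  cat(sprintf("<te_autonomy> %d elements, Spearman rho = %.3f\n", x$n, x$spearman_rho))
  cat(sprintf("  autonomous: %d, non-autonomous: %d, on-diagonal: %d\n",
              sum(x$elements$label == "AUTONOMOUS"),
              sum(x$elements$label == "NON_AUTONOMOUS"),
              sum(x$elements$label == "ON_DIAGONAL")))
  invisible(x)
}

#' Tidy a TE-autonomy result
#'
#' @param x A `te_autonomy` object.
#' @param ... Unused.
#' @return One row per element with counts, ranks and autonomy label.
#' @export
tidy.te_autonomy <- function(x, ...) x$elements

#' One-row summary of a TE-autonomy result
#'
#' @param x A `te_autonomy` object.
#' @param ... Unused.
#' @return Tibble with `spearman_rho`, `n_elements`, `n_autonomous`,
#'   `n_non_autonomous`.
#' @export
glance.te_autonomy <- function(x, ...) {
  tibble(spearman_rho = x$spearman_rho, n_elements = x$n,
         n_autonomous = sum(x$elements$label == "AUTONOMOUS"),
         n_non_autonomous = sum(x$elements$label == "NON_AUTONOMOUS"))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
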