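#' Pipeline configuration
#'
#' Holds every tunable threshold of the calling pipeline. Defaults are the
#' field-standard split-read values: 22nt terminal ends mapped with up to 3
#' mismatches, 300nt junction clustering, a minimum of 4 supporting split
#' reads, a spread window of 2x the read length, an anchor-span floor of
#' `read_length/2 - end_length`, a 50% locus-identity keep threshold, an 83%
#' repeat-identity discard threshold, a coverage-ratio pseudocount of 1 and a
#' heterozygous/CNV cutoff of CR < 1.5, and a 100nt ceiling for "tiny"
#' introns.
#'
#' @param end_length nt taken from each read end for split mapping.
#' @param max_mismatches Maximum mismatches allowed per mapped end.
#' @param cluster_range nt; single-linkage distance for junction clustering.
#' @param min_support Minimum split reads supporting a call.
#' @param window_multiplier Cluster spread ceiling, in read lengths.
#' @param identity_keep_min Minimum mean locus-realignment identity to keep.
#' @param repeat_identity_discard Genome ends more similar than this to any
#'   TE-library sequence are discarded as repetitive.
#' @param cr_pseudocount Pseudocount in the coverage-ratio denominator.
#' @param cr_het_max Calls with CR below this are annotated het-or-CNV.
#' @param tiny_intron_max nt; introns below this are "tiny" (annotation aid).
#' @param polyT_run_min,polyT_fraction_min Low-complexity filter: an element
#'   end with a single-nucleotide run at least `polyT_run_min` long, or a
#'   mono-nucleotide fraction at least `polyT_fraction_min`, is flagged.
#' @param adapter 3' adapter sequence removed during preprocessing.
#' @param min_qual Phred floor for 3' quality trimming.
#' @param min_len Minimum read length after trimming; defaults to
#'   `2 * end_length` so both terminal ends still exist.
#' @param polyA_run_min Minimum terminal A (or leading T) run trimmed.
#' @param rng_seed Seed recorded in run logs.
#' @return An object of class `pipeline_config` (a named list).
#' @export
pipeline_config <- function(end_length = 22L,
                            max_mismatches = 3L,
                            cluster_range = 300L,
                            min_support = 4L,
                            window_multiplier = 2,
                            identity_keep_min = 0.50,
                            repeat_identity_discard = 0.83,
                            cr_pseudocount = 1,
                            cr_het_max = 1.5,
                            tiny_intron_max = 100L,
                            polyT_run_min = 15L,
                            polyT_fraction_min = 0.8,
                            adapter = "AGATCGGAAGAGC",
                            min_qual = 20L,
                            min_len = NULL,
                            polyA_run_min = 10L,
                            rng_seed = 1L) {
  cfg <- list(end_length = as.integer(end_length),
              max_mismatches = as.integer(max_mismatches),
              cluster_range = as.integer(cluster_range),
              min_support = as.integer(min_support),
              window_multiplier = window_multiplier,
              identity_keep_min = identity_keep_min,
              repeat_identity_discard = repeat_identity_discard,
              cr_pseudocount = cr_pseudocount,
              cr_het_max = cr_het_max,
              tiny_intron_max = as.integer(tiny_intron_max),
              polyT_run_min = as.integer(polyT_run_min),
              polyT_fraction_min = polyT_fraction_min,
              adapter = adapter,
              min_qual = as.integer(min_qual),
              min_len = if (is.null(min_len)) 2L * as.integer(end_length) else as.integer(min_len),
              polyA_run_min = as.integer(polyA_run_min),
              rng_seed = as.integer(rng_seed))
  class(cfg) <- "pipeline_config"
  validate_pipeline_config(cfg)
  cfg
}

validate_pipeline_config <- function(cfg) {
  stopifnot(cfg$end_length >= 1L, cfg$min_support >= 1L,
            cfg$max_mismatches >= 0L, cfg$cluster_range >= 0L)
  for (f in c("identity_keep_min", "repeat_identity_discard", "polyT_fraction_min")) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1) abort(sprintf("%s must lie in [0, 1]", f))
  }
  if (cfg$window_multiplier <= 0) abort("window_multiplier must be positive")
  invisible(cfg)
}

#' Minimum anchor span for a given read length
#'
#' `span_min = read_length / 2 - end_length`; recomputed whenever the read
#' length changes, as the span filter scales with the input reads.
#'
#' @param config A [pipeline_config()].
#' @param read_length Read length in nt.
#' @return Minimum anchor span in nt.
#' @export
span_min <- function(config, read_length) {
  read_length / 2 - config$end_length
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config>\n")
  for (nm in names(x)) cat(sprintf("  %-24s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

#' Read / write a pipeline configuration as YAML
#'
#' Field names mirror the [pipeline_config()] arguments; unknown keys are an
#' error (listed in the message).
#'
#' @param path YAML file path.
#' @return [read_pipeline_config()] returns a `pipeline_config`;
#'   [write_pipeline_config()] returns `path` invisibly.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) abort(paste0("Unknown pipeline config keys: ", paste(bad, collapse = ", ")))
  do.call(pipeline_config, vals)
}

#' @rdname read_pipeline_config
#' @param config A [pipeline_config()] to serialize.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Simulation configuration
#'
#' Parameters of the synthetic-data generator. Defaults describe the study
#' conditions the package is tested under: one 200kb chromosome, 10 genes of
#' 5 exons, introns from 70nt (so tiny introns below 100nt occur) to 1.5kb,
#' 5 TE families of 0.5-1.5kb including a hopper-like element carrying an
#' internal poly-T tract, 6 planted insertions (4 homozygous intronic, 2
#' heterozygous 3'UTR), 100nt reads at a depth giving >= 10x usable junction
#' coverage, 0.5% substitution error, intron retention at 0.4, no exonization
#' (mirroring its absence in real data), 1% template-switch chimeras at 3
#' recurrent sites and 2% poly-A read-through artifacts.
#'
#' @param rng_seed Master seed; all outputs are bit-identical given the seed.
#' @param n_chroms,chrom_length Genome shape.
#' @param n_genes,exons_per_gene,exon_length_range,intron_length_range Gene
#'   architecture; `intron_length_range` must allow values below 100nt for a
#'   tiny intron to be planted (the first intron of the first gene is set to
#'   the range minimum when that minimum is below 100).
#' @param n_te_families,te_length_range,include_polyT_te TE library shape; if
#'   `include_polyT_te` the last family ("hopper_like") carries an internal
#'   T-homopolymer of at least 20nt.
#' @param insertions Tibble (`te_family`, `gene`, `site` in
#'   `c("intron","utr3")`, `zygosity` in `c("hom","het")`) or `NULL` for the
#'   default panel of 6.
#' @param rate_intron_retention,rate_exonization Per-read template rates for
#'   genes carrying an intronic TE.
#' @param rate_two_mrna_chimera Fraction of reads formed by template
#'   switching between two genes, at `n_chimera_sites` recurrent site pairs.
#' @param rate_polyA_artifact Fraction of reads that read through the poly-A
#'   tail in reverse complement (leading poly-T segments).
#' @param polyA_tail_length Poly-A tail appended to mRNA templates (nt).
#' @param rt_misincorporation Per-base misincorporation rate inside the
#'   reverse-transcribed tail, so some artifact T-runs are interrupted and
#'   survive terminal trimming (as observed for hopper/M4DM false calls).
#' @param indel_events Tibble (`gene`, `size` <= 60nt) of transcript-level
#'   deletions, or `NULL` for the default two events.
#' @param read_length,depth,error_rate Read geometry, mean reads per gene and
#'   per-base substitution error.
#' @param expression_sdlog Log-normal spread of per-gene expression.
#' @param te_autonomous_depth Mean reads per TE family transcribed
#'   autonomously from its consensus.
#' @param wgs_depth Fold-coverage per haplotype for [simulate_wgs_reads()].
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(rng_seed = 1L,
                       n_chroms = 1L,
                       chrom_length = 200000L,
                       n_genes = 10L,
                       exons_per_gene = 5L,
                       exon_length_range = c(150L, 400L),
                       intron_length_range = c(70L, 1500L),
                       n_te_families = 5L,
                       te_length_range = c(500L, 1500L),
                       include_polyT_te = TRUE,
                       insertions = NULL,
                       rate_intron_retention = 0.4,
                       rate_exonization = 0,
                       rate_two_mrna_chimera = 0.01,
                       n_chimera_sites = 3L,
                       rate_polyA_artifact = 0.02,
                       polyA_tail_length = 30L,
                       rt_misincorporation = 0.05,
                       indel_events = NULL,
                       read_length = 100L,
                       depth = 1200,
                       error_rate = 0.005,
                       expression_sdlog = 0.2,
                       te_autonomous_depth = 120,
                       wgs_depth = 20) {
  cfg <- as.list(environment())
  cfg$rng_seed <- as.integer(rng_seed)
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  rates <- c("rate_intron_retention", "rate_exonization", "rate_two_mrna_chimera",
             "rate_polyA_artifact", "error_rate", "rt_misincorporation")
  for (f in rates) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1) abort(sprintf("%s must lie in [0, 1]", f))
  }
  if (cfg$read_length < 2 * 22) {
    abort("read_length must be at least twice the 22nt end length")
  }
  if (!is.null(cfg$indel_events)) {
    ie <- as_tibble(cfg$indel_events)
    if (any(ie$size > 60)) abort("indel_events sizes must be <= 60nt")
  }
  for (f in c("n_chroms", "chrom_length", "n_genes", "exons_per_gene", "n_te_families")) {
    if (cfg[[f]] < 1) abort(sprintf("%s must be >= 1", f))
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  for (nm in names(x)) {
    val <- x[[nm]]
    if (is.data.frame(val)) val <- sprintf("<%d events>", nrow(val))
    cat(sprintf("  %-24s %s\n", nm, paste(format(val), collapse = " ")))
  }
  invisible(x)
}

#' @rdname read_pipeline_config
#' @export
read_sim_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(sim_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) abort(paste0("Unknown sim config keys: ", paste(bad, collapse = ", ")))
  for (f in c("insertions", "indel_events")) {
    if (!is.null(vals[[f]])) vals[[f]] <- as_tibble(as.data.frame(vals[[f]]))
  }
  do.call(sim_config, vals)
}

#' @rdname read_pipeline_config
#' @export
write_sim_config <- function(config, path) {
  vals <- unclass(config)
  for (f in c("insertions", "indel_events")) {
    if (!is.null(vals[[f]])) vals[[f]] <- as.list(as.data.frame(vals[[f]]))
  }
  yaml::write_yaml(vals, path)
  invisible(path)
}
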