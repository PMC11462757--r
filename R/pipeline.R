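#' Run the full calling pipeline on a read set
#'
#' Executes preprocess -> reference subtraction -> contaminant/TE screen ->
#' terminal-end extraction and mapping -> split-evidence assembly ->
#' clustering and filtering -> classification. In `"wgs"` mode poly-A
#' trimming, the poly-T low-complexity filter and junction-context
#' annotation are disabled (genomic libraries have no tails and no
#' transcript structure).
#'
#' @param reads Read tibble ([read_fastq()] or the simulator).
#' @param bundle A [reference_bundle()].
#' @param config A [pipeline_config()].
#' @param mode `"rnaseq"` or `"wgs"`.
#' @param sample_id Overrides the reads' sample label when given.
#' @return Object of class `te_pipeline_result`: a list with `calls`
#'   (classified call tibble), `evidence`, `consensus_counts` (per-TE
#'   end-to-end read tallies), `genome_alignments`, and `run_log` (every
#'   threshold used plus per-stage attrition counts).
#' @export
run_te_pipeline <- function(reads, bundle, config = pipeline_config(),
                            mode = c("rnaseq", "wgs"), sample_id = NULL) {
  mode <- match.arg(mode)
  if (!is.null(sample_id)) reads$sample_id <- sample_id
  if (!"sample_id" %in% names(reads)) reads$sample_id <- "sample"

  log <- list(mode = mode, thresholds = unclass(config))

  pre <- preprocess_reads(reads, config, mode = mode)
  log$preprocess <- attr(pre, "preprocess_log")

  read_length <- if (nrow(pre)) as.integer(round(median(nchar(pre$sequence)))) else 0L
  log$read_length <- read_length

  sub <- subtract_reference_mappers(pre, bundle, max_mm = config$max_mismatches)
  genome_alignments <- attr(sub, "genome_alignments")
  log$n_reference_subtracted <- attr(sub, "n_removed")

  scr <- screen_contaminants(sub, bundle, max_mm = config$max_mismatches)
  consensus_counts <- attr(scr, "te_consensus_counts")
  log$n_contaminant_screened <- attr(scr, "n_removed")
  log$n_candidate_reads <- nrow(scr)

  ends <- extract_ends(scr, end_length = config$end_length)
  log$n_too_short_for_ends <- attr(ends, "n_skipped")

  aligns <- map_read_ends(ends, bundle, max_mm = config$max_mismatches)
  evidence <- assemble_split_evidence(scr, aligns, bundle, config)
  log$n_split_evidence <- nrow(evidence)
  log$n_unassigned_reads <- attr(evidence, "n_unassigned")

  calls <- call_insertions(evidence, bundle, config,
                           read_length = max(read_length, 2L * config$end_length),
                           genome_alignments = genome_alignments,
                           polyT_filter = (mode == "rnaseq"))
  if (nrow(calls)) {
    calls <- classify_calls(calls, bundle, config,
                            annotate_context = (mode == "rnaseq"))
  } else {
    calls$call_class <- character(0)
    calls$junction_context <- character(0)
  }
  log$n_calls <- nrow(calls)
  log$n_pass_calls <- sum(calls$pass)

  structure(list(calls = calls, evidence = evidence,
                 consensus_counts = consensus_counts,
                 genome_alignments = genome_alignments,
                 run_log = log),
            class = "te_pipeline_result")
}

#' @export
print.te_pipeline_result <- function(x, ...) {
  cat("<te_pipeline_result>\n")
  cat(sprintf("  mode: %s, read length: %d nt\n", x$run_log$mode, x$run_log$read_length))
  cat(sprintf("  candidate reads: %d, split evidence: %d\n",
              x$run_log$n_candidate_reads, x$run_log$n_split_evidence))
  cat(sprintf("  calls: %d (%d PASS)\n", x$run_log$n_calls, x$run_log$n_pass_calls))
  if (nrow(x$calls)) {
    tab <- table(x$calls$call_class[x$calls$pass])
    if (length(tab)) {
      cat("  PASS classes: ",
          paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n", sep = "")
    }
  }
  invisible(x)
}

#' Tidy the calls of a pipeline result
#'
#' @param x A `te_pipeline_result`.
#' @param ... Unused.
#' @return The classified call tibble without the nested `members` column.
#' @export
tidy.te_pipeline_result <- function(x, ...) {
  x$calls |> select(-any_of("members"))
}

#' One-row summary of a pipeline run
#'
#' @param x A `te_pipeline_result`.
#' @param ... Unused.
#' @return Tibble of headline counts.
#' @export
glance.te_pipeline_result <- function(x, ...) {
  lg <- x$run_log
  tibble(mode = lg$mode, n_input_reads = lg$preprocess$n_input,
         n_candidate_reads = lg$n_candidate_reads,
         n_split_evidence = lg$n_split_evidence,
         n_calls = lg$n_calls, n_pass_calls = lg$n_pass_calls)
}

#' Write a pipeline run log as JSON
#'
#' @param result A `te_pipeline_result`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_run_log <- function(result, path) {
  jsonlite::write_json(result$run_log, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Run the pipeline from files (CLI backend)
#'
#' Thin wrapper loading references and FASTQ from disk, running
#' [run_te_pipeline()] and writing the call TSV/BED plus the JSON run log.
#'
#' @param fastq,fastq2 Input FASTQ path(s).
#' @param genome_path,te_path,ige_path,contaminant_path,gff_path Reference
#'   files for [load_reference_bundle()].
#' @param outdir Output directory.
#' @param config A [pipeline_config()].
#' @param mode `"rnaseq"` or `"wgs"`.
#' @param sample_id Sample label.
#' @return The `te_pipeline_result`, invisibly.
#' @export
run_call <- function(fastq, genome_path, te_path, ige_path = NULL,
                     contaminant_path = NULL, gff_path = NULL, outdir = ".",
                     fastq2 = NULL, config = pipeline_config(),
                     mode = c("rnaseq", "wgs"), sample_id = "sample") {
  mode <- match.arg(mode)
  for (p in c(fastq, fastq2, genome_path, te_path)) {
    if (!is.null(p) && !file.exists(p)) abort(sprintf("Input file not found: %s", p))
  }
  bundle <- load_reference_bundle(genome_path, te_path, ige_path,
                                  contaminant_path, gff_path)
  reads <- read_fastq(fastq, fastq2, sample_id = sample_id)
  res <- run_te_pipeline(reads, bundle, config, mode = mode)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write_call_table(res$calls, file.path(outdir, "calls.tsv"),
                   file.path(outdir, "calls.bed"))
  write_run_log(res, file.path(outdir, "run_log.json"))
  readr::write_tsv(res$consensus_counts, file.path(outdir, "te_consensus_counts.tsv"))
  invisible(res)
}
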