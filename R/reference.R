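#' Reference bundle: genome, TE library, IGE controls, contaminants, gene models
#'
#' A `reference_bundle` collects every reference the pipeline maps against:
#' the (repeat-masked) genome, the TE consensus library, the immobile gene
#' element (IGE) control set, contaminant sequences (rRNA and similar), and
#' gene models. Gene models are stored as one row per exon with 0-based
#' half-open coordinates; introns are derived as the gaps between consecutive
#' exons of a transcript.
#'
#' @param genome,te_library,ige_set,contaminants Named character vectors or
#'   `DNAStringSet`s. `ige_set` and `contaminants` may be empty.
#' @param gene_models Tibble with columns `gene_id`, `transcript_id`, `chrom`,
#'   `strand`, `exon_rank`, `start`, `end` (0-based half-open, one row per
#'   exon).
#' @param masked Logical flag recording whether the genome is repeat-masked.
#'   Both soft- and hard-masked genomes are accepted; hard-masked `N` stretches
#'   never count as matches during mapping.
#' @return An object of class `reference_bundle`.
#' @export
reference_bundle <- function(genome, te_library, ige_set = character(0),
                             contaminants = character(0), gene_models = NULL,
                             masked = TRUE) {
  genome <- as_named_character(genome, "genome sequences")
  te_library <- as_named_character(te_library, "TE consensus sequences")
  if (length(ige_set)) ige_set <- as_named_character(ige_set, "IGE sequences") else ige_set <- setNames(character(0), character(0))
  if (length(contaminants)) contaminants <- as_named_character(contaminants, "contaminant sequences") else contaminants <- setNames(character(0), character(0))
  if (is.null(gene_models)) {
    gene_models <- tibble(gene_id = character(0), transcript_id = character(0),
                          chrom = character(0), strand = character(0),
                          exon_rank = integer(0), start = integer(0), end = integer(0))
  }
  gene_models <- as_tibble(gene_models)
  needed <- c("gene_id", "transcript_id", "chrom", "strand", "exon_rank", "start", "end")
  missing_cols <- setdiff(needed, names(gene_models))
  if (length(missing_cols)) {
    abort(paste0("gene_models is missing columns: ", paste(missing_cols, collapse = ", ")))
  }
  obj <- structure(
    list(genome = genome, te_library = te_library, ige_set = ige_set,
         contaminants = contaminants, gene_models = gene_models, masked = masked),
    class = "reference_bundle")
  validate_reference_bundle(obj)
  obj
}

validate_reference_bundle <- function(bundle) {
  gm <- bundle$gene_models
  if (nrow(gm) == 0) return(invisible(bundle))
  bad_chrom <- setdiff(unique(gm$chrom), names(bundle$genome))
  if (length(bad_chrom)) {
    abort(paste0("gene_models reference unknown chromosomes: ",
                 paste(bad_chrom, collapse = ", ")))
  }
  lens <- nchar(bundle$genome)
  gm_chk <- gm |>
    mutate(chrom_len = unname(lens[.data$chrom]))
  if (any(gm_chk$start < 0 | gm_chk$end > gm_chk$chrom_len | gm_chk$start >= gm_chk$end)) {
    abort("gene_models contain intervals outside chromosome bounds or of non-positive width")
  }
  by_tx <- split(gm[order(gm$transcript_id, gm$exon_rank), ], gm$transcript_id[order(gm$transcript_id, gm$exon_rank)])
  for (tx in by_tx) {
    if (is.unsorted(tx$start, strictly = TRUE) && nrow(tx) > 1) {
      abort(sprintf("Exons of transcript %s are not sorted by position", tx$transcript_id[1]))
    }
    if (nrow(tx) > 1 && any(tx$start[-1] < tx$end[-nrow(tx)])) {
      abort(sprintf("Exons of transcript %s overlap", tx$transcript_id[1]))
    }
  }
  invisible(bundle)
}

#' @export
print.reference_bundle <- function(x, ...) {
  cat("<reference_bundle>\n")
  cat(sprintf("  genome:       %d sequence(s), %s nt total (%s)\n",
              length(x$genome), format(sum(nchar(x$genome)), big.mark = ","),
              if (isTRUE(x$masked)) "masked" else "unmasked"))
  cat(sprintf("  te_library:   %d consensus sequence(s)\n", length(x$te_library)))
  cat(sprintf("  ige_set:      %d control gene(s)\n", length(x$ige_set)))
  cat(sprintf("  contaminants: %d sequence(s)\n", length(x$contaminants)))
  cat(sprintf("  gene_models:  %d exon(s), %d gene(s)\n",
              nrow(x$gene_models), length(unique(x$gene_models$gene_id))))
  invisible(x)
}

#' Derive introns from a bundle's gene models
#'
#' Introns are the gaps between consecutive exons of a transcript.
#'
#' @param x A `reference_bundle` or a gene-model tibble.
#' @return Tibble with one row per intron (`gene_id`, `transcript_id`,
#'   `chrom`, `strand`, `intron_rank`, `start`, `end`; 0-based half-open).
#' @export
introns <- function(x) {
  gm <- if (inherits(x, "reference_bundle")) x$gene_models else as_tibble(x)
  if (nrow(gm) == 0) {
    return(tibble(gene_id = character(0), transcript_id = character(0),
                  chrom = character(0), strand = character(0),
                  intron_rank = integer(0), start = integer(0), end = integer(0)))
  }
  gm |>
    arrange(.data$transcript_id, .data$start) |>
    group_by(.data$gene_id, .data$transcript_id, .data$chrom, .data$strand) |>
    reframe({
      s <- .data$start; e <- .data$end
      tibble(intron_rank = seq_len(max(length(s) - 1L, 0L)),
             start = head(e, -1L), end = tail(s, -1L))
    }) |>
    filter(.data$end > .data$start)
}

#' @noRd
gene_spans <- function(gene_models) {
  gene_models |>
    group_by(.data$gene_id, .data$chrom, .data$strand) |>
    summarise(start = min(.data$start), end = max(.data$end), .groups = "drop")
}

#' Load a reference bundle from FASTA and GFF3 files
#'
#' @param genome_path,te_path FASTA files (required).
#' @param ige_path,contaminant_path FASTA files; may be missing/empty files.
#'   An empty IGE set is valid, but two-mRNA / InDel-splice triage is then
#'   disabled downstream (a warning is emitted).
#' @param gff_path GFF3 gene models with gene/mRNA/exon features linked by
#'   `ID`/`Parent` attributes.
#' @param masked Whether the genome FASTA is repeat-masked.
#' @return A [reference_bundle()].
#' @export
load_reference_bundle <- function(genome_path, te_path, ige_path = NULL,
                                  contaminant_path = NULL, gff_path = NULL,
                                  masked = TRUE) {
  read_fasta <- function(path, what) {
    if (is.null(path)) return(setNames(character(0), character(0)))
    if (!file.exists(path)) abort(sprintf("%s file not found: %s", what, path))
    x <- tryCatch(Biostrings::readDNAStringSet(path),
                  error = function(e) abort(sprintf("Malformed FASTA in %s file '%s': %s",
                                                    what, path, conditionMessage(e))))
    out <- as.character(x)
    names(out) <- sub("\\s.*$", "", names(out))
    if (anyDuplicated(names(out))) {
      abort(sprintf("Duplicate sequence names in %s file '%s'", what, path))
    }
    out
  }
  genome <- read_fasta(genome_path, "genome")
  te <- read_fasta(te_path, "TE library")
  ige <- read_fasta(ige_path, "IGE")
  contam <- read_fasta(contaminant_path, "contaminant")
  gm <- if (is.null(gff_path)) NULL else read_gene_models_gff3(gff_path)
  if (length(ige) == 0) {
    warn("IGE set is empty: two-mRNA and InDel/splice triage will be disabled downstream")
  }
  reference_bundle(genome, te, ige, contam, gm, masked = masked)
}

#' @noRd
read_gene_models_gff3 <- function(gff_path) {
  if (!file.exists(gff_path)) abort(sprintf("GFF3 file not found: %s", gff_path))
  gr <- tryCatch(rtracklayer::import(gff_path, format = "gff3"),
                 error = function(e) abort(sprintf("Malformed GFF3 '%s': %s",
                                                   gff_path, conditionMessage(e))))
  df <- as.data.frame(gr)
  if (!"type" %in% names(df)) abort(sprintf("GFF3 '%s' has no feature types", gff_path))
  tx <- df[df$type %in% c("mRNA", "transcript"), , drop = FALSE]
  tx_parent <- setNames(vapply(tx$Parent, function(p) if (length(p)) p[[1]] else NA_character_, character(1)),
                        tx$ID)
  ex <- df[df$type == "exon", , drop = FALSE]
  if (nrow(ex) == 0) abort(sprintf("GFF3 '%s' contains no exon features", gff_path))
  tx_id <- vapply(ex$Parent, function(p) if (length(p)) p[[1]] else NA_character_, character(1))
  gene_id <- unname(tx_parent[tx_id])
  gene_id[is.na(gene_id)] <- tx_id[is.na(gene_id)]
  out <- tibble(gene_id = gene_id,
                transcript_id = tx_id,
                chrom = as.character(ex$seqnames),
                strand = as.character(ex$strand),
                start = as.integer(ex$start) - 1L,  # GFF3 is 1-based closed
                end = as.integer(ex$end)) |>
    arrange(.data$gene_id, .data$transcript_id, .data$start) |>
    group_by(.data$transcript_id) |>
    mutate(exon_rank = row_number()) |>
    ungroup() |>
    select("gene_id", "transcript_id", "chrom", "strand", "exon_rank", "start", "end")
  out
}

#' Write a reference bundle back to FASTA + GFF3
#'
#' @param bundle A [reference_bundle()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named character vector of file paths.
#' @export
write_reference_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(genome = file.path(dir, "genome.fa"),
             te_library = file.path(dir, "te_library.fa"),
             ige_set = file.path(dir, "ige_set.fa"),
             contaminants = file.path(dir, "contaminants.fa"),
             gene_models = file.path(dir, "genes.gff3"))
  for (nm in c("genome", "te_library", "ige_set", "contaminants")) {
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(bundle[[nm]]), paths[[nm]])
  }
  write_gene_models_gff3(bundle$gene_models, paths[["gene_models"]])
  invisible(paths)
}

#' @noRd
write_gene_models_gff3 <- function(gene_models, path) {
  gm <- as_tibble(gene_models)
  genes <- gene_spans(gm)
  tx <- gm |>
    group_by(.data$gene_id, .data$transcript_id, .data$chrom, .data$strand) |>
    summarise(start = min(.data$start), end = max(.data$end), .groups = "drop")
  mk <- function(df, type, id = NULL, parent = NULL) {
    if (is.null(parent)) parent <- replicate(nrow(df), character(0), simplify = FALSE)
    GenomicRanges::GRanges(
      seqnames = df$chrom,
      ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
      strand = df$strand,
      type = type,
      ID = id %||% NA_character_,
      Parent = S4Vectors::List(as.list(parent)))
  }
  gr <- c(mk(genes, "gene", id = genes$gene_id),
          mk(tx, "mRNA", id = tx$transcript_id, parent = as.list(tx$gene_id)),
          mk(gm, "exon", id = paste0(gm$transcript_id, ".e", gm$exon_rank),
             parent = as.list(gm$transcript_id)))
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}
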