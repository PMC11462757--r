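# Shared fixtures. Simulations are built once per test run and cached; the
# "study" fixture uses the generator defaults (200kb genome, 10 genes, 6
# planted insertions of which 2 are heterozygous, 100nt reads at >= 10x
# junction coverage, 0.5% error), the "small" fixture is a faster variant
# for plumbing tests.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

small_sim <- function() {
  cached("small_sim", {
    cfg <- sim_config(rng_seed = 7, chrom_length = 60000L, n_genes = 6,
                      depth = 600, te_length_range = c(400L, 800L))
    bundle <- simulate_genome_and_annotations(cfg)
    planted <- plant_te_insertions(bundle, cfg)
    rna <- simulate_transcriptome_reads(planted, bundle, cfg)
    list(cfg = cfg, bundle = bundle, planted = planted, rna = rna)
  })
}

small_result <- function() {
  cached("small_result", {
    fx <- small_sim()
    run_te_pipeline(fx$rna$reads, fx$bundle, pipeline_config(), mode = "rnaseq")
  })
}

study_sim <- function() {
  cached("study_sim", {
    cfg <- sim_config(rng_seed = 1)
    bundle <- simulate_genome_and_annotations(cfg)
    planted <- plant_te_insertions(bundle, cfg)
    rna <- simulate_transcriptome_reads(planted, bundle, cfg)
    list(cfg = cfg, bundle = bundle, planted = planted, rna = rna)
  })
}

study_result <- function() {
  cached("study_result", {
    fx <- study_sim()
    run_te_pipeline(fx$rna$reads, fx$bundle, pipeline_config(), mode = "rnaseq")
  })
}

study_wgs_result <- function() {
  cached("study_wgs_result", {
    fx <- study_sim()
    wgs <- simulate_wgs_reads(fx$planted, fx$cfg)
    run_te_pipeline(wgs$reads, fx$bundle, pipeline_config(), mode = "wgs")
  })
}

# read tibble from bare sequences
mk_reads <- function(seqs, qual = NULL, ids = NULL, sample_id = "test") {
  tibble::tibble(
    read_id = ids %||% sprintf("r%04d", seq_along(seqs)),
    sequence = seqs,
    quality = qual %||% strrep("I", nchar(seqs)),
    mate_of = NA_character_,
    sample_id = sample_id)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# a minimal single-gene bundle for classify/geometry tests:
# chr1, one '+' gene with exons [1000,1200) [1500,1700) [2000,2200)
toy_bundle <- function(seed = 11) {
  set.seed(seed)
  genome <- c(chr1 = random_seq(15000))
  te <- c(TEA = random_seq(600), TEB = random_seq(500))
  gm <- tibble::tibble(
    gene_id = "gX", transcript_id = "gX.t1", chrom = "chr1", strand = "+",
    exon_rank = 1:3, start = c(1000L, 1500L, 2000L), end = c(1200L, 1700L, 2200L))
  ige <- c(gX = paste0(substr(genome, 1001, 1200), substr(genome, 1501, 1700),
                       substr(genome, 2001, 2200)))
  reference_bundle(genome, te, ige, gene_models = gm)
}

# junction reads tiling both sides of a TE planted at 0-based position p
junction_reads <- function(genome_seq, te_seq, p, L = 100L, each_side = TRUE,
                           prefix = "jr") {
  hap <- paste0(substr(genome_seq, 1, p), te_seq,
                substr(genome_seq, p + 1, nchar(genome_seq)))
  centers <- c(p, if (each_side) p + nchar(te_seq))
  starts <- unlist(lapply(centers, function(cc) (cc - 78L):(cc - 22L)))
  seqs <- substring(hap, starts + 1L, starts + L)
  mk_reads(seqs, ids = sprintf("%s%04d", prefix, seq_along(seqs)))
}
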