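# The synthetic-data generator: seeded determinism, planted genome/TE
# structure, haplotype zygosity, and the artifact classes.

test_that("same configuration and seed reproduce bit-identical outputs", {
  cfg <- sim_config(rng_seed = 13, chrom_length = 40000L, n_genes = 4, depth = 150)
  b1 <- simulate_genome_and_annotations(cfg)
  b2 <- simulate_genome_and_annotations(cfg)
  expect_identical(b1$genome, b2$genome)
  expect_identical(b1$te_library, b2$te_library)
  expect_identical(as.data.frame(b1$gene_models), as.data.frame(b2$gene_models))
  p1 <- plant_te_insertions(b1, cfg); p2 <- plant_te_insertions(b2, cfg)
  expect_identical(p1$haplotypes, p2$haplotypes)
  r1 <- simulate_transcriptome_reads(p1, b1, cfg)
  r2 <- simulate_transcriptome_reads(p2, b2, cfg)
  expect_identical(r1$reads, r2$reads)
  w1 <- simulate_wgs_reads(p1, cfg); w2 <- simulate_wgs_reads(p2, cfg)
  expect_identical(w1$reads, w2$reads)
})

test_that("genome carries a tiny intron and a poly-T TE when requested", {
  fx <- small_sim()
  intr <- introns(fx$bundle)
  expect_true(any(intr$end - intr$start < 100))
  hop <- fx$bundle$te_library[["hopper_like"]]
  expect_true(grepl(strrep("T", 20), hop))
  # a configuration whose range pins intron length writes/round-trips it
  cfg90 <- sim_config(rng_seed = 3, chrom_length = 40000L, n_genes = 3,
                      intron_length_range = c(90L, 700L))
  b90 <- simulate_genome_and_annotations(cfg90)
  dir <- withr::local_tempdir()
  paths <- write_reference_bundle(b90, dir)
  suppressWarnings(back <- load_reference_bundle(paths[["genome"]], paths[["te_library"]],
                                                 gff_path = paths[["gene_models"]]))
  i1 <- introns(back) |> dplyr::filter(gene_id == "g01", intron_rank == 1)
  expect_equal(i1$end - i1$start, 90L)
  # no tiny intron forced when the range floor is >= 100
  cfgbig <- sim_config(rng_seed = 3, chrom_length = 60000L, n_genes = 3,
                       intron_length_range = c(400L, 700L))
  bbig <- simulate_genome_and_annotations(cfgbig)
  expect_true(all(introns(bbig)$end - introns(bbig)$start >= 400))
})

test_that("heterozygous insertions sit on one haplotype, homozygous on both", {
  fx <- small_sim()
  ins <- fx$planted$insertions
  hapA <- fx$planted$haplotypes$A[["chr1"]]
  hapB <- fx$planted$haplotypes$B[["chr1"]]
  ref <- fx$bundle$genome[["chr1"]]
  hom_len <- sum(ins$te_length[ins$zygosity == "hom"])
  expect_equal(nchar(hapA), nchar(ref) + sum(ins$te_length))
  expect_equal(nchar(hapB), nchar(ref) + hom_len)
  het <- ins[ins$zygosity == "het", ][1, ]
  te_seq <- fx$bundle$te_library[[het$te_family]]
  sigA <- paste0(substr(ref, het$position - 19, het$position), substr(te_seq, 1, 20))
  expect_true(grepl(sigA, hapA, fixed = TRUE))        # junction on carrier
  expect_false(grepl(sigA, hapB, fixed = TRUE))       # reference on the other
  expect_true(grepl(substr(ref, het$position - 19, het$position + 20),
                    hapB, fixed = TRUE))
})

test_that("3'UTR insertions land inside the terminal exon; long TEs expand introns", {
  fx <- small_sim()
  gm <- fx$bundle$gene_models
  utr <- fx$planted$insertions |> dplyr::filter(site == "utr3")
  for (i in seq_len(nrow(utr))) {
    ex <- gm |> dplyr::filter(gene_id == utr$gene[i])
    term <- if (ex$strand[1] == "+") ex[which.max(ex$start), ] else ex[which.min(ex$start), ]
    expect_gt(utr$position[i], term$start)
    expect_lt(utr$position[i], term$end)
  }
  # a full-length 7.5kb element expands the carrier haplotype by 7.5kb
  cfg <- sim_config(rng_seed = 5, chrom_length = 60000L, n_genes = 3,
                    n_te_families = 1L, te_length_range = c(7500L, 7500L),
                    include_polyT_te = FALSE,
                    insertions = tibble::tibble(te_family = "TEfam1", gene = "g01",
                                                site = "intron", zygosity = "hom"))
  b <- simulate_genome_and_annotations(cfg)
  p <- plant_te_insertions(b, cfg)
  expect_equal(nchar(p$haplotypes$A[["chr1"]]) - nchar(b$genome[["chr1"]]), 7500L)
})

test_that("template-switch chimera count follows the binomial expectation", {
  cfg <- sim_config(rng_seed = 21, chrom_length = 80000L, n_genes = 8,
                    depth = 2000, rate_two_mrna_chimera = 0.01,
                    rate_polyA_artifact = 0, te_autonomous_depth = 0)
  b <- simulate_genome_and_annotations(cfg)
  p <- plant_te_insertions(b, cfg)
  r <- simulate_transcriptome_reads(p, b, cfg)
  n_gene_reads <- sum(grepl("_(std|chim)_", r$reads$read_id))
  n_chim <- sum(grepl("_chim_", r$reads$read_id))
  expected <- n_gene_reads * 0.01
  sigma <- sqrt(n_gene_reads * 0.01 * 0.99)
  expect_lt(abs(n_chim - expected), 3 * sigma)
})

test_that("switching artifact rates off removes those read classes", {
  cfg <- sim_config(rng_seed = 17, chrom_length = 50000L, n_genes = 4, depth = 300,
                    rate_two_mrna_chimera = 0, rate_polyA_artifact = 0,
                    rate_intron_retention = 0, te_autonomous_depth = 0,
                    insertions = tibble::tibble(te_family = c("TEfam1", "TEfam2"),
                                                gene = c("g01", "g02"),
                                                site = "intron", zygosity = "hom"))
  b <- simulate_genome_and_annotations(cfg)
  p <- plant_te_insertions(b, cfg)
  r <- simulate_transcriptome_reads(p, b, cfg)
  expect_false(any(grepl("_chim_|_polyA_|_te_", r$reads$read_id)))
  # with retention and exonization both zero, no read spans an intronic
  # TE junction: search for the planted junction signatures
  for (i in seq_len(nrow(p$insertions))) {
    ins <- p$insertions[i, ]
    te_seq <- b$te_library[[ins$te_family]]
    ref <- b$genome[[ins$chrom]]
    sig_left <- paste0(substr(ref, ins$position - 14, ins$position),
                       substr(te_seq, 1, 15))
    hits <- grepl(sig_left, r$reads$sequence, fixed = TRUE) |
      grepl(rc_chr(sig_left), r$reads$sequence, fixed = TRUE)
    expect_equal(sum(hits), 0L)
  }
})

test_that("WGS junction reads occur at a ~2:1 hom:het ratio", {
  cfg <- sim_config(rng_seed = 31, chrom_length = 60000L, n_genes = 4,
                    wgs_depth = 60,
                    te_length_range = c(600L, 900L),
                    insertions = tibble::tibble(te_family = c("TEfam1", "TEfam2"),
                                                gene = c("g01", "g02"),
                                                site = "intron",
                                                zygosity = c("hom", "het")))
  b <- simulate_genome_and_annotations(cfg)
  p <- plant_te_insertions(b, cfg)
  w <- simulate_wgs_reads(p, cfg)
  count_junction <- function(ins) {
    te_seq <- b$te_library[[ins$te_family]]
    ref <- b$genome[[ins$chrom]]
    sig <- paste0(substr(ref, ins$position - 11, ins$position), substr(te_seq, 1, 12))
    sum(grepl(sig, w$reads$sequence, fixed = TRUE) |
          grepl(rc_chr(sig), w$reads$sequence, fixed = TRUE))
  }
  n_hom <- count_junction(p$insertions[1, ])
  n_het <- count_junction(p$insertions[2, ])
  # hom junctions live on both haplotypes: expect n_hom ~ 2 * n_het
  lambda <- (n_hom + n_het) / 3
  expect_lt(abs(n_hom - 2 * lambda), 3 * sqrt(2 * lambda))
  expect_lt(abs(n_het - lambda), 3 * sqrt(lambda))
  expect_gt(n_hom, n_het)
})

test_that("zero depth yields an empty FASTQ with a warning", {
  cfg <- sim_config(rng_seed = 2, chrom_length = 40000L, n_genes = 3, depth = 0,
                    rate_two_mrna_chimera = 0, rate_polyA_artifact = 0,
                    te_autonomous_depth = 0)
  b <- simulate_genome_and_annotations(cfg)
  p <- plant_te_insertions(b, cfg)
  expect_warning(r <- simulate_transcriptome_reads(p, b, cfg), "zero reads")
  expect_equal(nrow(r$reads), 0L)
})

test_that("run_simulate writes a complete fixture with reproducible hashes", {
  cfg <- sim_config(rng_seed = 23, chrom_length = 90000L, n_genes = 8, depth = 60)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  m1 <- run_simulate(cfg, d1)
  m2 <- run_simulate(cfg, d2)
  expect_identical(m1$files, m2$files)
  expect_true(all(file.exists(file.path(d1, c("genome.fa", "te_library.fa", "ige_set.fa",
                                              "contaminants.fa", "genes.gff3",
                                              "reads_rna.fastq", "truth.tsv",
                                              "sim_config.yaml", "manifest.json")))))
  truth <- readr::read_tsv(file.path(d1, "truth.tsv"), show_col_types = FALSE)
  expect_true(all(c("TE_INSERTION", "INDEL") %in% truth$event_type))
  placed <- truth |> dplyr::filter(!is.na(position))
  expect_true(all(placed$position >= 0 & placed$position < 90000))
  expect_equal(anyDuplicated(placed[, c("event_type", "chrom", "position")]), 0L)
})

test_that("every simulated junction read matches a truth breakpoint signature", {
  fx <- small_sim()
  truth <- fx$planted$truth
  ref <- fx$bundle$genome[["chr1"]]
  # junction signatures (20nt genome + 20nt TE) for each planted insertion
  for (i in seq_len(nrow(truth))) {
    te_seq <- fx$bundle$te_library[[truth$element_name[i]]]
    p <- truth$position[i]
    sig <- paste0(substr(ref, p - 19, p), substr(te_seq, 1, 20))
    n_span <- sum(grepl(sig, fx$rna$reads$sequence, fixed = TRUE) |
                    grepl(rc_chr(sig), fx$rna$reads$sequence, fixed = TRUE))
    expect_gt(n_span, 0)
  }
})
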