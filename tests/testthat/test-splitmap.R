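# Terminal-end extraction, mismatch-tolerant end mapping (against the
# brute-force oracle), reference subtraction, contaminant screening and
# split-evidence assembly.

test_that("extract_ends takes 22nt from each terminus (0-based half-open)", {
  r250 <- mk_reads(random_seq(250, seed = 10))
  e <- extract_ends(r250, 22L)
  expect_equal(e$seq[e$end == "FIVE_PRIME"], substr(r250$sequence, 1, 22))
  expect_equal(e$seq[e$end == "THREE_PRIME"], substr(r250$sequence, 229, 250))

  r44 <- mk_reads(random_seq(44, seed = 11))
  e44 <- extract_ends(r44, 22L)
  expect_equal(paste0(e44$seq[e44$end == "FIVE_PRIME"],
                      e44$seq[e44$end == "THREE_PRIME"]),
               r44$sequence)                     # the two ends tile the read

  r30 <- mk_reads(random_seq(30, seed = 12))
  e30 <- extract_ends(r30, 22L)
  expect_equal(nrow(e30), 0L)
  expect_equal(attr(e30, "n_skipped"), 1L)
})

test_that("map_end agrees exactly with the brute-force Hamming oracle", {
  set.seed(20)
  targets <- c(chrA = random_seq(4000), chrB = random_seq(2500))
  queries <- character(0)
  # planted cases: 0..4 substitutions, forward and reverse complement
  base <- substr(targets[["chrA"]], 1201, 1222)
  queries <- c(queries,
               q0 = base,
               q1 = mutate_bases(base, 5, seed = 1),
               q3 = mutate_bases(base, c(2, 11, 20), seed = 2),
               q4 = mutate_bases(base, c(2, 7, 11, 20), seed = 3),
               qrc = rc_chr(substr(targets[["chrB"]], 501, 522)),
               qn = paste0(substr(base, 1, 20), "NN"),
               rand = random_seq(22))
  res <- map_end(queries, targets, target_db = "X", max_mismatches = 3L)
  for (nm in names(queries)) {
    got <- res[res$end_id == nm, c("target_name", "target_pos", "strand", "mismatches")]
    got <- got[order(got$target_name, got$target_pos, got$strand), ]
    want <- brute_force_hits(queries[[nm]], as.list(targets) |> setNames(names(targets)),
                             max_mm = 3L)
    expect_equal(as.data.frame(got), as.data.frame(want), ignore_attr = TRUE,
                 info = nm)
  }
  # boundary of the mismatch allowance: 3 accepted, 4 rejected
  expect_true(any(res$end_id == "q3" & res$target_pos == 1200L))
  expect_false(any(res$end_id == "q4" & res$target_pos == 1200L))
  # uniqueness bookkeeping
  expect_equal(unique(res$n_equal_best_hits[res$end_id == "q0"]), 1L)
})

test_that("the fast best-stratum path equals map_end's best stratum", {
  set.seed(30)
  targets <- c(chr1 = random_seq(20000))
  base_pos <- seq(100, 15000, by = 450)
  queries <- vapply(base_pos, function(p) {
    q <- substr(targets[["chr1"]], p, p + 21)
    k <- sample(0:3, 1)
    if (k > 0) q <- mutate_bases(q, sample(22, k), seed = p)
    if (runif(1) < 0.5) q <- rc_chr(q)
    q
  }, character(1))
  queries <- c(queries, vapply(1:5, function(i) random_seq(22), character(1)))
  ends <- tibble::tibble(read_id = sprintf("r%03d", seq_along(queries)),
                         end = "FIVE_PRIME",
                         end_id = sprintf("r%03d::FIVE_PRIME", seq_along(queries)),
                         seq = queries, read_length = 100L)
  bundle <- reference_bundle(targets, c(TEZ = random_seq(500)))
  fast <- map_read_ends(ends, bundle, max_mm = 3L) |>
    dplyr::filter(target_db == "GENOME") |>
    dplyr::select(end_id, target_name, target_pos, strand, mismatches, n_equal_best_hits) |>
    dplyr::arrange(end_id, target_pos, strand)
  slow <- map_end(ends, targets, target_db = "GENOME", max_mismatches = 3L) |>
    dplyr::group_by(end_id) |>
    dplyr::filter(mismatches == min(mismatches)) |>
    dplyr::mutate(n_equal_best_hits = dplyr::n()) |>
    dplyr::ungroup() |>
    dplyr::select(end_id, target_name, target_pos, strand, mismatches, n_equal_best_hits) |>
    dplyr::arrange(end_id, target_pos, strand)
  expect_equal(as.data.frame(fast), as.data.frame(slow))
})

test_that("reference subtraction removes end-to-end mappers and keeps junction reads", {
  set.seed(40)
  genome <- c(chr1 = random_seq(20000))
  te <- c(TEA = random_seq(600))
  bundle <- reference_bundle(genome, te)
  verbatim <- substr(genome, 3001, 3100)
  with_errors <- mutate_bases(verbatim, c(10, 50, 90), seed = 7)   # 3 mismatches
  too_many <- mutate_bases(verbatim, c(10, 30, 50, 90), seed = 8)  # 4 mismatches
  junction <- paste0(substr(genome, 5001, 5050), substr(te, 1, 50))
  spliced <- paste0(substr(genome, 7001, 7050), substr(genome, 7101, 7150))
  reads <- mk_reads(c(verbatim, with_errors, too_many, junction, spliced,
                      rc_chr(verbatim)))
  out <- subtract_reference_mappers(reads, bundle, max_mm = 3L)
  expect_setequal(out$read_id, c("r0003", "r0004", "r0005"))
  al <- attr(out, "genome_alignments")
  expect_equal(sort(al$read_id), c("r0001", "r0002", "r0006"))
  expect_equal(al$start[al$read_id == "r0001"], 3000L)
  expect_equal(al$end[al$read_id == "r0001"], 3100L)
  expect_equal(al$strand[al$read_id == "r0006"], "-")
})

test_that("contaminant screen drops element-internal reads and tallies TE consensus", {
  set.seed(41)
  genome <- c(chr1 = random_seq(10000))
  te <- c(TEA = random_seq(600), TEB = random_seq(500))
  contam <- c(rRNA = random_seq(900))
  bundle <- reference_bundle(genome, te, contaminants = contam)
  reads <- mk_reads(c(substr(te[["TEA"]], 101, 200),      # TE-internal
                      rc_chr(substr(te[["TEA"]], 301, 400)),
                      substr(contam[["rRNA"]], 11, 110),  # rRNA-derived
                      paste0(substr(genome, 2001, 2050), substr(te[["TEB"]], 1, 50)),
                      random_seq(100)))
  out <- screen_contaminants(reads, bundle, max_mm = 3L)
  expect_setequal(out$read_id, c("r0004", "r0005"))
  counts <- attr(out, "te_consensus_counts")
  expect_equal(counts$n_reads[counts$element_name == "TEA"], 2L)
  expect_equal(counts$n_reads[counts$element_name == "TEB"], 0L)
  expect_equal(attr(out, "n_removed"), 3L)
})

test_that("split evidence requires one unique genome end plus one element end", {
  set.seed(42)
  genome <- c(chr1 = random_seq(20000))
  te <- c(TEA = random_seq(600))
  ige <- c(gY = substr(genome, 9001, 9800))
  bundle <- reference_bundle(genome, te, ige)
  cfg <- pipeline_config()

  # a repeated genome segment makes an end non-unique
  dup <- substr(genome, 1001, 1022)
  genome_dup <- c(chr1 = paste0(genome[["chr1"]], strrep("G", 50), dup))
  bundle_dup <- reference_bundle(genome_dup, te, ige)

  reads <- mk_reads(c(
    paste0(substr(genome, 5001, 5050), substr(te, 1, 50)),     # genome5' + TE3'
    paste0(substr(te, 551, 600), substr(genome, 6001, 6050)),  # TE5' + genome3'
    paste0(dup, random_seq(28), substr(te, 1, 50)),            # ambiguous genome end
    random_seq(100)))                                          # maps nowhere
  ends <- extract_ends(reads, cfg$end_length)
  al <- map_read_ends(ends, bundle_dup, max_mm = 3L)
  ev <- assemble_split_evidence(reads, al, bundle_dup, cfg)
  expect_setequal(ev$read_id, c("r0001", "r0002"))
  expect_equal(ev$side[ev$read_id == "r0001"], "UPSTREAM")
  # seed-and-extend can overshoot by a base or two when the element start
  # happens to match the next genomic base
  expect_lte(abs(ev$junction_pos[ev$read_id == "r0001"] - 5050L), 2L)
  expect_equal(ev$side[ev$read_id == "r0002"], "DOWNSTREAM")
  expect_lte(abs(ev$junction_pos[ev$read_id == "r0002"] - 6000L), 2L)
  expect_equal(unique(ev$element_name), "TEA")
})

test_that("a TE hit outranks an IGE hit for the element end", {
  set.seed(43)
  genome <- c(chr1 = random_seq(20000))
  te <- c(TEA = random_seq(600))
  # IGE that contains the TE 5' start: the element end matches both databases
  ige <- c(gZ = paste0(random_seq(100), substr(te, 1, 200)))
  bundle <- reference_bundle(genome, te, ige)
  reads <- mk_reads(paste0(substr(genome, 5001, 5050), substr(te, 1, 50)))
  ends <- extract_ends(reads, 22L)
  al <- map_read_ends(ends, bundle, max_mm = 3L)
  ev <- assemble_split_evidence(reads, al, bundle, pipeline_config())
  expect_equal(ev$element_db, "TE")
  expect_equal(ev$element_name, "TEA")
})

test_that("no evidence ever comes from subtracted or screened reads", {
  fx <- small_sim()
  cfg <- pipeline_config()
  pre <- preprocess_reads(fx$rna$reads, cfg)
  sub <- subtract_reference_mappers(pre, fx$bundle, cfg$max_mismatches)
  scr <- screen_contaminants(sub, fx$bundle, cfg$max_mismatches)
  removed <- setdiff(pre$read_id, scr$read_id)
  ev <- small_result()$evidence
  expect_length(intersect(ev$read_id, removed), 0L)
  # and every evidence genome end re-aligns at its locus within max_mm
  g <- fx$bundle$genome[["chr1"]]
  idx <- sample(nrow(ev), min(80, nrow(ev)))
  for (i in idx) {
    seg <- substr(g, ev$anchor_start[i] + 1L, ev$anchor_end[i])
    q <- if (ev$genome_strand[i] == "-") rc_chr(ev$genome_end_seq[i]) else ev$genome_end_seq[i]
    d <- sum(strsplit(seg, "")[[1]] != strsplit(q, "")[[1]])
    expect_lte(d, cfg$max_mismatches)
  }
})
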