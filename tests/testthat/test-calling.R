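# Clustering and the quality filters, at the documented threshold
# boundaries.

# hand-built evidence rows
mk_evidence <- function(element, junctions, sides = NULL, chrom = "chr1",
                        anchor_starts = NULL, element_end_seq = NULL,
                        element_pos = 0L, genome_mm = 0L, element_db = "TE") {
  n <- length(junctions)
  sides <- sides %||% rep(c("UPSTREAM", "DOWNSTREAM"), length.out = n)
  anchor_starts <- anchor_starts %||% ifelse(sides == "UPSTREAM",
                                             junctions - 22L, junctions)
  tibble::tibble(
    read_id = sprintf("%s_ev%03d", element, seq_len(n)),
    chrom = chrom, genome_strand = "+",
    anchor_start = as.integer(anchor_starts),
    anchor_end = as.integer(anchor_starts + 22L),
    genome_mm = as.integer(rep_len(genome_mm, n)),
    genome_end_seq = vapply(seq_len(n), function(i) random_seq(22), character(1)),
    junction_pos = as.integer(junctions), side = sides,
    element_db = element_db, element_name = element,
    element_pos = as.integer(rep_len(element_pos, n)),
    element_strand = "+", element_mm = 0L,
    element_end_seq = element_end_seq %||%
      vapply(seq_len(n), function(i) random_seq(22), character(1)),
    sample_id = "s1")
}

test_that("single-linkage clustering respects the 300nt range and grouping keys", {
  set.seed(50)
  ev <- dplyr::bind_rows(
    mk_evidence("TEA", c(1000L, 1250L)),          # 250nt apart: one cluster
    mk_evidence("TEB", c(5000L, 5301L)),          # 301nt apart: two clusters
    mk_evidence("TEC", 9000L), mk_evidence("TED", 9000L))  # same pos, two TEs
  cl <- cluster_evidence(ev, cluster_range = 300L)
  expect_equal(nrow(cl[cl$element_name == "TEA", ]), 1L)
  expect_equal(nrow(cl[cl$element_name == "TEB", ]), 2L)
  expect_equal(nrow(cl[cl$element_name %in% c("TEC", "TED"), ]), 2L)
  # median position with ties to the smaller coordinate
  set.seed(51)
  cl4 <- cluster_evidence(mk_evidence("TEE", c(100L, 110L, 120L, 130L)), 300L)
  expect_equal(cl4$position, 110L)
  expect_equal(cl4$width, 30L)
  expect_equal(cl4$n_support, cl4$n_upstream + cl4$n_downstream)
})

test_that("support, window and span flags switch exactly at the printed bounds", {
  set.seed(52)
  cfg <- pipeline_config()
  cl3 <- cluster_evidence(mk_evidence("TEA", rep(1000L, 3)), 300L) |>
    support_and_spread_filter(cfg, read_length = 100L)
  cl4 <- cluster_evidence(mk_evidence("TEA", rep(1000L, 4)), 300L) |>
    support_and_spread_filter(cfg, read_length = 100L)
  expect_true(cl3$flag_min_support)     # 3 reads: below the 4-read floor
  expect_false(cl4$flag_min_support)    # 4 reads: kept

  # members spread over 210nt with 100nt reads: beyond the 2x window
  wide <- cluster_evidence(mk_evidence("TEB", c(1000L, 1070L, 1140L, 1210L)), 300L) |>
    support_and_spread_filter(cfg, read_length = 100L)
  expect_equal(wide$width, 210L)
  expect_true(wide$flag_window)
  ok <- cluster_evidence(mk_evidence("TEB", c(1000L, 1100L, 1200L)), 300L) |>
    support_and_spread_filter(cfg, read_length = 100L)
  expect_false(ok$flag_window)

  # 250nt reads: span floor is 250/2 - 22 = 103
  stacked <- cluster_evidence(
    mk_evidence("TEC", rep(2000L, 5), sides = rep("UPSTREAM", 5),
                anchor_starts = c(1910L, 1930L, 1950L, 1970L, 1978L)), 300L) |>
    support_and_spread_filter(cfg, read_length = 250L)
  expect_equal(stacked$span, 90L)       # 90 < 103: reads stacked, filtered
  expect_true(stacked$flag_span)
  spread <- cluster_evidence(
    mk_evidence("TEC", rep(2000L, 5), sides = rep("UPSTREAM", 5),
                anchor_starts = c(1890L, 1930L, 1950L, 1970L, 1990L)), 300L) |>
    support_and_spread_filter(cfg, read_length = 250L)
  expect_equal(spread$span, 122L)
  expect_false(spread$flag_span)
})

test_that("identity filters map the 50% keep and 83% repeat cutoffs", {
  set.seed(53)
  te <- c(TEA = random_seq(600))
  bundle <- reference_bundle(c(chr1 = random_seq(5000)), te)
  cfg <- pipeline_config()

  clean <- cluster_evidence(mk_evidence("TEA", rep(1000L, 4), genome_mm = 0L), 300L) |>
    identity_filter(bundle, cfg)
  expect_equal(clean$identity_score, 1.0)
  expect_false(clean$flag_low_identity)
  expect_false(clean$flag_repetitive)

  # mean realignment identity below 50%: 11+ mismatches over a 22nt anchor
  low <- cluster_evidence(mk_evidence("TEA", rep(1000L, 4), genome_mm = 12L), 300L) |>
    identity_filter(bundle, cfg)
  expect_lt(low$identity_score, 0.5)
  expect_true(low$flag_low_identity)

  # genome end 90.9% identical to a TE-library sequence (2 mismatches): above 83%
  rep_seq <- mutate_bases(substr(te[["TEA"]], 101, 122), c(3, 15), seed = 9)
  repcl <- cluster_evidence(mk_evidence("TEA", rep(1000L, 4)), 300L)
  repcl$members[[1]]$genome_end_seq <- rep(rep_seq, 4)
  repcl <- identity_filter(repcl, bundle, cfg)
  expect_equal(repcl$repeat_identity, 20 / 22, tolerance = 1e-9)
  expect_true(repcl$flag_repetitive)

  # 81.8% (4 mismatches): below the discard line
  rep_seq4 <- mutate_bases(substr(te[["TEA"]], 101, 122), c(3, 8, 15, 20), seed = 10)
  repcl4 <- cluster_evidence(mk_evidence("TEA", rep(1000L, 4)), 300L)
  repcl4$members[[1]]$genome_end_seq <- rep(rep_seq4, 4)
  repcl4 <- identity_filter(repcl4, bundle, cfg)
  expect_false(repcl4$flag_repetitive)
})

test_that("the poly-T filter catches homopolymer ends and hopper-tract hits", {
  set.seed(54)
  hop <- paste0(random_seq(200), strrep("T", 25), random_seq(200))
  bundle <- reference_bundle(c(chr1 = random_seq(5000)),
                             c(hopper_like = hop, TEA = random_seq(500)))
  cfg <- pipeline_config()

  polyt <- cluster_evidence(
    mk_evidence("TEA", rep(1000L, 4), element_end_seq = rep(strrep("T", 22), 4)), 300L) |>
    low_complexity_filter(cfg, bundle)
  expect_true(polyt$flag_polyT)

  random_ends <- cluster_evidence(mk_evidence("TEA", rep(1000L, 4)), 300L) |>
    low_complexity_filter(cfg, bundle)
  expect_false(random_ends$flag_polyT)

  # element end aligned wholly inside the hopper T-tract (tract at [200,225)):
  # flagged by the blacklist even when the observed end itself is not T-rich
  tract_hit <- cluster_evidence(
    mk_evidence("hopper_like", rep(1000L, 4), element_pos = 201L), 300L) |>
    low_complexity_filter(cfg, bundle)
  expect_true(tract_hit$flag_polyT)

  # mono-nucleotide fraction alone can trigger the flag
  frac_end <- paste0(strrep("A", 9), "C", strrep("A", 9), "G", "AA")
  fr <- cluster_evidence(
    mk_evidence("TEA", rep(1000L, 4), element_end_seq = rep(frac_end, 4)), 300L) |>
    low_complexity_filter(cfg, bundle)
  expect_true(fr$flag_polyT)
})

test_that("symmetry score is the clamped upstream percentage", {
  expect_equal(symmetry_score(5, 5), 50)
  expect_equal(symmetry_score(8, 0), 99)
  expect_equal(symmetry_score(0, 8), 1)
  expect_equal(symmetry_score(1, 3), 25)
  expect_equal(symmetry_score(c(2, 7), c(2, 3)), c(50, 70))
  expect_error(symmetry_score(0, 0))
})

test_that("coverage ratio follows n / (depth + pseudocount) with the 1.5 cutoff", {
  set.seed(55)
  cfg <- pipeline_config()
  cl <- cluster_evidence(mk_evidence("TEA", rep(1000L, 8)), 300L)
  depth3 <- tibble::tibble(read_id = sprintf("d%d", 1:3), chrom = "chr1",
                           start = 950L, end = 1050L, strand = "+")
  out <- coverage_ratio(cl, depth3, cfg)
  expect_equal(out$coverage_ratio, 8 / (3 + 1))      # = 2.0
  expect_equal(out$zygosity_label, "homozygous")

  cl4 <- cluster_evidence(mk_evidence("TEB", rep(1000L, 4)), 300L)
  depth7 <- tibble::tibble(read_id = sprintf("d%d", 1:7), chrom = "chr1",
                           start = 990L, end = 1090L, strand = "+")
  out4 <- coverage_ratio(cl4, depth7, cfg)
  expect_equal(out4$coverage_ratio, 0.5)
  expect_equal(out4$zygosity_label, "het_or_cnv")

  # reads not spanning the junction never count as local depth
  off <- tibble::tibble(read_id = "d1", chrom = "chr1",
                        start = 1000L, end = 1100L, strand = "+")
  out_off <- coverage_ratio(cl4, off, cfg)
  expect_equal(out_off$local_depth, 0L)
  expect_equal(out_off$coverage_ratio, 4)            # pseudocount saves the ratio

  out_null <- coverage_ratio(cl4, NULL, cfg)
  expect_equal(out_null$coverage_ratio, 4)
})

test_that("finalize keeps flagged clusters visible and marks clean ones PASS", {
  set.seed(56)
  bundle <- reference_bundle(c(chr1 = random_seq(5000)), c(TEA = random_seq(500)))
  ev <- dplyr::bind_rows(mk_evidence("TEA", rep(1000L, 6)),
                         mk_evidence("TEA", rep(3000L, 3)))
  calls <- call_insertions(ev, bundle, pipeline_config(), read_length = 100L)
  expect_equal(nrow(calls), 2L)
  clean <- calls[calls$position == 1000L, ]
  flagged <- calls[calls$position == 3000L, ]
  expect_true(clean$pass)
  expect_equal(clean$filter_flags, "")
  expect_false(flagged$pass)
  expect_match(flagged$filter_flags, "MIN_SUPPORT")
  # every PASS call satisfies all documented thresholds
  expect_true(clean$n_support >= 4 && clean$symmetry >= 1 && clean$symmetry <= 99 &&
                clean$identity_score >= 0.5 && clean$repeat_identity <= 0.83)
})
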