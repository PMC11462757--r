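# Synthetic-data generator: a seeded genome with gene models, a TE library
# (optionally including a hopper-like element with an internal poly-T
# tract), planted homozygous/heterozygous insertions on two haplotypes, and
# RNA-seq / WGS reads carrying the artifact structure seen in real
# transcriptome input: canonical splicing, intron retention, optional
# exonization, poly-A read-through (leading poly-T segments), recurrent
# template-switch two-mRNA chimeras, transcript-level InDels and tiny
# introns. Every planted event is recorded as ground truth.

#' Simulate a genome, gene models and reference collections
#'
#' Base composition is uniform i.i.d. (so 22-mers are unique with
#' overwhelming probability at desk scale) except for planted homopolymers.
#' When the intron length range allows introns below 100nt, the first intron
#' of the first gene is set to the range minimum so a tiny intron is always
#' present. The IGE control set is the reference mRNA of every simulated
#' gene; contaminants are two structural-RNA-like sequences.
#'
#' @param cfg A [sim_config()].
#' @return A [reference_bundle()] (genome flagged as masked: it carries no
#'   pre-existing TE copies, which is what repeat masking achieves).
#' @export
simulate_genome_and_annotations <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  withr::with_seed(cfg$rng_seed + 1L, {
    chrom_names <- paste0("chr", seq_len(cfg$n_chroms))
    genome <- setNames(vapply(chrom_names, function(x) random_dna(cfg$chrom_length),
                              character(1)), chrom_names)

    rows <- list()
    cursor <- setNames(rep(3000L, cfg$n_chroms), chrom_names)
    for (g in seq_len(cfg$n_genes)) {
      gid <- sprintf("g%02d", g)
      chrom <- chrom_names[(g - 1L) %% cfg$n_chroms + 1L]
      strand <- sample(c("+", "-"), 1)
      n_ex <- cfg$exons_per_gene
      ex_len <- sample_range(cfg$exon_length_range[1], cfg$exon_length_range[2], n_ex)
      in_len <- sample_range(cfg$intron_length_range[1], cfg$intron_length_range[2],
                              max(n_ex - 1L, 0L))
      if (g == 1L && n_ex > 1L && cfg$intron_length_range[1] < 100L) {
        in_len[1] <- cfg$intron_length_range[1]   # guaranteed tiny intron
      }
      start <- cursor[[chrom]]
      pos <- start
      for (e in seq_len(n_ex)) {
        rows[[length(rows) + 1L]] <- tibble(
          gene_id = gid, transcript_id = paste0(gid, ".t1"), chrom = chrom,
          strand = strand, exon_rank = e, start = pos, end = pos + ex_len[e])
        pos <- pos + ex_len[e] + if (e < n_ex) in_len[e] else 0L
      }
      cursor[[chrom]] <- pos + sample(1500:4000, 1)
      if (cursor[[chrom]] > cfg$chrom_length - 1000L) {
        abort(sprintf("genes do not fit chromosome length (gene %s ends at %d on %s)",
                      gid, pos, chrom))
      }
    }
    gene_models <- bind_rows(rows)

    te_len <- sample_range(cfg$te_length_range[1], cfg$te_length_range[2],
                           cfg$n_te_families)
    te_names <- paste0("TEfam", seq_len(cfg$n_te_families))
    te <- setNames(vapply(te_len, random_dna, character(1)), te_names)
    if (isTRUE(cfg$include_polyT_te)) {
      i <- cfg$n_te_families
      mid <- floor(nchar(te[[i]]) / 2)
      te[[i]] <- paste0(substr(te[[i]], 1L, mid), strrep("T", 25L),
                        substr(te[[i]], mid + 1L, nchar(te[[i]])))
      names(te)[i] <- "hopper_like"
    }

    ige <- setNames(vapply(unique(gene_models$gene_id), function(gid) {
      reference_mrna(gene_models, genome, gid)
    }, character(1)), unique(gene_models$gene_id))

    contam <- c(rRNA_like_1 = random_dna(1800L), rRNA_like_2 = random_dna(1200L))

    reference_bundle(genome, te, ige, contam, gene_models, masked = TRUE)
  })
}

# Reference mature mRNA of a gene (spliced exons, reverse-complemented for
# minus-strand genes, no tail).
#' @noRd
reference_mrna <- function(gene_models, genome, gene_id) {
  ex <- gene_models[gene_models$gene_id == gene_id, , drop = FALSE]
  ex <- ex[order(ex$start), , drop = FALSE]
  spliced <- paste(substring(genome[[ex$chrom[1]]], ex$start + 1L, ex$end), collapse = "")
  if (ex$strand[1] == "-") revcomp(spliced) else spliced
}

#' Plant TE insertions on two haplotypes
#'
#' Builds haplotype genomes A and B: homozygous insertions are applied to
#' both, heterozygous ones to haplotype A only. Intronic insertions go into
#' the gene's longest intron (midpoint); 3'UTR insertions go to the midpoint
#' of the 3'-terminal exon. All TEs are inserted in forward orientation
#' without target-site duplication.
#'
#' @param bundle A [reference_bundle()] from
#'   [simulate_genome_and_annotations()].
#' @param cfg A [sim_config()]. When `cfg$insertions` is `NULL` a default
#'   panel is planted: 4 homozygous intronic + 2 heterozygous 3'UTR
#'   insertions in the first 6 genes, cycling through the non-hopper TE
#'   families. 3'UTR insertions sit at the terminal exon midpoint.
#' @return List of class `planted_genome`: `haplotypes` (named list `A`,
#'   `B` of chromosome sets), `insertions` (resolved tibble with `chrom`,
#'   `position`, `intron_rank`), and `truth` (TruthRecord tibble).
#' @export
plant_te_insertions <- function(bundle, cfg) {
  gm <- bundle$gene_models
  genes <- unique(gm$gene_id)
  te_names <- setdiff(names(bundle$te_library), "hopper_like")
  ins <- cfg$insertions
  if (is.null(ins)) {
    k <- min(6L, length(genes))
    site <- rep(c("intron", "utr3"), c(min(4L, k), max(k - 4L, 0L)))
    ins <- tibble(te_family = te_names[(seq_len(k) - 1L) %% length(te_names) + 1L],
                  gene = genes[seq_len(k)], site = site,
                  zygosity = ifelse(site == "utr3", "het", "hom"))
  }
  ins <- as_tibble(ins)
  bad_gene <- setdiff(ins$gene, genes)
  if (length(bad_gene)) abort(paste0("Unknown target gene(s): ", paste(bad_gene, collapse = ", ")))
  bad_te <- setdiff(ins$te_family, names(bundle$te_library))
  if (length(bad_te)) abort(paste0("Unknown TE family(ies): ", paste(bad_te, collapse = ", ")))

  intr <- introns(gm)
  res <- withr::with_seed(cfg$rng_seed + 2L, {
    pmap(ins, function(te_family, gene, site, zygosity) {
      ex <- gm[gm$gene_id == gene, , drop = FALSE]
      ex <- ex[order(ex$start), , drop = FALSE]
      chrom <- ex$chrom[1]
      if (site == "intron") {
        gi <- intr[intr$gene_id == gene, , drop = FALSE]
        if (nrow(gi) == 0) abort(sprintf("gene %s has no intron to target", gene))
        gi <- gi[which.max(gi$end - gi$start), , drop = FALSE]
        pos <- gi$start + floor((gi$end - gi$start) / 2)
        rank <- gi$intron_rank
      } else if (site == "utr3") {
        # terminal exon midpoint, so junction reads have a full read-length
        # window on both sides of the insertion point
        utr_exon <- if (ex$strand[1] == "+") ex[nrow(ex), ] else ex[1, ]
        pos <- utr_exon$start + floor((utr_exon$end - utr_exon$start) / 2)
        rank <- NA_integer_
      } else {
        abort(sprintf("Unknown insertion site type '%s'", site))
      }
      tibble(te_family = te_family, gene = gene, site = site, zygosity = zygosity,
             chrom = chrom, position = as.integer(pos), intron_rank = rank,
             te_length = nchar(bundle$te_library[[te_family]]))
    }) |> list_rbind()
  })

  if (anyDuplicated(res[, c("chrom", "position")]) ||
      any(diff(sort(res$position[res$chrom == res$chrom[1]])) == 0)) {
    abort("Planted insertions overlap")
  }
  dup <- res |> count(.data$gene, .data$site, .data$intron_rank) |> filter(n > 1)
  if (nrow(dup) > 0) abort("Planted insertions overlap within a gene")

  build_hap <- function(which_hap) {
    hap <- bundle$genome
    use <- res[res$zygosity == "hom" | which_hap == "A", , drop = FALSE]
    for (chrom in unique(use$chrom)) {
      sub <- use[use$chrom == chrom, , drop = FALSE]
      sub <- sub[order(-sub$position), , drop = FALSE]
      s <- hap[[chrom]]
      for (i in seq_len(nrow(sub))) {
        p <- sub$position[i]
        s <- paste0(substr(s, 1L, p),
                    bundle$te_library[[sub$te_family[i]]],
                    substr(s, p + 1L, nchar(s)))
      }
      hap[[chrom]] <- s
    }
    hap
  }

  truth <- res |>
    transmute(event_type = "TE_INSERTION", element_name = .data$te_family,
              chrom = .data$chrom, position = .data$position,
              zygosity = .data$zygosity, rate = NA_real_,
              gene = .data$gene, site = .data$site)
  structure(list(haplotypes = list(A = build_hap("A"), B = build_hap("B")),
                 insertions = res, truth = truth),
            class = "planted_genome")
}

# 0-based spliced index of a genomic coordinate within a gene's exons
# (number of exonic bases strictly before `pos`).
#' @noRd
spliced_index <- function(ex, pos) {
  sum(pmax(0L, pmin(ex$end, pos) - ex$start))
}

# mRNA-orientation index (0-based) of genomic base `pos`.
#' @noRd
mrna_index <- function(ex, pos) {
  total <- sum(ex$end - ex$start)
  b <- spliced_index(ex, pos)
  if (ex$strand[1] == "+") b else total - b
}

#' Simulate RNA-seq reads from the planted haplotypes
#'
#' Reads are drawn from per-gene transcript templates: canonical spliced
#' mRNA (carrying a 3'UTR TE on carrier haplotypes), intron-retained
#' pre-mRNA at `rate_intron_retention` (whose junction reads span the
#' intron-TE boundary for intronic insertions), exonized chimeras at
#' `rate_exonization`, plus autonomous TE-consensus transcripts,
#' template-switch two-mRNA chimeras at recurrent sites, and poly-A
#' read-through artifacts with leading (possibly interrupted) poly-T
#' segments. Per-gene expression is log-normal; substitution errors are
#' uniform; everything is seeded.
#'
#' @param planted A `planted_genome` from [plant_te_insertions()].
#' @param bundle The matching [reference_bundle()].
#' @param cfg A [sim_config()].
#' @param sample_id Sample label for the read records.
#' @return List of class `sim_reads`: `reads` (read tibble), `truth`
#'   (TruthRecord tibble covering insertions, InDels, chimera sites and the
#'   artifact rates), `chimera_sites`.
#' @export
simulate_transcriptome_reads <- function(planted, bundle, cfg,
                                         sample_id = "sim_rna") {
  gm <- bundle$gene_models
  genome <- bundle$genome
  genes <- unique(gm$gene_id)
  ins_by_gene <- split(planted$insertions, planted$insertions$gene)
  indels <- cfg$indel_events
  if (is.null(indels)) {
    free <- setdiff(genes, planted$insertions$gene)
    k <- min(2L, length(free))
    indels <- tibble(gene = free[seq_len(k)], size = c(15L, 40L)[seq_len(k)])
  }
  indels <- as_tibble(indels)

  withr::with_seed(cfg$rng_seed + 3L, {
    # resolve InDel genomic positions (middle of the widest exon)
    indel_res <- if (nrow(indels)) {
      pmap(indels, function(gene, size) {
        ex <- gm[gm$gene_id == gene, , drop = FALSE]
        ex <- ex[order(ex$start), , drop = FALSE]
        e <- ex[which.max(ex$end - ex$start), , drop = FALSE]
        dstart <- e$start + floor((e$end - e$start - size) / 2)
        tibble(gene = gene, size = as.integer(size), chrom = e$chrom,
               dstart = as.integer(dstart))
      }) |> list_rbind()
    } else {
      tibble(gene = character(0), size = integer(0), chrom = character(0), dstart = integer(0))
    }

    tail_seq <- strrep("A", cfg$polyA_tail_length)

    gene_templates <- lapply(genes, function(gid) {
      build_gene_templates(gid, gm, genome, bundle, ins_by_gene[[gid]],
                           indel_res[indel_res$gene == gid, , drop = FALSE],
                           cfg, tail_seq)
    })
    names(gene_templates) <- genes

    # recurrent template-switch sites between reference mRNAs
    ref_mrna <- setNames(lapply(genes, function(g) paste0(reference_mrna(gm, genome, g), tail_seq)), genes)
    sites <- pick_chimera_sites(gm, ref_mrna, cfg)

    w <- rlnorm(length(genes), 0, cfg$expression_sdlog)
    w <- w / mean(w)
    n_per_gene <- rbinom(length(genes), size = round(2 * cfg$depth), prob = w / 2)
    L <- cfg$read_length

    all_reads <- list()
    for (gi in seq_along(genes)) {
      gid <- genes[gi]
      n_g <- n_per_gene[gi]
      if (n_g == 0) next
      tpl <- gene_templates[[gid]]
      u <- runif(n_g)
      is_chim <- u < cfg$rate_two_mrna_chimera & nrow(sites) > 0
      is_pa <- !is_chim & u < cfg$rate_two_mrna_chimera + cfg$rate_polyA_artifact
      is_std <- !is_chim & !is_pa

      seqs <- character(n_g)
      # ordinary transcript reads
      idx <- which(is_std)
      if (length(idx)) {
        hap <- sample(c("A", "B"), length(idx), replace = TRUE)
        v <- runif(length(idx))
        kind <- ifelse(v < cfg$rate_intron_retention, "retained",
                       ifelse(v < cfg$rate_intron_retention + cfg$rate_exonization &
                                !is.null(tpl$exonized), "exonized", "canonical"))
        for (j in seq_along(idx)) {
          t <- switch(kind[j],
                      canonical = tpl$canonical[[hap[j]]],
                      retained = tpl$retained[[hap[j]]],
                      exonized = tpl$exonized)
          seqs[idx[j]] <- draw_read(t, L)
        }
      }
      # poly-A read-through artifacts: either the reverse-complement cDNA
      # read primed in the tail (leading poly-T) or a sense read running off
      # the transcript end into the tail (trailing poly-A)
      idx <- which(is_pa)
      if (length(idx)) {
        full <- ref_mrna[[gid]]
        body_len <- nchar(full) - cfg$polyA_tail_length
        cdna <- revcomp(full)
        for (j in idx) {
          if (runif(1) < 0.5) {
            s <- substr(cdna, 1L, L)
            seqs[j] <- rt_interrupt(s, cfg$polyA_tail_length, cfg$rt_misincorporation,
                                    lead = TRUE)
          } else {
            t_in <- sample_range(12L, cfg$polyA_tail_length)
            en <- body_len + t_in
            s <- substr(full, en - L + 1L, en)
            seqs[j] <- rt_interrupt(s, t_in, cfg$rt_misincorporation, lead = FALSE)
          }
        }
      }
      # template-switch chimeras at recurrent sites
      idx <- which(is_chim)
      if (length(idx)) {
        for (j in idx) {
          st <- sites[sample.int(nrow(sites), 1), , drop = FALSE]
          q <- sample(30:(L - 30L), 1)
          donor <- ref_mrna[[st$donor_gene]]
          acceptor <- ref_mrna[[st$acceptor_gene]]
          seqs[j] <- paste0(substr(donor, st$donor_t - q + 1L, st$donor_t),
                            substr(acceptor, st$acceptor_t + 1L, st$acceptor_t + (L - q)))
        }
      }
      ok <- nchar(seqs) >= cfg$read_length * 0.5
      seqs <- seqs[ok]
      cls <- c("std", "polyA", "chim")[1L + is_pa[ok] + 2L * is_chim[ok]]
      all_reads[[gid]] <- tibble(seq = seqs, class = cls, gene = gid)
    }

    # autonomous TE-consensus transcripts
    te_names <- names(bundle$te_library)
    tw <- rlnorm(length(te_names), 0, 1)
    n_te <- rbinom(length(te_names), size = round(2 * cfg$te_autonomous_depth), prob = pmin(tw / mean(tw) / 2, 1))
    for (ti in seq_along(te_names)) {
      if (n_te[ti] == 0) next
      cons <- bundle$te_library[[te_names[ti]]]
      seqs <- vapply(seq_len(n_te[ti]), function(i) draw_read(cons, cfg$read_length),
                     character(1))
      all_reads[[paste0("te_", te_names[ti])]] <-
        tibble(seq = seqs[nzchar(seqs)], class = "te", gene = te_names[ti])
    }

    reads <- bind_rows(all_reads)
    if (nrow(reads) == 0) {
      warn("Simulated zero reads (depth too low?)")
      return(structure(list(reads = empty_reads(sample_id), truth = planted$truth,
                            chimera_sites = sites), class = "sim_reads"))
    }
    # substitution errors, then random orientation (artifact reads keep the
    # orientation that defines them)
    reads$seq <- apply_errors(reads$seq, cfg$error_rate)
    flip <- rbinom(nrow(reads), 1, 0.5) == 1 & reads$class %in% c("std", "te")
    reads$seq[flip] <- revcomp(reads$seq[flip])

    out <- tibble(read_id = sprintf("%s_%s_%06d", sample_id, reads$class, seq_len(nrow(reads))),
                  sequence = reads$seq,
                  quality = strrep("I", nchar(reads$seq)),
                  mate_of = NA_character_,
                  sample_id = sample_id)

    truth <- bind_rows(
      planted$truth,
      if (nrow(indel_res)) indel_res |>
        transmute(event_type = "INDEL", element_name = .data$gene,
                  chrom = .data$chrom, position = .data$dstart,
                  zygosity = "hom", rate = NA_real_, gene = .data$gene,
                  site = "exon"),
      if (nrow(sites)) sites |>
        transmute(event_type = "TWO_MRNA_ARTIFACT_RATE",
                  element_name = paste(.data$donor_gene, .data$acceptor_gene, sep = "|"),
                  chrom = .data$donor_chrom, position = .data$donor_pos,
                  zygosity = NA_character_, rate = cfg$rate_two_mrna_chimera,
                  gene = .data$donor_gene, site = "chimera_site"),
      tibble(event_type = "INTRON_RETENTION", element_name = NA_character_,
             chrom = NA_character_, position = NA_integer_,
             zygosity = NA_character_, rate = cfg$rate_intron_retention,
             gene = NA_character_, site = NA_character_),
      if (cfg$rate_exonization > 0)
        tibble(event_type = "EXONIZATION", element_name = NA_character_,
               chrom = NA_character_, position = NA_integer_,
               zygosity = NA_character_, rate = cfg$rate_exonization,
               gene = NA_character_, site = NA_character_))

    structure(list(reads = out, truth = truth, chimera_sites = sites),
              class = "sim_reads")
  })
}

#' @noRd
empty_reads <- function(sample_id) {
  tibble(read_id = character(0), sequence = character(0), quality = character(0),
         mate_of = character(0), sample_id = character(0))
}

#' @noRd
draw_read <- function(template, L) {
  n <- nchar(template)
  if (n < L) return("")
  s <- sample.int(n - L + 1L, 1)
  substr(template, s, s + L - 1L)
}

# Interrupt the reverse-transcribed tail region of an artifact read with
# misincorporated bases (homopolymer RT is error-prone), so a fraction of
# poly-T/poly-A segments survive terminal trimming. The tail region is the
# first `tail_len` bases when `lead`, otherwise the last `tail_len`.
#' @noRd
rt_interrupt <- function(seq, tail_len, rate, lead = TRUE) {
  if (rate <= 0) return(seq)
  w <- nchar(seq)
  k <- min(tail_len, w)
  hit <- which(runif(k) < rate)
  if (length(hit) == 0) return(seq)
  if (!lead) hit <- w - k + hit
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  for (p in hit) chars[p] <- sample(setdiff(DNA_BASES, chars[p]), 1)
  paste(chars, collapse = "")
}

#' @noRd
apply_errors <- function(seqs, rate) {
  if (rate <= 0) return(seqs)
  n_err <- rbinom(length(seqs), nchar(seqs), rate)
  idx <- which(n_err > 0)
  for (i in idx) {
    chars <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
    pos <- sample.int(length(chars), n_err[i])
    for (p in pos) chars[p] <- sample(setdiff(DNA_BASES, chars[p]), 1)
    seqs[i] <- paste(chars, collapse = "")
  }
  seqs
}

# Build the per-gene transcript templates (canonical and intron-retained for
# both haplotypes, plus the exonized chimera when enabled). Sequences are in
# mature-mRNA orientation with the poly-A tail appended.
#' @noRd
build_gene_templates <- function(gid, gm, genome, bundle, ins, indel, cfg, tail_seq) {
  ex <- gm[gm$gene_id == gid, , drop = FALSE]
  ex <- ex[order(ex$start), , drop = FALSE]
  chrom_seq <- genome[[ex$chrom[1]]]
  strand <- ex$strand[1]
  n_ex <- nrow(ex)

  exon_seq <- substring(chrom_seq, ex$start + 1L, ex$end)

  # transcript-level deletion (applies to every template of the gene)
  if (!is.null(indel) && nrow(indel) > 0) {
    for (i in seq_len(nrow(indel))) {
      e <- which(ex$start <= indel$dstart[i] & ex$end >= indel$dstart[i] + indel$size[i])[1]
      off <- indel$dstart[i] - ex$start[e]
      exon_seq[e] <- paste0(substr(exon_seq[e], 1L, off),
                            substr(exon_seq[e], off + indel$size[i] + 1L, nchar(exon_seq[e])))
    }
  }

  utr_ins <- if (!is.null(ins)) ins[ins$site == "utr3", , drop = FALSE] else NULL
  intron_ins <- if (!is.null(ins)) ins[ins$site == "intron", , drop = FALSE] else NULL

  exon_seq_for <- function(hap) {
    es <- exon_seq
    if (!is.null(utr_ins) && nrow(utr_ins) > 0 &&
        (utr_ins$zygosity[1] == "hom" || hap == "A")) {
      e <- if (strand == "+") n_ex else 1L
      off <- utr_ins$position[1] - ex$start[e]
      te <- bundle$te_library[[utr_ins$te_family[1]]]
      es[e] <- paste0(substr(es[e], 1L, off), te, substr(es[e], off + 1L, nchar(es[e])))
    }
    es
  }

  orient <- function(s) if (strand == "-") revcomp(s) else s

  canonical <- lapply(c(A = "A", B = "B"), function(hap) {
    paste0(orient(paste(exon_seq_for(hap), collapse = "")), tail_seq)
  })

  # intron-retained template: the TE-bearing intron for carrier genes,
  # otherwise the first intron
  r <- if (!is.null(intron_ins) && nrow(intron_ins) > 0) intron_ins$intron_rank[1] else 1L
  retained <- lapply(c(A = "A", B = "B"), function(hap) {
    if (n_ex < 2L) return(canonical[[hap]])
    es <- exon_seq_for(hap)
    iseq <- substr(chrom_seq, ex$end[r] + 1L, ex$start[r + 1L])
    if (!is.null(intron_ins) && nrow(intron_ins) > 0 &&
        (intron_ins$zygosity[1] == "hom" || hap == "A")) {
      off <- intron_ins$position[1] - ex$end[r]
      te <- bundle$te_library[[intron_ins$te_family[1]]]
      iseq <- paste0(substr(iseq, 1L, off), te, substr(iseq, off + 1L, nchar(iseq)))
    }
    body <- paste(c(es[seq_len(r)], iseq, es[(r + 1L):n_ex]), collapse = "")
    paste0(orient(body), tail_seq)
  })

  exonized <- NULL
  if (cfg$rate_exonization > 0 && !is.null(intron_ins) && nrow(intron_ins) > 0 && n_ex >= 2L) {
    te <- bundle$te_library[[intron_ins$te_family[1]]]
    te_part <- substr(te, 1L, min(600L, nchar(te)))
    if (strand == "+") {
      body <- paste(c(exon_seq[seq_len(r)], te_part), collapse = "")
      exonized <- paste0(body, tail_seq)
    } else {
      body <- paste(exon_seq[(r + 1L):n_ex], collapse = "")
      exonized <- paste0(paste0(revcomp(body), te_part), tail_seq)
    }
  }

  list(canonical = canonical, retained = retained, exonized = exonized)
}

# Recurrent template-switch donor/acceptor site pairs between distinct
# reference mRNAs; sites are mid-exon and leave enough template on both
# sides of the junction for a read.
#' @noRd
pick_chimera_sites <- function(gm, ref_mrna, cfg) {
  empty <- tibble(donor_gene = character(0), acceptor_gene = character(0),
                  donor_chrom = character(0), donor_pos = integer(0),
                  donor_t = integer(0), acceptor_t = integer(0))
  genes <- names(ref_mrna)
  if (cfg$rate_two_mrna_chimera <= 0 || length(genes) < 2 || cfg$n_chimera_sites < 1) {
    return(empty)
  }
  L <- cfg$read_length
  out <- list()
  tries <- 0L
  while (length(out) < cfg$n_chimera_sites && tries < 200L) {
    tries <- tries + 1L
    pair <- sample(genes, 2L)
    dex <- gm[gm$gene_id == pair[1], , drop = FALSE]
    dex <- dex[order(dex$start), , drop = FALSE]
    aex <- gm[gm$gene_id == pair[2], , drop = FALSE]
    aex <- aex[order(aex$start), , drop = FALSE]
    de <- dex[sample.int(nrow(dex), 1), , drop = FALSE]
    ae <- aex[sample.int(nrow(aex), 1), , drop = FALSE]
    if (de$end - de$start < 80L || ae$end - ae$start < 80L) next
    dpos <- sample_range(de$start + 30L, de$end - 30L)
    apos <- sample_range(ae$start + 30L, ae$end - 30L)
    dt <- mrna_index(dex, dpos)
    at <- mrna_index(aex, apos)
    dlen <- nchar(ref_mrna[[pair[1]]])
    alen <- nchar(ref_mrna[[pair[2]]])
    if (dt < L + 20L || dt > dlen - 10L) next
    if (at < 10L || at > alen - (L + 20L)) next
    out[[length(out) + 1L]] <- tibble(donor_gene = pair[1], acceptor_gene = pair[2],
                                      donor_chrom = de$chrom, donor_pos = as.integer(dpos),
                                      donor_t = as.integer(dt), acceptor_t = as.integer(at))
  }
  if (length(out) == 0) return(empty)
  list_rbind(out)
}

#' Simulate whole-genome DNA-seq reads from the haplotypes
#'
#' Uniform-coverage genomic reads from both haplotypes (half the total depth
#' each), with substitution errors and random orientation — no splicing and
#' no poly-A artifacts, the standard input regime the caller was designed
#' for.
#'
#' @param planted A `planted_genome`.
#' @param cfg A [sim_config()]; `wgs_depth` is the combined fold-coverage.
#' @param sample_id Sample label.
#' @return List of class `sim_reads` with `reads` and `truth`.
#' @export
simulate_wgs_reads <- function(planted, cfg, sample_id = "sim_wgs") {
  L <- cfg$read_length
  withr::with_seed(cfg$rng_seed + 4L, {
    all <- list()
    for (hap in c("A", "B")) {
      for (chrom in names(planted$haplotypes[[hap]])) {
        s <- planted$haplotypes[[hap]][[chrom]]
        n <- round(cfg$wgs_depth * nchar(s) / (2 * L))
        if (n < 1) next
        starts <- sample.int(nchar(s) - L + 1L, n, replace = TRUE)
        seqs <- substring(s, starts, starts + L - 1L)
        all[[paste(hap, chrom)]] <- tibble(seq = seqs, hap = hap)
      }
    }
    reads <- bind_rows(all)
    if (nrow(reads) == 0) {
      warn("Simulated zero WGS reads (depth too low?)")
      return(structure(list(reads = empty_reads(sample_id), truth = planted$truth),
                       class = "sim_reads"))
    }
    reads$seq <- apply_errors(reads$seq, cfg$error_rate)
    flip <- rbinom(nrow(reads), 1, 0.5) == 1
    reads$seq[flip] <- revcomp(reads$seq[flip])
    out <- tibble(read_id = sprintf("%s_%s_%06d", sample_id, reads$hap, seq_len(nrow(reads))),
                  sequence = reads$seq,
                  quality = strrep("I", nchar(reads$seq)),
                  mate_of = NA_character_,
                  sample_id = sample_id)
    structure(list(reads = out, truth = planted$truth), class = "sim_reads")
  })
}

#' Run the full simulator and write a fixture directory
#'
#' Writes the reference bundle (FASTA + GFF3), RNA-seq (and optionally WGS)
#' FASTQ, ground truth TSV, the configuration YAML and a manifest with file
#' MD5 hashes — the same seed always reproduces identical hashes.
#'
#' @param cfg A [sim_config()].
#' @param outdir Output directory.
#' @param wgs Also write WGS reads?
#' @return Invisibly, the manifest as a named list.
#' @export
run_simulate <- function(cfg, outdir, wgs = FALSE) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  bundle <- simulate_genome_and_annotations(cfg)
  planted <- plant_te_insertions(bundle, cfg)
  rna <- simulate_transcriptome_reads(planted, bundle, cfg)
  paths <- write_reference_bundle(bundle, outdir)
  rna_path <- file.path(outdir, "reads_rna.fastq")
  write_fastq(rna$reads, rna_path)
  truth_path <- file.path(outdir, "truth.tsv")
  readr::write_tsv(rna$truth, truth_path)
  cfg_path <- file.path(outdir, "sim_config.yaml")
  write_sim_config(cfg, cfg_path)
  files <- c(paths, reads_rna = rna_path, truth = truth_path, config = cfg_path)
  if (wgs) {
    wgs_reads <- simulate_wgs_reads(planted, cfg)
    wgs_path <- file.path(outdir, "reads_wgs.fastq")
    write_fastq(wgs_reads$reads, wgs_path)
    files <- c(files, reads_wgs = wgs_path)
  }
  manifest <- list(rng_seed = cfg$rng_seed,
                   files = as.list(setNames(unname(tools::md5sum(files)), names(files))))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
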