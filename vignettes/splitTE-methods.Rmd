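---
title: "Calling TE insertions and TE-mRNA chimeras from RNA-seq: methods and design"
author: "splitTE maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling TE insertions and TE-mRNA chimeras from RNA-seq: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

# The model

A de novo transposable element (TE) insertion at genomic position $p$
creates two novel junctions: left flank → TE 5' end, and TE 3' end → right
flank. Without target-site duplication both map to the same reference
coordinate $p$, so sequencing reads that span either junction carry a
breakpoint signature: a prefix (or suffix) that matches the reference
genome contiguously up to $p$, joined to element sequence. The caller's
unit of evidence is therefore a *split read*: its terminal 22nt ends are
mapped independently, and a read qualifies when one end maps **uniquely**
to the repeat-masked genome while the other end maps to a TE consensus or
to an immobile-gene-element (IGE) control mRNA, with at most 3 mismatches
per end.

In transcriptome data the same signature arises from processes that have
nothing to do with transposition:

* **splice junctions and InDel isoforms** — a read across an exon–exon
  junction (especially over tiny introns, <100nt) or across a small
  transcript-level deletion fails end-to-end genome alignment and split-maps
  with both ends near one gene;
* **two-mRNA chimeras** — template switching during library construction
  (or shared short sequences between genes) joins fragments of two distinct
  mRNAs;
* **poly-T artifacts** — reverse transcription of the poly-A tail yields
  T-homopolymer read segments that align into T-rich TE consensus regions
  (the hopper-like element).

The IGE set exists precisely to make the first two classes visible: ordinary
mRNAs are loaded into the element database as negative controls, so splice/
InDel and gene–gene events produce *IGE calls* that can be triaged instead
of masquerading as TE insertions.

# Pipeline stages and the parameters that matter

All coordinates are 0-based half-open; a junction coordinate is the index
of the first base after the upstream flank.

1. **Preprocessing** — adapter removal (≥10nt suffix overlap, ≤1 mismatch;
   adapter sequence is configuration, default the common 13nt Illumina
   stem), 3' quality trimming (Phred < 20, configurable), terminal poly-A /
   leading poly-T trimming (runs ≥10nt), exact-sequence deduplication
   (pair-aware). Reads shorter than `2 × end_length = 44nt` are dropped —
   below that no two disjoint ends exist. Order is fixed:
   adapters/quality → poly-A → duplicates.
2. **Reference subtraction** — reads aligning end-to-end to the masked
   genome with ≤3 mismatches are removed; their alignments are kept because
   they are the denominator material for the coverage ratio.
3. **Contaminant/TE screen** — reads aligning end-to-end to viral/structural
   RNA sequences or to a TE consensus are removed; per-family TE tallies
   from this stage are the "consensus expression" input of the autonomy
   analysis. Junction reads survive both screens because only one of their
   ends matches any one reference.
4. **End mapping** (`end_length = 22`, `max_mismatches = 3`) — the exported
   `map_end()` returns *every* locus within the mismatch budget on either
   strand, best stratum first, with `n_equal_best_hits` recording ties;
   uniqueness means exactly one best-stratum genome hit, and ties are
   discarded rather than broken randomly.
5. **Evidence assembly** — one evidence record per read; if both
   assignments are possible, a TE element end beats an IGE end (IGEs are
   the control class), then the 5'-anchored assignment is preferred. The
   genome anchor is extended base-by-base along the read (stopping at the
   first mismatch) before the junction coordinate is taken; without this
   seed-and-extend step the junction estimate inherits a uniform bias of up
   to `read_length − 44` nt from the read's start position, which would
   defeat both fine positioning and exon-boundary classification. The
   extension can overshoot by a base or two when the element start happens
   to match the next genomic base; clustering absorbs this.
6. **Clustering** (`cluster_range = 300`) — single linkage over junctions
   per (element, chromosome). Cluster position is the median member
   junction with ties to the smaller coordinate (robust, deterministic).
7. **Filters** — two distinct geometry quantities are tracked:
   *width* (junction spread; flagged `WINDOW` above
   `window_multiplier × read_length = 2L`) and *span* (genome-anchor
   extent; flagged `SPAN` below `L/2 − 22`, the stacked-reads signature).
   A single conflated quantity cannot serve both rules: a tiny-intron
   splice cluster has near-zero junction spread but anchors spanning
   ~`2(L − 22) + intron` nt, and would always trip a window test applied to
   anchor extent. Identity filters map the two published identity cutoffs
   onto two different quantities: mean locus-realignment identity of the
   genome anchors (keep ≥ 0.50, `LOW_IDENTITY` below) and best identity of
   any genome end against the repeat library (discard > 0.83, `REPETITIVE`
   above) — the first asks "is the anchor really this locus", the second
   "is the anchor secretly repeat sequence".
8. **Low-complexity screen** — `POLY_T` when any member's element end has a
   homopolymer run ≥15nt within its 22nt, a mono-nucleotide fraction ≥0.8,
   or aligns wholly inside a ≥20nt homopolymer tract of its element. The
   run/fraction defaults are not published values; they were chosen once so
   that the tail artifact is caught while a uniform random 22mer is flagged
   with probability far below $10^{-6}$ (a 15-run in 22nt has probability
   $\approx 8 \cdot 4^{-14}$), and they are configurable.
9. **Scores** — symmetry = `100 × n_upstream / n_support` clamped to
   [1, 99] (50 is ideal; 1/99 are fully one-sided, typical of artifacts and
   of isolated splice-side clusters). Coverage ratio
   `CR = n_support / (local_depth + 1)` with `local_depth` the number of
   subtracted (genome-mapped) reads whose alignment spans the junction
   point itself. A homozygous insertion leaves no reference-spanning reads
   (CR ≈ n_support), a heterozygous one leaves roughly one allele's worth
   (CR well below 1.5), so `CR < 1.5` is annotated `het_or_cnv`. Spanning
   the point, rather than overlapping a ±read-length window, is the
   denominator that makes this separation work: window-overlap counts are
   dominated by flanking reads that exist regardless of genotype and would
   push homozygous calls under the cutoff too.
10. **Triage** — element end in the TE library → `TE_MRNA_FUSION`; in the
    IGE set: same gene as the genomic locus (nearest gene within 10kb) →
    `INDEL_SPLICE`, otherwise `TWO_MRNA_FUSION`. For TE fusions the
    junction context against the union of exons across isoforms:
    `EXON_JUNCTION` within ±2nt of an exon boundary (the granularity of
    22nt anchoring), else `EXONIC_INSERTION` inside an exon,
    `INTRON_RETENTION` inside a gene, `INTERGENIC` outside. Flagged
    clusters are retained in the output with their flags — artifact classes
    are data, not noise to discard silently.

The **autonomy analysis** ranks per-element consensus read counts against
TE-mRNA fusion support (average ranks, Spearman rho as Pearson on ranks)
deliberately without normalising the raw counts; elements whose fusion rank
exceeds their consensus rank sit above the diagonal (expression tied to
host genes, non-autonomous). **Recurrence** merges calls across samples by
single linkage within the cluster range, so merging is symmetric,
transitive and order-independent.

In WGS mode, poly-A trimming, the poly-T filter and junction-context
annotation are switched off: genomic libraries have neither tails nor
transcript structure, which is also why two-mRNA fusions all but vanish
there.

# What the simulator emulates

`sim_config()` defaults describe the package's reference study: one 200kb
chromosome of i.i.d. uniform bases (so 22mers are unique with overwhelming
probability and "repeat-masked" is exact), 10 genes × 5 exons (exons
150–400nt, introns 70–1500nt with a guaranteed tiny intron <100nt), 5 TE
families of 0.5–1.5kb — desk-scale stand-ins; real elements run to 7.5kb and
the planting code handles that length — including a hopper-like family with
an internal 25nt T-tract, and 6 planted insertions: 4 homozygous intronic
(longest intron, midpoint), 2 heterozygous 3'UTR (terminal-exon midpoint,
so junction reads see a full window on both sides). Reads are 100nt at
~1200 per gene with log-normal expression spread (sdlog 0.2) and 0.5%
substitution error; at these settings each junction is spanned by well over
10 reads. Intron retention runs at 0.4 — far above physiological rates, but
it is the only transcript class that exposes intronic TE junctions, and the
study design needs those junctions covered at calling depth; exonization
defaults to 0, matching its absence in real tissue data. Template switching
(1% of reads) happens at 3 recurrent donor/acceptor site pairs rather than
uniformly at random — recurrence is what makes real two-mRNA artifacts
reach the 4-read support floor. Poly-A artifacts (2% of reads) read through
the 30nt tail in either orientation, with a 5% per-base misincorporation
rate inside the reverse-transcribed tail; the interrupted homopolymers are
the fraction that escapes terminal trimming, which is exactly why a
downstream call-level poly-T filter is needed at all. Transcript-level
InDels (≤60nt, default two events in TE-free genes) model InDel/splice
isoforms; haplotype genomes carry only the TE insertions, consistent with
InDel calls being a transcriptome-side phenomenon.

What the simulator does **not** model: realistic base-composition and
repeat landscapes (so real genomes will produce more `REPETITIVE` and
ambiguous-anchor losses than simulations show), indel sequencing errors,
PCR duplication structure, isoform mixtures beyond single-intron retention,
expression stochasticity beyond log-normal scaling, and target-site
duplications. Passing recovery tests on simulation therefore demonstrates
the machinery's correctness, not field performance on tissue RNA-seq.

# Numerical and degenerate-input choices

* Mapping kernels: `map_end()` is exhaustive (all loci ≤ max mismatches,
  N never counts as a match on either side); the pipeline's bulk path finds
  exact hits for all ends in one multi-pattern pass and escalates only
  endless ends to the exhaustive scan — the two routes provably return the
  same best stratum and are cross-checked in the tests. Full-read screening
  uses pigeonhole seed-and-verify (max_mm+1 disjoint seeds, one must be
  exact) with raw-byte verification.
* Determinism everywhere: sorted inputs before clustering, median-low
  positions, lexicographic tie-breaks for element ends, no random
  tie-breaking for uniqueness (ties are discarded), seeded generators via
  `withr::with_seed` (derived offsets per stage so each stage is
  independently reproducible).
* Degenerate inputs: an empty IGE set disables two-mRNA/InDel triage with a
  warning; zero depth yields an empty FASTQ with a warning; an empty call
  table yields zero category counts with a warning; fewer than 3 elements
  make Spearman rho undefined and raise an error.
* Read length enters the span/window bounds as the median post-trim length
  of the library.

# Test and acceptance design

The suite checks every printed boundary (4-read support, 22nt ends, 3
mismatches, 300nt clustering, 2× window, L/2−22 span, 50%/83% identity,
symmetry clamp, CR cutoff 1.5), agreement of `map_end()` with a brute-force
Hamming scan on the 200kb simulated genome, Spearman rho against an
independent quadratic-time oracle at 1e-12, recovery of the planted panel
(recall and precision ≥0.9 within ±25nt), artifact triage (chimera sites →
two-mRNA, InDel loci → InDel/splice, no exon-junction contexts when
exonization is off), and the RNA/WGS two-mRNA contrast. Two reported
choices deserve a note. First, triage accuracy at InDel loci is measured on
classified calls regardless of filter status: at the fixed 300nt linkage
range a mid-exon deletion cluster merges with the flanking splice clusters
of the same gene and exceeds the window bound, but classification is
orthogonal to the quality flags and is the property under test. Second, the
symmetry check uses the support-weighted mean over true-insertion calls
(total upstream reads over total support): per-cluster symmetry at ~10–20
supporting reads has a binomial spread of ±10–15 points, and the weighted
mean is the estimator of the underlying upstream fraction whose precision
matches a ±5-point band at the study's aggregate support. Simulation sizes
in the suite (60kb/6 genes for plumbing, the 200kb default study for
acceptance) were chosen once as the smallest designs in which every planted
event class is represented at calling depth.

# Known limitations

* Uniqueness against a desk-scale random genome is generous; on real
  genomes many genome ends fall in paralogous or repetitive sequence and
  are discarded, lowering sensitivity in exactly the regions TEs prefer.
* The caller reports one junction per read and one position per cluster; it
  does not assemble breakpoints, phase the two insertion junctions, or
  estimate insertion completeness (full-length vs truncated).
* CR-based zygosity conflates heterozygosity with local copy-number flux by
  construction; the label is `het_or_cnv`, not a genotype call.
* The two-mRNA class is a catch-all for template switching and shared-
  sequence alignment artifacts; the package flags them but does not model
  their mechanism further.
* Gapped/spliced alignment is out of scope: evidence comes only from
  ungapped 22nt end matches plus ungapped extension.
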