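---
title: "Detecting G-quadruplex clusters from ligand-stalled WGA sequencing"
author: "g4wga"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting G-quadruplex clusters from ligand-stalled WGA sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(g4wga)
```

## The measurement and its model

G-quadruplexes (G4s) are four-stranded structures formed by guanine-rich
DNA. When a G4-stabilising ligand (here a telomestatin derivative) is
bound, the strand-displacing polymerase used in multiple-displacement
whole-genome amplification (WGA) arrests at the structure. Amplifying the
same genomic DNA twice — once with and once without the ligand — and
sequencing both products therefore converts G4 *clusters* into a
coverage signal: regions dense in quadruplex-forming sequences are
under-represented in the ligand library.

The analysis operates on fixed, non-overlapping genomic windows (0.2 to
10 kbp; clusters are called on 10-kbp windows). For window $w$ with
mapped-read counts $c_L(w)$ (ligand) and $c_C(w)$ (control), the central
statistic is the depletion ratio

$$ r(w) = \frac{c_L(w)}{c_C(w)}, $$

computed on raw counts (the two library totals are within ~10% of each
other in the motivating data; an optional library-size normalisation
rescales $c_L$ by the total-count ratio and is reported as
`fold_change`). Windows with $c_C(w) = 0$ are unmappable or empty and
are flagged invalid rather than imputed; they are excluded from
correlations and can never be called clusters. A per-window two-sided
Fisher's exact test on
$[[c_L, T_L - c_L], [c_C, T_C - c_C]]$ (library totals $T_L, T_C$)
accompanies the ratio; it conditions on the window totals, so with
totals in the millions it is sensitive to percent-level differences and,
because WGA coverage is overdispersed relative to the binomial, it
should be read as a ranking statistic rather than a calibrated error
rate. Benjamini–Hochberg q-values are available but off by default,
since the calling criteria below use the ratio, not p.

Depletion alone does not distinguish a G4 cluster from any other
poorly amplified region, so calling combines three orthogonal
per-window features:

* `pqs_count` — putative quadruplex-forming sequences (PQS) predicted
  from the reference sequence by a G4Hunter implementation (below);
* `g4_pds_count` — experimentally mapped G4s from an external G4-seq
  track obtained under ligand (PDS) stabilisation;
* `ratio` — the depletion ratio above.

A 10-kbp window is a **G4 cluster** when
`pqs_count >= 24`, `g4_pds_count >= 10` and `ratio <= 0.292`
(defaults of `g4_thresholds()`), and a cluster is **ligand-inducible**
when it additionally carries at most 6 G4-seq sites from the K$^+$
(no-ligand) condition — its quadruplexes fold mainly when a ligand
stabilises them. Each qualifying window is one cluster; adjacent
qualifying windows are deliberately not merged (the published cluster
inventory is a window table; `merge_adjacent = TRUE` exists for
exploration).

## G4Hunter scoring

Each base receives a signed score from the homopolymer run containing
it: $+\min(k,4)$ in a run of $k$ guanines, $-\min(k,4)$ in a run of $k$
cytosines, 0 otherwise. Means over a sliding window of 25 nt are
thresholded at $|\bar{s}| \ge 1.2$ (the published defaults), and
overlapping or adjacent above-threshold windows of the same sign merge
into one PQS region; the sign gives the strand (G-rich `+`, C-rich
`-`), so one pass over the forward sequence suffices. Two reporting
choices are deliberate:

* the merged above-threshold *span* is reported without re-trimming to
  G/C boundaries — reproducible, testable, and recorded in the result's
  `metadata()`; a consequence is that the mean score over a long merged
  span can fall below the window threshold that triggered it;
* a PQS (and likewise a G4-seq interval or a TSS) is assigned to the
  single window containing its start coordinate, so every feature is
  counted exactly once and counts at a coarse bin equal the sum over
  its fine bins.

`N` scores 0 silently; other IUPAC ambiguity codes score 0 with a
one-time warning; anything else is an error naming the offset.

## Threshold derivation from control genes

The thresholds above are not free parameters: they are the mean feature
densities of a positive control set — genes with ligand-induced
$\gamma$H2AX (DNA-damage) enrichment, i.e. independently known G4-cluster
regions. `gene_set_features()` averages window features over each gene's
windows (per-gene means, then the mean over genes), and
`derive_thresholds()` maps the means to criteria: PQS rounds to the
nearest integer, the G4-seq PDS density takes its ceiling, the ratio is
used unrounded, and the K$^+$ density takes its floor — so means of
(24, 9.8, 0.292, 6.2) give (24, 10, 0.292, 6). Ceiling and floor are
guarded with a $10^{-8}$ tolerance so floating-point noise in a mean
cannot flip a criterion. A negative control set ($\gamma$H2AX-negative
genes) is a sanity report only: if its means do not fall on the
non-cluster side of every threshold a warning is raised, never an error.

## TSS enrichment

`tss_enrichment()` compares the fraction of called clusters containing
at least one transcription start site with the genome-wide fraction of
windows doing so, with an odds ratio and Fisher's exact p on the 2×2
cluster-by-has-TSS table. A TSS on a window boundary belongs to the
downstream window (half-open intervals throughout; BED coordinates on
disk are 0-based half-open, GRanges in memory 1-based).

## The synthetic-data generator

No public accession exists for the motivating libraries, so the package
ships a seeded generator that emulates the *mechanism* — polymerase
stalling producing window-level depletion — with full ground truth.
Defaults of `sim_config()` are the reference conditions used by the
test suite and the acceptance script:

* a 20-Mbp, 2-chromosome i.i.d. genome at GC 0.40 (sequence realism is
  only needed for PQS scanning; alignment is out of scope);
* 50 planted 10-kbp clusters of 40 canonical PQS motifs
  (G$_{3-4}$ loops of 1–3 A/T nt, random strand) against a background
  of 2.4 motifs per 10 kbp. Loops are kept short so every planted motif
  clears the G4Hunter threshold within one 25-nt window — a G$_3$ motif
  with 7-nt loops can legitimately score below 1.2 and would make
  ground truth ambiguous. Clusters are aligned to the 10-kbp analysis
  grid for the same reason. Motifs are placed one per equal-width slot
  at a random offset, which guarantees non-overlap without rejection
  sampling; a cluster too small for the requested density is an error;
* negative-binomial window counts: control
  $\mathrm{NB}(\mu = 2000, \text{size} = 20)$, ligand mean multiplied
  by 0.13 inside clusters and 1.0 outside. WGA coverage is
  overdispersed, hence NB rather than Poisson (Poisson is the
  size$\to\infty$ limit). Size 20 gives a per-window CV of ~22%,
  realistic for MDA coverage, and implies
  $E[r] \approx 0.13\,(1 + \mathrm{CV}_C^2) \approx 0.137$ for cluster
  windows, comfortably inside the recovery band the tests check
  ([0.11, 0.15]);
* surrogate tracks: the PDS track is every planted PQS; the K$^+$ track
  is a per-cluster subsample (inducible-designated clusters — 20% by
  default — retain 3 sites, others half), a subset of PDS by
  construction. The overlap structure of the real PDS/K$^+$ tracks is
  unknown; the subset relation is a simulator convention, not a claim
  about the real assay;
* TSS in 39% of clusters and 0.087 per 10-kbp window elsewhere,
  mirroring the published enrichment contrast;
* an optional per-read emitter realises each window count as uniform
  150-bp read starts within the window, exercising the BAM/SAM/BED
  counting path with exactly recoverable totals.

Everything derives from one seed (sub-streams at small fixed offsets),
so identical configurations give byte-identical FASTA, counts, tracks
and truth.

What the simulator does **not** emulate: repeat structure and
mappability bias, GC-dependent amplification, sequencing error, the WGA
branching process, or per-PQS stalling kinetics (depletion is a step
function on cluster membership, matching the window-level signal the
method actually uses). Passing tests therefore demonstrate that the
pipeline's inference is correct *given* window counts and a reference —
not that a real experiment will reach the same recall.

## Numerical and design choices

* **Fisher's exact test** is computed by direct hypergeometric
  summation (two-sided by probability mass, with the conventional
  $1+10^{-7}$ tie tolerance), vectorised over windows;
  `stats::fisher.test` agrees to $10^{-9}$ and serves as a cross-check
  in the tests, alongside an exhaustive-enumeration oracle. With
  extreme depletion at high depth, p underflows to 0; invariantly
  p $\in (0,1]$ only up to double precision.
* **Reads** are assigned by their leftmost mapped coordinate; unmapped,
  secondary and supplementary alignments are excluded (and tallied),
  MAPQ is not filtered by default since the motivating analysis states
  no such filter; both are arguments of `count_reads()`.
* **Correlation** between PQS counts and ratios is Pearson by default
  (only "correlation" is specified in the motivating work); Spearman is
  available for robustness. Zero variance yields `NA` with a warning,
  never 0.
* **Problem sizes in the tests**: oracle equivalence uses 500 random
  sequences up to 1 kb; the Fisher check enumerates all 2×2 tables with
  margins up to 50; end-to-end recovery runs the full 20-Mbp reference
  configuration. These sizes make the whole suite run in a few minutes
  on one CPU while keeping every check at full strength.

## Known limitations

* Cluster calling is strictly per-window: a cluster straddling a window
  boundary dilutes into two windows and may be missed near threshold;
  the motivating method shares this granularity.
* The per-window Fisher p is anti-conservative under NB overdispersion
  (see above) — on the synthetic reference data roughly 40% of
  background windows reach BH q < 0.05 for a percent-level depletion.
  This is why calling uses the ratio with control-gene-derived
  thresholds instead of p.
* `derive_thresholds()` assumes per-gene means (mean of window means
  per gene, then mean over genes); whether the original gene-level
  averages pooled windows instead is not documented.

## A worked example

```{r example, eval = FALSE}
cfg <- sim_config(genome_length = 2e6, n_clusters = 10, seed = 7)
sim <- simulate_g4_dataset(cfg)
res <- run_g4_pipeline(sim$genome, counts = sim$counts,
                       pds = sim$tracks$pds, kplus = sim$tracks$kplus,
                       tss = sim$tracks$tss, truth = sim$truth)
res$summary      # clusters and their mean ratio / PQS / PDS densities
res$evaluation   # recall and precision against the planted truth
res$enrichment   # TSS fractions, odds ratio, Fisher p
```
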