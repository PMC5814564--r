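# g4wga

Detection of G-quadruplex (G4) clusters from paired sequencing of
whole-genome-amplification (WGA) products prepared with and without a
G4-stabilising ligand.

## The problem

A ligand bound to a folded G-quadruplex arrests the strand-displacing
polymerase used in multiple-displacement WGA. Sequencing the amplified
material from a ligand-treated and an untreated reaction turns G4
*clusters* — regions dense in quadruplex-forming sequences — into a
read-depth signal: for a genomic window *w*, the depletion ratio

```
r(w) = reads_ligand(w) / reads_control(w)
```

drops far below 1 where the polymerase stalled. `g4wga` implements the
downstream computational pipeline for this assay, for genomicists who
have mapped, duplicate-removed reads for the two libraries and want the
cluster inventory:

- fixed-window read binning (BAM/SAM/BED or interval input; reads
  assigned by leftmost mapped coordinate, so counts are conserved and
  refine exactly across bin sizes);
- per-window depletion ratio, optional library-size-normalised fold
  change, two-sided Fisher's exact test against the library totals, and
  optional Benjamini–Hochberg q-values;
- a G4Hunter implementation for putative quadruplex-forming sequences
  (PQS): per-base scores ±min(run, 4) for G/C homopolymer runs, 25-nt
  sliding-window means thresholded at |mean| ≥ 1.2, same-sign regions
  merged; strand from the score sign;
- calling thresholds derived from positive (γH2AX-enriched) and
  negative control gene sets — positive-set means (24, 9.8, 0.292, 6.2)
  reproduce the criteria (PQS ≥ 24 per 10 kbp, G4-seq PDS ≥ 10,
  ratio ≤ 0.292, and K⁺ ≤ 6 for the ligand-inducible subset);
- cluster calling as the conjunction of PQS density, external G4-seq
  support and read depletion on 10-kbp windows; ligand-inducible
  extraction; TSS-overlap enrichment with odds ratio and Fisher p;
- BED / bedGraph / IGV-format track output for browser inspection;
- a seeded synthetic-data generator with planted ground truth
  (negative-binomial counts, step depletion on planted clusters,
  surrogate G4-seq and TSS tracks) so the entire pipeline is testable
  with no external downloads.

See `vignettes/g4-cluster-detection.Rmd` for the model, parameter
meanings and design choices.

## Worked example

```r
library(g4wga)

cfg <- sim_config(genome_length = 2e6, n_clusters = 10, seed = 7)
sim <- simulate_g4_dataset(cfg)
res <- run_g4_pipeline(sim$genome, counts = sim$counts,
                       pds = sim$tracks$pds, kplus = sim$tracks$kplus,
                       tss = sim$tracks$tss, truth = sim$truth)

res$thresholds
#> G4 cluster calling thresholds (per 10-kbp window):
#>   PQS count          >= 24
#>   G4-seq PDS count   >= 10
#>   depletion ratio    <= 0.292
#>   G4-seq K+ count    <= 6  (ligand-inducible)

str(res$summary)
#> List of 4
#>  $ n_clusters: int 10
#>  $ mean_ratio: num 0.112
#>  $ mean_pqs  : num 41
#>  $ mean_pds  : num 40

str(res$evaluation)   # against the planted truth
#> List of 5
#>  $ recall   : num 1
#>  $ precision: num 1
#>  $ n_true   : int 10
#>  $ n_called : int 10
#>  $ n_overlap: int 10

res$enrichment
#> TSS-overlap enrichment of G4 clusters
#>   clusters with >=1 TSS: 40.0% of 10
#>   genome-wide windows with >=1 TSS: 10.0%
#>   odds ratio 7.12, Fisher p = 0.0105
```

All ten planted clusters are recovered with no false calls; their mean
depletion ratio (0.112) sits near the simulated in-cluster depletion of
0.13, and clusters are four-fold enriched for transcription start
sites, as planted. With `outdir =` set, the pipeline also writes the
count/feature/cluster tables, PQS BED, ratio bedGraph and IGV tracks,
a human-readable summary and a JSON manifest with parameters and output
checksums.

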