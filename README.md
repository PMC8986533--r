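# wgdqc

Quantifying genetic instability in the first cell cycle after whole-genome
duplication (WGD).

When a diploid cell becomes tetraploid — by mitotic slippage, cytokinesis
failure or endoreplication — its very first S phase is perturbed: replication
forks behave abnormally, parts of the genome end up under- or
over-replicated, and DNA-damage foci accumulate. `wgdqc` implements the three
computational readouts used to measure this in single cells, each paired with
a seeded synthetic-data generator with known ground truth:

* **Single-cell copy-number calling and curation.** Per-cell binned read
  counts (1-Mb bins) are GC-corrected, optionally normalized to a matched G1
  reference, segmented by two independent callers — a CBS-style penalized
  changepoint search and a sticky Viterbi HMM — and anchored to integer
  states `round(mean/s)` under a ground-ploidy constraint (e.g. [3.5, 4.5]
  for 4n samples, [7.5, 8.5] for 8n). Libraries are then curated by
  - dual-caller concordance (≥ 0.95 for 2n, ≥ 0.90 for 4n/8n samples),
  - read depth (≥ 10 reads per chromosome copy per bin; 2-somy: 20 reads,
    3-somy: 30 reads, …; ≈ 60,000 total reads for a 2n G1 library and
    240,000 for an 8n G2/M library on a ~3,000-bin tiling), and
  - the wavy-pattern filter: for any state ≠ expected covering > 1 % of the
    genome, the non-rounded copy number
    `Mean_state / (Mean_expected / CN_expected)` must stay within 0.25 of
    the integer state (for 5-somy: within [4.75, 5.25]).

  Retained cells are scored for aneuploidy (mean |state − ploidy| per bin),
  aneuploid genome fraction, and cell-to-cell heterogeneity (per-bin Simpson
  diversity 1 − Σ f² of states), and drawn as genome-wide heatmaps.
* **DNA-combing fork metrics.** Fork speed = stretch × (CldU + IdU track
  length) / (2 × 30 min); asymmetry = CldU/IdU in pulse order; inter-origin
  distances along single fibers.
* **Nuclear damage quantification.** Otsu + watershed nucleus segmentation,
  difference-of-Gaussians focus detection, the coverage × mean-intensity
  damage index, foci normalized per nuclear area and DNA-stain intensity,
  the "≥ 10 foci" classification, and Manders M1/M2 with a seeded Costes
  pixel-randomization p-value (p = (1 + #{rand ≥ obs}) / (n + 1)).

See `vignettes/wgdqc-methods.Rmd` for the models, parameter choices and
limitations, and the numbered scripts under `analysis/` for the end-to-end
workflow (simulate → call → curate/score → fibers → foci).

## Worked example

Simulate one G2/M tetraploid cell (8 copies per bin after S phase) carrying a
61-bin over-replicated territory at 9 copies, call it with both callers,
curate it, and score it:

```r
library(wgdqc)

grid <- make_toy_genome(3, 1000, 1e6)            # ~3 Gb in 1-Mb bins
ks <- karyotype_spec(8,
  data.frame(chrom = "chr2", start_bin = 400, end_bin = 460, cn = 9),
  label = "4n G2/M")
lib <- simulate_cell_counts(grid, ks, sim_config(depth_per_copy = 12, seed = 7))

calls  <- call_copy_number(lib, grid, ploidy = 8,
                           ploidy_bounds = c(7.5, 8.5), max_state = 10)
report <- curate_library(lib, calls$changepoint, calls$hmm, "8n",
                         corrected = calls$corrected)
a <- aneuploidy_score(calls$changepoint)
```

This prints (via the corresponding `sprintf` calls):

```
concordance: 1.0000 (threshold 0.90)
mean reads per copy per bin: 12.02 (minimum 10)
decision: keep
aneuploidy score: 0.0190, aneuploid genome fraction: 0.0190
  chrom     start       end n_bins state
4  chr2 403000000 460000000     57 9
```

Both callers agree on the whole genome (concordance 1.0 against the 0.90
polyploid threshold), the library clears the 10 reads/copy depth rule at
12.02, and the injected 9-copy territory is recovered as a 57-bin segment
(the 61-bin truth, with a few boundary bins absorbed by noise). The
aneuploidy score 0.019 is the genome fraction at |state − 8| = 1.

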