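---
title: "Methods: quantifying genetic instability after whole-genome duplication"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying genetic instability after whole-genome duplication}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wgdqc)
```

# Scope and model

Unscheduled whole-genome duplication (a 2n cell becoming 4n by mitotic
slippage, cytokinesis failure or endoreplication) perturbs the very first
S phase that follows: forks run abnormally, territories of the genome end
up under- or over-replicated, and DNA-damage foci accumulate. `wgdqc`
implements the three quantitative readouts used to measure this in single
cells, together with seeded generators that produce inputs with known
ground truth:

1. **Single-cell copy-number calling and curation.** Binned read counts per
   cell are GC-corrected, optionally normalized to a matched G1 reference,
   segmented by two independent callers, anchored to integer copy-number
   states under a ground-ploidy constraint, and passed through a
   three-filter quality ledger (dual-caller concordance, per-copy read
   depth, wavy-pattern deviation). Retained cells are scored for
   aneuploidy, aneuploid genome fraction and cell-to-cell heterogeneity.
2. **DNA-combing fork metrics.** Fork speed from the combined CldU+IdU
   track length, fork asymmetry as the CldU/IdU length ratio in pulse
   order, and inter-origin distances along single fibers.
3. **Nuclear damage quantification.** Nucleus segmentation, focus
   detection, the coverage-times-intensity damage index, normalized focus
   counts, the "at least ten foci" classification, and Manders/Costes
   colocalization.

A 4n cell sampled at G2/M has completed S phase, so its expected copy
number per bin is 8; under- and over-replicated territories appear as 7-
and 9-copy states. All coordinates are 0-based half-open (BED convention).

# Count model and the synthetic genome

The toy genome tiles `n` chromosomes with contiguous fixed-width 1-Mb bins.
The sliding 500-kb-step scheme used on real data is realized, when wanted,
by calling the pipeline on a second half-offset tiling; the curation logic
is bin-scheme-agnostic, so the package's default is the single tiling. GC
content follows a deterministic bounded profile in [0.3, 0.6] mixing an
isochore-scale drift with fine-scale texture. The texture matters: if GC
varies only slowly along the genome, a single aberration occupies a narrow
GC band and any GC-bias fit partially absorbs it.

Counts for a bin with true copy number $c$ are drawn from a negative
binomial with mean $\mu = d \cdot c \cdot f_{GC} \cdot w$ and variance
$\phi\mu$, where $d$ is the depth per copy (reads/bin/copy), $f_{GC}$ a
quadratic multiplicative GC bias, and
$w(b) = 1 + A\sin(2\pi b/\text{period})$ a smooth multiplicative wave
emulating the wavy coverage artifact. Defaults: $\phi = 1.3$ (a
good-quality single-cell library; the dispersion of the real libraries is
not published, so this is a realistic placeholder, not a calibration) and
wave period 150 bins. The period was chosen so the artifact does what it
does in real data: undulate slowly enough, at chromosome-arm scale, that
segmentation emits whole spurious segments one copy above or below the
expected state instead of averaging the wave away. At dispersion 1 the
model degenerates to Poisson; identical seed and configuration reproduce
counts bit for bit.

# The two callers

The concordance filter needs two algorithmically independent opinions, so
the package ships two callers rather than reusing an external one.

**Changepoint caller.** A circular-binary-segmentation-style recursion per
chromosome: each scan finds the interior segment whose removal maximizes
the squared-error reduction per added changepoint and accepts it when that
normalized reduction exceeds $\lambda\,\hat\sigma^2\log N$
($\lambda = 1.5$ by default, $\hat\sigma$ from the median absolute
successive difference, $N$ the number of usable bins). Scanning for a whole
interior segment is essential: a plain best-single-split search cannot pay
for a short interior aberration (its single-split reduction is an order of
magnitude below the two-changepoint reduction). Each scan is $O(n^2)$ in
the chromosome's bin count, intended for the ~10^3-bins-per-chromosome
scale used here.

**HMM caller.** Hidden states are candidate copy numbers $0..s_{max}$ with
Gaussian emissions centered at $s \cdot d$, where $d$ is the robust
per-copy estimate (median signal / expected modal state), a shared noise
scale estimated from successive differences, and sticky transitions
(self-transition 0.95, i.e. expected sojourn 20 bins ≈ 20 Mb, matching the
segmental scale of real events). The Viterbi path is computed with a single
deterministic initialization — no EM, no random restarts — so identical
inputs always give identical profiles. Runs of equal states become
segments.

**Integer anchoring.** Both callers emit segments with means; states are
`round(mean / s)` (round half away from zero, so boundaries are
reproducible) for a global per-copy scale `s`, under the constraint that
the count-weighted mean assigned state — the continuous ground ploidy —
lies within the sample-class bounds ([3.5, 4.5] for 4n, [7.5, 8.5] for 8n
samples). The pipeline pins `s` to the median-anchored per-copy estimate.
This pinning is a deliberate design choice: if the scale were re-optimized
against the segment means, a strong coverage wave could be re-read as a
clean mosaic of adjacent states at a ~10% smaller scale, and the
wavy-pattern filter (below) would never see the artifact at its true
scale. When no per-copy estimate is supplied the scale is found by grid
search minimizing the weighted squared rounding error over feasible
scales.

# Curation

Three pure predicates, applied in a fixed order but order-independent in
their conjunction:

* **Concordance**: length-weighted fraction of the non-blacklisted genome
  on which the two callers agree; minimum 0.95 for 2n samples, 0.90 for
  4n/8n samples.
* **Read depth**: the mean over bins of `count / state` must be at least
  10 reads per chromosome copy (a bin called s-somy needs on average
  `10*s` reads; totals of 60,000 reads for a 2n G1 library and 240,000 for
  an 8n G2/M library on a ~3,000-bin tiling). Boundaries are read
  literally: exactly 10 passes.
* **Wavy pattern**: for every state other than the expected one occupying
  more than 1% of the genome, the non-rounded copy number
  `mean_state / (mean_expected / cn_expected)` is computed; a deviation of
  more than 0.25 copies from the integer state discards the library (for a
  5-somy call, values below 4.75 or above 5.25). Exactly 1% does not
  trigger; exactly 0.25 passes. The filter is armed for all sample classes
  by default and can be restricted per class by configuration.

The wavy filter's operating characteristic on simulation (euploid 4n
cells, depth 10/copy, 3,000 bins, 50 cells per arm): discard rate 0 at
amplitude 0 and 1.0 at amplitude 0.2, evaluated on the changepoint
caller's profile.

# Karyotype scores

Per cell, the aneuploidy score is the length-weighted mean of
$|s_b - p|$ over bins (expected ploidy $p$) and the aneuploid fraction is
the length-weighted fraction of bins with $s_b \ne p$. Across cells,
heterogeneity per bin is Simpson-type diversity $1 - \sum_s f_s^2$ of the
state distribution, averaged length-weighted over the genome. The
published score definitions live in the cited single-cell CNV literature
rather than in the study itself; this concrete, testable pair was chosen
to match their intent (deviation from euploidy; cell-to-cell state
variability per locus). Heatmaps draw one row per cell in given order (no
silent clustering) and export the exact state matrix as TSV.

# Fiber metrics

Fork speed is `stretch * (len_CldU + len_IdU) / (2 * pulse_minutes)` —
combined label length over the total 60 minutes of the two 30-minute
pulses; the per-pulse convention is declared rather than assumed, and both
the stretch factor (default 2 kb/µm, the standard combing constant) and
pulse length are recorded in every output. Asymmetry is CldU/IdU in pulse
order (a `max/min` variant exists for robustness analyses). Inter-origin
distances are consecutive-origin differences within a fiber. In the
generator, per-pulse speeds are normal truncated at zero; a stalled fork's
second pulse runs at a uniform [0, 0.5] multiple of its own first-pulse
speed, so stalling always produces a ratio above 2 — with an independent
second draw, a fast second pulse could mask the stall and certain stalling
would not guarantee asymmetry.

# Imaging

Nuclei are segmented by Otsu threshold, hole filling, watershed on the
distance map and a minimum-area filter (the original study segmented
nuclei manually; the automated substitution is the reproducible choice,
with every threshold exposed). Foci are detected by difference-of-Gaussians
band-pass filtering, local maxima above a prominence threshold, and greedy
non-maximum suppression; two spots closer than the suppression radius
merge into one detection by construction. The default prominence is six
times an iteratively clipped MAD of the band-pass response — evaluated on
the extranuclear background when quantifying whole fields, because the
noise floor inside a densely spotted nucleus is not estimable from the
nucleus itself. Absolute focus counts are parameter-dependent (the
original plugin's settings are unpublished); cross-condition comparisons
on matched parameters, like the at-least-ten-foci fraction, are the
meaningful outputs.

The damage index multiplies the percent coverage of positive pixels by
their mean intensity (zero when nothing is positive); the in-mask Otsu
default threshold makes the index scale-equivariant. Manders M1/M2 are
intensity fractions over the other channel's thresholded support; the
Costes test permutes pixel positions within the mask, counts ties against
rejection and adds one to numerator and denominator, so the p-value is
conservative with resolution 1/(n+1).

The image generator plants isotropic Gaussian spots (2D fields; projection
is assumed already done) with a minimum center separation of
`2*focus_sigma + 2` px so ground-truth spots are individually resolvable,
and shares exactly `round(overlap_fraction * n_foci)` centres with an
optional marker channel. Impossible packings raise errors rather than
silently truncating.

# Numerical and I/O choices

* Rounding of states: half away from zero, documented and tested.
* Degenerate inputs error loudly: all-zero counts, zero reference bins
  (named), all-state-0 profiles, unsatisfiable ploidy bounds, empty
  summaries.
* Tables round-trip exactly: doubles are serialized with 17 significant
  digits. Images are interchanged as 16-bit TIFF with a JSON sidecar
  carrying per-channel scales; one write-read cycle quantizes to 1/65535
  of the channel maximum and is bit-stable thereafter (floating-point
  TIFF round-trips are not reliable in the available stack).
* Every generator takes a seed; population generators derive per-cell
  child seeds deterministically, all below 2^31.

# Study problem sizes

The bundled studies (used by the acceptance checks and the `analysis/`
scripts) run at: 30 cells per arm on 3×1,000 bins at 10 reads/copy for
karyotype recovery; 50 cells per arm for the wavy operating
characteristic; 300 forks / 500 fibers for the combing estimators; 100
seeded images for spot recall; 200 experiments × 199 randomizations for
p-value uniformity. These sizes put Monte-Carlo error comfortably below
the tested margins while staying desk-scale.

# What the simulations do and do not show

The generators reproduce the statistical structure the analyses assume —
negative-binomial counts on a ploidy landscape with GC and wave biases,
truncated-normal fork kinetics with exponential origin spacing, Gaussian
foci on elliptical nuclei. They do not reproduce mappability variation,
replication-timing coverage structure, chromatin-dependent focus
morphology, segmentation-resistant nuclear shapes, or the original study's
cell lines, images and libraries. Passing tests therefore demonstrate
correctness and calibration of the computations on data that satisfies
the stated model, not that the biological effect sizes of the original
system are recovered.

A known operating-point subtlety: simulating clean cells at exactly
10 reads/copy places their observed mean depth exactly at the read-depth
filter's inclusive boundary, so sampling noise sends about half of such
cells below it. Libraries meant to be kept should be sequenced with
margin above the minimum (the worked keep-examples here use 12
reads/copy); the minimum is a discard line, not a target.
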