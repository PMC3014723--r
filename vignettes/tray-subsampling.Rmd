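---
title: "Fixed-area tray subsampling: model, calibration and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fixed-area tray subsampling: model, calibration and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(traysub)
```

## The protocol and its estimator

`traysub` models a three-phase laboratory routine for liquid-preserved
terrestrial invertebrate samples. A 4 mm sieve first removes large
specimens, which are counted exhaustively (phase 1). The remainder is
brushed into an even layer on a circular tray carrying a metal grid with 45
complete cells of 2.54 cm side; the plate's 412 cm² inner area equals 63.6
cell-areas ("cell-equivalents"). A technician counts the invertebrates in
*k* randomly selected complete cells (phase 2) and finally scans the
uncounted remainder for a few minutes, recording the presence of any taxon
not yet seen (phase 3).

Abundance is estimated by plug-in extrapolation: the mean count per counted
cell times the cell-equivalent multiplier, plus the phase-1 pool,

$$\hat N = \frac{1}{k}\sum_{j=1}^{k} x_j \times 63.6 + N_{\text{large}},$$

and is scored by *percent accuracy*, $100\,\hat N_2 / N_2$, where $N_2$ is
the true number of individuals in the tray portion (the sample minus the
large pool). Taxa richness is the union of taxa over the three phases; the
scan contributes presence only, never counts.

Two design constants deserve comment:

* **The multiplier is stored, not derived.** Raw division of the areas
  gives $412 / 6.45 \approx 63.9$, while the apparatus is specified with
  63.6 cell-equivalents. The stored value 63.6 is canonical everywhere
  downstream and is exposed in `tray_geometry()` for users with a different
  tray; `cell_area()` and `plate_area()` document the raw geometry, and a
  unit test asserts the two views agree to within half a cell.
* **The edge is one pooled region.** Only complete cells are selectable,
  so the partial cells around the rim (63.6 − 45 = 18.6 cell-equivalents)
  are unobservable at sub-region resolution. The simulator therefore pools
  them into a single edge region with the corresponding area weight — the
  simplest model consistent with what the protocol can see. An edge-free
  tray (`equivalent_cells == n_complete_cells`) is permitted for small test
  arenas.

Under even placement the expected count in each complete cell is
$N_2/63.6$, so the estimator is unbiased for $N_2$ regardless of *k*; the
package's Monte-Carlo evaluation verifies this and quantifies how precision
grows with *k*.

## What the synthetic generator emulates

No field samples ship with the package; `community_preset()` provides six
calibrated stand-ins ("pan"/"pitfall" × "low"/"moderate"/"high" abundance)
whose simulated samples reproduce the broad statistical structure of real
trap samples:

* **Sample totals** are drawn log-uniformly over each category's observed
  range (pan: 122–237, 286–375, 676–5,337; pitfall: 93–164, 314–384,
  504–813 individuals). Field reports give only ranges, and trap totals are
  strongly right-skewed, hence log-uniform rather than uniform.
* **Rank abundance** follows a deterministic lognormal series over 30 (pan)
  or 43 (pitfall) order/family-level taxa: weights
  $w_i = \mathrm{qlnorm}((i-\tfrac12)/S,\,0,\,\sigma)$. The shape
  $\sigma$ is calibrated per preset (2.50–3.12) so that the expected number
  of taxa realized with at least one individual matches the field mean
  richness for that trap and category (13.6–23.7 taxa). The calibration
  solves $\sum_i\bigl(1-(1-p_i)^N\bigr) = \text{target}$ averaged over the
  total's range; a test checks the realized means stay within about one
  taxon of the targets.
* **Large specimens.** A fixed set of large-bodied taxa (carabids,
  grasshoppers, crane flies, bees, …) carries a per-individual probability
  of retention on the 4 mm sieve (binomial thinning, 0.2–0.9 by taxon);
  most taxa pass through entirely.
* **Imperfect detection.** Six small, pale taxa (aphids, spittlebug
  nymphs, spiderlings, springtails, thrips, mites) are seen in a counted
  cell with probability 0.7 rather than 1, and are harder to pick up in
  the scan. The quick scan detects a not-yet-seen taxon with probability
  $1-(1-q)^m$, where $m$ is the number of its individuals still on the
  tray — including individuals missed inside counted cells, which remain
  physically present. The per-individual scan probability defaults to
  $q = 0.5$ (pale taxa 0.12), calibrated once so the full protocol misses
  on the order of two to three taxa per sample and detects roughly 80–90%
  of richness, the scale reported for the field evaluation. Detection
  parameters are deliberately coarse: field data constrain them only
  qualitatively.
* **Spatial placement.** The protocol brushes samples into an even layer,
  so placement defaults to multinomial with area weights
  (`clustering_theta = Inf`). Finite `clustering_theta` switches to a
  Dirichlet-multinomial with concentration $\theta \times$ area-weights,
  independently per taxon — a sensitivity knob for probing how clumping
  degrades precision (the area-weighted base measure keeps the estimator
  unbiased in expectation, so clustering widens intervals without shifting
  means). It is a hypothesis generator, not a fitted model of real trays.

Features of real samples the generator does **not** emulate: debris and
algal entanglement (absorbable into detection probabilities but not
modelled mechanistically), technician-to-technician variation, counting
errors inside cells beyond the miss mechanism, taxonomic misidentification,
and any ecological correlation between taxa. Passing tests therefore show
that the protocol's estimators behave correctly *given* this sampling
model, not that any particular field accuracy (e.g. the ~20%
overestimation reported for low-abundance pitfall samples, which has no
stated mechanism) is reproduced. The clustering and detection knobs let
users explore candidate mechanisms for such biases without asserting a
cause.

## The Monte-Carlo evaluation

`evaluate_design()` simulates `n_reps` samples per preset, runs the
protocol once per sample with an ordered 16-cell selection, and evaluates
every nested prefix $k = 1..16$ — mirroring the incremental way cells are
counted in practice and producing smooth accuracy/richness curves from a
single draw per sample rather than independent redraws per $k$. Percent
accuracy is averaged across sample-level scores (matching how means with
confidence intervals are reported for field samples), and 95% intervals
are normal-approximation mean ± 1.96 SE; with 1,000 samples per preset the
normal approximation is comfortably accurate, and the CI method is stated
here because field reports usually leave it unspecified. Samples whose
tray portion is empty have undefined accuracy; they are excluded and
counted in a diagnostics table rather than silently dropped. Per-taxon miss
rates are tabulated at $k = 16$ with the scan included, as the fraction of
samples containing the taxon in which all three phases failed.

Default problem sizes — 1,000 replicates per preset for evaluation-level
checks, 20,000 replicates for closed-form detection comparisons, 100 seeds
for conservation sweeps — were chosen so Monte-Carlo error is small
relative to the effects examined (3 Monte-Carlo SEs is the standard
tolerance throughout the stochastic tests) while keeping a full run on a
single core in the tens of seconds.

## Numerical and boundary conventions

* **Category boundaries** follow the printed inequalities literally:
  below 250 is low, 250–500 inclusive is moderate, above 500 is high.
  These are mutually exclusive and exhaustive only under this reading.
* **The full-count rule** recommends a complete count when the mean per
  cell after exactly 10 cells is *strictly* below 4; a mean of exactly 4
  proceeds with estimation, again following the printed inequality.
* **Percent accuracy** is defined on the phase-2 portion only, per the
  protocol's own formula. `write_estimates()` also reports the total
  estimate (phase 2 plus the large pool) as a convenience; its accuracy
  against the full total is a different, stricter quantity and is not the
  protocol's score.
* **CI overlap**: intervals sharing an endpoint are treated as
  overlapping, so `ci_nonoverlap()` is true only for strictly disjoint
  intervals — the conservative reading of "non-overlapping confidence
  intervals indicate significant differences".
* **Degenerate inputs**: `percent_accuracy()` and `percent_richness()`
  refuse zero denominators rather than returning `NaN`; `k = 0` is an
  error for the estimator; probability and range validation happens at
  construction (`taxa_spec()`, `community_config()`, `tray_geometry()`)
  so simulation code paths can assume valid parameters.
* **Determinism**: all randomness flows through R's RNG; a fixed seed
  reproduces realizations, protocol results and evaluation summaries
  bit for bit. File writers embed the package version, seed and a payload
  MD5 in a comment header for provenance.

## Real-data mode

`read_tally_sheet()` ingests the same comma-separated tally format the
simulator writes — one row per (sample, phase, cell, taxon) — validating
cell indices, duplicate records and malformed rows with line numbers.
Counted-but-empty cells are written explicitly so the number of counted
cells survives the round trip. Estimation, classification, the full-count
rule and richness work identically on real tallies; only accuracy scoring
requires ground truth, which real samples lack unless processed
completely.

## Limitations

The generator's presets are calibrated to one pair of trap studies from
one region; the detection and sieve parameters are plausible rather than
measured, and conclusions about *which* mechanism drives field biases are
outside what this simulator can establish. The estimator itself is the
protocol's plug-in extrapolation; design-based variants (ratio or
Horvitz-Thompson estimators, finite-population corrections for counting
many of the 45 cells) are deliberately out of scope.
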