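---
title: "Quantifying collective cell migration and comparative network rewiring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying collective cell migration and comparative network rewiring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ccmkit)
```

## The problem

Cytokines such as oncostatin M (OSM) can switch mammary epithelial cells
(e.g. MCF10A) from dispersed, individually motile behavior into cohesive,
directionally coordinated collective migration, while interferon-gamma
raises individual motility without coordination and EGF supports a
dispersed baseline. ccmkit quantifies these behaviors from cell-tracking
tables (track id, frame, x, y per imaging field) and, downstream, helps
prioritize molecular regulators by comparing condition-specific signaling
networks. Everything is exercised against a synthetic-data module with
known ground truth, so each estimator can be validated at desk scale
before being pointed at real tracking exports.

## The four phenotype metrics

For each field the package computes one `PhenotypeScore` row with four
metrics.

**Normalized cell count** (proliferation proxy). Tracked cells per frame
divided by the frame-0 count; reported at the final frame.

**MSD slope** (motility). The mean squared displacement at lag $\tau$ is
pooled over all tracks and all overlapping start points (the
ensemble–time average), using only displacement spans made of consecutive
observed frames — spans crossing a tracking gap are discarded rather than
interpolated. An ordinary least-squares line of MSD against
$\tau \in \{30, 60, \dots, 360\}$ minutes is fit *with* an intercept —
the intercept absorbs static localization noise — and the slope is the
motility readout. For 2D Brownian motion $\mathrm{MSD}(\tau) = 4D\tau$,
so the slope estimates $4D$. Per-track slopes can be obtained by calling
`msd_slope()` on single-track subsets for diagnostics; the headline
number is the pooled fit, the minimal-assumption reading of fitting one
linear model per condition.

**Nearest-neighbor index** (clustering). At each frame the mean distance
from each cell to its 2nd-nearest neighbor is divided by the expected
nearest-neighbor distance under a uniform-random (Poisson) model at the
same density $\rho = n/A$:

$$E[r_k] = \frac{\Gamma(k + 1/2)}{\Gamma(k)\sqrt{\rho\pi}},\qquad
E[r_1] = \frac{1}{2\sqrt{\rho}},\quad E[r_2] = \frac{3}{4\sqrt{\rho}}.$$

Two normalization modes are exposed because the conventional description
of this index mixes ranks: `"first"` (the default) divides the observed
2nd-nearest distance by $E[r_1]$, so complete spatial randomness (CSR)
scores $E[r_2]/E[r_1] = 3/2$; `"matched"` divides by $E[r_2]$ and is the
statistically consistent Clark–Evans-style index that converges to 1
under CSR. Both are deliberately available and every report names the
mode; values well below the CSR reference indicate clustering. No edge
correction is applied (none is conventional for this assay, and the
synthetic validation patterns live in the same window geometry). The
per-frame index is reported both time-averaged and at the final frame;
percent-change comparisons should use the final frame.

**Cosine collectivity.** For every consecutive frame pair and every focal
cell with a nonzero displacement, the 10 nearest cells at the starting
frame are found (among cells that also have a nonzero displacement over
that pair; fewer when the field has fewer, never padded) and the cosine
of the angle between the focal and each neighbor displacement is
computed. The metric is the grand mean over all (focal, neighbor, frame)
triples, which weights every focal cell equally — the alternative of
averaging all 45 neighbor–neighbor pairs is a defensible reading of
"cosine similarity between displacement vectors of the 10 nearest
cells", but the focal-versus-neighbor pairing is what ccmkit implements
and documents. Zero-length displacements are excluded (cosine
undefined) and the excluded count is returned. Independent isotropic
walkers give a mean near 0; shared drift drives the mean toward 1.

**QC jump filter.** Tracks containing any consecutive-frame displacement
strictly greater than 200 px per 30-min interval are treated as tracking
errors. The filter is stated for motility; ccmkit applies it to both
displacement-based metrics (MSD and cosine) but *not* to the
position-based metrics (cell count and nearest-neighbor distance), where
a single mis-link does not invalidate the detections themselves. A 200 px
step is retained — the exclusion is strict.

## Screen statistics

`normalize_to_control()` divides each score by the mean scrambled-control
(siSCR) score within its treatment × metric stratum. Ligand-level
comparisons use `dunnett_vs_control()` — Dunnett's many-to-one procedure
with EGF as control, via single-step multivariate-t adjustment on a
one-way fit. Both adjusted and model-based unadjusted p-values are
returned; the adjustment can only raise a p-value relative to the
unadjusted p from the same fitted model (note that a *pairwise* t-test
with its own two-group variance estimate is a different statistic and
need not sit below the adjusted p in any given sample).
Knockdown-versus-siSCR comparisons use unadjusted two-sided
pooled-variance Student t-tests per treatment, flagged as unadjusted
(Welch is available behind `var_equal = FALSE`); no multiplicity
correction is applied to these, mirroring common screen practice, and
reports label them accordingly.

**Effect enrichment.** To ask whether knockdowns perturb the OSM
phenotype more than the IFNG phenotype, each knockdown's effect is
aggregated as the Euclidean norm of the deviation of its replicate-mean
normalized four-metric vector from 1 (`knockdown_effect_sizes()`;
max-absolute is available as an alternative — the aggregation rule is
configurable precisely because "magnitude of phenotypic change" admits
several formalizations). The OSM/IFNG ratio per knockdown is a success
when above 1, and a one-sided exact binomial test at $p_0 = 0.5$ gives
the enrichment p-value. With 11 of 14 ratios above 1 the exact tail sum
is 0.0287.

A note on calibration: an exact binomial test on $n = 14$ knockdowns is
conservative by discreteness — the largest achievable size below 0.05 is
0.0287, so no implementation can reject at a 5% rate at that screen
size. The calibration checks in the test suite therefore run at a screen
size of 100, where the lattice admits a size of 0.0443, and separately
assert the small-$n$ conservatism (rejection rate ≤ 0.05 at $n = 14$).

**Phenotype PCA.** `phenotype_pca()` centers and unit-scales the metric
columns and decomposes knockdown × treatment replicate means (replicate-
level rows behind `by_replicate = TRUE`, matching designs where
replicates are of interest). Missing entries are imputed by the column
mean and counted. Each loading vector is oriented so its
largest-magnitude entry is positive — an arbitrary but deterministic
convention that removes run-to-run sign flips. Per-treatment mean scores
per component (`treatment_weights`) summarize which ligand dominates an
axis; a knockdown that disrupts OSM-specific behavior (motility up,
collectivity down under OSM only) separates along the component whose
loadings contrast motility against cosine similarity.

## Comparative network rewiring

Two condition networks (SIF edge lists, as emitted by causal-network
inference) are compared node by node. A node's **rewiring score** is the
number of incident edges that would have to be added or removed to turn
its connectivity in one network into its connectivity in the other: the
symmetric difference of its incident-edge sets. Edge identity includes
the relation label and orientation, so a change from activation to
inhibition costs two edits — the faithful reading of "connectivity" for
signed, directed signaling edges. Nodes present in only one network are
scored (their full degree counts as edits), not dropped. The raw edit
count — not the degree-normalized ratio, which is reported alongside —
feeds the prioritization: `weighted_rewiring()` multiplies it by
$\max(\mathrm{LFC}, 0)$ under the OSM condition, so candidates must be
both highly rewired and upregulated; signed and degree-normalized
weightings are available behind flags. Feature integration
(`integrate_features()`) favors proteomic over transcript records for
shared nodes and keeps features with LFC ≥ 1. The threshold is applied
to the signed LFC by default — the literal reading, which excludes
strongly downregulated features; `use_absolute = TRUE` retains them, and
which reading is intended in any given analysis is for the analyst to
decide. Ranking ties break deterministically by raw score then node
name, and `nominate_top_nodes()` returns the top 14 by default.

## What the simulator emulates — and what it does not

`simulate_tracks()` generates 2D tracks at 30-minute intervals over up to
48 h under three additive displacement components per frame: isotropic
Gaussian steps with per-axis variance $2D\Delta t$; fixed-heading
per-cluster drift of $v\,\Delta t$ (headings drawn once per cluster at
t0, producing the persistent co-drift the cosine metric must detect);
and a cohesive pull of $c\,\Delta t$ toward the cluster centroid, capped
at the centroid distance so cells never overshoot (which also makes the
contraction monotone in the noise-free limit). Boundaries reflect — a
confined field, avoiding artificial wrap-around neighbor pairs.
Divisions occur per cell per frame with probability
$\lambda\,\Delta t/60$; a daughter appears co-located with its parent on
the following frame under a new track id, a stated convention since
tracker behavior at mitosis varies. Injected tracking-error jumps are
exactly one per affected track, with an in-bounds destination drawn at
magnitude uniform in (200, 400] px; downstream positions shift rigidly
and are re-folded by the reflecting map, which is 1-Lipschitz, so an
injected jump is always detectable and no legitimate step is amplified
past the threshold.

The presets encode the three ligand regimes: `EGF_like` ($D = 5$
px²/min, no drift or cohesion), `IFNG_like` ($D = 20$, dispersed but
fast), `OSM_like` ($D = 5$, 8 clusters, cohesion 0.4, drift 0.5 px/min),
each with 200 cells, 96 frames, a 1000 px field and a division rate of
0.01 h⁻¹ (≈1.6-fold growth over 48 h, modest as befits treatments with
minimal proliferative effect). These values were fixed once as a
realistic emulation of an epithelial live-imaging experiment; with a
30-min interval, $D = 5$ px²/min gives per-frame steps of ≈17 px per
axis, of the order of a cell diameter.

What the simulator does **not** model: cell shape and exclusion volume,
contact inhibition, chemotactic gradients, track fragmentation and
re-identification errors (other than the single-jump artifact),
apoptosis, and 3D motion. Passing the recovery tests therefore shows the
estimators are correct under the generative assumptions they formalize —
not that real segmentation/tracking output is free of the biases those
missing features introduce.

## Numerical and design notes

- **Determinism.** Every simulator takes an explicit seed and uses an
  isolated RNG scope; a pipeline seed fans out to per-stage seeds by a
  stable string hash (`stage_seed()`), so stages rerun identically in
  isolation. All derived seeds stay below $2^{31}$.
- **Brownian-recovery validation.** The MSD oracle
  $\mathrm{MSD} = 4D\tau$ assumes unconfined diffusion, so recovery
  checks run on a 20000 px field where the reflected fraction is
  negligible; on a 1000 px field confinement visibly flattens MSD at
  long lags, which is physics, not estimator error.
- **Problem sizes.** The validation suite uses 100–500 tracks, 48–96
  frames, point patterns of 2000 points over 20 seeds, 50 simulated
  screens and 2000 null screens for calibration — sizes at which the
  Monte-Carlo error of each check is several times smaller than its
  tolerance.
- **Degenerate inputs.** Fewer than `nn_order + 1` cells make the NN
  index undefined (`NA` with a warning, never extrapolated); all-zero
  displacements make the cosine undefined; a single usable lag fits the
  MSD line through the origin; `compute_phenotype_table()` propagates
  per-metric `NA`s without aborting the table.
- **Tie-breaks.** Nominations order by (weighted score, raw score, node
  name); equal-score nodes therefore list alphabetically.

## Limitations

The nearest-neighbor expectation assumes homogeneous density across the
field; strong density gradients bias the index even without clustering.
The cosine metric measures local alignment, not group persistence or
rotation. The rewiring score treats the inferred networks as fixed
inputs — uncertainty in network inference is not propagated. And the
phenotype t-tests are intentionally unadjusted, so their per-comparison
p-values should be read as screening statistics, not confirmatory ones.
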