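# ccmkit

Quantifies **ligand-induced collective cell migration** from live-cell
tracking tables, and prioritizes candidate molecular regulators by
**comparative network rewiring**. It is written for imaging groups who
already run segmentation + tracking (the package consumes track tables:
track id, frame, x, y per field) and want the downstream quantification,
screen statistics, and network prioritization in one tested toolchain.

Cytokines reshape epithelial motility in distinct ways: one treatment can
leave cells dispersed and slow (EGF-like baseline), another makes single
cells fast but uncoordinated (IFNG-like), and a third drives cohesive,
co-moving clusters — collective cell migration (OSM-like). ccmkit
measures these regimes per imaging field with four metrics:

- **normalized cell count** — cells per frame / cells at T0 (proliferation);
- **MSD slope** — ordinary least-squares slope of the mean squared
  displacement over lags 30 min–6 h; for Brownian motion
  MSD(τ) = 4Dτ, so the slope estimates 4D (motility). Tracks with any
  single-interval jump > 200 px are excluded as tracking errors first;
- **nearest-neighbor index** — mean distance to the 2nd-nearest cell,
  normalized by the Poisson (complete spatial randomness) expectation
  E[r_k] = Γ(k+½)/(Γ(k)·√(ρπ)) at matched density; values below the CSR
  reference indicate clustering;
- **cosine collectivity** — mean cosine similarity between each cell's
  frame-to-frame displacement and those of its 10 nearest neighbors;
  ≈ 0 for independent walkers, → 1 under coordinated drift.

Screen-level statistics (control normalization, Dunnett many-to-one
tests, pairwise t-tests vs the scrambled control, phenotype PCA, and an
exact binomial test for condition-specific effect enrichment) and a
per-node **rewiring score** between two condition networks — the number
of incident edge edits separating a node's connectivity in the two
networks, weighted by log-fold change — complete the pipeline. A
synthetic-data module generates tracks, point patterns, phenotype tables
and network pairs with known ground truth; every estimator is validated
against closed forms or brute-force oracles on that synthetic data.

## Worked example

Simulate a dispersed (EGF-like) and a cohesive (OSM-like) field and
quantify both:

```r
library(ccmkit)
egf <- simulate_tracks(regime_preset("EGF_like", seed = 1L), condition = "EGF_like")
osm <- simulate_tracks(regime_preset("OSM_like", seed = 1L), condition = "OSM_like")
tab <- compute_phenotype_table(list(egf, osm))
tab[, c("condition", "cell_count_norm", "msd_slope", "nn_index", "cosine_similarity")]
#>   condition cell_count_norm msd_slope nn_index cosine_similarity
#> 1  EGF_like            1.65      18.9    1.517           0.00302
#> 2  OSM_like            1.64      34.2    0.441           0.24130
```

Counts are similar (both regimes divide at the same rate). The EGF-like
field reads as spatially random (nn_index ≈ 1.5, the CSR reference value
in the default "first" normalization mode) with uncoordinated motion
(cosine ≈ 0); the OSM-like field is strongly clustered (0.44) and
coordinated (0.24). The EGF-like MSD slope ≈ 19 px²/min matches 4D for
the preset's D = 5 px²/min, slightly flattened by field confinement.

Rank nodes by rewiring between two condition networks (bundled synthetic
demo files):

```r
net_osm  <- read_sif(system.file("extdata", "osm_network_synthetic.sif",
                                 package = "ccmkit"), condition = "OSM")
net_ifng <- read_sif(system.file("extdata", "ifng_network_synthetic.sif",
                                 package = "ccmkit"), condition = "IFNG")
feats <- read.delim(system.file("extdata", "features_osm_synthetic.tsv",
                                package = "ccmkit"))
ranked <- weighted_rewiring(net_osm, net_ifng, integrate_features(feats))
head(ranked, 3)
#>    node raw_rewiring degree_union normalized_rewiring lfc weighted_score rank
#> 1 STAT3            4            5                 0.8 1.8            7.2    1
#> 2 HIF1A            3            3                 1.0 2.1            6.3    2
#> 3   OSM            1            1                 1.0 3.0            3.0    3
nominate_top_nodes(ranked, 3)
#> [1] "STAT3" "HIF1A" "OSM"
```

`raw_rewiring` is the count of incident edge edits (relation label and
orientation included in edge identity) needed to transform the node's
connectivity from one condition to the other; the weighted score
multiplies it by max(LFC, 0) so nominated nodes are both highly rewired
and upregulated.

The full simulate → metrics → stats → rewire pipeline, with a manifest
of seeds and file checksums:

```r
run_ccm_pipeline("out_demo", seed = 1L)
```

or from a shell via `inst/scripts/ccm-pipeline.R`.

## Package layout

- `R/simkit.R` — synthetic tracks, point patterns, phenotype tables,
  network pairs with ground truth
- `R/trackio.R` — track-table I/O and validation
- `R/phenometrics.R` — the four phenotype metrics and QC
- `R/screenstats.R` — normalization, Dunnett, t-tests, PCA, enrichment
- `R/netrewire.R` — SIF I/O, feature integration, rewiring, nomination
- `R/pipeline.R` — end-to-end orchestration with seed fan-out
- `vignettes/quantifying-collective-migration.Rmd` — models, parameters,
  assumptions, design decisions, limitations
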