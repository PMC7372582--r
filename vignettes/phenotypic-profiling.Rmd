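---
title: "Phenotypic profiling of a multi-cell-line panel: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phenotypic profiling of a multi-cell-line panel: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(phenoscreen)
library(dplyr)
```

## The analysis problem

phenoscreen implements the analysis arc of an image-based (Cell Painting)
small-molecule screen run across a panel of cancer cell lines — here an
esophageal adenocarcinoma (EAC) panel of six cancer lines plus two
tissue-matched, non-transformed control lines (a Barrett's esophagus line
and a squamous esophageal line). The raw material is a CellProfiler-style
table of several hundred morphology features per segmented cell. From it
the pipeline produces:

1. **Well-level phenotypic profiles** — normalized, feature-selected
   fingerprints of each compound treatment;
2. **Mechanism-of-action (MoA) calls** — a balanced random forest trained
   on an annotated reference library dosed at 0.1/1/10 µM;
3. **Hit lists** — compounds with strong morphological activity
   (Mahalanobis distance from the DMSO controls in PCA space) or strong
   viability effects (nuclei-count z-scores), filtered by
   cancer-versus-control *selectivity* rules;
4. **Panel response clustering** — Spearman-distance, complete-linkage
   dendrograms of how the cell lines respond to the active compounds.

No imaging data ships with the package. Instead the `synth` generator
simulates whole screens with known ground truth, which is how every stage
is validated.

## Preprocessing model

The chain is fixed, in this order:

| stage | operation | default |
|---|---|---|
| 1 | median of cells → image profile | — |
| 2 | QC: drop images with `n_cells < min_cells` or flagged | `min_cells = 20` |
| 3 | divide by the plate's DMSO median, per feature | — |
| 4 | drop NA / zero- and near-zero-variance / correlated features | `freq_cut = 19`, `unique_cut = 0.1`, `|r| > 0.95` |
| 5 | global z-scaling | — |
| 6 | median of images → well profile | — |

Notes on the open choices:

* **Aggregation statistic.** Medians at both aggregation levels: the
  image level is explicitly median-based in standard practice and the
  well level follows for consistency and robustness to the occasional
  segmentation artifact.
* **QC boundary.** `n_cells < 20` is strict: an image with exactly 20
  cells is kept.
* **Division by the DMSO median** makes the per-plate DMSO median of
  every retained feature exactly 1, which removes multiplicative plate
  effects exactly (a property the generator's plate-effect model is
  designed to exercise). A feature whose DMSO median is 0 on any plate is
  dropped rather than rescued with an epsilon — division artifacts would
  otherwise dominate every downstream distance.
* **Near-zero-variance parameters** follow the conventional 95/5
  frequency-ratio and 10% unique-fraction defaults; the procedure's name
  fixes its shape but not its constants.
* **Correlation pruning** is greedy: at each step the most correlated
  violating pair is located and the member with the larger mean absolute
  correlation to everything else is removed (name order breaks ties, so
  the result is deterministic). Pearson correlation is used at this step;
  selection runs before scaling, which is immaterial because Pearson
  correlation is affine-invariant.
* **Scaling** is the standard z-transform (subtract mean, then divide by
  SD) — the two operations are sometimes listed in the other order in
  prose descriptions, but only the conventional transform makes the
  post-hoc mean-0/SD-1 contract hold.
* **Per-line statistics.** Feature selection, scaling, PCA and the DMSO
  reference are all computed per cell line: each line of the panel is an
  independently analysable assay, and lines differ morphologically enough
  that pooled feature selection would be dominated by between-line
  variance. Cross-line work (classifier transfer) intersects the
  per-line feature sets (`harmonize_features()`).

## The MoA classifier

A random forest with `ntree = 500`, class-stratified bootstraps, and a
per-class sample size equal to the smallest class (so imbalanced
reference libraries cannot bias the votes). All three screening
concentrations of a reference compound are pooled under one class label;
DMSO wells form their own class (the reference embedding plots controls
alongside the eight classes, and including them gives the classifier an
explicit "inactive" pole). Class probabilities are tree-vote fractions.
Two evaluations are reported, because they answer different questions:

* **OOB error** (per line) — internal generalization on the line the
  model was trained on;
* **Leave-one-cell-line-out** — a model trained on the other EAC lines
  is tested on the held-out line; this measures whether mechanism
  signatures transfer to a line the model has never seen.

## Hit calling

**Phenotypic arm.** Well profiles are projected onto the first 15
principal components (typically ~90% of the variance of a
feature-selected profile; a `variance_target` mode is available), and
each well's squared Mahalanobis distance
\(D^2 = (x-\mu)^\top \Sigma^{-1} (x-\mu)\) from the DMSO score
distribution is computed via Cholesky triangular solves — the covariance
is never inverted explicitly. The squared-distance convention is the
package's working scale (consistent with thresholds in the thousands on
screen-scale data); `squared = FALSE` gives the root if needed.

Because any absolute threshold is data-scale-specific, the default is
calibration from the null at the 99.9th percentile. Three calibrations
exist and they are *not* interchangeable:

* `"f"` (default): with \(\mu, \Sigma\) estimated from \(n\) DMSO wells
  in \(p\) dimensions, the squared distance of a *new* null well follows
  \(\tfrac{p(n-1)(n+1)}{n(n-p)} F_{p,\,n-p}\). At \(n \approx 5p\) the
  chi-squared tail understates this substantially (we measured inert
  false-positive rates of ~5% instead of 0.1% before adopting the F
  form).
* `"chisq"`: the large-\(n\) limit, adequate when DMSO wells are
  plentiful.
* `"empirical"`: the DMSO wells' own distances are *in-sample* (biased
  small), so this needs many wells to be trustworthy.

A compound is a per-line hit when its distance strictly exceeds the
threshold, and *selective* when it hits in at least `min_eac_lines = 2`
EAC lines and in neither control line.

**Viability arm.** Per-well nuclei counts are z-scored against the
plate's DMSO wells; replicate wells are summarized by the median z. A
line-level hit is \(z \le -3\); it counts toward selectivity only if at
least one control line shows a gap \(z_{ctrl} - z_{EAC} \ge 2\) (so an
EAC z of −3 needs a control at −1 or better). A compound is selective
with ≥ 2 qualifying EAC lines. Wells whose images were removed by QC are
excluded from this arm — artifact fields of view corrupt total counts —
and compounds missing a control-line z are excluded from selectivity and
logged.

A known limitation of the literal *difference* margin: when a compound
kills everything deeply (say z ≈ −6 panel-wide), between-line noise can
produce a ≥ 2 gap and admit a non-selective cytotoxin. The worked
boundary example (EAC −3 / control −1) sits in the regime the rule was
designed for; very deep kills are better triaged by the phenotypic arm's
control-line exclusion, which the final union inherits.

The screen's hit list is the union of both selective sets with
provenance flags (`both`, `phenotypic_only`, `viability_only`).

## Response clustering and embeddings

Per-compound response vectors (z-scores or Mahalanobis distances across
the panel) are centered and scaled per compound, so clustering compares
response *patterns*, not magnitudes; rows without variance are excluded.
Cell-line distance is \(1 - \rho_{Spearman}\) (range 0–2) and linkage is
complete, whose merge heights are non-decreasing. Dendrograms export to
Newick (via ape) and JSON.

t-SNE is provided for visualization as an exact \(O(n^2)\)
implementation (bisection-calibrated perplexity, momentum gradient
descent with early exaggeration, deterministic given a seed; defaults
perplexity 30, 1000 iterations). It is intended for a few hundred to a
few thousand wells and is never used quantitatively downstream.
Dose-response trajectories project a query compound dose by dose into
the reference PCA space and report distance to the DMSO centroid plus
the nearest reference class by centroid distance — the quantitative
version of "moves from the DMSO cloud into the DNA-damage cluster".

## The synthetic screen generator

`generate_screen()` draws per-cell features from a log-normal model: for
feature \(f\) of a cell in well \(w\), plate \(p\), line \(l\),

\[
\log x = \mu_{lf} + \pi_{pf} + \delta_{wf}
       + s_{kf}\, g(d)\, e\, \sigma_c + \varepsilon,
\qquad \varepsilon \sim N(0, \sigma_c^2),
\]

with line baseline \(\mu\), per-plate multiplicative plate effect
\(\pi \sim N(0, 0.15^2)\), per-well effect \(\delta \sim N(0, 0.1^2)\),
cell noise \(\sigma_c = 0.3\), and a *sparse signed class signature*
\(s_k\) (10% of features at ±1, per class, not forced disjoint — the
phenotype of a mechanism is compartment-localized, so signatures should
be sparse and classification non-trivial). \(e\) is `effect_size` in
units of \(\sigma_c\) (default 2), and \(g(d)\) scales the signature by
dose: 0.25/0.6/1 at 0.1/1/10 µM. The dose shape is a modeling choice —
no dose-response model is inherited from any screen — and the
multiplicative form is the simplest one that makes class probability
rise with dose.

Cells per image are Poisson around `cells_per_image_mean`; a configured
fraction of images is forced to 0–19 cells (artifact images, below the
QC threshold by construction). Per-well nuclei counts are the summed
cells of that well's images, and truly active compounds reduce the
Poisson mean by `viability_kill` × \(g(d)\) in their active lines only —
the same generator drives both the morphology and the viability arm.
Planted *selective* actives are active in ≥ 2 EAC lines and no control;
optional *broad* actives hit every line and must be rejected by the
selectivity rules.

Defaults mirror the emulated assay geometry: 8 lines (6 EAC + 2
control), 733 features, 384-well plates, ~300 cells per field, 5 fields
per well, reference library of 7 mechanistic classes × 5 compounds at 3
doses × 2 replicates with DMSO as the 8th class, and a single-dose
screening library of 500 compounds with 20 planted selective actives.

**What the generator does not emulate** — and hence what passing tests
do *not* establish about real screens: correlated feature blocks within
compartments (features are conditionally independent given the well),
spatial plate gradients (edge effects), segmentation errors that bias
features rather than counts, batch drift over imaging time, and
phenotypes that change shape rather than magnitude with dose.

## Validation conditions and numerical choices

Tests and the acceptance suite run the generator at reduced sizes chosen
for statistical adequacy (all conditions below are package choices,
stated here so they are reproducible):

* **Null calibration**: single line, 60 features, 250 inert compounds,
  ~346 DMSO wells, 15 components, 10 seeds. The DMSO count matters: with
  \(\Sigma\) estimated from \(n\) wells, out-of-sample \(D^2\) has mean
  \(\approx p\,\tfrac{n-1}{n-p-2}\), so \(n\) must be several hundred for
  the mean to sit within 10% of \(p\); at \(n = 346, p = 15\) the
  expected inflation is ~5%.
* **Planted-hit recovery**: the full 8-line panel, 500 screen compounds,
  20 selective actives, effect 2.0 SD, 100 features, 60 cells × 2 fields
  per well, F-calibrated thresholds at the 99.9th percentile.
* **Classifier**: one line at the full 733 features (OOB error ≤ 10%;
  permuted labels land within 3 SE of the 12.5% chance level);
  transfer uses 6 EAC lines at 150 features, where every
  leave-one-line-out fold must clear 3× chance.
* **Clustering**: 120-compound screens with 30 selective + 15 broad
  actives; the two control lines — which share the "sensitive to broad
  cytotoxins, resistant to EAC-selective actives" profile — must form
  their own clade in ≥ 9/10 seeds.

Other numerical conventions: degenerate inputs fail loudly (a plate
without surviving DMSO images, a zero-variance feature reaching the
scaler, a singular DMSO covariance — with a pointer to Ledoit–Wolf
shrinkage toward a scaled identity, available when DMSO wells are
scarce); correlation and clustering tie-breaks are lexicographic so
reruns are bit-identical; the pipeline's single seed fans out to
per-stage derived seeds so stages can be rerun in isolation.

## A worked miniature run

```{r run, eval = FALSE}
cfg <- run_config(
  screen = screen_config(n_features = 100, include_reference = FALSE,
                         n_screen_compounds = 500, n_selective = 20,
                         cells_per_image_mean = 60, n_sites = 2),
  seed = 71)
run <- run_pipeline(cfg)
run$report$recovery
```

On this configuration the combined hit list recovers all 20 planted
selective compounds with no false discoveries (sensitivity 1.0, FDR 0);
the same numbers are recomputed by the test suite. The full-scale
defaults (733 features, 300 cells × 5 fields) produce multi-gigabyte
cell tables and are intended for explicit, chunked use rather than the
quick-start path.

## Known limitations

* The independence of features in the generator makes feature selection
  easier than on real Cell Painting data, where correlated blocks are
  the norm; the correlation filter is exercised mainly by the duplicated
  and latent-factor fixtures in the tests.
* The viability margin rule admits deep pan-cytotoxins in principle (see
  above); the union with the phenotypic arm mitigates but does not
  remove this.
* t-SNE here is exact and quadratic; embedding tens of thousands of
  wells needs a Barnes–Hut implementation instead.
* Absolute Mahalanobis thresholds (e.g. 1500) only transfer between
  screens on the same feature scale and PCA dimensionality; use the
  null-calibrated mode anywhere else.
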