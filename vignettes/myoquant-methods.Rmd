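---
title: "Quantifying myoblast fusion and cell shape: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying myoblast fusion and cell shape: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`myoquant` quantifies myogenic differentiation assays imaged by
multi-channel fluorescence microscopy: how many nuclei have fused into
multinucleated, myosin-heavy-chain (MyHC) expressing myotubes, how
elongated cells are, what fraction of cells carries a proliferation or
transduction marker, and whether treatments (gene knockdown, kinase
inhibitors such as Sunitinib, dose gradients) shift those quantities.
This vignette is the package's methods account: the image-analysis
procedure, the statistical model family, the synthetic-data generator
that stands in for undeposited raw images, and the numerical choices
behind each.

## The assay quantities

**Fusion index.** The fraction of all nuclei in a field of view that sit
inside MyHC-positive cells containing at least two nuclei. `fusion_index()`
returns the raw numerator and denominator counts alongside the ratio so
that the counts — not the ratio — feed the binomial models. A gate marker
(typically GFP marking transduced cells) restricts the numerator; the
denominator stays all nuclei in the field by default, with a `"gated"`
switch for the alternative convention.

**Myotube size classes.** Myotubes are binned by nuclei per myotube into
inclusive classes: small (2–4), medium (5–9), large (10–24) and very
large (25+). The classes partition all counts from 2 upwards; a count
below 2 is not a myotube and is an error.

**Marker fractions.** `marker_fraction()` returns `k` positive of `n`
gated cells; an empty gate yields a missing value with a warning, never a
silent zero.

**Engraftment.** `engraftment_summary()` aggregates per-section counts of
donor (human LAMIN A/C-positive) nuclei inside or outside host myofibres
and donor SPECTRIN-positive fibres into per-muscle totals, per-section
means, and a mean profile along the sectioned muscle.

## Image analysis

`segment_frame()` implements the procedure in five steps.

1. **Band-pass pre-processing** (`bandpass_preprocess()`). Low-frequency
   background staining is estimated by a Gaussian blur at `low_sigma`
   (default 50 px, chosen large relative to a cell) and subtracted,
   clipping at zero; frames smaller than the filter support are
   edge-replicate padded first. High-intensity non-specific artifacts are
   then removed by a size-and-morphology rule: pixels above the
   `artifact_min_intensity` quantile (default 0.999) mark candidates, and
   the *containing* foreground object is zeroed when it is small
   (area at most `artifact_max_area`, default 30 px², below a nucleus
   cross-section) and blob-like (solidity > 0.9). Operating on the
   containing object rather than the thresholded fragment matters: a
   noise-bright pixel inside a genuine nucleus must not punch a hole in
   it, which would later fragment the watershed.
2. **Nucleus detection** (`detect_nuclei()`). Global Otsu threshold on
   the pre-processed nuclear (DAPI) channel, hole filling, watershed on
   the distance transform to split touching nuclei, and a minimum-area
   filter (default 20 px²). Labels follow raster-scan order of each
   component's first pixel, so output is deterministic.
3. **Voronoi segregation** (`voronoi_segment_cells()`). Cells with
   overlapping cytoplasm are segregated using the nuclei as anchors:
   every cytoplasm pixel takes the label of the nearest nucleus, with
   distance measured *geodesically* — along 8-connected paths inside the
   cytoplasm mask (multi-source Dijkstra, compiled) — so touching cells
   split along the equidistant ridge but disconnected cytoplasm is never
   bridged across background. Ties go to the lower nucleus label;
   components containing no nucleus are dropped.
4. **Myotube grouping.** A per-nucleus Voronoi split is correct for
   mononucleate myoblasts but would dismember a myotube into one cell
   per nucleus. When a `myotube_marker` channel is available (default
   `"MyHC"`), each connected cytoplasm component is classified on it:
   positive components are kept whole as single multinucleate cells,
   negative components are Voronoi-split. With `myotube_marker = NULL`
   the procedure is the pure shape-assay variant.
5. **Per-cell measurement.** Nuclei are assigned to the cell occupying
   their centroid pixel (fallback: majority label over the nucleus mask;
   a nucleus over background is flagged unassigned and conserved in the
   diagnostics). Marker positivity is the mean in-cell intensity against
   an Otsu threshold over per-cell means, or a fixed value.

**Eccentricity.** For a cell's pixel set with covariance eigenvalues
$\lambda_1 \ge \lambda_2$, eccentricity is
$e = \sqrt{1 - \lambda_2/\lambda_1}$: 0 for a disk, approaching 1 for a
line, and invariant to translation, rotation and intensity scaling. Note
the direction: some descriptions of this assay run the scale the other
way (circle = 1, line = 0); this package uses the standard moments
convention (circle = 0), which matches the underlying image-analysis
libraries. Any monotone statement about elongation is unaffected, only
the sign of effects flips. The frame summary is the *unweighted* mean
over retained cells — non-border, above `min_cell_area` — since nothing
in the assay definition suggests area weighting; border cells are
excluded because their shape is truncated (configurable).

## Statistical models

All fits are implemented in the package; `stats::glm` and `lme4::glmer`
appear only as independent cross-checks in the test suite.

**Factorial logistic models** (`fit_binomial_glm()`). Treatment-coded
designs built by `build_design()`: intercept $\mu$ (the reference
condition), main effects $\beta$ per factor, interaction products, an
optional dose slope $c$ (linear in concentration on the logit scale) and
an optional batch factor, so the linear predictor is
$y = \mu + \sum_j \beta_j \delta_j + c \cdot \text{dose}$ with
$\delta_j \in \{0, 1\}$ indicating whether the effect is present.
Fitting is iteratively reweighted least squares run to
$\max|\Delta\beta| < 10^{-10}$ (at most 100 iterations); the covariance
is the inverse Fisher information. Grouped (successes/trials) and
expanded Bernoulli data give identical estimates. Complete separation is
detected as coefficients diverging beyond |30| on the logit scale and is
an explicit error, as is non-convergence (with the step trace).

**Quasi-Poisson count models** (`fit_quasipoisson_glm()`). Log-link IRLS
with Poisson working weights; the dispersion
$\hat\varphi = X^2_{\text{Pearson}} / (n - p)$ scales the standard
errors, and coefficient tests use the $t$ distribution on $n - p$
degrees of freedom. Used for cell counts across conditions, where
variance routinely exceeds the mean.

**Random-intercept logistic models** (`fit_binomial_glmm()`). Biological
replication (mouse, or independent experiment) enters as a scalar
Gaussian random intercept $u_g \sim N(0, \sigma_g^2)$. The marginal
likelihood integrates each group's Bernoulli likelihood over $u_g$ by
*adaptive Gauss–Hermite quadrature*: 20 nodes by default, centred and
scaled at the Laplace mode of each group's integrand, which is accurate
for binary data with few groups where penalised quasi-likelihood is
biased. Nodes and weights come from the Golub–Welsch
eigen-decomposition. The likelihood is maximised over
$(\beta, \log\sigma_g)$ by BFGS, started at the fixed-effects fit;
rows with identical design within a group are aggregated first, which
makes each likelihood evaluation cheap without changing it. A boundary
solution ($\sigma_g < 10^{-8}$, or no likelihood gain over the
fixed-effects model) collapses to the plain GLM with $\sigma_g = 0$.
Standard errors come from the observed information (numerical Hessian),
fixed-effect block after inversion.

**Linear models** (`fit_linear_model()`). Ordinary least squares for
continuous responses (per-frame mean eccentricity against dose), with
approximate two-sided $p$-values from the $t$ statistic on $n - p$
degrees of freedom.

**Reporting** (`effect_report()`). Per term: odds ratio (or rate ratio)
$e^{\hat\beta}$ with the Wald interval
$e^{\hat\beta \pm 1.96\,\mathrm{SE}}$ — Wald rather than profile
intervals, matching the estimate ± SE convention of the tables this
reporting style follows. Per condition: the fitted response-scale value
from the summed coefficients. By convention the intercept's variance
contribution is *omitted* from non-baseline condition intervals
(`omit_intercept_error = TRUE`), so treatment intervals reflect
treatment uncertainty only and the baseline interval is unchanged; the
full delta-method interval is available by flag. No multiplicity
correction is applied anywhere: each model's $p$-values are reported as
computed, and readers should treat families of tests accordingly.

## The synthetic-data generator

No raw micrographs or per-cell tables are publicly deposited for this
assay family, so `generate_scene()` produces fields with full ground
truth that exercise every downstream stage:

- **Cells** are non-overlapping filled ellipses. Mononucleate myoblasts
  draw true eccentricity from a truncated normal
  (`eccentricity_mean`/`eccentricity_sd`) with semi-minor axis 10–16 px
  (at least 10 px, where rasterised moments agree with the analytic
  eccentricity to within 0.02). Myotubes are elongated ellipses
  (aspect at least 4:1) holding $k$ nuclei in one or two rows along the
  major axis, $k$ drawn from the four size classes by
  `nuclei_count_weights` (uniform within class, very-large capped at
  40). Non-overlap plus a 2 px margin keeps the truth unambiguous;
  placement is rejection sampling, largest cells first, with an explicit
  error after 1000 failed attempts.
- **Channels** (16-bit, full scale 65535): nuclei as 4 px-radius disks
  at 32000; cytoplasm ellipses at 18000 with ±15% per-cell brightness
  jitter; one channel per marker, rendered on positive cells at 22000.
  A marker named `MyHC` is forced positive on myotubes (they express it
  by definition); other markers are independent Bernoulli draws, so
  their truth-table frequencies converge to `marker_probs`.
- **Corruption**: a smooth two-axis cosine background gradient of
  relative amplitude `background_amplitude`; `speckle_density` saturated
  3–9 px speckles per megapixel; additive Gaussian noise (`noise_sd`).
  These are chosen so that the low-pass and artifact-removal halves of
  the pre-processing are *each* necessary: omitting the background
  subtraction breaks Otsu thresholds, omitting speckle removal creates
  false nuclei.
- **Reproducibility**: geometry, marker states and noise come from three
  sub-streams derived from the single seed, so changing the noise level
  never moves a cell.

The default study conditions for the recovery benchmarks are 100 cells
on a 640×640 field, background amplitude 0.3, 5 speckles per megapixel
and noise SD 300 — a dense, visibly corrupted field on which the
pipeline still recovers nucleus counts within 2%, nucleus-to-cell
assignment above 98% and the fusion index within 0.02 of truth.

`generate_outcomes()` and `generate_counts()` simulate the statistical
layer directly: Bernoulli outcomes under the factorial/dose logistic
model with group random intercepts, and counts with variance
`dispersion × mean` via a gamma–Poisson mixture (exactly Poisson at
dispersion 1).

What the generator does **not** emulate: point-spread-function optics,
3-D structure, chromatic shift, uneven focus, touching or overlapping
cells, and real myotube morphology (branching, curvature). Passing the
recovery benchmarks therefore demonstrates the internal consistency of
the pipeline under controlled corruption, not segmentation performance
on arbitrary real micrographs.

## Dose-response recovery design

End-to-end recovery of a dose effect is checked by programming a
per-nucleus fusion probability $p(d) = \mathrm{logit}^{-1}(\mu + c d +
u_g)$ and inverting the generator's expected fusion index to get the
myotube fraction: $f = p / (p + (1 - p) E[k])$ with $E[k]$ the expected
nuclei per myotube (`myotube_fraction_for_fusion()`), so the logit of
the expected fusion index is exactly linear in dose. Because nuclei
arrive in myotube-sized clusters, per-frame fusion counts are
overdispersed relative to independent Bernoulli nuclei; the recovery
model therefore includes a frame-level ("experiment") random intercept,
which absorbs that clustering honestly instead of understating the dose
coefficient's standard error. Three replicate frames per dose-by-group
cell (4 doses × 3 groups) put the truth within two standard errors of
the estimate.

## Numerical choices and edge cases

- Coordinates are 0-based `(row, col)` in all per-cell output.
- Otsu thresholds use a 256-bin histogram over the observed range.
- Voronoi distances are chamfer-metric (1, √2) geodesics; ties break to
  the lower label for determinism.
- Eccentricity requires at least 5 pixels; collinear regions
  ($\lambda_2 = 0$) are an error, as the ratio is undefined at 1.
- Zero detected nuclei, zero retained cells and empty marker gates warn
  and return missing values; zero *total* nuclei for a fusion index is
  an error naming the frame.
- GLMM quadrature is validated by node-count stability (20 vs 40 nodes
  agree within $10^{-6}$ in log-likelihood).
- Every simulation entry point takes an explicit integer seed; the
  pipeline derives per-frame seeds from its single run seed.

## Known limitations

- One scalar random intercept; no crossed or nested random effects.
- Marker classification by Otsu over per-cell means assumes both classes
  are present in the frame; single-class frames need a fixed threshold.
- The myotube/myoblast distinction rests on the differentiation marker;
  without it, multinucleate objects are split per nucleus.
- Physical pixel size is carried as metadata only; no micron-scale
  calibration is applied.
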