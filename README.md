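# myoquant

Quantitative analysis of myogenic differentiation assays from
multi-channel fluorescence microscopy, for researchers studying muscle
stem (satellite) cell biology and disorders such as facioscapulohumeral
muscular dystrophy (FSHD), where DUX4 expression suppresses myoblast
differentiation and candidate rescues (gene knockdown, tyrosine kinase
inhibitors like Sunitinib) are screened by imaging.

The package covers the full analysis path:

- **Synthetic scenes with ground truth** (`generate_scene()`): fields of
  elliptical myoblasts and multinucleated myotubes with nuclear (DAPI),
  cytoplasm (Tubulin-like) and marker (MyHC, EdU, GFP, ...) channels,
  corrupted by background gradients, saturated speckles and noise — so
  every downstream stage is testable without any image download.
- **Segmentation** (`segment_frame()`): band-pass pre-processing,
  Otsu + watershed nucleus detection, nucleus-anchored *geodesic Voronoi*
  segregation of overlapping cytoplasm, marker-gated myotube grouping,
  and per-cell moments-based eccentricity
  `e = sqrt(1 - lambda2/lambda1)` (0 = disk, → 1 = line).
- **Assay metrics** (`fusion_index()`, `classify_myotube_size()`,
  `marker_fraction()`, `engraftment_summary()`): the fusion index is the
  ratio of nuclei inside MyHC-positive cells with ≥ 2 nuclei to all
  nuclei in the field; myotubes are classed small (2–4), medium (5–9),
  large (10–24), very large (25+) nuclei.
- **Statistics, implemented from first principles** (`fit_model()`):
  factorial/dose logistic models
  `y = mu + sum(beta_j * delta_j) + c * dose` fitted by IRLS;
  quasi-Poisson count models with Pearson dispersion; random-intercept
  logistic mixed models (per-mouse or per-experiment) fitted by adaptive
  Gauss–Hermite quadrature; linear models with approximate-t p-values;
  odds-ratio effect reports with the intercept-error-omitted interval
  convention. `stats::glm` / `lme4::glmer` are used only as independent
  cross-checks in the tests.

Everything is tidyverse-shaped: per-cell and per-frame results are
tibbles, fitted models have `tidy()` / `glance()` methods, and result
types have `autoplot()` / `plot_*()` views.

## Worked example

Simulate a corrupted field, segment it, and score fusion:

```r
library(myoquant)

sc <- generate_scene(scene_params(
  n_cells = 100, myotube_fraction = 0.15, background_amplitude = 0.3,
  speckle_density = 5, noise_sd = 300, seed = 42))
sc
#> <myo_scene> 640x640 px, 100 cells (12 myotubes), 145 nuclei, channels: dapi, cyto, MyHC

seg <- segment_frame(sc$frame)
summarise_frame(seg)
#> # A tibble: 1 × 8
#>   condition  dose group frame_id n_cells n_retained n_nuclei mean_eccentricity
#> 1 control       0 g1    frame_1      100        100      145             0.628

fusion_index(dplyr::filter(seg$cells, retained))
#> # A tibble: 1 × 3
#>   fused_nuclei total_nuclei fusion_index
#> 1           57          145        0.393
```

The pipeline recovered all 145 true nuclei and the exact truth-table
fusion index (57/145): `fusion_index(sc$cells)` returns the same counts.
The frame mean eccentricity (0.628) reflects the default programmed cell
shape distribution (mean 0.6) plus the elongated myotubes.

Fit a mixed logistic model to simulated per-cell outcomes — here a
factor that lowers the odds of differentiation, with a per-mouse random
intercept:

```r
d <- generate_outcomes(outcome_spec(
  factors = "DUX4", mu = 0.4, beta = c(DUX4 = -1.2), n_groups = 3,
  random_sd = 0.3, cells_per_group_per_condition = 400, seed = 42))
fit <- fit_model(d, model_spec("binomial_bernoulli", "outcome",
                               factors = "DUX4",
                               random_intercept = "mouse"))
tidy(fit)
#> # A tibble: 2 × 5
#>   term        estimate std.error statistic  p.value
#> 1 (Intercept)    0.605    0.116       5.22 1.84e- 7
#> 2 DUX4          -1.21     0.0857    -14.1  5.75e-45

effect_report(fit)$conditions
#> # A tibble: 2 × 6
#>   condition linear_predictor     se fitted conf_low conf_high
#> 1 baseline             0.605 0.116   0.647    0.593     0.697
#> 2 DUX4                -0.601 0.0857  0.354    0.317     0.393
```

The programmed effect (−1.2 log-odds, intercept 0.4) is recovered within
one standard error, and the condition table gives the fitted
probabilities with Wald intervals (intercept error omitted for the
non-baseline condition, per the reporting convention; set
`omit_intercept_error = FALSE` for full delta-method intervals).

`run_pipeline()` chains simulate → segment → metrics → fit from a single
seeded configuration (R list or YAML) and writes TIFFs, truth and
per-cell CSVs, an effect-report JSON and a reproducibility manifest.

See `vignettes/myoquant-methods.Rmd` for the models, their assumptions,
and every numerical choice.

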