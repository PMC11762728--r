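---
title: "Methods: diversification rates and lineage ages along elevational gradients"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: diversification rates and lineage ages along elevational gradients}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(divelev)
```

## The question and the pipeline

Mountain transects divide elevation into discrete bands and record which
genera occur in each band. Given such occurrence records, a time-calibrated
genus-level phylogeny, per-genus extant species counts, and a way to assign
climate values to bands, one can ask how the *evolutionary tempo* of a clade
is arranged along elevational and thermal gradients: are low (warm)
elevations occupied by rapidly diversifying young lineages, and are high
(cold) elevations occupied by old, slowly diversifying ones?

`divelev` implements that analysis as a chain of small, separately testable
stages:

1. **phylogeny** — read, validate, and prune the chronogram; extract stem ages;
2. **rates** — per-genus net diversification rates from species counts and stem ages;
3. **gradients** — per-band means of rates and ages (DivElev, AgeElev), richness, and relative scales;
4. **climate** — per-gradient elevation-to-Bioclim calibration models;
5. **regress** — beta regression for DivElev and an identity-link Poisson-variance GLM for AgeElev, with likelihood-ratio and AICc model comparison;
6. **comparative** — phylogenetic signal (Pagel's lambda) in genus thermal preference, and Brownian-motion ancestral state reconstruction;
7. **synth** — a seeded generator producing all inputs with known ground truth;
8. **pipeline** — orchestration (`run_config()`, `run_pipeline()`, `report_bundle()`).

## Net diversification rates

For a genus with `n` extant species and stem age `t` (Ma), the
maximum-likelihood net diversification rate under a constant-rate
birth–death model with relative extinction `eps = mu/lambda` is

    r_hat = log(n (1 - eps) + eps) / t

(`ms_stem_rate()`). The default `eps = 0` reduces to `log(n)/t`, which is 0
exactly for monospecific genera. The logarithm is natural — that is what the
ML derivation gives — but the base is exposed as an argument so the
sensitivity of reported rates to that convention can be audited.

Stem age is defined as the depth of the tip's parent node on the ultrametric
tree: the time since the genus split from its sister lineage. This is the
standard convention when per-genus ages are read off a dated tree; crown
ages would require sampling below the genus level, which genus-level
chronograms do not provide.

`rate_distribution_summary()` reports the rate histogram in the bins
`[0, 0.1)`, `[0.1, 0.2]`, `(0.2, Inf)` together with the count of exact
zeros. Whether the middle bin is closed on both sides is a reporting
convention, not a mathematical fact, so the half-open variant is reported
alongside whenever the two disagree.

## Band statistics

DivElev and AgeElev are *unweighted arithmetic means* of per-genus rate and
stem age over the **distinct** genera recorded in one band of one gradient
(`band_stats()`, default `per_genus = TRUE`). The alternative — averaging
over raw records, so that a genus recorded twice counts twice — is kept as
`per_genus = FALSE` because both variants are legitimate and comparing them
shows whether band means are driven by repeated records of extreme genera.
`dedupe()` performs the one-record-per-genus-per-band reduction explicitly.

Relative elevation (`rel_elev`) is a band's elevation as a percentage of the
highest occupied band on its gradient; relative richness (`rel_rich`) is the
band's genus richness as a percentage of the gradient's maximum. Both are
computed within gradient × dataset class, so gradients of very different
extents become comparable.

Group comparisons across the all / epiphyte / non-epiphyte datasets use the
classical one-way ANOVA F (`one_way_anova()`), followed — only when the
ANOVA is significant — by Tukey's honest significant differences
(`tukey_hsd()`). The Tukey step is implemented as Tukey–Kramer (via
`stats::TukeyHSD`) because the three dataset classes have unequal numbers of
band means. Degenerate corners are fixed by definition rather than left to
floating point: zero within-group variance with unequal means gives
`F = Inf, p = 0`; fully identical data give `F = 0, p = 1`.

## Climate calibration

Band climate values come from per-gradient polynomial regressions of a
Bioclim variable on elevation (`fit_lapse_model()`). Temperature variables
(Bio1, Bio5, Bio6) are fitted as straight lapse lines and always accepted:
temperature declines essentially linearly with elevation at transect scale.
Precipitation (Bio12–Bio19) can be strongly non-monotonic, so degrees 1–3
are compared and the best degree is chosen by maximum adjusted R²
(AICc selection is available via `select = "aicc"`); the model is accepted
only when its adjusted R² exceeds the threshold (default 0.5). Rejected
models refuse to predict (`predict_climate()` errors), so poorly calibrated
precipitation never silently enters the regressions — the affected cells
stay `NA`. Exact-location ("direct") values always take precedence over
model predictions in `attach_climate()`.

Raster extraction is deliberately out of scope: calibration points arrive as
CSV, produced upstream or by the generator.

## Regression engines

**DivElev** lies in (0, 1) by construction (rates per Myr are far below 1),
so it is modelled by beta regression: mean–precision parameterization with
density shapes `mu * phi` and `(1 - mu) * phi`, logit link on the mean,
constant precision `phi`. The fit (`beta_fit()`) maximizes the exact beta
log-likelihood with an analytic score: L-BFGS-B (with `log(phi)` bounded
above, see below) followed by Newton polishing. Convergence is declared when
the Newton decrement — the projected log-likelihood gain of one more Newton
step — falls below `1e-8`; unlike a raw score norm this criterion is
invariant to predictor scaling and to the size of `phi`. Initialization uses
least squares on `logit(y)` for the mean coefficients and a delta-method
moment estimate for `phi`; both are deterministic, so the fit is seed-free.
Internally, non-intercept design columns are centred and scaled and the
estimates and covariance mapped back, which keeps the quadratic-term fits
well conditioned. Goodness of fit is the pseudo-R²: the squared Pearson
correlation between the linear predictor and `logit(y)`.

Numerical choices worth stating:

* Responses exactly 0 (bands holding only monospecific genera) or 1 are
  incompatible with the beta density. When any boundary value is present the
  whole response vector is compressed by `(y (n - 1) + 0.5) / n`
  (`compress_unit_interval()`), the standard remedy; interior-only vectors
  are untouched.
* `log(phi)` is capped at 30. A zero-dispersion response (e.g. all values
  equal, or a noiseless logistic curve) drives `phi` to infinity, where the
  likelihood is unbounded; at the cap the mean coefficients are already
  machine-precision converged and the fit is returned flagged as a boundary
  solution rather than erroring.

**AgeElev** is a positive continuous mean (Ma). It is modelled by a GLM with
Poisson variance and **identity** link (`glm_fit()`): coefficients then live
directly on the age scale (an intercept near 50 Ma and a slope in Ma/°C),
which is the only reading under which published coefficient magnitudes for
such models make sense — a log link would put intercepts of ~50 on the
exponent. Continuous responses are handled by quasi-likelihood scoring
(IRLS via `stats::glm` with `quasi(identity, mu)`), with the Poisson
deviance and log-likelihood extended continuously (`lgamma(y + 1)` for
`log y!`) so that likelihood-ratio tests and AICc remain defined;
`rounding = TRUE` gives the strict integer-Poisson likelihood instead. The
explained variance is the Kullback–Leibler deviance ratio
`1 - deviance / null deviance`, reported unadjusted, and defined as 0 when
the null deviance vanishes.

Model comparison: `lr_test()` (statistic `2 * delta logLik`, chi-squared on
the parameter-count difference, with the AICc difference reported
alongside) and `aicc()` (`-2 logL + 2k + 2k(k+1)/(n-k-1)`). For quadratic
temperature terms, `quadratic_vertex()` returns the stationary point
`-b1 / (2 b2)` with a maximum/minimum label — the temperature at which a
hump-shaped age curve peaks.

## Phylogenetic signal and ancestral states

Genus thermal preference is the pooled unweighted mean of the band climate
values over all of a genus's records (`genus_temp_pref()`); Bio1 is the
primary trait and Bio6 runs through the identical code path.

Pagel's lambda rescales the off-diagonal (shared-path) entries of the
Brownian-motion tip covariance while leaving the diagonal intact
(`lambda_transform()`). `pagel_lambda()` profiles the multivariate-normal
likelihood — root state by GLS and rate `sigma²` by its ML estimate, both
concentrated out — and maximizes over `lambda` in `[0, 1]` by bounded 1-D
search (tolerance `1e-6`), explicitly comparing the interior optimum against
both boundaries. The search is not extended above 1: the upper feasible
limit there depends on the tree, and the `[0, 1]` scale is what the signal
statistic is meant to convey. Significance is a likelihood-ratio test
against `lambda = 0` on one degree of freedom.

`asr_bm()` reconstructs ancestral states under untransformed Brownian
motion by dense-matrix GLS: the joint tip/node covariance is built from
shared path lengths (`ape::dist.nodes` + `ape::mrca`), and each internal
node estimate is the conditional expectation given the tips with the GLS
root plugged in. Node variances come from the conditional normal, inflated
by the uncertainty of the estimated root (universal kriging); the 95% CI is
`estimate ± 1.96 sd`. We chose the dense route over a linear-time
pruning recursion deliberately: at genus scale (a few hundred tips) the
dense solves cost milliseconds, the code is a direct transcription of the
estimator's definition, and the tests verify numerical equality with an
independent ML implementation (`phytools::fastAnc`) to `1e-8`. By default
the reconstruction is on the untransformed tree — matching the common
practice of reporting lambda and then reconstructing under plain BM — with
`lambda` available as an argument for reconstruction on the rescaled
covariance.

## The synthetic generator: what it emulates, and what it does not

`synth_config()` fixes the study conditions for all tests:

| knob | default | rationale |
|---|---|---|
| `n_tips` | 180 | genus-level tree of the size such compilations work with |
| `crown_age` | 400 Ma | deep crown age of an ancient land-plant lineage |
| `birth`, `death` | 0.03, 0.01 /Myr | mild turnover; rescaled to the crown age |
| `trait_root` | 11 °C | a cool-temperate ancestral preference |
| `trait_sigma2` | 0.05 °C²/Myr | tip preferences spread over a few °C |
| `trait_lambda` | 1 | pure BM unless a test varies it |
| `rich_a`, `rich_b` | 0, 0.003 | `r(T) = max(0, a + bT)`: warm genera diversify faster, rates 0–0.1 /Myr |
| `n_gradients` | 6 | multiple transects, seeded sea-level temperatures 26 ± 2 °C |
| `lapse` | 5.5 °C/km | standard environmental lapse rate |
| `max_elevation`, `band_width` | 4000 m, 250 m | typical tropical-transect extent and banding |
| `niche_breadth` | 3 °C | genus occupies every band within preference ± breadth |

Species numbers are generated by *inverting the estimator*:
`n = round(exp(r(T) t))` (exponent capped at `log(1e6)`), so
`ms_stem_rate()` applied to the generated `(n, t)` recovers the generating
regime up to integer rounding — that inversion is itself a test oracle.
Band occupancy is deterministic given the thermal niche (no detection
noise) by default so that occupancy tests can be exhaustive; a `dropout`
probability is available to stress-test the band statistics. Epiphyte
labels are assigned by thermal preference (above the configured quantile),
encoding the warm-adapted epiphyte pattern the group comparisons should
detect.

Every generator is a pure function of its config: the seed fully determines
the output, and each sub-generator draws from its own seed offset so that
regenerating one input never perturbs another.

What the generator does **not** emulate — and therefore what green tests do
not certify about field data: observation effort differing among source
studies, taxonomic error and synonym churn, spatially structured
precipitation (Bio12 is a single smooth quadratic surface), detection
failure at range edges, and richness regimes where extinction decouples
`n` from the net-rate inversion. Conclusions about real transects still
require the real inputs.

## Problem sizes and runtime choices

The test-suite simulation studies run at sizes chosen to give the
statistics room to converge while keeping the whole suite interactive:
coverage of the beta-regression Wald intervals over 200 replicates of
`n = 500`; the GLM vertex at `n = 600`; likelihood-ratio type-I error over
500 null simulations of `n = 60`; lambda recovery and null behaviour over
100 + 100 replicates on a 200-tip tree; and 100 end-to-end pipeline
replicates at 100 tips × 4 gradients. The Monte-Carlo covariance check for
the trait simulator uses 2,000 draws on a 5-tip tree.

## Known limitations

* The beta regression has constant precision; variable-precision models
  (precision covariates) are out of scope.
* No mixed effects or spatial autocorrelation: gradients enter only through
  their band means and climate calibrations.
* No multiple-testing correction across the many fitted regressions; the
  per-model p-values are reported as-is.
* `pagel_lambda` and `asr_bm` build dense covariance matrices; they are
  comfortable to a few hundred tips but are not meant for trees of tens of
  thousands of tips.
* The ANOVA/Tukey stage assumes homoscedastic groups; strongly
  heteroscedastic band means deserve a Welch-type analysis that the package
  does not provide.
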