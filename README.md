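# divelev

Diversification rates and lineage ages along elevational gradients.

`divelev` is an R package for asking how the evolutionary tempo of a clade
is arranged along mountain gradients. It links three kinds of input —
genus occurrence records from banded elevational transects, a
time-calibrated genus-level phylogeny, and per-genus extant species counts
— and answers: are warm low elevations occupied by young, rapidly
diversifying lineages while cold high elevations hold old, slow ones? The
motivating application is liverworts, a lineage whose species richness
peaks at cool mid-elevations, but every stage is generic.

## The core quantities

**Net diversification rate.** For a genus with `n` extant species and stem
age `t` (Ma), the maximum-likelihood net rate under a constant-rate
birth–death model with relative extinction ε = μ/λ is

    r̂ = log(n(1 − ε) + ε) / t        (ε = 0:  r̂ = log(n)/t)

so monospecific genera have r̂ = 0 exactly (`ms_stem_rate()`).

**Band means.** DivElev and AgeElev are the unweighted arithmetic means of
per-genus rate and stem age over the distinct genera recorded in one
elevational band of one gradient, alongside genus richness and the
within-gradient relative elevation/richness percentages (`band_stats()`).

**Climate.** Band climate comes from per-gradient calibration models:
linear lapse fits for temperature (Bio1/Bio5/Bio6), polynomial fits of
degree 1–3 for precipitation accepted only when adjusted R² > 0.5
(`fit_lapse_model()`, `attach_climate()`).

**Regression.** DivElev (a rate in (0,1)) is fitted by beta regression
(logit mean link, constant precision φ, exact ML with analytic score;
goodness of fit is the pseudo-R², the squared correlation between linear
predictor and logit response). AgeElev is fitted by a GLM with Poisson
variance and identity link, so coefficients are in Ma and Ma/°C; fits are
compared by likelihood-ratio tests and AICc, and quadratic temperature
fits report their stationary point −β₁/(2β₂) — the temperature at which a
hump-shaped age curve peaks (`beta_fit()`, `glm_fit()`, `lr_test()`,
`quadratic_vertex()`).

**Comparative.** Genus thermal preference (mean band Bio1 over a genus's
records) is tested for phylogenetic signal with Pagel's λ (profile ML over
[0, 1], LR test against λ = 0) and reconstructed at internal nodes under
Brownian motion by GLS, with conditional-normal variances and 95% CIs
(`pagel_lambda()`, `asr_bm()`).

A seeded synthetic generator (`synth_config()`, `synth_dataset()`)
produces all inputs with known ground truth — birth–death chronogram,
λ-scaled Brownian thermal preferences, richness driven by a
temperature-dependent rate regime, and thermal-niche band occupancy — so
the entire pipeline is testable without any field data.

## A worked example

```r
library(divelev)

cfg <- run_config(synth = synth_config(seed = 7),
                  formulas = c("div_elev ~ bio1", "age_elev ~ bio1 + bio1^2"))
bundle <- run_pipeline(cfg)
report_bundle(bundle)
```

```
== Diversification rates ==
180 genera | rates 0.000-0.068 | mean 0.019 | median 0.022 | 76 zero
bins: [0,0.1)=180  [0.1,0.2]=0  (0.2,Inf)=0 

== Regression models ==
-- div_elev ~ bio1 --
Beta regression (logit link, constant precision)
             estimate          se
(Intercept) -4.968141 0.044219674
bio1         0.102872 0.003080075
phi = 2653.466 | logLik = 330.434 | pseudo-R2 = 0.942 | n = 74
...
== Group comparison: div_elev == F(2,171) = 31.528, p = 2.21e-12
                   pair         diff          lwr          upr        p_adj
1          epiphyte-all  0.005228199  0.001155997  0.009300401 7.783588e-03
2      non_epiphyte-all -0.010193154 -0.014570050 -0.005816257 3.962087e-07
3 non_epiphyte-epiphyte -0.015421353 -0.020053125 -0.010789581 1.162515e-12

== Phylogenetic signal (bio1) ==
Pagel's lambda = 1.000 (logLik -334.480; vs lambda=0: LR 197.38, p 7.79e-45)
  sigma2 = 0.04535, root state = 10.069, n = 167 tips

Ancestral root estimate: 10.07 deg C (sigma2 0.04853)
```

Reading the output: the generator evolved thermal preferences under pure
Brownian motion (λ = 1 recovered exactly) around a root preference of
11 °C (reconstructed at 10.07 °C), and made warm-adapted genera diversify
faster — which the pipeline recovers as a strongly positive DivElev–Bio1
slope on the logit scale (0.103 per °C, pseudo-R² 0.94) and as epiphytes
(the warm-adapted class) out-diversifying non-epiphytes in the group
comparison (Tukey–Kramer p < 1e-11).

Every stage is also callable on its own (`read_chronogram()`,
`prune_to_taxa()`, `rate_table()`, `dedupe()`, `band_stats()`,
`fit_climate_models()`, `beta_fit()`, `pagel_lambda()`, `asr_bm()`), and
`read_run_config()` loads the same configuration from YAML.

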