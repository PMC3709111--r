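---
title: "Detecting unimodal species response with a logit-linear mixed model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting unimodal species response with a logit-linear mixed model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The question

Species abundances along an environmental gradient are classically pictured
as unimodal ("niche") curves: a species is most likely present near its
optimum and rarer away from it. With presence–absence data the standard
unimodal model is the Gaussian logistic curve

$$\operatorname{logit} p_{ij} = a_j - \frac{(x_i - u_j)^2}{2 t_j^2},$$

where site $i$ has gradient value $x_i$ and species $j$ has maximum $a_j$,
optimum $u_j$ and tolerance (niche width) $t_j$. Fitting this curve species
by species is fragile: rare species, species with optima outside the sampled
range, and separation all break the per-species quadratic logistic
regression.

This package tests for unimodal response *without* fitting any quadratic
term, using a generalized linear mixed model that is linear in $x$.

## The model and why it works

`fit_glmm()` fits the binomial-logit mixed model

$$\operatorname{logit} p_{ij} = \beta_0 + \beta_1 x_i + \alpha_j + \beta_j x_i + \gamma_i,$$

with correlated random species intercepts $\alpha_j$ and slopes $\beta_j$, and
an independent random site effect $\gamma_i$ (`y ~ 1 + x + (1 + x | species)
+ (1 | site)` in `lme4` notation, Laplace approximation).

The trick is an exact reparameterization. If every species follows the
Gaussian logistic curve with a *common* tolerance $t$, expanding the square
gives, per species, an intercept $a_j - u_j^2/(2t^2)$, a slope $u_j/t^2$,
and one shared curvature term $-x_i^2/(2t^2)$. The first two are exactly the
random species intercept and slope; the shared curvature depends only on the
site and is absorbed by $\gamma_i$. Under unimodal response the site effects
are therefore not noise — they are an n-shaped quadratic function of the
gradient.

`unimodality_test()` exploits this: it regresses the conditional modes of
$\gamma_i$ on $x$, $x^2$ and the site total $S_i$ (the number of species
observed at the site, a proxy for overall site favourability) by ordinary
least squares and tests the $x^2$ coefficient. A significantly negative
coefficient is evidence of unimodal response, and its magnitude implies a
common tolerance $t = 1/\sqrt{-2\,b_{x^2}}$. The z-ratio is referred to the
Student $t$ distribution on the residual degrees of freedom, which makes the
reported p-value identical to the ANOVA F-test of adding $x^2$ — both are
returned, along with the normal-reference p-value, and `p_anova == p_x2`
holds exactly. `run_unimodal_pipeline()` chains the two steps.

```{r}
library(unimodal)
sim <- simulate_gaussian(sim_config(n = 50, m = 100, t = 1, seed = 1))
res <- run_unimodal_pipeline(sim$data)
res$test
```

Because the species slope under this reparameterization is $u_j/t^2$, the
fitted random slopes should be proportional to the species optima.
`slope_vs_optimum()` checks this against independent per-species quadratic
logistic fits (`fit_species_glms()`), and `common_tolerance_transform()`
maps an extended fit with a fixed $x^2$ term back to Gaussian parameters
($t$ from the fixed curvature, $u_j = t^2 \beta_{1j}$ from the total slope,
with site effects adjusted by $x_i^2/(2t^2)$); `qq_site_effects()` then
checks that the adjusted site effects look normal.

## The simulator

`simulate_gaussian()` draws communities from the Gaussian logistic curve:
$x_i \sim U(-2, 2)$, optima $u_j \sim U(-\tau, \tau)$ with $\tau = 2 + t$ by
default (so some optima fall outside the sampled range), maxima
$a_j \sim N(0, 1)$, and Bernoulli presences. Defaults are the study
conditions used throughout the tests: $n = 50$ sites, $m = 100$ species.
Variants: a log-normal tolerance spread (`sigma_t`) for unequal niche
widths, and a normal gradient/optima option (`distribution = "normal"`).
`series_grid()` packages the three example designs (varying $t$, varying
tolerance spread, varying species number). `simulate_null()` draws from the
mixed model itself — by construction no unimodality — for type-I-error
studies. Draw order is fixed (x, u, a, t, y) so a seed pins the dataset.

`whittaker_beta()` characterizes simulated gradients: $\beta_w =
T/\bar S - 1$ falls from strong turnover at $t = 0.5$ to weak turnover at
$t = 4$.

## Numerical choices

* The mixed model uses the Laplace approximation with the `bobyqa`
  optimizer and derivative checks disabled — the fastest stable
  configuration for these binary crossed-effects fits; results are
  invariant to site/species ordering and are checked against a from-scratch
  penalized-likelihood solver (`conditional_modes_fixed()`) in the tests.
* **Boundary site variance.** When the curvature signal is weak relative to
  the binomial noise, the maximum-likelihood site-effect variance can land
  exactly at zero, making every conditional mode zero even though fits
  arbitrarily close to the boundary carry the full signal. The test
  statistic is invariant to the overall scale of the site effects, and as
  the variance shrinks the modes collapse along a fixed direction: the
  per-site sums of response residuals. The pipeline substitutes that
  limiting direction in the boundary case, flags the result
  (`boundary_site_variance = TRUE`), and reports no implied tolerance
  (scale-free input). This matters in practice for wide-tolerance data
  (e.g. $t = 4$), where the quadratic trend is strong but small in
  amplitude.
* The site effects enter the regression as data: their estimation
  uncertainty is ignored, and $S$ enters untransformed. A constant $S$ is
  dropped with a message; other exact collinearities are errors.

## Limitations

* **Anti-conservative under slope-heavy nulls.** When data are generated
  from the linear mixed model itself with large random-slope variance, the
  test rejects more than its nominal level (the package's own null
  simulations at unit variances show roughly 2–4× the nominal 5% rate).
  The mechanism is the $S$ covariate: with substantial slope variance the
  information a site carries depends on $|x_i|$, so the sampling noise of
  $\hat\gamma_i$ and $S_i$ share gradient-dependent structure, and
  conditioning on $S$ overdisperses the $x^2$ coefficient. Without $S$ (or
  with small slope variance) the test is calibrated — the site effects show
  no quadratic trend on $x^2$ alone. Treat borderline p-values with
  caution when the fitted slope variance is large; the detection results on
  genuinely unimodal data are orders of magnitude below any such
  inflation.
* The test targets a *common* curvature. Strongly unequal tolerances
  dilute it toward the average; skewed or bimodal responses are outside
  its scope.
* One gradient only; no abundance models.
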