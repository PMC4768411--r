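---
title: "Controlling the mixed directional FDR in many-to-one comparisons"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Controlling the mixed directional FDR in many-to-one comparisons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mdfdr)
```

## The testing problem

A design with `q` experimental groups and one reference group
(`p = q + 1` groups, `n_g` samples each) is observed on `m` features.
For every feature `j` and comparison `i` there are three possible
conclusions — up-regulated, down-regulated, or no call — so a procedure
can err in two ways: rejecting a truly null (feature, comparison) pair,
or rejecting a non-null pair with the wrong sign (a directional, or
type III, error). Writing `V` for the number of such false or
wrongly-signed directional rejections and `D` for the number of
directional rejections altogether, the mixed directional false
discovery rate is

$$\mathrm{mdFDR} = E\left[\frac{V}{\max(D, 1)}\right].$$

Feature-wise BH plus sign-by-fold-change does not control this
quantity; the error budget must cover the pairwise multiplicity and the
sign decisions jointly.

## The three-step algorithm

`run_mdfdr()` implements the general algorithm:

1. a per-feature *screening* p-value `P_j` tests the global null that no
   group differs from the reference; BH step-up at level `alpha` selects
   `R` features;
2. within each selected feature, the `q` pairwise hypotheses are tested
   at the data-dependent level `R * alpha / m` by a procedure that
   controls the mixed directional *familywise* error (mdFWER) within the
   feature;
3. rejected pairwise hypotheses are signed by their statistic.

Under independence of the feature-wise p-value vectors, the selection
level `R * alpha / m` exactly absorbs the step-1 multiplicity, giving
strong mdFDR control at `alpha`; the simulations below probe robustness
to dependence. When `R = 0` the pairwise stage is skipped. A feature can
survive screening yet receive no pairwise rejection (a marginally
significant screening p-value); such features are reported as not
differentially expressed but retained in `decisions_table()` output and
counted in `undirected` — under the default simulation conditions this
affects well under 5 % of selected features.

## The Dunnett instantiation

With pooled within-group variance `s_j^2` on `nu = sum(n_g) - p` degrees
of freedom, the many-to-one statistics

$$T_{ij} = \frac{\bar{x}_{ij} - \bar{x}_{0j}}
{s_j\sqrt{1/n_i + 1/n_0}}$$

are jointly multivariate t under the feature's global null, with
correlation `r_ik = gamma_i * gamma_k`, `gamma_i = sqrt(n_i/(n_i+n_0))`
(all 1/2 when balanced). The screening p-value is the max-|T| tail,

$$P_j = P\!\left(\max_i |T_i| \ge \max_i |T_{ij}|\right),$$

and the single-step adjusted pairwise p-value is the same tail evaluated
at `|T_ij|`. Both facts are exploited: `screening_pvalue()` and
`dunnett_pairwise_pvalue()` are the same function evaluated at different
thresholds, and the adjusted p-value never exceeds `q` times the
two-sided t p-value (the Bonferroni bound), which is exactly why this
instantiation outperforms Bonferroni-style alternatives. The sign
convention is experimental minus reference: "up" means higher mean
expression in the experimental group.

Features with zero pooled variance cannot be standardized; they carry no
evidence, receive screening p-value 1, and are never selected.
Missing values are rejected outright — the degrees-of-freedom
bookkeeping assumes complete data, and imputation is out of scope.

## Numerical evaluation of the tail

Conditioning on the reference-group disturbance `Z_0` and the pooled
scale `W = sqrt(chi^2_nu / nu)` makes the `q` components independent:

$$P\!\left(\max_i |T_i| < c\right) = \int_0^\infty\!\!\int_{-\infty}^\infty
\prod_{i=1}^{q}\left[\Phi\!\left(\tfrac{cw - \gamma_i z}{\sqrt{1-\gamma_i^2}}\right)
 - \Phi\!\left(\tfrac{-cw - \gamma_i z}{\sqrt{1-\gamma_i^2}}\right)\right]
\varphi(z)\, f_W(w)\, dz\, dw.$$

`dunnett_tail()` evaluates this with 64-point Gauss–Legendre rules in
each dimension, the `z` range truncated at ±9 and the `w` range at the
10⁻¹⁵ and 1−10⁻¹⁵ quantiles of `W`. Doubling the node counts changes
the result by less than 10⁻¹⁰ across `c ∈ [0, 9]`, and results agree
with an independent Monte-Carlo sampler and with `mvtnorm`'s rectangle
probabilities in the test suite. Values are clipped to [0, 1] to absorb
rounding. The representation does not require equal correlations, so
unbalanced designs use the same quadrature; only a user-supplied
correlation matrix without the product structure falls back to seeded
Monte-Carlo evaluation (`mc_draws`, `mc_seed`), which reports its
standard error as an attribute.

Simulations evaluate the same tail at hundreds of thousands of points
under one null model, so `dunnett_tail_fun()` precomputes the tail on a
grid (step 0.01 up to c = 3, 0.02 up to 9, 0.1 up to 14) and
interpolates with a monotone Fritsch–Carlson spline; the interpolation
error is below 2 × 10⁻⁶ absolute, negligible against the BH thresholds
(≥ alpha/m = 5 × 10⁻⁵ at the default study size) and irrelevant to any
averaged operating characteristic.

## Step-2 procedures and the comparator family

Five procedures are studied, all sharing steps 1–3 and differing in the
screening test and the within-feature mdFWER procedure:

| name | screening | step-2 inputs | step-2 rule at level L = Rα/m |
|---|---|---|---|
| `dunnett` | max-\|T\| tail | Dunnett-adjusted p | reject iff p ≤ L |
| `holm` | max-\|T\| tail | Dunnett-adjusted p | step-down L/(q−i+1) |
| `hochberg` | max-\|T\| tail | Dunnett-adjusted p | step-up L/(q−i+1) |
| `bonferroni` | max-\|T\| tail | Dunnett-adjusted p | reject iff p ≤ L/q |
| `guo` | q·min raw p | raw two-sided t p | reject iff p ≤ L/q |

A genuinely open design choice was which p-values feed the
Holm/Hochberg/Bonferroni variants: the raw two-sided t p-values or the
Dunnett-adjusted ones. We feed them the *adjusted* p-values. Two
considerations decide it. First, with raw inputs the Holm variant's
feature-level threshold (smallest p ≤ L/q) would coincide with the
Bonferroni-screening comparator's pairwise threshold while using the
strictly better max-|T| screen, so the Holm variant would dominate that
comparator — yet a step-down/step-up stage on raw p-values would also
out-reject the single-step Dunnett threshold on features with several
true effects, inverting the expected ordering of the family. Second,
with adjusted inputs the whole family is coherently ordered by
construction — single-step ⊇ Hochberg ⊇ Holm ⊇ Bonferroni on every
dataset — which matches both the simulated power ordering and the
relative feature counts the methods produce on real data. The raw-p
variants remain available through `run_mdfdr(pairwise_p = "raw")`; they
control mdFWER within features too, they just sit outside the
single-step-dominated family. The `guo` comparator keeps raw p-values
because that is the earlier procedure it reproduces.

Ties in sorted p-values share a threshold, so step outcomes are
order-independent; zero p-values are rejected at any positive level.
`bh_select()`, `holm_directional()` and `hochberg_directional()`
delegate to `stats::p.adjust`, whose adjusted-p formulation is
algebraically identical to the step rules; hand-worked examples of every
rule are locked into the test suite.

## What the simulator emulates

`simulate_dataset()` reproduces the operating-characteristics study
design: `p = 4` groups (reference last), `n = 10` samples per group,
`m = 1000` features, expression `Z ~ N(mu_gj, 1)`; the reference mean is
always 0; a proportion `pi1` of features is non-null with each
experimental mean drawn independently from `U(0, 2.5)` (so every
non-null pair is truly up-regulated, and with sigma = 1 the
signal-to-noise is deliberately modest). `m0 = round(m(1 - pi1))`
features are fully null. Three exact equicorrelation structures are
generated by shared factors (`sqrt(rho)·Z_shared + sqrt(1-rho)·Z_own`,
cost O(mN), no Cholesky): `independent`; `within_sample` (feature pairs
correlate at `rho` inside each sample); `within_feature` (sample pairs
correlate at `rho` inside each feature). Defaults are the study
conditions; `rho = 0.2` is the dependence level examined.

`score_run()` uses per-pair accounting: every directional call is one
discovery, false when it lands on a null pair or carries the wrong
sign; average power is the proportion of truly non-null pairs rejected
with the correct sign. This is the standard accounting in the mdFDR
literature and the only one consistent with a *discovery-proportion*
error rate; whether power could instead be averaged per feature is a
reporting choice that does not affect control.

`simulate_operating_characteristics()` evaluates all procedures on the
*same* replications (a paired design that sharpens power comparisons),
with per-replication seeds drawn once from the root seed, and returns
means with Monte-Carlo standard errors; `detail = TRUE` keeps the
per-replication matrices. The test suite and the acceptance script use
200 replications per cell (the headline study used more); at that size
the standard error of an mdFDR estimate is about 0.001 and of a power
estimate about 0.003, ample for the qualitative conclusions, and a full
five-procedure cell runs in under ten seconds.

What passing these simulations does *not* show: the generator draws
Gaussian, homoscedastic, equicorrelated data with balanced groups and
all-positive effects. Real expression data are heavier-tailed, have
feature-specific variances and block-structured correlation, and mix
up- and down-regulation. mdFDR control under BH-style selection is
proven for independent feature p-value vectors and probed here under
two exchangeable dependence structures — not under arbitrary
dependence.

## Defaults and limitations

* `alpha = 0.05` is the target mdFDR; the pairwise level `Rα/m` is used
  exactly as realized, with no rounding of `R`.
* Normalization, probe-set summarization and missing-data handling are
  upstream of this package; features are tested as given, including
  duplicate probe sets for one gene (they are distinct features here).
* One-sided Dunnett variants, step-down Dunnett, heteroscedastic
  statistics, and adaptive (pi0-estimating) BH are not implemented.
* Unbalanced designs are fully supported in the pipeline (the product
  correlation and quadrature do not need balance); the simulator itself
  is balanced, as in the study it reproduces.
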