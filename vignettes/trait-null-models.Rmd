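---
title: "Trait-based null models for fruit-body assemblages: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trait-based null models for fruit-body assemblages: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sporotraits)
```

## The question and the approach

Macrofungi differ enormously in how they invest in sexual reproduction:
some species produce few large fruit bodies, others many small ones. For
soil-dwelling fungi this investment is expected to reflect how the species
acquires carbon. Ectomycorrhizal (ECM) species draw on a relatively
reliable host-derived carbon stream, while saprotrophic (ST) species
depend on dead organic matter, a patchier and less predictable resource.
`sporotraits` implements an assemblage-level analysis of this idea: for
every plot, guild and year it summarises the reproductive traits of the
co-occurring species, asks whether those summaries deviate from two
explicit null expectations, and regresses raw and null-standardized
summaries on a stand-productivity gradient.

Two traits are carried per species:

* **Fruit-body size**, indexed by the squared mean cap diameter
  $d^2$ (mm$^2$), a standard biomass proxy for agaric fruit bodies.
* **Fruit-body number**, the species' total fruit-body count divided by
  the number of plots on which it was recorded.

Both are log10-transformed *at the species level* before any averaging,
and assemblage means are unweighted across species — every species counts
once, regardless of abundance. A community-weighted-mean variant is
deliberately not offered: weighting by counts would conflate the
size-number trade-off with composition.

Species recorded on fewer than four distinct plots (counted across all
years) are removed before analysis; with fewer occupied plots the
per-species mean fruit-body number is too unstable to serve as a trait.
The threshold is the `min_plots` argument of `occupancy_filter()` and
defaults to 4.

## The two null models

Observed assemblage means are scored as standardized effect sizes,

$$\mathrm{SES} = \frac{\text{observed} - \overline{x}_{\text{null}}}
{s_{\text{null}}},$$

with $s_{\text{null}}$ the sample (n−1) standard deviation across null
replicates (100 by default). The (n−1) convention matters only in the
third decimal at 100 replicates, but it is fixed so results are exactly
reproducible. |SES| > 2 is read, conventionally, as a significant
deviation. A null with zero spread (for example a plot whose richness
equals the pool size) yields an undefined SES and is flagged rather than
returned as ±Inf.

**Regional-pool null** (`regional_pool_null()`). Each replicate draws,
without replacement, as many species from the guild's regional pool as the
assemblage holds, and records the mean log10 size of the draw. This asks:
do the species co-occurring here differ in size from a random selection of
the species that could occur in the region? Only size is supported —
fruit-body *counts* are a local field measurement with no regional
analogue, and the API enforces this restriction rather than silently
returning nonsense.

**Local swap null** (`independent_swap()`, `swap_null()`). Comparisons of
assemblage means with richness, or with anything correlated with richness,
can be spurious because the mean is itself computed from the species-by-
site matrix. The fixed-fixed null breaks the trait-occurrence association
while holding both matrix marginals: random pairs of rows and columns are
sampled and, whenever the 2×2 submatrix is a checkerboard, it is swapped
to the opposite pattern. Species occupancies and plot richness are
conserved exactly — by construction, every plot's null distribution is
richness-matched.

The chain is run sequentially with a burn-in of $10f$ successful swaps and
$f \cdot 2$ swaps between samples, where $f$ is the number of presences in
the matrix — standard practice for sequential swap nulls and cheap at this
scale. Both controls are arguments; `restart = TRUE` switches to
independent restarts from the observed matrix for users who prefer
randomizations that are independent by construction. Swap attempts are
rejection-sampled (only successful swaps count), with a budget of $10^6$
attempts per requested swap so that a matrix without checkerboards (for
example, an all-ones matrix) returns unchanged with a warning instead of
hanging. The attempt loop is implemented in C (via Rcpp) because
checkerboard acceptance is a few percent at realistic matrix densities;
the chain consumes R's RNG stream, so `set.seed()` governs it like any
other simulation. The independent swap is known to sample the fixed-fixed
class non-uniformly in general; no correction is applied, and the
ergodicity test below checks coverage of the class, not uniformity.

## The resource gradient

Stand structure is summarised by a PCA of eight plot-level variables
(tree count, growing-stock volume, basal area, mean DBH, three cover
layers, stand age) computed on the correlation matrix, i.e. on
z-standardized variables. The first component is interpreted as resource
availability and is oriented so that volume loads positively; the second
captures stand succession and is oriented so that age loads positively.
Orientation is convention, not inference — fixing it keeps signs of
downstream regression slopes interpretable. Missing values are mean-
imputed with a warning; constant variables are dropped (their
correlations are undefined).

## The regression model

Each response metric (raw mean log size, raw mean log number, and the SES
variants) is modelled as

$$y_{pgt} = \mathbf{x}_{pgt}^\top\beta + b_p + \varepsilon_{pgt},
\qquad b_p \sim N(0, \sigma^2_{\text{plot}}), \quad
\varepsilon_{pgt} \sim N(0, \sigma^2_{g}),$$

with fixed effects guild (reference ST), year (factor, reference first
year), resource, stand age, guild×resource and guild×year; a plot random
intercept absorbing the repeated measurements of each plot across years;
and a separate residual variance per guild, since ST and ECM metrics
differ visibly in spread. Effects are reported as z-values
(estimate/standard error). The three-way guild×resource×year interaction
is excluded by default and available behind `with_three_way = TRUE`.

`hlmm()` fits this model by REML: the three variance parameters are
log-parameterized and optimized numerically (Nelder-Mead, relative
tolerance 1e−12), with fixed effects profiled out by generalized least
squares at every evaluation. Because the covariance matrix is block
diagonal by plot and each block is a diagonal plus a rank-one term, every
evaluation uses the Woodbury identity per plot rather than a dense solve.
This engine is deliberately minimal — exactly one random intercept and
one variance-stratum factor — which is all this design needs; on shared
test data its estimates, standard errors and REML log-likelihood agree
with `nlme::lme(weights = varIdent(...))` to at least five digits.

Numerical edge cases: a rank-deficient design raises an error naming the
aliased terms; non-convergence raises an error carrying the optimizer
trace; a constant response returns a flagged fit with zero slopes and
undefined z-values; a truly zero plot variance drives the log-variance
parameter to a large negative value, which is reported as a variance of
effectively zero (the GLS fit then coincides with the no-random-effect
fit). With no random effect and a single variance group the fit reduces
exactly to ordinary least squares.

The "adjusted R²" reported with each fit is the squared correlation
between the marginal (fixed-effects) fitted values and the response,
adjusted for the number of fixed-effect parameters. Adjusted R² has no
canonical definition for weighted mixed models; ours is recorded here and
in the output metadata so the number is interpretable, and it should not
be compared against other software's definitions.

## What the generator emulates

`simulate_dataset()` produces a complete synthetic study so that every
stage is testable without field data. Its defaults are the study
conditions assumed throughout the package's tests:

| parameter | default | what it encodes |
|---|---|---|
| `n_plots`, `years` | 48, 2009-2011 | survey extent: 48 plots, three seasons |
| `n_pool` | 300 ECM + 300 ST | regional pool size per guild |
| `size_mean`, `size_sd` | 3.2 / 2.6, 0.5 | log10 mm² fruit-body size; ECM larger than ST, spanning roughly 30 mm² to 30,000 mm² |
| `tradeoff_intercept/slope/sd` | 4, 1, 0.3 | log10 count = 4 − log10 size + noise: a species of 400 mm² produces ~25 fruit bodies per occupied plot |
| `occupancy_sdlog` | 1.2 | lognormal occupancy weights: few widespread, many rare species |
| `richness_target` | 12 ECM / 10 ST | expected per-plot, per-year guild richness |
| `lambda0` | ECM 0.5, ST 2.5 | baseline size-filter strength: strong for ST, weak for ECM |
| `lambda1` | 0.5, 0.5 | coupling of filter strength to the resource gradient |
| `env_noise` | 0.4 | noise on the stand variables, in latent-signal sd units |
| `age_coupling` | 0.1 | weak dependence of stand age on the resource latent |
| `count_dispersion` | 1 | negative-binomial dispersion of realized counts (heavy right tail) |

Species enter a plot/year with probability proportional to their
occupancy weight times $\exp(-\lambda(r)\,(x - \mu_g))$, where $x$ is the
species' log10 size, $\mu_g$ the guild pool mean, and
$\lambda(r) = \max(0, \lambda_0 - \lambda_1 r)$ declines with the plot's
latent resource level $r$. Under the defaults this produces the package's
reference pattern: ST assemblages strongly smaller than the regional
expectation everywhere, ECM assemblages mostly indistinguishable from it,
and both guilds' mean size rising (and mean number falling, via the
trade-off) towards productive plots. Setting `lambda0 = c(ECM = 0, ...)`
and `lambda1 = 0` per guild switches the filter off, which is how the
neutrality and calibration tests are constructed. Filtering acts on the
pool-to-plot step; the swap null instead probes trait-occurrence structure
*within* the realized matrix, so the two effects can be switched
independently.

Realized counts are drawn negative-binomially around each species'
characteristic count with zeros promoted to one (a present species has at
least one fruit body). The whole dataset is a deterministic function of
`(config, seed)`; the three stages draw from fixed seed substreams
(`seed + 101/202/303`) so that, for instance, enlarging the pool does not
perturb the environment table.

What the generator does **not** emulate: spatial autocorrelation between
plots, within-season phenology, host-tree identity, detection error, and
year-to-year persistence of mycelia (years are independent draws). Tests
that pass on synthetic data therefore establish that the estimators
recover the structure they target under a clean assembly process — not
that field data meet these assumptions.

One property of the synthetic communities deserves emphasis because it is
equally true of real ones: plot-level SES values within a dataset are not
independent, since plots share the same finite, occupancy-skewed species
set. Averages of SES across the plots of one survey therefore wander much
more than independent-sample intuition suggests. The package's
calibration checks break this dependence explicitly (traits are
re-shuffled against occurrences independently per plot) and use 1000
plot draws so the calibration bands sit at three Monte-Carlo standard
errors; users comparing mean SES between surveys should expect the same
dependence in their data.

## Problem sizes and other fixed choices

* Calibration and pattern-recovery checks run at the default study size
  (48 plots × 3 years × 600 pool species); gradient-direction recovery is
  replicated 50 times at that size, and the neutrality calibration uses
  500 single-year plots per guild. These sizes were chosen so every check
  completes in seconds to a couple of minutes on one core.
* Row and column order of every matrix, and row order of every output
  table, is lexicographic, so reruns are byte-identical.
* The fruit-body-number trait defaults to the pooled definition (one
  value per species from all years); a per-year variant
  (`count_mode = "per_year"`) is provided because either reading of
  "counts divided by occupied plots" is defensible when sampling spans
  several years. The pooled default treats the trait as a species
  property, which is how it enters the null models.
* Zero-count records are dropped on load: presence means at least one
  fruit body. Duplicate (plot, species, year) keys are schema errors, not
  silently summed.

## Known limitations

* `hlmm()` supports exactly one random intercept and one residual-variance
  factor; crossed or nested random effects, spatial correlation
  structures, and small-sample (Kenward-Roger-type) corrections are out
  of scope — inference is by z-values.
* The independent swap's non-uniform sampling of the fixed-fixed class is
  inherited, not corrected.
* The regional-pool null ignores regional abundance: every pool species
  is equally likely to be drawn. A colonization-weighted pool would need
  data the package does not model.
* SES values from the two null models answer different questions (regional
  filtering vs within-survey trait-occurrence structure) and are not
  interchangeable, even though both are reported on the same scale.
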