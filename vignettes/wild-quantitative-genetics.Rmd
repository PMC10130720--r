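---
title: "Estimating heritability, evolvability and selection on floral traits in the wild"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating heritability, evolvability and selection on floral traits in the wild}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wildqg)
```

## The scientific problem

Whether a floral trait can evolve in a wild population depends on two
ingredients of the breeder's equation: selection acting on the trait and
heritable variation for the trait to respond with. `wildqg` implements a
complete workflow for measuring both on the same individuals of a wild
plant population, without pedigrees or crosses:

1. **Genomic relatedness.** SNP genotypes (e.g. from
   genotyping-by-sequencing) are quality-filtered and converted into a
   genome-wide realized relatedness matrix (GRM).
2. **Animal models.** Replicated floral phenotypes are decomposed with a
   GRM-structured linear mixed model into additive genetic, site,
   permanent-environment and flower-level residual variance, yielding
   narrow-sense heritability and mean-standardized evolvability.
3. **Selection analysis.** Fruit set (fruits per flower scar) is treated
   as binomial fitness; spline-based fitness surfaces give standardized
   linear and quadratic selection differentials and gradients as averaged
   derivatives of relative fitness, with plant-level bootstrap inference.
4. **Power.** GREML-style calculations quantify how detectable small
   heritabilities and genetic correlations are at the study's sample size.

A first-class synthetic-data generator emulates the field design the
workflow targets — six sites along an elevation gradient, 40 tagged plants
per site, five flowers per plant, a panel of a few thousand SNPs — with
known ground truth, so every stage is testable end to end.

## The model

For a flower-level trait record the animal model is

$$y = X\beta + Z_1 a + Z_2 s + Z_3 i + e,$$

with elevation as a fixed covariate, $a \sim N(0,\, \mathrm{GRM}\, V_a)$,
$s \sim N(0, I V_s)$ (site of origin), $i \sim N(0, I V_i)$ (permanent
environment: consistent differences among individuals beyond genetics) and
$e \sim N(0, I V_{error})$ (variation among flowers of one plant).
Heritability and evolvability are computed per posterior draw:

$$h^2 = \frac{V_a}{V_a + V_s + V_i + V_{error}}, \qquad
  e = \frac{V_a}{\bar{x}^2},$$

the latter reported in percent of the squared trait mean. A bivariate
version with 2×2 covariance blocks per random term gives the genetic
correlation $r_G = \mathrm{cov}_a/\sqrt{V_{a1} V_{a2}}$. A "naive" model
variant omits elevation and site; comparing it with the full model (by DIC
and by the inflation of $h^2$) shows how much apparent heritability is
really shared environment.

### Sampler

The posterior is explored with a blocked Gibbs sampler written for exactly
this model class. All location effects (fixed, site, additive) are drawn
jointly from the mixed-model equations with the permanent-environment
effects integrated out — at the plant level the marginal residual variance
is $V_i + V_{error}/m$ for $m$ replicate flowers — and the
permanent-environment effects are then drawn from their exact conditional.
This collapsed update eliminates the pathologically slow mixing that
separate updates of two plant-level effect vectors produce. Variances are
drawn from conditional scaled inverse-chi-squared distributions
(inverse-Wishart for the bivariate blocks). Flower-level records enter
only through per-plant sufficient statistics (means and the within-plant
sum of squares), so an iteration costs one Cholesky factorization of a
(fixed + site + plants) matrix.

Priors default to near-flat scaled inverse-chi-squared distributions
(scale 1, 0.002 degrees of freedom); for traits whose additive variance
may sit at zero, parameter expansion is available: the additive and site
effects are rescaled by working parameters with standard-normal priors,
which implies a heavier-tailed scaled chi-squared prior with one degree of
freedom on the effect scale and markedly improves mixing near the
boundary. DIC uses the conditional-on-random-effects deviance,
$\mathrm{DIC} = 2\overline{D} - D(\bar\theta)$, the convention of the
Bayesian mixed-model software family this model class comes from.

Chain lengths are the user's choice; the analysis drivers under
`analysis/` use 13 000 iterations (3 000 burn-in, thinning 5), which gives
several thousand effective samples for the well-mixing components, while
the test suite uses shorter chains (about 2 000–8 000 iterations) sized so
that whole replicate experiments run in minutes; the properties asserted
there (coverage, bias, ordering of models) are robust to that choice.

### Selection estimators

Selection is estimated on plant means (the independent biological unit;
replicate flowers are averaged). Traits are variance-standardized, so all
coefficients are in SD units. Expected absolute fitness
$\hat W(z)$ comes from a binomial GAM (logit link, fruits out of flower
scars) with penalized spline terms for the trait(s), a ridge-penalized
(random-effect) site term and a spline in elevation; smoothing parameters
are chosen by REML. Relative fitness is $w(z) = \hat W(z)/\bar W$ with
$\bar W$ the mean prediction over the observed plants, each at its own
covariate values. The standardized coefficients are averaged derivatives:

$$\beta_j = \overline{\partial w/\partial z_j}, \qquad
  \gamma_{jk} = \overline{\partial^2 w/\partial z_j \partial z_k},$$

approximated by central finite differences with step $10^{-3}$ SD and
averaged over the observed phenotype distribution. Univariate surfaces
yield the differentials $s$ and $c$; the bivariate surface yields the
gradients $\beta$ and the symmetric $\gamma$ matrix including the
interaction. Quadratic coefficients follow the averaged-second-derivative
convention *without* halving — i.e. twice the corresponding quadratic
regression coefficient; in the identity-link, unpenalized limit the
estimators reduce exactly to the classical least-squares gradients (this
equivalence is a unit test). Standard errors and two-sided p-values come
from resampling plants with replacement (default 2 000 replicates) with a
+1 continuity correction on the bootstrap sign counts.

### Power

For a GREML-style analysis the sampling error of $\hat h^2$ is
$\sqrt{2/(n^2 \mathrm{var}_{rel})}$ with $\mathrm{var}_{rel}$ the variance
of off-diagonal relatedness, and power follows from a one-degree
non-central chi-squared test. The conventional unrelated-sample value
$\mathrm{var}_{rel} = 2\times 10^{-5}$ is the default; a sample containing
relatives has larger $\mathrm{var}_{rel}$ and correspondingly more power,
so the empirical GRM value can be substituted (`var_rel = "auto"`). For
the genetic correlation we use a delta-method approximation to the
sampling variance of $\hat r_G$ from the bivariate GREML (co)variance
estimates with fully overlapping samples, and a two-sided normal test; at
$r_G = 0$ the power equals the significance level exactly.

## The synthetic-data generator

The generator is the package's study stand-in, and its defaults *are* the
emulated design: 6 sites, 40 plants per site, 5 flowers per plant, 2 000
SNPs (configurable up to the full panel size of roughly ten thousand).

* **Genotypes** arise by gene dropping: full-sib families (mean sibship 3)
  with Hardy–Weinberg founder parents at shared allele frequencies
  (uniform on 0.05–0.5), so between-site differentiation is negligible
  while pairwise relatedness varies — most pairs below 0.2 with a long
  right tail of sibs near 0.5, the precondition for GRM-based estimation.
  A migration fraction (0.1) places some family members in foreign sites.
* **Breeding values** are genotype-based — sums of per-locus effects over
  centred dosages — rescaled so the realized additive variance equals the
  target $V_a$ exactly, which makes parameter-recovery tests sharp.
  Effects for the two traits are drawn with correlation $r_G$ (default
  0.06).
* **Phenotypes** add elevation slope, site, permanent-environment and
  flower-level residual effects. The drawn environmental effect vectors
  are standardized to exact zero mean, unit variance and exact pairwise
  correlation: with only six site values the *realized* variance of raw
  draws would otherwise wander far from the target and make the emulated
  variance partition meaningless. The cross-trait environmental
  correlation is solved analytically so that plant means correlate at 0.43.
* **Default trait parameters.** Flower weight (mean 20 mg): $V_a = 2.66$,
  $V_s = 10.07$, $V_i = 3.61$, $V_{error} = 2.66$, giving $h^2 = 0.14$,
  a 53/33/14 site/individual/within variance partition, repeatability
  around 86% and a plant-mean CV near 21%. Standard-petal area (mean
  55 mm²): $V_a = 0.16$ (i.e. $h^2 = 0.001$), $V_s = 63.6$, $V_i = 66.6$,
  $V_{error} = 28.6$. Per-site elevations span 120–850 m (the design's
  elevation gradient; the exact values are a package choice) with small
  positive elevation slopes on both traits.
* **Fitness** follows a Gaussian stabilizing surface on plant-mean
  standard-petal area: fruit probability
  $p(z) = p_{max}\exp(-(z-\theta)^2/2\omega^2)$, flower scars
  $1+\mathrm{Poisson}(29)$, fruits binomial. With the optimum at the trait
  mean, the analytic standardized quadratic gradient is
  $\gamma = -1/(1+\omega_{sd}^2)$; the default width $\omega_{sd} = 3.26$
  SD is the solution of $\gamma = -0.086$. The generator records both this
  normal-theory value and its empirical counterpart over the simulated
  plants.
* **Censuses** draw Poisson visit counts at 0.015 visits per flower per
  3-minute census, partitioned multinomially among taxa (91% honeybee,
  7% bumblebee, 2% other).

What the generator does *not* emulate: linkage disequilibrium and genotyping
error in the SNP panel, selfing or inbreeding dynamics, spatial
autocorrelation within sites, G×E, and non-Gaussian trait distributions.
Passing tests therefore demonstrate correctness of the estimators under
the design's idealized stochastic structure, not robustness to those
real-data complications.

## Numerical choices and edge cases

* QC filter order is locus call rate → MAF → individual call rate → oHET,
  with oHET recomputed on the surviving individuals; the report carries
  per-step counts so the order's effect stays visible. Whether individual
  call rate should precede locus filtering is ambiguous in the field; the
  chosen order is documented in the report itself.
* The GRM uses a single global denominator $2\sum_k p_k(1-p_k)$
  (VanRaden "method 1"), frequencies from the analysed sample, and drops
  monomorphic loci with a logged count. Missing dosages are mean-imputed
  (the expectation under the estimated allele frequency).
* `stabilize_for_inversion()` adds a diagonal ridge (base $10^{-6}$,
  doubled until the smallest eigenvalue clears $10^{-8}$) so duplicated
  individuals cannot break the animal model; the ridge applied is
  recorded.
* Elevation is centred and scaled to unit SD inside the design matrix:
  since elevation is constant within site, the fixed-effect block is held
  up only by the priors, and unscaled metres make the mixed-model
  equations ill-conditioned. The slope is reported per elevation SD.
* Variance-partition moment estimators truncate negative components at
  zero and renormalize; unbalanced designs use the classical
  expected-mean-squares coefficients.
* Bootstrap refits that fail are dropped and counted; more than 10%
  failures aborts. Derivative steps below $10^{-8}$ SD are rejected.
* With only a handful of sites the site-variance posterior is heavy-tailed
  (its 95% interval can reach an order of magnitude above the point
  estimate); that is a property of six site levels under weak priors, not
  of the sampler.

## Design decisions that were genuinely open

* **"Independent chains."** The target of five thousand independent MCMC
  samples is read as an effective-sample-size target for one long chain,
  not five thousand literal chains; the drivers' default chain lengths are
  sized accordingly.
* **Uniform standardization of selection coefficients.** Differentials
  and gradients are all variance-standardized; reported tables from field
  studies sometimes mix standardizations between differentials and
  gradients, so exact scale comparisons of $c$ values should be made with
  care.
* **Census share rounding.** Taxon visit shares are reported as computed
  (e.g. 331 of 364 visits rounds to 91%), even where a source table may
  round differently.
* **$\bar W$** is the mean of model-predicted fitness over observed
  plants, not raw mean fruit set — consistency with the derivative
  estimator matters more than matching the raw mean (the two differ by
  the GAM's smoothing).
* The pipeline's interface is R functions plus the numbered scripts under
  `analysis/`; a shell CLI would add nothing for an analysis whose users
  work in R.

## Limitations

Heritability estimates at this design (about 240 plants, six sites) carry
wide credible intervals, and the power analysis shows that $h^2$ below
about 0.1 is essentially undetectable — conclusions about "zero"
heritability are really conclusions about upper bounds. The genetic
correlation is weakly identified when either trait's additive variance is
near zero. DIC for hierarchical models depends on the deviance convention;
only within-convention comparisons are meaningful. The bootstrap treats
plants as exchangeable and ignores any spatial dependence within sites
beyond the modelled terms.

## A worked example

```{r example, eval = FALSE}
study <- simulate_study(sim_config(seed = 7))
G <- stabilize_for_inversion(vanraden_grm(impute_missing(study$genotypes)))
fit <- fit_univariate_animal_model(
  build_model_matrices(study$phenotypes, model_spec("flower_weight_mg"), G),
  chain = chain_control(n_iter = 3000, burnin = 1000, thin = 2))
heritability(fit)$mean     # ~0.15 for this seed; truth 0.14
evolvability(fit)$mean     # ~0.6% of the squared trait mean
```

The numbers printed by the `analysis/` drivers and by
`scripts/acceptance.R` are produced by exactly these functions at longer
chain lengths.
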