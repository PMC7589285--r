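---
title: "Estimating repeatability and heritability of social-cue use in breeding-site choice"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating repeatability and heritability of social-cue use in breeding-site choice}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cueqg)
```

## The problem

Migratory cavity nesters prospect before settling: the presence and success
of conspecifics, and of resident competitors such as great tits, are cues
about site quality.  Because a pair's nest-site decision is a *joint*
phenotype — both the female and the male contribute to it — estimating its
genetic basis needs more than a standard animal model: the additive genetic
values of both mates act on one phenotype, and a cross-sex additive genetic
covariance can amplify or dampen the response to selection.

`cueqg` implements the full analysis chain: distance-weighted cue response
variables, pedigree relationship matrices, Bayesian mixed models for
repeatability and for the joint-phenotype animal model, and the derived
ratios with highest-posterior-density (HPD) summaries.

## Cue response variables

For a pair that chose box $i$ in year $t$, the raw response for a cue is

$$Y_i = N_i - \frac{\sum_b p_b N_b}{\sum_b p_b},$$

where the sum runs over all boxes $b$ that were empty (available) in the
patch on the pair's choice date, $p_b$ is the box's historical occupancy
probability, and

$$N_i = \sum_{j \in \text{patch}} e^{-d_{ij}/\alpha}\, c_j$$

is the neighbourhood value: $c_j$ is an occupancy indicator (abundance
cues) or a fledgling count (success cues) in the reference year, and
$d_{ij}$ the planar Euclidean distance in meters.  Design choices worth
making explicit:

* **The focal box is part of its own neighbourhood** (weight
  $e^0 = 1$); at $\alpha = 1$ m the neighbourhood is effectively the focal
  box alone.
* **No truncation**: all same-patch boxes contribute however small their
  weight.  The "radius" reported by `nonnegligible_radius()` (largest
  integer $d$ with weight $> 0.05$; 20, 2, 248, 32 and 224 m at the five
  default scales) is descriptive only.
* **Patch restriction is absolute**: boxes of other patches never enter,
  no matter how close in coordinates.
* **Occupancy weighting applies to the availability average only**, not
  inside the neighbourhood sums; if all available boxes have $p_b = 0$
  (possible in synthetic data) the unweighted mean is used with a warning.
* **Missingness**: a previous-year cue in a patch-year with no records at
  all is missing, not zero; partially missing records are an error naming
  the boxes, since they indicate a malformed dataset rather than an
  unmonitored patch.
* **Normalization** divides each cue's responses by the root mean square
  over all non-missing observations of that cue (once, over the full
  analysis dataset after event exclusions), so `mean(y^2) = 1` and variance
  components are comparable across cues.  Events lacking a defined status
  for either pair member are dropped before anything else.

## Relationship matrices

`prune_pedigree()` keeps phenotyped individuals and all their ancestors.
`additive_matrix()` uses the tabular method (diagonal $1 + F_i$, unknown
parents treated as unrelated non-inbred founders).  `dominance_matrix()`
uses the standard non-inbred construction
$D_{ij} = \tfrac14 (A_{s_i s_j} A_{d_i d_j} + A_{s_i d_j} A_{d_i s_j})$
with unit diagonal and zeros whenever a parent is unknown; an
inbreeding-corrected dominance matrix is out of scope and its absence is a
known approximation.  Mate relatedness ($2k_\text{mean}$, the mean
$A_{fm}$ over the female-male pairs) is computed from the same matrix.

## The models

Repeatability stage, per cue:

$$y = X\beta + Z_1 PI_f + Z_2 PI_m + Z_3 Patch + Z_4 Box + e.$$

Genetic stage, for cues passing the repeatability screen:

$$y = X\beta + Z_5 a_f + Z_6 a_m + Z_7 Dom_f + Z_8 Dom_m
      + Z_9 PI_f + Z_{10} PI_m + Z_{11} Patch + Z_{12} Box + e,$$

with $(a_f, a_m) \sim \mathrm{MVN}(0, C_A \otimes A)$.  The fixed design is
the full factorial of female status $\times$ male status $\times$ choice
date (statuses: yearling, older philopatric, older immigrant; 18 columns),
with the date centered — whether the original analyses centered it is not
recoverable, so centering is applied and recorded here.  An intercept-only
design is available and is what the simulators use by default (with small
simulated studies the full factorial can have empty cells and is then
reported as rank deficient rather than silently dropped).

The female-male permanent-environment covariance is never fitted; the
dominance covariance is available in principle but off by default.  Derived
metrics are computed per draw and then summarized:
$R$-ratios from the repeatability draws, and from the genetic draws

$$V_P = V_{A f} + V_{A m} + 2k_\text{mean}\, 2\,\mathrm{Cov}_A
        + V_{DOM f} + V_{DOM m} + V_{PI f} + V_{PI m}
        + V_{PATCH} + V_{BOX} + V_R,$$

$$V_{A\,\text{total}} = V_{Af} + V_{Am} + 2\,\mathrm{Cov}_A, \qquad
  T^2 = V_{A\,\text{total}} / V_P.$$

The $2k_\text{mean} \cdot 2\mathrm{Cov}_A$ reading of the covariance term
treats it as the covariance contribution of two correlated genetic values
whose correlation is scaled by mate relatedness; at realistic
$2k_\text{mean} \approx 10^{-3}$ it is numerically negligible, which is why
the two plausible readings of the term cannot be distinguished empirically.
Medians of ratios are used throughout — ratios of medians are a different
(wrong) quantity and the test suite checks the distinction.

## The sampler

All full conditionals of the Gaussian hierarchical model are available in
closed form, so the model is fitted by blocked Gibbs sampling with no
tuning:

1. **Location effects** ($\beta$ and all random effects) are drawn from
   multivariate-normal full conditionals by sparse Cholesky solves of the
   mixed-model equations.  When only one update block exists this is a
   single joint draw.  With both female- and male-indexed effects present,
   effects are drawn in three blocks — (fixed, patch, box), female-side
   ($a_f, Dom_f, PI_f$), male-side — because the female-male coupling
   created by shared observations (the "mating graph") makes the joint
   equations fill in heavily under any ordering, while each sex-block stays
   pedigree-sparse and factors in milliseconds.  The blocks are full
   conditional draws, so the chain remains a valid Gibbs sampler; the cost
   is somewhat slower mixing of the female/male split of strongly coupled
   effects, which the retained-draw diagnostics monitor.
2. **Working parameters.**  Every non-residual variance is parameter
   expanded: the effect enters the model as $\alpha_k \eta_k$ with
   $\eta_k \sim N(0, \sigma^2_{\eta k} K)$ and
   $\alpha_k \sim N(0, 1000)$.  The reported component is
   $\alpha_k^2 \sigma^2_{\eta k}$, which mixes well near zero — essential
   here because most genetic components of interest are near zero.  The
   2x2 genetic block uses one working parameter per sex around an
   inverse-Wishart (`V = diag(2)`, `nu = 2`) base matrix; the reference
   software's exact expansion parameterization is not published, so this
   scheme is validated against conjugate closed forms instead of against a
   line-by-line reimplementation.
3. **Variances** are drawn from scaled inverse-$\chi^2$ (scalar) or
   inverse-Wishart (2x2) full conditionals; the residual prior is
   inverse-Wishart with `V = 1`, `nu = 1`.

Numerical choices: the additive precision over the full pruned pedigree is
obtained by a direct dense solve followed by dropping entries below
`1e-8` (the pedigree structure guarantees the true inverse is sparse); the
dominance matrix is restricted to phenotyped individuals — an exact
marginalization for multivariate-normal effects — and inverted block by
block over the connected components of its nonzero graph, which for
realistic pedigrees are small sib/cousin clusters.  Cholesky failures
escalate through diagonal jitter from `1e-8` and are logged.  Fixed effects
carry a `1e-8` ridge so the equations are always positive definite;
per-chain seeds are derived deterministically from the master seed.

## Chain protocols and problem sizes

`mcmc_settings(profile = "paper")` is the full field protocol (3 chains of
2,550,000 iterations, burn-in 50,000, thinning 500).  The `"desk"` profile
(3 chains of 55,000, burn-in 5,000, thinning 50) suits interactive work.
The package's own validation suites use explicitly passed, smaller
protocols (typically one chain of 1,100–11,000 iterations retaining
400–10,000 draws) on simulated studies of 800–1,500 pair-years with
roughly 300–700 phenotyped individuals per sex; these sizes were chosen so
that the whole suite, including twenty-replicate recovery studies, runs on
a single desktop core while posterior medians of the well-identified
components are stable to within a few percent.  Single chains are used in
replicate studies because the quantities checked there are medians, not
convergence diagnostics; multi-chain PSRF checks are exercised separately.

## The repeatability screen

"The posterior of total repeatability is distributed away from zero" is a
visual criterion in the original workflow and cannot be recovered exactly.
It is operationalized as a configurable rule (`screen_rule()`): the lower
bound of the 95% HPD interval of $R_\text{total}$ must be at least 0.01
and at most 20% of the posterior mass may lie below 0.01.  On posteriors
shaped like the retained cues of the study system (median around 0.11 with
HPD from about 0.04 to 0.20) the rule passes; on posteriors piled onto
zero it fails.  Cues passing the screen get the genetic model with the
cross-sex covariance first; if the covariance HPD spans zero the headline
heritabilities come from a refit without it.

## What the simulators emulate — and what they do not

`simulate_landscape()` reproduces the geometry that matters for the cue
computation: discrete patch squares, boxes in excess, beta-distributed
historical occupancy (mean 2/3).  `simulate_pedigree()` grows founders
through random-pairing generations with Poisson sibships, partial
recruitment and unknown-parent immigrants.  `simulate_choice_histories()`
produces yearly great-tit occupancy, sequential flycatcher settlement
(softmax over attraction-weighted neighbourhood values, computed with the
same cue operators the analysis uses; uniform when all attractions are
zero), bounded-Poisson fledgling counts, random re-pairing of survivors
with patch-assortative alignment (so that philopatric-by-philopatric
status cells are populated), and statuses derived from individual
histories.  `simulate_phenotypes()` draws additive values by
generation-ordered gene dropping — exact for the pedigree MVN, including
the bivariate female/male case with cross-sex covariance and
inbreeding-adjusted Mendelian variances — dominance deviations through a
PSD square root of `D`, and iid permanent, patch, box and residual effects.

Simulated survivors breed in ~2–3 seasons on average, more than the wild
population's typical 1–2, which sharpens the separation of permanent
individual from residual variance at desk scale; real data will give wider
permanent-effect posteriors than the tests suggest.  Other features of real
data the generator does not emulate: extra-pair paternity (the social
pedigree is taken at face value), heterospecific feedback on tit dynamics,
climate or phenology trends, and density-dependent demography.  Passing
tests therefore demonstrate correctness of the estimator on data from the
assumed model, not robustness to these violations.

## Known limitations

* Non-Gaussian responses, REML inference, multi-trait models and indirect
  genetic effects from non-mate neighbours are out of scope.
* The dominance construction ignores inbreeding in `D` (standard, but an
  approximation in inbred pedigrees).
* The spatial scales $\alpha$ are inputs, not estimated; selecting them by
  model comparison across scales is a separate exercise.
* With few records per individual the female/male split of permanent and
  genetic variance is weakly identified; totals ($R_\text{total}$,
  $T^2$) are the robust quantities.
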