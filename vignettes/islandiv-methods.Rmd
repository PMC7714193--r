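---
title: "Modelling land-use effects on alien and native island assemblages"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling land-use effects on alien and native island assemblages}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(islandiv)
```

## The scientific problem

Islands host assemblages that are both unusually vulnerable to human
disturbance and unusually prone to invasion. `islandiv` implements a pipeline
for asking, with hierarchical site-level biodiversity data, three linked
questions:

1. How do land use and related pressures (human population density, distance
   to the nearest road) change the local **total abundance** and **species
   richness** of native versus alien species?
2. Do island characteristics — area, isolation (surrounding landmass), and
   per-capita GDP as an economic proxy — predict alien diversity, and does
   the effect differ among land uses?
3. How does land-use change reshape **community composition**: do converted
   sites hold novel species relative to minimally-disturbed sites, and do
   assemblages within a land use become more alike (biotic homogenization)?

The data model mirrors collated land-use comparison databases: records are
organised as data source > study > spatial block > site, with a status label
(native / alien / unknown) per taxon.

## Site-level diversity models

For each status separately, a site's total abundance is the sum of its
measurements (divided by sampling effort when effort varies within the
study), and its richness is the number of distinct taxa recorded with a
positive measurement. Studies that targeted a single status leave the other
status missing; whole-assemblage studies whose classified records are all
one status contribute zeros for the absent status. Because not every species
can be classified, each site is weighted by its proportion of classified
species.

Abundance is rarely a comparable count across studies, so it is rescaled to
`[0, 1]` within each study (one shared maximum across native and alien rows —
the two statuses stay on a common scale) and square-root transformed, then
modelled with a Gaussian linear mixed model. Richness is modelled as Poisson
with a log link; an observation-level random effect (OLRE) absorbs
extra-Poisson variance. Human population density is `ln(x+1)`-transformed,
road distance `ln`-transformed (`ln(x+1)` if the data contain zeros, which
gridded road-distance products do not but simulated data may), both min-max
rescaled over the modelling dataset and entered as orthonormal quadratic
polynomials (`stats::poly`, i.e. Gram–Schmidt of the centred powers).

Six candidate random-effect structures are supported, from random land-use
slopes within study plus intercepts for study, block-in-study and island,
down to a study intercept alone. `select_random_structure()` compares
candidates by AIC (REML for Gaussian fits, Laplace ML for Poisson) and drops
candidates that fail to converge — the criterion is a package convention;
comparing non-nested random structures by AIC is the common practice where a
single prescribed test does not exist. Fixed effects are then simplified by
backward stepwise elimination with ML likelihood-ratio tests
(`backward_simplify()`), respecting marginality: a main effect is never
tested while it appears in a retained interaction. Collinearity is screened
with generalized variance inflation factors computed from the determinant
formula on the fixed-effect correlation matrix.

## Compositional similarity

Turnover is measured with the **asymmetric Jaccard index** over all ordered
within-study site pairs: `J_R = S_ij / S_j` (the share of site *j*'s species
also found at site *i*) and its abundance version `J_A = A_ij / A_j`. Both
are 1 when *j*'s assemblage is nested in *i*'s, 0 when the sites share
nothing, and undefined when site *j* is empty (such pairs are dropped; the
reverse direction, with a non-empty *j*, is kept — the statistic reads as
"the share of *j*'s assemblage present at *i*", so an empty *j* is 0/0).

Pairs carry a 49-level ordered land-use contrast (baseline
`PriMin-PriMin`, natural spatial turnover among minimally-disturbed sites),
the haversine geographic distance (sphere radius 6,378,137 m) divided by the
median maximum linear extent of the sites and ln-transformed (0 = adjacent
sites), and a Gower environmental distance over altitude and four
bioclimatic variables with ranges computed once over the modelling dataset
(a single dissimilarity definition across studies, rather than per-study
ranges). Similarities are logit-transformed after compressing `[0,1]` to
`[0.01, 0.99]` (`y -> 0.01 + 0.98 y`); compression rather than clamping
keeps the transform strictly monotone. Environmental distance enters as its
cube root. Studies with presence-only records, varying effort, or a single
sampled species contribute no pairs, so richness- and abundance-based models
use the same studies; pairs with zero geographic distance or missing
environmental data are excluded, and every exclusion is counted in the pair
table's `exclusions` attribute.

Because every site enters many pairs, standard tests are invalid.
Significance comes from **within-study permutation**: the response is
shuffled among rows within each study (explanatory columns and weights stay
in place), the nested model pair is refitted, and the inclusive Monte-Carlo
p-value `(1 + #{null >= observed}) / (1 + n_perm)` is reported — with 199
permutations the attainable floor is 1/200 = 0.005. Coefficient tests are
two-tailed by absolute value. Each term test in
`stepwise_with_permutation()` regenerates its permutations from a seed tree
(master seed, then one stream per test, then one per permutation), so
results are reproducible and independent of execution order; reusing one set
of permuted datasets across tests would be equally valid, regeneration was
chosen for statelessness.

## Reporting scale

Fitted models are reported as percentage change versus the `PriMin`
baseline. Square-root-scale abundance fits back-transform as
`(s1^2/s0^2 - 1) * 100` with the group's Wald limits transformed the same
way (hence asymmetric intervals); the baseline prediction puts all numeric
covariates — including the orthogonal polynomial columns — at zero. Log-link
richness fits report `(exp(beta) - 1) * 100` with exponentiated Wald limits.
Similarity fits report the 13 focal contrasts (PriMin against each land use;
each land use with itself) on the adjusted-logit scale and back-transformed;
contrasts supported by fewer than 3 studies are flagged unreliable rather
than silently shown.

## The synthetic generator

`simulate_dataset()` is a first-class, tested forward model of the
statistical structure the analysis assumes — not of real biogeography (no
species–area curves, no phylogenetic structure, no spatial autocorrelation
beyond the built-in distance decay). Its key design choices:

* **Exact effect channels.** Species presence is Bernoulli with probability
  proportional to the status' richness effect for the site's land use, a
  per-species geographic retention, an isolation multiplier for aliens, and
  gamma site-level heterogeneity. Counts for present species are
  zero-truncated gamma-Poisson whose conditional means allocate the site's
  expected total so that the *classified* total abundance of each status has
  expectation `baseline x land-use effect x exp(study + block + island +
  slope deviations)` **exactly** — classification failure is orthogonal to
  abundance, so generating truths are recoverable without
  transformation-bias corrections.
* **Distance decay.** Each species is anchored at a random point in its
  study's extent; retention falls as `(1 + d/100 m)^(-decay_rate_geo)` and
  is normalised within species so that decay concentrates occurrences near
  anchors without changing mean occupancy. Nearby sites therefore share more
  species, and mean `J_R` among distant pairs falls strictly as the decay
  rate rises.
* **Overdispersion with one dial.** `overdispersion` (theta) sets the count
  model's quadratic overdispersion (`Var = mu + theta mu^2`; 0 is Poisson)
  and scales the gamma occupancy heterogeneity (CV^2 = theta/4), so richness
  is genuinely overdispersed and the OLRE in the richness model has signal
  to absorb.
* **Unclassified species** are relabelled `unknown` at the species level
  with probability `unclassified_fraction`, making the expected site weight
  `1 - unclassified_fraction`.

Default conditions: 20 studies of 12 sites on 6 islands (blocks of 2 per
study), native/alien pools of 80/30 species per island, native abundance
effects 0.97/0.88/0.70/0.79/0.68/0.92 (Primary through Urban, PriMin = 1)
and native richness effects down to 0.50 (cropland) and 0.35 (pasture) —
effect sizes of the order reported for island assemblages — alien effects
strongly positive in human-dominated land uses, isolation slope -2.9 on log
alien occupancy per unit surrounding landmass, overdispersion 0.35,
random-effect SDs 0.25/0.1/0.1/0.08 (study/block/island/slope, log scale),
decay rate 0.15, and 20% unclassified species. With baseline occupancies of
0.5 (native) and 0.2 (alien) these defaults put the alien share of
classified species in minimally-used primary vegetation near one-sixth.
These sizes keep a full replicate (simulate, metrics, two mixed models)
around two seconds, so calibration and coverage experiments run at
hundreds of replicates.

What passing tests on these data do **not** show: robustness to taxonomic
error, spatially autocorrelated sampling, non-multiplicative land-use
effects, or informative missingness of classification — none of which the
generator emulates.

## Numerical choices and degenerate inputs

* Gaussian fits use REML for estimation and selection, ML for
  likelihood-ratio comparisons; Poisson fits always use the Laplace
  approximation (bobyqa optimizer). Convergence and singularity are recorded
  on every fit, never silently discarded; a singular fit (a variance
  component at zero) is a report, not an error.
* Nested ML log-likelihood differences below zero by less than 0.02 are
  treated as optimizer noise and clamped to zero; larger inversions abort
  the simplification step.
* Weights of zero drop the observation (a site with no classified species
  carries no information); rank-deficient fixed-effect designs raise an
  error naming the aliased columns rather than letting the optimizer drop
  them.
* `alpha = 0` in the stepwise routines disables dropping and returns the
  full model.
* All-zero abundance studies rescale to zeros without division errors; an
  all-equal pressure covariate cannot be min-max rescaled and raises an
  error naming the covariate.
* Status precedence in `attach_status()` is island scope over country
  scope; conflicting duplicate keys within one scope are an error, not a
  silent pick.

## Worked example

```{r example}
library(islandiv)

run <- run_pipeline(sim_config(seed = 1), permutations = FALSE)
dplyr::filter(run$effects, status == "native", channel == "abundance")
run$alien_share
autoplot(run$effects)
```

## Known limitations

* Wald intervals (normal quantiles) are used throughout, as is conventional
  for these models; with few studies they are slightly anticonservative, and
  profile or parametric-bootstrap intervals are out of scope.
* The permutation scheme assumes exchangeability of responses within
  studies; restricted schemes (e.g. within blocks) are not implemented.
* External data sources — status databases, GIS rasters for population
  density and road distance, island polygon and buffer computations — are
  out of scope: statuses, pressures and island traits arrive as columns.
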