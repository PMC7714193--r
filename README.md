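# islandiv

Mixed-effects and permutation-based tools for quantifying how land-use
change and related human pressures reshape **alien versus native species
assemblages on islands**, using hierarchical site-level biodiversity data
(data source > study > block > site records with a native/alien/unknown
status per taxon).

## What it computes

**Site-level diversity.** Per site and status: effort-corrected total
abundance and species richness, with each site weighted by its proportion of
classified species. Abundance is rescaled to a shared `[0, 1]` scale within
each study and square-root transformed, then modelled with a Gaussian linear
mixed model; richness is modelled as Poisson (log link) with an
observation-level random effect for overdispersion. Candidate random-effect
structures (random land-use slopes within study; intercepts for study, block
nested in study, island) are compared by AIC, and fixed effects are
simplified backwards with ML likelihood-ratio tests under marginality.
Results are reported as percentage change versus minimally-used primary
vegetation (**PriMin**), back-transformed with asymmetric Wald intervals.

**Compositional similarity.** For all ordered within-study site pairs, the
asymmetric Jaccard indices

```
J_R = S_ij / S_j        J_A = A_ij / A_j
```

where `S_ij` (`A_ij`) is the number (summed abundance at site *j*) of
species common to both sites, and `S_j` (`A_j`) the number (summed
abundance) of all species at site *j*. Both equal 1 when site *j*'s
assemblage is nested in site *i*'s and 0 when the sites share nothing.
Similarities are modelled on an adjusted logit scale against a 49-level
ordered land-use contrast (baseline `PriMin-PriMin`), ln geographic distance
scaled by the median maximum linear extent, and cube-root Gower
environmental distance. Because pairs are non-independent, terms are tested
by **within-study permutation** of the response (199 permutations by
default; the inclusive Monte-Carlo p-value has floor 1/200 = 0.005), with
two-tailed coefficient tests.

**Synthetic data.** `simulate_dataset()` generates PREDICTS-style datasets
with known multiplicative land-use effects on abundance and richness per
status, gamma-Poisson counts, geographic distance decay of composition, an
island-isolation effect on alien occupancy, and a configurable unclassified
fraction — so the whole pipeline is testable end to end with exact
generating truths.

## Worked example

```r
library(islandiv)

run <- run_pipeline(sim_config(seed = 1), permutations = FALSE)
subset(run$effects, status == "native" & channel == "abundance")
```

```
    land_use percent_change ci_low ci_high
1     PriMin           0.00    0.0    0.00
2    Primary          -6.68  -17.8    5.16
3  Secondary         -15.17  -25.9   -3.68
4 Plantation         -31.51  -40.0  -22.43
5   Cropland         -23.40  -33.5  -12.52
6    Pasture         -34.93  -43.5  -25.81
7      Urban         -17.12  -27.5   -6.05
```

Native total abundance falls by about 35% in pastures, 31% in plantation
forests, 23% in croplands and 15% in secondary vegetation relative to
PriMin — the generating truths for this seed are -32, -30, -21 and -12%, all
inside the asymmetric 95% intervals. The alien share of classified species
at PriMin sites for the same run:

```r
run$alien_share[1, ]
#>   land_use share_richness share_abundance n_sites
#> 1   PriMin           14.8            23.8      52
```

`autoplot(run$effects)` draws the forest-style percentage-change panel;
`plot_similarity_contrasts(run$similarity)` shows compositional similarity
for the focal land-use contrasts against the `PriMin-PriMin` baseline.

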