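# vocalconverge

Tools for studying **vocal convergence** — the increase in acoustic
similarity between individuals' calls as they form social relationships —
in the frequency-modulated contact calls of group-living bats.

Bats isolated from their group produce short (3–50 ms) downward FM
"contact calls" that carry individual signatures. When strangers are
housed together, their calls are predicted to converge, and within a
group, pairs with the strongest cooperative relationships (food sharing)
are predicted to converge further. Testing these predictions requires a
per-pair similarity measure that controls for both callers' identities,
and regression machinery for dyadic outcomes. This package implements the
whole chain, plus a synthetic-data generator with complete ground truth so
every statistical step can be validated.

## What the package computes

1. **Synthetic recordings** (`make_population`, `apply_convergence`,
   `generate_recording_session`): bats with known FM-contour signatures
   (start/end frequency, duration, curvature), site-level group
   signatures, heavy-tailed call counts, a dyadic social structure
   (kinship, co-housing, allogrooming/food-sharing rates), and injected
   convergence of known strength.
2. **Call detection and filtering** (`detect_calls`, `filter_calls`,
   `remove_clipped`, `resample_to_250k`): amplitude + spectral-density
   segmentation at 250 kHz; inclusion filters of 3–50 ms duration, ≥10 kHz
   peak frequency, ≤0.99 relative amplitude.
3. **35 acoustic features per call** (`extract_all`): 27 spectro-temporal
   measures and 8 slope measures of the tracked fundamental contour.
4. **Caller similarity** (`caller_similarity`): linear discriminant
   analysis classifying calls to bats (leave-one-out accuracy, permutation
   null with randomized caller labels), then for each pair of bats

   &nbsp;&nbsp;&nbsp;&nbsp;*S* = 1 − *D* / max(*D*),

   where *D* is the Mahalanobis distance between the two callers'
   centroids under the pooled within-class covariance. Exact zeros are
   floored at 0.001 so a beta likelihood can model the outcome.
5. **Dyadic regression** (`fit_beta_mm`, `run_model_battery`): Bayesian
   beta **multi-membership** models, logit(μ) = α + Xβ + ½*u*ᵢ + ½*u*ⱼ,
   with per-bat random intercepts, fitted in JAGS; a five-model battery
   disentangles kinship, co-housing, affiliation
   (log(observed+1)/log(sampling)) and food sharing, with split R-hat and
   bulk/tail ESS diagnostics plus posterior predictive checks.
6. **Pre/post-introduction convergence tests** (`pre_post_similarity`,
   `mantel_spearman`, `fit_gaussian_mm`, `pdfa_site`): similarity change
   between two independent DFAs, a Spearman Mantel test permuting
   individuals, a Gaussian multi-membership model of the change, and a
   permuted site-classification DFA that holds out whole bats.

A staged pipeline (`run_pipeline`, YAML-configurable, fully seeded and
byte-reproducible; see `inst/scripts/run-pipeline.R` for a shell wrapper)
runs simulate → detect → features → similarity → models → convergence and
writes CSV/JSON artifacts with a hash manifest.

## Worked example

```r
library(vocalconverge)
# 1. simulate a population: 14 bats from 2 sites, half captured into a colony
pop <- make_population(14, 2, config = convergence_spec(0.5, 0),
                       seed = 7, p_captive = 0.5)
converged <- apply_convergence(pop)

# 2. synthesize calls and extract the 35 acoustic features
calls <- simulate_feature_table(converged$bats, calls_per_bat = 80, seed = 8)
dim(calls)
#> [1] 1120   38

# 3. caller similarity from the discriminant analysis
S <- caller_similarity(calls, min_calls = 60)
round(unclass(S)[1:5, 1:5], 3)
#>       bat01 bat02 bat03 bat04 bat05
#> bat01 1.000 0.517 0.262 0.694 0.578
#> bat02 0.517 1.000 0.018 0.772 0.194
#> bat03 0.262 0.018 1.000 0.129 0.204
#> bat04 0.694 0.772 0.129 1.000 0.320
#> bat05 0.578 0.194 0.204 0.320 1.000

cv <- classify_loocv(calls[, c("bat_id", as.character(feature_names()))])
round(cv$overall, 3)
#> [1] 0.688

# 4. dyadic regression: does co-housing predict similarity?
dyads <- build_dyad_table(S, converged$social, converged$bats)
fit <- fit_beta_mm(dyads, "cohoused",
                   mcmc = mcmc_control(chains = 4, iter = 3000,
                                       warmup = 1000, seed = 9))
print(fit)
#> <mm_fit: beta outcome, 91 dyads, 14 bats, 4 chains>
#>  parameter    mean      sd  ci_2.5  ci_97.5  rhat ess_bulk ess_tail
#>  intercept -0.2200 0.07266 -0.3623 -0.07867 1.002     3258     5890
#>   cohoused  0.6068 0.24545  0.1186  1.07968 1.005     1230     2346
#>  sigma_bat  1.3519 0.31865  0.8685  2.10704 1.006     2075     2625
#>        phi 12.8468 2.05303  9.1261 17.26535 1.002     3075     3767
```

Calls classify back to their caller at 69% (chance here is ~7%), and the
co-housing coefficient is positive with a 95% credible interval excluding
zero — the injected convergence (half the distance to the colony mean) is
recovered as higher similarity among co-housed pairs while both bats'
identities are controlled by the multi-membership random effects.

The methods vignette (`vignettes/vocal-convergence-methods.Rmd`) documents
the models, every tunable parameter, the generator's assumptions and the
package's numerical choices.

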