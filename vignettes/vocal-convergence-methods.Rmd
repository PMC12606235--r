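---
title: "Measuring vocal convergence in contact calls: models and design choices"
author: "vocalconverge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring vocal convergence in contact calls}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific problem

Group-living bats produce short, downward frequency-modulated "contact
calls" when socially isolated. These calls carry individual signatures, and
a long-standing hypothesis holds that forming affiliative relationships
makes the calls of partners more alike over time (*vocal convergence*).
Testing that hypothesis requires (a) a per-pair measure of call similarity
that controls for both callers' identities, and (b) an experimental
contrast: bats recorded before and after being housed with strangers.

`vocalconverge` implements the full analysis chain for this design, plus a
synthetic-data generator that produces recordings with known ground truth
at every level — individual signatures, group signatures, social structure
and injected convergence — so that every stage of the statistical pipeline
can be validated against truth it was not told.

## Caller similarity from a discriminant analysis

Calls are summarized by 35 acoustic features (below) and classified to
caller with a linear discriminant analysis (LDA) on all features, priors
proportional to class sizes. Individuality is reported as leave-one-out
cross-validated accuracy; a randomized-label permutation null (the same
non-cross-validated DFA refitted with shuffled caller labels) gives the
chance distribution.

Pairwise dissimilarity between callers *i* and *j* is the Mahalanobis
distance between their class centroids under the pooled within-class
covariance \(\Sigma\):

\[ D_{ij} = \sqrt{(\mu_i-\mu_j)^\top \Sigma^{-1} (\mu_i-\mu_j)},
\qquad S_{ij} = 1 - \frac{D_{ij}}{\max(D)} . \]

Similarity is normalized *within the analysis that produced it*: each DFA
has its own \(\max(D)\). The pair attaining the maximum distance would get
similarity exactly 0, which a beta-distributed outcome cannot take, so
exact zeros are replaced by 0.001. Because several features are exact
linear combinations of others (the IQR-type measures), \(\Sigma\) is
rank-deficient by construction; a relative ridge of \(10^{-8}\bar\sigma^2\)
is added before inversion. Centroid differences have no component in the
null directions, so distances are insensitive to the ridge size over many
orders of magnitude.

## The 35 acoustic features

Each detected call contributes 27 spectro-temporal measures and 8 slope
measures of the tracked fundamental contour (times in ms, frequencies in
kHz, slopes in kHz/ms):

* **Temporal**: duration; the 25/50/75% quantiles and IQR of cumulative
  envelope energy.
* **Spectral**, from the band-limited (10–125 kHz) aggregated power
  spectrum: mean, SD, median, quartiles, IQR, skewness, kurtosis, spectral
  entropy, spectral flatness; plus time entropy over frame energies and
  their product (overall entropy); peak frequency and mean per-frame peak
  frequency.
* **Dominant-frequency contour** (per-frame spectral argmax over frames
  holding at least 5% of the maximum frame energy): mean/min/max/start/end,
  range, slope = (end − start)/duration, and modulation index = cumulative
  absolute change / range (defined as 0 for a flat contour).
* **Fundamental slope measures**, from a dominant-bin tracker with
  sub-bin parabolic interpolation, a tonality voicing criterion and a
  continuity constraint: max, min, mean and minimum-absolute inter-frame
  slope; counts of positive and negative slopes; turns (sign changes
  between consecutive slopes exceeding 0.1 kHz/ms in magnitude); and
  segments (maximal runs of voiced frames).

The 27-measure list is a reconstruction of the standard spectro-temporal
suite used for bioacoustic feature extraction; the exact upstream
definitions are not available in machine-readable form, so the definitions
above are normative for this package. Two readings of "absolute minimum
slope" exist; the default is \(\min |s|\), with \(|\min s|\) available via
`slope_measures(..., absmin = "abs_min")`.

The spectrogram default is a 256-sample Hann window (≈1 ms at 250 kHz)
with 75% overlap, which guarantees at least three frames for the shortest
admissible (3 ms) call.

## Call detection and the inclusion filters

Detection combines an amplitude criterion — a 0.5 ms sliding RMS envelope
must exceed `median + 5·MAD` of itself (a robust noise floor that tolerates
sparse calls) — with a spectral-density criterion: at least 70% of the
candidate segment's spectral energy must lie above 10 kHz, which rejects
low-frequency transients. Candidate runs closer than 2 ms (below the
minimum call duration) are merged. The inclusion filters are read
literally: durations in [3, 50] ms inclusive, peak frequency at or above
10 kHz, and removal of calls whose maximum amplitude after full-scale
normalization of the recording exceeds 0.99 (0.99 exactly is kept).
Recordings digitized above 250 kHz are decimated to exactly 250 kHz with a
zero-phase order-128 FIR low-pass, so digitization rate cannot leak into
the measures.

## Dyadic regression: beta multi-membership models

Similarity for the pair \(d=(i,j)\) is modelled as

\[ y_d \sim \mathrm{Beta}(\mu_d\phi, (1-\mu_d)\phi), \qquad
\mathrm{logit}(\mu_d) = \alpha + X_d\beta + \tfrac12 u_i + \tfrac12 u_j,
\qquad u \sim \mathcal N(0, \sigma^2_{bat}), \]

where the half-half multi-membership weights (configurable) make the
random-effect structure symmetric in the two members. Five models with
different inclusion predicates disentangle kinship, co-housing and
affiliation: kinship alone; kinship conditioned on co-housing and
affiliation (with zero affiliation for pairs that never met); co-housing
among non-kin adult-female cross-site pairs; affiliation among non-kin
adult females caged together (kinship ≤ 0.05); and food sharing among the
subset with known sharing rates. Affiliation pools allogrooming and
food-sharing seconds *before* the lograte transform
\(\log(\mathrm{observed}+1)/\log(\mathrm{sampling})\), because the two
behaviours proxy one underlying affiliative dimension. Continuous
predictors are z-scaled with the sample (n−1) SD.

Sampling runs in JAGS with 4 chains of 6000 iterations (2000 warmup) by
default. Priors: Normal(0, 1000 sd) on intercept and coefficients — a
proper, effectively flat prior, since JAGS cannot express improper flats —
half-Student-t(3, 0, 2.5) on \(\sigma_{bat}\), Gamma(0.01, 0.01) on
\(\phi\). The contract on the sampler is calibration, not identity of
implementation: simulation-based checks must show ≈95% CI coverage of
known generating values, and the test suite enforces this at 50 replicates
of 300 dyads. Convergence is monitored with rank-normalized split R-hat
and bulk/tail effective sample sizes; any parameter with R-hat > 1.01
raises a flag (never a silent acceptance). Posterior predictive checks
compare observed mean and SD with their replicated distributions.

## Pre/post-introduction convergence tests

For an introduction experiment the package fits two independent DFAs —
residents plus the focal bats' pre-introduction calls, and the same
residents plus their post-introduction calls — and differences the two
similarity matrices on common pairs. Because each DFA is normalized by its
own \(\max(D)\), the change matrix mixes two scales; the inference is
therefore rank- and sign-based in the predicted direction:

* **Mantel test** of the change matrix against the binary
  introduced-versus-familiar indicator, Spearman correlation over
  off-diagonal pairs, null built by jointly permuting rows and columns of
  one matrix (permuting *individuals*, preserving the dyadic dependence),
  one-tailed in the predicted positive direction (two-tailed by flag). An
  exact mode enumerates all \(n!\) permutations for small designs.
* **Gaussian multi-membership model** of the similarity change on the
  introduced indicator, same random-effect structure and diagnostics as the
  beta models (the outcome can be negative, hence Gaussian).
* **Permuted site DFA**: calls are classified to capture site with whole
  bats held out in rotation (one bat's calls are never split between
  training and test — calls within a bat are pseudo-replicates), and the
  null permutes bat-to-site assignments preserving site sizes. Convergence
  predicts lower site accuracy after the groups merge.

## What the synthetic generator emulates — and what it does not

Bats get per-individual FM-contour signatures: exponential-decay sweeps
\(f(t) = f_{end} + (f_{start}-f_{end})e^{-ct/T}\) parameterized by start and
end frequency, duration and curvature, with between-bat SDs several times
the within-bat SDs (that asymmetry is what makes callers classifiable).
Sites add a group-level mean offset on all four parameters (founder
effects and prior within-group convergence are what site-classification
analyses detect). Calls carry a slow random frequency wobble (~0.8 kHz SD,
100–400 Hz components) and occasional deep amplitude dips: contact calls
are not clean parametric sweeps, and these two ingredients give the
contour-microstructure features (turns, sign counts, segment counts)
natural within-bat variation. Call counts per bat are lognormal
(median 2500, log-SD 1.464, truncated to [100, 100000]), reproducing the
strong right skew of isolation-recording sample sizes (mean ≈ 7300 ≫
median). Sessions place calls at non-overlapping random onsets in white
Gaussian noise with sub-millisecond ground truth.

Convergence is injected mechanistically: co-housed bats' contour means
move a fraction `delta_cohouse` toward their captive group's mean, plus a
partner-specific pull of up to `delta_bond` weighted by each pair's
food-sharing lograte. Only means move; within-bat SDs stay put, so
convergence shifts caller centroids without changing within-class
covariance — the simplest mechanism the similarity measure should detect.
The defaults (0.25 and 0.15) are moderate effects: visible against
individual signatures but far from collapse; direction-check analyses use
0.5–0.7 to emulate a strong co-housing manipulation. For pre/post designs,
`apply_convergence(scope = "within-site")` produces the pre-introduction
state (each site's bats already converged among themselves), and the full
scope produces the post state; within-site pairwise distances then cancel
exactly between epochs, isolating the introduced-pair signal.

Deliberately not modelled: harmonic structure, nonlinear phenomena,
reverberation (isolation chambers are foam-lined), and discrete call-type
repertoires — the generator draws from a unimodal per-bat distribution,
which matches the view of contact-call variation as continuous rather than
categorical. Passing tests on this generator therefore validate the
statistical machinery (detection calibration, similarity geometry, model
calibration, permutation-null behaviour), not the acoustic realism of any
particular species' calls.

## Numerical choices and degenerate inputs

* Covariance ridge: \(10^{-8}\times\) mean diagonal, only when the Cholesky
  factorization fails.
* Turn-count threshold: slopes below 0.1 kHz/ms in magnitude are treated
  as negligible (suppresses frame-quantization jitter); configurable.
* Voicing: a frame is voiced when its spectral peak-to-mean ratio is ≥ 4
  and its energy ≥ 10% of the maximum frame energy; white noise is mostly
  unvoiced under this rule, and deep amplitude dips split the contour.
* An empty contour yields zero counts and zero slope statistics; a
  single-frame spectrogram, a segment shorter than one window, outcomes
  outside (0, 1), and permutation of a site with one bat are errors, not
  silent answers.
* Empty model selections and empty post-filter tables warn explicitly.
* Every stochastic routine takes a seed; pipeline stages derive sub-seeds
  by hashing (global seed, stage name), and rerunning a configuration
  reproduces every output file byte for byte.

## Problem sizes used by the test and calibration suites

Chosen to exercise the statistics at meaningful sizes: null calibration of
the permutation tests uses 200 replicates of zero-signal designs (4 bats ×
25 calls for the randomized-label DFA; 10-bat dyadic matrices for the
Mantel test) at 99 permutations each; parameter recovery uses 50
replicates of 300 dyads (25 bats) for the beta model and 50 replicates of
66 dyads (12 bats) for the Gaussian model, with 2–3 chains of 900–2500
iterations per fit; feature invariants are asserted over 10,000 synthetic
calls; end-to-end direction checks use 14–16 bats with 60 calls each.
Full-scale MCMC defaults (4 × 6000) are used for real analyses; the
shorter calibration chains are justified by the same coverage checks they
compute.

## Known limitations

* The 27-measure suite is a reconstruction (see above); numerical values
  are not interchangeable with other implementations measure-for-measure,
  though the measure *set* and geometry are.
* Similarity is comparable only within one DFA; cross-analysis comparisons
  must go through the change-matrix machinery.
* The beta models require outcomes strictly inside (0, 1) — hence the
  0.001 floor — and dyad tables with fewer than 10 rows are refused.
* The detector is validated against the generator's ground truth, not
  against hand-labelled field recordings; its two thresholds (envelope
  factor, spectral fraction) are explicit configuration, not learned.
* With few never-met bats, the co-housing coefficient and the bat random
  effects are weakly separated (co-housing is almost a bat-level
  property); expect slow MCMC mixing and widen chains accordingly.
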