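---
title: "Context-aware consistency checking for volunteered phenology records"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Context-aware consistency checking for volunteered phenology records}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Volunteered phenology records — "my lilac first flowered on day 132" —
are cheap to collect at continental scale but carry occasional
implausible entries: transcription errors, mis-identified phenophases,
or genuinely anomalous events such as autumn re-flowering after a
frost. A fixed plausibility window cannot separate these from good
records, because what counts as a plausible flowering date depends on
where, and under what accumulated climate, the observation was made: day
95 is unremarkable in a warm lowland site and suspicious in a cold
mountain one.

`phenoflag` implements a context-aware check. Each record is described
by eleven contextual variables, records are grouped into contextually
homogeneous clusters, and a record is flagged only when its onset day of
year (DOY) is extreme *relative to its own cluster*. A final module
quantifies what the flagged records do to the long-term trend in onset
dates — the quantity most phenological analyses ultimately report.

## The workflow

### 1. Context: eleven variables

Three geographic variables (latitude, longitude, elevation in metres)
plus eight cumulative climatic variables, each summed from 1 January of
the observation year to the reported onset day: maximum, minimum and
mean daily temperature (degree-days), day length (s), precipitation (mm), solar
radiation (W/m^2^·day), snow water equivalent (kg/m^2^·day) and water
vapour pressure (Pa·day). Sums, not averages, because phenological
development responds to *accumulated* forcing. The mean daily
temperature is `(tmax + tmin)/2`, so its sum is exactly the mean of the
other two temperature sums — a useful internal consistency check that
the test suite asserts.

Two bookkeeping decisions worth knowing about:

* **Standardisation.** The raw variables span seven orders of magnitude
  (cumulative day length is about 5×10^6^ s; latitude about 42). Any
  Euclidean-distance method applied to the raw matrix sees only one or
  two columns, so `pheno_qc()` z-scores each column (sample standard
  deviation) by default; `standardize = FALSE` gives the literal
  unscaled analysis.
* **Climate lookup is by exact `location_id` and year.** Gridding or
  interpolating climate onto observation sites is data preparation, out
  of the package's scope, and a gap in a series before the onset day is
  a hard error rather than a silent partial sum.

### 2. Embedding: exact t-SNE to two dimensions

The eleven-dimensional context matrix is embedded to 2-D with exact
(O(n^2^)) t-distributed stochastic neighbour embedding — at a few
thousand records there is no need for tree or interpolation
approximations. Input-space affinities are per-row Gaussians whose
bandwidths are calibrated by bisection so every row's conditional
perplexity (the smooth effective-neighbour count) matches the target to
within 10^-4^; the bisection actually runs to machine convergence so an
independent re-implementation agrees with the affinity matrix to
10^-10^. Squared distances are floored at 10^-12^ so duplicate sites
cannot produce infinite precisions.

The optimiser follows the original algorithm's conventions: 1000
gradient-descent iterations, learning rate 200, momentum 0.5 switching
to 0.8 at iteration 250, adaptive per-coordinate gains, early
exaggeration ×4 for the first 100 iterations, and initial coordinates
drawn N(0, 10^-4^) from the seed. The reported `kl_final` and
`kl_initial` are both computed on the *unexaggerated* affinities; the
final-not-worse-than-initial contract refers to these and holds at
sensible iteration counts (several hundred or more — at very short runs
the layout can still carry the distortion that early exaggeration
introduces).

Perplexity is either fixed by the user or chosen by
`perplexity_sweep()`: candidates 5–50 in steps of 5, each embedded and
clustered, keeping the value that yields the most mixture components
(ties to the smallest value). This operationalises "the perplexity that
best spreads and separates the observations"; any visual-inspection
component of that judgement is deliberately excluded as irreproducible.

### 3. Clustering: constrained Gaussian mixtures selected by BIC

The embedding is clustered with Gaussian mixtures under the ten
covariance parameterisations generated by the decomposition
Σ~k~ = λ~k~ D~k~ A~k~ D~k~ᵀ (volume λ, shape A with det A = 1,
orientation D), from spherical-equal (EII) to fully varying (VVV). EM
is standard; the constrained M-steps use closed forms where they exist
and a 20-step fixed-point alternation between volume and shape for VEI
(the one diagonal family without a joint closed form); EEV/VEV work on
the eigen-decompositions of the component scatter matrices.

Numerical choices: convergence when the relative log-likelihood change
drops below 10^-8^ (at most 500 iterations); covariance eigenvalues
floored at 10^-6^; initialisation by k-means++ hard assignments with 5
restarts keeping the best final log-likelihood (the classical
alternative is model-based hierarchical agglomeration; k-means++ with
restarts is simpler and reproducible from a single seed). A start whose
components collapse below one observation of mass is discarded and
redrawn.

Model selection maximises BIC = 2 log L − k log n over every
(family, G) pair; ties go to fewer parameters, then to the canonical
family order. Both the full family × G table and the per-family maximum
are reported. Each observation receives its posterior component
probabilities; the clustering *uncertainty* is one minus the maximum
posterior, and points with uncertainty strictly above 0.5 are set aside
as unresolvable — they could be inconsistent or merely mis-clustered,
and judging them inside any one cluster would be arbitrary.

A property of this step that users should expect: **BIC counts mixture
components, not clusters.** t-SNE equalises density inside a
well-separated group, and a flat-topped disk of a couple of hundred
points is better approximated — in likelihood-per-parameter terms — by
two overlapping Gaussians than by one. With ~200 points per group the
selected G therefore routinely runs at about twice the number of
visually distinct groups (reference mixture software behaves the same
way on the same embeddings). This barely affects the flagging step,
because the sub-components of a group share the same onset-DOY
distribution, but it means component labels should not be read as a
census of distinct environments, and label-agreement scores against a
generative truth plateau well below 1 even when the embedding separates
the truth perfectly. The package keeps BIC — the selection rule the
field's mixture tooling uses — rather than switching to a
cluster-merging criterion, and reports the behaviour honestly in its
validation scores.

### 4. Flagging: Tukey fences per cluster

Within each retained cluster the onset DOYs are summarised by Tukey
hinges (the `fivenum()` convention behind the classic boxplot — the
convention matters at small n because it changes who is flagged), and
the fences are placed 1.5 interquartile ranges beyond the hinges.
Records below the lower fence are `inconsistent_early`, above the upper
fence `inconsistent_late`, everything else `consistent`; members of
clusters with fewer than five retained records stay `unresolved`
(quartiles of four points are noise). Under a normal DOY distribution
about 0.7% of records fall outside the fences, a figure the acceptance
suite reproduces on a million-draw sample.

Whether unresolved records belong in the denominator of an
"inconsistency rate" is a judgement call, so `summarize_flags()` reports
the rate both over resolved records and over all records.

### 5. Impact: trends with and without the flagged records

`fit_trend()` is ordinary least squares of onset DOY on calendar year
(continuous, uncentered — the slope is centering-invariant, and slopes
are reported both per year and per decade). `compare_trends()` fits the
trend on all resolved records and on the consistent subset, then tests
whether the slopes differ with the ANCOVA
`doy ~ year + consistency + year:consistency`; the interaction
coefficient *is* the slope difference (the test suite asserts this
against two separate fits to 10^-10^), and its t-test is the
slope-difference test.

## The synthetic campaign generator

`simulate_phenology()` produces the ground-truthed data every
end-to-end experiment runs on. Design, and what it does and does not
emulate:

* **Context clusters.** Sites are drawn from a latent 3-D mixture of
  the configured covariance family (`simulate_family_parameters()`
  builds components that genuinely exercise the family's freedoms —
  distinct volumes/shapes/orientations wherever allowed) and mapped to
  geography and six site climate drivers. Every driver carries
  independent site-level wobble so no latent direction dominates; a
  strongly elongated cluster would otherwise be fragmented by the
  embedding.
* **Daily climate** is a seasonal sinusoid per driver (coldest
  mid-January) plus day-to-day noise, enough to exercise accumulation
  and clustering. It has no spatial autocorrelation, no weather fronts,
  no inter-annual climate trend — emulating a gridded weather product
  is out of scope.
* **Onsets.** Cluster base date (spring, staggered 18 days per
  cluster), advanced 0.6 days per degree of site mean temperature, plus
  the planted year trend (default −0.37 days/year over 1980–2013) and
  Gaussian noise. `within_cluster_doy_sd` (default 5 days) is the
  *total* within-cluster dispersion — the quantity the fences operate
  on — so the generator budgets the residual noise after accounting for
  the variance the trend and the climate coupling contribute.
* **Planted inconsistencies.** A configured fraction (default 3%) of
  onsets is shifted by ±5 within-cluster standard deviations, half
  early, half late. The shifted date is used when building the record's
  context, exactly as a wrong reported date would be in a real
  campaign.
* **Status series.** `simulate_status_series()` emulates the
  "Yes"/"No" phenophase monitoring protocol on a regular visit
  schedule; deriving onsets from it recovers the true date to within
  one visit interval with uncertainty bounded by the interval.

Everything is bit-reproducible from the seed. Passing tests on this
generator demonstrates that the workflow's machinery is correct and
that its detection properties hold under clustered, climate-driven,
trend-bearing data; it does not demonstrate robustness to real-data
features the generator omits (spatial climate structure, observer
heterogeneity, non-Gaussian onset noise).

## Validation experiment sizes

The shipped experiments use: 10^6^ draws for the fence-coverage check;
600 observations, 3 clusters, 10 seeds for the end-to-end recovery
experiment (fixed perplexity 30, G searched over 1–6 — twice the
generated group count — with all ten families); 600 points per fit for
the family-recovery study (each family × 10 seeds, G fixed at the true
value 3); and 1000 records per seed for the trend-contamination study.
These sizes give stable medians while keeping a full run in the
minutes range on one core.

## Known limitations

* Exact t-SNE is quadratic in n; beyond ~10^4^ records the embedding
  step dominates runtime.
* Component labels over-partition contextual groups (see above); treat
  them as homogeneous strata for outlier testing, not as a count of
  environments.
* The Tukey rule tests onset DOY only, per cluster; it will not catch a
  record whose date is typical but whose *context* is wrong (that
  record mostly becomes `unresolved` via clustering uncertainty).
* Trend comparison uses independent-error OLS; spatially or temporally
  correlated errors, mixed effects and changepoints are out of scope.
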