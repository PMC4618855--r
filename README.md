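# phenoflag

Context-aware consistency checking for volunteered phenological
observations.

Citizen-science phenology campaigns collect flowering-onset dates
("first flower on day 132 of 2011") at continental scale. A small
fraction of the records is implausible — transcription errors,
mis-identified phenophases, genuine anomalies — and a fixed plausibility
window cannot find them, because a normal flowering date in a warm
lowland site is an outlandish one on a cold mountainside. Left in, such
records bias the headline quantity of phenological analysis: the trend
in onset dates over the years.

`phenoflag` flags inconsistent records *relative to their environmental
context*:

1. **Context** — each record gets 11 contextual variables: latitude,
   longitude, elevation, and eight climate sums accumulated from
   1 January to the reported onset day (max/min/mean temperature, day
   length, precipitation, solar radiation, snow water equivalent,
   vapour pressure).
2. **Embedding** — the standardised context matrix is mapped to 2-D by
   exact t-SNE (perplexity fixed or chosen by a 5–50 sweep that
   maximises the number of clusters found downstream).
3. **Clustering** — Gaussian mixtures under the ten constrained
   covariance families Σ<sub>k</sub> = λ<sub>k</sub>D<sub>k</sub>A<sub>k</sub>D<sub>k</sub>ᵀ
   (EII … VVV), fitted by EM and selected by BIC = 2 log L − k log n;
   records with clustering uncertainty 1 − max posterior > 0.5 are set
   aside as unresolved.
4. **Flagging** — within each cluster, onset days outside the Tukey
   fences (hinges ± 1.5 IQR; ~0.7% of a normal sample) are flagged
   `inconsistent_early` / `inconsistent_late`.
5. **Impact** — ordinary least squares of onset day on year, with and
   without the flagged records, plus the ANCOVA
   `doy ~ year * consistency` whose interaction term is the
   slope-difference test.

A seeded synthetic-campaign generator (`simulate_phenology()`) with
known ground truth — clustered context conditions, climate-driven
onsets, a planted trend, planted inconsistencies, "Yes"/"No" status
series — backs every validation experiment.

## Worked example

```r
library(phenoflag)

# a synthetic campaign: 600 records, 3 context clusters, 3% of onsets
# shifted by 5 within-cluster standard deviations, trend -0.37 days/yr
sim <- simulate_phenology(sim_config(seed = 1))

qc <- pheno_qc(sim$observations, sim$climate,
               perplexity = 30, G_range = 1:6, seed = 1)
print(qc)
#> Context-aware consistency check (n = 600)
#>   embedding: perplexity 30, final KL 0.5907
#>   clustering: EEI, G = 6, BIC -8960.1428
#>   flags: consistent 582, inconsistent_early 9, inconsistent_late 9, unresolved 0
#>   inconsistency rate 3% of resolved observations
#>   trend full -0.305 vs clean -0.345 days/year (slope-difference p = 0.0039)

score_recovery(qc$flags, sim$ground_truth, qc$assignments,
               qc$impact$clean)[c("sensitivity", "precision")]
#> $sensitivity
#> [1] 1
#> $precision
#> [1] 1
```

Reading the output: the 11-variable context of the 600 records was
embedded at perplexity 30 and clustered (BIC selected a diagonal,
equal-shape family with 6 components — mixture components over-count
visually distinct groups on t-SNE output, which is expected and
harmless for flagging; see the vignette). 18 records fall outside their
cluster's Tukey fences, a 3.0% inconsistency rate matching the planted
3%, and here all 18 flags land exactly on the planted records.
Excluding them moves the estimated trend from −0.305 to −0.345
days/year (truth −0.37), i.e. the inconsistent records masked about
half a day per decade of advancement; the ANCOVA confirms the slopes
differ.

Per-observation verdicts are in `qc$flags`; `summary(qc)` adds
per-cluster fences; `plot(qc)` shows the embedded clusters with flagged
points circled.

File-based use (CSV in, CSV artifacts out) goes through
`run_pipeline()` or the thin command-line driver:

```sh
Rscript inst/cli/phenoflag simulate --out campaign/ --seed 1
Rscript inst/cli/phenoflag run-all --observations campaign/observations.csv \
    --climate campaign/climate.csv --perplexity 30 --g-range 1,6 --out run/
```

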