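# emgsynergy

Muscle-synergy dimensionality analysis for multichannel surface EMG.

How many independent control signals can a person produce with their forearm
muscles? For myoelectric prosthesis users this number — the dimensionality
of the muscle activation space — bounds how many degrees of freedom a
simultaneous and proportional control interface can drive, and it varies
with clinical condition (level of amputation, age). `emgsynergy` estimates
it from NinaPro-style multichannel sEMG recordings (labeled movement blocks,
2 kHz, ring + anatomical electrodes) and characterizes *which* synergies a
subject retains.

## The method

Pooled, normalized EMG envelopes `E` (n electrodes x T samples) are
factorized by non-negative matrix factorization,

```
E ≈ W H,   W ≥ 0 (n × k),   H ≥ 0 (k × T)
```

with multiplicative (Lee–Seung, Frobenius) updates. Reconstruction quality
is the variance accounted for, `VAF = 100 (1 − SSE/SST)`, computed globally
and per electrode. The number of synergies is selected by a repeated
cross-validation protocol: random 75/25 extraction/validation splits, `W`
fit on the extraction part, `H` refit on the validation part, best of 50
repeats per candidate `k`; the chosen `k` is the minimum achieving
validation global VAF > 95% **and** every per-electrode VAF > 85%.

Extracted synergies are typed across subjects by their movement-activation
profiles (z-normalized 17-element vectors of mean activation per simple
movement), clustered by k-means under the correlation distance `1 − r` with
silhouette-selected cluster count; each cluster is described by its
representative movements (mean + 2 SD rule). Patient synergies are
classified against control clusters by nearest centroid, gated by the
cluster's maximum within-cluster distance; synergy counts are related to
clinical covariates by Spearman/Wilcoxon/Mann–Whitney statistics.

A synthetic-data generator (`make_ground_truth()`, `synthesize()`,
`make_cohort()`) produces labeled recordings from known synergy structure —
including amplitude-modulated broadband carriers so the envelope stage is
genuinely exercised, and Gaussian-copula clinical covariates — making every
stage testable without any data download.

## Worked example

```r
library(emgsynergy)

gt  <- make_ground_truth(n_electrodes = 10, k_true = 4, seed = 42,
                         movement_duration = 0.5, rest_duration = 0.25)
rec <- synthesize(gt, seed = 43, subject_id = "C01")
rec
#> <emg_recording> subject C01, exercise B
#>   153500 samples x 10 channels @ 2000 Hz
#>   channels: RING1, RING2, RING3, RING4, RING5, RING6, RING7, RING8, FDS, EDS
#>   movements: 17 distinct (1, 2, 3, 4, 5, 6, 7, 8, 9, 10)

pool <- rec |> envelope() |> downsample(100) |> pool_movements()
dim_res <- estimate_k(pool, n_repeats = 10, seed = 7)
dim_res
#> <dimensionality_result> chosen k = 4 (of 10 channels, 10 repeats/k)
#>   criteria: global VAF > 95%, local VAF > 85%
tidy(dim_res)
#> # A tibble: 10 × 4
#>       k global_vaf min_local_vaf criteria_met
#>   <int>      <dbl>         <dbl> <lgl>
#> 1     1       50.3          25.3 FALSE
#> 2     2       73.1          27.9 FALSE
#> 3     3       86.9          35.4 FALSE
#> 4     4       99.9          99.8 TRUE
#> 5     5       99.9          99.9 TRUE
#> # …
```

The validation VAF saturates exactly at the planted dimensionality: the
dual criterion first holds at `k = 4`, the generator's true synergy count.
Refit at the chosen `k` and summarize each synergy by its
movement-activation profile:

```r
mod   <- factorize(pool, dim_res$chosen_k, seed = 7)
feats <- build_features(mod, pool$movement_of_sample, E = pool$E,
                        subject_id = "C01")
feats[, 1:5]
#> # A tibble: 4 × 5
#>   subject_id synergy_index explained_variance_share     m1     m2
#>   <chr>              <int>                    <dbl>  <dbl>  <dbl>
#> 1 C01                    1                     32.6  1.57   1.64
#> 2 C01                    2                     22.1 -0.473 -0.515
#> 3 C01                    3                     31.0 -0.526 -0.459
#> 4 C01                    4                     20.4 -0.520 -0.462
```

Synergy 1 is strongly recruited by the first movements (its profile is
~1.6 SD above its mean there) and explains ~33% of the EMG variance on its
own; shares need not sum to 100 because synergies overlap. Pooled across a
control cohort, `cluster_features()` groups such profiles into synergy
types, `representative_movements()` names each type, and
`assign_patient_synergies()` classifies patient synergies against the
types (`0` = no control type is close enough). `run_subject()` /
`run_cohort()` orchestrate the whole chain, and `autoplot()` methods draw
the VAF curves and the type-by-movement activation heatmap.

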