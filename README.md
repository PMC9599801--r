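# eegpli

Phase lag index (PLI) connectivity analysis for resting-state EEG in
two-group clinical cohorts — built around the question of whether alpha-band
functional connectivity separates type 2 diabetes patients with mild
cognitive impairment (T2DM-MCI) from cognitively normal diabetic controls
(T2DM-NC), and whether it tracks cognition (MoCA score).

The package is aimed at EEG researchers who want a tested, reproducible
implementation of this analysis: a synthetic cohort generator with known
coupling ground truth (real patient recordings are not distributable), the
preprocessing chain, PLI connectivity, the group statistics, and a
cross-validated logistic-regression classifier with a permutation-based
empirical chance level.

## The measure

For two channels with instantaneous phase difference Δφ(t_k), k = 1…N,

    PLI = | ⟨ sign Δφ(t_k) ⟩ |

with Δφ wrapped to (−π, π] and sign(0) = 0. PLI is 0 when phase differences
are symmetric around zero — including spurious zero-lag coupling from volume
conduction — and 1 when one signal consistently leads or lags the other.
Phases come from the analytic signal of zero-phase band-filtered 3-s epochs;
per-epoch PLI is averaged across epochs into a channel × channel matrix per
band (delta 1–4, theta 4–8, alpha 8–13, beta 13–30 Hz), and the mean over
all channel pairs is the global synchronization summary.

## Worked example

```r
library(eegpli)

# a reduced synthetic study: 2 x 30 subjects, 16 channels @ 500 Hz, 5 min
cfg <- study_config(seed = 7, out_dir = "study_out")
res <- run_study(cfg)

res$global_comparison
#> # A tibble: 4 × 7
#>   band  statistic  p_value mean_mci mean_nc  sd_mci   sd_nc
#>   <chr>     <dbl>    <dbl>    <dbl>   <dbl>   <dbl>   <dbl>
#> 1 alpha    -3.88  0.000104    0.837   0.869 0.0330  0.0190
#> 2 beta     -2.96  0.00303     0.551   0.560 0.0116  0.00898
#> 3 delta     2.64  0.00831     0.591   0.583 0.0114  0.0110
#> 4 theta    -0.111 0.912       0.718   0.718 0.00680 0.00649

glance(res$classifier)
#> # A tibble: 1 × 10
#>   accuracy specificity sensitivity precision    f1   auc empirical_chance_level ...
#> 1       75        76.7        73.3      75.9  74.6 0.778                   63.3
```

Reading: the patient group's global alpha PLI is significantly reduced
(rank-sum z = −3.88; the generator plants the effect only in alpha — the
small beta/delta signals are leakage at the band edges and chance), and the
classifier separates the groups at 75% accuracy against a 63.3% empirical
chance level (95th percentile of 500 label-permutation accuracies), with
AUC 0.778 from the pooled held-out probabilities.

Every stage is also usable on its own and returns tibbles that chain with
the pipe:

```r
dat  <- generate_cohort(cohort_spec(seed = 1))        # full 62-ch study spec
ep   <- preprocess_recording(dat$recordings[[1]])     # reref/filter/epoch/reject
conn <- cohort_connectivity(dat$recordings)           # per-subject, per-band
conn |> global_band_comparison(dat$cohort)            # rank-sum per band
conn |> pli_features(dat$cohort, "global_pairs8") |>  # classifier features
  with(evaluate_classifier(x, labels, seed = 1))
autoplot(conn$matrix[[1]])                            # connectivity heatmap
```

`validate_table1()` recomputes the published cohort-characteristics
statistics from their printed summaries (gender χ² = 0.601, education
t = 0.443, duration t = −0.576, all matched at 3 decimals; the age and MoCA
cells are reported as known not reproducible from rounded summaries).

A thin CLI covering the same stages lives in `exec/eegpli`
(`simulate`, `preprocess`, `connectivity`, `stats`, `classify`, `run-all`,
`validate-table1`).

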