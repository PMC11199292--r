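# microstability

Resting-state EEG **microstate** analysis and trait-association statistics
in R.

During eyes-closed rest, the scalp potential topography stays in one of a
few quasi-stable configurations ("microstates", classes A–D) for ~40–120 ms
before switching. How *stable* that temporal organization is — long
durations, few occurrences — varies strongly between people and behaves
like a neural trait. This package implements the full chain from raw
multichannel EEG to per-subject stability metrics and their association
with a questionnaire-based trait (the 12-item short-form Aggression
Questionnaire), including gender-moderated regression. It is aimed at
researchers who want a scriptable, fully tested, reproducible version of
the standard microstate pipeline plus the statistics layer that usually
lives in separate point-and-click tools.

## What it computes

For average-referenced topographies $\mathbf v_t$ with global field power
$\mathrm{GFP}_t$ (spatial SD across channels):

1. maps at GFP peaks → **AAHC** (atomize-agglomerate hierarchical
   clustering, polarity-invariant, GFP-weighted principal-direction
   centroids) → K = 4 subject maps;
2. subject maps pooled → grand-mean maps → sorted to canonical A–D
   templates by exhaustive permutation matching;
3. backfitting: each GFP peak labeled by its best map, other samples
   inherit the nearest peak's label → durations (ms), occurrences (1/s),
   coverage, and global explained variance
   $\mathrm{GEV} = \sum_t(\mathrm{GFP}_t\,r_t)^2 / \sum_t \mathrm{GFP}_t^2$;
4. statistics: one-way random-effects ICC across the four classes,
   fixed-vs-random-intercept likelihood-ratio comparison, standardized
   regression of the trait on mean duration/occurrence, and moderation
   ($y = b_0 + b_1 x + b_2 g + b_3 xg$) with per-gender simple slopes.

A synthetic-data module (`simulate_cohort()`) generates 64-channel,
512 Hz eyes-closed EEG whose topography at each instant is one of four
planted maps driven by a sign-flipping 10 Hz carrier, with per-subject mean
state durations drawn from a population law, plus a cohort table in which
aggression depends linearly on true stability with a gender-dependent
slope — so every stage is testable against ground truth without any data
download.

## Worked example

End-to-end on a small synthetic cohort (10 subjects, 60 s each):

```r
library(microstability)
res <- demo_cohort_analysis(seed = 1, n_subjects = 10, record_seconds = 60)
res$grand_mean
#> <microstate_model> K=4 (grand_mean), 64 channels, GEV total = 0.999
head(res$subject_stats[, c("subject_id", "gender", "aq_total",
                           "mean_duration", "mean_occurrence", "gev_total")])
#>   subject_id gender aq_total mean_duration mean_occurrence gev_total
#> 1       S001   male 3.666667      69.25553        3.491667 0.9183743
#> 2       S002 female 3.500000      86.32303        2.816667 0.9554596
#> 3       S003   male 3.833333      90.68125        2.700000 0.9578436
#> 4       S004 female 3.916667      87.98288        2.754167 0.9483997
#> 5       S005 female 3.833333      74.02004        3.279167 0.9276328
#> 6       S006 female 3.916667     102.90477        2.362500 0.9636984
```

The four grand-mean maps explain 99.9% of the pooled subject-map variance;
per-subject GEV of the continuous data is 0.92–0.96, and recovered mean
durations (69–103 ms here) track each subject's planted value. The ICCs
across the four classes are printed by `res$analysis` (0.986 for durations
in this run), confirming that stability is a subject-level tendency. At
n = 10 the trait regression grid is sampling noise — trait effects need a
real sample size:

```r
cf <- cohort_sim_config(n_subjects = 1000, beta_male = -0.471,
                        beta_female = -0.141, clip = TRUE, seed = 2)
sim <- simulate_cohort(cf, make_eeg = FALSE)
tab <- score_aq_table(sim$subjects)
m <- moderation_model1(tab$aq_total, sim$truth$true_mean_duration_ms,
                       tab$gender)
#> male slope:   -0.414  p = 4.9e-19
#> female slope: -0.147  p = 0.00041
#> interaction b = -0.294 , p = 2.5e-06 , R2 change = 0.021
```

The planted per-gender standardized slopes (−0.471 / −0.141) are recovered
within sampling error, and the gender × duration interaction is detected.

For real data, pass `.vhdr` paths (or `eeg_recording` objects) and a
subject CSV to `run_pipeline()`; see `?run_pipeline` and the vignette
`vignettes/microstate-stability.Rmd` for the model, parameter defaults, and
known limitations.

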