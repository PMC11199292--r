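---
title: "Microstate stability: model, algorithms, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Microstate stability: model, algorithms, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microstability)
```

## The model

Resting-state EEG topographies do not wander continuously: the scalp
potential field stays in one quasi-stable configuration for roughly
40–120 ms and then switches abruptly to another. These configurations are
the *microstates*; in eyes-closed rest, four classes (conventionally labeled
A–D) account for most of the signal variance. This package quantifies, per
subject, how *stable* that temporal organization is — long durations and few
occurrences mean high stability — and relates that stability to a
questionnaire-based trait (here: the 12-item short-form aggression
questionnaire), including whether gender moderates the association.

Formally, at sample $t$ the average-referenced topography is
$\mathbf{v}_t \in \mathbb{R}^C$ (zero mean across the $C$ channels). The
global field power is the spatial standard deviation
$\mathrm{GFP}_t = \sqrt{\tfrac1C \sum_c (v_{tc} - \bar v_t)^2}$. The
segmentation model assumes $\mathbf{v}_t \approx a_t\,\mathbf{u}_{L(t)}$
where $\mathbf{u}_1,\dots,\mathbf{u}_K$ are unit-norm class maps, $L(t)$ a
piecewise-constant label sequence, and $a_t$ a signed scalar activation.
Because $a_t$ changes sign (in eyes-closed rest the dominant carrier is
alpha-band), all comparisons between topographies are *polarity-invariant*:
a map and its negation are the same microstate. Fit is summarized by the
global explained variance
$$\mathrm{GEV} = \frac{\sum_t \big(\mathrm{GFP}_t \cdot
  \mathrm{corr}(\mathbf{v}_t, \mathbf{u}_{L(t)})\big)^2}{\sum_t
  \mathrm{GFP}_t^2}.$$

## The processing chain

1. **Preprocessing** (`preprocess_recording()`): zero-phase (forward–backward)
   4th-order Butterworth band-pass, default 1.5–20 Hz, plus a 2 Hz-wide
   band-stop at the power-line frequency (default 60 Hz); optional
   interpolation of bad channels as the mean of their 4 nearest neighbors by
   geodesic distance on the montage sphere; segmentation of the eyes-closed
   condition into non-overlapping 2 s epochs; rejection of any epoch with a
   sample exceeding ±100 μV; average referencing. The filter realization,
   neighbor count, and whole-epoch rejection granularity are this package's
   choices where the procedure is conventionally described only by corner
   frequencies and thresholds; all counts are recorded in provenance.
2. **Peak extraction** (`extract_gfp_peak_maps()`): topographies are taken at
   local maxima of the GFP trace (strict rise, loose fall; computed within
   each epoch), where the topographic signal-to-noise ratio is best.
3. **Clustering** (`aahc()`): atomize-agglomerate hierarchical clustering.
   Starting from singletons, the cluster contributing least GEV is dissolved
   and each of its members is reassigned to the cluster whose centroid it
   correlates with most strongly (squared, polarity-invariant). A centroid is
   the first principal direction of its GFP-weighted member maps — the plain
   mean would cancel under polarity flips. After agglomeration a Lloyd-style
   polish (reassign all maps, recompute centroids, iterate to a fixed point)
   removes the path dependence of the greedy atomization order; on small
   instances with equally represented sources the result coincides with the
   exhaustive max-GEV partition (verified against a brute-force oracle in the
   tests). Greedy atomization can still lose a *coherent but low-power*
   source when sources are strongly unbalanced — an inherent property of the
   procedure, not of this implementation. Rank-deficient input yields fewer
   than K maps with a warning rather than fabricated maps.
4. **Grand mean and sorting** (`cluster_grand_mean()`, `sort_maps()`): all
   subjects' maps are pooled (unit weight) and re-clustered; the resulting K
   maps are matched to canonical A–D template orientations by exhaustive
   search over all $K!$ label permutations, maximizing summed
   polarity-invariant correlation (ties broken by the lexicographically
   smallest permutation). Each subject's maps are then relabeled against the
   grand mean the same way, and backfitting uses the subject's own relabeled
   maps.
5. **Backfitting and metrics** (`backfit()`, `compute_stats()`): each GFP
   peak takes the label of its best-correlated map; every other sample
   inherits the label of its nearest peak in the same epoch (midpoint rule,
   ties to the earlier peak); no temporal smoothing. A run is a maximal
   same-label span within one epoch. Durations average run lengths,
   excluding edge-truncated runs by default (epochs are discontinuous after
   artifact rejection, so runs are never merged across epochs); occurrence
   counts runs starting strictly inside an epoch per second of labeled time;
   coverage is the sample share. `mean_duration` and `mean_occurrence` are
   *unweighted* means across the four classes — the metrics the trait
   analysis uses. With truncation handling off, the identity
   $\sum_k \mathrm{dur}_k \times \mathrm{occ}_k = 1000 \cdot \sum_k
   \mathrm{cov}_k$ ms/s holds exactly.

### Temporal resolution

Nearest-peak inheritance means label boundaries are only resolved to the
inter-peak spacing. With a 10 Hz carrier the GFP peaks twice per cycle, i.e.
every ~25 ms, so (i) sample-level agreement with a planted sequence
saturates near 85% even noiselessly although agreement *at* the peaks is
exact, and (ii) runs shorter than the spacing merge into their neighbors,
inflating recovered durations for subjects whose true mean duration
approaches the spacing (a 50 ms subject recovers ~15% high, an 80 ms subject
within a few percent). Both effects are symmetric around run boundaries, so
cohort-level means and between-subject ordering are preserved; the tests
assert exactly that.

## The statistical layer

* `score_aq()`: total = mean of the 12 items; subscales (physical, verbal,
  hostility, anger) = mean of their three consecutive items; no reverse
  scoring, no imputation.
* `icc_oneway()`: one-way random-effects ICC of a metric over the four
  classes, $\sigma^2_b / (\sigma^2_b + \sigma^2_w)$ with components from a
  REML random-intercept fit (lme4); negative estimates are truncated at
  zero by the fitter. The one-way consistency form was chosen because the
  design has no rater structure; the metric's affine scale cancels.
* `compare_fixed_vs_random_intercept()`: both models carry class as a fixed
  factor; the mixed model adds a subject intercept; both fit by ML; the LRT
  is referred to $\chi^2_1$, which is conservative at the variance boundary
  (`boundary_mixture = TRUE` switches to the 50:50 $\chi^2_0{:}\chi^2_1$
  mixture).
* `regress_standardized()`: OLS on z-scored variables, so the slope is the
  Pearson correlation and $R^2 = \beta^2$.
* `moderation_model1()`: $y = b_0 + b_1 x + b_2 g + b_3 xg$ with $y, x$
  z-scored over the whole sample and $g$ coded 0/1 from the factor's level
  order (swapping the coding flips $b_3$'s sign and leaves its p-value
  unchanged). Simple slopes are standardized regressions *within* each
  gender, matching how per-group coefficients are conventionally reported;
  $\Delta R^2$ is against the no-interaction model. No multiple-testing
  correction is applied anywhere (each cell at two-sided α = 0.05), which is
  recorded in the output metadata.

## The synthetic-data generator

`simulate_cohort()` is first-class, tested code: it defines the conditions
under which every downstream claim is validated.

* **Montage**: a deterministic 64-channel extended 10-10 cap on a spherical
  head model (peripheral ring at 72° inclination, midline, slerp-interpolated
  coronal arcs, inferior temporal ring).
* **Maps**: four canonical orientations — two mirrored frontal-diagonal
  gradients (A, B), a posterior–anterior gradient (C), a fronto-central
  focal pattern (D) — zero-mean, unit-norm, maximal pairwise |corr| ≈ 0.54.
* **Dynamics**: a semi-Markov label sequence; run lengths i.i.d. gamma,
  discretized to ≥1 sample; next state uniform over the other K−1 (no
  self-transitions). Population law of per-subject mean durations:
  normal with mean 80 ms, SD 15 ms (centering the 40–120 ms range reported
  for healthy rest), floored at 20 ms; within-subject run-length SD 15 ms.
* **Signal**: sample $t$ = map × carrier, carrier = 10 Hz sinusoid (the
  dominant eyes-closed rhythm) with a slow amplitude modulation and random
  phase, so polarity flips within every state — the property that forces
  polarity-invariant clustering. Within-state dynamics are not characterized
  by the source literature; the oscillatory carrier is an explicit modeling
  assumption, not an inference.
* **Noise**: spatially white Gaussian scaled to a target signal-to-noise RMS
  ratio (default 5). Real EEG noise is spatially correlated and includes
  ocular/muscle artifacts; the generator only offers amplitude spikes
  (`inject_spikes()`) to exercise the ±100 μV rule. Passing tests therefore
  demonstrate correctness of the algorithms under the stated model, not
  robustness to every real-world artifact class.
* **Trait model**: aggression$_i$ = $\beta_{g(i)} \cdot z(\text{true mean
  duration}_i) + \varepsilon_i$. Defaults plant $\beta_{male} = -0.471$,
  $\beta_{female} = -0.141$ with residual SD $\sqrt{1-\beta^2}$, so the
  planted values are standardized slopes exactly. The latent score maps
  affinely onto the 1–6 scale (center 3.5, scale 0.55) and is discretized
  into 12 item responses whose mean is within 1/24 of the target
  (mean-preserving ±1 jitter spreads the items). A target outside 1–6
  raises an error by default; `clip = TRUE` winsorizes instead, which
  matters only for >4.5 SD draws in very large cohorts and leaves slope
  recovery unaffected. Gender proportions default to 58 female : 43 male
  per 101.

## Problem sizes and numerical choices

The tests and the acceptance script run end-to-end EEG cohorts of 5–8
subjects at 120 s each plus trait-model simulations at n = 101 (1000
replicates), n = 2000 (slope recovery), and 2000-replicate null
calibrations; these sizes put Monte-Carlo error well inside each asserted
band. GFP uses the population (divide-by-C) form; zero-variance
topographies are rejected rather than silently normalized; centroid signs
are fixed against the heaviest member map for determinism; the duration
fallback (all runs when every run of a class is truncated) and absent
classes are flagged in the output rather than imputed.

## Known limitations

* No ICA-based ocular cleaning and no manual inspection stage; externally
  cleaned data can be supplied directly.
* Fixed K; no cluster-number selection criteria.
* Temporal resolution bounded by the GFP peak spacing (see above).
* The EDF format is not supported; BrainVision (.vhdr/.vmrk/.eeg) is the
  interchange format, with a reader and writer included.
* The moderation analysis is a plain interaction model; no mediation,
  no causal claims.

## A minimal run

```{r demo, eval = FALSE}
res <- demo_cohort_analysis(seed = 1, n_subjects = 10, record_seconds = 60)
res$grand_mean
head(res$subject_stats[, c("subject_id", "gender", "aq_total",
                           "mean_duration", "mean_occurrence", "gev_total")])
res$analysis
```
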