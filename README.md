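# pulsefusion

Sensor-fusion screening for the traditional-Chinese-medicine (TCM) **wiry
pulse** from two low-cost wearable signals:

* a single-channel **photoplethysmography (PPG)** waveform from the wrist
  (25 Hz, 5 minutes per subject), and
* a **galvanic skin response (GSR)** panel: skin resistance at the 12
  bilateral Ryodoraku acupoints (LU9, PC7, HT7, SI5, TE4, LI5, BL65, LV3,
  ST42, SP3, GB40, KD4 — left and right), 5 s at 200 Hz per point, each
  reduced to its median.

The pipeline denoises the PPG trace (zero-phase 0.5–8 Hz bandpass, then a
periodic moving-average filter that phase-aligns beat periods and averages
`k = 3` neighbours), slides a 10-s window at a 1-s hop (290 windows per
5-minute recording), delineates per-beat fiducials — pulse onset (PWB),
systolic peak (PWSP), diastolic peak (PWDP) — with an event-related
moving-average detector plus a smoothed-second-derivative search, and
computes per window:

* 8 time-domain features: Euclidean distances PWSP–PWDP, PWDP–PWE and
  PWSP–PWB in the (time, min-max-normalized amplitude) plane, the
  systolic-peak angle `∠C = arccos((a² + b² − c²) / 2ab)` from the
  adjacent-sample triangle, systolic and diastolic phase durations, the
  PWSP→PWDP propagation time, and the inter-beat interval;
* 10 harmonic features C1–C10: the amplitude spectrum (`2|X_k|/N`) at the
  bins nearest `n·f₀`, where the base frequency `f₀ = HR/60` (96 bpm →
  C1 at 1.6 Hz, C2 at 3.2 Hz).

The fused 42-feature vector (18 PPG + 24 GSR) feeds a fully connected
network (42 → 30 → 30 → 30 → 1, ReLU hidden, sigmoid output, Adam) that is
evaluated with **subject-level** stratified 5-fold cross-validation — all
windows of a subject stay in one fold; with 80 subjects each fold trains on
64 and tests on 16 (8 per class). Modality-ablation tables and 500-tree
random-forest feature importances (with Welch group statistics on
per-subject means) complete the analysis. Because no real recordings are
deposited, the package includes a tested synthetic-cohort generator whose
group effects encode the reported wiry/non-wiry difference directions;
everything below runs on synthetic data.

## Worked example

```r
library(pulsefusion)

cohort <- simulate_cohort(cohort_config(n_wiry = 8, n_control = 8,
                                        duration = 120, seed = 42))
feats  <- extract_cohort_features(cohort)   # 16 x 110 windows x 42 features
cv     <- cross_validate(feats, fcn_config(seed = 42), k = 4, seed = 42)
glance(cv)
#> # A tibble: 1 × 5
#>   feature_subset     k n_subjects segment_accuracy subject_accuracy
#>   <chr>          <dbl>      <int>            <dbl>            <dbl>
#> 1 all42              4         16            0.766             0.75

head(tidy(feature_importance(feats, seed = 42)), 3)
#> # A tibble: 3 × 8
#>   feature      weight  rank wiry_mean wiry_sd non_wiry_mean non_wiry_sd p_value
#>   <chr>         <dbl> <int>     <dbl>   <dbl>         <dbl>       <dbl>   <dbl>
#> 1 gsr_HT7_left 0.128      1   190995.  4.18e4       260431.    38827.   0.00399
#> 2 f3           0.0967     2      174.  1.46e0          169.        3.48 0.00737
#> 3 gsr_LU9_left 0.0728     3   181361.  3.70e4       232742.    32823.   0.0109
```

Sixteen subjects with 2-minute recordings is a deliberately small demo:
subject-level accuracy is 0.75 here, and the top-ranked features are the
shifted GSR channels and the systolic-peak angle (f3) — wiry subjects'
mean angle is larger (174° vs 169°) and their resistance at the shifted
acupoints lower, the directions built into the generator. At the full
study design (80 subjects, 5-minute recordings) fused accuracy reaches the
low 0.90s and clearly exceeds either modality alone; see below.

`autoplot()` methods exist for recordings, cross-validation results and
importance reports, and `plot_fiducials()` overlays detected beats on a
window. A thin command-line wrapper lives at `inst/cli/pulsefusion.R`
(`pipeline`, `simulate`, `features` subcommands over a JSON/YAML
`pipeline_config()`).

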