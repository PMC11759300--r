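# musclenet

Objective assessment of bulbar motor involvement — the degeneration of
speech and swallowing function that marks diseases such as amyotrophic
lateral sclerosis (ALS) — currently relies on clinical rating scales that
miss the long prodromal phase. `musclenet` implements a multiplex
**functional mandibular muscle network** built from six-channel surface
EMG (sEMG) of the jaw muscles during speech, and turns it into
quantitative, interpretable markers of disease. It is aimed at speech
motor control and clinical neurophysiology researchers who record
bilateral anterior temporalis (TEMP), masseter (MAS) and anterior belly
of digastric (ABD) muscles at 2,000 Hz, plus 3D jaw kinematics at 100 Hz.

## What it computes

For every sentence-level recording the pipeline extracts **48 features**:

* **Nodal (12).** Each channel is reduced to a local standard deviation
  series (non-overlapping 50 ms windows),
  `V_j = sqrt( sum_{i=(j-1)L+1}^{jL} (U_i - Ubar_j)^2 / (L - 1) )`,
  and mapped to a natural visibility graph: points `x < y` are connected
  iff every intermediate `z` satisfies
  `(V_y - V_z)/(y - z) > (V_y - V_x)/(y - x)`.
  Two descriptors summarize each graph: **density** `2m / (M(M-1))`
  (overall level of activity) and the **spectral radius ratio**
  `lambda_max(A) / mean degree` (variability of activity).
* **Edgewise (36).** All 15 muscle pairs are full-wave rectified, reduced
  to jointly selected stationary 1 s epochs around activity bursts, and
  submitted to Welch magnitude-squared coherence
  `|R_xy|^2 = |S_xy|^2 / (S_xx S_yy)`
  (1,024-point Hamming window, 75% overlap, 4,096-point FFT). Within the
  theta/alpha (4–12 Hz), beta (12–30 Hz) and low-gamma (30–60 Hz) bands,
  coherence is zeroed unless some bin exceeds the independence
  significance level `S = 1 - 0.05^(1/(L_hat - 1))`, then Fisher
  z-transformed. The resulting 45 weights (15 edges × 3 band layers) form
  the multiplex network, summarized by mean nodal strength,
  assortativity, global efficiency, per-muscle weighted clustering and
  right-vs-left laterality indices.
* **Kinematics.** From the jaw-to-incisor distance series: acceleration
  time, mean acceleration over the accelerating phase, and stiffness
  (max speed / max excursion).

Downstream, the 48 features are reduced by maximum-likelihood factor
analysis with oblimin rotation (factor count from parallel analysis,
tenBerge factor scores), screened for disease effects with linear
mixed-effects models (`feature ~ group * node_or_band + (1 | subject)`,
estimated-marginal-mean contrasts, Bonferroni), linked to jaw kinematics
by backward-stepwise mixed models, and fed to repeated cross-validated
RF / SVM / KNN classifiers.

A seeded synthetic cohort generator (burst-structured sEMG with
band-limited common drives, crosstalk, line noise and stage-dependent
disease effects; quasi-periodic jaw traces) stands in for human
recordings, so the entire pipeline is testable end to end.

## Worked example

```r
library(musclenet)

cfg <- cohort_config(n_control = 3, n_als_prodromal = 0,
                     n_als_symptomatic = 3, sentences_per_subject = 3,
                     sentence_duration_s = 5, seed = 42)
run <- run_pipeline(cfg, stages = c("features", "kinematics"))
run
#> <musclenet_run>
#>   features: 18 records x 48 feature columns
#>   kinematics: 18 records

dplyr::select(run$features, subject_id, stage, sentence,
              density_RMAS, nodstr_beta, ge_beta)
#> # A tibble: 18 x 6
#>   subject_id stage   sentence density_RMAS nodstr_beta ge_beta
#> 1 S01        control        1        0.117       5.17    1.03
#> 2 S01        control        2        0.118       3.04    0.871
#> ...

fit_lme_nodal(run$features, "density")
#> <muscle_lme> density ~ group * node + (1 | subject)
#>      effect statistic df1 df2    p.value
#>       group 9.3181211   1   4 0.03793319
#>        node 0.2916851   5  92 0.91646011
#>  group:node 1.0872029   5  92 0.37279145
#> R2 marginal 0.362, conditional 0.549
```

Even on this miniature cohort the symptomatic profiles lower
visibility-graph density (the group effect above) and beta-band nodal
strength, the directions expected for reduced, more irregular myoelectric
activity and weakened intermuscular coupling. On the full study design
(10 controls, 7 prodromal + 8 symptomatic ALS subjects, 19 sentences)
the factor scores separate groups with cross-validated AUC above 0.8 for
all three classifiers.

`exec/musclenet` exposes the same pipeline as a command-line tool
(`simulate`, `preprocess`, `features`, `kinematics`, `factors`,
`run-all`), reading and writing tab-delimited matrices with JSON
sidecars.

## Limitations

The synthetic generator is a stand-in, not a fit to human data: its
coupling magnitudes, burst statistics and effect sizes are stipulated
(see the methods vignette), so passing tests demonstrate internal
consistency and statistical calibration of the pipeline, not clinical
performance. Real-data properties — electrode artifacts, hum harmonics,
inter-subject anatomy — are out of scope.
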