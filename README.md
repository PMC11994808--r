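# mcir

Personalized quantification of vaccine reactogenicity from continuous
wearable biosignals.

## What it does

Diary-based reactogenicity grading is coarse and confounded by the nocebo
effect.  Chest-patch biosensors record coincident 1-minute heart rate (HR),
heart-rate variability (HRV), respiration rate (RR), activity and skin
temperature, quality-graded by an ECG signal-quality index (SQI).  `mcir`
turns those streams into an objective, continuous response measure:

1. **Digital twin** — a per-individual similarity-based baseline model
   (auto-associative kernel regression over an exemplar memory `D`):
   for a z-scored query `x`, weights `w_i ∝ 1/(1 + ‖x − D_i‖/h)` give the
   estimate `x̂ = Σ w_i D_i` and residual `r = x − x̂`.  Training needs
   ≥ 2500 filtered 1-minute samples over ≥ 3 calendar days before the dose.
2. **MCIR** — the Multivariate Change Index of Reactogenicity: 15-minute
   block means of the residual vector are reduced to a Mahalanobis distance
   `d` against a baseline null calibration and transformed through the
   baseline's empirical CDF, `MCIR = max(0, (F̂(d) − q)/(1 − q))` with
   `q = 0.95` — bounded in [0, 1] and exactly zero under typical baseline
   variation.
3. **Response metrics** — the 72-h AUC Total Response `A_i/A_T`
   (accumulated MCIR area over the full 72 h × 1 rectangle) and a
   *detectable response* rule: ≥ 50 % of 15-min steps above 0.10 in some
   6-h sliding window, plus more than 1 h of persistent non-zero MCIR.
4. **Validation layer** — bootstrap TPR/SPC/FPR/PPV/NPV/ACC of the
   detectable rule against control windows, Kolmogorov–Smirnov and
   Wilcoxon signed-rank comparisons, Spearman correlations, and robust
   IRLS line fits (Welsch and Andrews weights, shared tune 0.8 on a
   MAD-based scale).
5. **Synthetic cohorts** — a generator with circadian, activity-coupled
   physiology, AR(1) noise, SQI dropout and injectable post-dose
   perturbations with ground truth, so the whole pipeline is exercisable
   end to end without any private data.

## Worked example

```r
library(mcir)

# one synthetic individual, dose at noon of day 5, injected magnitude 2
coh <- simulate_cohort(1, seed = 3, magnitude_sampler = function(k) rep(2, k))
sc  <- score_dose(coh$series[[1]], coh$doses$dose_time[1])
sc$twin
#> <twin_model> 250 exemplars, bandwidth 3.029, 6552 training samples (2021-03-01 -- 2021-03-06 11:59:00)
sc$summary
#> <response_summary> S001 dose NA: AUC Total Response 0.5542, detectable TRUE
#>   onset 2021-03-06 18:30:00, offset 2021-03-08 22:15:00
```

The twin trained on 6552 pre-dose minutes; the injected response fills 55 %
of the maximal 72-h MCIR area, is classified detectable, and its
onset/offset bracket the perturbation.  Reconstructing classifier
performance from a sensitivity, a specificity and the class sizes:

```r
confusion_metrics(tpr = 1.0, spc = 0.677, n_pos = 66, n_neg = 76)
#> <performance_estimate> TPR 100.0%, SPC 67.7%, FPR 32.3%, PPV 72.9%, NPV 100.0%, ACC 82.7%
```

A thin CLI over the same functions lives at `inst/cli/mcir-cli.R`
(`simulate`, `score`, `validate` verbs).  See the methods vignette
(`vignettes/mcir-methods.Rmd`) for the model, its assumptions, and every
numerical design choice.

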