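# respseg

Data-driven segmentation of clinical-trial patients into **responders** and
**non-responders**, for biostatisticians analysing oncology trials with
early tumor-size follow-up and overall-survival endpoints.

Most response classifiers dichotomise a predicted probability at 0.5. With
imbalanced response rates that threshold is rarely where the decision
boundary should sit. `respseg` instead:

1. builds per-trial logistic models of best overall response (responder =
   CR/PR, non-responder = SD/PD) from baseline covariates (sex, age,
   weight, smoking, race) and principal-component scores of the four-visit
   percent tumor-size change from baseline;
2. searches **seven cross-validation technique families** (LOOCV,
   leave-pair-out with p = 2, a 75/25 hold-out, K-fold K = 3–10, repeated
   K-fold with 2–4 repeats, stratified K-fold K = 3–5, repeated stratified
   K-fold — 47 configurations) and, for each, finds the probability cutoff
   maximising the F1 score of out-of-fold predictions; the technique with
   the largest best cutoff is selected (the maximum-F1 rule is also
   available);
3. pools two training trials into a scoring system — the score of test
   patient *p* is the mean linear predictor
   `score_p = γ̄·sex + σ̄·age + λ̄·weight + δ̄·smoke + φ̄·race + Σ μ̄_j·pc_j + η̄`,
   with each coefficient the arithmetic mean of the two trials' fits — and
   segments test patients by
   `responder ⇔ logit⁻¹(score_p) > B_cut`, where `B_cut = (c₁ + c₂)/2` is
   the mean of the two training trials' best cutoffs (the *standard*
   comparator uses the same scoring system with `B_cut = 0.5`);
4. evaluates both segmentations with classification metrics (accuracy, MSE,
   specificity, precision, recall), Kaplan–Meier curves and the log-rank
   test, Cox proportional-hazards and Weibull/lognormal accelerated
   failure-time regressions adjusted for the design covariates, and an AIC
   comparison between the two methods' fits.

A synthetic trial generator (`sim_config()`, `make_trial_triplet()`)
reproduces the full data schema — covariate mix, correlated tumor
trajectories, a logistic response model, Weibull survival with a protective
responder effect, administrative censoring — with known ground truth, so
the whole pipeline is testable without access-restricted trial data.

## Worked example

```r
library(respseg)

cfg <- sim_config(seed = 1L)                       # defaults: 30% responders, 25% censoring
tri <- make_trial_triplet(cfg, seed = 1L,
                          sizes = c(train_a = 600, train_b = 140, test = 600))
report <- run_and_compare(tri$train_a, tri$train_b, tri$test, seed = 1L)
print(report)
```

```
== Responder segmentation report ==
test trial: TEST | seed 1 | rule max_cutoff | 2 PC(s)

-- novel method (bcut = 0.4368) --
  chosen CV: RepeatedKFold(k=4, repeats=3) (cutoff 0.378) / RepeatedStratifiedKFold(k=5, repeats=2) (cutoff 0.495)
  groups: 394 non-responder / 206 responder
  accuracy 0.752 | mse 0.248 | specificity 0.787 | precision 0.558 | recall 0.665
  log-rank: chisq 0.292, p 0.589
  COX group effect: 1.040 [0.772, 1.402], p 0.7943; AIC 4917.742
  AFT group effect: 0.973 [0.768, 1.232], p 0.8204; AIC 6229.487

-- standard method (bcut = 0.5000) --
  groups: 437 non-responder / 163 responder
  accuracy 0.767 | mse 0.233 | specificity 0.848 | precision 0.601 | recall 0.566
  log-rank: chisq 0.510, p 0.4753
  COX group effect: 0.987 [0.725, 1.343], p 0.9326; AIC 4917.803
  AFT group effect: 1.014 [0.794, 1.294], p 0.9125; AIC 6229.527

COX AIC: novel 4917.742 vs standard 4917.803 -> novel (dAIC -0.061)
AFT AIC: novel 6229.487 vs standard 6229.527 -> novel (dAIC -0.039)
```

Reading the output: each training trial selected its own CV technique and
F1-optimal cutoff (0.378 and 0.495 here), and their mean, `bcut = 0.437`,
replaces the conventional 0.5 — so the novel method calls 206 rather than
163 test patients responders, trading precision for recall. The group rows
give each method's adjusted hazard ratio / time ratio for the
responder-vs-non-responder contrast on the test trial, and the AIC lines
compare the two methods' survival fits (lower is better). Because the
group indicator is a threshold of the adjusted covariates, the adjusted
group effect is conservative; the log-rank line is the sharper marginal
comparison.

The same pipeline is scriptable from a shell via the thin CLI:

```sh
respseg_cli=$(Rscript -e 'cat(system.file("cli", "respseg", package = "respseg"))')
Rscript "$respseg_cli" simulate --out simdir --n 600 --seed 1
Rscript "$respseg_cli" compare --train-a simdir/train_a.csv \
    --train-b simdir/train_b.csv --test simdir/test.csv --out outdir --seed 1
```

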