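---
title: "Data-driven responder segmentation: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Data-driven responder segmentation: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Oncology trials classify each patient's best overall response (BOR) into
CR/PR/SD/PD; CR and PR patients are *responders*. A model that predicts the
probability of response from early data is only actionable once the
probability is dichotomised, and the conventional threshold of 0.5 is
arbitrary: with imbalanced response rates the probability scale is shifted
and 0.5 can sit far from the decision boundary that best recovers the
responder class. `respseg` implements a data-driven alternative: the
threshold is chosen by maximising the F1 score of out-of-fold predictions,
and — because the out-of-fold probabilities themselves depend on how the
data are resampled — the resampling scheme is *also* selected, by searching
seven cross-validation technique families.

## Data model

One row per patient: sex, age (ordinal bins 18–<65 / 65–75 / >75), weight
class (≤75 / >75 kg), smoking status (never < former < current), race
(caucasian / non-caucasian), baseline tumor size (sum of longest diameters,
mm), tumor sizes at the first four visits, BOR, and right-censored overall
survival (days, event indicator). Age and weight are modelled as single
ordinal/binary covariates because coarse bins are what a pooled multi-trial
analysis can rely on; readers with continuous values can pass them in the
CSV and they are binned on entry. Patients missing any of the four visits
are excluded from model fitting, with a logged count — the four-visit
trajectory is the landmark feature set and imputing it would manufacture
signal.

## Features

The trajectory feature for patient $p$ is the percent change from baseline
at visit $j$:

$$x_{pj} = 100\,\frac{s_{pj} - b_p}{b_p}, \qquad j = 1,\dots,4 .$$

A principal component analysis of the centered $n \times 4$ percent-change
matrix compresses the trajectory; by default two components are retained
(the regression tables of interest involve a second component, and two
components capture level and slope of a monotone trajectory). Loadings use
a fixed sign convention (largest-magnitude element positive) so results are
identical across linear-algebra backends. The design matrix is, in fixed
order: `sex, age, weight, smoking, race, pc_1..pc_k` with the documented
0/1/2 encodings; the intercept is handled by the fitter.

Each training trial gets its own PCA for its own logistic fit. For the test
trial the package fits a PCA on the *pooled* training trajectories and
projects test patients with it (`pca_basis = "pooled"`, the default): a
single deterministic basis that uses no test information. The alternative
(`"per_trial"`) projects the test trial with each training trial's basis
and averages the two feature sets; both are exposed because neither choice
is forced by the method's definition, and the pooled basis is the default
because it is the least arbitrary single basis.

## The cross-validation technique grid

Seven families are enumerated, 47 configurations in total by default:

| family | grid | splits produced |
|---|---|---|
| LOOCV | — | $n$ singletons |
| LpOCV ($p=2$) | — | all $\binom{n}{2}$ pairs, capped |
| HoldOut | test fraction 0.25 | 1 |
| K-fold | $K = 3..10$ | $K$ |
| Repeated K-fold | $K = 3..10$, repeats $2..4$ | $K\times r$ |
| Stratified K-fold | $K = 3..5$ | $K$ |
| Repeated stratified K-fold | $K = 3..5$, repeats $2..4$ | $K\times r$ |

For each configuration the package fits an unpenalised logistic regression
on every training part and predicts the validation part, giving each
patient an out-of-fold probability (arithmetic mean when a patient is
validated more than once; only the held-out quarter for HoldOut). All
randomness flows from one master seed through deterministic per-technique
seeds, so every run is exactly reproducible.

Numerical choices worth knowing:

* **Leave-pair-out cap.** $\binom{n}{2}$ explodes at trial scale, so when
  it exceeds `lpo_cap` (default 2000) that many distinct pairs are drawn,
  seeded. The deviation is deterministic and logged in the split count.
* **Separation fallback.** Small folds can separate perfectly; the MLE then
  diverges. The fitter detects this and refits with a tiny ridge penalty
  (1e-6, slopes only) so coefficients stay finite, with a warning.
* **Single-class folds** are skipped with a warning; a technique whose
  every split is single-class fails and is dropped from the search (an
  aggregated error is raised if all techniques fail).

## Cutoff search and technique selection

For probabilities $q_p$ and labels $y_p$, a patient is predicted responder
iff $q_p > c$ (strictly). F1 is evaluated at every candidate cutoff — the
sorted unique probabilities plus 0 — which covers every achievable
confusion matrix; ties are broken toward the *smallest* maximising cutoff,
favouring sensitivity. F1 is defined as 0 when nothing is predicted
positive.

The technique whose out-of-fold predictions yield the **largest best
cutoff** is selected (`rule = "max_cutoff"`, the default). Selecting the
largest *F1* is the statistically natural alternative and is exposed as
`rule = "max_f1"`; both are reported side by side in the selection object,
because the maximum-cutoff rule, while the method's stated behaviour, is
not obviously optimal. F1 is computed on the pooled out-of-fold
predictions rather than averaged per fold: pooling uses every prediction
once and is well defined for every family including LOOCV, where per-fold
F1 is degenerate.

## Scoring system and segmentation

Two training trials $d = 1, 2$ each contribute a full-data logistic fit
(the CV search selects the technique and its cutoff; final coefficients
come from the full-trial refit, since the scoring system is defined with
one coefficient per feature per trial) and a best cutoff $c_d$. The pooled
score of test patient $p$ is the mean linear predictor

$$\mathrm{score}_p = \bar\gamma\,\mathrm{sex}_p + \bar\sigma\,\mathrm{age}_p
 + \bar\lambda\,\mathrm{weight}_p + \bar\delta\,\mathrm{smoke}_p
 + \bar\phi\,\mathrm{race}_p + \textstyle\sum_j \bar\mu_j\,\mathrm{pc}_{jp}
 + \bar\eta,$$

with every barred quantity the arithmetic mean of the two trials'
coefficients, and the pooled threshold is

$$B_\mathrm{cut} = \tfrac{1}{2}(c_1 + c_2), \qquad
\mathrm{responder}_p \iff \operatorname{logit}^{-1}(\mathrm{score}_p) > B_\mathrm{cut}.$$

The division by two *is* the averaging of the two training cutoffs — it is
applied once, not on top of an already-averaged cutoff (thresholds near
0.36 from halving a ~0.72 cutoff would be inconsistent with cutoffs being
comparable across methods). Probabilities, not raw scores, are compared
with $B_\mathrm{cut}$, since cutoffs live in $(0,1)$. A probability exactly
equal to the threshold is a non-responder (strict inequality). The
*standard* comparator is identical except that no resampling is used and
$B_\mathrm{cut} = 0.5$.

## Evaluation

Against known BOR labels the package reports accuracy, MSE (for binary
predictions the misclassification rate, so accuracy + MSE = 1 exactly),
specificity, precision and recall; zero-denominator metrics are reported
as 0 with an explicit flag so tables have no missing cells. Survival
separation between the segmented groups is quantified by Kaplan–Meier
curves (log–log 95% intervals; medians undefined when the curve never
reaches 0.5), the two-group log-rank test, a Cox proportional-hazards
regression (Efron tie handling — the library-standard choice; hazard
ratios) and a parametric accelerated failure-time regression (Weibull by
default, lognormal selectable; effects are *time ratios* $e^{\beta}$ —
they are sometimes mislabelled hazard ratios in applied tables, which they
are not). Both regressions adjust for the design covariates plus the group
indicator, and AIC ($-2\log L + 2k$) compares the novel- and
standard-method fits of the same kind.

Note an interpretive subtlety the package does not hide: the group
indicator is a deterministic threshold of the adjusted covariates, so the
*adjusted* group effect is identified only through the thresholding
nonlinearity and is conservative; the unadjusted log-rank comparison is the
sharper view of marginal separation.

## Synthetic trials

`sim_config()` / `make_trial_triplet()` generate trials with the structure
the method assumes: categorical covariates at prevalences typical of
late-stage lung-cancer populations (≈78% male, ≈45% current smokers, ≈95%
caucasian, ≈60% above 75 kg, age bins ≈ 55/36/9%), log-normal baseline
sizes, a latent per-patient shrinkage rate driving correlated percent
changes over four visits (rate mean −4%/visit, SD 6, visit noise SD 5
percent points), a logistic BOR model on the encoded covariates plus the
mean percent change (coefficient −0.10 per percent point) with the
intercept calibrated by root finding to a target responder prevalence
(default 0.3), and Weibull survival (shape 1.2, scale 420 days) with a true
responder log-hazard ratio of $\log 0.668$ plus small covariate effects,
under uniform administrative censoring calibrated to a target fraction
(default 0.25). Default triplet sizes are 600/140/600, echoing the
small/large trial mix the schema is modelled on. `null_model = TRUE` zeroes
every coefficient for type-I-error studies.

What the generator does *not* emulate: RECIST lesion-level measurement,
visit-schedule irregularity, informative censoring or dropout, non-monotone
trajectory shapes (pseudo-progression), or between-trial heterogeneity in
the generating coefficients. Passing tests therefore certify the
*machinery* — calibration, determinism, recovery of planted effects — not
performance on any real trial.

## Simulation study sizes

The packaged studies run at deliberately chosen scales: the cutoff-departure
study (responder prevalence 0.2) uses two 300-patient training trials per
replicate, 50 replicates — 300 sits inside the 140–960 patient range the
schema targets, and below that scale the per-trial cutoffs are dominated by
fold noise from ~30 responders per trial; the null type-I-error study uses
150/150/200 for 100 replicates (null behaviour is not scale-sensitive);
parameter-recovery checks for Cox and AFT use n = 3000. The leave-pair-out
cap is lowered to 300 pairs inside the replicated studies.

## Known limitations

* The maximum-cutoff selection rule is implemented as specified but has no
  optimality argument; `max_f1` is the recommended alternative when the
  goal is classification quality rather than reproducing the method.
* Coefficients are averaged across trials without weighting by trial size
  or precision; a precision-weighted pool would be natural but is not part
  of the method.
* Averaging coefficients fitted against per-trial PCA bases assumes the
  bases are comparable; the sign convention and shared trajectory scale
  make this reasonable for monotone tumor trajectories, but strongly
  heterogeneous trials could rotate components apart.
* No recalibration of probabilities across trials, no proportional-hazards
  diagnostics, no competing risks.
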