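---
title: "mirvote: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{mirvote: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Most lymph-node-negative (LNN) breast-cancer patients are classified as
high-risk by clinical and histopathological criteria and receive adjuvant
systemic therapy, although a large fraction would be cured by surgery and
radiotherapy alone. mirvote implements an ensemble classification strategy
that uses tumor miRNA expression to identify patients with an *ultralow*
long-term risk of regional or distant metastasis — candidates for sparing
systemic treatment. The design it operationalizes is a pair-matched
case-control cohort of systemically untreated LNN patients: every patient
who developed metastases within 10 years is matched to a recurrence-free
patient with the same tumor type, ER status and grade and closely similar
age, tumor diameter and year of surgery, so that an expression-based
classifier cannot simply re-learn the classical markers.

## The pipeline

The fitting function `mirvote()` runs leave-one-pair-out cross-validation
(LOPO-CV) on a paired cohort:

1. Hold out one matched pair. On the remaining pairs, test every miRNA
   with a paired two-sided t-test on the matched case-minus-control
   differences and adjust with Benjamini–Hochberg; select the features
   with FDR < 5% (falling back to the 10 smallest-p features when none
   pass, the regime external cohorts present).
2. Train seven classifiers on the remaining samples, restricted to those
   features and z-standardized with training means/SDs: radial-kernel SVM
   (RSVM), random forest (RF), Gaussian naive Bayes (NB), linear-kernel
   SVM (LSVM), Cox risk-sum (COX-RS), k-nearest neighbors (KNN) and ridge
   logistic regression (LR).
3. Each method votes whether each held-out patient is likely to recur:
   probability methods vote 1 at probability ≥ 0.5, COX-RS votes 1
   strictly above its training-median risk-sum, KNN votes its class.
4. Repeat until every pair has been left out once; each patient collects
   0–7 votes. Patients with 0 votes form the ultralow-risk group, 0–1
   votes the low-risk group, 2–7 votes the high-risk group.

Because feature selection is repeated inside every fold on training pairs
only, the held-out pair can never influence its own feature set. This
leakage ban is what makes the held-out accuracy an honest estimate; the
test suite verifies it both by construction (corrupting a held-out pair
leaves that fold's feature set bit-identical) and statistically (at zero
planted effect, every method's held-out accuracy stays within 0.4–0.6).

### The COX-RS scorer

The Cox risk-sum is the one bespoke method: one univariate proportional-
hazards model is fitted per selected feature on the standardized training
expression, giving coefficients $\hat\beta_j$; a patient's score is
$RS_i = \sum_j \hat\beta_j z_{ij}$ and the vote threshold is the median of
the training risk-sums. This is the simplest construction consistent with
a per-patient "Cox risk regression sum"; the original supplementary
definition is not recoverable from the main text, so the construction is
an explicit stand-in, isolated behind the same fit/score/vote contract as
the other methods.

### Hyperparameters

All knobs are fixed, seedable defaults exposed via `method_control()`
(and a YAML `methods:` config via `read_method_config()`); none are tuned
inside the CV. RSVM: cost 1, RBF width by the median heuristic, Platt
scaling. LSVM: cost 1, Platt scaling. RF: 500 trees,
`mtry = floor(sqrt(p))`, bootstrap sampling, probability = fraction of
trees voting recurrence. KNN: k = 5 — odd, so majority votes cannot tie.
LR: ridge penalty fixed at 1 because selected features can approach the
sample count and an unpenalized fit may not exist. The probability tie at
exactly 0.5 votes *toward* recurrence: for a treatment-sparing classifier
the conservative direction is to demand unanimous zeros for ultralow risk.

Because the environment provides no SVM or random-forest package, the SVMs
solve the standard dual quadratic program directly (`quadprog`) and the
forest is a compact compiled implementation (bootstrap + Gini CART); both
are exercised against behavioral oracles (separable-cloud sanity checks,
label-swap symmetry, determinism) rather than against a reference library.

## Risk-group cutoffs

`assign_risk_groups()` implements both published regimes. The *fixed*
cutoff is ultralow = {0 votes}, low = {0, 1}. The *auto* cutoff adapts to
the dataset: with minimum observed vote $v$, ultralow = $\{v\}$ and low =
$\{v, v+1\}$. The auto rule reproduces the development regime mechanically
(minimum 0 gives {0}/{0,1}) and the external regime in which no patient
receives fewer than 2 votes (giving {2}/{2,3}).

## External-cohort transfer

Platforms differ, so `harmonize_features()` intersects the mature-miRNA
panels (reference order), and expression is always standardized within a
cohort, never pooled across cohorts. `preselect_method_features()` ranks
the shared features by paired-DE p-value in the reference cohort and
picks, per method, the top-$k$ set (default grid 5/10/20/50) with the best
reference LOPO-CV accuracy, smaller $k$ winning ties. The grid-accuracy
criterion is this package's reading of "most informative set per method";
the original procedure lives in an inaccessible supplement.
`external_validation()` then cross-validates entirely within the external
cohort with those fixed feature sets. For unpaired external cohorts the
folds are stratified leave-two-out: cases and controls are shuffled under
the seed and fold $i$ holds out the $i$-th of each, surplus samples of the
larger arm held out singly, so every patient is voted on exactly once.
This mirrors the paired scheme in the absence of any published rule for
unmatched cohorts.

## The synthetic cohort

`simulate_cohort()` states the world the tests run in. Each sample carries
a latent recurrence-risk score: cases at $+\delta/2$, controls at
$-\delta/2$, with half of the controls ("indolent" tumors) shifted a
further $\delta_{extra}=1$ down, plus Normal(0, 0.5) personal noise.
Informative features load on this score; the loading is calibrated
analytically so the expected case-minus-control difference equals
$\delta$ in pooled within-group SD units (a literal loading of 1 cannot
meet that contract once the indolent shift is active). The graded latent
score — rather than a clean binary separation — is what produces a graded
0–7 vote distribution and makes controls' votes correlate with their
indolence, both of which the tests assert.

Defaults reproduce the published cohort's shape: 80 pairs × 1212 miRNAs,
50 informative features, equicorrelated noise ρ = 0.2 (unstated in the
source; a nonzero value keeps FDR behavior realistic), case event times
lognormal (sdlog 0.6, meanlog solved so the ≤120-month truncated mean is
58.5 months), control follow-up Normal(250.35, 30) truncated at 60
months. Covariates (age, size, ER/PR, grade, type, year) are drawn per
pair and shared within it, with ±3-unit jitter on the continuous ones so
that the greedy matcher has real work to do. What the generator does
*not* emulate: array probe-level noise, batch effects, platform-specific
panels, or correlation between covariates and expression — so a green
test establishes the pipeline's statistical mechanics, not clinical
performance.

The matcher itself (`match_pairs()`) is greedy nearest-neighbor: cases in
input order, exact equality on tumor type/ER/grade, calipers of ±10
years, ±10 mm, ±5 years of surgery (the study states matching variables
but no algorithm or tolerances; these are explicit knobs, not claims),
distance = sum of caliper-normalized absolute differences, ties to the
first control in input order.

## Numerical choices and degenerate inputs

* Zero-variance paired differences: flagged, `p = 1`, never an exception.
* Zero-variance features at training: dropped with a warning.
* BH adjustment is the package's own step-up implementation, tested to
  1e-12 against brute force and `p.adjust`.
* The one-tailed Fisher test is the hypergeometric upper tail of
  non-recurrent patients in the risk group, margins fixed — tested against
  exhaustive enumeration of all tables with the same margins.
* Cox models with every event in one arm (an ultralow group with zero
  recurrences) have monotone partial likelihood: the HR is reported as
  flagged/unbounded, not an error. Similarly, a covariate that perfectly
  predicts group membership is excluded from the logistic independence
  model and reported `n/a`.
* The accuracy significance in `confusion_metrics()` is a one-sided exact
  binomial test against chance (p = 1/2); the test behind the published
  accuracy p-values is unnamed, so this is a documented stand-in.

## Known limitations

The published per-method accuracies (77–86%), the 217 differentially
expressed miRNAs, the HR of 19.85 and the 37/80 ultralow count require
the deposited patient cohorts and are out of reach at desk scale; the
property suites (null calibration, power/recovery, oracle equivalence,
HR coverage) stand in for them. Event times and censoring are drawn
independently of expression given the latent score; real cohorts couple
them more intricately. The COX-RS construction, SVM/KNN hyperparameters
and the preselection criterion are stand-ins for supplementary material
that the main text does not reproduce.
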