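---
title: "Hybrid human-machine prognosis: models, design choices and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid human-machine prognosis: models, design choices and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mshybrid)
```

`mshybrid` turns a human-machine forecast-combination analysis of the
relapsing-remitting (RR) to secondary-progressive (SP) transition in
multiple sclerosis into a reusable pipeline. This vignette is the
package's own account of the science: the models and their assumptions,
the parameters that matter, the places where the design was genuinely
open and what we chose, and what the validation suite does and does not
establish.

## The prediction problem

A clinical record is one visit of one patient. For each record and each
horizon $h \in \{180, 360, 720\}$ days, the binary outcome $y_h$ states
whether the patient had reached the SP phase $h$ days after the visit.
Since SP is absorbing, $y_{180} \le y_{360} \le y_{720}$ within a record;
the readers enforce this invariant (violations warn by default and can be
promoted to errors, because an authoritative source file may be
inconsistent without being unusable). All forecasts are scores in
$[0, 1]$; performance is measured exclusively by the area under the ROC
curve, so only the ranking of records matters.

## The machine agent: modified leave-one-patient-out

Records of one patient are strongly correlated, so an ordinary
leave-one-out both trains on near-duplicates of the held-out record and
rewards models for recognising patients rather than prognosis. The
protocol in `fit_predict_loo()` avoids this: for each patient, all their
visits are withheld; `n_sets` (default 50) training sets are drawn, each
holding exactly one uniformly chosen visit per remaining patient; one
model is trained per set; each withheld record receives one probability
per model ("unitary predictions"), their mean (the forecast) and their
sample standard deviation (the dispersion).

Design choices where the protocol description leaves room:

* **Unitary prediction = model-level probability.** The per-model class-1
  probability, not per-tree votes; only this reading is consistent with
  averaging the 50 models' predictions.
* **Base learner.** A pluggable contract (`fit`/`predict_probability`);
  the default is a probability forest (`ranger`, 100 trees, package
  defaults otherwise). The protocol, not the learner, is the artifact.
* **One-class training sets.** At the 180-day horizon prevalence is near
  12%, so an 83-record set can be all-negative. The learner then predicts
  the constant class probability (0 or 1), keeping all `n_sets` unitary
  values per record rather than dropping sets.
* **Missing features.** Median imputation with medians computed inside
  each training set only, so no information flows from the scored patient.
* **Seeding.** One named substream per (excluded patient, set index);
  results are invariant to the order patients are processed, which is
  asserted by a test that shuffles the input rows.

## The human agent: Singles, Pairs, Group

Raters score records on the discrete 0-5 scale, normalized by $s/5$. Any
strictly monotone map gives identical AUCs, so the choice is innocuous
for evaluation, but it is fixed because the hybrid stage combines
normalized ratings with machine probabilities on one scale.

* *Singles*: one AUC per rater over exactly the records that rater
  scored; reported as mean ± SD across raters. A rater whose records are
  all one class has an undefined AUC and is excluded from the mean, with
  a message - silently dropping them would bias the summary, erroring
  would make sparse panels unusable.
* *Pairs*: only records with at least two ratings; two are chosen
  uniformly when more exist, and the two normalized ratings are averaged
  per record *before* the AUC. The value is stochastic; the default
  reports the mean over 100 independent selections (`n_draws = 1`
  recovers the single-draw variant), since a one-draw value at this
  sample size carries visible selection noise.
* *Group*: per-record mean of all ratings; deterministic.

## The hybrid combiner

For one agent and one horizon, each record's dispersion of unitary
predictions is converted into a normalized concordance rank: sort by
dispersion ascending, assign raw ranks $R \in \{1..N\}$ with average
ranks on ties, and rescale to $(N-R)/(N-1)$, so the most concordant
record gets 1 and the most scattered 0. If every dispersion is equal the
rescaling is undefined; all records then get 0.5 (the average-rank limit)
with a warning.

Open design points and how we resolved them:

* **Concordance statistic.** The sample standard deviation of the
  unitary values: symmetric, scale-aware, and zero exactly at full
  agreement. (The interquartile range would also serve; SD is the
  default because 50 unitary values make it stable.)
* **Combination rule.** The literal rule "sum the two squared ranks",
  $r_H^2 + r_M^2$, contains no forecast direction: a record on which an
  agent is unanimously *negative* ranks as high as one where it is
  unanimously *positive*, so the sum cannot order records for a ROC
  analysis by itself. The package's default `weighted` mode therefore
  uses the squared ranks as consistency weights on the forecast means,
  $H = (r_H^2 m_H + r_M^2 m_M)/(r_H^2 + r_M^2)$, falling back to the
  plain mean when both weights vanish. The literal `sum_sq_ranks` mode is
  retained for fidelity, and the degraded `linear_ranks` (unsquared
  weights) and `unranked` (inverse-dispersion weights) ablations are
  implemented as modes.
* **Rank scope.** Ranks are computed per horizon and per agent over the
  full shared record set; nothing suggests pooling horizons, and pooling
  would let a horizon with generally tighter ensembles dominate.
* **Human dispersion.** Uses *all* ratings available for a record, not
  the Pairs subsample. Records with a single rating have no within-record
  dispersion; the experiment driver assigns them the panel's maximum
  dispersion (treat an unreplicated opinion as unconfirmed), which only
  lowers their weight, never fabricates confidence.
* **File-based machine scores.** When only per-record mean probabilities
  are available (no unitary values), the machine's dispersion is unknown;
  the driver then gives the machine a uniform rank of 0.5 everywhere and
  flags the run (`machine_rank_fallback` in the manifest), making hybrid
  values in that mode explicitly mode-dependent.

## Evaluation

`roc_auc()` implements the Mann-Whitney formulation with half-credit for
tied scores; the reported curve collapses ties so its trapezoidal area
equals the rank statistic exactly. Tests verify, on random instances,
agreement with an $O(n^2)$ pair-count oracle to $10^{-12}$, the
complement identity $\mathrm{AUC}(s) + \mathrm{AUC}(-s) = 1$, invariance
under strictly increasing transforms, and agreement with an independent
reference implementation.

`bootstrap_auc()` resamples records with replacement (percentile CI;
quartiles and full range are stored so summaries can be drawn as boxes =
quartiles, whiskers = range). Resamples with one outcome class are
redrawn, preserving the replicate count; the number of redraws is
recorded. Because same-patient records are correlated, a patient-level
cluster bootstrap is available (`unit = "patient"`) as a robustness
option; the record-level bootstrap remains the default to match the
analysis the package reimplements. `auc_difference()` applies identical
resample indices to both agents (paired design), reports the percentile
CI of the AUC difference, significance read from whether that CI excludes
zero, and a two-sided tail-mass p-value; 1000 replicates by default - the
replication count is a convention, not an estimate.

## The synthetic cohort generator

The real clinical feature table is not publicly available, so the
generator emulates the *statistical structure* the analysis relies on,
not MS clinical variables:

* Patient-level latent risk $u \sim N(0,1)$; visits per patient are
  truncated-geometric (mean 6.27, max 15) to match the unbalanced
  84-patient / ~527-record shape; visits are equally spaced.
* Transition: the residual time from a patient's *last* recorded visit is
  exponential with rate $e^{\beta u}/s$, so every recorded visit is in
  the RR phase and many patients transition only after their last visit.
  Labels are monotone across horizons by construction, and earlier visits
  of a patient are farther from the transition.
* Defaults $\beta = 3.22$, $s = 880$ days and spacing 103 days were fixed
  once by matching the generator's closed-form record-level prevalence
  (`expected_prevalence()`, a 1-D integral over the latent risk and the
  visit structure) to the cohort's published prevalences 12.3 % / 23.7 %
  / 40.0 % at 180/360/720 days. The closed form doubles as the
  independent oracle for the generator's validation test.
* Features are affine in $u$ with independent Gaussian noise of SD
  $1/\texttt{signal\_strength}$; they carry prognostic signal but no
  clinical semantics (no EDSS trajectories, relapse counts, or treatment
  effects).
* Raters: the latent rating mixes the record's true transition
  probability with uniform noise, `skill` weighting the signal; noise is
  stretched by `1 + dispersion_coupling * hardness`, where hardness is
  largest for records whose true probability is near 0.5; discretization
  to 0-5 uses equal-width bins. Defaults (42 raters x 50 records,
  `skill = 0.15`, coupling 1) put the simulated Singles near 0.57-0.60
  and the Group near 0.65-0.70 at 180 days, bracketing the published
  operating points; a single skill parameter cannot hit both exactly
  because real raters' errors are more idiosyncratic than the model's.
* Machine ensembles: unitary predictions are drawn around an anchor
  $w\,y + (1-w)\,\eta$ with effective signal weight
  $w = \texttt{skill}^{\,1 + \texttt{coupling} \times \texttt{hardness}}$,
  so hard records get both a weaker anchor and a wider spread. This
  yields the dispersion-correctness coupling the hybrid exploits, and the
  limits behave correctly (skill 1: perfect separation; skill 0:
  uninformative). The default `skill = 0.25` places the simulated
  machine near AUC 0.71 at 180 days.
* All randomness flows from one master seed through named substreams
  (cohort / raters / ensemble / per-patient fits), so components can be
  regenerated independently and runs are bit-reproducible.

What passing tests on synthetic data therefore show: the protocol,
aggregation, combination and evaluation machinery are correct, and the
hybrid's advantage follows from dispersion-correctness coupling plus
complementary agents. What they cannot show: that real MS clinical data
exhibit that coupling at the simulated strength, or that the published
effect sizes transfer.

## Validation suite and problem sizes

The acceptance tests use these study conditions and sizes, chosen to make
Monte-Carlo error small relative to the asserted margins while keeping a
default run in minutes: generator validation pools 2000 default cohorts
and compares pooled prevalence to the closed form within three
ratio-estimator standard errors; bootstrap null coverage uses 500 cohorts
x 1000 replicates and requires 93-97 % coverage at the nominal 95 %
level; the hybrid improvement property uses 200 replicate cohorts at the
default configuration, requiring the weighted hybrid to beat both single
agents in at least 80 % of cohorts and the cohort-level 95 % CI of the
mean improvement (against both the Group and the machine agent) to
exclude zero. The per-cohort improvement (~0.05 AUC at ~500 records) sits
below what a single cohort's paired bootstrap can resolve, which is why
the property is asserted at the replication level; the single-cohort
paired bootstrap is still computed and reported by the acceptance script.
Reproduction of the published single-agent values (machine 0.710 / 0.670
/ 0.679, Group 0.703, Singles 0.57 at 180 days, label counts
527/65/125/211) runs against user-supplied copies of the deposited
tables; the published *hybrid* values are not reproducible from public
data because the machine agent's unitary predictions were never deposited
and the combination rule admits the two readings described above - both
are implemented.

## Known limitations

* The questionnaire block-layout reader is best-effort; the long CSV
  layout is normative.
* The generator's visit process (equal spacing, truncated-geometric
  counts) is a stand-in; follow-up length and visit cadence of the real
  cohort are not published.
* No learned combination weights (stacking, meta-learners): the fixed
  rank rule is the object of study.
* Retraining the machine agent cannot be bit-identical to the published
  score files (learner versions and seeds differ); file-based scores are
  the faithful route for reproduction, retraining for method study.
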