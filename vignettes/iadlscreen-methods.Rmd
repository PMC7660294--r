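---
title: "Screening for dementia onset from smart-home IADL sensor logs: methods"
author: "iadlscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening for dementia onset from smart-home IADL sensor logs: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iadlscreen)
```

## The screening problem

Instrumental activities of daily living (IADLs) — sweeping a kitchen,
filling a medicine dispenser, preparing soup in a microwave — demand
planning, sequencing and sustained attention, which are precisely the
faculties eroded early in dementia and mild cognitive impairment (MCI).
A smart home instrumented with passive-infrared motion sensors records,
at no burden to the resident, when and where movement happens while such
tasks are performed. `iadlscreen` implements a complete pipeline that
turns raw timestamped sensor event logs of scripted eight-task IADL
sessions into a binary screen: *cognitively impaired* (dementia or MCI,
the positive class) versus *cognitively healthy*.

The pipeline has seven stages: log parsing, synthetic-cohort simulation
(for testing and method development without access to restricted
participant data), feature extraction, class-conditional imputation of
missing task durations, MRMR feature ranking, class-imbalance correction,
and cost-sensitive classifier evaluation.

## Event logs and cognitive labels

A session log is line-oriented text, `<clock-time> <sensor-id> <state>`,
e.g. `09:07:02.27948 M015 OFF`. An observer annotates the beginning and
end of each of the eight scripted tasks; since annotation tokens vary by
deployment, the parser's *dialect* is configurable (a regular expression
whose first capture group is the task number; the default reads
`TASK_<k> BEGIN|END` lines). Clock times become seconds relative to the
session start, rounded to the dialect's 10 µs precision so that
write→parse round trips are exact. Out-of-order stamps are stably sorted
rather than rejected — ambient logging pipelines jitter — and a backwards
jump larger than 12 h is treated as a midnight wrap.

Participants carry a 10-way cognitive category that collapses to three
parent groups: dementia and MCI (codes 1–2) are *impaired*; the five
healthy age subgroups (codes 3–7) are *healthy*; other-medical, at-risk
and diagnosis-unavailable records (codes 8–10) are *unknown* and are
discarded before modelling.

## The synthetic cohort generator

The generator exists so every downstream stage is testable end to end.
Each synthetic participant attempts tasks 1–8 in order. Per task $k$ the
class-conditional behaviour is:

* completion: Bernoulli($p_k$);
* duration of a completed task: lognormal($\mu_k$, $\sigma_k$) seconds;
* motion events: per task-relevant sensor, ON/OFF pairs at Poisson rate
  $\lambda$ events/s across the task window; corridor/doorway
  ("transition") sensors fire at $\rho\lambda$, the wandering proxy.

Defaults, chosen once as the study conditions: healthy $p_k = 0.97$,
impaired $p_k = 0.75$; impaired $\mu_k = \mu_k^{healthy} + \log 1.6$
(tasks stretch by 60%) with a larger $\sigma$ (0.45 vs 0.30); impaired
$\rho = 2$; impaired $\lambda = \lambda^{healthy}/1.6$ so that *mean*
per-sensor event counts stay comparable between classes while durations
stretch — matching the qualitative pattern that separates the groups in
the source data (longer times, lower task scores, similar overall event
volume). Healthy baseline durations are 180–420 s per task and
$\lambda^{healthy} = 0.04$ events/s/sensor. Inter-task idle gaps are
Uniform(5, 30) s; they only exercise the trimming logic. Cohort sizes
default to the study's: 56 impaired / 194 healthy training participants
and 20 / 34 test participants.

What the generator does **not** emulate: door/item/temperature sensors
(tokens pass through but are never simulated), second-floor activity,
task-order errors, within-task pauses, and any fitted correspondence to
real CASAS marginals. A test passing on this cohort therefore
demonstrates the pipeline's correctness and qualitative behaviour, not
field performance on real homes.

## Feature extraction

Events are first trimmed to the span from the first BEGIN to the last
END. The fixed 38-predictor manifest is:

* `tDuration_1..8` — END − BEGIN per task, 0 s when a task was not done;
* `s<SensorID>` — ON-transition counts for the 27 retained ground-floor
  motion sensors (M001–M026 and M051; the upper-floor block M027–M050 is
  excluded). A full activate/deactivate cycle counts once: counting OFF
  transitions too would exactly double every count.
* derived: `TotalTime` (sum of the eight durations), `TaskScore`
  (number of completed tasks, 0–8), `Total_sEvents` (sum of the 27
  retained counts).

An optional 39th predictor, `Age`, is the midpoint of the participant's
age band ("45-59" → 52; open bands "75+" → 80). It is off by default;
it belongs to a secondary analysis variant. The retained-sensor set is a
configuration default, not a constant — the 27th ground-floor sensor's
identity depends on deployment.

## Imputation of missing durations

A zero duration means "task not done"; left at zero it reads as "done
instantly", which inverts its meaning. The rule replaces every zero with
**twice the maximum observed nonzero duration of that task within the
row's cognitive group**, then recomputes `TotalTime` from the updated
durations. `TaskScore` is deliberately not recomputed — it still counts
genuinely completed tasks.

The class-conditional maximum poses a leakage question the formal
procedure leaves open: the group of a *test* row is exactly what the
model must predict. The package therefore fits the rule on training data
only and gives unlabelled or test rows the pooled fallback (twice the
maximum over all training groups). The class-conditional variant remains
available for labelled training data, and a pooled mode
(`mode = "pooled"`) reproduces the simpler per-column-maximum reading.
A group/column with no observed nonzero duration has no maximum; asking
it to impute is an error rather than a silent guess.

Standardization (centre by the sample mean, scale by the $n-1$ sample
standard deviation) is provided for parallel-coordinates style exports
and inspection; classifiers train on raw features, where tree and
ensemble results are scale-invariant anyway. A zero-variance column maps
to zeros with a warning.

## MRMR feature ranking

Relevance and redundancy are measured by plug-in mutual information on
discretized variables, in nats:

$$E(X,Z) = \sum_{i,j} P(x_i, z_j)\,\log\frac{P(x_i,z_j)}{P(x_i)P(z_j)}$$

Continuous predictors are discretized by equal-frequency (quantile)
binning with $B = 10$ bins by default — robust to the heavy right tails
of task durations; columns with at most $B$ distinct values keep one
code per value. The estimator is the empirical double sum; zero-joint
cells contribute zero.

Ranking is forward addition under the mutual-information quotient:
step 1 selects the candidate with maximal relevance $V_x = E(x, y)$
(the redundancy term is undefined for an empty selected set); every
later step selects $\arg\max_x V_x / W_x$ with
$W_x = |S|^{-1}\sum_{z \in S} E(x, z)$. Ties break by larger $V_x$, then
lexicographic name. A candidate with $W_x = 0$ but $V_x > 0$ — relevant
yet independent of everything selected — wins its step outright. The
base of the logarithm only scales scores; the ordering is base-invariant.

On real data from the source study the top-ranked features are task
durations (task 5 first), `TotalTime`, `TaskScore` and a pair of
specific sensors; that ordering depends on the external dataset and is
treated as an expected qualitative outcome, not a test anchor. The
package's planted-signal check instead generates cohorts whose class
signal lives *only* in durations and verifies the durations outrank all
sensor counts in at least 18 of 20 seeds.

## Imbalance correction

Two oversamplers operate on the training matrix only:

* **Duplication** — minority rows resampled with replacement up to a
  configured target; every added row is an exact copy. The emulation
  profile targets 206 minority rows (400 total), matching the balanced
  duplicate training instance of the study.
* **Safe-level SMOTE** — synthetic rows $x + u\,(x_{nn} - x)$ between a
  minority seed row and one of its $k = 5$ nearest minority neighbours
  (Euclidean distance on raw predictors, matching the pipeline's order
  of operations; a standardize-first option exists because raw durations
  dominate the metric). The *safe level* of a point is the number of
  minority members among its $k$ nearest neighbours of any class.
  With $sl_s$ (seed) and $sl_n$ (neighbour): equal safe levels give
  $u \sim U(0,1)$; a safer seed gives $u \sim U(0, sl_n/sl_s)$; a safer
  neighbour gives $u \sim U(1 - sl_s/sl_n, 1)$; an unsafe neighbour
  ($sl_n = 0$) duplicates the seed ($u = 0$). When both safe levels are
  zero the original formulation generates nothing; to keep the
  configured target count exact and the output deterministic, the seed
  row is duplicated in that case. The emulation profile stretches the
  56 minority rows to 197 (391 total) — both targets are configured
  numbers from the study, not derived quantities.

## Classifiers, cost bias and metrics

The comparison suite mirrors a standard desktop classification-learner
toolbox: decision trees (fine/medium/coarse ≈ decreasing depth presets),
linear discriminant, logistic regression, kernel naive Bayes (Gaussian
kernel density estimates per class and feature, normal-reference
bandwidth), SVM (quadratic/cubic polynomial or Gaussian kernels), KNN
(fine $k=1$; medium $k=10$; cubic $k=10$ under Minkowski $p=3$), bagged
trees (bootstrap forest with all predictors available at every split),
gradient-boosted trees, RUSBoosted trees (AdaBoost with per-round random
undersampling of the majority class, shallow tree weak learners), and a
single-hidden-layer feed-forward network (width 10, weight decay,
standardized inputs).

Evaluation is stratified 5-fold cross-validation — stratification chosen
because a 56/194 imbalance makes unstratified folds erratic — with
confusion counts pooled over folds (they always sum to $n$), plus a
held-out test evaluation. With impaired as the positive class:

$$\text{sensitivity}=\frac{TP}{TP+FN},\quad
\text{specificity}=\frac{TN}{TN+FP},\quad
\text{precision}=\frac{TP}{TP+FP},\quad
F = \frac{2TP}{2TP+FP+FN}$$

Zero denominators yield `NA` markers, never errors. The published
comparison tables this structure mirrors contain F-score and cost cells
that contradict their own printed confusion counts; the package computes
the positive-class formulas above and catalogues the inconsistent cells
in its test fixture rather than matching them.

A missed impaired participant is far costlier than a false alarm, so the
suite supports a misclassification cost matrix, default
$c_{FN} = 30$, $c_{FP} = 1$ (total cost $30\,FN + FP$). Trees receive it
as a native loss matrix; other learners receive the ratio
$c_{FN}/c_{FP}$ as a positive-class weight (case weights, priors,
class weights or vote weights, whichever the learner supports). The
cost-bias sanity check — raising $c_{FN}$ from 1 to 10 or 30 must not
lower median cross-validated sensitivity — is run on the pruned (coarse)
tree: the deliberately overfit fine preset sits at ceiling sensitivity
on the synthetic cohort, where fold-level noise from prior-shifted split
selection swamps the monotone effect; the pruned tree, logistic and LDA
all show it cleanly.

## Numerical and design choices

* **Determinism.** Every stochastic stage takes a seed; the pipeline
  derives per-stage seeds from one master seed by a fixed affine scheme,
  so adding a stage never shifts an earlier stream. Identical
  configuration and seed give byte-identical artifacts.
* **Degenerate inputs.** Empty logs parse to empty, valid objects; a
  task's END before its BEGIN is a data error naming the task; an empty
  minority class cannot be balanced; a zero-variance label cannot be
  ranked. Tasks missing from the markers simply score zero.
* **Problem sizes in the checks.** The oracle comparisons use small
  instances (3–5 predictors, $n \le 60$; 200 random joint tables); the
  planted-signal and end-to-end checks use cohorts of 100/class and the
  full 56/194 + 20/34 emulation respectively, with 10–20 seeds — sizes
  at which every property examined is already stable.
* **Sensor identity of the 27th retained sensor** (M051 by default) is
  configuration, because the source material does not print it.
* **Feature-count readings.** The source material variously counts
  51–59, 35–59, 35, 38 and 39 features; the package fixes the
  38-predictor reading (8 durations + 27 sensors + 3 derived) with Age
  as the optional 39th.

## Known limitations

Task boundaries come from observer annotations, not activity
recognition; logs without markers yield empty feature rows. The
generator's distributional choices (lognormal durations, Poisson
firings) are stated, not fitted to real data, so absolute performance
numbers on synthetic cohorts say nothing about field accuracy. The
kernel naive Bayes assumes per-feature independence given class, clearly
false for durations and their own sums, yet it is kept for parity with
the comparison suite. Headline published accuracies depend on an
external restricted dataset and an unpublished split; the package
reproduces their metric arithmetic exactly and their pipeline
structurally, nothing more.
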