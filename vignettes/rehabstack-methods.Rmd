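---
title: "Methods: synthetic mobility-test cohorts and hybrid incremental classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic mobility-test cohorts and hybrid incremental classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rehabstack)
```

## The problem

Home-based rehabilitation after stroke or in frailty is monitored with two
timed mobility tests: the Timed Up and Go (TUG) and the Five Time Sit To
Stand (FTSTS). A support system at home must, from a test's completion time
and the user's demographics (age, height, weight, BMI, sex), (1) recognise
which stage of the test the user struggles with (the *difficulty* axis —
walk, turn, stand/sit, normal, fast for TUG; slow, fast for FTSTS) and (2)
track a plausible clinical *condition* (18 TUG condition classes, 13 for
FTSTS, from healthy and geriatric through Parkinson's stages, dementia,
arthritis, stroke, vestibular and spinal conditions). No public datasets
exist at this granularity, and the system must keep adapting to one user on
low-power hardware while remaining auditable.

`rehabstack` implements the full loop: a summary-statistics-driven cohort
generator, preprocessing, a boosted-trees + k-NN classifier pair, a
trend-gated hybrid selection and incremental retraining engine with safety
flags, and evaluation utilities.

## Synthetic cohorts from summary statistics

Published cohort studies report, per condition class, the mean and SD of
completion time, age, BMI, weight and height, plus the fraction of female
subjects. The generator turns one such parameter set into an `n`-row feature
table:

1. draw each of time, age and BMI i.i.d. from its Normal and **sort** each
   column ascending — sorting aligns the quantiles of the marginals, which
   induces the (approximately linear) relationships seen in practice:
   slower times with higher age, higher age with higher BMI;
2. **insert variability** by swapping `round(f·n)` randomly chosen index
   pairs at most `swap_window` positions apart (defaults: f = 0.15,
   window = n/4). Swaps are permutations, so every column's sample moments
   are exactly preserved; only cross-column rank correlations are relaxed.
   Age is swapped on its own; BMI first on its own, then jointly with the
   linked {BMI, weight, sex} block, the identical swap sequence applied to
   all three so their internal structure survives;
3. assign sex deterministically — the first `floor(n·%female)` entries are
   female (coded 0) — before the joint block swap distributes them;
4. derive height from the (weight, BMI) pair as `H = sqrt(W/BMI)`, the
   inversion of BMI = W/H². (The un-rooted ratio `W/BMI`, which yields H²,
   is available behind `literal = TRUE` for comparison.) The height column
   is then affinely rescaled so its sample mean and SD match the published
   values exactly, and BMI is recomputed as `W/H²` so the row identity is
   exact. The recomputation drifts the BMI column's moments; the drift is
   returned and warned about above 10% relative. We prioritise the row-wise
   identity over exact BMI moments because downstream consumers (outlier
   screening, SMOTE, the classifiers) all assume internally consistent
   records;
5. truncate all Gaussian draws at physical bounds (time, weight, BMI > 0,
   age ≥ 0) by redrawing — the Normal tails would otherwise admit
   impossible values.

`validate_correlations()` compares the generated table's Pearson matrix
with a reference (e.g. from a recorded dataset) and is the intended knob
for tuning the swap fractions: more swaps pull the near-perfect
correlations of sorted columns down toward a realistic target.

The shipped parameter files (18 TUG and 13 FTSTS condition classes, 280 and
240 rows per class) are **synthetic stand-ins**: clinically plausible values
bounded by the published cohort ranges (TUG ages [5,112] y, heights
[0.81,2.20) m, weights (30,136) kg; FTSTS ages (11,93] y, heights
[0.94,2.35) m, weights (22,120) kg), flagged `non_canonical` in the file
metadata. Results that depend on them are structural demonstrations, not
clinical estimates.

## Preprocessing

* **Outliers**: a single screening pass removes a record iff any continuous
  feature deviates from its column mean by more than three column SDs, both
  computed once on the input. The pass is deliberately not iterated — an
  iterated 3σ rule keeps shaving the tails of clean data.
* **Normalisation**: per-feature min–max to [−1, 1], fitted on training
  data only; constant features map to 0; the inverse is exact.
* **SMOTE**: every class is raised to the majority count; each synthetic
  record is `x + u(x_nn − x)` with `u ~ U(0,1)` and `x_nn` one of the
  parent's 5 nearest minority neighbours in raw feature space. The binary
  sex code is copied from the parent and BMI is recomputed from the
  interpolated weight and height, keeping every synthetic row internally
  consistent. Balancing runs on the whole labelled pool *before* the
  train/test split — this mirrors reported per-class totals that include
  test data, and the resulting synthetic-parent leakage across the split is
  recorded in the balance report rather than silently accepted.

## The base models

`rehab_train()` is the fitting function. It makes a seeded stratified 80/20
split, fits the normalizer on the training split, and tunes both models by
stratified 5-fold grid-search cross-validation (mean fold accuracy, ties to
the first grid point for determinism):

* **Boosted trees** (xgboost, multiclass softmax; probabilities via the
  softprob variant of the same model). The default grid crosses
  eta {0.05, 0.1, 0.3}, number of rounds {50, 100, 200} and maximum depth
  {3, 2C, 4C} (C = number of classes, 2C being the conventional starting
  depth for a C-class problem); subsample, colsample, regularisation and
  minimum child weight are held at fixed defaults but accepted in the grid.
  A full Cartesian product over all eleven parameters is possible but not a
  sane default on embedded-class hardware.
* **k-NN** with Euclidean distance on the normalized features and
  vote-fraction probabilities; k tuned over {1, 3, 5, 7, 9} (5 is the
  conventional starting point). The store is a plain (X, y) matrix so a
  session's record can be appended in O(1) and probabilities stay exact.

The fitted pair also carries per-class centroids (arithmetic means in
normalized feature space) — the reference points for the hybrid engine —
and xgboost's gain-based feature importances, normalised to sum to one.

**Incremental updates** append the record to the k-NN store, update the
labelled class's centroid as a running mean, and warm-start the boosted
model: `warm_rounds = 5` additional rounds are fitted on the accumulated
training set *on top of cached class margins* of the existing ensemble. The
chain-of-boosters representation is mathematically identical to warm
starting (boosting is additive in the margin; the constant base score
cancels in the softmax) but its per-update training cost does not grow with
the number of past updates, which is what a light computational footprint
on home hardware requires.

## The hybrid session engine

Each session: the new completion time is appended to the user's history; a
degree-2 polynomial (least squares, 0-based session index) is fitted and
its derivative at the last index is the **improvement rate** (negative =
getting faster). Both models predict both axes; for each axis the Euclidean
distances between each candidate class's centroid and the healthy centroid
are computed (healthy reference: the `healthy` condition class; for the
difficulty axes, which have no clinical healthy class, the non-impaired
class — `normal` for TUG, `fast` for FTSTS); and the final prediction is
selected:

| trend | rule |
|---|---|
| models agree | the agreed class (it is both closest and farthest) |
| improving | candidate closer to the healthy centroid |
| worsening | candidate farther from the healthy centroid |
| steady | most frequent past final prediction (baseline) |

Both models of both axes are then retrained incrementally with the selected
final label — the self-training loop that individualises the system — and
the safety state is computed: *possible fall* (test started, never
completed, timeout elapsed), *sensor anomaly* (event stream violating the
start→phases→complete grammar, or a physically implausible time),
*forcing* (improvement rate steeper than `forcing_threshold` while the
final prediction deviates from the baseline), *deterioration* (worsening
status on `deterioration_window = 3` consecutive sessions). A co-morbidity
drift alert fires when the final condition differs from the
clinician-initialised one in ≥ 80% of the last 10 sessions.

### Trend detection: guarding the self-training loop

The selection table above makes the improvement status a steering signal
for self-training: a *wrong* improving/worsening status at a session where
the two models disagree routes the wrong label into both training stores,
and the error then reinforces itself. The paper of record for this design
problem is the classic self-training failure mode, and the engine therefore
treats trend detection conservatively; the paper the method derives from
specifies no trend test, so the following are this package's choices:

* the steady band is `max(epsilon, t_{df,0.995} · SE(rate))`, with
  `epsilon` defaulting to 1% of the user's mean completion time — the rate
  must be statistically distinguishable from stationary noise at 99%
  confidence. Conservatism is deliberate: the cost of a missed trend is a
  delayed status change, the cost of a false trend is a wrong retraining
  label and a false alarm to a carer;
* the polynomial degree is capped at `n − 2` (while at least linear) so a
  residual degree of freedom exists whenever possible; an exactly
  polynomial history (zero residuals) is taken at face value against
  `epsilon` alone;
* histories with fewer than two residual degrees of freedom cannot support
  a noise estimate; they fall back to a minimum-detectable-change floor of
  15% of the mean completion time, mid-range of published test–retest MDC95
  values for timed mobility tests;
* a non-steady status steers selection only when observed on two
  consecutive sessions (the raw status still drives the deterioration
  flag). Confirmation on consecutive assessments is standard monitoring
  practice.

All four are configurable (`hybrid_config()`, `improvement_rate()`).

### Held-out evaluation of the hybrid

`evaluate_hybrid_holdout()` replays a test split as {participant,
difficulty-class} session streams — the evaluation unit of the instrumented
study this emulates, where a participant performs a block of repetitions of
one condition. Within a stream the baseline is built from the stream's own
previous finals; before any baseline exists, the candidate whose class
centroid is nearest to the incoming record arbitrates (nearest-centroid
classification, using machinery the engine already has). Models are not
retrained here, isolating the selection rule.

## Fixtures: what they emulate and what they do not

The real 8-participant instrumented study is not public. The fixture
(`fixture_experiment()`) reproduces its published *shape*: the per-class
pre-balance counts (TUG walk/turn/stand-sit 40, fast 39, normal 24; FTSTS
slow 33, fast 40), eight participants with the study's demographic skew
(one female, ages 20–45), and class-separated completion times. Two choices
matter:

* class time ranges are disjoint with between-class gaps wider than the
  within-class spread, making completion time the dominant feature — the
  published feature-importance structure of such experiments;
* each (participant, class) pair has a characteristic time and repetitions
  scatter around it with 3% coefficient of variation, the way repeated
  clinical timing measurements behave; times are not spread uniformly over
  the class range.

Session streams (`fixture_session_stream()`) realise named trends
(improving/worsening/steady/forcing/abandon) with 2% CV noise around the
trend line.

Consequently, passing tests on these fixtures demonstrate the *mechanics* —
balancing counts, separability recovery, trend gating, self-reinforcement,
flag logic — not clinical performance. Real data have overlapping classes,
non-stationary noise, and demographic confounding the fixtures only hint
at; accuracy numbers on fixtures are upper bounds by construction.

## Numerical and scale choices

* All randomness flows from explicit integer seeds; child seeds are derived
  by a counter scheme (`derive_seed()`), so partial re-runs reproduce.
* Probability ties break toward the lowest class code; grid ties toward the
  first grid point; equal candidate distances toward the boosted model.
* The demonstration pipeline and the reproduction script train the TUG
  condition axis on 40 rows per class (18 classes, 720 rows) with a
  one-point grid — the condition axis is a supporting input to the
  difficulty-stream simulations there, and this size keeps a full
  40-stream × 200-session simulation within minutes on one core. The
  generator's own defaults remain the full 280/240 rows per class.
* The individualisation study simulates 8 individuals × 5 TUG difficulty
  classes × 200 sessions (8 000 sessions, both axes retrained every
  session).

## Known limitations

* The shipped cohort statistics are invented stand-ins; any conclusion
  about real TUG/FTSTS populations requires replacing them with harvested
  values.
* SMOTE before the split leaks synthetic-parent information into held-out
  folds; cross-validated accuracies on balanced fixtures are optimistic.
  The balance report says so explicitly.
* Boosted trees cannot extrapolate between disjoint training clusters: a
  record falling in the inter-class time gap is routed to one side of it.
  The hybrid's agreement/centroid/baseline machinery absorbs most such
  cases, which is visible in the traces as k-NN or the baseline correcting
  the boosted candidate near class boundaries.
* The trend guard trades sensitivity for specificity; slow genuine drifts
  (well under 1% of the mean per session) are reported steady and surface
  instead through the deterioration flag's longer window.
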