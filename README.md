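# rehabstack

Individualised machine-learning support for home-based rehabilitation built
on two standard mobility tests: the Timed Up and Go (TUG — rise from a chair,
walk 3 m, turn, return, sit) and the Five Time Sit To Stand (FTSTS — five
sit-to-stand cycles as fast as possible), both scored by completion time.

The package is aimed at researchers prototyping ambient rehabilitation
support systems who need (a) labelled training data in a field with no
public datasets, and (b) a classifier that adapts to one user over months of
unsupervised home use while remaining auditable.

It provides:

* **A synthetic cohort generator.** Per-class feature tables
  (completion time, age, BMI, weight, height, sex) are synthesised from
  published summary statistics (per-class mean/SD and % female). Linear
  relationships between features are induced by drawing each feature from
  its Gaussian and sorting; realism is restored by swapping a controlled
  number of index pairs, with linked features ({BMI, weight, sex}) swapped
  jointly so their mutual structure survives. Height is derived from the
  (weight, BMI) pair via BMI = W/H², then affinely rescaled to the published
  height moments, and BMI is recomputed so the identity holds on every row.
  A correlation-matrix check against a reference tunes the swap fractions.
* **Preprocessing:** BMI derivation, single-pass >3σ outlier screening,
  [−1, 1] min–max normalisation with exact inverse, and SMOTE class
  balancing (convex combinations of minority records and their k nearest
  minority neighbours, BMI recomputed on synthetic rows).
* **A hybrid classifier pair** (`rehab_train()`): gradient-boosted trees
  (xgboost, multiclass softmax) and a k-NN store, each tuned by stratified
  5-fold grid-search cross-validation on an 80/20 split. The fitted
  `model_pair` carries the normalizer, per-class centroids, gain-based
  feature importances and the held-out split, and has `print`, `summary`
  and `predict` methods.
* **A per-session engine** (`run_session()`): fits a polynomial to the
  user's completion-time history and takes its end derivative as the
  improvement rate; predicts difficulty and condition with both models;
  resolves disagreements by Euclidean distance between the candidate
  classes' centroids and the healthy centroid, gated by the improvement
  trend (improving → closest to healthy, worsening → farthest, steady →
  most-frequent baseline); incrementally retrains both models with the
  selected label; and raises safety flags (possible fall, sensor anomaly,
  forcing, deterioration) plus a co-morbidity drift alert when the
  predicted condition persistently departs from the clinician-initialised
  one.
* **Evaluation:** confusion matrices, per-class and macro
  sensitivity/specificity/precision/F1, cumulative-accuracy curves,
  improvement fractions and difficulty↔condition association tables.

The per-class statistics behind the shipped generator defaults
(`inst/extdata/*_synthetic.yaml`) are invented, clinically plausible
stand-ins bounded by published cohort ranges and flagged `non_canonical`;
the original source statistics are not publicly available.

## Worked example

```r
library(rehabstack)

# Experiment-style FTSTS fixture (8 participants, slow/fast), balanced
fx  <- fixture_experiment("FTSTS", seed = 13)
bal <- smote_balance(fx, "difficulty", k_neighbors = 5, seed = 14)
print(bal$report)
#> <balance_report> axis difficulty: 7 synthetic record(s)
#>   fast          40 ->  40 (+0)
#>   slow          33 ->  40 (+7)

pair <- rehab_train(bal$dataset, "difficulty", seed = 21)
print(pair)
#> <model_pair> FTSTS difficulty (2 classes)
#>   xgboost: eta=0.05, n_estimators=50, max_depth=3 (CV acc 0.967)
#>   k-NN: k=1 (CV acc 0.983), store 64 records
#>   incremental updates applied: 0 (booster chain length 1)

test_accuracy(pair)
#>    xgb    knn
#>      1      1

ev <- evaluate_hybrid_holdout(pair)
ev$accuracy
#> [1] 1
```

`smote_balance` reports how many synthetic records each class received to
reach the majority count (here 7 for the slow class). `rehab_train` reports
the hyperparameters chosen by cross-validation and the store size; on this
fixture the two classes' completion-time ranges do not overlap, so both base
models and the hybrid selection reach perfect held-out accuracy.

A full demonstration pipeline (fixture → balance → train → simulate
sessions → evaluate) is `run_pipeline(run_config(seed = 1))`; a thin CLI
over the same functions is in `inst/cli/rehabstack.R`.

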