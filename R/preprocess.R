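# Data preparation: BMI derivation, >3-sigma outlier screening, [-1,1]
# normalization with exact inverse, and SMOTE class balancing.

#' Body mass index
#'
#' BMI = weight / height^2, in kg/m2.
#'
#' @param weight_kg Weight in kilograms (> 0), vectorised.
#' @param height_m Height in metres (> 0), vectorised.
#' @return Numeric vector of BMI values.
#' @examples
#' compute_bmi(80, 2.0) # 20
#' @export
compute_bmi <- function(weight_kg, height_m) {
  if (any(weight_kg <= 0) || any(height_m <= 0)) {
    stop("weight and height must be strictly positive", call. = FALSE)
  }
  weight_kg / height_m^2
}

#' Remove records more than 3 column standard deviations from the column mean
#'
#' A single screening pass: column means and standard deviations of the five
#' continuous features are computed once on the input, and a record is dropped
#' iff any of its features deviates from that feature's mean by more than
#' three of that feature's standard deviations. The binary sex code is not
#' screened. The pass is not iterated; survivors are guaranteed to satisfy
#' the bound against the pass-one statistics, not against re-estimated ones.
#'
#' @param dataset An unnormalized [rehab_dataset()] with at least 2 records.
#' @return List with `dataset` (survivors, original row order) and `removed`
#'   (integer indices of dropped rows in the input).
#' @export
remove_outliers <- function(dataset) {
  stopifnot(inherits(dataset, "rehab_dataset"))
  if (!is.null(dataset$normalization)) {
    stop("outlier removal expects an unnormalized dataset", call. = FALSE)
  }
  df <- dataset$data
  if (nrow(df) < 2) {
    stop("need at least 2 records to estimate column statistics",
         call. = FALSE)
  }
  feats <- continuous_features()
  mu <- vapply(df[feats], mean, 0)
  sdv <- vapply(df[feats], stats::sd, 0)
  out <- rep(FALSE, nrow(df))
  for (i in seq_along(feats)) {
    if (sdv[i] > 0) {
      out <- out | abs(df[[feats[i]]] - mu[i]) > 3 * sdv[i]
    }
  }
  removed <- which(out)
  dataset$data <- df[!out, , drop = FALSE]
  rownames(dataset$data) <- NULL
  list(dataset = dataset, removed = removed)
}

new_normalizer <- function(range) {
  # range: features x c(min, max) matrix
  stopifnot(all(range[, "max"] >= range[, "min"]))
  structure(list(range = range), class = "rehab_normalizer")
}

#' Fit, apply and invert [-1, 1] feature normalization
#'
#' `fit_normalizer()` learns per-feature (min, max) from a training dataset.
#' `apply_normalizer()` maps each feature affinely so training min maps to -1
#' and training max to +1; a constant feature maps to 0. `invert_normalizer()`
#' is the exact inverse (round-trip error below 1e-9). Fit on training data
#' only; values outside the training range map outside \eqn{[-1, 1]} and are
#' clipped with a warning when building a normalized dataset.
#'
#' @param dataset A [rehab_dataset()] (unnormalized for `fit`; for `apply`
#'   unnormalized, for `invert` normalized).
#' @return `fit_normalizer()`: a `rehab_normalizer`; the others: the
#'   transformed dataset.
#' @export
fit_normalizer <- function(dataset) {
  stopifnot(inherits(dataset, "rehab_dataset"))
  if (!is.null(dataset$normalization)) {
    stop("dataset is already normalized", call. = FALSE)
  }
  feats <- rehab_features()
  rng <- t(vapply(dataset$data[feats], range, c(min = 0, max = 0)))
  colnames(rng) <- c("min", "max")
  new_normalizer(rng)
}

# normalize a plain numeric matrix/data.frame of feature columns
normalize_values <- function(values, params) {
  feats <- rownames(params$range)
  v <- as.matrix(values[, feats, drop = FALSE])
  lo <- params$range[, "min"]
  hi <- params$range[, "max"]
  span <- hi - lo
  out <- v
  for (j in seq_along(feats)) {
    out[, j] <- if (span[j] > 0) 2 * (v[, j] - lo[j]) / span[j] - 1 else 0
  }
  out
}

denormalize_values <- function(values, params) {
  feats <- rownames(params$range)
  v <- as.matrix(values[, feats, drop = FALSE])
  lo <- params$range[, "min"]
  hi <- params$range[, "max"]
  span <- hi - lo
  out <- v
  for (j in seq_along(feats)) {
    out[, j] <- if (span[j] > 0) (v[, j] + 1) / 2 * span[j] + lo[j] else lo[j]
  }
  out
}

#' @rdname fit_normalizer
#' @param params A fitted `rehab_normalizer`.
#' @export
apply_normalizer <- function(dataset, params) {
  stopifnot(inherits(dataset, "rehab_dataset"))
  if (!inherits(params, "rehab_normalizer")) {
    stop("normalizer has not been fitted", call. = FALSE)
  }
  if (!is.null(dataset$normalization)) {
    stop("dataset is already normalized", call. = FALSE)
  }
  vals <- normalize_values(dataset$data, params)
  if (any(vals < -1 | vals > 1)) {
    warning("values outside the training range clipped to [-1, 1]",
            call. = FALSE)
    vals <- pmin(pmax(vals, -1), 1)
  }
  dataset$data[rownames(params$range)] <- as.data.frame(vals)
  dataset$normalization <- params
  dataset
}

#' @rdname fit_normalizer
#' @export
invert_normalizer <- function(dataset, params = dataset$normalization) {
  stopifnot(inherits(dataset, "rehab_dataset"))
  if (!inherits(params, "rehab_normalizer")) {
    stop("normalizer has not been fitted", call. = FALSE)
  }
  vals <- denormalize_values(dataset$data, params)
  dataset$data[rownames(params$range)] <- as.data.frame(vals)
  dataset$normalization <- NULL
  dataset
}

#' @export
print.rehab_normalizer <- function(x, ...) {
  cat("<rehab_normalizer> training ranges:\n")
  print(round(x$range, 4))
  invisible(x)
}

#' Balance classes by synthetic minority oversampling (SMOTE)
#'
#' Every class is raised to the majority-class count. Each synthetic record is
#' a convex combination `x + u * (x_nn - x)`, `u ~ U(0, 1)`, of a minority
#' record `x` and one of its `k` nearest minority-class neighbours in raw
#' (unnormalized) feature space. The binary sex code is copied from the parent
#' record, and BMI is recomputed from the interpolated weight and height so
#' the BMI identity holds exactly on every synthetic row. Majority-class
#' records are never modified. Balancing is applied to the whole labelled
#' pool before any train/test split; the resulting leakage between synthetic
#' points and their parents is reported as a warning attribute on the report.
#'
#' @param dataset An unnormalized, labelled [rehab_dataset()]; every class
#'   needs at least 2 records.
#' @param label_axis `"difficulty"` or `"condition"`.
#' @param k_neighbors Number of nearest neighbours considered per parent;
#'   capped at (minority class size - 1).
#' @param seed Integer seed; mandatory, all randomness flows from it.
#' @return List with `dataset` (balanced) and `report` (a `balance_report`
#'   with per-class before/after counts, `generated_total`,
#'   `generated_per_class`, and per-synthetic provenance rows).
#' @export
smote_balance <- function(dataset, label_axis = c("difficulty", "condition"),
                          k_neighbors = 5, seed) {
  stopifnot(inherits(dataset, "rehab_dataset"))
  label_axis <- match.arg(label_axis)
  if (missing(seed)) stop("seed is required", call. = FALSE)
  if (!is.null(dataset$normalization)) {
    stop("SMOTE interpolates in raw feature space; unnormalize first",
         call. = FALSE)
  }
  df <- dataset$data
  if (!label_axis %in% names(df)) {
    stop("dataset has no '", label_axis, "' labels", call. = FALSE)
  }
  labs <- df[[label_axis]]
  counts <- table(labs)
  target <- max(counts)
  feats <- rehab_features()
  interp_feats <- c("completion_time_s", "age_y", "height_m", "weight_kg")

  synth_rows <- list()
  provenance <- list()
  gen_per_class <- stats::setNames(integer(length(counts)), names(counts))
  with_seed(seed, for (cls in names(counts)) {
    n_gen <- target - counts[[cls]]
    gen_per_class[[cls]] <- as.integer(n_gen)
    if (n_gen == 0) next
    idx <- which(labs == cls)
    if (length(idx) < 2) {
      stop("cannot oversample class '", cls, "' of size 1", call. = FALSE)
    }
    k <- min(k_neighbors, length(idx) - 1)
    X <- as.matrix(df[idx, feats])
    D <- as.matrix(stats::dist(X))
    parents <- sample(seq_along(idx), n_gen, replace = TRUE)
    for (g in seq_len(n_gen)) {
      p <- parents[g]
      nn_order <- order(D[p, ])
      nn_order <- nn_order[nn_order != p]
      nb <- nn_order[sample.int(k, 1)]
      u <- stats::runif(1)
      row <- df[idx[p], , drop = FALSE]
      for (f in interp_feats) {
        row[[f]] <- df[[f]][idx[p]] + u * (df[[f]][idx[nb]] - df[[f]][idx[p]])
      }
      row$bmi <- compute_bmi(row$weight_kg, row$height_m)
      synth_rows[[length(synth_rows) + 1]] <- row
      provenance[[length(provenance) + 1]] <- data.frame(
        class = cls, parent = idx[p], neighbor = idx[nb], u = u)
    }
  })
  generated_total <- length(synth_rows)
  if (generated_total > 0) {
    dataset$data <- rbind(df, do.call(rbind, synth_rows))
    rownames(dataset$data) <- NULL
  }
  after <- table(dataset$data[[label_axis]])
  report <- structure(
    list(label_axis = label_axis,
         before = as.list(counts), after = as.list(after),
         generated_total = generated_total,
         generated_per_class = as.list(gen_per_class),
         provenance = if (generated_total > 0) do.call(rbind, provenance)
                      else NULL,
         leakage_note = paste(
           "balancing was applied to the whole labelled pool;",
           "synthetic points share information with their parents across",
           "any later train/test split")),
    class = "balance_report"
  )
  list(dataset = dataset, report = report)
}

#' @export
print.balance_report <- function(x, ...) {
  cat(sprintf("<balance_report> axis %s: %d synthetic record(s)\n",
              x$label_axis, x$generated_total))
  for (cls in names(x$before)) {
    cat(sprintf("  %-12s %3d -> %3d (+%d)\n", cls, x$before[[cls]],
                x$after[[cls]], x$generated_per_class[[cls]]))
  }
  invisible(x)
}

#' Serialize a balance report for audit logs
#'
#' @param report A `balance_report`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_balance_report <- function(report, path) {
  out <- report[c("label_axis", "before", "after", "generated_total",
                  "generated_per_class", "leakage_note")]
  out$provenance <- report$provenance
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
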