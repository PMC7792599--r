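# Evaluation surfaces: confusion matrices, one-vs-rest metrics, cumulative
# accuracy curves, run improvement fractions and the difficulty-condition
# association table.

#' Confusion matrix over a taxonomy
#'
#' Cell (i, j) counts records of true class i predicted as class j, with
#' rows/columns in the taxonomy's fixed class order.
#'
#' @param true_labels,predicted_labels Equal-length character vectors of
#'   class names.
#' @param taxonomy A [rehab_taxonomy()].
#' @return A square integer matrix of class `rehab_confusion`.
#' @export
confusion <- function(true_labels, predicted_labels, taxonomy) {
  if (length(true_labels) != length(predicted_labels)) {
    stop("label sequences have different lengths", call. = FALSE)
  }
  label_code(true_labels, taxonomy)      # validate
  label_code(predicted_labels, taxonomy) # validate
  classes <- taxonomy$classes
  cm <- table(factor(true_labels, levels = classes),
              factor(predicted_labels, levels = classes))
  cm <- unclass(as.matrix(cm))
  dimnames(cm) <- list(true = classes, predicted = classes)
  structure(cm, class = c("rehab_confusion", "matrix"))
}

#' @export
print.rehab_confusion <- function(x, ...) {
  cat(sprintf("<confusion matrix> %d records, accuracy %.4f\n",
              sum(x), sum(diag(unclass(x))) / sum(x)))
  print(unclass(x))
  invisible(x)
}

#' One-vs-rest metrics from a confusion matrix
#'
#' Per-class sensitivity (recall), specificity, precision and F1 from
#' one-vs-rest TP/FP/FN/TN counts, plus overall accuracy. F1 is the harmonic
#' mean of precision and sensitivity (0 when both are 0). A class never
#' predicted has precision 0 and is flagged in `undefined_precision`. Macro
#' averages are unweighted means over the classes present in the true
#' labels.
#'
#' @param cm A [confusion()] matrix with at least one record.
#' @return List of class `metrics_report`: `per_class` data frame, `macro`
#'   named vector, `accuracy`, `undefined_precision`.
#' @export
metrics <- function(cm) {
  m <- unclass(cm)
  total <- sum(m)
  if (total == 0) stop("empty confusion matrix", call. = FALSE)
  classes <- rownames(m)
  tp <- diag(m)
  fn <- rowSums(m) - tp
  fp <- colSums(m) - tp
  tn <- total - tp - fn - fp
  safe_div <- function(a, b) ifelse(b > 0, a / b, 0)
  sens <- safe_div(tp, tp + fn)
  spec <- safe_div(tn, tn + fp)
  prec <- safe_div(tp, tp + fp)
  f1 <- ifelse(prec + sens > 0, 2 * prec * sens / (prec + sens), 0)
  per_class <- data.frame(class = classes, sensitivity = sens,
                          specificity = spec, precision = prec, f1 = f1,
                          support = rowSums(m), row.names = NULL)
  present <- rowSums(m) > 0
  macro <- c(sensitivity = mean(sens[present]),
             specificity = mean(spec[present]),
             precision = mean(prec[present]), f1 = mean(f1[present]))
  structure(list(per_class = per_class, macro = macro,
                 accuracy = sum(tp) / total,
                 undefined_precision = classes[tp + fp == 0]),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> accuracy %.4f\n", x$accuracy))
  cat("macro: ", paste(sprintf("%s=%.4f", names(x$macro), x$macro),
                       collapse = ", "), "\n")
  print(x$per_class, digits = 4)
  if (length(x$undefined_precision) > 0) {
    cat("precision set to 0 (class never predicted):",
        paste(x$undefined_precision, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Cumulative accuracy over a session history
#'
#' `curve[t]` is the fraction of correct predictions over sessions 1..t —
#' the individualisation curve tracking whether the incremental retraining
#' loop is improving the user's predictions over time.
#'
#' @param correct Logical (or 0/1) vector of per-session correctness.
#' @return Numeric vector of the same length.
#' @examples
#' cumulative_accuracy(c(1, 1, 0, 1)) # 1, 1, 2/3, 3/4
#' @export
cumulative_accuracy <- function(correct) {
  if (length(correct) == 0) stop("empty correctness sequence", call. = FALSE)
  cumsum(as.numeric(correct)) / seq_along(correct)
}

#' Fraction of runs whose cumulative accuracy did not decline
#'
#' For each run, compares the cumulative accuracy at the final session with
#' the first evaluable session; returns the fraction of runs where it
#' improved or stayed the same.
#'
#' @param runs List of per-run correctness sequences (each length >= 2).
#' @return Fraction in \eqn{[0, 1]}.
#' @export
improvement_fraction <- function(runs) {
  stopifnot(length(runs) > 0, all(vapply(runs, length, 0L) >= 2))
  ok <- vapply(runs, function(r) {
    curve <- cumulative_accuracy(r)
    curve[length(curve)] >= curve[1]
  }, TRUE)
  mean(ok)
}

#' Most frequent condition associated with each difficulty cluster
#'
#' Groups paired per-session predictions by difficulty class and reports the
#' modal co-predicted condition per group (ties resolved lexicographically;
#' empty groups omitted).
#'
#' @param difficulty_predictions,condition_predictions Equal-length character
#'   vectors of paired predictions.
#' @return Data frame with columns `difficulty`, `condition`, `n`.
#' @export
association_table <- function(difficulty_predictions, condition_predictions) {
  if (length(difficulty_predictions) != length(condition_predictions)) {
    stop("prediction sequences have different lengths", call. = FALSE)
  }
  groups <- split(condition_predictions, difficulty_predictions)
  rows <- lapply(names(groups), function(d) {
    counts <- table(groups[[d]])
    top <- sort(names(counts)[counts == max(counts)])[1]
    data.frame(difficulty = d, condition = top, n = length(groups[[d]]))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
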