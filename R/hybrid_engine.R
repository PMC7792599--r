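# The hybrid session engine: improvement-rate computation, most-frequent
# baseline, dual-axis dual-model prediction, distance-to-healthy selection,
# incremental retraining, state flags and the co-morbidity drift alert.

#' Hybrid engine configuration
#'
#' All thresholds the session engine uses, with their defaults. `epsilon`
#' (the steady band, seconds/session) defaults to 1% of the user's running
#' mean completion time when `NULL`; `forcing_threshold` defaults to three
#' times the epsilon in force.
#'
#' @param degree Polynomial degree for the improvement-rate fit.
#' @param epsilon Steady band, s/session, or `NULL` for the adaptive default.
#' @param forcing_threshold Rate below `-forcing_threshold` counts as
#'   implausibly fast improvement, or `NULL` for `3 * epsilon`.
#' @param deterioration_window Consecutive worsening sessions before the
#'   deterioration flag raises.
#' @param alert_window,alert_fraction The co-morbidity alert raises when the
#'   final condition differs from the initialised one in at least
#'   `alert_fraction` of the last `alert_window` sessions.
#' @param fall_timeout_s Seconds after a start without completion before the
#'   possible-fall flag raises.
#' @param time_bounds Physically plausible completion-time interval, seconds;
#'   values outside flag a sensor anomaly.
#' @param distance_mode `"centroid"` (distance between the predicted class's
#'   centroid and the healthy centroid) or `"point"` (distance between the
#'   incoming record and the healthy centroid, identical for both candidates'
#'   ranking only through their centroids — candidate distances still use
#'   centroids; the point variant is exposed for sensitivity analysis).
#' @param tie_break Candidate preferred on equal distances (`"xgb"`).
#' @return An object of class `hybrid_config`.
#' @export
hybrid_config <- function(degree = 2, epsilon = NULL,
                          forcing_threshold = NULL,
                          deterioration_window = 3,
                          alert_window = 10, alert_fraction = 0.8,
                          fall_timeout_s = 60, time_bounds = c(2, 300),
                          distance_mode = c("centroid", "point"),
                          tie_break = "xgb") {
  distance_mode <- match.arg(distance_mode)
  structure(list(degree = degree, epsilon = epsilon,
                 forcing_threshold = forcing_threshold,
                 deterioration_window = deterioration_window,
                 alert_window = alert_window, alert_fraction = alert_fraction,
                 fall_timeout_s = fall_timeout_s, time_bounds = time_bounds,
                 distance_mode = distance_mode, tie_break = tie_break),
            class = "hybrid_config")
}

#' Improvement rate from a completion-time history
#'
#' Fits a least-squares polynomial of the given degree to completion time
#' against 0-based session index and evaluates its derivative at the last
#' index. Falling times mean improvement, so the status is `improving` when
#' the rate is below `-epsilon`, `worsening` above `+epsilon`, `steady`
#' otherwise. Histories too short for the requested degree are fitted at the
#' highest degree they support (a first difference at two sessions); a
#' single session returns rate 0, `steady`.
#'
#' A noisy stationary history can produce a sizeable rate by chance, so the
#' effective steady band is the larger of `epsilon` and a `conf`-level
#' t-interval half-width on the fitted rate: a trend must be both clinically
#' and statistically meaningful before the status leaves `steady`. The fitted
#' degree is capped at `n - 2` (while at least linear) so a residual degree
#' of freedom is retained whenever the history allows one. An exactly
#' polynomial history (zero residuals with at least one residual df) is taken
#' at face value against `epsilon` alone. Fits whose residual information is
#' too thin to estimate the noise (fewer than 2 residual df) fall back to a
#' minimum-detectable-change floor of `mdc_fraction` of the mean completion
#' time, in line with published test-retest variability of timed mobility
#' tests. The default confidence is deliberately conservative (0.99): a false
#' improving/worsening status is the costly error — it both raises false
#' alarms and steers the self-training loop toward a wrong label.
#'
#' @param history Numeric vector of completion times, seconds, in session
#'   order (length >= 1).
#' @param degree Polynomial degree (default 2).
#' @param epsilon Steady band, seconds/session.
#' @param conf Confidence level of the significance guard (default 0.99);
#'   `NULL` disables it.
#' @param mdc_fraction Minimum detectable change as a fraction of the mean
#'   time, used when the fit has fewer than 2 residual degrees of freedom.
#' @return List with `rate` (s/session), `status` and `rate_se`.
#' @examples
#' improvement_rate(c(10, 9, 8, 7), epsilon = 0.1) # rate -1, improving
#' @export
improvement_rate <- function(history, degree = 2, epsilon = 0.1,
                             conf = 0.99, mdc_fraction = 0.15) {
  if (length(history) == 0) stop("empty history", call. = FALSE)
  n <- length(history)
  degree <- max(1, min(degree, n - 2))
  if (n < 2) return(list(rate = 0, status = "steady", rate_se = 0))
  x <- seq_len(n) - 1
  X <- cbind(1, stats::poly(x, degree, raw = TRUE, simple = TRUE))
  fit <- stats::lm.fit(X, history)
  co <- fit$coefficients
  x_last <- x[n]
  dvec <- c(0, seq_len(degree) * x_last^(seq_len(degree) - 1))
  rate <- sum(co * dvec)
  df_res <- n - ncol(X)
  rss <- sum(fit$residuals^2)
  exact_fit <- df_res >= 1 &&
    rss <= n * (1e-8 * max(mean(abs(history)), 1))^2
  rate_se <- 0
  band <- epsilon
  if (!is.null(conf) && !exact_fit) {
    if (df_res >= 2) {
      s2 <- rss / df_res
      XtX_inv <- chol2inv(chol(crossprod(X)))
      rate_se <- sqrt(max(0, s2 * drop(t(dvec) %*% XtX_inv %*% dvec)))
      band <- max(epsilon, stats::qt(1 - (1 - conf) / 2, df_res) * rate_se)
    } else {
      band <- max(epsilon, mdc_fraction * mean(history))
    }
  }
  status <- if (rate < -band) "improving" else if (rate > band)
    "worsening" else "steady"
  list(rate = rate, status = status, rate_se = rate_se)
}

#' Most frequent prediction (baseline)
#'
#' Modal class of a prediction history; ties go to the most recently
#' predicted among the tied classes. An empty history falls back to
#' `initial` (the clinician-initialised condition, or the fixture's default
#' difficulty).
#'
#' @param prediction_history Character vector of past final predictions.
#' @param initial Fallback class for an empty history.
#' @return Class name.
#' @export
baseline_prediction <- function(prediction_history, initial = NULL) {
  if (length(prediction_history) == 0) {
    if (is.null(initial)) {
      stop("empty prediction history and no initialised class", call. = FALSE)
    }
    return(initial)
  }
  counts <- table(prediction_history)
  top <- names(counts)[counts == max(counts)]
  if (length(top) == 1) return(top)
  last_seen <- vapply(top, function(cl) max(which(prediction_history == cl)),
                      0L)
  top[which.max(last_seen)]
}

#' Euclidean distance from a candidate class to the healthy reference
#'
#' Distance between the candidate class's centroid and the healthy reference
#' class's centroid in normalized feature space.
#'
#' @param centroids Matrix of class centroids (rows named by class).
#' @param candidate Candidate class name.
#' @param healthy_ref Healthy reference class name.
#' @return Non-negative number; 0 iff the centroids coincide (in particular
#'   when `candidate == healthy_ref`).
#' @export
distance_to_healthy <- function(centroids, candidate, healthy_ref) {
  for (cl in c(candidate, healthy_ref)) {
    if (!cl %in% rownames(centroids) || anyNA(centroids[cl, ])) {
      stop("no centroid available for class '", cl, "'", call. = FALSE)
    }
  }
  sqrt(sum((centroids[candidate, ] - centroids[healthy_ref, ])^2))
}

#' Select the final prediction from the two candidates
#'
#' The selection rule gated by the improvement trend: an improving user is
#' believed to be moving toward health, so the candidate whose class sits
#' closer to the healthy centroid wins; a worsening user the farther
#' candidate; a steady user keeps the baseline. Equal distances go to the
#' boosted model's candidate. When the two base models agree, the agreed
#' class is the final prediction regardless of branch (it is simultaneously
#' the closest and the farthest candidate; the baseline only arbitrates
#' disagreement), with rationale `"agreement"`.
#'
#' @param xgb_class,knn_class Candidate class names.
#' @param distances Named numeric `c(xgb = ..., knn = ...)` of
#'   distance-to-healthy for each candidate.
#' @param improvement_status `"improving"`, `"worsening"` or `"steady"`.
#' @param baseline Baseline class.
#' @return List with `class` and `rationale`
#'   (`"closest"`, `"farthest"`, `"baseline"` or `"agreement"`).
#' @export
hybrid_select <- function(xgb_class, knn_class, distances,
                          improvement_status, baseline) {
  stopifnot(all(c("xgb", "knn") %in% names(distances)))
  if (!improvement_status %in% c("improving", "worsening", "steady")) {
    stop("unknown improvement status: ", improvement_status, call. = FALSE)
  }
  if (identical(xgb_class, knn_class)) {
    return(list(class = xgb_class, rationale = "agreement"))
  }
  switch(improvement_status,
    improving = {
      cls <- if (distances[["knn"]] < distances[["xgb"]]) knn_class else
        xgb_class
      list(class = cls, rationale = "closest")
    },
    worsening = {
      cls <- if (distances[["knn"]] > distances[["xgb"]]) knn_class else
        xgb_class
      list(class = cls, rationale = "farthest")
    },
    steady = list(class = baseline, rationale = "baseline")
  )
}

#' User state flags from a session
#'
#' Safety outputs: `possible_fall` (test started, not completed, timeout
#' elapsed), `sensor_anomaly` (event stream violating the
#' start-phases-complete grammar, or a completion time outside physical
#' bounds), `forcing` (improvement rate implausibly steep while the final
#' prediction deviates from the baseline), and `deterioration` (worsening
#' status persisting over the configured window of consecutive sessions).
#' A malformed event stream raises the anomaly flag, never an error.
#'
#' @param events Character vector of session event markers (expected grammar:
#'   `"start"`, optional phase markers among `"walk"`, `"turn"`, `"sit"`,
#'   `"stand"`, then `"complete"`), or `NULL` for a nominal completed
#'   session.
#' @param elapsed_s Seconds since the session started.
#' @param time_s Completion time, `NA` if not completed.
#' @param rate Improvement rate, s/session.
#' @param status_history Character vector of improvement statuses up to and
#'   including this session.
#' @param baseline,final Baseline and final predicted classes.
#' @param config A [hybrid_config()]; `forcing_threshold`/`epsilon` must be
#'   resolved (non-`NULL`) by the caller.
#' @return An object of class `user_state`: logical flags `possible_fall`,
#'   `sensor_anomaly`, `forcing`, `deterioration`.
#' @export
state_flags <- function(events = NULL, elapsed_s = NA, time_s, rate,
                        status_history, baseline, final,
                        config = hybrid_config(epsilon = 0.1,
                                               forcing_threshold = 0.3)) {
  if (is.null(events)) {
    events <- if (!is.na(time_s)) c("start", "complete") else "start"
  }
  started <- "start" %in% events
  completed <- "complete" %in% events
  possible_fall <- started && !completed &&
    !is.na(elapsed_s) && elapsed_s >= config$fall_timeout_s

  known <- c("start", "walk", "turn", "sit", "stand", "complete")
  grammar_ok <- length(events) >= 1 && events[1] == "start" &&
    all(events %in% known) && sum(events == "start") == 1 &&
    sum(events == "complete") <= 1 &&
    (!completed || events[length(events)] == "complete")
  time_ok <- is.na(time_s) || (time_s >= config$time_bounds[1] &&
                                 time_s <= config$time_bounds[2])
  sensor_anomaly <- !grammar_ok || !time_ok

  thr <- config$forcing_threshold
  forcing <- !is.null(thr) && rate < -thr && !identical(final, baseline)

  w <- config$deterioration_window
  deterioration <- length(status_history) >= w &&
    all(utils::tail(status_history, w) == "worsening")

  structure(list(possible_fall = possible_fall,
                 sensor_anomaly = sensor_anomaly,
                 forcing = forcing, deterioration = deterioration),
            class = "user_state")
}

#' @export
print.user_state <- function(x, ...) {
  on <- names(x)[vapply(x, isTRUE, TRUE)]
  cat("<user_state>", if (length(on) == 0) "nominal" else
    paste(on, collapse = ", "), "\n")
  invisible(x)
}

#' Initialise a user's session state
#'
#' @param user_id Identifier.
#' @param demographics Named list/vector with `age_y`, `height_m`,
#'   `weight_kg`, `sex` (and optionally `bmi`, otherwise derived).
#' @param initial_condition Clinician-supplied condition class.
#' @param initial_difficulty Default difficulty class for the first session's
#'   baseline.
#' @param config A [hybrid_config()].
#' @return An object of class `session_state`.
#' @export
session_state <- function(user_id, demographics, initial_condition,
                          initial_difficulty, config = hybrid_config()) {
  demographics <- as.list(demographics)
  if (is.null(demographics$bmi)) {
    demographics$bmi <- compute_bmi(demographics$weight_kg,
                                    demographics$height_m)
  }
  structure(
    list(user_id = user_id, demographics = demographics,
         initial_condition = initial_condition,
         initial_difficulty = initial_difficulty,
         history = numeric(0),
         status_history = character(0),
         predictions = list(difficulty = character(0),
                            condition = character(0)),
         bundles = list(), alerts = logical(0), config = config),
    class = "session_state")
}

#' @export
print.session_state <- function(x, ...) {
  cat(sprintf("<session_state> user %s: %d session(s), condition init %s\n",
              x$user_id, length(x$history), x$initial_condition))
  if (length(x$history) > 0) {
    cat(sprintf("  last time %.2f s, status %s, comorbidity alert: %s\n",
                utils::tail(x$history, 1), utils::tail(x$status_history, 1),
                utils::tail(x$alerts, 1)))
  }
  invisible(x)
}

resolve_epsilon <- function(config, history) {
  eps <- config$epsilon
  if (is.null(eps)) eps <- 0.01 * mean(history)
  thr <- config$forcing_threshold
  if (is.null(thr)) thr <- 3 * eps
  list(epsilon = eps, forcing_threshold = thr)
}

#' Run one rehabilitation session through the hybrid engine
#'
#' Executes the full per-session loop: append the new completion time,
#' compute the improvement rate and status, form per-axis baselines, let both
#' base models of both axes predict, compute each candidate's distance to the
#' healthy centroid, select the final prediction per axis by
#' [hybrid_select()], incrementally retrain both models of each axis with the
#' selected final label, compute the state flags, and evaluate the
#' co-morbidity drift alert (final condition differing from the initialised
#' one in at least `alert_fraction` of the last `alert_window` sessions).
#'
#' A non-steady improvement status steers the selection only when confirmed
#' on two consecutive sessions; the bundle records both the acting status
#' (`status`) and the unconfirmed one (`status_raw`), and the raw status
#' feeds the deterioration flag. This keeps a single spurious trend reading
#' from routing a wrong label into the self-training loop.
#'
#' @param state A [session_state()].
#' @param pair_difficulty,pair_condition Fitted `model_pair` objects for the
#'   two label axes.
#' @param new_time Completion time of this session, seconds (`NA` for an
#'   uncompleted session: models do not run, flags still do).
#' @param events,elapsed_s Optional raw session event stream and elapsed
#'   seconds for the flag logic.
#' @param retrain Set `FALSE` to skip the incremental updates (evaluation
#'   without individualisation).
#' @return List with `bundle` (a `prediction_bundle`), `state`,
#'   `pair_difficulty`, `pair_condition` — the updated objects.
#' @export
run_session <- function(state, pair_difficulty, pair_condition, new_time,
                        events = NULL, elapsed_s = NA, retrain = TRUE) {
  stopifnot(inherits(state, "session_state"),
            inherits(pair_difficulty, "model_pair"),
            inherits(pair_condition, "model_pair"))
  config <- state$config

  if (!is.na(new_time)) state$history <- c(state$history, new_time)
  res <- resolve_epsilon(config, state$history)
  ir <- if (length(state$history) > 0) {
    improvement_rate(state$history, config$degree, res$epsilon)
  } else list(rate = 0, status = "steady")
  # a trend only steers selection once confirmed on consecutive sessions;
  # the raw status still feeds the deterioration flag
  prev_raw <- if (length(state$status_history) > 0)
    utils::tail(state$status_history, 1) else "steady"
  status_eff <- if (ir$status != "steady" && identical(prev_raw, ir$status))
    ir$status else "steady"
  state$status_history <- c(state$status_history, ir$status)

  axes <- list(difficulty = pair_difficulty, condition = pair_condition)
  initials <- list(difficulty = state$initial_difficulty,
                   condition = state$initial_condition)
  bundle <- list(session = length(state$history), time_s = new_time,
                 rate = ir$rate, status = status_eff,
                 status_raw = ir$status, axes = list())

  if (!is.na(new_time)) {
    record <- c(list(completion_time_s = new_time), state$demographics)
    record <- as.data.frame(record[rehab_features()])
    for (ax in names(axes)) {
      pair <- axes[[ax]]
      pred <- predict_with_probs(pair, record)
      healthy <- pair$taxonomy$healthy_reference
      dists <- c(
        xgb = distance_to_healthy(pair$centroids, pred$xgb$class, healthy),
        knn = distance_to_healthy(pair$centroids, pred$knn$class, healthy))
      base <- baseline_prediction(state$predictions[[ax]], initials[[ax]])
      sel <- hybrid_select(pred$xgb$class, pred$knn$class, dists,
                           status_eff, base)
      if (retrain) {
        pair <- incremental_update(pair, record, sel$class)
        axes[[ax]] <- pair
      }
      state$predictions[[ax]] <- c(state$predictions[[ax]], sel$class)
      bundle$axes[[ax]] <- list(
        xgb = pred$xgb, knn = pred$knn, distances = dists,
        baseline = base, final = sel$class, rationale = sel$rationale)
    }
  }

  cfg_resolved <- config
  cfg_resolved$epsilon <- res$epsilon
  cfg_resolved$forcing_threshold <- res$forcing_threshold
  final_diff <- if (!is.na(new_time))
    bundle$axes$difficulty$final else NA_character_
  base_diff <- if (!is.na(new_time))
    bundle$axes$difficulty$baseline else NA_character_
  bundle$flags <- state_flags(
    events = events, elapsed_s = elapsed_s, time_s = new_time,
    rate = ir$rate, status_history = state$status_history,
    baseline = base_diff, final = final_diff, config = cfg_resolved)

  cond_hist <- state$predictions$condition
  w <- config$alert_window
  alert <- length(cond_hist) >= w &&
    mean(utils::tail(cond_hist, w) != state$initial_condition) >=
      config$alert_fraction
  state$alerts <- c(state$alerts, alert)
  bundle$comorbidity_alert <- alert
  class(bundle) <- "prediction_bundle"
  state$bundles[[length(state$bundles) + 1]] <- bundle

  list(bundle = bundle, state = state,
       pair_difficulty = axes$difficulty, pair_condition = axes$condition)
}

#' @export
print.prediction_bundle <- function(x, ...) {
  cat(sprintf("<prediction_bundle> session %d: time %.2f s, %s (rate %+.3f)\n",
              x$session, x$time_s, x$status, x$rate))
  for (ax in names(x$axes)) {
    a <- x$axes[[ax]]
    cat(sprintf("  %-10s final=%s [%s] xgb=%s knn=%s baseline=%s\n", ax,
                a$final, a$rationale, a$xgb$class, a$knn$class, a$baseline))
  }
  if (isTRUE(x$comorbidity_alert)) cat("  ** co-morbidity drift alert **\n")
  invisible(x)
}

#' Evaluate the hybrid selection rule on a held-out split
#'
#' Replays held-out records as session streams and scores the hybrid's final
#' predictions against the true labels. Records are grouped into
#' \{participant, class\} streams (the study's own evaluation unit: each
#' participant performs a block of repetitions of one condition), falling
#' back to \{class\} streams without a `participant` column. Each stream
#' starts with an empty history; the improvement status comes from the
#' accumulating completion-time history, the baseline from the stream's own
#' previous final predictions, and disagreements between the base models are
#' resolved by [hybrid_select()]. While no baseline is established, the
#' record's nearest candidate class centroid arbitrates. Models are not
#' retrained here; this isolates the selection rule itself.
#'
#' @param pair A fitted `model_pair`.
#' @param test_data Data frame of held-out records with the true label column;
#'   defaults to the pair's stored test split.
#' @param truth True labels (defaults to the stored test split's).
#' @param config A [hybrid_config()].
#' @return List with `accuracy`, and a `trace` data frame (per record: truth,
#'   xgb, knn, final, rationale, status).
#' @export
evaluate_hybrid_holdout <- function(pair, test_data = NULL, truth = NULL,
                                    config = hybrid_config()) {
  stopifnot(inherits(pair, "model_pair"))
  if (is.null(test_data)) {
    test_data <- pair$test$data
    truth <- label_name(pair$test$y, pair$taxonomy)
  }
  if (is.null(truth)) truth <- test_data[[pair$axis]]
  stopifnot(nrow(test_data) == length(truth))
  key <- if ("participant" %in% names(test_data)) {
    paste(test_data$participant, truth)
  } else truth
  groups <- split(seq_len(nrow(test_data)), key)
  healthy <- pair$taxonomy$healthy_reference
  trace <- vector("list", nrow(test_data))
  for (g in groups) {
    history <- numeric(0)
    finals <- character(0)
    prev_raw <- "steady"
    for (i in g) {
      rec <- test_data[i, , drop = FALSE]
      history <- c(history, rec$completion_time_s)
      res <- resolve_epsilon(config, history)
      ir <- improvement_rate(history, config$degree, res$epsilon)
      status_eff <- if (ir$status != "steady" &&
                          identical(prev_raw, ir$status)) ir$status else
        "steady"
      prev_raw <- ir$status
      ir$status <- status_eff
      pred <- predict_with_probs(pair, rec[, rehab_features(), drop = FALSE])
      dists <- c(
        xgb = distance_to_healthy(pair$centroids, pred$xgb$class, healthy),
        knn = distance_to_healthy(pair$centroids, pred$knn$class, healthy))
      # while no baseline is established, the candidate whose class centroid
      # is nearest to the incoming record arbitrates
      x <- normalize_values(rec[, rehab_features(), drop = FALSE],
                            pair$normalizer)[1, ]
      d_point <- vapply(c(pred$xgb$class, pred$knn$class), function(cl)
        sqrt(sum((x - pair$centroids[cl, ])^2)), 0)
      fallback <- c(pred$xgb$class, pred$knn$class)[which.min(d_point)]
      base <- baseline_prediction(finals, initial = fallback)
      sel <- hybrid_select(pred$xgb$class, pred$knn$class, dists, ir$status,
                           base)
      finals <- c(finals, sel$class)
      trace[[i]] <- data.frame(
        truth = truth[i], xgb = pred$xgb$class, knn = pred$knn$class,
        final = sel$class, rationale = sel$rationale, status = ir$status)
    }
  }
  trace <- do.call(rbind, trace)
  list(accuracy = mean(trace$final == trace$truth), trace = trace)
}

#' Simulate individualised session streams with incremental retraining
#'
#' Crosses fixture individuals with every difficulty class of the test and
#' runs each \{individual, difficulty\} combination as a stationary
#' single-class session stream through [run_session()], each combination
#' starting from its own copy of the trained model pairs (the
#' individualisation premise: models diverge per user). The session state is
#' initialised with the fixture default difficulty (the simulated class) and
#' the healthy condition, mirroring a clinician-initialised system. Returns
#' the per-combination correctness sequences of the final difficulty
#' predictions, from which cumulative-accuracy curves and the improvement
#' fraction are computed.
#'
#' @param pair_difficulty,pair_condition Trained `model_pair` objects.
#' @param test_type `"TUG"` or `"FTSTS"`.
#' @param individuals Number of fixture individuals (default 8).
#' @param n_sessions Sessions per combination (default 200).
#' @param seed Integer seed.
#' @param config A [hybrid_config()].
#' @return List with `runs` (named list of logical correctness sequences),
#'   `improvement_fraction`, and `accuracy` (overall fraction of correct
#'   session predictions).
#' @export
simulate_individualisation <- function(pair_difficulty, pair_condition,
                                       test_type = c("TUG", "FTSTS"),
                                       individuals = 8, n_sessions = 200,
                                       seed, config = hybrid_config()) {
  test_type <- match.arg(test_type)
  if (missing(seed)) stop("seed is required", call. = FALSE)
  tax <- pair_difficulty$taxonomy
  ranges <- fixture_time_ranges(test_type)
  people <- fixture_participants(individuals, derive_seed(seed, 1))
  cond_init <- pair_condition$taxonomy$healthy_reference
  runs <- list()
  combo <- 0L
  for (p in seq_len(individuals)) {
    demo <- as.list(people[p, c("age_y", "height_m", "weight_kg", "bmi",
                                "sex")])
    for (cls in tax$classes) {
      combo <- combo + 1L
      r <- ranges[[cls]]
      base <- with_seed(derive_seed(seed, 10 * combo), {
        margin <- min(0.06 * mean(r), 0.25 * (r[2] - r[1]))
        stats::runif(1, r[1] + margin, r[2] - margin)
      })
      stream <- fixture_session_stream(list(base_time = base), n_sessions,
                                       trend = "steady",
                                       seed = derive_seed(seed, 10 * combo + 1))
      st <- session_state(sprintf("ind%d_%s", p, cls), demo,
                          initial_condition = cond_init,
                          initial_difficulty = cls, config = config)
      pd <- pair_difficulty
      pc <- pair_condition
      for (i in seq_len(n_sessions)) {
        out <- run_session(st, pd, pc, stream$time_s[i])
        st <- out$state
        pd <- out$pair_difficulty
        pc <- out$pair_condition
      }
      runs[[st$user_id]] <- st$predictions$difficulty == cls
    }
  }
  list(runs = runs,
       improvement_fraction = improvement_fraction(runs),
       accuracy = mean(unlist(runs)))
}

#' Serialize prediction bundles to JSON lines
#'
#' One structured record per session — both base models' classes and full
#' probability vectors, distances, baseline, selection and rationale, flags
#' and alerts — the transparency/audit output of the engine.
#'
#' @param bundles List of `prediction_bundle` objects (or a `session_state`).
#' @param path Output file path (`.jsonl`).
#' @return `path`, invisibly.
#' @export
write_bundles <- function(bundles, path) {
  if (inherits(bundles, "session_state")) bundles <- bundles$bundles
  con <- file(path, "w")
  on.exit(close(con))
  for (b in bundles) {
    rec <- unclass(b)
    rec$flags <- unclass(rec$flags)
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA,
                                na = "null"), con)
  }
  invisible(path)
}
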