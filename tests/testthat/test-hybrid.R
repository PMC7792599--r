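test_that("improvement rate recovers exact trends and guards noisy ones", {
  r <- improvement_rate(c(10, 9, 8, 7), epsilon = 0.1)
  expect_equal(r$rate, -1)
  expect_equal(r$status, "improving")

  r <- improvement_rate(c(8, 8, 8, 8), epsilon = 0.1)
  expect_equal(r$rate, 0)
  expect_equal(r$status, "steady")

  r <- improvement_rate(c(7, 8, 9), epsilon = 0.1)
  expect_equal(r$rate, 1)
  expect_equal(r$status, "worsening")

  # exact quadratic: derivative of the fit at the last index
  r <- improvement_rate((0:4)^2, epsilon = 0.1)
  expect_equal(r$rate, 8, tolerance = 1e-9)
  expect_equal(r$status, "worsening")

  expect_error(improvement_rate(numeric(0)), "empty")
  expect_equal(improvement_rate(5)$status, "steady")

  # a small two-session wobble is below the minimum detectable change ...
  expect_equal(improvement_rate(c(19.9, 17.5), epsilon = 0.19)$status,
               "steady")
  # ... a transition-sized two-session jump is not
  expect_equal(improvement_rate(c(18.2, 7.2), epsilon = 0.13)$status,
               "improving")

  # stationary noise rarely leaves steady under the significance guard
  set.seed(57)
  statuses <- vapply(1:200, function(i) {
    h <- 12 + rnorm(sample(4:30, 1), 0, 0.35)
    improvement_rate(h, epsilon = 0.12)$status
  }, "")
  expect_gt(mean(statuses == "steady"), 0.97)
})

test_that("baseline prediction is modal with recency tie-break", {
  expect_equal(baseline_prediction(c("A", "A", "B")), "A")
  expect_equal(baseline_prediction(c("A", "B")), "B")
  expect_equal(baseline_prediction("C"), "C")
  expect_equal(baseline_prediction(c("A", "B", "A", "B")), "B")
  expect_equal(baseline_prediction(character(0), initial = "stroke"), "stroke")
  expect_error(baseline_prediction(character(0)), "no initialised")
})

test_that("distance to healthy is the centroid Euclidean distance", {
  cents <- rbind(healthy = c(0, 0), stroke = c(3, 4))
  expect_equal(distance_to_healthy(cents, "healthy", "healthy"), 0)
  expect_equal(distance_to_healthy(cents, "stroke", "healthy"), 5)
  set.seed(58)
  cents6 <- matrix(rnorm(18), nrow = 3,
                   dimnames = list(c("a", "b", "healthy"), NULL))
  for (cl in c("a", "b")) {
    expect_equal(distance_to_healthy(cents6, cl, "healthy"),
                 sqrt(sum((cents6[cl, ] - cents6["healthy", ])^2)))
  }
  expect_error(distance_to_healthy(cents, "dementia", "healthy"),
               "no centroid")
})

test_that("hybrid selection matches the enumerated truth table", {
  dist_cases <- list(c(xgb = 0.2, knn = 0.5), c(xgb = 0.5, knn = 0.2),
                     c(xgb = 0.3, knn = 0.3))
  for (status in c("improving", "worsening", "steady")) {
    for (d in dist_cases) {
      sel <- hybrid_select("A", "B", d, status, baseline = "C")
      # independent enumeration of the rule
      expected <- if (status == "steady") {
        list(class = "C", rationale = "baseline")
      } else if (status == "improving") {
        list(class = if (d[["knn"]] < d[["xgb"]]) "B" else "A",
             rationale = "closest")
      } else {
        list(class = if (d[["knn"]] > d[["xgb"]]) "B" else "A",
             rationale = "farthest")
      }
      expect_equal(sel, expected)
    }
    # agreement wins regardless of branch and distances
    expect_equal(hybrid_select("A", "A", dist_cases[[1]], status, "C"),
                 list(class = "A", rationale = "agreement"))
  }
  expect_error(hybrid_select("A", "B", dist_cases[[1]], "plateau", "C"),
               "unknown improvement status")
})

test_that("state flags encode the four safety conditions", {
  cfg <- hybrid_config(epsilon = 0.1, forcing_threshold = 0.3,
                       fall_timeout_s = 60, time_bounds = c(2, 300))
  # started, never completed, timeout elapsed: possible fall
  f <- state_flags(events = "start", elapsed_s = 90, time_s = NA, rate = 0,
                   status_history = "steady", baseline = "walk",
                   final = "walk", config = cfg)
  expect_true(f$possible_fall)

  # nominal completed session: all flags off
  f <- state_flags(time_s = 12, rate = 0.01, status_history = "steady",
                   baseline = "walk", final = "walk", config = cfg)
  expect_false(any(unlist(f)))

  # malformed event stream flags an anomaly instead of erroring
  f <- state_flags(events = c("complete", "banana"), elapsed_s = 10,
                   time_s = 12, rate = 0, status_history = "steady",
                   baseline = "walk", final = "walk", config = cfg)
  expect_true(f$sensor_anomaly)

  # physically impossible time flags an anomaly
  f <- state_flags(time_s = 900, rate = 0, status_history = "steady",
                   baseline = "walk", final = "walk", config = cfg)
  expect_true(f$sensor_anomaly)

  # steep improvement away from the baseline flags forcing
  f <- state_flags(time_s = 8, rate = -1.5, status_history = "improving",
                   baseline = "walk", final = "fast", config = cfg)
  expect_true(f$forcing)
  f <- state_flags(time_s = 8, rate = -1.5, status_history = "improving",
                   baseline = "fast", final = "fast", config = cfg)
  expect_false(f$forcing)

  # three consecutive worsening sessions flag deterioration
  f <- state_flags(time_s = 15, rate = 0.5,
                   status_history = c("steady", rep("worsening", 3)),
                   baseline = "walk", final = "walk", config = cfg)
  expect_true(f$deterioration)
  f <- state_flags(time_s = 15, rate = 0.5,
                   status_history = c("worsening", "steady", "worsening"),
                   baseline = "walk", final = "walk", config = cfg)
  expect_false(f$deterioration)
})

# a small trained pair of pairs for session tests, built once
local_pairs <- local({
  fx <- fixture_experiment("FTSTS", seed = 61)
  bal <- smote_balance(fx, "difficulty", seed = 62)
  pd <- rehab_train(bal$dataset, "difficulty",
                    boosted = boosted_spec(grid = list(eta = 0.3,
                                                       n_estimators = 30,
                                                       max_depth = 3)),
                    knn = knn_spec(k_grid = 5), seed = 63)
  stats <- read_cohort_stats(default_cohort_stats_path("FTSTS"))
  stats <- lapply(stats, function(s) { s$n <- 25L; s })
  synth <- suppressWarnings(generate_dataset(
    stats, variability_config(seed = 64), rehab_taxonomy("FTSTS", "condition")))
  pc <- rehab_train(synth, "condition",
                    boosted = boosted_spec(grid = list(eta = 0.3,
                                                       n_estimators = 30,
                                                       max_depth = 4)),
                    knn = knn_spec(k_grid = 5), seed = 65)
  list(pd = pd, pc = pc)
})

test_that("run_session follows the algorithm line order and audits cleanly", {
  demo <- list(age_y = 30, height_m = 1.78, weight_kg = 80, sex = 1)
  st <- session_state("u1", demo, initial_condition = "healthy",
                      initial_difficulty = "slow")
  pd <- local_pairs$pd
  pc <- local_pairs$pc
  stream <- fixture_session_stream(list(base_time = 19), 25, "steady",
                                   seed = 66)
  for (i in 1:25) {
    out <- run_session(st, pd, pc, stream$time_s[i])
    st <- out$state
    pd <- out$pair_difficulty
    pc <- out$pair_condition
    b <- out$bundle$axes$difficulty
    # transparency: both models, probabilities, distances, rationale present
    expect_true(all(c("xgb", "knn", "distances", "baseline", "final",
                      "rationale") %in% names(b)))
    expect_equal(sum(b$xgb$prob), 1, tolerance = 1e-6)
    # models agreeing means the agreed class is final regardless of branch
    if (b$xgb$class == b$knn$class) expect_equal(b$final, b$xgb$class)
    # selection soundness: the bundle satisfies the hybrid_select truth table
    resel <- hybrid_select(b$xgb$class, b$knn$class, b$distances,
                           out$bundle$status, b$baseline)
    expect_equal(list(class = b$final, rationale = b$rationale), resel)
  }
  expect_length(st$history, 25)
  expect_length(st$predictions$difficulty, 25)
  # retraining grew both stores
  expect_equal(nrow(pd$knn$X), nrow(local_pairs$pd$knn$X) + 25)
  expect_equal(nrow(pc$knn$X), nrow(local_pairs$pc$knn$X) + 25)

  # bundles serialize without loss of the audit fields
  path <- tempfile(fileext = ".jsonl")
  write_bundles(st, path)
  lines <- readLines(path)
  expect_length(lines, 25)
  rec <- jsonlite::fromJSON(lines[1])
  expect_true(all(c("axes", "flags", "comorbidity_alert") %in% names(rec)))
})

test_that("a persistently different condition raises the co-morbidity alert", {
  demo <- list(age_y = 30, height_m = 1.78, weight_kg = 80, sex = 1)
  # initialise with a condition the healthy-range stream will not predict
  st <- session_state("u2", demo, initial_condition = "parkinsons_stage_4",
                      initial_difficulty = "fast",
                      config = hybrid_config(alert_window = 10,
                                             alert_fraction = 0.8))
  pd <- local_pairs$pd
  pc <- local_pairs$pc
  stream <- fixture_session_stream(list(base_time = 7), 20, "steady",
                                   seed = 67)
  alerts <- logical(20)
  for (i in 1:20) {
    out <- run_session(st, pd, pc, stream$time_s[i])
    st <- out$state
    pd <- out$pair_difficulty
    pc <- out$pair_condition
    alerts[i] <- out$bundle$comorbidity_alert
  }
  drift <- mean(utils::tail(st$predictions$condition, 10) !=
                  "parkinsons_stage_4")
  expect_equal(utils::tail(alerts, 1), drift >= 0.8)
  expect_true(any(alerts)) # the stream never predicts stage 4 at 7 s
  # no alert before the window fills
  expect_false(any(alerts[1:9]))
})

test_that("an uncompleted session skips prediction but still flags", {
  demo <- list(age_y = 30, height_m = 1.78, weight_kg = 80, sex = 1)
  st <- session_state("u3", demo, initial_condition = "healthy",
                      initial_difficulty = "slow")
  out <- run_session(st, local_pairs$pd, local_pairs$pc, NA_real_,
                     events = "start", elapsed_s = 120)
  expect_true(out$bundle$flags$possible_fall)
  expect_length(out$state$predictions$difficulty, 0)
  expect_length(out$state$history, 0)
})

test_that("self-reinforcement keeps cumulative accuracy non-decreasing", {
  # stationary single-class streams with a correct initial prediction:
  # after a 10-session warm-up the cumulative accuracy must not decline
  n_runs <- 20
  ok <- vapply(seq_len(n_runs), function(s) {
    pd <- local_pairs$pd
    pc <- local_pairs$pc
    demo <- list(age_y = 25 + s, height_m = 1.7 + 0.01 * (s %% 5),
                 weight_kg = 70 + s %% 10, sex = s %% 2)
    st <- session_state(paste0("sr", s), demo, initial_condition = "healthy",
                        initial_difficulty = "slow")
    stream <- fixture_session_stream(list(base_time = 19), 60, "steady",
                                     seed = 700 + s)
    for (i in 1:60) {
      out <- run_session(st, pd, pc, stream$time_s[i])
      st <- out$state; pd <- out$pair_difficulty; pc <- out$pair_condition
    }
    curve <- cumulative_accuracy(st$predictions$difficulty == "slow")
    all(diff(curve[10:60]) >= -1e-12)
  }, TRUE)
  expect_gte(mean(ok), 0.95)
})
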