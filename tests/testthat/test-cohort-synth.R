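test_that("sorted Gaussian sampling honours its contract", {
  expect_equal(sample_sorted_gaussian(10, 0, 5, seed = 1), rep(10, 5))
  expect_length(sample_sorted_gaussian(3, 1, 0, seed = 1), 0)
  expect_error(sample_sorted_gaussian(3, -1, 5, seed = 1), "sigma")
  for (s in 1:5) {
    x <- sample_sorted_gaussian(12, 4, 100, seed = s)
    expect_false(is.unsorted(x))
  }
  # moment recovery at n = 10000: mean within 10 standard errors, sd within 5%
  x <- sample_sorted_gaussian(10, 2, 10000, seed = 42)
  expect_lt(abs(mean(x) - 10), 10 * 2 / sqrt(10000))
  expect_lt(abs(sd(x) - 2) / 2, 0.05)
  # truncation keeps draws above the bound
  y <- sample_sorted_gaussian(1, 2, 500, seed = 7, lower = 0)
  expect_true(all(y > 0))
})

test_that("variability swaps permute without changing any multiset", {
  x <- sort(rnorm(100))
  expect_equal(insert_variability(x, 0, 10, seed = 1),
               structure(x, swaps = matrix(integer(0), ncol = 2)))
  for (frac in c(0.1, 0.5, 1)) {
    y <- insert_variability(x, frac, 25, seed = frac * 100)
    expect_equal(sort(y), x)
    expect_equal(mean(y), mean(x))
    expect_equal(sd(y), sd(x))
  }
  # linked columns move with the identical swap sequence
  cols <- list(a = 1:50, b = 51:100)
  out <- insert_variability(cols, 0.4, 10, seed = 3)
  expect_equal(out$b - out$a, rep(50L, 50))
  expect_error(insert_variability(list(1:3, 1:4), 0.2, 2, seed = 1),
               "mismatched")
  # swap locality bound
  sw <- attr(insert_variability(1:200, 0.5, 5, seed = 9), "swaps")
  expect_true(all(abs(sw[, 1] - sw[, 2]) <= 5))
})

test_that("rank correlation decays monotonically with swap fraction", {
  x <- sort(rnorm(200, 50, 10))
  mean_rho <- vapply(c(0, 0.1, 0.3, 0.6), function(frac) {
    mean(vapply(1:50, function(s) {
      y <- insert_variability(x, frac, 50, seed = s)
      cor(x, y, method = "spearman")
    }, 0))
  }, 0)
  expect_equal(mean_rho[1], 1)
  expect_true(all(diff(mean_rho) < 0))
})

test_that("sex assignment is exact and deterministic", {
  expect_equal(assign_sex(10, 0.4), c(rep(0L, 4), rep(1L, 6)))
  expect_equal(assign_sex(5, 0), rep(1L, 5))
  expect_equal(assign_sex(5, 1), rep(0L, 5))
  expect_equal(sum(assign_sex(137, 0.53) == 0), floor(137 * 0.53))
})

test_that("height derivation matches target moments and the BMI identity", {
  out <- derive_height(80, 20, 2.0, 0)
  expect_equal(out$height, 2.0)
  expect_equal(out$bmi, 20)

  set.seed(11)
  w <- runif(60, 55, 95)
  b <- runif(60, 20, 32)
  res <- suppressWarnings(derive_height(w, b, 1.7, 0.09))
  expect_equal(mean(res$height), 1.7, tolerance = 1e-9)
  expect_equal(sd(res$height), 0.09, tolerance = 1e-9)
  expect_lt(max(abs(res$bmi - w / res$height^2)), 1e-6)

  # the literal un-rooted form is available but differs
  res_lit <- suppressWarnings(derive_height(w, b, 1.7, 0.09, literal = TRUE))
  expect_false(isTRUE(all.equal(res$height, res_lit$height)))

  # infeasible targets produce an error, not silent negative heights
  expect_error(suppressWarnings(derive_height(w, b, 0.1, 3)), "infeasible")
})

test_that("class generation follows the sorted-then-varied line order", {
  st <- cohort_stats("stroke", 50, 19, 6, 65, 11, 27, 4, 77, 14, 1.69, 0.09,
                     0.42, test_type = "TUG")
  cfg0 <- variability_config(0, 0, seed = 21)
  tab <- generate_class(st, cfg0)
  expect_equal(nrow(tab), 50)
  # with no swaps every sorted pair is perfectly rank-correlated
  expect_equal(cor(tab$completion_time_s, tab$age_y, method = "spearman"), 1)
  expect_equal(cor(tab$completion_time_s, tab$weight_kg, method = "spearman"), 1)
  # BMI identity on every generated row
  expect_lt(max(abs(tab$bmi - tab$weight_kg / tab$height_m^2)), 1e-10)
  # exact sex proportion
  expect_equal(sum(tab$sex == 0), floor(50 * 0.42))
  # n = 0 gives an empty table
  st0 <- st; st0$n <- 0L
  expect_equal(nrow(generate_class(st0, cfg0)), 0)

  # swaps leave the drawn per-column moments untouched (permutation property)
  st2 <- st; st2$n <- 280L
  base <- generate_class(st2, variability_config(0, 0, seed = 22))
  varied <- generate_class(st2, variability_config(0.3, 0.3, seed = 22))
  for (col in c("completion_time_s", "age_y", "weight_kg")) {
    expect_equal(sort(varied[[col]]), sort(base[[col]]), tolerance = 1e-12)
  }
  # drawn moments sit within Monte-Carlo bounds of the requested parameters
  expect_lt(abs(mean(varied$completion_time_s) - 19), 10 * 6 / sqrt(280))
  expect_lt(abs(sd(varied$age_y) - 11) / 11, 0.15)
  expect_equal(mean(varied$height_m), 1.69, tolerance = 1e-9)
  expect_equal(sd(varied$height_m), 0.09, tolerance = 1e-9)
})

test_that("dataset generation assembles the full taxonomies", {
  tug_tax <- rehab_taxonomy("TUG", "condition")
  tug <- suppressWarnings(generate_dataset(
    read_cohort_stats(default_cohort_stats_path("TUG")),
    variability_config(seed = 23), tug_tax))
  expect_equal(nrow(tug$data), 5040)
  expect_equal(unname(table(tug$data$condition)["stroke"]), 280)

  ftsts <- suppressWarnings(generate_dataset(
    read_cohort_stats(default_cohort_stats_path("FTSTS")),
    variability_config(seed = 24), rehab_taxonomy("FTSTS", "condition")))
  expect_equal(nrow(ftsts$data), 3120)

  # value-level determinism
  tug2 <- suppressWarnings(generate_dataset(
    read_cohort_stats(default_cohort_stats_path("TUG")),
    variability_config(seed = 23), tug_tax))
  expect_identical(tug$data, tug2$data)

  # single class
  st <- cohort_stats("fast", 7, 6, 1, 30, 5, 24, 2, 70, 8, 1.75, 0.06, 0.5)
  tax1 <- rehab_taxonomy("FTSTS", "difficulty")
  expect_error(generate_dataset(list(st), variability_config(seed = 1), tax1),
               "do not match")
})

test_that("correlation validation agrees with a naive oracle", {
  df <- make_feature_df(60, seed = 25)
  df$difficulty <- "walk"
  ds <- rehab_dataset(df, "TUG")
  feats <- rehab_features()
  X <- as.matrix(df[feats])
  # brute-force double-loop Pearson matrix
  n <- nrow(X)
  ref <- diag(6)
  for (i in 1:6) for (j in 1:6) {
    xi <- X[, i] - mean(X[, i]); xj <- X[, j] - mean(X[, j])
    ref[i, j] <- sum(xi * xj) / sqrt(sum(xi^2) * sum(xj^2))
  }
  dimnames(ref) <- list(feats, feats)
  rep1 <- validate_correlations(ds, ref, tolerance = 1e-8)
  expect_lt(rep1$max_abs_diff, 1e-12)
  expect_true(rep1$pass)

  # a zero-swap synthetic class fails a moderate reference
  st <- cohort_stats("geriatric", 120, 12, 3, 78, 7, 26, 4, 70, 12, 1.65,
                     0.09, 0.6, test_type = "TUG")
  tab <- generate_class(st, variability_config(0, 0, seed = 26))
  tab$condition <- "geriatric"
  ds2 <- rehab_dataset(tab, "TUG",
                       taxonomies = list(condition = rehab_taxonomy("TUG", "condition")))
  moderate <- diag(6)
  dimnames(moderate) <- list(feats, feats)
  moderate["completion_time_s", "age_y"] <- 0.5
  moderate["age_y", "completion_time_s"] <- 0.5
  rep2 <- validate_correlations(ds2, moderate, tolerance = 0.3)
  expect_gt(abs(rep2$correlation["completion_time_s", "age_y"]), 0.9)
  expect_false(rep2$pass)

  # constant features are flagged and excluded
  df3 <- make_feature_df(10, seed = 27)
  df3$sex <- 1
  df3$difficulty <- "walk"
  rep3 <- validate_correlations(rehab_dataset(df3, "TUG"), diag(6), 0.99)
  expect_equal(rep3$excluded, "sex")
})

test_that("experiment fixtures have the published shape and separability", {
  tug <- fixture_experiment("TUG", seed = 28)
  expect_equal(nrow(tug$data), 183)
  expect_equal(as.integer(table(tug$data$difficulty)[c("walk", "normal")]),
               c(40L, 24L))
  expect_equal(length(unique(tug$data$participant)), 8)
  expect_equal(sum(tug$data$sex == 0) > 0, TRUE)

  ftsts <- fixture_experiment("FTSTS", seed = 29)
  slow <- ftsts$data$completion_time_s[ftsts$data$difficulty == "slow"]
  fast <- ftsts$data$completion_time_s[ftsts$data$difficulty == "fast"]
  expect_gt(min(slow), max(fast)) # zero class overlap by construction
})

test_that("session streams realise their named trends", {
  prof <- list(base_time = 15)
  imp <- fixture_session_stream(prof, 100, "improving", seed = 30)
  expect_lt(coef(lm(time_s ~ session, imp))[2], 0)
  wor <- fixture_session_stream(prof, 100, "worsening", seed = 31)
  expect_gt(coef(lm(time_s ~ session, wor))[2], 0)
  ab <- fixture_session_stream(prof, 50, "abandon", seed = 32)
  expect_true(any(!ab$completed))
  expect_true(all(is.na(ab$time_s[!ab$completed])))
  expect_error(fixture_session_stream(prof, 10, "jumping", seed = 33))
})
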