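# shared builders for small in-code fixtures

make_feature_df <- function(n, seed = 1, time = NULL) {
  set.seed(seed)
  height <- runif(n, 1.55, 1.9)
  weight <- runif(n, 55, 95)
  data.frame(
    completion_time_s = if (is.null(time)) runif(n, 6, 20) else time,
    age_y = runif(n, 20, 80),
    height_m = height,
    weight_kg = weight,
    bmi = weight / height^2,
    sex = sample(c(0, 1), n, replace = TRUE)
  )
}

# two difficulty classes with disjoint single-feature (completion time)
# ranges: demographics are constant so time alone carries the label, and
# times sit on a replicated lattice so every split retains the class extremes
make_separable_ftsts <- function(n_per_class = 20, seed = 1) {
  set.seed(seed)
  times <- c(rep(seq(17, 21, by = 1), length.out = n_per_class),
             rep(seq(5, 9, by = 1), length.out = n_per_class))
  df <- data.frame(
    completion_time_s = times,
    age_y = 30, height_m = 1.75, weight_kg = 75,
    bmi = 75 / 1.75^2, sex = 1,
    difficulty = rep(c("slow", "fast"), each = n_per_class)
  )
  rehab_dataset(df, test_type = "FTSTS",
                provenance = "experimental_fixture")
}

# brute-force k-NN vote fractions (independent oracle)
oracle_knn_probs <- function(X_train, y_codes, x, k, n_classes) {
  d <- sqrt(rowSums((X_train - matrix(x, nrow(X_train), length(x),
                                      byrow = TRUE))^2))
  nn <- order(d)[seq_len(k)]
  tabulate(y_codes[nn] + 1L, nbins = n_classes) / k
}
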