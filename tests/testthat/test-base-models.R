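test_that("both base models reach perfect CV accuracy on a separable toy", {
  ds <- make_separable_ftsts(20, seed = 41)
  pair <- rehab_train(ds, "difficulty",
                      boosted = boosted_spec(grid = list(eta = 0.3,
                                                         n_estimators = 50,
                                                         max_depth = 3)),
                      knn = knn_spec(k_grid = c(1, 3, 5)), seed = 42)
  expect_equal(max(pair$cv_report$xgb$mean_accuracy), 1)
  expect_equal(max(pair$cv_report$knn$mean_accuracy), 1)
  expect_equal(unname(test_accuracy(pair)), c(1, 1))

  # a one-point grid is chosen verbatim
  expect_equal(pair$cv_report$chosen$xgb$eta, 0.3)
  expect_equal(pair$cv_report$chosen$xgb$n_estimators, 50)
  expect_equal(pair$cv_report$chosen$xgb$max_depth, 3)

  # grid-search selection equals exhaustive evaluation of the recorded grid
  rep4 <- rehab_train(ds, "difficulty",
                      boosted = boosted_spec(grid = list(eta = c(0.1, 0.3),
                                                         n_estimators = c(20, 50),
                                                         max_depth = 3)),
                      seed = 43)$cv_report
  expect_equal(nrow(rep4$xgb), 4)
  best <- which.max(rep4$xgb$mean_accuracy)
  expect_equal(rep4$chosen$xgb$eta, rep4$xgb$eta[best])
  expect_equal(rep4$chosen$xgb$n_estimators, rep4$xgb$n_estimators[best])
})

test_that("training is deterministic under a fixed seed", {
  ds <- make_separable_ftsts(15, seed = 44)
  spec <- boosted_spec(grid = list(eta = c(0.1, 0.3), n_estimators = 20,
                                   max_depth = c(2, 4)))
  p1 <- rehab_train(ds, "difficulty", boosted = spec, seed = 45)
  p2 <- rehab_train(ds, "difficulty", boosted = spec, seed = 45)
  expect_identical(p1$cv_report$chosen, p2$cv_report$chosen)
  expect_identical(p1$cv_report$xgb, p2$cv_report$xgb)
  expect_identical(p1$knn$X, p2$knn$X)
  expect_identical(p1$centroids, p2$centroids)
})

test_that("default depth grid scales with the class count", {
  grid <- rehabstack:::expand_boosted_grid(boosted_spec(), n_classes = 5)
  expect_setequal(unique(grid$max_depth), c(3, 10, 20))
  expect_error(boosted_spec(grid = list(nu = 1)), "unknown")
})

test_that("stratified folding fails loudly when a class is too small", {
  df <- make_feature_df(24, seed = 46)
  df$difficulty <- c(rep("slow", 4), rep("fast", 20))
  ds <- rehab_dataset(df, "FTSTS")
  expect_error(
    rehab_train(ds, "difficulty",
                boosted = boosted_spec(grid = list(eta = 0.3,
                                                   n_estimators = 10,
                                                   max_depth = 2)),
                folds = 5, seed = 47),
    "stratified")
})

test_that("probability vectors are proper and k-NN matches the vote oracle", {
  ds <- make_separable_ftsts(15, seed = 48)
  pair <- rehab_train(ds, "difficulty",
                      boosted = boosted_spec(grid = list(eta = 0.3,
                                                         n_estimators = 20,
                                                         max_depth = 3)),
                      knn = knn_spec(k_grid = 5), seed = 49)
  newdata <- make_feature_df(10, seed = 50)
  pred <- suppressWarnings(predict(pair, newdata))
  for (m in c("xgb", "knn")) {
    expect_true(all(pred[[m]]$prob >= 0))
    expect_equal(unname(rowSums(pred[[m]]$prob)), rep(1, 10), tolerance = 1e-6)
    # argmax equals the returned class
    expect_equal(max.col(pred[[m]]$prob, ties.method = "first") - 1L,
                 pred[[m]]$code)
  }

  # k-NN vote fractions vs exhaustive neighbour oracle on <= 30 points
  X <- rehabstack:::normalize_values(newdata, pair$normalizer)
  for (i in 1:10) {
    expect_equal(unname(pred$knn$prob[i, ]),
                 oracle_knn_probs(pair$knn$X, pair$knn$y, X[i, ],
                                  pair$knn$k, 2))
  }

  # all neighbours of one class give probability 1
  rec <- ds$data[1, rehab_features()] # deep in the slow cloud
  p1 <- predict_with_probs(pair, rec)
  expect_equal(unname(p1$knn$prob["slow"]), 1)
})

test_that("centroids are class means and translate with the data", {
  df <- make_feature_df(12, seed = 51)
  df$difficulty <- rep(c("slow", "fast"), each = 6)
  ds <- rehab_dataset(df, "FTSTS")
  nds <- apply_normalizer(ds, fit_normalizer(ds))
  cents <- class_centroids(nds, "difficulty")
  feats <- rehab_features()
  expect_equal(cents["slow", ],
               colMeans(as.matrix(nds$data[nds$data$difficulty == "slow",
                                           feats])))
  # single record: the centroid is that record
  one <- nds
  one$data <- nds$data[1, , drop = FALSE]
  expect_equal(class_centroids(one, "difficulty")[1, ],
               unlist(nds$data[1, feats]))
  # two records: the midpoint
  two <- nds
  two$data <- nds$data[1:2, , drop = FALSE]
  two$data$difficulty <- "slow"
  expect_equal(class_centroids(two, "difficulty")["slow", ],
               colMeans(as.matrix(nds$data[1:2, feats])))
  # translating every feature by delta translates every centroid by delta
  shifted <- nds
  shifted$data[feats] <- nds$data[feats] + 0.01
  expect_equal(class_centroids(shifted, "difficulty"), cents + 0.01,
               tolerance = 1e-12)
})

test_that("incremental updates insert, re-centre and reinforce", {
  ds <- make_separable_ftsts(15, seed = 52)
  pair <- rehab_train(ds, "difficulty",
                      boosted = boosted_spec(grid = list(eta = 0.3,
                                                         n_estimators = 20,
                                                         max_depth = 3)),
                      knn = knn_spec(k_grid = 1), seed = 53)
  rec <- make_feature_df(1, seed = 54)
  rec$completion_time_s <- 12 # mid-gap record
  up <- incremental_update(pair, rec, "slow")
  expect_equal(nrow(up$knn$X), nrow(pair$knn$X) + 1)
  expect_length(up$xgb_chain, 2)

  # k-NN with k = 1 queried at the new record returns the new label
  up$knn$k <- 1L
  p <- suppressWarnings(predict(up, rec))
  expect_equal(p$knn$class, "slow")

  # the class centroid equals recomputation from scratch
  x_new <- rehabstack:::normalize_values(rec, pair$normalizer)[1, ]
  scratch <- colMeans(rbind(pair$knn$X[pair$knn$y == 0, , drop = FALSE],
                            x_new))
  expect_equal(up$centroids["slow", ], scratch, tolerance = 1e-12)

  # updating with the pair's own confident prediction keeps it unchanged
  rec2 <- ds$data[2, rehab_features()]
  before <- suppressWarnings(predict_with_probs(pair, rec2))
  up2 <- incremental_update(pair, rec2, before$xgb$class)
  after <- suppressWarnings(predict_with_probs(up2, rec2))
  expect_equal(after$xgb$class, before$xgb$class)
  expect_equal(after$knn$class, before$knn$class)

  expect_error(incremental_update(pair, rec, "sprinting"), "unknown")
})

test_that("feature importances are a distribution dominated by the ruling feature", {
  ds <- make_separable_ftsts(20, seed = 55)
  pair <- rehab_train(ds, "difficulty",
                      boosted = boosted_spec(grid = list(eta = 0.3,
                                                         n_estimators = 30,
                                                         max_depth = 3)),
                      seed = 56)
  imp <- pair$feature_importances
  expect_true(all(imp >= 0))
  expect_equal(sum(imp), 1, tolerance = 1e-6)
  # completion time alone determines the label here
  expect_equal(names(which.max(imp)), "completion_time_s")
})
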