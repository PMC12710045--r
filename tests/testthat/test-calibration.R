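test_that("metric suite matches hand evaluation of the scoring formulas", {
  perfect <- tibble::tibble(measured_m = c(0.4, 0.8, 1.2),
                            predicted_m = c(0.4, 0.8, 1.2))
  m <- evaluate_predictions(perfect)
  expect_equal(m$r2, 1)
  expect_equal(c(m$mae, m$mse, m$rmse), c(0, 0, 0))

  # Zm = (0, 2), Zp = (1, 1): every error is 1, and the predictor is the mean
  m2 <- evaluate_predictions(tibble::tibble(measured_m = c(0, 2),
                                            predicted_m = c(1, 1)))
  expect_equal(m2$mae, 1)
  expect_equal(m2$mse, 1)
  expect_equal(m2$rmse, 1)
  expect_equal(m2$r2, 0)

  # constant predictor at mean(y) has R2 = 0 by definition
  y <- c(0.5, 0.7, 1.1, 0.9)
  m3 <- evaluate_predictions(tibble::tibble(measured_m = y,
                                            predicted_m = mean(y)))
  expect_equal(m3$r2, 0)

  # zero variance in y: R2 undefined, not 0
  m4 <- evaluate_predictions(tibble::tibble(measured_m = c(1, 1, 1),
                                            predicted_m = c(1, 2, 3)))
  expect_true(is.na(m4$r2))
  expect_false(is.na(m4$rmse))
})

test_that("metrics are invariant to a common permutation of the pairs", {
  set.seed(11)
  zm <- runif(60, 0.3, 1.3); zp <- zm + rnorm(60, 0, 0.05)
  a <- evaluate_predictions(tibble::tibble(measured_m = zm, predicted_m = zp))
  perm <- sample(60)
  b <- evaluate_predictions(tibble::tibble(measured_m = zm[perm],
                                           predicted_m = zp[perm]))
  expect_equal(a, b)
})

test_that("polynomial fit recovers exact coefficients and nests by degree", {
  x <- seq(0.1, 1.5, length.out = 30)
  exact <- tibble::tibble(extracted_m = x, measured_m = 2 * x^2 + 1)
  fit <- fit_polynomial(exact, degree = 2)
  expect_equal(fit$coefficients, c(1, 0, 2), tolerance = 1e-8)
  expect_equal(evaluate_model(fit, exact)$r2, 1, tolerance = 1e-12)

  set.seed(5)
  noisy <- tibble::tibble(extracted_m = x,
                          measured_m = 0.5 + x + rnorm(30, 0, 0.1))
  r2s <- vapply(1:3, function(d) {
    evaluate_model(fit_polynomial(noisy, d), noisy)$r2
  }, numeric(1))
  expect_true(all(diff(r2s) >= -1e-12))

  expect_error(fit_polynomial(exact[1:2, ], degree = 2), "degree")
  flat <- tibble::tibble(extracted_m = rep(1, 5), measured_m = 1:5)
  expect_error(fit_polynomial(flat, 1), "identical")
})

test_that("regression families fit, predict and respect their degenerate limits", {
  set.seed(9)
  train <- tibble::tibble(extracted_m = runif(60, 0.2, 1.2))
  train$measured_m <- 0.2 + 1.1 * train$extracted_m + rnorm(60, 0, 0.02)

  # k = 1 nearest neighbour memorises the training set
  knn1 <- fit_regressor(train, "knn", knn_k = 1)
  expect_equal(predict(knn1, train), train$measured_m)

  # Huber on clean linear data agrees with OLS
  clean <- tibble::tibble(extracted_m = train$extracted_m,
                          measured_m = 0.2 + 1.1 * train$extracted_m)
  hub <- fit_regressor(clean, "huber")
  ols <- coef(lm(measured_m ~ extracted_m, clean))
  expect_equal(unname(coef(hub$fit)[2]), unname(ols[2]), tolerance = 1e-6)

  # single-predictor least-angle regression reduces to OLS
  lar <- fit_regressor(train, "lar")
  ols2 <- unname(coef(lm(measured_m ~ extracted_m, train)))
  expect_equal(unname(lar$coefficients), ols2, tolerance = 1e-8)

  # orthogonal matching pursuit likewise
  omp <- fit_regressor(train, "omp")
  expect_equal(unname(omp$coefficients), ols2, tolerance = 1e-8)

  expect_error(fit_regressor(train, "deep_net"), "unknown")
  expect_error(fit_regressor(train[1:3, ], "rfr"), "at least 5")
})

test_that("all catalogued families produce finite deterministic predictions", {
  set.seed(2)
  train <- tibble::tibble(extracted_m = runif(80, 0.2, 1.2))
  train$measured_m <- 0.9 * train$extracted_m^2 + 1.05 * train$extracted_m +
    rnorm(80, 0, 0.03)
  newx <- tibble::tibble(extracted_m = seq(0.3, 1.1, length.out = 11))
  fams <- c("poly2", "rfr", "knn", "huber", "lar", "ridge", "lightgbm",
            "dtr", "etr", "omp", "bayes_ridge", "adaboost", "catboost")
  for (f in fams) {
    m1 <- fit_regressor(train, f, seed = 42)
    p1 <- predict(m1, newx)
    expect_true(all(is.finite(p1)), info = f)
    # on smooth data every family should interpolate reasonably
    truth <- 0.9 * newx$extracted_m^2 + 1.05 * newx$extracted_m
    expect_lt(sqrt(mean((p1 - truth)^2)), 0.15, label = f)
    m2 <- fit_regressor(train, f, seed = 42)
    expect_equal(predict(m2, newx), p1, info = f)
  }
})

test_that("Spearman validation equals Pearson on average ranks", {
  inc <- tibble::tibble(measured_m = 1:10, predicted_m = (1:10)^3)
  expect_equal(spearman_validation(inc), 1)
  dec <- tibble::tibble(measured_m = 1:10, predicted_m = -(1:10))
  expect_equal(spearman_validation(dec), -1)

  set.seed(3)
  for (i in 1:5) {
    zm <- sample(1:8, 30, replace = TRUE)  # ties on purpose
    zp <- zm + rnorm(30)
    got <- spearman_validation(tibble::tibble(measured_m = zm,
                                              predicted_m = zp))
    expect_equal(got, cor(rank(zm), rank(zp)), tolerance = 1e-12)
  }
  const <- tibble::tibble(measured_m = rep(1, 5), predicted_m = 1:5)
  expect_error(spearman_validation(const), "constant")
})

test_that("train/test protocol prefers the quadratic model under quadratic distortion", {
  plots <- sprintf("P%03d", 1:60)
  ser <- tidyr::expand_grid(plot_id = plots, time_point = 1:5)
  set.seed(14)
  ser$extracted_m <- runif(nrow(ser), 0.2, 1.2)
  ser$measured_m <- 0.9 * ser$extracted_m^2 + 1.05 * ser$extracted_m +
    rnorm(nrow(ser), 0, 0.03)
  rep <- train_test_protocol(ser, plots[1:24], c(4, 5),
                             families = c("poly1", "poly2"))
  expect_equal(rep$train_n, 120)
  expect_equal(rep$best_family, "poly2")
  r2 <- rep$metrics$r2
  expect_gt(r2[rep$metrics$family == "poly2"],
            r2[rep$metrics$family == "poly1"])
  expect_true(all(rep$spearman$spearman > 0.9))
  expect_error(train_test_protocol(ser, plots[1:24], 99,
                                   families = "poly1"), "test set")
})

test_that("parametric models round-trip through JSON", {
  set.seed(4)
  train <- tibble::tibble(extracted_m = runif(40, 0.2, 1.2))
  train$measured_m <- 1 + 0.8 * train$extracted_m + rnorm(40, 0, 0.02)
  for (f in c("poly2", "lar", "bayes_ridge")) {
    m <- fit_regressor(train, f)
    path <- withr::local_tempfile(fileext = ".json")
    save_calibration_json(m, path)
    m2 <- load_calibration_json(path)
    expect_equal(predict(m2, train), predict(m, train), tolerance = 1e-9,
                 info = f)
  }
  rf <- fit_regressor(train, "rfr")
  expect_error(save_calibration_json(rf, tempfile()), "parametric")
})

test_that("tidy and glance summarise calibration objects", {
  train <- simulate_calibration_pairs(50, seed = 6)
  m <- fit_polynomial(train, 2)
  td <- tidy(m)
  expect_equal(nrow(td), 3)
  expect_named(td, c("term", "estimate"))
  gl <- glance(m)
  expect_equal(gl$family, "poly2")
})
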