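#' Prediction accuracy metrics
#'
#' The metric suite used to score height calibration models:
#' `R2 = 1 - sum((Zm - Zp)^2) / sum((Zm - mean(Zm))^2)`,
#' `MAE = mean(|Zm - Zp|)`, `MSE = mean((Zm - Zp)^2)`, `RMSE = sqrt(MSE)`,
#' `RMSLE = sqrt(mean((log(1 + Zp) - log(1 + Zm))^2))` and
#' `MAPE = mean(|Zm - Zp| / |Zm|)`, where `Zm` are measured and `Zp`
#' predicted heights. When the measured values have zero variance R2 is
#' undefined and returned as `NA`, not 0; RMSLE is `NA` if any value is
#' `<= -1`; MAPE is `NA` if any measured value is 0.
#'
#' @param data Data frame holding the paired values.
#' @param measured,predicted Column names (tidy-eval) of measured and
#'   predicted heights.
#' @return A one-row tibble: `n`, `r2`, `mae`, `mse`, `rmse`, `rmsle`,
#'   `mape`.
#' @export
evaluate_predictions <- function(data, measured = measured_m,
                                 predicted = predicted_m) {
  zm <- rlang::eval_tidy(rlang::enquo(measured), data)
  zp <- rlang::eval_tidy(rlang::enquo(predicted), data)
  stopifnot(length(zm) == length(zp))
  ok <- is.finite(zm) & is.finite(zp)
  zm <- zm[ok]; zp <- zp[ok]
  n <- length(zm)
  if (n < 2) stop("need at least 2 paired finite values", call. = FALSE)
  ss_res <- sum((zm - zp)^2)
  ss_tot <- sum((zm - mean(zm))^2)
  r2 <- if (ss_tot == 0) NA_real_ else 1 - ss_res / ss_tot
  mse <- mean((zm - zp)^2)
  rmsle <- if (any(zm <= -1) || any(zp <= -1)) NA_real_ else
    sqrt(mean((log1p(zp) - log1p(zm))^2))
  mape <- if (any(zm == 0)) NA_real_ else mean(abs(zm - zp) / abs(zm))
  tibble::tibble(n = n, r2 = r2, mae = mean(abs(zm - zp)), mse = mse,
                 rmse = sqrt(mse), rmsle = rmsle, mape = mape)
}

#' Spearman rank correlation between predicted and measured heights
#'
#' Rank correlation with average ranks for ties, used to validate calibrated
#' predictions against whole-panel manual measurements.
#'
#' @inheritParams evaluate_predictions
#' @return The correlation coefficient.
#' @export
spearman_validation <- function(data, measured = measured_m,
                                predicted = predicted_m) {
  zm <- rlang::eval_tidy(rlang::enquo(measured), data)
  zp <- rlang::eval_tidy(rlang::enquo(predicted), data)
  ok <- is.finite(zm) & is.finite(zp)
  zm <- zm[ok]; zp <- zp[ok]
  if (length(zm) < 3) stop("need at least 3 pairs", call. = FALSE)
  if (stats::sd(zm) == 0 || stats::sd(zp) == 0) {
    stop("constant vector: rank correlation undefined", call. = FALSE)
  }
  stats::cor(zm, zp, method = "spearman")
}

new_calibration_model <- function(family, fit, x_name, y_name, n, extra = list()) {
  structure(c(list(family = family, fit = fit, x_name = x_name,
                   y_name = y_name, training_n = n), extra),
            class = "calibration_model")
}

#' Polynomial height calibration
#'
#' Least-squares polynomial of degree 1-3 mapping UAV-extracted heights to
#' manually measured heights.
#'
#' @param data Training pairs.
#' @param degree Polynomial degree (1, 2 or 3).
#' @param x,y Column names (tidy-eval) of extracted and measured heights.
#' @return A `calibration_model`.
#' @export
fit_polynomial <- function(data, degree = 2, x = extracted_m,
                           y = measured_m) {
  stopifnot(degree %in% 1:3)
  xv <- rlang::eval_tidy(rlang::enquo(x), data)
  yv <- rlang::eval_tidy(rlang::enquo(y), data)
  ok <- is.finite(xv) & is.finite(yv)
  xv <- xv[ok]; yv <- yv[ok]
  if (length(xv) < degree + 1) {
    stop("need at least degree + 1 observations", call. = FALSE)
  }
  if (stats::sd(xv) == 0) stop("all x values identical", call. = FALSE)
  df <- data.frame(.x = xv, .y = yv)
  fit <- stats::lm(.y ~ poly(.x, degree, raw = TRUE), data = df)
  new_calibration_model(paste0("poly", degree), fit,
                        rlang::as_name(rlang::enquo(x)),
                        rlang::as_name(rlang::enquo(y)), length(xv),
                        list(coefficients = unname(stats::coef(fit))))
}

# --- small in-package regressors -------------------------------------------

# Least-angle regression path (Efron et al.); returns the path endpoint,
# which for a full run equals the OLS fit on all predictors.
fit_lar_path <- function(X, y) {
  n <- nrow(X); p <- ncol(X)
  mx <- colMeans(X); sx <- apply(X, 2, stats::sd)
  sx[sx == 0] <- 1
  Xs <- scale(X, mx, sx); my <- mean(y); ys <- y - my
  beta <- rep(0, p)
  active <- integer(0)
  mu <- rep(0, n)
  for (step in seq_len(p)) {
    r <- ys - mu
    cvec <- drop(crossprod(Xs, r))
    if (length(active) < p) {
      cand <- setdiff(seq_len(p), active)
      j <- cand[which.max(abs(cvec[cand]))]
      active <- c(active, j)
    }
    s <- sign(cvec[active]); s[s == 0] <- 1
    Xa <- sweep(Xs[, active, drop = FALSE], 2, s, `*`)
    Ga <- crossprod(Xa)
    one <- rep(1, length(active))
    w <- solve(Ga, one)
    Aa <- 1 / sqrt(sum(w))
    u <- drop(Xa %*% (Aa * w))        # equiangular direction
    Cmax <- max(abs(cvec))
    a <- drop(crossprod(Xs, u))
    if (length(active) == p) {
      gam <- Cmax / Aa
    } else {
      cand <- setdiff(seq_len(p), active)
      g1 <- (Cmax - cvec[cand]) / (Aa - a[cand])
      g2 <- (Cmax + cvec[cand]) / (Aa + a[cand])
      gs <- c(g1, g2); gs <- gs[gs > 1e-12 & is.finite(gs)]
      gam <- if (length(gs)) min(gs, Cmax / Aa) else Cmax / Aa
    }
    mu <- mu + gam * u
    beta[active] <- beta[active] + gam * Aa * w * s
  }
  b <- beta / sx
  c(intercept = my - sum(b * mx), b)
}

# Orthogonal matching pursuit: greedy correlation selection with OLS refit.
fit_omp <- function(X, y, n_nonzero = ncol(X)) {
  p <- ncol(X)
  sel <- integer(0)
  r <- y - mean(y)
  Xc <- scale(X, scale = FALSE)
  for (k in seq_len(min(n_nonzero, p))) {
    cand <- setdiff(seq_len(p), sel)
    cors <- abs(drop(crossprod(Xc[, cand, drop = FALSE], r)))
    sel <- c(sel, cand[which.max(cors)])
    fit <- stats::lm.fit(cbind(1, X[, sel, drop = FALSE]), y)
    r <- fit$residuals
  }
  b <- rep(0, p)
  b[sel] <- fit$coefficients[-1]
  c(fit$coefficients[1], b)
}

# Bayesian ridge via evidence (type-II ML) iteration; intercept unpenalised.
fit_bayes_ridge <- function(X, y, max_iter = 200, tol = 1e-8) {
  mx <- colMeans(X); my <- mean(y)
  Xc <- scale(X, mx, FALSE); yc <- y - my
  n <- nrow(Xc); p <- ncol(Xc)
  XtX <- crossprod(Xc); Xty <- crossprod(Xc, yc)
  ev <- eigen(XtX, symmetric = TRUE, only.values = TRUE)$values
  alpha <- 1e-6; beta <- 1 / max(stats::var(yc), 1e-12)
  w <- rep(0, p)
  for (it in seq_len(max_iter)) {
    A <- XtX * beta + diag(alpha, p)
    w_new <- drop(solve(A, beta * Xty))
    gam <- sum(beta * ev / (alpha + beta * ev))
    rss <- sum((yc - Xc %*% w_new)^2)
    alpha <- gam / max(sum(w_new^2), 1e-12)
    beta <- max(n - gam, 1e-6) / max(rss, 1e-12)
    if (sum(abs(w_new - w)) < tol) { w <- w_new; break }
    w <- w_new
  }
  c(my - sum(w * mx), w)
}

# AdaBoost.R2 over regression trees.
fit_adaboost_r2 <- function(X, y, n_estimators = 50, max_depth = 3) {
  n <- nrow(X)
  wts <- rep(1 / n, n)
  models <- list(); betas <- numeric(0)
  df <- data.frame(y = y, X)
  for (m in seq_len(n_estimators)) {
    idx <- sample.int(n, n, replace = TRUE, prob = wts)
    fit <- rpart::rpart(y ~ ., data = df[idx, , drop = FALSE],
                        control = rpart::rpart.control(
                          maxdepth = max_depth, cp = 0, minsplit = 5,
                          xval = 0))
    pred <- stats::predict(fit, df)
    err <- abs(pred - y)
    emax <- max(err)
    if (emax <= 0) { models[[m]] <- fit; betas[m] <- 1e-10; break }
    L <- err / emax
    ebar <- sum(wts * L)
    if (ebar >= 0.5) break
    beta <- ebar / (1 - ebar)
    wts <- wts * beta^(1 - L)
    wts <- wts / sum(wts)
    models[[m]] <- fit
    betas[m] <- beta
  }
  if (!length(models)) {
    fit <- rpart::rpart(y ~ ., data = df,
                        control = rpart::rpart.control(maxdepth = max_depth,
                                                       cp = 0, xval = 0))
    models <- list(fit); betas <- 0.5
  }
  list(models = models, betas = betas)
}

predict_adaboost_r2 <- function(obj, newdf) {
  P <- vapply(obj$models, function(m) stats::predict(m, newdf),
              numeric(nrow(newdf)))
  P <- matrix(P, nrow = nrow(newdf))
  w <- log(1 / pmax(obj$betas, 1e-12))
  # weighted median across estimators
  apply(P, 1, function(row) {
    o <- order(row)
    cw <- cumsum(w[o])
    row[o][which(cw >= 0.5 * sum(w))[1]]
  })
}

#' Machine-learning height calibration
#'
#' Fits one of the regression families used for UAV-to-manual height
#' calibration: random forest (`rfr`), k-nearest neighbours (`knn`), Huber
#' robust regression (`huber`), least-angle regression (`lar`), ridge
#' (`ridge`), gradient-boosted trees in two presets (`lightgbm`-like
#' loss-guided and `catboost`-like depth-wise), decision tree (`dtr`), extra
#' trees (`etr`), orthogonal matching pursuit (`omp`), Bayesian ridge
#' (`bayes_ridge`) and AdaBoost.R2 (`adaboost`). Polynomial families
#' (`poly1`, `poly2`, `poly3`) are routed to [fit_polynomial()]. Stochastic
#' families are deterministic given `seed`.
#'
#' @param data Training pairs.
#' @param family Family name (see above).
#' @param x,y Column names (tidy-eval) of extracted and measured heights.
#' @param seed RNG seed for stochastic families.
#' @param knn_k Neighbourhood size for `knn`.
#' @return A `calibration_model`.
#' @export
fit_regressor <- function(data, family, x = extracted_m, y = measured_m,
                          seed = 1L, knn_k = 5L) {
  families <- c("poly1", "poly2", "poly3", "rfr", "knn", "huber", "lar",
                "ridge", "lightgbm", "dtr", "etr", "omp", "bayes_ridge",
                "adaboost", "catboost")
  if (!family %in% families) {
    stop(sprintf("unknown regression family '%s'", family), call. = FALSE)
  }
  xq <- rlang::enquo(x); yq <- rlang::enquo(y)
  if (family %in% c("poly1", "poly2", "poly3")) {
    return(rlang::inject(
      fit_polynomial(data, degree = as.integer(sub("poly", "", family)),
                     x = !!xq, y = !!yq)))
  }
  xv <- rlang::eval_tidy(xq, data)
  yv <- rlang::eval_tidy(yq, data)
  ok <- is.finite(xv) & is.finite(yv)
  xv <- xv[ok]; yv <- yv[ok]
  n <- length(xv)
  if (n < 5) stop("need at least 5 training pairs", call. = FALSE)
  X <- matrix(xv, ncol = 1, dimnames = list(NULL, "x1"))
  xn <- rlang::as_name(xq); yn <- rlang::as_name(yq)

  fit <- with_seed(seed, switch(family,
    rfr = randomForest::randomForest(X, yv, ntree = 300),
    knn = list(X = X, y = yv, k = as.integer(knn_k)),
    huber = MASS::rlm(yv ~ xv, psi = MASS::psi.huber, maxit = 100),
    lar = fit_lar_path(X, yv),
    ridge = {
      lam <- 1e-3 * n
      mx <- colMeans(X); my <- mean(yv)
      Xc <- scale(X, mx, FALSE)
      b <- drop(solve(crossprod(Xc) + diag(lam, ncol(X)),
                      crossprod(Xc, yv - my)))
      c(my - sum(b * mx), b)
    },
    lightgbm = xgboost::xgboost(
      X, yv, nrounds = 100, verbosity = 0, nthreads = 1, seed = seed,
      learning_rate = 0.1, grow_policy = "lossguide", max_leaves = 31,
      max_depth = 0, subsample = 0.9, min_child_weight = 2,
      tree_method = "hist"),
    dtr = rpart::rpart(y ~ x1, data = data.frame(y = yv, x1 = xv),
                       control = rpart::rpart.control(cp = 0.001,
                                                      minsplit = 5,
                                                      xval = 0)),
    etr = ranger::ranger(y = yv, x = data.frame(x1 = xv), num.trees = 300,
                         splitrule = "extratrees", seed = seed),
    omp = fit_omp(X, yv),
    bayes_ridge = fit_bayes_ridge(X, yv),
    adaboost = fit_adaboost_r2(X, yv),
    catboost = xgboost::xgboost(
      X, yv, nrounds = 150, verbosity = 0, nthreads = 1, seed = seed,
      learning_rate = 0.1, grow_policy = "depthwise", max_depth = 4,
      subsample = 0.8, colsample_bytree = 1, tree_method = "hist")
  ))
  extra <- if (family %in% c("lar", "ridge", "omp", "bayes_ridge")) {
    list(coefficients = unname(fit))
  } else list()
  new_calibration_model(family, fit, xn, yn, n, extra)
}

#' @export
predict.calibration_model <- function(object, newdata, ...) {
  xv <- if (is.numeric(newdata)) newdata
        else rlang::eval_tidy(rlang::sym(object$x_name), newdata)
  fam <- object$family
  if (grepl("^poly", fam)) {
    return(unname(stats::predict(object$fit,
                                 data.frame(.x = xv))))
  }
  switch(fam,
    rfr = unname(stats::predict(object$fit,
                                matrix(xv, ncol = 1,
                                       dimnames = list(NULL, "x1")))),
    knn = FNN::knn.reg(train = object$fit$X, y = object$fit$y,
                       test = matrix(xv, ncol = 1),
                       k = object$fit$k)$pred,
    huber = unname(stats::predict(object$fit, data.frame(xv = xv))),
    lar = ,
    ridge = ,
    omp = ,
    bayes_ridge = unname(object$fit[1] + object$fit[2] * xv),
    lightgbm = ,
    catboost = stats::predict(object$fit, matrix(xv, ncol = 1)),
    dtr = unname(stats::predict(object$fit, data.frame(x1 = xv))),
    etr = stats::predict(object$fit, data.frame(x1 = xv))$predictions,
    adaboost = predict_adaboost_r2(object$fit, data.frame(x1 = xv)),
    stop("cannot predict for family ", fam)
  )
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf("<calibration_model> family = %s, trained on %d pairs\n",
              x$family, x$training_n))
  if (!is.null(x$coefficients)) {
    cat("  coefficients:",
        paste(format(x$coefficients, digits = 4), collapse = " "), "\n")
  }
  invisible(x)
}

#' Score a calibration model on paired data
#'
#' @param model A `calibration_model`.
#' @param data Data frame containing the model's x and y columns.
#' @return A one-row metrics tibble (see [evaluate_predictions()]).
#' @export
evaluate_model <- function(model, data) {
  pred <- stats::predict(model, data)
  obs <- rlang::eval_tidy(rlang::sym(model$y_name), data)
  evaluate_predictions(tibble::tibble(measured_m = obs, predicted_m = pred))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @method tidy calibration_model
#' @export
tidy.calibration_model <- function(x, ...) {
  if (!is.null(x$coefficients)) {
    tibble::tibble(term = c("(Intercept)",
                            paste0("x^", seq_along(x$coefficients[-1]))),
                   estimate = x$coefficients)
  } else {
    tibble::tibble(term = character(), estimate = numeric())
  }
}

#' @method glance calibration_model
#' @export
glance.calibration_model <- function(x, ...) {
  tibble::tibble(family = x$family, training_n = x$training_n,
                 parametric = !is.null(x$coefficients))
}

#' Train / test calibration protocol
#'
#' Mirrors the field protocol: a small set of training plots is manually
#' measured at every time point; the whole panel is measured at the late
#' `test_times` only. Each requested family is fitted on the pooled
#' training-plot pairs and scored on them; the best family (largest training
#' R2, ties broken by smallest RMSE) is used to predict the whole panel, and
#' predictions are validated against the panel measurements by Spearman
#' correlation at each test time. Training plots are excluded from the test
#' rows so no (plot, time) cell is used on both sides.
#'
#' @param series A `plot_height_series` tibble with `extracted_m` and
#'   `measured_m` columns.
#' @param train_plots Character vector of training plot ids.
#' @param test_times Integer time points at which the whole panel was
#'   measured.
#' @param families Regression families to compare (see [fit_regressor()]).
#' @param seed RNG seed for stochastic families.
#' @return A `calibration_report`: list with `metrics` (per-family training
#'   metrics), `best_family`, `models`, `spearman` (per test time) and
#'   `predictions`.
#' @export
train_test_protocol <- function(series, train_plots, test_times,
                                families = c("poly1", "poly2", "poly3"),
                                seed = 1L) {
  stopifnot(all(c("plot_id", "time_point", "extracted_m", "measured_m")
                %in% names(series)))
  train <- dplyr::filter(series, .data$plot_id %in% train_plots,
                         is.finite(.data$extracted_m),
                         is.finite(.data$measured_m))
  if (nrow(train) == 0) stop("empty training set", call. = FALSE)
  test <- dplyr::filter(series, .data$time_point %in% test_times,
                        !(.data$plot_id %in% train_plots),
                        is.finite(.data$extracted_m),
                        is.finite(.data$measured_m))
  if (nrow(test) == 0) stop("empty test set", call. = FALSE)

  models <- purrr::map(families, function(f) {
    fit_regressor(train, f, seed = seed)
  })
  names(models) <- families
  metrics <- purrr::map_dfr(models, evaluate_model, data = train,
                            .id = "family")
  ord <- order(-metrics$r2, metrics$rmse)
  best <- metrics$family[ord[1]]

  bm <- models[[best]]
  test$predicted_m <- stats::predict(bm, test)
  sp <- test |>
    dplyr::group_by(.data$time_point) |>
    dplyr::summarise(n = dplyr::n(),
                     spearman = spearman_validation(
                       dplyr::pick(dplyr::everything())),
                     .groups = "drop")
  structure(list(metrics = tibble::as_tibble(metrics), best_family = best,
                 models = models, spearman = sp, predictions = test,
                 train_n = nrow(train)),
            class = "calibration_report")
}

#' @export
print.calibration_report <- function(x, ...) {
  cat(sprintf("<calibration_report> %d families on %d training pairs\n",
              nrow(x$metrics), x$train_n))
  cat(sprintf("  best family: %s (R2 = %.4f, RMSE = %.4f)\n", x$best_family,
              x$metrics$r2[x$metrics$family == x$best_family],
              x$metrics$rmse[x$metrics$family == x$best_family]))
  print(x$spearman)
  invisible(x)
}

#' @method tidy calibration_report
#' @export
tidy.calibration_report <- function(x, ...) x$metrics

#' @method glance calibration_report
#' @export
glance.calibration_report <- function(x, ...) {
  best <- x$metrics[x$metrics$family == x$best_family, ]
  tibble::tibble(best_family = x$best_family, train_n = x$train_n,
                 r2 = best$r2, rmse = best$rmse,
                 spearman_min = min(x$spearman$spearman),
                 spearman_max = max(x$spearman$spearman))
}

#' Persist a closed-form calibration model as JSON
#'
#' Parametric families (polynomials, `lar`, `ridge`, `omp`, `bayes_ridge`)
#' round-trip through a small JSON document; tree ensembles have no
#' closed-form representation and are not supported here.
#'
#' @param model A parametric `calibration_model`.
#' @param path JSON path.
#' @return `save_calibration_json` returns `path` invisibly;
#'   `load_calibration_json` returns a `calibration_model` usable with
#'   [predict()].
#' @export
save_calibration_json <- function(model, path) {
  if (is.null(model$coefficients)) {
    stop("only parametric families can be saved as JSON", call. = FALSE)
  }
  jsonlite::write_json(list(family = model$family,
                            x_name = model$x_name, y_name = model$y_name,
                            training_n = model$training_n,
                            coefficients = model$coefficients),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_calibration_json
#' @export
load_calibration_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  co <- as.numeric(obj$coefficients)
  fam <- obj$family
  if (grepl("^poly", fam)) {
    # rebuild a minimal lm-free polynomial predictor
    m <- new_calibration_model(fam, NULL, obj$x_name, obj$y_name,
                               obj$training_n, list(coefficients = co))
    m$fit <- NULL
    class(m) <- c("calibration_model_json", class(m))
    return(m)
  }
  new_calibration_model(fam, co, obj$x_name, obj$y_name, obj$training_n,
                        list(coefficients = co))
}

#' @export
predict.calibration_model_json <- function(object, newdata, ...) {
  xv <- if (is.numeric(newdata)) newdata
        else rlang::eval_tidy(rlang::sym(object$x_name), newdata)
  drop(outer(xv, seq_along(object$coefficients) - 1, `^`) %*%
         object$coefficients)
}
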