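#' K-means clustering of growth trajectories
#'
#' Lloyd's algorithm with k-means++ seeding, run `n_init` times and keeping
#' the restart with the lowest within-cluster sum of squares. Trajectories
#' are clustered on raw heights in metres (no standardisation): the time
#' points share units and absolute height differences are part of the growth
#' habit being grouped. Missing cells are mean-imputed per time point first.
#'
#' @param series Accession-by-time numeric matrix, or a `plot_height_series`
#'   tibble (its `extracted_m` column is spread to a matrix).
#' @param k Number of clusters.
#' @param seed RNG seed; results are deterministic given the seed.
#' @param n_init Number of restarts.
#' @param impute Mean-impute missing cells per time point before clustering
#'   (`FALSE` raises an error on missing cells).
#' @return A `growth_clusters` object: `assignments` tibble, `centers`
#'   matrix, `wcss`, `k`, `sizes`, `seed`.
#' @export
cluster_growth <- function(series, k, seed = 1L, n_init = 10L,
                           impute = TRUE) {
  m <- as_series_matrix(series)
  if (k < 1) stop("k must be >= 1", call. = FALSE)
  if (k > nrow(m)) stop("k exceeds the number of accessions", call. = FALSE)
  if (anyNA(m)) {
    if (!impute) stop("missing cells present; impute or drop first",
                      call. = FALSE)
    for (j in seq_len(ncol(m))) {
      m[is.na(m[, j]), j] <- mean(m[, j], na.rm = TRUE)
    }
  }
  km <- with_seed(seed, kmeans_pp(m, k, n_init))
  structure(list(
    assignments = tibble::tibble(
      plot_id = rownames(m) %||% sprintf("P%03d", seq_len(nrow(m))),
      cluster = km$cluster),
    centers = km$centers, wcss = km$tot.withinss, k = as.integer(k),
    sizes = as.integer(km$size), seed = as.integer(seed)
  ), class = "growth_clusters")
}

# k-means++ seeding + Lloyd iterations, best of n_init by total WCSS
kmeans_pp <- function(m, k, n_init) {
  u <- unique(m)
  if (nrow(u) <= k) {
    # fewer distinct rows than clusters: every distinct row is a centre
    cl <- match(apply(m, 1, paste, collapse = "\r"),
                apply(u, 1, paste, collapse = "\r"))
    return(list(cluster = cl, centers = u,
                size = as.integer(table(factor(cl, seq_len(nrow(u))))),
                tot.withinss = 0))
  }
  best <- NULL
  for (i in seq_len(n_init)) {
    centers <- m[kmeanspp_seeds(m, k), , drop = FALSE]
    km <- suppressWarnings(
      stats::kmeans(m, centers = centers, iter.max = 100,
                    algorithm = "Lloyd"))
    if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
  }
  best
}

kmeanspp_seeds <- function(m, k) {
  n <- nrow(m)
  idx <- integer(k)
  idx[1] <- sample.int(n, 1)
  if (k == 1) return(idx)
  d2 <- rowSums(sweep(m, 2, m[idx[1], ])^2)
  for (j in 2:k) {
    # d2 > 0 somewhere is guaranteed upstream (more distinct rows than k)
    idx[j] <- sample.int(n, 1, prob = d2 / sum(d2))
    d2 <- pmin(d2, rowSums(sweep(m, 2, m[idx[j], ])^2))
  }
  idx
}

as_series_matrix <- function(series) {
  if (is.matrix(series)) return(series)
  if (inherits(series, "plot_height_series") || is.data.frame(series)) {
    col <- intersect(c("predicted_m", "extracted_m"), names(series))[1]
    return(series_matrix(series, col))
  }
  stop("series must be a matrix or a plot_height_series", call. = FALSE)
}

#' @export
print.growth_clusters <- function(x, ...) {
  cat(sprintf("<growth_clusters> k = %d, WCSS = %.4f, sizes: %s\n",
              x$k, x$wcss, paste(x$sizes, collapse = "/")))
  invisible(x)
}

#' @method tidy growth_clusters
#' @export
tidy.growth_clusters <- function(x, ...) x$assignments

#' @method glance growth_clusters
#' @export
glance.growth_clusters <- function(x, ...) {
  tibble::tibble(k = x$k, wcss = x$wcss, n = sum(x$sizes),
                 min_size = min(x$sizes), max_size = max(x$sizes))
}

#' Within-cluster sum of squares across a range of k
#'
#' The elbow diagnostic: WCSS per candidate k, plus the k at which the
#' second difference of log-WCSS is largest (the sharpest proportional
#' slope change; the log scale keeps the always-huge first drop of a
#' spread-out panel from masking the true elbow). No elbow is suggested
#' when the curve decays smoothly (largest second difference not clearly
#' above the rest) or when fewer than three k values are scanned.
#'
#' @inheritParams cluster_growth
#' @param k_range Candidate cluster counts.
#' @return A tibble `k`, `wcss` with attribute `elbow` (suggested k or `NA`).
#' @export
elbow_curve <- function(series, k_range = 1:10, seed = 1L, n_init = 10L) {
  if (length(k_range) == 0) stop("k_range is empty", call. = FALSE)
  k_range <- sort(unique(as.integer(k_range)))
  wcss <- vapply(k_range, function(k) {
    cluster_growth(series, k, seed = derive_seed(seed, k),
                   n_init = n_init)$wcss
  }, numeric(1))
  out <- tibble::tibble(k = k_range, wcss = wcss)
  elbow <- NA_integer_
  if (length(k_range) >= 3 && all(diff(k_range) == 1)) {
    d2 <- diff(diff(log(pmax(wcss, 1e-12))))   # at interior k values
    if (length(d2)) {
      top <- which.max(d2)
      others <- d2[-top]
      # require the winner to stand clearly above the remaining curvature
      if (!length(others) || d2[top] > 2 * max(others, 0)) {
        elbow <- k_range[top + 1L]
      }
    }
  }
  attr(out, "elbow") <- elbow
  out
}

#' Gap statistic for choosing the number of clusters
#'
#' Tibshirani's gap statistic: `Gap(k) = E*[log W_k] - log W_k`, where the
#' expectation is over `B` reference data sets drawn uniformly over a box
#' aligned with the principal components of the data (Tibshirani's method
#' "b"; growth trajectories are strongly correlated across time points, and
#' a raw feature-wise box would be almost empty of realistic curves). The
#' chosen k is the global maximiser of the gap curve.
#'
#' @inheritParams cluster_growth
#' @param k_range Candidate cluster counts.
#' @param B Number of uniform reference data sets (>= 10 recommended).
#' @return A `gap_result`: tibble `k`, `log_wk`, `e_log_wk`, `gap`, `se`,
#'   plus `chosen_k`.
#' @export
gap_statistic <- function(series, k_range = 1:8, B = 50L, seed = 1L,
                          n_init = 10L) {
  if (B < 1) stop("B must be >= 1", call. = FALSE)
  if (length(k_range) == 0) stop("k_range is empty", call. = FALSE)
  m <- as_series_matrix(series)
  if (anyNA(m)) {
    for (j in seq_len(ncol(m))) m[is.na(m[, j]), j] <- mean(m[, j],
                                                            na.rm = TRUE)
  }
  k_range <- sort(unique(as.integer(k_range)))
  log_wk <- vapply(k_range, function(k) {
    log(with_seed(derive_seed(seed, 17L * k), kmeans_pp(m, k, n_init))
        $tot.withinss)
  }, numeric(1))
  ctr <- colMeans(m)
  mc <- sweep(m, 2, ctr)
  V <- svd(mc, nu = 0)$v
  mp <- mc %*% V                      # PCA-rotated coordinates
  lo <- apply(mp, 2, min); hi <- apply(mp, 2, max)
  ref_log <- with_seed(derive_seed(seed, 977L), {
    vapply(seq_len(B), function(b) {
      refp <- vapply(seq_len(ncol(m)),
                     function(j) stats::runif(nrow(m), lo[j], hi[j]),
                     numeric(nrow(m)))
      ref <- refp %*% t(V)
      vapply(k_range, function(k) {
        log(kmeans_pp(ref, k, max(1L, n_init %/% 2))$tot.withinss)
      }, numeric(1))
    }, numeric(length(k_range)))
  })
  ref_log <- matrix(ref_log, nrow = length(k_range))
  e_log <- rowMeans(ref_log)
  se <- apply(ref_log, 1, stats::sd) * sqrt(1 + 1 / B)
  gap <- e_log - log_wk
  structure(list(
    table = tibble::tibble(k = k_range, log_wk = log_wk, e_log_wk = e_log,
                           gap = gap, se = se),
    chosen_k = k_range[which.max(gap)], B = as.integer(B),
    seed = as.integer(seed)
  ), class = "gap_result")
}

#' @export
print.gap_result <- function(x, ...) {
  cat(sprintf("<gap_result> chosen k = %d (B = %d references)\n",
              x$chosen_k, x$B))
  print(x$table)
  invisible(x)
}

#' @method tidy gap_result
#' @export
tidy.gap_result <- function(x, ...) x$table

#' @method glance gap_result
#' @export
glance.gap_result <- function(x, ...) {
  tibble::tibble(chosen_k = x$chosen_k, B = x$B,
                 max_gap = max(x$table$gap))
}

#' @method autoplot gap_result
#' @export
autoplot.gap_result <- function(object, ...) {
  ggplot2::ggplot(object$table, ggplot2::aes(x = .data$k, y = .data$gap)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$gap - .data$se,
                                          ymax = .data$gap + .data$se)) +
    ggplot2::geom_vline(xintercept = object$chosen_k, linetype = 2) +
    ggplot2::labs(x = "number of clusters k", y = "gap statistic") +
    ggplot2::theme_minimal()
}

#' Per-cluster growth dynamics
#'
#' Mean trajectory, maximum height and time of maximum for each cluster,
#' reported in order of increasing mean growth rate (height gained per day
#' over the observation window).
#'
#' @param clusters A `growth_clusters` object.
#' @param series The matrix or series the clustering was run on.
#' @param times Acquisition days matching the series columns; defaults to
#'   column index.
#' @return A tibble with one row per cluster and a `mean_curve` list-column.
#' @export
cluster_dynamics <- function(clusters, series, times = NULL) {
  m <- as_series_matrix(series)
  if (anyNA(m)) {
    for (j in seq_len(ncol(m))) m[is.na(m[, j]), j] <- mean(m[, j],
                                                            na.rm = TRUE)
  }
  cl <- clusters$assignments$cluster
  stopifnot(length(cl) == nrow(m))
  times <- times %||% seq_len(ncol(m))
  rows <- lapply(sort(unique(cl)), function(g) {
    sub <- m[cl == g, , drop = FALSE]
    if (nrow(sub) == 0) stop("empty cluster", call. = FALSE)
    mu <- unname(colMeans(sub))
    tibble::tibble(
      cluster = g, n = nrow(sub),
      max_height_m = max(mu), time_of_max = times[which.max(mu)],
      growth_rate = (mu[length(mu)] - mu[1]) / (times[length(times)] -
                                                  times[1]),
      mean_curve = list(tibble::tibble(time = times, height_m = mu))
    )
  })
  out <- dplyr::bind_rows(rows)
  out <- out[order(out$growth_rate), ]
  out$rate_rank <- seq_len(nrow(out))
  out
}

#' Adjusted Rand index between two partitions
#'
#' Permutation-invariant agreement between cluster assignments, used to score
#' cluster recovery against generator truth. 1 means identical partitions,
#' ~0 chance agreement.
#'
#' @param a,b Two label vectors of equal length.
#' @return The adjusted Rand index.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- length(a)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  maxidx <- (sum_a + sum_b) / 2
  if (maxidx == expected) return(0)
  (sum_ij - expected) / (maxidx - expected)
}
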