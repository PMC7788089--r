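#' Chemical-space coverage of a test set
#'
#' A trustworthy test set must live inside the region of descriptor
#' space the training data occupies. Both matrices are standardized by
#' the training statistics, a calibration radius r* is set to the
#' `radius_quantile` quantile of train-to-train k-th nearest-neighbor
#' distances, and a test point counts as covered when its k-th nearest
#' training neighbor lies within r*. The statistic is computed in the
#' full descriptor space; 2D embeddings ([embed_2d()]) are for plotting
#' only, since they distort distances.
#'
#' @param x_train,x_test Numeric matrices with identical columns.
#' @param k Neighbor rank. Default 1.
#' @param radius_quantile Calibration quantile. Default 0.95: by
#'   exchangeability, test points drawn from the training distribution
#'   are covered at about this rate.
#' @return A `coverage_report`: `coverage_fraction`, `radius`, `k`,
#'   `radius_quantile`, `covered` (per-test-point logical).
#' @export
coverage_score <- function(x_train, x_test, k = 1, radius_quantile = 0.95) {
  x_train <- as.matrix(x_train); x_test <- as.matrix(x_test)
  if (!identical(colnames(x_train), colnames(x_test))) {
    stop("train and test matrices must share columns")
  }
  if (k >= nrow(x_train)) stop("k must be smaller than the training size")
  center <- colMeans(x_train)
  scale <- apply(x_train, 2, stats::sd)
  scale[scale == 0] <- 1
  st <- function(m) sweep(sweep(m, 2, center), 2, scale, "/")
  tr <- st(x_train); te <- st(x_test)
  dtr <- as.matrix(stats::dist(tr))
  diag(dtr) <- Inf
  kth <- function(v) sort(v, partial = k)[k]
  d_train <- apply(dtr, 1, kth)
  r_star <- stats::quantile(d_train, radius_quantile, names = FALSE)
  dte <- cross_dist(te, tr)
  d_test <- apply(dte, 1, kth)
  covered <- d_test <= r_star
  structure(list(coverage_fraction = mean(covered), radius = r_star,
                 k = k, radius_quantile = radius_quantile,
                 n_train = nrow(tr), n_test = nrow(te), covered = covered),
            class = "coverage_report")
}

cross_dist <- function(a, b) {
  sq <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  sq[sq < 0] <- 0
  sqrt(sq)
}

#' @export
print.coverage_report <- function(x, ...) {
  cat(sprintf("<coverage_report> %.1f%% of %d test points within r* = %.3f (k = %d, q = %.2f, n_train = %d)\n",
              100 * x$coverage_fraction, x$n_test, x$radius, x$k,
              x$radius_quantile, x$n_train))
  invisible(x)
}

#' Compatibility of solubility distributions
#'
#' Two-sample Kolmogorov-Smirnov comparison of the train and test LogS
#' distributions. A test set whose target distribution departs from the
#' training one measures extrapolation, not accuracy.
#'
#' @param y_train,y_test Non-empty numeric vectors of LogS values.
#' @param threshold Maximum KS statistic D for a pass. Default 0.15.
#' @return List with `D`, `p_value`, `threshold` and `pass`.
#' @export
distribution_compat <- function(y_train, y_test, threshold = 0.15) {
  stopifnot(length(y_train) > 0, length(y_test) > 0)
  ks <- suppressWarnings(stats::ks.test(y_train, y_test))
  list(D = unname(ks$statistic), p_value = unname(ks$p.value),
       threshold = threshold, pass = unname(ks$statistic) <= threshold)
}
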