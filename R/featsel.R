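#' LASSO feature selection
#'
#' Fits an L1-penalized linear model over a logarithmic penalty grid
#' (100 points spanning four decades below the smallest penalty that
#' zeroes every coefficient), picks the penalty minimizing k-fold
#' cross-validated error, and returns the features with nonzero
#' coefficients, ordered by decreasing absolute coefficient. Features
#' are standardized internally, so selection is invariant to affine
#' rescaling of any input column.
#'
#' @param x Numeric feature matrix (n x p) with column names.
#' @param y Numeric response (LogS).
#' @param folds Number of CV folds (>= 2). Default 5.
#' @param seed Integer seed controlling the fold assignment.
#' @param rule Penalty choice: `"min"` (CV-error minimizer, default) or
#'   `"1se"` (largest penalty within one SE of the minimum).
#' @return A `feature_selection` object: list with `method`, `selected`
#'   (ordered names), `diagnostics` (name, coefficient), and
#'   `hyperparameters`.
#' @export
lasso_select <- function(x, y, folds = 5, seed = 1, rule = c("min", "1se")) {
  rule <- match.arg(rule)
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  stopifnot(nrow(x) == length(y), nrow(x) >= folds, folds >= 2)
  if (stats::sd(y) == 0) {
    warning("constant target: no feature carries information")
    return(new_feature_selection("lasso", character(),
                                 data.frame(name = character(),
                                            coefficient = numeric()),
                                 list(folds = folds, seed = seed, rule = rule)))
  }
  set.seed(seed)
  foldid <- sample(rep(seq_len(folds), length.out = nrow(x)))
  cv <- glmnet::cv.glmnet(x, y, foldid = foldid, nlambda = 100,
                          lambda.min.ratio = 1e-4, standardize = TRUE)
  lam <- if (rule == "min") cv$lambda.min else cv$lambda.1se
  beta <- stats::coef(cv, s = lam)[-1, 1]
  nz <- beta[beta != 0]
  ord <- order(abs(nz), decreasing = TRUE)
  new_feature_selection(
    "lasso",
    names(nz)[ord],
    data.frame(name = names(nz)[ord], coefficient = unname(nz)[ord],
               stringsAsFactors = FALSE),
    list(folds = folds, seed = seed, rule = rule, lambda = lam))
}

new_feature_selection <- function(method, selected, diagnostics, hyper) {
  structure(list(method = method, selected = selected,
                 diagnostics = diagnostics, hyperparameters = hyper),
            class = "feature_selection")
}

#' @export
print.feature_selection <- function(x, ...) {
  cat(sprintf("<feature_selection: %s> %d features\n", x$method,
              length(x$selected)))
  if (length(x$selected)) {
    cat("  ", paste(utils::head(x$selected, 10), collapse = ", "),
        if (length(x$selected) > 10) ", ..." else "", "\n", sep = "")
  }
  invisible(x)
}

#' Pearson-correlation feature selection
#'
#' Ranks features by absolute Pearson correlation with the target,
#' keeps the top `k` (or all with |r| above `threshold`), then greedily
#' drops any feature correlating above `redundancy_r` with an
#' already-kept, higher-ranked feature. Zero-variance features are
#' treated as having zero correlation.
#'
#' @param x Numeric feature matrix with column names.
#' @param y Numeric response.
#' @param k Number of features to keep; overrides `threshold` when given.
#' @param threshold Minimum |r| with the target. Default 0.1.
#' @param redundancy_r Maximum allowed |r| between kept features.
#'   Default 0.95.
#' @return A `feature_selection` object with per-feature correlations as
#'   diagnostics.
#' @export
pcc_select <- function(x, y, k = NULL, threshold = 0.1, redundancy_r = 0.95) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  stopifnot(nrow(x) == length(y), nrow(x) >= 3)
  r <- apply(x, 2, function(col) {
    if (stats::sd(col) == 0 || stats::sd(y) == 0) 0
    else stats::cor(col, y)
  })
  ord <- order(abs(r), decreasing = TRUE)
  candidates <- if (!is.null(k)) ord[seq_len(min(k, length(ord)))]
                else ord[abs(r[ord]) >= threshold]
  kept <- integer()
  for (j in candidates) {
    redundant <- length(kept) &&
      any(abs(suppressWarnings(stats::cor(x[, j], x[, kept, drop = FALSE]))) >
            redundancy_r, na.rm = TRUE)
    if (!redundant) kept <- c(kept, j)
  }
  new_feature_selection(
    "pcc",
    colnames(x)[kept],
    data.frame(name = colnames(x)[kept], correlation = unname(r[kept]),
               stringsAsFactors = FALSE),
    list(k = k, threshold = threshold, redundancy_r = redundancy_r))
}
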