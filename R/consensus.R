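#' Member configuration for the consensus model
#'
#' Defaults: a single-hidden-layer neural network of 100 units trained
#' with early stopping on a 10\% validation split; a 500-tree random
#' forest; and 500 rounds of gradient boosting at learning rate 0.05
#' with early stopping on a 10\% validation split. All three are
#' exposed here so that desk-scale experiments can run lighter members.
#'
#' @param ann,rf,xgb Named lists overriding individual member settings.
#' @return A `consensus_config` list.
#' @export
consensus_config <- function(ann = list(), rf = list(), xgb = list()) {
  defaults <- list(
    ann = list(size = 100, decay = 1e-4, chunk = 50, max_chunks = 12,
               patience = 2, val_frac = 0.1),
    rf = list(num_trees = 500, mtry = NULL, min_node_size = 5),
    xgb = list(nrounds = 500, eta = 0.05, max_depth = 6, subsample = 0.8,
               early_stopping_rounds = 25, val_frac = 0.1))
  defaults$ann[names(ann)] <- ann
  defaults$rf[names(rf)] <- rf
  defaults$xgb[names(xgb)] <- xgb
  structure(defaults, class = "consensus_config")
}

#' A light configuration for repeated desk-scale experiments
#'
#' Same architecture, smaller members (16-unit network, 300 trees, 300
#' boosting rounds at rate 0.1); used by the simulation experiments that
#' retrain the consensus tens of times.
#'
#' @return A `consensus_config`.
#' @export
consensus_config_light <- function() {
  consensus_config(ann = list(size = 16, chunk = 60, max_chunks = 5),
                   rf = list(num_trees = 300),
                   xgb = list(nrounds = 300, eta = 0.1,
                              early_stopping_rounds = 15))
}

member_seed <- function(seed, member) seed + c(ann = 101L, rf = 202L, xgb = 303L)[[member]]

fit_ann <- function(x, y, cfg, seed) {
  set.seed(seed)
  n <- nrow(x)
  n_val <- max(1L, round(cfg$val_frac * n))
  val <- sample.int(n, n_val)
  xt <- x[-val, , drop = FALSE]; yt <- y[-val]
  xv <- x[val, , drop = FALSE]; yv <- y[val]
  nw <- (ncol(x) + 1L) * cfg$size + cfg$size + 1L
  best <- NULL; best_rmse <- Inf; stale <- 0L; wts <- NULL
  for (i in seq_len(cfg$max_chunks)) {
    args <- list(x = xt, y = yt, size = cfg$size, linout = TRUE,
                 decay = cfg$decay, maxit = cfg$chunk, trace = FALSE,
                 MaxNWts = nw + 10L)
    if (!is.null(wts)) args$Wts <- wts
    fit <- do.call(nnet::nnet, args)
    wts <- fit$wts
    rmse <- sqrt(mean((stats::predict(fit, xv) - yv)^2))
    if (rmse < best_rmse - 1e-8) {
      best <- fit; best_rmse <- rmse; stale <- 0L
    } else {
      stale <- stale + 1L
      if (stale >= cfg$patience) break
    }
  }
  best
}

#' Train the ANN/RF/XGB consensus model
#'
#' Fits the three member regressors on identical standardized training
#' data and returns them as one `consensus_model`. All randomness (ANN
#' initialisation and validation split, forest bootstraps, boosting
#' subsampling) derives from `seed` through fixed per-member offsets,
#' so the same call reproduces the same model bit-for-bit.
#'
#' @param x Numeric feature matrix (n >= 20 rows) with column names.
#' @param y Numeric LogS targets, finite, non-constant.
#' @param config A [consensus_config()].
#' @param seed Integer pipeline seed.
#' @return A `consensus_model` with members, the feature standardization
#'   parameters fitted on `x`, per-member in-sample errors in
#'   `training_log`, and in-sample consensus fits in `fitted`.
#' @seealso [predict.consensus_model()], [evaluate()], [cross_validate()]
#' @export
train_consensus <- function(x, y, config = consensus_config(), seed = 1) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  if (nrow(x) < 20L) stop("need at least 20 training rows")
  if (length(y) != nrow(x)) stop("length(y) != nrow(x)")
  bad_rows <- which(!stats::complete.cases(x) | !is.finite(y))
  if (length(bad_rows)) {
    stop("non-finite entries in rows: ",
         paste(utils::head(bad_rows, 10), collapse = ", "))
  }
  if (stats::sd(y) == 0) stop("degenerate target: zero variance")
  center <- colMeans(x)
  scale <- apply(x, 2, stats::sd)
  scale[scale == 0] <- 1
  xs <- sweep(sweep(x, 2, center), 2, scale, "/")

  ann <- fit_ann(xs, y, config$ann, member_seed(seed, "ann"))
  rf <- ranger::ranger(y = y, x = as.data.frame(xs),
                       num.trees = config$rf$num_trees,
                       # p/3 is the usual regression default; ranger's own
                       # default (sqrt(p)) is the classification convention
                       mtry = config$rf$mtry %||% max(1L, floor(ncol(xs) / 3)),
                       min.node.size = config$rf$min_node_size,
                       seed = member_seed(seed, "rf"), num.threads = 1)
  xcfg <- config$xgb
  set.seed(member_seed(seed, "xgb"))
  n <- nrow(xs)
  n_val <- max(1L, round(xcfg$val_frac * n))
  val <- sample.int(n, n_val)
  dtrain <- xgboost::xgb.DMatrix(xs[-val, , drop = FALSE], label = y[-val])
  dval <- xgboost::xgb.DMatrix(xs[val, , drop = FALSE], label = y[val])
  xgb <- xgboost::xgb.train(
    params = list(eta = xcfg$eta, max_depth = xcfg$max_depth,
                  subsample = xcfg$subsample, nthread = 1,
                  seed = member_seed(seed, "xgb"),
                  objective = "reg:squarederror"),
    data = dtrain, nrounds = xcfg$nrounds,
    evals = list(val = dval),
    early_stopping_rounds = xcfg$early_stopping_rounds, verbose = 0)

  model <- structure(
    list(members = list(ann = ann, rf = rf, xgb = xgb),
         feature_names = colnames(x),
         scaler = list(center = center, scale = scale),
         seed = seed, config = config, y = y, call = match.call()),
    class = "consensus_model")
  fit <- predict(model, x)
  model$fitted <- fit$mean
  model$training_log <- data.frame(
    member = c("ann", "rf", "xgb", "consensus"),
    rmse = c(sqrt(mean((fit$ann - y)^2)), sqrt(mean((fit$rf - y)^2)),
             sqrt(mean((fit$xgb - y)^2)), sqrt(mean((fit$mean - y)^2))))
  model
}

#' Aggregate member predictions into consensus and uncertainty
#'
#' The aggregation contract of the consensus model: the prediction is
#' the unweighted arithmetic mean of the member predictions and the
#' uncertainty is their n-1 sample standard deviation. Exposed so the
#' contract can be exercised on raw member values; [predict.consensus_model()]
#' routes through this function.
#'
#' @param members Numeric matrix (rows = compounds, columns = members)
#'   or a vector of one compound's member predictions.
#' @return Data frame with `mean` and `uncertainty`.
#' @export
consensus_aggregate <- function(members) {
  m <- if (is.matrix(members)) members else matrix(members, nrow = 1)
  data.frame(mean = rowMeans(m), uncertainty = apply(m, 1, stats::sd))
}

member_predict <- function(model, xs) {
  cbind(ann = as.numeric(stats::predict(model$members$ann, xs)),
        rf = stats::predict(model$members$rf, as.data.frame(xs),
                            num.threads = 1)$predictions,
        xgb = stats::predict(model$members$xgb, xgboost::xgb.DMatrix(xs)))
}

#' Predict LogS with uncertainty
#'
#' The consensus prediction is the unweighted mean of the three member
#' predictions; its uncertainty is their n-1 sample standard deviation,
#' which tracks how strongly the members disagree on a compound.
#'
#' @param object A `consensus_model`.
#' @param newdata Matrix or data frame whose columns match the model's
#'   `feature_names` (order-insensitive; mismatches are an error naming
#'   the missing/extra columns).
#' @param ... Unused.
#' @return Data frame with `mean`, `uncertainty`, and member columns
#'   `ann`, `rf`, `xgb`.
#' @export
predict.consensus_model <- function(object, newdata, ...) {
  x <- as.matrix(newdata)
  if (is.null(colnames(x)) && ncol(x) == length(object$feature_names)) {
    colnames(x) <- object$feature_names
  }
  missing <- setdiff(object$feature_names, colnames(x))
  extra <- setdiff(colnames(x), object$feature_names)
  if (length(missing) || length(extra)) {
    stop("feature mismatch; missing: [",
         paste(missing, collapse = ", "), "], extra: [",
         paste(extra, collapse = ", "), "]")
  }
  x <- x[, object$feature_names, drop = FALSE]
  xs <- sweep(sweep(x, 2, object$scaler$center), 2, object$scaler$scale, "/")
  m <- member_predict(object, xs)
  out <- data.frame(consensus_aggregate(m), m)
  rownames(out) <- rownames(newdata)
  out
}

#' @export
print.consensus_model <- function(x, ...) {
  cat("Consensus solubility model (ANN + RF + XGB)\n")
  cat(sprintf("  %d features, %d training compounds, seed %d\n",
              length(x$feature_names), length(x$y), x$seed))
  cat("  in-sample RMSE (LogS):",
      paste(sprintf("%s %.3f", x$training_log$member, x$training_log$rmse),
            collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.consensus_model <- function(object, ...) {
  res <- stats::residuals(object)
  structure(list(training_log = object$training_log,
                 n = length(object$y),
                 p = length(object$feature_names),
                 seed = object$seed,
                 resid_quantiles = stats::quantile(res)),
            class = "summary.consensus_model")
}

#' @export
print.summary.consensus_model <- function(x, ...) {
  cat(sprintf("Consensus model: %d compounds x %d descriptors (seed %d)\n",
              x$n, x$p, x$seed))
  cat("In-sample errors (LogS):\n")
  print(x$training_log, row.names = FALSE)
  cat("Residual quantiles:\n")
  print(round(x$resid_quantiles, 4))
  invisible(x)
}

#' @export
residuals.consensus_model <- function(object, ...) {
  object$y - object$fitted
}

#' Observed-vs-fitted plot with uncertainty shading
#'
#' @param x A `consensus_model`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.consensus_model <- function(x, ...) {
  graphics::plot(x$fitted, x$y, xlab = "fitted LogS", ylab = "observed LogS",
                 pch = 16, col = grDevices::grey(0.3, 0.5), ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}

#' Regression error metrics
#'
#' @param predicted,observed Equal-length numeric vectors (n >= 2).
#' @return A `solubility_metrics` list: `mae` (mean absolute error),
#'   `rmse` (root mean squared error), `r2` (1 - SSE/SST about the
#'   observed mean) and `n`.
#' @export
evaluate <- function(predicted, observed) {
  if (length(predicted) != length(observed)) stop("length mismatch")
  if (length(observed) < 2L) stop("need at least 2 observations")
  d <- predicted - observed
  sst <- sum((observed - mean(observed))^2)
  structure(list(mae = mean(abs(d)),
                 rmse = sqrt(mean(d^2)),
                 r2 = 1 - sum(d^2) / sst,
                 n = length(observed)),
            class = "solubility_metrics")
}

#' @export
print.solubility_metrics <- function(x, ...) {
  cat(sprintf("MAE %.3f  RMSE %.3f  R2 %.3f  (n = %d, LogS units)\n",
              x$mae, x$rmse, x$r2, x$n))
  invisible(x)
}

#' Cross-validate the consensus model
#'
#' Out-of-fold predictions are assembled over all rows and evaluated
#' once globally. When a `selector` is supplied, feature selection is
#' refit inside each training fold so the held-out rows never influence
#' which descriptors are used.
#'
#' @param x Feature matrix.
#' @param y LogS targets.
#' @param scheme `"kfold"` or `"loo"` (leave-one-out; each compound
#'   predicted by a model trained on all others).
#' @param k Number of folds for `"kfold"`. Default 10.
#' @param config Member configuration.
#' @param seed Seed for fold assignment and member training.
#' @param selector Optional `function(x, y)` returning a
#'   `feature_selection` to apply per fold.
#' @param loo_block For `"loo"`, train one model per block of this many
#'   held-out compounds instead of per compound (an explicit
#'   approximation for smoke runs); 1 = exact LOO.
#' @return List with `metrics` (global [evaluate()]), `predictions`
#'   (per-row out-of-fold mean/uncertainty/fold) and `folds`.
#' @export
cross_validate <- function(x, y, scheme = c("kfold", "loo"), k = 10,
                           config = consensus_config(), seed = 1,
                           selector = NULL, loo_block = 1L) {
  scheme <- match.arg(scheme)
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  n <- nrow(x)
  if (scheme == "kfold") {
    if (k > n) stop("k > n")
    set.seed(seed)
    fold <- sample(rep(seq_len(k), length.out = n))
  } else {
    if (n < 2L) stop("need n >= 2 for loo")
    set.seed(seed)
    fold <- if (loo_block > 1L) {
      sample(rep(seq_len(ceiling(n / loo_block)), length.out = n))
    } else seq_len(n)
  }
  pred <- unc <- rep(NA_real_, n)
  sel_sizes <- integer()
  for (f in sort(unique(fold))) {
    test <- fold == f
    xtr <- x[!test, , drop = FALSE]; ytr <- y[!test]
    xte <- x[test, , drop = FALSE]
    if (!is.null(selector)) {
      sel <- selector(xtr, ytr)
      keep <- sel$selected
      if (length(keep) == 0L) keep <- colnames(x)
      sel_sizes <- c(sel_sizes, length(keep))
      xtr <- xtr[, keep, drop = FALSE]
      xte <- xte[, keep, drop = FALSE]
    }
    m <- train_consensus(xtr, ytr, config = config, seed = seed + f)
    p <- predict(m, xte)
    pred[test] <- p$mean
    unc[test] <- p$uncertainty
  }
  list(metrics = evaluate(pred, y),
       predictions = data.frame(fold = fold, mean = pred, uncertainty = unc,
                                observed = y),
       folds = sort(unique(fold)),
       selected_per_fold = sel_sizes)
}
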