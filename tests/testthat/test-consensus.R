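# tiny member settings for scheme-mechanics tests where model quality
# is irrelevant
tiny_config <- consensus_config(
  ann = list(size = 2, chunk = 10, max_chunks = 2),
  rf = list(num_trees = 50),
  xgb = list(nrounds = 30, eta = 0.3, early_stopping_rounds = 5))

sim_xy <- function(n, p = 6, noise = 0.3, seed = 1) {
  set.seed(seed)
  x <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("x", 1:p)))
  list(x = x, y = drop(x %*% c(1.5, -1, 0.8, rep(0, p - 3))) +
         rnorm(n, 0, noise))
}

test_that("metrics match hand-computable cases and their identities", {
  m <- evaluate(c(1, 2, 3), c(1, 2, 3))
  expect_equal(c(m$mae, m$rmse, m$r2), c(0, 0, 1))
  obs <- c(0, 1, 2, 5)
  m <- evaluate(rep(mean(obs), 4), obs)
  expect_equal(m$r2, 0)
  m <- evaluate(c(0, 0), c(1, -1))
  expect_equal(c(m$mae, m$rmse, m$r2), c(1, 1, 0))
  expect_error(evaluate(1:3, 1:4), "length")
  expect_error(evaluate(1, 1), "at least 2")
  set.seed(4)
  for (i in 1:20) {
    a <- rnorm(10); b <- rnorm(10)
    m <- evaluate(a, b)
    expect_lte(m$mae, m$rmse)
    expect_lte(m$r2, 1)
  }
})

test_that("aggregation is the member mean with sample-SD uncertainty", {
  agg <- consensus_aggregate(c(1, 2, 3))
  expect_equal(agg$mean, 2.0)
  expect_equal(agg$uncertainty, 1.0)
  agg <- consensus_aggregate(matrix(c(1, 1, 1), 1))
  expect_equal(agg$uncertainty, 0)
  m <- matrix(rnorm(30), 10, 3)
  agg <- consensus_aggregate(m)
  expect_equal(agg$mean, rowMeans(m))
  expect_true(all(agg$uncertainty >= 0))
})

test_that("training is seeded-deterministic and beats the constant fit", {
  d <- sim_xy(200, seed = 5)
  m1 <- train_consensus(d$x, d$y, tiny_config, seed = 7)
  m2 <- train_consensus(d$x, d$y, tiny_config, seed = 7)
  probe <- sim_xy(50, seed = 6)$x
  expect_equal(predict(m1, probe), predict(m2, probe))
  expect_lt(m1$training_log$rmse[m1$training_log$member == "consensus"],
            sd(d$y))
})

test_that("degenerate inputs are refused with informative errors", {
  d <- sim_xy(30, seed = 8)
  expect_error(train_consensus(d$x[1:10, ], d$y[1:10], tiny_config), "20")
  expect_error(train_consensus(d$x, rep(2, 30), tiny_config), "zero variance")
  xbad <- d$x; xbad[3, 2] <- NA
  expect_error(train_consensus(xbad, d$y, tiny_config), "rows: 3")
})

test_that("prediction validates the feature contract", {
  d <- sim_xy(40, seed = 9)
  m <- train_consensus(d$x, d$y, tiny_config, seed = 1)
  p <- predict(m, d$x)
  expect_equal(p$mean, rowMeans(p[, c("ann", "rf", "xgb")]))
  expect_equal(p$uncertainty,
               apply(p[, c("ann", "rf", "xgb")], 1, sd))
  shuffled <- d$x[, rev(colnames(d$x))]
  expect_equal(predict(m, shuffled), p)
  expect_error(predict(m, d$x[, 1:3]), "missing.*x4")
  xtra <- cbind(d$x, zz = 1)
  expect_error(predict(m, xtra), "extra.*zz")
})

test_that("model methods expose fit quality and residuals", {
  d <- sim_xy(60, seed = 10)
  m <- train_consensus(d$x, d$y, tiny_config, seed = 2)
  expect_equal(residuals(m), d$y - m$fitted)
  s <- summary(m)
  expect_s3_class(s, "summary.consensus_model")
  expect_output(print(m), "Consensus")
  expect_output(print(s), "Residual quantiles")
})

test_that("the consensus never trails the worst member on held-out data", {
  for (s in 1:3) {
    d <- sim_xy(300, seed = 20 + s)
    m <- train_consensus(d$x[1:200, ], d$y[1:200], tiny_config, seed = s)
    p <- predict(m, d$x[201:300, ])
    truth <- d$y[201:300]
    rmse <- function(v) sqrt(mean((v - truth)^2))
    expect_lte(rmse(p$mean),
               max(rmse(p$ann), rmse(p$rf), rmse(p$xgb)) + 1e-12)
  }
})

test_that("high-uncertainty predictions carry larger errors", {
  gaps <- sapply(1:3, function(s) {
    u <- generate_universe(synth_config(n_compounds = 700, seed = 30 + s))
    y <- corrupt_test_labels(u$true_logs, 0.3, seed = s)
    m <- train_consensus(u$descriptors[1:400, ], y[1:400],
                         consensus_config_light(), seed = s)
    p <- predict(m, u$descriptors[401:700, ])
    err <- abs(p$mean - u$true_logs[401:700])
    q <- quantile(p$uncertainty, c(0.1, 0.9))
    mean(err[p$uncertainty >= q[2]]) - mean(err[p$uncertainty <= q[1]])
  })
  expect_gt(mean(gaps), 0)
  expect_gte(sum(gaps > 0), 2L)
})

test_that("k-fold assembles exactly one out-of-fold prediction per row", {
  d <- sim_xy(100, seed = 40)
  cv <- cross_validate(d$x, d$y, "kfold", k = 10, config = tiny_config,
                       seed = 3)
  expect_equal(sort(unique(cv$predictions$fold)), 1:10)
  expect_true(all(is.finite(cv$predictions$mean)))
  expect_equal(as.vector(table(cv$predictions$fold)), rep(10L, 10))
  expect_error(cross_validate(d$x[1:5, ], d$y[1:5], "kfold", k = 10,
                              config = tiny_config), "k > n")
})

test_that("leave-one-out trains on all but one compound per fold", {
  d <- sim_xy(24, seed = 41)
  cv <- cross_validate(d$x, d$y, "loo", config = tiny_config, seed = 1)
  expect_length(cv$folds, 24L)
  expect_true(all(is.finite(cv$predictions$mean)))
  blocked <- cross_validate(d$x, d$y, "loo", config = tiny_config, seed = 1,
                            loo_block = 4L)
  expect_lte(length(blocked$folds), 6L)
})

test_that("fold-wise feature selection is refit inside each training fold", {
  d <- sim_xy(120, p = 8, seed = 42)
  cv <- cross_validate(d$x, d$y, "kfold", k = 4, config = tiny_config,
                       seed = 2,
                       selector = function(x, y) lasso_select(x, y, seed = 1))
  expect_length(cv$selected_per_fold, 4L)
  expect_true(all(cv$selected_per_fold <= 8))
  expect_true(all(is.finite(cv$predictions$mean)))
})

test_that("cross-validated error sits in the pilot band above the noise floor", {
  for (s in 1:2) {
    u <- generate_universe(synth_config(n_compounds = 1200, seed = s))
    y <- corrupt_test_labels(u$true_logs, 0.3, seed = s + 50)
    cv <- cross_validate(u$descriptors, y, "kfold", k = 10,
                         config = consensus_config_light(), seed = s)
    expect_gte(cv$metrics$rmse, 0.3)
    expect_lte(cv$metrics$rmse, 0.65)
  }
})

test_that("model archives round-trip and reject corruption", {
  d <- sim_xy(40, seed = 50)
  m <- train_consensus(d$x, d$y, tiny_config, seed = 4)
  f <- tempfile(fileext = ".rds")
  save_model_archive(m, f)
  back <- load_model_archive(f)
  expect_equal(predict(back, d$x), predict(m, d$x))
  bad <- tempfile(fileext = ".rds")
  saveRDS(list(1), bad)
  expect_error(load_model_archive(bad), "corrupt")
  expect_error(load_model_archive(tempfile()), "not found")
})
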