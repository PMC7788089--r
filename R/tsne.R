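# Exact t-SNE (O(n^2)), sufficient for the desk-scale visual diagnostics
# this package produces; deterministic given the seed.

tsne_affinities <- function(x, perplexity) {
  n <- nrow(x)
  d2 <- as.matrix(stats::dist(x))^2
  target <- log(perplexity)
  P <- matrix(0, n, n)
  for (i in seq_len(n)) {
    di <- d2[i, -i]
    if (all(di == 0)) {
      P[i, -i] <- 1 / (n - 1)
      next
    }
    lo <- -Inf; hi <- Inf; beta <- 1
    for (iter in 1:50) {
      w <- exp(-di * beta)
      sw <- sum(w)
      if (sw == 0) { hi <- beta; beta <- if (is.finite(lo)) (lo + beta) / 2 else beta / 2; next }
      p <- w / sw
      h <- -sum(p[p > 0] * log(p[p > 0]))
      if (abs(h - target) < 1e-5) break
      if (h > target) { lo <- beta; beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2 }
      else { hi <- beta; beta <- if (is.finite(lo)) (lo + beta) / 2 else beta / 2 }
    }
    P[i, -i] <- w / sum(w)
  }
  P <- (P + t(P)) / (2 * n)
  pmax(P, 1e-12)
}

tsne_embed <- function(x, perplexity = 30, seed = 1, max_iter = 500) {
  n <- nrow(x)
  P <- tsne_affinities(x, perplexity)
  set.seed(seed)
  y <- matrix(stats::rnorm(n * 2, sd = 1e-4), n, 2)
  vel <- matrix(0, n, 2)
  gains <- matrix(1, n, 2)
  # learning rate scaled with n (the n/12 heuristic); a fixed large rate
  # diverges on tiny inputs where pairwise affinities are O(1)
  eta <- max(0.2, n / 12)
  for (iter in seq_len(max_iter)) {
    ex <- if (iter <= 100) 4 else 1  # early exaggeration
    d2 <- as.matrix(stats::dist(y))^2
    num <- 1 / (1 + d2)
    diag(num) <- 0
    Q <- pmax(num / sum(num), 1e-12)
    L <- (ex * P - Q) * num
    grad <- 4 * (diag(rowSums(L)) - L) %*% y
    mom <- if (iter <= 250) 0.5 else 0.8
    gains <- ifelse(sign(grad) != sign(vel), gains + 0.2, gains * 0.8)
    gains[gains < 0.01] <- 0.01
    vel <- mom * vel - eta * gains * grad
    y <- y + vel
    y <- sweep(y, 2, colMeans(y))
  }
  y
}

#' 2D embedding of the chemical space (t-SNE)
#'
#' Embeds training and test descriptor rows together with exact
#' t-distributed stochastic neighbor embedding, for visual inspection
#' of how the test compounds sit inside the training chemical space.
#' Visualization only: the quantitative coverage check is
#' [coverage_score()], computed in full descriptor space.
#'
#' @param x_train Descriptor matrix for training compounds.
#' @param x_test Optional matrix for test compounds (same columns).
#' @param perplexity t-SNE perplexity; combined n must be at least
#'   3 x perplexity.
#' @param seed Seed; identical seeds give identical coordinates.
#' @param max_iter Gradient-descent iterations. Default 500.
#' @return Data frame with `dim1`, `dim2` and `set` ("train"/"test").
#' @export
embed_2d <- function(x_train, x_test = NULL, perplexity = 30, seed = 1,
                     max_iter = 500) {
  x_train <- as.matrix(x_train)
  x <- if (is.null(x_test)) x_train else {
    x_test <- as.matrix(x_test)
    if (!identical(colnames(x_train), colnames(x_test))) {
      stop("train and test matrices must share columns")
    }
    rbind(x_train, x_test)
  }
  if (nrow(x) < 3 * perplexity) {
    stop("perplexity too large: need n >= 3 * perplexity (n = ", nrow(x), ")")
  }
  y <- tsne_embed(x, perplexity = perplexity, seed = seed,
                  max_iter = max_iter)
  data.frame(dim1 = y[, 1], dim2 = y[, 2],
             set = rep(c("train", "test"),
                       c(nrow(x_train), nrow(x) - nrow(x_train))),
             stringsAsFactors = FALSE)
}
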