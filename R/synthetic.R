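#' Configuration for the synthetic multi-source generator
#'
#' The generator emulates the structure of a multi-source solubility
#' database: several sources with distinct measurement noise levels,
#' partially overlapping compound coverage (the multi-lab groups that
#' drive quality estimation), verbatim cross-source duplicates, and
#' misprint-style corruptions (decade shifts of +/- 1 log unit and sign
#' flips). Defaults describe four sources of clearly graded quality
#' (noise SDs 0.7, 0.4, 0.3, 0.25 LogS, spanning the range observed
#' across public solubility sources), half coverage per source, and a
#' sparse linear truth over 20 standard-normal descriptors with a mild
#' quadratic term and intercept -3 (so true LogS has mean about -3 and
#' SD about 2, the scale typical of aqueous solubility tables).
#'
#' @param n_compounds Number of compounds in the universe.
#' @param n_sources Number of sources (>= 2 for multi-lab structure).
#' @param sigma Per-source noise SD in LogS (recycled to `n_sources`).
#' @param bias Per-source additive offset in LogS (recycled).
#' @param overlap Probability each source measures each compound.
#' @param dup_rate Probability a measurement is replaced by a verbatim
#'   copy of another source's measurement of the same compound.
#' @param misprint_rate Probability a measurement is corrupted.
#' @param misprint_kinds Subset of `c("decade-shift", "sign-flip")`.
#' @param n_descriptors Number of synthetic descriptors.
#' @param truth_coef Coefficient vector of the sparse linear truth;
#'   default `c(1.5, -1, 0.8, -0.6, 0.5, 0, ...)`.
#' @param quadratic Coefficient of the mild quadratic term (on the
#'   second descriptor). 0 disables the nonlinearity.
#' @param intercept True LogS intercept. Default -3.
#' @param epsilon Test-label corruption SD for observed-performance
#'   experiments.
#' @param seed Integer seed; every downstream draw derives from it.
#' @return A validated `synth_config` list.
#' @export
synth_config <- function(n_compounds = 2000, n_sources = 4,
                         sigma = c(0.7, 0.4, 0.3, 0.25), bias = 0,
                         overlap = 0.5, dup_rate = 0, misprint_rate = 0,
                         misprint_kinds = c("decade-shift", "sign-flip"),
                         n_descriptors = 20, truth_coef = NULL,
                         quadratic = 0.3, intercept = -3, epsilon = 0,
                         seed = 1) {
  stopifnot(n_compounds >= 0, n_sources >= 2,
            all(sigma >= 0), overlap >= 0, overlap <= 1,
            dup_rate >= 0, dup_rate <= 1,
            misprint_rate >= 0, misprint_rate <= 1,
            all(misprint_kinds %in% c("decade-shift", "sign-flip")),
            epsilon >= 0)
  if (is.null(truth_coef)) {
    truth_coef <- c(1.5, -1, 0.8, -0.6, 0.5,
                    rep(0, max(0, n_descriptors - 5)))[seq_len(n_descriptors)]
  }
  stopifnot(length(truth_coef) == n_descriptors)
  structure(list(n_compounds = n_compounds, n_sources = n_sources,
                 sigma = rep(sigma, length.out = n_sources),
                 bias = rep(bias, length.out = n_sources),
                 overlap = overlap, dup_rate = dup_rate,
                 misprint_rate = misprint_rate,
                 misprint_kinds = misprint_kinds,
                 n_descriptors = n_descriptors, truth_coef = truth_coef,
                 quadratic = quadratic, intercept = intercept,
                 epsilon = epsilon, seed = as.integer(seed)),
            class = "synth_config")
}

random_inchikey <- function(n) {
  block <- function(k) {
    apply(matrix(sample(LETTERS, n * k, replace = TRUE), n, k), 1,
          paste, collapse = "")
  }
  paste0(block(14), "-", block(10), "-", block(1))
}

#' Generate a synthetic compound universe
#'
#' Draws descriptor vectors (independent standard normals), computes
#' the true LogS from the configured sparse linear + quadratic truth
#' model, and assigns unique InChIKey-shaped identity keys so the real
#' pipeline code paths (grouping, leakage checks) run unmodified.
#'
#' @param config A [synth_config()].
#' @return A `synthetic_universe`: list with `keys`, `descriptors`
#'   (n x p matrix), `true_logs` and the `config`.
#' @export
generate_universe <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  n <- config$n_compounds
  p <- config$n_descriptors
  keys <- character(0)
  while (length(keys) < n) {
    keys <- unique(c(keys, random_inchikey(n - length(keys))))
  }
  x <- matrix(stats::rnorm(n * p), n, p,
              dimnames = list(NULL, sprintf("d%03d", seq_len(p))))
  truth <- config$intercept + as.numeric(x %*% config$truth_coef)
  if (config$quadratic != 0 && p >= 2) {
    truth <- truth + config$quadratic * (x[, 2]^2 - 1)
  }
  structure(list(keys = keys, descriptors = x, true_logs = truth,
                 config = config),
            class = "synthetic_universe")
}

#' Sample per-source measurement tables from a universe
#'
#' For each source s and compound, with probability `overlap` a
#' measurement `truth + bias_s + N(0, sigma_s^2)` is emitted. With
#' probability `dup_rate` the value is replaced by a verbatim copy of
#' an earlier source's measurement of the same compound (an exact
#' duplicate, within any positive tolerance). With probability
#' `misprint_rate` the value is corrupted by a +/-1 decade shift or a
#' sign flip. Every duplication and corruption is recorded in the
#' hidden ground-truth ledger attached as attribute `truth_ledger`.
#'
#' @param universe A [generate_universe()] result.
#' @param config Configuration; defaults to the universe's.
#' @return Named list of `source_dataset`s (ids "S1", "S2", ...), with
#'   attribute `truth_ledger`: a data frame of every emitted
#'   measurement, its clean value, and any corruption applied.
#' @export
sample_sources <- function(universe, config = universe$config) {
  stopifnot(inherits(universe, "synthetic_universe"))
  set.seed(config$seed + 1L)
  n <- length(universe$keys)
  ids <- paste0("S", seq_len(config$n_sources))
  ledger <- list()
  datasets <- list()
  emitted <- list()  # per-compound list of (source, value) already drawn
  for (s in seq_along(ids)) {
    measured <- which(stats::runif(n) < config$overlap)
    if (length(measured) == 0L) {
      datasets[[ids[s]]] <- as_source_dataset(
        data.frame(compound_id = character(), smiles = character(),
                   inchikey = character(), logs = numeric(),
                   source_id = character(), stringsAsFactors = FALSE),
        ids[s])
      next
    }
    clean <- universe$true_logs[measured] + config$bias[s] +
      stats::rnorm(length(measured), 0, config$sigma[s])
    value <- clean
    dup_of <- rep(NA_character_, length(measured))
    is_dup <- stats::runif(length(measured)) < config$dup_rate
    for (j in which(is_dup)) {
      prev <- emitted[[universe$keys[measured[j]]]]
      if (!is.null(prev)) {
        pick <- prev[[sample.int(length(prev), 1L)]]
        value[j] <- pick$value
        dup_of[j] <- pick$source
      }
    }
    kind <- rep(NA_character_, length(measured))
    hit <- stats::runif(length(measured)) < config$misprint_rate
    for (j in which(hit)) {
      kind[j] <- if (length(config$misprint_kinds) == 1L) config$misprint_kinds
                 else sample(config$misprint_kinds, 1L)
      value[j] <- switch(kind[j],
                         "decade-shift" = value[j] + sample(c(-1, 1), 1L),
                         "sign-flip" = -value[j])
    }
    keys <- universe$keys[measured]
    if (config$dup_rate > 0) {
      for (j in seq_along(measured)) {
        entry <- list(list(source = ids[s], value = value[j]))
        emitted[[keys[j]]] <- c(emitted[[keys[j]]], entry)
      }
    }
    ledger[[s]] <- data.frame(
      inchikey = keys, source_id = ids[s],
      true_logs = universe$true_logs[measured],
      clean_value = clean, value = value,
      duplicate_of = dup_of, misprint = kind,
      stringsAsFactors = FALSE)
    datasets[[ids[s]]] <- as_source_dataset(
      data.frame(compound_id = keys, smiles = "",
                 inchikey = keys, logs = value, source_id = ids[s],
                 stringsAsFactors = FALSE),
      ids[s])
  }
  structure(datasets, truth_ledger = do.call(rbind, ledger))
}

#' Corrupt test labels with internal error
#'
#' Adds independent Gaussian noise of SD `epsilon` to true LogS values,
#' emulating a test set with internal error: a perfect predictor
#' evaluated against such labels shows an observed RMSE of about
#' `epsilon`, and a model of actual RMSE `a` shows about
#' `sqrt(a^2 + epsilon^2)`.
#'
#' @param y_true Numeric vector of true LogS.
#' @param epsilon Corruption SD (>= 0).
#' @param seed Integer seed.
#' @return Corrupted copy of `y_true`.
#' @export
corrupt_test_labels <- function(y_true, epsilon, seed = 1) {
  stopifnot(epsilon >= 0)
  set.seed(seed)
  y_true + stats::rnorm(length(y_true), 0, epsilon)
}
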