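#' Resolve a pipeline configuration
#'
#' Fills defaults, validates the fields each stage needs, and returns a
#' fully expanded configuration. Every command writes the resolved
#' configuration (plus the seed) into its output directory so artifacts
#' can be reproduced.
#'
#' @param config A named list, or a path to a YAML/JSON config file.
#'   Recognized blocks: `inputs` (list of `list(path, source_id)` CSVs),
#'   `synthetic` (arguments to [synth_config()], used when no inputs),
#'   `quality` (`tol`, `gap`, `sd_cutoff`, `size_floor`, `resolve`),
#'   `model` (`light`, `scheme`, `k`), `seed`, `out_dir`.
#' @return The resolved configuration list (class `pipeline_config`).
#' @export
resolve_config <- function(config = list()) {
  if (is.character(config)) {
    config <- if (grepl("[.]json$", config)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      if (!requireNamespace("yaml", quietly = TRUE)) {
        stop("reading YAML configs requires the yaml package")
      }
      yaml::read_yaml(config)
    }
  }
  stopifnot(is.list(config))
  out <- list(
    inputs = config$inputs,
    synthetic = config$synthetic %||% list(),
    quality = utils::modifyList(
      list(tol = 0.01, gap = 1.0, sd_cutoff = 0.50, size_floor = 500,
           resolve = "best-source"),
      config$quality %||% list()),
    model = utils::modifyList(
      list(light = TRUE, scheme = "kfold", k = 10, loo_block = 10),
      config$model %||% list()),
    seed = as.integer(config$seed %||% 1L),
    out_dir = config$out_dir %||% tempfile("soluq-run-"))
  stopifnot(out$quality$tol > 0, out$quality$sd_cutoff >= 0,
            out$quality$size_floor >= 0,
            out$quality$resolve %in% c("best-source", "mean"))
  class(out) <- "pipeline_config"
  out
}

write_artifacts <- function(config, stage) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- unclass(config)
  jsonlite::write_json(cfg, file.path(config$out_dir, "resolved_config.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  message(sprintf("[%s] out_dir=%s seed=%d", stage, config$out_dir,
                  config$seed))
}

load_pipeline_sources <- function(config) {
  if (!is.null(config$inputs)) {
    datasets <- lapply(config$inputs, function(inp) {
      read_measurements(inp$path, inp$source_id,
                        column_map = inp$column_map)
    })
    names(datasets) <- vapply(config$inputs, function(i) i$source_id,
                              character(1))
    list(datasets = datasets, universe = NULL)
  } else {
    syn <- do.call(synth_config, utils::modifyList(
      list(seed = config$seed), config$synthetic))
    universe <- generate_universe(syn)
    list(datasets = sample_sources(universe), universe = universe)
  }
}

#' Assess per-source data quality
#'
#' Reads (or simulates) the configured sources, computes the per-source
#' and merged pooled multi-lab SD table, flags misprint-style outliers,
#' and writes `quality_report.csv`, `quality_evidence.json` and
#' `outlier_flags.csv` into the output directory.
#'
#' @param config See [resolve_config()].
#' @return The quality table, invisibly.
#' @export
cmd_assess_quality <- function(config = list()) {
  config <- resolve_config(config)
  write_artifacts(config, "assess-quality")
  src <- load_pipeline_sources(config)
  tab <- quality_table(src$datasets, tol = config$quality$tol)
  groups <- attr(tab, "groups")
  flags <- do.call(rbind, lapply(groups, flag_outliers,
                                 gap = config$quality$gap))
  utils::write.csv(tab, file.path(config$out_dir, "quality_report.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    lapply(attr(tab, "reports"), function(r) {
      list(source_id = r$source_id, sd = r$sd, n_sd = r$n_sd,
           n_groups = r$n_groups, per_group = r$per_group)
    }),
    file.path(config$out_dir, "quality_evidence.json"),
    auto_unbox = TRUE, digits = NA, na = "null")
  utils::write.csv(flags %||% data.frame(),
                   file.path(config$out_dir, "outlier_flags.csv"),
                   row.names = FALSE)
  message(sprintf("[assess-quality] %d sources, %d outlier flags",
                  length(src$datasets), NROW(flags)))
  invisible(tab)
}

experiment_frame <- function(src, config) {
  # shared scaffolding: quality table, test-source choice, descriptors
  tab <- quality_table(src$datasets, tol = config$quality$tol)
  per_source <- tab[tab$source_id != "All", , drop = FALSE]
  test_source <- select_test_set(per_source,
                                 size_floor = config$quality$size_floor)
  test_ds <- src$datasets[[test_source]]
  test_groups <- lapply(group_by_compound(list(test_ds)),
                        classify_duplicates, tol = config$quality$tol)
  test_tab <- data.frame(
    inchikey = vapply(test_groups, function(g) g$inchikey, character(1)),
    logs = vapply(test_groups, function(g) mean(g$distinct_values),
                  numeric(1)),
    stringsAsFactors = FALSE)
  list(tab = per_source, test_source = test_source, test_tab = test_tab)
}

descriptor_rows <- function(universe, keys) {
  universe$descriptors[match(keys, universe$keys), , drop = FALSE]
}

fit_and_score <- function(universe, train_tab, test_tab, config, seed) {
  xtr <- descriptor_rows(universe, train_tab$inchikey)
  xte <- descriptor_rows(universe, test_tab$inchikey)
  cfg <- if (isTRUE(config$model$light)) consensus_config_light()
         else consensus_config()
  model <- train_consensus(xtr, train_tab$logs, config = cfg, seed = seed)
  pred <- predict(model, xte)
  evaluate(pred$mean, test_tab$logs)
}

#' Run a headline experiment
#'
#' Reproducible recipes over the synthetic generator (or supplied CSVs
#' plus a descriptor universe): `per-source` trains one consensus per
#' source and scores it on the quality-selected test source, pairing
#' each source's pooled SD with its test RMSE; `quality-selected`
#' vs `all-data` contrasts training on the curated retained sources
#' against training on everything; `loo-augmented` folds the test
#' source into training under (blocked) leave-one-out;
#' `observed-vs-actual` measures the observed RMSE of predictors with
#' known actual error against labels corrupted with internal error
#' epsilon.
#'
#' @param config See [resolve_config()]. Synthetic-backed experiments
#'   require no inputs; the generator defaults apply.
#' @param experiment One of `"per-source"`, `"quality-selected"`,
#'   `"all-data"`, `"loo-augmented"`, `"observed-vs-actual"`.
#' @return Experiment-specific results (also written as
#'   `metrics.json` in the output directory).
#' @export
cmd_run_experiment <- function(config = list(),
                               experiment = c("per-source",
                                              "quality-selected",
                                              "all-data",
                                              "loo-augmented",
                                              "observed-vs-actual")) {
  experiment <- match.arg(experiment)
  config <- resolve_config(config)
  write_artifacts(config, paste0("run-experiment:", experiment))
  src <- load_pipeline_sources(config)
  if (is.null(src$universe)) {
    stop("experiments need the synthetic universe for descriptors; ",
         "configure the synthetic block")
  }
  universe <- src$universe
  frame <- experiment_frame(src, config)
  test_keys <- frame$test_tab$inchikey
  result <- switch(
    experiment,
    "per-source" = {
      rows <- lapply(frame$tab$source_id[frame$tab$source_id != frame$test_source],
                     function(s) {
        ttab <- build_training_table(src$datasets[s], frame$tab,
                                     test_keys = test_keys,
                                     tol = config$quality$tol,
                                     resolve = config$quality$resolve)
        met <- fit_and_score(universe, ttab, frame$test_tab, config,
                             config$seed)
        data.frame(source_id = s,
                   sd = frame$tab$sd[frame$tab$source_id == s],
                   n_train = nrow(ttab), rmse = met$rmse, mae = met$mae,
                   stringsAsFactors = FALSE)
      })
      do.call(rbind, rows)
    },
    "quality-selected" = ,
    "all-data" = {
      excl <- exclude_low_quality(
        frame$tab[frame$tab$source_id != frame$test_source, , drop = FALSE],
        sd_cutoff = config$quality$sd_cutoff)
      keep <- if (experiment == "quality-selected") excl$retained
              else frame$tab$source_id[frame$tab$source_id != frame$test_source]
      ttab <- build_training_table(src$datasets[keep], frame$tab,
                                   test_keys = test_keys,
                                   tol = config$quality$tol,
                                   resolve = config$quality$resolve)
      met <- fit_and_score(universe, ttab, frame$test_tab, config,
                           config$seed)
      list(trained_on = keep, excluded = excl$excluded,
           n_train = nrow(ttab), metrics = met)
    },
    "loo-augmented" = {
      excl <- exclude_low_quality(
        frame$tab[frame$tab$source_id != frame$test_source, , drop = FALSE],
        sd_cutoff = config$quality$sd_cutoff)
      ttab <- build_training_table(src$datasets[excl$retained], frame$tab,
                                   test_keys = test_keys,
                                   tol = config$quality$tol,
                                   resolve = config$quality$resolve)
      xtr <- rbind(descriptor_rows(universe, ttab$inchikey),
                   descriptor_rows(universe, frame$test_tab$inchikey))
      ytr <- c(ttab$logs, frame$test_tab$logs)
      n_fixed <- nrow(ttab)
      n_test <- nrow(frame$test_tab)
      cfg <- if (isTRUE(config$model$light)) consensus_config_light()
             else consensus_config()
      block <- max(1L, as.integer(config$model$loo_block))
      set.seed(config$seed)
      fold <- sample(rep(seq_len(ceiling(n_test / block)),
                         length.out = n_test))
      pred <- rep(NA_real_, n_test)
      for (f in unique(fold)) {
        hold <- which(fold == f)
        keep_rows <- c(seq_len(n_fixed), n_fixed + setdiff(seq_len(n_test), hold))
        m <- train_consensus(xtr[keep_rows, , drop = FALSE], ytr[keep_rows],
                             config = cfg, seed = config$seed + f)
        pred[hold] <- predict(m, xtr[n_fixed + hold, , drop = FALSE])$mean
      }
      list(metrics = evaluate(pred, frame$test_tab$logs),
           n_train = n_fixed + n_test - 1L, loo_block = block)
    },
    "observed-vs-actual" = {
      syn <- universe$config
      eps <- if (syn$epsilon > 0) syn$epsilon else 0.5
      a <- 0.4
      y <- universe$true_logs
      y_obs <- corrupt_test_labels(y, eps, seed = config$seed + 7L)
      set.seed(config$seed + 8L)
      imperfect <- y + stats::rnorm(length(y), 0, a)
      list(epsilon = eps, actual_rmse = a,
           observed_rmse_oracle = sqrt(mean((y - y_obs)^2)),
           observed_rmse_model = sqrt(mean((imperfect - y_obs)^2)),
           expected_model = sqrt(a^2 + eps^2), n = length(y))
    })
  path <- file.path(config$out_dir, "metrics.json")
  jsonlite::write_json(result, path, auto_unbox = TRUE, digits = NA,
                       force = TRUE, na = "null")
  message(sprintf("[run-experiment:%s] metrics written to %s", experiment,
                  path))
  result
}

#' Persist a trained consensus model
#'
#' Writes the model as an RDS archive alongside a JSON manifest (seed,
#' feature names, configuration) used to verify the archive on load.
#'
#' @param model A `consensus_model`.
#' @param path Archive path (`.rds`); the manifest is written next to
#'   it as `<path>.manifest.json`.
#' @return `path`, invisibly.
#' @export
save_model_archive <- function(model, path) {
  stopifnot(inherits(model, "consensus_model"))
  saveRDS(model, path)
  jsonlite::write_json(
    list(format = "soluq-consensus-1", seed = model$seed,
         n_features = length(model$feature_names),
         feature_names = model$feature_names),
    paste0(path, ".manifest.json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_model_archive
#' @export
load_model_archive <- function(path) {
  if (!file.exists(path)) stop("archive not found: ", path)
  model <- readRDS(path)
  if (!inherits(model, "consensus_model")) stop("corrupt archive: ", path)
  manifest_path <- paste0(path, ".manifest.json")
  if (file.exists(manifest_path)) {
    man <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
    if (!identical(man$feature_names, model$feature_names)) {
      stop("archive manifest does not match model features")
    }
  }
  model
}

#' Predict solubility for a CSV of SMILES
#'
#' Computes descriptors for each input SMILES with the configured
#' engine and writes per-row consensus predictions. Unparseable SMILES
#' are emitted with an error code, never dropped.
#'
#' @param archive Path to a [save_model_archive()] file.
#' @param input_csv CSV with a `smiles` column.
#' @param out_csv Output path.
#' @param engine A [descriptor_engine()].
#' @return The predictions data frame, invisibly.
#' @export
cmd_predict <- function(archive, input_csv, out_csv,
                        engine = descriptor_engine("rdkit")) {
  model <- load_model_archive(archive)
  inp <- utils::read.csv(input_csv, stringsAsFactors = FALSE)
  if (!"smiles" %in% names(inp)) stop("input CSV lacks a smiles column")
  desc <- compute_descriptors(inp$smiles, engine)
  ok <- !(inp$smiles %in% attr(desc, "errors")$smiles)
  out <- data.frame(smiles = inp$smiles, mean = NA_real_,
                    uncertainty = NA_real_, ann = NA_real_, rf = NA_real_,
                    xgb = NA_real_, error = "", stringsAsFactors = FALSE)
  if (any(ok)) {
    # sporadic engine gaps on parsed structures are imputed batch-wise
    x <- impute_descriptors(desc[ok, , drop = FALSE])$x
    x <- x[, model$feature_names, drop = FALSE]
    pred <- predict(model, x)
    out[ok, c("mean", "uncertainty", "ann", "rf", "xgb")] <- pred
  }
  out$error[!ok] <- "unparseable SMILES"
  utils::write.csv(out, out_csv, row.names = FALSE)
  invisible(out)
}
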