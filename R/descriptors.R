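#' The 2D descriptor manifest
#'
#' The 123 descriptors are organised in six groups: atom-based (19),
#' ring-based (6), bond-based (9), computed octanol-water LogP (1),
#' topological indices (18) and electrotopological-state (E-state)
#' descriptors (70). The manifest maps each name to its group and pins
#' the engine that computes it; it ships as versioned JSON so it can be
#' swapped without touching code.
#'
#' @param path Manifest file; defaults to the copy installed with the
#'   package.
#' @return A data frame (`name`, `group`) with attributes `engine` and
#'   `engine_version`.
#' @export
descriptor_manifest <- function(path = NULL) {
  path <- path %||% system.file("extdata", "descriptor_manifest.json",
                                package = "soluq", mustWork = TRUE)
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- m$descriptors
  stopifnot(sum(table(out$group)) == m$n_descriptors,
            !anyDuplicated(out$name))
  attr(out, "engine") <- m$engine
  attr(out, "engine_version") <- m$engine_version
  out
}

#' Create a descriptor engine
#'
#' Descriptor computation is pluggable. The `"rdkit"` engine shells out
#' to a bundled Python helper (RDKit must be importable by `python`);
#' the `"table"` engine serves precomputed descriptor rows from a data
#' frame keyed by SMILES, which keeps the rest of the pipeline runnable
#' on stored matrices.
#'
#' @param type Engine type.
#' @param python Path to the python interpreter (rdkit engine).
#' @param table Data frame with a `smiles` column plus descriptor
#'   columns (table engine).
#' @return A `descriptor_engine` object.
#' @export
descriptor_engine <- function(type = c("rdkit", "table"),
                              python = Sys.which("python"),
                              table = NULL) {
  type <- match.arg(type)
  if (type == "rdkit") {
    if (!nzchar(python)) stop("no python interpreter found for the rdkit engine")
    script <- system.file("python", "descriptors.py", package = "soluq",
                          mustWork = TRUE)
    eng <- list(type = "rdkit", python = python, script = script)
  } else {
    stopifnot(is.data.frame(table), "smiles" %in% names(table))
    eng <- list(type = "table", table = table)
  }
  structure(eng, class = "descriptor_engine")
}

run_rdkit <- function(engine, mode, smiles) {
  fin <- tempfile(fileext = ".csv")
  fout <- tempfile(fileext = ".csv")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  utils::write.csv(data.frame(smiles = smiles, stringsAsFactors = FALSE),
                   fin, row.names = FALSE)
  status <- system2(engine$python, c(engine$script, mode, fin, fout),
                    stdout = FALSE, stderr = FALSE)
  if (status != 0L || !file.exists(fout)) {
    stop("rdkit descriptor helper failed (exit ", status, ")")
  }
  utils::read.csv(fout, stringsAsFactors = FALSE)
}

#' Compute 2D descriptors for SMILES strings
#'
#' Deterministic for a given canonical structure and engine version.
#' Unparseable SMILES are never dropped silently: their rows are filled
#' with NA and listed in the `errors` attribute.
#'
#' @param smiles Character vector of SMILES.
#' @param engine A [descriptor_engine()].
#' @param manifest Descriptor manifest; defaults to the shipped one.
#' @return Numeric matrix (length(smiles) x 123) with the manifest's
#'   column order, rownames = smiles, and attribute `errors` (data frame
#'   `smiles`, `error` for failed rows).
#' @export
compute_descriptors <- function(smiles, engine,
                                manifest = descriptor_manifest()) {
  stopifnot(inherits(engine, "descriptor_engine"))
  names <- manifest$name
  if (engine$type == "rdkit") {
    res <- run_rdkit(engine, "descriptors", smiles)
    missing_cols <- setdiff(names, colnames(res))
    if (length(missing_cols)) {
      stop("engine output lacks manifest descriptors: ",
           paste(utils::head(missing_cols, 5), collapse = ", "))
    }
    x <- as.matrix(res[, names, drop = FALSE])
    x[x == ""] <- NA
    bad <- !is.na(res$error) & nzchar(res$error)
  } else {
    idx <- match(smiles, engine$table$smiles)
    cols <- intersect(names, setdiff(names(engine$table), "smiles"))
    if (!setequal(cols, names)) {
      stop("table engine lacks manifest descriptors")
    }
    x <- as.matrix(engine$table[idx, names, drop = FALSE])
    bad <- is.na(idx)
  }
  suppressWarnings(storage.mode(x) <- "double")
  x[bad, ] <- NA_real_
  rownames(x) <- names(smiles) %||% smiles
  attr(x, "errors") <- data.frame(
    smiles = smiles[bad],
    error = rep("unparseable SMILES", sum(bad)),
    stringsAsFactors = FALSE)
  x
}

#' Convert SMILES to InChIKeys
#'
#' The pipeline's structure-normalization hook: suitable as the
#' `inchikey_hook` argument of [read_measurements()].
#'
#' @param smiles Character vector of SMILES.
#' @param engine An rdkit [descriptor_engine()].
#' @return Character vector of InChIKeys, NA where conversion failed.
#' @export
smiles_to_inchikey <- function(smiles, engine = descriptor_engine("rdkit")) {
  stopifnot(inherits(engine, "descriptor_engine"),
            identical(engine$type, "rdkit"))
  res <- run_rdkit(engine, "inchikey", smiles)
  out <- res$inchikey
  out[!nzchar(out)] <- NA_character_
  out
}

#' Impute missing descriptor values with training medians
#'
#' Engine failures leave NA rows; E-state columns are legitimately
#' zero-heavy, so failures are imputed with the per-column training
#' median rather than zero.
#'
#' @param x Descriptor matrix with possible NAs.
#' @param medians Optional per-column medians (from the training set);
#'   computed from `x` when absent.
#' @return List with the imputed `x` and the `medians` used.
#' @export
impute_descriptors <- function(x, medians = NULL) {
  if (is.null(medians)) {
    medians <- apply(x, 2, stats::median, na.rm = TRUE)
    medians[is.na(medians)] <- 0
  }
  for (j in seq_len(ncol(x))) {
    nas <- is.na(x[, j])
    if (any(nas)) x[nas, j] <- medians[[j]]
  }
  list(x = x, medians = medians)
}
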