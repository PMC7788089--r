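#' @keywords internal
INCHIKEY_PATTERN <- "^[A-Z]{14}-[A-Z]{10}-[A-Z]$"

MEASUREMENT_COLUMNS <- c("compound_id", "smiles", "inchikey", "logs", "source_id")

#' Validate a single measurement record
#'
#' Checks the invariants every record must satisfy before entering the
#' pipeline: a well-formed 27-character InChIKey (14 characters, dash, 10
#' characters, dash, 1 character, all uppercase letters), a finite LogS
#' value (log10 of molar solubility), and a non-empty source label.
#' Validation never raises; it reports.
#'
#' @param record A list or one-row data frame with fields `compound_id`,
#'   `smiles`, `inchikey`, `logs`, `source_id`.
#' @return A list with elements `ok` (logical) and `violations`
#'   (character vector, empty when `ok`).
#' @examples
#' validate_record(list(compound_id = "c1", smiles = "CCO",
#'                      inchikey = "LFQSCWFLJHTTHZ-UHFFFAOYSA-N",
#'                      logs = -0.24, source_id = "A"))
#' @export
validate_record <- function(record) {
  violations <- character()
  key <- as.character(record$inchikey %||% "")
  if (length(key) != 1L || is.na(key) || !grepl(INCHIKEY_PATTERN, key)) {
    violations <- c(violations, "inchikey: does not match InChIKey pattern")
  }
  logs <- suppressWarnings(as.numeric(record$logs %||% NA_real_))
  if (length(logs) != 1L || is.na(logs) || !is.finite(logs)) {
    violations <- c(violations, "logs: not a finite number")
  }
  src <- as.character(record$source_id %||% "")
  if (length(src) != 1L || is.na(src) || !nzchar(src)) {
    violations <- c(violations, "source_id: empty")
  }
  list(ok = length(violations) == 0L, violations = violations)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Construct a source dataset from a data frame of records
#'
#' @param df Data frame with the measurement columns.
#' @param source_id Label stamped on every record.
#' @param parse_report Optional parse report to attach.
#' @return A `source_dataset`: a data frame with attributes `source_id`,
#'   `declared_size` and `parse_report`.
#' @export
as_source_dataset <- function(df, source_id, parse_report = NULL) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  missing <- setdiff(MEASUREMENT_COLUMNS, names(df))
  if (length(missing)) {
    stop("missing columns: ", paste(missing, collapse = ", "))
  }
  df <- df[, MEASUREMENT_COLUMNS]
  df$source_id <- rep(as.character(source_id), length.out = nrow(df))
  rownames(df) <- NULL
  structure(df,
            source_id = as.character(source_id),
            declared_size = nrow(df),
            parse_report = parse_report,
            class = c("source_dataset", "data.frame"))
}

#' Read a CSV of solubility measurements
#'
#' Reads one source's measurement table. Rows failing validation (bad
#' InChIKey, unparseable or non-finite LogS) are rejected, counted and
#' reported; nothing is dropped silently, so accepted + rejected equals
#' the input row count. Records lacking an InChIKey but carrying SMILES
#' can be completed through `inchikey_hook` (e.g. [smiles_to_inchikey()]
#' with an RDKit engine); without a hook such rows are rejected.
#'
#' @param path Path to a CSV file with a header.
#' @param source_id Source label applied to all rows.
#' @param column_map Named character vector mapping the canonical names
#'   (`compound_id`, `smiles`, `inchikey`, `logs`) to the file's header
#'   names. Defaults to identity.
#' @param inchikey_hook Optional function mapping a character vector of
#'   SMILES to InChIKeys (NA where conversion fails).
#' @return A [as_source_dataset()] object. The attached parse report
#'   (`attr(x, "parse_report")`) lists accepted/rejected counts and
#'   per-row rejection reasons.
#' @export
read_measurements <- function(path, source_id, column_map = NULL,
                              inchikey_hook = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = FALSE)
  defaults <- c(compound_id = "compound_id", smiles = "smiles",
                inchikey = "inchikey", logs = "logs")
  map <- defaults
  if (!is.null(column_map)) map[names(column_map)] <- column_map
  need <- map[c("compound_id", "smiles", "inchikey", "logs")]
  absent <- setdiff(unname(need[c("logs", "inchikey")]), names(raw))
  # compound_id / smiles may be genuinely absent; identity and structure
  # columns are required unless a hook can supply the key
  if (map[["logs"]] %in% absent) stop("mapped column not in file: ", map[["logs"]])
  if (map[["inchikey"]] %in% absent && is.null(inchikey_hook) &&
      !(map[["smiles"]] %in% names(raw))) {
    stop("mapped column not in file: ", map[["inchikey"]])
  }
  n <- nrow(raw)
  get_col <- function(nm) {
    if (map[[nm]] %in% names(raw)) as.character(raw[[map[[nm]]]])
    else rep(NA_character_, n)
  }
  df <- data.frame(compound_id = get_col("compound_id"),
                   smiles = get_col("smiles"),
                   inchikey = get_col("inchikey"),
                   logs = suppressWarnings(as.numeric(get_col("logs"))),
                   source_id = rep(as.character(source_id), n),
                   stringsAsFactors = FALSE)
  df$inchikey[is.na(df$inchikey)] <- ""
  needs_key <- !grepl(INCHIKEY_PATTERN, df$inchikey) & !is.na(df$smiles) &
    nzchar(df$smiles %||% "")
  if (!is.null(inchikey_hook) && any(needs_key)) {
    keys <- inchikey_hook(df$smiles[needs_key])
    keys[is.na(keys)] <- ""
    df$inchikey[needs_key] <- keys
  }
  reasons <- character(n)
  keep <- logical(n)
  for (i in seq_len(n)) {
    v <- validate_record(df[i, ])
    keep[i] <- v$ok
    if (!v$ok) reasons[i] <- paste(v$violations, collapse = "; ")
  }
  report <- list(input = n, accepted = sum(keep), rejected = sum(!keep),
                 reasons = data.frame(row = which(!keep),
                                      reason = reasons[!keep],
                                      stringsAsFactors = FALSE))
  if (n == 0L) warning("empty measurement file: ", path)
  as_source_dataset(df[keep, , drop = FALSE], source_id, parse_report = report)
}

#' Write measurement records to disk
#'
#' Serializes records so that they round-trip losslessly through
#' [read_measurements()]: fields are quoted, and LogS is written at full
#' double precision (at least 15 significant digits).
#'
#' @param x A `source_dataset` or data frame of measurement records.
#' @param path Output path.
#' @param format Output format; only `"csv"` is supported.
#' @return `path`, invisibly.
#' @export
write_measurements <- function(x, path, format = "csv") {
  if (!identical(format, "csv")) {
    stop("unknown format '", format, "'; supported formats: csv")
  }
  df <- as.data.frame(x)[, MEASUREMENT_COLUMNS]
  df$logs <- formatC(df$logs, digits = 15, format = "g")
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @export
print.source_dataset <- function(x, ...) {
  rep <- attr(x, "parse_report")
  cat(sprintf("<source_dataset '%s'> %d records\n",
              attr(x, "source_id"), nrow(x)))
  if (!is.null(rep)) {
    cat(sprintf("  parsed: %d accepted, %d rejected\n",
                rep$accepted, rep$rejected))
  }
  if (nrow(x)) print(utils::head(as.data.frame(x), 5))
  invisible(x)
}
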