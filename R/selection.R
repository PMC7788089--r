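#' Select the test set by quality
#'
#' The observed performance of a model is floored by the internal error
#' of its test labels, so the test set should be the highest-quality
#' source that is still large enough to cover the training chemical
#' space. Among sources whose filtered size meets `size_floor`, the one
#' with the smallest pooled multi-lab SD wins; ties break toward larger
#' N(SD) (more evidence behind the estimate), then lexicographic id.
#'
#' @param reports A quality table (data frame with `source_id`,
#'   `filtered_size`, `n_sd`, `sd`) as produced by [quality_table()], or
#'   a list of `quality_report`s plus a `filtered_size` column bound in.
#' @param size_floor Minimum filtered size for eligibility. Default 500.
#' @return The selected `source_id` (character scalar).
#' @export
select_test_set <- function(reports, size_floor = 500) {
  tab <- as_quality_frame(reports)
  eligible <- tab[!is.na(tab$sd) & tab$filtered_size >= size_floor, , drop = FALSE]
  if (nrow(eligible) == 0L) {
    biggest <- tab$source_id[which.max(tab$filtered_size)]
    stop("no source meets size floor ", size_floor,
         "; largest available is '", biggest, "' (",
         max(tab$filtered_size), " records)")
  }
  ord <- order(eligible$sd, -eligible$n_sd, eligible$source_id)
  eligible$source_id[ord[1L]]
}

as_quality_frame <- function(reports) {
  if (is.data.frame(reports)) return(reports)
  data.frame(
    source_id = vapply(reports, function(r) r$source_id, character(1)),
    filtered_size = vapply(reports, function(r) r$filtered_size %||% NA_integer_,
                           numeric(1)),
    n_sd = vapply(reports, function(r) r$n_sd, integer(1)),
    sd = vapply(reports, function(r) r$sd, numeric(1)),
    stringsAsFactors = FALSE)
}

#' Exclude low-quality sources from training
#'
#' Sources whose pooled multi-lab SD exceeds `sd_cutoff` contribute more
#' noise than signal at training time and are removed before the
#' training tables are merged.
#'
#' @param reports Quality table or list of reports (see
#'   [select_test_set()]).
#' @param sd_cutoff Exclusion threshold in LogS units. Default 0.50.
#' @return List with `excluded` (data frame: `source_id`, `sd`, `reason`)
#'   and `retained` (character vector of source ids).
#' @export
exclude_low_quality <- function(reports, sd_cutoff = 0.50) {
  tab <- as_quality_frame(reports)
  bad <- !is.na(tab$sd) & tab$sd > sd_cutoff
  list(
    excluded = data.frame(source_id = tab$source_id[bad], sd = tab$sd[bad],
                          reason = rep("low quality", sum(bad)),
                          stringsAsFactors = FALSE),
    retained = tab$source_id[!bad])
}

#' Build a curated, leakage-free training table
#'
#' Merges the retained sources into one row per compound. Records are
#' grouped by InChIKey, duplicate clusters are collapsed at `tol` (as in
#' [classify_duplicates()]), and when genuine multi-lab disagreement
#' survives, the consolidated LogS is resolved by reliability ranking:
#' the cluster containing a record from the lowest-SD source wins
#' (`resolve = "best-source"`), or the mean of all distinct values is
#' taken (`resolve = "mean"`). Compounds present in `test_keys` are
#' dropped before anything else, so duplicate collapsing can never move
#' a test compound into training.
#'
#' @param datasets List of retained `source_dataset`s.
#' @param reports Quality table covering every retained source.
#' @param test_keys Character vector of InChIKeys reserved for testing.
#' @param tol Duplicate tolerance in LogS. Default 0.01.
#' @param resolve Disagreement resolution rule.
#' @return A `training_table` data frame (`inchikey`, `smiles`, `logs`,
#'   `provenance`, `n_alternatives`), ordered by InChIKey, with attribute
#'   `excluded_test_keys` (count removed for leakage) and `alternatives`
#'   (log of resolved disagreements).
#' @export
build_training_table <- function(datasets, reports, test_keys = character(),
                                 tol = 0.01,
                                 resolve = c("best-source", "mean")) {
  resolve <- match.arg(resolve)
  if (length(datasets) == 0L) stop("empty retained set")
  records <- bind_records(datasets)
  tab <- as_quality_frame(reports)
  have <- unique(records$source_id)
  if (!all(have %in% tab$source_id)) {
    stop("no quality report for source(s): ",
         paste(setdiff(have, tab$source_id), collapse = ", "))
  }
  # reliability rank: lowest SD first; undefined SDs rank last
  sd_of <- stats::setNames(tab$sd, tab$source_id)
  in_test <- records$inchikey %in% test_keys
  excluded_test_keys <- length(unique(records$inchikey[in_test]))
  records <- records[!in_test, , drop = FALSE]
  groups <- lapply(group_by_compound(records), classify_duplicates, tol = tol)
  alternatives <- list()
  rows <- lapply(groups, function(g) {
    reps <- g$distinct_values
    if (length(reps) == 1L) {
      logs <- reps
    } else if (resolve == "mean") {
      logs <- mean(reps)
    } else {
      src_sd <- sd_of[g$members$source_id]
      src_sd[is.na(src_sd)] <- Inf
      best_member <- order(src_sd, g$members$source_id)[1L]
      best_cluster <- which(vapply(g$clusters, function(ix) best_member %in% ix,
                                   logical(1)))
      logs <- reps[best_cluster]
      alternatives[[g$inchikey]] <<- reps
    }
    smiles <- g$members$smiles
    smiles <- smiles[!is.na(smiles) & nzchar(smiles)]
    data.frame(inchikey = g$inchikey,
               smiles = if (length(smiles)) smiles[1L] else NA_character_,
               logs = logs,
               provenance = paste(sort(unique(g$members$source_id)),
                                  collapse = ";"),
               n_alternatives = length(reps),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(out)) {
    out <- data.frame(inchikey = character(), smiles = character(),
                      logs = numeric(), provenance = character(),
                      n_alternatives = integer(), stringsAsFactors = FALSE)
  }
  out <- out[order(out$inchikey), , drop = FALSE]
  rownames(out) <- NULL
  if (any(out$inchikey %in% test_keys)) {
    stop("leakage: test compound present in training table")
  }
  structure(out,
            excluded_test_keys = excluded_test_keys,
            alternatives = alternatives,
            class = c("training_table", "data.frame"))
}
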