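#' Group measurement records by compound identity
#'
#' Compounds are matched across sources by InChIKey alone; SMILES is
#' carried as payload and never used for matching. Every input record
#' appears in exactly one group.
#'
#' @param records A data frame of validated measurement records, or a
#'   list of `source_dataset`s (rows are concatenated).
#' @return A list of `compound_group` objects, ordered by InChIKey.
#'   Duplicate clusters are not yet computed; see [classify_duplicates()].
#' @export
group_by_compound <- function(records) {
  records <- bind_records(records)
  if (nrow(records) == 0L) return(list())
  idx <- split(seq_len(nrow(records)), records$inchikey)
  groups <- lapply(names(idx), function(key) {
    members <- records[idx[[key]], , drop = FALSE]
    rownames(members) <- NULL
    structure(list(inchikey = key, members = members,
                   clusters = NULL, distinct_values = NULL),
              class = "compound_group")
  })
  groups[order(vapply(groups, function(g) g$inchikey, character(1)))]
}

bind_records <- function(records) {
  if (is.data.frame(records)) return(as.data.frame(records))
  do.call(rbind, lapply(records, function(d) as.data.frame(d)[, MEASUREMENT_COLUMNS]))
}

#' Partition a compound's measurements into duplicate clusters
#'
#' Two records of the same compound whose LogS values lie within `tol`
#' of each other are treated as copies of one measurement, not as
#' independent evidence of variability. Merging is single-linkage: any
#' chain of values with adjacent gaps within `tol` collapses into one
#' cluster, so no pair inside tolerance is ever split. Each cluster is
#' represented by the arithmetic mean of its members; the representatives
#' are the group's distinct values. A group is "multi-lab" when at least
#' two distinct values remain.
#'
#' @param group A `compound_group` from [group_by_compound()].
#' @param tol Merge tolerance in LogS units (inclusive). Default 0.01.
#' @return The group with `clusters` (list of member index vectors),
#'   `distinct_values` (cluster means, ascending) and `multi_lab` filled.
#' @export
classify_duplicates <- function(group, tol = 0.01) {
  stopifnot(inherits(group, "compound_group"), tol > 0)
  values <- group$members$logs
  n <- length(values)
  if (n == 0L) stop("empty compound group")
  ord <- order(values)
  sorted <- values[ord]
  # single-linkage in one dimension: cut where the adjacent gap exceeds tol
  breaks <- which(diff(sorted) > tol)
  starts <- c(1L, breaks + 1L)
  ends <- c(breaks, n)
  clusters <- mapply(function(s, e) sort(ord[s:e]), starts, ends,
                     SIMPLIFY = FALSE)
  group$clusters <- clusters
  group$distinct_values <- vapply(clusters, function(ix) mean(values[ix]),
                                  numeric(1))
  group$multi_lab <- length(clusters) >= 2L
  group
}

#' Sample standard deviation of a compound's distinct multi-lab values
#'
#' @param distinct_values At least two LogS values (one per duplicate
#'   cluster).
#' @return The n-1 denominator sample standard deviation.
#' @export
compound_sd <- function(distinct_values) {
  if (length(distinct_values) < 2L) {
    stop("not multi-lab: fewer than 2 distinct values")
  }
  stats::sd(distinct_values)
}

#' Pooled multi-lab standard deviation of a dataset
#'
#' The quality of a source (or a merged set of sources) is estimated as
#' the pooled standard deviation of its multi-lab measurements. A
#' multi-lab compound group (at least two distinct values after
#' duplicate collapse) contributes when at least one of its member
#' records comes from a source in `scope`. The values entering the pool
#' are the distinct values originating from the scope, so that summing
#' N(SD) over disjoint sources counts every multi-lab value exactly
#' once; each value's deviation is taken about the group's consensus
#' mean (the mean of *all* the group's distinct values). With m_g the
#' scope's distinct-value count in group g and n_g the group's total,
#' \deqn{SD = \sqrt{ \frac{\sum_g \sum_{v \in scope, g} (v - \bar v_g)^2}
#'                        {\sum_g m_g (n_g - 1)/n_g} },
#'       \quad N(SD) = \sum_g m_g,}
#' the denominator being the degrees of freedom carried by deviations
#' about a mean estimated from n_g values. When the scope covers every
#' value of every group (e.g. the merged set) this reduces to the
#' classical pooled form \eqn{\sqrt{\sum_g SS_g / \sum_g (n_g - 1)}}.
#'
#' @param groups Classified `compound_group`s (see [classify_duplicates()]).
#' @param scope Character vector of source ids defining the dataset, or a
#'   single id.
#' @param name Label for the report; defaults to the scope ids joined.
#' @return A `quality_report`: list with `source_id`, `sd` (NA when no
#'   group contributes), `n_sd`, `n_groups` and `per_group` evidence.
#' @export
dataset_sd <- function(groups, scope, name = NULL) {
  stopifnot(length(scope) >= 1L)
  name <- name %||% paste(scope, collapse = "+")
  contrib <- Filter(function(g) {
    !is.null(g$clusters) && isTRUE(g$multi_lab) &&
      any(g$members$source_id %in% scope)
  }, groups)
  if (length(contrib) == 0L) {
    rep <- list(source_id = name, sd = NA_real_, n_sd = 0L, n_groups = 0L,
                per_group = data.frame(inchikey = character(),
                                       n_distinct = integer(),
                                       n_in_scope = integer(),
                                       group_sd = numeric()))
    class(rep) <- "quality_report"
    return(rep)
  }
  stats_g <- lapply(contrib, function(g) {
    v <- g$distinct_values
    n_g <- length(v)
    in_scope <- vapply(g$clusters, function(ix) {
      any(g$members$source_id[ix] %in% scope)
    }, logical(1))
    m_g <- sum(in_scope)
    list(ss = sum((v[in_scope] - mean(v))^2),
         df = m_g * (n_g - 1) / n_g,
         m_g = m_g, n_g = n_g,
         group_sd = compound_sd(v))
  })
  ss <- vapply(stats_g, `[[`, numeric(1), "ss")
  df <- vapply(stats_g, `[[`, numeric(1), "df")
  m_g <- vapply(stats_g, `[[`, numeric(1), "m_g")
  per_group <- data.frame(
    inchikey = vapply(contrib, function(g) g$inchikey, character(1)),
    n_distinct = vapply(stats_g, function(s) as.integer(s$n_g), integer(1)),
    n_in_scope = as.integer(m_g),
    group_sd = vapply(stats_g, `[[`, numeric(1), "group_sd"),
    stringsAsFactors = FALSE)
  rep <- list(source_id = name,
              sd = sqrt(sum(ss) / sum(df)),
              n_sd = as.integer(sum(m_g)),
              n_groups = length(contrib),
              per_group = per_group)
  class(rep) <- "quality_report"
  rep
}

#' @export
print.quality_report <- function(x, ...) {
  cat(sprintf("<quality_report '%s'> SD = %s LogS, N(SD) = %d over %d multi-lab groups\n",
              x$source_id,
              if (is.na(x$sd)) "undefined" else formatC(x$sd, digits = 3, format = "f"),
              x$n_sd, x$n_groups))
  invisible(x)
}

#' Per-source and merged quality table
#'
#' Convenience wrapper assembling one [dataset_sd()] report per source
#' plus a merged row over all sources, in the layout of a per-dataset
#' quality table (source, size, N(SD), SD).
#'
#' @param datasets Named list of `source_dataset`s.
#' @param tol Duplicate tolerance passed to [classify_duplicates()].
#' @param merged_name Label of the merged row. Default "All".
#' @return A data frame with columns `source_id`, `size`, `filtered_size`,
#'   `n_groups`, `n_sd`, `sd`; the per-group reports are attached as
#'   attribute `reports`.
#' @export
quality_table <- function(datasets, tol = 0.01, merged_name = "All") {
  sources <- vapply(datasets, function(d) attr(d, "source_id"), character(1))
  groups <- lapply(group_by_compound(datasets), classify_duplicates, tol = tol)
  reports <- lapply(sources, function(s) dataset_sd(groups, s))
  merged <- dataset_sd(groups, sources, name = merged_name)
  all_reports <- c(reports, list(merged))
  sizes <- c(vapply(datasets, nrow, integer(1)),
             length(unique(bind_records(datasets)$inchikey)))
  out <- data.frame(
    source_id = vapply(all_reports, function(r) r$source_id, character(1)),
    size = sizes,
    filtered_size = sizes,
    n_groups = vapply(all_reports, function(r) r$n_groups, integer(1)),
    n_sd = vapply(all_reports, function(r) r$n_sd, integer(1)),
    sd = vapply(all_reports, function(r) r$sd, numeric(1)),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "reports") <- all_reports
  attr(out, "groups") <- groups
  out
}

#' Flag misprint-style outliers in a compound group
#'
#' Compares each distinct value against the median of the group's other,
#' not-yet-flagged distinct values and flags the most deviant value
#' whenever its deviation reaches `gap`, then repeats on the remainder
#' (peeling, so that a gross outlier does not contaminate the reference
#' median of the others). A flagged value carries reason
#' `magnitude-gap`; additionally `decade-shift` when the deviation is
#' within 0.05 of a whole number of log-decades (a unit/decade misprint
#' pattern), and `sign-flip` when negating the value lands within 0.05
#' of that median (a sign carried over wrongly in transcription). Ties
#' in deviation peel the more positive value first: implausibly high
#' solubilities are the typical misprint direction. Flags are advisory:
#' values are reported, never removed here.
#'
#' @param group A classified `compound_group`.
#' @param gap Deviation threshold in LogS units. Default 1.0.
#' @return A data frame of flags (`inchikey`, `value`, `reason`,
#'   `median_others`, `deviation`), zero rows when nothing is flagged.
#' @export
flag_outliers <- function(group, gap = 1.0) {
  stopifnot(inherits(group, "compound_group"))
  if (is.null(group$clusters)) stop("group not classified; run classify_duplicates()")
  v <- group$distinct_values
  empty <- data.frame(inchikey = character(), value = numeric(),
                      reason = character(), median_others = numeric(),
                      deviation = numeric(), stringsAsFactors = FALSE)
  out <- empty
  active <- seq_along(v)
  while (length(active) >= 2L) {
    med <- vapply(seq_along(active), function(j) {
      stats::median(v[active[-j]])
    }, numeric(1))
    dev <- abs(v[active] - med)
    if (max(dev) < gap) break
    # all values tied at the maximum deviation are flagged together: a
    # decade-apart pair is symmetric evidence and names no culprit
    worst <- which(dev > max(dev) - 1e-9)
    for (w in worst) {
      reasons <- "magnitude-gap"
      if (round(dev[w]) >= 1 && abs(dev[w] - round(dev[w])) <= 0.05) {
        reasons <- c(reasons, "decade-shift")
      }
      if (abs(-v[active[w]] - med[w]) <= 0.05) {
        reasons <- c(reasons, "sign-flip")
      }
      out <- rbind(out, data.frame(inchikey = group$inchikey,
                                   value = v[active[w]],
                                   reason = reasons,
                                   median_others = med[w],
                                   deviation = dev[w],
                                   stringsAsFactors = FALSE))
    }
    active <- active[-worst]
  }
  rownames(out) <- NULL
  out
}
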