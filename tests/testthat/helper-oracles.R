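# Independent oracles and record builders shared across the suite.

rand_key <- function(n = 1) {
  blk <- function(k) apply(matrix(sample(LETTERS, n * k, TRUE), n, k), 1,
                           paste, collapse = "")
  paste0(blk(14), "-", blk(10), "-", blk(1))
}

make_records <- function(logs, inchikey = rand_key(1), source_id = "S1",
                         compound_id = NULL, smiles = "") {
  n <- length(logs)
  data.frame(compound_id = compound_id %||% paste0("c", seq_len(n)),
             smiles = smiles,
             inchikey = rep(inchikey, length.out = n),
             logs = logs,
             source_id = rep(source_id, length.out = n),
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

make_group <- function(logs, source_id = "S1", tol = 0.01,
                       inchikey = rand_key(1)) {
  g <- group_by_compound(make_records(logs, inchikey = inchikey,
                                      source_id = source_id))[[1]]
  classify_duplicates(g, tol = tol)
}

# Brute-force single-linkage: connected components of the "within tol"
# graph over all pairs, found by label propagation.
oracle_single_linkage <- function(values, tol = 0.01) {
  n <- length(values)
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (abs(values[i] - values[j]) <= tol && comp[j] > comp[i]) {
        comp[comp == comp[j]] <- comp[i]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  comp
}

# Brute-force pooled SD from raw cluster representatives: scope values'
# squared deviations about the full group mean, pooled with the
# m_g (n_g - 1) / n_g degrees of freedom.
oracle_pooled_sd <- function(group_values, group_in_scope) {
  ss <- 0; df <- 0; n_sd <- 0L
  for (k in seq_along(group_values)) {
    v <- group_values[[k]]
    keep <- group_in_scope[[k]]
    if (length(v) < 2 || !any(keep)) next
    ss <- ss + sum((v[keep] - mean(v))^2)
    df <- df + sum(keep) * (length(v) - 1) / length(v)
    n_sd <- n_sd + sum(keep)
  }
  list(sd = if (df > 0) sqrt(ss / df) else NA_real_, n_sd = n_sd)
}
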