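test_that("grouping partitions records by InChIKey", {
  k <- rand_key(2)
  recs <- rbind(make_records(c(-1, -2), inchikey = k[1]),
                make_records(-3, inchikey = k[2]))
  groups <- group_by_compound(recs)
  expect_length(groups, 2L)
  expect_setequal(vapply(groups, function(g) nrow(g$members), integer(1)),
                  c(2L, 1L))
  expect_length(group_by_compound(recs[0, ]), 0L)
  expect_length(group_by_compound(make_records(c(1, 2, 3),
                                               inchikey = k[1])), 1L)
})

test_that("duplicate clustering follows the 0.01 LogS single-linkage rule", {
  g <- make_group(c(-3.100, -3.105))
  expect_length(g$clusters, 1L)
  expect_false(g$multi_lab)
  g <- make_group(c(-3.10, -3.50))
  expect_length(g$clusters, 2L)
  expect_true(g$multi_lab)
  # chained merging: adjacent gaps 0.009 connect all three
  g <- make_group(c(-3.100, -3.109, -3.118))
  expect_length(g$clusters, 1L)
  expect_equal(g$distinct_values, mean(c(-3.100, -3.109, -3.118)))
})

test_that("clustering matches the brute-force connected-components oracle", {
  set.seed(7)
  for (rep in 1:200) {
    n <- sample(2:8, 1)
    vals <- round(rnorm(n, -3, 0.02), 3)
    g <- make_group(vals)
    comp <- oracle_single_linkage(vals)
    expect_equal(length(g$clusters), length(unique(comp)))
    # same partition, not just the same count
    got <- lapply(g$clusters, sort)
    want <- unname(lapply(split(seq_len(n), comp), sort))
    expect_setequal(lapply(got, paste, collapse = ","),
                    lapply(want, paste, collapse = ","))
  }
})

test_that("compound_sd is the sample SD of distinct values", {
  expect_equal(compound_sd(c(-2.0, -2.2)), 0.2 / sqrt(2))
  expect_equal(compound_sd(c(1, 2, 3)), 1.0)
  expect_error(compound_sd(-5.0), "not multi-lab")
})

test_that("dataset_sd reproduces the pooled formula on worked examples", {
  k <- rand_key(2)
  recs <- rbind(make_records(c(-2.0, -2.2), inchikey = k[1]),
                make_records(c(1, 2, 3), inchikey = k[2]))
  groups <- lapply(group_by_compound(recs), classify_duplicates)
  r <- dataset_sd(groups, "S1")
  expect_equal(r$sd, sqrt((0.02 + 2.0) / (1 + 2)))
  expect_equal(r$n_sd, 5L)
  expect_equal(r$n_groups, 2L)
  # one group reduces to the compound SD
  r1 <- dataset_sd(lapply(group_by_compound(
    make_records(c(1, 2, 3))), classify_duplicates), "S1")
  expect_equal(r1$sd, 1.0)
  expect_equal(r1$n_sd, 3L)
  # singleton-only scope has no multi-lab evidence
  r0 <- dataset_sd(lapply(group_by_compound(
    make_records(-5)), classify_duplicates), "S1")
  expect_true(is.na(r0$sd))
  expect_equal(r0$n_sd, 0L)
})

test_that("dataset_sd matches a brute-force recomputation on random groups", {
  set.seed(11)
  for (rep in 1:50) {
    n_groups <- sample(2:10, 1)
    sources <- paste0("S", 1:3)
    recs <- do.call(rbind, lapply(seq_len(n_groups), function(i) {
      n <- sample(2:5, 1)
      make_records(rnorm(n, -3, 0.5), inchikey = rand_key(1),
                   source_id = sample(sources, n, TRUE))
    }))
    groups <- lapply(group_by_compound(recs), classify_duplicates)
    for (scope in list("S1", c("S2", "S3"), sources)) {
      r <- dataset_sd(groups, scope)
      vals <- lapply(groups, function(g) g$distinct_values)
      keep <- lapply(groups, function(g) {
        vapply(g$clusters, function(ix) {
          any(g$members$source_id[ix] %in% scope)
        }, logical(1))
      })
      multi <- vapply(groups, function(g) isTRUE(g$multi_lab), logical(1))
      o <- oracle_pooled_sd(vals[multi], keep[multi])
      expect_equal(r$sd, o$sd)
      expect_equal(r$n_sd, o$n_sd)
    }
  }
})

test_that("SDs are shift-invariant and scale-equivariant", {
  set.seed(3)
  recs <- do.call(rbind, lapply(1:8, function(i) {
    make_records(rnorm(3, -3, 0.4), inchikey = rand_key(1),
                 source_id = sample(c("S1", "S2"), 3, TRUE))
  }))
  base <- dataset_sd(lapply(group_by_compound(recs), classify_duplicates), "S1")
  shifted <- recs; shifted$logs <- shifted$logs + 5
  r_shift <- dataset_sd(lapply(group_by_compound(shifted),
                               classify_duplicates), "S1")
  expect_equal(r_shift$sd, base$sd)
  scaled <- recs; scaled$logs <- scaled$logs * -2
  # scale the tolerance too so the partition is preserved under scaling
  r_scale <- dataset_sd(lapply(group_by_compound(scaled),
                               classify_duplicates, tol = 0.02), "S1")
  expect_equal(r_scale$sd, 2 * base$sd)
})

test_that("adding a multi-lab group never decreases N(SD)", {
  set.seed(5)
  recs <- make_records(c(-1, -2), inchikey = rand_key(1))
  groups <- lapply(group_by_compound(recs), classify_duplicates)
  before <- dataset_sd(groups, "S1")$n_sd
  more <- rbind(recs, make_records(c(0, 1, 2), inchikey = rand_key(1)))
  after <- dataset_sd(lapply(group_by_compound(more), classify_duplicates),
                      "S1")$n_sd
  expect_gte(after, before)
})

test_that("outlier flags follow the leave-one-out median rules", {
  g <- make_group(c(-3.1, -3.2, -6.2))
  flags <- flag_outliers(g)
  expect_setequal(flags$reason, c("magnitude-gap", "decade-shift"))
  expect_equal(unique(flags$value), -6.2)
  expect_equal(unique(flags$median_others), -3.15)
  expect_equal(unique(flags$deviation), 3.05)
  # small disagreement is not an outlier at the default gap
  expect_equal(nrow(flag_outliers(make_group(c(-3.1, -3.2)))), 0L)
  # exact negation is a sign flip
  flags <- flag_outliers(make_group(c(-2.0, 2.0)))
  expect_true("sign-flip" %in% flags$reason)
  # unclassified groups are refused
  g_raw <- group_by_compound(make_records(c(-1, -2)))[[1]]
  expect_error(flag_outliers(g_raw), "classif")
})

test_that("quality_table assembles per-source rows plus a merged row", {
  set.seed(8)
  u <- generate_universe(synth_config(n_compounds = 150, n_sources = 3,
                                      sigma = 0.3, overlap = 0.8, seed = 8))
  src <- sample_sources(u)
  tab <- quality_table(src)
  expect_equal(nrow(tab), 4L)
  expect_equal(tab$source_id[4], "All")
  expect_true(all(tab$sd > 0, na.rm = TRUE))
  # origin attribution: per-source N(SD) sums to the merged total, except
  # that a cluster spanning two sources credits both
  expect_gte(sum(tab$n_sd[1:3]), tab$n_sd[4])
})
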