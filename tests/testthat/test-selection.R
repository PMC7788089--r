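test_that("the published quality table selects E and excludes A and F", {
  tab <- reference_quality_table()
  expect_equal(select_test_set(tab, size_floor = 500), "E")
  rest <- tab[tab$source_id != "E", ]
  excl <- exclude_low_quality(rest, sd_cutoff = 0.50)
  expect_setequal(excl$excluded$source_id, c("A", "F"))
  expect_setequal(excl$retained, c("B", "C", "D", "G", "H", "I"))
  expect_true(all(excl$excluded$reason == "low quality"))
})

test_that("test-set selection breaks ties by evidence then id", {
  tab <- data.frame(source_id = c("X", "Y"), filtered_size = c(600, 600),
                    n_sd = c(100L, 200L), sd = c(0.30, 0.30))
  expect_equal(select_test_set(tab, 500), "Y")
  tab$n_sd <- c(100L, 100L)
  expect_equal(select_test_set(tab, 500), "X")
  expect_error(select_test_set(tab, 1000), "size floor 1000")
})

test_that("exclusion thresholds behave at the extremes", {
  tab <- reference_quality_table()
  expect_equal(nrow(exclude_low_quality(tab, 1.0)$excluded), 0L)
  expect_equal(length(exclude_low_quality(tab, 0)$retained), 0L)
})

test_that("disagreements resolve to the most reliable source", {
  k <- rand_key(1)
  ds1 <- as_source_dataset(make_records(-3.0, inchikey = k,
                                        source_id = "G1"), "G1")
  ds2 <- as_source_dataset(make_records(-3.4, inchikey = k,
                                        source_id = "G2"), "G2")
  reports <- data.frame(source_id = c("G1", "G2"), filtered_size = c(1, 1),
                        n_sd = c(10L, 10L), sd = c(0.37, 0.58))
  tt <- build_training_table(list(ds1, ds2), reports)
  expect_equal(tt$logs, -3.0)
  expect_equal(tt$provenance, "G1;G2")
  expect_equal(tt$n_alternatives, 2L)
  # mean resolution averages the distinct values instead
  tm <- build_training_table(list(ds1, ds2), reports, resolve = "mean")
  expect_equal(tm$logs, -3.2)
})

test_that("near-duplicates collapse to their cluster mean", {
  k <- rand_key(1)
  ds1 <- as_source_dataset(make_records(-3.000, inchikey = k,
                                        source_id = "G1"), "G1")
  ds2 <- as_source_dataset(make_records(-3.004, inchikey = k,
                                        source_id = "G2"), "G2")
  reports <- data.frame(source_id = c("G1", "G2"), filtered_size = c(1, 1),
                        n_sd = c(10L, 10L), sd = c(0.3, 0.4))
  tt <- build_training_table(list(ds1, ds2), reports)
  expect_equal(tt$logs, -3.002)
  expect_equal(tt$provenance, "G1;G2")
  expect_equal(tt$n_alternatives, 1L)
})

test_that("test compounds never leak into the training table", {
  set.seed(13)
  u <- generate_universe(synth_config(n_compounds = 200, n_sources = 3,
                                      sigma = 0.3, overlap = 0.7, seed = 13))
  src <- sample_sources(u)
  tab <- quality_table(src)
  test_keys <- u$keys[1:50]
  tt <- build_training_table(src, tab, test_keys = test_keys)
  expect_length(intersect(tt$inchikey, test_keys), 0L)
  expect_gt(attr(tt, "excluded_test_keys"), 0L)
  expect_false(anyDuplicated(tt$inchikey) > 0)
  # a compound present only in the test set is absent and counted
  only_test <- intersect(test_keys, unlist(lapply(src, `[[`, "inchikey")))
  expect_gte(attr(tt, "excluded_test_keys"), 1L)
  expect_false(any(only_test %in% tt$inchikey))
})

test_that("curation is deterministic and monotone in added sources", {
  set.seed(17)
  u <- generate_universe(synth_config(n_compounds = 120, n_sources = 3,
                                      sigma = 0.3, overlap = 0.7, seed = 17))
  src <- sample_sources(u)
  tab <- quality_table(src)
  t1 <- build_training_table(src, tab)
  t2 <- build_training_table(src, tab)
  expect_identical(t1, t2)
  smaller <- build_training_table(src[1:2], tab)
  expect_true(all(smaller$inchikey %in% t1$inchikey))
})

test_that("an empty retained set is refused", {
  expect_error(build_training_table(list(), data.frame()), "empty")
})
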