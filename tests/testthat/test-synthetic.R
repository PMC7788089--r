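test_that("configs validate rates and coefficient lengths", {
  expect_error(synth_config(overlap = 1.5))
  expect_error(synth_config(n_sources = 1))
  expect_error(synth_config(misprint_kinds = "typo"))
  expect_error(synth_config(truth_coef = 1:3))
  cfg <- synth_config(sigma = 0.3)
  expect_length(cfg$sigma, cfg$n_sources)
})

test_that("universes are seeded-reproducible with valid unique keys", {
  cfg <- synth_config(n_compounds = 50, seed = 99)
  u1 <- generate_universe(cfg)
  u2 <- generate_universe(cfg)
  expect_identical(u1, u2)
  expect_false(anyDuplicated(u1$keys) > 0)
  expect_true(all(grepl("^[A-Z]{14}-[A-Z]{10}-[A-Z]$", u1$keys)))
  expect_true(all(is.finite(u1$true_logs)))
  empty <- generate_universe(synth_config(n_compounds = 0))
  expect_length(empty$keys, 0L)
})

test_that("a zero truth model leaves only the intercept", {
  u <- generate_universe(synth_config(n_compounds = 20,
                                      truth_coef = rep(0, 20),
                                      quadratic = 0, intercept = -3))
  expect_equal(u$true_logs, rep(-3, 20))
})

test_that("noiseless full-overlap sources agree exactly", {
  cfg <- synth_config(n_compounds = 40, sigma = 0, overlap = 1, seed = 5)
  u <- generate_universe(cfg)
  src <- sample_sources(u)
  expect_length(src, 4L)
  groups <- lapply(group_by_compound(src), classify_duplicates)
  expect_true(all(vapply(groups, function(g) length(g$clusters) == 1L,
                         logical(1))))
  r <- dataset_sd(groups, names(src))
  expect_true(is.na(r$sd))
  expect_equal(r$n_sd, 0L)
})

test_that("duplicate injection copies values verbatim across sources", {
  cfg <- synth_config(n_compounds = 200, sigma = 0.3, overlap = 0.9,
                      dup_rate = 0.3, seed = 6)
  src <- sample_sources(generate_universe(cfg))
  led <- attr(src, "truth_ledger")
  dups <- led[!is.na(led$duplicate_of), ]
  expect_gt(nrow(dups), 0L)
  for (i in seq_len(min(20, nrow(dups)))) {
    donor <- led[led$inchikey == dups$inchikey[i] &
                   led$source_id == dups$duplicate_of[i], ]
    expect_equal(dups$value[i], donor$value[1])
  }
})

test_that("misprints shift by whole decades or flip signs in the ledger", {
  cfg <- synth_config(n_compounds = 300, sigma = 0.2,
                      misprint_rate = 0.1, seed = 7)
  src <- sample_sources(generate_universe(cfg))
  led <- attr(src, "truth_ledger")
  mis <- led[!is.na(led$misprint), ]
  expect_gt(nrow(mis), 0L)
  shift <- mis[mis$misprint == "decade-shift", ]
  expect_true(all(abs(abs(shift$value - shift$clean_value) - 1) < 1e-12))
  flip <- mis[mis$misprint == "sign-flip", ]
  expect_true(all(abs(flip$value + flip$clean_value) < 1e-12))
})

test_that("outlier flags recover ledgered misprints in replicate-grade data", {
  # detection regime: replicate-grade noise well below the 1-decade
  # misprint magnitude, flag gap below that magnitude
  recall <- numeric(0); false_rate <- numeric(0)
  for (s in 1:3) {
    cfg <- synth_config(sigma = 0.15, misprint_rate = 0.02,
                        misprint_kinds = "decade-shift", seed = s)
    src <- sample_sources(generate_universe(cfg))
    led <- attr(src, "truth_ledger")
    groups <- lapply(group_by_compound(src), classify_duplicates)
    flags <- do.call(rbind, lapply(groups, flag_outliers, gap = 0.6))
    mis <- led[!is.na(led$misprint), ]
    hit <- mapply(function(k, v) {
      any(flags$inchikey == k & abs(flags$value - v) <= 0.011)
    }, mis$inchikey, mis$value)
    recall <- c(recall, hit)
    clean <- setdiff(flags$inchikey, mis$inchikey)
    n_clean_groups <- sum(vapply(groups, function(g) {
      isTRUE(g$multi_lab) && !(g$inchikey %in% mis$inchikey)
    }, logical(1)))
    false_rate <- c(false_rate, length(clean) / n_clean_groups)
  }
  expect_gte(mean(recall), 0.8)
  expect_lte(mean(false_rate), 0.02)
})

test_that("estimated per-source SD ordering tracks the true noise levels", {
  correct <- 0L
  for (s in 1:20) {
    u <- generate_universe(synth_config(seed = s))
    tab <- quality_table(sample_sources(u))
    sds <- tab$sd[match(paste0("S", 1:4), tab$source_id)]
    correct <- correct + identical(order(sds, decreasing = TRUE), 1:4)
  }
  expect_gte(correct, 19L)
})

test_that("label corruption is seeded and exact at epsilon zero", {
  y <- rnorm(100)
  expect_identical(corrupt_test_labels(y, 0, seed = 1), y)
  a <- corrupt_test_labels(y, 0.5, seed = 2)
  b <- corrupt_test_labels(y, 0.5, seed = 2)
  expect_identical(a, b)
  expect_gt(sd(a - y), 0.3)
})
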