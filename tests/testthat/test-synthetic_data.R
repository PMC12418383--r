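test_that("sequence generation is seeded, length-bounded, and GC-calibrated", {
  spec <- synthetic_spec(n_sequences = 50, length_range = c(30, 60), seed = 17)
  d1 <- generate_utrs(spec)
  d2 <- generate_utrs(spec)
  expect_identical(d1$sequence, d2$sequence)  # pure function of spec + seed
  expect_true(all(nchar(d1$sequence) >= 30 & nchar(d1$sequence) <= 60))

  rich <- generate_utrs(synthetic_spec(n_sequences = 1000, gc_bias = 0.7,
                                       length_range = c(80, 120), seed = 18))
  gc <- vapply(rich$sequence,
               function(s) gc_metrics(s)[["gc_content"]], numeric(1))
  expect_lt(abs(mean(gc) - 0.7), 0.02)
})

test_that("planted families have the designed identity structure", {
  spec0 <- synthetic_spec(length_range = c(120, 160), n_cluster_seeds = 3,
                          members_per_seed = 4, mutation_rate = 0, seed = 19)
  pl0 <- plant_clusters(spec0)
  expect_equal(nrow(pl0$dataset), 3 * 5)
  expect_equal(length(unique(pl0$truth$family)), 3)
  for (k in 1:3) {
    fam <- pl0$dataset$sequence[pl0$truth$family == k]
    expect_true(all(fam == fam[1]))  # zero mutation: exact copies
  }

  spec1 <- synthetic_spec(length_range = c(120, 160), n_cluster_seeds = 4,
                          members_per_seed = 10, mutation_rate = 0.1, seed = 20)
  pl1 <- plant_clusters(spec1)
  p <- similarity_params()
  ident <- unlist(lapply(1:4, function(k) {
    fam <- pl1$dataset$sequence[pl1$truth$family == k]
    pairwise_identity(fam[1], fam[-1], p)  # members vs their seed
  }))
  # substitutions always change the base: expected identity = 1 - rate
  expect_lt(abs(mean(ident) - 0.9), 0.02)
  # seeds are mutually dissimilar under the same metric
  seeds <- pl1$dataset$sequence[grepl("_seed$", pl1$dataset$id)]
  for (i in 1:3) {
    expect_true(all(pairwise_identity(seeds[i], seeds[(i + 1):4], p) < 0.3))
  }
})

test_that("skewed family sizes are honored", {
  sizes <- c(10, 5, 2)
  pl <- plant_clusters(synthetic_spec(length_range = c(120, 160),
                                      n_cluster_seeds = 3,
                                      members_per_seed = sizes, seed = 21))
  expect_equal(as.integer(table(pl$truth$family)), sizes + 1L)  # members + seed
})

test_that("simulated TE is the declared linear model of the features", {
  set.seed(22)
  ds <- utr_dataset(sprintf("u%02d", 1:40), replicate(40, random_seq(60)))
  cfg <- feature_config(k_max = 1, include_structure = FALSE)
  w <- c(gc_content = -1, uAUG_count = -0.5)
  noiseless <- simulate_te(ds, w, noise_sd = 0, seed = 23, config = cfg)
  X <- suppressWarnings(extract_features(noiseless, cfg))
  Z <- scale(X[, names(w)])
  expect_equal(noiseless$te_value, as.numeric(Z %*% w), tolerance = 1e-12)
  expect_true(all(noiseless$rpkm > 10))  # filtering stays a no-op
  expect_identical(filter_dataset(noiseless)$id, noiseless$id)
  expect_error(simulate_te(ds, c(bogus_feature = 1), config = cfg), "unknown feature")
})

test_that("target R-squared calibration puts the linear oracle near sqrt(R2)", {
  ds <- generate_utrs(synthetic_spec(n_sequences = 800, length_range = c(40, 80),
                                     seed = 24))
  cfg <- feature_config(k_max = 1, include_structure = FALSE)
  w <- c(gc_content = -1, uAUG_count = -0.5, kmer1_A = 0.5)
  ds <- simulate_te(ds, w, target_r2 = 0.8, seed = 25, config = cfg)
  X <- suppressWarnings(extract_features(ds, cfg))
  # the generating linear model itself is the performance ceiling
  fit <- lm(ds$te_value ~ X[, names(w)])
  expect_lt(abs(pearson_r(fitted(fit), ds$te_value) - sqrt(0.8)), 0.03)
})

test_that("family intercepts add label structure shared within families", {
  pl <- plant_clusters(synthetic_spec(length_range = c(120, 160),
                                      n_cluster_seeds = 5,
                                      members_per_seed = 8, seed = 26))
  cfg <- feature_config(k_max = 1, include_structure = FALSE)
  ds <- simulate_te(pl$dataset, c(gc_content = 1), noise_sd = 0.01, seed = 27,
                    config = cfg, family = pl$truth$family, family_effect_sd = 3)
  fit <- aov(ds$te_value ~ factor(pl$truth$family))
  # family explains most of the variance at sd 3 vs tiny noise
  ss <- summary(fit)[[1]][["Sum Sq"]]
  expect_gt(ss[1] / sum(ss), 0.8)
  expect_error(simulate_te(pl$dataset, c(gc_content = 1), config = cfg,
                           family_effect_sd = 1), "family labels")
})

test_that("simulated plates recover planted ratios", {
  truth <- setNames(runif(20, 0.1, 8), paste0("s", 1:20))
  clean <- simulate_plates(truth, n_plates = 3, cv = 0, seed = 28)
  res <- compute_abi(clean)
  expect_equal(res$abi[match(names(truth), res$sample_id)], unname(truth),
               tolerance = 1e-9)
  expect_identical(clean, simulate_plates(truth, n_plates = 3, cv = 0, seed = 28))

  set.seed(29)
  big_truth <- setNames(runif(100, 0.2, 5), paste0("x", 1:100))
  noisy <- simulate_plates(big_truth, n_plates = 3, cv = 0.1, seed = 30)
  res2 <- compute_abi(noisy)
  rel_err <- abs(res2$abi[match(names(big_truth), res2$sample_id)] - big_truth) /
    big_truth
  expect_lt(mean(rel_err), 0.1)
})
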