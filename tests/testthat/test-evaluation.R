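test_that("pearson_r follows its definition and rejects degenerate input", {
  x <- c(1, 2, 3)
  expect_equal(pearson_r(x, x), 1)
  expect_equal(pearson_r(x, -x), -1)
  # hand computation: centered cross-product 3, variances 2 and 42/9
  expect_equal(pearson_r(c(1, 2, 3), c(1, 2, 4)),
               3 / sqrt(2 * 42 / 9), tolerance = 1e-12)
  expect_equal(round(pearson_r(c(1, 2, 3), c(1, 2, 4)), 4), 0.982)
  expect_error(pearson_r(c(1, 1, 1), x), "zero variance")
  expect_error(pearson_r(x, c(2, 2, 2)), "zero variance")
  # invariant under positive affine maps of either argument
  set.seed(8)
  a <- rnorm(50); b <- a + rnorm(50)
  expect_equal(pearson_r(3 * a + 2, b), pearson_r(a, b))
  expect_equal(pearson_r(a, 0.1 * b - 5), pearson_r(a, b))
})

test_that("cross-validation partitions the data with balanced folds", {
  set.seed(9)
  n <- 47
  X <- matrix(rnorm(n * 2), n, 2, dimnames = list(NULL, c("a", "b")))
  y <- rnorm(n)
  # oracle model: memorize nothing, predict the true labels (pass y as x)
  rep_ <- run_cv(y, y,
                 fit_fun = function(x, yy) NULL,
                 predict_fun = function(m, x) x,
                 scheme = cv_scheme("standard", folds = 10, seed = 1))
  expect_equal(rep_$mean_r, 1)
  expect_equal(rep_$pooled_r, 1)
  expect_equal(rep_$mse, 0)
  folds <- rep_$folds[[1]]
  expect_setequal(unique(folds), 1:10)
  expect_true(max(table(folds)) - min(table(folds)) <= 1)
  expect_equal(sort(unname(tapply(seq_len(n), folds, length))),
               sort(unname(table(folds))))
})

test_that("standard CV is deterministic; randomized repetitions vary", {
  set.seed(10)
  X <- matrix(rnorm(60 * 3), 60, 3, dimnames = list(NULL, paste0("f", 1:3)))
  y <- X[, 1] + rnorm(60, 0, 0.5)
  std1 <- run_cv_rf(X, y, rf_params(n_estimators = 30, seed = 2),
                    cv_scheme("standard", folds = 5, seed = 3))
  std2 <- run_cv_rf(X, y, rf_params(n_estimators = 30, seed = 2),
                    cv_scheme("standard", folds = 5, seed = 3))
  expect_identical(std1$per_fold_r, std2$per_fold_r)
  rnd <- run_cv_rf(X, y, rf_params(n_estimators = 30, seed = 2),
                   cv_scheme("randomized", folds = 5, seed = 3,
                             repetitions = 3))
  expect_length(rnd$per_fold_r, 15)
  per_rep <- split(rnd$per_fold_r, rep(1:3, each = 5))
  expect_gt(stats::sd(vapply(per_rep, mean, numeric(1))), 0)
})

test_that("binned absolute errors match hand arithmetic and report empties", {
  obs <- c(0.5, 0.5, 1.5, 2.5)
  pred <- c(1.0, 0.0, 1.5, 4.0)
  tab <- binned_abs_error(pred, obs, edges = c(0, 1, 2))
  # intervals: (-Inf,0) [0,1) [1,2) [2,Inf)
  expect_equal(tab$n, c(0, 2, 1, 1))
  expect_true(is.na(tab$mae[1]))
  expect_equal(tab$mae[2], 0.5)   # |1-0.5|, |0-0.5|
  expect_equal(tab$mae[3], 0)
  expect_equal(tab$mae[4], 1.5)
  # perfect predictions: all zero
  tab0 <- binned_abs_error(obs, obs, edges = c(0, 1, 2))
  expect_true(all(tab0$mae[tab0$n > 0] == 0))
  # one bin spanning everything reproduces the overall MAE
  tab1 <- binned_abs_error(pred, obs, edges = numeric(0))
  expect_equal(tab1$mae, mean(abs(pred - obs)))
  expect_error(binned_abs_error(pred, obs, edges = c(1, 1)), "increasing")
})

test_that("bias slopes satisfy the exact error-slope relation", {
  obs <- c(0, 1, 2, 3, 4)
  expect_equal(bias_slopes(obs, obs),
               list(slope_pred_vs_actual = 1, slope_error_vs_actual = 0))
  expect_equal(bias_slopes(rep(2, 5), obs),
               list(slope_pred_vs_actual = 0, slope_error_vs_actual = -1))
  expect_equal(bias_slopes(0.5 * obs, obs)$slope_pred_vs_actual, 0.5)
  expect_equal(bias_slopes(0.5 * obs, obs)$slope_error_vs_actual, -0.5)
  set.seed(11)
  p <- rnorm(40); o <- rnorm(40)
  sl <- bias_slopes(p, o)
  expect_equal(sl$slope_error_vs_actual, sl$slope_pred_vs_actual - 1)
  expect_error(bias_slopes(p, rep(1, 40)), "constant")
})

test_that("ablation shares folds and detects planted group dependence", {
  set.seed(12)
  ds <- utr_dataset(sprintf("s%02d", 1:60), replicate(60, random_seq(50)))
  cfg <- feature_config(k_max = 1, include_structure = TRUE)
  ds <- simulate_te(ds, c(MFE = 1, mean_distance = 0.5), target_r2 = 0.9,
                    seed = 13, config = cfg)
  X <- suppressWarnings(extract_features(ds, cfg))
  groups <- list(all = c("SEQUENCE", "STRUCTURE", "CODON"),
                 all2 = c("SEQUENCE", "STRUCTURE", "CODON"),
                 no_structure = c("SEQUENCE", "CODON"))
  tab <- ablation_study(X, ds$te_value, groups,
                        rf_params(n_estimators = 50, seed = 14),
                        cv_scheme("standard", folds = 5, seed = 15))
  expect_equal(nrow(tab), 3)
  # identical subsets give identical results (shared folds and seeds)
  expect_equal(tab$mean_r[tab$subset == "all"], tab$mean_r[tab$subset == "all2"])
  # dropping the group the label depends on hurts
  expect_lt(tab$mean_r[tab$subset == "no_structure"],
            tab$mean_r[tab$subset == "all"])
  expect_error(ablation_study(X, ds$te_value, list(none = "NOPE")), "no features")
})
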