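#' Cross-validation scheme
#'
#' @param mode `"standard"`: one seeded shuffle, then fixed contiguous folds
#'   (deterministic for a given seed). `"randomized"`: the data are
#'   re-shuffled independently before each repetition.
#' @param folds Number of folds (default 10).
#' @param seed Integer seed.
#' @param repetitions Number of repetitions (only meaningful in randomized
#'   mode; default 1).
#' @return A `cv_scheme` object.
#' @export
cv_scheme <- function(mode = c("standard", "randomized"), folds = 10L,
                      seed = 1L, repetitions = 1L) {
  mode <- match.arg(mode)
  stopifnot(folds >= 2L, repetitions >= 1L)
  structure(list(mode = mode, folds = as.integer(folds),
                 seed = as.integer(seed), repetitions = as.integer(repetitions)),
            class = "cv_scheme")
}

# Balanced fold assignment: seeded shuffle, then contiguous chunks whose
# sizes differ by at most one.
make_folds <- function(n, folds, seed) {
  ord <- with_seed(seed, sample.int(n))
  sizes <- rep(n %/% folds, folds) + (seq_len(folds) <= n %% folds)
  assign_fold <- integer(n)
  assign_fold[ord] <- rep(seq_len(folds), times = sizes)
  assign_fold
}

# Evaluate f with a temporary RNG state; the caller's stream is untouched.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Pearson correlation coefficient
#'
#' Linear correlation between predicted and observed values. Zero variance
#' in either argument is an error (not 0, not NA): a constant prediction
#' vector means the comparison is undefined.
#'
#' @param predicted,observed Numeric vectors of equal length >= 2.
#' @return A single correlation in `[-1, 1]`.
#' @export
pearson_r <- function(predicted, observed) {
  stopifnot(length(predicted) == length(observed), length(predicted) >= 2L)
  if (anyNA(predicted) || anyNA(observed)) stop("NA in inputs to pearson_r")
  if (stats::sd(predicted) == 0 || stats::sd(observed) == 0) {
    stop("pearson_r undefined: zero variance in input")
  }
  stats::cor(predicted, observed)
}

#' Run k-fold cross-validation
#'
#' Each fold serves as the test set once while the remaining folds train the
#' model; every index is tested exactly once per repetition. The headline
#' metric is the unweighted mean of per-fold Pearson correlations; the
#' pooled-prediction correlation is also reported for transparency.
#'
#' @param x Training inputs: a feature matrix (subset by rows) or a vector of
#'   sequences (subset by elements).
#' @param y Numeric labels.
#' @param fit_fun `function(x_train, y_train) -> model`.
#' @param predict_fun `function(model, x_test) -> numeric predictions`.
#' @param scheme A [cv_scheme()].
#' @return An `eval_report` list: `per_fold_r`, `mean_r`, `pooled_r`, `mse`,
#'   `predictions` (pooled, in input order; randomized mode keeps the last
#'   repetition), `folds` (assignment per repetition), `scheme`.
#' @export
run_cv <- function(x, y, fit_fun, predict_fun, scheme = cv_scheme()) {
  n <- length(y)
  if (n < scheme$folds) stop("fewer samples than folds")
  take <- function(obj, idx) {
    if (is.matrix(obj) || is.data.frame(obj)) obj[idx, , drop = FALSE] else obj[idx]
  }
  reps <- if (scheme$mode == "randomized") scheme$repetitions else 1L
  per_fold_r <- numeric(0)
  preds <- rep(NA_real_, n)
  sq_err <- c()
  fold_list <- vector("list", reps)
  for (r in seq_len(reps)) {
    rep_seed <- scheme$seed + (r - 1L)
    assign_fold <- make_folds(n, scheme$folds, rep_seed)
    fold_list[[r]] <- assign_fold
    for (f in seq_len(scheme$folds)) {
      test <- assign_fold == f
      model <- fit_fun(take(x, which(!test)), y[!test])
      p <- predict_fun(model, take(x, which(test)))
      preds[test] <- p
      sq_err <- c(sq_err, (p - y[test])^2)
      if (stats::sd(y[test]) == 0 || stats::sd(p) == 0) {
        warning("fold ", f, " has zero-variance labels or predictions; excluded from mean_r")
      } else {
        per_fold_r <- c(per_fold_r, pearson_r(p, y[test]))
      }
    }
  }
  structure(list(per_fold_r = per_fold_r,
                 mean_r = mean(per_fold_r),
                 pooled_r = if (stats::sd(preds) > 0) pearson_r(preds, y) else NA_real_,
                 mse = mean(sq_err),
                 predictions = preds,
                 folds = fold_list,
                 scheme = scheme),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %s %d-fold CV: mean r = %.4f (pooled r = %.4f, MSE = %.4f)\n",
              x$scheme$mode, x$scheme$folds, x$mean_r, x$pooled_r, x$mse))
  invisible(x)
}

#' Convenience: cross-validate the randomized-tree regressor
#'
#' @param X Feature matrix, `y` labels.
#' @param y Numeric labels.
#' @param params An [rf_params()].
#' @param scheme A [cv_scheme()].
#' @return An `eval_report` (see [run_cv()]).
#' @export
run_cv_rf <- function(X, y, params = rf_params(), scheme = cv_scheme()) {
  run_cv(X, y,
         fit_fun = function(x, yy) train_rf(x, yy, params),
         predict_fun = predict_rf,
         scheme = scheme)
}

#' Mean absolute error per label interval
#'
#' Observations are assigned to half-open intervals `[edge_j, edge_{j+1})`
#' defined by the supplied boundaries (plus the two unbounded outer
#' intervals); the mean |predicted - observed| is reported per interval.
#' Empty intervals are reported as `NA`, not 0.
#'
#' @param predicted,observed Numeric vectors of equal length.
#' @param edges Strictly increasing interval boundaries.
#' @return Data frame with columns `interval`, `n`, `mae`.
#' @export
binned_abs_error <- function(predicted, observed, edges) {
  stopifnot(length(predicted) == length(observed))
  if (is.unsorted(edges, strictly = TRUE)) stop("edges must be strictly increasing")
  full <- c(-Inf, edges, Inf)
  idx <- findInterval(observed, full, rightmost.closed = FALSE)
  abs_err <- abs(predicted - observed)
  k <- length(full) - 1L
  res <- data.frame(
    interval = sprintf("[%s, %s)", full[seq_len(k)], full[seq_len(k) + 1L]),
    n = vapply(seq_len(k), function(j) sum(idx == j), integer(1)),
    mae = vapply(seq_len(k), function(j) {
      if (any(idx == j)) mean(abs_err[idx == j]) else NA_real_
    }, numeric(1)),
    stringsAsFactors = FALSE
  )
  res
}

#' Regression-to-the-mean diagnostics
#'
#' Ordinary least-squares slopes of `predicted ~ observed` and
#' `(predicted - observed) ~ observed`. By linearity of OLS the two slopes
#' satisfy `slope_error = slope_pred - 1` exactly. A fitted slope below 1
#' indicates the model compresses the label range: it overestimates low and
#' underestimates high values.
#'
#' @param predicted,observed Numeric vectors, `observed` non-constant.
#' @return Named list `slope_pred_vs_actual`, `slope_error_vs_actual`.
#' @export
bias_slopes <- function(predicted, observed) {
  stopifnot(length(predicted) == length(observed), length(observed) >= 2L)
  if (stats::sd(observed) == 0) stop("bias_slopes undefined: observed is constant")
  s_pred <- stats::cov(predicted, observed) / stats::var(observed)
  list(slope_pred_vs_actual = s_pred,
       slope_error_vs_actual = s_pred - 1)
}

#' Feature-group ablation study
#'
#' Cross-validates the randomized-tree model on subsets of feature groups,
#' sharing fold assignments (and tree seeds) across subsets so comparisons
#' are paired.
#'
#' @param X Feature matrix from [extract_features()] (must carry a manifest).
#' @param y Labels.
#' @param group_sets Named list of character vectors of group labels (subsets
#'   of `SEQUENCE`, `STRUCTURE`, `CODON`), e.g.
#'   `list(all = c("SEQUENCE","STRUCTURE","CODON"), no_structure = c("SEQUENCE","CODON"))`.
#' @param params An [rf_params()].
#' @param scheme A [cv_scheme()].
#' @return Data frame (one row per subset) with columns `subset`, `n_features`,
#'   `mean_r`, `mse`, sorted by decreasing `mean_r`.
#' @export
ablation_study <- function(X, y, group_sets, params = rf_params(),
                           scheme = cv_scheme()) {
  manifest <- feature_manifest(X)
  if (is.null(names(group_sets))) {
    names(group_sets) <- vapply(group_sets, paste, character(1), collapse = "+")
  }
  rows <- lapply(names(group_sets), function(nm) {
    groups <- group_sets[[nm]]
    keep <- manifest$name[manifest$group %in% groups]
    if (!length(keep)) stop("subset '", nm, "' selects no features")
    rep_ <- run_cv_rf(X[, keep, drop = FALSE], y, params, scheme)
    data.frame(subset = nm, n_features = length(keep),
               mean_r = rep_$mean_r, mse = rep_$mse, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$mean_r), , drop = FALSE]
  rownames(out) <- NULL
  out
}
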