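#' Hyperparameters for the randomized-tree regressor
#'
#' The regressor is an ensemble of extremely randomized regression trees
#' (random split thresholds, no bootstrap resampling); predictions are the
#' unweighted mean of the tree outputs.
#'
#' @param n_estimators Number of trees (default 100).
#' @param max_features Fraction of features considered per split (default
#'   0.8; in (0, 1]).
#' @param min_samples_leaf Minimum terminal node size (default 1).
#' @param max_depth Maximum tree depth, `NULL` for unlimited (default).
#' @param min_samples_split Minimum node size eligible for splitting
#'   (default 2).
#' @param bootstrap Draw bootstrap samples per tree (default `FALSE`: every
#'   tree sees the full training set, the classical extremely-randomized
#'   setting).
#' @param seed Integer RNG seed controlling tree randomness.
#' @return An `rf_params` object.
#' @export
rf_params <- function(n_estimators = 100L, max_features = 0.8,
                      min_samples_leaf = 1L, max_depth = NULL,
                      min_samples_split = 2L, bootstrap = FALSE, seed = 1L) {
  stopifnot(n_estimators >= 1L, max_features > 0, max_features <= 1,
            min_samples_leaf >= 1L)
  structure(list(n_estimators = as.integer(n_estimators),
                 max_features = max_features,
                 min_samples_leaf = as.integer(min_samples_leaf),
                 max_depth = max_depth,
                 min_samples_split = as.integer(min_samples_split),
                 bootstrap = bootstrap,
                 seed = as.integer(seed)),
            class = "rf_params")
}

#' Train the randomized-tree regressor
#'
#' @param X Numeric feature matrix (rows = samples) with column names;
#'   matrices from [extract_features()] carry their manifest along.
#' @param y Numeric response (expression labels), same length as `nrow(X)`.
#' @param params An [rf_params()].
#' @return An `rf_bundle`: trained ensemble, feature-name manifest,
#'   hyperparameters, per-feature impurity importances (normalized to sum to
#'   1), and a training-data fingerprint.
#' @export
train_rf <- function(X, y, params = rf_params()) {
  stopifnot(inherits(params, "rf_params"), is.matrix(X))
  if (nrow(X) != length(y)) stop("nrow(X) must equal length(y)")
  if (nrow(X) < 2L) stop("need at least 2 training samples")
  if (anyNA(X) || anyNA(y) || any(!is.finite(X)) || any(!is.finite(y))) {
    stop("X and y must be finite with no missing values")
  }
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  df <- as.data.frame.matrix(X)
  names(df) <- colnames(X)  # preserve names exactly
  fit <- ranger::ranger(
    x = df, y = y,
    num.trees = params$n_estimators,
    mtry = max(1L, ceiling(params$max_features * ncol(X))),
    min.bucket = params$min_samples_leaf,
    min.node.size = params$min_samples_split,
    max.depth = if (is.null(params$max_depth)) 0L else params$max_depth,
    splitrule = "extratrees", num.random.splits = 1L,
    replace = params$bootstrap,
    sample.fraction = 1,
    importance = "impurity",
    seed = params$seed, num.threads = 1L
  )
  imp <- fit$variable.importance
  imp <- pmax(imp, 0)
  if (sum(imp) > 0) imp <- imp / sum(imp)
  structure(list(forest = fit,
                 manifest = colnames(X),
                 params = params,
                 importances = imp,
                 fingerprint = list(n = nrow(X), p = ncol(X),
                                    y_range = range(y), y_sum = sum(y))),
            class = "rf_bundle")
}

#' Predict with a trained randomized-tree ensemble
#'
#' Columns of `X` are matched to the training manifest by name (reordered if
#' permuted); missing or extra features are an error.
#'
#' @param bundle An `rf_bundle` from [train_rf()].
#' @param X Feature matrix with the same columns as at training.
#' @return Numeric vector of predictions, one per row (each the unweighted
#'   mean of the tree outputs, hence bounded by the training label range).
#' @export
predict_rf <- function(bundle, X) {
  stopifnot(inherits(bundle, "rf_bundle"), is.matrix(X))
  if (is.null(colnames(X))) {
    if (ncol(X) != length(bundle$manifest)) {
      stop("unnamed matrix with ", ncol(X), " columns; model expects ",
           length(bundle$manifest))
    }
    colnames(X) <- bundle$manifest
  }
  missing_cols <- setdiff(bundle$manifest, colnames(X))
  extra <- setdiff(colnames(X), bundle$manifest)
  if (length(missing_cols) || length(extra)) {
    stop("feature mismatch; missing: [",
         paste(utils::head(missing_cols, 5L), collapse = ", "),
         "], extra: [", paste(utils::head(extra, 5L), collapse = ", "), "]")
  }
  df <- as.data.frame.matrix(X[, bundle$manifest, drop = FALSE])
  names(df) <- bundle$manifest
  stats::predict(bundle$forest, data = df, num.threads = 1L)$predictions
}

#' Default hyperparameter grid
#'
#' @return A named list of candidate values: `n_estimators` (50, 100, 150),
#'   `min_samples_leaf` (1, 2, 4), `max_features` (0.5, 0.8) -- 18
#'   combinations in total.
#' @export
default_rf_grid <- function() {
  list(n_estimators = c(50L, 100L, 150L),
       min_samples_leaf = c(1L, 2L, 4L),
       max_features = c(0.5, 0.8))
}

#' Grid search over randomized-tree hyperparameters
#'
#' Evaluates every combination in the grid by k-fold cross-validated mean
#' squared error and returns the argmin. Folds are contiguous deterministic
#' splits after one seeded shuffle, shared across combinations so the
#' comparison is paired. MSE ties break toward smaller `n_estimators`, then
#' larger `min_samples_leaf` (prefer the simpler model).
#'
#' @param X,y Training data as in [train_rf()].
#' @param grid Named list of candidate vectors (default [default_rf_grid()]).
#' @param folds Number of CV folds (default 10).
#' @param seed Seed for the fold shuffle and tree randomness.
#' @return A list with `best` (an [rf_params()]) and `table` (one row per
#'   combination with its CV mean MSE, sorted by MSE).
#' @export
rf_grid_search <- function(X, y, grid = default_rf_grid(), folds = 10L, seed = 1L) {
  stopifnot(length(grid) > 0, all(lengths(grid) > 0))
  n <- nrow(X)
  if (folds > n) stop("folds (", folds, ") exceeds the number of samples (", n, ")")
  combos <- expand.grid(grid, stringsAsFactors = FALSE)
  assign_fold <- make_folds(n, folds, seed)
  mse <- vapply(seq_len(nrow(combos)), function(i) {
    p <- rf_params(n_estimators = combos$n_estimators[i],
                   max_features = combos$max_features[i],
                   min_samples_leaf = combos$min_samples_leaf[i],
                   seed = seed)
    fold_mse <- vapply(seq_len(folds), function(f) {
      test <- assign_fold == f
      fit <- train_rf(X[!test, , drop = FALSE], y[!test], p)
      mean((predict_rf(fit, X[test, , drop = FALSE]) - y[test])^2)
    }, numeric(1))
    mean(fold_mse)
  }, numeric(1))
  tab <- cbind(combos, mse = mse)
  ord <- order(tab$mse, tab$n_estimators, -tab$min_samples_leaf)
  tab <- tab[ord, , drop = FALSE]
  rownames(tab) <- NULL
  best <- rf_params(n_estimators = tab$n_estimators[1L],
                    max_features = tab$max_features[1L],
                    min_samples_leaf = tab$min_samples_leaf[1L],
                    seed = seed)
  list(best = best, table = tab)
}
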