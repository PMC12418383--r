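#' Configuration of a dataset-compression experiment
#'
#' @param similarity A [similarity_params()] (threshold etc.).
#' @param selection `"none"`, `"percentage"`, or `"count"`.
#' @param selection_param Fraction for percentage mode (e.g. 0.5) or
#'   per-cluster count for count mode (e.g. 6).
#' @param model `"rf"` or `"seqnet"`.
#' @param feature_config A [feature_config()] (RF path only).
#' @param rf_params An [rf_params()] (RF path only).
#' @param seqnet_config,seqnet_train A [seqnet_config()] /
#'   [seqnet_train_config()] (network path only).
#' @param seed Master seed for the subset sampling and the random control.
#' @return An `experiment_config`.
#' @export
experiment_config <- function(similarity = similarity_params(),
                              selection = c("count", "percentage", "none"),
                              selection_param = 6,
                              model = c("rf", "seqnet"),
                              feature_config = utr5xpress::feature_config(),
                              rf_params = utr5xpress::rf_params(),
                              seqnet_config = utr5xpress::seqnet_config(),
                              seqnet_train = seqnet_train_config(),
                              seed = 1L) {
  structure(list(similarity = similarity, selection = match.arg(selection),
                 selection_param = selection_param, model = match.arg(model),
                 feature_config = feature_config, rf_params = rf_params,
                 seqnet_config = seqnet_config, seqnet_train = seqnet_train,
                 seed = as.integer(seed)),
            class = "experiment_config")
}

#' Run a clustering-based dataset-compression experiment
#'
#' End-to-end orchestration: cluster the dataset, hold out the
#' representative test set (representatives of all multi-member clusters),
#' select a training subset from the remaining sequences by the configured
#' rule, train the model on (a) the full non-test data, (b) the clustered
#' subset, and (c) a size-matched random control subset, and evaluate all
#' three on the held-out representatives. Test representatives never enter
#' any training subset (asserted at run time).
#'
#' @param dataset A labeled, filtered [utr_dataset()].
#' @param config An [experiment_config()].
#' @param clustering Optionally a precomputed `utr_clustering` of `dataset`
#'   (skips re-clustering).
#' @param features Optionally a precomputed feature matrix for `dataset`
#'   (rows = `dataset$id`; RF path only).
#' @return A list report: subset sizes, held-out Pearson r of the full /
#'   clustered-subset / random-control models, `compression_rate`, and
#'   `accuracy_restoration` (clustered subset vs full).
#' @export
run_compression_experiment <- function(dataset, config = experiment_config(),
                                       clustering = NULL, features = NULL) {
  stopifnot(inherits(config, "experiment_config"))
  if (anyNA(dataset$te_value)) stop("dataset has missing TE labels; filter first")
  if (is.null(clustering)) clustering <- greedy_cluster(dataset, config$similarity)
  test_ids <- build_test_set(clustering)
  if (length(test_ids) < 3L) stop("representative test set too small (",
                                  length(test_ids), " sequences)")
  pool_ids <- setdiff(dataset$id, test_ids)
  subset_ids <- switch(config$selection,
    none = pool_ids,
    percentage = select_percentage(clustering, config$selection_param,
                                   seed = config$seed, exclude = test_ids),
    count = select_count(clustering, config$selection_param,
                         seed = config$seed, exclude = test_ids))
  random_ids <- with_seed(config$seed + 1L,
                          sample(pool_ids, length(subset_ids)))
  if (length(intersect(test_ids, c(subset_ids, random_ids)))) {
    stop("leakage: test representatives appear in a training subset")
  }

  if (config$model == "rf") {
    if (is.null(features)) features <- extract_features(dataset, config$feature_config)
    stopifnot(all(dataset$id %in% rownames(features)))
    fit_eval <- function(train_ids) {
      fit <- train_rf(features[train_ids, , drop = FALSE],
                      dataset$te_value[match(train_ids, dataset$id)],
                      config$rf_params)
      pred <- predict_rf(fit, features[test_ids, , drop = FALSE])
      pearson_r(pred, dataset$te_value[match(test_ids, dataset$id)])
    }
  } else {
    fit_eval <- function(train_ids) {
      sel <- match(train_ids, dataset$id)
      net <- train_seqnet(dataset$sequence[sel], dataset$te_value[sel],
                          config$seqnet_config, config$seqnet_train)
      pred <- predict_seqnet(net, dataset$sequence[match(test_ids, dataset$id)])
      pearson_r(pred, dataset$te_value[match(test_ids, dataset$id)])
    }
  }

  r_full <- fit_eval(pool_ids)
  r_subset <- if (setequal(subset_ids, pool_ids)) r_full else fit_eval(subset_ids)
  r_random <- if (setequal(random_ids, pool_ids)) r_full else fit_eval(random_ids)
  cm <- compression_metrics(length(pool_ids), length(subset_ids), r_full, r_subset)
  list(n_total = nrow(dataset),
       n_clusters = length(clustering$clusters),
       n_test = length(test_ids),
       n_full = length(pool_ids),
       n_subset = length(subset_ids),
       selection = config$selection,
       r_full = r_full, r_subset = r_subset, r_random = r_random,
       compression_rate = cm$compression_rate,
       accuracy_restoration = cm$accuracy_restoration,
       test_ids = test_ids, subset_ids = subset_ids, random_ids = random_ids,
       seed = config$seed)
}
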