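#' Specification of a synthetic 5'UTR library
#'
#' The generators emulate the statistical structure the modeling pipeline
#' assumes: variable-length 5'UTRs (at most 200 nt) with a controllable GC
#' bias, redundant families of similar sequences (seed sequences plus point
#' mutants), labels generated as a known function of extracted features plus
#' Gaussian noise on the log-TE scale, and replicate-plate bioluminescence
#' with reference wells. Every generator is a pure function of its spec and
#' seed.
#'
#' @param n_sequences Number of sequences for [generate_utrs()].
#' @param length_range Inclusive length range (min >= 10, max <= 200).
#' @param gc_bias Target GC fraction in (0, 1).
#' @param n_cluster_seeds,members_per_seed Planted-cluster structure for
#'   [plant_clusters()]: number of seed sequences and mutants per seed.
#'   `members_per_seed` may be a single count (uniform family sizes) or a
#'   vector of length `n_cluster_seeds` (skewed family sizes, as in real
#'   redundancy-heavy libraries where a few families dominate).
#' @param mutation_rate Per-base substitution probability in `[0, 1)` for
#'   mutants. A substitution always changes the base (drawn from the three
#'   alternatives), so the expected mutant-to-seed identity is exactly
#'   `1 - mutation_rate`.
#' @param seed Integer RNG seed.
#' @return A `synthetic_spec` object.
#' @export
synthetic_spec <- function(n_sequences = 100L, length_range = c(60L, 100L),
                           gc_bias = 0.5, n_cluster_seeds = 0L,
                           members_per_seed = 0L, mutation_rate = 0.1,
                           seed = 1L) {
  stopifnot(length_range[1L] >= 10L, length_range[2L] <= 200L,
            length_range[1L] <= length_range[2L],
            gc_bias > 0, gc_bias < 1,
            mutation_rate >= 0, mutation_rate < 1,
            length(members_per_seed) %in% c(1L, n_cluster_seeds))
  structure(list(n_sequences = as.integer(n_sequences),
                 length_range = as.integer(length_range),
                 gc_bias = gc_bias,
                 n_cluster_seeds = as.integer(n_cluster_seeds),
                 members_per_seed = as.integer(members_per_seed),
                 mutation_rate = mutation_rate,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

random_utr <- function(len, gc_bias) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE,
               prob = c((1 - gc_bias) / 2, gc_bias / 2,
                        gc_bias / 2, (1 - gc_bias) / 2)),
        collapse = "")
}

#' Generate random 5'UTR sequences
#'
#' Sequences are i.i.d. with the target GC bias; lengths are uniform over
#' the configured range. TE and RPKM start out missing (add them with
#' [simulate_te()]).
#'
#' @param spec A [synthetic_spec()].
#' @return A [utr_dataset()] with ids `utr_0001`, `utr_0002`, ...
#' @export
generate_utrs <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(spec$seed, {
    lens <- sample(seq(spec$length_range[1L], spec$length_range[2L]),
                   spec$n_sequences, replace = TRUE)
    seqs <- vapply(lens, random_utr, character(1), gc_bias = spec$gc_bias)
    utr_dataset(sprintf("utr_%04d", seq_len(spec$n_sequences)), seqs,
                cell_line = "synthetic",
                provenance = sprintf("generate_utrs(n=%d, gc=%.2f, seed=%d)",
                                     spec$n_sequences, spec$gc_bias, spec$seed))
  })
}

mutate_sequence <- function(sequence, rate) {
  v <- strsplit(sequence, "")[[1L]]
  hit <- which(stats::runif(length(v)) < rate)
  for (j in hit) v[j] <- sample(setdiff(c("A", "C", "G", "T"), v[j]), 1L)
  paste(v, collapse = "")
}

#' Generate a dataset with planted cluster structure
#'
#' Draws `n_cluster_seeds` mutually dissimilar seed sequences (pairwise
#' identity below `dissimilarity`, rejection-sampled with up to `max_draws`
#' attempts per seed) and expands each into `members_per_seed` mutants by
#' i.i.d. per-base substitution. The dataset contains the seeds plus their
#' mutants; the returned truth table records which planted family each
#' sequence belongs to.
#'
#' @param spec A [synthetic_spec()] with `n_cluster_seeds >= 2` and
#'   `members_per_seed >= 1`.
#' @param params A [similarity_params()] supplying the identity metric used
#'   for the seed-dissimilarity check.
#' @param dissimilarity Maximum allowed pairwise seed identity (default 0.3).
#' @param max_draws Rejection-sampling budget per seed (default 100; an
#'   error is raised if it is exhausted).
#' @return List with `dataset` (a [utr_dataset()]) and `truth` (data frame
#'   `id`, `family` with one family per seed).
#' @export
plant_clusters <- function(spec, params = similarity_params(),
                           dissimilarity = 0.3, max_draws = 100L) {
  stopifnot(inherits(spec, "synthetic_spec"),
            spec$n_cluster_seeds >= 2L, all(spec$members_per_seed >= 1L))
  fam_size <- rep_len(spec$members_per_seed, spec$n_cluster_seeds)
  with_seed(spec$seed, {
    seeds <- character(0)
    for (k in seq_len(spec$n_cluster_seeds)) {
      ok <- FALSE
      for (d in seq_len(max_draws)) {
        len <- sample(seq(spec$length_range[1L], spec$length_range[2L]), 1L)
        cand <- random_utr(len, spec$gc_bias)
        if (!length(seeds) ||
            all(pairwise_identity(cand, seeds, params) < dissimilarity)) {
          seeds <- c(seeds, cand)
          ok <- TRUE
          break
        }
      }
      if (!ok) {
        stop("could not draw seed ", k, " with pairwise identity < ",
             dissimilarity, " in ", max_draws, " attempts")
      }
    }
    ids <- character(0); seqs <- character(0); family <- integer(0)
    for (k in seq_along(seeds)) {
      ids <- c(ids, sprintf("fam%02d_seed", k),
               sprintf("fam%02d_m%03d", k, seq_len(fam_size[k])))
      seqs <- c(seqs, seeds[k],
                vapply(seq_len(fam_size[k]), function(i) {
                  mutate_sequence(seeds[k], spec$mutation_rate)
                }, character(1)))
      family <- c(family, rep(k, fam_size[k] + 1L))
    }
    list(dataset = utr_dataset(ids, seqs, cell_line = "synthetic",
                               provenance = sprintf(
                                 "plant_clusters(k=%d, m=%d, rate=%.2f, seed=%d)",
                                 spec$n_cluster_seeds, spec$members_per_seed,
                                 spec$mutation_rate, spec$seed)),
         truth = data.frame(id = ids, family = family, stringsAsFactors = FALSE))
  })
}

#' Simulate feature-linked TE labels
#'
#' Generates `te = sum_f w_f * z_f + Normal(0, noise_sd)` where `z_f` are
#' z-scored feature columns, directly on the log-TE scale. RPKM values are
#' drawn above the default abundance filter cutoff so filtering is a no-op
#' unless a test plants violations. Either `noise_sd` is given explicitly, or
#' `target_r2` sets it so the population R-squared of the linear signal is
#' the requested value (`noise_sd = sd(signal) * sqrt((1 - R2)/R2)`; the best
#' achievable prediction correlation is then `sqrt(R2)`).
#'
#' @param dataset A [utr_dataset()].
#' @param weights Named numeric vector of feature weights; names must be
#'   feature-matrix columns (e.g. `c(gc_content = -1, MFE = 1, uAUG_count = -0.5)`).
#' @param noise_sd Gaussian noise standard deviation (ignored when
#'   `target_r2` is given).
#' @param target_r2 Optional population R-squared in (0, 1); the R-squared is
#'   taken against the full systematic part (features plus any family
#'   effect).
#' @param seed Integer seed for the noise and RPKM draws.
#' @param config A [feature_config()] used to compute the features the
#'   weights refer to.
#' @param family Optional grouping of the records (a vector of family labels
#'   aligned with `dataset`, e.g. the truth table of [plant_clusters()]).
#' @param family_effect_sd Standard deviation of a per-family random
#'   intercept added to the label (default 0). This emulates
#'   cluster-correlated regulation: closely similar 5'UTRs share expression
#'   determinants (structural context, shared cis-elements) beyond what the
#'   extracted features capture, so family identity carries label information
#'   that no feature-only model can recover for families absent from
#'   training.
#' @return The dataset with `te_value` and `rpkm` filled in; attributes
#'   `te_signal` (noise-free signal), `te_weights`, `te_noise_sd`.
#' @export
simulate_te <- function(dataset, weights, noise_sd = 0, target_r2 = NULL,
                        seed = 1L, config = feature_config(),
                        family = NULL, family_effect_sd = 0) {
  stopifnot(length(weights) >= 1L, !is.null(names(weights)))
  X <- extract_features(dataset, config)
  unknown <- setdiff(names(weights), colnames(X))
  if (length(unknown)) {
    stop("unknown feature name(s) in te_model: ", paste(unknown, collapse = ", "))
  }
  Z <- scale(X[, names(weights), drop = FALSE])
  Z[is.nan(Z)] <- 0  # constant feature columns carry no signal
  signal <- as.numeric(Z %*% weights)
  with_seed(seed, {
    if (family_effect_sd > 0) {
      if (is.null(family) || length(family) != nrow(dataset)) {
        stop("family labels (one per record) are required when family_effect_sd > 0")
      }
      fam <- as.integer(factor(family))
      b <- stats::rnorm(max(fam), 0, family_effect_sd)
      signal <- signal + b[fam]
    }
    if (!is.null(target_r2)) {
      stopifnot(target_r2 > 0, target_r2 < 1)
      noise_sd <- stats::sd(signal) * sqrt((1 - target_r2) / target_r2)
    }
    dataset$te_value <- signal + stats::rnorm(nrow(dataset), 0, noise_sd)
    dataset$rpkm <- stats::runif(nrow(dataset), 10.5, 200)
  })
  attr(dataset, "te_signal") <- signal
  attr(dataset, "te_weights") <- weights
  attr(dataset, "te_noise_sd") <- noise_sd
  attr(dataset, "provenance") <- paste0(
    provenance(dataset),
    sprintf("; simulate_te(%s, noise_sd=%.3g, seed=%d)",
            paste(names(weights), collapse = "+"), noise_sd, seed))
  dataset
}

#' Simulate replicate-plate bioluminescence measurements
#'
#' Each plate gets a reference well with a log-normally drawn signal level;
#' each sample's signal is `true_ratio * reference * lognormal(cv)` with
#' duplicate technical reps emitted per well. At `cv = 0`, [compute_abi()]
#' recovers the planted ratios exactly.
#'
#' @param abi_truth Named numeric vector of true per-sample ratios.
#' @param n_plates Number of replicate plates (default 3).
#' @param cv Relative (log-normal) measurement noise, >= 0.
#' @param seed Integer seed.
#' @param reference_level Median raw signal of reference wells (luminescence
#'   counts; default 1e5).
#' @return A long-format data frame with columns `plate_id`, `well`,
#'   `sample_id`, `technical_rep`, `signal`, `is_reference`.
#' @export
simulate_plates <- function(abi_truth, n_plates = 3L, cv = 0, seed = 1L,
                            reference_level = 1e5) {
  stopifnot(!is.null(names(abi_truth)), cv >= 0, n_plates >= 1L)
  lnoise <- function(n) if (cv > 0) stats::rlnorm(n, -cv^2 / 2, cv) else rep(1, n)
  with_seed(seed, {
    rows <- lapply(seq_len(n_plates), function(p) {
      ref <- reference_level * stats::rlnorm(1L, 0, 0.2)
      samples <- c("REF", names(abi_truth))
      truth <- c(1, unname(abi_truth))
      well_mean <- truth * ref * c(1, lnoise(length(abi_truth)))
      do.call(rbind, lapply(seq_along(samples), function(i) {
        data.frame(plate_id = sprintf("plate%d", p),
                   well = sprintf("%s%02d", LETTERS[(i - 1L) %/% 12L + 1L],
                                  (i - 1L) %% 12L + 1L),
                   sample_id = samples[i],
                   technical_rep = 1:2,
                   signal = well_mean[i] * lnoise(2L),
                   is_reference = samples[i] == "REF",
                   stringsAsFactors = FALSE)
      }))
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}
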