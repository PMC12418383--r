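#' Soft-classification bin specification
#'
#' The expression codec turns a continuous expression value into a
#' probability distribution over `n_bins` ordered categories and back. A
#' value `e` (already on the bin scale, 0 ... n_bins-1) is modeled as a
#' latent normal `rho ~ N(mu = e + mu_offset, sd = sigma)`; category `i`
#' receives the probability mass of `rho` in `[i, i+1)`, with the first and
#' last category absorbing the lower and upper tails. The affine `label_map`
#' (scale, shift) converts between TE space and bin space and is persisted
#' with trained models so decoding is always reversible.
#'
#' Edge convention: bin 0 covers `(-Inf, 1)` and bin `n_bins-1` covers
#' `[n_bins-1, Inf)`; every interior bin is the half-open `[i, i+1)`. The
#' single boundary point has zero probability mass under the normal model,
#' so the convention only matters for consistency.
#'
#' @param n_bins Number of expression categories (default 29, bins 0..28).
#' @param mu_offset Offset added to `e` for the latent mean (default 0.5,
#'   centering the normal in the bin's interval).
#' @param sigma Standard deviation of the latent normal (default 0.5).
#' @param scale,shift Affine TE-to-bin map: `bin = (te - shift) / scale`.
#'   Defaults give the identity map.
#' @return A `bin_spec` object.
#' @seealso [fit_bin_spec()] to anchor the label map on a dataset.
#' @export
bin_spec <- function(n_bins = 29L, mu_offset = 0.5, sigma = 0.5,
                     scale = 1, shift = 0) {
  stopifnot(n_bins >= 2L, sigma > 0, is.finite(scale), scale != 0)
  structure(list(n_bins = as.integer(n_bins), mu_offset = mu_offset,
                 sigma = sigma, scale = scale, shift = shift),
            class = "bin_spec")
}

#' Fit the TE-to-bin label map on observed labels
#'
#' Anchors the affine map so the smallest observed TE lands on bin 0 and the
#' largest on bin `n_bins - 1`.
#'
#' @param te_values Numeric TE labels (NAs ignored).
#' @inheritParams bin_spec
#' @return A [bin_spec()] with fitted `scale` and `shift`.
#' @export
fit_bin_spec <- function(te_values, n_bins = 29L, mu_offset = 0.5, sigma = 0.5) {
  te_values <- te_values[is.finite(te_values)]
  stopifnot(length(te_values) >= 2L)
  lo <- min(te_values); hi <- max(te_values)
  if (hi == lo) stop("cannot fit a label map on constant TE values")
  bin_spec(n_bins, mu_offset, sigma,
           scale = (hi - lo) / (n_bins - 1), shift = lo)
}

#' Convert between TE space and bin space
#'
#' Exact affine transform and inverse; `bin_to_te(te_to_bin(x))` is the
#' identity up to floating point.
#'
#' @param value Numeric vector.
#' @param spec A [bin_spec()].
#' @return Numeric vector of the same length.
#' @export
te_to_bin <- function(value, spec) {
  stopifnot(inherits(spec, "bin_spec"))
  (value - spec$shift) / spec$scale
}

#' @rdname te_to_bin
#' @export
bin_to_te <- function(value, spec) {
  stopifnot(inherits(spec, "bin_spec"))
  value * spec$scale + spec$shift
}

#' Encode expression values as soft bin distributions
#'
#' @param e Numeric vector of expression values on the bin scale.
#' @param spec A [bin_spec()].
#' @return A matrix of dimension `length(e) x n_bins`; each row is a valid
#'   probability distribution (non-negative, summing to 1).
#' @export
encode_expression <- function(e, spec = bin_spec()) {
  stopifnot(inherits(spec, "bin_spec"))
  if (any(!is.finite(e))) stop("non-finite expression value(s)")
  nb <- spec$n_bins
  mu <- e + spec$mu_offset
  edges <- seq_len(nb - 1L)  # interior edges 1 ... nb-1
  # cumulative mass below each interior edge, per value
  cum <- vapply(edges, function(b) stats::pnorm(b, mean = mu, sd = spec$sigma),
                numeric(length(e)))
  cum <- matrix(cum, nrow = length(e))
  probs <- cbind(cum[, 1L, drop = FALSE],
                 if (nb > 2L) cum[, -1L, drop = FALSE] - cum[, -(nb - 1L), drop = FALSE],
                 1 - cum[, nb - 1L, drop = FALSE])
  probs[probs < 0] <- 0  # guard against cancellation
  probs / rowSums(probs)
}

check_distribution <- function(dist, tol = 1e-9) {
  if (is.null(dim(dist))) dist <- matrix(dist, nrow = 1L)
  if (any(dist < -tol)) stop("negative probabilities in bin distribution")
  s <- rowSums(dist)
  if (any(abs(s - 1) > 1e-6)) {
    stop("bin distribution rows must sum to 1 (max deviation ",
         format(max(abs(s - 1))), ")")
  }
  dist
}

#' Decode a bin distribution to an expression value
#'
#' Returns the distribution's expectation over bin indices:
#' `Expression = sum_i probs[i] * i` with bins indexed 0 ... n_bins-1.
#'
#' @param dist A probability vector of length `n_bins` or a matrix with one
#'   distribution per row.
#' @param spec A [bin_spec()].
#' @return Numeric vector of decoded expression values on the bin scale
#'   (convert with [bin_to_te()] if needed).
#' @export
decode_expression <- function(dist, spec = bin_spec()) {
  stopifnot(inherits(spec, "bin_spec"))
  dist <- check_distribution(dist)
  if (ncol(dist) != spec$n_bins) {
    stop("distribution has ", ncol(dist), " bins, spec expects ", spec$n_bins)
  }
  as.numeric(dist %*% (seq_len(spec$n_bins) - 1L))
}

#' Kullback-Leibler divergence between bin distributions
#'
#' `KL(target || predicted) = sum_i target_i * log(target_i / predicted_i)`
#' with the convention `0 * log 0 = 0`. Predicted probabilities are floored
#' at `eps` before the logarithm for numerical stability.
#'
#' @param target,predicted Probability vectors of equal length, or matrices
#'   with one distribution per row (row-wise divergences are returned).
#' @param eps Floor applied to predicted probabilities (default 1e-12).
#' @return Non-negative numeric vector of divergences (in nats).
#' @export
kl_divergence <- function(target, predicted, eps = 1e-12) {
  if (is.null(dim(target))) target <- matrix(target, nrow = 1L)
  if (is.null(dim(predicted))) predicted <- matrix(predicted, nrow = 1L)
  if (!all(dim(target) == dim(predicted))) {
    stop("target and predicted distributions have mismatched shapes")
  }
  check_distribution(target)
  check_distribution(predicted)
  p <- pmax(predicted, eps)
  terms <- target * (log(pmax(target, eps)) - log(p))
  terms[target == 0] <- 0
  pmax(rowSums(terms), 0)
}
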