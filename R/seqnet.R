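#' One-hot encode a batch of sequences with dynamic padding
#'
#' Sequences are encoded over channels A, C, G, T and right-padded with
#' all-zero columns to the longest sequence in the batch (dynamic padding --
#' sequences are never truncated; anything longer than `max_len` is an
#' error). Each real position is one-hot (channels sum to 1), padded
#' positions are all-zero.
#'
#' @param sequences Character vector of A/C/G/T sequences.
#' @param max_len Hard length cap (default 200).
#' @param pad_to Optional fixed padded length (defaults to the batch
#'   maximum); useful for checking padding invariance.
#' @return A `one_hot_batch`: list with `x` (numeric array
#'   `[position, item, channel]`), `mask` (numeric `[position, item]`, 1 at
#'   real positions), `lengths`, and `channels = c("A","C","G","T")`.
#' @export
one_hot_encode <- function(sequences, max_len = 200L, pad_to = NULL) {
  stopifnot(length(sequences) >= 1L)
  vapply(sequences, check_one_sequence, character(1))
  lens <- nchar(sequences)
  if (any(lens > max_len)) {
    stop("sequence(s) longer than max_len = ", max_len,
         " (padding never truncates): index ",
         paste(utils::head(which(lens > max_len), 5L), collapse = ", "))
  }
  L <- if (is.null(pad_to)) max(lens) else as.integer(pad_to)
  if (L < max(lens)) stop("pad_to is shorter than the longest sequence")
  n <- length(sequences)
  x <- array(0, dim = c(L, n, 4L))
  channels <- c("A", "C", "G", "T")
  for (i in seq_len(n)) {
    codes <- match(strsplit(sequences[i], "")[[1L]], channels)
    x[cbind(seq_len(lens[i]), i, codes)] <- 1
  }
  mask <- matrix(0, L, n)
  for (i in seq_len(n)) mask[seq_len(lens[i]), i] <- 1
  structure(list(x = x, mask = mask, lengths = lens, channels = channels),
            class = "one_hot_batch")
}

#' Network architecture configuration
#'
#' The network is a fully convolutional soft-classifier over expression
#' bins: a stem (standard convolution, batch normalization, SiLU), six
#' convolutional blocks with grouped convolutions, squeeze-and-excitation
#' gates whose excitation stage uses a low-rank bilinear factorization, and
#' channel-wise residual connections; channel-count changes are handled by
#' resizing blocks shaped like the stem. All convolutions are "same"-padded
#' and stride 1 (blocks act on channels only, never downsample positions).
#' The head is a pointwise convolution followed by masked global average
#' pooling over real positions and a softmax over the bins, so every output
#' row is a valid bin distribution.
#'
#' @param stem_channels Channels after the stem (default 256).
#' @param block_channels Channel counts of the six blocks
#'   (default `c(128, 128, 64, 64, 64, 64)`).
#' @param stem_kernel Stem / resizing-block kernel size (default 7, odd).
#' @param block_kernel Grouped-convolution kernel size (default 3, odd).
#' @param n_bins Output bins (default 29).
#' @param groups Group count of the grouped convolutions (default 4; every
#'   channel count must be divisible by it).
#' @param se_rank Rank of the squeeze-and-excitation factorization; `NULL`
#'   (default) uses channels/4 per block.
#' @param max_len Maximum input length (default 200).
#' @return A `seqnet_config`.
#' @export
seqnet_config <- function(stem_channels = 256L,
                          block_channels = c(128L, 128L, 64L, 64L, 64L, 64L),
                          stem_kernel = 7L, block_kernel = 3L,
                          n_bins = 29L, groups = 4L, se_rank = NULL,
                          max_len = 200L) {
  stopifnot(stem_kernel %% 2L == 1L, block_kernel %% 2L == 1L,
            all(c(stem_channels, block_channels) %% groups == 0L))
  structure(list(stem_channels = as.integer(stem_channels),
                 block_channels = as.integer(block_channels),
                 stem_kernel = as.integer(stem_kernel),
                 block_kernel = as.integer(block_kernel),
                 n_bins = as.integer(n_bins), groups = as.integer(groups),
                 se_rank = se_rank, max_len = as.integer(max_len)),
            class = "seqnet_config")
}

# ---- internal layer machinery -------------------------------------------
# Activations flow as matrices of shape (L*n, C); row index = position +
# (item-1)*L, so the matrix doubles as an array [L, n, C]. `mv` is the 0/1
# mask over rows; every op output is re-masked so padded positions stay
# exactly zero and results are invariant to the declared padded length.

shift_rows <- function(m, s, L, n) {
  if (s == 0L) return(m)
  C <- ncol(m)
  a <- m; dim(a) <- c(L, n, C)
  out <- array(0, dim = c(L, n, C))
  if (s > 0L) out[seq_len(L - s), , ] <- a[seq_len(L - s) + s, , ]
  else out[seq_len(L + s) - s, , ] <- a[seq_len(L + s), , ]
  dim(out) <- c(L * n, C)
  out
}

group_mask <- function(c_in, c_out, k, groups) {
  gm <- array(0, dim = c(c_in, c_out, k))
  gi <- rep(seq_len(groups), each = c_in / groups)
  go <- rep(seq_len(groups), each = c_out / groups)
  for (g in seq_len(groups)) gm[gi == g, go == g, ] <- 1
  gm
}

init_conv <- function(c_in, c_out, k, groups = 1L, out_scale = 1) {
  fan_in <- k * c_in / groups
  W <- array(stats::rnorm(c_in * c_out * k, 0, sqrt(2 / fan_in) * out_scale),
             dim = c(c_in, c_out, k))
  wmask <- if (groups > 1L) group_mask(c_in, c_out, k, groups) else NULL
  if (!is.null(wmask)) W <- W * wmask
  list(type = "conv", W = W, b = numeric(c_out), wmask = wmask)
}

conv_fwd <- function(op, x, L, n) {
  k <- dim(op$W)[3L]
  r <- (k - 1L) %/% 2L
  y <- matrix(0, nrow(x), dim(op$W)[2L])
  for (j in seq_len(k)) {
    y <- y + shift_rows(x, j - r - 1L, L, n) %*% op$W[, , j]
  }
  sweep(y, 2L, op$b, "+")
}

conv_bwd <- function(op, x, dy, L, n) {
  k <- dim(op$W)[3L]
  r <- (k - 1L) %/% 2L
  dW <- array(0, dim = dim(op$W))
  dx <- matrix(0, nrow(x), ncol(x))
  for (j in seq_len(k)) {
    s <- j - r - 1L
    dW[, , j] <- crossprod(shift_rows(x, s, L, n), dy)
    dx <- dx + shift_rows(dy, -s, L, n) %*% t(op$W[, , j])
  }
  if (!is.null(op$wmask)) dW <- dW * op$wmask
  list(dW = dW, db = colSums(dy), dx = dx)
}

init_bn <- function(C) {
  list(type = "bn", gamma = rep(1, C), beta = numeric(C),
       run_mean = numeric(C), run_var = rep(1, C))
}

bn_fwd <- function(op, x, mv, train, eps = 1e-5) {
  if (train) {
    N <- sum(mv)
    mu <- colSums(x * mv) / N
    xc <- sweep(x, 2L, mu)
    v <- colSums(xc * xc * mv) / N
  } else {
    mu <- op$run_mean; v <- op$run_var
    xc <- sweep(x, 2L, mu)
    N <- sum(mv)
  }
  ivar <- 1 / sqrt(v + eps)
  xhat <- sweep(xc, 2L, ivar, "*")
  y <- sweep(sweep(xhat, 2L, op$gamma, "*"), 2L, op$beta, "+")
  list(y = y, cache = list(xhat = xhat, ivar = ivar, N = N, mu = mu, v = v))
}

bn_bwd <- function(op, cache, dy, mv) {
  xhat <- cache$xhat; ivar <- cache$ivar; N <- cache$N
  dgamma <- colSums(dy * xhat)
  dbeta <- colSums(dy)
  dxhat <- sweep(dy, 2L, op$gamma, "*")
  s1 <- colSums(dxhat)           # dy already masked
  s2 <- colSums(dxhat * xhat)
  dx <- sweep(dxhat, 2L, s1 / N) - sweep(xhat, 2L, s2 / N, "*")
  dx <- sweep(dx, 2L, ivar, "*") * mv
  list(dgamma = dgamma, dbeta = dbeta, dx = dx)
}

silu <- function(x) x * stats::plogis(x)
silu_grad <- function(x) {
  s <- stats::plogis(x)
  s * (1 + x * (1 - s))
}

init_se <- function(C, rank) {
  list(type = "se",
       U = matrix(stats::rnorm(C * rank, 0, sqrt(2 / C)), C, rank),
       bu = numeric(rank),
       V = matrix(stats::rnorm(rank * C, 0, sqrt(1 / rank)), rank, C),
       bv = numeric(C))
}

item_pool <- function(x, L, n) {
  a <- x; dim(a) <- c(L, n * ncol(x))
  matrix(colSums(a), n, ncol(x))
}

se_fwd <- function(op, x, L, n, lens) {
  s <- item_pool(x, L, n) / lens
  u <- sweep(s %*% op$U, 2L, op$bu, "+")
  a <- silu(u)
  v <- sweep(a %*% op$V, 2L, op$bv, "+")
  g <- stats::plogis(v)
  ib <- rep(seq_len(n), each = L)
  list(y = x * g[ib, , drop = FALSE],
       cache = list(xin = x, s = s, u = u, a = a, g = g, ib = ib))
}

se_bwd <- function(op, cache, dy, L, n, lens, mv) {
  x <- cache$xin
  g_full <- cache$g[cache$ib, , drop = FALSE]
  dx <- dy * g_full
  dg <- item_pool(dy * x, L, n)
  dv <- dg * cache$g * (1 - cache$g)
  dV <- crossprod(cache$a, dv)
  dbv <- colSums(dv)
  da <- dv %*% t(op$V)
  du <- da * silu_grad(cache$u)
  dU <- crossprod(cache$s, du)
  dbu <- colSums(du)
  ds <- (du %*% t(op$U)) / lens
  dx <- dx + ds[cache$ib, , drop = FALSE] * mv
  list(dU = dU, dbu = dbu, dV = dV, dbv = dbv, dx = dx)
}

# ---- network assembly ----------------------------------------------------

#' Build the soft-classification network
#'
#' Initializes all weights (He-style for convolutions) from the given seed.
#'
#' @param config A [seqnet_config()].
#' @param seed Integer seed for weight initialization.
#' @return A `seqnet` object (untrained): config, ops (layer stack with
#'   parameters), `bin_spec = NULL` until training, empty `loss_trace`.
#' @export
build_seqnet <- function(config = seqnet_config(), seed = 1L) {
  stopifnot(inherits(config, "seqnet_config"))
  with_seed(seed, {
    ops <- list()
    push <- function(op) ops[[length(ops) + 1L]] <<- op
    push(init_conv(4L, config$stem_channels, config$stem_kernel))
    push(init_bn(config$stem_channels))
    push(list(type = "silu"))
    prev <- config$stem_channels
    for (ci in config$block_channels) {
      if (ci != prev) {  # resizing block, shaped like the stem
        push(init_conv(prev, ci, config$stem_kernel))
        push(init_bn(ci))
        push(list(type = "silu"))
        prev <- ci
      }
      rank <- if (is.null(config$se_rank)) max(1L, ci %/% 4L) else config$se_rank
      push(list(type = "save"))
      push(init_conv(ci, ci, config$block_kernel, groups = config$groups))
      push(init_bn(ci))
      push(list(type = "silu"))
      push(init_se(ci, rank))
      push(init_conv(ci, ci, 1L))        # pointwise
      push(init_bn(ci))
      push(list(type = "add"))
    }
    push(init_conv(prev, config$n_bins, 1L, out_scale = 0.1))  # head
    structure(list(config = config, ops = ops, bin_spec = NULL,
                   loss_trace = numeric(0)),
              class = "seqnet")
  })
}

#' @export
print.seqnet <- function(x, ...) {
  n_par <- sum(vapply(x$ops, function(op) {
    sum(vapply(op[names(op) %in% c("W", "b", "gamma", "beta", "U", "bu", "V", "bv")],
               length, integer(1)))
  }, numeric(1)))
  cat(sprintf("<seqnet> stem %d, blocks [%s], %d bins, %s parameters; %s\n",
              x$config$stem_channels,
              paste(x$config$block_channels, collapse = ","),
              x$config$n_bins, format(n_par, big.mark = ","),
              if (length(x$loss_trace)) sprintf("trained %d epochs (final KL %.4f)",
                                                length(x$loss_trace),
                                                x$loss_trace[length(x$loss_trace)])
              else "untrained"))
  invisible(x)
}

seqnet_forward <- function(net, batch, train = FALSE, keep_cache = FALSE) {
  L <- dim(batch$x)[1L]; n <- dim(batch$x)[2L]
  x <- batch$x; dim(x) <- c(L * n, 4L)
  mv <- as.numeric(batch$mask); dim(mv) <- NULL
  lens <- batch$lengths
  caches <- if (keep_cache) vector("list", length(net$ops)) else NULL
  saved <- NULL
  for (i in seq_along(net$ops)) {
    op <- net$ops[[i]]
    inp <- x
    if (op$type == "conv") {
      x <- conv_fwd(op, x, L, n)
    } else if (op$type == "bn") {
      res <- bn_fwd(op, x, mv, train)
      x <- res$y
      if (train) {  # update running stats in the enclosing trainer
        net$ops[[i]]$run_mean <- 0.9 * op$run_mean + 0.1 * res$cache$mu
        net$ops[[i]]$run_var <- 0.9 * op$run_var + 0.1 * res$cache$v
      }
      if (keep_cache) caches[[i]] <- res$cache
    } else if (op$type == "silu") {
      x <- silu(x)
    } else if (op$type == "se") {
      res <- se_fwd(op, x, L, n, lens)
      x <- res$y
      if (keep_cache) caches[[i]] <- res$cache
    } else if (op$type == "save") {
      saved <- x
    } else if (op$type == "add") {
      x <- x + saved
    }
    x <- x * mv
    if (keep_cache && is.null(caches[[i]])) caches[[i]] <- inp
  }
  logits <- item_pool(x, L, n) / lens
  z <- logits - apply(logits, 1L, max)
  ez <- exp(z)
  probs <- ez / rowSums(ez)
  list(probs = probs, logits = logits, caches = caches, net = net,
       L = L, n = n, mv = mv, lens = lens)
}

seqnet_backward <- function(net, fwd, dlogits) {
  L <- fwd$L; n <- fwd$n; mv <- fwd$mv; lens <- fwd$lens
  ib <- rep(seq_len(n), each = L)
  dx <- (dlogits / lens)[ib, , drop = FALSE] * mv
  grads <- vector("list", length(net$ops))
  dsaved <- NULL
  for (i in rev(seq_along(net$ops))) {
    op <- net$ops[[i]]
    dx <- dx * mv
    if (op$type == "conv") {
      g <- conv_bwd(op, fwd$caches[[i]], dx, L, n)
      grads[[i]] <- g[c("dW", "db")]
      dx <- g$dx
    } else if (op$type == "bn") {
      g <- bn_bwd(op, fwd$caches[[i]], dx, mv)
      grads[[i]] <- g[c("dgamma", "dbeta")]
      dx <- g$dx
    } else if (op$type == "silu") {
      dx <- dx * silu_grad(fwd$caches[[i]])
    } else if (op$type == "se") {
      g <- se_bwd(op, fwd$caches[[i]], dx, L, n, lens, mv)
      grads[[i]] <- g[c("dU", "dbu", "dV", "dbv")]
      dx <- g$dx
    } else if (op$type == "save") {
      dx <- dx + dsaved
    } else if (op$type == "add") {
      dsaved <- dx
    }
  }
  grads
}

param_fields <- c(W = "dW", b = "db", gamma = "dgamma", beta = "dbeta",
                  U = "dU", bu = "dbu", V = "dV", bv = "dbv")

#' Training configuration (Lion optimizer)
#'
#' The Lion optimizer keeps one momentum buffer per parameter and applies
#' sign-based updates:
#' `update = sign(beta1 * m + (1 - beta1) * g)`, then
#' `m <- beta2 * m + (1 - beta2) * g`, with decoupled weight decay. Defaults
#' follow the optimizer's published recommendation (learning rates roughly
#' 3-10x smaller than Adam's).
#'
#' @param lr Learning rate (default 1e-4).
#' @param beta1,beta2 Momentum interpolation factors (defaults 0.9, 0.99).
#' @param weight_decay Decoupled weight decay (default 1e-2; applied to
#'   convolution and excitation weights, not to biases or normalization
#'   parameters).
#' @param epochs Training epochs (default 30).
#' @param batch_size Minibatch size (default 64).
#' @param seed Seed for shuffling (weight init is seeded in [build_seqnet()]).
#' @return A `seqnet_train_config`.
#' @export
seqnet_train_config <- function(lr = 1e-4, beta1 = 0.9, beta2 = 0.99,
                                weight_decay = 1e-2, epochs = 30L,
                                batch_size = 64L, seed = 1L) {
  stopifnot(lr > 0, epochs >= 1L, batch_size >= 1L)
  structure(list(lr = lr, beta1 = beta1, beta2 = beta2,
                 weight_decay = weight_decay, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), seed = as.integer(seed)),
            class = "seqnet_train_config")
}

lion_step <- function(net, grads, mom, cfg) {
  decayed <- c("W", "U", "V")
  for (i in seq_along(net$ops)) {
    if (is.null(grads[[i]])) next
    op <- net$ops[[i]]
    for (p in names(param_fields)) {
      if (is.null(op[[p]])) next
      g <- grads[[i]][[param_fields[[p]]]]
      if (is.null(g)) next
      m <- mom[[i]][[p]]
      if (is.null(m)) m <- g * 0
      u <- sign(cfg$beta1 * m + (1 - cfg$beta1) * g)
      if (p %in% decayed) u <- u + cfg$weight_decay * op[[p]]
      op[[p]] <- op[[p]] - cfg$lr * u
      if (p == "W" && !is.null(op$wmask)) op[[p]] <- op[[p]] * op$wmask
      mom[[i]][[p]] <- cfg$beta2 * m + (1 - cfg$beta2) * g
    }
    net$ops[[i]] <- op
  }
  list(net = net, mom = mom)
}

#' Train the soft-classification network
#'
#' Minimizes the mean Kullback-Leibler divergence between the encoded target
#' bin distributions and the network's output distributions, using the Lion
#' optimizer. Fully deterministic for fixed seeds on one CPU.
#'
#' @param sequences Character vector of training sequences.
#' @param te Numeric TE labels (TE scale).
#' @param config A [seqnet_config()].
#' @param train_config A [seqnet_train_config()].
#' @param spec A [bin_spec()]; by default fitted to `te` with
#'   [fit_bin_spec()] and stored with the model.
#' @param net Optionally continue training an existing `seqnet`.
#' @param verbose Print per-epoch loss (default `FALSE`).
#' @return The trained `seqnet` with `loss_trace` (per-epoch mean KL, nats)
#'   and the `bin_spec` attached.
#' @export
train_seqnet <- function(sequences, te, config = seqnet_config(),
                         train_config = seqnet_train_config(),
                         spec = NULL, net = NULL, verbose = FALSE) {
  stopifnot(length(sequences) == length(te), all(is.finite(te)))
  if (is.null(spec)) {
    spec <- if (stats::sd(te) > 0) fit_bin_spec(te, n_bins = config$n_bins)
            else bin_spec(n_bins = config$n_bins)
  }
  if (is.null(net)) net <- build_seqnet(config, seed = train_config$seed)
  net$bin_spec <- spec
  targets <- encode_expression(te_to_bin(te, spec), spec)
  n <- length(sequences)
  mom <- vector("list", length(net$ops))
  trace <- net$loss_trace
  with_seed(train_config$seed + 1L, {
    for (epoch in seq_len(train_config$epochs)) {
      ord <- sample.int(n)
      total <- 0
      for (start in seq(1L, n, by = train_config$batch_size)) {
        idx <- ord[start:min(start + train_config$batch_size - 1L, n)]
        batch <- one_hot_encode(sequences[idx], max_len = net$config$max_len)
        fwd <- seqnet_forward(net, batch, train = TRUE, keep_cache = TRUE)
        net <- fwd$net  # running BN stats
        tt <- targets[idx, , drop = FALSE]
        kl <- kl_divergence(tt, fwd$probs)
        if (any(!is.finite(kl))) stop("divergent loss (non-finite KL) at epoch ", epoch)
        total <- total + sum(kl)
        dlogits <- (fwd$probs - tt) / length(idx)
        grads <- seqnet_backward(net, fwd, dlogits)
        upd <- lion_step(net, grads, mom, train_config)
        net <- upd$net; mom <- upd$mom
      }
      trace <- c(trace, total / n)
      if (verbose) message(sprintf("epoch %d: mean KL %.4f", epoch, total / n))
    }
  })
  net$loss_trace <- trace
  net
}

#' Predict bin distributions
#'
#' Forward pass in evaluation mode (running batch-norm statistics).
#'
#' @param net A trained `seqnet`.
#' @param sequences Character vector of sequences.
#' @param batch_size Evaluation batch size (default 128).
#' @return Matrix `length(sequences) x n_bins`; each row is a valid bin
#'   distribution.
#' @export
predict_seqnet_probs <- function(net, sequences, batch_size = 128L) {
  stopifnot(inherits(net, "seqnet"))
  out <- matrix(0, length(sequences), net$config$n_bins)
  for (start in seq(1L, length(sequences), by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, length(sequences))
    batch <- one_hot_encode(sequences[idx], max_len = net$config$max_len)
    out[idx, ] <- seqnet_forward(net, batch, train = FALSE)$probs
  }
  out
}

#' Predict expression values
#'
#' Forward pass, decode each output distribution to its expectation over bin
#' indices, then map back to the TE scale through the model's stored label
#' map.
#'
#' @inheritParams predict_seqnet_probs
#' @return Numeric vector of TE-scale predictions, bounded by the label-map
#'   images of bins 0 and `n_bins - 1`.
#' @export
predict_seqnet <- function(net, sequences, batch_size = 128L) {
  if (is.null(net$bin_spec)) stop("net carries no bin_spec; train it first")
  probs <- predict_seqnet_probs(net, sequences, batch_size)
  bin_to_te(decode_expression(probs, net$bin_spec), net$bin_spec)
}
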