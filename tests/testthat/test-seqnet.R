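tiny_config <- function() {
  seqnet_config(stem_channels = 8, block_channels = c(8, 4), stem_kernel = 5,
                block_kernel = 3, n_bins = 5, groups = 2, se_rank = 2,
                max_len = 30)
}

test_that("one-hot encoding pads dynamically and never truncates", {
  b <- one_hot_encode(c("ACGT", "GG"), max_len = 10)
  expect_equal(dim(b$x), c(4, 2, 4))          # padded to batch max, not 10
  expect_equal(b$lengths, c(4, 2))
  # channel order A, C, G, T
  expect_equal(b$x[1, 1, ], c(1, 0, 0, 0))
  expect_equal(b$x[3, 2, ], c(0, 0, 0, 0))    # padding all-zero
  expect_equal(b$x[1, 2, ], c(0, 0, 1, 0))
  # real positions one-hot, padded positions zero
  sums <- apply(b$x, c(1, 2), sum)
  expect_equal(sums, b$mask)
  b2 <- one_hot_encode(c("ACGT", "TTTT"))
  expect_equal(dim(b2$x)[1], 4)               # equal lengths: no padding
  expect_true(all(apply(b2$x, c(1, 2), sum) == 1))
  expect_error(one_hot_encode("ACGTACGT", max_len = 4), "never truncates")
  expect_error(one_hot_encode("ACNT"), "non-ACGT")
})

test_that("analytic gradients match numerical differentiation", {
  set.seed(42)
  net <- build_seqnet(tiny_config(), seed = 9)
  seqs <- c("ACGTACGTACGT", "GGGCCCAAA", "ATATATATATATATAT")
  te <- c(0.5, 2.0, 3.5)
  spec <- fit_bin_spec(te, n_bins = 5)
  targets <- encode_expression(te_to_bin(te, spec), spec)
  batch <- one_hot_encode(seqs, max_len = 20)
  loss_fn <- function(nn) {
    mean(kl_divergence(targets, seqnet_forward(nn, batch, train = TRUE)$probs,
                       eps = 0))
  }
  fwd <- seqnet_forward(net, batch, train = TRUE, keep_cache = TRUE)
  grads <- seqnet_backward(net, fwd, (fwd$probs - targets) / 3)

  eps <- 1e-6
  pf <- c(W = "dW", b = "db", gamma = "dgamma", beta = "dbeta",
          U = "dU", bu = "dbu", V = "dV", bv = "dbv")
  worst <- 0
  for (i in seq_along(net$ops)) {
    op <- net$ops[[i]]
    for (p in names(pf)) {
      if (is.null(op[[p]]) || is.null(grads[[i]][[pf[[p]]]])) next
      for (j in sample(length(op[[p]]), min(3, length(op[[p]])))) {
        if (!is.null(op$wmask) && p == "W" && op$wmask[j] == 0) next
        n1 <- net; n1$ops[[i]][[p]][j] <- n1$ops[[i]][[p]][j] + eps
        n2 <- net; n2$ops[[i]][[p]][j] <- n2$ops[[i]][[p]][j] - eps
        num <- (loss_fn(n1) - loss_fn(n2)) / (2 * eps)
        ana <- grads[[i]][[pf[[p]]]][j]
        worst <- max(worst, abs(num - ana) / max(1e-8, abs(num) + abs(ana)))
      }
    }
  }
  expect_lt(worst, 1e-4)
})

test_that("outputs are valid bin distributions of the configured width", {
  net <- build_seqnet(seqnet_config(), seed = 1)  # full-width default config
  b <- one_hot_encode(c("ACGTACGTACGTACGT", "GGCCGGCC"))
  out <- seqnet_forward(net, b)
  expect_equal(dim(out$probs), c(2, 29))
  expect_equal(rowSums(out$probs), c(1, 1), tolerance = 1e-6)
  expect_true(all(out$probs >= 0))
  # evaluation mode is deterministic
  out2 <- seqnet_forward(net, b)
  expect_identical(out$probs, out2$probs)
})

test_that("masked pooling makes outputs invariant to the declared padding", {
  set.seed(2)
  net <- build_seqnet(tiny_config(), seed = 3)
  seqs <- c("ACGTACGTAC", "GGG", "ATATATATATATAT")
  b_tight <- one_hot_encode(seqs)                # padded to 14
  b_wide <- one_hot_encode(seqs, pad_to = 30)    # padded to 30
  p1 <- seqnet_forward(net, b_tight)$probs
  p2 <- seqnet_forward(net, b_wide)$probs
  expect_equal(p1, p2, tolerance = 1e-5)
  # duplicate inputs give identical outputs
  b3 <- one_hot_encode(c(seqs[1], seqs[1]))
  p3 <- seqnet_forward(net, b3)$probs
  expect_equal(p3[1, ], p3[2, ], tolerance = 1e-12)
})

test_that("training reduces the KL loss and is seed-reproducible", {
  set.seed(4)
  seqs <- replicate(40, random_seq(sample(15:25, 1)))
  te <- vapply(seqs, function(s) upstream_aug_count(s), integer(1))
  tc <- seqnet_train_config(lr = 1e-3, epochs = 4, batch_size = 16, seed = 5)
  net <- train_seqnet(seqs, te, tiny_config(), tc)
  expect_length(net$loss_trace, 4)
  expect_lt(net$loss_trace[4], net$loss_trace[1])
  net2 <- train_seqnet(seqs, te, tiny_config(), tc)
  expect_identical(net$loss_trace, net2$loss_trace)
  preds <- predict_seqnet(net, seqs)
  lo <- bin_to_te(0, net$bin_spec); hi <- bin_to_te(4, net$bin_spec)
  expect_true(all(preds >= lo & preds <= hi))
})

test_that("a single repeated sequence is memorized to its label", {
  seqs <- rep("ACGGGTACGTTACGATGCAT", 8)
  te <- rep(2, 8)
  spec <- bin_spec(n_bins = 5)  # identity label map; label sits at bin 2
  net <- train_seqnet(seqs, te, tiny_config(),
                      seqnet_train_config(lr = 3e-3, epochs = 150,
                                          batch_size = 8, seed = 6),
                      spec = spec)
  expect_lt(net$loss_trace[length(net$loss_trace)], 0.05)
  pred_bin <- decode_expression(predict_seqnet_probs(net, seqs[1]), spec)
  target_bin <- decode_expression(encode_expression(2, spec), spec)
  expect_lt(abs(pred_bin - target_bin), 0.1)
})
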