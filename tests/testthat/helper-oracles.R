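# Independent oracles used across test files. These deliberately avoid the
# package's own computational paths.

# Expected decoded value of the codec under the latent-normal model:
# E[clamp(floor(rho), 0, n_bins - 1)] with rho ~ N(e + mu_offset, sigma),
# computed by direct summation over a wide integer range.
oracle_decode <- function(e, n_bins = 29, mu_offset = 0.5, sigma = 0.5) {
  ks <- seq(-200L, 200L + n_bins)
  p <- pnorm(ks + 1, mean = e + mu_offset, sd = sigma) -
    pnorm(ks, mean = e + mu_offset, sd = sigma)
  sum(pmin(pmax(ks, 0), n_bins - 1) * p)
}

# Random sequence helpers.
random_seq <- function(len, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# Greedy incremental clustering written as a literal transcription of the
# procedure: sort longest-first, compare each sequence against existing
# representatives one at a time in creation order, join the first cluster
# whose representative passes the threshold, else found a new cluster.
# Scalar identity calls, no vectorization, no prefilter.
brute_force_cluster <- function(dataset, params) {
  ord <- order(-nchar(dataset$sequence), dataset$id)
  ids <- dataset$id[ord]
  seqs <- dataset$sequence[ord]
  reps <- character(0)
  members <- list()
  for (i in seq_along(seqs)) {
    assigned <- 0L
    for (j in seq_along(reps)) {
      if (pairwise_identity(seqs[i], reps[j], params) >= params$threshold) {
        assigned <- j
        break
      }
    }
    if (assigned > 0L) {
      members[[assigned]] <- c(members[[assigned]], ids[i])
    } else {
      reps <- c(reps, seqs[i])
      members[[length(reps)]] <- ids[i]
    }
  }
  members
}

partition_signature <- function(members) {
  lapply(members, sort)
}

# Point-mutate a sequence (substitutions only, always changing the base).
mutate_sequence_for_test <- function(sequence, rate) {
  v <- strsplit(sequence, "")[[1]]
  hit <- which(runif(length(v)) < rate)
  for (j in hit) v[j] <- sample(setdiff(c("A", "C", "G", "T"), v[j]), 1)
  paste(v, collapse = "")
}

# Random probability vector over k bins.
random_distribution <- function(k) {
  x <- rexp(k)
  x / sum(x)
}
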