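test_that("pairwise identity matches forced-alignment oracles", {
  p <- similarity_params()
  expect_equal(pairwise_identity("ACGT", "ACGT", p), 1)
  expect_equal(pairwise_identity("AAAA", "TTTT", p), 0)
  # single substitution between 8-mers: 7 matching columns out of 8
  expect_equal(pairwise_identity("ACGTACGT", "ACGAACGT", p), 7 / 8)
  # prefix with a forced terminal gap block: 8 matches over 10 columns
  expect_equal(pairwise_identity("ACGTACGT", "ACGTACGTTT", p), 8 / 10)

  # with prohibitive interior gaps, equal-length alignments are ungapped,
  # so identity equals the plain per-position match fraction
  set.seed(21)
  for (rep_ in 1:25) {
    L <- sample(20:80, 1)
    a <- random_seq(L); b <- random_seq(L)
    hamming <- mean(strsplit(a, "")[[1]] == strsplit(b, "")[[1]])
    expect_equal(pairwise_identity(a, b, p), hamming)
    expect_equal(pairwise_identity(a, b, p), pairwise_identity(b, a, p))
  }
  expect_error(pairwise_identity("", "ACGT", p), "empty")
})

test_that("shorter-sequence denominator is selectable", {
  p <- similarity_params(denominator = "shorter")
  expect_equal(pairwise_identity("ACGTACGT", "ACGTACGTTT", p), 1)  # 8/8
  expect_equal(pairwise_identity("ACGT", "ACGT", p), 1)
})

test_that("greedy clustering follows the longest-first first-fit procedure", {
  p <- similarity_params(threshold = 0.5)
  ds <- utr_dataset(c("a", "b", "c"), rep("ACGTACGTACGT", 3))
  cl <- greedy_cluster(ds, p)
  expect_equal(length(cl$clusters), 1)
  expect_equal(sort(cl$clusters[[1]]$member_ids), c("a", "b", "c"))

  ds2 <- utr_dataset(c("polyA", "polyT"),
                     c(strrep("A", 40), strrep("T", 40)))
  cl2 <- greedy_cluster(ds2, p)
  expect_equal(length(cl2$clusters), 2)

  # representative is the longest member of its cluster
  set.seed(31)
  base <- random_seq(60)
  ds3 <- utr_dataset(c("short", "long"),
                     c(substr(base, 1, 50), base))
  cl3 <- greedy_cluster(ds3, p)
  expect_equal(length(cl3$clusters), 1)
  expect_equal(cl3$clusters[[1]]$representative_id, "long")
})

test_that("greedy clustering equals the literal brute-force reference", {
  set.seed(41)
  thresholds <- c(0.3, 0.5, 0.8)
  for (inst in 1:30) {
    n <- sample(6:25, 1)
    ds <- utr_dataset(sprintf("s%02d", 1:n),
                      replicate(n, random_seq(sample(20:60, 1))))
    p <- similarity_params(threshold = thresholds[(inst %% 3) + 1])
    got <- lapply(greedy_cluster(ds, p)$clusters, function(cl) cl$member_ids)
    want <- brute_force_cluster(ds, p)
    expect_identical(partition_signature(got), partition_signature(want))
  }
})

test_that("the clustering is a partition and thresholds act monotonically", {
  set.seed(51)
  ds <- utr_dataset(sprintf("s%02d", 1:30),
                    replicate(30, random_seq(sample(40:80, 1))))
  n_clusters <- vapply(c(0.2, 0.35, 0.5, 0.7, 0.9), function(th) {
    cl <- greedy_cluster(ds, similarity_params(threshold = th))
    asg <- cluster_assignments(cl)
    expect_setequal(asg$member_id, ds$id)        # every id exactly once
    expect_equal(nrow(asg), nrow(ds))
    expect_equal(sum(cluster_sizes(cl)), nrow(ds))
    length(cl$clusters)
  }, integer(1))
  expect_true(all(diff(n_clusters) >= 0))
})

test_that("representative test set excludes singletons", {
  p <- similarity_params(threshold = 0.5)
  set.seed(61)
  s1 <- random_seq(60); s2 <- random_seq(60)
  ds <- utr_dataset(
    c("a1", "a2", "a3", "b1", "b2", "solo"),
    c(s1,
      mutate_sequence_for_test(s1, 0.05), mutate_sequence_for_test(s1, 0.05),
      s2, mutate_sequence_for_test(s2, 0.05),
      random_seq(60)))
  cl <- greedy_cluster(ds, p)
  expect_equal(length(cl$clusters), 3)
  ts <- build_test_set(cl)
  expect_length(ts, 2)
  reps <- vapply(cl$clusters[cluster_sizes(cl) >= 2],
                 function(x) x$representative_id, character(1))
  expect_setequal(ts, reps)

  singles <- utr_dataset(c("x", "y"), c(strrep("A", 30), strrep("G", 30)))
  cls <- greedy_cluster(singles, p)
  expect_warning(empty <- build_test_set(cls), "singleton")
  expect_length(empty, 0)
})

test_that("subset selection obeys count and ceiling rules deterministically", {
  fake <- structure(list(clusters = list(
    list(representative_id = "r1", member_ids = paste0("a", 1:10)),
    list(representative_id = "r2", member_ids = paste0("b", 1:4)),
    list(representative_id = "r3", member_ids = paste0("c", 1:3))
  ), params = similarity_params(), n = 17), class = "utr_clustering")

  sel <- select_count(fake, per_cluster = 6, seed = 5)
  expect_length(intersect(sel, paste0("a", 1:10)), 6)
  expect_length(intersect(sel, paste0("b", 1:4)), 4)   # fewer than six: all
  expect_length(intersect(sel, paste0("c", 1:3)), 3)
  expect_identical(sel, select_count(fake, per_cluster = 6, seed = 5))
  expect_true(length(sel) <= sum(pmin(6, cluster_sizes(fake))))

  half <- select_percentage(fake, 0.5, seed = 2)
  expect_length(intersect(half, paste0("a", 1:10)), 5)
  expect_length(intersect(half, paste0("b", 1:4)), 2)
  expect_length(intersect(half, paste0("c", 1:3)), 2)  # ceil(1.5)
  expect_identical(half, select_percentage(fake, 0.5, seed = 2))

  all_of_them <- select_percentage(fake, 1.0, seed = 9, exclude = c("a1", "b1"))
  expect_setequal(all_of_them, setdiff(c(paste0("a", 1:10), paste0("b", 1:4),
                                         paste0("c", 1:3)), c("a1", "b1")))
  # exclusions are respected by count selection too
  sel2 <- select_count(fake, per_cluster = 6, seed = 5, exclude = paste0("b", 1:4))
  expect_length(intersect(sel2, paste0("b", 1:4)), 0)
})

test_that("compression metrics follow their definitions", {
  m <- compression_metrics(5838, 2468, 0.9, 0.84)
  expect_equal(m$compression_rate, 1 - 2468 / 5838)
  expect_equal(round(m$compression_rate, 2), 0.58)
  expect_equal(compression_metrics(100, 100, 0.8, 0.8)$accuracy_restoration, 1)
  expect_equal(compression_metrics(100, 100, 0.8, 0.8)$compression_rate, 0)
  expect_equal(compression_metrics(10, 5, 0.6, 0.3)$accuracy_restoration, 0.5)
  expect_error(compression_metrics(10, 5, 0, 0.3), "undefined")
})

test_that("clustering files round-trip the assignment table", {
  set.seed(71)
  ds <- utr_dataset(sprintf("s%d", 1:8), replicate(8, random_seq(50)))
  cl <- greedy_cluster(ds, similarity_params(threshold = 0.4))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  clstr <- withr::local_tempfile(fileext = ".clstr")
  write_clustering(cl, tsv, clstr, dataset = ds)
  back <- read.table(tsv, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  expect_equal(back, cluster_assignments(cl))
  expect_equal(sum(grepl("^>Cluster", readLines(clstr))), length(cl$clusters))
})
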