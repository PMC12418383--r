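#' Sequence-similarity parameters for greedy clustering
#'
#' Pairwise identity is computed from an optimal Needleman-Wunsch global
#' alignment. The default scoring (match +1, mismatch -2, gap opening 100,
#' gap extension 10) makes interior gaps effectively prohibitive, so gaps
#' mostly absorb length differences -- appropriate for redundancy detection,
#' where wandering gap placement would inflate the identity of unrelated
#' sequences. With the default `"alignment_length"` denominator, unrelated
#' random sequences score around 0.25, well below the 0.5 clustering
#' threshold; the CD-HIT-style `"shorter"` denominator is selectable but
#' scores unrelated nucleotide sequences so high that thresholds near 0.5
#' become unusable.
#'
#' @param threshold Identity threshold in (0, 1] for cluster membership
#'   (default 0.5).
#' @param denominator `"alignment_length"` (matches / alignment columns,
#'   default) or `"shorter"` (matches / length of the shorter sequence,
#'   capped at 1).
#' @param match,mismatch Alignment match/mismatch scores.
#' @param gap_opening,gap_extension Gap penalties (positive costs).
#' @param best_match If `TRUE`, a sequence joins the best-scoring qualifying
#'   cluster instead of the first one in creation order (default `FALSE`:
#'   first-fit, the classical greedy-incremental rule).
#' @return A `similarity_params` object.
#' @export
similarity_params <- function(threshold = 0.5,
                              denominator = c("alignment_length", "shorter"),
                              match = 1, mismatch = -2,
                              gap_opening = 100, gap_extension = 10,
                              best_match = FALSE) {
  denominator <- match.arg(denominator)
  stopifnot(threshold > 0, threshold <= 1)
  structure(list(threshold = threshold, denominator = denominator,
                 match = match, mismatch = mismatch,
                 gap_opening = gap_opening, gap_extension = gap_extension,
                 best_match = best_match),
            class = "similarity_params")
}

#' Pairwise sequence identity
#'
#' Fraction of identical aligned positions of an optimal global alignment,
#' divided by the denominator chosen in `params`. Symmetric and capped at 1.
#'
#' @param a A single sequence (character).
#' @param b A sequence or character vector of sequences; identities of `a`
#'   against each element are returned in one vectorized alignment call.
#' @param params A [similarity_params()].
#' @return Numeric vector of identities in `[0, 1]`, one per element of `b`.
#' @export
pairwise_identity <- function(a, b, params = similarity_params()) {
  stopifnot(is.character(a), length(a) == 1L, is.character(b), length(b) >= 1L)
  if (!nzchar(a) || any(!nzchar(b))) stop("empty sequence in pairwise_identity")
  mat <- Biostrings::nucleotideSubstitutionMatrix(
    match = params$match, mismatch = params$mismatch, baseOnly = TRUE)
  al <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAStringSet(b),
    subject = Biostrings::DNAString(a),
    type = "global", substitutionMatrix = mat,
    gapOpening = params$gap_opening, gapExtension = params$gap_extension)
  matches <- Biostrings::nmatch(al)
  denom <- if (params$denominator == "alignment_length") {
    # alignment columns = base-base columns + gap columns (incl. terminal)
    nchar(b) + nchar(a) - (matches + Biostrings::nmismatch(al))
  } else {
    pmin(nchar(a), nchar(b))
  }
  pmin(matches / denom, 1)
}

#' Greedy incremental sequence clustering
#'
#' Sequences are sorted from longest to shortest (length ties broken
#' lexicographically by id for determinism). The first sequence founds the
#' first cluster and becomes its representative. Each subsequent sequence is
#' compared against the existing representatives and joins the first cluster
#' (in creation order) whose representative it matches at or above the
#' identity threshold; otherwise it founds a new cluster as representative.
#' Because sequences are processed longest-first, every representative is
#' the longest member of its cluster.
#'
#' @param dataset A [utr_dataset()] (or any data frame with `id` and
#'   `sequence` columns).
#' @param params A [similarity_params()].
#' @return A `utr_clustering`: list with `clusters` (each a list with
#'   `representative_id`, `member_ids` -- representative first), `params`,
#'   and `n` (number of sequences).
#' @export
greedy_cluster <- function(dataset, params = similarity_params()) {
  stopifnot(nrow(dataset) >= 1L)
  ord <- order(-nchar(dataset$sequence), dataset$id)
  ids <- dataset$id[ord]
  seqs <- dataset$sequence[ord]
  rep_seq <- character(0)
  members <- list()
  for (i in seq_along(seqs)) {
    placed <- FALSE
    if (length(rep_seq)) {
      ident <- pairwise_identity(seqs[i], rep_seq, params)
      hit <- which(ident >= params$threshold)
      if (length(hit)) {
        j <- if (params$best_match) hit[which.max(ident[hit])] else hit[1L]
        members[[j]] <- c(members[[j]], ids[i])
        placed <- TRUE
      }
    }
    if (!placed) {
      rep_seq <- c(rep_seq, seqs[i])
      members[[length(rep_seq)]] <- ids[i]
    }
  }
  clusters <- lapply(members, function(m) {
    list(representative_id = m[1L], member_ids = m)
  })
  structure(list(clusters = clusters, params = params, n = nrow(dataset)),
            class = "utr_clustering")
}

#' @export
print.utr_clustering <- function(x, ...) {
  sizes <- cluster_sizes(x)
  cat(sprintf("<utr_clustering> %d sequences in %d clusters (threshold %.2f); %d singletons\n",
              x$n, length(x$clusters), x$params$threshold, sum(sizes == 1L)))
  invisible(x)
}

#' Cluster sizes
#' @param clustering A `utr_clustering`.
#' @return Integer vector of member counts per cluster, in creation order.
#' @export
cluster_sizes <- function(clustering) {
  vapply(clustering$clusters, function(cl) length(cl$member_ids), integer(1))
}

#' Cluster assignment table
#' @param clustering A `utr_clustering`.
#' @return Data frame with columns `member_id`, `cluster_index` (1-based,
#'   creation order), `is_representative`.
#' @export
cluster_assignments <- function(clustering) {
  rows <- lapply(seq_along(clustering$clusters), function(i) {
    cl <- clustering$clusters[[i]]
    data.frame(member_id = cl$member_ids, cluster_index = i,
               is_representative = cl$member_ids == cl$representative_id,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Build the representative test set
#'
#' Representative ids of all clusters with at least two members. Singleton
#' clusters are excluded: their representative would have no similar
#' sequence left in the training data, so the model could not be expected to
#' have learned anything about it.
#'
#' @param clustering A `utr_clustering`.
#' @return Character vector of representative ids (possibly empty, with a
#'   warning, if every cluster is a singleton).
#' @export
build_test_set <- function(clustering) {
  keep <- cluster_sizes(clustering) >= 2L
  if (!any(keep)) {
    warning("all clusters are singletons; the representative test set is empty")
    return(character(0))
  }
  vapply(clustering$clusters[keep], function(cl) cl$representative_id, character(1))
}

#' Percentage-based training-subset selection
#'
#' From each cluster, after removing excluded (e.g. test-set) ids, a seeded
#' uniform sample of `ceiling(fraction * remaining)` members is drawn, so no
#' non-empty cluster contributes zero sequences.
#'
#' @param clustering A `utr_clustering`.
#' @param fraction Sampling fraction in (0, 1].
#' @param seed Integer seed (selection is a pure function of clustering,
#'   fraction, seed and exclusions).
#' @param exclude Ids to remove before sampling.
#' @return Character vector of selected training ids.
#' @export
select_percentage <- function(clustering, fraction, seed = 1L, exclude = character(0)) {
  stopifnot(fraction > 0, fraction <= 1)
  with_seed(seed, {
    unlist(lapply(clustering$clusters, function(cl) {
      avail <- setdiff(cl$member_ids, exclude)
      if (!length(avail)) return(character(0))
      k <- ceiling(fraction * length(avail))
      avail[sample.int(length(avail), k)]
    }))
  })
}

#' Count-based training-subset selection
#'
#' Samples up to `per_cluster` members uniformly from each cluster (after
#' exclusions); clusters with fewer members contribute all of them.
#'
#' @param clustering A `utr_clustering`.
#' @param per_cluster Members to draw per cluster (default 6).
#' @param seed Integer seed.
#' @param exclude Ids to remove before sampling.
#' @return Character vector of selected training ids.
#' @export
select_count <- function(clustering, per_cluster = 6L, seed = 1L, exclude = character(0)) {
  stopifnot(per_cluster >= 1L)
  with_seed(seed, {
    unlist(lapply(clustering$clusters, function(cl) {
      avail <- setdiff(cl$member_ids, exclude)
      if (!length(avail)) return(character(0))
      k <- min(per_cluster, length(avail))
      avail[sample.int(length(avail), k)]
    }))
  })
}

#' Dataset compression and accuracy restoration metrics
#'
#' @param full_n,subset_n Sizes of the full and compressed training sets.
#' @param r_full,r_subset Model correlations achieved with the full and
#'   compressed training sets.
#' @return Named list: `compression_rate = 1 - subset_n/full_n`,
#'   `accuracy_restoration = r_subset / r_full`.
#' @export
compression_metrics <- function(full_n, subset_n, r_full, r_subset) {
  stopifnot(full_n > 0)
  if (r_full == 0) stop("accuracy restoration undefined: r_full is 0")
  list(compression_rate = 1 - subset_n / full_n,
       accuracy_restoration = r_subset / r_full)
}

#' Write a clustering to disk
#'
#' Writes a TSV (`member_id`, `cluster_index`, `is_representative`) and
#' optionally a `.clstr`-style text layout compatible with CD-HIT tooling.
#'
#' @param clustering A `utr_clustering`.
#' @param path_tsv Output TSV path.
#' @param path_clstr Optional `.clstr` output path.
#' @param dataset Optional [utr_dataset()] supplying sequence lengths for the
#'   `.clstr` layout (lengths are reported as 0 without it).
#' @return `path_tsv`, invisibly.
#' @export
write_clustering <- function(clustering, path_tsv, path_clstr = NULL, dataset = NULL) {
  utils::write.table(cluster_assignments(clustering), path_tsv, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(path_clstr)) {
    len_of <- function(id) {
      if (is.null(dataset)) 0L else nchar(dataset$sequence[match(id, dataset$id)])
    }
    lines <- unlist(lapply(seq_along(clustering$clusters), function(i) {
      cl <- clustering$clusters[[i]]
      c(sprintf(">Cluster %d", i - 1L),
        vapply(seq_along(cl$member_ids), function(j) {
          id <- cl$member_ids[j]
          tag <- if (id == cl$representative_id) "*" else
            sprintf("at %.2f%%", 100 * clustering$params$threshold)
          sprintf("%d\t%dnt, >%s... %s", j - 1L, len_of(id), id, tag)
        }, character(1)))
    }))
    writeLines(lines, path_clstr)
  }
  invisible(path_tsv)
}
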