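#' Feature extraction configuration
#'
#' Controls which feature groups [extract_features()] computes. Features fall
#' into three groups: SEQUENCE (k-mer frequencies, GC metrics, upstream AUG
#' count), CODON (in-frame triplet usage), and STRUCTURE (thermodynamic
#' folding descriptors from RNAfold).
#'
#' @param k_min,k_max Range of k-mer sizes (defaults 1 and 6; all 4^k k-mers
#'   per size are emitted).
#' @param include_kmer,include_gc,include_aug,include_codon,include_structure
#'   Logical switches for the individual feature families.
#' @param temperature Folding temperature in degrees Celsius (default 37,
#'   mammalian cell context).
#' @param standardize Z-score the feature matrix columns (default `FALSE`;
#'   tree ensembles are scale-invariant, the switch exists for other
#'   consumers).
#' @return A `feature_config` list.
#' @export
feature_config <- function(k_min = 1L, k_max = 6L,
                           include_kmer = TRUE, include_gc = TRUE,
                           include_aug = TRUE, include_codon = TRUE,
                           include_structure = TRUE,
                           temperature = 37, standardize = FALSE) {
  stopifnot(k_min >= 1L, k_min <= k_max)
  structure(list(k_min = as.integer(k_min), k_max = as.integer(k_max),
                 include_kmer = include_kmer, include_gc = include_gc,
                 include_aug = include_aug, include_codon = include_codon,
                 include_structure = include_structure,
                 temperature = temperature, standardize = standardize),
            class = "feature_config")
}

all_kmers <- function(k) {
  bases <- c("A", "C", "G", "T")
  if (k == 1L) return(bases)
  grid <- do.call(expand.grid, c(rep(list(bases), k), stringsAsFactors = FALSE))
  # column-major expand.grid: first factor varies fastest; reorder so the
  # leftmost base varies slowest, giving the conventional AAA, AAC, ... order
  apply(grid[, rev(seq_len(k)), drop = FALSE], 1L, paste, collapse = "")
}

#' k-mer frequencies of a sequence
#'
#' For each k in `k_min:k_max`, every one of the 4^k k-mers gets frequency
#' count / (L - k + 1), i.e. the fraction of overlapping length-k windows it
#' occupies. For a sequence shorter than k all frequencies of that size are 0.
#'
#' @param sequence A single A/C/G/T string.
#' @param k_min,k_max k-mer size range (defaults 1 and 6).
#' @return Named numeric vector with names like `"kmer3_ACG"`; per-k
#'   frequencies sum to 1 for sequences of length >= k.
#' @export
kmer_frequencies <- function(sequence, k_min = 1L, k_max = 6L) {
  sequence <- check_one_sequence(sequence)
  dna <- Biostrings::DNAString(sequence)
  L <- nchar(sequence)
  out <- lapply(seq(k_min, k_max), function(k) {
    counts <- Biostrings::oligonucleotideFrequency(dna, width = k)
    freqs <- if (L >= k) counts / (L - k + 1) else counts * 0
    names(freqs) <- paste0("kmer", k, "_", names(counts))
    freqs
  })
  unlist(out)
}

#' GC content metrics
#'
#' @param sequence A single A/C/G/T string.
#' @return Named vector: `gc_content` = (#G + #C)/L, `at_ratio` = (#A + #T)/L,
#'   and `cg_ratio` = #C/#G (0 with a warning when the sequence has no G, to
#'   keep the feature matrix finite and dense).
#' @export
gc_metrics <- function(sequence) {
  sequence <- check_one_sequence(sequence)
  counts <- Biostrings::letterFrequency(Biostrings::DNAString(sequence),
                                        letters = c("A", "C", "G", "T"))
  L <- nchar(sequence)
  cg_ratio <- if (counts[["G"]] > 0) counts[["C"]] / counts[["G"]] else {
    warning("cg_ratio: sequence has no G; emitting 0")
    0
  }
  c(gc_content = unname(counts[["G"]] + counts[["C"]]) / L,
    at_ratio = unname(counts[["A"]] + counts[["T"]]) / L,
    cg_ratio = unname(cg_ratio))
}

#' Count upstream AUG triplets
#'
#' Number of ATG occurrences at any offset of the 5'UTR (the main start codon
#' is excluded by construction of the input). Overlapping occurrences count.
#' Each such triplet can seed an upstream open reading frame that suppresses
#' main-ORF translation.
#'
#' @param sequence A single A/C/G/T string.
#' @return Integer count.
#' @export
upstream_aug_count <- function(sequence) {
  sequence <- check_one_sequence(sequence)
  Biostrings::countPattern("ATG", Biostrings::DNAString(sequence))
}

#' Codon usage frequencies
#'
#' Frequencies of the 64 triplets read in frame 0 from the 5' end in
#' non-overlapping steps of three, normalized by the number of complete
#' codons. A 5'UTR has no defined reading frame, so this fixed convention is
#' applied to whatever sequence is provided; a trailing incomplete triplet is
#' ignored and sequences shorter than 3 get an all-zero vector.
#'
#' @param sequence A single A/C/G/T string.
#' @return Named numeric vector `codon_AAA` ... `codon_TTT` summing to 1 for
#'   sequences of length >= 3.
#' @export
codon_usage <- function(sequence) {
  sequence <- check_one_sequence(sequence)
  counts <- Biostrings::oligonucleotideFrequency(Biostrings::DNAString(sequence),
                                                 width = 3L, step = 3L)
  n <- nchar(sequence) %/% 3L
  freqs <- if (n > 0) counts / n else counts * 0
  names(freqs) <- paste0("codon_", names(counts))
  freqs
}

check_one_sequence <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  if (!nzchar(sequence)) stop("empty sequence")
  if (grepl("[^ACGT]", sequence)) stop("sequence contains non-ACGT characters")
  sequence
}

#' RNA secondary-structure descriptors
#'
#' Folds sequences with ViennaRNA's RNAfold (nearest-neighbor thermodynamic
#' model) and returns, per sequence: the minimum free energy `mfe`, the MFE
#' with G-quadruplex scoring enabled `mfe_gquad`, their difference
#' `gquad_energy = mfe_gquad - mfe` (<= 0: allowing an extra stabilizing
#' motif class can only lower or preserve the MFE), and the ensemble mean
#' base-pair distance `mean_bp_distance` (RNAfold's ensemble diversity, a
#' structural-flexibility proxy in nt).
#'
#' @param sequences Character vector of A/C/G/T sequences.
#' @param ids Optional ids used in error messages (defaults to seq index).
#' @param temperature Folding temperature in Celsius (default 37).
#' @return A data frame with columns `mfe`, `mfe_gquad`, `gquad_energy`,
#'   `mean_bp_distance` (kcal/mol, kcal/mol, kcal/mol, nt).
#' @export
fold_descriptors <- function(sequences, ids = NULL, temperature = 37) {
  stopifnot(length(sequences) >= 1L)
  if (is.null(ids)) ids <- as.character(seq_along(sequences))
  vapply(sequences, check_one_sequence, character(1))
  plain <- run_rnafold(sequences, ids, gquad = FALSE, partfunc = TRUE,
                       temperature = temperature)
  quad <- run_rnafold(sequences, ids, gquad = TRUE, partfunc = FALSE,
                      temperature = temperature)
  mfe_gquad <- pmin(quad$mfe, plain$mfe)  # guard against backend rounding
  data.frame(mfe = plain$mfe,
             mfe_gquad = mfe_gquad,
             gquad_energy = mfe_gquad - plain$mfe,
             mean_bp_distance = plain$diversity,
             row.names = ids)
}

run_rnafold <- function(sequences, ids, gquad, partfunc, temperature) {
  if (Sys.which("RNAfold") == "") {
    stop("RNAfold not found on the PATH; install ViennaRNA to compute structure features")
  }
  fa <- tempfile(fileext = ".fa")
  on.exit(unlink(fa), add = TRUE)
  writeLines(paste0(">", seq_along(sequences), "\n", sequences), fa)
  args <- c("--noPS", "--noconv", sprintf("--temp=%g", temperature))
  if (gquad) args <- c(args, "--gquad")
  if (partfunc) args <- c(args, "-p", "--noDP")
  out <- suppressWarnings(system2("RNAfold", args = args, stdin = fa,
                                  stdout = TRUE, stderr = TRUE))
  status <- attr(out, "status")
  if (!is.null(status) && status != 0) {
    stop("RNAfold failed (status ", status, ") on batch starting at id ", ids[1L],
         ": ", paste(utils::tail(out, 2L), collapse = " "))
  }
  parse_rnafold(out, length(sequences), ids, partfunc)
}

parse_rnafold <- function(lines, n, ids, partfunc) {
  starts <- grep("^>", lines)
  if (length(starts) != n) {
    stop("RNAfold output could not be parsed: expected ", n, " records, found ",
         length(starts))
  }
  mfe <- numeric(n)
  diversity <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    block <- lines[starts[i]:(if (i < n) starts[i + 1L] - 1L else length(lines))]
    mfe_line <- grep("\\(\\s*-?[0-9.]+\\s*\\)\\s*$", block, value = TRUE)[1L]
    if (is.na(mfe_line)) stop("RNAfold: no MFE line for id ", ids[i])
    mfe[i] <- as.numeric(sub(".*\\(\\s*(-?[0-9.]+)\\s*\\)\\s*$", "\\1", mfe_line))
    if (partfunc) {
      div_line <- grep("ensemble diversity", block, value = TRUE)[1L]
      if (is.na(div_line)) stop("RNAfold: no ensemble diversity for id ", ids[i])
      diversity[i] <- as.numeric(sub(".*ensemble diversity\\s+([0-9.]+).*", "\\1", div_line))
    }
  }
  list(mfe = mfe, diversity = diversity)
}

#' Extract the full feature matrix for a dataset
#'
#' Assembles the model feature space -- k-mer frequencies, GC metrics,
#' upstream AUG count, codon usage, and folding descriptors -- into a numeric
#' matrix with one row per record (in dataset order) plus a manifest mapping
#' every column to its feature group. Deterministic for a fixed configuration.
#'
#' @param dataset A [utr_dataset()] (typically filtered).
#' @param config A [feature_config()].
#' @return A numeric matrix with `rownames = dataset$id` and attribute
#'   `manifest`: a data frame (`name`, `group`) with group one of
#'   `"SEQUENCE"`, `"STRUCTURE"`, `"CODON"`. Retrieve it with
#'   [feature_manifest()].
#' @export
extract_features <- function(dataset, config = feature_config()) {
  stopifnot(inherits(config, "feature_config"))
  name <- character(0)
  group <- character(0)
  cols <- list()
  if (config$include_kmer) {
    kn <- unlist(lapply(seq(config$k_min, config$k_max),
                        function(k) paste0("kmer", k, "_", all_kmers(k))))
    name <- c(name, kn); group <- c(group, rep("SEQUENCE", length(kn)))
  }
  if (config$include_gc) {
    name <- c(name, "gc_content", "at_ratio", "cg_ratio")
    group <- c(group, rep("SEQUENCE", 3L))
  }
  if (config$include_aug) {
    name <- c(name, "uAUG_count"); group <- c(group, "SEQUENCE")
  }
  if (config$include_codon) {
    cn <- paste0("codon_", all_kmers(3L))
    name <- c(name, cn); group <- c(group, rep("CODON", length(cn)))
  }
  if (config$include_structure) {
    name <- c(name, "MFE", "Gquad_energy", "mean_distance")
    group <- c(group, rep("STRUCTURE", 3L))
  }
  manifest <- data.frame(name = name, group = group, stringsAsFactors = FALSE)

  n <- nrow(dataset)
  mat <- matrix(0, nrow = n, ncol = nrow(manifest),
                dimnames = list(dataset$id, manifest$name))
  if (n > 0) {
    per_record <- lapply(seq_len(n), function(i) {
      seqi <- dataset$sequence[i]
      v <- numeric(0)
      if (config$include_kmer) {
        v <- c(v, kmer_frequencies(seqi, config$k_min, config$k_max))
      }
      if (config$include_gc) v <- c(v, suppressWarnings(gc_metrics(seqi)))
      if (config$include_aug) v <- c(v, uAUG_count = upstream_aug_count(seqi))
      if (config$include_codon) v <- c(v, codon_usage(seqi))
      v
    })
    seqpart <- do.call(rbind, per_record)
    mat[, colnames(seqpart)] <- seqpart
    if (config$include_structure) {
      fd <- fold_descriptors(dataset$sequence, ids = dataset$id,
                             temperature = config$temperature)
      mat[, "MFE"] <- fd$mfe
      mat[, "Gquad_energy"] <- fd$gquad_energy
      mat[, "mean_distance"] <- fd$mean_bp_distance
    }
  }
  if (config$standardize && n > 1) {
    mu <- colMeans(mat)
    sdv <- apply(mat, 2L, stats::sd)
    sdv[sdv == 0] <- 1
    mat <- sweep(sweep(mat, 2L, mu), 2L, sdv, "/")
  }
  attr(mat, "manifest") <- manifest
  mat
}

#' Feature group manifest of an extracted matrix
#' @param x A matrix produced by [extract_features()].
#' @return Data frame with columns `name` and `group`.
#' @export
feature_manifest <- function(x) {
  m <- attr(x, "manifest")
  if (is.null(m)) stop("x carries no feature manifest")
  m
}
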