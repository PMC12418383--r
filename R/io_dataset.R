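#' Construct a 5'UTR dataset
#'
#' A `utr_dataset` is the package's central container: one row per 5'UTR with
#' its sequence, translation-efficiency (TE) label on a log scale, RPKM
#' abundance, and cell-line tag. TE and RPKM are consumed as given -- they are
#' never computed from reads.
#'
#' @param id Character vector of unique record identifiers.
#' @param sequence Character vector of nucleotide sequences. Normalized to
#'   upper case with U mapped to T; must contain only A/C/G/T afterwards.
#' @param te_value Numeric TE labels on a log scale (may be negative);
#'   `NA` marks a missing label.
#' @param rpkm Non-negative numeric abundance values; `NA` if unknown.
#' @param cell_line Character cell-line tags (e.g. `"HEK293T"`, `"PC3"`).
#' @param provenance Free-text description of the source and filters applied.
#'
#' @return An object of class `utr_dataset`: a data frame with columns
#'   `id`, `sequence`, `te_value`, `rpkm`, `cell_line` and a `provenance`
#'   attribute.
#' @export
utr_dataset <- function(id, sequence, te_value = NA_real_, rpkm = NA_real_,
                        cell_line = NA_character_, provenance = "") {
  n <- length(id)
  stopifnot(length(sequence) == n)
  df <- data.frame(
    id = as.character(id),
    sequence = normalize_sequence(sequence),
    te_value = rep_len(as.numeric(te_value), n),
    rpkm = rep_len(as.numeric(rpkm), n),
    cell_line = rep_len(as.character(cell_line), n),
    stringsAsFactors = FALSE
  )
  attr(df, "provenance") <- provenance
  class(df) <- c("utr_dataset", "data.frame")
  validate_utr_dataset(df)
  df
}

#' @export
print.utr_dataset <- function(x, ...) {
  cat(sprintf("<utr_dataset> %d records\n", nrow(x)))
  if (nzchar(provenance(x))) cat("provenance:", provenance(x), "\n")
  cat(sprintf("with TE: %d | with RPKM: %d | length range: %s\n",
              sum(!is.na(x$te_value)), sum(!is.na(x$rpkm)),
              if (nrow(x)) paste(range(nchar(x$sequence)), collapse = "-") else "-"))
  invisible(x)
}

#' Provenance of a dataset
#' @param x A `utr_dataset`.
#' @return The provenance string.
#' @export
provenance <- function(x) {
  p <- attr(x, "provenance")
  if (is.null(p)) "" else p
}

normalize_sequence <- function(sequence) {
  chartr("U", "T", toupper(as.character(sequence)))
}

validate_utr_dataset <- function(df) {
  if (anyDuplicated(df$id)) {
    stop("duplicate ids in dataset: ",
         paste(unique(df$id[duplicated(df$id)]), collapse = ", "))
  }
  if (any(!nzchar(df$sequence))) {
    stop("empty sequence for id(s): ", paste(df$id[!nzchar(df$sequence)], collapse = ", "))
  }
  bad <- grepl("[^ACGT]", df$sequence)
  if (any(bad)) {
    stop("non-ACGT characters in sequence(s): ", paste(df$id[bad], collapse = ", "))
  }
  if (any(df$rpkm < 0, na.rm = TRUE)) {
    stop("negative RPKM for id(s): ",
         paste(df$id[which(df$rpkm < 0)], collapse = ", "))
  }
  invisible(df)
}

#' Read 5'UTR sequences from a FASTA file
#'
#' Sequences are case-folded to upper case and U is mapped to T so that all
#' downstream modules see a single A/C/G/T alphabet. The header token before
#' the first whitespace becomes the record id. TE and RPKM start out missing;
#' join them with [read_annotation_table()].
#'
#' @param path Path to a (multi-record, wrapped or unwrapped) FASTA file.
#' @param on_invalid What to do with records containing characters outside
#'   A/C/G/T/U after normalization (e.g. ambiguity codes such as N):
#'   `"reject"` (default) raises an error listing the offending ids,
#'   `"drop"` excludes those records with a warning.
#'
#' @return A [utr_dataset()].
#' @export
read_utr_fasta <- function(path, on_invalid = c("reject", "drop")) {
  on_invalid <- match.arg(on_invalid)
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop("malformed FASTA in ", path, ": ", conditionMessage(e))
  )
  ids <- sub("\\s.*$", "", names(set))
  seqs <- normalize_sequence(as.character(set))
  bad <- grepl("[^ACGT]", seqs)
  if (any(bad)) {
    if (on_invalid == "reject") {
      stop("non-ACGTU characters in record(s): ", paste(ids[bad], collapse = ", "),
           " (use on_invalid = \"drop\" to skip them)")
    }
    warning(sprintf("dropped %d record(s) with non-ACGTU characters: %s",
                    sum(bad), paste(ids[bad], collapse = ", ")))
    ids <- ids[!bad]
    seqs <- seqs[!bad]
  }
  utr_dataset(ids, seqs,
              provenance = sprintf("read_utr_fasta(%s): %d records", path, length(ids)))
}

#' Write a dataset to FASTA
#'
#' @param dataset A [utr_dataset()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_utr_fasta <- function(dataset, path) {
  set <- Biostrings::DNAStringSet(dataset$sequence)
  names(set) <- dataset$id
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Join an annotation table onto a dataset
#'
#' Reads a delimited table (TSV or CSV, auto-detected from content) with a
#' header row and joins TE values, RPKM and cell-line tags onto FASTA records
#' by exact, case-sensitive id match. Empty TE cells stay missing (`NA`),
#' never 0.
#'
#' @param path Path to the annotation table.
#' @param dataset A [utr_dataset()] whose ids the table rows should match.
#' @param columns Named character vector mapping the canonical column roles
#'   `id`, `te`, `rpkm`, `cell_line` to the column names used in the file.
#'
#' @return The dataset with `te_value`, `rpkm` and `cell_line` filled in.
#' @export
read_annotation_table <- function(path, dataset,
                                  columns = c(id = "id", te = "te",
                                              rpkm = "rpkm", cell_line = "cell_line")) {
  if (!file.exists(path)) stop("annotation table not found: ", path)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                           na.strings = c("NA", ""), check.names = FALSE)
  if (!(columns[["id"]] %in% names(tab))) {
    stop("annotation table lacks id column '", columns[["id"]], "'")
  }
  tab_id <- as.character(tab[[columns[["id"]]]])
  if (anyDuplicated(tab_id)) {
    stop("duplicate ids in annotation table: ",
         paste(unique(tab_id[duplicated(tab_id)]), collapse = ", "))
  }
  unmatched <- setdiff(tab_id, dataset$id)
  if (length(unmatched)) {
    warning(sprintf("%d annotation row(s) with ids absent from the dataset (e.g. %s)",
                    length(unmatched), utils::head(unmatched, 3L)))
  }
  idx <- match(dataset$id, tab_id)
  pick <- function(role, current) {
    col <- columns[[role]]
    if (is.null(col) || !(col %in% names(tab))) return(current)
    out <- current
    hit <- !is.na(idx)
    out[hit] <- tab[[col]][idx[hit]]
    out
  }
  dataset$te_value <- as.numeric(pick("te", dataset$te_value))
  dataset$rpkm <- as.numeric(pick("rpkm", dataset$rpkm))
  dataset$cell_line <- as.character(pick("cell_line", dataset$cell_line))
  validate_utr_dataset(dataset)
  attr(dataset, "provenance") <- paste0(
    provenance(dataset), sprintf("; annotated from %s (%d rows, %d unmatched)",
                                 path, nrow(tab), length(unmatched)))
  dataset
}

#' Filter a dataset for model training
#'
#' Keeps records that carry a TE label and whose RPKM strictly exceeds
#' `rpkm_min`. Low-abundance transcripts are excluded because their TE
#' estimates (Ribo-seq/RNA-seq ratios) are dominated by Poisson counting
#' noise. The filter is idempotent and never mutates surviving records.
#'
#' @param dataset A [utr_dataset()].
#' @param rpkm_min RPKM cutoff; records must exceed it strictly (default 10).
#' @return The filtered [utr_dataset()], with removal counts recorded in the
#'   provenance.
#' @export
filter_dataset <- function(dataset, rpkm_min = 10) {
  missing_te <- is.na(dataset$te_value)
  low_rpkm <- !missing_te & (is.na(dataset$rpkm) | dataset$rpkm <= rpkm_min)
  keep <- !missing_te & !low_rpkm
  out <- dataset[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "provenance") <- paste0(
    provenance(dataset),
    sprintf("; filter_dataset: removed %d missing-TE, %d with RPKM <= %g; %d kept",
            sum(missing_te), sum(low_rpkm), rpkm_min, sum(keep)))
  class(out) <- c("utr_dataset", "data.frame")
  out
}
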