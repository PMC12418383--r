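#' Read a long-format plate measurement table
#'
#' Expected columns: `plate_id`, `well`, `sample_id`, `technical_rep`,
#' `signal`, `is_reference` (logical or 0/1). One sample per plate must be
#' flagged as the reference.
#'
#' @param path TSV file path.
#' @return A data frame of well measurements.
#' @export
read_plate_table <- function(path) {
  if (!file.exists(path)) stop("plate table not found: ", path)
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  required <- c("plate_id", "sample_id", "signal", "is_reference")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols)) {
    stop("plate table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  tab$is_reference <- as.logical(tab$is_reference)
  if (any(tab$signal < 0)) stop("negative signal in plate table")
  tab
}

#' Average technical replicates
#'
#' Arithmetic mean of the technical-replicate signals per (plate, sample);
#' bioluminescence is typically measured in duplicate and averaged before
#' any normalization.
#'
#' @param measurements Data frame as from [read_plate_table()].
#' @return Data frame with one row per (plate_id, sample_id): columns
#'   `plate_id`, `sample_id`, `signal` (mean), `n_reps`, `is_reference`.
#' @export
aggregate_technical <- function(measurements) {
  key <- interaction(measurements$plate_id, measurements$sample_id, drop = TRUE)
  agg <- lapply(split(measurements, key), function(g) {
    if (length(unique(g$is_reference)) != 1L) {
      stop("inconsistent is_reference flag for sample ", g$sample_id[1L],
           " on plate ", g$plate_id[1L])
    }
    data.frame(plate_id = g$plate_id[1L], sample_id = g$sample_id[1L],
               signal = mean(g$signal), n_reps = nrow(g),
               is_reference = g$is_reference[1L], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, agg)
  rownames(out) <- NULL
  out
}

#' Compute average bioluminescence intensity (ABI)
#'
#' For each sample, its technical-replicate-averaged signal on each plate is
#' divided by the reference well's signal on the same plate; the ABI is the
#' arithmetic mean of this normalized ratio across the replicate plates:
#' `ABI = (1/n) * sum_i experimental_i / reference_i`. The per-plate ratio
#' cancels plate-wide multiplicative effects (cell density, reagent batch),
#' so scaling all signals on one plate leaves every ABI unchanged, and the
#' reference sample's own ABI is exactly 1.
#'
#' @param measurements Data frame of well measurements (raw technical
#'   replicates; they are averaged first).
#' @param n_required_plates Expected number of replicate plates per sample
#'   (default 3); samples present on fewer plates are still computed, with a
#'   warning, and their actual `n_plates` reported.
#' @return Data frame with columns `sample_id`, `abi`, `n_plates`, plus a
#'   `ratios` attribute (named list of per-plate ratios).
#' @export
compute_abi <- function(measurements, n_required_plates = 3L) {
  agg <- aggregate_technical(measurements)
  refs <- agg[agg$is_reference, , drop = FALSE]
  if (anyDuplicated(refs$plate_id)) {
    stop("more than one reference sample on plate(s): ",
         paste(unique(refs$plate_id[duplicated(refs$plate_id)]), collapse = ", "))
  }
  plates <- unique(agg$plate_id)
  no_ref <- setdiff(plates, refs$plate_id)
  if (length(no_ref)) stop("plate(s) without a reference well: ",
                           paste(no_ref, collapse = ", "))
  if (any(refs$signal <= 0)) {
    stop("reference signal is zero on plate(s): ",
         paste(refs$plate_id[refs$signal <= 0], collapse = ", "))
  }
  ref_signal <- stats::setNames(refs$signal, refs$plate_id)
  samples <- unique(agg$sample_id)
  ratios <- lapply(samples, function(s) {
    g <- agg[agg$sample_id == s, , drop = FALSE]
    stats::setNames(g$signal / ref_signal[as.character(g$plate_id)], g$plate_id)
  })
  names(ratios) <- samples
  n_plates <- vapply(ratios, length, integer(1))
  if (any(n_plates == 0L)) stop("sample(s) present on no plates")
  short <- n_plates < n_required_plates
  if (any(short)) {
    warning(sprintf("%d sample(s) measured on fewer than %d plates: %s",
                    sum(short), n_required_plates,
                    paste(utils::head(samples[short], 5L), collapse = ", ")))
  }
  out <- data.frame(sample_id = samples,
                    abi = vapply(ratios, mean, numeric(1)),
                    n_plates = n_plates,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "ratios") <- ratios
  out
}
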