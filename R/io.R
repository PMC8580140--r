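# Plain-text and NIfTI interfaces. TSV writers fall back to utils when the
# readr package is unavailable.

write_tsv_file <- function(x, path) {
  if (requireNamespace("readr", quietly = TRUE)) {
    readr::write_tsv(x, path)
  } else {
    utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Write an event schedule as a BIDS-flavoured events table
#'
#' Columns `onset`, `duration`, `trial_type` (tab-separated), plus the
#' executed finger for the free-selection design.
#'
#' @param schedule an [event_schedule].
#' @param path output file path (`.tsv`).
#' @return The path, invisibly.
#' @export
write_events_tsv <- function(schedule, path) {
  d <- data.frame(onset = schedule$onset, duration = schedule$duration,
                  trial_type = schedule$condition)
  if ("finger" %in% names(schedule)) d$finger <- schedule$finger
  write_tsv_file(d, path)
}

#' Write a cohort table as TSV
#'
#' @param cohort a [simulate_cohort()] table.
#' @param path output file path.
#' @return The path, invisibly.
#' @export
write_cohort_tsv <- function(cohort, path) {
  write_tsv_file(as.data.frame(cohort), path)
}

#' Read or write a region-of-interest mask as NIfTI
#'
#' The mask is stored as a binary volume; the affine is written into the
#' NIfTI header. Requires the `RNifti` package.
#'
#' @param mask an `roi_mask` (for writing).
#' @param path file path (`.nii` or `.nii.gz`).
#' @param hemisphere hemisphere tag to attach on reading.
#' @return `write_roi_nifti` returns the path; `read_roi_nifti` an
#'   `roi_mask`.
#' @export
write_roi_nifti <- function(mask, path) {
  if (!requireNamespace("RNifti", quietly = TRUE)) {
    stop("NIfTI input/output needs the RNifti package", call. = FALSE)
  }
  vol <- array(0L, mask$dim)
  vol[mask$coords] <- 1L
  # RNifti's xform maps 0-based indices; shift the 1-based convention
  aff <- mask$affine
  aff[1:3, 4] <- aff[1:3, 4] + aff[1:3, 1:3] %*% rep(1, 3)
  img <- RNifti::asNifti(vol)
  RNifti::sform(img) <- structure(aff, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_roi_nifti
#' @export
read_roi_nifti <- function(path, hemisphere = "left") {
  if (!requireNamespace("RNifti", quietly = TRUE)) {
    stop("NIfTI input/output needs the RNifti package", call. = FALSE)
  }
  img <- RNifti::readNifti(path)
  vol <- as.array(img)
  coords <- which(vol != 0, arr.ind = TRUE)
  aff <- structure(RNifti::xform(img), code = NULL)
  aff <- matrix(as.numeric(aff), 4, 4, dimnames = NULL)
  aff[1:3, 4] <- aff[1:3, 4] - aff[1:3, 1:3] %*% rep(1, 3)
  new_roi_mask(coords, aff, hemisphere, dim = dim(vol))
}

#' Serialize an MVB fit to JSON
#'
#' Free energy, weight spread and the greedy trace as JSON (weights are
#' exported separately as TSV by [write_tsv_file] conventions). Requires
#' `jsonlite`.
#'
#' @param fit an [fit_mvb()] result.
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_mvb_json <- function(fit, path) {
  if (!requireNamespace("jsonlite", quietly = TRUE)) {
    stop("JSON export needs the jsonlite package", call. = FALSE)
  }
  jsonlite::write_json(list(free_energy = fit$F, spread = fit$spread,
                            converged = fit$converged,
                            trace = fit$trace),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
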