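#' Discrete-cosine high-pass filter columns
#'
#' Returns an orthonormal discrete cosine basis spanning frequencies at or
#' below `1/cutoff` Hz (including the constant), so that projecting these
#' columns out of model and data high-pass filters both. The number of
#' columns, including the constant, is `floor(2 * n_scans * TR / cutoff) + 1`,
#' the conventional discrete-cosine high-pass construction.
#'
#' @param n_scans number of scans.
#' @param TR repetition time, seconds.
#' @param cutoff filter cutoff period, seconds (default 128, i.e. 1/128 Hz).
#' @return A `n_scans` x K matrix with orthonormal columns named
#'   `hp_0 ... hp_{K-1}`; K = 0 (with a warning) when the run is shorter than
#'   the cutoff period.
#' @examples
#' C <- cosine_highpass_set(261, 1.97)
#' ncol(C) # 9
#' max(abs(crossprod(C) - diag(ncol(C)))) # orthonormal
#' @export
cosine_highpass_set <- function(n_scans, TR, cutoff = 128) {
  stopifnot(n_scans >= 2, TR > 0, cutoff > 0)
  run_seconds <- n_scans * TR
  if (run_seconds <= cutoff) {
    warning("run shorter than the cutoff period; returning an empty filter set")
    return(matrix(numeric(0), nrow = n_scans, ncol = 0))
  }
  k_max <- floor(2 * run_seconds / cutoff) # highest retained order
  i <- seq_len(n_scans)
  cols <- vapply(0:k_max, function(k) {
    if (k == 0) {
      rep(1 / sqrt(n_scans), n_scans)
    } else {
      sqrt(2 / n_scans) * cos(pi * (2 * i - 1) * k / (2 * n_scans))
    }
  }, numeric(n_scans))
  colnames(cols) <- paste0("hp_", 0:k_max)
  cols
}

#' Grand-mean scale a data matrix to 100
#'
#' Multiplies all values by `100 / mean(data)` so the grand mean over all
#' voxels and scans equals exactly 100, the conventional scaling under which
#' regression coefficients read as percent of whole-session signal.
#'
#' @param data scans x voxels numeric matrix with positive grand mean.
#' @return The rescaled matrix.
#' @export
grand_mean_scale <- function(data) {
  data <- as.matrix(data)
  gm <- mean(data)
  if (!is.finite(gm) || gm <= 0) {
    stop("grand mean must be positive; input looks malformed", call. = FALSE)
  }
  data * (100 / gm)
}

#' Build a first-level design matrix from an event schedule
#'
#' Convolves condition onset impulses with the canonical haemodynamic basis on
#' a fine time grid, samples the result at scan acquisition times, and appends
#' optional nuisance columns and the discrete-cosine high-pass set.
#'
#' @param schedule an [event_schedule] (or any data frame with `onset` and
#'   `condition` columns plus `n_scans`/`TR` supplied explicitly).
#' @param n_scans,TR run geometry; defaults taken from the schedule.
#' @param basis haemodynamic basis, see [canonical_hrf()].
#' @param conditions which condition labels get regressors (default: all in
#'   order of first appearance).
#' @param nuisance optional scans x q matrix of confound columns (e.g. motion
#'   surrogates).
#' @param highpass include the cosine filter columns (default `TRUE`).
#' @param cutoff high-pass cutoff, seconds.
#' @return A `design_matrix` object: list with `X` (scans x columns, named),
#'   `idx_task`, `idx_hp`, `idx_nuisance`, `basis`, `conditions`, `TR`.
#' @export
build_design_matrix <- function(schedule, n_scans = NULL, TR = NULL,
                                basis = c("canonical", "canonical+temporal+dispersion"),
                                conditions = NULL, nuisance = NULL,
                                highpass = TRUE, cutoff = 128) {
  basis <- match.arg(basis)
  n_scans <- n_scans %||% attr(schedule, "n_scans")
  TR <- TR %||% attr(schedule, "TR")
  stopifnot(!is.null(n_scans), !is.null(TR))
  conditions <- conditions %||% unique(as.character(schedule$condition))

  hrf <- canonical_hrf(TR, basis)
  task <- do.call(cbind, lapply(conditions, function(cond) {
    onsets <- schedule$onset[schedule$condition == cond]
    regs <- convolve_onsets(onsets, hrf, n_scans, TR)
    colnames(regs) <- paste0(cond, "_", colnames(hrf$kernels))
    regs
  }))

  X <- task
  idx_task <- seq_len(ncol(task))
  idx_nuisance <- integer(0)
  if (!is.null(nuisance)) {
    nuisance <- as.matrix(nuisance)
    stopifnot(nrow(nuisance) == n_scans)
    if (is.null(colnames(nuisance))) {
      colnames(nuisance) <- paste0("nuis_", seq_len(ncol(nuisance)))
    }
    idx_nuisance <- ncol(X) + seq_len(ncol(nuisance))
    X <- cbind(X, nuisance)
  }
  idx_hp <- integer(0)
  if (highpass) {
    hp <- cosine_highpass_set(n_scans, TR, cutoff)
    idx_hp <- ncol(X) + seq_len(ncol(hp))
    X <- cbind(X, hp)
  } else {
    # always keep an intercept so betas are relative to baseline
    X <- cbind(X, intercept = rep(1, n_scans))
    idx_hp <- ncol(X)
  }
  structure(list(X = X, idx_task = idx_task, idx_hp = idx_hp,
                 idx_nuisance = idx_nuisance, basis = basis,
                 conditions = conditions, TR = TR, n_scans = n_scans),
            class = "design_matrix")
}

# Convolve a set of onset impulses with each kernel of an hrf_basis and
# sample at scan times (t = (i-1) * TR).
convolve_onsets <- function(onsets, hrf, n_scans, TR) {
  dt <- hrf$dt
  n_fine <- ceiling(n_scans * TR / dt) + length(hrf$time)
  sticks <- numeric(n_fine)
  idx <- pmin(n_fine, floor(onsets / dt) + 1L)
  for (i in idx) sticks[i] <- sticks[i] + 1
  out <- vapply(seq_len(ncol(hrf$kernels)), function(j) {
    conv <- stats::convolve(sticks, rev(hrf$kernels[, j]), type = "open")
    conv <- conv[seq_len(n_fine)]
    scan_idx <- pmin(n_fine, floor(((seq_len(n_scans) - 1) * TR) / dt) + 1L)
    conv[scan_idx]
  }, numeric(n_scans))
  colnames(out) <- colnames(hrf$kernels)
  out
}

#' @export
print.design_matrix <- function(x, ...) {
  cat(sprintf("<design_matrix> %d scans x %d columns (%d task, %d nuisance, %d filter), basis: %s\n",
              nrow(x$X), ncol(x$X), length(x$idx_task), length(x$idx_nuisance),
              length(x$idx_hp), x$basis))
  invisible(x)
}

#' Export a design matrix as a tibble for audit
#'
#' @param x a `design_matrix`.
#' @param ... unused.
#' @return A tibble with one row per scan and one column per regressor.
#' @export
as_tibble.design_matrix <- function(x, ...) {
  tibble::as_tibble(as.data.frame(x$X))
}
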