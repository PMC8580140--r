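#' Canonical haemodynamic response function and its derivatives
#'
#' Builds the standard double-gamma haemodynamic response kernel, optionally
#' together with its temporal and dispersion partial derivatives, sampled on a
#' fine time grid for later convolution with event onsets.
#'
#' The double-gamma uses the field-standard parameters: response delay 6 s,
#' undershoot delay 16 s, unit dispersions, response/undershoot amplitude
#' ratio 6, and a 32 s kernel. The temporal derivative is the (negative)
#' finite difference with respect to a 1 s onset shift; the dispersion
#' derivative is the finite difference with respect to the response dispersion
#' (step 0.01). The canonical kernel is normalised to unit peak, so the
#' coefficient of an isolated event reads as its peak response amplitude.
#'
#' @param TR repetition time in seconds (must be positive; recorded for
#'   downstream sampling, the kernel itself is on the `dt` grid).
#' @param basis `"canonical"` for the double-gamma alone, or
#'   `"canonical+temporal+dispersion"` for all three kernels.
#' @param dt sampling step of the kernel grid, seconds.
#' @param duration kernel length in seconds.
#' @return An object of class `hrf_basis`: a list with `time` (grid, seconds)
#'   and `kernels` (grid-length x 1 or 3 matrix, columns named).
#' @examples
#' h <- canonical_hrf(1.97, "canonical")
#' h$time[which.max(h$kernels[, 1])] # peaks near 5 s
#' @export
canonical_hrf <- function(TR, basis = c("canonical", "canonical+temporal+dispersion"),
                          dt = 0.1, duration = 32) {
  if (!is.numeric(TR) || length(TR) != 1L || TR <= 0) {
    stop("`TR` must be a positive scalar (seconds)", call. = FALSE)
  }
  basis <- match.arg(basis)
  t <- seq(0, duration, by = dt)

  dgam <- function(t, delay_r = 6, delay_u = 16, disp_r = 1, disp_u = 1, ratio = 6) {
    stats::dgamma(t, shape = delay_r / disp_r, scale = disp_r) -
      stats::dgamma(t, shape = delay_u / disp_u, scale = disp_u) / ratio
  }

  h_raw <- dgam(t)
  scale <- max(h_raw)
  h <- h_raw / scale
  if (basis == "canonical") {
    kernels <- matrix(h, ncol = 1, dimnames = list(NULL, "canonical"))
  } else {
    shift <- 1 # seconds
    h_shift <- dgam(pmax(t - shift, 0)) / scale # same normalisation as h
    temporal <- (h - h_shift) / shift
    dd <- 0.01
    h_disp <- dgam(t, disp_r = 1 + dd) / scale
    dispersion <- (h - h_disp) / dd
    kernels <- cbind(canonical = h, temporal = temporal, dispersion = dispersion)
  }
  structure(list(time = t, kernels = kernels, dt = dt, TR = TR, basis = basis),
            class = "hrf_basis")
}

#' @export
print.hrf_basis <- function(x, ...) {
  cat(sprintf("<hrf_basis> %s, dt = %gs, %g s kernel, TR = %gs\n",
              x$basis, x$dt, max(x$time), x$TR))
  invisible(x)
}
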