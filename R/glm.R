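#' Fit a prewhitened general linear model to a BOLD session
#'
#' Estimates the temporal autocorrelation of the noise with an
#' AR(1)-plus-white-noise covariance model by restricted maximum likelihood,
#' pooled over the supplied voxels, then prewhitens both model and data with
#' the inverse square root of the fitted covariance and estimates the
#' regression coefficients by ordinary least squares on the whitened system.
#'
#' The noise covariance is parameterised as
#' `V = (1 - m) I + m * Q(phi)`, with `Q(phi)` the unit-diagonal AR(1)
#' correlation matrix and `m` the proportion of noise variance carried by the
#' autoregressive component; per-voxel scale is profiled out of the restricted
#' likelihood. `(phi, m)` are found by direct maximisation of the pooled
#' restricted log-likelihood (initialised from pooled Yule-Walker moments of
#' the OLS residuals), which is the same objective an expectation-maximisation
#' scheme would climb but is more robust on the nearly-white boundary.
#'
#' @param data scans x voxels numeric matrix.
#' @param design a [build_design_matrix()] object (full column rank).
#' @param reml_tol convergence tolerance on the restricted log-likelihood.
#' @param reml_maxit iteration cap for the likelihood search.
#' @return A `glm_fit` object: `betas` (columns x voxels), `sigma2` (residual
#'   variance per voxel on the whitened scale), `noise` (a `noise_model`:
#'   `phi`, `mix`, `lag1 = phi * mix`, restricted log-likelihood, convergence
#'   flag), whitening matrix `W`, and the design.
#' @export
fit_prewhitened_glm <- function(data, design, reml_tol = 1e-6, reml_maxit = 64) {
  stopifnot(inherits(design, "design_matrix"))
  data <- as.matrix(data)
  X <- design$X
  if (nrow(data) != nrow(X)) {
    stop("data and design must share the scan count", call. = FALSE)
  }
  check_full_rank(X)

  nm <- reml_ar1_white(data, X, tol = reml_tol, maxit = reml_maxit)
  W <- whitening_operator(nrow(X), nm$phi, nm$mix)
  WX <- W %*% X
  Wy <- W %*% data
  qr_wx <- qr(WX)
  betas <- qr.coef(qr_wx, Wy)
  res <- qr.resid(qr_wx, Wy)
  n <- nrow(X); p <- ncol(X)
  sigma2 <- colSums(res^2) / (n - p)
  lag1 <- colSums(res[-1, , drop = FALSE] * res[-n, , drop = FALSE]) /
    pmax(colSums(res^2), .Machine$double.eps)
  rownames(betas) <- colnames(X)
  structure(list(betas = betas, sigma2 = sigma2, noise = nm, W = W,
                 design = design, residual_lag1 = lag1),
            class = "glm_fit")
}

check_full_rank <- function(X) {
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    dropped <- colnames(X)[qr_x$pivot[(qr_x$rank + 1):ncol(X)]]
    stop("design matrix is rank deficient; collinear columns: ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

# Pooled restricted maximum likelihood for the AR(1)+white covariance.
# Profile objective over (phi, mix) with per-voxel variance profiled out:
#   -2L = v log|V| + v log|X'V^-1 X| + (n - p) sum_v log(y_v' P y_v)
reml_ar1_white <- function(data, X, tol = 1e-6, maxit = 64) {
  n <- nrow(X); p <- ncol(X); v <- ncol(data)

  # Yule-Walker moments of pooled OLS residuals for initial values
  r <- qr.resid(qr(X), data)
  denom <- sum(r^2)
  rho1 <- sum(r[-1, , drop = FALSE] * r[-n, , drop = FALSE]) / denom
  rho2 <- sum(r[-(1:2), , drop = FALSE] * r[seq_len(n - 2), , drop = FALSE]) / denom
  phi0 <- if (abs(rho1) > 0.05) rho2 / rho1 else rho1
  phi0 <- max(min(phi0, 0.9), -0.9)
  mix0 <- if (abs(phi0) > 1e-3) max(min(rho1 / phi0, 0.95), 0.05) else 0.5

  neg2_reml <- function(par) {
    phi <- tanh(par[1]); m <- stats::plogis(par[2])
    V <- (1 - m) * diag(n) + m * ar1_cor(n, phi)
    U <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(U)) return(1e10)
    # L^-1 applied to X and data (V = U'U, L = t(U))
    A <- forwardsolve(t(U), X)
    B <- forwardsolve(t(U), data)
    XtVX <- crossprod(A)
    cx <- tryCatch(chol(XtVX), error = function(e) NULL)
    if (is.null(cx)) return(1e10)
    E <- crossprod(A, B)
    q <- colSums(B^2) - colSums(E * chol2inv(cx) %*% E)
    q <- pmax(q, .Machine$double.eps)
    2 * v * sum(log(diag(U))) + 2 * v * sum(log(diag(cx))) + (n - p) * sum(log(q))
  }

  opt <- stats::optim(c(atanh(phi0), stats::qlogis(mix0)), neg2_reml,
                      method = "Nelder-Mead",
                      control = list(maxit = maxit * 4, reltol = tol))
  phi <- tanh(opt$par[1]); mix <- stats::plogis(opt$par[2])
  structure(list(phi = phi, mix = mix, lag1 = phi * mix,
                 restricted_loglik = -opt$value / 2,
                 converged = opt$convergence == 0),
            class = "noise_model")
}

# W such that W V W' = I for V = (1-m) I + m Q(phi)
whitening_operator <- function(n, phi, mix) {
  V <- (1 - mix) * diag(n) + mix * ar1_cor(n, phi)
  forwardsolve(t(chol(V)), diag(n))
}

#' @export
print.noise_model <- function(x, ...) {
  cat(sprintf("<noise_model> AR(1)+white: phi = %.3f, AR share = %.2f, effective lag-1 = %.3f (%s)\n",
              x$phi, x$mix, x$lag1, if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' @export
print.glm_fit <- function(x, ...) {
  cat(sprintf("<glm_fit> %d coefficients x %d voxels\n", nrow(x$betas), ncol(x$betas)))
  print(x$noise)
  invisible(x)
}

#' Canonical-kernel condition betas from a fitted GLM
#'
#' Extracts the coefficients of the canonical haemodynamic regressor for each
#' condition (ignoring derivative and nuisance columns), the quantities that
#' downstream region-of-interest averages and decoders consume.
#'
#' @param fit a [fit_prewhitened_glm()] result.
#' @param conditions condition labels; default all in the design.
#' @return conditions x voxels matrix.
#' @export
condition_betas <- function(fit, conditions = NULL) {
  stopifnot(inherits(fit, "glm_fit"))
  conditions <- conditions %||% fit$design$conditions
  rows <- paste0(conditions, "_canonical")
  missing <- setdiff(rows, rownames(fit$betas))
  if (length(missing) > 0) {
    stop("conditions not in design: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  out <- fit$betas[rows, , drop = FALSE]
  rownames(out) <- conditions
  out
}

#' Least-squares-separate trial-wise betas
#'
#' Estimates one activation pattern per trial by fitting, for each trial, a
#' model containing a regressor for that trial alone plus a single regressor
#' aggregating every other trial (plus the high-pass filter and any nuisance
#' columns). This stabilises single-trial estimates under rapid designs.
#'
#' @param data scans x voxels matrix.
#' @param schedule an [event_schedule]; every event is treated as a trial.
#' @param basis haemodynamic basis for the trial regressors (canonical only is
#'   used for the returned betas).
#' @param n_scans,TR run geometry; defaults from the schedule.
#' @param nuisance optional confound columns.
#' @param highpass,cutoff cosine filter settings, as in [build_design_matrix()].
#' @param W optional whitening matrix (e.g. from a [fit_prewhitened_glm()])
#'   applied to model and data before estimation.
#' @return A trials x voxels matrix of single-trial betas, with the schedule
#'   attached as attribute `schedule`.
#' @export
lss_betas <- function(data, schedule, basis = "canonical",
                      n_scans = NULL, TR = NULL, nuisance = NULL,
                      highpass = TRUE, cutoff = 128, W = NULL) {
  data <- as.matrix(data)
  n_scans <- n_scans %||% attr(schedule, "n_scans")
  TR <- TR %||% attr(schedule, "TR")
  stopifnot(!is.null(n_scans), !is.null(TR), nrow(data) == n_scans)
  n_trials <- nrow(schedule)
  if (n_trials < 2) stop("least-squares separate needs at least 2 trials", call. = FALSE)

  hrf <- canonical_hrf(TR, basis)
  # single-trial canonical regressors, one column per trial
  Tmat <- vapply(seq_len(n_trials), function(i) {
    convolve_onsets(schedule$onset[i], hrf, n_scans, TR)[, "canonical"]
  }, numeric(n_scans))
  total <- rowSums(Tmat)

  extra <- NULL
  if (!is.null(nuisance)) extra <- as.matrix(nuisance)
  if (highpass) {
    extra <- cbind(extra, cosine_highpass_set(n_scans, TR, cutoff))
  } else {
    extra <- cbind(extra, intercept = rep(1, n_scans))
  }

  if (!is.null(W)) {
    data <- W %*% data
    Tmat <- W %*% Tmat
    total <- W %*% total
    extra <- W %*% extra
  }

  betas <- matrix(NA_real_, n_trials, ncol(data))
  for (i in seq_len(n_trials)) {
    Xi <- cbind(target = Tmat[, i], others = total - Tmat[, i], extra)
    qx <- qr(Xi)
    if (qx$rank < ncol(Xi)) {
      stop(sprintf("single-trial model for trial %d is rank deficient (overlapping trials?)", i),
           call. = FALSE)
    }
    betas[i, ] <- qr.coef(qx, data)[1, ]
  }
  attr(betas, "schedule") <- schedule
  betas
}
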