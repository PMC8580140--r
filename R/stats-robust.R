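#' Standardized linear and quadratic age terms
#'
#' Returns the standardized linear age predictor and the re-standardized
#' square of it, each with mean 0 and SD 1 over the cohort (population SD,
#' denominator n - 1).
#'
#' @param age numeric vector of ages in years.
#' @return A tibble with columns `z_age` and `z_age2`.
#' @export
age_terms <- function(age) {
  stopifnot(is.numeric(age), length(age) >= 3)
  z <- as.numeric(scale(age))
  z2 <- as.numeric(scale(z^2))
  tibble::tibble(z_age = z, z_age2 = z2)
}

#' Robust lifespan regression with a joint age Wald test
#'
#' Fits an M-estimated linear model with Huber weights (tuning constant
#' 1.345) and tests the age block (or any named block of terms) with a
#' two-tailed robust Wald F test using the Huber sandwich covariance of the
#' M-estimator. Per-term tests are hierarchical: they are flagged as reported
#' only when the block test passes `alpha`.
#'
#' @param data data frame containing the response and predictors.
#' @param formula model formula (predictors should already be standardized;
#'   use [age_terms()] for age).
#' @param block character vector of coefficient names forming the tested
#'   block; defaults to every term containing `"z_age"`.
#' @param alpha level gating the per-term tests (default 0.05).
#' @return A `harold_rfit` object with elements `fit` (the `rlm` fit),
#'   `vcov` (sandwich covariance), `block_test` (F, df, p, R2 as % weighted
#'   variance explained), and `terms` (tibble of estimates, robust SEs, t, p,
#'   and a `reported` flag). Supports [generics::tidy()] and
#'   [generics::glance()].
#' @export
robust_regress <- function(data, formula, block = NULL, alpha = 0.05) {
  mf <- stats::model.frame(formula, data = data)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(formula, data = data)
  n <- nrow(X); p <- ncol(X)
  if (n <= p + 2) stop("too few observations for the model", call. = FALSE)
  check_full_rank(X)

  fit <- MASS::rlm(X, y, psi = MASS::psi.huber, k = 1.345, maxit = 50)
  V <- huber_sandwich(fit, X)

  block <- block %||% grep("z_age", colnames(X), value = TRUE)
  if (length(block) == 0) stop("empty test block", call. = FALSE)
  missing <- setdiff(block, colnames(X))
  if (length(missing) > 0) {
    stop("block terms not in model: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  bt <- wald_block_test(fit$coefficients, V, block, df2 = n - p)
  bt$r2_pct <- 100 * weighted_r2_gain(y, X, fit, block)

  se <- sqrt(diag(V))
  tval <- fit$coefficients / se
  terms <- tibble::tibble(
    term = colnames(X), estimate = unname(fit$coefficients),
    std.error = unname(se), statistic = unname(tval),
    p.value = unname(2 * stats::pt(abs(tval), df = n - p, lower.tail = FALSE)),
    reported = colnames(X) %in% block & bt$p < alpha |
      !(colnames(X) %in% block)
  )
  structure(list(fit = fit, vcov = V, block = block, block_test = bt,
                 terms = terms, n = n, formula = formula),
            class = "harold_rfit")
}

# Huber sandwich covariance of the M-estimator:
#   A = mean psi'(r/s) x x',  B = s^2 mean psi(r/s)^2 x x',  V = A^-1 B A^-1 / n
huber_sandwich <- function(fit, X, k = 1.345) {
  n <- nrow(X)
  s <- fit$s
  u <- fit$residuals / s
  w <- MASS::psi.huber(u, k = k)            # psi(u)/u
  psi_val <- w * u
  psi_der <- MASS::psi.huber(u, k = k, deriv = 1)
  A <- crossprod(X * psi_der, X) / n
  B <- crossprod(X * psi_val) * s^2 / n # X' diag(psi^2) X
  Ai <- solve(A)
  (Ai %*% B %*% Ai) / n
}

wald_block_test <- function(coef, V, block, df2) {
  idx <- match(block, names(coef))
  b <- coef[idx]
  Vb <- V[idx, idx, drop = FALSE]
  q <- length(idx)
  Fstat <- as.numeric(crossprod(b, solve(Vb, b))) / q
  list(F = Fstat, df1 = q, df2 = df2,
       p = stats::pf(Fstat, q, df2, lower.tail = FALSE))
}

# proportion of weighted variance uniquely explained by the block, using the
# robust fit's final IRLS weights
weighted_r2_gain <- function(y, X, fit, block) {
  w <- fit$w
  X0 <- X[, setdiff(colnames(X), block), drop = FALSE]
  rss <- function(M) {
    f <- stats::lm.wfit(M, y, w)
    sum(w * f$residuals^2)
  }
  rss0 <- rss(X0)
  rss1 <- sum(w * fit$residuals^2)
  ybar <- stats::weighted.mean(y, w)
  tss <- sum(w * (y - ybar)^2)
  max((rss0 - rss1) / tss, 0)
}

#' @export
print.harold_rfit <- function(x, ...) {
  bt <- x$block_test
  cat(sprintf("<harold_rfit> robust regression, n = %d\n", x$n))
  cat(sprintf("  block [%s]: F(%d,%d) = %.2f, p = %.4g, R2 = %.2f%%\n",
              paste(x$block, collapse = ", "), bt$df1, bt$df2, bt$F, bt$p, bt$r2_pct))
  invisible(x)
}

#' Age-by-ipsilateral compensation interaction model
#'
#' Tests whether the relation between ipsilateral activation and a
#' performance outcome changes over the lifespan: the outcome is regressed
#' robustly on standardized ipsilateral activation, standardized linear and
#' quadratic age, and their interactions; the interaction block Wald test is
#' the compensation readout (compensation predicts higher ipsilateral
#' activation to go with better performance increasingly at older ages).
#'
#' @param data data frame (e.g. a [simulate_cohort()] table).
#' @param y,ipsi column names of the outcome (reaction-time summary) and
#'   ipsilateral activation.
#' @param alpha gating level for per-term tests.
#' @return A `harold_rfit` whose block test covers the two interaction terms.
#' @export
compensation_interaction <- function(data, y = "rt_sd", ipsi = "ipsi_mean",
                                     alpha = 0.05) {
  d <- prepare_model_frame(data, y, ipsi)
  f <- stats::as.formula(paste(y, "~ z_ipsi + z_age + z_age2 + z_ipsi:z_age + z_ipsi:z_age2"))
  robust_regress(d, f, block = c("z_ipsi:z_age", "z_ipsi:z_age2"), alpha = alpha)
}

#' Ipsilateral-by-contralateral partial-compensation model
#'
#' Partial compensation ("walking stick") predicts ipsilateral activation to
#' help only when contralateral function is low, i.e. an interaction between
#' the two hemispheres' activations in predicting performance.
#'
#' @param data data frame with the named columns.
#' @param y,ipsi,contra column names.
#' @param include_age add the standardized age terms as covariates.
#' @param alpha gating level.
#' @return A `harold_rfit` whose block test is the single
#'   ipsilateral-by-contralateral interaction.
#' @export
partial_compensation <- function(data, y = "rt_sd", ipsi = "ipsi_mean",
                                 contra = "contra_mean", include_age = FALSE,
                                 alpha = 0.05) {
  d <- prepare_model_frame(data, y, ipsi, contra)
  rhs <- "z_ipsi + z_contra + z_ipsi:z_contra"
  if (include_age) rhs <- paste(rhs, "+ z_age + z_age2")
  f <- stats::as.formula(paste(y, "~", rhs))
  robust_regress(d, f, block = "z_ipsi:z_contra", alpha = alpha)
}

prepare_model_frame <- function(data, y, ipsi, contra = NULL) {
  stopifnot(y %in% names(data), ipsi %in% names(data))
  if (stats::sd(data[[ipsi]]) == 0) {
    stop("ipsilateral activation is constant; model is rank deficient", call. = FALSE)
  }
  d <- data
  if (!all(c("z_age", "z_age2") %in% names(d))) {
    at <- age_terms(d$age)
    d$z_age <- at$z_age; d$z_age2 <- at$z_age2
  }
  d$z_ipsi <- as.numeric(scale(d[[ipsi]]))
  if (!is.null(contra)) {
    stopifnot(contra %in% names(data))
    if (stats::sd(data[[contra]]) == 0) {
      stop("contralateral activation is constant; model is rank deficient", call. = FALSE)
    }
    d$z_contra <- as.numeric(scale(d[[contra]]))
  }
  d
}
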