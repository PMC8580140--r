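test_that("the canonical haemodynamic kernel has the standard double-gamma shape", {
  h <- canonical_hrf(1.97, "canonical+temporal+dispersion", dt = 0.1)
  expect_equal(ncol(h$kernels), 3)
  expect_equal(unname(h$kernels[1, 1]), 0)   # vanishes at the origin
  expect_gt(sum(h$kernels[, 1]), 0)          # positive main lobe dominates
  # independently locate the double-gamma peak from the closed form
  tt <- seq(0, 32, by = 0.1)
  closed <- stats::dgamma(tt, shape = 6, scale = 1) -
    stats::dgamma(tt, shape = 16, scale = 1) / 6
  expect_equal(h$time[which.max(h$kernels[, 1])], tt[which.max(closed)])
  expect_equal(h$time[which.max(h$kernels[, 1])], 5, tolerance = 0.1) # ~5 s peak
  expect_error(canonical_hrf(0), "positive")
})

test_that("the cosine high-pass set follows the count rule and filters as intended", {
  C <- cosine_highpass_set(261, 1.97, 128)
  expect_equal(ncol(C), floor(2 * 261 * 1.97 / 128) + 1) # 9 incl. constant
  expect_lt(max(abs(crossprod(C) - diag(ncol(C)))), 1e-10)
  tt <- (0:260) * 1.97
  project_out <- function(x) x - C %*% crossprod(C, x)
  slow <- sin(2 * pi * tt / 300) # below the cutoff frequency
  expect_lt(stats::sd(project_out(slow)) / stats::sd(slow), 0.1) # >90% removed
  fast <- sin(2 * pi * tt / 64)
  expect_gt(stats::sd(project_out(fast)) / stats::sd(fast), 0.9) # >90% survives
  expect_warning(empty <- cosine_highpass_set(30, 1.97, 128), "shorter")
  expect_equal(ncol(empty), 0)
})

test_that("grand-mean scaling is exact, affine and guarded", {
  x <- matrix(50, 10, 4)
  expect_equal(grand_mean_scale(x), matrix(100, 10, 4))
  set.seed(1)
  y <- matrix(rexp(200) + 1, 50, 4)
  ys <- grand_mean_scale(y)
  expect_equal(mean(ys), 100, tolerance = 1e-9)
  expect_equal(stats::cor(ys), stats::cor(y), tolerance = 1e-12)
  expect_error(grand_mean_scale(y - 100), "positive")
})

test_that("restricted-likelihood noise estimates recover the generating autocorrelation", {
  set.seed(21)
  n <- 261; v <- 70
  design <- build_design_matrix(
    generate_event_schedule("sensorimotor", 3, n, 1.97), basis = "canonical")
  white <- matrix(rnorm(n * v), n, v)
  fitw <- fit_prewhitened_glm(white, design)
  expect_lt(abs(fitw$noise$phi), 0.05)
  ar <- sapply(1:v, function(j) as.numeric(stats::arima.sim(list(ar = 0.4), n)))
  fita <- fit_prewhitened_glm(ar, design)
  expect_lt(abs(fita$noise$phi - 0.4), 0.05)
  expect_lt(abs(mean(fita$residual_lag1)), 0.05) # pooled residual autocorrelation
})

test_that("rank-deficient designs are refused with the collinear columns named", {
  design <- build_design_matrix(
    generate_event_schedule("sensorimotor", 3, 120, 1.97,
                            n_bimodal = 30, n_unimodal = 2), basis = "canonical")
  design$X <- cbind(design$X, dup = design$X[, 1])
  expect_error(fit_prewhitened_glm(matrix(rnorm(120 * 3), 120, 3), design),
               "rank deficient.*dup")
})

test_that("filtering then fitting equals fitting with the filter columns included", {
  set.seed(5)
  sched <- generate_event_schedule("sensorimotor", 8, 150, 1.97,
                                   n_bimodal = 40, n_unimodal = 4)
  design <- build_design_matrix(sched, basis = "canonical")
  y <- matrix(rnorm(150 * 3), 150, 3)
  # joint fit (filter columns in the model), plain OLS for the comparison
  b_joint <- qr.coef(qr(design$X), y)[design$idx_task, , drop = FALSE]
  hp <- design$X[, design$idx_hp, drop = FALSE]
  P <- diag(150) - hp %*% t(hp) # orthonormal columns
  Xf <- P %*% design$X[, design$idx_task, drop = FALSE]
  b_filt <- qr.coef(qr(Xf), P %*% y)
  expect_equal(b_joint, b_filt, tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("whitened betas are unbiased on synthetic AR(1) data", {
  set.seed(31)
  sched <- generate_event_schedule("sensorimotor", 2, 120, 1.97,
                                   n_bimodal = 40, n_unimodal = 4)
  design <- build_design_matrix(sched, basis = "canonical")
  reg <- design$X[, "bimodal_canonical"]
  amp <- 1.5
  est <- replicate(200, {
    noise <- sapply(1:4, function(j) as.numeric(stats::arima.sim(list(ar = 0.3), 120)))
    y <- amp * reg + noise
    fit <- fit_prewhitened_glm(y, design)
    mean(condition_betas(fit, "bimodal"))
  })
  expect_lt(abs(mean(est) - amp) / amp, 0.02)
})

test_that("least-squares-separate betas preserve trial count and recover isolated trials", {
  sched <- generate_event_schedule("sensorimotor", 5, 200, 1.97,
                                   n_bimodal = 12, n_unimodal = 0)
  # widen the gaps so trials are isolated
  sched$onset <- seq(5, by = 25, length.out = 12)
  amp <- c(1, 1.5, 2)
  hrf <- canonical_hrf(1.97, "canonical")
  regs <- vapply(sched$onset, function(o) {
    haroldmvb:::convolve_onsets(o, hrf, 200, 1.97)[, 1]
  }, numeric(200))
  y <- regs %*% matrix(rep(1, 12)) %*% t(amp) # every trial at the voxel amplitude
  b <- lss_betas(y, sched, highpass = FALSE)
  expect_equal(nrow(b), 12)
  expect_equal(unname(colMeans(b)), amp, tolerance = 1e-6)
})

test_that("least-squares-separate beats naive all-trials least squares under rapid designs", {
  set.seed(41)
  n_trials <- 200; TR <- 1.97
  onsets <- cumsum(runif(n_trials, 2.5, 3.5))
  n_scans <- ceiling((max(onsets) + 20) / TR)
  sched <- haroldmvb:::new_event_schedule(
    tibble::tibble(onset = onsets, duration = 0, condition = "bimodal",
                   cond_type = "bimodal"),
    n_scans = n_scans, TR = TR, design = "sensorimotor")
  hrf <- canonical_hrf(TR, "canonical")
  Tmat <- vapply(onsets, function(o) {
    haroldmvb:::convolve_onsets(o, hrf, n_scans, TR)[, 1]
  }, numeric(n_scans))
  amps <- rnorm(n_trials, 1, 0.5)
  y <- matrix(Tmat %*% amps + rnorm(n_scans, 0, 0.6), ncol = 1)
  b_lss <- lss_betas(y, sched, highpass = FALSE)[, 1]
  b_lsa <- qr.coef(qr(cbind(Tmat, 1)), y)[1:n_trials, 1] # naive: all trials separate
  expect_gt(stats::cor(b_lss, amps), stats::cor(b_lsa, amps))
  expect_error(lss_betas(y, sched[1, ], highpass = FALSE), "at least 2")
})
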