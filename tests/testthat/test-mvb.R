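make_problem <- function(seed = 1, n = 64, v = 8, signal_voxel = NULL,
                         noise_sd = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * v), n, v)
  t_vec <- if (is.null(signal_voxel)) {
    rnorm(n, sd = noise_sd)
  } else {
    X[, signal_voxel]
  }
  raw_mvb_problem(t_vec, X)
}

test_that("target preparation residualizes against the confound basis", {
  sched <- generate_event_schedule("sensorimotor", 2, 150, 1.97,
                                   n_bimodal = 40, n_unimodal = 4)
  design <- build_design_matrix(sched, basis = "canonical+temporal+dispersion")
  set.seed(3)
  data <- matrix(rnorm(150 * 6), 150, 6)
  contrast <- as.numeric(grepl("bimodal_canonical",
                               colnames(design$X)[design$idx_task]))
  prob <- prepare_target(design, contrast, data)
  # orthogonal to every confound column (normalized inner products)
  ip <- abs(crossprod(prob$X0, prob$target)) /
    (sqrt(colSums(prob$X0^2)) * sqrt(sum(prob$target^2)))
  expect_lt(max(ip), 1e-8)
  expect_lt(max(abs(crossprod(prob$X0, prob$X))), 1e-8)
  # idempotent: residualizing the prepared pieces changes nothing
  q0 <- qr(prob$X0)
  expect_equal(as.numeric(qr.resid(q0, prob$target)), prob$target, tolerance = 1e-10)
  expect_error(prepare_target(design, rep(0, length(contrast)), data), "non-zero")
  expect_error(prepare_target(design, contrast[-1], data), "length")
})

test_that("a noiseless single-voxel target is identified decisively", {
  prob <- make_problem(seed = 2, signal_voxel = 3)
  fit <- fit_mvb(prob)
  others <- abs(fit$weights[-3])
  expect_gt(abs(fit$weights[3]), 10 * max(others, 1e-12))
  shuf <- prob
  shuf$target <- phase_shuffle(prob$target, seed = 11)
  expect_gt(fit$F - fit_mvb(shuf)$F, 3)
})

test_that("pure-noise decoding shows no real-versus-shuffled evidence gap", {
  set.seed(7)
  gaps <- replicate(50, {
    prob <- make_problem(seed = sample.int(1e6, 1))
    shuf <- prob
    shuf$target <- phase_shuffle(prob$target, seed = sample.int(1e6, 1))
    fit_mvb(prob)$F - fit_mvb(shuf)$F
  })
  expect_lt(abs(mean(gaps)), 1)
})

test_that("free energy is invariant to voxel order and non-decreasing along the greedy path", {
  for (seed in 1:20) {
    prob <- make_problem(seed = seed, signal_voxel = if (seed %% 2) 1 else NULL,
                         noise_sd = 1)
    if (seed %% 2) prob$target <- prob$target + rnorm(prob$n, sd = 0.5)
    fit <- fit_mvb(prob)
    expect_true(all(diff(fit$trace$F) > -1e-6))
    perm <- sample(prob$v)
    prob_p <- raw_mvb_problem(prob$target, prob$X[, perm])
    expect_equal(fit_mvb(prob_p)$F, fit$F, tolerance = 1e-6)
  }
})

test_that("fixed-hyperparameter free energy matches the closed-form ridge evidence", {
  for (seed in 1:20) {
    prob <- make_problem(seed = 100 + seed)
    s2 <- runif(1, 0.5, 2); lam <- runif(1, 0.05, 1)
    fit <- fit_mvb(prob, fixed = list(noise_var = s2, prior_var = lam))
    oracle <- ridge_log_evidence(prob$target, prob$X, s2, lam)
    expect_lt(abs(fit$F - oracle), 0.1)
  }
})

test_that("weight spread follows its definition", {
  expect_equal(weight_spread(c(2, 2, 2, 2)), 0)
  expect_equal(weight_spread(c(-1, 1)), 1)
  w <- c(0.2, -0.4, 1.1)
  expect_equal(weight_spread(3 * w), 3 * weight_spread(w))
  expect_error(weight_spread(1), "at least 2")
})

test_that("phase shuffling preserves the spectrum and mean while decorrelating", {
  set.seed(9)
  for (n in c(261, 262)) { # odd and even lengths
    x <- as.numeric(stats::arima.sim(list(ar = 0.5), n)) + 3
    y <- phase_shuffle(x, seed = 4)
    expect_equal(Mod(stats::fft(y)), Mod(stats::fft(x)), tolerance = 1e-8)
    expect_equal(mean(y), mean(x), tolerance = 1e-8)
    expect_false(isTRUE(all.equal(x, y)))
  }
  x <- as.numeric(stats::arima.sim(list(ar = 0.3), 261))
  rs <- vapply(1:200, function(s) stats::cor(x, phase_shuffle(x, s)), numeric(1))
  expect_lt(abs(mean(rs)), 0.05)
  expect_error(phase_shuffle(1:3, 1), "at least 4")
})
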