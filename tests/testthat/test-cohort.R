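test_that("cohorts are bit-identical for identical spec and seed", {
  sp <- tiny_spec(seed = 11)
  a <- simulate_cohort(sp, level = "bold")
  b <- simulate_cohort(sp, level = "bold")
  expect_identical(tibble::as_tibble(a), tibble::as_tibble(b))
  expect_identical(attr(a, "sessions")[[3]]$data, attr(b, "sessions")[[3]]$data)
})

test_that("spec invariants are enforced at construction", {
  expect_error(cohort_spec(1), "n_subjects")
  expect_error(cohort_spec(10, age_range = c(80, 20)), "age_range")
  expect_error(cohort_spec(10, noise_params = list(phi = 1.2)), "AR\\(1\\)")
  expect_error(cohort_spec(10, noise_params = list(sd = -1)), "innovation")
  expect_error(cohort_spec(10, rt_params = list(subject_sd_sd = 0)), "positive")
})

test_that("amplitude age laws go the expected way and are recoverable by regression", {
  sp <- cohort_spec(400, seed = 3, scenario = "haroldnull")
  co <- simulate_cohort(sp)
  # generator's own law: ipsilateral larger at 80 than at 20, contralateral opposite
  law <- haroldmvb:::amp_law
  expect_gt(law(sp$amplitude_params$ipsi, 80), law(sp$amplitude_params$ipsi, 20))
  expect_lt(law(sp$amplitude_params$contra, 80), law(sp$amplitude_params$contra, 20))
  # recover the linear components from the generated truths
  fit_i <- stats::lm(amp_ipsi_true ~ poly(age, 2, raw = TRUE), data = co)
  expect_gt(summary(fit_i)$coefficients[2, 1], 0)
  fit_c <- stats::lm(amp_contra_true ~ age, data = co)
  expect_equal(unname(stats::coef(fit_c)[2]), sp$amplitude_params$contra[["lin"]],
               tolerance = 0.25)
})

test_that("noiseless, drift-free sessions return the generating amplitudes through the GLM", {
  sp <- cohort_spec(3, seed = 5, n_voxels = 5, n_scans = 120,
                    noise_params = list(phi = 0, sd = 0, drift = 0),
                    schedule_args = list(n_bimodal = 30, n_unimodal = 2))
  co <- simulate_cohort(sp, level = "bold")
  sess <- attr(co, "sessions")[[1]]
  truth <- attr(co, "truths")[[1]]
  design <- build_design_matrix(sess$schedule, basis = "canonical")
  fit <- fit_prewhitened_glm(sess$data, design) # unscaled: betas in truth units
  cb <- condition_betas(fit, "bimodal")
  idx_ipsi <- which(sess$hemi == "ipsi")
  expected <- truth$amp_ipsi * haroldmvb:::voxel_profile(5)
  expect_equal(unname(cb[1, idx_ipsi]), expected, tolerance = 1e-6)
})

test_that("AR(1) noise empirically matches the generating coefficient", {
  sp <- cohort_spec(3, seed = 9, n_voxels = 40, n_scans = 261,
                    amplitude_params = list(contra = c(intercept = 0, lin = 0, quad = 0),
                                            ipsi = c(intercept = 0, lin = 0, quad = 0),
                                            subject_sd = 0),
                    noise_params = list(phi = 0.4, sd = 1, drift = 0))
  co <- simulate_cohort(sp, level = "bold")
  noise <- attr(co, "sessions")[[1]]$data - 100
  n <- nrow(noise)
  expect_gt(length(noise), 10000) # sample size behind the check
  r1 <- sum(noise[-1, ] * noise[-n, ]) / sum(noise^2)
  expect_equal(r1, 0.4, tolerance = 0.05)
})

test_that("reaction-time laws behave by construction", {
  # positive SD age slope: older generating SDs exceed younger ones
  sp <- cohort_spec(300, seed = 13, rt_params = list(subject_sd_mean = 1e-9,
                                                     subject_sd_sd = 1e-9))
  truths <- lapply(1:300, function(i) subject_truth(sp, i, patterns = FALSE))
  age <- vapply(truths, `[[`, numeric(1), "age")
  sds <- vapply(truths, `[[`, numeric(1), "rt_sd")
  expect_gt(mean(sds[age > 70]), mean(sds[age < 35]))
  # zero slopes, zero participant noise: one shared distribution
  sp0 <- cohort_spec(20, seed = 14,
                     rt_params = list(mean_slope = 0, sd_slope = 0,
                                      subject_sd_mean = 1e-9, subject_sd_sd = 1e-9))
  truths0 <- lapply(1:20, function(i) subject_truth(sp0, i, patterns = FALSE))
  expect_equal(diff(range(vapply(truths0, `[[`, numeric(1), "rt_mean"))), 0,
               tolerance = 1e-6)
  expect_equal(diff(range(vapply(truths0, `[[`, numeric(1), "rt_sd"))), 0,
               tolerance = 1e-6)
  expect_error(simulate_rt(truths0[[1]], sp0, n_trials = 1, seed = 1), "at least 2")
})

test_that("compensation coupling yields a negative RT-ipsilateral partial correlation", {
  co <- simulate_cohort(cohort_spec(500, seed = 17, scenario = "compensation"))
  r_rt <- stats::resid(stats::lm(rt_sd ~ age + I(age^2), data = co))
  r_ip <- stats::resid(stats::lm(amp_ipsi_true ~ age + I(age^2), data = co))
  expect_lt(stats::cor(r_rt, r_ip), 0)
})

test_that("scenario semantics: ipsilateral noise scaling tracks amplitude only under haroldnull", {
  sp_null <- cohort_spec(5, seed = 1, scenario = "haroldnull")
  sp_comp <- cohort_spec(5, seed = 1, scenario = "compensation")
  scale_null <- haroldmvb:::ipsi_noise_scale(sp_null, 80)
  expect_gt(scale_null, haroldmvb:::ipsi_noise_scale(sp_null, 25))
  expect_equal(haroldmvb:::ipsi_noise_scale(sp_comp, 80), 1)
})
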