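test_that("standardized age terms have mean zero and unit variance", {
  at <- age_terms(runif(100, 18, 87))
  expect_equal(mean(at$z_age), 0, tolerance = 1e-8)
  expect_equal(stats::sd(at$z_age), 1, tolerance = 1e-8)
  expect_equal(mean(at$z_age2), 0, tolerance = 1e-8)
  expect_equal(stats::sd(at$z_age2), 1, tolerance = 1e-8)
})

test_that("robust regression recovers noiseless coefficients exactly", {
  at <- age_terms(runif(200, 18, 87))
  d <- tibble::tibble(z_age = at$z_age, z_age2 = at$z_age2, y = 2 * at$z_age)
  fit <- robust_regress(d, y ~ z_age + z_age2)
  est <- fit$terms$estimate[match(c("z_age", "z_age2"), fit$terms$term)]
  expect_equal(est, c(2, 0), tolerance = 1e-8)
  expect_error(robust_regress(d[1:4, ], y ~ z_age + z_age2), "few")
})

test_that("robust slopes resist gross outliers better than least squares", {
  set.seed(3)
  wins <- replicate(60, {
    n <- 200
    x <- rnorm(n)
    y <- 0.5 * x + rnorm(n)
    bad <- order(abs(x), decreasing = TRUE)[1:20] # gross high-leverage errors
    y[bad] <- -sign(x[bad]) * runif(20, 8, 15)
    d <- tibble::tibble(x = x, y = y)
    rob <- robust_regress(d, y ~ x, block = "x")$terms$estimate[2]
    ols <- stats::coef(stats::lm(y ~ x, d))[2]
    abs(rob - 0.5) < abs(ols - 0.5)
  })
  expect_gte(mean(wins), 0.9)
})

test_that("standardization is invariant to the age unit", {
  co <- simulate_cohort(cohort_spec(300, seed = 51, scenario = "haroldnull"))
  co_dec <- co
  co_dec$age <- co_dec$age / 10 # decades
  at <- age_terms(co_dec$age)
  co_dec$z_age <- at$z_age; co_dec$z_age2 <- at$z_age2
  f1 <- compensation_interaction(co, y = "rt_sd")
  f2 <- compensation_interaction(co_dec, y = "rt_sd")
  expect_equal(f1$terms$estimate, f2$terms$estimate, tolerance = 1e-6)
  expect_equal(f1$block_test$F, f2$block_test$F, tolerance = 1e-6)
  o1 <- ordinal_boost_regress(tibble::tibble(age = co$age,
                                             category = rep(c("ambiguous", "boost"), 150)))
  o2 <- ordinal_boost_regress(tibble::tibble(age = co$age / 10,
                                             category = rep(c("ambiguous", "boost"), 150)))
  expect_equal(o1$terms$odds.ratio, o2$terms$odds.ratio, tolerance = 1e-6)
})

test_that("degenerate activation inputs are refused", {
  co <- simulate_cohort(cohort_spec(50, seed = 53))
  co$ipsi_mean <- 1
  expect_error(compensation_interaction(co), "constant")
  co2 <- simulate_cohort(cohort_spec(50, seed = 54))
  co2$contra_mean <- co2$ipsi_mean
  expect_error(partial_compensation(co2), "rank deficient")
})

test_that("hemisphere-interaction models detect built-in partial compensation", {
  set.seed(61)
  n <- 586
  zc <- rnorm(n); zi <- rnorm(n)
  y <- 300 - 5 * zc - 4 * zi * zc + rnorm(n, 0, 8) # ipsi helps when contra low
  d <- tibble::tibble(rt_sd = y, ipsi_mean = zi, contra_mean = zc,
                      age = runif(n, 18, 87))
  fit <- partial_compensation(d)
  expect_lt(fit$block_test$p, 0.05)
  # independent hemispheres: interaction stays calibrated
  fp <- replicate(100, {
    m <- 200
    d0 <- tibble::tibble(rt_sd = rnorm(m), ipsi_mean = rnorm(m),
                         contra_mean = rnorm(m), age = runif(m, 18, 87))
    partial_compensation(d0)$block_test$p < 0.05
  })
  expect_gt(mean(fp), 0.005)
  expect_lt(mean(fp), 0.12)
})

test_that("ordinal regression of boost categories falls back to binary when needed", {
  set.seed(71)
  n <- 120
  age <- runif(n, 18, 87)
  z <- scale(age)
  p <- stats::plogis(1.2 * z)
  cat3 <- ifelse(runif(n) < p, "boost", ifelse(runif(n) < 0.2, "reduction", "ambiguous"))
  o3 <- ordinal_boost_regress(tibble::tibble(age = age, category = cat3))
  expect_equal(o3$method, "ordinal")
  expect_gt(o3$terms$odds.ratio[o3$terms$term == "z_age"], 1)
  cat2 <- ifelse(runif(n) < p, "boost", "ambiguous") # no reductions observed
  o2 <- ordinal_boost_regress(tibble::tibble(age = age, category = cat2))
  expect_equal(o2$method, "binary")
  expect_gt(o2$terms$odds.ratio[1], 1)
  expect_error(ordinal_boost_regress(tibble::tibble(age = age,
                                                    category = rep("boost", n))),
               "one boost category")
})

test_that("continuous null Bayes factors separate null from real effects", {
  set.seed(81)
  null_bfs <- replicate(100, {
    n <- 586
    d <- tibble::tibble(z1 = rnorm(n), z2 = rnorm(n), y = rnorm(n))
    bf_continuous_null(d, y ~ z1 + z2, drop = "z2")$bf01
  })
  expect_gt(stats::median(null_bfs), 3)
  n <- 586
  d <- tibble::tibble(z1 = rnorm(n), z2 = rnorm(n))
  d$y <- 0.3 * d$z2 + rnorm(n)
  expect_lt(bf_continuous_null(d, y ~ z1 + z2, drop = "z2")$bf01, 1 / 3)
  d$ycopy <- d$y
  expect_lt(bf_continuous_null(d, y ~ z1 + ycopy, drop = "ycopy")$bf01, 1e-6)
  expect_error(bf_continuous_null(d, y ~ z1 + z2, drop = "zz"), "nested")
})

test_that("directional categorical Bayes factors track the slope sign", {
  set.seed(91)
  n <- 150
  age <- runif(n, 18, 87)
  z <- as.numeric(scale(age))
  mk <- function(beta) {
    tibble::tibble(age = age,
                   category = ifelse(runif(n) < stats::plogis(-0.3 + beta * z),
                                     "boost", "ambiguous"))
  }
  neg <- bf_directional_categorical(mk(-1), seed = 1)
  expect_gt(neg$bf01, 3)   # evidence against a positive age effect
  expect_true(neg$converged)
  pos <- bf_directional_categorical(mk(1.5), seed = 2)
  expect_lt(pos$bf01, 1)
  # zero slope: no directional evidence either way, posterior mass near 1/2
  flat <- replicate(30, {
    bf_directional_categorical(mk(0)[sample(n, 50), ],
                               seed = sample.int(1e6, 1))$posterior_prob_positive
  })
  expect_lt(abs(mean(flat) - 0.5), 0.15)
  expect_gt(mean(flat > 0.5), 0.2) # both directions occur
  expect_lt(mean(flat > 0.5), 0.8)
})

test_that("Bayes factor interpretation uses the stated evidence bands", {
  expect_equal(interpret_bf(4), "substantial")
  expect_equal(interpret_bf(22), "strong")
  expect_equal(interpret_bf(2), "anecdotal")
  expect_equal(interpret_bf(1), "anecdotal (boundary)")
  expect_equal(interpret_bf(0.2), "favors alternative")
  expect_error(interpret_bf(-1), "positive")
})
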