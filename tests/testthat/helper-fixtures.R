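# Shared small fixtures, built once per test run.

tiny_spec <- function(seed = 7, scenario = "haroldnull", n_subjects = 6,
                      n_voxels = 6, design = "sensorimotor") {
  cohort_spec(n_subjects, seed = seed, design = design, scenario = scenario,
              n_voxels = n_voxels, n_scans = if (design == "sensorimotor") 120 else 160,
              schedule_args = if (design == "sensorimotor") {
                list(n_bimodal = 40, n_unimodal = 4)
              } else {
                list(n_trials = 80)
              })
}

# a decoding problem with known structure, free of design/confound plumbing
raw_mvb_problem <- function(target, X) {
  structure(list(target = as.numeric(target), X = as.matrix(X),
                 X0 = matrix(0, length(target), 0),
                 n = length(target), v = ncol(X)),
            class = "mvb_problem")
}

# independent closed-form log marginal likelihood of the Bayesian ridge
# decoder (single all-voxel subset): weight-space determinant identity,
# deliberately a different route than the package's scan-space evaluation
ridge_log_evidence <- function(t_vec, X, noise_var, prior_var) {
  n <- length(t_vec); v <- ncol(X)
  XtX <- crossprod(X)
  M <- noise_var * diag(v) + prior_var * XtX
  d <- eigen(XtX, symmetric = TRUE, only.values = TRUE)$values
  logdet <- (n - v) * log(noise_var) + sum(log(noise_var + prior_var * d))
  Xt <- crossprod(X, t_vec)
  quad <- (sum(t_vec^2) - prior_var * sum(Xt * solve(M, Xt))) / noise_var
  -0.5 * (n * log(2 * pi) + logdet + quad)
}

# exhaustive best 2-voxel-subset evidence, maximised over hyperparameters
# with the closed form above (independent of the greedy path)
best_pair_evidence <- function(t_vec, X) {
  pairs <- utils::combn(ncol(X), 2)
  best <- -Inf
  for (p in seq_len(ncol(pairs))) {
    Xp <- X[, pairs[, p], drop = FALSE]
    f <- function(th) -ridge_log_evidence(t_vec, Xp, exp(th[1]), exp(th[2]))
    opt <- stats::optim(c(log(stats::var(t_vec)), 0), f, method = "Nelder-Mead",
                        control = list(maxit = 300, reltol = 1e-8))
    best <- max(best, -opt$value)
  }
  best
}

make_finger_patterns <- function(n_per_class = 20, v = 10, sep = 4, noise = 1,
                                 seed = 1) {
  set.seed(seed)
  classes <- c("index", "middle", "ring", "little")
  centroids <- matrix(rnorm(4 * v, sd = sep), 4, v)
  labels <- rep(classes, each = n_per_class)
  X <- centroids[rep(1:4, each = n_per_class), ] +
    matrix(rnorm(4 * n_per_class * v, sd = noise), 4 * n_per_class, v)
  list(X = X, labels = labels)
}
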