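#' Specify a synthetic lifespan cohort
#'
#' A `cohort_spec` fixes every generating parameter of the synthetic cohort:
#' sample size, age range, task design, scenario, amplitude age laws,
#' information (pattern) parameters, noise model and reaction-time laws.
#' Identical specs with identical seeds yield bit-identical cohorts.
#'
#' Three scenarios differ only in what the rising ipsilateral activity means:
#'
#' * `haroldnull`: ipsilateral mean amplitude rises with age (with quadratic
#'   flattening) while contralateral falls, but ipsilateral noise scales with
#'   its amplitude so the signal-to-noise ratio, and hence decodable
#'   information, is age-flat (nonspecific hyperactivation).
#' * `compensation`: the rising ipsilateral amplitude carries genuinely
#'   increasing unique information (noise does not scale up), and reaction
#'   time variability is negatively coupled to ipsilateral activation,
#'   increasingly so at older ages.
#' * `dedifferentiation`: ipsilateral amplitude rises but its
#'   signal-to-noise ratio declines with age.
#'
#' @param n_subjects number of participants (>= 2).
#' @param age_range lifespan bounds in years, `c(low, high)`, low < high.
#' @param seed master integer seed.
#' @param design `"sensorimotor"` (one right-index press per trial) or
#'   `"free_selection"` (four fingers, specified/choice).
#' @param scenario ground-truth generating scenario (see Details).
#' @param n_voxels voxels per region of interest (default 70).
#' @param n_scans,TR run geometry; defaults 261 scans (sensorimotor) or 296
#'   (free selection) at TR = 1.97 s.
#' @param amplitude_params,info_params,noise_params,rt_params generating
#'   parameters; see the defaults in the function signature. Age laws are
#'   centred at 50 years; amplitudes are in arbitrary units relative to an
#'   AR(1) innovation standard deviation of 1.
#' @param meas_sd measurement noise standard deviation used by the
#'   summary-level generator (stand-in for GLM estimation error).
#' @param schedule_args extra arguments for [generate_event_schedule()]
#'   (e.g. reduced trial counts for small test fixtures).
#' @return A `cohort_spec` object.
#' @export
cohort_spec <- function(n_subjects, age_range = c(18, 87), seed = 1,
                        design = c("sensorimotor", "free_selection"),
                        scenario = c("haroldnull", "compensation", "dedifferentiation"),
                        n_voxels = 70, n_scans = NULL, TR = 1.97,
                        amplitude_params = list(), info_params = list(),
                        noise_params = list(), rt_params = list(),
                        meas_sd = 0.1, schedule_args = list()) {
  design <- match.arg(design)
  scenario <- match.arg(scenario)
  if (n_subjects < 2) stop("n_subjects must be >= 2", call. = FALSE)
  if (length(age_range) != 2 || age_range[1] >= age_range[2]) {
    stop("age_range must be c(low, high) with low < high", call. = FALSE)
  }
  n_scans <- n_scans %||% if (design == "sensorimotor") 261L else 296L

  ap <- utils::modifyList(list(
    contra = c(intercept = 1.0, lin = -0.006, quad = 0),
    ipsi = c(intercept = 0.45, lin = 0.008, quad = -0.00012),
    subject_sd = 0.12
  ), amplitude_params)

  ip <- utils::modifyList(list(
    contra_sep = 0.35, contra_sep_slope = 0,
    ipsi_sep = 0.15,
    ipsi_sep_slope = switch(scenario, compensation = 0.003,
                            dedifferentiation = -0.002, 0)
  ), info_params)

  np <- utils::modifyList(list(phi = 0.2, sd = 1.0, drift = 2.0), noise_params)
  if (abs(np$phi) >= 1) stop("AR(1) coefficient must lie in (-1, 1)", call. = FALSE)
  if (np$sd < 0) stop("innovation SD must be non-negative", call. = FALSE)

  rp <- utils::modifyList(list(
    mean0 = 320, mean_slope = 1.0, sd0 = 55, sd_slope = 0.8,
    subject_sd_mean = 25, subject_sd_sd = 10,
    ipsi_main = if (scenario == "compensation") -4 else 0,
    ipsi_age_interaction = if (scenario == "compensation") -8 else 0
  ), rt_params)
  if (rp$subject_sd_sd <= 0 || rp$subject_sd_mean <= 0) {
    stop("reaction-time SDs must be positive", call. = FALSE)
  }

  structure(list(n_subjects = as.integer(n_subjects), age_range = age_range,
                 seed = as.integer(seed), design = design, scenario = scenario,
                 n_voxels = as.integer(n_voxels), n_scans = as.integer(n_scans),
                 TR = TR, amplitude_params = ap, info_params = ip,
                 noise_params = np, rt_params = rp, meas_sd = meas_sd,
                 schedule_args = schedule_args),
            class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf("<cohort_spec> %d subjects aged %g-%g, %s design, scenario: %s, %d voxels/ROI, seed %d\n",
              x$n_subjects, x$age_range[1], x$age_range[2], x$design,
              x$scenario, x$n_voxels, x$seed))
  invisible(x)
}

# mean-amplitude age law, centred at 50 years
amp_law <- function(par, age) {
  unname(par["intercept"] + par["lin"] * (age - 50) + par["quad"] * (age - 50)^2)
}

# ipsilateral noise scaling implementing the scenario semantics
ipsi_noise_scale <- function(spec, age) {
  amp_ref <- amp_law(spec$amplitude_params$ipsi, 50)
  amp_now <- amp_law(spec$amplitude_params$ipsi, age)
  ratio <- pmax(amp_now, 0.05) / pmax(amp_ref, 0.05)
  switch(spec$scenario,
         haroldnull = ratio,        # SNR age-flat
         compensation = 1,          # SNR rises with amplitude
         dedifferentiation = ratio^2) # SNR falls with age
}

#' Ground truth for one participant
#'
#' Reproducible from `(spec, index)` alone: all random draws use a
#' per-subject sub-seed derived from the spec's master seed.
#'
#' @param spec a [cohort_spec()].
#' @param i subject index in `1:n_subjects`.
#' @param patterns draw the per-condition voxel pattern vectors (needed for
#'   BOLD simulation; skipped by the summary-level generator). Patterns are
#'   drawn last, so the age, amplitude and reaction-time values are identical
#'   either way.
#' @return A `subject_truth` list: age, true mean amplitudes per hemisphere,
#'   per-condition pattern vectors, noise scaling, and the generating
#'   reaction-time mean/SD.
#' @export
subject_truth <- function(spec, i, patterns = TRUE) {
  stopifnot(inherits(spec, "cohort_spec"), i >= 1, i <= spec$n_subjects)
  seeds <- sub_seeds(spec$seed, spec$n_subjects)
  subject_truth_seeded(spec, i, seeds[i], patterns)
}

subject_truth_seeded <- function(spec, i, seed_i, patterns = TRUE) {
  local_seed(seed_i, {
    age <- stats::runif(1, spec$age_range[1], spec$age_range[2])
    ap <- spec$amplitude_params
    ipsi_dev <- stats::rnorm(1, 0, ap$subject_sd)
    amp_contra <- amp_law(ap$contra, age) + stats::rnorm(1, 0, ap$subject_sd)
    amp_ipsi <- amp_law(ap$ipsi, age) + ipsi_dev

    ip <- spec$info_params
    sep_contra <- max(ip$contra_sep + ip$contra_sep_slope * (age - 50), 0.02)
    sep_ipsi <- max(ip$ipsi_sep + ip$ipsi_sep_slope * (age - 50), 0.02)

    # participant-level reaction-time generating values
    rp <- spec$rt_params
    span <- diff(spec$age_range)
    z_age <- (age - mean(spec$age_range)) / (span / sqrt(12))
    z_ipsi <- if (ap$subject_sd > 0) ipsi_dev / ap$subject_sd else 0
    rt_mean <- rp$mean0 + rp$mean_slope * (age - 50) + stats::rnorm(1, 0, rp$subject_sd_mean)
    rt_sd <- rp$sd0 + rp$sd_slope * (age - 50) +
      rp$ipsi_main * z_ipsi + rp$ipsi_age_interaction * z_ipsi * z_age +
      stats::rnorm(1, 0, rp$subject_sd_sd)
    rt_sd <- max(rt_sd, 5)

    fingers <- c("index", "middle", "ring", "little")
    v <- spec$n_voxels
    pat <- if (patterns) {
      list(contra = finger_patterns(fingers, 2L * v), # extra ranked voxels for controls
           ipsi = finger_patterns(fingers, v))
    } else NULL

    structure(list(index = i, age = age, amp_contra = amp_contra,
                   amp_ipsi = amp_ipsi, ipsi_resid_z = z_ipsi,
                   sep_contra = sep_contra, sep_ipsi = sep_ipsi,
                   noise_scale_ipsi = ipsi_noise_scale(spec, age),
                   patterns = pat, rt_mean = rt_mean, rt_sd = rt_sd,
                   seed = seed_i),
              class = "subject_truth")
  })
}

# zero-mean, unit-norm finger pattern directions over v voxels
finger_patterns <- function(fingers, v) {
  P <- matrix(stats::rnorm(length(fingers) * v), length(fingers), v)
  P <- sweep(P, 2, colMeans(P)) # zero mean over fingers, so mean response = amp
  P <- P / sqrt(rowSums(P^2))
  rownames(P) <- fingers
  P
}

#' Simulate an event-related BOLD session for one participant
#'
#' Per-voxel series are built as condition amplitudes times voxel spatial
#' profiles (plus finger-specific pattern components in the free-selection
#' design), convolved with the canonical haemodynamic response, on top of a
#' 100-unit baseline, slow cosine drift below the 1/128 Hz cutoff, and AR(1)
#' noise. The contralateral region carries twice the nominal voxel count so
#' voxel-count-matched control analyses can extend it by next-ranked voxels.
#'
#' @param truth a [subject_truth()].
#' @param schedule an [event_schedule] consistent with the spec's design.
#' @param spec the [cohort_spec()].
#' @return A `bold_session`: list with `data` (scans x voxels), `hemi`
#'   (factor `contra`/`ipsi` per voxel), `rank` (statistic-like voxel rank
#'   within hemisphere), the schedule and the truth.
#' @export
simulate_bold <- function(truth, schedule, spec) {
  stopifnot(inherits(truth, "subject_truth"), inherits(spec, "cohort_spec"))
  if (attr(schedule, "design") != spec$design) {
    stop("schedule design does not match the cohort spec", call. = FALSE)
  }
  np <- spec$noise_params
  if (abs(np$phi) >= 1) stop("non-stationary AR parameter", call. = FALSE)
  n_scans <- attr(schedule, "n_scans"); TR <- attr(schedule, "TR")
  v <- spec$n_voxels
  v_contra <- 2L * v

  local_seed(truth$seed + 1L, {
    hrf <- canonical_hrf(TR, "canonical")
    conds <- unique(as.character(schedule$condition))
    regs <- do.call(cbind, lapply(conds, function(cond) {
      convolve_onsets(schedule$onset[schedule$condition == cond], hrf, n_scans, TR)[, 1]
    }))
    colnames(regs) <- conds

    profile_c <- voxel_profile(v_contra)
    profile_i <- voxel_profile(v)
    amps_contra <- amp_matrix(conds, truth$amp_contra, profile_c,
                              truth$patterns$contra, truth$sep_contra, spec$design)
    amps_ipsi <- amp_matrix(conds, truth$amp_ipsi, profile_i,
                            truth$patterns$ipsi, truth$sep_ipsi, spec$design)

    signal <- regs %*% cbind(amps_contra, amps_ipsi)
    n_vox <- ncol(signal)

    drift <- matrix(0, n_scans, n_vox)
    if (np$drift > 0) {
      hp <- cosine_highpass_set(n_scans, TR, 128)
      k <- min(3L, ncol(hp) - 1L)
      if (k > 0) {
        co <- matrix(stats::rnorm(k * n_vox, 0, np$drift), k, n_vox)
        drift <- hp[, 1 + seq_len(k), drop = FALSE] %*% co
      }
    }

    noise_sd <- c(rep(np$sd, v_contra), rep(np$sd * truth$noise_scale_ipsi, v))
    noise <- matrix(0, n_scans, n_vox)
    if (np$sd > 0) {
      innov <- matrix(stats::rnorm(n_scans * n_vox), n_scans, n_vox)
      innov <- sweep(innov, 2, noise_sd, "*")
      noise <- apply(innov, 2, function(w) {
        as.numeric(stats::filter(w, np$phi, method = "recursive",
                                 init = w[1] / sqrt(max(1 - np$phi^2, 1e-8))))
      })
    }

    structure(list(data = 100 + signal + drift + noise,
                   hemi = factor(c(rep("contra", v_contra), rep("ipsi", v)),
                                 levels = c("contra", "ipsi")),
                   rank = c(seq_len(v_contra), seq_len(v)),
                   schedule = schedule, truth = truth, TR = TR,
                   n_scans = n_scans),
              class = "bold_session")
  })
}

# declining positive spatial profile, mean 1 (so the region mean tracks the
# generating amplitude and later-ranked voxels respond more weakly)
voxel_profile <- function(v) {
  p <- exp(-1.2 * (seq_len(v) - 1) / v)
  p / mean(p)
}

amp_matrix <- function(conds, amp, profile, patterns, sep, design) {
  v <- length(profile)
  out <- matrix(0, length(conds), v, dimnames = list(conds, NULL))
  for (cond in conds) {
    base <- amp * profile
    if (design == "free_selection" && cond %in% rownames(patterns)) {
      base <- base + sep * patterns[cond, seq_len(v)]
    }
    out[cond, ] <- base
  }
  out
}

#' @export
print.bold_session <- function(x, ...) {
  cat(sprintf("<bold_session> %d scans x %d voxels (%d contra incl. reserve, %d ipsi)\n",
              x$n_scans, ncol(x$data), sum(x$hemi == "contra"), sum(x$hemi == "ipsi")))
  invisible(x)
}

#' Simulate trial-wise reaction times for one participant
#'
#' Trials are drawn from a normal distribution with the participant-level
#' mean and SD fixed in the [subject_truth()] (which encode the cohort's age
#' laws and, under the compensation scenario, the coupling between
#' ipsilateral activation and reaction-time variability), truncated below at
#' 120 ms.
#'
#' @param truth a [subject_truth()].
#' @param spec the [cohort_spec()].
#' @param n_trials number of trials (>= 2).
#' @param seed integer seed.
#' @return Numeric vector of trial reaction times in ms.
#' @export
simulate_rt <- function(truth, spec, n_trials, seed) {
  stopifnot(inherits(truth, "subject_truth"))
  if (n_trials < 2) stop("need at least 2 trials", call. = FALSE)
  if (truth$rt_sd <= 0) stop("generated reaction-time SD must be positive", call. = FALSE)
  local_seed(seed, {
    rt <- stats::rnorm(n_trials, truth$rt_mean, truth$rt_sd)
    while (any(bad <- rt < 120)) {
      rt[bad] <- stats::rnorm(sum(bad), truth$rt_mean, truth$rt_sd)
    }
    rt
  })
}

#' Generate a full synthetic cohort
#'
#' Produces the per-participant table every downstream stage consumes. At
#' `level = "summary"` the measured region means are the true amplitudes plus
#' measurement noise (`meas_sd`), a fast stand-in for the imaging path used
#' by large calibration simulations; at `level = "bold"` full BOLD sessions
#' are attached (run [run_univariate()] to fill the measured means via the
#' GLM).
#'
#' @param spec a [cohort_spec()].
#' @param level `"summary"` or `"bold"`.
#' @return A `harold_cohort` tibble with columns `participant`, `age`,
#'   `z_age`, `z_age2` (standardized linear/quadratic age), true and measured
#'   amplitudes, `rt_mean`, `rt_sd` and `scenario`; the spec is attached as
#'   attribute `spec`, BOLD sessions (if any) as attribute `sessions`.
#' @export
simulate_cohort <- function(spec, level = c("summary", "bold")) {
  level <- match.arg(level)
  subj_seeds <- sub_seeds(spec$seed, spec$n_subjects)
  truths <- lapply(seq_len(spec$n_subjects), function(i) {
    subject_truth_seeded(spec, i, subj_seeds[i], patterns = level == "bold")
  })
  n_trials <- if (spec$design == "sensorimotor") 120L else 240L
  rt_seeds <- sub_seeds(spec$seed + 1L, spec$n_subjects)

  rt_stats <- vapply(seq_along(truths), function(i) {
    rt <- simulate_rt(truths[[i]], spec, n_trials, rt_seeds[i])
    c(mean(rt), stats::sd(rt))
  }, numeric(2))
  rows <- tibble::tibble(
    participant = seq_along(truths),
    age = vapply(truths, `[[`, numeric(1), "age"),
    amp_contra_true = vapply(truths, `[[`, numeric(1), "amp_contra"),
    amp_ipsi_true = vapply(truths, `[[`, numeric(1), "amp_ipsi"),
    rt_mean = rt_stats[1, ], rt_sd = rt_stats[2, ]
  )

  meas_seed <- sub_seeds(spec$seed + 2L, 1L)
  sessions <- NULL
  if (level == "summary") {
    meas <- local_seed(meas_seed, {
      matrix(stats::rnorm(2 * nrow(rows), 0, spec$meas_sd), ncol = 2)
    })
    rows$contra_mean <- rows$amp_contra_true + meas[, 1]
    rows$ipsi_mean <- rows$amp_ipsi_true + meas[, 2]
  } else {
    sched_seeds <- sub_seeds(spec$seed + 3L, spec$n_subjects)
    sessions <- lapply(seq_along(truths), function(i) {
      sched <- do.call(generate_event_schedule,
                       c(list(design = spec$design, seed = sched_seeds[i],
                              n_scans = spec$n_scans, TR = spec$TR),
                         spec$schedule_args))
      simulate_bold(truths[[i]], sched, spec)
    })
    rows$contra_mean <- NA_real_
    rows$ipsi_mean <- NA_real_
  }

  at <- age_terms(rows$age)
  rows <- dplyr::mutate(rows, z_age = at$z_age, z_age2 = at$z_age2,
                        scenario = spec$scenario,
                        .after = "age")
  structure(rows, spec = spec, sessions = sessions, truths = truths,
            class = c("harold_cohort", class(rows)))
}

#' @export
print.harold_cohort <- function(x, ...) {
  spec <- attr(x, "spec")
  cat(sprintf("<harold_cohort> %d participants, %s design, scenario: %s%s\n",
              nrow(x), spec$design, spec$scenario,
              if (is.null(attr(x, "sessions"))) " (summary level)" else " (with BOLD sessions)"))
  NextMethod()
}
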