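#' Categorize a log-evidence difference
#'
#' The bilateral-minus-contralateral difference in log model evidence is
#' coded `boost` when above 3 nats, `reduction` when below -3, and
#' `ambiguous` in the closed interval in between; 3 nats corresponds to a
#' Bayes factor just above 20, conventionally strong evidence.
#'
#' @param delta numeric vector of log-evidence differences (nats).
#' @return Factor with levels `reduction`, `ambiguous`, `boost`.
#' @export
categorize_boost <- function(delta) {
  if (any(!is.finite(delta))) stop("log-evidence differences must be finite", call. = FALSE)
  factor(ifelse(delta > 3, "boost", ifelse(delta < -3, "reduction", "ambiguous")),
         levels = c("reduction", "ambiguous", "boost"))
}

#' Convert a log-evidence difference to a Bayes factor
#'
#' @param delta log-evidence difference in nats.
#' @return `exp(delta)`.
#' @export
logdiff_to_bayes_factor <- function(delta) {
  if (any(!is.finite(delta))) stop("log-evidence differences must be finite", call. = FALSE)
  exp(delta)
}

#' Reliability filter from phase-shuffled reference fits
#'
#' A participant's decoder is considered reliable when the free energy of the
#' real bilateral model exceeds the mean over phase-shuffled reference fits
#' by more than 3 nats (strictly). Also reports the group-level one-tailed
#' t-test that the cohort mean of these true-minus-shuffled differences
#' exceeds 3.
#'
#' @param f_real numeric vector, one real-model free energy per participant.
#' @param f_shuffled matrix (participants x shuffles) or list of per-
#'   participant shuffled free energies.
#' @return A list with `delta_null` (per participant), `included` (logical),
#'   `n_included`, `n_excluded`, and `group_test` (t statistic, df, p for
#'   mean > 3).
#' @export
reliability_filter <- function(f_real, f_shuffled) {
  if (is.list(f_shuffled)) {
    if (any(lengths(f_shuffled) == 0)) {
      stop("every participant needs at least one shuffled fit", call. = FALSE)
    }
    mean_shuf <- vapply(f_shuffled, mean, numeric(1))
  } else {
    f_shuffled <- as.matrix(f_shuffled)
    if (ncol(f_shuffled) < 1) stop("every participant needs at least one shuffled fit", call. = FALSE)
    mean_shuf <- rowMeans(f_shuffled)
  }
  stopifnot(length(f_real) == length(mean_shuf))
  delta_null <- f_real - mean_shuf
  included <- delta_null > 3
  gt <- stats::t.test(delta_null, mu = 3, alternative = "greater")
  list(delta_null = delta_null, included = included,
       n_included = sum(included), n_excluded = sum(!included),
       group_test = list(t = unname(gt$statistic), df = unname(gt$parameter),
                         p = gt$p.value, mean = mean(delta_null)))
}

#' Run the MVB boost model comparison on a cohort
#'
#' For every participant: fit the first-level GLM (AR(1)+white prewhitening),
#' decode the action-versus-baseline contrast with multivariate Bayes from
#' (i) the bilateral voxel set and (ii) the contralateral set alone, take the
#' difference in free energy, categorize it at the +/-3 nats thresholds, and
#' filter out participants whose bilateral decoder does not beat its
#' phase-shuffled reference by more than 3 nats.
#'
#' Voxel-count-matched controls re-run the same comparison with the bilateral
#' set halved (a seeded hemisphere-balanced subsample, with a fresh
#' reliability filter because the bilateral model changed) or the
#' contralateral set doubled by its next-ranked reserve voxels.
#'
#' @param cohort a [simulate_cohort()] result at `level = "bold"`.
#' @param mode `"main"`, `"halve_bilateral"` or `"double_contralateral"`.
#' @param shuffles phase-shuffled reference fits per participant (default 20).
#' @param seed integer seed for shuffles and subsampling.
#' @param max_steps greedy step cap passed to [fit_mvb()].
#' @param progress print a dot per participant.
#' @return A `boost_records` tibble: one row per participant with
#'   `F_bilateral`, `F_contralateral`, `delta`, `category`, `delta_null`,
#'   `included`, `spread_contra`, `spread_ipsi`, plus `age` and measured
#'   region means; the group reliability test and mode are attributes.
#' @export
run_mvb_boost <- function(cohort, mode = c("main", "halve_bilateral", "double_contralateral"),
                          shuffles = 20, seed = 1, max_steps = 8, progress = FALSE) {
  mode <- match.arg(mode)
  sessions <- attr(cohort, "sessions")
  if (is.null(sessions)) {
    stop("cohort has no BOLD sessions; simulate with level = \"bold\"", call. = FALSE)
  }
  spec <- attr(cohort, "spec")
  v <- spec$n_voxels
  n_subj <- length(sessions)
  seeds <- sub_seeds(seed, n_subj)

  rows <- vector("list", n_subj)
  for (i in seq_len(n_subj)) {
    rows[[i]] <- boost_one(sessions[[i]], v, mode, shuffles, seeds[i], max_steps)
    if (progress) cat(".")
  }
  if (progress) cat("\n")
  rec <- dplyr::bind_rows(rows)
  rec$participant <- cohort$participant
  rec$age <- cohort$age
  rec$z_age <- cohort$z_age
  rec$z_age2 <- cohort$z_age2
  rel <- reliability_filter(rec$F_bilateral, matrix(rec$delta_null_mean_shuf, ncol = 1))
  # per-participant filter already computed inside boost_one; recompute group test
  rec$included <- rec$delta_null > 3
  rec$category <- categorize_boost(rec$delta)
  out <- dplyr::relocate(rec, "participant", "age")
  structure(tibble::as_tibble(out), mode = mode,
            group_reliability = rel$group_test,
            class = c("boost_records", class(tibble::tibble())))
}

boost_one <- function(session, v, mode, shuffles, seed, max_steps) {
  hemi <- session$hemi
  idx_contra <- which(hemi == "contra" & session$rank <= v)
  idx_ipsi <- which(hemi == "ipsi")[seq_len(min(v, sum(hemi == "ipsi")))]

  seeds <- sub_seeds(seed, shuffles + 1L)
  if (mode == "halve_bilateral") {
    pick <- local_seed(seeds[shuffles + 1L], {
      c(sample(idx_contra, floor(v / 2)), sample(idx_ipsi, ceiling(v / 2)))
    })
    idx_bilateral <- sort(pick)
  } else if (mode == "double_contralateral") {
    reserve <- which(hemi == "contra" & session$rank > v)
    if (length(reserve) < v) {
      stop("not enough reserve contralateral voxels to double the model", call. = FALSE)
    }
    idx_contra <- c(idx_contra, reserve[seq_len(v)])
    idx_bilateral <- c(which(hemi == "contra" & session$rank <= v), idx_ipsi)
  } else {
    idx_bilateral <- c(idx_contra, idx_ipsi)
  }

  design <- build_design_matrix(session$schedule, basis = "canonical")
  scaled <- grand_mean_scale(session$data)
  fit <- fit_prewhitened_glm(scaled[, idx_bilateral, drop = FALSE], design)
  W <- fit$W

  contrast <- action_contrast(design)
  prob_bil <- prepare_target(design, contrast, scaled[, idx_bilateral, drop = FALSE], W = W)
  prob_con <- prepare_target(design, contrast, scaled[, idx_contra, drop = FALSE], W = W)

  fit_bil <- fit_mvb(prob_bil, max_steps = max_steps)
  fit_con <- fit_mvb(prob_con, max_steps = max_steps)

  f_shuf <- vapply(seq_len(shuffles), function(s) {
    ps <- prob_bil
    ps$target <- phase_shuffle(prob_bil$target, seeds[s])
    fit_mvb(ps, max_steps = max_steps)$F
  }, numeric(1))

  hemi_bil <- hemi[idx_bilateral]
  tibble::tibble(
    F_bilateral = fit_bil$F, F_contralateral = fit_con$F,
    delta = fit_bil$F - fit_con$F,
    delta_null = fit_bil$F - mean(f_shuf),
    delta_null_mean_shuf = mean(f_shuf),
    spread_contra = weight_spread(fit_bil$weights[hemi_bil == "contra"]),
    spread_ipsi = if (any(hemi_bil == "ipsi")) {
      weight_spread(fit_bil$weights[hemi_bil == "ipsi"])
    } else NA_real_,
    n_vox_bilateral = length(idx_bilateral),
    n_vox_contralateral = length(idx_contra)
  )
}

# contrast averaging the canonical regressors over analysed conditions
# (bimodal trials, or the four fingers), i.e. action versus baseline
action_contrast <- function(design) {
  Xt_names <- colnames(design$X)[design$idx_task]
  analysed <- if ("bimodal_canonical" %in% Xt_names) {
    "bimodal_canonical"
  } else {
    grep("_canonical$", Xt_names, value = TRUE)
  }
  as.numeric(Xt_names %in% analysed) / length(analysed)
}

#' @export
print.boost_records <- function(x, ...) {
  cat(sprintf("<boost_records> mode: %s, %d participants (%d included)\n",
              attr(x, "mode"), nrow(x), sum(x$included)))
  print(table(x$category[x$included]))
  NextMethod()
}

#' Voxel-count-matched control analyses
#'
#' Re-runs the boost comparison with the voxel counts of the two compared
#' models equated, either by halving the bilateral set (seeded 50/50
#' hemisphere-balanced subsample; the phase-shuffling reliability step is
#' repeated because the bilateral model changed) or by doubling the
#' contralateral set with its next-ranked reserve voxels.
#'
#' @param cohort a BOLD-level [simulate_cohort()] result.
#' @param mode `"halve_bilateral"` or `"double_contralateral"`.
#' @param ... passed to [run_mvb_boost()].
#' @return A `boost_records` tibble, as [run_mvb_boost()].
#' @export
voxel_matched_controls <- function(cohort, mode = c("halve_bilateral", "double_contralateral"),
                                   ...) {
  mode <- match.arg(mode)
  run_mvb_boost(cohort, mode = mode, ...)
}
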