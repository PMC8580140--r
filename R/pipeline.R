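#' Fill measured region means from the imaging path
#'
#' Runs the prewhitened GLM for every BOLD session and replaces the
#' `contra_mean` / `ipsi_mean` columns with the unweighted mean over each
#' region's voxels of the condition-average canonical beta (grand-mean-scaled
#' data, conditions averaged over the analysed trial types).
#'
#' @param cohort a BOLD-level [simulate_cohort()] result.
#' @param progress print a dot per participant.
#' @return The cohort with measured means filled in.
#' @export
run_univariate <- function(cohort, progress = FALSE) {
  sessions <- attr(cohort, "sessions")
  if (is.null(sessions)) stop("cohort has no BOLD sessions", call. = FALSE)
  spec <- attr(cohort, "spec")
  v <- spec$n_voxels
  for (i in seq_along(sessions)) {
    sess <- sessions[[i]]
    idx_contra <- which(sess$hemi == "contra" & sess$rank <= v)
    idx_ipsi <- which(sess$hemi == "ipsi")
    idx <- c(idx_contra, idx_ipsi)
    design <- build_design_matrix(sess$schedule, basis = "canonical")
    fit <- fit_prewhitened_glm(grand_mean_scale(sess$data)[, idx, drop = FALSE], design)
    conds <- analysed_conditions(spec$design, design$conditions)
    cb <- colMeans(condition_betas(fit, conds))
    cohort$contra_mean[i] <- mean(cb[seq_along(idx_contra)])
    cohort$ipsi_mean[i] <- mean(cb[length(idx_contra) + seq_along(idx_ipsi)])
    if (progress) cat(".")
  }
  if (progress) cat("\n")
  cohort
}

analysed_conditions <- function(design, conditions) {
  if (design == "sensorimotor") {
    intersect("bimodal", conditions)
  } else {
    intersect(c("index", "middle", "ring", "little"), conditions)
  }
}

#' Run a full experiment-shaped analysis pipeline
#'
#' Wires the stages together for one synthetic cohort: univariate age-effect
#' tables for both region means, behavioral age-by-ipsilateral interaction
#' models with null Bayes factors, the MVB boost comparison with ordinal
#' regression of the categories on age plus a directional Bayes factor, and
#' (free-selection design only) the MVPA finger-decoding boost. Every random
#' stage consumes a sub-seed derived from `config$seed`, all of which are
#' recorded in the returned manifest together with the decision thresholds.
#'
#' @param config a list (or YAML file path, read with the `yaml` package):
#'   `n_subjects`, `design`, `scenario`, `seed`, `n_voxels`, `shuffles`,
#'   `stages` (character subset of `univariate`, `behavioral`, `mvb`,
#'   `mvpa`), `thresholds` (`log_evidence`, `chance`, `alpha`), plus any
#'   [cohort_spec()] argument under `cohort`.
#' @return A `harold_report` list: `cohort`, one result element per stage,
#'   and `manifest` (seeds, thresholds, sizes, per-stage timings, errors).
#' @export
run_experiment <- function(config = list()) {
  if (is.character(config)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading YAML configs needs the yaml package", call. = FALSE)
    }
    config <- yaml::read_yaml(config)
  }
  cfg <- utils::modifyList(list(
    n_subjects = 24, design = "sensorimotor", scenario = "haroldnull",
    seed = 1, n_voxels = 16, shuffles = 5,
    stages = c("univariate", "behavioral", "mvb", "mvpa"),
    thresholds = list(log_evidence = 3, chance = 25, alpha = 0.05),
    cohort = list()
  ), config)
  seeds <- sub_seeds(cfg$seed, 4)
  manifest <- list(seed = cfg$seed, stage_seeds = seeds,
                   thresholds = cfg$thresholds, design = cfg$design,
                   scenario = cfg$scenario, n_subjects = cfg$n_subjects,
                   n_voxels = cfg$n_voxels, timings = list(), errors = list())
  report <- list()

  spec <- do.call(cohort_spec, utils::modifyList(list(
    n_subjects = cfg$n_subjects, design = cfg$design, scenario = cfg$scenario,
    seed = seeds[1], n_voxels = cfg$n_voxels
  ), cfg$cohort))
  cohort <- simulate_cohort(spec, level = "bold")

  stage <- function(name, code) {
    t0 <- Sys.time()
    res <- tryCatch(code, error = function(e) {
      manifest$errors[[name]] <<- conditionMessage(e)
      NULL
    })
    manifest$timings[[name]] <<- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    res
  }

  if ("univariate" %in% cfg$stages) {
    cohort <- stage("univariate_glm", run_univariate(cohort)) %||% cohort
    report$univariate <- stage("univariate_table", univariate_age_table(cohort))
  }
  if ("behavioral" %in% cfg$stages) {
    report$behavioral <- stage("behavioral", behavioral_tables(cohort))
  }
  if ("mvb" %in% cfg$stages) {
    report$mvb <- stage("mvb_boost", {
      rec <- run_mvb_boost(cohort, shuffles = cfg$shuffles, seed = seeds[2])
      inc <- rec[rec$included, , drop = FALSE]
      ord <- if (length(unique(inc$category)) >= 2) {
        ordinal_boost_regress(inc)
      } else NULL
      bf <- if (!is.null(ord)) {
        bf_directional_categorical(inc, seed = seeds[3])
      } else NULL
      list(records = rec, category_counts = table(inc$category),
           ordinal = ord, directional_bf01 = bf)
    })
  }
  if ("mvpa" %in% cfg$stages && cfg$design == "free_selection") {
    report$mvpa <- stage("mvpa", {
      acc <- run_mvpa(cohort, seed = seeds[4])
      inc <- acc[acc$included, , drop = FALSE]
      list(accuracies = acc,
           boost_age = robust_regress(inc, acc_boost ~ z_age + z_age2))
    })
  }

  report$cohort <- cohort
  report$manifest <- manifest
  structure(report, class = "harold_report")
}

univariate_age_table <- function(cohort) {
  purrr::map_dfr(c(contralateral = "contra_mean", ipsilateral = "ipsi_mean"),
                 function(col) {
    f <- stats::as.formula(paste(col, "~ z_age + z_age2"))
    fit <- robust_regress(cohort, f)
    broomify_block(fit)
  }, .id = "roi")
}

behavioral_tables <- function(cohort) {
  purrr::map_dfr(c(rt_sd = "rt_sd", rt_mean = "rt_mean"), function(col) {
    fit <- compensation_interaction(cohort, y = col)
    bf <- bf_continuous_null(
      prepare_model_frame(cohort, col, "ipsi_mean"),
      stats::as.formula(paste(col, "~ z_ipsi + z_age + z_age2 + z_ipsi:z_age + z_ipsi:z_age2")),
      drop = c("z_ipsi:z_age", "z_ipsi:z_age2"))
    out <- broomify_block(fit)
    out$bf01_interaction <- bf$bf01
    out$bf01_label <- bf$label
    out
  }, .id = "measure")
}

broomify_block <- function(fit) {
  bt <- fit$block_test
  tibble::tibble(F = bt$F, df1 = bt$df1, df2 = bt$df2, p = bt$p,
                 r2_pct = bt$r2_pct,
                 terms = list(fit$terms))
}

#' @export
print.harold_report <- function(x, ...) {
  m <- x$manifest
  cat(sprintf("<harold_report> %s / %s, n = %d, seed %d\n",
              m$design, m$scenario, m$n_subjects, m$seed))
  cat("  stages run:", paste(setdiff(names(x), c("cohort", "manifest")), collapse = ", "), "\n")
  if (length(m$errors) > 0) {
    cat("  stage errors:", paste(names(m$errors), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Packaged deterministic test cohorts
#'
#' `tiny` (12 subjects, 16 voxels per region, 120 scans, reduced trial
#' count) keeps a full-pipeline run fast for continuous testing; `standard`
#' (100 subjects, 70 voxels, full runs) mirrors the reference task geometry.
#' Both are pure functions of the built-in seed.
#'
#' @param size `"tiny"` or `"standard"`.
#' @param scenario generating scenario (default `"haroldnull"`).
#' @param design task design (default `"sensorimotor"`).
#' @param level `"bold"` or `"summary"`.
#' @param seed master seed (default 104).
#' @return A [simulate_cohort()] result.
#' @export
make_fixture <- function(size = c("tiny", "standard"),
                         scenario = "haroldnull", design = "sensorimotor",
                         level = "bold", seed = 104) {
  size <- match.arg(size)
  spec <- if (size == "tiny") {
    cohort_spec(12, seed = seed, design = design, scenario = scenario,
                n_voxels = 16, n_scans = 120,
                schedule_args = if (design == "sensorimotor") {
                  list(n_bimodal = 50, n_unimodal = 4)
                } else {
                  list(n_trials = 80)
                })
  } else {
    cohort_spec(100, seed = seed, design = design, scenario = scenario,
                n_voxels = 70)
  }
  simulate_cohort(spec, level = level)
}
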