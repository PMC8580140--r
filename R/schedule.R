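#' Generate an event schedule for one scanning run
#'
#' Builds the trial timing and condition sequence for either task design:
#'
#' * `sensorimotor`: 120 bimodal audio/visual trials plus 8 unimodal catch
#'   trials (4 auditory, 4 visual), with stimulus onset asynchronies between
#'   2 and 26 s drawn from a truncated geometric mixture over 2 s null slots
#'   (sparse event-related timing with null trials).
#' * `free_selection`: 240 finger-press trials in 12 blocks of 20, separated
#'   by 4.2 s or 6.2 s gaps; 120 "specified" trials split equally over the
#'   four fingers and 120 "choice" trials where the executed finger is drawn
#'   from the three cued digits; the condition sequence never contains four
#'   or more trials of the same condition type in a row.
#'
#' @param design `"sensorimotor"` or `"free_selection"`.
#' @param seed integer seed; the schedule is a pure function of
#'   `(design, seed, n_scans, TR)`.
#' @param n_scans run length in scans (261 and 296 are the reference values).
#' @param TR repetition time, seconds.
#' @param n_bimodal,n_unimodal,n_trials optional reduced trial counts for
#'   small test fixtures; defaults are the full task sizes.
#' @param choice_repeat_bias probability bump for repeating the previous
#'   executed finger on choice trials (default 0, i.e. uniform over the cued
#'   three).
#' @return An `event_schedule`: a tibble with columns `onset` (s), `duration`
#'   (s), `condition`, `cond_type` and (free selection) `finger`, carrying
#'   `n_scans`, `TR` and `design` as attributes.
#' @export
generate_event_schedule <- function(design = c("sensorimotor", "free_selection"),
                                    seed, n_scans, TR,
                                    n_bimodal = 120, n_unimodal = 8,
                                    n_trials = 240, choice_repeat_bias = 0) {
  design <- match.arg(design)
  stopifnot(n_scans > 0, TR > 0)
  local_seed(seed, {
    if (design == "sensorimotor") {
      schedule_sensorimotor(n_scans, TR, n_bimodal, n_unimodal)
    } else {
      schedule_free_selection(n_scans, TR, n_trials, choice_repeat_bias)
    }
  })
}

schedule_sensorimotor <- function(n_scans, TR, n_bimodal, n_unimodal,
                                  soa_min = 2, soa_max = 26, tail_margin = 8) {
  n_events <- n_bimodal + n_unimodal
  budget <- n_scans * TR - tail_margin
  if (budget < soa_min * n_events) {
    stop("design does not fit run: ", n_events, " events need at least ",
         soa_min * n_events + tail_margin, " s, run is ", round(n_scans * TR, 1), " s",
         call. = FALSE)
  }
  # gaps = 2 s stimulation slot + geometric number of 2 s null slots,
  # truncated to [soa_min, soa_max]; mean tuned to the available budget
  target_mean <- budget / n_events
  p <- min(0.95, max(0.05, 2 / target_mean))
  draw_gaps <- function() {
    g <- soa_min + 2 * stats::rgeom(n_events, p)
    g[g > soa_max] <- soa_max
    g
  }
  gaps <- draw_gaps()
  # repair: shrink the largest gaps (never below the minimum) until it fits
  for (iter in seq_len(10000)) {
    if (sum(gaps) <= budget) break
    i <- which.max(gaps)
    if (gaps[i] <= soa_min) break
    gaps[i] <- gaps[i] - 2
  }
  if (sum(gaps) > budget) stop("design does not fit run", call. = FALSE)
  onsets <- cumsum(gaps)

  condition <- rep("bimodal", n_events)
  if (n_unimodal > 0) {
    uni_pos <- sample(n_events, n_unimodal)
    half <- floor(n_unimodal / 2)
    condition[uni_pos] <- sample(c(rep("unimodal_audio", half),
                                   rep("unimodal_visual", n_unimodal - half)))
  }
  new_event_schedule(
    tibble::tibble(onset = onsets, duration = 0, condition = condition,
                   cond_type = ifelse(condition == "bimodal", "bimodal", "unimodal")),
    n_scans = n_scans, TR = TR, design = "sensorimotor"
  )
}

schedule_free_selection <- function(n_scans, TR, n_trials, choice_repeat_bias,
                                    block_size = 20, within_soa = 2.1,
                                    tail_margin = 8) {
  if (n_trials %% 2 != 0) stop("trial count must be even", call. = FALSE)
  fingers <- c("index", "middle", "ring", "little")
  n_blocks <- ceiling(n_trials / block_size)
  block_gaps <- sample(c(4.2, 6.2), max(n_blocks - 1, 0), replace = TRUE)
  total <- 2 + (n_trials - 1) * within_soa + sum(block_gaps - within_soa) + tail_margin
  if (total > n_scans * TR) {
    stop("design does not fit run: needs ", round(total, 1), " s, run is ",
         round(n_scans * TR, 1), " s", call. = FALSE)
  }

  # condition types: half specified, half choice, no run of >= 4 alike
  type_seq <- sample_condition_types(n_trials)

  # specified trials: equal split over the four fingers
  n_spec <- sum(type_seq == "specified")
  per_finger <- n_spec / 4
  if (per_finger != floor(per_finger)) {
    spec_fingers <- sample(rep(fingers, length.out = n_spec))
  } else {
    spec_fingers <- sample(rep(fingers, each = per_finger))
  }
  finger <- character(n_trials)
  finger[type_seq == "specified"] <- spec_fingers
  prev <- NULL
  for (i in which(type_seq == "choice")) {
    cued <- sample(fingers, 3)
    prob <- rep(1, 3)
    if (choice_repeat_bias > 0 && !is.null(prev) && prev %in% cued) {
      prob[cued == prev] <- 1 + choice_repeat_bias * 3
    }
    finger[i] <- sample(cued, 1, prob = prob / sum(prob))
    prev <- finger[i]
  }

  onsets <- numeric(n_trials)
  t <- 2
  for (i in seq_len(n_trials)) {
    onsets[i] <- t
    t <- t + within_soa
    if (i %% block_size == 0 && i < n_trials) {
      t <- t - within_soa + block_gaps[i / block_size]
    }
  }
  new_event_schedule(
    tibble::tibble(onset = onsets, duration = 0, condition = finger,
                   cond_type = type_seq, finger = finger),
    n_scans = n_scans, TR = TR, design = "free_selection"
  )
}

# half specified / half choice with no run of >= 4 identical types;
# sequential draw with restart on dead ends
sample_condition_types <- function(n_trials, max_restart = 1000) {
  for (attempt in seq_len(max_restart)) {
    left <- c(specified = n_trials / 2, choice = n_trials / 2)
    seqs <- character(n_trials)
    ok <- TRUE
    for (i in seq_len(n_trials)) {
      cand <- names(left)[left > 0]
      if (i >= 4 && length(unique(seqs[(i - 3):(i - 1)])) == 1) {
        cand <- setdiff(cand, seqs[i - 1])
      }
      if (length(cand) == 0) { ok <- FALSE; break }
      pick <- if (length(cand) == 1) cand else sample(cand, 1, prob = left[cand])
      seqs[i] <- pick
      left[pick] <- left[pick] - 1
    }
    if (ok) return(seqs)
  }
  stop("could not build a condition sequence without long repeats", call. = FALSE)
}

new_event_schedule <- function(df, n_scans, TR, design) {
  structure(df, n_scans = n_scans, TR = TR, design = design,
            class = c("event_schedule", class(df)))
}

#' Validate an event schedule against its design constraints
#'
#' Checks strictly increasing onsets, fit within the run, the 2 s minimum
#' inter-onset gap for the sensorimotor design, and the absence of runs of
#' four or more identical condition types for the free-selection design.
#'
#' @param schedule an [event_schedule].
#' @return `TRUE` invisibly; otherwise an error describing the violation.
#' @export
validate_event_schedule <- function(schedule) {
  stopifnot(inherits(schedule, "event_schedule"))
  onset <- schedule$onset
  if (any(diff(onset) <= 0)) stop("onsets must be strictly increasing", call. = FALSE)
  run_seconds <- attr(schedule, "n_scans") * attr(schedule, "TR")
  if (max(onset) > run_seconds) stop("onsets exceed the run", call. = FALSE)
  if (attr(schedule, "design") == "sensorimotor") {
    gaps <- diff(c(0, onset))
    if (any(gaps < 2 - 1e-9)) stop("inter-onset gaps below 2 s", call. = FALSE)
  } else {
    types <- schedule$cond_type
    r <- rle(types)
    if (any(r$lengths >= 4)) stop("four or more identical condition types in a row", call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
print.event_schedule <- function(x, ...) {
  cat(sprintf("<event_schedule> %s: %d events over %.1f s (%d scans, TR = %gs)\n",
              attr(x, "design"), nrow(x),
              attr(x, "n_scans") * attr(x, "TR"), attr(x, "n_scans"), attr(x, "TR")))
  NextMethod()
}
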