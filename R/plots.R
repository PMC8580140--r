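#' Plot lifespan trajectories of region activation
#'
#' Scatter of measured region means against age with robust quadratic fits,
#' the visual summary of the hemispheric-asymmetry pattern: contralateral
#' activation falling and ipsilateral rising (then flattening) over the
#' lifespan.
#'
#' @param object a [simulate_cohort()] cohort with measured means.
#' @param ... unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.harold_cohort <- function(object, ...) {
  d <- tidyr::pivot_longer(tibble::as_tibble(object),
                           cols = c("contra_mean", "ipsi_mean"),
                           names_to = "roi", values_to = "activation")
  d$roi <- ifelse(d$roi == "contra_mean", "contralateral", "ipsilateral")
  ggplot2::ggplot(d, ggplot2::aes(.data$age, .data$activation, colour = .data$roi)) +
    ggplot2::geom_point(alpha = 0.5, size = 1) +
    ggplot2::geom_smooth(method = MASS::rlm, formula = y ~ x + I(x^2), se = FALSE) +
    ggplot2::labs(x = "age (years)", y = "mean activation (a.u.)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the greedy free-energy trace of an MVB fit
#'
#' @param object an [fit_mvb()] result.
#' @param ... unused.
#' @return A ggplot object showing free energy against active subset size.
#' @exportS3Method ggplot2::autoplot
autoplot.mvb_fit <- function(object, ...) {
  ggplot2::ggplot(object$trace, ggplot2::aes(.data$size, .data$F)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_continuous(trans = "log2") +
    ggplot2::labs(x = "active voxels", y = "free energy (nats)") +
    ggplot2::theme_minimal()
}

#' Plot boost categories over the lifespan
#'
#' Jittered per-participant log-evidence differences against age, coloured
#' by category, with the +/- 3 nats decision band.
#'
#' @param records a [run_mvb_boost()] table.
#' @param included_only drop participants failing the reliability filter.
#' @return A ggplot object.
#' @export
plot_boost <- function(records, included_only = TRUE) {
  d <- if (included_only) records[records$included, , drop = FALSE] else records
  ggplot2::ggplot(d, ggplot2::aes(.data$age, .data$delta, colour = .data$category)) +
    ggplot2::geom_hline(yintercept = c(-3, 3), linetype = "dashed", colour = "grey50") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = "age (years)",
                  y = "log evidence difference (bilateral - contralateral, nats)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot decoding accuracy by region
#'
#' @param mvpa a [run_mvpa()] table.
#' @return A ggplot of per-region balanced accuracies with the 25% chance
#'   line.
#' @export
plot_mvpa_accuracy <- function(mvpa) {
  d <- tidyr::pivot_longer(mvpa, cols = c("acc_contra", "acc_ipsi", "acc_bilateral"),
                           names_to = "roi", values_to = "accuracy")
  d$roi <- sub("acc_", "", d$roi)
  ggplot2::ggplot(d, ggplot2::aes(.data$roi, .data$accuracy)) +
    ggplot2::geom_hline(yintercept = 25, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_boxplot(width = 0.5, outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.1, alpha = 0.5, size = 1) +
    ggplot2::labs(x = NULL, y = "balanced accuracy (%)") +
    ggplot2::theme_minimal()
}
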