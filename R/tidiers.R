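#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom tibble as_tibble
#' @export
tibble::as_tibble

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a robust lifespan regression
#'
#' @param x a `harold_rfit`.
#' @param ... unused.
#' @return Tibble of terms with estimates, robust (sandwich) standard
#'   errors, t statistics, p values and the hierarchical `reported` flag.
#' @exportS3Method generics::tidy
tidy.harold_rfit <- function(x, ...) x$terms

#' @exportS3Method generics::glance
glance.harold_rfit <- function(x, ...) {
  bt <- x$block_test
  tibble::tibble(statistic = bt$F, df1 = bt$df1, df2 = bt$df2,
                 p.value = bt$p, r2_pct = bt$r2_pct, nobs = x$n)
}

#' Tidy an MVB decoding fit
#'
#' @param x an `mvb_fit`.
#' @param ... unused.
#' @return Tibble with one row per voxel: posterior mean weight and whether
#'   the voxel is in the selected subset.
#' @exportS3Method generics::tidy
tidy.mvb_fit <- function(x, ...) {
  tibble::tibble(voxel = seq_len(x$v), weight = x$weights,
                 active = x$weights != 0)
}

#' @exportS3Method generics::glance
glance.mvb_fit <- function(x, ...) {
  tibble::tibble(free_energy = x$F, spread = x$spread,
                 subset_size = max(x$trace$size), steps = nrow(x$trace),
                 noise_var = x$hyper$noise_var, converged = x$converged)
}

#' @exportS3Method generics::tidy
tidy.boost_ordfit <- function(x, ...) x$terms

#' @exportS3Method generics::glance
glance.boost_ordfit <- function(x, ...) {
  tibble::tibble(method = x$method, nobs = x$n,
                 n_reduction = unname(x$categories["reduction"]),
                 n_ambiguous = unname(x$categories["ambiguous"]),
                 n_boost = unname(x$categories["boost"]))
}
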