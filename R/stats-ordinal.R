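#' Ordinal regression of boost categories on age
#'
#' Regresses the per-participant model-comparison outcome (ordered
#' `reduction < ambiguous < boost`) on standardized linear age (optionally
#' plus the quadratic term) with a proportional-odds model. When only two of
#' the three categories occur, a binary logistic model is used instead and
#' flagged in the output. Odds ratios above 1 mean a boost becomes more
#' likely with age.
#'
#' @param data data frame with a `category` column (factor or character with
#'   levels among `reduction`, `ambiguous`, `boost`) and `age` (or
#'   pre-computed `z_age`/`z_age2`).
#' @param quadratic include the standardized quadratic age term.
#' @param conf_level confidence level for the odds-ratio interval.
#' @return A `boost_ordfit` object: tibble `terms` (term, estimate = log
#'   odds, odds.ratio, conf.low/high, statistic z, p.value), `method`
#'   (`"ordinal"` or `"binary"`), and the underlying fit.
#' @export
ordinal_boost_regress <- function(data, quadratic = FALSE, conf_level = 0.95) {
  stopifnot("category" %in% names(data))
  d <- as.data.frame(data)
  if (!all(c("z_age", "z_age2") %in% names(d))) {
    at <- age_terms(d$age)
    d$z_age <- at$z_age; d$z_age2 <- at$z_age2
  }
  levels_all <- c("reduction", "ambiguous", "boost")
  cat_chr <- as.character(d$category)
  present <- levels_all[levels_all %in% unique(cat_chr)]
  if (length(present) < 2) {
    stop("only one boost category observed; cannot regress", call. = FALSE)
  }
  rhs <- if (quadratic) "z_age + z_age2" else "z_age"
  f <- stats::as.formula(paste("category ~", rhs))
  zcrit <- stats::qnorm(1 - (1 - conf_level) / 2)

  if (length(present) == 3) {
    d$category <- factor(cat_chr, levels = levels_all, ordered = TRUE)
    fit <- MASS::polr(f, data = d, Hess = TRUE)
    sm <- summary(fit)
    ct <- sm$coefficients[seq_along(stats::coef(fit)), , drop = FALSE]
    est <- ct[, "Value"]; se <- ct[, "Std. Error"]
    method <- "ordinal"
  } else {
    # binary: probability of the higher of the two observed categories
    hi <- present[length(present)]
    d$category_bin <- as.integer(cat_chr == hi)
    fb <- stats::as.formula(paste("category_bin ~", rhs))
    fit <- stats::glm(fb, data = d, family = stats::binomial())
    ct <- summary(fit)$coefficients[-1, , drop = FALSE]
    est <- ct[, "Estimate"]; se <- ct[, "Std. Error"]
    method <- "binary"
  }
  z <- est / se
  terms <- tibble::tibble(
    term = rownames(ct) %||% names(est),
    estimate = unname(est), std.error = unname(se),
    odds.ratio = exp(unname(est)),
    conf.low = exp(unname(est - zcrit * se)),
    conf.high = exp(unname(est + zcrit * se)),
    statistic = unname(z),
    p.value = unname(2 * stats::pnorm(abs(z), lower.tail = FALSE))
  )
  structure(list(terms = terms, method = method, fit = fit,
                 n = nrow(d), categories = table(factor(cat_chr, levels = levels_all))),
            class = "boost_ordfit")
}

#' @export
print.boost_ordfit <- function(x, ...) {
  cat(sprintf("<boost_ordfit> %s regression of boost category on age, n = %d\n",
              x$method, x$n))
  cat("  categories:", paste(names(x$categories), x$categories, sep = "=", collapse = ", "), "\n")
  print(x$terms)
  invisible(x)
}

#' Interpret a Bayes factor for the null
#'
#' Jeffreys-style evidence bands for `BF01` (null over alternative):
#' `(1, 3]` anecdotal, `(3, 10]` substantial, `> 10` strong evidence in
#' favour of the null; values at exactly 1 sit on the band edge and values
#' below 1 favour the alternative.
#'
#' @param bf01 positive Bayes factor(s) for the null.
#' @return Character vector of labels.
#' @export
interpret_bf <- function(bf01) {
  if (any(!is.finite(bf01) | bf01 <= 0)) {
    stop("Bayes factors must be positive and finite", call. = FALSE)
  }
  vapply(bf01, function(b) {
    if (b > 10) "strong"
    else if (b > 3) "substantial"
    else if (b > 1) "anecdotal"
    else if (b == 1) "anecdotal (boundary)"
    else "favors alternative"
  }, character(1))
}
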