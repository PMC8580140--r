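#' Normalize trial patterns to [-1, 1] per voxel
#'
#' For each voxel, affinely maps its values across trials onto `[-1, 1]`.
#' Constant voxels are mapped to 0 with a warning.
#'
#' @param x trials x voxels matrix of single-trial betas.
#' @return Matrix of the same shape with per-voxel range `[-1, 1]`.
#' @export
normalize_patterns <- function(x) {
  x <- as.matrix(x)
  rng <- apply(x, 2, range)
  const <- rng[2, ] - rng[1, ] <= 0
  if (any(const)) {
    warning(sum(const), " constant voxel(s) mapped to 0")
  }
  out <- x
  for (j in seq_len(ncol(x))) {
    if (const[j]) {
      out[, j] <- 0
    } else {
      out[, j] <- 2 * (x[, j] - rng[1, j]) / (rng[2, j] - rng[1, j]) - 1
    }
  }
  out
}

#' Decode the executed finger from trial patterns
#'
#' Trains a multiclass linear support-vector machine (one-versus-one binary
#' learners, unit cost) on randomly assigned folds and returns the balanced
#' decoding accuracy: per-class recalls averaged within each test fold, then
#' averaged over folds. Balanced accuracy equals plain accuracy when classes
#' are balanced; four-class chance is 25%.
#'
#' If a random fold draw leaves a class absent from a training set, folds are
#' re-drawn with stratification and a warning.
#'
#' @param x trials x voxels matrix (normalize first with
#'   [normalize_patterns()]).
#' @param labels factor or character vector of executed fingers.
#' @param folds number of cross-validation folds (default 4).
#' @param seed integer seed for the fold assignment.
#' @return Balanced accuracy in percent, with the per-fold accuracies as
#'   attribute `per_fold`.
#' @export
decode_fingers <- function(x, labels, folds = 4, seed = 1) {
  x <- as.matrix(x)
  labels <- factor(labels)
  stopifnot(nrow(x) == length(labels))
  if (any(table(labels) < folds)) {
    stop("need at least `folds` trials per class", call. = FALSE)
  }
  n <- nrow(x)
  assign_folds <- function(stratified) {
    local_seed(seed, {
      if (!stratified) {
        sample(rep(seq_len(folds), length.out = n))
      } else {
        f <- integer(n)
        for (cl in levels(labels)) {
          idx <- which(labels == cl)
          f[idx] <- sample(rep(seq_len(folds), length.out = length(idx)))
        }
        f
      }
    })
  }
  fold_id <- assign_folds(stratified = FALSE)
  degenerate <- any(vapply(seq_len(folds), function(k) {
    length(unique(labels[fold_id != k])) < nlevels(labels) ||
      sum(fold_id == k) == 0
  }, logical(1)))
  if (degenerate) {
    warning("a class was absent from a training fold; re-folding with stratification")
    fold_id <- assign_folds(stratified = TRUE)
  }

  per_fold <- vapply(seq_len(folds), function(k) {
    train <- fold_id != k
    fit <- e1071::svm(x[train, , drop = FALSE], labels[train],
                      kernel = "linear", cost = 1, scale = FALSE)
    pred <- stats::predict(fit, x[!train, , drop = FALSE])
    truth <- labels[!train]
    recalls <- vapply(levels(labels), function(cl) {
      if (!any(truth == cl)) return(NA_real_)
      mean(pred[truth == cl] == cl)
    }, numeric(1))
    mean(recalls, na.rm = TRUE)
  }, numeric(1))
  acc <- 100 * mean(per_fold)
  attr(acc, "per_fold") <- 100 * per_fold
  acc
}

#' Accuracy boost from adding ipsilateral voxels
#'
#' Signed difference between bilateral and contralateral-only decoding
#' accuracy; positive values mean the ipsilateral voxels added information.
#'
#' @param bilateral_acc,contralateral_acc accuracies in percent.
#' @return `bilateral_acc - contralateral_acc`.
#' @export
accuracy_boost <- function(bilateral_acc, contralateral_acc) {
  stopifnot(all(bilateral_acc >= 0 & bilateral_acc <= 100),
            all(contralateral_acc >= 0 & contralateral_acc <= 100))
  as.numeric(bilateral_acc) - as.numeric(contralateral_acc)
}

#' Chance-level exclusion filter for the accuracy boost analysis
#'
#' Participants whose bilateral decoding accuracy is at or below four-class
#' chance (25%) are excluded from the boost analysis.
#'
#' @param bilateral_acc accuracy in percent.
#' @return Logical: `TRUE` when the participant is included.
#' @export
chance_filter <- function(bilateral_acc) {
  stopifnot(all(bilateral_acc >= 0 & bilateral_acc <= 100))
  bilateral_acc > 25
}

#' Finger decoding for a whole free-selection cohort
#'
#' For each participant: least-squares-separate trial betas, per-voxel
#' normalization, then balanced one-versus-one SVM decoding from the
#' contralateral set, the ipsilateral set and their combination, plus the
#' bilateral-minus-contralateral accuracy boost and the chance filter.
#'
#' @param cohort a BOLD-level [simulate_cohort()] with the free-selection
#'   design.
#' @param folds,seed cross-validation settings.
#' @return A tibble with one row per participant: accuracies per voxel set
#'   (percent), `acc_boost`, and `included`.
#' @export
run_mvpa <- function(cohort, folds = 4, seed = 1) {
  sessions <- attr(cohort, "sessions")
  spec <- attr(cohort, "spec")
  if (is.null(sessions)) stop("cohort has no BOLD sessions", call. = FALSE)
  if (spec$design != "free_selection") {
    stop("finger decoding needs the free-selection design", call. = FALSE)
  }
  v <- spec$n_voxels
  seeds <- sub_seeds(seed, length(sessions))
  rows <- purrr::map2_dfr(sessions, seq_along(sessions), function(sess, i) {
    idx_contra <- which(sess$hemi == "contra" & sess$rank <= v)
    idx_ipsi <- which(sess$hemi == "ipsi")
    betas <- lss_betas(grand_mean_scale(sess$data), sess$schedule)
    labels <- sess$schedule$finger
    acc <- function(idx) {
      decode_fingers(normalize_patterns(betas[, idx, drop = FALSE]), labels,
                     folds = folds, seed = seeds[i])
    }
    a_con <- acc(idx_contra); a_ips <- acc(idx_ipsi)
    a_bil <- acc(c(idx_contra, idx_ipsi))
    tibble::tibble(participant = i,
                   acc_contra = as.numeric(a_con), acc_ipsi = as.numeric(a_ips),
                   acc_bilateral = as.numeric(a_bil),
                   acc_boost = accuracy_boost(a_bil, a_con),
                   included = chance_filter(a_bil))
  })
  dplyr::left_join(rows,
                   dplyr::select(tibble::as_tibble(cohort), "participant", "age",
                                 "z_age", "z_age2"),
                   by = "participant")
}
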