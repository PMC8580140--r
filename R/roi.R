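#' Gaussian smoothing of a 3-D statistic map
#'
#' Separable Gaussian smoothing at a stated full width at half maximum, used
#' only to define regions of interest (downstream analyses always use
#' unsmoothed data). The kernel is normalized, so the map total is preserved
#' away from the edges.
#'
#' @param map 3-D numeric array.
#' @param fwhm_mm kernel full width at half maximum, mm (default 10).
#' @param voxel_size_mm isotropic voxel size, mm.
#' @return Smoothed array of the same dimensions.
#' @export
smooth_map <- function(map, fwhm_mm = 10, voxel_size_mm = 3) {
  stopifnot(length(dim(map)) == 3)
  if (fwhm_mm <= 0) stop("FWHM must be positive", call. = FALSE)
  sigma <- fwhm_mm / (2 * sqrt(2 * log(2))) / voxel_size_mm
  half <- max(1L, ceiling(3 * sigma))
  kern <- stats::dnorm(-half:half, sd = sigma)
  kern <- kern / sum(kern)
  out <- map
  norm <- array(1, dim(map)) # renormalise at the edges (constant maps unchanged)
  for (d in 1:3) {
    out <- convolve_axis(out, kern, d)
    norm <- convolve_axis(norm, kern, d)
  }
  out / norm
}

# zero-padded 1-D convolution along axis d of a 3-D array
convolve_axis <- function(a, kern, d) {
  half <- (length(kern) - 1L) / 2L
  perm <- switch(d, c(1, 2, 3), c(2, 1, 3), c(3, 1, 2))
  ap <- aperm(a, perm)
  dm <- dim(ap)
  m <- matrix(ap, nrow = dm[1])
  n <- nrow(m)
  res <- matrix(0, n, ncol(m))
  for (off in -half:half) {
    w <- kern[off + half + 1]
    src <- (1:n) - off
    ok <- src >= 1 & src <= n
    res[ok, ] <- res[ok, ] + w * m[src[ok], ]
  }
  out <- array(res, dm)
  aperm(out, order(perm))
}

#' Select a region of interest by statistic rank around a peak
#'
#' Finds the suprathreshold local maximum nearest the landmark (in world mm),
#' then grows a 26-connected neighbourhood from that peak, admitting voxels
#' in descending statistic order, until exactly `k` voxels are selected.
#'
#' @param map 3-D statistic array (e.g. a smoothed group t map).
#' @param landmark_mm world coordinate (length 3) of the anatomical landmark
#'   (e.g. the hand knob).
#' @param k number of voxels to select (default 70).
#' @param affine 4x4 voxel-index-to-world matrix; default centres the grid
#'   with 3 mm isotropic voxels.
#' @param threshold minimum statistic for a candidate peak.
#' @param hemisphere label stored in the mask (`"left"`/`"right"`); default
#'   inferred from the sign of the landmark x coordinate (left hemisphere has
#'   negative x).
#' @return An `roi_mask`: integer voxel coordinates (`k` x 3), the affine,
#'   hemisphere tag and `k`.
#' @export
select_roi <- function(map, landmark_mm, k = 70, affine = default_affine(dim(map)),
                       threshold = 0, hemisphere = NULL) {
  stopifnot(length(dim(map)) == 3, length(landmark_mm) == 3)
  dm <- dim(map)
  if (sum(is.finite(map)) < k) {
    stop("fewer than k candidate voxels available (", sum(is.finite(map)), ")",
         call. = FALSE)
  }
  peaks <- local_maxima(map, threshold)
  if (nrow(peaks) == 0) stop("no suprathreshold peak found", call. = FALSE)
  world <- voxel_to_world(peaks, affine)
  d2 <- colSums((t(world) - landmark_mm)^2)
  peak <- peaks[which.min(d2), ]

  sel <- grow_by_rank(map, peak, k)
  if (nrow(sel) < k) {
    stop("connected neighbourhood holds only ", nrow(sel), " voxels (< k)", call. = FALSE)
  }
  hemisphere <- hemisphere %||% if (landmark_mm[1] < 0) "left" else "right"
  new_roi_mask(sel, affine, hemisphere, dim = dm)
}

default_affine <- function(dm, voxel_size = 3) {
  a <- diag(c(rep(voxel_size, 3), 1))
  a[1:3, 4] <- -voxel_size * (dm + 1) / 2
  a
}

voxel_to_world <- function(coords, affine) {
  h <- cbind(coords, 1) %*% t(affine)
  h[, 1:3, drop = FALSE]
}

world_to_voxel <- function(world, affine) {
  h <- cbind(world, 1) %*% t(solve(affine))
  h[, 1:3, drop = FALSE]
}

neighbour_offsets <- local({
  g <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  g[rowSums(abs(g)) > 0, , drop = FALSE] # 26-connectivity
})

local_maxima <- function(map, threshold) {
  dm <- dim(map)
  cand <- which(map > threshold & is.finite(map), arr.ind = TRUE)
  if (nrow(cand) == 0) return(cand)
  keep <- vapply(seq_len(nrow(cand)), function(r) {
    ijk <- cand[r, ]
    nb <- sweep(neighbour_offsets, 2, ijk, "+")
    ok <- nb[, 1] >= 1 & nb[, 1] <= dm[1] & nb[, 2] >= 1 & nb[, 2] <= dm[2] &
      nb[, 3] >= 1 & nb[, 3] <= dm[3]
    all(map[nb[ok, , drop = FALSE]] <= map[ijk[1], ijk[2], ijk[3]])
  }, logical(1))
  cand[keep, , drop = FALSE]
}

grow_by_rank <- function(map, peak, k) {
  dm <- dim(map)
  enc <- function(ijk) ijk[, 1] + dm[1] * (ijk[, 2] - 1) + dm[1] * dm[2] * (ijk[, 3] - 1)
  region <- matrix(peak, ncol = 3)
  in_region <- new.env(hash = TRUE)
  assign(as.character(enc(region)), TRUE, envir = in_region)
  frontier <- data.frame(code = numeric(0), i = integer(0), j = integer(0),
                         k = integer(0), val = numeric(0))
  push_neighbours <- function(ijk) {
    nb <- sweep(neighbour_offsets, 2, ijk, "+")
    ok <- nb[, 1] >= 1 & nb[, 1] <= dm[1] & nb[, 2] >= 1 & nb[, 2] <= dm[2] &
      nb[, 3] >= 1 & nb[, 3] <= dm[3]
    nb <- nb[ok, , drop = FALSE]
    codes <- enc(nb)
    new <- !vapply(codes, function(cd) {
      exists(as.character(cd), envir = in_region)
    }, logical(1)) & !(codes %in% frontier$code)
    nb <- nb[new, , drop = FALSE]
    if (nrow(nb) > 0) {
      vals <- map[nb]
      frontier <<- rbind(frontier, data.frame(code = codes[new], i = nb[, 1],
                                              j = nb[, 2], k = nb[, 3], val = vals))
    }
  }
  push_neighbours(peak)
  while (nrow(region) < k && nrow(frontier) > 0) {
    frontier <- frontier[is.finite(frontier$val), , drop = FALSE]
    if (nrow(frontier) == 0) break
    top <- which.max(frontier$val)
    ijk <- as.integer(frontier[top, c("i", "j", "k")])
    assign(as.character(frontier$code[top]), TRUE, envir = in_region)
    frontier <- frontier[-top, , drop = FALSE]
    region <- rbind(region, ijk)
    push_neighbours(ijk)
  }
  dimnames(region) <- NULL
  region
}

new_roi_mask <- function(coords, affine, hemisphere, dim) {
  coords <- unique(matrix(as.integer(coords), ncol = 3))
  structure(list(coords = coords, affine = affine, hemisphere = hemisphere,
                 k = nrow(coords), dim = dim),
            class = "roi_mask")
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(sprintf("<roi_mask> %d voxels, %s hemisphere\n", x$k, x$hemisphere))
  invisible(x)
}

#' Mirror a region of interest across the midline
#'
#' Reverses the sign of the world x coordinate of every voxel (the grid
#' coordinates are recomputed through the affine), producing the homotopic
#' mask in the opposite hemisphere. Mirroring twice returns the original
#' mask.
#'
#' @param mask an [select_roi()] mask whose affine maps the grid into a
#'   world frame symmetric about x = 0.
#' @return The mirrored `roi_mask` with the hemisphere tag flipped.
#' @export
mirror_roi <- function(mask) {
  stopifnot(inherits(mask, "roi_mask"))
  world <- voxel_to_world(mask$coords, mask$affine)
  world[, 1] <- -world[, 1]
  grid <- world_to_voxel(world, mask$affine)
  rounded <- round(grid)
  if (max(abs(grid - rounded)) > 1e-6) {
    stop("mirrored voxels do not land on the grid; affine is not midline-symmetric",
         call. = FALSE)
  }
  dm <- mask$dim
  inside <- rounded[, 1] >= 1 & rounded[, 1] <= dm[1] &
    rounded[, 2] >= 1 & rounded[, 2] <= dm[2] &
    rounded[, 3] >= 1 & rounded[, 3] <= dm[3]
  if (!all(inside)) {
    stop("mirrored voxel falls outside the image grid", call. = FALSE)
  }
  new_roi_mask(rounded, mask$affine,
               hemisphere = if (mask$hemisphere == "left") "right" else "left",
               dim = dm)
}

#' Mean activation over a region of interest
#'
#' Unweighted mean of the condition-average beta over the mask voxels.
#'
#' @param betas 3-D array of (condition-average) betas on the mask's grid.
#' @param mask an `roi_mask`.
#' @return Scalar mean activation.
#' @export
roi_mean <- function(betas, mask) {
  stopifnot(inherits(mask, "roi_mask"), length(dim(betas)) == 3)
  if (!all(dim(betas) == mask$dim)) {
    stop("beta grid does not match the mask grid", call. = FALSE)
  }
  vals <- betas[mask$coords]
  if (length(vals) == 0) stop("mask does not intersect the beta grid", call. = FALSE)
  mean(vals)
}
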