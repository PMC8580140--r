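test_that("smoothing an impulse yields the stated kernel width and preserves mass", {
  dm <- c(21, 21, 21)
  imp <- array(0, dm); imp[11, 11, 11] <- 1
  sm <- smooth_map(imp, fwhm_mm = 10, voxel_size_mm = 3)
  expect_equal(sum(sm), 1, tolerance = 1e-6)
  prof <- sm[, 11, 11]
  half <- max(prof) / 2
  # linear interpolation of the half-maximum crossings, in mm
  xs <- (seq_len(dm[1]) - 11) * 3
  above <- which(prof >= half)
  lo <- min(above); hi <- max(above)
  left <- xs[lo - 1] + (half - prof[lo - 1]) / (prof[lo] - prof[lo - 1]) * 3
  right <- xs[hi] + (prof[hi] - half) / (prof[hi] - prof[hi + 1]) * 3
  expect_equal(right - left, 10, tolerance = 1.5) # half a voxel
  const <- array(2, dm)
  smc <- smooth_map(const, 10, 3)
  expect_equal(smc, const, tolerance = 1e-9) # edge-renormalised kernel
  expect_error(smooth_map(imp, fwhm_mm = 0), "positive")
})

make_blob_map <- function(dm, centre, height = 10, width = 18) {
  g <- expand.grid(i = 1:dm[1], j = 1:dm[2], k = 1:dm[3])
  d2 <- (g$i - centre[1])^2 + (g$j - centre[2])^2 + (g$k - centre[3])^2
  array(height * exp(-d2 / width), dm)
}

test_that("region selection picks the nearest peak and exactly k voxels by rank", {
  dm <- c(20, 20, 16)
  aff <- haroldmvb:::default_affine(dm)
  blobA <- make_blob_map(dm, c(5, 10, 8))
  blobB <- make_blob_map(dm, c(16, 10, 8), height = 8)
  map <- blobA + blobB
  lmB <- as.numeric(haroldmvb:::voxel_to_world(matrix(c(15, 10, 8), 1), aff))
  m <- select_roi(map, lmB, k = 40, affine = aff)
  expect_equal(m$k, 40)
  # selection drawn from blob B: all voxels nearer B's centre than A's
  dB <- rowSums((sweep(m$coords, 2, c(16, 10, 8)))^2)
  dA <- rowSums((sweep(m$coords, 2, c(5, 10, 8)))^2)
  expect_true(all(dB < dA))
  # the selected voxels are the 40 largest of B's neighbourhood
  expect_gte(min(map[m$coords]), sort(blobB[blobB > 0], decreasing = TRUE)[60] * 0.5)
  expect_error(select_roi(array(1, c(2, 2, 2)), c(0, 0, 0), k = 70), "fewer than k")
})

test_that("mirroring flips world x, preserves size, and is an involution", {
  dm <- c(40, 30, 30)
  aff <- diag(c(2, 2, 2, 1)); aff[1:3, 4] <- c(-42, -30, 24) # x symmetric about 0
  coords <- matrix(c(40, 4, 15), 1) # world x = 2*40 - 42 = +38
  mask <- haroldmvb:::new_roi_mask(coords, aff, "right", dm)
  w <- haroldmvb:::voxel_to_world(mask$coords, aff)
  expect_equal(unname(w[1, ]), c(38, -22, 54))
  mm <- mirror_roi(mask)
  wm <- haroldmvb:::voxel_to_world(mm$coords, aff)
  expect_equal(unname(wm[1, ]), c(-38, -22, 54))
  expect_equal(mm$hemisphere, "left")
  expect_equal(mm$k, mask$k)
  back <- mirror_roi(mm)
  expect_equal(back$coords, mask$coords)
  # sorted |x| multiset preserved on a larger mask
  set.seed(2)
  big <- haroldmvb:::new_roi_mask(cbind(sample(5:35, 10), sample(1:30, 10),
                                        sample(1:30, 10)), aff, "right", dm)
  bigm <- mirror_roi(big)
  expect_equal(sort(abs(haroldmvb:::voxel_to_world(bigm$coords, aff)[, 1])),
               sort(abs(haroldmvb:::voxel_to_world(big$coords, aff)[, 1])))
})

test_that("region means are linear and exact", {
  dm <- c(10, 10, 7)
  aff <- haroldmvb:::default_affine(dm)
  coords <- cbind(1:7, 1:7, 1:7)
  mask <- haroldmvb:::new_roi_mask(coords, aff, "left", dm)
  b <- array(3.5, dm)
  expect_equal(roi_mean(b, mask), 3.5)
  expect_equal(roi_mean(2 * b, mask), 7)
  seqmap <- array(0, dm)
  seqmap[coords] <- 1:7
  expect_equal(roi_mean(seqmap, mask), 4) # mean of 1..7
  m70 <- haroldmvb:::new_roi_mask(as.matrix(expand.grid(1:10, 1:7, 1))[1:70, ],
                                  aff, "left", dm)
  s70 <- array(0, dm); s70[m70$coords] <- 1:70
  expect_equal(roi_mean(s70, m70), 35.5)
  expect_error(roi_mean(array(0, c(2, 2, 2)), mask), "grid")
})

test_that("age-free region definition leaves the age test calibrated", {
  set.seed(71)
  dm <- c(12, 12, 8)
  base <- make_blob_map(dm, c(6, 6, 4), height = 3)
  reps <- 200; n_subj <- 30
  hits <- logical(reps)
  for (r in seq_len(reps)) {
    age <- runif(n_subj, 18, 87)
    subj <- lapply(seq_len(n_subj), function(s) base + array(rnorm(prod(dm)), dm))
    avg <- Reduce(`+`, subj) / n_subj
    m <- select_roi(avg, c(0, 0, 0), k = 15, affine = haroldmvb:::default_affine(dm))
    means <- vapply(subj, roi_mean, numeric(1), mask = m)
    hits[r] <- summary(stats::lm(means ~ age))$coefficients[2, 4] < 0.05
  }
  expect_gt(mean(hits), 0.01)
  expect_lt(mean(hits), 0.11)
})
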