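test_that("synthetic Gaussian PSFs are normalized, symmetric and sized right", {
  p <- syntheticPSF(c(0.1, 0.1, 0.1), c(9, 9, 9), 0.15, 0.15)
  v <- stackValues(p)
  expect_equal(sum(v), 1, tolerance = 1e-12)
  # isotropic case: spherical symmetry under axis permutation
  expect_lt(max(abs(v - aperm(v, c(2, 1, 3)))), 1e-10)
  expect_lt(max(abs(v - aperm(v, c(3, 2, 1)))), 1e-10)
  # axial FWHM in um of an anisotropic PSF matches 2.355 sigma_z
  pa <- syntheticPSF(c(0.05, 0.05, 0.1), c(41, 21, 21), 0.2, 0.5)
  prof <- stackValues(pa)[, 11, 11]
  half <- max(prof) / 2
  # half-maximum crossings by linear interpolation
  lo <- min(which(prof >= half)); hi <- max(which(prof >= half))
  z1 <- lo - 1 + (half - prof[lo - 1]) / (prof[lo] - prof[lo - 1])
  z2 <- hi + (prof[hi] - half) / (prof[hi] - prof[hi + 1])
  fwhm <- (z2 - z1) * 0.1                    # um
  expect_lt(abs(fwhm - 2.355 * 0.5), 0.1)    # within one voxel
  expect_error(syntheticPSF(c(0.1, 0.1, 0.1), c(8, 9, 9), 0.1, 0.1), "odd")
})

test_that("planted beads are detected to subvoxel accuracy", {
  centers <- rbind(c(8, 10, 12), c(12, 30, 14), c(16, 12, 36), c(9, 38, 38))
  bs <- bead_field(centers)
  det <- detectMicrospheres(bs, 50, c(5, 6, 6))
  expect_identical(nrow(det$centers), 4L)
  ord <- order(det$centers[, 1] * 1e6 + det$centers[, 2] * 1e3 +
                 det$centers[, 3])
  ord_t <- order(centers[, 1] * 1e6 + centers[, 2] * 1e3 + centers[, 3])
  expect_lt(max(abs(det$centers[ord, ] - centers[ord_t, ])), 0.5)
})

test_that("beads with overlapping windows are both discarded", {
  centers <- rbind(c(12, 20, 20), c(12, 24, 26))  # closer than 2x window
  bs <- bead_field(centers)
  w <- testthat::capture_warnings(det <- detectMicrospheres(bs, 50, c(5, 6, 6)))
  expect_true(any(grepl("overlap", w)))
  expect_identical(nrow(det$centers), 0L)
  expect_error(extractAndSumProfiles(bs, det), "no beads")
})

test_that("an empty stack yields no beads", {
  s <- ImageStack(array(0, c(8, 16, 16)), c(0.1, 0.1, 0.3))
  expect_error(detectMicrospheres(s, 10, c(2, 2, 2)), "empty|signal")
})

test_that("summing identical noise-free beads reproduces one profile", {
  centers <- rbind(c(8, 10, 12), c(12, 30, 14), c(16, 12, 36), c(9, 38, 38))
  bs <- bead_field(centers)
  det <- detectMicrospheres(bs, 50, c(5, 6, 6))
  psf <- extractAndSumProfiles(bs, det)
  expect_identical(mProfiles(psf), 4L)
  expect_equal(sum(stackValues(psf)), 1, tolerance = 1e-9)
  single <- bead_field(centers[1, , drop = FALSE])
  det1 <- detectMicrospheres(single, 50, c(5, 6, 6))
  psf1 <- extractAndSumProfiles(single, det1)
  expect_lt(max(abs(stackValues(psf) - stackValues(psf1))), 1e-6)
  # centre of mass sits on the centre voxel
  v <- stackValues(psf)
  d <- dim(v)
  gz <- apply(v, 1, sum); gy <- apply(v, 2, sum); gx <- apply(v, 3, sum)
  com <- c(sum(seq_len(d[1]) * gz), sum(seq_len(d[2]) * gy),
           sum(seq_len(d[3]) * gx))
  expect_lt(max(abs(com - (d + 1) / 2)), 0.25)
})

test_that("summing M noisy profiles raises the peak SNR about sqrt(M)-fold", {
  # Poisson counts: summing M replicate bead images multiplies the peak
  # mean by M, so the Poisson peak SNR grows by sqrt(M).
  set.seed(51)
  ctr <- matrix(c(12, 24, 24), 1)
  for (M in c(4, 9, 16)) {
    single <- bead_field(ctr, poisson = TRUE)
    acc <- stackValues(single)
    for (m in seq_len(M - 1))
      acc <- acc + stackValues(bead_field(ctr, poisson = TRUE))
    snr1 <- estimatePeakSNR(single)@snr
    snrM <- estimatePeakSNR(ImageStack(acc, c(0.1, 0.1, 0.3),
                                       "photon-count"))@snr
    expect_lt(abs(snrM / snr1 - sqrt(M)) / sqrt(M), 0.2)
  }
})

test_that("a single heavily noisy bead still yields a valid PSF", {
  set.seed(52)
  bs <- bead_field(matrix(c(12, 24, 24), 1), amp = 30, poisson = TRUE)
  det <- detectMicrospheres(bs, 10, c(5, 6, 6))
  psf <- extractAndSumProfiles(bs, det)
  expect_identical(mProfiles(psf), 1L)
  expect_true(all(stackValues(psf) >= 0))
  expect_equal(sum(stackValues(psf)), 1, tolerance = 1e-9)
})

test_that("resampling preserves identity, physical width and unit sum", {
  p <- syntheticPSF(c(0.1, 0.1, 0.3), c(9, 31, 31), 0.4, 0.6)
  expect_identical(resamplePSF(p, voxelDims(p)), p)
  # downsample by exactly 2 in x: the physical sigma is unchanged
  r <- resamplePSF(p, c(0.2, 0.1, 0.3))
  expect_equal(sum(stackValues(r)), 1, tolerance = 1e-9)
  sigma_um <- function(psf, ax, h) {
    v <- stackValues(psf)
    prof <- apply(v, ax, sum)
    idx <- seq_along(prof)
    mu <- sum(idx * prof) / sum(prof)
    sqrt(sum((idx - mu)^2 * prof) / sum(prof)) * h
  }
  expect_lt(abs(sigma_um(r, 3, 0.2) - sigma_um(p, 3, 0.1)) /
              sigma_um(p, 3, 0.1), 0.02)
  expect_error(resamplePSF(p, c(10, 10, 10)), "coarser")
})
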