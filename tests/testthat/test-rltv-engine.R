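uniform_psf3 <- function(dims = c(0.136, 0.136, 0.707)) {
  k <- array(stats::runif(27), c(3, 3, 3)); k <- k / sum(k)
  names(dims) <- c("hx", "hy", "hz")
  methods::new("PointSpreadFunction", values = k, voxelDims = dims,
               units = "arbitrary-intensity", mProfiles = 0L)
}

delta_psf3 <- function(dims = c(0.136, 0.136, 0.707)) {
  k <- array(0, c(3, 3, 3)); k[2, 2, 2] <- 1
  names(dims) <- c("hx", "hy", "hz")
  methods::new("PointSpreadFunction", values = k, voxelDims = dims,
               units = "arbitrary-intensity", mProfiles = 0L)
}

test_that("relative change and MSE follow their definitions", {
  set.seed(41)
  a <- ImageStack(array(stats::runif(4^3, 1, 9), c(4, 4, 4)), c(1, 1, 1))
  b <- ImageStack(2 * stackValues(a), c(1, 1, 1))
  expect_equal(relativeChange(a, a), 0)
  expect_equal(relativeChange(a, b), 1)
  r <- ImageStack(array(stats::runif(4^3), c(4, 4, 4)), c(1, 1, 1))
  expect_equal(relativeChange(a, r),
               sqrt(sum((stackValues(r) - stackValues(a))^2)) /
                 sqrt(sum(stackValues(a)^2)))
  expect_equal(imageMSE(a, a), 0)
  t2 <- ImageStack(array(2, c(4, 4, 4)), c(1, 1, 1))
  e1 <- ImageStack(array(1, c(4, 4, 4)), c(1, 1, 1))
  expect_equal(imageMSE(t2, e1, normalize = FALSE), 1)
  expect_equal(imageMSE(t2, e1, normalize = TRUE), 0.25)
  expect_equal(imageMSE(a, r),
               mean(((stackValues(r) - stackValues(a)) / max(stackValues(a)))^2))
  expect_error(imageMSE(ImageStack(array(0, c(4, 4, 4)), c(1, 1, 1)), e1),
               "normalize")
})

test_that("the classical RL step has i as fixed point under a delta PSF", {
  set.seed(42)
  i <- ImageStack(array(stats::runif(5 * 6 * 7, 1, 50), c(5, 6, 7)),
                  c(0.136, 0.136, 0.707))
  st <- rlStep(i, i, delta_psf3(), lambda = 0, pad_mode = "none")
  expect_false(st$aborted)
  expect_lt(max(abs(stackValues(st$estimate) - stackValues(i))), 1e-8)
})

test_that("lambda = 0 iterates conserve flux and stay nonnegative", {
  set.seed(43)
  for (case in 1:10) {
    i <- ImageStack(array(stats::runif(8^3, 0, 100), c(8, 8, 8)), c(1, 1, 1))
    psf <- uniform_psf3(c(1, 1, 1))
    o <- i
    for (s in 1:3) {
      st <- rlStep(o, i, psf, lambda = 0, pad_mode = "none")
      expect_false(st$aborted)
      o <- st$estimate
      expect_true(all(stackValues(o) >= 0))
      expect_lt(abs(sum(stackValues(o)) - sum(stackValues(i))) /
                  sum(stackValues(i)), 1e-6)
    }
  }
})

test_that("if i == o (*) h then o is a fixed point of the lambda = 0 update", {
  truth <- generatePhantom("blocky", c(8, 32, 32), seed = 44)
  psf <- test_psf(voxelDims(truth))
  i <- fftConvolve(truth, psf, pad_mode = "none")
  st <- rlStep(truth, i, psf, lambda = 0, pad_mode = "none")
  expect_lt(max(abs(stackValues(st$estimate) - stackValues(truth))) /
              max(stackValues(truth)), 1e-8)
})

test_that("an unstable lambda drives the denominator negative and aborts", {
  v <- array(1, c(8, 16, 16))
  v[, , 9:16] <- 100                      # sharp two-level step
  i <- ImageStack(v, c(0.136, 0.136, 0.707), "photon-count")
  st <- rlStep(i, i, uniform_psf3(), lambda = 1e3)
  expect_true(st$aborted)
  expect_identical(stackValues(st$estimate), v)  # previous estimate retained
})

test_that("the first-iteration lambda_lsq is calibrated to 50/SNR", {
  ds <- small_dataset(snr = 22.7, seed = 45, shape = c(8L, 32L, 32L))
  img <- degradedStack(ds)
  res <- estimateLambdaLsq(img, img, datasetPSF(ds), snr = 22.7,
                           pad_mode = "none")
  expect_equal(res$lambda, 50 / 22.7, tolerance = 1e-12)
  # reusing the stored C reproduces the same value at the same iterate
  res2 <- estimateLambdaLsq(img, img, datasetPSF(ds), C = res$C,
                            pad_mode = "none")
  expect_equal(res2$lambda, res$lambda, tolerance = 1e-12)
})

test_that("the closed-form lambda_lsq minimizes the residual functional", {
  ds <- small_dataset(snr = 22.7, seed = 46, shape = c(8L, 32L, 32L))
  img <- degradedStack(ds)
  psf <- datasetPSF(ds)
  eps <- 1e-9 * (max(stackValues(img)) - min(stackValues(img)))
  lam <- estimateLambdaLsq(img, img, psf, C = 1, epsilon_tv = eps,
                           pad_mode = "none")$lambda
  # rebuild r and d from public building blocks
  blur <- stackValues(fftConvolve(img, psf, pad_mode = "none"))
  ratio <- ifelse(blur > 1e-12 * max(abs(blur)), stackValues(img) / blur, 0)
  corr <- stackValues(fftConvolve(ImageStack(ratio, voxelDims(img)), psf,
                                  adjoint = TRUE, pad_mode = "none"))
  r <- 1 - corr
  d <- stackValues(tvDivergence(img, epsilon = eps,
                                spacing = voxelDims(img) * 1000))
  Ffun <- function(l) sum((r - l * d)^2)
  grid <- seq(lam * 0.9, lam * 1.1, length.out = 4001)
  lam_grid <- grid[which.min(vapply(grid, Ffun, numeric(1)))]
  expect_equal(lam, lam_grid, tolerance = 1e-4)
  # and the closed form itself to high precision
  expect_equal(lam, sum(r * d) / sum(d * d), tolerance = 1e-8)
})

test_that("a flat estimate has no TV force and yields lambda 0", {
  i <- ImageStack(array(5, c(6, 6, 6)), c(0.136, 0.136, 0.707))
  expect_warning(
    res <- estimateLambdaLsq(i, i, uniform_psf3(), snr = 10,
                             pad_mode = "none"),
    "zero")
  expect_equal(res$lambda, 0)
})

test_that("noise-free unregularized deconvolution strictly reduces the MSE", {
  truth <- generatePhantom("blocky", c(8, 32, 32), seed = 47)
  psf <- test_psf(voxelDims(truth))
  i <- fftConvolve(truth, psf, pad_mode = "none")
  res <- deconvolve(i, psf, lambda = 0, max_iterations = 50,
                    pad_mode = "none", truth = truth)
  tr <- diagTrace(res)
  expect_lt(tr$mse[50], tr$mse[1])
  expect_lt(tr$mse[50], imageMSE(truth, i))
  expect_identical(stopReason(res), "max-iterations")
})

test_that("max_iterations = 1 returns after a single step", {
  ds <- small_dataset(seed = 48, shape = c(8L, 32L, 32L))
  res <- deconvolve(degradedStack(ds), datasetPSF(ds), lambda = 0.5,
                    max_iterations = 1, pad_mode = "none")
  expect_identical(iterationsRun(res), 1L)
  expect_identical(stopReason(res), "max-iterations")
})

test_that("the lambda-trace rule stops five steps after the maximum", {
  # stub the raw estimator so the lambda trace peaks at iteration 3
  vals <- c(1, 2, 3, 2.5, 2.4, 2.3, 2.2, 2.1, 2.0, 1.9, 1.8, 1.7)
  calls <- new.env(); calls$n <- 0L
  testthat::local_mocked_bindings(
    .lambda_raw = function(ctx, o, corr = NULL, d = NULL, warn = TRUE) {
      calls$n <- calls$n + 1L
      vals[calls$n]
    },
    .package = "rltv")
  i <- ImageStack(array(50, c(6, 6, 6)), c(0.136, 0.136, 0.707),
                  "photon-count")
  res <- deconvolve(i, delta_psf3(), lambda = "auto", max_iterations = 20,
                    stop_window = 5, snr = 50, pad_mode = "none")
  expect_identical(stopReason(res), "converged-window")
  expect_identical(iterationsRun(res), 8L)
  expect_identical(recommendedIndex(res), 8L)
  tr <- diagTrace(res)
  expect_identical(which.max(tr$lambda), 3L)
  # the calibration makes the first lambda equal 50/SNR
  expect_equal(tr$lambda[1], 1, tolerance = 1e-12)
})

test_that("the auto-stop estimate lands within a factor 3 of the best MSE", {
  ratios <- vapply(1:10, function(k) {
    ds <- small_dataset(snr = 22.7, seed = 200 + k)
    stoppingCriterionReport(ds, max_iter = 40)$ratio
  }, numeric(1))
  expect_lte(stats::median(ratios), 3)
})
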