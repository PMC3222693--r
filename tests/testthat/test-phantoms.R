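test_that("phantom generation is deterministic per seed", {
  for (tex in c("blocky", "honeycomb", "bead-cluster")) {
    a <- generatePhantom(tex, c(8, 32, 32), seed = 61)
    b <- generatePhantom(tex, c(8, 32, 32), seed = 61)
    expect_identical(stackValues(a), stackValues(b))
    c2 <- generatePhantom(tex, c(8, 32, 32), seed = 62)
    expect_false(identical(stackValues(a), stackValues(c2)))
  }
})

test_that("blocky phantoms expose several distinct intensity levels", {
  a <- stackValues(generatePhantom("blocky", c(16, 48, 48), seed = 63))
  lv <- setdiff(unique(round(a, 6)), 0)
  expect_gte(length(lv[lv > 0.1 * max(a)]), 2)
})

test_that("honeycomb interiors occupy 40-90 percent of the volume", {
  a <- stackValues(generatePhantom("honeycomb", c(16, 48, 48), seed = 64))
  bg_frac <- mean(a < 0.5 * max(a))
  expect_gt(bg_frac, 0.4)
  expect_lt(bg_frac, 0.9)
})

test_that("the smoothing protocol is the identity when N = S = 0", {
  truth <- generatePhantom("blocky", c(8, 32, 32), seed = 65)
  psf <- test_psf(voxelDims(truth))
  out <- makeSmoothSynthetic(truth, psf, n_rounds = 0, steps_per_deconv = 0)
  expect_identical(stackValues(out), stackValues(truth))
})

test_that("smoothing removes energy above the PSF cutoff", {
  ds <- small_dataset(snr = 10, seed = 66, shape = c(8L, 32L, 32L))
  img <- degradedStack(ds)
  out <- makeSmoothSynthetic(img, datasetPSF(ds), n_rounds = 1,
                             steps_per_deconv = 10, pad_mode = "none")
  hf_energy <- function(v) {
    # energy in the upper half of the frequency range along each axis
    sp <- abs(stats::fft(v / sqrt(length(v))))^2
    d <- dim(v)
    fz <- pmin(0:(d[1] - 1), d[1] - 0:(d[1] - 1)) / d[1]
    fy <- pmin(0:(d[2] - 1), d[2] - 0:(d[2] - 1)) / d[2]
    fx <- pmin(0:(d[3] - 1), d[3] - 0:(d[3] - 1)) / d[3]
    hi <- outer(outer(fz > 0.25, fy > 0.25, "|"), fx > 0.25, "|")
    sum(sp[hi])
  }
  expect_lte(hf_energy(stackValues(out) / max(stackValues(out))),
             hf_energy(stackValues(img) / max(stackValues(img))))
})

test_that("the reference smoothing parameters keep the output nonnegative", {
  ds <- small_dataset(snr = 10, seed = 67, shape = c(8L, 32L, 32L))
  out <- makeSmoothSynthetic(degradedStack(ds), datasetPSF(ds),
                             n_rounds = 4, steps_per_deconv = 200,
                             lambda = 0, pad_mode = "none")
  expect_true(all(stackValues(out) >= 0))
})

test_that("degradation hits the target peak photon count exactly", {
  truth <- generatePhantom("blocky", c(8, 32, 32), seed = 68)
  psf <- test_psf(voxelDims(truth))
  ds <- degradeStack(truth, psf, 22.7, seed = 68)
  blur <- fftConvolve(truth, psf, pad_mode = "none")
  scaled <- ImageStack(stackValues(blur) * ds@scale, voxelDims(truth))
  expect_lt(abs(estimatePeakSNR(scaled)@peakMean - 22.7^2), 0.5)
  expect_true(all(stackValues(degradedStack(ds)) ==
                    round(stackValues(degradedStack(ds)))))
})

test_that("degraded counts are Poisson around the scaled blurred mean", {
  truth <- generatePhantom("blocky", c(8, 32, 32), seed = 69)
  psf <- test_psf(voxelDims(truth))
  ds0 <- degradeStack(truth, psf, 22.7, seed = 1)
  blur <- fftConvolve(truth, psf, pad_mode = "none")
  mu <- stackValues(blur) * ds0@scale
  peak <- which.max(mu)
  draws <- vapply(1:200, function(k)
    stackValues(degradedStack(degradeStack(truth, psf, 22.7,
                                           seed = 1000 + k)))[peak],
    numeric(1))
  expect_lt(abs(mean(draws) - mu[peak]) / mu[peak], 0.02)
  expect_lt(abs(stats::var(draws) / mu[peak] - 1), 0.15)
})

test_that("estimated SNR of degraded stacks closes on the target", {
  for (target in c(5, 10, 22.7, 50, 100)) {
    ds <- small_dataset(snr = target, seed = 70)
    est <- estimatePeakSNR(degradedStack(ds))@snr
    expect_lt(abs(est - target) / target, 0.1)
  }
})

test_that("restoration beats doing nothing on every texture", {
  for (tex in c("blocky", "honeycomb", "bead-cluster")) {
    truth <- generatePhantom(tex, c(16, 32, 32), seed = 71)
    psf <- test_psf(voxelDims(truth))
    ds <- degradeStack(truth, psf, 10, seed = 71)
    res <- deconvolve(degradedStack(ds), datasetPSF(ds), lambda = "auto",
                      max_iterations = 30, pad_mode = "none",
                      truth = scaled_truth(ds))
    mse0 <- imageMSE(truth, stackValues(degradedStack(ds)) / ds@scale)
    expect_lt(min(diagTrace(res)$mse), mse0)
  }
})
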