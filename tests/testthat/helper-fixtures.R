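# Shared fixtures, built in code at test time and cached per session.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, builder(), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

test_psf <- function(dims = c(0.136, 0.136, 0.707)) {
  syntheticPSF(dims, c(5L, 9L, 9L), sigma_xy = 0.15, sigma_z = 0.45)
}

# Small degraded blocky dataset for engine-level tests.
small_dataset <- function(snr = 22.7, seed = 1L, shape = c(16L, 32L, 32L)) {
  truth <- generatePhantom("blocky", shape, seed = seed)
  psf <- test_psf(voxelDims(truth))
  degradeStack(truth, psf, snr, seed = seed)
}

# Noise-free dataset whose truth is a smooth synthetic (the repeated
# convolve/deconvolve protocol), so that unregularized RL can actually
# reach it.
noise_free_dataset <- function(seed = 7L, shape = c(16L, 32L, 32L)) {
  truth0 <- generatePhantom("blocky", shape, seed = seed)
  psf <- test_psf(voxelDims(truth0))
  truth <- makeSmoothSynthetic(truth0, psf, n_rounds = 1L,
                               steps_per_deconv = 30L, pad_mode = "none")
  blur <- fftConvolve(truth, psf, pad_mode = "none")
  m0 <- estimatePeakSNR(blur)@peakMean
  scale <- 515.29 / m0
  methods::new("DegradedDataset", truth = truth,
      degraded = ImageStack(stackValues(blur) * scale, voxelDims(truth0),
                            "photon-count"),
      psf = psf, targetSnr = Inf, scale = scale, seed = as.integer(seed))
}

# Truth rescaled to the photon-count scale of a dataset.
scaled_truth <- function(ds) {
  ImageStack(stackValues(truthStack(ds)) * ds@scale,
             voxelDims(truthStack(ds)), "arbitrary-intensity")
}

# A bead calibration field: well-separated Gaussian beads of peak
# amplitude `amp` at integer positions, optionally Poisson sampled.
bead_field <- function(centers, shape = c(24L, 48L, 48L),
                       sigma_vox = c(1.2, 1.5, 1.5), amp = 500,
                       poisson = FALSE, seed = NULL) {
  a <- array(0, shape)
  z <- seq_len(shape[1]); y <- seq_len(shape[2]); x <- seq_len(shape[3])
  for (i in seq_len(nrow(centers))) {
    ctr <- centers[i, ]
    q <- outer(outer((z - ctr[1])^2 / (2 * sigma_vox[1]^2),
                     (y - ctr[2])^2 / (2 * sigma_vox[2]^2), "+"),
               (x - ctr[3])^2 / (2 * sigma_vox[3]^2), "+")
    a <- a + amp * exp(-q)
  }
  if (poisson) {
    if (!is.null(seed)) set.seed(seed)
    a <- array(stats::rpois(length(a), a) * 1.0, dim(a))
  }
  ImageStack(a, c(0.1, 0.1, 0.3), "photon-count")
}
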