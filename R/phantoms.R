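#' @include AllGenerics.R
NULL

#' Generate a ground-truth phantom
#'
#' Synthetic 3D objects emulating the textures seen in confocal recordings
#' of cardiomyocytes:
#' \describe{
#'   \item{blocky}{random ellipsoids and rods at several intensity levels
#'     on a low background -- the mitochondria-like texture of spherical
#'     shapes, lines, homogeneous and heterogeneous areas;}
#'   \item{honeycomb}{thickened walls of a random Voronoi tessellation --
#'     the sarcolemma/t-tubule-like texture;}
#'   \item{bead-cluster}{a cluster of small bright spheres -- the punctate
#'     texture of a microsphere recording.}
#' }
#' Object sizes default to 3-10x the typical confocal PSF width at the
#' default voxel dimensions, and every texture keeps an empty border of at
#' least a few voxels so that blurring stays inside the volume.
#' Deterministic per seed.
#'
#' @param texture \code{"blocky"}, \code{"honeycomb"} or
#'   \code{"bead-cluster"}.
#' @param shape extents \code{(nz, ny, nx)}, at least \code{(8, 32, 32)}.
#' @param dims voxel dimensions \code{(hx, hy, hz)} in micrometres.
#' @param intensity_levels positive intensity levels used for the objects
#'   (the background sits at 5 percent of the brightest level).
#' @param seed integer RNG seed.
#' @return An [ImageStack-class] with arbitrary-intensity units.
#' @export
generatePhantom <- function(texture = c("blocky", "honeycomb", "bead-cluster"),
                            shape = c(32L, 64L, 64L),
                            dims = c(0.136, 0.136, 0.707),
                            intensity_levels = c(0.4, 0.7, 1.0),
                            seed = 1L) {
  texture <- match.arg(texture)
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < c(8L, 32L, 32L)))
    stop("shape must be (nz, ny, nx) with nz >= 8, ny >= 32, nx >= 32")
  dims <- .as_voxel_dims(dims)
  if (any(intensity_levels <= 0)) stop("intensity levels must be positive")
  v <- withSeed(seed, switch(texture,
    "blocky" = .phantom_blocky(shape, dims, intensity_levels),
    "honeycomb" = .phantom_honeycomb(shape, dims, intensity_levels),
    "bead-cluster" = .phantom_beads(shape, dims, intensity_levels)))
  new("ImageStack", values = v, voxelDims = dims,
      units = "arbitrary-intensity")
}

# physical coordinate grids (um), one value per voxel
.coord_grids <- function(shape, dims) {
  z <- (seq_len(shape[1]) - 0.5) * dims["hz"]
  y <- (seq_len(shape[2]) - 0.5) * dims["hy"]
  x <- (seq_len(shape[3]) - 0.5) * dims["hx"]
  list(z = array(rep(z, times = shape[2] * shape[3]), shape),
       y = array(rep(rep(y, each = shape[1]), times = shape[3]), shape),
       x = array(rep(x, each = shape[1] * shape[2]), shape))
}

# margins (um) kept clear of object centres near each border
.phantom_margin <- function(dims) {
  c(z = 3.1 * unname(dims["hz"]), y = 6.1 * unname(dims["hy"]),
    x = 6.1 * unname(dims["hx"]))
}

.runif_center <- function(ext, mar) {
  c(stats::runif(1, mar["z"], ext[1] - mar["z"]),
    stats::runif(1, mar["y"], ext[2] - mar["y"]),
    stats::runif(1, mar["x"], ext[3] - mar["x"]))
}

.phantom_blocky <- function(shape, dims, levels) {
  g <- .coord_grids(shape, dims)
  ext <- c(shape[1] * dims["hz"], shape[2] * dims["hy"],
           shape[3] * dims["hx"])
  mar <- .phantom_margin(dims)
  bg <- 0.05 * max(levels)
  v <- array(bg, shape)
  n_ell <- 10L
  for (k in seq_len(n_ell)) {
    ctr <- .runif_center(ext, mar)
    ax_xy <- stats::runif(2, 0.5, 1.5)   # semi-axes, um
    ax_z <- stats::runif(1, 0.9, 2.2)
    lev <- sample(levels, 1)
    inside <- ((g$z - ctr[1]) / ax_z)^2 + ((g$y - ctr[2]) / ax_xy[1])^2 +
              ((g$x - ctr[3]) / ax_xy[2])^2 <= 1
    v[inside] <- pmax(v[inside], lev)
  }
  n_rod <- 4L
  for (k in seq_len(n_rod)) {
    ctr <- .runif_center(ext, mar)
    theta <- stats::runif(1, 0, pi)      # in-plane orientation
    len <- stats::runif(1, 3, 6)         # um
    rad <- stats::runif(1, 0.25, 0.45)
    lev <- sample(levels, 1)
    ux <- cos(theta); uy <- sin(theta)
    dx <- g$x - ctr[3]; dy <- g$y - ctr[2]; dz <- g$z - ctr[1]
    t <- dx * ux + dy * uy
    t <- pmin(pmax(t, -len / 2), len / 2)
    r2 <- (dx - t * ux)^2 + (dy - t * uy)^2 + dz^2
    v[r2 <= rad^2] <- pmax(v[r2 <= rad^2], lev)
  }
  v
}

.phantom_honeycomb <- function(shape, dims, levels) {
  g <- .coord_grids(shape, dims)
  ext <- c(shape[1] * dims["hz"], shape[2] * dims["hy"],
           shape[3] * dims["hx"])
  bg <- 0.05 * max(levels)
  # cell seeds roughly every 2.5 um in-plane
  n_seed <- max(6L, as.integer(round(prod(ext[2:3]) / 2.5^2)))
  sz <- stats::runif(n_seed, 0, ext[1])
  sy <- stats::runif(n_seed, 0, ext[2])
  sx <- stats::runif(n_seed, 0, ext[3])
  d1 <- array(Inf, shape); d2 <- array(Inf, shape)
  for (k in seq_len(n_seed)) {
    # anisotropy: cells are columnar along z (walls mostly vertical)
    dk <- sqrt(0.1 * (g$z - sz[k])^2 + (g$y - sy[k])^2 + (g$x - sx[k])^2)
    closer <- dk < d1
    d2[closer] <- d1[closer]; d1[closer] <- dk[closer]
    between <- !closer & dk < d2
    d2[between] <- dk[between]
  }
  wall <- (d2 - d1) < 0.45   # wall thickness, um
  # keep a clear border so blur stays inside the volume
  mar <- .phantom_margin(dims)
  border <- g$z < mar["z"] | g$z > ext[1] - mar["z"] |
            g$y < mar["y"] | g$y > ext[2] - mar["y"] |
            g$x < mar["x"] | g$x > ext[3] - mar["x"]
  v <- array(bg, shape)
  v[wall & !border] <- max(levels)
  v[border] <- 0
  v
}

.phantom_beads <- function(shape, dims, levels) {
  g <- .coord_grids(shape, dims)
  ext <- c(shape[1] * dims["hz"], shape[2] * dims["hy"],
           shape[3] * dims["hx"])
  v <- array(0, shape)
  ctr0 <- ext / 2
  n_beads <- 12L
  rad <- 0.25
  for (k in seq_len(n_beads)) {
    ctr <- ctr0 + c(stats::rnorm(1, 0, ext[1] / 8),
                    stats::rnorm(1, 0, ext[2] / 8),
                    stats::rnorm(1, 0, ext[3] / 8))
    mar <- .phantom_margin(dims)
    ctr <- pmin(pmax(ctr, mar + rad), ext - mar - rad)
    inside <- (g$z - ctr[1])^2 + (g$y - ctr[2])^2 + (g$x - ctr[3])^2 <= rad^2
    v[inside] <- max(levels)
  }
  # guarantee at least one bead even on very coarse grids
  if (max(v) == 0) {
    iz <- round(shape[1] / 2); iy <- round(shape[2] / 2)
    ix <- round(shape[3] / 2)
    v[iz, iy, ix] <- max(levels)
  }
  v
}

#' Smooth-synthetic image by repeated convolution/deconvolution
#'
#' Produces a smooth synthetic object from a (possibly noisy) input image
#' by alternating Richardson-Lucy deconvolution and convolution with the
#' same PSF: \code{o_0 = deconv(i)}, then N rounds of
#' \code{o_k = deconv(o_(k-1) (*) h)}, each deconvolution running S steps
#' at the given lambda.  There are N+1 deconvolutions and N convolutions,
#' the extra deconvolution keeping small details at the scale of the
#' object rather than of the blurred image.  The reference protocol uses
#' \code{N = 4, S = 200, lambda = 0}.
#'
#' @param image input [ImageStack-class].
#' @param psf [PointSpreadFunction-class].
#' @param n_rounds N, number of convolve+deconvolve rounds.
#' @param steps_per_deconv S, RL steps per deconvolution (0 = identity).
#' @param lambda fixed TV parameter for the inner deconvolutions.
#' @param pad_mode convolution boundary handling.
#' @return An [ImageStack-class].
#' @export
makeSmoothSynthetic <- function(image, psf, n_rounds = 4L,
                                steps_per_deconv = 200L, lambda = 0,
                                pad_mode = c("reflect", "none")) {
  stopifnot_stack(image, "image")
  pad_mode <- match.arg(pad_mode)
  if (n_rounds < 0 || steps_per_deconv < 0)
    stop("n_rounds and steps_per_deconv must be >= 0")
  dec <- function(img) {
    if (steps_per_deconv == 0L) return(img)
    res <- deconvolve(img, psf, lambda = lambda,
                      max_iterations = steps_per_deconv,
                      pad_mode = pad_mode)
    if (res@stopReason == "aborted-negative" && res@iterationsRun == 0L)
      stop("inner deconvolution aborted at the first step")
    res@estimate
  }
  o <- dec(image)
  if (n_rounds > 0) for (k in seq_len(n_rounds)) {
    o <- dec(fftConvolve(o, psf, pad_mode = pad_mode))
  }
  o
}

#' Degrade a ground-truth object to a target peak SNR
#'
#' Implements the image-formation model \code{i = Poisson(scale * (o (*)
#' h))}: the truth is blurred with the PSF, scaled so that the maximum of
#' the 3x3x3-averaged blurred image equals \code{target_snr^2} (the peak
#' SNR convention of [estimatePeakSNR()]), and Poisson sampled.
#' Deterministic per seed.
#'
#' @param truth ground-truth [ImageStack-class].
#' @param psf [PointSpreadFunction-class].
#' @param target_snr target peak SNR (> 0).
#' @param seed integer RNG seed.
#' @param pad_mode convolution boundary handling for the blurring step;
#'   the default \code{"none"} (cyclic) matches the benchmark protocol,
#'   whose phantoms carry empty borders.
#' @return A [DegradedDataset-class].
#' @export
degradeStack <- function(truth, psf, target_snr, seed = 1L,
                         pad_mode = c("none", "reflect")) {
  stopifnot_stack(truth, "truth")
  pad_mode <- match.arg(pad_mode)
  if (target_snr <= 0) stop("target_snr must be positive")
  if (max(truth@values) == 0) stop("truth is all zero")
  blur <- fftConvolve(truth, psf, pad_mode = pad_mode)
  m0 <- max(.uniform_filter3(blur@values))
  scale <- target_snr^2 / m0
  counts <- withSeed(seed, {
    array(stats::rpois(length(blur@values), scale * blur@values),
          dim(blur@values))
  })
  degraded <- new("ImageStack", values = counts * 1.0,
                  voxelDims = truth@voxelDims, units = "photon-count")
  est <- estimatePeakSNR(degraded)@snr
  if (abs(est - target_snr) > 0.1 * target_snr)
    warning(sprintf("estimated peak SNR %.3g deviates >10%% from target %.3g",
                    est, target_snr))
  new("DegradedDataset", truth = truth, degraded = degraded, psf = psf,
      targetSnr = target_snr, scale = scale, seed = as.integer(seed))
}
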