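#' @include AllGenerics.R
NULL

#' Synthetic anisotropic Gaussian PSF
#'
#' A separable Gaussian sampled on the voxel grid, normalized to unit sum.
#' Confocal PSFs are elongated along the optical axis, so typically
#' \code{sigma_z > sigma_xy}.
#'
#' @param dims voxel dimensions \code{(hx, hy, hz)} in micrometres.
#' @param shape odd extents \code{(nz, ny, nx)}.
#' @param sigma_xy lateral standard deviation in micrometres.
#' @param sigma_z axial standard deviation in micrometres.
#' @return A [PointSpreadFunction-class] with \code{mProfiles = 0}.
#' @examples
#' psf <- syntheticPSF(c(0.136, 0.136, 0.707), c(5, 9, 9), 0.15, 0.45)
#' sum(stackValues(psf))  # 1
#' @export
syntheticPSF <- function(dims, shape, sigma_xy, sigma_z) {
  dims <- .as_voxel_dims(dims)
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape %% 2L == 0L))
    stop("shape must be three odd extents (nz, ny, nx)")
  if (sigma_xy <= 0 || sigma_z <= 0) stop("sigmas must be positive")
  ctr <- (shape + 1L) / 2
  z <- (seq_len(shape[1]) - ctr[1]) * dims["hz"]
  y <- (seq_len(shape[2]) - ctr[2]) * dims["hy"]
  x <- (seq_len(shape[3]) - ctr[3]) * dims["hx"]
  gz <- exp(-z^2 / (2 * sigma_z^2))
  gy <- exp(-y^2 / (2 * sigma_xy^2))
  gx <- exp(-x^2 / (2 * sigma_xy^2))
  v <- outer(outer(gz, gy), gx)
  dim(v) <- shape
  v <- v / sum(v)
  new("PointSpreadFunction", values = v, voxelDims = dims,
      units = "arbitrary-intensity", mProfiles = 0L)
}

#' Detect fluorescent microspheres in a calibration stack
#'
#' Finds local intensity maxima above a threshold, refines each to the
#' intensity centre of mass within a window, and discards candidates whose
#' windows overlap each other or the stack border (overlapping profiles
#' would contaminate the summed PSF).
#'
#' @param stack bead calibration [ImageStack-class].
#' @param min_intensity detection threshold (absolute intensity).
#' @param window half-extent of the extraction window per axis,
#'   \code{(wz, wy, wx)} in voxels.
#' @return list with \code{centers} (n x 3 matrix of subvoxel (z, y, x)
#'   coordinates, 1-based) and \code{window}.
#' @export
detectMicrospheres <- function(stack, min_intensity, window) {
  stopifnot_stack(stack)
  a <- stack@values
  window <- as.integer(window)
  if (length(window) != 3L || any(window < 1L))
    stop("window must be three positive half-extents (wz, wy, wx)")
  if (max(a) <= 0) stop("empty stack: no signal")
  d <- dim(a)
  p <- padReplicate(a, c(1L, 1L, 1L))
  nbmax <- array(-Inf, d)
  for (dz in 0:2) for (dy in 0:2) for (dx in 0:2) {
    if (dz == 1 && dy == 1 && dx == 1) next
    nbmax <- pmax(nbmax, p[dz + seq_len(d[1]), dy + seq_len(d[2]),
                           dx + seq_len(d[3]), drop = FALSE])
  }
  cand <- which(a > min_intensity & a >= nbmax, arr.ind = TRUE)
  if (nrow(cand) == 0) stop("no beads found above threshold")
  # windows must fit inside the stack
  fits <- cand[, 1] > window[1] & cand[, 1] <= d[1] - window[1] &
          cand[, 2] > window[2] & cand[, 2] <= d[2] - window[2] &
          cand[, 3] > window[3] & cand[, 3] <= d[3] - window[3]
  cand <- cand[fits, , drop = FALSE]
  # discard all members of overlapping pairs (separation <= 2*window on
  # every axis means the windows intersect)
  n <- nrow(cand)
  keep <- rep(TRUE, n)
  if (n > 1) {
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      if (all(abs(cand[i, ] - cand[j, ]) <= 2L * window)) {
        keep[i] <- keep[j] <- FALSE
      }
    }
  }
  if (!all(keep))
    warning(sprintf("%d candidate(s) discarded due to overlapping windows",
                    sum(!keep)))
  cand <- cand[keep, , drop = FALSE]
  if (nrow(cand) == 0) {
    warning("no usable beads after overlap/border filtering")
    return(list(centers = matrix(numeric(0), 0, 3,
                                 dimnames = list(NULL, c("z", "y", "x"))),
                window = window))
  }
  centers <- matrix(0, nrow(cand), 3,
                    dimnames = list(NULL, c("z", "y", "x")))
  for (i in seq_len(nrow(cand))) {
    w <- .extract_window(a, cand[i, ], window)
    centers[i, ] <- cand[i, ] - window - 1 + .center_of_mass(pmax(w, 0))
  }
  list(centers = centers, window = window)
}

.extract_window <- function(a, ctr, w) {
  a[(ctr[1] - w[1]):(ctr[1] + w[1]),
    (ctr[2] - w[2]):(ctr[2] + w[2]),
    (ctr[3] - w[3]):(ctr[3] + w[3]), drop = FALSE]
}

.center_of_mass <- function(w) {
  s <- sum(w)
  if (s == 0) return((dim(w) + 1) / 2)
  d <- dim(w)
  g <- expand.grid(z = seq_len(d[1]), y = seq_len(d[2]), x = seq_len(d[3]))
  c(sum(g$z * w) / s, sum(g$y * w) / s, sum(g$x * w) / s)
}

# Trilinear shift of a 3D array by a (possibly fractional) offset, replicate
# boundary: out[v] = a[v + shift].
.shift3 <- function(a, shift) {
  d <- dim(a)
  i0 <- floor(shift)
  f <- shift - i0
  samp <- function(off) {
    iz <- pmin(pmax(seq_len(d[1]) + i0[1] + off[1], 1), d[1])
    iy <- pmin(pmax(seq_len(d[2]) + i0[2] + off[2], 1), d[2])
    ix <- pmin(pmax(seq_len(d[3]) + i0[3] + off[3], 1), d[3])
    a[iz, iy, ix, drop = FALSE]
  }
  out <- array(0, d)
  for (oz in 0:1) for (oy in 0:1) for (ox in 0:1) {
    wz <- if (oz == 1) f[1] else 1 - f[1]
    wy <- if (oy == 1) f[2] else 1 - f[2]
    wx <- if (ox == 1) f[3] else 1 - f[3]
    wgt <- wz * wy * wx
    if (wgt > 0) out <- out + wgt * samp(c(oz, oy, ox))
  }
  out
}

# Median intensity of the six faces of a window (local background estimate).
.face_median <- function(w) {
  d <- dim(w)
  stats::median(c(w[1, , ], w[d[1], , ], w[, 1, ], w[, d[2], ],
                  w[, , 1], w[, , d[3]]))
}

#' Extract, align and sum bead intensity profiles into a PSF
#'
#' For each detected bead: extract the window, subtract the local
#' background (median of the six window faces, clipped at zero), shift the
#' profile so its centre of mass sits on the centre voxel (trilinear
#' subvoxel shift), then sum all profiles and normalize to unit sum.
#' Summing M profiles raises the peak SNR of the PSF estimate by about
#' sqrt(M), so no further denoising is applied.
#'
#' @param stack bead calibration [ImageStack-class].
#' @param detection result of [detectMicrospheres()].
#' @return A [PointSpreadFunction-class] with \code{mProfiles} set to the
#'   number of beads used.
#' @export
extractAndSumProfiles <- function(stack, detection) {
  stopifnot_stack(stack)
  centers <- detection$centers
  w <- detection$window
  if (nrow(centers) == 0) stop("no beads to extract")
  a <- stack@values
  acc <- NULL
  used <- 0L
  for (i in seq_len(nrow(centers))) {
    ctr <- round(centers[i, ])
    prof <- .extract_window(a, ctr, w)
    prof <- pmax(prof - .face_median(prof), 0)
    if (sum(prof) == 0) next
    # shift so the centre of mass lands on the centre voxel
    com <- .center_of_mass(prof)
    prof <- .shift3(prof, com - (dim(prof) + 1) / 2)
    acc <- if (is.null(acc)) prof else acc + prof
    used <- used + 1L
  }
  if (used == 0L) stop("all profiles rejected (no intensity above background)")
  acc <- pmax(acc, 0)
  acc <- acc / sum(acc)
  new("PointSpreadFunction", values = acc, voxelDims = stack@voxelDims,
      units = "arbitrary-intensity", mProfiles = used)
}

#' Resample a PSF onto a different voxel grid
#'
#' Cubic-spline interpolation axis by axis onto the target spacing; the
#' resampled kernel keeps the physical extent of the source (odd extents
#' preserved) and is renormalized to unit sum.  Needed because a measured
#' PSF rarely shares the voxel dimensions of the image to be deconvolved.
#'
#' @param psf a [PointSpreadFunction-class].
#' @param target target voxel dimensions \code{(hx, hy, hz)} in
#'   micrometres.
#' @return A [PointSpreadFunction-class] on the target grid.
#' @export
resamplePSF <- function(psf, target) {
  if (!is(psf, "PointSpreadFunction"))
    stop("psf must be a PointSpreadFunction")
  target <- .as_voxel_dims(target)
  if (any(target <= 0) || any(!is.finite(target)))
    stop("target dims must be positive and finite")
  src <- psf@voxelDims
  if (all(abs(target - src) < 1e-12)) return(psf)
  d <- dim(psf@values)
  # spacing per array axis (z, y, x)
  hs <- unname(src[c("hz", "hy", "hx")])
  ht <- unname(target[c("hz", "hy", "hx")])
  half_new <- floor(((d - 1) / 2) * hs / ht)
  if (any(half_new < 1))
    stop("target grid is coarser than the whole PSF extent")
  v <- psf@values
  for (ax in 1:3) {
    if (abs(hs[ax] - ht[ax]) < 1e-12) next
    n <- dim(v)[ax]
    ctr <- (n + 1) / 2
    xout <- ctr + seq(-half_new[ax], half_new[ax]) * ht[ax] / hs[ax]
    v <- .resample_axis(v, ax, xout)
  }
  v <- pmax(v, 0)
  v <- v / sum(v)
  new("PointSpreadFunction", values = v, voxelDims = target,
      units = psf@units, mProfiles = psf@mProfiles)
}

# Cubic-spline resample of one axis of a 3D array at positions xout (in
# source index units).
.resample_axis <- function(v, ax, xout) {
  d <- dim(v)
  dn <- d; dn[ax] <- length(xout)
  out <- array(0, dn)
  idx <- seq_len(d[ax])
  others <- setdiff(1:3, ax)
  for (i in seq_len(d[others[1]])) for (j in seq_len(d[others[2]])) {
    sel <- vector("list", 3)
    sel[[ax] ] <- idx; sel[[others[1]]] <- i; sel[[others[2]]] <- j
    line <- do.call(`[`, c(list(v), sel))
    fit <- stats::spline(idx, line, xout = xout, method = "natural")$y
    seln <- sel; seln[[ax]] <- seq_along(xout)
    out <- do.call(`[<-`, c(list(out), seln, list(fit)))
  }
  out
}
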