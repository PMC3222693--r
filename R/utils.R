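# Internal helpers shared across modules.

# Evaluate expr with a temporary RNG state seeded from `seed`, restoring the
# caller's .Random.seed afterwards so package routines never disturb the
# global stream.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  expr
}

# Replicate-pad a 3D array by pad = c(pz, py, px) voxels on each side.
padReplicate <- function(a, pad) {
  d <- dim(a)
  iz <- pmin(pmax(seq_len(d[1] + 2 * pad[1]) - pad[1], 1L), d[1])
  iy <- pmin(pmax(seq_len(d[2] + 2 * pad[2]) - pad[2], 1L), d[2])
  ix <- pmin(pmax(seq_len(d[3] + 2 * pad[3]) - pad[3], 1L), d[3])
  a[iz, iy, ix, drop = FALSE]
}

# Reflect-pad (mirror without repeating the edge sample would be "symmetric
# minus one"; here we use whole-sample symmetric reflection, the common
# image-processing choice) with possibly asymmetric amounts.
.reflect_index <- function(n, lo, hi) {
  i <- seq_len(n + lo + hi) - lo
  # map i in 1..n by reflecting at the edges (period 2n, symmetric)
  j <- (i - 1) %% (2 * n)
  j <- ifelse(j >= n, 2 * n - 1 - j, j)
  j + 1L
}

padReflect <- function(a, lo, hi = lo) {
  d <- dim(a)
  a[.reflect_index(d[1], lo[1], hi[1]),
    .reflect_index(d[2], lo[2], hi[2]),
    .reflect_index(d[3], lo[3], hi[3]), drop = FALSE]
}

# L2 norm over all voxels.
l2norm <- function(a) sqrt(sum(a * a))

stopifnot_stack <- function(x, arg = "stack") {
  if (!is(x, "ImageStack"))
    stop(sprintf("%s must be an ImageStack", arg))
  invisible(TRUE)
}
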