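# Independent oracles, written as plain triple loops without sharing any
# code with the package internals.

# Cyclic (circular) convolution in direct space: out[v] = sum_k a[v-k] h[k],
# with the kernel centre treated as lag zero.
oracle_circular_convolve <- function(a, k, adjoint = FALSE) {
  d <- dim(a)
  kd <- dim(k)
  ctr <- (kd + 1) %/% 2
  if (adjoint) {
    # mirror the kernel through its centre
    k <- k[rev(seq_len(kd[1])), rev(seq_len(kd[2])), rev(seq_len(kd[3])),
           drop = FALSE]
  }
  out <- array(0, d)
  for (z in seq_len(d[1])) for (y in seq_len(d[2])) for (x in seq_len(d[3])) {
    acc <- 0
    for (kz in seq_len(kd[1])) for (ky in seq_len(kd[2]))
      for (kx in seq_len(kd[3])) {
        lz <- kz - ctr[1]; ly <- ky - ctr[2]; lx <- kx - ctr[3]
        sz <- ((z - lz - 1) %% d[1]) + 1
        sy <- ((y - ly - 1) %% d[2]) + 1
        sx <- ((x - lx - 1) %% d[3]) + 1
        acc <- acc + a[sz, sy, sx] * k[kz, ky, kx]
      }
    out[z, y, x] <- acc
  }
  out
}

# Straightforward re-implementation of the TV divergence scheme: for each
# axis, the normalized gradient component combines the forward difference
# along that axis with central differences along the other two; the
# divergence takes backward differences of the components.  Out-of-range
# samples replicate the edge.
oracle_tv_divergence <- function(o, h = c(1, 1, 1), eps) {
  d <- dim(o)
  g <- function(z, y, x) {
    o[min(max(z, 1), d[1]), min(max(y, 1), d[2]), min(max(x, 1), d[3])]
  }
  pxf <- function(z, y, x) {
    fx <- (g(z, y, x + 1) - g(z, y, x)) / h[1]
    cy <- (g(z, y + 1, x) - g(z, y - 1, x)) / (2 * h[2])
    cz <- (g(z + 1, y, x) - g(z - 1, y, x)) / (2 * h[3])
    fx / sqrt(fx^2 + cy^2 + cz^2 + eps^2)
  }
  pyf <- function(z, y, x) {
    cx <- (g(z, y, x + 1) - g(z, y, x - 1)) / (2 * h[1])
    fy <- (g(z, y + 1, x) - g(z, y, x)) / h[2]
    cz <- (g(z + 1, y, x) - g(z - 1, y, x)) / (2 * h[3])
    fy / sqrt(cx^2 + fy^2 + cz^2 + eps^2)
  }
  pzf <- function(z, y, x) {
    cx <- (g(z, y, x + 1) - g(z, y, x - 1)) / (2 * h[1])
    cy <- (g(z, y + 1, x) - g(z, y - 1, x)) / (2 * h[2])
    fz <- (g(z + 1, y, x) - g(z, y, x)) / h[3]
    fz / sqrt(cx^2 + cy^2 + fz^2 + eps^2)
  }
  out <- array(0, d)
  for (z in seq_len(d[1])) for (y in seq_len(d[2])) for (x in seq_len(d[3])) {
    dv <- 0
    if (x > 1) dv <- dv + (pxf(z, y, x) - pxf(z, y, x - 1)) / h[1]
    if (y > 1) dv <- dv + (pyf(z, y, x) - pyf(z, y - 1, x)) / h[2]
    if (z > 1) dv <- dv + (pzf(z, y, x) - pzf(z - 1, y, x)) / h[3]
    out[z, y, x] <- dv
  }
  out
}
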