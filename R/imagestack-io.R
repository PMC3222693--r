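#' @include AllGenerics.R
NULL

# Sidecar metadata dialect: a plain-text key=value file "<image>.meta.txt"
# next to the image.  Keys: shape=nz,ny,nx; dtype; endian; hx; hy; hz
# (voxel sizes in um); units; for TIFF additionally scale (decoded pixel
# values are multiplied by it) and encoding.  RAW files require the
# sidecar; for TIFF it supplements the (often absent) voxel-size tags.

.sidecar_path <- function(path) paste0(path, ".meta.txt")

.read_sidecar <- function(path) {
  sp <- .sidecar_path(path)
  if (!file.exists(sp)) return(NULL)
  lines <- readLines(sp, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  out <- list()
  for (p in kv) {
    if (length(p) < 2) next
    out[[trimws(p[1])]] <- trimws(paste(p[-1], collapse = "="))
  }
  out
}

.write_sidecar <- function(path, fields) {
  writeLines(paste0(names(fields), "=", unlist(fields)), .sidecar_path(path))
}

.meta_voxel_dims <- function(meta) {
  if (is.null(meta) || is.null(meta$hx) || is.null(meta$hy) ||
      is.null(meta$hz))
    return(NULL)
  .as_voxel_dims(c(as.numeric(meta$hx), as.numeric(meta$hy),
                   as.numeric(meta$hz)))
}

.dtype_info <- function(dtype) {
  switch(dtype,
    "uint8"   = list(what = "integer", size = 1L, signed = FALSE),
    "uint16"  = list(what = "integer", size = 2L, signed = FALSE),
    "float32" = list(what = "double",  size = 4L, signed = TRUE),
    "float64" = list(what = "double",  size = 8L, signed = TRUE),
    stop(sprintf("unsupported dtype '%s'", dtype)))
}

#' Read a 3D image stack
#'
#' Reads a multi-page TIFF or a RAW binary stack (with its plain-text
#' sidecar) into an [ImageStack-class], normalizing the axis order to
#' \code{(z, y, x)} with the TIFF page index as z.  Voxel dimensions are
#' taken from the sidecar when present, else from the \code{voxelDims}
#' argument; if neither provides them the read fails -- no guessing.
#'
#' @param path file path.
#' @param format \code{"auto"} (by extension), \code{"tiff"} or
#'   \code{"raw"}.
#' @param voxelDims fallback voxel dimensions \code{(hx, hy, hz)} in
#'   micrometres when no metadata is available.
#' @param units fallback intensity units.
#' @return An [ImageStack-class].
#' @seealso [writeStack()]
#' @export
readStack <- function(path, format = c("auto", "tiff", "raw"),
                      voxelDims = NULL, units = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  if (format == "auto") {
    format <- if (grepl("\\.tiff?$", path, ignore.case = TRUE)) "tiff"
              else "raw"
  }
  meta <- .read_sidecar(path)
  vd <- .meta_voxel_dims(meta)
  if (is.null(vd)) {
    if (is.null(voxelDims))
      stop("missing voxel dimensions: none in metadata and no voxelDims given")
    vd <- .as_voxel_dims(voxelDims)
  }
  un <- units %||% meta$units %||% "photon-count"
  if (format == "tiff") {
    pages <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    if (length(pages) < 3L)
      stop("stack must have at least 3 z-planes (2D-only input?)")
    if (any(!vapply(pages, is.matrix, logical(1))))
      stop("only single-channel grayscale TIFF stacks are supported")
    d <- c(length(pages), dim(pages[[1]]))
    v <- array(0, d)
    for (z in seq_len(d[1])) v[z, , ] <- pages[[z]]
    scale <- if (!is.null(meta$scale)) as.numeric(meta$scale) else 1
    v <- v * scale
    if (!is.null(meta$encoding) && meta$encoding == "uint16")
      v <- round(v)
  } else {
    if (is.null(meta))
      stop(sprintf("missing sidecar for raw file: %s", .sidecar_path(path)))
    if (is.null(meta$shape) || is.null(meta$dtype))
      stop("raw sidecar must provide shape and dtype")
    d <- as.integer(strsplit(meta$shape, ",")[[1]])
    if (length(d) != 3L)
      stop("raw shape must be nz,ny,nx (2D-only input?)")
    info <- .dtype_info(meta$dtype)
    endian <- meta$endian %||% "little"
    con <- file(path, "rb")
    on.exit(close(con))
    v <- readBin(con, what = info$what, n = prod(d), size = info$size,
                 signed = info$signed, endian = endian)
    if (length(v) != prod(d)) stop("raw file truncated or corrupt")
    v <- array(as.double(v), d)
  }
  if (any(v < 0)) {
    if (min(v) < -1e-6 * max(abs(v)))
      warning("negative voxel values clipped to zero on read")
    v[v < 0] <- 0
  }
  new("ImageStack", values = v, voxelDims = vd, units = un)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a 3D image stack
#'
#' Writes an [ImageStack-class] as a multi-page TIFF (one page per
#' z-plane) or as RAW binary, always accompanied by the plain-text sidecar
#' carrying shape, dtype, voxel sizes and units, so that
#' \code{readStack(writeStack(x))} restores values and geometry.  RAW is
#' lossless (float64 by default).  TIFF pages are 16-bit unsigned when the
#' values are integers within range (lossless), else 32-bit float scaled
#' by \code{max(values)} (lossless to single precision).
#'
#' @param stack an [ImageStack-class].
#' @param path output file path.
#' @param format \code{"auto"}, \code{"tiff"} or \code{"raw"}.
#' @param dtype RAW sample type: \code{"float64"} (default),
#'   \code{"float32"}, \code{"uint16"} or \code{"uint8"}.
#' @return \code{path}, invisibly.
#' @export
writeStack <- function(stack, path, format = c("auto", "tiff", "raw"),
                       dtype = "float64") {
  stopifnot_stack(stack)
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.tiff?$", path, ignore.case = TRUE)) "tiff"
              else "raw"
  }
  if (!dir.exists(dirname(path)))
    stop(sprintf("directory does not exist: %s", dirname(path)))
  v <- stack@values
  d <- dim(v)
  vd <- stack@voxelDims
  meta <- list(shape = paste(d, collapse = ","),
               hx = format(vd["hx"], digits = 17),
               hy = format(vd["hy"], digits = 17),
               hz = format(vd["hz"], digits = 17),
               units = stack@units)
  if (format == "tiff") {
    integral <- all(v == round(v))
    if (integral && max(v) <= 65535) {
      scale <- 65535
      pages <- lapply(seq_len(d[1]), function(z) v[z, , ] / scale)
      tiff::writeTIFF(pages, path, bits.per.sample = 16L,
                      compression = "none")
      meta$encoding <- "uint16"
    } else {
      scale <- max(v)
      if (scale == 0) scale <- 1
      pages <- lapply(seq_len(d[1]), function(z) v[z, , ] / scale)
      tiff::writeTIFF(pages, path, bits.per.sample = 32L,
                      compression = "none", reduce = FALSE)
      meta$encoding <- "float32"
    }
    meta$scale <- format(scale, digits = 17)
  } else {
    info <- .dtype_info(dtype)
    if (info$what == "integer" && !all(v == round(v)))
      stop("non-integer values cannot be written with an integer dtype")
    meta$dtype <- dtype
    meta$endian <- "little"
    con <- file(path, "wb")
    on.exit(close(con))
    if (info$what == "integer") {
      lim <- if (info$size == 1L) 255L else 65535L
      if (max(v) > lim)
        stop(sprintf("values exceed %s range", dtype))
      iv <- as.integer(v)
      # writeBin stores signed integers; wrap to two's complement so the
      # unsigned read (signed = FALSE) restores the original values
      half <- (lim + 1L) %/% 2L
      iv[iv >= half] <- iv[iv >= half] - lim - 1L
      writeBin(iv, con, size = info$size, endian = "little")
    } else
      writeBin(as.double(v), con, size = info$size, endian = "little")
  }
  .write_sidecar(path, meta)
  invisible(path)
}
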