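#' @include AllClasses.R
NULL

#' Construct an ImageStack
#'
#' @param values 3D numeric array indexed \code{[z, y, x]} of nonnegative,
#'   finite voxel values.
#' @param voxelDims numeric length-3 vector of voxel edge lengths in
#'   micrometres, in the order \code{(hx, hy, hz)}; names are optional.
#' @param units \code{"photon-count"} or \code{"arbitrary-intensity"}.
#' @return An [ImageStack-class] object.
#' @examples
#' s <- ImageStack(array(1, c(3, 4, 4)), c(0.1, 0.1, 0.3))
#' voxelDims(s)
#' @export
ImageStack <- function(values, voxelDims, units = "photon-count") {
  values <- .as_stack_array(values)
  voxelDims <- .as_voxel_dims(voxelDims)
  new("ImageStack", values = values, voxelDims = voxelDims, units = units)
}

.as_stack_array <- function(values) {
  if (is.null(dim(values)) || length(dim(values)) != 3L)
    stop("values must be a 3D array (z, y, x)")
  storage.mode(values) <- "double"
  values
}

.as_voxel_dims <- function(voxelDims) {
  if (length(voxelDims) != 3L)
    stop("voxelDims must have length 3: (hx, hy, hz) in micrometres")
  voxelDims <- as.double(voxelDims)
  names(voxelDims) <- c("hx", "hy", "hz")
  voxelDims
}

#' Accessors for the package's S4 containers
#'
#' \code{stackValues} returns the raw 3D array, \code{voxelDims} the named
#' \code{c(hx=, hy=, hz=)} voxel sizes in micrometres, \code{stackUnits}
#' the intensity units, and \code{mProfiles} the number of bead profiles
#' summed into a PSF.
#'
#' @param x an [ImageStack-class], [PointSpreadFunction-class] or
#'   [VoxelField-class] object.
#' @return See the individual descriptions.
#' @name accessors
#' @aliases stackValues voxelDims stackUnits mProfiles
NULL

#' @rdname accessors
#' @export
setGeneric("stackValues", function(x) standardGeneric("stackValues"))
#' @rdname accessors
#' @export
setGeneric("voxelDims", function(x) standardGeneric("voxelDims"))
#' @rdname accessors
#' @export
setGeneric("stackUnits", function(x) standardGeneric("stackUnits"))
#' @rdname accessors
#' @export
setGeneric("mProfiles", function(x) standardGeneric("mProfiles"))

#' @rdname accessors
setMethod("stackValues", "ImageStack", function(x) x@values)
#' @rdname accessors
setMethod("stackValues", "VoxelField", function(x) x@values)
#' @rdname accessors
setMethod("voxelDims", "ImageStack", function(x) x@voxelDims)
#' @rdname accessors
setMethod("voxelDims", "VoxelField", function(x) x@voxelDims)
#' @rdname accessors
setMethod("stackUnits", "ImageStack", function(x) x@units)
#' @rdname accessors
setMethod("mProfiles", "PointSpreadFunction", function(x) x@mProfiles)

#' Result accessors
#'
#' Accessors for [DeconvolutionResult-class], [DegradedDataset-class],
#' [LambdaGridResult-class] and [InverseRelationFit-class].
#'
#' @param x a result object.
#' @name result-accessors
#' @aliases estimate stopReason iterationsRun recommendedIndex diagTrace
#'   calibrationC truthStack degradedStack datasetPSF lambdaOpt cFit
NULL

#' @rdname result-accessors
#' @export
setGeneric("estimate", function(x) standardGeneric("estimate"))
#' @rdname result-accessors
#' @export
setGeneric("stopReason", function(x) standardGeneric("stopReason"))
#' @rdname result-accessors
#' @export
setGeneric("iterationsRun", function(x) standardGeneric("iterationsRun"))
#' @rdname result-accessors
#' @export
setGeneric("recommendedIndex", function(x) standardGeneric("recommendedIndex"))
#' @rdname result-accessors
#' @export
setGeneric("diagTrace", function(x) standardGeneric("diagTrace"))
#' @rdname result-accessors
#' @export
setGeneric("calibrationC", function(x) standardGeneric("calibrationC"))
#' @rdname result-accessors
#' @export
setGeneric("truthStack", function(x) standardGeneric("truthStack"))
#' @rdname result-accessors
#' @export
setGeneric("degradedStack", function(x) standardGeneric("degradedStack"))
#' @rdname result-accessors
#' @export
setGeneric("datasetPSF", function(x) standardGeneric("datasetPSF"))
#' @rdname result-accessors
#' @export
setGeneric("lambdaOpt", function(x) standardGeneric("lambdaOpt"))
#' @rdname result-accessors
#' @export
setGeneric("cFit", function(x) standardGeneric("cFit"))

#' @rdname result-accessors
setMethod("estimate", "DeconvolutionResult", function(x) x@estimate)
#' @rdname result-accessors
setMethod("stopReason", "DeconvolutionResult", function(x) x@stopReason)
#' @rdname result-accessors
setMethod("iterationsRun", "DeconvolutionResult", function(x) x@iterationsRun)
#' @rdname result-accessors
setMethod("recommendedIndex", "DeconvolutionResult",
  function(x) x@recommendedIndex)
#' @rdname result-accessors
setMethod("diagTrace", "DeconvolutionResult", function(x) x@trace)
#' @rdname result-accessors
setMethod("calibrationC", "DeconvolutionResult", function(x) x@calibrationC)
#' @rdname result-accessors
setMethod("truthStack", "DegradedDataset", function(x) x@truth)
#' @rdname result-accessors
setMethod("degradedStack", "DegradedDataset", function(x) x@degraded)
#' @rdname result-accessors
setMethod("datasetPSF", "DegradedDataset", function(x) x@psf)
#' @rdname result-accessors
setMethod("lambdaOpt", "LambdaGridResult", function(x) x@lambdaOpt)
#' @rdname result-accessors
setMethod("cFit", "InverseRelationFit", function(x) x@cFit)

setMethod("show", "ImageStack", function(object) {
  d <- dim(object@values)
  cat(sprintf("%s: %d x %d x %d voxels (z, y, x), %s\n",
              class(object), d[1], d[2], d[3], object@units))
  cat(sprintf("  voxel size: %.4g x %.4g x %.4g um (hx, hy, hz)\n",
              object@voxelDims["hx"], object@voxelDims["hy"],
              object@voxelDims["hz"]))
  cat(sprintf("  value range: [%.4g, %.4g], total intensity %.6g\n",
              min(object@values), max(object@values), sum(object@values)))
  if (is(object, "PointSpreadFunction"))
    cat(sprintf("  summed bead profiles (M): %d\n", object@mProfiles))
  invisible(object)
})

setMethod("show", "SnrEstimate", function(object) {
  cat(sprintf("Peak SNR estimate: %.4g (peak mean %.6g counts, %s)\n",
              object@snr, object@peakMean, object@convention))
  invisible(object)
})

setMethod("show", "DeconvolutionResult", function(object) {
  cat(sprintf("DeconvolutionResult: %d iterations, stop reason '%s'\n",
              object@iterationsRun, object@stopReason))
  cat(sprintf("  recommended estimate: iteration %d\n",
              object@recommendedIndex))
  if (!is.na(object@calibrationC))
    cat(sprintf("  lambda_lsq calibration C: %.6g\n", object@calibrationC))
  if (nrow(object@trace) > 0) {
    last <- object@trace[nrow(object@trace), ]
    cat(sprintf("  last step: lambda %.4g, tau1 %.4g\n",
                last$lambda, last$tau1))
  }
  invisible(object)
})

setMethod("show", "DegradedDataset", function(object) {
  d <- dim(object@truth@values)
  cat(sprintf("DegradedDataset: %d x %d x %d, target peak SNR %.4g, scale %.6g, seed %d\n",
              d[1], d[2], d[3], object@targetSnr, object@scale, object@seed))
  invisible(object)
})

setMethod("show", "LambdaGridResult", function(object) {
  cat(sprintf("LambdaGridResult (SNR %.4g): %d lambda values, lambda_opt %.4g\n",
              object@snr, length(object@lambdaGrid), object@lambdaOpt))
  invisible(object)
})

setMethod("show", "InverseRelationFit", function(object) {
  cat(sprintf("InverseRelationFit: lambda_opt = %.4g / SNR (%d SNR levels)\n",
              object@cFit, nrow(object@pairs)))
  invisible(object)
})
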