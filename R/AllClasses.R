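#' @import methods
#' @importFrom Rcpp sourceCpp
#' @useDynLib rltv, .registration = TRUE
NULL

.stack_units <- c("photon-count", "arbitrary-intensity")

#' ImageStack: a 3D fluorescence image stack
#'
#' The central data container of the package: a 3D array of nonnegative
#' voxel values indexed \code{[z, y, x]} together with the physical voxel
#' dimensions in micrometres.  It holds recorded images \code{i}, objects
#' \code{o} and deconvolution estimates alike.
#'
#' @slot values 3D numeric array, dimensions \code{(nz, ny, nx)}; all
#'   entries finite and >= 0.
#' @slot voxelDims named numeric vector \code{c(hx=, hy=, hz=)}, the voxel
#'   edge lengths in micrometres along the fast in-plane axis (x), the
#'   second in-plane axis (y) and the optical axis (z).
#' @slot units either \code{"photon-count"} (each voxel is a photon count,
#'   Poisson statistics exact) or \code{"arbitrary-intensity"}.
#'
#' @seealso [ImageStack()] for the user constructor, [stackValues()],
#'   [voxelDims()], [stackUnits()].
#' @exportClass ImageStack
setClass("ImageStack",
  representation(values = "array", voxelDims = "numeric", units = "character"))

setValidity("ImageStack", function(object) {
  v <- object@values
  d <- object@voxelDims
  if (length(dim(v)) != 3L)
    return("values must be a 3D array (z, y, x)")
  if (any(dim(v) < 3L))
    return("stack must have at least 3 voxels along every axis")
  if (!all(is.finite(v)))
    return("all voxel values must be finite")
  if (any(v < 0))
    return("all voxel values must be nonnegative")
  if (length(d) != 3L || !identical(names(d), c("hx", "hy", "hz")))
    return("voxelDims must be a named numeric vector c(hx=, hy=, hz=)")
  if (!all(is.finite(d)) || any(d <= 0))
    return("voxel dimensions must be strictly positive and finite")
  if (length(object@units) != 1L || !(object@units %in% .stack_units))
    return(sprintf("units must be one of: %s",
                   paste(.stack_units, collapse = ", ")))
  TRUE
})

#' PointSpreadFunction: a normalized 3D blur kernel
#'
#' An [ImageStack] normalized to unit sum with odd extent along every axis
#' (so the centre voxel is well defined).  \code{mProfiles} records how many
#' bead profiles were summed to estimate it (0 for synthetic PSFs).
#'
#' @slot mProfiles integer, number of summed microsphere profiles.
#' @seealso [syntheticPSF()], [extractAndSumProfiles()], [resamplePSF()].
#' @exportClass PointSpreadFunction
setClass("PointSpreadFunction", contains = "ImageStack",
  representation(mProfiles = "integer"))

setValidity("PointSpreadFunction", function(object) {
  v <- object@values
  if (any(dim(v) %% 2L == 0L))
    return("PSF extent must be odd along every axis")
  s <- sum(v)
  if (abs(s - 1) > 1e-9)
    return(sprintf("PSF must be normalized to unit sum (got %.12g)", s))
  if (length(object@mProfiles) != 1L || is.na(object@mProfiles) ||
      object@mProfiles < 0L)
    return("mProfiles must be a single nonnegative integer")
  TRUE
})

#' VoxelField: a signed per-voxel field
#'
#' Same geometry as the [ImageStack] it was derived from, but values may be
#' negative; used for the TV divergence field div(grad o / |grad o|).
#'
#' @exportClass VoxelField
setClass("VoxelField",
  representation(values = "array", voxelDims = "numeric"))

setValidity("VoxelField", function(object) {
  if (length(dim(object@values)) != 3L)
    return("values must be a 3D array")
  if (!all(is.finite(object@values)))
    return("all field values must be finite")
  TRUE
})

#' SnrEstimate: Poisson peak signal-to-noise estimate
#'
#' @slot snr dimensionless peak SNR.
#' @slot peakMean maximum of the 3x3x3-averaged image, in photon counts.
#' @slot convention \code{"sqrt-of-mean"} (snr = sqrt(peakMean), the
#'   Poisson mean/sigma reading) or \code{"mean"} (snr = peakMean).
#' @exportClass SnrEstimate
setClass("SnrEstimate",
  representation(snr = "numeric", peakMean = "numeric", convention = "character"))

setValidity("SnrEstimate", function(object) {
  if (object@peakMean <= 0 || object@snr <= 0)
    return("snr and peakMean must be positive")
  if (!(object@convention %in% c("sqrt-of-mean", "mean")))
    return("convention must be 'sqrt-of-mean' or 'mean'")
  if (object@convention == "sqrt-of-mean" &&
      abs(object@snr^2 - object@peakMean) >
        1e-8 * max(1, object@peakMean))
    return("under sqrt-of-mean convention snr^2 must equal peakMean")
  TRUE
})

#' DeconvolutionResult: outcome of an RL-TV deconvolution run
#'
#' @slot estimate the returned [ImageStack] estimate.
#' @slot stopReason one of \code{"converged-window"} (the lambda-trace
#'   stopping rule fired), \code{"aborted-negative"} (the multiplicative
#'   update produced a negative voxel and the previous estimate was kept),
#'   \code{"max-iterations"}.
#' @slot iterationsRun number of completed iterations.
#' @slot recommendedIndex iteration at which the stopping rule fired (equal
#'   to \code{iterationsRun} for the lambda-trace rule).
#' @slot trace data.frame with one row per completed iteration: columns
#'   \code{iteration}, \code{lambda}, \code{tau1}, \code{tau2}, \code{mse}.
#'   \code{tau1[s]} is the relative change from iterate s-1 to s,
#'   \code{tau2[s]} the relative change from iterate s-2 to s (NA where
#'   undefined); \code{mse} is NA unless a ground truth was supplied.
#' @slot calibrationC the constant C of the lambda_lsq estimator (NA for
#'   fixed-lambda runs).
#' @exportClass DeconvolutionResult
setClass("DeconvolutionResult",
  representation(estimate = "ImageStack", stopReason = "character",
    iterationsRun = "integer", recommendedIndex = "integer",
    trace = "data.frame", calibrationC = "numeric"))

#' DegradedDataset: a simulated ground-truth / degraded image pair
#'
#' The synthetic stand-in for a recorded photon-counting image: a known
#' object blurred with a PSF, scaled so the 3x3x3-averaged blurred maximum
#' equals SNR^2, and Poisson sampled.
#'
#' @slot truth ground-truth object (arbitrary intensity units).
#' @slot degraded Poisson-sampled photon-count stack.
#' @slot psf the [PointSpreadFunction] used for blurring.
#' @slot targetSnr target peak SNR of the degraded stack.
#' @slot scale intensity multiplier applied to the blurred truth before
#'   Poisson sampling.
#' @slot seed RNG seed used.
#' @exportClass DegradedDataset
setClass("DegradedDataset",
  representation(truth = "ImageStack", degraded = "ImageStack",
    psf = "PointSpreadFunction", targetSnr = "numeric", scale = "numeric",
    seed = "integer"))

#' LambdaGridResult: lambda grid search summary
#'
#' @slot snr peak SNR of the dataset searched.
#' @slot lambdaGrid the grid of fixed lambda values.
#' @slot minMse per-lambda minimum MSE over iterations.
#' @slot stepsToMin per-lambda iteration index of the minimum MSE.
#' @slot lambdaOpt grid argmin of \code{minMse} (ties broken toward the
#'   smaller lambda).
#' @exportClass LambdaGridResult
setClass("LambdaGridResult",
  representation(snr = "numeric", lambdaGrid = "numeric", minMse = "numeric",
    stepsToMin = "integer", lambdaOpt = "numeric"))

setValidity("LambdaGridResult", function(object) {
  n <- length(object@lambdaGrid)
  if (length(object@minMse) != n || length(object@stepsToMin) != n)
    return("minMse and stepsToMin must match the grid length")
  if (!(object@lambdaOpt %in% object@lambdaGrid))
    return("lambdaOpt must be a grid member")
  TRUE
})

#' InverseRelationFit: origin-constrained fit of lambda_opt = C / SNR
#'
#' @slot pairs data.frame with columns \code{snr}, \code{lambdaOpt}.
#' @slot cFit fitted constant C.
#' @slot residuals per-pair residuals lambdaOpt - cFit/snr.
#' @exportClass InverseRelationFit
setClass("InverseRelationFit",
  representation(pairs = "data.frame", cFit = "numeric",
    residuals = "numeric"))

setValidity("InverseRelationFit", function(object) {
  if (object@cFit <= 0) return("cFit must be positive")
  TRUE
})
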