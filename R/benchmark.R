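#' @include AllGenerics.R
NULL

#' Fixed-lambda grid search for the optimal TV parameter
#'
#' Deconvolves a degraded dataset once per grid value with fixed lambda,
#' tracking the MSE against the known truth each iteration, and reports the
#' per-lambda minimal MSE, the step at which it is attained, and the grid
#' argmin \code{lambda_opt} (ties broken toward the smaller lambda: weaker
#' regularization is preferred at equal error).  Runs that abort on
#' negativity report the minimum over their completed steps (the MSE of
#' the input image if no step completed).
#'
#' @param dataset a [DegradedDataset-class].
#' @param lambda_grid nonempty vector of lambda values >= 0.
#' @param max_iter iteration cap per run.
#' @param pad_mode convolution boundary handling (default \code{"none"},
#'   matching [degradeStack()]).
#' @param patience early-exit patience for the MSE trace (see
#'   [deconvolve()]); \code{Inf} disables.
#' @return A [LambdaGridResult-class].
#' @export
lambdaGridSearch <- function(dataset, lambda_grid, max_iter = 60L,
                             pad_mode = c("none", "reflect"),
                             patience = 15L) {
  if (!is(dataset, "DegradedDataset"))
    stop("dataset must be a DegradedDataset")
  pad_mode <- match.arg(pad_mode)
  if (length(lambda_grid) == 0 || any(lambda_grid < 0))
    stop("lambda_grid must be nonempty with values >= 0")
  mse0 <- imageMSE(dataset@truth,
                   dataset@degraded@values / dataset@scale)
  min_mse <- numeric(length(lambda_grid))
  steps <- integer(length(lambda_grid))
  for (k in seq_along(lambda_grid)) {
    res <- deconvolve(dataset@degraded, dataset@psf,
                      lambda = lambda_grid[k], max_iterations = max_iter,
                      pad_mode = pad_mode, truth = .scaled_truth(dataset),
                      patience = patience)
    tr <- res@trace
    if (nrow(tr) == 0) {           # aborted before completing a step
      min_mse[k] <- mse0
      steps[k] <- 0L
    } else {
      min_mse[k] <- min(tr$mse)
      steps[k] <- which.min(tr$mse)
    }
  }
  # argmin with ties resolved toward the smaller lambda
  ord <- order(lambda_grid)
  opt <- lambda_grid[ord][which.min(min_mse[ord])]
  new("LambdaGridResult", snr = dataset@targetSnr,
      lambdaGrid = as.double(lambda_grid), minMse = min_mse,
      stepsToMin = steps, lambdaOpt = opt)
}

# Truth expressed in the photon-count scale of the degraded image, so that
# MSE (normalized by max) compares like with like.
.scaled_truth <- function(dataset) {
  new("ImageStack", values = dataset@truth@values * dataset@scale,
      voxelDims = dataset@truth@voxelDims, units = "arbitrary-intensity")
}

#' Fit the inverse relation lambda_opt = C / SNR
#'
#' Origin-constrained least squares of grid-search optima against 1/SNR
#' across noise levels; the reference value of the constant is about 50.
#'
#' @param results list of [LambdaGridResult-class] objects at >= 3
#'   distinct SNR levels.
#' @return An [InverseRelationFit-class].
#' @export
fitInverseRelation <- function(results) {
  if (is(results, "LambdaGridResult")) results <- list(results)
  snr <- vapply(results, function(r) r@snr, numeric(1))
  lam <- vapply(results, function(r) r@lambdaOpt, numeric(1))
  if (length(unique(snr)) < 3)
    stop("need lambda_opt at >= 3 distinct SNR levels")
  x <- 1 / snr
  c_fit <- sum(x * lam) / sum(x * x)
  new("InverseRelationFit",
      pairs = data.frame(snr = snr, lambdaOpt = lam),
      cFit = c_fit, residuals = lam - c_fit * x)
}

#' Oscillation diagnostic tau2/tau1 along a fixed-lambda run
#'
#' Runs a fixed-lambda deconvolution and reports, for each iteration s at
#' which both are defined, \code{tau1(s) = ||o_(s+1)-o_s||/||o_s||} and
#' \code{tau2(s) = ||o_(s+2)-o_s||/||o_s||} and their ratio.  A ratio
#' stabilizing below 1 indicates oscillation between successive estimates
#' (stationary MSE under near-optimal regularization); a ratio above 1
#' indicates progressive drift, as in unregularized RL on noisy data.
#'
#' @param dataset a [DegradedDataset-class].
#' @param lambda fixed TV parameter.
#' @param max_iter iterations to run (>= 3).
#' @param pad_mode convolution boundary handling.
#' @return data.frame with columns \code{s}, \code{tau1}, \code{tau2},
#'   \code{ratio}.
#' @export
oscillationTrace <- function(dataset, lambda, max_iter = 60L,
                             pad_mode = c("none", "reflect")) {
  if (!is(dataset, "DegradedDataset"))
    stop("dataset must be a DegradedDataset")
  pad_mode <- match.arg(pad_mode)
  if (max_iter < 3) stop("max_iter must be >= 3")
  res <- deconvolve(dataset@degraded, dataset@psf, lambda = lambda,
                    max_iterations = max_iter, pad_mode = pad_mode)
  .oscillation_from_trace(res@trace)
}

# tau1[k] in the trace is anchored at iterate k-1; tau2[k] at iterate k-2.
# The ratio at anchor s therefore combines tau2[s+2] with tau1[s+1].
.oscillation_from_trace <- function(tr) {
  n <- nrow(tr)
  if (n < 2) return(data.frame(s = integer(0), tau1 = numeric(0),
                               tau2 = numeric(0), ratio = numeric(0)))
  s <- 0:(n - 2)
  tau1 <- tr$tau1[s + 1]
  tau2 <- tr$tau2[s + 2]
  data.frame(s = s, tau1 = tau1, tau2 = tau2, ratio = tau2 / tau1)
}

#' Evaluate the lambda-trace stopping criterion against the MSE optimum
#'
#' Runs the automatic-lambda deconvolution with truth tracking and
#' summarizes how the stopped estimate compares with the best estimate on
#' the same trajectory.
#'
#' @param dataset a [DegradedDataset-class].
#' @param max_iter iteration cap.
#' @param stop_window steps past the lambda_lsq maximum (default 5).
#' @param pad_mode convolution boundary handling.
#' @param extra_iterations if > 0, the run is continued this many
#'   iterations past the stopping point (ignoring the criterion) and the
#'   over-iterated MSE is reported too.
#' @return list with \code{stop_index}, \code{lambda_max_index},
#'   \code{mse_at_stop}, \code{min_mse}, \code{min_mse_index},
#'   \code{ratio} (stop MSE over trajectory minimum), \code{stop_reason},
#'   and when requested \code{mse_overrun}.
#' @export
stoppingCriterionReport <- function(dataset, max_iter = 60L, stop_window = 5L,
                                    pad_mode = c("none", "reflect"),
                                    extra_iterations = 0L) {
  if (!is(dataset, "DegradedDataset"))
    stop("dataset must be a DegradedDataset")
  pad_mode <- match.arg(pad_mode)
  truth <- .scaled_truth(dataset)
  res <- deconvolve(dataset@degraded, dataset@psf, lambda = "auto",
                    max_iterations = max_iter, stop_window = stop_window,
                    pad_mode = pad_mode, truth = truth)
  tr <- res@trace
  out <- list(stop_index = res@recommendedIndex,
              lambda_max_index = if (nrow(tr)) which.max(tr$lambda)
                                 else NA_integer_,
              mse_at_stop = if (nrow(tr)) tr$mse[res@recommendedIndex]
                            else NA_real_,
              min_mse = if (nrow(tr)) min(tr$mse) else NA_real_,
              min_mse_index = if (nrow(tr)) which.min(tr$mse)
                              else NA_integer_,
              stop_reason = res@stopReason)
  out$ratio <- out$mse_at_stop / out$min_mse
  if (extra_iterations > 0 && res@stopReason == "converged-window") {
    over <- deconvolve(dataset@degraded, dataset@psf, lambda = "auto",
                       max_iterations = res@recommendedIndex +
                         as.integer(extra_iterations),
                       stop_window = max_iter + extra_iterations,
                       pad_mode = pad_mode, truth = truth)
    otr <- over@trace
    out$mse_overrun <- otr$mse[nrow(otr)]
  }
  out
}
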