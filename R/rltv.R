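#' @include AllGenerics.R
NULL

# Length-unit factor applied to voxel dimensions (stored in um) before they
# enter the TV stencil.  The lambda scale of the engine is tied to this
# choice: with spacings in nm, typical |div| values on photon-counting data
# sit in the 0.01-0.1 range, which is what makes lambda ~ 50/SNR (a few
# units at usual SNRs) a stable, near-optimal setting of the multiplicative
# update's denominator 1 - lambda*div.  See the methods vignette.
.TV_SPACING_PER_UM <- 1000

.tv_spacing <- function(stack) stack@voxelDims * .TV_SPACING_PER_UM

# --- relative change and MSE ------------------------------------------------

#' Relative L2 change between two estimates
#'
#' \code{tau = ||b - a||_2 / ||a||_2} over all voxels; the convergence
#' diagnostic tau_d compares iterates d steps apart.
#'
#' @param a,b [ImageStack-class] objects (or bare arrays) of equal shape.
#' @return Nonnegative scalar.
#' @export
relativeChange <- function(a, b) {
  av <- if (is(a, "ImageStack")) a@values else a
  bv <- if (is(b, "ImageStack")) b@values else b
  if (!identical(dim(av), dim(bv))) stop("shapes differ")
  na <- l2norm(av)
  if (na == 0) stop("reference estimate has zero norm")
  l2norm(bv - av) / na
}

#' Mean squared error between truth and estimate
#'
#' With \code{normalize = TRUE} (default) both images are first divided by
#' \code{max(truth)}, making the error scale-free; this is the
#' restoration-quality metric used throughout the benchmark protocol.
#'
#' @param truth,estimate [ImageStack-class] objects (or bare arrays) of
#'   equal shape.
#' @param normalize divide both by \code{max(truth)} first.
#' @return Nonnegative scalar.
#' @export
imageMSE <- function(truth, estimate, normalize = TRUE) {
  tv <- if (is(truth, "ImageStack")) truth@values else truth
  ev <- if (is(estimate, "ImageStack")) estimate@values else estimate
  if (!identical(dim(tv), dim(ev))) stop("shapes differ")
  if (normalize) {
    m <- max(tv)
    if (m == 0) stop("cannot normalize: max(truth) == 0")
    tv <- tv / m
    ev <- ev / m
  }
  mean((ev - tv)^2)
}

# --- internal context -------------------------------------------------------
# ctx bundles everything the inner loop needs: the recorded image, the FFT
# plan with precomputed OTF, TV spacings (nm) and the epsilon.

.make_ctx <- function(image, psf, pad_mode, epsilon_tv = NULL) {
  a <- image@values
  eps <- epsilon_tv
  if (is.null(eps)) {
    rng <- max(a) - min(a)
    eps <- if (rng > 0) 1e-9 * rng else 1e-12
  }
  list(image = a,
       plan = .make_conv_plan(dim(a), psf@values, pad_mode),
       spacing = .tv_spacing(image),
       eps_abs = eps)
}

.rl_correction <- function(ctx, o) {
  blur <- .plan_convolve(ctx$plan, o)
  tol <- 1e-12 * max(abs(blur))
  ratio <- ifelse(blur > tol, ctx$image / blur, 0)
  .plan_convolve(ctx$plan, ratio, adjoint = TRUE)
}

.tv_field <- function(ctx, o) {
  .tv_divergence_cpp(o, dim(o), ctx$spacing[1], ctx$spacing[2],
                     ctx$spacing[3], ctx$eps_abs)
}

.lambda_raw <- function(ctx, o, corr = NULL, d = NULL, warn = TRUE) {
  if (is.null(corr)) corr <- .rl_correction(ctx, o)
  if (is.null(d)) d <- .tv_field(ctx, o)
  dd <- sum(d * d)
  if (dd == 0) {
    if (warn) warning("TV force is identically zero; returning lambda = 0")
    return(0)
  }
  sum((1 - corr) * d) / dd
}

# --- exported single-step / estimator interfaces ---------------------------

#' One multiplicative RL-TV iteration
#'
#' Applies the multiplicative gradient-type update
#' \deqn{o^{(s+1)} = \frac{\left[\left(i / (o^{(s)} \otimes h)\right)
#'   \otimes h^*\right] o^{(s)}}{1 - \lambda\,
#'   \mathrm{div}(\nabla o^{(s)}/|\nabla o^{(s)}|)}}
#' voxelwise.  Voxels where the blurred estimate vanishes contribute ratio 0
#' (support preservation).  If the denominator crosses zero anywhere the new
#' estimate would turn negative; the step then aborts, signalling an
#' unstable choice of \code{lambda}, and the previous estimate is retained.
#'
#' @param estimate current nonnegative estimate ([ImageStack-class]).
#' @param image recorded image ([ImageStack-class]).
#' @param psf [PointSpreadFunction-class] resampled to the image grid.
#' @param lambda TV regularization parameter (>= 0).
#' @param epsilon_tv absolute TV magnitude regularization; default
#'   \code{1e-9 * range(image)}.
#' @param pad_mode convolution boundary handling, see [fftConvolve()].
#' @return list with \code{estimate} (an [ImageStack-class]) and logical
#'   \code{aborted}.
#' @export
rlStep <- function(estimate, image, psf, lambda = 0, epsilon_tv = NULL,
                   pad_mode = c("reflect", "none")) {
  stopifnot_stack(estimate, "estimate"); stopifnot_stack(image, "image")
  pad_mode <- match.arg(pad_mode)
  if (!is.numeric(lambda) || lambda < 0) stop("lambda must be >= 0")
  ctx <- .make_ctx(image, psf, pad_mode, epsilon_tv)
  o <- estimate@values
  corr <- .rl_correction(ctx, o)
  denom <- if (lambda > 0) 1 - lambda * .tv_field(ctx, o) else 1
  newo <- corr * o / denom
  if (any(newo < 0))
    return(list(estimate = estimate, aborted = TRUE))
  list(estimate = new("ImageStack", values = newo,
                      voxelDims = image@voxelDims, units = image@units),
       aborted = FALSE)
}

#' Least-squares estimate of the TV regularization parameter
#'
#' At iterate \code{o}, writes the Euler-Lagrange residual of the
#' regularized maximum-likelihood equation as \code{r - lambda*d}, with
#' \code{r = 1 - (i/(o (*) h)) (*) h*} its lambda-free part and
#' \code{d = div(grad o/|grad o|)} the TV field, and minimizes
#' \code{F(lambda) = sum_v (r_v - lambda d_v)^2}, giving
#' \code{lambda_raw = sum(r*d)/sum(d^2)}.  The returned value is
#' \code{C * lambda_raw}: formally \code{C = 1}, but on the first iteration
#' C is calibrated so that \code{C * lambda_raw = 50/SNR}, the empirically
#' near-optimal first-iteration value.
#'
#' @param estimate current estimate ([ImageStack-class]).
#' @param image recorded image.
#' @param psf [PointSpreadFunction-class].
#' @param snr peak SNR of the recorded image ([SnrEstimate-class] or a
#'   positive number); required when \code{calibrate = TRUE}.
#' @param C calibration constant from a previous calibrated call.
#' @param calibrate logical; treat this call as the first iteration and
#'   derive C from \code{snr}.
#' @param epsilon_tv,pad_mode see [rlStep()].
#' @return list with \code{lambda} (clamped at 0) and \code{C}.
#' @export
estimateLambdaLsq <- function(estimate, image, psf, snr = NULL, C = NULL,
                              calibrate = is.null(C), epsilon_tv = NULL,
                              pad_mode = c("reflect", "none")) {
  stopifnot_stack(estimate, "estimate"); stopifnot_stack(image, "image")
  pad_mode <- match.arg(pad_mode)
  ctx <- .make_ctx(image, psf, pad_mode, epsilon_tv)
  raw <- .lambda_raw(ctx, estimate@values)
  if (calibrate) {
    sv <- if (is(snr, "SnrEstimate")) snr@snr else snr
    if (is.null(sv) || !is.numeric(sv) || sv <= 0)
      stop("a positive SNR is required to calibrate C")
    C <- if (raw != 0) (50 / sv) / raw else 1
  }
  list(lambda = max(0, C * raw), C = C)
}

# --- full deconvolution -----------------------------------------------------

#' Regularized Richardson-Lucy deconvolution
#'
#' Runs the RL-TV iteration from \code{o^(0) = i} with either a fixed TV
#' regularization parameter (\code{lambda} numeric) or the automatic
#' per-iteration least-squares estimate (\code{lambda = "auto"}, calibrated
#' so the first-iteration value is 50/SNR).
#'
#' Stopping, in order of precedence:
#' \enumerate{
#'   \item negativity abort: the multiplicative update produced a negative
#'     voxel; the last nonnegative estimate is returned
#'     (\code{"aborted-negative"});
#'   \item lambda-trace rule (auto mode only): the iteration stops
#'     \code{stop_window} (default 5) steps after the running maximum of
#'     the lambda_lsq trace, returning the estimate at the stopping
#'     iteration (\code{"converged-window"});
#'   \item with a finite \code{patience} and \code{truth} given, a
#'     fixed-lambda run stops once the tracked MSE has not improved for
#'     \code{patience} consecutive iterations (\code{"patience-mse"}; the
#'     trajectory minimum is then bracketed -- used by the benchmark grid
#'     searches);
#'   \item \code{max_iterations} reached (\code{"max-iterations"}).
#' }
#'
#' @param image recorded [ImageStack-class] (photon counts for auto mode).
#' @param psf [PointSpreadFunction-class] resampled to the image grid.
#' @param lambda \code{"auto"} or a fixed value >= 0.
#' @param max_iterations iteration cap S.
#' @param stop_window steps to continue past the lambda_lsq maximum.
#' @param epsilon_tv TV magnitude regularization (absolute); default
#'   \code{1e-9 * range(image)}.
#' @param pad_mode convolution boundary handling, see [fftConvolve()].
#' @param truth optional ground-truth [ImageStack-class]; when given, the
#'   per-iteration normalized MSE is recorded in the trace.
#' @param snr peak SNR used to calibrate the auto-lambda constant C;
#'   default \code{estimatePeakSNR(image)}.
#' @param lambda_freeze if TRUE (ablation mode) the auto lambda is
#'   estimated once at the first iteration and then held fixed.
#' @param patience see stopping rules above; default \code{Inf}.
#' @return A [DeconvolutionResult-class].
#' @examples
#' psf <- syntheticPSF(c(0.136, 0.136, 0.707), c(5, 7, 7), 0.15, 0.45)
#' o <- generatePhantom(texture = "blocky", shape = c(12, 32, 32),
#'                      dims = c(0.136, 0.136, 0.707), seed = 1)
#' ds <- degradeStack(o, psf, target_snr = 20, seed = 1)
#' res <- deconvolve(degradedStack(ds), psf, lambda = "auto",
#'                   max_iterations = 15, truth = truthStack(ds))
#' res
#' @export
deconvolve <- function(image, psf, lambda = "auto", max_iterations = 50,
                       stop_window = 5, epsilon_tv = NULL,
                       pad_mode = c("reflect", "none"), truth = NULL,
                       snr = NULL, lambda_freeze = FALSE, patience = Inf) {
  stopifnot_stack(image, "image")
  if (!is(psf, "PointSpreadFunction"))
    stop("psf must be a PointSpreadFunction")
  pad_mode <- match.arg(pad_mode)
  auto <- identical(lambda, "auto")
  if (!auto && (!is.numeric(lambda) || length(lambda) != 1L || lambda < 0))
    stop("lambda must be \"auto\" or a single number >= 0")
  if (max_iterations < 1 || stop_window < 1)
    stop("max_iterations and stop_window must be >= 1")

  ctx <- .make_ctx(image, psf, pad_mode, epsilon_tv)
  snr_val <- NA_real_
  if (auto) {
    snr_val <- if (is(snr, "SnrEstimate")) snr@snr
               else if (is.numeric(snr)) snr
               else estimatePeakSNR(image)@snr
  }
  track <- !is.null(truth)
  if (track) {
    tmax <- max(truth@values)
    if (tmax == 0) stop("truth is all zero")
    tnorm <- truth@values / tmax
  }

  o <- ctx$image                 # o^(0) = i
  o_prev <- NULL                 # o^(s-2) at diagnostic time
  Ccal <- NA_real_
  lam_auto <- NA_real_
  lam_trace <- tau1 <- tau2 <- mse_trace <- numeric(0)
  status <- "max-iterations"
  iter <- 0L
  mse_best <- Inf
  mse_best_at <- 0L

  while (iter < max_iterations) {
    corr <- .rl_correction(ctx, o)
    need_d <- auto || lambda > 0
    d <- if (need_d) .tv_field(ctx, o) else NULL
    if (auto && (iter == 0L || !lambda_freeze)) {
      raw <- .lambda_raw(ctx, o, corr = corr, d = d, warn = FALSE)
      if (iter == 0L) Ccal <- if (raw != 0) (50 / snr_val) / raw else 1
      lam_auto <- max(0, Ccal * raw)
    }
    lam <- if (auto) lam_auto else lambda
    denom <- if (lam > 0) 1 - lam * d else 1
    newo <- corr * o / denom
    if (any(newo < 0)) {
      status <- "aborted-negative"
      break
    }
    iter <- iter + 1L
    lam_trace[iter] <- lam
    tau1[iter] <- l2norm(newo - o) / l2norm(o)
    tau2[iter] <- if (iter >= 2L) l2norm(newo - o_prev) / l2norm(o_prev)
                  else NA_real_
    if (track) {
      mse_trace[iter] <- mean((newo / tmax - tnorm)^2)
      if (mse_trace[iter] < mse_best) {
        mse_best <- mse_trace[iter]
        mse_best_at <- iter
      }
    } else mse_trace[iter] <- NA_real_
    o_prev <- o
    o <- newo
    if (auto && iter - which.max(lam_trace) >= stop_window) {
      status <- "converged-window"
      break
    }
    if (track && is.finite(patience) && iter - mse_best_at >= patience) {
      status <- "patience-mse"
      break
    }
  }

  trace <- data.frame(iteration = seq_len(iter), lambda = lam_trace,
                      tau1 = tau1, tau2 = tau2, mse = mse_trace)
  new("DeconvolutionResult",
      estimate = new("ImageStack", values = o, voxelDims = image@voxelDims,
                     units = image@units),
      stopReason = status, iterationsRun = iter,
      recommendedIndex = iter, trace = trace, calibrationC = Ccal)
}
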