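#' Sparse hemodynamic deconvolution of a single voxel time series
#'
#' Recovers a piecewise-constant activity-inducing signal `s` from a BOLD
#' series `y` by minimising `0.5 * ||y - H s||^2 + lam * ||D s||_1`, where
#' `H` is causal convolution with the HRF kernel and `D` the first
#' difference. Solved by FISTA with an exact total-variation proximal step;
#' a step that would increase the objective falls back to a plain proximal
#' gradient step from the previous iterate, so the objective trace is
#' non-increasing.
#'
#' @param series numeric BOLD time series (longer than the kernel).
#' @param kernel HRF kernel from [hrf_kernel()].
#' @param lam regularisation weight (>= 0).
#' @param max_iter iteration cap.
#' @param tol relative objective-change stopping tolerance.
#' @return list with `activity`, `innovations` (first differences, first
#'   entry 0), `objective_trace`, and `iterations`.
#' @export
deconvolve_voxel <- function(series, kernel, lam, max_iter = 500, tol = 1e-5) {
  if (anyNA(series)) stop("`series` contains NA/NaN", call. = FALSE)
  if (length(series) <= length(kernel)) {
    stop("`series` must be longer than the kernel", call. = FALSE)
  }
  if (lam < 0) stop("`lam` must be >= 0", call. = FALSE)
  fit <- .fista_tv_cpp(as.numeric(series), as.numeric(kernel), lam,
                       as.integer(max_iter), tol)
  list(activity = fit$activity,
       innovations = c(0, diff(fit$activity)),
       objective_trace = fit$objective_trace,
       iterations = fit$iterations)
}

#' Robust noise SD estimate from first differences
#'
#' `median(|d - median(d)|) / 0.6745 / sqrt(2)` with `d = diff(y)`: the MAD
#' of the differenced series rescaled to the SD of the underlying white
#' noise (differencing doubles the variance, hence the `sqrt(2)`).
#'
#' @param series numeric time series.
#' @return estimated noise SD.
#' @export
estimate_noise_sd <- function(series) {
  d <- diff(series)
  median(abs(d - median(d))) / 0.6745 / sqrt(2)
}

#' Deconvolve every in-mask voxel of a session
#'
#' Applies [deconvolve_voxel()] voxel-wise with a per-voxel weight
#' `lam_v = lambda_factor * sigma_v * sqrt(T)`, `sigma_v` the robust noise
#' estimate of [estimate_noise_sd()]. Voxels outside the mask are skipped.
#'
#' @param session a `bold_session`.
#' @param mask logical array; defaults to the session mask.
#' @param lambda_factor scale on the noise-calibrated weight (default 1).
#' @param kernel HRF kernel; default `hrf_kernel(session$tr)`.
#' @param max_iter,tol solver controls as in [deconvolve_voxel()].
#' @param subject,session_id provenance labels carried to transient selection.
#' @return object of class `innovation_set`: `activity` and `innovations`
#'   (voxel x time, masked voxels only, in array order), `lambda_used`,
#'   `iterations`, `objective` per voxel, `max_objective_increase`
#'   (monotonicity diagnostic), `mask`, `scrub_mask`, `tr`, and provenance.
#' @export
deconvolve_session <- function(session, mask = session$mask,
                               lambda_factor = 1,
                               kernel = hrf_kernel(session$tr),
                               max_iter = 500, tol = 1e-5,
                               subject = "sub01", session_id = "ses1") {
  stopifnot(inherits(session, "bold_session"))
  if (!all(dim(mask) == dim(session$bold)[1:3])) {
    stop("mask does not match the session grid", call. = FALSE)
  }
  if (!any(mask)) stop("empty mask", call. = FALSE)
  Y <- t(session_matrix(session, mask))  # T x V
  T <- nrow(Y)
  sig <- apply(Y, 2, estimate_noise_sd)
  lam <- lambda_factor * sig * sqrt(T)
  fit <- .fista_tv_mat_cpp(Y, as.numeric(kernel), lam,
                           as.integer(max_iter), tol)
  activity <- t(fit$activity)  # V x T
  innovations <- cbind(0, t(apply(activity, 1, diff)))
  structure(
    list(activity = activity, innovations = innovations,
         lambda_used = lam, iterations = fit$iterations,
         objective = fit$objective,
         max_objective_increase = fit$max_objective_increase,
         mask = mask, scrub_mask = session$scrub_mask, tr = session$tr,
         subject = subject, session_id = session_id),
    class = "innovation_set"
  )
}

#' @export
print.innovation_set <- function(x, ...) {
  cat("<innovation_set>", nrow(x$activity), "voxels x", ncol(x$activity),
      "volumes;", x$subject, x$session_id, "\n")
  invisible(x)
}
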