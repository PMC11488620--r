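#' Canonical double-gamma hemodynamic response kernel
#'
#' Discretely sampled double-gamma HRF used as the forward operator of the
#' sparse deconvolution and of the synthetic BOLD generator. The response
#' gamma has its mode at `peak` seconds and the undershoot gamma at
#' `undershoot` seconds, mixed at `undershoot_ratio`; the kernel is scaled
#' so its maximum equals 1, which makes activity amplitudes directly
#' comparable to BOLD amplitudes.
#'
#' @param tr repetition time in seconds (sampling interval).
#' @param duration kernel support in seconds (>= 20 s, default 32 s).
#' @param peak mode of the response gamma in seconds.
#' @param undershoot mode of the undershoot gamma in seconds.
#' @param undershoot_ratio relative undershoot amplitude.
#' @return numeric vector of length `floor(duration / tr)`, sampled at
#'   `t = tr * (0:(n-1))`.
#' @examples
#' h <- hrf_kernel(2)
#' which.max(h)  # peak at t = 6 s
#' @export
hrf_kernel <- function(tr, duration = 32, peak = 6, undershoot = 16,
                       undershoot_ratio = 1 / 6) {
  if (!is.numeric(tr) || length(tr) != 1L || tr <= 0) {
    stop("`tr` must be a single positive number", call. = FALSE)
  }
  if (duration < 20) {
    stop("`duration` must be at least 20 s to cover the undershoot", call. = FALSE)
  }
  n <- floor(duration / tr)
  t <- tr * (0:(n - 1))
  # gamma pdf with rate 1 has mode shape - 1, so shape = mode + 1
  h <- dgamma(t, shape = peak + 1, rate = 1) -
    undershoot_ratio * dgamma(t, shape = undershoot + 1, rate = 1)
  h / max(h)
}

# causal convolution truncated to the input length
convolve_causal <- function(x, kernel) {
  T <- length(x)
  full <- stats::convolve(x, rev(kernel), type = "open")
  full[seq_len(T)]
}
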