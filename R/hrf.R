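#' Canonical double-gamma hemodynamic response function
#'
#' Difference of two gamma densities: a positive lobe peaking ~5 s after
#' the event and a delayed, down-scaled undershoot. Defaults are the
#' canonical parameters (peak delay 6 s, undershoot delay 16 s, both
#' dispersions 1 s, peak:undershoot ratio 6, 32 s support); the kernel is
#' normalized to a peak value of 1 and is exactly 0 at t = 0.
#'
#' @param dt Sampling step in seconds.
#' @param duration Kernel length in seconds (default 32).
#' @param peak_delay,undershoot_delay Gamma shape parameters (s).
#' @param peak_disp,undershoot_disp Gamma dispersions (s).
#' @param ratio Peak-to-undershoot amplitude ratio.
#' @return An `hrf_kernel`: list with `times`, `values`, `dt`.
#' @export
hrf_double_gamma <- function(dt, duration = 32, peak_delay = 6,
                             undershoot_delay = 16, peak_disp = 1,
                             undershoot_disp = 1, ratio = 6) {
  if (dt <= 0) abort("`dt` must be positive.")
  pars <- c(duration, peak_delay, undershoot_delay, peak_disp,
            undershoot_disp, ratio)
  if (any(pars <= 0)) abort("All HRF parameters must be positive.")
  times <- seq(0, duration, by = dt)
  vals <- dgamma(times, shape = peak_delay / peak_disp, scale = peak_disp) -
    dgamma(times, shape = undershoot_delay / undershoot_disp,
           scale = undershoot_disp) / ratio
  vals <- vals / max(vals)
  structure(list(times = times, values = vals, dt = dt), class = "hrf_kernel")
}

#' Convolve, standardize, and downsample a regressor to TR rate
#'
#' Applies the standard EEG-informed fMRI post-processing to an EEG-rate
#' series: causal convolution with the HRF kernel (zero-padded start, same
#' length), z-scoring to mean 0 / SD 1, then downsampling to TR rate by
#' averaging all samples inside each TR interval (set
#' `method = "sample"` for point-sampling at TR onsets instead).
#'
#' @param series Numeric EEG-rate series.
#' @param sfreq Sampling rate (Hz).
#' @param tr Repetition time (s).
#' @param n_tr Number of output TRs.
#' @param hrf An [hrf_double_gamma()] kernel sampled at `1/sfreq`
#'   (default constructed on the fly).
#' @param method `"average"` (default) or `"sample"`.
#' @return Numeric vector of length `n_tr`. A zero-variance input yields an
#'   all-zero output with a warning (nothing to standardize).
#' @export
finalize_regressor <- function(series, sfreq, tr, n_tr,
                               hrf = hrf_double_gamma(dt = 1 / sfreq),
                               method = c("average", "sample")) {
  method <- match.arg(method)
  n <- length(series)
  spt <- sfreq * tr
  if (n < spt) abort("Series shorter than one TR of samples.")
  if (n_tr * spt > n + spt - 1) abort("`n_tr` exceeds the available samples.")
  if (sd(series) < .Machine$double.eps^0.5) {
    warn("Zero-variance regressor; returning zeros.")
    return(numeric(n_tr))
  }
  h <- hrf$values
  conv <- convolve(series, rev(h), type = "open")[seq_len(n)]
  s <- sd(conv)
  if (s < .Machine$double.eps^0.5) {
    warn("Zero-variance regressor after convolution; returning zeros.")
    return(numeric(n_tr))
  }
  z <- (conv - mean(conv)) / s
  if (method == "sample") {
    idx <- pmin(n, round((seq_len(n_tr) - 1) * spt) + 1L)
    return(z[idx])
  }
  starts <- round((seq_len(n_tr) - 1) * spt) + 1L
  ends <- pmin(n, round(seq_len(n_tr) * spt))
  vapply(seq_len(n_tr), function(i) mean(z[starts[i]:ends[i]]), 0)
}
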