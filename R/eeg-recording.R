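#' Multichannel EEG recording container
#'
#' A lightweight container for a continuous multichannel EEG segment:
#' a channels-by-samples potential matrix (microvolts) plus sampling rate,
#' channel names, and a table of bad (artifact-contaminated) sample
#' intervals that downstream steps must avoid.
#'
#' @param data Numeric matrix, channels (p) x samples (n).
#' @param sfreq Sampling frequency in Hz.
#' @param channel_names Optional character vector of length p.
#' @param bad_intervals Optional tibble/data frame with integer columns
#'   `start`, `end` giving 1-based inclusive sample ranges to treat as
#'   unusable (e.g. residual scanner artifact).
#'
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, sfreq, channel_names = NULL, bad_intervals = NULL) {
  data <- as.matrix(data)
  if (!is.numeric(data) || nrow(data) < 2) {
    abort("`data` must be a numeric matrix with at least 2 channel rows.")
  }
  if (!is.numeric(sfreq) || length(sfreq) != 1 || sfreq <= 0) {
    abort("`sfreq` must be a single positive number (Hz).")
  }
  if (is.null(channel_names)) {
    channel_names <- paste0("ch", seq_len(nrow(data)))
  }
  if (length(channel_names) != nrow(data)) {
    abort("`channel_names` length must match the number of channel rows.")
  }
  if (is.null(bad_intervals)) {
    bad_intervals <- tibble::tibble(start = integer(), end = integer())
  } else {
    bad_intervals <- tibble::as_tibble(bad_intervals)
    stopifnot(all(c("start", "end") %in% names(bad_intervals)))
    n <- ncol(data)
    if (nrow(bad_intervals) > 0 &&
        (any(bad_intervals$start < 1) || any(bad_intervals$end > n) ||
         any(bad_intervals$start > bad_intervals$end))) {
      abort("`bad_intervals` must satisfy 1 <= start <= end <= n_samples.")
    }
  }
  structure(
    list(data = unname(data), sfreq = sfreq,
         channel_names = channel_names, bad_intervals = bad_intervals),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s), %d bad interval(s)\n",
              nrow(x$data), ncol(x$data), x$sfreq,
              ncol(x$data) / x$sfreq, nrow(x$bad_intervals)))
  invisible(x)
}

n_samples <- function(eeg) ncol(eeg$data)

#' Re-reference EEG to the common average
#'
#' Subtracts the across-channel mean from every sample so each column of the
#' potential matrix sums to zero, the reference convention assumed by
#' microstate topographic analysis.
#'
#' @param eeg An [eeg_recording()].
#' @return The recording with per-sample channel means removed.
#' @export
average_reference <- function(eeg) {
  eeg$data <- sweep(eeg$data, 2, colMeans(eeg$data))
  eeg
}

#' Zero-phase band-pass filter
#'
#' Applies a forward-backward (zero-phase) Butterworth band-pass, the
#' standard preconditioning before microstate segmentation. The default
#' band used throughout the pipeline is 2-20 Hz, with 1-40 Hz as the usual
#' alternative configuration.
#'
#' @param eeg An [eeg_recording()].
#' @param low,high Band edges in Hz; requires `0 < low < high < sfreq / 2`.
#' @param order Butterworth section order (applied twice by filtfilt).
#' @return A filtered [eeg_recording()] of identical dimensions.
#' @export
bandpass_filter <- function(eeg, low = 2, high = 20, order = 4) {
  ny <- eeg$sfreq / 2
  if (!(low > 0 && low < high && high < ny)) {
    abort("Band edges must satisfy 0 < low < high < Nyquist.")
  }
  bf <- signal::butter(order, c(low, high) / ny, type = "pass")
  eeg$data <- t(apply(eeg$data, 1, function(x) signal::filtfilt(bf, x)))
  eeg
}

#' Global field power
#'
#' GFP at each sample is the spatial standard deviation of the scalp
#' potential across the p electrodes:
#' \deqn{GFP(t) = \sqrt{\sum_i (v_i(t) - \bar v(t))^2 / p}.}
#' Its local maxima mark moments of high topographic signal-to-noise and
#' are the points submitted to microstate clustering.
#'
#' @param eeg An [eeg_recording()].
#' @return A `gfp_series` object: list with `values` (length n, nonnegative)
#'   and `sfreq`.
#' @export
compute_gfp <- function(eeg) {
  centered <- sweep(eeg$data, 2, colMeans(eeg$data))
  structure(
    list(values = sqrt(colMeans(centered^2)), sfreq = eeg$sfreq),
    class = "gfp_series"
  )
}

#' Detect GFP peaks
#'
#' Smooths the GFP series with a Gaussian-weighted moving average over
#' `smooth_window` samples (sigma = 1 sample) and returns indices of strict
#' local maxima of the smoothed series. Peaks falling inside bad intervals
#' are dropped.
#'
#' @param gfp A `gfp_series` from [compute_gfp()], or a plain numeric
#'   vector.
#' @param smooth_window Odd window length in samples (default 5).
#' @param bad_intervals Optional tibble with `start`/`end` sample ranges;
#'   peaks inside any interval are excluded.
#' @return Integer vector of peak sample indices.
#' @export
detect_gfp_peaks <- function(gfp, smooth_window = 5, bad_intervals = NULL) {
  if (smooth_window < 1 || smooth_window %% 2 == 0) {
    abort("`smooth_window` must be an odd positive integer.")
  }
  x <- if (inherits(gfp, "gfp_series")) gfp$values else as.numeric(gfp)
  n <- length(x)
  if (n < smooth_window) abort("GFP series shorter than the smoothing window.")
  half <- (smooth_window - 1) / 2
  kern <- dnorm(seq(-half, half), sd = 1)
  kern <- kern / sum(kern)
  sm <- as.numeric(stats::filter(x, kern, sides = 2))
  # edges (NA after symmetric filtering) can never be strict interior maxima
  idx <- which(sm[-c(1, n)] > sm[-c(n - 1, n)] & sm[-c(1, n)] > sm[-c(1, 2)]) + 1L
  idx <- idx[!is.na(sm[idx])]
  if (!is.null(bad_intervals) && nrow(bad_intervals) > 0) {
    bad <- rep(FALSE, n)
    for (r in seq_len(nrow(bad_intervals))) {
      bad[bad_intervals$start[r]:bad_intervals$end[r]] <- TRUE
    }
    idx <- idx[!bad[idx]]
  }
  idx
}

#' Subsample peak indices
#'
#' Uniform random subsample without replacement down to `max_n` indices
#' (all indices returned if there are fewer), deterministic given `seed`.
#' Caps the number of topographies submitted to clustering.
#'
#' @param indices Integer vector of candidate peak indices.
#' @param max_n Maximum number retained (default 10000).
#' @param seed Integer seed for the subsample draw.
#' @return Integer vector of at most `max_n` indices (sorted).
#' @export
sample_peaks <- function(indices, max_n = 10000, seed = 1) {
  if (length(indices) <= max_n) return(indices)
  sort(withr::with_seed(seed, sample(indices, max_n, replace = FALSE)))
}

#' @importFrom stats dnorm
NULL
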