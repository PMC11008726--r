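#' Build a TR censor mask from motion and EEG artifacts
#'
#' A TR is censored if the root-mean-square of its motion parameters
#' exceeds `rms_threshold` (default 0.2) or if its acquisition interval
#' overlaps any bad EEG interval. A subject whose censored fraction
#' exceeds one third of the TRs is flagged unusable (too little data left
#' to estimate the GLM).
#'
#' @param motion Numeric matrix/data frame, n_TR rows x 6 or 12 motion
#'   parameter columns (aligned with TRs).
#' @param eeg_bad_intervals Tibble with `start`/`end` EEG sample ranges
#'   (1-based inclusive), or `NULL`.
#' @param sfreq EEG sampling rate (Hz).
#' @param tr Repetition time (s).
#' @param rms_threshold Motion RMS censoring threshold (default 0.2).
#' @return A tibble with columns `tr` (index), `censored` (logical),
#'   `motion_rms`; attributes `"usable"` (logical subject flag) and
#'   `"censored_fraction"`.
#' @export
build_censor_mask <- function(motion, eeg_bad_intervals = NULL, sfreq = 250,
                              tr = 2, rms_threshold = 0.2) {
  motion <- as.matrix(motion)
  n_tr <- nrow(motion)
  rms <- sqrt(rowMeans(motion^2))
  censored <- rms > rms_threshold
  if (!is.null(eeg_bad_intervals) && nrow(eeg_bad_intervals) > 0) {
    spt <- sfreq * tr
    tr_start <- (seq_len(n_tr) - 1) * spt + 1
    tr_end <- seq_len(n_tr) * spt
    for (r in seq_len(nrow(eeg_bad_intervals))) {
      overlap <- tr_start <= eeg_bad_intervals$end[r] &
        tr_end >= eeg_bad_intervals$start[r]
      censored <- censored | overlap
    }
  }
  out <- tibble::tibble(tr = seq_len(n_tr), censored = censored,
                        motion_rms = rms)
  frac <- mean(censored)
  attr(out, "censored_fraction") <- frac
  attr(out, "usable") <- frac <= 1 / 3
  out
}

#' Write a censor mask in keep-column convention
#'
#' Writes a single 0/1 column (1 = keep, 0 = censored), one row per TR,
#' the convention understood by common fMRI GLM tools.
#'
#' @param mask A tibble from [build_censor_mask()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_censor_file <- function(mask, path) {
  writeLines(as.character(as.integer(!mask$censored)), path)
  invisible(path)
}
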