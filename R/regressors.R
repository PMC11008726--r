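#' Direct time course of one microstate
#'
#' Absolute cosine similarity between every (unit-normalized) EEG sample
#' and a single template topography: values in \[0, 1\], with 1 when the
#' sample equals the template up to polarity, 0 when orthogonal.
#'
#' @param eeg An [eeg_recording()].
#' @param template Length-p numeric topography.
#' @return Numeric vector of length n in \[0, 1\].
#' @export
direct_timecourse <- function(eeg, template) {
  template <- template - mean(template)
  template <- template / sqrt(sum(template^2))
  f <- compute_similarity(eeg, matrix(template, nrow = 1))
  as.numeric(f[, 1])
}

# indicator series of consecutive pairs (L_u = i, L_{u+1} in `to`), u = 1..n-1
pair_indicator <- function(labels, i, to) {
  n <- length(labels)
  as.integer(labels[-n] == i & labels[-1] %in% to)
}

# causal windowed count of a pair-indicator series: at sample t, the number
# of pairs (u, u+1) fully inside [t - w + 1, t]; initial windows truncated
windowed_pair_count <- function(q, window_samples) {
  n <- length(q) + 1L
  C <- c(0, cumsum(q))                       # C[u+1] = sum q_1..q_u
  t <- seq_len(n)
  a <- pmax(1L, t - window_samples + 1L)     # window start
  C[t] - C[a]                                # pairs with a <= u <= t-1
}

#' Microstate activity regressor
#'
#' Sliding-window count of switches *out of* microstate `i`: the number of
#' consecutive label pairs (L_u = i, L_{u+1} = j, j != i) whose samples both
#' lie inside the causal window of `window_samples` samples ending at t.
#' The window is shifted by one sample; initial windows are truncated.
#'
#' @param labels Integer label sequence in `[1, K]`.
#' @param i Microstate index.
#' @param window_samples Window length in samples (>= 2).
#' @param k Number of microstate classes (default `max(labels)`).
#' @return Nonnegative integer vector of length `length(labels)`.
#' @export
activity_regressor <- function(labels, i, window_samples, k = max(labels)) {
  if (window_samples < 2) abort("`window_samples` must be >= 2.")
  if (i < 1 || i > k) abort("`i` outside [1, K].")
  q <- pair_indicator(labels, i, setdiff(seq_len(k), i))
  windowed_pair_count(q, window_samples)
}

#' Microstate transition regressor
#'
#' Sliding-window count of transitions from microstate `i` to microstate
#' `j` (self-transitions `i == j` allowed), with the same causal window
#' convention as [activity_regressor()].
#'
#' @inheritParams activity_regressor
#' @param j Destination microstate index.
#' @return Nonnegative integer vector of length `length(labels)`.
#' @export
transition_regressor <- function(labels, i, j, window_samples, k = max(labels)) {
  if (window_samples < 2) abort("`window_samples` must be >= 2.")
  if (i < 1 || i > k || j < 1 || j > k) abort("Indices outside [1, K].")
  q <- pair_indicator(labels, i, j)
  windowed_pair_count(q, window_samples)
}

#' Build the full microstate regressor set
#'
#' Constructs all three regressor families from a label sequence (and, for
#' the direct time courses, the recording plus templates): `DT_A..DT_D`
#' (absolute cosine similarity), `AT_A..AT_D` (windowed switch-out counts)
#' and `TS_i_j` for all ordered pairs including self-transitions (windowed
#' transition counts). Each EEG-rate series is then convolved with the
#' double-gamma HRF, standardized, and averaged within TR intervals to
#' produce the TR-rate design columns.
#'
#' @param labels Integer label sequence at EEG rate.
#' @param eeg Optional [eeg_recording()] (required for DT regressors).
#' @param templates Optional [microstate_templates()] or K x p matrix.
#' @param sfreq Sampling rate (Hz).
#' @param window_s Sliding-window length in seconds (default 2).
#' @param tr Repetition time in seconds.
#' @param n_tr Number of TRs for the TR-rate series.
#' @param hrf Optional [hrf_double_gamma()] kernel; default canonical.
#' @param k Number of classes.
#' @return A `regressor_set`: list with `eeg_rate` (n x q named matrix),
#'   `tr_rate` (tibble, n_tr x q), `window_s`, `sfreq`, `tr`.
#' @export
regressor_set <- function(labels, eeg = NULL, templates = NULL, sfreq = 250,
                          window_s = 2, tr = 2, n_tr = NULL, hrf = NULL,
                          k = max(labels)) {
  w <- round(window_s * sfreq)
  letters_k <- if (k <= 26) LETTERS[seq_len(k)] else as.character(seq_len(k))
  cols <- list()
  if (!is.null(eeg) && !is.null(templates)) {
    tpl <- if (inherits(templates, "microstate_templates")) templates$templates else as.matrix(templates)
    f <- compute_similarity(eeg, tpl)
    for (i in seq_len(k)) cols[[paste0("DT_", letters_k[i])]] <- as.numeric(f[, i])
  }
  for (i in seq_len(k)) {
    cols[[paste0("AT_", letters_k[i])]] <- activity_regressor(labels, i, w, k)
  }
  for (i in seq_len(k)) for (j in seq_len(k)) {
    cols[[paste0("TS_", letters_k[i], "_", letters_k[j])]] <-
      transition_regressor(labels, i, j, w, k)
  }
  eeg_rate <- do.call(cbind, cols)
  if (is.null(n_tr)) n_tr <- floor(length(labels) / (sfreq * tr))
  if (is.null(hrf)) hrf <- hrf_double_gamma(dt = 1 / sfreq)
  tr_rate <- vapply(colnames(eeg_rate), function(nm) {
    finalize_regressor(eeg_rate[, nm], sfreq = sfreq, tr = tr, n_tr = n_tr,
                       hrf = hrf)
  }, numeric(n_tr))
  structure(
    list(eeg_rate = eeg_rate, tr_rate = tibble::as_tibble(as.data.frame(tr_rate)),
         window_s = window_s, sfreq = sfreq, tr = tr),
    class = "regressor_set"
  )
}

#' @export
print.regressor_set <- function(x, ...) {
  cat(sprintf("<regressor_set> %d EEG-rate series (n = %d @ %g Hz), %d TRs @ %g s, window %g s\n",
              ncol(x$eeg_rate), nrow(x$eeg_rate), x$sfreq,
              nrow(x$tr_rate), x$tr, x$window_s))
  cat("  names:", paste(head(colnames(x$eeg_rate), 8), collapse = ", "),
      if (ncol(x$eeg_rate) > 8) "..." else "", "\n")
  invisible(x)
}
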