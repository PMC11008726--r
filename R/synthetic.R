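#' Generate synthetic microstate template topographies
#'
#' Draws `k` zero-mean, unit-norm scalp topographies over `n_channels`
#' electrodes. Vectors are first orthonormalized (Gram-Schmidt on white
#' noise) and then optionally smoothed along the channel index with a
#' Gaussian kernel of width controlled by `smoothness`; smoothing trades
#' exact orthogonality for spatial coherence, and the result is accepted
#' only if all pairwise absolute cosine similarities stay below 0.8 (the
#' draw is repeated with fresh noise otherwise, still deterministic given
#' `seed`). With `smoothness = 0` the set is exactly orthogonal.
#'
#' @param n_channels Number of electrodes (p).
#' @param k Number of templates; requires `k <= n_channels`.
#' @param smoothness Nonnegative scalar; Gaussian kernel sigma in channel
#'   units is `2 * smoothness`.
#' @param seed Integer seed.
#' @return A k x p numeric matrix; each row has zero mean and unit norm.
#' @export
generate_templates <- function(n_channels, k, smoothness = 0.5, seed = 1) {
  if (k > n_channels || k < 1) abort("Require 1 <= k <= n_channels.")
  withr::with_seed(seed, {
    for (attempt in 1:20) {
      raw <- matrix(rnorm(n_channels * k), nrow = n_channels)
      raw <- sweep(raw, 2, colMeans(raw))    # zero-mean subspace first
      q <- qr.Q(qr(raw))[, seq_len(k), drop = FALSE]
      q <- sweep(q, 2, colMeans(q))          # exact for all non-degenerate cols
      norms <- sqrt(colSums(q^2))
      # k = p leaves one degenerate direction (no k-th zero-mean orthogonal
      # vector exists); replace it with a fresh random zero-mean draw and
      # rely on the pairwise-similarity acceptance check below
      for (d in which(norms < 1e-8)) {
        v <- rnorm(n_channels)
        v <- v - mean(v)
        q[, d] <- v
      }
      tpl <- t(q)
      if (smoothness > 0) {
        sig <- 2 * smoothness
        half <- max(1L, ceiling(3 * sig))
        kern <- dnorm(seq(-half, half), sd = sig)
        kern <- kern / sum(kern)
        tpl <- t(apply(tpl, 1, function(v) {
          vpad <- c(rev(v[seq_len(half)]), v, rev(v[n_channels - seq_len(half) + 1]))
          as.numeric(stats::filter(vpad, kern, sides = 2))[half + seq_len(n_channels)]
        }))
      }
      tpl <- tpl - rowMeans(tpl)
      tpl <- tpl / sqrt(rowSums(tpl^2))
      cs <- abs(tcrossprod(tpl))
      diag(cs) <- 0
      if (max(cs) < 0.8) return(unname(tpl))
    }
  })
  abort("Could not draw templates with pairwise |cos| < 0.8; lower `smoothness`.")
}

#' Simulate a microstate label sequence
#'
#' Simulates a first-order Markov chain of microstate labels at the EEG
#' sampling rate. `transition_matrix` supplies the conditional switch
#' destinations (its off-diagonal structure, renormalized row-wise); the
#' stay probability on the diagonal is derived from `mean_dwell_ms` so that
#' dwell times are geometric with the requested mean (about 50 ms for
#' resting-state microstates). If `mean_dwell_ms` is `NULL` the matrix is
#' used as-is, including its diagonal.
#'
#' @param transition_matrix K x K row-stochastic matrix.
#' @param mean_dwell_ms Expected dwell per state in milliseconds, or `NULL`.
#' @param sfreq Sampling frequency (Hz).
#' @param duration_s Length of the sequence in seconds.
#' @param seed Integer seed.
#' @return Integer vector of length `round(duration_s * sfreq)` with values
#'   in `[1, K]`; the effective (row-stochastic) one-step matrix is attached
#'   as attribute `"effective_matrix"`.
#' @export
generate_state_sequence <- function(transition_matrix, mean_dwell_ms = 50,
                                    sfreq = 250, duration_s = 300, seed = 1) {
  P <- as.matrix(transition_matrix)
  k <- nrow(P)
  if (ncol(P) != k || any(P < 0) || any(abs(rowSums(P) - 1) > 1e-8)) {
    abort("`transition_matrix` must be square, nonnegative and row-stochastic.")
  }
  if (sfreq <= 0) abort("`sfreq` must be positive.")
  n <- round(duration_s * sfreq)

  eff <- P
  if (!is.null(mean_dwell_ms)) {
    dwell_samples <- mean_dwell_ms * sfreq / 1000
    if (dwell_samples < 1) abort("`mean_dwell_ms` shorter than one sample.")
    p_stay <- 1 - 1 / dwell_samples
    for (i in seq_len(k)) {
      off <- P[i, ]
      off[i] <- 0
      if (sum(off) == 0) {         # absorbing row: no destinations to switch to
        eff[i, ] <- 0
        eff[i, i] <- 1
      } else {
        eff[i, ] <- (1 - p_stay) * off / sum(off)
        eff[i, i] <- p_stay
      }
    }
  }

  # segment-based simulation: dwell lengths are geometric (success prob =
  # per-sample switch probability), destinations follow the off-diagonal row
  labels <- withr::with_seed(seed, {
    state <- sample.int(k, 1)
    segs_states <- integer(0)
    segs_len <- integer(0)
    total <- 0L
    while (total < n) {
      p_switch <- 1 - eff[state, state]
      if (p_switch <= 0) {         # absorbing: dwell forever
        segs_states <- c(segs_states, state)
        segs_len <- c(segs_len, n - total)
        total <- n
        break
      }
      dwell <- stats::rgeom(1, p_switch) + 1L
      segs_states <- c(segs_states, state)
      segs_len <- c(segs_len, dwell)
      total <- total + dwell
      off <- eff[state, ]
      off[state] <- 0
      state <- sample.int(k, 1, prob = off)
    }
    rep(segs_states, segs_len)[seq_len(n)]
  })
  attr(labels, "effective_matrix") <- eff
  labels
}

#' Uniform off-diagonal switch matrix
#'
#' Convenience constructor: equal probability of switching to every other
#' state (row-stochastic with zero diagonal), the default destination model
#' for the synthetic generator.
#'
#' @param k Number of states.
#' @return K x K row-stochastic matrix with zero diagonal.
#' @export
uniform_switch_matrix <- function(k) {
  P <- matrix(1 / (k - 1), k, k)
  diag(P) <- 0
  P
}

#' Smoothed rectified amplitude process
#'
#' Per-sample positive amplitude applied to the active template: a Gaussian
#' process smoothed over ~100 ms, scaled to the requested mean/sd, and
#' rectified at a small positive floor. Emulates slow waxing/waning of
#' topographic strength (an alpha-envelope stand-in).
#'
#' @param n Number of samples.
#' @param sfreq Sampling frequency (Hz).
#' @param mean,sd Target mean and standard deviation before rectification.
#' @param seed Integer seed.
#' @return Numeric vector of length `n`, strictly positive.
#' @export
generate_amplitude <- function(n, sfreq = 250, mean = 1, sd = 0.3, seed = 1) {
  withr::with_seed(seed, {
    z <- rnorm(n)
    sig <- max(1, round(0.1 * sfreq))  # ~100 ms smoothing
    half <- 3 * sig
    kern <- dnorm(seq(-half, half), sd = sig)
    kern <- kern / sum(kern)
    zpad <- c(rev(z[seq_len(half)]), z, rev(z[n - seq_len(half) + 1]))
    zs <- as.numeric(stats::filter(zpad, kern, sides = 2))[half + seq_len(n)]
    zs <- zs / sd(zs) * sd + mean
    pmax(zs, 0.05)
  })
}

#' Assemble synthetic EEG from templates, labels and amplitudes
#'
#' Realizes the generative model of microstate analysis: each sample is the
#' active template scaled by a positive amplitude, with a random polarity
#' sign per dwell segment (topographies alternate polarity within a
#' microstate, and all downstream similarity measures are polarity
#' invariant), plus isotropic Gaussian channel noise.
#'
#' @param templates K x p matrix of unit-norm topographies.
#' @param state_sequence Integer labels in `[1, K]`, length n.
#' @param amplitude Positive per-sample scalars, length n.
#' @param noise_sd Channel noise standard deviation.
#' @param sfreq Sampling frequency (Hz).
#' @param seed Integer seed (noise and polarity draws).
#' @return An [eeg_recording()] with ground-truth attributes
#'   `"polarity"` (per-sample sign) retained for testing.
#' @export
generate_eeg <- function(templates, state_sequence, amplitude, noise_sd = 0.2,
                         sfreq = 250, seed = 1) {
  n <- length(state_sequence)
  if (length(amplitude) != n) {
    abort("`amplitude` and `state_sequence` must have equal length.")
  }
  p <- ncol(templates)
  seg_id <- cumsum(c(1L, diff(state_sequence) != 0))
  withr::with_seed(seed, {
    seg_sign <- sample(c(-1, 1), max(seg_id), replace = TRUE)
    signs <- seg_sign[seg_id]
    clean <- t(templates[state_sequence, , drop = FALSE]) *
      rep(amplitude * signs, each = p)
    noise <- if (noise_sd > 0) {
      matrix(rnorm(p * n, sd = noise_sd), nrow = p)
    } else 0
    out <- eeg_recording(clean + noise, sfreq = sfreq)
  })
  attr(out, "polarity") <- signs
  out
}

#' Generate synthetic BOLD data from planted regressors
#'
#' Inverts the EEG-informed GLM to create ground truth: each ROI time
#' series is a linear combination of TR-rate regressors (already
#' HRF-convolved) with known coupling coefficients, plus a small
#' 3rd-order polynomial drift and Gaussian noise, on a baseline of 100
#' (scaled-signal convention).
#'
#' @param regressors Numeric matrix, n_TR x q, columns named.
#' @param coupling Numeric matrix q x n_rois (or a named list of per-ROI
#'   vectors matching regressor columns) of coupling coefficients.
#' @param bold_noise_sd Noise standard deviation.
#' @param n_rois Number of ROIs.
#' @param drift_sd Standard deviation of the random polynomial drift
#'   coefficients (0 disables drift).
#' @param tr Repetition time (s) recorded on the returned dataset.
#' @param seed Integer seed.
#' @param parcellation Optional per-ROI network ids stored on the dataset.
#' @return A `bold_dataset` (see [bold_dataset()]) with attribute
#'   `"coupling"` storing the planted coefficients.
#' @export
generate_bold <- function(regressors, coupling, bold_noise_sd = 1,
                          n_rois = 70, drift_sd = 0.5, tr = 2, seed = 1,
                          parcellation = NULL) {
  X <- as.matrix(regressors)
  n_tr <- nrow(X)
  if (is.list(coupling) && !is.matrix(coupling)) {
    B <- matrix(0, ncol(X), n_rois, dimnames = list(colnames(X), NULL))
    for (nm in names(coupling)) B[nm, ] <- coupling[[nm]]
    coupling <- B
  }
  coupling <- as.matrix(coupling)
  stopifnot(nrow(coupling) == ncol(X), ncol(coupling) == n_rois)
  signal_part <- X %*% coupling                    # n_tr x n_rois
  withr::with_seed(seed, {
    drift <- if (drift_sd > 0) {
      basis <- cbind(poly(seq_len(n_tr), 3))
      basis %*% matrix(rnorm(3 * n_rois, sd = drift_sd), 3, n_rois)
    } else 0
    noise <- if (bold_noise_sd > 0) {
      matrix(rnorm(n_tr * n_rois, sd = bold_noise_sd), n_tr, n_rois)
    } else 0
    data <- t(100 + signal_part + drift + noise)   # ROI x TR
  })
  out <- bold_dataset(data, tr = tr, parcellation = parcellation)
  attr(out, "coupling") <- coupling
  out
}

#' Simulate a full synthetic EEG-BOLD subject
#'
#' End-to-end single-subject generator: templates, Markov label sequence,
#' amplitude process, EEG per the generative superposition model, true
#' microstate regressors built from the *planted* labels/templates,
#' HRF-convolved and downsampled to TR, and BOLD coupled to a chosen subset
#' of those regressors. Defaults mirror the study geometry: 32 channels,
#' 250 Hz, 4 states with ~50 ms dwell, TR = 2 s, 244 volumes (488 s), and
#' a 7-network style parcellation.
#'
#' @param n_channels,k,sfreq,duration_s EEG geometry; `duration_s` defaults
#'   to `n_tr * tr`.
#' @param mean_dwell_ms Mean microstate dwell (ms).
#' @param noise_sd EEG channel noise SD (relative to unit template norm).
#' @param amplitude_mean,amplitude_sd Amplitude process parameters.
#' @param tr,n_tr BOLD timing.
#' @param n_rois Number of ROIs; parcellation assigns them round-robin to 7
#'   networks.
#' @param coupling Named list: regressor name -> per-ROI coefficient vector
#'   (or scalar, recycled). Default plants a negative coupling of the
#'   microstate-A activity regressor on network-1 ROIs.
#' @param bold_noise_sd,drift_sd BOLD noise and drift scales.
#' @param window_s Sliding-window length (s) for activity/transition counts.
#' @param seed Integer master seed (per-component seeds derived from it).
#' @return List with elements `truth` (templates, state_sequence, amplitude,
#'   effective transition matrix, coupling, seeds), `eeg`, `regressors`
#'   (a [regressor_set()] built from the planted labels), and `bold`.
#' @export
simulate_subject <- function(n_channels = 32, k = 4, sfreq = 250,
                             mean_dwell_ms = 50, noise_sd = 0.2,
                             amplitude_mean = 1, amplitude_sd = 0.3,
                             tr = 2, n_tr = 244, duration_s = n_tr * tr,
                             n_rois = 70,
                             coupling = list(AT_A = c(rep(-0.5, 10), rep(0, 60))),
                             bold_noise_sd = 1, drift_sd = 0.5,
                             window_s = 2, seed = 1) {
  seeds <- seed * 10L + 0:4
  templates <- generate_templates(n_channels, k, smoothness = 0.5, seed = seeds[1])
  states <- generate_state_sequence(uniform_switch_matrix(k), mean_dwell_ms,
                                    sfreq, duration_s, seed = seeds[2])
  n <- length(states)
  amplitude <- generate_amplitude(n, sfreq, amplitude_mean, amplitude_sd,
                                  seed = seeds[3])
  eeg <- generate_eeg(templates, states, amplitude, noise_sd, sfreq,
                      seed = seeds[4])
  regs <- regressor_set(labels = states, eeg = eeg, templates = templates,
                        sfreq = sfreq, window_s = window_s, tr = tr, n_tr = n_tr)
  parcellation <- rep_len(seq_len(7), n_rois)
  coupling_vecs <- lapply(coupling, function(v) rep_len(v, n_rois))
  bold <- generate_bold(as.matrix(regs$tr_rate), coupling_vecs, bold_noise_sd,
                        n_rois, drift_sd, tr = tr, seed = seeds[5],
                        parcellation = parcellation)
  list(
    truth = list(templates = templates, state_sequence = states,
                 amplitude = amplitude,
                 transition_matrix = attr(states, "effective_matrix"),
                 mean_dwell_ms = mean_dwell_ms, noise_sd = noise_sd,
                 coupling = coupling_vecs, bold_noise_sd = bold_noise_sd,
                 seed = seed),
    eeg = eeg, regressors = regs, bold = bold
  )
}
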