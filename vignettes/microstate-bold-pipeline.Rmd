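---
title: "Linking EEG microstate dynamics to BOLD fMRI: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking EEG microstate dynamics to BOLD fMRI: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msbold)
```

## The scientific problem

EEG microstates are quasi-stable scalp potential topographies that persist
for a few tens of milliseconds before abruptly switching to another
configuration. Resting-state recordings are dominated by a small number of
recurring classes (conventionally labeled A through D for the canonical
four). How these electrophysiological states relate to the much slower
hemodynamic signal measured by fMRI is an open question: does a microstate
index the activation of one specific resting-state network, or does
microstate *switching* track reconfiguration across networks?

`msbold` implements a complete analysis chain for this question on
simultaneous EEG-fMRI data:

1. **Segmentation** — extract microstate templates from EEG,
2. **Regressor construction** — turn the segmentation into three families
   of BOLD-predicting regressors,
3. **GLM analysis** — estimate and test the coupling of each regressor with
   BOLD at the group level, with permutation cluster-extent correction and
   network-overlap summaries,
4. **Cross-modal prediction** — a multi-output time-delay neural network
   (mTDNN) that predicts BOLD from microstate information and vice versa,

together with a **synthetic generator** that produces simultaneous
EEG-BOLD datasets with known ground truth, so every stage of the chain is
testable end-to-end without access to any cohort data.

## The generative model

The synthetic module, and the segmentation model itself, assume each EEG
sample is one active template plus noise:

$$x_t = \sum_{i=1}^{K} a_t^i \, \mathrm{MS}_i + \epsilon_t,$$

where $\mathrm{MS}_i$ is a unit-norm, zero-mean topography over the $p$
electrodes, $a_t^i$ is a positive per-sample amplitude that is nonzero only
for the active state, and $\epsilon_t$ is isotropic channel noise. The
active state follows a first-order Markov chain with geometric dwell times.

Concrete choices in `simulate_subject()` (the defaults *are* the study
conditions and are not tuned per-test):

* **Geometry**: 32 channels, 250 Hz sampling, 4 states, TR = 2 s,
  244 volumes; a 70-ROI set assigned round-robin to 7 networks stands in
  for a 7-network cortical parcellation.
* **Dwell**: mean 50 ms (the literature's typical resting microstate
  duration). The user-supplied transition matrix supplies switch
  *destinations* (off-diagonal, renormalized); the diagonal stay
  probability is derived from the requested mean dwell, so dwell times are
  geometric with the right mean and the effective one-step matrix is
  row-stochastic by construction.
* **Amplitude** $a_t$: a Gaussian process smoothed over ~100 ms, scaled to
  mean 1 / SD 0.3, rectified at a small positive floor. This is a simple
  stand-in for the waxing and waning of topographic strength (an
  alpha-envelope-like modulation); no published amplitude model exists, so
  the choice is deliberately generic.
* **Polarity**: each dwell segment receives a random ±1 sign. Microstate
  analysis is polarity-invariant (all similarity measures take absolute
  values), and injecting sign flips makes the test suite exercise that
  invariance rather than assume it.
* **EEG noise**: channel noise SD 0.2 relative to the unit-norm template.
  No quantitative SNR for real recordings is available to calibrate
  against; this level is chosen so that a realistic amount of work is left
  for the clustering (per-sample spatial correlation with the truth is far
  from 1, while averaging over thousands of GFP peaks recovers templates
  accurately).
* **BOLD**: ROI × TR series are a linear combination of HRF-convolved
  regressors with *known* coupling coefficients, plus a small random
  3rd-order polynomial drift (exercising the GLM's drift nuisance), white
  noise of SD 1, and a baseline of 100 (scaled-signal convention). The
  default plants a **negative** coupling of −0.5 between the microstate-A
  activity regressor and the network-1 ROIs, mirroring the directionality
  the analysis is designed to detect.

What the generator does **not** emulate: volume conduction from realistic
cortical sources (no lead fields), scanner and ballistocardiogram
artifacts (the pipeline accepts *cleaned* EEG by contract), spatially
autocorrelated BOLD noise, and physiological confounds. Passing tests
therefore demonstrate the correctness of the algorithms under the stated
generative assumptions, not robustness to every pathology of real
recordings.

## Segmentation

`extract_templates()` runs the standard topographic pipeline:

* **Band-pass** 2–20 Hz by default (zero-phase 4th-order Butterworth,
  applied forward and backward); 1–40 Hz is the common alternative and is a
  single configuration switch.
* **GFP**: the spatial standard deviation across channels at each sample,
  $\mathrm{GFP}(t) = \sqrt{\sum_i (v_i(t)-\bar v(t))^2 / p}$. Peaks of the
  GFP have high topographic signal-to-noise; the series is smoothed with a
  Gaussian-weighted moving average over 5 samples (σ = 1 sample — only the
  window length is conventionally fixed, so the σ is our choice) and strict
  local maxima are kept, excluding any marked bad intervals.
* **Peak subsampling**: at most 10 000 peaks, drawn uniformly without
  replacement, deterministic given the seed.
* **AAHC**: atomize-and-agglomerate hierarchical clustering. Every map
  starts as a singleton cluster; the cluster with the lowest contribution
  to the global explained variance is dissolved and its members are
  reassigned to the surviving cluster with the highest *squared* spatial
  correlation (so polarity is irrelevant). Cluster centroids are the
  leading principal direction of the member maps rather than their mean —
  the members carry arbitrary signs, and the first eigenvector of the
  scatter matrix is the polarity-safe analogue of averaging. Contributions
  are weighted by squared GFP.
* **Group template**: subject template sets are aligned to a reference by
  the optimal one-to-one assignment over all $K!$ permutations (maximizing
  total absolute correlation), sign-flipped, averaged, renormalized, and
  re-referenced to the running mean until the assignment stabilizes (at
  most 10 iterations).
* **Backfitting**: every sample is normalized to unit norm (cosine
  similarity then equals the dot product) and assigned to the template
  with the highest absolute similarity. Ties break to the lowest template
  index — determinism matters more than any scientific argument here, as
  exact ties are measure-zero events. Zero-norm samples (possible after
  filtering or censoring) get an all-zero similarity row and inherit the
  previous label (label 1 if the recording starts degenerate). Backfitting
  uses *all* samples, not only GFP peaks: the similarity matrix is defined
  over every time point, and the regressors below need sample-rate label
  sequences.

Global explained variance (GEV) is the GFP²-weighted squared correlation
between each sample and its assigned template, normalized by total GFP².
It is an *output* of the segmentation that depends on the dataset's noise
level; published GEV values from any cohort cannot be reproduced without
that cohort's recordings, and the test suite instead verifies the GEV
computation against a brute-force per-sample oracle and checks that
noiseless data yields exactly 1.

## Regressor families

Three families summarize the segmentation for fMRI analysis, from a label
sequence $L_t \in [1, K]$ at EEG rate:

* **Direct time course** $\mathrm{DT}_i = |x^T \mathrm{MS}_i| \in [0,1]$:
  moment-to-moment spatial similarity with template $i$.
* **Activity** $\mathrm{AT}^i$: the number of switches *out of* state $i$
  — consecutive label pairs $(L_u = i, L_{u+1} = j \ne i)$ — inside a
  sliding window of $w$ = 2 s. On the worked sequence
  $L = [1,1,1,3,3,4,4,1,1,2,2,1,2,3]$ with the whole sequence as window,
  $\mathrm{AT}^1 = 3$.
* **Transition** $\mathrm{TS}^{i \to j}$: the analogous windowed count of
  $i \to j$ pairs, for all ordered pairs including self-transitions
  (16 regressors for $K = 4$).

Window convention: the window is *causal* (it ends at the current sample)
and a pair is counted when both of its samples lie inside the window;
initial windows are truncated. Causality avoids explaining the current
BOLD value with future EEG. These conventions give two exact identities
that the test suite asserts over thousands of random windows:
$\mathrm{AT}^i = \sum_{j \ne i} \mathrm{TS}^{i \to j}$ at every position,
and all $K^2$ transition counts (self included) sum to $w - 1$ in every
full window.

Each EEG-rate series is then convolved with the canonical double-gamma
HRF (positive lobe peaking ~5 s, undershoot at ~15 s; peak delay 6 s,
undershoot delay 16 s, dispersions 1 s, ratio 6 — all five exposed as
parameters since only the functional family is conventionally fixed),
z-scored, and downsampled to TR by averaging the samples within each TR
interval (point-sampling at TR onsets is available as an option).
Convolution is causal with zero padding, so regressors never anticipate
the EEG.

The regressor families are strongly mutually correlated by construction,
so the GLM uses **one regressor of interest per model**, never several
jointly.

## GLM and cluster correction

The subject-level design is the microstate regressor plus nuisances:
intercept, 3rd-order orthogonal polynomial drift, 12 motion columns when
available, and any precomputed nuisance series (ventricle principal
components, local white-matter average) supplied as extra columns — the
pipeline accepts these as inputs rather than estimating them from
anatomy. TRs are censored when the motion RMS exceeds 0.2 or the TR
overlaps a bad EEG interval, and a subject with more than a third of TRs
censored is flagged unusable. Censored rows are dropped from both the
data and the design before ordinary least squares.

Group inference is a per-unit one-sample t-test of the subject betas.
Family-wise error across units is controlled by a **sign-flip
permutation** of the maximum cluster extent: under the null the subject
betas are sign-symmetric, so each permutation flips subject signs,
recomputes the t map, thresholds two-sidedly at the voxel-level p
(default 0.005), and records the largest cluster. Observed clusters are
significant when their extent reaches the (1 − 0.05) quantile of this null.
With few subjects the flips are enumerated exhaustively. Clusters are
contiguous runs in ROI mode and 26-connected components when integer 3D
coordinates are supplied. The minimum significant extent is a quantile of
the data's own permutation null — it changes with the data's smoothness,
group size, and unit count, and is therefore reported as an output, never
treated as a constant. On unsmoothed synthetic ROIs the null extents are
small and discrete, which makes the correction somewhat conservative
(empirical family-wise error at or below the nominal 0.05); this is the
usual discreteness behavior of extent-based inference at coarse spatial
resolution.

Network overlap is the percentage of significant-cluster units falling in
each network of a parcellation (background excluded from the network rows
but kept in the denominator).

## mTDNN

The multi-output time-delay network maps tapped delay-line inputs
$x_{t-1}, \dots, x_{t-\tau}$ (per input series) through one shared hidden
layer to all outputs simultaneously:
$z = \sigma(W x + b)$, $\hat y = \tilde W z + c$, with $\sigma = \tanh$
(the conventional choice; the identity activation is available and in
that limit, with vanishing penalty, the network provably matches ordinary
least squares on the delay matrix — an equivalence the test suite
checks). Training minimizes mean squared error plus an L2 penalty on both
weight matrices (default strength $10^{-2}$), optimized by BFGS with
analytic gradients; `epochs` bounds the iteration count (default 100) and
the random initialization is fixed by the seed, so training is exactly
reproducible. This regularized least-squares objective replaces a
Bayesian-regularization backpropagation trainer with a functional
equivalent: both shrink the weights of an MSE objective; we fix the
shrinkage rather than re-estimating it per epoch.

Evaluation is strictly chronological. Architecture (hidden width in
{5, 10, 20, 40} × delays 1–5) is selected by grid search on the first 30
TRs with an internal 80/20 chronological split, scored by the average
correlation between predicted and true outputs — the inner split is our
choice, as only the 30-TR budget is conventional. Performance is then
measured by expanding-window cross-validation from an initial window of
31 TRs: train on TRs 1..k, predict k+1 (horizon 1) and k+2 (horizon 2),
grow by one TR, repeat until the end of the run. Horizon-2 predictions
come from a *separately trained* direct 2-step model whose delay lines
start at lag 2 — never from feeding a horizon-1 prediction back in — so
no information beyond TR k ever reaches a prediction (a property the test
suite verifies by perturbing future TRs). The 30-TR grid window versus
31-TR initial CV window discrepancy is kept as conventional; both are
configurable. Pooled Pearson correlation over all test points is reported
per output and horizon; censored test TRs are skipped and counted.

Four experiments quantify the information flow in both directions:
(a) BOLD from microstate dynamics (20 activity + transition regressors →
7 network signals), (b) BOLD from the 4 direct time courses, (c) dynamics
from BOLD, and (d) time courses from BOLD. On synthetic data coupled
through the dynamics only, experiment (a) outperforms (b), and every
experiment degrades from horizon 1 to horizon 2 — the qualitative
signatures the architecture is designed to expose.

## Numerical and design choices

* Ties everywhere (winner-take-all, AAHC reassignment, grid search) break
  to the lowest index, for exact reproducibility.
* AAHC centroids are leading eigenvectors of 32 × 32 scatter matrices;
  the dissolution loop recomputes only the clusters that received members.
* Template sets are ordered by descending explained-variance contribution
  at extraction; alignment to a reference then determines the A–D labels.
* Zero-variance regressors (e.g. a constant label sequence) standardize to
  all-zero columns with a warning rather than NaNs.
* Exact orthogonality of synthetic templates is only possible for
  $k \le p-1$ because zero-mean (average-referenced) topographies live in
  a $(p-1)$-dimensional subspace; the generator orthonormalizes inside
  that subspace and fills any degenerate direction with a fresh random
  zero-mean draw under the pairwise-similarity cap of 0.8.
* Permutation t statistics are computed vectorized over all sign patterns
  at once (the per-unit sum of squares is sign-invariant, so only the
  means need matrix work).

## Problem sizes used by the tests and the acceptance script

All empirical checks run on synthetic data regenerated at run time: the
segmentation fixture uses a single 300 s recording (75 000 samples, 32
channels, ~6000 GFP peaks); GLM recovery uses 220 TRs with 100 noise
seeds; the family-wise-error calibration uses 100 repetitions of a
10-subject null group at 500 permutations; the prediction experiments use
100-TR runs with the expanding window starting at 31 TRs. These sizes
were chosen as the smallest at which the Monte-Carlo error of each check
is comfortably below its tolerance.

## Known limitations

* Dataset-bound published quantities — a cohort's explained variance, a
  particular minimum cluster extent in voxels, cluster coordinate tables,
  or absolute prediction correlations on a given cohort — are not
  reproducible from synthetic data and are deliberately not targets of
  the test suite; the suite checks the *properties* of each computation
  instead (oracles, invariances, calibration, parameter recovery).
* The synthetic EEG is a template superposition, not a forward-modeled
  source simulation; segmentation accuracy on real data will be lower.
* ROI-mode cluster correction treats adjacent ROI indices as neighbors
  (a declared chain); supply voxel coordinates for true spatial
  clustering.
* The mTDNN is intentionally small (one shared hidden layer); it is a
  measurement instrument for cross-modal information, not a forecasting
  architecture.

## A minimal run

```{r example, eval = FALSE}
library(msbold)

sim <- simulate_subject(n_tr = 150, seed = 7)       # 300 s EEG + BOLD
tpl <- extract_templates(sim$eeg, band = c(2, 20), k = 4, seed = 7)

filt <- bandpass_filter(average_reference(sim$eeg), 2, 20)
bf   <- backfit(filt, tpl)
explained_variance(filt, tpl, bf$labels)$total

regs <- regressor_set(bf$labels, eeg = filt, templates = tpl,
                      sfreq = 250, window_s = 2, tr = 2, n_tr = 150)
fit  <- fit_subject_glm(sim$bold, build_design_matrix(regs$tr_rate$AT_A))
head(fit)
```
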