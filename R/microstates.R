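#' Microstate template set
#'
#' K labeled, unit-norm, zero-mean topographies at subject or group level.
#' For K = 4 the labels follow the canonical A-D convention (the order is
#' by descending explained-variance contribution at extraction time).
#'
#' @param templates K x p numeric matrix.
#' @param labels Character labels, default `LETTERS[1:K]`.
#' @param level `"subject"` or `"group"`.
#' @return A `microstate_templates` object.
#' @export
microstate_templates <- function(templates, labels = NULL, level = "subject") {
  templates <- as.matrix(templates)
  templates <- templates - rowMeans(templates)
  nrm <- sqrt(rowSums(templates^2))
  if (any(nrm == 0)) abort("Zero-norm template row.")
  templates <- templates / nrm
  k <- nrow(templates)
  if (is.null(labels)) labels <- if (k <= 26) LETTERS[seq_len(k)] else as.character(seq_len(k))
  structure(list(templates = unname(templates), labels = labels, level = level),
            class = "microstate_templates")
}

#' @export
print.microstate_templates <- function(x, ...) {
  cat(sprintf("<microstate_templates> %d templates x %d channels (%s level): %s\n",
              nrow(x$templates), ncol(x$templates), x$level,
              paste(x$labels, collapse = ", ")))
  invisible(x)
}

# leading principal direction of a set of maps (rows), polarity-safe;
# sign fixed so the largest-magnitude loading is positive
principal_map <- function(maps) {
  if (nrow(maps) == 1) {
    v <- maps[1, ]
  } else {
    v <- eigen(crossprod(maps), symmetric = TRUE)$vectors[, 1]
  }
  v <- v / sqrt(sum(v^2))
  if (v[which.max(abs(v))] < 0) v <- -v
  v
}

#' Atomize-and-agglomerate hierarchical clustering of topographies
#'
#' AAHC clusters m peak topographies into k microstate classes. Every map
#' starts as its own cluster; at each step the cluster contributing least
#' to the global explained variance is dissolved and each of its members is
#' reassigned to the surviving cluster with the highest squared spatial
#' correlation (polarity invariant: a map and its negation are identical
#' for this purpose). Cluster centroids are the leading principal direction
#' of their member maps. Stops when k clusters remain.
#'
#' @param maps m x p matrix of topographies (normalized internally to zero
#'   mean and unit norm per row).
#' @param k Number of microstate classes (default 4).
#' @param weights Optional nonnegative per-map weights (e.g. squared GFP)
#'   for the explained-variance contributions; default equal weights.
#' @return A [microstate_templates()] with attribute `"assignment"` (the
#'   final cluster index, 1..k, per input map) and `"contribution"` (the
#'   per-template explained-variance share of the clustered maps).
#' @export
aahc_cluster <- function(maps, k = 4, weights = NULL) {
  maps <- as.matrix(maps)
  m <- nrow(maps)
  if (m <= k) abort("Need more maps than clusters (m > k).")
  maps <- maps - rowMeans(maps)
  nrm <- sqrt(rowSums(maps^2))
  keep <- nrm > 0
  maps <- maps[keep, , drop = FALSE] / nrm[keep]
  if (is.null(weights)) weights <- rep(1, nrow(maps)) else weights <- weights[keep]
  m <- nrow(maps)

  assign_vec <- seq_len(m)
  centroids <- maps                           # row c = centroid of cluster c
  contrib <- weights                          # singleton: corr = 1
  active <- rep(TRUE, m)
  n_active <- m

  recompute <- function(c_id) {
    mem <- which(assign_vec == c_id)
    cen <- principal_map(maps[mem, , drop = FALSE])
    centroids[c_id, ] <<- cen
    d <- as.numeric(maps[mem, , drop = FALSE] %*% cen)
    contrib[c_id] <<- sum(weights[mem] * d^2)
  }

  while (n_active > k) {
    act <- which(active)
    c_min <- act[which.min(contrib[act])]
    members <- which(assign_vec == c_min)
    active[c_min] <- FALSE
    n_active <- n_active - 1L
    act <- which(active)
    sims <- abs(maps[members, , drop = FALSE] %*% t(centroids[act, , drop = FALSE]))
    dest <- act[max.col(sims, ties.method = "first")]
    assign_vec[members] <- dest
    for (c_id in unique(dest)) recompute(c_id)
  }

  act <- which(active)
  ord <- act[order(contrib[act], decreasing = TRUE)]
  templates <- centroids[ord, , drop = FALSE]
  final_assign <- match(assign_vec, ord)
  out <- microstate_templates(templates, level = "subject")
  attr(out, "assignment") <- final_assign
  attr(out, "contribution") <- contrib[ord] / sum(contrib[ord])
  out
}

# all permutations of 1..k (k small)
permutations_of <- function(k) {
  if (k == 1) return(matrix(1L, 1, 1))
  sub <- permutations_of(k - 1)
  do.call(rbind, lapply(seq_len(k), function(i) {
    rest <- seq_len(k)[-i]
    cbind(i, matrix(rest[sub], nrow(sub)))
  }))
}

#' Align subject template sets and average into a group template
#'
#' Each subject's templates are reordered and sign-flipped to maximize the
#' total absolute spatial correlation with a reference (optimal one-to-one
#' assignment over all K! permutations; K is small). The group template is
#' the renormalized mean of the aligned sets; the procedure re-references
#' to the current mean and repeats until the assignment is stable, at most
#' `max_iter` iterations.
#'
#' @param subject_sets List of [microstate_templates()] sharing p and K.
#' @param reference A [microstate_templates()]; defaults to the first
#'   subject's set.
#' @param max_iter Maximum refinement iterations (default 10).
#' @return A group-level [microstate_templates()].
#' @export
align_and_average_templates <- function(subject_sets, reference = NULL,
                                        max_iter = 10) {
  stopifnot(length(subject_sets) >= 1)
  p <- ncol(subject_sets[[1]]$templates)
  k <- nrow(subject_sets[[1]]$templates)
  for (s in subject_sets) {
    if (ncol(s$templates) != p || nrow(s$templates) != k) {
      abort("All subject sets must share channel count and K.")
    }
  }
  if (is.null(reference)) reference <- subject_sets[[1]]
  ref <- reference$templates
  perms <- permutations_of(k)

  align_one <- function(tpl, ref) {
    cors <- tpl %*% t(ref)                       # k x k dot products
    scores <- apply(perms, 1, function(pm) sum(abs(cors[cbind(pm, seq_len(k))])))
    pm <- perms[which.max(scores), ]
    aligned <- tpl[pm, , drop = FALSE]
    sgn <- sign(rowSums(aligned * ref))
    sgn[sgn == 0] <- 1
    list(templates = aligned * sgn, perm = pm)
  }

  prev_perms <- NULL
  for (it in seq_len(max_iter)) {
    aligned <- lapply(subject_sets, function(s) align_one(s$templates, ref))
    cur_perms <- vapply(aligned, function(a) paste(a$perm, collapse = ","), "")
    mean_tpl <- Reduce(`+`, lapply(aligned, `[[`, "templates")) / length(aligned)
    mean_tpl <- mean_tpl - rowMeans(mean_tpl)
    mean_tpl <- mean_tpl / sqrt(rowSums(mean_tpl^2))
    ref <- mean_tpl
    if (!is.null(prev_perms) && identical(cur_perms, prev_perms)) break
    prev_perms <- cur_perms
  }
  microstate_templates(ref, labels = reference$labels, level = "group")
}

#' Absolute cosine similarity between EEG samples and templates
#'
#' Average-references the data, normalizes every sample to unit Euclidean
#' norm (so cosine similarity equals the dot product), and returns the
#' n x K matrix of absolute similarities in \[0, 1\]. Zero-norm samples get
#' an all-zero row and are flagged.
#'
#' @param eeg An [eeg_recording()].
#' @param templates A [microstate_templates()] (or K x p matrix).
#' @return n x K numeric matrix with attribute `"flagged"` (logical vector
#'   of zero-norm samples); columns named by template label.
#' @export
compute_similarity <- function(eeg, templates) {
  tpl <- if (inherits(templates, "microstate_templates")) templates$templates else as.matrix(templates)
  labels <- if (inherits(templates, "microstate_templates")) templates$labels else as.character(seq_len(nrow(tpl)))
  x <- sweep(eeg$data, 2, colMeans(eeg$data))
  nrm <- sqrt(colSums(x^2))
  flagged <- nrm < .Machine$double.eps^0.5
  nrm[flagged] <- 1
  xn <- x / rep(nrm, each = nrow(x))
  f <- abs(t(xn) %*% t(tpl))
  f[flagged, ] <- 0
  f <- pmin(f, 1)
  colnames(f) <- labels
  attr(f, "flagged") <- flagged
  f
}

#' Winner-take-all microstate labeling
#'
#' Assigns every sample to the template with the highest absolute
#' similarity; exact ties break to the lowest template index. Flagged
#' (zero-norm) samples inherit the previous sample's label (label 1 if the
#' sequence starts flagged).
#'
#' @param f Similarity matrix from [compute_similarity()].
#' @return Integer label vector in `[1, K]`, length n.
#' @export
assign_labels <- function(f) {
  lab <- max.col(f, ties.method = "first")
  flagged <- attr(f, "flagged")
  if (!is.null(flagged) && any(flagged)) {
    for (t in which(flagged)) {
      lab[t] <- if (t == 1) 1L else lab[t - 1]
    }
  }
  lab
}

#' Global explained variance of a microstate segmentation
#'
#' GFP-weighted squared spatial correlation between each sample and its
#' assigned template, partitioned by template:
#' total GEV = sum_t GFP_t^2 corr(x_t, T_L(t))^2 / sum_t GFP_t^2.
#'
#' @param eeg An [eeg_recording()].
#' @param templates A [microstate_templates()].
#' @param labels Integer labels aligned with samples.
#' @return List with `total` (scalar) and `per_template` (tibble with
#'   columns `template`, `gev`); the per-template values sum to the total.
#' @export
explained_variance <- function(eeg, templates, labels) {
  tpl <- templates$templates
  x <- sweep(eeg$data, 2, colMeans(eeg$data))
  gfp2 <- colMeans(x^2)
  nrm <- sqrt(colSums(x^2))
  ok <- nrm > 0
  corr <- numeric(length(labels))
  dots <- colSums(x * t(tpl[labels, , drop = FALSE])) # dot(x_t, T_{L_t})
  corr[ok] <- dots[ok] / nrm[ok]
  w <- gfp2 * corr^2
  denom <- sum(gfp2)
  per <- vapply(seq_len(nrow(tpl)), function(i) sum(w[labels == i]) / denom, 0)
  list(total = sum(per),
       per_template = tibble::tibble(template = templates$labels, gev = per))
}

#' Extract microstate templates from one recording
#'
#' Convenience wrapper for the subject-level segmentation pipeline:
#' band-pass filter, GFP, Gaussian-smoothed peak detection, random peak
#' subsampling (up to `max_peaks`), AAHC clustering into `k` templates.
#'
#' @param eeg An [eeg_recording()].
#' @param band Length-2 numeric band in Hz (default `c(2, 20)`).
#' @param k Number of microstate classes.
#' @param max_peaks Maximum GFP peaks submitted to clustering.
#' @param smooth_window GFP smoothing window (samples).
#' @param seed Seed for the peak subsample.
#' @return A [microstate_templates()]; peak indices used are attached as
#'   attribute `"peaks"`.
#' @export
extract_templates <- function(eeg, band = c(2, 20), k = 4, max_peaks = 10000,
                              smooth_window = 5, seed = 1) {
  filt <- bandpass_filter(average_reference(eeg), band[1], band[2])
  gfp <- compute_gfp(filt)
  peaks <- detect_gfp_peaks(gfp, smooth_window, bad_intervals = eeg$bad_intervals)
  peaks <- sample_peaks(peaks, max_peaks, seed = seed)
  maps <- t(filt$data[, peaks, drop = FALSE])
  out <- aahc_cluster(maps, k = k, weights = gfp$values[peaks]^2)
  attr(out, "peaks") <- peaks
  out
}

#' Backfit templates to a recording
#'
#' Computes the similarity matrix and winner-take-all label sequence of a
#' (typically band-passed) recording against a template set.
#'
#' @inheritParams compute_similarity
#' @return List with `similarity` (n x K) and `labels` (integer vector).
#' @export
backfit <- function(eeg, templates) {
  f <- compute_similarity(eeg, templates)
  list(similarity = f, labels = assign_labels(f))
}
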