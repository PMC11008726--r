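#' BOLD dataset container
#'
#' Units (ROIs or voxels) by TR matrix of scaled BOLD signal, with timing,
#' an optional per-TR censor vector, optional integer 3D coordinates (for
#' voxel-mode clustering) and an optional per-unit network parcellation id
#' (0 = background).
#'
#' @param data Numeric matrix, units x n_TR.
#' @param tr Repetition time (s).
#' @param censor Logical vector (TRUE = censored) of length n_TR, or `NULL`.
#' @param unit_coords Optional integer matrix units x 3.
#' @param parcellation Optional integer vector of per-unit network ids.
#' @return A `bold_dataset` object.
#' @export
bold_dataset <- function(data, tr = 2, censor = NULL, unit_coords = NULL,
                         parcellation = NULL) {
  data <- as.matrix(data)
  n_tr <- ncol(data)
  if (is.null(censor)) censor <- rep(FALSE, n_tr)
  if (length(censor) != n_tr) abort("`censor` length must equal n_TR.")
  if (!is.null(unit_coords)) {
    unit_coords <- as.matrix(unit_coords)
    stopifnot(nrow(unit_coords) == nrow(data), ncol(unit_coords) == 3)
    if (anyDuplicated(unit_coords)) abort("Unit coordinates must be unique.")
  }
  if (!is.null(parcellation) && length(parcellation) != nrow(data)) {
    abort("`parcellation` length must equal the number of units.")
  }
  structure(list(data = unname(data), tr = tr, censor = censor,
                 unit_coords = unit_coords, parcellation = parcellation),
            class = "bold_dataset")
}

#' @export
print.bold_dataset <- function(x, ...) {
  cat(sprintf("<bold_dataset> %d units x %d TRs @ %g s (%d censored)\n",
              nrow(x$data), ncol(x$data), x$tr, sum(x$censor)))
  invisible(x)
}

#' Build a subject-level GLM design matrix
#'
#' One microstate regressor of interest (named `ms`) plus the nuisance
#' block: intercept, orthogonal polynomial drift (order 3 by default),
#' motion parameters, and any extra precomputed nuisance columns
#' (e.g. ventricle principal components, local white-matter average).
#'
#' @param regressor TR-rate microstate regressor (length n_TR).
#' @param motion Optional n_TR x m motion parameter matrix.
#' @param extra Optional named n_TR x e matrix of additional nuisances.
#' @param poly_order Drift polynomial order (default 3).
#' @return Numeric matrix n_TR x q with named columns, `ms` first.
#' @export
build_design_matrix <- function(regressor, motion = NULL, extra = NULL,
                                poly_order = 3) {
  n_tr <- length(regressor)
  drift <- poly(seq_len(n_tr), poly_order)
  colnames(drift) <- paste0("poly", seq_len(poly_order))
  X <- cbind(ms = regressor, intercept = rep(1, n_tr), drift)
  if (!is.null(motion)) {
    motion <- as.matrix(motion)
    colnames(motion) <- colnames(motion) %||% paste0("motion", seq_len(ncol(motion)))
    X <- cbind(X, motion)
  }
  if (!is.null(extra)) {
    extra <- as.matrix(extra)
    colnames(extra) <- colnames(extra) %||% paste0("nuis", seq_len(ncol(extra)))
    X <- cbind(X, extra)
  }
  X
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fit the subject-level GLM
#'
#' Ordinary least squares of every unit's BOLD series on the design
#' matrix, with censored TRs removed from both sides. Returns the
#' coefficient of the microstate regressor (column `ms`) per unit.
#'
#' @param bold A [bold_dataset()].
#' @param design Design matrix from [build_design_matrix()].
#' @param censor Optional logical censor vector overriding `bold$censor`.
#' @return Tibble with columns `unit` and `beta`; the full coefficient
#'   matrix is attached as attribute `"coefficients"`.
#' @export
fit_subject_glm <- function(bold, design, censor = NULL) {
  censor <- censor %||% bold$censor
  keep <- !censor
  X <- design[keep, , drop = FALSE]
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    abort(paste0("Design matrix is rank deficient after censoring; ",
                 "collinear column(s): ", paste(bad, collapse = ", ")))
  }
  Y <- t(bold$data[, keep, drop = FALSE])
  coefs <- qr.coef(qrX, Y)                     # q x units
  out <- tibble::tibble(unit = seq_len(nrow(bold$data)),
                        beta = as.numeric(coefs["ms", ]))
  attr(out, "coefficients") <- coefs
  out
}

#' Group-level one-sample t-test on subject betas
#'
#' Per-unit one-sample t statistic of the subject coefficients against
#' zero (t = mean / SE, dof = n_subjects - 1), with two-sided p-values.
#' Zero-variance units get `NA` statistics and are flagged.
#'
#' @param betas Numeric matrix, subjects x units.
#' @return A `group_stat` object: tibble with columns `unit`, `mean_beta`,
#'   `tstat`, `p`, plus attributes `dof` and `flagged`.
#' @export
group_ttest <- function(betas) {
  betas <- as.matrix(betas)
  n <- nrow(betas)
  if (n < 3) abort("Group t-test needs at least 3 subjects.")
  mu <- colMeans(betas)
  s <- apply(betas, 2, sd)
  flagged <- s < .Machine$double.eps^0.5
  tstat <- ifelse(flagged, NA_real_, mu / (s / sqrt(n)))
  p <- 2 * pt(-abs(tstat), df = n - 1)
  out <- tibble::tibble(unit = seq_along(mu), mean_beta = mu,
                        tstat = tstat, p = p)
  attr(out, "dof") <- n - 1L
  attr(out, "flagged") <- flagged
  class(out) <- c("group_stat", class(out))
  out
}

# connected components of a logical mask: chain adjacency (1D ROI mode) or
# 26-connectivity on integer 3D coordinates (voxel mode); union-find
find_clusters <- function(mask, coords = NULL) {
  idx <- which(mask)
  if (length(idx) == 0) return(list())
  if (is.null(coords)) {
    breaks <- c(0, which(diff(idx) != 1), length(idx))
    return(lapply(seq_len(length(breaks) - 1),
                  function(i) idx[(breaks[i] + 1):breaks[i + 1]]))
  }
  sub <- coords[idx, , drop = FALSE]
  key <- function(xyz) paste(xyz[, 1], xyz[, 2], xyz[, 3])
  pos <- setNames(seq_along(idx), key(sub))
  parent <- seq_along(idx)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  for (o in seq_len(nrow(offs))) {
    nb <- sweep(sub, 2, -offs[o, ])
    j <- pos[key(nb)]
    ok <- !is.na(j)
    for (i in which(ok)) {
      ri <- find(i); rj <- find(j[i])
      if (ri != rj) parent[ri] <- rj
    }
  }
  roots <- vapply(seq_along(idx), find, 0L)
  unname(split(idx, roots))
}

# per-unit one-sample t stats for sign-flip permutations, vectorized:
# S: n_perm x n_subjects matrix of +-1; B: subjects x units
perm_tstats <- function(S, B) {
  n <- ncol(S)
  ssq <- colSums(B^2)                         # invariant under sign flips
  M <- (S %*% B) / n                          # n_perm x units means
  V <- (matrix(ssq, nrow(S), length(ssq), byrow = TRUE) - n * M^2) / (n - 1)
  V[V < 0] <- 0
  M / sqrt(V / n)
}

#' Permutation cluster-extent correction
#'
#' Family-wise error control for the group map via sign-flipping: under
#' the null the subject coefficients are symmetric about zero, so each
#' permutation flips subject signs, recomputes the one-sample t map,
#' thresholds at the two-sided voxel-level p, and records the maximum
#' cluster extent. Observed clusters (supra-threshold units of a common
#' sign, chain-adjacent in ROI mode or 26-connected in voxel mode) are
#' significant if their extent reaches the (1 - cluster_p) quantile of the
#' null maximum extent. If there are fewer than `n_perm` distinct sign
#' patterns the flips are enumerated exhaustively.
#'
#' @param betas Subjects x units coefficient matrix.
#' @param voxel_p Two-sided unit-level threshold (default 0.005).
#' @param cluster_p Cluster-level FWE threshold (default 0.05).
#' @param n_perm Number of sign-flip permutations (default 10000; >= 100).
#' @param unit_coords Optional integer units x 3 coordinates for
#'   26-connectivity clustering; `NULL` for chain adjacency.
#' @param seed Integer seed for the sign draws.
#' @return A `cluster_map`: tibble with one row per observed cluster
#'   (`cluster`, `size`, `peak_t`, `sign`, `significant`, `units`
#'   list-column) plus attributes `min_extent` (smallest significant
#'   extent under the null), `t_threshold`, `null_max_extent`, `dof`.
#' @export
permutation_cluster_correction <- function(betas, voxel_p = 0.005,
                                           cluster_p = 0.05, n_perm = 10000,
                                           unit_coords = NULL, seed = 1) {
  betas <- as.matrix(betas)
  n <- nrow(betas)
  if (n_perm < 100) abort("`n_perm` must be at least 100.")
  dof <- n - 1
  tcrit <- qt(1 - voxel_p / 2, df = dof)

  obs <- group_ttest(betas)
  tvec <- obs$tstat
  tvec[is.na(tvec)] <- 0

  cluster_from_t <- function(tv) {
    cl_pos <- find_clusters(tv > tcrit, unit_coords)
    cl_neg <- find_clusters(tv < -tcrit, unit_coords)
    c(cl_pos, cl_neg)
  }

  if (2^n <= n_perm) {
    S <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
  } else {
    S <- withr::with_seed(seed,
      matrix(sample(c(-1, 1), n_perm * n, replace = TRUE), n_perm, n))
  }
  Tperm <- perm_tstats(S, betas)
  null_max <- vapply(seq_len(nrow(Tperm)), function(r) {
    cl <- cluster_from_t(Tperm[r, ])
    if (length(cl) == 0) 0L else max(lengths(cl))
  }, 0L)
  min_extent <- as.integer(quantile(null_max, 1 - cluster_p, type = 1)) + 1L

  clusters <- cluster_from_t(tvec)
  rows <- purrr::map_dfr(seq_along(clusters), function(i) {
    u <- clusters[[i]]
    pk <- u[which.max(abs(tvec[u]))]
    tibble::tibble(cluster = i, size = length(u), peak_t = tvec[pk],
                   sign = sign(tvec[pk]), significant = length(u) >= min_extent,
                   units = list(u))
  })
  if (nrow(rows) == 0) {
    rows <- tibble::tibble(cluster = integer(), size = integer(),
                           peak_t = numeric(), sign = numeric(),
                           significant = logical(), units = list())
  }
  attr(rows, "min_extent") <- min_extent
  attr(rows, "t_threshold") <- tcrit
  attr(rows, "null_max_extent") <- null_max
  attr(rows, "dof") <- dof
  class(rows) <- c("cluster_map", class(rows))
  rows
}

#' Network overlap of significant clusters
#'
#' Percentage of significant-cluster units falling inside each network of
#' a parcellation (0 = background, excluded from network rows but counted
#' in the denominator so percentages can sum to less than 100).
#'
#' @param clusters A `cluster_map` from [permutation_cluster_correction()].
#' @param parcellation Integer per-unit network ids (0 = background).
#' @param networks Optional network ids to report (default: all nonzero
#'   ids present in the parcellation).
#' @return Tibble with columns `network`, `n_units`, `percent`.
#' @export
network_overlap <- function(clusters, parcellation, networks = NULL) {
  if (is.null(networks)) networks <- sort(unique(parcellation[parcellation != 0]))
  sig <- clusters[clusters$significant, , drop = FALSE]
  units <- unlist(sig$units)
  if (length(units) == 0) {
    return(tibble::tibble(network = networks, n_units = 0L, percent = numeric(length(networks))))
  }
  total <- length(units)
  counts <- vapply(networks, function(nw) sum(parcellation[units] == nw), 0L)
  tibble::tibble(network = networks, n_units = counts,
                 percent = 100 * counts / total)
}

#' @importFrom stats pt
NULL
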