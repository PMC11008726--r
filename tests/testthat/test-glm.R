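test_that("subject GLM recovers coefficients and respects censoring", {
  set.seed(20)
  n_tr <- 100
  x <- rnorm(n_tr)
  drift <- 0.3 * seq_len(n_tr) / n_tr
  y <- 2 * x + drift + 5
  bold <- bold_dataset(rbind(y), tr = 2)
  fit <- fit_subject_glm(bold, build_design_matrix(x))
  expect_equal(fit$beta, 2, tolerance = 1e-8)

  # regressor orthogonal to the signal and all nuisances: beta ~ 0
  z <- residuals(lm(rnorm(n_tr) ~ y + poly(seq_len(n_tr), 3)))
  fit0 <- fit_subject_glm(bold, build_design_matrix(z))
  expect_equal(fit0$beta, 0, tolerance = 1e-8)

  # censored rows excluded: corrupt some TRs, censor them, recover beta
  y_bad <- y; y_bad[5:10] <- 1000
  boldc <- bold_dataset(rbind(y_bad), tr = 2,
                        censor = seq_len(n_tr) %in% 5:10)
  fitc <- fit_subject_glm(boldc, build_design_matrix(x))
  expect_equal(fitc$beta, 2, tolerance = 1e-8)

  # rank deficiency names the collinear column
  expect_error(
    fit_subject_glm(bold, build_design_matrix(x, extra = cbind(dup = x))),
    "dup")
})

test_that("subject GLM is unbiased for planted negative coupling", {
  sim <- simulate_subject(n_tr = 220, n_rois = 10,
                          coupling = list(AT_A = -0.5), seed = 31)
  at <- sim$regressors$tr_rate$AT_A
  design <- build_design_matrix(at)
  betas <- vapply(1:100, function(s) {
    bold <- generate_bold(as.matrix(sim$regressors$tr_rate),
                          sapply(colnames(sim$regressors$tr_rate),
                                 function(nm) rep(if (nm == "AT_A") -0.5 else 0, 10),
                                 simplify = FALSE),
                          bold_noise_sd = 1, n_rois = 10, seed = 4000 + s)
    fit_subject_glm(bold, design)$beta[1]
  }, 0)
  mc_se <- sd(betas) / sqrt(100)
  expect_lt(abs(mean(betas) + 0.5), 3 * mc_se)
  expect_lt(abs(mean(betas) + 0.5), 0.05)
})

test_that("group t-test matches its definition and closed-form power", {
  set.seed(21)
  B <- matrix(rnorm(40 * 200), 40, 200)
  gt <- group_ttest(B)
  expect_equal(attr(gt, "dof"), 39L)
  j <- 17
  expect_equal(gt$tstat[j], mean(B[, j]) / (sd(B[, j]) / sqrt(40)),
               tolerance = 1e-12)

  # all-subject-identical unit: zero variance flagged
  B2 <- cbind(B, rep(0.7, 40))
  gt2 <- group_ttest(B2)
  expect_true(is.na(gt2$tstat[201]))
  expect_true(attr(gt2, "flagged")[201])

  # type-I rate at p < 0.005 under the null
  set.seed(22)
  Bnull <- matrix(rnorm(40 * 4000), 40, 4000)
  rate <- mean(group_ttest(Bnull)$p < 0.005)
  expect_lt(abs(rate - 0.005), 0.002)

  # empirical power matches the noncentral-t closed form
  set.seed(23)
  Balt <- matrix(rnorm(40 * 4000, mean = 0.5), 40, 4000)
  emp_power <- mean(group_ttest(Balt)$p < 0.005)
  tcrit <- qt(1 - 0.0025, 39)
  ncp <- 0.5 * sqrt(40)
  theo <- 1 - pt(tcrit, 39, ncp) + pt(-tcrit, 39, ncp)
  expect_lt(abs(emp_power - theo), 0.03)

  expect_error(group_ttest(B[1:2, ]), "3 subjects")
})

test_that("permutation correction finds a planted cluster and not noise", {
  set.seed(24)
  n_sub <- 12; n_unit <- 300
  B <- matrix(rnorm(n_sub * n_unit), n_sub, n_unit)
  block <- 51:250                            # strong 200-unit block
  B[, block] <- B[, block] + 2
  cm <- permutation_cluster_correction(B, n_perm = 500, seed = 3)
  sig_units <- sort(unique(unlist(cm$units[cm$significant])))
  expect_gt(length(intersect(sig_units, block)), 150)
  expect_lt(length(setdiff(sig_units, block)), 20)
  expect_true(all(cm$size[cm$significant] >= attr(cm, "min_extent")))

  # few subjects: exhaustive sign flips
  B5 <- matrix(rnorm(5 * 50), 5, 50)
  cm5 <- permutation_cluster_correction(B5, n_perm = 500, seed = 1)
  expect_length(attr(cm5, "null_max_extent"), 2^5)

  expect_error(permutation_cluster_correction(B, n_perm = 10), "at least 100")
})

test_that("voxel-mode clustering uses 26-connectivity", {
  # two spatially separate blobs on a 5x5x2 grid
  coords <- as.matrix(expand.grid(x = 1:5, y = 1:5, z = 1:2))
  mask <- rep(FALSE, nrow(coords))
  blob1 <- which(coords[, 1] <= 2 & coords[, 2] <= 2)
  blob2 <- which(coords[, 1] >= 4 & coords[, 2] >= 4)
  mask[c(blob1, blob2)] <- TRUE
  cl <- msbold:::find_clusters(mask, coords)
  expect_length(cl, 2)
  expect_setequal(unlist(cl), c(blob1, blob2))
  # diagonal touch merges under 26-connectivity
  m2 <- rep(FALSE, nrow(coords))
  a <- which(coords[, 1] == 2 & coords[, 2] == 2 & coords[, 3] == 1)
  b <- which(coords[, 1] == 3 & coords[, 2] == 3 & coords[, 3] == 2)
  m2[c(a, b)] <- TRUE
  expect_length(msbold:::find_clusters(m2, coords), 1)
})

test_that("permutation correction is invariant to unit relabeling", {
  set.seed(25)
  B <- matrix(rnorm(10 * 80), 10, 80)
  B[, 11:30] <- B[, 11:30] + 1.5
  coords <- cbind(seq_len(80), 1L, 1L)       # chain expressed as 3D coords
  cm1 <- permutation_cluster_correction(B, n_perm = 300, unit_coords = coords,
                                        seed = 5)
  perm <- sample(80)
  cm2 <- permutation_cluster_correction(B[, perm], n_perm = 300,
                                        unit_coords = coords[perm, ],
                                        seed = 5)
  u1 <- sort(unique(unlist(cm1$units[cm1$significant])))
  u2 <- sort(unique(perm[unlist(cm2$units[cm2$significant])]))
  expect_identical(u1, u2)
  expect_identical(attr(cm1, "min_extent"), attr(cm2, "min_extent"))
})

test_that("network overlap percentages match a brute-force tally", {
  parc <- c(rep(1L, 30), rep(2L, 30), rep(3L, 30), rep(0L, 10))
  cm <- tibble::tibble(cluster = 1:2, size = c(10L, 5L),
                       peak_t = c(4, -4), sign = c(1, -1),
                       significant = c(TRUE, TRUE),
                       units = list(1:10, 25:29))
  class(cm) <- c("cluster_map", class(cm))
  ov <- network_overlap(cm, parc)
  units <- c(1:10, 25:29)
  for (nw in 1:3) {
    expect_equal(ov$percent[ov$network == nw],
                 100 * sum(parc[units] == nw) / length(units))
  }
  # single cluster fully inside one network
  cm2 <- cm[1, ]; cm2$units <- list(31:40)
  class(cm2) <- c("cluster_map", class(cm2))
  ov2 <- network_overlap(cm2, parc)
  expect_equal(ov2$percent, c(0, 100, 0))
  # empty map: zero table
  cm0 <- cm[0, ]
  expect_true(all(network_overlap(cm0, parc)$percent == 0))
})

test_that("tidiers summarise GLM results", {
  set.seed(26)
  B <- matrix(rnorm(8 * 40), 8, 40)
  gt <- group_ttest(B)
  expect_named(tidy(gt), c("unit", "mean_beta", "tstat", "p"))
  expect_equal(glance(gt)$n_units, 40)
  cm <- permutation_cluster_correction(B, n_perm = 200, seed = 2)
  expect_false("units" %in% names(tidy(cm)))
  expect_equal(glance(cm)$n_clusters, nrow(cm))
})
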