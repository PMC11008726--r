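test_that("AAHC separates exact sign-flipped clusters perfectly", {
  tpl <- generate_templates(16, 4, smoothness = 0, seed = 1)
  set.seed(2)
  lab <- sample(1:4, 200, replace = TRUE)
  maps <- tpl[lab, ] * sample(c(-1, 1), 200, replace = TRUE)
  out <- aahc_cluster(maps, k = 4)
  cors <- template_match(out$templates, tpl)
  expect_equal(unname(cors), rep(1, 4), tolerance = 1e-9)
})

test_that("AAHC recovers planted templates from noisy peak maps", {
  tpl <- generate_templates(32, 4, smoothness = 0.5, seed = 7)
  set.seed(7)
  lab <- sample(1:4, 1200, replace = TRUE)
  maps <- tpl[lab, ] * sample(c(-1, 1), 1200, replace = TRUE) +
    matrix(rnorm(1200 * 32, sd = 0.2), 1200, 32)
  out <- aahc_cluster(maps, k = 4)
  cors <- template_match(out$templates, tpl)
  expect_true(all(cors >= 0.95))
})

test_that("AAHC degenerate and error cases behave", {
  set.seed(1)
  maps <- matrix(rnorm(50 * 8), 50, 8)
  one <- aahc_cluster(maps, k = 1)
  # k = 1: template equals the first principal direction of all maps
  norm_maps <- maps - rowMeans(maps)
  norm_maps <- norm_maps / sqrt(rowSums(norm_maps^2))
  pc1 <- eigen(crossprod(norm_maps), symmetric = TRUE)$vectors[, 1]
  expect_equal(abs(sum(one$templates[1, ] * pc1 / sqrt(sum(pc1^2)))), 1,
               tolerance = 1e-9)
  expect_error(aahc_cluster(maps[1:3, ], k = 4), "m > k")
})

test_that("AAHC agrees with the exhaustive 2-partition oracle", {
  tpl <- generate_templates(6, 2, smoothness = 0, seed = 3)
  set.seed(3)
  lab <- rep(1:2, each = 6)
  maps <- tpl[lab, ] * sample(c(-1, 1), 12, replace = TRUE) +
    matrix(rnorm(12 * 6, sd = 0.3), 12, 6)
  maps <- maps - rowMeans(maps)
  maps <- maps / sqrt(rowSums(maps^2))
  aahc <- attr(aahc_cluster(maps, k = 2), "assignment")
  oracle <- exhaustive_two_partition(maps)$assignment
  agree <- max(mean(aahc == oracle), mean(aahc == 3 - oracle))
  expect_gte(agree, 0.9)
})

test_that("group alignment undoes permutations and sign flips exactly", {
  ref <- microstate_templates(generate_templates(16, 4, seed = 4))
  perms <- list(c(2, 1, 4, 3), c(3, 4, 1, 2), c(4, 3, 2, 1))
  subs <- lapply(perms, function(pm) {
    sgn <- rep(c(-1, 1), 2)
    microstate_templates(ref$templates[pm, ] * sgn)
  })
  grp <- align_and_average_templates(subs, reference = ref)
  expect_equal(grp$templates, ref$templates, tolerance = 1e-9)
  expect_equal(grp$level, "group")

  # single subject: aligned output equals that subject's set
  solo <- align_and_average_templates(subs[1])
  expect_equal(abs(solo$templates %*% t(subs[[1]]$templates)) |> diag() |>
                 sort(decreasing = TRUE) |> head(1), 1, tolerance = 1e-9,
               ignore_attr = TRUE)

  # noise averaging: group correlation to truth beats each individual's
  noisy <- lapply(1:6, function(s) {
    set.seed(s)
    microstate_templates(ref$templates + matrix(rnorm(64, sd = 0.15), 4, 16))
  })
  grp2 <- align_and_average_templates(noisy, reference = ref)
  grp_cor <- mean(abs(diag(grp2$templates %*% t(ref$templates))))
  ind_cor <- vapply(noisy, function(s) {
    mean(template_match(s$templates, ref$templates))
  }, 0)
  expect_true(all(grp_cor >= ind_cor))

  bad <- microstate_templates(generate_templates(8, 4, seed = 1))
  expect_error(align_and_average_templates(list(ref, bad)), "share")
})

test_that("similarity is absolute cosine with flagged zero-norm samples", {
  tpl <- microstate_templates(generate_templates(8, 3, smoothness = 0, seed = 5))
  X <- t(rbind(tpl$templates[2, ],          # equals template 2
               -tpl$templates[2, ],         # negated: polarity invariance
               tpl$templates[1, ],
               0 * tpl$templates[1, ]))     # zero-norm sample
  f <- compute_similarity(eeg_recording(X, 250), tpl)
  expect_equal(unname(f[1, 2]), 1, tolerance = 1e-9)
  expect_equal(unname(f[2, 2]), 1, tolerance = 1e-9)
  expect_equal(unname(f[3, 1]), 1, tolerance = 1e-9)
  expect_equal(unname(f[4, ]), rep(0, 3))
  expect_true(all(f >= 0 & f <= 1))
  expect_identical(attr(f, "flagged"), c(FALSE, FALSE, FALSE, TRUE))

  # orthogonal sample: zero row
  tpl2 <- microstate_templates(generate_templates(8, 4, smoothness = 0, seed = 5))
  ortho <- tpl2$templates[4, ]
  f2 <- compute_similarity(eeg_recording(cbind(ortho), 250),
                           microstate_templates(tpl2$templates[1:3, ]))
  expect_equal(max(f2), 0, tolerance = 1e-9)
})

test_that("winner-take-all labels follow argmax, ties and carry-forward rules", {
  f <- rbind(c(0.9, 0.1, 0.2, 0.3),
             c(0.1, 0.5, 0.5, 0.2),   # tie between 2 and 3 -> 2
             c(0.0, 0.0, 0.0, 0.1))
  expect_identical(assign_labels(f), c(1L, 2L, 4L))

  # flagged rows inherit the previous label; label 1 if first
  fz <- rbind(c(0, 0, 0), c(0.2, 0.9, 0.1), c(0, 0, 0))
  attr(fz, "flagged") <- c(TRUE, FALSE, TRUE)
  expect_identical(assign_labels(fz), c(1L, 2L, 2L))
})

test_that("backfitting a planted sequence reproduces its labels", {
  tpl <- generate_templates(16, 4, smoothness = 0, seed = 6)
  lab <- c(1L, 1L, 1L, 3L, 3L, 4L, 4L, 1L, 1L, 2L, 2L, 1L, 2L, 3L)
  eeg <- make_template_eeg(tpl, lab, seed = 8)
  bf <- backfit(eeg, microstate_templates(tpl))
  expect_identical(bf$labels, lab)
})

test_that("explained variance is 1 for noiseless data and matches the oracle", {
  tpl <- generate_templates(12, 4, smoothness = 0, seed = 9)
  set.seed(9)
  lab <- sample(1:4, 300, replace = TRUE)
  amp <- runif(300, 0.5, 2)
  eeg <- make_template_eeg(tpl, lab, amp, noise_sd = 0, seed = 2)
  tset <- microstate_templates(tpl)
  ev <- explained_variance(eeg, tset, lab)
  expect_equal(ev$total, 1, tolerance = 1e-9)
  expect_equal(sum(ev$per_template$gev), ev$total, tolerance = 1e-12)

  # random labels explain less than the true assignment
  set.seed(10)
  ev_rand <- explained_variance(eeg, tset, sample(1:4, 300, replace = TRUE))
  expect_lt(ev_rand$total, ev$total)

  # noisy fixture equals the brute-force per-sample recomputation
  eeg_n <- make_template_eeg(tpl, lab, amp, noise_sd = 0.2, seed = 7)
  bf <- backfit(eeg_n, tset)
  ev_n <- explained_variance(eeg_n, tset, bf$labels)
  expect_equal(ev_n$total, naive_gev(eeg_n$data, tpl, bf$labels),
               tolerance = 1e-10)
})
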