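test_that("delay matrix stacks lagged inputs without leakage", {
  dm <- build_delay_matrix(cbind(1:4), max_delay = 2, horizon = 1)
  expect_equal(dm$X, rbind(c(2, 1), c(3, 2)))
  expect_equal(dm$target_rows, 3:4)

  dm1 <- build_delay_matrix(cbind(1:5), max_delay = 1)
  expect_equal(dm1$X, cbind(1:4))
  expect_equal(dm1$target_rows, 2:5)

  # horizon 2 shifts all lags one step further back
  dm2 <- build_delay_matrix(cbind(1:6), max_delay = 2, horizon = 2)
  expect_equal(dm2$X, rbind(c(2, 1), c(3, 2), c(4, 3)))
  expect_equal(dm2$target_rows, 4:6)

  # two inputs: columns grouped by lag
  dmm <- build_delay_matrix(cbind(a = 1:4, b = 11:14), max_delay = 2)
  expect_equal(dmm$colnames, c("a_lag1", "b_lag1", "a_lag2", "b_lag2"))
  expect_equal(dmm$X[1, ], c(2, 12, 1, 11))

  expect_error(build_delay_matrix(cbind(1:3), max_delay = 3), "too short")
  expect_error(build_delay_matrix(cbind(1:9), 2, horizon = 3), "1 or 2")
})

test_that("training learns a noiseless linear map and is seed-deterministic", {
  set.seed(30)
  X <- matrix(rnorm(80 * 3), 80, 3)
  Y <- X %*% matrix(c(1, -2, 0.5, 0.3, 1, -1), 3, 2)
  m1 <- train_mtdnn(X, Y, n_hidden = 10, reg = 1e-4, seed = 1, epochs = 200)
  r <- diag(cor(predict(m1, X), Y))
  expect_true(all(r >= 0.99))

  m2 <- train_mtdnn(X, Y, n_hidden = 10, reg = 1e-4, seed = 1, epochs = 200)
  expect_identical(m1$W, m2$W)
  expect_identical(m1$V, m2$V)

  # constant rows give constant predictions
  Xc <- matrix(1, 5, 3)
  pc <- predict(m1, Xc)
  expect_equal(apply(pc, 2, sd), c(0, 0), tolerance = 1e-12)

  expect_error(train_mtdnn(cbind(c(1, NA)), cbind(1:2)), "Non-finite")
})

test_that("with identity activation and tiny penalty the network matches OLS", {
  set.seed(31)
  n <- 120
  inputs <- matrix(rnorm(n * 2), n, 2)
  targets <- cbind(0.8 * c(0, inputs[-n, 1]) + 0.1 * rnorm(n),
                   -0.5 * c(0, inputs[-n, 2]) + 0.1 * rnorm(n))
  dm <- build_delay_matrix(inputs, max_delay = 2)
  Y <- targets[dm$target_rows, ]
  mod <- train_mtdnn(dm$X, Y, n_hidden = 8, reg = 1e-9, seed = 2,
                     epochs = 500, activation = "identity")
  pred_nn <- predict(mod, dm$X)
  pred_ols <- cbind(1, dm$X) %*% qr.coef(qr(cbind(1, dm$X)), Y)
  for (j in 1:2) {
    expect_gt(cor(pred_nn[, j], pred_ols[, j]), 1 - 1e-3)
  }
})

test_that("held-out correlation is near zero for independent targets", {
  rs <- vapply(1:20, function(s) {
    set.seed(1000 + s)
    n <- 70
    x <- matrix(rnorm(n * 3), n, 3)
    y <- matrix(rnorm(n * 2), n, 2)
    cv <- expanding_window_cv(x, y, initial = 31, n_hidden = 5, max_delay = 1,
                              epochs = 40, seed = s)
    mean(cv$r, na.rm = TRUE)
  }, 0)
  expect_true(all(abs(rs) < 0.2))
})

test_that("expanding-window bookkeeping and skipping follow the design", {
  set.seed(32)
  n <- 34
  x <- matrix(rnorm(n), n, 1)
  y <- matrix(0.9 * c(0, x[-n, 1]) + 0.05 * rnorm(n), n, 1)
  cv <- expanding_window_cv(x, y, initial = 31, n_hidden = 5, max_delay = 1,
                            epochs = 50, seed = 1)
  # k = 31, 32: two steps for each horizon
  expect_equal(cv$n_test[cv$horizon == 1], 2)
  expect_equal(cv$n_test[cv$horizon == 2], 2)

  # censored test TRs are skipped and counted
  censor <- rep(FALSE, n); censor[33] <- TRUE
  cvc <- expanding_window_cv(x, y, initial = 31, n_hidden = 5, max_delay = 1,
                             epochs = 50, seed = 1, censor = censor)
  expect_equal(attr(cvc, "n_skipped"), 2L)   # tested at both horizons

  expect_error(expanding_window_cv(x[1:20, , drop = FALSE],
                                   y[1:20, , drop = FALSE], initial = 31),
               "initial")
  expect_error(expanding_window_cv(x, y[1:20, , drop = FALSE]), "equal TR")
})

test_that("predictions never use information beyond the training window", {
  set.seed(33)
  n <- 40
  x <- matrix(rnorm(n * 2), n, 2)
  y <- matrix(0.8 * c(0, x[-n, 1]) + 0.1 * rnorm(n), n, 1)
  cv1 <- expanding_window_cv(x, y, initial = 31, n_hidden = 5, max_delay = 1,
                             epochs = 50, seed = 4)
  # perturb everything after the first fold's horizon-2 test point
  x2 <- x; y2 <- y
  x2[34:n, ] <- rnorm(length(34:n) * 2)
  y2[34:n, ] <- rnorm(length(34:n))
  cv2 <- expanding_window_cv(x2, y2, initial = 31, n_hidden = 5, max_delay = 1,
                             epochs = 50, seed = 4)
  p1 <- attr(cv1, "predictions")$pred
  p2 <- attr(cv2, "predictions")$pred
  expect_equal(p1[["1"]][[1]], p2[["1"]][[1]], tolerance = 1e-12)
  expect_equal(p1[["2"]][[1]], p2[["2"]][[1]], tolerance = 1e-12)
})

test_that("grid search selects the true lag on a lag-3 fixture", {
  hits <- vapply(1:20, function(s) {
    set.seed(2000 + s)
    n <- 40
    x <- matrix(rnorm(n), n, 1)
    y <- matrix(c(rep(0, 3), x[seq_len(n - 3), 1]) + 0.05 * rnorm(n), n, 1)
    gs <- grid_search_tdnn(x, y, neuron_grid = 5, delay_grid = 1:3,
                           window = 30, seed = s, epochs = 80)
    gs$max_delay == 3
  }, TRUE)
  expect_gte(mean(hits), 0.8)

  # a one-cell grid returns that cell
  set.seed(34)
  x <- matrix(rnorm(40), 40, 1); y <- matrix(rnorm(40), 40, 1)
  gs1 <- grid_search_tdnn(x, y, neuron_grid = 7, delay_grid = 2, window = 30)
  expect_equal(gs1$n_hidden, 7)
  expect_equal(gs1$max_delay, 2)

  # pure-noise target still returns a valid grid member
  gsn <- grid_search_tdnn(x, y, neuron_grid = c(5, 10), delay_grid = 1:2,
                          window = 30, seed = 9, epochs = 40)
  expect_true(gsn$n_hidden %in% c(5, 10))
  expect_true(gsn$max_delay %in% 1:2)
})

test_that("the four experiments have the right shapes and ids", {
  set.seed(35)
  n <- 40
  dt_regs <- matrix(rnorm(n * 4), n, 4,
                    dimnames = list(NULL, paste0("DT_", LETTERS[1:4])))
  dyn_regs <- matrix(rnorm(n * 20), n, 20)
  bold <- matrix(rnorm(n * 7), n, 7, dimnames = list(NULL, paste0("net", 1:7)))
  res <- run_four_experiments(dt_regs, dyn_regs, bold, initial = 31,
                              n_hidden = 5, max_delay = 1, epochs = 30, seed = 1)
  expect_setequal(unique(res$experiment), c("a", "b", "c", "d"))
  counts <- table(res$experiment, res$horizon)
  expect_equal(unname(counts["a", "1"]), 7)   # 20 inputs -> 7 outputs
  expect_equal(unname(counts["c", "1"]), 20)  # 7 inputs -> 20 outputs
  expect_equal(unname(counts["d", "2"]), 4)
  expect_error(run_four_experiments(dt_regs[1:20, ], dyn_regs, bold),
               "aligned")
})
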