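#' Build a tapped delay-line design matrix
#'
#' Stacks lagged copies of every input series into predictor rows. The row
#' targeting time t contains x_{t-h}, ..., x_{t-h-max_delay+1} for every
#' input, where `horizon` h is 1 (default) or 2; no current-time values
#' leak into the predictors.
#'
#' @param inputs Numeric matrix n_TR x r (columns = input series).
#' @param max_delay Number of past TRs per input (1..5 in the usual grid).
#' @param horizon Prediction horizon in TRs (1 or 2).
#' @return List with `X` (rows x r*max_delay, columns named
#'   `<input>_lag<l>`), and `target_rows` (time indices the rows target).
#' @export
build_delay_matrix <- function(inputs, max_delay, horizon = 1) {
  inputs <- as.matrix(inputs)
  n <- nrow(inputs)
  r <- ncol(inputs)
  if (!horizon %in% c(1, 2)) abort("`horizon` must be 1 or 2.")
  first <- max_delay + horizon
  if (n < first + 1) abort("Series too short for the requested delays.")
  rows <- first:n
  lags <- horizon:(horizon + max_delay - 1)
  X <- do.call(cbind, lapply(lags, function(l) inputs[rows - l, , drop = FALSE]))
  nms <- colnames(inputs) %||% paste0("x", seq_len(r))
  colnames(X) <- as.vector(vapply(lags, function(l) paste0(nms, "_lag", l),
                                  character(r)))
  list(X = unname(X) , colnames = colnames(X), target_rows = rows)
}

tdnn_pack <- function(W, b, V, c) c(as.numeric(W), b, as.numeric(V), c)

tdnn_unpack <- function(theta, m, d, o) {
  i <- 0
  W <- matrix(theta[i + seq_len(m * d)], m, d); i <- i + m * d
  b <- theta[i + seq_len(m)]; i <- i + m
  V <- matrix(theta[i + seq_len(o * m)], o, m); i <- i + o * m
  c <- theta[i + seq_len(o)]
  list(W = W, b = b, V = V, c = c)
}

tdnn_forward <- function(par, X, activation) {
  A <- X %*% t(par$W) + matrix(par$b, nrow(X), length(par$b), byrow = TRUE)
  H <- if (activation == "tanh") tanh(A) else A
  Yhat <- H %*% t(par$V) + matrix(par$c, nrow(X), length(par$c), byrow = TRUE)
  list(A = A, H = H, Yhat = Yhat)
}

#' Train a multi-output time-delay neural network
#'
#' One shared hidden layer (tanh by default) maps the tapped delay-line
#' predictors to all outputs simultaneously, so the hidden weights are
#' shared across outputs. The objective is mean squared error plus an L2
#' penalty on the weight matrices, minimized with BFGS using analytic
#' gradients; `epochs` bounds the number of BFGS iterations.
#' Deterministic given `seed` (which fixes the weight initialization).
#'
#' @param X Predictor matrix (rows x d), e.g. from [build_delay_matrix()].
#' @param Y Target matrix (rows x o).
#' @param n_hidden Hidden-layer width m.
#' @param reg L2 penalty strength (default 1e-2).
#' @param seed Integer seed for initialization.
#' @param epochs Maximum optimizer iterations (default 100).
#' @param activation `"tanh"` (default) or `"identity"`.
#' @param bias Include bias terms (default TRUE).
#' @return A `tdnn_model` with weights `W`, `b`, `V`, `c`, the
#'   configuration, and the final loss.
#' @export
train_mtdnn <- function(X, Y, n_hidden = 10, reg = 1e-2, seed = 1,
                        epochs = 100, activation = c("tanh", "identity"),
                        bias = TRUE) {
  activation <- match.arg(activation)
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (any(!is.finite(X)) || any(!is.finite(Y))) abort("Non-finite training values.")
  n <- nrow(X); d <- ncol(X); o <- ncol(Y); m <- n_hidden

  obj <- function(theta) {
    par <- tdnn_unpack(theta, m, d, o)
    fwd <- tdnn_forward(par, X, activation)
    E <- fwd$Yhat - Y
    mean(E^2) + reg * (sum(par$W^2) + sum(par$V^2))
  }
  grad <- function(theta) {
    par <- tdnn_unpack(theta, m, d, o)
    fwd <- tdnn_forward(par, X, activation)
    E <- fwd$Yhat - Y                        # n x o
    scale <- 2 / (n * o)
    gV <- scale * t(E) %*% fwd$H + 2 * reg * par$V
    gc <- if (bias) scale * colSums(E) else numeric(o)
    dH <- E %*% par$V                        # n x m
    dA <- if (activation == "tanh") dH * (1 - fwd$H^2) else dH
    gW <- scale * t(dA) %*% X + 2 * reg * par$W
    gb <- if (bias) scale * colSums(dA) else numeric(m)
    tdnn_pack(gW, gb, gV, gc)
  }

  theta0 <- withr::with_seed(seed, {
    w0 <- rnorm(m * d, sd = 1 / sqrt(d))
    v0 <- rnorm(o * m, sd = 1 / sqrt(m))
    c(w0, numeric(m), v0, numeric(o))
  })
  fit <- optim(theta0, obj, grad, method = "BFGS",
               control = list(maxit = epochs, reltol = 1e-10))
  if (!is.finite(fit$value)) {
    abort(sprintf("Training diverged (loss = %g, n = %d, m = %d).",
                  fit$value, n, m))
  }
  par <- tdnn_unpack(fit$par, m, d, o)
  structure(list(W = par$W, b = par$b, V = par$V, c = par$c,
                 n_hidden = m, activation = activation, reg = reg,
                 seed = seed, epochs = epochs, loss = fit$value,
                 d = d, o = o),
            class = "tdnn_model")
}

#' @export
print.tdnn_model <- function(x, ...) {
  cat(sprintf("<tdnn_model> %d inputs -> %d hidden (%s) -> %d outputs, reg %g, loss %.4g\n",
              x$d, x$n_hidden, x$activation, x$o, x$reg, x$loss))
  invisible(x)
}

#' Predict from a trained mTDNN
#'
#' @param object A `tdnn_model`.
#' @param newdata Predictor rows (matching the training delay structure;
#'   for horizon-2 forecasts supply rows built with `horizon = 2` and a
#'   model trained on such rows - the direct multi-step strategy).
#' @param ... Unused.
#' @return Numeric matrix rows x o of predictions.
#' @export
predict.tdnn_model <- function(object, newdata, ...) {
  newdata <- matrix(as.numeric(newdata), ncol = object$d)
  tdnn_forward(object, newdata, object$activation)$Yhat
}

#' Grid search for mTDNN architecture
#'
#' Evaluates every (hidden width, delay) pair on the first `window` TRs
#' using an internal chronological 80/20 split, scoring by the average
#' Pearson correlation between true and predicted outputs on the held-out
#' tail, and returns the best pair (ties resolve to the earlier grid
#' entry). If every fit is degenerate the first grid cell is returned with
#' a warning.
#'
#' @param inputs,targets TR-rate matrices (n x r, n x o).
#' @param neuron_grid Candidate hidden widths (default `c(5, 10, 20, 40)`).
#' @param delay_grid Candidate delays (default `1:5`).
#' @param window Number of initial TRs used (default 30).
#' @param seed,reg,epochs,activation Passed to [train_mtdnn()].
#' @return List with `n_hidden`, `max_delay`, and the score table
#'   (`scores` tibble).
#' @export
grid_search_tdnn <- function(inputs, targets, neuron_grid = c(5, 10, 20, 40),
                             delay_grid = 1:5, window = 30, seed = 1,
                             reg = 1e-2, epochs = 100,
                             activation = "tanh") {
  inputs <- as.matrix(inputs); targets <- as.matrix(targets)
  if (nrow(inputs) < window) abort("Need at least `window` TRs for the grid search.")
  xin <- inputs[seq_len(window), , drop = FALSE]
  yin <- targets[seq_len(window), , drop = FALSE]
  grid <- expand.grid(n_hidden = neuron_grid, max_delay = delay_grid)
  scores <- vapply(seq_len(nrow(grid)), function(g) {
    md <- grid$max_delay[g]
    dm <- build_delay_matrix(xin, md, horizon = 1)
    Xg <- dm$X; Yg <- yin[dm$target_rows, , drop = FALSE]
    n_tr_rows <- floor(0.8 * nrow(Xg))
    if (n_tr_rows < 2 || nrow(Xg) - n_tr_rows < 2) return(NA_real_)
    tr_idx <- seq_len(n_tr_rows)
    mod <- train_mtdnn(Xg[tr_idx, , drop = FALSE], Yg[tr_idx, , drop = FALSE],
                       n_hidden = grid$n_hidden[g], reg = reg, seed = seed,
                       epochs = epochs, activation = activation)
    pred <- predict(mod, Xg[-tr_idx, , drop = FALSE])
    obs <- Yg[-tr_idx, , drop = FALSE]
    rs <- vapply(seq_len(ncol(obs)), function(j) {
      if (sd(obs[, j]) == 0 || sd(pred[, j]) == 0) return(NA_real_)
      cor(obs[, j], pred[, j])
    }, 0)
    mean(rs, na.rm = TRUE)
  }, 0)
  if (all(is.na(scores))) {
    warn("All grid cells degenerate; returning the first grid entry.")
    best <- 1L
  } else {
    best <- which.max(scores)
  }
  list(n_hidden = grid$n_hidden[best], max_delay = grid$max_delay[best],
       scores = tibble::as_tibble(cbind(grid, score = scores)))
}

#' Expanding-window time-series cross-validation
#'
#' Chronological evaluation: train on TRs 1..k, predict TR k+1 (horizon 1)
#' and TR k+2 (horizon 2, from a separately trained direct 2-step model),
#' then grow the window by one TR, for k = `initial` .. n-2. Pooled
#' Pearson correlation between true and predicted values over all test
#' points is reported per output and horizon. Censored test TRs are
#' skipped and counted.
#'
#' @param inputs,targets TR-rate matrices (n x r, n x o).
#' @param initial Initial training length in TRs (default 31).
#' @param n_hidden,max_delay Architecture (e.g. from [grid_search_tdnn()]).
#' @param reg,epochs,activation,seed Passed to [train_mtdnn()].
#' @param censor Optional logical per-TR censor vector; censored test TRs
#'   are skipped.
#' @return A `cv_result` tibble: columns `output`, `horizon`, `r`,
#'   `n_test`; attribute `"n_skipped"` counts censored test points, and
#'   `"predictions"` holds the pooled truth/prediction pairs.
#' @export
expanding_window_cv <- function(inputs, targets, initial = 31, n_hidden = 10,
                                max_delay = 1, reg = 1e-2, epochs = 100,
                                activation = "tanh", seed = 1, censor = NULL) {
  inputs <- as.matrix(inputs); targets <- as.matrix(targets)
  n <- nrow(inputs)
  if (nrow(targets) != n) abort("Inputs and targets must have equal TR counts.")
  if (n < initial + 3) abort("Need at least `initial` + 3 TRs.")
  o <- ncol(targets)
  onames <- colnames(targets) %||% paste0("y", seq_len(o))
  if (is.null(censor)) censor <- rep(FALSE, n)

  preds <- list(`1` = list(), `2` = list())
  truths <- list(`1` = list(), `2` = list())
  n_skipped <- 0L
  for (k in initial:(n - 2)) {
    for (h in 1:2) {
      t_test <- k + h
      if (censor[t_test]) { n_skipped <- n_skipped + 1L; next }
      dm <- build_delay_matrix(inputs[seq_len(t_test), , drop = FALSE],
                               max_delay, horizon = h)
      train_rows <- dm$target_rows <= k
      if (sum(train_rows) < 3) next
      mod <- train_mtdnn(dm$X[train_rows, , drop = FALSE],
                         targets[dm$target_rows[train_rows], , drop = FALSE],
                         n_hidden = n_hidden, reg = reg, seed = seed + k,
                         epochs = epochs, activation = activation)
      test_row <- which(dm$target_rows == t_test)
      ph <- as.character(h)
      preds[[ph]][[length(preds[[ph]]) + 1]] <-
        predict(mod, dm$X[test_row, , drop = FALSE])
      truths[[ph]][[length(truths[[ph]]) + 1]] <-
        targets[t_test, , drop = FALSE]
    }
  }

  out <- purrr::map_dfr(1:2, function(h) {
    ph <- as.character(h)
    P <- do.call(rbind, preds[[ph]])
    Tm <- do.call(rbind, truths[[ph]])
    purrr::map_dfr(seq_len(o), function(j) {
      r <- if (is.null(P) || nrow(P) < 3 || sd(Tm[, j]) == 0 || sd(P[, j]) == 0) {
        NA_real_
      } else cor(Tm[, j], P[, j])
      tibble::tibble(output = onames[j], horizon = h, r = r,
                     n_test = if (is.null(P)) 0L else nrow(P))
    })
  })
  attr(out, "n_skipped") <- n_skipped
  attr(out, "predictions") <- list(pred = preds, truth = truths)
  class(out) <- c("cv_result", class(out))
  out
}

#' Run the four bidirectional prediction experiments
#'
#' The four microstate/BOLD prediction tasks evaluated with
#' [expanding_window_cv()]: (a) BOLD from microstate dynamics (20 activity
#' + transition regressors -> 7 network signals); (b) BOLD from microstate
#' direct time courses (4 -> 7); (c) microstate dynamics from BOLD
#' (7 -> 20); (d) microstate time courses from BOLD (7 -> 4).
#'
#' @param dt_regs n x 4 matrix of TR-rate direct time-course regressors.
#' @param dyn_regs n x 20 matrix of TR-rate activity + transition
#'   regressors.
#' @param bold n x 7 matrix of TR-rate network BOLD signals.
#' @param initial,n_hidden,max_delay,reg,epochs,activation,seed,censor
#'   Passed to [expanding_window_cv()].
#' @return Tibble binding the four `cv_result`s with an `experiment`
#'   column in `c("a","b","c","d")`.
#' @export
run_four_experiments <- function(dt_regs, dyn_regs, bold, initial = 31,
                                 n_hidden = 10, max_delay = 1, reg = 1e-2,
                                 epochs = 100, activation = "tanh", seed = 1,
                                 censor = NULL) {
  dt_regs <- as.matrix(dt_regs); dyn_regs <- as.matrix(dyn_regs)
  bold <- as.matrix(bold)
  n <- nrow(bold)
  if (nrow(dt_regs) != n || nrow(dyn_regs) != n) {
    abort("All series must be aligned with the same number of TRs.")
  }
  specs <- list(a = list(x = dyn_regs, y = bold),
                b = list(x = dt_regs, y = bold),
                c = list(x = bold, y = dyn_regs),
                d = list(x = bold, y = dt_regs))
  purrr::map_dfr(names(specs), function(id) {
    cv <- expanding_window_cv(specs[[id]]$x, specs[[id]]$y, initial = initial,
                              n_hidden = n_hidden, max_delay = max_delay,
                              reg = reg, epochs = epochs,
                              activation = activation, seed = seed,
                              censor = censor)
    dplyr::mutate(tibble::as_tibble(cv), experiment = id, .before = 1)
  })
}
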