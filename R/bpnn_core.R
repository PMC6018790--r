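#' @title Three-layer back-propagation network
#' @description Feedforward network with one tanh hidden layer and an
#'   identity output neuron, trained by full-batch gradient descent on the
#'   mean squared error, plus the hidden-layer size search over
#'   round(sqrt(m + n)) + alpha, alpha = 1..10.
#' @name bpnn_core
NULL

#' Training configuration
#'
#' @param learning_rate Gradient-descent step size (default 0.1).
#' @param max_epochs Maximum number of full-batch epochs (default 1000).
#' @param error_goal Stop once the epoch MSE (on the normalized dose scale)
#'   drops to this value or below (default 0.001).
#' @return Object of class `train_config`.
#' @export
train_config <- function(learning_rate = 0.1, max_epochs = 1000, error_goal = 0.001) {
  if (learning_rate < 0) stop_invalid("train_config: learning_rate must be >= 0")
  if (max_epochs < 1) stop_invalid("train_config: max_epochs must be >= 1")
  if (error_goal < 0) stop_invalid("train_config: error_goal must be >= 0")
  structure(list(learning_rate = learning_rate, max_epochs = as.integer(max_epochs),
                 error_goal = error_goal),
            class = "train_config")
}

#' Random network initialisation
#'
#' All weights and thresholds (biases) drawn i.i.d. uniform on \[-1, 1\].
#'
#' @param m Input neurons. @param h Hidden neurons. @param n Output neurons.
#' @param seed Integer seed for reproducibility.
#' @return Object of class `network_parameters`: `w_ih` (h x m), `b_h` (h),
#'   `w_ho` (n x h), `b_o` (n).
#' @export
init_network <- function(m, h, n = 1, seed = NULL) {
  if (m < 1 || h < 1 || n < 1) stop_invalid("init_network: m, h, n must be >= 1")
  with_seed(seed, {
    structure(list(w_ih = matrix(stats::runif(h * m, -1, 1), h, m),
                   b_h = stats::runif(h, -1, 1),
                   w_ho = matrix(stats::runif(n * h, -1, 1), n, h),
                   b_o = stats::runif(n, -1, 1),
                   m = as.integer(m), h = as.integer(h), n = as.integer(n)),
              class = "network_parameters")
  })
}

#' Forward pass
#'
#' `y = w_ho . tanh(w_ih . x + b_h) + b_o` per row of `x`.
#'
#' @param params `network_parameters`.
#' @param x Numeric matrix, one row per sample, `m` columns.
#' @return Numeric matrix of predictions (rows x n; a vector when n = 1).
#' @export
forward <- function(params, x) {
  x <- as.matrix(x)
  if (ncol(x) != params$m) {
    stop_invalid("forward: input has ", ncol(x), " columns but the network expects ", params$m)
  }
  hid <- tanh(x %*% t(params$w_ih) + matrix(params$b_h, nrow(x), params$h, byrow = TRUE))
  out <- hid %*% t(params$w_ho) + matrix(params$b_o, nrow(x), params$n, byrow = TRUE)
  if (params$n == 1) as.vector(out) else out
}

# Analytic gradient of the mean squared error w.r.t. all parameters.
# Shared by training and the finite-difference oracle in the tests.
bp_gradient <- function(params, x, y) {
  x <- as.matrix(x)
  y <- matrix(y, nrow(x), params$n)
  ns <- nrow(x)
  hlin <- x %*% t(params$w_ih) + matrix(params$b_h, ns, params$h, byrow = TRUE)
  hid <- tanh(hlin)
  yhat <- hid %*% t(params$w_ho) + matrix(params$b_o, ns, params$n, byrow = TRUE)
  err <- yhat - y
  dY <- 2 * err / (ns * params$n)
  dW_ho <- t(dY) %*% hid
  db_o <- colSums(dY)
  dH <- (dY %*% params$w_ho) * (1 - hid^2)
  dW_ih <- t(dH) %*% x
  db_h <- colSums(dH)
  list(w_ih = dW_ih, b_h = db_h, w_ho = dW_ho, b_o = db_o,
       mse = mean(err^2))
}

#' Back-propagation training
#'
#' Full-batch gradient descent on the MSE. Each epoch records the MSE of the
#' current parameters; training stops as soon as it reaches `error_goal`
#' (stop reason `"error_goal"`) or after `max_epochs` (`"max_epochs"`).
#'
#' @param params Initial `network_parameters` (random or GA-optimised).
#' @param x Feature matrix (rows x m), normalized scale.
#' @param y Target vector/matrix, normalized scale.
#' @param config A [train_config()].
#' @return List with `params` (trained), `loss` (per-epoch MSE trajectory),
#'   `epochs`, `stop_reason`.
#' @export
train_backprop <- function(params, x, y, config = train_config()) {
  x <- as.matrix(x)
  if (nrow(x) == 0) stop_invalid("train_backprop: empty training data")
  if (ncol(x) != params$m) stop_invalid("train_backprop: data width does not match network")
  loss <- numeric(0)
  stop_reason <- "max_epochs"
  for (epoch in seq_len(config$max_epochs)) {
    g <- bp_gradient(params, x, y)
    if (!is.finite(g$mse)) {
      stop_invalid("train_backprop: training diverged (non-finite loss) at epoch ", epoch)
    }
    loss[epoch] <- g$mse
    if (g$mse <= config$error_goal) {
      stop_reason <- "error_goal"
      break
    }
    lr <- config$learning_rate
    params$w_ih <- params$w_ih - lr * g$w_ih
    params$b_h <- params$b_h - lr * g$b_h
    params$w_ho <- params$w_ho - lr * g$w_ho
    params$b_o <- params$b_o - lr * g$b_o
  }
  list(params = params, loss = loss, epochs = length(loss), stop_reason = stop_reason)
}

# Candidate hidden sizes: round-half-away-from-zero of sqrt(m + n), plus each
# integer alpha. For m = 12, n = 1 this is {5, 6, ..., 14}.
hidden_candidates <- function(m, n = 1, alpha_range = 1:10) {
  if (length(alpha_range) == 0) stop_invalid("hidden_candidates: empty alpha range")
  if (!all(alpha_range %in% 1:10)) {
    stop_invalid("hidden_candidates: alpha must be integers in 1..10")
  }
  sort(unique(round_half_out(sqrt(m + n)) + as.integer(alpha_range)))
}

#' Hidden-layer size search
#'
#' Evaluates every candidate hidden size `round(sqrt(m + n)) + alpha`
#' (alpha = 1..10 by default) by training a freshly initialised network
#' (fixed seed) on a seeded 80/20 internal holdout and measuring the
#' holdout MAE, on the dose scale when an inverse transform is supplied.
#' Ties go to the smaller hidden size.
#'
#' @param x Feature matrix, normalized scale.
#' @param y Target vector, normalized scale.
#' @param alpha_range Integers in 1..10 to add to round(sqrt(m + n)).
#' @param seed Seed for the holdout split and each candidate's initialisation.
#' @param config [train_config()] used for every candidate.
#' @param holdout_fraction Fraction of rows held out for evaluation.
#' @param invert Optional function mapping normalized predictions/targets
#'   back to mg/d before the MAE (default identity).
#' @return List with `h` (chosen size), `table` (data.frame of h and MAE),
#'   and `protocol` describing the split.
#' @export
hidden_size_search <- function(x, y, alpha_range = 1:10, seed = 1L,
                               config = train_config(), holdout_fraction = 0.2,
                               invert = identity) {
  x <- as.matrix(x)
  m <- ncol(x)
  cand <- hidden_candidates(m, 1, alpha_range)
  n_all <- nrow(x)
  idx <- with_seed(seed, sample.int(n_all))
  n_hold <- max(1L, round(holdout_fraction * n_all))
  hold <- idx[seq_len(n_hold)]
  fit <- idx[-seq_len(n_hold)]
  if (length(fit) == 0) stop_invalid("hidden_size_search: no rows left to fit on")
  mae <- vapply(cand, function(h) {
    net <- init_network(m, h, 1, seed = seed)
    tr <- train_backprop(net, x[fit, , drop = FALSE], y[fit], config)
    pred <- forward(tr$params, x[hold, , drop = FALSE])
    mean(abs(invert(pred) - invert(y[hold])))
  }, numeric(1))
  tab <- data.frame(h = cand, mae = mae)
  list(h = cand[which.min(mae)], table = tab,
       protocol = list(holdout_fraction = holdout_fraction, seed = seed))
}
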