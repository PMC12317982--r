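# Single-hidden-layer neural-network regressor: ReLU activation, Adam
# optimizer, L2 weight penalty. Full-batch updates (the training sets here
# are far smaller than a typical minibatch), Glorot-uniform initialization,
# and tolerance-based early stopping on the training loss.

#' Hyperparameters of the affinity regressor
#'
#' Defaults are the ones the predictor is defined with: 100 hidden ReLU
#' units, Adam with initial learning rate 0.001, L2 penalty 0.0001, at most
#' 1000 iterations.
#'
#' @param hidden_units Hidden layer width.
#' @param learning_rate Initial Adam step size.
#' @param l2_penalty L2 regularization coefficient (applied to weights, not
#'   biases, scaled by 1/n).
#' @param max_iterations Maximum full-batch iterations.
#' @param tol Training-loss improvement below which (for
#'   \code{n_iter_no_change} consecutive iterations) training stops early;
#'   0 (the default) disables early stopping and runs the full iteration
#'   budget. On datasets this small, full-batch Adam shows a momentum
#'   transient that a loss-plateau rule mistakes for convergence, so the
#'   fixed budget is the reliable default.
#' @param n_iter_no_change Patience for the tolerance rule.
#' @return A list of class \code{"mlp_control"}.
#' @export
mlp_control <- function(hidden_units = 100L, learning_rate = 0.001,
                        l2_penalty = 1e-4, max_iterations = 1000L,
                        tol = 0, n_iter_no_change = 10L) {
  stopifnot(hidden_units > 0, learning_rate > 0, l2_penalty >= 0,
            max_iterations > 0)
  structure(list(hidden_units = as.integer(hidden_units),
                 learning_rate = learning_rate, l2_penalty = l2_penalty,
                 max_iterations = as.integer(max_iterations), tol = tol,
                 n_iter_no_change = as.integer(n_iter_no_change)),
            class = "mlp_control")
}

mlp_fit <- function(X, y, control = mlp_control(), seed = 1L) {
  stopifnot(is.matrix(X), nrow(X) == length(y))
  n <- nrow(X); p <- ncol(X); h <- control$hidden_units
  local_seed(seed)
  glorot <- function(fan_in, fan_out, nr, nc) {
    b <- sqrt(6 / (fan_in + fan_out))
    matrix(stats::runif(nr * nc, -b, b), nr, nc)
  }
  W1 <- glorot(p, h, p, h);  b1 <- glorot(p, h, 1, h)
  W2 <- glorot(h, 1, h, 1);  b2 <- glorot(h, 1, 1, 1)
  params <- list(W1 = W1, b1 = b1, W2 = W2, b2 = b2)
  m <- lapply(params, function(w) w * 0)
  v <- lapply(params, function(w) w * 0)
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  alpha <- control$l2_penalty
  t <- 0L
  best_loss <- Inf; no_improve <- 0L; converged <- FALSE
  loss_curve <- numeric(0)

  for (it in seq_len(control$max_iterations)) {
    A1 <- sweep(X %*% params$W1, 2L, params$b1[1L, ], `+`)
    H <- pmax(A1, 0)
    yhat <- drop(H %*% params$W2) + params$b2[1L, 1L]
    resid <- yhat - y
    loss <- mean(resid^2) / 2 +
      alpha / (2 * n) * (sum(params$W1^2) + sum(params$W2^2))
    loss_curve <- c(loss_curve, loss)

    d2 <- matrix(resid / n, n, 1L)
    grad <- list(
      W1 = NULL, b1 = NULL,
      W2 = crossprod(H, d2) + alpha / n * params$W2,
      b2 = matrix(sum(d2), 1L, 1L))
    dH <- (d2 %*% t(params$W2)) * (A1 > 0)
    grad$W1 <- crossprod(X, dH) + alpha / n * params$W1
    grad$b1 <- matrix(colSums(dH), 1L)

    t <- t + 1L
    for (k in names(params)) {
      m[[k]] <- beta1 * m[[k]] + (1 - beta1) * grad[[k]]
      v[[k]] <- beta2 * v[[k]] + (1 - beta2) * grad[[k]]^2
      mhat <- m[[k]] / (1 - beta1^t)
      vhat <- v[[k]] / (1 - beta2^t)
      params[[k]] <- params[[k]] - control$learning_rate *
        mhat / (sqrt(vhat) + eps)
    }

    if (control$tol > 0) {
      if (loss > best_loss - control$tol) {
        no_improve <- no_improve + 1L
        if (no_improve >= control$n_iter_no_change) { converged <- TRUE; break }
      } else no_improve <- 0L
    }
    if (loss < best_loss) best_loss <- loss
  }
  if (!converged && control$tol > 0)
    warning("optimizer did not converge within ", control$max_iterations,
            " iterations; returning the model as-is")
  structure(list(W1 = params$W1, b1 = params$b1, W2 = params$W2,
                 b2 = params$b2, control = control, seed = seed,
                 n_iter = length(loss_curve), converged = converged,
                 loss_curve = loss_curve),
            class = "mlp_net")
}

mlp_forward <- function(net, X) {
  H <- pmax(sweep(X %*% net$W1, 2L, net$b1[1L, ], `+`), 0)
  drop(H %*% net$W2) + net$b2[1L, 1L]
}
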