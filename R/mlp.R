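# Small feedforward network for tabular regression: tanh hidden layers,
# linear output, L2 penalty on weights, full-batch Adam. Sized for cohorts
# of tens to hundreds of samples with 9 features.

mlp_init <- function(sizes, seed) {
  withr::with_seed(seed, {
    lapply(seq_len(length(sizes) - 1L), function(l) {
      fan_in <- sizes[l]; fan_out <- sizes[l + 1L]
      lim <- sqrt(6 / (fan_in + fan_out))  # Glorot uniform
      list(W = matrix(stats::runif(fan_in * fan_out, -lim, lim), fan_in, fan_out),
           b = numeric(fan_out))
    })
  })
}

mlp_forward <- function(layers, X) {
  acts <- vector("list", length(layers) + 1L)
  acts[[1L]] <- X
  n_l <- length(layers)
  for (l in seq_len(n_l)) {
    z <- acts[[l]] %*% layers[[l]]$W
    z <- sweep(z, 2L, layers[[l]]$b, "+")
    acts[[l + 1L]] <- if (l < n_l) tanh(z) else z
  }
  acts
}

#' Fit a multi-layer perceptron regressor
#'
#' Feedforward network with tanh hidden activations and a linear output
#' unit, trained by full-batch Adam on the penalized squared loss
#' `0.5 * mean((f(x) - y)^2) + 0.5 * alpha * sum(W^2) / n` (biases
#' unpenalized). Training stops at `max_iter` iterations or when the loss
#' has not improved by `tol` for `n_iter_no_change` consecutive iterations.
#' Deterministic under `seed`.
#'
#' @param X Numeric matrix of predictors (standardized features).
#' @param y Numeric response (years).
#' @param hidden Integer vector of hidden-layer sizes, e.g. `c(16)` or `c(8, 8)`.
#' @param alpha L2 regularization strength.
#' @param learning_rate Adam step size.
#' @param max_iter,tol,n_iter_no_change Stopping controls.
#' @param seed Integer seed for weight initialization.
#' @return Object of class `ag_mlp`.
#' @export
mlp_fit <- function(X, y, hidden = c(16L), alpha = 1e-4, learning_rate = 1e-3,
                    max_iter = 5000L, tol = 1e-4, n_iter_no_change = 10L,
                    seed = 1L) {
  X <- as.matrix(X)
  n <- nrow(X)
  sizes <- c(ncol(X), hidden, 1L)
  layers <- mlp_init(sizes, seed)
  n_l <- length(layers)
  m_st <- lapply(layers, function(l) list(W = l$W * 0, b = l$b * 0))
  v_st <- lapply(layers, function(l) list(W = l$W * 0, b = l$b * 0))
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  best <- Inf; stale <- 0L

  for (it in seq_len(max_iter)) {
    acts <- mlp_forward(layers, X)
    resid <- acts[[n_l + 1L]] - y                      # n x 1
    loss <- 0.5 * mean(resid^2) +
      0.5 * alpha * sum(vapply(layers, function(l) sum(l$W^2), numeric(1L))) / n

    delta <- resid / n                                  # d(0.5*mean r^2)/d out
    for (l in rev(seq_len(n_l))) {
      gW <- crossprod(acts[[l]], delta) + alpha * layers[[l]]$W / n
      gb <- colSums(delta)
      if (l > 1L) {
        delta <- (delta %*% t(layers[[l]]$W)) * (1 - acts[[l]]^2)
      }
      m_st[[l]]$W <- b1 * m_st[[l]]$W + (1 - b1) * gW
      m_st[[l]]$b <- b1 * m_st[[l]]$b + (1 - b1) * gb
      v_st[[l]]$W <- b2 * v_st[[l]]$W + (1 - b2) * gW^2
      v_st[[l]]$b <- b2 * v_st[[l]]$b + (1 - b2) * gb^2
      corr1 <- 1 - b1^it; corr2 <- 1 - b2^it
      layers[[l]]$W <- layers[[l]]$W -
        learning_rate * (m_st[[l]]$W / corr1) / (sqrt(v_st[[l]]$W / corr2) + eps)
      layers[[l]]$b <- layers[[l]]$b -
        learning_rate * (m_st[[l]]$b / corr1) / (sqrt(v_st[[l]]$b / corr2) + eps)
    }

    if (loss < best - tol) { best <- loss; stale <- 0L } else stale <- stale + 1L
    if (stale >= n_iter_no_change) break
  }
  structure(list(layers = layers, sizes = sizes, loss = best, n_iter = it),
            class = "ag_mlp")
}

#' @rdname mlp_fit
#' @param object An `ag_mlp`.
#' @param newdata Matrix of predictors.
#' @param ... Unused.
#' @export
predict.ag_mlp <- function(object, newdata, ...) {
  acts <- mlp_forward(object$layers, as.matrix(newdata))
  drop(acts[[length(acts)]])
}
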