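# Minimal feed-forward network for binary classification: one
# rectified-linear hidden layer, logistic output, binary cross-entropy
# with L2 penalty, trained full-batch with the adaptive-moment (Adam)
# optimizer. Biases are carried as augmented weight rows so each layer
# is a single BLAS GEMM; training is bitwise reproducible for a fixed
# seed.

#' Train a single-hidden-layer perceptron
#'
#' Full-batch Adam with plateau-based early stopping. Because full-batch
#' training takes exactly one gradient step per epoch (rather than one
#' per minibatch), the default step size is larger than typical
#' minibatch settings; together with early stopping this reaches the
#' loss plateau well inside the epoch cap on panel-sized inputs.
#'
#' @param X Numeric matrix, samples x features (expected in \[0, 1\]
#'   after min-max normalization).
#' @param y Integer 0/1 response, one per row of `X`.
#' @param hidden Hidden layer width (default 100).
#' @param max_iter Epoch cap for Adam (default 500).
#' @param seed Integer seed controlling weight initialization.
#' @param learning_rate Adam step size (default 0.01).
#' @param alpha L2 penalty weight on connection weights (biases exempt),
#'   scaled by 1/n.
#' @param tol,n_iter_no_change Early-stopping rule: training stops when
#'   the loss has failed to improve by more than `tol` for
#'   `n_iter_no_change` consecutive epochs.
#' @return An `mlp_model` list of weights plus training diagnostics
#'   (`n_iter`, `loss`, `converged`).
#' @export
mlp_fit <- function(X, y, hidden = 100L, max_iter = 500L, seed = 0L,
                    learning_rate = 0.01, alpha = 1e-4,
                    tol = 1e-4, n_iter_no_change = 10L) {
  stopifnot(is.matrix(X), nrow(X) == length(y))
  n <- nrow(X); d <- ncol(X); h <- as.integer(hidden)
  y <- as.numeric(y)
  X1 <- cbind(X, 1)                      # bias as augmented input column

  init <- withr::with_seed(as.integer(seed), {
    lim1 <- sqrt(6 / (d + h)); lim2 <- sqrt(6 / (h + 1))
    list(W1 = rbind(matrix(stats::runif(d * h, -lim1, lim1), d, h), 0),
         W2 = c(stats::runif(h, -lim2, lim2), 0))
  })
  W1 <- init$W1                          # (d+1) x h, last row = hidden bias
  W2 <- matrix(init$W2, ncol = 1)        # (h+1) x 1, last entry = output bias

  mW1 <- vW1 <- matrix(0, d + 1, h)
  mW2 <- vW2 <- matrix(0, h + 1, 1)
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  pen1 <- rbind(matrix(alpha / n, d, h), 0)   # no penalty on bias rows
  pen2 <- matrix(c(rep(alpha / n, h), 0), ncol = 1)

  best_loss <- Inf; no_change <- 0L; it <- 0L; loss <- NA_real_
  while (it < max_iter) {
    it <- it + 1L
    Z1 <- X1 %*% W1
    H <- pmax(Z1, 0)
    H1 <- cbind(H, 1)
    z2 <- drop(H1 %*% W2)
    p <- 1 / (1 + exp(-z2))
    pc <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    loss <- -mean(y * log(pc) + (1 - y) * log(1 - pc)) +
      alpha / (2 * n) * (sum(W1[-(d + 1), ]^2) + sum(W2[-(h + 1)]^2))

    dz2 <- matrix((p - y) / n, ncol = 1)
    dW2 <- crossprod(H1, dz2) + pen2 * W2
    dH <- tcrossprod(dz2, W2[seq_len(h), , drop = FALSE])
    dZ1 <- dH * (Z1 > 0)
    dW1 <- crossprod(X1, dZ1) + pen1 * W1

    bc1 <- 1 - beta1^it; bc2 <- 1 - beta2^it
    mW1 <- beta1 * mW1 + (1 - beta1) * dW1; vW1 <- beta2 * vW1 + (1 - beta2) * dW1^2
    W1 <- W1 - learning_rate * (mW1 / bc1) / (sqrt(vW1 / bc2) + eps)
    mW2 <- beta1 * mW2 + (1 - beta1) * dW2; vW2 <- beta2 * vW2 + (1 - beta2) * dW2^2
    W2 <- W2 - learning_rate * (mW2 / bc1) / (sqrt(vW2 / bc2) + eps)

    if (loss < best_loss - tol) {
      best_loss <- loss; no_change <- 0L
    } else {
      no_change <- no_change + 1L
      if (no_change >= n_iter_no_change) break
    }
  }
  structure(list(W1 = W1, W2 = W2, hidden = h,
                 n_iter = it, loss = loss,
                 converged = it < max_iter),
            class = "mlp_model")
}

#' Predict class labels with a fitted perceptron
#'
#' @param model An `mlp_model` from [mlp_fit()].
#' @param X Numeric matrix with the same feature columns used at fit time.
#' @return Integer vector of 0/1 predictions (threshold 0.5).
#' @export
mlp_predict <- function(model, X) {
  H <- pmax(cbind(X, 1) %*% model$W1, 0)
  p <- 1 / (1 + exp(-drop(cbind(H, 1) %*% model$W2)))
  as.integer(p > 0.5)
}
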