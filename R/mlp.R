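# Small fully-connected regression network: ReLU hidden layers, linear
# output, uniform weight initialization, full-batch Adam on MSE loss.
# Written in-package because no installed package provides a multi-hidden-
# layer perceptron regressor; sized for the feature tables at hand
# (<= a few thousand rows, ~12 inputs, 6 neurons per layer).

#' Fit a multilayer perceptron regressor
#'
#' @param X numeric matrix (rows = samples, scaled features).
#' @param y numeric response vector.
#' @param hidden integer vector of hidden-layer widths, e.g. `c(6, 6, 6)`.
#' @param epochs maximum training epochs (full-batch Adam steps).
#' @param lr Adam learning rate.
#' @param init_range weights drawn from U(-init_range, init_range); biases 0.
#' @param patience early stop after this many epochs without improvement.
#' @param seed optional RNG seed for the initialization.
#' @param restarts small uniform initializations occasionally start dead
#'   (all ReLU units inactive, the network collapses to the constant
#'   predictor); if training plateaus no better than the constant
#'   predictor, the fit is retried from a fresh initialization up to this
#'   many times (seed shifted deterministically).
#' @return object of class `vtmech_mlp` with weights, `final_mse`,
#'   `epochs_run`, `converged`, `n_restarts`, and the training loss curve.
#' @export
mlp_fit <- function(X, y, hidden = c(6, 6, 6), epochs = 2000, lr = 1e-3,
                    init_range = 0.05, patience = 200, seed = NULL,
                    restarts = 3) {
  vy <- mean((y - mean(y))^2)
  for (r in 0:restarts) {
    fit <- .mlp_fit_once(X, y, hidden, epochs, lr, init_range, patience,
                         if (is.null(seed)) NULL else seed + r * 7919L)
    fit$n_restarts <- r
    if (vy == 0 || fit$final_mse < 0.98 * vy || r == restarts) return(fit)
  }
}

.mlp_fit_once <- function(X, y, hidden, epochs, lr, init_range, patience,
                          seed) {
  X <- as.matrix(X); y <- as.numeric(y)
  stopifnot(nrow(X) == length(y), all(hidden >= 1))
  if (!is.null(seed)) set.seed(seed)
  sizes <- c(ncol(X), hidden, 1L)
  L <- length(sizes) - 1
  W <- lapply(seq_len(L), function(l)
    matrix(runif(sizes[l] * sizes[l + 1], -init_range, init_range),
           sizes[l], sizes[l + 1]))
  B <- lapply(seq_len(L), function(l) numeric(sizes[l + 1]))

  mW <- lapply(W, function(w) w * 0); vW <- mW
  mB <- lapply(B, function(b) b * 0); vB <- mB
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  n <- nrow(X)
  best <- Inf; best_W <- W; best_B <- B; since <- 0
  loss_curve <- numeric(0)

  for (ep in seq_len(epochs)) {
    # forward
    A <- vector("list", L + 1); A[[1]] <- X
    Z <- vector("list", L)
    for (l in seq_len(L)) {
      Z[[l]] <- sweep(A[[l]] %*% W[[l]], 2, B[[l]], `+`)
      A[[l + 1]] <- if (l < L) pmax(Z[[l]], 0) else Z[[l]]
    }
    pred <- A[[L + 1]][, 1]
    resid <- pred - y
    mse <- mean(resid^2)
    loss_curve[ep] <- mse
    if (mse < best - 1e-12) { best <- mse; best_W <- W; best_B <- B; since <- 0 }
    else { since <- since + 1; if (since >= patience) break }

    # backward
    delta <- matrix(2 * resid / n, n, 1)
    for (l in L:1) {
      gW <- crossprod(A[[l]], delta)
      gB <- colSums(delta)
      if (l > 1) delta <- (delta %*% t(W[[l]])) * (Z[[l - 1]] > 0)
      # Adam update
      mW[[l]] <- b1 * mW[[l]] + (1 - b1) * gW
      vW[[l]] <- b2 * vW[[l]] + (1 - b2) * gW^2
      mB[[l]] <- b1 * mB[[l]] + (1 - b1) * gB
      vB[[l]] <- b2 * vB[[l]] + (1 - b2) * gB^2
      mhW <- mW[[l]] / (1 - b1^ep); vhW <- vW[[l]] / (1 - b2^ep)
      mhB <- mB[[l]] / (1 - b1^ep); vhB <- vB[[l]] / (1 - b2^ep)
      W[[l]] <- W[[l]] - lr * mhW / (sqrt(vhW) + eps)
      B[[l]] <- B[[l]] - lr * mhB / (sqrt(vhB) + eps)
    }
  }
  structure(list(W = best_W, B = best_B, hidden = hidden,
                 final_mse = best, epochs_run = length(loss_curve),
                 converged = since >= patience || best < 1e-12,
                 loss_curve = loss_curve),
            class = "vtmech_mlp")
}

#' @export
predict.vtmech_mlp <- function(object, newdata, ...) {
  A <- as.matrix(newdata)
  L <- length(object$W)
  for (l in seq_len(L)) {
    A <- sweep(A %*% object$W[[l]], 2, object$B[[l]], `+`)
    if (l < L) A <- pmax(A, 0)
  }
  A[, 1]
}

#' @export
print.vtmech_mlp <- function(x, ...) {
  cat(sprintf("<vtmech_mlp> hidden [%s], %d epochs, training MSE %.4g%s\n",
              paste(x$hidden, collapse = ", "), x$epochs_run, x$final_mse,
              if (!x$converged) " (epoch cap reached before plateau)" else ""))
  invisible(x)
}
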