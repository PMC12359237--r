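# Single-hidden-layer network internals: initialisation, forward pass,
# backward pass and the Adam optimiser with decoupled weight decay.
# All arrays are dense base-R matrices; batches are rows.

.nn_init <- function(din, dh, dout) {
  # fan-in-scaled (He) init for the ReLU hidden layer; zero biases
  list(Wh = matrix(stats::rnorm(din * dh, sd = sqrt(2 / din)), din, dh),
       bh = numeric(dh),
       Wout = matrix(stats::rnorm(dh * dout, sd = sqrt(1 / dh)), dh, dout),
       bout = numeric(dout))
}

#' Feed-forward pass of the flux estimator network
#'
#' Computes `V0 = relu(X Wh + bh) Wout + bout`; with `training = TRUE`,
#' inverted dropout is applied to the hidden activation.
#'
#' @param X scaled feature matrix, batch x din.
#' @param weights list with `Wh`, `bh`, `Wout`, `bout`.
#' @param training logical; enables dropout.
#' @param dropout dropout rate in `[0, 1)`.
#' @return batch x dout matrix of initial flux estimates. With
#'   `training = TRUE` the intermediates needed for backpropagation are
#'   attached as attribute `"cache"`.
#' @export
nn_forward <- function(X, weights, training = FALSE, dropout = 0) {
  X <- as.matrix(X)
  if (ncol(X) != nrow(weights$Wh))
    stop("feature dimension mismatch: X has ", ncol(X), " columns, Wh expects ",
         nrow(weights$Wh))
  Z <- sweep(X %*% weights$Wh, 2, weights$bh, "+")
  H <- pmax(Z, 0)
  mask <- NULL
  Hd <- H
  if (training && dropout > 0) {
    mask <- matrix(stats::rbinom(length(H), 1, 1 - dropout), nrow(H), ncol(H)) /
      (1 - dropout)
    Hd <- H * mask
  }
  V0 <- sweep(Hd %*% weights$Wout, 2, weights$bout, "+")
  if (training) attr(V0, "cache") <- list(X = X, Z = Z, Hd = Hd, mask = mask)
  V0
}

# gradient of a scalar loss wrt weights, given dL/dV0 and the forward cache
.nn_backward <- function(dV0, weights, cache) {
  dWout <- crossprod(cache$Hd, dV0)
  dbout <- colSums(dV0)
  dHd <- dV0 %*% t(weights$Wout)
  dH <- if (is.null(cache$mask)) dHd else dHd * cache$mask
  dZ <- dH * (cache$Z > 0)
  list(Wh = crossprod(cache$X, dZ), bh = colSums(dZ), Wout = dWout, bout = dbout)
}

.adam_init <- function(weights) {
  list(m = lapply(weights, function(w) w * 0),
       v = lapply(weights, function(w) w * 0),
       t = 0L)
}

# one AdamW step; weight decay (decoupled) applies to Wh/Wout only
.adam_step <- function(weights, grads, state, lr, weight_decay = 0,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(weights)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    weights[[nm]] <- weights[[nm]] - lr * mhat / (sqrt(vhat) + eps)
    if (weight_decay > 0 && nm %in% c("Wh", "Wout"))
      weights[[nm]] <- weights[[nm]] - lr * weight_decay * weights[[nm]]
  }
  list(weights = weights, state = state)
}

# per-feature standardisation fitted on training data only
.fit_scaler <- function(X) {
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  scl[!is.finite(scl) | scl < 1e-12] <- 1
  list(center = ctr, scale = scl)
}

.apply_scaler <- function(X, scaler) {
  sweep(sweep(as.matrix(X), 2, scaler$center, "-"), 2, scaler$scale, "/")
}
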