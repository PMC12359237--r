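#' Data loss: normalized error (default) or mean squared error
#'
#' The normalized error (NE) of a batch of predictions is the Euclidean
#' norm of the residual divided by the norm of the reference, averaged over
#' samples -- a scale-free criterion that does not favour large fluxes. A
#' `"elementwise"` variant averages per-entry relative errors instead, and
#' `"mse"` computes the plain mean squared error used by the MSE-based
#' strategy.
#'
#' @param V batch x n flux predictions (full flux space).
#' @param Vref batch x k reference fluxes.
#' @param pref projection matrix (k x n) mapping flux space to the
#'   reference quantities.
#' @param mode `"norm_ratio"` (default NE), `"elementwise"`, or `"mse"`.
#' @return scalar loss.
#' @export
data_loss <- function(V, Vref, pref, mode = c("norm_ratio", "elementwise", "mse")) {
  mode <- match.arg(mode)
  P <- unclass(pref)
  V <- matrix(V, ncol = ncol(P))
  Vref <- matrix(Vref, ncol = nrow(P))
  R <- tcrossprod(V, P) - Vref
  if (mode == "mse") return(mean(R^2))
  refnorm <- sqrt(rowSums(Vref^2))
  if (any(refnorm < 1e-300))
    stop("normalized error undefined: a reference flux vector has zero norm")
  if (mode == "norm_ratio") return(mean(sqrt(rowSums(R^2)) / refnorm))
  mean(abs(R) / pmax(abs(Vref), 1e-12))
}

# gradient of data_loss wrt V (batch mean included)
.data_loss_grad <- function(V, Vref, pref, mode) {
  P <- unclass(pref)
  V <- matrix(V, ncol = ncol(P))
  Vref <- matrix(Vref, ncol = nrow(P))
  N <- nrow(V)
  R <- tcrossprod(V, P) - Vref
  if (mode == "mse") return((2 / (N * ncol(R))) * (R %*% P))
  refnorm <- sqrt(rowSums(Vref^2))
  if (mode == "norm_ratio") {
    rn <- sqrt(rowSums(R^2))
    scale <- ifelse(rn > 1e-300, 1 / (rn * refnorm), 0)
    return(((R * scale) %*% P) / N)
  }
  (((sign(R) / pmax(abs(Vref), 1e-12)) / ncol(R)) %*% P) / N
}

#' Soft bound on the mechanistic loss
#'
#' Leaves the loss unchanged below `threshold` and penalises the excess
#' with a multiplicative `factor` above it:
#' `threshold + factor * (L - threshold)`. Continuous at the threshold, so
#' the optimisation surface has no cliff.
#'
#' @param L_mech non-negative mechanistic loss value.
#' @param threshold positive threshold.
#' @param factor multiplicative penalty (> 1) on the excess.
#' @return the bounded loss (and, as attribute `"slope"`, the local
#'   multiplier used for gradients).
#' @export
apply_bound_strategy <- function(L_mech, threshold, factor) {
  stopifnot(threshold > 0, factor > 1)
  if (L_mech <= threshold) {
    structure(L_mech, slope = 1)
  } else {
    structure(threshold + factor * (L_mech - threshold), slope = factor)
  }
}

#' Exponential-moving-average loss balancing
#'
#' Normalises the data and mechanistic losses by exponential averages of
#' their own histories so that both contribute at comparable magnitude.
#' The averages are state, excluded from gradient flow: each term's
#' gradient multiplier is `1 / ema`.
#'
#' @param L_data,L_mech current loss values.
#' @param state list with `ema_data`, `ema_mech` (NULL on the first step,
#'   which initialises the averages to the current losses).
#' @param decay EMA decay in (0, 1).
#' @return list: `total`, `w_data`, `w_mech` (the 1/ema multipliers) and
#'   the updated `state`.
#' @export
ema_balance <- function(L_data, L_mech, state = NULL, decay = 0.9) {
  stopifnot(decay > 0, decay < 1)
  if (is.null(state) || is.null(state$ema_data)) {
    state <- list(ema_data = L_data, ema_mech = L_mech)
  } else {
    state$ema_data <- decay * state$ema_data + (1 - decay) * L_data
    state$ema_mech <- decay * state$ema_mech + (1 - decay) * L_mech
  }
  wd <- 1 / max(state$ema_data, 1e-12)
  wm <- 1 / max(state$ema_mech, 1e-12)
  list(total = wd * L_data + wm * L_mech, w_data = wd, w_mech = wm,
       state = state)
}

#' Phase-scheduled loss weights
#'
#' Three training phases: a mechanistic phase with fixed weights
#' (10% data / 90% mechanistic), a linear transition, and a final phase at
#' `final_data_weight` for the data term. Weights always sum to 1.
#'
#' @param epoch zero-based epoch index.
#' @param schedule list with `phase1_end`, `transition_len`,
#'   `phase1_data_weight` and `final_data_weight`.
#' @return numeric `c(w_data, w_mech)`.
#' @export
scheduler_weights <- function(epoch, schedule) {
  p1 <- schedule$phase1_end
  tr <- schedule$transition_len
  w0 <- schedule$phase1_data_weight
  w1 <- schedule$final_data_weight
  wd <- if (epoch < p1) w0
        else if (epoch < p1 + tr) w0 + (epoch - p1) / tr * (w1 - w0)
        else w1
  c(w_data = wd, w_mech = 1 - wd)
}

#' Combine loss components according to a balancing strategy
#'
#' Dispatches on the configured strategy and returns the scalar used for
#' backpropagation together with the effective gradient multipliers of the
#' data loss (`w_data`) and the mechanistic loss (`w_mech`), plus updated
#' strategy state (used by the EMA strategy).
#'
#' Strategies: `mse_base` and `unbalanced` sum all terms; `c_balanced`
#' multiplies the data term by `c`; `divided` keeps the data term only (the
#' mechanistic layer stays active in the forward pass); `bound` applies
#' [apply_bound_strategy()] to the mechanistic sum; `ema` applies
#' [ema_balance()]; `scheduler` (and `scheduler_bound`) weight the two
#' parts by [scheduler_weights()].
#'
#' @param components list with `L1`, `L2`, `L3`, `L4`.
#' @param config a [minn_control()] list.
#' @param epoch zero-based epoch (used by the scheduler).
#' @param state strategy state from the previous call (or NULL).
#' @return list: `total`, `w_data`, `w_mech`, `state`.
#' @export
total_loss <- function(components, config, epoch = 0, state = NULL) {
  L1 <- components$L1
  Lm <- components$L2 + components$L3 + components$L4
  st <- config$strategy
  out <- switch(
    st,
    mse_base = ,
    unbalanced = list(total = L1 + Lm, w_data = 1, w_mech = 1, state = state),
    c_balanced = list(total = config$c * L1 + Lm, w_data = config$c, w_mech = 1,
                      state = state),
    divided = list(total = L1, w_data = 1, w_mech = 0, state = state),
    bound = {
      bl <- apply_bound_strategy(Lm, config$bound_threshold, config$bound_factor)
      list(total = config$c * L1 + as.numeric(bl), w_data = config$c,
           w_mech = attr(bl, "slope"), state = state)
    },
    ema = ema_balance(L1, Lm, state, config$ema_decay),
    scheduler = {
      w <- scheduler_weights(epoch, config$schedule)
      list(total = w[1] * L1 + w[2] * Lm, w_data = unname(w[1]),
           w_mech = unname(w[2]), state = state)
    },
    scheduler_bound = {
      w <- scheduler_weights(epoch, config$schedule)
      bl <- apply_bound_strategy(Lm, config$bound_threshold, config$bound_factor)
      list(total = w[1] * L1 + w[2] * as.numeric(bl), w_data = unname(w[1]),
           w_mech = unname(w[2]) * attr(bl, "slope"), state = state)
    },
    stop("unknown strategy: ", st)
  )
  out
}
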