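#' Bundle the mechanistic quantities consumed by the network
#'
#' Packages the stoichiometric matrix of a (split, possibly reduced) model
#' together with the two projection matrices: `pin` selecting the fluxes
#' whose measured values act as upper bounds, and `pref` mapping the full
#' flux vector to the measured reference fluxes.
#'
#' @param model a split `metabolic_model` (all `lb >= 0`).
#' @param pin `projection_matrix` with role `"input_bounds"` (may have zero
#'   rows if no measured bounds are used).
#' @param pref `projection_matrix` with role `"reference_fluxes"`.
#' @return object of class `mechanistic_context` with elements `S`, `Pin`,
#'   `Pref`, and the counts `m` (metabolites), `n` (reactions), `nin`.
#' @export
mechanistic_context <- function(model, pin, pref) {
  if (any(model$lb < 0)) stop("mechanistic_context requires a split model (all lb >= 0)")
  S <- unclass(model$S)
  Pin <- unclass(pin)
  Pref <- unclass(pref)
  if (ncol(Pin) != ncol(S) || ncol(Pref) != ncol(S))
    stop("projection column counts must equal the number of reactions")
  structure(list(S = S, Pin = Pin, Pref = Pref,
                 m = nrow(S), n = ncol(S), nin = nrow(Pin),
                 model_id = model$id, reactions = colnames(S)),
            class = "mechanistic_context")
}

#' @export
print.mechanistic_context <- function(x, ...) {
  cat("Mechanistic context for", x$model_id, ":", x$m, "metabolites,",
      x$n, "reactions,", x$nin, "bounded inputs,", nrow(x$Pref),
      "reference fluxes\n")
  invisible(x)
}

#' Flux-balance constraint loss
#'
#' The mechanistic loss evaluated on a batch of candidate flux
#' distributions: the steady-state term `(1/m) ||S v||^2`, the upper-bound
#' term `(1/nin) ||relu(Pin v - vin)||^2` and the non-negativity term
#' `(1/n) ||relu(-v)||^2`, each averaged over the batch. All three are zero
#' exactly when every row of `V` is a feasible flux distribution respecting
#' its measured input bounds.
#'
#' @param V batch x n matrix of flux distributions.
#' @param ctx a `mechanistic_context`.
#' @param Vin batch x nin matrix of measured input fluxes (upper bounds);
#'   ignored when the context has no input rows.
#' @return list with components `L2`, `L3`, `L4` and their sum `total`.
#' @export
fba_loss <- function(V, ctx, Vin = NULL) {
  V <- matrix(V, ncol = ctx$n)
  N <- nrow(V)
  SV <- tcrossprod(V, ctx$S)            # N x m
  L2 <- mean(rowSums(SV^2)) / ctx$m
  if (ctx$nin > 0) {
    if (is.null(Vin)) stop("context has input bounds but Vin is missing")
    Vin <- matrix(Vin, ncol = ctx$nin)
    U <- pmax(tcrossprod(V, ctx$Pin) - Vin, 0)
    L3 <- mean(rowSums(U^2)) / ctx$nin
  } else L3 <- 0
  L4 <- mean(rowSums(pmax(-V, 0)^2)) / ctx$n
  list(L2 = L2, L3 = L3, L4 = L4, total = L2 + L3 + L4)
}

#' Analytic gradient of the flux-balance loss
#'
#' Per-sample gradient of `L2 + L3 + L4` with respect to `V` (no batch
#' averaging): the update direction used by the mechanistic layer.
#' @inheritParams fba_loss
#' @return matrix of the same shape as `V`.
#' @export
fba_loss_grad <- function(V, ctx, Vin = NULL) {
  V <- matrix(V, ncol = ctx$n)
  G <- (2 / ctx$m) * (tcrossprod(V, ctx$S) %*% ctx$S)
  if (ctx$nin > 0) {
    Vin <- matrix(Vin, ncol = ctx$nin)
    U <- pmax(tcrossprod(V, ctx$Pin) - Vin, 0)
    G <- G + (2 / ctx$nin) * (U %*% ctx$Pin)
  }
  G <- G - (2 / ctx$n) * pmax(-V, 0)
  G
}

#' Mechanistic refinement layer
#'
#' Unrolled gradient descent on the flux-balance loss: starting from the
#' network estimate `V0`, takes `k_iter` steps `V <- V - lr_mech * dL/dV`.
#' The loop is differentiable with respect to `V0` (see the internal
#' backward pass), so training gradients flow through the refinement.
#'
#' @param V0 batch x n matrix of initial flux estimates.
#' @param ctx a `mechanistic_context`.
#' @param Vin measured input bounds (batch x nin), if the context has any.
#' @param lr_mech positive step size.
#' @param k_iter number of gradient steps (>= 1).
#' @return refined batch x n matrix `Vout`.
#' @export
mechanistic_refine <- function(V0, ctx, Vin = NULL, lr_mech = 0.01, k_iter = 10L) {
  stopifnot(lr_mech > 0, k_iter >= 1)
  .refine_forward(V0, ctx, Vin, lr_mech, k_iter)$V
}

.refine_forward <- function(V0, ctx, Vin, lr_mech, k_iter) {
  V <- matrix(V0, ncol = ctx$n)
  iterates <- vector("list", k_iter)
  for (t in seq_len(k_iter)) {
    iterates[[t]] <- V
    V <- V - lr_mech * fba_loss_grad(V, ctx, Vin)
  }
  list(V = V, iterates = iterates)
}

# Reverse-mode pass through the unrolled refinement: G is dLoss/dVout; the
# Hessian of the FBA loss is piecewise constant, H(V) = (2/m) S'S +
# (2/nin) Pin' D1 Pin + (2/n) D2 with D1 = 1[Pin v > vin], D2 = 1[v < 0].
.refine_backward <- function(G, iterates, ctx, Vin, lr_mech) {
  for (t in rev(seq_along(iterates))) {
    V <- iterates[[t]]
    HG <- (2 / ctx$m) * (tcrossprod(G, ctx$S) %*% ctx$S)
    if (ctx$nin > 0) {
      M1 <- (tcrossprod(V, ctx$Pin) - matrix(Vin, ncol = ctx$nin)) > 0
      HG <- HG + (2 / ctx$nin) * ((tcrossprod(G, ctx$Pin) * M1) %*% ctx$Pin)
    }
    HG <- HG + (2 / ctx$n) * (G * (V < 0))
    G <- G - lr_mech * HG
  }
  G
}
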