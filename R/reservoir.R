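#' Sample a dataset of FBA solutions over randomised exchange fluxes
#'
#' Draws `n` exchange-flux vectors uniformly within the given ranges, fixes
#' those exchanges (tight bound pairs) and solves FBA; infeasible draws are
#' redrawn and counted. The result is the training set for a neural FBA
#' surrogate: every record pairs an exchange vector `vin` with a full
#' optimal flux distribution `vout`.
#'
#' @param model a split `metabolic_model`.
#' @param vin_ids reaction ids (split form) of the exchanges to randomise,
#'   e.g. uptake `_rev` directions and secretion forward directions.
#' @param ranges named list (or k x 2 matrix) of sampling intervals, one
#'   per `vin_ids` entry.
#' @param n number of records.
#' @param seed integer seed.
#' @param max_tries abort when fewer than `n` feasible draws are found in
#'   `max_tries` attempts (feasibility below ~1% triggers the abort).
#' @param parsimonious take the parsimonious member of each FBA optimum
#'   (default). This keeps the exchange-to-flux map single-valued when the
#'   optimal face is degenerate, which the surrogate needs to learn it.
#' @return object of class `reservoir_dataset`: list with `vin` (n x k),
#'   `vout` (n x n_reactions), `objective` (n), and `meta`.
#' @export
sample_fba_dataset <- function(model, vin_ids, ranges, n = 2000, seed = 1L,
                               max_tries = 100 * n, parsimonious = TRUE) {
  miss <- setdiff(vin_ids, model$reactions)
  if (length(miss)) stop("unknown exchange reaction(s): ", paste(miss, collapse = ", "))
  if (is.matrix(ranges)) ranges <- split(ranges, row(ranges))
  if (length(ranges) != length(vin_ids)) stop("one range per exchange required")
  if (any(vapply(ranges, function(r) r[2] < r[1], logical(1))))
    stop("empty sampling range")
  set.seed(as.integer(seed))
  k <- length(vin_ids)
  vin <- matrix(NA_real_, n, k, dimnames = list(NULL, vin_ids))
  vout <- matrix(NA_real_, n, length(model$reactions),
                 dimnames = list(NULL, model$reactions))
  objective <- numeric(n)
  got <- 0L; tries <- 0L; redraws <- 0L
  while (got < n) {
    tries <- tries + 1L
    if (tries > max_tries)
      stop("feasibility rate too low: ", got, " feasible draws in ", tries,
           " attempts (", sprintf("%.2f%%", 100 * got / tries), ")")
    draw <- vapply(ranges, function(r) stats::runif(1, r[1], r[2]), numeric(1))
    ov <- stats::setNames(lapply(draw, function(v) c(v, v)), vin_ids)
    sol <- tryCatch(if (parsimonious) solve_pfba(model, overrides = ov)
                    else solve_fba(model, overrides = ov),
                    error = function(e) NULL)
    if (is.null(sol) || sol$status != "optimal") { redraws <- redraws + 1L; next }
    got <- got + 1L
    vin[got, ] <- draw
    vout[got, ] <- sol$values
    objective[got] <- sol$objective
  }
  structure(list(vin = vin, vout = vout, objective = objective,
                 meta = list(model_id = model$id, vin_ids = vin_ids,
                             ranges = ranges, seed = as.integer(seed),
                             redraws = redraws)),
            class = "reservoir_dataset")
}

#' @export
print.reservoir_dataset <- function(x, ...) {
  cat("Reservoir dataset:", nrow(x$vin), "FBA solutions over",
      ncol(x$vin), "randomised exchanges (", x$meta$redraws, "infeasible redraws )\n")
  invisible(x)
}

#' Persist a reservoir dataset as CSV + JSON metadata sidecar
#' @param dataset a `reservoir_dataset`.
#' @param prefix output path prefix.
#' @return file paths, invisibly.
#' @export
write_reservoir_dataset <- function(dataset, prefix) {
  f1 <- paste0(prefix, ".csv")
  utils::write.csv(cbind(dataset$vin, dataset$vout), f1, row.names = FALSE,
                   quote = FALSE)
  f2 <- paste0(prefix, "_meta.json")
  jsonlite::write_json(dataset$meta, f2, auto_unbox = TRUE, digits = NA)
  invisible(c(f1, f2))
}

#' Pretrain a neural FBA surrogate on sampled FBA solutions
#'
#' Trains a MINN whose only inputs are the exchange fluxes (`din = k`, no
#' omics) to reproduce the full FBA flux distribution, with the usual
#' composite loss (the reference projection is the identity over all
#' reactions). The returned block is frozen: its weights are never updated
#' again.
#'
#' @param dataset a `reservoir_dataset`.
#' @param model the split `metabolic_model` the dataset came from.
#' @param control a [minn_control()]; defaults tuned for the surrogate task.
#' @param holdout fraction of records held out to report surrogate NE.
#' @param seed integer seed.
#' @return object of class `pretrained_block`: the underlying `minn` fit,
#'   `frozen = TRUE`, and `holdout_ne`.
#' @export
pretrain_block <- function(dataset, model, control = NULL, holdout = 0.2,
                           seed = 1L) {
  stopifnot(inherits(dataset, "reservoir_dataset"))
  if (is.null(control))
    control <- minn_control(strategy = "c_balanced", c = 10, dh = 128,
                            lr_nn = 3e-3, epochs = 500)
  n <- nrow(dataset$vin)
  set.seed(as.integer(seed))
  ho <- sample.int(n, max(1L, round(holdout * n)))
  tr <- setdiff(seq_len(n), ho)

  ident <- diag(length(model$reactions))
  dimnames(ident) <- list(model$reactions, model$reactions)
  pref <- structure(ident, class = c("projection_matrix", "matrix", "array"),
                    role = "reference_fluxes", target_ids = model$reactions)
  pin <- build_projection(model,
                          stats::setNames(as.list(colnames(dataset$vin)),
                                          paste0("in_", colnames(dataset$vin))),
                          role = "input_bounds")
  ctx <- mechanistic_context(model, pin, pref)

  feats <- dataset$vin
  colnames(feats) <- paste0("vin_", colnames(dataset$vin))
  mk <- function(idx) omics_dataset(feats[idx, , drop = FALSE],
                                    dataset$vout[idx, , drop = FALSE],
                                    dataset$vin[idx, , drop = FALSE])
  fit <- minn(mk(tr), ctx, control, seed = seed)
  pr <- predict(fit, mk(ho))
  ho_ne <- data_loss(pr$V, dataset$vout[ho, , drop = FALSE], pref)
  structure(list(fit = fit, frozen = TRUE, holdout_ne = ho_ne,
                 vin_ids = colnames(dataset$vin)),
            class = "pretrained_block")
}

#' @export
print.pretrained_block <- function(x, ...) {
  cat("Pretrained FBA-surrogate block (frozen):",
      length(x$vin_ids), "exchanges ->", x$fit$context$n, "reactions;",
      sprintf("held-out NE %.4f\n", x$holdout_ne))
  invisible(x)
}

# forward through the frozen block, returning cache for input gradients
.block_forward <- function(block, vin_pred) {
  fit <- block$fit
  X <- .apply_scaler(vin_pred, fit$scaler)
  V0 <- nn_forward(X, fit$weights, training = TRUE, dropout = 0)
  cache <- attr(V0, "cache")
  ref <- .refine_forward(V0, fit$context, vin_pred, fit$control$lr_mech,
                         fit$control$k_iter)
  list(V = ref$V, cache = cache, ref = ref)
}

# dLoss/d(vin_pred) given dLoss/dVout of the block.
# Note the refinement consumes vin_pred twice: as the network input and as
# the upper bound inside the FBA loss; both paths carry gradient.
.block_backward <- function(block, fwd, G, vin_pred) {
  fit <- block$fit
  ctx <- fit$context
  # path 1: through the unrolled refinement to V0, then through the net
  G0 <- .refine_backward(G, fwd$ref$iterates, ctx, vin_pred, fit$control$lr_mech)
  dZ <- (G0 %*% t(fit$weights$Wout)) * (fwd$cache$Z > 0)
  dXscaled <- dZ %*% t(fit$weights$Wh)
  dvin_net <- sweep(dXscaled, 2, fit$scaler$scale, "/")
  # path 2: vin appears in the bound term of every refinement step
  dvin_bound <- matrix(0, nrow(vin_pred), ncol(vin_pred))
  Gt <- G
  for (t in rev(seq_along(fwd$ref$iterates))) {
    V <- fwd$ref$iterates[[t]]
    act <- (tcrossprod(V, ctx$Pin) - vin_pred) > 0
    # d(step_t)/d(vin) = +lr * (2/nin) Pin' D1 contribution
    dvin_bound <- dvin_bound +
      fit$control$lr_mech * (2 / ctx$nin) * (tcrossprod(Gt, ctx$Pin) * act)
    HG <- (2 / ctx$m) * (tcrossprod(Gt, ctx$S) %*% ctx$S) +
      (2 / ctx$nin) * ((tcrossprod(Gt, ctx$Pin) * act) %*% ctx$Pin) +
      (2 / ctx$n) * (Gt * (V < 0))
    Gt <- Gt - fit$control$lr_mech * HG
  }
  dvin_net + dvin_bound
}

#' Train the reservoir configuration: omics -> exchange fluxes -> frozen block
#'
#' A fresh single-hidden-layer network maps omics features (plus the
#' measured medium exchanges) to the block's exchange-flux vector; the
#' frozen surrogate then produces the full flux distribution, and the data
#' loss compares its projection with the reference fluxes. Only the front
#' network's weights are updated.
#'
#' @param dataset an `omics_dataset` whose targets are reference fluxes.
#' @param block a frozen `pretrained_block`.
#' @param pref projection matrix mapping the block's flux space to the
#'   dataset targets.
#' @param control [minn_control()] for the front network (its `lr_mech`,
#'   `k_iter` and strategy fields govern only the loss composition; the
#'   mechanistic refinement lives inside the block).
#' @param seed integer seed.
#' @return object of class `reservoir_minn` with `$front` weights, the
#'   frozen `$block`, `$scaler`, `$log`.
#' @export
train_reservoir_minn <- function(dataset, block, pref, control = NULL,
                                 seed = 1L) {
  stopifnot(inherits(block, "pretrained_block"), isTRUE(block$frozen))
  if (is.null(control))
    control <- minn_control(strategy = "c_balanced", c = 10, dh = 64,
                            lr_nn = 3e-3, epochs = 400)
  set.seed(as.integer(seed))
  X_raw <- dataset$features
  N <- nrow(X_raw)
  k <- length(block$vin_ids)
  scaler <- .fit_scaler(X_raw)
  X <- .apply_scaler(X_raw, scaler)
  Vref <- dataset$targets
  P <- unclass(pref)
  ctx <- block$fit$context

  weights <- .nn_init(ncol(X), control$dh, k)
  opt <- .adam_init(weights)
  state <- NULL
  block_w0 <- block$fit$weights   # for the frozen-contract audit
  log <- data.frame(epoch = integer(0), L1 = numeric(0), L2 = numeric(0),
                    L3 = numeric(0), L4 = numeric(0), total = numeric(0))
  for (epoch in seq_len(control$epochs) - 1L) {
    V0f <- nn_forward(X, weights, training = TRUE, dropout = control$dropout)
    cache <- attr(V0f, "cache")
    vin_pred <- matrix(V0f, N, k)
    fwd <- .block_forward(block, vin_pred)
    Vout <- fwd$V
    L1 <- data_loss(Vout, Vref, pref, mode = control$ne_mode)
    mech <- fba_loss(Vout, ctx, vin_pred)
    tl <- total_loss(list(L1 = L1, L2 = mech$L2, L3 = mech$L3, L4 = mech$L4),
                     control, epoch = epoch, state = state)
    state <- tl$state
    if (!is.finite(tl$total)) stop("non-finite loss at epoch ", epoch)
    G <- tl$w_data * .data_loss_grad(Vout, Vref, pref, mode = control$ne_mode)
    if (tl$w_mech != 0) G <- G + (tl$w_mech / N) * fba_loss_grad(Vout, ctx, vin_pred)
    dvin <- .block_backward(block, fwd, G, vin_pred)
    if (tl$w_mech != 0) {
      # direct dependence of the bound term L3 on vin at the output
      U <- pmax(tcrossprod(Vout, ctx$Pin) - vin_pred, 0)
      dvin <- dvin - (tl$w_mech / N) * (2 / ctx$nin) * U
    }
    grads <- .nn_backward(dvin, weights, cache)
    stepped <- .adam_step(weights, grads, opt, control$lr_nn, control$weight_decay)
    weights <- stepped$weights
    opt <- stepped$state
    log[nrow(log) + 1L, ] <- c(epoch, L1, mech$L2, mech$L3, mech$L4, tl$total)
  }
  stopifnot(identical(block$fit$weights, block_w0))  # frozen contract
  structure(list(front = weights, block = block, scaler = scaler,
                 control = control, log = log,
                 feature_names = colnames(X_raw),
                 target_names = colnames(Vref), pref = pref,
                 train_fingerprint = .fingerprint(X_raw)),
            class = "reservoir_minn")
}

#' @export
print.reservoir_minn <- function(x, ...) {
  cat("Reservoir MINN:", length(x$feature_names), "features ->",
      length(x$block$vin_ids), "exchanges -> frozen FBA surrogate\n")
  last <- x$log[nrow(x$log), ]
  cat(sprintf("  final L1 %.4f | L2 %.3g\n", last$L1, last$L2))
  invisible(x)
}

#' Predict with a reservoir model
#' @param object a `reservoir_minn`.
#' @param newdata `omics_dataset` or feature matrix.
#' @param ... unused.
#' @return list: `vin` (predicted exchange fluxes), `V` (full flux
#'   distribution from the frozen block), `projected` (reference-flux
#'   predictions).
#' @export
predict.reservoir_minn <- function(object, newdata, ...) {
  if (inherits(newdata, "omics_dataset")) newdata <- newdata$features
  newdata <- as.matrix(newdata)
  miss <- setdiff(object$feature_names, colnames(newdata))
  if (length(miss)) stop("newdata lacks feature column(s): ",
                         paste(miss, collapse = ", "))
  newdata <- newdata[, object$feature_names, drop = FALSE]
  X <- .apply_scaler(newdata, object$scaler)
  vin <- nn_forward(X, object$front, training = FALSE)
  colnames(vin) <- object$block$vin_ids
  fit <- object$block$fit
  Xb <- .apply_scaler(vin, fit$scaler)
  V0 <- nn_forward(Xb, fit$weights, training = FALSE)
  V <- mechanistic_refine(V0, fit$context, vin, fit$control$lr_mech,
                          fit$control$k_iter)
  proj <- tcrossprod(V, unclass(object$pref))
  colnames(proj) <- object$target_names
  list(vin = vin, V = V, projected = proj)
}

#' Parsimonious FBA constrained by reservoir-predicted exchange fluxes
#'
#' Fixes the measured medium uptakes and imposes the predicted exchange
#' fluxes as tight bound pairs (value +/- `tol`), then runs pFBA. If the
#' combined constraints are infeasible, the predicted bounds are relaxed
#' multiplicatively (1%, 5%, 10%) before giving up; any relaxation is
#' recorded in the result's `relaxation` attribute.
#'
#' @param model a split `metabolic_model`.
#' @param vin_pred named numeric: predicted exchange fluxes (reaction ids
#'   of the split model).
#' @param base named numeric: measured exchanges fixed exactly (e.g.
#'   glucose and oxygen uptake on their `_rev` reactions).
#' @param tol half-width of the imposed bound pair.
#' @return a `flux_vector` (attribute `relaxation`: fraction applied).
#' @export
reservoir_constrain_pfba <- function(model, vin_pred, base, tol = 1e-6) {
  stopifnot(!is.null(names(vin_pred)), !is.null(names(base)))
  for (rel in c(0, 0.01, 0.05, 0.10)) {
    ov <- c(lapply(base, function(v) c(v, v)),
            lapply(vin_pred, function(v) {
              w <- max(abs(v) * rel, tol)
              c(max(v - w, 0), v + w)   # split model: fluxes stay non-negative
            }))
    names(ov) <- c(names(base), names(vin_pred))
    sol <- tryCatch(solve_pfba(model, overrides = ov), error = function(e) NULL)
    if (!is.null(sol) && sol$status == "optimal") {
      if (rel > 0)
        message("constrained pFBA required relaxing predicted bounds by ",
                sprintf("%.0f%%", 100 * rel))
      attr(sol, "relaxation") <- rel
      return(sol)
    }
  }
  stop("constrained pFBA infeasible even after 10% relaxation; constraints: ",
       paste(sprintf("%s=%.4g", names(vin_pred), vin_pred), collapse = ", "))
}
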