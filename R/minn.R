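#' Control parameters for fitting a metabolic-informed neural network
#'
#' @param dh hidden-layer width.
#' @param lr_nn learning rate of the network optimiser (Adam).
#' @param lr_mech step size of the mechanistic gradient-descent layer.
#' @param k_iter number of unrolled mechanistic gradient steps.
#' @param dropout dropout rate on the hidden activation during training.
#' @param weight_decay decoupled L2 regularisation on the weight matrices.
#' @param c multiplier of the data loss for the `c_balanced` (and `bound`)
#'   strategies.
#' @param epochs training epochs.
#' @param batch_size mini-batch size; `NULL` uses the full training set
#'   (the natural choice at chemostat-dataset scale, a few tens of samples).
#' @param strategy loss-balancing strategy; one of `"mse_base"`,
#'   `"unbalanced"`, `"c_balanced"`, `"bound"`, `"ema"`, `"scheduler"`,
#'   `"scheduler_bound"`, `"divided"`.
#' @param bound_threshold,bound_factor parameters of the mechanistic-loss
#'   bound (see [apply_bound_strategy()]).
#' @param ema_decay decay of the exponential-average loss balancing.
#' @param schedule phase scheduler: `phase1_end` (epochs of the
#'   mechanistic-dominated phase), `transition_len`, `final_len`,
#'   `phase1_data_weight` (0.1: 90% mechanistic at the start) and
#'   `final_data_weight` (tunable in \[0.8, 1\]).
#' @param ne_mode normalized-error flavour for the data loss
#'   (`"norm_ratio"` or `"elementwise"`); the `mse_base` strategy always
#'   uses mean squared error.
#' @return a list of class `minn_control`.
#' @export
minn_control <- function(dh = 64, lr_nn = 1e-3, lr_mech = 0.01, k_iter = 10L,
                         dropout = 0, weight_decay = 0, c = 10,
                         epochs = 300L, batch_size = NULL,
                         strategy = c("c_balanced", "mse_base", "unbalanced",
                                      "bound", "ema", "scheduler",
                                      "scheduler_bound", "divided"),
                         bound_threshold = 0.1, bound_factor = 10,
                         ema_decay = 0.9,
                         schedule = list(phase1_end = 30L, transition_len = 40L,
                                         final_len = 80L,
                                         phase1_data_weight = 0.1,
                                         final_data_weight = 0.9),
                         ne_mode = c("norm_ratio", "elementwise")) {
  strategy <- match.arg(strategy)
  ne_mode <- match.arg(ne_mode)
  stopifnot(dh >= 1, lr_nn > 0, lr_mech > 0, k_iter >= 1,
            dropout >= 0, dropout < 1, weight_decay >= 0, c > 0, epochs >= 1)
  if (!is.null(schedule$final_data_weight) &&
      (schedule$final_data_weight < 0.8 || schedule$final_data_weight > 1))
    stop("final_data_weight must lie in [0.8, 1]")
  structure(list(dh = as.integer(dh), lr_nn = lr_nn, lr_mech = lr_mech,
                 k_iter = as.integer(k_iter), dropout = dropout,
                 weight_decay = weight_decay, c = c,
                 epochs = as.integer(epochs), batch_size = batch_size,
                 strategy = strategy, bound_threshold = bound_threshold,
                 bound_factor = bound_factor, ema_decay = ema_decay,
                 schedule = schedule, ne_mode = ne_mode),
            class = "minn_control")
}

#' Fit a metabolic-informed neural network
#'
#' Trains the hybrid model: a single-hidden-layer ReLU network maps scaled
#' omics features to an initial flux estimate, an unrolled gradient-descent
#' layer refines the estimate toward the flux-balance constraint set, and
#' backpropagation minimises the strategy-weighted combination of the
#' normalized data error and the constraint-violation terms. Feature
#' standardisation is fitted on the training data only; targets are not
#' scaled (the normalized error is scale-free). Fully deterministic given
#' `seed`.
#'
#' @param dataset an [omics_dataset()]; its `vin` columns must match the
#'   context's input-bound projection targets (same order).
#' @param context a [mechanistic_context()].
#' @param control a [minn_control()] list.
#' @param seed integer seed controlling initialisation, dropout and batch
#'   shuffling.
#' @return an object of class `minn` with methods [predict.minn()],
#'   [print.minn()], [summary.minn()], [coef.minn()], [plot.minn()] and
#'   [residuals.minn()]. `$log` holds the per-epoch loss components.
#' @export
minn <- function(dataset, context, control = minn_control(), seed = 1L) {
  stopifnot(inherits(dataset, "omics_dataset"),
            inherits(context, "mechanistic_context"))
  if (ncol(dataset$targets) != nrow(context$Pref))
    stop("dataset has ", ncol(dataset$targets), " targets but Pref has ",
         nrow(context$Pref), " rows")
  if (ncol(dataset$vin) != context$nin)
    stop("dataset has ", ncol(dataset$vin), " vin columns but the context expects ",
         context$nin)
  set.seed(as.integer(seed))
  X_raw <- dataset$features
  N <- nrow(X_raw)
  scaler <- .fit_scaler(X_raw)
  X <- .apply_scaler(X_raw, scaler)
  Vref <- dataset$targets
  Vin <- dataset$vin
  din <- ncol(X)
  dout <- context$n

  weights <- .nn_init(din, control$dh, dout)
  opt <- .adam_init(weights)
  state <- NULL
  bs <- if (is.null(control$batch_size)) N else min(control$batch_size, N)
  nb <- ceiling(N / bs)
  dmode <- if (control$strategy == "mse_base") "mse" else control$ne_mode

  log <- data.frame(epoch = integer(0), L1 = numeric(0), L2 = numeric(0),
                    L3 = numeric(0), L4 = numeric(0), total = numeric(0),
                    w_data = numeric(0), w_mech = numeric(0))
  for (epoch in seq_len(control$epochs) - 1L) {
    ord <- if (nb > 1) sample.int(N) else seq_len(N)
    ep <- c(L1 = 0, L2 = 0, L3 = 0, L4 = 0, total = 0)
    wlast <- c(1, 1)
    for (ib in seq_len(nb)) {
      idx <- ord[((ib - 1) * bs + 1):min(ib * bs, N)]
      Xb <- X[idx, , drop = FALSE]
      Vinb <- Vin[idx, , drop = FALSE]
      V0 <- nn_forward(Xb, weights, training = TRUE, dropout = control$dropout)
      cache <- attr(V0, "cache")
      ref <- .refine_forward(V0, context, Vinb, control$lr_mech, control$k_iter)
      Vout <- ref$V
      L1 <- data_loss(Vout, Vref[idx, , drop = FALSE], context$Pref, mode = dmode)
      mech <- fba_loss(Vout, context, Vinb)
      comp <- list(L1 = L1, L2 = mech$L2, L3 = mech$L3, L4 = mech$L4)
      tl <- total_loss(comp, control, epoch = epoch, state = state)
      state <- tl$state
      if (!is.finite(tl$total)) {
        bad <- names(comp)[!vapply(comp, is.finite, logical(1))]
        stop("non-finite training loss at epoch ", epoch,
             if (length(bad)) paste0(" (component ", paste(bad, collapse = ","), ")")
             else paste0(" (total = ", tl$total, ")"))
      }
      # gradient at Vout: strategy-weighted data + mechanistic terms
      Nb <- length(idx)
      G <- tl$w_data * .data_loss_grad(Vout, Vref[idx, , drop = FALSE],
                                       context$Pref, mode = dmode)
      if (tl$w_mech != 0)
        G <- G + (tl$w_mech / Nb) * fba_loss_grad(Vout, context, Vinb)
      G0 <- .refine_backward(G, ref$iterates, context, Vinb, control$lr_mech)
      grads <- .nn_backward(G0, weights, cache)
      stepped <- .adam_step(weights, grads, opt, control$lr_nn,
                            control$weight_decay)
      weights <- stepped$weights
      opt <- stepped$state
      fr <- Nb / N
      ep <- ep + fr * c(comp$L1, comp$L2, comp$L3, comp$L4, tl$total)
      wlast <- c(tl$w_data, tl$w_mech)
    }
    log[nrow(log) + 1L, ] <- c(epoch, ep, wlast)
  }

  structure(list(weights = weights, control = control, scaler = scaler,
                 context = context, log = log, seed = as.integer(seed),
                 feature_names = colnames(X_raw),
                 target_names = colnames(dataset$targets),
                 train_fingerprint = .fingerprint(X_raw),
                 train_data = dataset),
            class = "minn")
}

# cheap deterministic fingerprint of a numeric matrix (leakage audits)
.fingerprint <- function(M) {
  v <- as.numeric(M)
  sprintf("%d:%.10e:%.10e", length(v), sum(v), sum(v * seq_along(v)))
}

#' Predict flux distributions from omics features
#'
#' Applies the stored feature scaler, the feed-forward estimator
#' (dropout off) and the mechanistic refinement, returning the full
#' refined flux matrix together with its projection onto the reference
#' fluxes.
#'
#' @param object a fitted `minn`.
#' @param newdata an `omics_dataset`, or a feature matrix with the training
#'   feature columns (then `vin` must be supplied if the context uses
#'   input bounds).
#' @param vin measured input fluxes when `newdata` is a bare matrix.
#' @param refine apply the mechanistic layer (default TRUE; FALSE returns
#'   the raw network output V0).
#' @param ... unused.
#' @return list with `V` (batch x n refined fluxes) and `projected`
#'   (batch x k reference-flux predictions).
#' @export
predict.minn <- function(object, newdata, vin = NULL, refine = TRUE, ...) {
  if (inherits(newdata, "omics_dataset")) {
    vin <- newdata$vin
    newdata <- newdata$features
  }
  newdata <- as.matrix(newdata)
  miss <- setdiff(object$feature_names, colnames(newdata))
  if (length(miss))
    stop("newdata lacks feature column(s): ", paste(miss, collapse = ", "))
  newdata <- newdata[, object$feature_names, drop = FALSE]
  ctx <- object$context
  if (ctx$nin > 0 && is.null(vin))
    stop("vin is required: the context constrains ", ctx$nin, " input fluxes")
  X <- .apply_scaler(newdata, object$scaler)
  V0 <- nn_forward(X, object$weights, training = FALSE)
  V <- if (refine)
    mechanistic_refine(V0, ctx, vin, object$control$lr_mech, object$control$k_iter)
  else V0
  proj <- tcrossprod(V, ctx$Pref)
  colnames(proj) <- object$target_names
  rownames(proj) <- rownames(newdata)
  colnames(V) <- ctx$reactions
  rownames(V) <- rownames(newdata)
  list(V = V, projected = proj)
}

#' @export
print.minn <- function(x, ...) {
  cat("Metabolic-informed neural network (strategy:", x$control$strategy, ")\n")
  cat("  ", length(x$feature_names), "features ->", x$control$dh, "hidden ->",
      x$context$n, "reactions;", x$control$k_iter, "mechanistic steps\n")
  last <- x$log[nrow(x$log), ]
  cat(sprintf("  final losses: L1 %.4g | L2 %.4g | L3 %.4g | L4 %.4g\n",
              last$L1, last$L2, last$L3, last$L4))
  invisible(x)
}

#' @export
summary.minn <- function(object, ...) {
  pr <- predict(object, object$train_data)
  ne <- data_loss(pr$V, object$train_data$targets, object$context$Pref)
  mech <- fba_loss(pr$V, object$context, object$train_data$vin)
  out <- list(control = object$control, epochs = nrow(object$log),
              train_ne = ne, train_L2 = mech$L2, train_L3 = mech$L3,
              train_L4 = mech$L4, log_tail = utils::tail(object$log, 5))
  class(out) <- "summary.minn"
  out
}

#' @export
print.summary.minn <- function(x, ...) {
  cat("MINN fit (", x$epochs, " epochs, strategy ", x$control$strategy, ")\n", sep = "")
  cat(sprintf("  training NE: %.4f | steady-state L2: %.3g | bound L3: %.3g | negativity L4: %.3g\n",
              x$train_ne, x$train_L2, x$train_L3, x$train_L4))
  cat("  last epochs:\n")
  print(x$log_tail, row.names = FALSE)
  invisible(x)
}

#' @export
coef.minn <- function(object, ...) object$weights

#' @export
residuals.minn <- function(object, ...) {
  pr <- predict(object, object$train_data)
  pr$projected - object$train_data$targets
}

#' @export
fitted.minn <- function(object, ...) predict(object, object$train_data)$projected

#' Training curves of a fitted network
#'
#' Plots the loss components per epoch on a log scale.
#' @param x a fitted `minn`.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.minn <- function(x, ...) {
  l <- x$log
  comp <- as.matrix(l[, c("L1", "L2", "L3", "L4")])
  comp[comp <= 0] <- NA
  graphics::matplot(l$epoch, comp, type = "l", lty = 1, log = "y",
                    xlab = "epoch", ylab = "loss component", ...)
  graphics::legend("topright", legend = c("L1 (data)", "L2 (steady state)",
                                          "L3 (upper bounds)", "L4 (negativity)"),
                   col = 1:4, lty = 1, bty = "n")
  invisible(x)
}
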