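#' @title Constraint-based solvers: FBA, pFBA, FVA and flux-space projection
#' @name cbm-solvers
#' @description Linear- and quadratic-programming services over
#'   `metabolic_model` objects, all backed by [solve_qp()].
NULL

.apply_overrides <- function(model, overrides) {
  if (is.null(overrides) || !length(overrides)) return(model)
  ids <- names(overrides)
  miss <- setdiff(ids, model$reactions)
  if (length(miss)) stop("override references unknown reaction(s): ",
                         paste(miss, collapse = ", "))
  for (id in ids) {
    bnd <- overrides[[id]]
    if (length(bnd) != 2) stop("override for ", id, " must be c(lb, ub)")
    i <- match(id, model$reactions)
    model$lb[i] <- bnd[1]
    model$ub[i] <- bnd[2]
  }
  if (any(model$lb > model$ub)) stop("override produced lb > ub")
  model
}

.flux_vector <- function(values, model, status, objective = NA_real_) {
  structure(list(values = stats::setNames(values, model$reactions),
                 model_id = model$id, status = status, objective = objective),
            class = "flux_vector")
}

#' @export
print.flux_vector <- function(x, ...) {
  cat("Flux vector for model", x$model_id, "- status:", x$status, "\n")
  if (x$status != "infeasible") {
    cat("  objective:", format(x$objective), "\n")
    nz <- sum(abs(x$values) > 1e-9)
    cat("  ", nz, "of", length(x$values), "reactions carry flux (|v| > 1e-9)\n")
  }
  invisible(x)
}

#' Flux balance analysis
#'
#' Maximises the model's objective reaction subject to the steady-state
#' constraint `S v = 0` and the reaction bounds.
#'
#' @param model a `metabolic_model`.
#' @param overrides optional named list `reaction id -> c(lb, ub)` applied on
#'   top of the stored bounds (e.g. measured uptake rates, or constraints
#'   coming from a reservoir prediction).
#' @return a `flux_vector` with `status` `"optimal"` or `"infeasible"`.
#' @export
solve_fba <- function(model, overrides = NULL) {
  model <- .apply_overrides(model, overrides)
  obj <- as.numeric(model$reactions == model$objective)
  r <- solve_qp(obj, A = model$S, b = rep(0, nrow(model$S)),
                lb = model$lb, ub = model$ub, maximize = TRUE)
  if (r$status == "infeasible")
    return(.flux_vector(rep(NA_real_, length(model$reactions)), model, "infeasible"))
  if (r$status != "optimal")
    stop("FBA solve failed with status '", r$status, "'")
  .flux_vector(r$x, model, "optimal", objective = r$objective)
}

#' Parsimonious flux balance analysis
#'
#' Two-stage LP: first the FBA optimum of the objective is found, then the
#' objective flux is fixed at that optimum and the total flux `sum(v)` is
#' minimised over the split (all-non-negative) model. On a model with
#' reversible reactions the second stage minimises `sum(|v|)` via the
#' canonical positive/negative split.
#'
#' @inheritParams solve_fba
#' @param fraction_of_optimum fix the objective at this fraction of its FBA
#'   optimum (default 1, i.e. equality at the optimum).
#' @return a `flux_vector`; `attr(, "total_flux")` holds the minimised sum.
#' @export
solve_pfba <- function(model, overrides = NULL, fraction_of_optimum = 1) {
  model <- .apply_overrides(model, overrides)
  fba <- solve_fba(model)
  if (fba$status != "optimal") return(fba)
  i <- match(model$objective, model$reactions)
  # Fix the optimum exactly first (the solver substitutes pinned variables
  # out, which is numerically clean); if stage 2 then fails -- stage 1 is
  # accurate to solver tolerance only, and a slightly-off pinned optimum
  # can be infeasible on tightly constrained models -- retry with a small
  # band around the optimum.
  stage2 <- NULL
  for (otol in c(0, 1e-4, 1e-3) * max(1, abs(fba$objective))) {
    lb <- model$lb; ub <- model$ub
    lb[i] <- fraction_of_optimum * fba$objective - otol
    if (fraction_of_optimum >= 1) ub[i] <- min(ub[i], fba$objective + otol)
    split_needed <- any(lb < 0)
    if (!split_needed) {
      r <- solve_qp(rep(1, length(lb)), A = model$S, b = rep(0, nrow(model$S)),
                    lb = lb, ub = ub)
      if (r$status == "optimal") {
        stage2 <- list(v = r$x, total = r$objective)
        break
      }
    } else {
      # canonical split: v = p - q, p,q >= 0, minimise 1'(p + q)
      n <- length(lb)
      A <- cbind(model$S, -model$S)
      lo <- c(pmax(lb, 0), pmax(-ub, 0))
      hi <- c(pmax(ub, 0), pmax(-lb, 0))
      r <- solve_qp(rep(1, 2 * n), A = A, b = rep(0, nrow(model$S)),
                    lb = lo, ub = hi)
      if (r$status == "optimal") {
        stage2 <- list(v = r$x[seq_len(n)] - r$x[n + seq_len(n)],
                       total = r$objective)
        break
      }
    }
  }
  if (is.null(stage2)) stop("pFBA stage 2 failed: ", r$status)
  out <- .flux_vector(stage2$v, model, "optimal", objective = stage2$v[i])
  attr(out, "total_flux") <- stage2$total
  out
}

#' Flux variability analysis
#'
#' Per-reaction minimum and maximum attainable flux under the model
#' constraints, via 2 LPs per reaction. By default the objective is *not*
#' fixed at its optimum, so the ranges describe the whole feasible space;
#' use `fraction_of_optimum > 0` to constrain growth.
#'
#' @param model a `metabolic_model`.
#' @param reactions reaction ids to analyse (default: all).
#' @param fraction_of_optimum require objective >= this fraction of the FBA
#'   optimum (0 disables the requirement).
#' @return data.frame with columns `reaction`, `min`, `max`.
#' @export
run_fva <- function(model, reactions = model$reactions, fraction_of_optimum = 0) {
  miss <- setdiff(reactions, model$reactions)
  if (length(miss)) stop("unknown reaction(s): ", paste(miss, collapse = ", "))
  lb <- model$lb; ub <- model$ub
  if (fraction_of_optimum > 0) {
    fba <- solve_fba(model)
    if (fba$status != "optimal") stop("model infeasible; cannot run FVA")
    lb[match(model$objective, model$reactions)] <- fraction_of_optimum * fba$objective
  } else {
    # feasibility check
    fba <- solve_fba(model)
    if (fba$status != "optimal") stop("model infeasible; cannot run FVA")
  }
  b0 <- rep(0, nrow(model$S))
  res <- t(vapply(reactions, function(id) {
    obj <- as.numeric(model$reactions == id)
    lo <- solve_qp(obj, A = model$S, b = b0, lb = lb, ub = ub)
    hi <- solve_qp(obj, A = model$S, b = b0, lb = lb, ub = ub, maximize = TRUE)
    if (lo$status != "optimal" || hi$status != "optimal")
      stop("FVA LP failed for reaction ", id)
    c(lo$objective, hi$objective)
  }, numeric(2)))
  data.frame(reaction = reactions, min = res[, 1], max = res[, 2],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Project measured fluxes onto the steady-state solution space
#'
#' Finds the feasible flux distribution whose projected values are closest
#' (in Euclidean distance) to a measured flux vector: the quadratic program
#' `min ||P v - v_measured||^2` (optionally weighted) subject to `S v = 0`
#' and the model bounds. The projected result `P v` is the "FBA fit" version
#' of the measurements.
#'
#' @param model a `metabolic_model`.
#' @param pref a `projection_matrix` from [build_projection()] mapping flux
#'   space to the measured quantities.
#' @param v_measured numeric vector, one value per projection row.
#' @param weights optional positive weights on the squared residuals
#'   (default: unweighted).
#' @return a `flux_vector`; attributes `fitted` (`P v`) and `distance`
#'   (Euclidean distance achieved, on the unweighted scale).
#' @export
fit_to_solution_space <- function(model, pref, v_measured, weights = NULL) {
  P <- unclass(pref)
  if (length(v_measured) != nrow(P))
    stop("length(v_measured) != nrow(pref): ", length(v_measured), " vs ", nrow(P))
  if (is.null(weights)) weights <- rep(1, nrow(P))
  if (any(weights <= 0)) stop("weights must be positive")
  W <- diag(weights, nrow(P))
  Q <- 2 * crossprod(P, W %*% P)
  cvec <- -2 * as.numeric(crossprod(P, W %*% v_measured))
  # tiny ridge keeps Q positive definite when P is rank deficient in v-space
  diag(Q) <- diag(Q) + 1e-10
  r <- solve_qp(cvec, Q = Q, A = model$S, b = rep(0, nrow(model$S)),
                lb = model$lb, ub = model$ub)
  if (r$status != "optimal")
    stop("flux-space projection infeasible or failed (status ", r$status, ")")
  out <- .flux_vector(r$x, model, "optimal")
  fitted <- as.numeric(P %*% r$x)
  attr(out, "fitted") <- stats::setNames(fitted, rownames(P))
  attr(out, "distance") <- sqrt(sum((fitted - v_measured)^2))
  out
}

#' Write a flux vector as CSV (reaction id, flux)
#' @param flux a `flux_vector`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_flux_csv <- function(flux, path) {
  utils::write.csv(data.frame(reaction = names(flux$values), flux = flux$values,
                              row.names = NULL),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
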