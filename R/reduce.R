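#' Remove reactions that cannot carry flux (FVA-guided reduction)
#'
#' Runs flux variability analysis and keeps only reactions whose
#' `[min, max]` span exceeds `flux_tol`; metabolites left with all-zero
#' stoichiometric rows are dropped, so loss normalisation by the metabolite
#' count reflects the reduced model. By default the objective is not fixed
#' at its optimum during the FVA (so alternative pathways that only carry
#' flux away from the optimum are retained); set `fraction_of_optimum` to
#' restrict the ranges to near-optimal states.
#'
#' The objective reaction and any reactions named in `protect` (e.g. the
#' measured exchange reactions used as model inputs) are never removed.
#'
#' @param model a feasible `metabolic_model`.
#' @param flux_tol span threshold below which a reaction counts as blocked.
#' @param fraction_of_optimum passed to [run_fva()].
#' @param protect reaction ids exempt from removal.
#' @return the reduced `metabolic_model`.
#' @export
fva_reduce <- function(model, flux_tol = 1e-9, fraction_of_optimum = 0,
                       protect = character(0)) {
  fva <- run_fva(model, fraction_of_optimum = fraction_of_optimum)
  span <- fva$max - fva$min
  keep <- span > flux_tol | model$reactions %in% c(model$objective, protect)
  .subset_model(model, keep)
}

#' Remove reactions inactive across sampled FBA simulations
#'
#' Runs `n_sim` FBA simulations, each with a random single-gene knockout and
#' a glucose uptake bound drawn uniformly from `glc_range`, and removes the
#' reactions whose flux stays within `flux_tol` of zero in every feasible
#' simulation. Solutions are computed parsimoniously (pFBA) so that
#' alternative optima do not spuriously activate reactions.
#'
#' @param model a feasible `metabolic_model` (split form recommended).
#' @param glc_id id of the glucose uptake reaction whose upper bound is
#'   resampled (on a split model, the `_rev` exchange direction).
#' @param n_sim number of simulations.
#' @param glc_range numeric length-2 interval for the sampled uptake bound.
#' @param seed integer seed; the reduction is reproducible given the seed.
#' @param flux_tol activity threshold.
#' @param protect reaction ids exempt from removal (the objective and
#'   `glc_id` always are).
#' @param parsimonious use pFBA (default) rather than plain FBA solutions.
#' @return the reduced `metabolic_model`.
#' @export
fba_sample_reduce <- function(model, glc_id, n_sim = 2000, glc_range = c(1, 10),
                              seed = 1L, flux_tol = 1e-9,
                              protect = character(0), parsimonious = TRUE) {
  if (!glc_id %in% model$reactions) stop("unknown glucose reaction: ", glc_id)
  genes <- model_genes(model)
  set.seed(seed)
  active <- rep(FALSE, length(model$reactions))
  n_ok <- 0L
  for (k in seq_len(n_sim)) {
    m <- model
    if (length(genes)) m <- knockout_genes(m, sample(genes, 1L))
    g <- stats::runif(1, glc_range[1], glc_range[2])
    i <- match(glc_id, m$reactions)
    m$ub[i] <- min(m$ub[i], g)
    m$lb[i] <- min(m$lb[i], m$ub[i])
    sol <- tryCatch(if (parsimonious) solve_pfba(m) else solve_fba(m),
                    error = function(e) NULL)
    if (is.null(sol) || sol$status != "optimal") next
    n_ok <- n_ok + 1L
    active <- active | (abs(sol$values) > flux_tol)
  }
  if (n_ok == 0L) stop("all ", n_sim, " sampled FBA simulations were infeasible")
  keep <- active | model$reactions %in% c(model$objective, glc_id, protect)
  .subset_model(model, keep)
}

# keep a reaction subset, dropping metabolites with all-zero rows
.subset_model <- function(model, keep) {
  S <- model$S[, keep, drop = FALSE]
  nzrow <- rowSums(S != 0) > 0
  metabolic_model(model$id, S[nzrow, , drop = FALSE],
                  model$lb[keep], model$ub[keep], model$objective,
                  gpr = model$gpr[keep],
                  metabolites = model$metabolites[nzrow],
                  reactions = model$reactions[keep],
                  medium = model$medium)
}
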