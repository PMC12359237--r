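#' Construct a genome-scale metabolic model object
#'
#' The container used throughout the package: a stoichiometric matrix with
#' reaction bounds, gene-protein-reaction (GPR) rules and an objective
#' reaction. Flux units are mmol·gDW^-1·h^-1 (the objective, typically
#' biomass, is h^-1).
#'
#' @param id model identifier.
#' @param S stoichiometric matrix, metabolites x reactions. Row and column
#'   names are used as metabolite and reaction ids if `metabolites` /
#'   `reactions` are not given.
#' @param lb,ub numeric reaction bounds (length = ncol(S)).
#' @param objective id of the objective reaction (must be a column of S).
#' @param gpr character vector of GPR boolean rules (`"g1 and (g2 or g3)"`),
#'   `""` for reactions without gene association.
#' @param metabolites,reactions optional id vectors overriding dimnames.
#' @param medium optional named numeric: exchange reaction id -> maximum
#'   uptake. Stored as metadata; bounds remain authoritative.
#' @return an object of class `metabolic_model`.
#' @seealso [split_reversible()], [solve_fba()], [read_sbml()]
#' @export
metabolic_model <- function(id, S, lb, ub, objective,
                            gpr = rep("", ncol(S)),
                            metabolites = rownames(S), reactions = colnames(S),
                            medium = NULL) {
  S <- as.matrix(S)
  if (is.null(metabolites)) stop("metabolite ids required (rownames(S) or `metabolites`)")
  if (is.null(reactions)) stop("reaction ids required (colnames(S) or `reactions`)")
  if (length(metabolites) != nrow(S)) stop("length(metabolites) != nrow(S)")
  if (length(reactions) != ncol(S)) stop("length(reactions) != ncol(S)")
  if (anyDuplicated(reactions)) stop("duplicated reaction ids")
  if (length(lb) != ncol(S) || length(ub) != ncol(S)) stop("bounds must have one entry per reaction")
  if (any(!is.finite(lb) & lb > 0) || any(is.na(lb)) || any(is.na(ub))) stop("NA bounds")
  if (any(lb > ub)) stop("lower_bound > upper_bound for: ",
                         paste(reactions[lb > ub], collapse = ", "))
  if (!objective %in% reactions) stop("objective reaction not in model: ", objective)
  if (length(gpr) != ncol(S)) stop("gpr must have one entry per reaction")
  dimnames(S) <- list(metabolites, reactions)
  structure(list(id = id, metabolites = metabolites, reactions = reactions,
                 S = S, lb = as.numeric(lb), ub = as.numeric(ub),
                 gpr = as.character(gpr), objective = objective,
                 medium = medium),
            class = "metabolic_model")
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat("Metabolic model:", x$id, "\n")
  cat("  ", length(x$metabolites), "metabolites x", length(x$reactions), "reactions\n")
  cat("  reversible (lb < 0):", sum(x$lb < 0), "\n")
  cat("  objective:", x$objective, "\n")
  invisible(x)
}

#' @export
dim.metabolic_model <- function(x) dim(x$S)

#' Gene ids referenced by a model's GPR rules
#' @param model a `metabolic_model`.
#' @return character vector of gene ids.
#' @export
model_genes <- function(model) {
  toks <- unlist(regmatches(model$gpr, gregexpr("[A-Za-z0-9_.-]+", model$gpr)))
  sort(unique(setdiff(toks, c("and", "or", "AND", "OR"))))
}

#' Split reversible reactions into forward/reverse pairs
#'
#' Every reaction with a negative lower bound is replaced by a forward
#' reaction with bounds (0, ub) and a reverse reaction with bounds (0, -lb)
#' whose stoichiometric column is negated, so that all fluxes of the
#' resulting model are non-negative. Irreversible reactions are untouched.
#' Ids gain deterministic `_fwd` / `_rev` suffixes; after splitting, uptake
#' through an exchange reaction is carried by its `_rev` direction.
#' Idempotent: splitting a split model changes nothing.
#'
#' @param model a `metabolic_model`.
#' @return a `metabolic_model` with all `lb >= 0`.
#' @export
split_reversible <- function(model) {
  rev <- model$lb < 0
  if (!any(rev)) return(model)
  cols <- list(); ids <- character(0); lb <- numeric(0); ub <- numeric(0); gpr <- character(0)
  obj <- model$objective
  for (i in seq_along(model$reactions)) {
    if (rev[i]) {
      cols <- c(cols, list(model$S[, i], -model$S[, i]))
      ids <- c(ids, paste0(model$reactions[i], "_fwd"), paste0(model$reactions[i], "_rev"))
      lb <- c(lb, 0, 0)
      ub <- c(ub, max(model$ub[i], 0), -model$lb[i])
      gpr <- c(gpr, model$gpr[i], model$gpr[i])
      if (model$reactions[i] == obj) obj <- paste0(model$reactions[i], "_fwd")
    } else {
      cols <- c(cols, list(model$S[, i]))
      ids <- c(ids, model$reactions[i])
      lb <- c(lb, model$lb[i]); ub <- c(ub, model$ub[i])
      gpr <- c(gpr, model$gpr[i])
    }
  }
  S <- do.call(cbind, cols)
  rownames(S) <- model$metabolites
  metabolic_model(model$id, S, lb, ub, obj, gpr = gpr,
                  metabolites = model$metabolites, reactions = ids,
                  medium = model$medium)
}

#' Map net-reaction targets of a split model to fwd/rev column pairs
#'
#' Given a reaction id of the *unsplit* model, returns the signed id set on
#' the split model (`id`, or `id_fwd` minus `id_rev`). Used to declare
#' projection targets conveniently.
#' @param model a split `metabolic_model`.
#' @param ids character vector of original reaction ids.
#' @return named list of signed-id character vectors suitable for
#'   [build_projection()].
#' @export
net_flux_targets <- function(model, ids) {
  out <- lapply(ids, function(id) {
    if (id %in% model$reactions) return(id)
    fwd <- paste0(id, "_fwd"); rev <- paste0(id, "_rev")
    if (fwd %in% model$reactions && rev %in% model$reactions)
      return(c(fwd, paste0("-", rev)))
    stop("reaction not found in model (as is or as _fwd/_rev pair): ", id)
  })
  names(out) <- ids
  out
}

#' Build a projection matrix from flux space to a set of labelled targets
#'
#' Each target is a set of signed reaction ids (a leading `-` negates); the
#' corresponding row of the k x n matrix has +1/-1 entries so that
#' `P %*% v` returns the k target values (e.g. net flux of a split pair as
#' `v_fwd - v_rev`).
#'
#' @param model a `metabolic_model`.
#' @param targets named list: label -> character vector of (signed) reaction
#'   ids, e.g. `list(net_R1 = c("R1_fwd", "-R1_rev"))`.
#' @param role `"input_bounds"` (rows restricted to single +1 entries, the
#'   form used for upper-bound constraints) or `"reference_fluxes"`.
#' @return matrix of class `projection_matrix` with attributes `role` and
#'   `target_ids`.
#' @export
build_projection <- function(model, targets, role = c("reference_fluxes", "input_bounds")) {
  role <- match.arg(role)
  if (is.null(names(targets)) || any(names(targets) == ""))
    stop("targets must be a named list")
  n <- length(model$reactions)
  P <- matrix(0, length(targets), n, dimnames = list(names(targets), model$reactions))
  for (k in seq_along(targets)) {
    ids <- targets[[k]]
    sign <- ifelse(startsWith(ids, "-"), -1, 1)
    ids <- sub("^-", "", ids)
    miss <- setdiff(ids, model$reactions)
    if (length(miss)) stop("unknown reaction id(s) in target '", names(targets)[k],
                           "': ", paste(miss, collapse = ", "))
    P[k, ids] <- sign
  }
  if (role == "input_bounds") {
    if (any(P < 0) || any(rowSums(P != 0) != 1))
      stop("input_bounds projections must have exactly one +1 entry per row")
  }
  if (any(rowSums(P != 0) == 0)) stop("projection row without nonzero entries")
  structure(P, class = c("projection_matrix", "matrix", "array"),
            role = role, target_ids = names(targets))
}

#' Read a metabolic model from the package's compact JSON format
#'
#' The format mirrors the widely used constraint-based-model JSON layout:
#' `{"id", "objective", "metabolites": [...], "reactions": [{"id", "lb",
#' "ub", "gpr", "mets": {met: coef}}]}`.
#' @param path file path.
#' @return a `metabolic_model`.
#' @export
read_model_json <- function(path) {
  j <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  mets <- vapply(j$metabolites, identity, character(1))
  nr <- length(j$reactions)
  S <- matrix(0, length(mets), nr)
  ids <- character(nr); lb <- numeric(nr); ub <- numeric(nr); gpr <- character(nr)
  for (i in seq_len(nr)) {
    r <- j$reactions[[i]]
    ids[i] <- r$id; lb[i] <- r$lb; ub[i] <- r$ub
    gpr[i] <- if (is.null(r$gpr)) "" else r$gpr
    idx <- match(names(r$mets), mets)
    if (anyNA(idx)) stop("reaction ", r$id, " references unknown metabolite")
    S[idx, i] <- unlist(r$mets)
  }
  rownames(S) <- mets; colnames(S) <- ids
  metabolic_model(j$id, S, lb, ub, j$objective, gpr = gpr)
}

#' Write a metabolic model in the compact JSON format
#' @param model a `metabolic_model`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_model_json <- function(model, path) {
  rx <- lapply(seq_along(model$reactions), function(i) {
    nz <- which(model$S[, i] != 0)
    list(id = model$reactions[i], lb = model$lb[i], ub = model$ub[i],
         gpr = model$gpr[i],
         mets = as.list(stats::setNames(model$S[nz, i], model$metabolites[nz])))
  })
  jsonlite::write_json(list(id = model$id, objective = model$objective,
                            metabolites = model$metabolites, reactions = rx),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
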