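#' Construct a toy genome-scale metabolic model
#'
#' Builds a small but structurally representative network: a glucose-like
#' uptake chain, a branch point with a parallel two-step pathway (so
#' parsimonious FBA distinguishes routes), an oxygen-requiring energy
#' reaction, 1-3 secretion exchanges and a biomass drain as objective. One
#' internal reaction is reversible, so [split_reversible()] has work to do.
#' Reactions carry simple GPR rules, making every internal step
#' knock-out-able.
#'
#' @param chain_len extra linear steps between uptake and the branch point
#'   (>= 1).
#' @param n_secretion number of secretion exchanges (1-3).
#' @param glc_max maximum glucose uptake (mmol·gDW^-1·h^-1).
#' @param o2_max maximum oxygen uptake.
#' @return an unsplit `metabolic_model` (exchanges are reversible with
#'   negative lower bounds; uptake is negative flux, standard convention).
#' @export
make_toy_gem <- function(chain_len = 1L, n_secretion = 3L, glc_max = 10,
                         o2_max = 20) {
  stopifnot(chain_len >= 1, n_secretion >= 1, n_secretion <= 3)
  mid <- if (chain_len > 1) paste0("m", seq_len(chain_len - 1)) else character(0)
  mets <- c("glc", mid, "A", "C", "P",
            "Q", "E", "o2", paste0("s", seq_len(n_secretion)))
  rx <- list()
  add <- function(id, stoich, lb, ub, gpr = "") {
    rx[[length(rx) + 1L]] <<- list(id = id, stoich = stoich, lb = lb, ub = ub,
                                   gpr = gpr)
  }
  # exchanges (negative flux = uptake)
  add("EX_glc", c(glc = -1), -glc_max, 1000)
  add("EX_o2", c(o2 = -1), -o2_max, 1000)
  for (k in seq_len(n_secretion))
    add(paste0("EX_s", k), stats::setNames(-1, paste0("s", k)), 0, 1000)
  # uptake chain glc -> ... -> A
  chain_mets <- c("glc", mid, "A")
  for (k in seq_len(chain_len))
    add(paste0("T", k),
        stats::setNames(c(-1, 1), chain_mets[k + 0:1]), 0, 1000,
        gpr = paste0("gT", k))
  # branch: a capacity-limited one-step route A -> P in parallel with an
  # unlimited two-step route A -> C -> P. Parsimonious FBA fills the short
  # route first, so the optimum is unique and route choice is informative.
  add("R_AP", c(A = -1, P = 1), 0, 6, gpr = "g1")
  add("R_AC", c(A = -1, C = 1), 0, 1000, gpr = "g2a or g2b")
  add("R_CP", c(C = -1, P = 1), 0, 1000, gpr = "g4")
  # reversible interconversion P <-> Q
  add("R_PQ", c(P = -1, Q = 1), -1000, 1000, gpr = "g5")
  # respiration: Q + o2 -> 2 E
  add("R_resp", c(Q = -1, o2 = -1, E = 2), 0, 1000, gpr = "g6")
  # non-growth-associated maintenance: free energy drain. Gives the oxygen
  # balance slack, so exchange fluxes can be fixed jointly without the
  # feasible set collapsing to a measure-zero surface.
  add("NGAM", c(E = -1), 0, 1000)
  # secretion routes
  sec_src <- c("P", "Q", "C")
  for (k in seq_len(n_secretion))
    add(paste0("SEC", k),
        stats::setNames(c(-1, 1), c(sec_src[k], paste0("s", k))), 0, 1000,
        gpr = paste0("gs", k))
  # biomass drain
  add("BIOMASS", c(P = -1, Q = -1, E = -0.5), 0, 1000)

  S <- matrix(0, length(mets), length(rx), dimnames = list(mets, vapply(rx, `[[`, "", "id")))
  for (i in seq_along(rx)) S[names(rx[[i]]$stoich), i] <- rx[[i]]$stoich
  m <- metabolic_model("toy_gem", S,
                       vapply(rx, `[[`, 0, "lb"), vapply(rx, `[[`, 0, "ub"),
                       "BIOMASS", gpr = vapply(rx, `[[`, "", "gpr"))
  if (solve_fba(m)$status != "optimal" || solve_fba(m)$objective <= 1e-6)
    stop("toy model construction is infeasible")
  m
}

# orthonormal basis of null(S) via SVD
.null_basis <- function(S) {
  sv <- svd(S, nu = 0, nv = ncol(S))
  r <- sum(sv$d > max(dim(S)) * max(sv$d) * 1e-12)
  if (r == ncol(S)) return(matrix(0, ncol(S), 0))
  sv$v[, (r + 1):ncol(S), drop = FALSE]
}

#' Simulate a chemostat-style multi-omics dataset from a toy model
#'
#' Emulates the structure of the classic E. coli chemostat compendium: a
#' wild-type series across dilution-rate analogues (implemented as a grid
#' of glucose-uptake bounds) plus a series of single-gene knockout
#' mutants, all solved with parsimonious FBA on the split model to obtain
#' ground-truth flux distributions. Omics features are noisy monotone
#' functions (saturating by default) of weighted sums of small random flux
#' subsets; the measured glucose/oxygen uptakes are copied from the true
#' solution and appear both as features and as the mechanistic input
#' bounds. Targets are the projected true fluxes, optionally pushed off
#' the steady-state solution space by a controlled amount.
#'
#' @param model a *split* `metabolic_model` (all bounds >= 0), e.g.
#'   `split_reversible(make_toy_gem())`.
#' @param n_dilution number of wild-type "dilution rate" levels.
#' @param ko_genes genes to knock out, one sample each (default: all model
#'   genes except those whose loss kills growth outright is *not* checked;
#'   infeasible conditions are skipped with a message).
#' @param glc_range interval of glucose uptake bounds sampled across
#'   wild-type samples and fixed at its midpoint for knockouts.
#' @param target_ids reactions (original, unsplit ids allowed) whose net
#'   fluxes are the prediction targets; default: biomass, all exchanges
#'   and the branch reactions.
#' @param n_transcripts,n_proteins number of omics features of each kind.
#' @param link `"saturating"` (`z / (z + K)`) or `"linear"` feature link.
#' @param noise_sd additive Gaussian noise on the omics feature scale.
#' @param target_noise_sd additive Gaussian noise on the reference fluxes.
#' @param secretion_range optional interval: per sample, each secretion
#'   exchange (`EX_s*`) is fixed at a value drawn uniformly from this range,
#'   emulating regulatory overflow metabolism that growth-maximising FBA
#'   with uptake bounds alone cannot anticipate. `NULL` leaves secretion
#'   free (pFBA then secretes nothing).
#' @param offspace_delta magnitude of the off-solution-space perturbation
#'   added to the targets (0 = targets stay exactly reachable). The
#'   perturbation direction lies in the orthogonal complement of the image
#'   of null(S) under the target projection, so the perturbed targets are
#'   genuinely unreachable at steady state.
#' @param seed integer; all randomness flows from it.
#' @return an `omics_dataset`; attributes `truth` (sample x reaction true
#'   flux matrix), `conditions` (data.frame), `pref` (the target
#'   projection), `vin_ids` (input-bound reaction ids).
#' @export
simulate_omics_dataset <- function(model, n_dilution = 5,
                                   ko_genes = NULL,
                                   glc_range = c(2, 10),
                                   target_ids = NULL,
                                   n_transcripts = 12L, n_proteins = 8L,
                                   link = c("saturating", "linear"),
                                   noise_sd = 0, target_noise_sd = 0,
                                   secretion_range = NULL,
                                   offspace_delta = 0, seed = 1L) {
  link <- match.arg(link)
  if (any(model$lb < 0)) stop("simulate_omics_dataset expects a split model")
  set.seed(as.integer(seed))
  if (is.null(ko_genes)) ko_genes <- model_genes(model)
  if (is.null(target_ids)) {
    ex <- grep("^EX_", unique(sub("_(fwd|rev)$", "", model$reactions)), value = TRUE)
    target_ids <- unique(c("BIOMASS", ex, "R_AP", "R_AC", "R_PQ"))
    target_ids <- target_ids[target_ids %in%
      c(model$reactions, sub("_(fwd|rev)$", "", model$reactions))]
  }
  pref <- build_projection(model, net_flux_targets(model, target_ids))
  glc_rev <- "EX_glc_rev"
  o2_rev <- "EX_o2_rev"
  if (!all(c(glc_rev, o2_rev) %in% model$reactions))
    stop("model must have split glucose/oxygen exchanges (EX_glc, EX_o2)")
  pin <- build_projection(model, list(glc_uptake = glc_rev, o2_uptake = o2_rev),
                          role = "input_bounds")

  glc_levels <- seq(glc_range[1], glc_range[2], length.out = n_dilution)
  cond <- data.frame(sample = character(0), type = character(0),
                     ko = character(0), glc_bound = numeric(0))
  truth <- list()
  for (d in seq_len(n_dilution)) {
    cond[nrow(cond) + 1L, ] <- list(sprintf("WT_D%02d", d), "wildtype", "",
                                    glc_levels[d])
  }
  for (g in ko_genes) {
    cond[nrow(cond) + 1L, ] <- list(paste0("KO_", g), "knockout", g,
                                    mean(glc_range))
  }

  sec_ids <- grep("^EX_s[0-9]+$", model$reactions, value = TRUE)
  keep <- logical(nrow(cond))
  for (i in seq_len(nrow(cond))) {
    m <- model
    if (cond$ko[i] != "") m <- knockout_genes(m, cond$ko[i])
    j <- match(glc_rev, m$reactions)
    m$ub[j] <- min(m$ub[j], cond$glc_bound[i])
    if (!is.null(secretion_range) && length(sec_ids)) {
      sv <- stats::runif(length(sec_ids), secretion_range[1], secretion_range[2])
      js <- match(sec_ids, m$reactions)
      ok <- m$ub[js] > 0            # a knocked-out secretion route stays shut
      m$lb[js[ok]] <- sv[ok]
      m$ub[js[ok]] <- sv[ok]
    }
    sol <- tryCatch(solve_pfba(m), error = function(e) NULL)
    if (is.null(sol) || sol$status != "optimal" || sol$objective < 1e-8) {
      message("condition ", cond$sample[i], " infeasible or non-growing; skipped")
      next
    }
    keep[i] <- TRUE
    truth[[cond$sample[i]]] <- sol$values
  }
  cond <- cond[keep, , drop = FALSE]
  V <- do.call(rbind, truth)                    # samples x n
  n <- ncol(V)

  # omics features: weighted sums of random flux subsets through a link.
  # Subsets are drawn among fluxes that actually vary across conditions
  # (constant fluxes carry no signal, and near-constant features make
  # leave-one-out scaling degenerate); the half-saturation constant is
  # matched to each feature's own range so the link stays informative.
  nfeat <- n_transcripts + n_proteins
  fmap <- vector("list", nfeat)
  X <- matrix(0, nrow(V), nfeat)
  vsd <- apply(V, 2, stats::sd)
  informative <- which(vsd > 0.02 * max(vsd))
  for (j in seq_len(nfeat)) {
    sz <- sample(1:3, 1)
    sub <- informative[sample.int(length(informative), min(sz, length(informative)))]
    wts <- stats::runif(length(sub), 0.5, 1.5)
    z <- as.numeric(V[, sub, drop = FALSE] %*% wts)
    K <- stats::runif(1, 0.3, 1.5) * max(stats::median(z), 1e-3)
    fmap[[j]] <- list(idx = sub, w = wts, K = K)
    X[, j] <- if (link == "saturating") z / (z + K) else z
  }
  if (noise_sd > 0) X <- X + matrix(stats::rnorm(length(X), sd = noise_sd),
                                    nrow(X), ncol(X))
  colnames(X) <- c(paste0("tx_", seq_len(n_transcripts)),
                   paste0("prot_", seq_len(n_proteins)))

  vin <- V[, c(glc_rev, o2_rev), drop = FALSE]
  colnames(vin) <- c("glc_uptake", "o2_uptake")
  Xall <- cbind(X, glc_uptake_feat = vin[, 1], o2_uptake_feat = vin[, 2])

  targets <- tcrossprod(V, unclass(pref))
  colnames(targets) <- rownames(pref)
  if (target_noise_sd > 0)
    targets <- targets + matrix(stats::rnorm(length(targets), sd = target_noise_sd),
                                nrow(targets), ncol(targets))
  if (offspace_delta > 0) {
    NB <- .null_basis(unclass(model$S))
    reach <- unclass(pref) %*% NB               # k x q image of null(S)
    qs <- qr(reach)
    Qfull <- qr.Q(qs, complete = TRUE)
    rk <- qs$rank
    if (rk >= nrow(pref))
      stop("target projection spans the whole space; no off-space direction exists")
    y <- Qfull[, rk + 1L]                       # unit vector orthogonal to image
    targets <- targets + offspace_delta *
      matrix(y, nrow(targets), ncol(targets), byrow = TRUE)
  }

  ds <- omics_dataset(Xall, targets, vin,
                      metadata = cond[, c("sample", "type", "ko", "glc_bound")])
  rownames(ds$features) <- cond$sample
  rownames(ds$targets) <- cond$sample
  rownames(ds$vin) <- cond$sample
  rownames(V) <- cond$sample
  attr(ds, "truth") <- V
  attr(ds, "conditions") <- cond
  attr(ds, "pref") <- pref
  attr(ds, "pin") <- pin
  attr(ds, "feature_map") <- fmap
  ds
}
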