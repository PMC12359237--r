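#' Regression metrics for a single held-out sample
#'
#' Computed across the reference fluxes of one sample: coefficient of
#' determination `r2 = 1 - SS_res / SS_tot`, mean absolute error, root mean
#' squared error and the normalized error `||pred - ref|| / ||ref||`. With
#' a constant reference vector `r2` is undefined and reported as `NA`.
#'
#' @param v_pred,v_ref numeric vectors of equal length (>= 2).
#' @return list with `r2`, `mae`, `rmse`, `ne`.
#' @export
metric_suite <- function(v_pred, v_ref) {
  stopifnot(length(v_pred) == length(v_ref), length(v_ref) >= 2)
  res <- v_pred - v_ref
  ss_tot <- sum((v_ref - mean(v_ref))^2)
  list(r2 = if (ss_tot > 0) 1 - sum(res^2) / ss_tot else NA_real_,
       mae = mean(abs(res)),
       rmse = sqrt(mean(res^2)),
       ne = sqrt(sum(res^2)) / sqrt(sum(v_ref^2)))
}

#' Steady-state violation of a flux distribution
#'
#' `(1/m) ||S v||^2` -- the same steady-state term the training loss uses,
#' reported as a feasibility proxy for predicted flux distributions.
#' @param V flux vector, or a batch matrix with one distribution per row.
#' @param S stoichiometric matrix (m x n).
#' @return scalar (or per-row vector) violation.
#' @export
steady_state_violation <- function(V, S) {
  if (is.null(dim(V))) return(sum(as.numeric(S %*% V)^2) / nrow(S))
  rowSums(tcrossprod(V, S)^2) / nrow(S)
}

#' Default hyperparameter search space for the nested cross-validation
#'
#' Ranges drawn log-uniformly except `dropout` and `final_data_weight`
#' (uniform). For the scheduler strategy only `final_data_weight` is
#' searched; for `c_balanced`/`bound` the `c` constant joins the search.
#' @param ... named overrides, e.g. `dropout = c(0, 0.2)`.
#' @return named list of length-2 ranges.
#' @export
minn_search_space <- function(...) {
  sp <- list(dh = c(64, 1024), lr_nn = c(1e-4, 1e-2), dropout = c(0, 0.5),
             weight_decay = c(1e-6, 1e-2), c = c(1, 1e4),
             final_data_weight = c(0.8, 1))
  utils::modifyList(sp, list(...))
}

# randomized hyperparameter draw around a base control
.draw_config <- function(base, strategy, space = minn_search_space()) {
  runif_log <- function(r) exp(stats::runif(1, log(r[1]), log(r[2])))
  if (strategy == "scheduler") {
    sch <- base$schedule
    sch$final_data_weight <- stats::runif(1, space$final_data_weight[1],
                                          space$final_data_weight[2])
    base$schedule <- sch
    return(base)
  }
  base$dh <- as.integer(round(runif_log(space$dh)))
  base$lr_nn <- runif_log(space$lr_nn)
  base$dropout <- stats::runif(1, space$dropout[1], space$dropout[2])
  base$weight_decay <- runif_log(space$weight_decay)
  if (strategy %in% c("c_balanced", "bound")) base$c <- runif_log(space$c)
  base
}

#' Nested leave-one-out / 5-fold cross-validation of the MINN
#'
#' The outer loop leaves one sample out; the inner loop runs 5-fold CV on
#' the remaining samples over a randomized hyperparameter search
#' (selection criterion: mean validation NE), then the selected
#' configuration is retrained on all training samples and evaluated on the
#' held-out sample. Feature scaling and hyperparameter choice therefore
#' depend only on each split's training data. Deterministic given `seed`.
#'
#' @param dataset an `omics_dataset` (>= 6 samples).
#' @param context a `mechanistic_context` matching the dataset.
#' @param base_control a [minn_control()] supplying everything the search
#'   does not vary (strategy, epochs, mechanistic step, ...).
#' @param search_budget number of random configurations tried per outer
#'   split (1 keeps `base_control` but still runs the inner loop).
#' @param search_space ranges for the randomized search, see
#'   [minn_search_space()].
#' @param inner_k folds of the inner loop.
#' @param seed integer; all per-split seeds derive from it.
#' @return an `evaluation_report`: `per_split` data.frame (one row per
#'   held-out sample: metrics, steady-state violation, chosen
#'   hyperparameters, fingerprints) and `aggregate` (mean and sd per
#'   metric).
#' @export
nested_loo_cv <- function(dataset, context, base_control = minn_control(),
                          search_budget = 5L, inner_k = 5L,
                          search_space = minn_search_space(), seed = 1L) {
  N <- nrow(dataset$features)
  if (N < 6) stop("nested LOO + ", inner_k, "-fold needs at least 6 samples")
  strategy <- base_control$strategy
  per <- NULL
  for (i in seq_len(N)) {
    tr_idx <- setdiff(seq_len(N), i)
    dtr <- .subset_samples(dataset, tr_idx)
    # inner 5-fold over the training samples
    set.seed(seed * 10000L + i)
    fold <- rep_len(seq_len(inner_k), length(tr_idx))[sample.int(length(tr_idx))]
    cands <- lapply(seq_len(search_budget), function(q) {
      set.seed(seed * 100000L + i * 100L + q)
      if (q == 1) base_control else .draw_config(base_control, strategy, search_space)
    })
    inner_ne <- vapply(seq_along(cands), function(q) {
      nes <- vapply(seq_len(inner_k), function(f) {
        va <- which(fold == f)
        if (!length(va)) return(NA_real_)
        dfit <- .subset_samples(dtr, setdiff(seq_along(tr_idx), va))
        dval <- .subset_samples(dtr, va)
        fit <- minn(dfit, context, cands[[q]],
                    seed = seed * 1000L + i * 10L + f)
        pr <- predict(fit, dval)
        data_loss(pr$V, dval$targets, context$Pref)
      }, numeric(1))
      mean(nes, na.rm = TRUE)
    }, numeric(1))
    best <- which.min(inner_ne)
    fit <- tryCatch(minn(dtr, context, cands[[best]], seed = seed * 1000L + i),
                    error = function(e) e)
    if (inherits(fit, "error")) {
      warning("outer split ", i, " failed to train: ", conditionMessage(fit))
      row <- data.frame(sample = rownames(dataset$features)[i], r2 = NA,
                        mae = NA, rmse = NA, ne = NA, l2 = NA,
                        failed = TRUE, chosen_dh = NA, chosen_lr = NA,
                        chosen_c = NA, inner_ne = NA,
                        train_fingerprint = NA_character_)
      per <- rbind(per, row)
      next
    }
    dte <- .subset_samples(dataset, i)
    pr <- predict(fit, dte)
    ms <- metric_suite(as.numeric(pr$projected), as.numeric(dte$targets))
    cc <- cands[[best]]
    row <- data.frame(sample = rownames(dataset$features)[i],
                      r2 = ms$r2, mae = ms$mae, rmse = ms$rmse, ne = ms$ne,
                      l2 = steady_state_violation(as.numeric(pr$V), context$S),
                      failed = FALSE,
                      chosen_dh = cc$dh, chosen_lr = cc$lr_nn, chosen_c = cc$c,
                      inner_ne = inner_ne[best],
                      train_fingerprint = fit$train_fingerprint)
    per <- rbind(per, row)
  }
  ok <- !per$failed
  if (any(!ok)) warning(sum(!ok), " split(s) failed; excluded from aggregation")
  agg <- do.call(rbind, lapply(c("r2", "mae", "rmse", "ne", "l2"), function(m) {
    v <- per[[m]][ok]
    data.frame(metric = m, mean = mean(v, na.rm = TRUE),
               sd = stats::sd(v, na.rm = TRUE))
  }))
  structure(list(per_split = per, aggregate = agg, strategy = strategy,
                 seed = seed, search_budget = search_budget,
                 inner_k = inner_k,
                 n_outer = N, n_inner_fits = search_budget * inner_k),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("Evaluation report (", x$strategy, "): ", x$n_outer,
      " leave-one-out splits, ", x$inner_k, "-fold inner loop, budget ",
      x$search_budget, "\n", sep = "")
  print(x$aggregate, row.names = FALSE)
  invisible(x)
}

#' Write an evaluation report as CSV (per split) + JSON (aggregate)
#' @param report an `evaluation_report`.
#' @param prefix output path prefix.
#' @return file paths, invisibly.
#' @export
write_evaluation_report <- function(report, prefix) {
  f1 <- paste0(prefix, "_per_split.csv")
  utils::write.csv(report$per_split, f1, row.names = FALSE)
  f2 <- paste0(prefix, "_aggregate.json")
  jsonlite::write_json(list(strategy = report$strategy, seed = report$seed,
                            aggregate = report$aggregate),
                       f2, auto_unbox = TRUE, digits = NA)
  invisible(c(f1, f2))
}

#' Uptake-constrained parsimonious FBA baseline
#'
#' For each sample, applies the sample's gene knockout (from the dataset
#' metadata column `ko`, empty for wild type), fixes the measured uptake
#' fluxes, runs pFBA and scores the projected solution against the
#' reference fluxes -- the purely mechanistic baseline the hybrid model is
#' compared with.
#'
#' @param dataset an `omics_dataset` whose `vin` columns are the measured
#'   uptakes, in the order of `uptake_ids`.
#' @param model a split `metabolic_model`.
#' @param pref projection matrix onto the dataset targets.
#' @param uptake_ids reaction ids (split form) to fix from `vin`.
#' @param extra_overrides optional named list of additional per-sample
#'   constraints: a function(sample_index) returning an overrides list.
#' @return an `evaluation_report` (one row per sample; `l2` is the
#'   steady-state violation of the pFBA solution, ~0 by construction).
#' @export
pfba_baseline <- function(dataset, model, pref,
                          uptake_ids = c("EX_glc_rev", "EX_o2_rev"),
                          extra_overrides = NULL) {
  if (ncol(dataset$vin) != length(uptake_ids))
    stop("dataset vin must supply one measurement per uptake reaction")
  N <- nrow(dataset$features)
  P <- unclass(pref)
  per <- NULL
  for (i in seq_len(N)) {
    ov <- stats::setNames(lapply(seq_along(uptake_ids),
                                 function(j) rep(dataset$vin[i, j], 2)),
                          uptake_ids)
    if (!is.null(extra_overrides)) ov <- utils::modifyList(ov, extra_overrides(i))
    m <- model
    ko <- dataset$metadata$ko[i]
    if (!is.null(ko) && !is.na(ko) && ko != "") m <- knockout_genes(m, ko)
    sol <- tryCatch(solve_pfba(m, overrides = ov), error = function(e) NULL)
    if (is.null(sol) || sol$status != "optimal") {
      per <- rbind(per, data.frame(sample = rownames(dataset$features)[i],
                                   r2 = NA, mae = NA, rmse = NA, ne = NA,
                                   l2 = NA, failed = TRUE))
      next
    }
    pred <- as.numeric(P %*% sol$values)
    ms <- metric_suite(pred, as.numeric(dataset$targets[i, ]))
    per <- rbind(per, data.frame(sample = rownames(dataset$features)[i],
                                 r2 = ms$r2, mae = ms$mae, rmse = ms$rmse,
                                 ne = ms$ne,
                                 l2 = steady_state_violation(sol$values, model$S),
                                 failed = FALSE))
  }
  ok <- !per$failed
  agg <- do.call(rbind, lapply(c("r2", "mae", "rmse", "ne", "l2"), function(m) {
    v <- per[[m]][ok]
    data.frame(metric = m, mean = mean(v, na.rm = TRUE),
               sd = stats::sd(v, na.rm = TRUE))
  }))
  structure(list(per_split = per, aggregate = agg, strategy = "pfba_baseline",
                 seed = NA_integer_, search_budget = 0L, inner_k = 0L,
                 n_outer = N, n_inner_fits = 0L),
            class = "evaluation_report")
}
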