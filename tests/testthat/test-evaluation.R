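test_that("the metric suite matches hand arithmetic", {
  m <- metric_suite(c(1, 2), c(2, 2))
  expect_equal(m$mae, 0.5)
  expect_equal(m$rmse, sqrt(0.5), tolerance = 1e-12)     # 0.70710...
  expect_equal(m$ne, 1 / sqrt(8), tolerance = 1e-12)     # 0.35355...
  expect_true(is.na(m$r2))                               # constant reference
  p <- metric_suite(c(1, 2, 3), c(1, 2, 3))
  expect_equal(unlist(p), c(r2 = 1, mae = 0, rmse = 0, ne = 0))
  ref <- c(1, 3, 5)
  expect_equal(metric_suite(rep(mean(ref), 3), ref)$r2, 0)
  # r2 never exceeds one
  set.seed(1)
  for (i in 1:20) {
    r <- metric_suite(rnorm(5), rnorm(5))
    expect_lte(r$r2, 1)
  }
})

test_that("steady-state violation is the quadratic form it claims to be", {
  S <- matrix(c(1, -1), 1, 2)
  expect_equal(steady_state_violation(c(2, 1), S), 1)
  expect_equal(steady_state_violation(c(4, 2), S), 4)    # homogeneity deg 2
  sol <- solve_fba(toy_split())
  expect_lt(steady_state_violation(sol$values, unclass(toy_split()$S)), 1e-12)
  # batch form agrees with the vector form
  V <- rbind(c(2, 1), c(4, 2))
  expect_equal(steady_state_violation(V, S), c(1, 4))
})

test_that("nested LOO + 5-fold runs the exact protocol, deterministically", {
  ds6 <- .subset_samples(toy_dataset(), 1:6)
  ctx <- toy_context()
  ctrl <- minn_control(epochs = 40, dh = 12, lr_nn = 3e-3, c = 10)
  rep1 <- nested_loo_cv(ds6, ctx, ctrl, search_budget = 2,
                        search_space = minn_search_space(dh = c(8, 32),
                                                         lr_nn = c(1e-3, 1e-2),
                                                         dropout = c(0, 0.2),
                                                         c = c(1, 100)),
                        seed = 17)
  expect_equal(nrow(rep1$per_split), 6L)
  expect_equal(rep1$n_outer, 6L)
  expect_equal(rep1$inner_k, 5L)
  rep2 <- nested_loo_cv(ds6, ctx, ctrl, search_budget = 2,
                        search_space = minn_search_space(dh = c(8, 32),
                                                         lr_nn = c(1e-3, 1e-2),
                                                         dropout = c(0, 0.2),
                                                         c = c(1, 100)),
                        seed = 17)
  expect_identical(rep1$per_split, rep2$per_split)       # bit-identical
  # no leakage: each split's final fit was trained on data excluding the
  # held-out sample (fingerprint recomputed independently here)
  for (i in 1:6) {
    fp <- minn:::.fingerprint(ds6$features[-i, , drop = FALSE])
    expect_identical(rep1$per_split$train_fingerprint[i], fp)
  }
  # aggregate equals recomputation from the per-split values
  expect_equal(rep1$aggregate$mean[rep1$aggregate$metric == "ne"],
               mean(rep1$per_split$ne))
  expect_equal(rep1$aggregate$sd[rep1$aggregate$metric == "rmse"],
               sd(rep1$per_split$rmse))
  expect_error(nested_loo_cv(.subset_samples(toy_dataset(), 1:5), ctx, ctrl),
               "at least 6")
})

test_that("cross-validated predictions beat a mean-predictor baseline", {
  ds <- toy_dataset()
  ctx <- toy_context()
  rep1 <- nested_loo_cv(ds, ctx,
                        minn_control(epochs = 250, dh = 24, lr_nn = 3e-3,
                                     c = 10),
                        search_budget = 1, seed = 9)
  mean_ne <- sapply(seq_len(nrow(ds$features)), function(i) {
    mu <- colMeans(ds$targets[-i, , drop = FALSE])
    sqrt(sum((mu - ds$targets[i, ])^2)) / sqrt(sum(ds$targets[i, ]^2))
  })
  got <- rep1$aggregate$mean[rep1$aggregate$metric == "ne"]
  expect_lt(got, mean(mean_ne))
})

test_that("the pFBA baseline is near-perfect on data it generated", {
  ds <- toy_dataset()       # noiseless, generated by pFBA
  rep1 <- pfba_baseline(ds, toy_split(), attr(ds, "pref"))
  expect_equal(nrow(rep1$per_split), nrow(ds$features))
  expect_false(any(rep1$per_split$failed))
  expect_lt(rep1$aggregate$mean[rep1$aggregate$metric == "ne"], 1e-4)
  # data from a non-parsimonious flux pattern score worse than zero error
  ds2 <- simulate_omics_dataset(toy_split(), n_dilution = 6,
                                ko_genes = character(0),
                                secretion_range = c(0.3, 0.8), seed = 8)
  rep2 <- pfba_baseline(ds2, toy_split(), attr(ds2, "pref"))
  expect_gt(rep2$aggregate$mean[rep2$aggregate$metric == "ne"], 0.01)
})

test_that("evaluation reports serialise to CSV + JSON", {
  ds <- toy_dataset()
  rep1 <- pfba_baseline(ds, toy_split(), attr(ds, "pref"))
  pre <- withr::local_tempfile()
  write_evaluation_report(rep1, pre)
  per <- read.csv(paste0(pre, "_per_split.csv"))
  expect_equal(nrow(per), rep1$n_outer)
  agg <- jsonlite::fromJSON(paste0(pre, "_aggregate.json"))
  expect_identical(agg$strategy, "pfba_baseline")
})
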