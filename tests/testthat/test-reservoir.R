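test_that("sampled FBA records are reproducible optimal solutions", {
  fx <- res_fixtures()
  rds2 <- sample_fba_dataset(fx$sp, fx$vin_ids, fx$ranges, n = 25, seed = 3)
  rds3 <- sample_fba_dataset(fx$sp, fx$vin_ids, fx$ranges, n = 25, seed = 3)
  expect_identical(rds2$vin, rds3$vin)
  expect_identical(rds2$vout, rds3$vout)
  # every record: steady state and optimality at its own exchange values
  S <- unclass(fx$sp$S)
  for (i in 1:10) {
    v <- rds2$vout[i, ]
    expect_lt(max(abs(S %*% v)), 1e-6)
    expect_true(all(v >= -1e-7))
    ov <- setNames(lapply(rds2$vin[i, ], function(x) c(x, x)), fx$vin_ids)
    ref <- solve_fba(fx$sp, overrides = ov)
    expect_equal(rds2$objective[i], ref$objective, tolerance = 1e-5)
  }
  # constraint violation at the record level (the training contract)
  pin <- build_projection(fx$sp, setNames(as.list(fx$vin_ids), fx$vin_ids),
                          role = "input_bounds")
  ident <- diag(length(fx$sp$reactions))
  dimnames(ident) <- list(fx$sp$reactions, fx$sp$reactions)
  ctx <- mechanistic_context(fx$sp, pin, structure(ident,
         class = c("projection_matrix", "matrix", "array")))
  lf <- fba_loss(rds2$vout, ctx, rds2$vin)
  expect_lt(lf$total, 1e-9)
})

test_that("a collapsed sampling range reproduces the single known solution", {
  fx <- res_fixtures()
  pt <- list(c(6, 6), c(2, 2), c(0.3, 0.3), c(0.2, 0.2), c(0.1, 0.1))
  rds <- sample_fba_dataset(fx$sp, fx$vin_ids, pt, n = 1, seed = 9)
  ov <- setNames(lapply(c(6, 2, 0.3, 0.2, 0.1), function(x) c(x, x)),
                 fx$vin_ids)
  ref <- solve_pfba(fx$sp, overrides = ov)
  expect_equal(as.numeric(rds$vout[1, ]), unname(ref$values), tolerance = 1e-5)
})

test_that("the pretrained surrogate reaches low held-out error and stays frozen", {
  fx <- res_fixtures()
  expect_lt(fx$blk$holdout_ne, 0.1)
  expect_true(fx$blk$frozen)
  # reproducing an in-training record
  i <- 5
  fitb <- fx$blk$fit
  Xb <- cbind(matrix(fx$rds$vin[i, ], 1,
                     dimnames = list(NULL, paste0("vin_", fx$vin_ids))))
  pr <- predict(fitb, Xb, vin = fx$rds$vin[i, , drop = FALSE])
  ne <- sqrt(sum((pr$V - fx$rds$vout[i, ])^2)) / sqrt(sum(fx$rds$vout[i, ]^2))
  expect_lt(ne, 0.1)
})

test_that("reservoir training recovers exchange fluxes and never touches the block", {
  fx <- res_fixtures()
  ds <- memo("res_ds", simulate_omics_dataset(fx$sp, n_dilution = 30,
             secretion_range = c(0.1, 0.9), seed = 21))
  w_before <- fx$blk$fit$weights
  rm1 <- memo("res_rm1",
              train_reservoir_minn(ds, fx$blk, attr(ds, "pref"),
                                   minn_control(strategy = "c_balanced", c = 10,
                                                dh = 48, lr_nn = 3e-3,
                                                epochs = 400), seed = 7))
  expect_identical(fx$blk$fit$weights, w_before)   # frozen contract
  pr <- predict(rm1, ds)
  truth <- attr(ds, "truth")[, fx$vin_ids]
  relerr <- abs(pr$vin - truth) / pmax(abs(truth), 0.1)
  expect_lt(median(relerr), 0.1)
  # predicted exchanges stay largely inside the sampled training ranges
  lo <- vapply(fx$ranges, `[`, 0, 1)
  hi <- vapply(fx$ranges, `[`, 0, 2)
  inside <- sweep(pr$vin, 2, lo - 0.3, ">=") & sweep(pr$vin, 2, hi + 0.3, "<=")
  expect_gte(mean(inside), 0.9)
})

test_that("constrained pFBA honors imposed exchanges and helps on secretion-active data", {
  fx <- res_fixtures()
  ds <- memo("res_ds", simulate_omics_dataset(fx$sp, n_dilution = 30,
             secretion_range = c(0.1, 0.9), seed = 21))
  rm1 <- memo("res_rm1",
              train_reservoir_minn(ds, fx$blk, attr(ds, "pref"),
                                   minn_control(strategy = "c_balanced", c = 10,
                                                dh = 48, lr_nn = 3e-3,
                                                epochs = 400), seed = 7))
  pr <- predict(rm1, ds)
  pref <- attr(ds, "pref")
  P <- unclass(pref)
  sec <- c("EX_s1", "EX_s2", "EX_s3")
  ne_con <- ne_unc <- numeric(0)
  for (i in seq_len(min(nrow(ds$features), 10))) {
    base <- c(EX_glc_rev = unname(ds$vin[i, 1]), EX_o2_rev = unname(ds$vin[i, 2]))
    vp <- pmin(pmax(pr$vin[i, sec], 0), 1)   # clip to the trained range
    sol <- tryCatch(suppressMessages(reservoir_constrain_pfba(fx$sp, vp, base)),
                    error = function(e) NULL)
    if (is.null(sol)) next
    if (attr(sol, "relaxation") == 0)
      expect_equal(unname(sol$values[sec]), unname(vp), tolerance = 1e-5)
    ref <- ds$targets[i, ]
    ne_con <- c(ne_con, sqrt(sum((P %*% sol$values - ref)^2)) / sqrt(sum(ref^2)))
    unc <- solve_pfba(fx$sp, overrides = list(EX_glc_rev = rep(base[1], 2),
                                              EX_o2_rev = rep(base[2], 2)))
    ne_unc <- c(ne_unc, sqrt(sum((P %*% unc$values - ref)^2)) / sqrt(sum(ref^2)))
  }
  # direction: adding predicted secretion constraints does not hurt on
  # data generated with secretion the plain pFBA cannot know about
  expect_gt(length(ne_con), 0)
  expect_lte(mean(ne_con), mean(ne_unc) + 1e-8)
})

test_that("perfect exchange predictions reproduce unconstrained pFBA", {
  fx <- res_fixtures()
  unc <- solve_pfba(fx$sp, overrides = list(EX_glc_rev = c(8, 8),
                                            EX_o2_rev = c(2, 2)))
  vp <- unc$values[c("EX_s1", "EX_s2", "EX_s3")]
  sol <- reservoir_constrain_pfba(fx$sp, vp,
                                  base = c(EX_glc_rev = 8, EX_o2_rev = 2))
  # agreement to ~0.25% of the uptake scale; the instance is fully pinned
  # and degenerate, where the interior-point solver leaves a small dual gap
  expect_lt(max(abs(sol$values - unc$values)), 0.02)
  expect_equal(attr(sol, "relaxation"), 0)
})

test_that("reservoir datasets persist to CSV with a JSON sidecar", {
  fx <- res_fixtures()
  pre <- withr::local_tempfile()
  files <- write_reservoir_dataset(fx$rds, pre)
  d <- read.csv(paste0(pre, ".csv"), check.names = FALSE)
  expect_equal(nrow(d), nrow(fx$rds$vin))
  meta <- jsonlite::fromJSON(paste0(pre, "_meta.json"))
  expect_identical(meta$model_id, "toy_gem")
})
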