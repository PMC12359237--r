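test_that("FBA solves textbook toy cases", {
  expect_equal(solve_fba(chain_model())$objective, 2, tolerance = 1e-7)
  expect_equal(solve_fba(branch_model())$objective, 4, tolerance = 1e-7)
  z <- solve_fba(chain_model(), overrides = list(R1 = c(0, 0)))
  expect_equal(z$objective, 0, tolerance = 1e-7)
  expect_error(solve_fba(chain_model(), overrides = list(NOPE = c(0, 1))),
               "unknown reaction")
})

test_that("pFBA routes flux through the shortest pathway", {
  p <- solve_pfba(parallel_model())
  expect_equal(p$objective, 2, tolerance = 1e-6)
  expect_equal(unname(p$values["DIRECT"]), 2, tolerance = 1e-5)
  expect_lt(abs(p$values["TO_C"]), 1e-5)
})

test_that("pFBA suppresses internal cycles and matches FBA on unique optima", {
  p <- solve_pfba(loop_model())
  expect_equal(p$objective, 2, tolerance = 1e-5)
  # the A->B->A cycle carries nothing under parsimony
  expect_lt(min(p$values["AB"], p$values["BA"]), 1e-5)
  # unique-solution chain: pFBA == FBA
  f <- solve_fba(chain_model())
  p2 <- solve_pfba(chain_model())
  expect_equal(p2$values, f$values, tolerance = 1e-5)
})

test_that("pFBA keeps the FBA optimum and never increases total flux", {
  set.seed(11)
  for (rep in 1:5) {
    m <- toy_split()
    ov <- list(EX_glc_rev = c(0, runif(1, 2, 10)))
    f <- solve_fba(m, overrides = ov)
    p <- solve_pfba(m, overrides = ov)
    expect_equal(p$objective, f$objective, tolerance = 1e-5)
    expect_lte(attr(p, "total_flux"), sum(f$values) + 1e-5)
    expect_lt(max(abs(m$S %*% p$values)), 1e-6)
  }
})

test_that("FVA ranges match a brute-force per-reaction oracle", {
  m <- branch_model()
  fva <- run_fva(m)
  for (i in seq_along(m$reactions)) {
    obj <- as.numeric(seq_along(m$reactions) == i)
    lo <- lp_vertex_oracle(obj, m$S, rep(0, nrow(m$S)), m$lb, m$ub,
                           maximize = FALSE)
    hi <- lp_vertex_oracle(obj, m$S, rep(0, nrow(m$S)), m$lb, m$ub,
                           maximize = TRUE)
    expect_equal(fva$min[i], lo$val, tolerance = 1e-6)
    expect_equal(fva$max[i], hi$val, tolerance = 1e-6)
  }
})

test_that("FVA flags single pathways and dead ends", {
  fva <- run_fva(chain_model())
  expect_equal(fva$min, rep(0, 3), tolerance = 1e-6)
  expect_equal(fva$max, rep(2, 3), tolerance = 1e-6)
  # add a dead-end consumer of a metabolite nobody regenerates
  S <- rbind(A = c(1, -1, 0), B = c(0, 1, -1), D = c(0, 0, 0))
  S["D", 2] <- 0
  S <- cbind(S, DEAD = c(0, 0, -1))
  m <- metabolic_model("dead", S, rep(0, 4), c(2, 10, 10, 10), "R3",
                       reactions = c("R1", "R2", "R3", "DEAD"))
  fva2 <- run_fva(m)
  expect_equal(fva2$min[4], 0, tolerance = 1e-7)
  expect_equal(fva2$max[4], 0, tolerance = 1e-7)
})

test_that("flux-space projection solves the worked example and beats random points", {
  S <- matrix(c(1, -1), 1, 2, dimnames = list("A", c("R1", "R2")))
  m <- metabolic_model("mini", S, c(0, 0), c(10, 10), "R2")
  P <- build_projection(m, list(R1 = "R1", R2 = "R2"))
  fit <- fit_to_solution_space(m, P, c(2, 1))
  expect_equal(unname(attr(fit, "fitted")), c(1.5, 1.5), tolerance = 1e-5)
  expect_equal(attr(fit, "distance")^2, 0.5, tolerance = 1e-5)
  # already-feasible measurement: zero distance
  fit0 <- fit_to_solution_space(m, P, c(3, 3))
  expect_lt(attr(fit0, "distance"), 1e-4)
  # sampling oracle on the toy model: fitted point beats 1000 random
  # feasible points in distance to the measurement
  set.seed(2)
  sp <- toy_split()
  ds <- toy_dataset()
  pref <- attr(ds, "pref")
  meas <- ds$targets[1, ] + rnorm(ncol(ds$targets), sd = 0.5)
  ft <- fit_to_solution_space(sp, pref, meas)
  expect_lt(max(abs(sp$S %*% ft$values)), 1e-5)
  dists <- replicate(1000, {
    ov <- list(EX_glc_rev = c(0, runif(1, 1, 10)),
               EX_o2_rev = c(0, runif(1, 0.5, 10)))
    v <- solve_fba(sp, overrides = ov)$values
    sqrt(sum((as.numeric(unclass(pref) %*% v) - meas)^2))
  })
  expect_lte(attr(ft, "distance"), min(dists) + 1e-6)
})

test_that("projection respects irreversibility bounds (grid-search oracle)", {
  # 2-reaction model, measurement pushes R1 negative; optimum clips at 0
  S <- matrix(c(1, -1), 1, 2, dimnames = list("A", c("R1", "R2")))
  m <- metabolic_model("mini", S, c(0, 0), c(10, 10), "R2")
  P <- build_projection(m, list(R1 = "R1", R2 = "R2"))
  meas <- c(-2, 1)
  fit <- fit_to_solution_space(m, P, meas)
  grid <- seq(0, 10, by = 0.001)           # feasible set is v1 = v2 = t
  dist2 <- (grid - meas[1])^2 + (grid - meas[2])^2
  best_t <- grid[which.min(dist2)]
  expect_equal(unname(fit$values), c(best_t, best_t), tolerance = 1e-3)
})

test_that("all solver outputs satisfy the steady-state tolerance", {
  for (m in list(chain_model(), branch_model(), parallel_model(), toy_split())) {
    f <- solve_fba(m)
    expect_lt(max(abs(m$S %*% f$values)), 1e-6)
    p <- solve_pfba(m)
    expect_lt(max(abs(m$S %*% p$values)), 1e-6)
  }
})
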