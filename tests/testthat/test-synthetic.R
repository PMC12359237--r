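test_that("the toy model grows, has a reversible reaction and a parallel route", {
  m <- make_toy_gem()
  expect_gt(solve_fba(m)$objective, 0)
  expect_gt(sum(m$lb < 0), 2)          # exchanges + internal R_PQ
  expect_true(all(c("R_AP", "R_AC", "R_CP") %in% m$reactions))
  # pFBA distinguishes the routes: short route saturates first
  sp <- split_reversible(m)
  p <- solve_pfba(sp, overrides = list(EX_glc_rev = c(0, 4)))
  expect_lt(p$values["R_AC"], 1e-5)
  p2 <- solve_pfba(sp, overrides = list(EX_glc_rev = c(0, 10)))
  expect_gt(p2$values["R_AC"], 0.1)    # overflow takes the long route
  # construction is deterministic
  expect_identical(make_toy_gem()$S, m$S)
})

test_that("noiseless simulated targets lie on the steady-state space", {
  ds <- toy_dataset()
  V <- attr(ds, "truth")
  S <- unclass(toy_split()$S)
  expect_lt(max(steady_state_violation(V, S)), 1e-10)
  expect_false(anyNA(ds$features))
  # measured inputs appear as both features and mechanistic bounds
  expect_true(all(c("glc_uptake_feat", "o2_uptake_feat") %in%
                  colnames(ds$features)))
  expect_equal(unname(ds$features[, "glc_uptake_feat"]),
               unname(ds$vin[, "glc_uptake"]))
})

test_that("a 5-dilution + 24-knockout design mirrors the chemostat compendium shape", {
  m <- make_toy_gem(chain_len = 3)        # more genes to knock out
  sp <- split_reversible(m)
  genes <- model_genes(sp)
  ds <- simulate_omics_dataset(sp, n_dilution = 5, ko_genes = genes,
                               n_transcripts = 20, n_proteins = 10, seed = 2)
  cond <- attr(ds, "conditions")
  expect_equal(sum(cond$type == "wildtype"), 5L)
  expect_gt(sum(cond$type == "knockout"), 0)
  expect_equal(ncol(ds$features), 20 + 10 + 2)
  expect_equal(nrow(ds$features), nrow(cond))
})

test_that("off-space perturbation creates genuine, monotone infeasibility", {
  sp <- toy_split()
  deltas <- c(0.05, 0.2, 0.8)
  viols <- sapply(deltas, function(d) {
    ds <- simulate_omics_dataset(sp, n_dilution = 6, ko_genes = character(0),
                                 offspace_delta = d, seed = 3)
    pref <- attr(ds, "pref")
    ft <- fit_to_solution_space(sp, pref, ds$targets[2, ])
    attr(ft, "distance")
  })
  expect_true(all(viols > 1e-3))          # targets genuinely unreachable
  expect_true(all(diff(viols) > 0))       # magnitude controls violation
  # the projection recovers the unperturbed fluxes
  ds0 <- simulate_omics_dataset(sp, n_dilution = 6, ko_genes = character(0),
                                offspace_delta = 0, seed = 3)
  dsP <- simulate_omics_dataset(sp, n_dilution = 6, ko_genes = character(0),
                                offspace_delta = 0.5, seed = 3)
  ft <- fit_to_solution_space(sp, attr(dsP, "pref"), dsP$targets[4, ])
  expect_equal(unname(attr(ft, "fitted")), unname(ds0$targets[4, ]),
               tolerance = 1e-3)
})

test_that("datasets round-trip through the CSV tables and validate sample ids", {
  ds <- toy_dataset()
  pre <- withr::local_tempfile()
  write_omics_tables(ds, pre)
  ds2 <- read_omics_tables(paste0(pre, "_features.csv"),
                           paste0(pre, "_targets.csv"),
                           paste0(pre, "_vin.csv"),
                           paste0(pre, "_metadata.csv"))
  expect_equal(ds2$features, ds$features)
  expect_equal(ds2$targets, ds$targets)
  expect_equal(ds2$vin, ds$vin)
  # corrupt one sample id: the offender is named
  tab <- read.csv(paste0(pre, "_targets.csv"), check.names = FALSE)
  tab$sample[3] <- "MYSTERY"
  write.csv(tab, paste0(pre, "_targets.csv"), row.names = FALSE, quote = FALSE)
  expect_error(read_omics_tables(paste0(pre, "_features.csv"),
                                 paste0(pre, "_targets.csv")),
               "MYSTERY")
})

test_that("all generator randomness flows from the single seed", {
  sp <- toy_split()
  a <- simulate_omics_dataset(sp, n_dilution = 5, noise_sd = 0.05,
                              secretion_range = c(0.1, 0.5), seed = 77)
  b <- simulate_omics_dataset(sp, n_dilution = 5, noise_sd = 0.05,
                              secretion_range = c(0.1, 0.5), seed = 77)
  c <- simulate_omics_dataset(sp, n_dilution = 5, noise_sd = 0.05,
                              secretion_range = c(0.1, 0.5), seed = 78)
  expect_identical(a$features, b$features)
  expect_identical(a$targets, b$targets)
  expect_false(identical(a$features, c$features))
})

test_that("feature/target label collisions and missing values are rejected", {
  X <- matrix(1, 2, 2, dimnames = list(NULL, c("a", "b")))
  Y <- matrix(1, 2, 1, dimnames = list(NULL, "a"))
  expect_error(omics_dataset(X, Y), "disjoint")
  Y2 <- matrix(c(1, NA), 2, 1, dimnames = list(NULL, "t"))
  expect_error(omics_dataset(X, Y2), "missing")
})
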