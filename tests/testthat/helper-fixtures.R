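# Shared fixtures and independent oracles, built in code at test time.

# -- independent LP oracle: brute-force vertex enumeration ------------------
# max/min cvec'x s.t. A x = b, lb <= x <= ub, for tiny n. Enumerates all
# basic solutions (choose n - rank(A) variables fixed at a bound, solve the
# equality system for the rest) and returns the best feasible value.
lp_vertex_oracle <- function(cvec, A, b, lb, ub, maximize = TRUE, tol = 1e-8) {
  n <- length(cvec)
  A <- as.matrix(A)
  r <- qr(A)$rank
  free_ct <- n - r
  best <- NULL
  combos <- utils::combn(n, free_ct)
  for (j in seq_len(ncol(combos))) {
    fixed <- combos[, j]
    basics <- setdiff(seq_len(n), fixed)
    grid <- as.matrix(expand.grid(lapply(fixed, function(i) unique(c(lb[i], ub[i])))))
    for (g in seq_len(nrow(grid))) {
      x <- numeric(n)
      x[fixed] <- grid[g, ]
      rhs <- b - A[, fixed, drop = FALSE] %*% x[fixed]
      sol <- tryCatch(qr.solve(A[, basics, drop = FALSE], rhs),
                      error = function(e) NULL)
      if (is.null(sol)) next
      x[basics] <- sol
      if (max(abs(A %*% x - b)) > tol) next
      if (any(x < lb - tol) || any(x > ub + tol)) next
      val <- sum(cvec * x)
      if (is.null(best) || (maximize && val > best$val) ||
          (!maximize && val < best$val))
        best <- list(val = val, x = x)
    }
  }
  best
}

# -- small models -----------------------------------------------------------
chain_model <- function(cap = 2) {
  S <- rbind(c(1, -1, 0), c(0, 1, -1))
  dimnames(S) <- list(c("A", "B"), c("R1", "R2", "R3"))
  metabolic_model("chain", S, c(0, 0, 0), c(cap, 10, 10), "R3")
}

# branch point: uptake <= 4 feeds two routes with capacities 1 and 3
branch_model <- function() {
  S <- rbind(A = c(1, -1, -1, 0),
             P = c(0, 1, 1, -1))
  colnames(S) <- c("UP", "R_a", "R_b", "OUT")
  metabolic_model("branch", S, rep(0, 4), c(4, 1, 3, 10), "OUT")
}

# parallel routes of different length: A -> B direct (1 step) vs via C
# (2 steps), equal capacity; pFBA should route everything directly
parallel_model <- function() {
  S <- rbind(A = c(1, -1, -1, 0, 0),
             C = c(0, 0, 1, -1, 0),
             B = c(0, 1, 0, 1, -1))
  colnames(S) <- c("UP", "DIRECT", "TO_C", "FROM_C", "OUT")
  metabolic_model("parallel", S, rep(0, 5), c(2, 10, 10, 10, 10), "OUT")
}

# model with an internal 2-cycle that FBA may activate but pFBA must not
loop_model <- function() {
  S <- rbind(A = c(1, -1, 1, -1),
             B = c(0, 1, -1, 0))
  colnames(S) <- c("UP", "AB", "BA", "OUT")
  metabolic_model("loop", S, rep(0, 4), c(2, 10, 10, 10), "OUT")
}

# memoised heavier fixtures (built once per test run)
.fixture_env <- new.env(parent = emptyenv())
memo <- function(key, expr) {
  if (!exists(key, .fixture_env)) assign(key, force(expr), .fixture_env)
  get(key, .fixture_env)
}

toy_split <- function() memo("toy_split", split_reversible(make_toy_gem()))

ecoli_core <- function() memo("ecoli_core", {
  read_model_json(system.file("extdata", "e_coli_core.json", package = "minn"))
})

toy_dataset <- function() memo("toy_dataset", {
  simulate_omics_dataset(toy_split(), n_dilution = 6,
                         ko_genes = c("g1", "g2a"), seed = 5)
})

toy_context <- function() {
  ds <- toy_dataset()
  memo("toy_context", mechanistic_context(toy_split(), attr(ds, "pin"),
                                          attr(ds, "pref")))
}

# a random split-feasible toy instance for property tests
random_toy_instance <- function(n_extra = 0) {
  m <- make_toy_gem()
  split_reversible(m)
}

res_fixtures <- function() {
  memo("res_fixtures", {
    sp <- toy_split()
    vin_ids <- c("EX_glc_rev", "EX_o2_rev", "EX_s1", "EX_s2", "EX_s3")
    ranges <- list(c(2, 10), c(0.5, 4), c(0, 1), c(0, 1), c(0, 1))
    rds <- sample_fba_dataset(sp, vin_ids, ranges, n = 150, seed = 3)
    blk <- pretrain_block(rds, sp,
                          minn_control(strategy = "c_balanced", c = 100,
                                       dh = 96, lr_nn = 3e-3, epochs = 800),
                          seed = 4)
    list(sp = sp, vin_ids = vin_ids, ranges = ranges, rds = rds, blk = blk)
  })
}
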