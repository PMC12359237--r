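make_ctx <- function(S, Pin = NULL, Pref = NULL) {
  n <- ncol(S)
  if (is.null(Pin)) Pin <- matrix(0, 0, n)
  if (is.null(Pref)) Pref <- diag(n)
  list(S = S, Pin = Pin, Pref = Pref, m = nrow(S), n = n, nin = nrow(Pin))
}

test_that("flux-balance loss reproduces hand-computed values", {
  # one metabolite, producer/consumer: L2 = (1/1)|2-1|^2 = 1
  ctx <- make_ctx(matrix(c(1, -1), 1, 2))
  l <- fba_loss(matrix(c(2, 1), 1), ctx)
  expect_equal(l$L2, 1)
  expect_equal(l$L4, 0)
  # one entry -0.3 with n = 2: L4 = 0.3^2 / 2
  l2 <- fba_loss(matrix(c(-0.3, 0.3), 1), make_ctx(matrix(0, 1, 2)))
  expect_equal(l2$L4, 0.045)
  # an exact FBA solution respecting its input bounds scores zero
  sp <- toy_split()
  sol <- solve_fba(sp)
  Pin <- matrix(0, 1, length(sp$reactions))
  Pin[1, match("EX_glc_rev", sp$reactions)] <- 1
  ctx3 <- make_ctx(unclass(sp$S), Pin = Pin)
  l3 <- fba_loss(matrix(sol$values, 1), ctx3,
                 Vin = matrix(sol$values["EX_glc_rev"] + 1e-9, 1))
  expect_lt(l3$total, 1e-12)
})

test_that("the loss is zero exactly on feasible flux distributions", {
  ctx <- make_ctx(matrix(c(1, -1), 1, 2), Pin = matrix(c(1, 0), 1, 2))
  # feasible: steady state, under bound, non-negative
  expect_equal(fba_loss(matrix(c(1, 1), 1), ctx, Vin = matrix(2))$total, 0)
  # each violation type alone drives it positive
  expect_gt(fba_loss(matrix(c(2, 1), 1), ctx, Vin = matrix(5))$total, 0)  # S v != 0
  expect_gt(fba_loss(matrix(c(3, 3), 1), ctx, Vin = matrix(2))$total, 0)  # bound
  expect_gt(fba_loss(matrix(c(-1, -1), 1), ctx, Vin = matrix(2))$total, 0) # negative
})

test_that("analytic gradient matches central differences on 100 random instances", {
  set.seed(123)
  worst <- 0
  for (rep in 1:100) {
    m <- sample(1:4, 1); n <- sample(2:6, 1); nin <- sample(0:2, 1)
    S <- matrix(rnorm(m * n), m, n)
    Pin <- matrix(0, nin, n)
    if (nin > 0) for (i in seq_len(nin)) Pin[i, sample(n, 1)] <- 1
    ctx <- make_ctx(S, Pin = Pin)
    V <- matrix(rnorm(n), 1)
    Vin <- matrix(runif(max(nin, 1))[seq_len(nin)], 1, nin)
    G <- fba_loss_grad(V, ctx, Vin)
    h <- 1e-6
    fd <- vapply(seq_len(n), function(j) {
      vp <- V; vm <- V; vp[j] <- vp[j] + h; vm[j] <- vm[j] - h
      (fba_loss(vp, ctx, Vin)$total - fba_loss(vm, ctx, Vin)$total) / (2 * h)
    }, numeric(1))
    rel <- max(abs(G - fd)) / max(1e-8, max(abs(fd)))
    worst <- max(worst, rel)
  }
  expect_lt(worst, 1e-5)
})

test_that("refinement reproduces the hand-worked single step", {
  ctx <- make_ctx(matrix(c(1, -1), 1, 2))
  V0 <- matrix(c(2, 1), 1)
  # gradient of (1/1)|v1 - v2|^2 is 2(v1-v2) * (1, -1) = (2, -2)
  V1 <- mechanistic_refine(V0, ctx, lr_mech = 0.1, k_iter = 1)
  expect_equal(as.numeric(V1), c(1.8, 1.2))
  expect_equal(fba_loss(V1, ctx)$L2, 0.36)
})

test_that("refinement monotonically decreases the loss for admissible steps", {
  ctx <- make_ctx(matrix(c(1, -1), 1, 2))
  # quadratic term Hessian: 2 S'S / m, largest eigenvalue 4 -> stable below 0.5
  V <- matrix(c(2, 1), 1)
  losses <- numeric(6)
  for (k in 1:6) {
    losses[k] <- fba_loss(V, ctx)$total
    V <- mechanistic_refine(V, ctx, lr_mech = 0.1, k_iter = 1)
  }
  expect_true(all(diff(losses) < 0))
  # random instances: loss never increases when lr < 1 / lambda_max
  set.seed(5)
  for (rep in 1:10) {
    m <- sample(1:3, 1); n <- sample(2:5, 1)
    S <- matrix(rnorm(m * n), m, n)
    ctx <- make_ctx(S)
    lam <- max(eigen(2 * crossprod(S) / m, only.values = TRUE)$values) +
      2 / n   # negativity term adds at most 2/n to the curvature
    V <- matrix(rnorm(n) * 2, 1)
    l0 <- fba_loss(V, ctx)$total
    V5 <- mechanistic_refine(V, ctx, lr_mech = 0.9 / lam, k_iter = 5)
    expect_lte(fba_loss(V5, ctx)$total, l0 + 1e-12)
  }
})

test_that("feasible inputs are fixed points of the refinement", {
  sp <- toy_split()
  sol <- solve_fba(sp)
  ctx <- make_ctx(unclass(sp$S))
  V <- matrix(sol$values, 1)
  Vk <- mechanistic_refine(V, ctx, lr_mech = 0.05, k_iter = 25)
  expect_equal(as.numeric(Vk), as.numeric(V), tolerance = 1e-6)
})

test_that("the unrolled refinement is differentiable (reverse pass matches FD)", {
  set.seed(9)
  m <- 2; n <- 4; nin <- 1
  S <- matrix(rnorm(m * n), m, n)
  Pin <- matrix(0, 1, n); Pin[1, 2] <- 1
  ctx <- make_ctx(S, Pin = Pin)
  V0 <- matrix(rnorm(2 * n), 2, n)
  Vin <- matrix(runif(2), 2, 1)
  W <- matrix(rnorm(2 * n), 2, n)        # arbitrary downstream gradient
  fwd <- minn:::.refine_forward(V0, ctx, Vin, 0.05, 6)
  G0 <- minn:::.refine_backward(W, fwd$iterates, ctx, Vin, 0.05)
  h <- 1e-6
  fd <- V0 * 0
  for (i in seq_along(V0)) {
    vp <- V0; vm <- V0
    vp[i] <- vp[i] + h; vm[i] <- vm[i] - h
    fp <- sum(W * minn:::.refine_forward(vp, ctx, Vin, 0.05, 6)$V)
    fm <- sum(W * minn:::.refine_forward(vm, ctx, Vin, 0.05, 6)$V)
    fd[i] <- (fp - fm) / (2 * h)
  }
  expect_lt(max(abs(G0 - fd)) / max(abs(fd)), 1e-6)
})
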