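test_that("the feed-forward pass matches hand evaluation of the ReLU net", {
  w0 <- list(Wh = matrix(0, 1, 1), bh = 0, Wout = matrix(0, 1, 1), bout = 0)
  expect_equal(as.numeric(nn_forward(matrix(3), w0)), 0)
  # din = dh = dout = 1: Wh=1, bh=0, Wout=2, bout=1
  w <- list(Wh = matrix(1, 1, 1), bh = 0, Wout = matrix(2, 1, 1), bout = 1)
  expect_equal(as.numeric(nn_forward(matrix(3), w)), 7)    # relu(3)*2+1
  expect_equal(as.numeric(nn_forward(matrix(-3), w)), 1)   # relu(-3)=0
  # identical rows give identical outputs outside training
  X <- matrix(c(1, 2, 1, 2), 2, 2, byrow = TRUE)
  out <- nn_forward(X, list(Wh = matrix(rnorm(4), 2, 2), bh = rnorm(2),
                            Wout = matrix(rnorm(4), 2, 2), bout = rnorm(2)))
  expect_equal(out[1, ], out[2, ])
  expect_error(nn_forward(matrix(1, 1, 3), w), "dimension mismatch")
})

test_that("training is deterministic and drives the constraint loss down", {
  ds <- toy_dataset()
  ctx <- toy_context()
  ctrl <- minn_control(epochs = 150, dh = 24, lr_nn = 3e-3, c = 10)
  f1 <- minn(ds, ctx, ctrl, seed = 31)
  f2 <- minn(ds, ctx, ctrl, seed = 31)
  expect_identical(f1$weights, f2$weights)
  # mechanistic loss decreases by at least 10x from its starting value
  lfba <- f1$log$L2 + f1$log$L3 + f1$log$L4
  expect_lt(tail(lfba, 1), lfba[1] / 10)
  expect_s3_class(f1, "minn")
  expect_output(print(f1), "Metabolic-informed")
})

test_that("a converged fit predicts noiseless training data below NE 0.05", {
  ds <- toy_dataset()
  ctx <- toy_context()
  fit <- minn(ds, ctx, minn_control(epochs = 400, dh = 32, lr_nn = 3e-3,
                                    c = 10, lr_mech = 0.05, k_iter = 20),
              seed = 2)
  pr <- predict(fit, ds)
  expect_lt(data_loss(pr$V, ds$targets, ctx$Pref), 0.05)
  # refined outputs are near non-negative relative to the flux scale, and
  # the refinement only improves on the raw network output
  pr0 <- predict(fit, ds, refine = FALSE)
  expect_gt(min(pr$V), -0.05 * max(abs(pr$V)))
  expect_gte(min(pr$V), min(pr0$V) - 1e-9)
  # constant-feature batches map to identical rows
  X2 <- ds$features[c(1, 1), , drop = FALSE]
  pr2 <- predict(fit, X2, vin = ds$vin[c(1, 1), , drop = FALSE])
  expect_equal(pr2$V[1, ], pr2$V[2, ])
  expect_error(predict(fit, ds$features[, -1]), "lacks feature")
})

test_that("model methods expose coefficients, residuals and training curves", {
  ds <- toy_dataset()
  ctx <- toy_context()
  fit <- minn(ds, ctx, minn_control(epochs = 30, dh = 8), seed = 3)
  expect_named(coef(fit), c("Wh", "bh", "Wout", "bout"))
  r <- residuals(fit)
  expect_equal(dim(r), dim(ds$targets))
  expect_equal(unname(fitted(fit) - ds$targets), unname(r))
  s <- summary(fit)
  expect_s3_class(s, "summary.minn")
  expect_output(print(s), "training NE")
  pdf(NULL)
  on.exit(dev.off())
  expect_silent(plot(fit))
})

test_that("training aborts with a diagnostic on divergence", {
  ds <- toy_dataset()
  ctx <- toy_context()
  # a mechanistic step far above the stability bound makes the unrolled
  # refinement blow up exponentially and the loss overflow
  expect_error(
    minn(ds, ctx, minn_control(epochs = 50, lr_nn = 1e-3, lr_mech = 1e3,
                               k_iter = 60), seed = 1),
    "non-finite")
})

test_that("configs and trained models survive a JSON round trip", {
  ctrl <- minn_control(dh = 17, c = 3.5, strategy = "bound",
                       bound_threshold = 0.2)
  f <- withr::local_tempfile(fileext = ".json")
  write_minn_config(ctrl, f)
  ctrl2 <- read_minn_config(f)
  expect_equal(ctrl2$dh, 17L)
  expect_equal(ctrl2$c, 3.5)
  expect_identical(ctrl2$strategy, "bound")

  ds <- toy_dataset()
  ctx <- toy_context()
  fit <- minn(ds, ctx, minn_control(epochs = 20, dh = 8), seed = 4)
  g <- withr::local_tempfile(fileext = ".json")
  save_minn(fit, g)
  fit2 <- load_minn(g, ctx)
  pr1 <- predict(fit, ds)
  pr2 <- predict(fit2, ds)
  expect_equal(pr1$V, pr2$V, tolerance = 1e-12)
  h <- withr::local_tempfile(fileext = ".csv")
  write_training_log(fit, h)
  expect_equal(nrow(read.csv(h)), 20L)
})
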