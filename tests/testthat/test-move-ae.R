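test_that("analytic BPTT gradients match central finite differences", {
  cfg <- tiny_move_cfg(seed = 9)
  params <- withr::with_seed(9, gaitlatent:::init_move_ae_params(cfg))
  x <- tiny_windows(8, 10, 4, seed = 3)
  xb <- gaitlatent:::windows_to_cube(x)
  lg <- gaitlatent:::moveae_loss_grad(params, xb)
  eps <- 1e-6  # small enough that LSTM curvature does not bias the quotient
  worst <- 0
  withr::with_seed(99, {
    for (nm in names(params)) {
      for (i in sample(length(params[[nm]]), min(4, length(params[[nm]])))) {
        p1 <- params; p1[[nm]][i] <- p1[[nm]][i] + eps
        p2 <- params; p2[[nm]][i] <- p2[[nm]][i] - eps
        ng <- (gaitlatent:::moveae_loss(p1, xb) -
               gaitlatent:::moveae_loss(p2, xb)) / (2 * eps)
        ag <- as.numeric(lg$grads[[nm]])[i]
        worst <- max(worst, abs(ng - ag) / max(1e-4, abs(ng) + abs(ag)))
      }
    }
  })
  expect_lt(worst, 1e-3)
})

test_that("a repeated window is fit to near zero error", {
  x <- withr::with_seed(21, {
    w <- matrix(rnorm(10 * 4), 10, 4)
    out <- array(0, c(16, 10, 4))
    for (i in 1:16) out[i, , ] <- w + 0.01 * rnorm(40)
    out
  })
  m <- train_move_ae(x, tiny_move_cfg(iters = 2000, lr = 3e-3, seed = 2))
  expect_lt(sqrt(m$final_loss), 0.05)
})

test_that("training and inference are deterministic given the seed", {
  x <- tiny_windows(32, 10, 4, seed = 5)
  cfg <- tiny_move_cfg(iters = 60, lr = 3e-3, seed = 7)
  m1 <- train_move_ae(x, cfg)
  m2 <- train_move_ae(x, cfg)
  expect_equal(m1$final_loss, m2$final_loss, tolerance = 1e-6)
  expect_identical(encode(m1, x), encode(m2, x))
  z <- encode(m1, x)
  expect_identical(decode(m1, z), decode(m1, z))
  m3 <- train_move_ae(x, tiny_move_cfg(iters = 60, lr = 3e-3, seed = 8))
  expect_false(isTRUE(all.equal(m1$final_loss, m3$final_loss)))
})

test_that("loss history is finite and decreases over training", {
  x <- tiny_windows(64, 10, 4, seed = 6)
  m <- train_move_ae(x, tiny_move_cfg(iters = 200, lr = 3e-3, seed = 4))
  expect_true(all(is.finite(m$loss_history)))
  expect_lt(m$loss_history[length(m$loss_history)], m$loss_history[1])
})

test_that("shape contracts and mismatches are enforced", {
  x <- tiny_windows(16, 10, 4, seed = 2)
  m <- train_move_ae(x, tiny_move_cfg(iters = 30, lr = 3e-3, seed = 1))
  z <- encode(m, x)
  expect_equal(dim(z), c(16, 2))
  y <- decode(m, z)
  expect_equal(dim(y), dim(x))
  expect_error(encode(m, tiny_windows(4, 9, 4, seed = 1)),
               class = "gaitlatent_error_shape")
  expect_error(decode(m, z[, 1, drop = FALSE]), class = "gaitlatent_error_shape")
  expect_error(train_move_ae(x[1:4, , ], tiny_move_cfg(batch = 8)),
               class = "gaitlatent_error_argument")
})

test_that("frame-shuffled windows carry no forward/backward signal", {
  # control for the temporal-sensitivity property: destroying frame order
  # in training and evaluation data must push reversal classification to
  # chance, confirming that temporal structure drives the separation
  st <- generate_study(1, 0, 0, duration = 20, seed = 55)
  prep <- preprocess_study(st)
  W <- prep$windows$x
  n <- dim(W)[1]
  comb <- array(0, c(2 * n, 60, 14))
  comb[1:n, , ] <- W
  comb[(n + 1):(2 * n), , ] <- reverse_windows(W)
  lab <- rep(c("fwd", "rev"), each = n)
  sh <- shuffle_window_frames(comb, seed = 33)
  m <- train_move_ae(sh, move_ae_config(iters = 400, lr = 3e-3, seed = 13))
  err <- classify_latent(encode(m, sh), lab)
  expect_gt(err, 0.4)
  expect_lt(err, 0.6)
})
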