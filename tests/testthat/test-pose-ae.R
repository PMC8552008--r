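# Randomize biases/shifts so no pre-activation sits exactly on a ReLU kink
# (zero-initialized nets are nondifferentiable there and finite differences
# would probe subgradients).
randomized_params <- function(cfg, seed) {
  p <- withr::with_seed(seed, gaitlatent:::init_pose_ae_params(cfg))
  withr::with_seed(seed + 1, {
    for (nm in grep("decb|latb|outb|encB", names(p), value = TRUE)) {
      p[[nm]] <- stats::rnorm(length(p[[nm]]), 0, 0.3)
    }
  })
  p
}

test_that("compiled kernel agrees with the plain-R reference implementation", {
  cfg <- pose_ae_config(input = 5, latent = 2, hidden = c(6, 4))
  p <- randomized_params(cfg, 4)
  x <- tiny_poses(40, 5, seed = 8)
  ref <- gaitlatent:::poseae_loss_grad_ref(p, x, 2L)
  cpp <- gaitlatent:::poseae_loss_grad(c(p, list(n_hidden = 2L)), x)
  expect_equal(cpp$loss, ref$loss, tolerance = 1e-12)
  for (nm in names(p)) {
    expect_equal(as.numeric(cpp$grads[[nm]]), as.numeric(ref$grads[[nm]]),
                 tolerance = 1e-10, label = nm)
  }
})

test_that("analytic gradients match central finite differences", {
  cfg <- pose_ae_config(input = 5, latent = 2, hidden = c(6, 4))
  p <- randomized_params(cfg, 4)
  x <- tiny_poses(40, 5, seed = 8)
  full <- c(p, list(n_hidden = 2L))
  lg <- gaitlatent:::poseae_loss_grad(full, x)
  loss_of <- function(q) gaitlatent:::poseae_loss_grad(c(q, list(n_hidden = 2L)), x)$loss
  eps <- 1e-6
  worst <- 0
  withr::with_seed(99, {
    for (nm in names(p)) {
      for (i in sample(length(p[[nm]]), min(4, length(p[[nm]])))) {
        q1 <- p; q1[[nm]][i] <- q1[[nm]][i] + eps
        q2 <- p; q2[[nm]][i] <- q2[[nm]][i] - eps
        ng <- (loss_of(q1) - loss_of(q2)) / (2 * eps)
        ag <- as.numeric(lg$grads[[nm]])[i]
        worst <- max(worst, abs(ng - ag) / max(1e-6, abs(ng) + abs(ag)))
      }
    }
  })
  expect_lt(worst, 1e-4)
})

test_that("a repeated pose is fit to near zero error", {
  x <- withr::with_seed(12, {
    pose <- rnorm(14)
    matrix(rep(pose, each = 60), 60, 14) + 0.01 * rnorm(60 * 14)
  })
  m <- train_pose_ae(x, pose_ae_config(iters = 300, lr = 2e-3, seed = 2))
  expect_lt(sqrt(m$final_loss), 0.05)
})

test_that("training is deterministic given the seed", {
  x <- small_prep()$poses$x[1:200, ]
  cfg <- pose_ae_config(iters = 150, lr = 2e-3, seed = 5)
  m1 <- train_pose_ae(x, cfg)
  m2 <- train_pose_ae(x, cfg)
  expect_equal(m1$final_loss, m2$final_loss, tolerance = 1e-6)
  expect_identical(encode(m1, x), encode(m2, x))
  expect_identical(decode(m1, encode(m1, x)), decode(m2, encode(m2, x)))
  m3 <- train_pose_ae(x, pose_ae_config(iters = 150, lr = 2e-3, seed = 6))
  expect_false(isTRUE(all.equal(m1$final_loss, m3$final_loss)))
})

test_that("loss stays finite and decreases; divergence raises a named error", {
  x <- small_prep()$poses$x[1:200, ]
  m <- train_pose_ae(x, pose_ae_config(iters = 200, lr = 2e-3, seed = 5))
  expect_true(all(is.finite(m$loss_history)))
  expect_lt(m$loss_history[length(m$loss_history)], m$loss_history[1])
  # non-finite inputs surface as a divergence error with the iteration index
  xbad <- x
  xbad[1, 1] <- Inf
  expect_error(train_pose_ae(xbad, pose_ae_config(iters = 10, seed = 5)),
               class = "gaitlatent_error_diverged")
})

test_that("a 1-D nonlinear curve in 14-space is captured by a 2-D bottleneck", {
  x <- withr::with_seed(13, {
    t <- runif(500)
    raw <- cbind(sin(2 * pi * t), cos(2 * pi * t), sin(4 * pi * t + 0.5),
                 t^2, exp(t) - 1, cos(4 * pi * t - 1), t^3 - t,
                 sin(6 * pi * t), abs(t - 0.5), cos(2 * pi * t)^2,
                 t, sqrt(t + 0.1), sin(2 * pi * t + 1), cos(6 * pi * t))
    scale(raw)
  })
  m <- train_pose_ae(x, pose_ae_config(iters = 1500, lr = 2e-3, seed = 3))
  expect_gte(vaf(x, reconstruct(m, x)), 95)
})

test_that("shape contracts and width mismatches are enforced", {
  x <- small_prep()$poses$x[1:100, ]
  m <- train_pose_ae(x, pose_ae_config(iters = 50, lr = 2e-3, seed = 1))
  z <- encode(m, x)
  expect_equal(dim(z), c(100, 2))
  expect_equal(dim(decode(m, z)), dim(x))
  expect_error(encode(m, x[, 1:10]), class = "gaitlatent_error_shape")
  expect_error(decode(m, z[, 1, drop = FALSE]), class = "gaitlatent_error_shape")
  expect_error(train_pose_ae(x[1, , drop = FALSE], pose_ae_config()),
               class = "gaitlatent_error_argument")
})
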