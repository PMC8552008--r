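test_that("classifier error behaves on canonical configurations", {
  z <- withr::with_seed(1, rbind(matrix(rnorm(100, 0, 0.1), 50, 2),
                                 matrix(rnorm(100, 10, 0.1), 50, 2)))
  lab <- rep(c("a", "b"), each = 50)
  expect_equal(classify_latent(z, lab), 0)
  # duplication leaves the error ratio unchanged
  e1 <- classify_latent(z + withr::with_seed(2, rnorm(200, 0, 3)), lab)
  z2 <- rbind(z, z)
  e2 <- classify_latent(z2 + withr::with_seed(2, rbind(m <- matrix(rnorm(200, 0, 3), 100, 2), m)),
                        c(lab, lab))
  expect_equal(e1, e2, tolerance = 1e-12)
  expect_error(classify_latent(z, rep("a", 100)),
               class = "gaitlatent_error_labels")
  expect_error(classify_latent(z[1:3, ], c("a", "a", "b")),
               class = "gaitlatent_error_labels")
})

test_that("randomly permuted labels over balanced classes give near-chance error", {
  k <- 4
  withr::with_seed(3, {
    z <- matrix(rnorm(4000), 2000, 2)
    lab <- sample(rep(letters[1:k], each = 2000 / k))
  })
  err <- classify_latent(z, lab)
  expect_gt(err, (1 - 1 / k) - 0.05)
  expect_lt(err, (1 - 1 / k) + 0.05)
})

test_that("run_task records per-repetition errors with PCA deterministic", {
  prep <- small_prep()
  runs <- run_task("movement", prep, reducers = "pca", repetitions = 10,
                   seed = 1)
  expect_equal(nrow(runs), 10)
  expect_length(unique(runs$error), 1)
  expect_true(all(runs$error >= 0 & runs$error <= 1))
  expect_error(run_task("individual", preprocess_study(generate_study(1, 0, 0, 10, seed = 2)),
                        reducers = "pca", seed = 1),
               class = "gaitlatent_error_task")
  flat_only <- preprocess_study(generate_study(2, 0, 0, 10, seed = 3))
  expect_error(run_task("movement", flat_only, reducers = "pca", seed = 1),
               class = "gaitlatent_error_task")
})

test_that("autoencoder repetitions vary with the retraining seed", {
  prep <- small_prep()
  runs <- run_task("movement", prep, reducers = "pose_ae", repetitions = 2,
                   seed = 4,
                   pose_config = pose_ae_config(iters = 60, lr = 2e-3))
  expect_equal(nrow(runs), 2)
  # rerunning with the same master seed reproduces the errors exactly
  runs2 <- run_task("movement", prep, reducers = "pose_ae", repetitions = 2,
                    seed = 4,
                    pose_config = pose_ae_config(iters = 60, lr = 2e-3))
  expect_identical(runs$error, runs2$error)
})

test_that("KS comparison matches brute-force ECDF gaps", {
  expect_equal(compare_runs(c(0.1, 0.2, 0.3), c(0.1, 0.2, 0.3))$statistic, 0)
  expect_equal(compare_runs(c(0.1, 0.2), c(0.8, 0.9))$statistic, 1)
  expect_equal(compare_runs(c(0.1, 0.2, 0.3), c(0.2, 0.3, 0.4))$statistic,
               1 / 3, tolerance = 1e-12)
  # symmetric in its arguments
  a <- c(0.05, 0.2, 0.22, 0.4)
  b <- c(0.1, 0.3)
  expect_equal(compare_runs(a, b)$statistic, compare_runs(b, a)$statistic)
  expect_error(compare_runs(numeric(0), a), class = "gaitlatent_error_argument")
})

test_that("summarize_runs aggregates per task and reducer", {
  runs <- data.frame(task = "movement",
                     reducer = rep(c("pca", "pose_ae"), each = 3),
                     rep = rep(1:3, 2),
                     error = c(0.2, 0.2, 0.2, 0.1, 0.2, 0.3))
  s <- summarize_runs(runs)
  expect_equal(nrow(s), 2)
  expect_equal(s$mean_error[s$reducer == "pose_ae"], 0.2)
  expect_equal(s$sd_error[s$reducer == "pca"], 0)
})
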