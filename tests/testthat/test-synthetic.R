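test_that("channel schema has the documented structure", {
  full <- channel_schema()
  expect_equal(nrow(full), 18)
  expect_false(any(duplicated(full$channel)))
  red <- channel_schema(reduced = TRUE)
  expect_equal(nrow(red), 14)
  expect_false(any(red$joint == "knee" & red$plane != "sagittal"))
})

test_that("profiles are deterministic in (template, subject, seed) and distinct across subjects", {
  a <- make_profile("flat", 0, seed = 42)
  b <- make_profile("flat", 0, seed = 42)
  expect_identical(a, b)
  c2 <- make_profile("flat", 1, seed = 42)
  expect_true(any(a$modes$level$amp != c2$modes$level$amp))
  expect_error(class_template("jogging"), class = "gaitlatent_error_template")
})

test_that("distinct flat subjects have distinct noise-free mean poses", {
  mean_pose <- function(i) {
    p <- make_profile("flat", i, seed = 42, noise_sd = 0)
    r <- generate_recording(p, duration = p$period_frames / 60, seed = 42,
                            noise_sd = 0)
    colMeans(r$angles)
  }
  mp <- t(vapply(0:7, mean_pose, numeric(18)))
  d <- as.matrix(stats::dist(mp))
  expect_true(all(d[upper.tri(d)] > 0))
})

test_that("noise-free cyclic recordings are exactly periodic", {
  p <- make_profile("flat", 0, seed = 42, noise_sd = 0)
  p$period_frames <- 60L  # cadence exactly 1 stride/s at 60 Hz
  p$cadence <- 1
  r <- generate_recording(p, duration = 4, seed = 1, noise_sd = 0)
  expect_identical(r$angles[1:60, ], r$angles[61:120, ])
  # autocorrelation at one period is exactly 1
  ac <- stats::cor(r$angles[1:180, 1], r$angles[61:240, 1])
  expect_equal(ac, 1, tolerance = 1e-12)
})

test_that("zero amplitudes and zero noise give a constant offset pose", {
  p <- make_profile("flat", 0, seed = 42, noise_sd = 0)
  p$modes$level$amp[] <- 0
  r <- generate_recording(p, duration = 1, seed = 1, noise_sd = 0)
  expect_true(all(abs(sweep(r$angles, 2, p$modes$level$offset)) == 0))
})

test_that("additive noise has the configured standard deviation", {
  p <- make_profile("flat", 0, seed = 9)
  clean <- generate_recording(p, duration = 10000 / 60, seed = 5, noise_sd = 0)
  noisy <- generate_recording(p, duration = 10000 / 60, seed = 5, noise_sd = 2)
  resid <- noisy$angles - clean$angles
  sds <- apply(resid, 2, stats::sd)
  expect_true(all(sds > 1.8 & sds < 2.2))
})

test_that("a reversed noise-free recording is not a circular shift of the forward one", {
  p <- make_profile("flat", 0, seed = 77, noise_sd = 0)
  r <- generate_recording(p, duration = p$period_frames / 60, seed = 77,
                          noise_sd = 0)
  x <- r$angles
  P <- nrow(x)
  xr <- x[P:1, ]
  mind <- min(vapply(0:(P - 1), function(s) {
    max(abs(xr - x[((seq_len(P) - 1 + s) %% P) + 1, ]))
  }, numeric(1)))
  expect_gt(mind, 1e-9)
})

test_that("generate_study honours counts, unique ids and seed determinism", {
  st <- generate_study(8, 11, 13, duration = 5, seed = 7)
  expect_length(st$recordings, 32)
  expect_length(unique(names(st$recordings)), 32)
  acts <- vapply(st$recordings, `[[`, character(1), "activity")
  expect_equal(unname(table(acts)[c("flat", "stair", "natural")]),
               c(8L, 11L, 13L), ignore_attr = TRUE)
  one <- generate_study(0, 0, 1, duration = 10, seed = 7)
  expect_length(one$recordings, 1)
  expect_equal(one$recordings[[1]]$activity, "natural")
  a <- generate_study(2, 2, 0, duration = 10, seed = 7)
  b <- generate_study(2, 2, 0, duration = 10, seed = 7)
  expect_identical(lapply(a$recordings, `[[`, "angles"),
                   lapply(b$recordings, `[[`, "angles"))
})

test_that("flat and stair class means are separated well beyond the noise level", {
  prep <- small_prep()
  fl <- prep$poses$info$activity == "flat"
  # back to degrees so the margin is comparable to the 2-degree noise SD
  dmeans <- abs(colMeans(prep$poses$x[fl, ]) -
                colMeans(prep$poses$x[!fl, ])) * prep$standardizer$sd
  expect_gte(sum(dmeans >= 2), 4)
})

test_that("natural recordings mix segment types and idle pelvic speed is exactly zero", {
  p <- make_profile("natural", 0, seed = 31)
  r <- generate_recording(p, duration = 60, seed = 31)
  expect_true(any(r$pelvic_speed == 0))   # idle
  expect_true(any(r$pelvic_speed > 0.3))  # active
  expect_true(any(is.finite(r$cycle_phase)) && any(!is.finite(r$cycle_phase)))
})

test_that("recordings round-trip through CSV plus sidecar", {
  p <- make_profile("flat", 0, seed = 4)
  r <- generate_recording(p, duration = 2, seed = 4)
  path <- file.path(withr::local_tempdir(), "rec.csv")
  write_recording(r, path)
  r2 <- read_recording(path)
  expect_equal(r2$angles, r$angles, tolerance = 1e-8)
  expect_equal(r2$pelvic_speed, r$pelvic_speed, tolerance = 1e-8)
  expect_identical(r2$subject_id, r$subject_id)
  expect_identical(r2$activity, r$activity)
  expect_identical(r2$channels, r$channels)
})
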