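test_that("channel selection keeps 14 channels, is idempotent and drops knee off-sagittal data", {
  p <- make_profile("flat", 0, seed = 1)
  r <- generate_recording(p, duration = 2, seed = 1)
  sentinel <- 9999
  r$angles[, "knee_left_frontal"] <- sentinel
  s1 <- select_channels(r)
  expect_equal(ncol(s1$angles), 14)
  expect_identical(s1$channels, channel_schema(reduced = TRUE)$channel)
  expect_false(any(s1$angles == sentinel))
  expect_identical(select_channels(s1), s1)
  r$angles <- r$angles[, -1, drop = FALSE]
  r$channels <- colnames(r$angles)
  expect_error(select_channels(r), class = "gaitlatent_error_channels")
})

make_const_rec <- function(value, n = 50) {
  ang <- matrix(value, n, 14)
  colnames(ang) <- channel_schema(reduced = TRUE)$channel
  new_rec <- gaitlatent:::new_recording
  new_rec(ang, subject_id = paste0("c", value), activity = "flat", rate = 60)
}

test_that("standardizer pools frames across recordings", {
  # constant +1 and -1 recordings of equal length: mean 0, SD 1
  s <- fit_standardizer(list(make_const_rec(1), make_const_rec(-1)))
  expect_equal(unname(s$mean), rep(0, 14))
  expect_equal(unname(s$sd), rep(1, 14))
  # z-scoring a single recording by its own standardizer
  p <- make_profile("flat", 0, seed = 2)
  r <- select_channels(generate_recording(p, duration = 5, seed = 2))
  s1 <- fit_standardizer(list(r))
  z <- standardize(s1, r$angles)
  expect_lt(max(abs(colMeans(z))), 1e-9)
  expect_lt(max(abs(sqrt(colMeans(z^2) - colMeans(z)^2) - 1)), 1e-9)
  # streaming moments match a brute-force concatenation oracle
  st <- generate_study(1, 1, 1, duration = 10, seed = 3)
  recs <- lapply(st$recordings, select_channels)
  s2 <- fit_standardizer(recs)
  pooled <- do.call(rbind, lapply(recs, `[[`, "angles"))
  expect_equal(unname(s2$mean), unname(colMeans(pooled)), tolerance = 1e-12)
  expect_equal(unname(s2$sd),
               unname(sqrt(colMeans(pooled^2) - colMeans(pooled)^2)),
               tolerance = 1e-12)
  expect_error(fit_standardizer(list(make_const_rec(1))),
               class = "gaitlatent_error_degenerate")
})

test_that("standardize and unstandardize are inverse within 1e-9", {
  prep <- small_prep()
  r <- prep$recordings[[1]]
  z <- standardize(prep$standardizer, r$angles)
  back <- unstandardize(prep$standardizer, z)
  expect_lt(max(abs(back - r$angles)), 1e-9)
})

test_that("pelvic-velocity filter extracts qualifying active runs", {
  p <- make_profile("flat", 0, seed = 5)
  r <- select_channels(generate_recording(p, duration = 400 / 60, seed = 5))
  r$pelvic_speed <- rep(0, 400)
  expect_length(filter_by_pelvic_velocity(r, threshold = 0.1), 0)
  r$pelvic_speed <- rep(1, 400)
  segs <- filter_by_pelvic_velocity(r, threshold = 0.1)
  expect_length(segs, 1)
  expect_identical(segs[[1]]$angles, r$angles)
  r$pelvic_speed <- c(rep(0, 100), rep(1, 200), rep(0, 100))
  segs <- filter_by_pelvic_velocity(r, threshold = 0.1, min_segment = 60)
  expect_length(segs, 1)
  expect_equal(nrow(segs[[1]]$angles), 200)
  expect_identical(segs[[1]]$angles, r$angles[101:300, ])
  r$pelvic_speed <- NULL
  expect_error(filter_by_pelvic_velocity(r), class = "gaitlatent_error_pelvic")
})

test_that("pose sampling takes every stride-th frame and round-trips", {
  p <- make_profile("flat", 0, seed = 6)
  r <- select_channels(generate_recording(p, duration = 10, seed = 6))
  std <- fit_standardizer(list(r))
  ps <- sample_poses(r, std, stride = 10)
  expect_equal(nrow(ps$x), 60)
  expect_equal(ps$info$frame, seq(0, 590, by = 10))
  back <- unstandardize(std, ps$x)
  expect_lt(max(abs(back - r$angles[ps$info$frame + 1, ])), 1e-9)
  r5 <- r
  r5$angles <- r$angles[1:5, ]
  r5$pelvic_speed <- r$pelvic_speed[1:5]
  r5$cycle_phase <- r$cycle_phase[1:5]
  expect_equal(nrow(sample_poses(r5, std, stride = 10)$x), 1)
})

test_that("window sampling respects boundaries and matches the pose view", {
  p <- make_profile("flat", 0, seed = 6)
  r <- select_channels(generate_recording(p, duration = 10, seed = 6))
  std <- fit_standardizer(list(r))
  ws <- sample_windows(r, std, window = 60, stride = 10)
  expect_equal(dim(ws$x), c(55, 60, 14))
  expect_equal(ws$info$start_frame, seq(0, 540, by = 10))
  trunc_to <- function(n) {
    r2 <- r
    r2$angles <- r$angles[seq_len(n), ]
    r2$pelvic_speed <- r$pelvic_speed[seq_len(n)]
    r2$cycle_phase <- r$cycle_phase[seq_len(n)]
    r2
  }
  expect_equal(dim(sample_windows(trunc_to(60), std)$x)[1], 1)
  expect_equal(dim(sample_windows(trunc_to(59), std)$x)[1], 0)
  # every window row equals the standardized source frame (= pose view)
  ps <- sample_poses(r, std, stride = 1)
  for (i in c(1, 20, 55)) {
    for (rr in c(1, 31, 60)) {
      expect_equal(ws$x[i, rr, ], unname(ps$x[ws$info$start_frame[i] + rr, ]),
                   tolerance = 1e-12)
    }
  }
})

test_that("preprocess_study filters only the natural class and standardizes pooled frames", {
  st <- generate_study(1, 1, 2, duration = 30, seed = 8)
  prep <- preprocess_study(st)
  # natural recordings were split into active segments; idle frames dropped
  acts <- vapply(prep$recordings, `[[`, character(1), "activity")
  expect_true(sum(acts == "natural") >= 2)
  nat <- prep$recordings[acts == "natural"]
  expect_true(all(vapply(nat, function(r) all(r$pelvic_speed > 0), logical(1))))
  # pooled standardized frames have mean 0, SD 1
  pooled <- do.call(rbind, lapply(prep$recordings, function(r)
    standardize(prep$standardizer, r$angles)))
  expect_lt(max(abs(colMeans(pooled))), 1e-9)
  expect_lt(max(abs(sqrt(colMeans(pooled^2) - colMeans(pooled)^2) - 1)), 1e-9)
  # provenance never crosses subjects
  expect_true(all(prep$windows$info$subject %in% names(st$recordings)))
})
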