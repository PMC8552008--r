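test_that("pca model satisfies its algebraic contracts", {
  prep <- small_prep()
  m <- fit_pca(prep$poses$x)
  d <- ncol(prep$poses$x)
  expect_lt(max(abs(crossprod(m$components) - diag(d))), 1e-8)
  expect_true(all(diff(m$eigenvalues) <= 1e-12))
  expect_equal(sum(m$eigenvalues),
               sum(gaitlatent:::col_pop_var(prep$poses$x)), tolerance = 1e-6)
  # deterministic: repeated fits identical (sign convention fixed)
  expect_identical(m, fit_pca(prep$poses$x))
  # reconstruction VAF equals cumulative explained variance (spot widths)
  for (k in c(2, 5)) {
    expect_equal(vaf(prep$poses$x, reconstruct(m, prep$poses$x, k = k)),
                 pca_explained(m, k), tolerance = 1e-6)
  }
})

test_that("rank-1 data is captured exactly by one component", {
  withr::with_seed(10, {
    dir <- rnorm(14)
    dir <- dir / sqrt(sum(dir^2))
    t <- rnorm(100)
    x <- outer(t, dir) + matrix(rep(rnorm(14), each = 100), 100, 14)
  })
  m <- fit_pca(x)
  expect_gt(m$eigenvalues[1], 0)
  expect_true(all(m$eigenvalues[-1] <= 1e-10))
  expect_lt(max(abs(reconstruct(m, x, k = 1) - x)), 1e-8)
})

test_that("projection matches hand-computed arithmetic on three points", {
  # three points on the line through (1,1,0,...)/sqrt(2), offset by mean
  d <- 14
  v <- c(1, 1, rep(0, d - 2)) / sqrt(2)
  x <- rbind(-2 * v, 0 * v, 2 * v) + 5
  m <- fit_pca(rbind(x, x, x, x, x))  # replicate to satisfy n > d
  z <- encode(m, x, k = 1)
  expect_equal(as.numeric(z), c(-2, 0, 2), tolerance = 1e-8)
  expect_lt(max(abs(decode(m, z) - x)), 1e-8)
})

test_that("isotropic data yields a nearly flat spectrum at large n", {
  x <- withr::with_seed(11, matrix(rnorm(10000 * 14), 10000, 14))
  m <- fit_pca(x)
  expect_lt(m$eigenvalues[1] / m$eigenvalues[14], 1.5)
})

test_that("encode and decode handle means, full rank and bad widths", {
  prep <- small_prep()
  m <- fit_pca(prep$poses$x)
  expect_lt(max(abs(encode(m, matrix(m$mean, 1), k = 2))), 1e-10)
  x <- prep$poses$x[1:20, ]
  expect_lt(max(abs(reconstruct(m, x, k = 14) - x)), 1e-8)
  # decode is affine: decode(a) + decode(b) - decode(0) = decode(a + b)
  a <- encode(m, x[1:5, ], k = 2)
  b <- encode(m, x[6:10, ], k = 2)
  expect_equal(decode(m, a + b), decode(m, a) + decode(m, b) - decode(m, a * 0),
               tolerance = 1e-8)
  expect_error(encode(m, x, k = 0), class = "gaitlatent_error_argument")
  expect_error(encode(m, x, k = 15), class = "gaitlatent_error_argument")
  expect_error(fit_pca(x[1:10, ]), class = "gaitlatent_error_argument")
})
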