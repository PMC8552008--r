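# Shared fixtures, built once per test run and cached.
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixtures, inherits = FALSE)) {
    assign(name, expr, envir = .fixtures)
  }
  get(name, envir = .fixtures, inherits = FALSE)
}

# Two flat + two stair subjects, 20 s each: enough structure for class
# and subject contrasts at unit-test cost.
small_study <- function() fixture("small_study",
  generate_study(2, 2, 0, duration = 20, seed = 42))

small_prep <- function() fixture("small_prep", preprocess_study(small_study()))

# A tiny random pose matrix for contract tests.
tiny_poses <- function(n = 40, d = 14, seed = 7) {
  withr::with_seed(seed, matrix(stats::rnorm(n * d), n, d))
}

# Tiny Move-AE problem: short windows, few channels, small net.
tiny_move_cfg <- function(...) {
  args <- list(window = 10L, channels = 4L, td_width = 8L, hidden = 5L,
               mid = 4L, batch = 8L, record_every = 10L)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(move_ae_config, args)
}

tiny_windows <- function(n = 24, T = 10, C = 4, seed = 3) {
  withr::with_seed(seed, array(stats::rnorm(n * T * C), c(n, T, C)))
}
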