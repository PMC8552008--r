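#' Configuration for the movement autoencoder
#'
#' A sequence autoencoder that embeds a one-second movement window
#' (60 timesteps x 14 channels) as a single 2-D latent point. The encoder
#' is a time-distributed fully connected layer of width 64, two
#' bidirectional LSTM layers, and an intermediate fully connected layer
#' that reduces the recurrent summary to the latent width; the decoder
#' mirrors it (the latent vector is repeated across all timesteps to form
#' the decoder's input sequence). Training minimizes mean squared
#' reconstruction error over all window entries with Adam on mini-batches.
#'
#' @param window window length in frames.
#' @param channels channel count.
#' @param latent bottleneck width.
#' @param td_width width of the time-distributed dense layers.
#' @param hidden LSTM hidden units per direction.
#' @param mid width of the intermediate dense layer before the latent.
#' @param lr Adam learning rate.
#' @param iters mini-batch gradient steps (default 8000; analyses at desk
#'   scale use fewer — see the methods vignette).
#' @param batch mini-batch size.
#' @param seed integer seed for initialization and batch sampling.
#' @param record_every record the training loss every this many steps.
#' @return a `move_ae_config` list.
#' @export
move_ae_config <- function(window = 60L, channels = 14L, latent = 2L,
                           td_width = 64L, hidden = 32L, mid = 16L,
                           lr = 1e-3, iters = 8000L, batch = 32L,
                           seed = 1L, record_every = 50L) {
  stopifnot(window >= 2, batch >= 1, latent >= 1, iters >= 1)
  structure(list(window = as.integer(window), channels = as.integer(channels),
                 latent = as.integer(latent), td_width = as.integer(td_width),
                 hidden = as.integer(hidden), mid = as.integer(mid),
                 lr = lr, iters = as.integer(iters), batch = as.integer(batch),
                 seed = as.integer(seed), record_every = as.integer(record_every)),
            class = "move_ae_config")
}

init_lstm <- function(din, h) {
  W <- matrix(stats::rnorm((din + h) * 4 * h, 0, 1 / sqrt(din + h)), din + h, 4 * h)
  b <- numeric(4 * h)
  b[(h + 1):(2 * h)] <- 1  # forget-gate bias opens the memory path early
  list(W = W, b = b)
}

init_move_ae_params <- function(cfg) {
  C <- cfg$channels; D <- cfg$td_width; H <- cfg$hidden
  K <- cfg$latent; Mw <- cfg$mid
  dense <- function(fi, fo) matrix(stats::rnorm(fi * fo, 0, 1 / sqrt(fi)), fi, fo)
  e1 <- init_lstm(D, H); e1b <- init_lstm(D, H)
  e2 <- init_lstm(2 * H, H); e2b <- init_lstm(2 * H, H)
  d1 <- init_lstm(K, H); d1b <- init_lstm(K, H)
  d2 <- init_lstm(2 * H, H); d2b <- init_lstm(2 * H, H)
  list(W_in = dense(C, D), b_in = numeric(D),
       enc1f_W = e1$W, enc1f_b = e1$b, enc1b_W = e1b$W, enc1b_b = e1b$b,
       enc2f_W = e2$W, enc2f_b = e2$b, enc2b_W = e2b$W, enc2b_b = e2b$b,
       W_mid = dense(2 * H, Mw), b_mid = numeric(Mw),
       W_lat = dense(Mw, K), b_lat = numeric(K),
       dec1f_W = d1$W, dec1f_b = d1$b, dec1b_W = d1b$W, dec1b_b = d1b$b,
       dec2f_W = d2$W, dec2f_b = d2$b, dec2b_W = d2b$W, dec2b_b = d2b$b,
       W_td = dense(2 * H, D), b_td = numeric(D),
       W_out = dense(D, C), b_out = numeric(C))
}

# n x window x channels array -> cube layout (batch, channels, timesteps)
windows_to_cube <- function(x) aperm(x, c(1, 3, 2))

window_array <- function(x) {
  if (inherits(x, "window_set")) x <- x$x
  if (length(dim(x)) != 3) gl_stop("windows must be an n x time x channels array",
                                   "gaitlatent_error_shape")
  x
}

#' Train the movement autoencoder
#'
#' Mini-batch Adam on mean squared reconstruction error over all window
#' entries. Batches are sampled uniformly with replacement from the
#' training windows; initialization and batch sampling both draw from a
#' stream seeded by `config$seed`, so training is fully deterministic.
#'
#' @param windows a `window_set` or n x window x channels array of
#'   standardized movement windows, n >= batch size.
#' @param config a [move_ae_config()].
#' @return a `move_ae_model` with trained parameters, the config,
#'   `final_loss` (on the full training set) and `loss_history`
#'   (recorded mini-batch losses).
#' @export
train_move_ae <- function(windows, config = move_ae_config()) {
  x <- window_array(windows)
  n <- dim(x)[1]
  if (dim(x)[2] != config$window || dim(x)[3] != config$channels) {
    gl_stop(sprintf("windows are %d x %d but config expects %d x %d",
                    dim(x)[2], dim(x)[3], config$window, config$channels),
            "gaitlatent_error_shape")
  }
  if (n < config$batch) {
    gl_stop("need at least one full mini-batch of windows",
            "gaitlatent_error_argument")
  }
  with_child_seed(config$seed, "move_ae/train", {
    params <- init_move_ae_params(config)
    state <- adam_init(params)
    history <- numeric(0)
    for (it in seq_len(config$iters)) {
      idx <- sample.int(n, config$batch)
      xb <- windows_to_cube(x[idx, , , drop = FALSE])
      lg <- moveae_loss_grad(params, xb)
      if (!is.finite(lg$loss)) {
        gl_stop(sprintf("non-finite training loss at step %d", it),
                "gaitlatent_error_diverged")
      }
      if (it %% config$record_every == 0 || it == 1L || it == config$iters) {
        history <- c(history, lg$loss)
      }
      st <- adam_step(params, lg$grads, state, config$lr)
      params <- st$params
      state <- st$state
    }
    model <- structure(list(params = params, config = config,
                            loss_history = history),
                       class = c("move_ae_model", "reducer"))
    # final loss on a deterministic subsample (BPTT-free evaluation of the
    # full training set is done on demand via move_ae_eval_loss)
    model$final_loss <- move_ae_eval_loss(model,
                                          x[seq_len(min(n, 2048L)), , , drop = FALSE])
    model
  })
}

# Full-dataset reconstruction loss, evaluated in chunks to bound the
# memory held by the BPTT caches.
move_ae_eval_loss <- function(model, x, chunk = 256L) {
  x <- window_array(x)
  n <- dim(x)[1]
  tot <- 0
  for (s in seq(1L, n, by = chunk)) {
    e <- min(n, s + chunk - 1L)
    tot <- tot + moveae_loss(model$params,
                             windows_to_cube(x[s:e, , , drop = FALSE])) * (e - s + 1L)
  }
  tot / n
}

#' @rdname encode
#' @export
encode.move_ae_model <- function(reducer, x, ...) {
  x <- window_array(x)
  cfg <- reducer$config
  if (dim(x)[2] != cfg$window || dim(x)[3] != cfg$channels) {
    gl_stop("window shape does not match the trained model",
            "gaitlatent_error_shape")
  }
  n <- dim(x)[1]
  out <- matrix(0, n, cfg$latent)
  chunk <- 512L
  for (s in seq(1L, n, by = chunk)) {
    e <- min(n, s + chunk - 1L)
    out[s:e, ] <- moveae_encode_cpp(reducer$params,
                                    windows_to_cube(x[s:e, , , drop = FALSE]))
  }
  out
}

#' @rdname encode
#' @export
decode.move_ae_model <- function(reducer, latent, ...) {
  latent <- as.matrix(latent)
  cfg <- reducer$config
  if (ncol(latent) != cfg$latent) {
    gl_stop("latent width does not match the trained model",
            "gaitlatent_error_shape")
  }
  n <- nrow(latent)
  out <- array(0, dim = c(n, cfg$window, cfg$channels))
  chunk <- 512L
  for (s in seq(1L, n, by = chunk)) {
    e <- min(n, s + chunk - 1L)
    y <- moveae_decode_cpp(reducer$params, latent[s:e, , drop = FALSE],
                           cfg$window)
    out[s:e, , ] <- aperm(y, c(1, 3, 2))
  }
  out
}
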