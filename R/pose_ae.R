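#' Configuration for the pose autoencoder
#'
#' A feed-forward autoencoder that reconstructs a single 14-dimensional
#' standardized pose through a narrow bottleneck. The encoder and decoder
#' are three-layer blocks; batch normalization is applied to every encoder
#' hidden layer (and only there), hidden activations are rectified linear,
#' and the latent and output layers are linear. Training minimizes mean
#' squared reconstruction error with the Adam optimizer on the full batch.
#'
#' @param input input width (14 for the analysis schema).
#' @param latent bottleneck width (default 2; swept 2..8 for the
#'   dimensional-variance analysis).
#' @param hidden encoder hidden widths, mirrored by the decoder.
#' @param lr Adam learning rate.
#' @param iters full-batch gradient iterations (default 8000; analyses at
#'   desk scale use fewer — see the methods vignette).
#' @param seed integer seed for parameter initialization.
#' @param record_every record the training loss every this many iterations.
#' @return a `pose_ae_config` list.
#' @export
pose_ae_config <- function(input = 14L, latent = 2L, hidden = c(64L, 32L, 16L),
                           lr = 1e-3, iters = 8000L, seed = 1L,
                           record_every = 50L) {
  stopifnot(latent >= 1, iters >= 1, length(hidden) >= 1)
  structure(list(input = as.integer(input), latent = as.integer(latent),
                 hidden = as.integer(hidden), lr = lr,
                 iters = as.integer(iters), seed = as.integer(seed),
                 record_every = as.integer(record_every)),
            class = "pose_ae_config")
}

# Flat named parameter list: encW<l>/encG<l>/encB<l> (weights, batch-norm
# gain and shift) per encoder layer, latW/latb, decW<l>/decb<l>, outW/outb.
# Encoder layers carry no bias: the batch-norm shift plays that role.
init_pose_ae_params <- function(cfg) {
  dense <- function(fi, fo, gain = sqrt(2)) {
    matrix(stats::rnorm(fi * fo, 0, gain / sqrt(fi)), fi, fo)
  }
  widths <- c(cfg$input, cfg$hidden)
  L <- length(cfg$hidden)
  p <- list()
  for (l in seq_len(L)) {
    p[[paste0("encW", l)]] <- dense(widths[l], widths[l + 1])
    p[[paste0("encG", l)]] <- rep(1, widths[l + 1])
    p[[paste0("encB", l)]] <- numeric(widths[l + 1])
  }
  p$latW <- dense(cfg$hidden[L], cfg$latent, gain = 1)
  p$latb <- numeric(cfg$latent)
  dwidths <- c(cfg$latent, rev(cfg$hidden))
  for (l in seq_len(L)) {
    p[[paste0("decW", l)]] <- dense(dwidths[l], dwidths[l + 1])
    p[[paste0("decb", l)]] <- numeric(dwidths[l + 1])
  }
  p$outW <- dense(cfg$hidden[1], cfg$input, gain = 1)
  p$outb <- numeric(cfg$input)
  p
}

with_n_hidden <- function(params, cfg) {
  c(params, list(n_hidden = length(cfg$hidden)))
}

# ---- reference implementation (plain R) ---------------------------------
# Used by the test suite as an independent check of the compiled kernel;
# identical math, identical parameter layout.

bn_eps <- 1e-5

poseae_loss_grad_ref <- function(params, x, L) {
  n <- nrow(x); d <- ncol(x)
  a_in <- zhat <- bnout <- h <- vector("list", L)
  inv <- bm <- bv <- vector("list", L)
  a <- x
  for (l in seq_len(L)) {
    a_in[[l]] <- a
    z <- a %*% params[[paste0("encW", l)]]
    bm[[l]] <- colMeans(z)
    bv[[l]] <- colMeans(z^2) - bm[[l]]^2
    inv[[l]] <- 1 / sqrt(bv[[l]] + bn_eps)
    zhat[[l]] <- sweep(sweep(z, 2, bm[[l]], `-`), 2, inv[[l]], `*`)
    bnout[[l]] <- sweep(sweep(zhat[[l]], 2, params[[paste0("encG", l)]], `*`),
                        2, params[[paste0("encB", l)]], `+`)
    h[[l]] <- pmax(bnout[[l]], 0)
    a <- h[[l]]
  }
  lat_in <- a
  latent <- sweep(a %*% params$latW, 2, params$latb, `+`)
  a <- latent
  d_in <- dz_pre <- vector("list", L)
  for (l in seq_len(L)) {
    d_in[[l]] <- a
    z <- sweep(a %*% params[[paste0("decW", l)]], 2,
               params[[paste0("decb", l)]], `+`)
    dz_pre[[l]] <- z
    a <- pmax(z, 0)
  }
  out_in <- a
  y <- sweep(a %*% params$outW, 2, params$outb, `+`)

  loss <- mean((y - x)^2)
  g <- list()
  dy <- 2 * (y - x) / (n * d)
  g$outW <- crossprod(out_in, dy)
  g$outb <- colSums(dy)
  da <- dy %*% t(params$outW)
  for (l in rev(seq_len(L))) {
    dz <- da * (dz_pre[[l]] > 0)
    g[[paste0("decW", l)]] <- crossprod(d_in[[l]], dz)
    g[[paste0("decb", l)]] <- colSums(dz)
    da <- dz %*% t(params[[paste0("decW", l)]])
  }
  g$latW <- crossprod(lat_in, da)
  g$latb <- colSums(da)
  da <- da %*% t(params$latW)
  for (l in rev(seq_len(L))) {
    dbn <- da * (bnout[[l]] > 0)
    gam <- params[[paste0("encG", l)]]
    g[[paste0("encG", l)]] <- colSums(dbn * zhat[[l]])
    g[[paste0("encB", l)]] <- colSums(dbn)
    dzh <- sweep(dbn, 2, gam, `*`)
    t1 <- sweep(dzh, 2, colMeans(dzh), `-`)
    t2 <- sweep(zhat[[l]], 2, colMeans(dzh * zhat[[l]]), `*`)
    dz <- sweep(t1 - t2, 2, inv[[l]], `*`)
    g[[paste0("encW", l)]] <- crossprod(a_in[[l]], dz)
    da <- dz %*% t(params[[paste0("encW", l)]])
  }
  list(loss = loss, grads = g,
       bn = stats::setNames(c(bm, bv), c(paste0("m", seq_len(L)),
                                         paste0("v", seq_len(L)))))
}

# ---- Adam on flat/nested parameter lists --------------------------------

adam_init <- function(params) {
  zero <- function(p) rapply(p, function(x) x * 0, how = "replace")
  list(m = zero(params), v = zero(params), t = 0L)
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  upd <- function(p, g, m, v) {
    if (is.list(p)) {
      if (!is.null(names(p)) && !is.null(names(g))) g <- g[names(p)]
      out <- Map(upd, p, g, m, v)
      return(list(p = lapply(out, `[[`, "p"), m = lapply(out, `[[`, "m"),
                  v = lapply(out, `[[`, "v")))
    }
    g <- as.numeric(g)
    dim(g) <- dim(p)
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    mhat <- m / (1 - beta1^t)
    vhat <- v / (1 - beta2^t)
    list(p = p - lr * mhat / (sqrt(vhat) + eps), m = m, v = v)
  }
  out <- Map(upd, params, grads[names(params)], state$m, state$v)
  list(params = lapply(out, `[[`, "p"),
       state = list(m = lapply(out, `[[`, "m"),
                    v = lapply(out, `[[`, "v"), t = t))
}

# ---- training ------------------------------------------------------------

#' Train the pose autoencoder
#'
#' Full-batch Adam on mean squared reconstruction error. Training is fully
#' deterministic given the configuration seed: parameter initialization is
#' the only stochastic step and it draws from a seeded stream, so two runs
#' with identical data and seed produce identical models. Batch-norm
#' statistics are tracked as exponential moving averages during training
#' and frozen for inference.
#'
#' @param poses a `pose_set` or n x d matrix of standardized poses (n >= 2).
#' @param config a [pose_ae_config()].
#' @return a `pose_ae_model` with the trained parameters, frozen batch-norm
#'   statistics, the config, `final_loss` and the recorded `loss_history`.
#' @export
train_pose_ae <- function(poses, config = pose_ae_config()) {
  x <- pose_matrix(poses)
  if (nrow(x) < 2) gl_stop("need at least 2 poses", "gaitlatent_error_argument")
  if (ncol(x) != config$input) {
    gl_stop(sprintf("pose width %d does not match config input %d",
                    ncol(x), config$input), "gaitlatent_error_shape")
  }
  L <- length(config$hidden)
  params <- with_child_seed(config$seed, "pose_ae/init",
                            init_pose_ae_params(config))
  state <- adam_init(params)
  history <- numeric(0)
  bn_run <- lapply(config$hidden, function(w) list(m = numeric(w), v = rep(1, w)))
  mom <- 0.1
  for (it in seq_len(config$iters)) {
    lg <- poseae_loss_grad(with_n_hidden(params, config), x)
    if (!is.finite(lg$loss)) {
      gl_stop(sprintf("non-finite training loss at iteration %d", it),
              "gaitlatent_error_diverged")
    }
    for (l in seq_len(L)) {
      bn_run[[l]]$m <- (1 - mom) * bn_run[[l]]$m + mom * as.numeric(lg$bn[[paste0("m", l)]])
      bn_run[[l]]$v <- (1 - mom) * bn_run[[l]]$v + mom * as.numeric(lg$bn[[paste0("v", l)]])
    }
    if (it %% config$record_every == 0 || it == 1L || it == config$iters) {
      history <- c(history, lg$loss)
    }
    st <- adam_step(params, lg$grads, state, config$lr)
    params <- st$params
    state <- st$state
  }
  model <- structure(list(params = params, bn_stats = bn_run, config = config,
                          loss_history = history),
                     class = c("pose_ae_model", "reducer"))
  model$final_loss <- mean((reconstruct(model, x) - x)^2)
  model
}

#' @rdname encode
#' @export
encode.pose_ae_model <- function(reducer, x, ...) {
  x <- pose_matrix(x)
  if (ncol(x) != reducer$config$input) {
    gl_stop("pose width does not match the trained model",
            "gaitlatent_error_shape")
  }
  poseae_encode_cpp(with_n_hidden(reducer$params, reducer$config), x,
                    reducer$bn_stats)
}

#' @rdname encode
#' @export
decode.pose_ae_model <- function(reducer, latent, ...) {
  latent <- as.matrix(latent)
  if (ncol(latent) != reducer$config$latent) {
    gl_stop("latent width does not match the trained model",
            "gaitlatent_error_shape")
  }
  poseae_decode_cpp(with_n_hidden(reducer$params, reducer$config), latent)
}
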