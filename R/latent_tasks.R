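#' Classify latent points with a fixed radial-basis-function SVM
#'
#' Fits a C-classification SVM with an RBF kernel on the latent
#' coordinates and returns the resubstitution error: the fraction of the
#' same points that are misclassified. Resubstitution error is the
#' evaluation used throughout — the question is how separable classes are
#' in a given latent space, not how well a tuned classifier generalizes —
#' and the SVM parameters are fixed identically for every task and every
#' reducer: cost 1, kernel width `gamma = 1 / (d * var(X))` where `d` is
#' the latent dimension and `var(X)` the variance of all coordinate
#' entries.
#'
#' @param latent n x k matrix of latent coordinates.
#' @param labels class labels, one per row; at least 2 distinct values
#'   and 2 points per class.
#' @param cost SVM regularization constant.
#' @return error rate in `[0, 1]`.
#' @export
classify_latent <- function(latent, labels, cost = 1) {
  latent <- as.matrix(latent)
  labels <- factor(labels)
  if (nlevels(labels) < 2) {
    gl_stop("need at least 2 distinct labels", "gaitlatent_error_labels")
  }
  if (min(table(labels)) < 2) {
    gl_stop("need at least 2 points per class", "gaitlatent_error_labels")
  }
  v <- stats::var(as.vector(latent)) * (length(latent) - 1) / length(latent)
  gamma <- 1 / (ncol(latent) * v)
  fit <- e1071::svm(x = latent, y = labels, kernel = "radial",
                    cost = cost, gamma = gamma, scale = FALSE)
  pred <- stats::predict(fit, latent)
  mean(pred != labels)
}

#' Latent-space classification tasks with repeated reducer trainings
#'
#' Runs one of the two evaluation tasks over a set of reducers:
#'
#' * `"movement"` — classify flat-ground vs stair points in the latent
#'   space; the natural-movement data is excluded because it mixes both
#'   kinds of activity.
#' * `"individual"` — identify which subject a flat-ground point came
#'   from; only flat-ground data is used.
#'
#' For the autoencoders each repetition retrains the network from a fresh
#' seeded initialization before fitting the classifier, so the spread of
#' errors reflects run-to-run variation in how the data gets embedded.
#' PCA is deterministic: it is fitted once and its single error is
#' recorded for every repetition. PCA and the pose autoencoder operate on
#' pose samples, the movement autoencoder on windows; PCA's latent space
#' is its first two principal-component scores, fitted on the pooled task
#' data.
#'
#' @param task `"movement"` or `"individual"`.
#' @param prep a [preprocess_study()] result.
#' @param reducers subset of `c("pca", "pose_ae", "move_ae")`.
#' @param repetitions number of repeated trainings (default 10).
#' @param seed master integer seed; repetition r of reducer m draws from
#'   the child stream `task/<task>/<m>/<r>`.
#' @param pose_config,move_config autoencoder configurations (seeds are
#'   overridden per repetition).
#' @param latent_hook optional function `(latent, labels) -> list(latent,
#'   labels)` applied before classification (e.g. outlier screening);
#'   disabled by default.
#' @return a data.frame with columns `task`, `reducer`, `rep`, `error`.
#' @export
run_task <- function(task = c("movement", "individual"), prep,
                     reducers = c("pca", "pose_ae", "move_ae"),
                     repetitions = 10L, seed = 1L,
                     pose_config = pose_ae_config(),
                     move_config = move_ae_config(),
                     latent_hook = NULL) {
  task <- match.arg(task)
  reducers <- match.arg(reducers, several.ok = TRUE)
  keep <- if (task == "movement") c("flat", "stair") else "flat"
  pose_idx <- prep$poses$info$activity %in% keep
  win_idx <- prep$windows$info$activity %in% keep
  if (task == "movement" &&
      length(unique(prep$poses$info$activity[pose_idx])) < 2) {
    gl_stop("movement task needs both flat and stair data",
            "gaitlatent_error_task")
  }
  px <- prep$poses$x[pose_idx, , drop = FALSE]
  plab <- if (task == "movement") prep$poses$info$activity[pose_idx]
          else prep$poses$info$subject[pose_idx]
  wx <- prep$windows$x[win_idx, , , drop = FALSE]
  wlab <- if (task == "movement") prep$windows$info$activity[win_idx]
          else prep$windows$info$subject[win_idx]
  if (task == "individual" && length(unique(plab)) < 2) {
    gl_stop("individual task needs at least 2 flat-ground subjects",
            "gaitlatent_error_task")
  }

  score <- function(latent, labels) {
    if (!is.null(latent_hook)) {
      h <- latent_hook(latent, labels)
      latent <- h$latent
      labels <- h$labels
    }
    classify_latent(latent, labels)
  }

  rows <- list()
  for (m in reducers) {
    errs <- if (m == "pca") {
      model <- fit_pca(px)
      rep(score(encode(model, px, k = 2), plab), repetitions)
    } else if (m == "pose_ae") {
      vapply(seq_len(repetitions), function(r) {
        cfg <- pose_config
        cfg$seed <- child_seed(seed, sprintf("task/%s/pose_ae/%d", task, r))
        score(encode(train_pose_ae(px, cfg), px), plab)
      }, numeric(1))
    } else {
      vapply(seq_len(repetitions), function(r) {
        cfg <- move_config
        cfg$seed <- child_seed(seed, sprintf("task/%s/move_ae/%d", task, r))
        score(encode(train_move_ae(wx, cfg), wx), wlab)
      }, numeric(1))
    }
    rows[[m]] <- data.frame(task = task, reducer = m,
                            rep = seq_len(repetitions), error = errs)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Compare two error distributions with the two-sample KS test
#'
#' The Kolmogorov-Smirnov statistic is the maximum gap between the two
#' empirical distribution functions; it is well suited to comparing
#' repeated-run error distributions with unequal variances.
#'
#' @param a,b numeric vectors of per-repetition error rates.
#' @return a `ks_comparison` list with `statistic` and `p_value`.
#' @export
compare_runs <- function(a, b) {
  if (length(a) == 0 || length(b) == 0) {
    gl_stop("both error lists must be nonempty", "gaitlatent_error_argument")
  }
  # ties between discretized error rates are expected; the asymptotic
  # statistic is still the exact maximum ECDF gap
  kt <- suppressWarnings(stats::ks.test(a, b))
  structure(list(statistic = unname(kt$statistic),
                 p_value = unname(kt$p.value)),
            class = "ks_comparison")
}

#' Summarize classification runs
#'
#' Mean and standard deviation of the per-repetition errors for each
#' reducer, in the style `mean +/- sd`.
#'
#' @param runs a [run_task()] result (rows from several calls may be
#'   rbind-ed together).
#' @return a data.frame with one row per (task, reducer).
#' @export
summarize_runs <- function(runs) {
  agg <- stats::aggregate(error ~ task + reducer, data = runs,
                          FUN = function(e) c(mean = mean(e), sd = stats::sd(e),
                                              median = stats::median(e)))
  out <- data.frame(task = agg$task, reducer = agg$reducer,
                    mean_error = agg$error[, "mean"],
                    sd_error = agg$error[, "sd"],
                    median_error = agg$error[, "median"])
  out[order(out$task, out$mean_error), ]
}
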