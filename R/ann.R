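# Per-session feed-forward network mapping EMG envelopes plus sternum and
# sacrum kinematics to the 3D net moment at L5/S1.
#
# Architecture is fixed: 16 inputs -> 31 sigmoid hidden units -> 3 linear
# outputs.  Orientation quaternions are deliberately excluded from the
# features: inclination information is already present in the accelerometer
# signals, and magnetic disturbances in industrial environments make
# heading estimates unreliable.  Training minimizes the mean squared error
# over the three moment components with a full-batch quasi-Newton method
# (L-BFGS) on standardized inputs and targets, and stops once the summed
# per-axis training RMSE falls below 10 Nm.

ANN_HIDDEN <- 31L
ANN_RMSE_CRITERION <- 10   # Nm; sum of RMSE Mx + RMSE My + RMSE Mz

#' Assemble the 16-column network feature matrix
#'
#' Per sample: the four EMG envelopes plus 3D angular velocity and 3D
#' linear acceleration from the sternum and sacrum sensors
#' (4 + 2 x (3 + 3) = 16).  Rows from multiple trials are concatenated with
#' per-row trial bookkeeping.  Trials must be calibrated, synchronized and
#' carry envelopes.
#'
#' @param ses a [session()].
#' @param trial_ids trials to include, in order.
#' @return object of class `feature_matrix`: matrix `X` (n x 16), times
#'   `t`, per-row `trial` ids.
#' @export
build_feature_matrix <- function(ses, trial_ids) {
  stopifnot(inherits(ses, "session"))
  Xs <- list(); ts <- list(); ids <- list()
  for (id in trial_ids) {
    tr <- session_trial(ses, id)
    for (s in c("sternum", "sacrum"))
      if (is.null(tr$immu[[s]]))
        stop(sprintf("trial '%s': missing inertial stream '%s'", id, s))
    for (ch in emg_channels())
      if (is.null(tr$emg[[ch]]) || is.null(tr$emg[[ch]]$envelope))
        stop(sprintf("trial '%s': missing EMG envelope '%s'", id, ch))

    key <- function(tt) as.integer(round(tt / SAMPLE_DT))
    k_immu <- key(tr$immu$sternum$t)
    common <- k_immu
    for (ch in emg_channels())
      common <- intersect(common, key(tr$emg[[ch]]$t_env))
    if (!length(common))
      stop(sprintf("trial '%s': no common time base across streams", id))
    common <- sort(common)

    cols <- list()
    for (ch in emg_channels()) {
      es <- tr$emg[[ch]]
      cols[[ch]] <- es$envelope[match(common, key(es$t_env))]
    }
    for (s in c("sternum", "sacrum")) {
      st <- tr$immu[[s]]
      rows <- match(common, key(st$t))
      pre <- if (s == "sternum") "st" else "sa"
      for (j in 1:3) cols[[paste0(pre, "_w", c("x", "y", "z")[j])]] <-
          st$angvel[rows, j]
      for (j in 1:3) cols[[paste0(pre, "_a", c("x", "y", "z")[j])]] <-
          st$linacc[rows, j]
    }
    X <- do.call(cbind, cols)
    Xs[[id]] <- X
    ts[[id]] <- common * SAMPLE_DT
    ids[[id]] <- rep(id, nrow(X))
  }
  X <- do.call(rbind, Xs)
  if (ncol(X) != 16L) stop("feature matrix must have exactly 16 columns")
  if (anyNA(X)) stop("feature matrix contains missing values")
  structure(list(X = X, t = unlist(ts, use.names = FALSE),
                 trial = unlist(ids, use.names = FALSE)),
            class = "feature_matrix")
}

sigmoid <- function(z) 1 / (1 + exp(-z))

ann_unpack <- function(par, p, h, k) {
  i <- 0
  W1 <- matrix(par[i + seq_len(p * h)], p, h); i <- i + p * h
  b1 <- par[i + seq_len(h)]; i <- i + h
  W2 <- matrix(par[i + seq_len(h * k)], h, k); i <- i + h * k
  b2 <- par[i + seq_len(k)]
  list(W1 = W1, b1 = b1, W2 = W2, b2 = b2)
}

ann_forward <- function(w, X) {
  H <- sigmoid(sweep(X %*% w$W1, 2, w$b1, `+`))
  list(H = H, Y = sweep(H %*% w$W2, 2, w$b2, `+`))
}

#' Train the per-session moment-estimation network
#'
#' Supervised training against linked-segment-model target moments.
#' Inputs and targets are standardized internally (per feature / per axis);
#' weights start from a small seeded random initialization and are fitted
#' by full-batch L-BFGS on the mean squared error.  Optimization halts as
#' soon as the summed per-axis training RMSE drops below 10 Nm (the fixed
#' training criterion); if the criterion is not reached within
#' `max_epochs` iterations the fit is restarted from a fresh
#' initialization (up to `restarts` attempts) and the best model is
#' returned with `converged = FALSE` and a warning.
#'
#' @param features a [build_feature_matrix()] result.
#' @param targets a [net_moment_series()] (or n x 3 matrix) aligned
#'   sample-wise with `features`.
#' @param seed integer seed for the weight initialization.
#' @param max_epochs optimizer iteration budget per restart.
#' @param restarts maximum number of random restarts.
#' @return object of class `ann_model` with the weight matrices, the
#'   normalization parameters and a `training` record (epochs, summed RMSE
#'   in Nm, seed, converged flag).
#' @export
train_ann <- function(features, targets, seed = 1L, max_epochs = 2000L,
                      restarts = 3L) {
  stopifnot(inherits(features, "feature_matrix"))
  Y <- if (inherits(targets, "net_moment_series")) targets$M
       else as.matrix(targets)
  X <- features$X
  if (nrow(Y) != nrow(X))
    stop("features and targets are not aligned sample-wise")
  p <- ncol(X); h <- ANN_HIDDEN; k <- ncol(Y)
  if (nrow(X) < 10 * (p * h + h + h * k + k))
    warning("fewer than 10 samples per network weight; training may overfit")

  xc <- colMeans(X); xs <- pmax(apply(X, 2, stats::sd), 1e-8)
  yc <- colMeans(Y); ys <- pmax(apply(Y, 2, stats::sd), 1e-8)
  Xs <- sweep(sweep(X, 2, xc), 2, xs, `/`)
  Ys <- sweep(sweep(Y, 2, yc), 2, ys, `/`)
  n <- nrow(Xs)

  rmse_sum <- function(w) {
    E <- ann_forward(w, Xs)$Y - Ys
    sum(ys * sqrt(colMeans(E^2)))
  }
  fn <- function(par) {
    w <- ann_unpack(par, p, h, k)
    E <- ann_forward(w, Xs)$Y - Ys
    v <- 0.5 * sum(E^2) / n
    if (!is.finite(v)) stop("non-finite training loss")
    v
  }
  gr <- function(par) {
    w <- ann_unpack(par, p, h, k)
    fw <- ann_forward(w, Xs)
    E <- (fw$Y - Ys) / n
    dH <- (E %*% t(w$W2)) * fw$H * (1 - fw$H)
    c(crossprod(Xs, dH), colSums(dH), crossprod(fw$H, E), colSums(E))
  }

  best <- NULL
  chunk <- 200L
  for (r in seq_len(restarts)) {
    set.seed(seed + r - 1L)
    lim <- sqrt(6 / (p + h))
    par <- c(stats::runif(p * h, -lim, lim), numeric(h),
             stats::runif(h * k, -lim, lim), numeric(k))
    epochs <- 0L
    repeat {
      fit <- stats::optim(par, fn, gr, method = "L-BFGS-B",
                          control = list(maxit = chunk))
      par <- fit$par
      epochs <- epochs + chunk
      rs <- rmse_sum(ann_unpack(par, p, h, k))
      if (rs < ANN_RMSE_CRITERION || epochs >= max_epochs ||
          fit$convergence == 0) break
    }
    cand <- list(par = par, rmse = rs, epochs = epochs, seed = seed + r - 1L)
    if (is.null(best) || cand$rmse < best$rmse) best <- cand
    if (best$rmse < ANN_RMSE_CRITERION) break
  }
  converged <- best$rmse < ANN_RMSE_CRITERION
  if (!converged)
    warning(sprintf(
      "training criterion not met: summed per-axis RMSE %.2f Nm >= %d Nm",
      best$rmse, ANN_RMSE_CRITERION))
  w <- ann_unpack(best$par, p, h, k)
  structure(list(W1 = w$W1, b1 = w$b1, W2 = w$W2, b2 = w$b2,
                 x_center = xc, x_scale = xs, y_center = yc, y_scale = ys,
                 feature_names = colnames(X),
                 training = list(epochs = best$epochs,
                                 rmse_sum = best$rmse, seed = best$seed,
                                 converged = converged)),
            class = "ann_model")
}

#' Predict L5/S1 net moments with a trained network
#'
#' Deterministic forward pass; the model's stored normalization is applied,
#' so the model must come from the same session (same calibration and
#' units) as the features.
#'
#' @param model an [train_ann()] result.
#' @param features a [build_feature_matrix()] result.
#' @return a [net_moment_series()].
#' @export
predict_moments <- function(model, features) {
  stopifnot(inherits(model, "ann_model"),
            inherits(features, "feature_matrix"))
  X <- features$X
  if (ncol(X) != length(model$x_center))
    stop(sprintf("feature count mismatch: %d columns, model expects %d",
                 ncol(X), length(model$x_center)))
  Xs <- sweep(sweep(X, 2, model$x_center), 2, model$x_scale, `/`)
  Yh <- ann_forward(model, Xs)$Y
  Y <- sweep(sweep(Yh, 2, model$y_scale, `*`), 2, model$y_center, `+`)
  net_moment_series(features$t, Y)
}

#' @export
print.ann_model <- function(x, ...) {
  cat(sprintf(
    "ann_model 16->%d->3 (sigmoid hidden): summed training RMSE %.2f Nm, %s after %d epochs (seed %d)\n",
    ANN_HIDDEN, x$training$rmse_sum,
    if (x$training$converged) "converged" else "NOT converged",
    x$training$epochs, x$training$seed))
  invisible(x)
}
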