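#' Huber loss
#'
#' Robust regression loss, mean per voxel:
#' `L = r^2 / 2` for `|r| <= delta`, `delta * |r| - delta^2 / 2` otherwise,
#' with residual `r = pred - target`. Quadratic near zero (mean-squared-error
#' behaviour), linear in the tails (mean-absolute-error behaviour), with a
#' continuous first derivative at `|r| = delta`. The default threshold is
#' `delta = 1`, matching dose fields normalized by the maximum prescription.
#'
#' @param pred,target numeric arrays / `volume_grid`s of identical shape.
#' @param delta positive threshold (default 1).
#' @return Mean Huber loss (scalar, `>= 0`; 0 iff `pred == target`).
#' @export
huber_loss <- function(pred, target, delta = 1) {
  if (is_volume_grid(pred)) pred <- pred$values
  if (is_volume_grid(target)) target <- target$values
  if (!identical(dim(pred), dim(target)) || length(pred) != length(target))
    stop("pred and target shapes differ", call. = FALSE)
  if (delta <= 0) stop("delta must be positive", call. = FALSE)
  r <- abs(pred - target)
  mean(ifelse(r <= delta, r^2 / 2, delta * r - delta^2 / 2))
}

## d(mean Huber)/d(pred), elementwise (without the 1/n factor).
huber_grad <- function(r, delta) {
  ifelse(abs(r) <= delta, r, delta * sign(r))
}

## Central-difference gradient magnitude (edge/penumbra feature).
grad_mag3d <- function(arr, spacing_mm) {
  d <- dim(arr)
  gx <- array(0, d); gy <- array(0, d); gz <- array(0, d)
  gx[2:(d[1] - 1), , ] <- (arr[3:d[1], , ] - arr[1:(d[1] - 2), , ]) / (2 * spacing_mm)
  gy[, 2:(d[2] - 1), ] <- (arr[, 3:d[2], ] - arr[, 1:(d[2] - 2), ]) / (2 * spacing_mm)
  gz[, , 2:(d[3] - 1)] <- (arr[, , 3:d[3]] - arr[, , 1:(d[3] - 2)]) / (2 * spacing_mm)
  sqrt(gx^2 + gy^2 + gz^2)
}

## Separable 3D Gaussian smoothing (zero-padded, normalized kernel).
smooth3d <- function(arr, sigma_mm, spacing_mm) {
  k <- gauss_kernel_1d(sigma_mm, spacing_mm)
  d <- dim(arr)
  T1 <- conv_matrix(k, d[1]); T2 <- conv_matrix(k, d[2]); T3 <- conv_matrix(k, d[3])
  a <- array(T1 %*% matrix(arr, d[1]), d)
  a <- aperm(array(T2 %*% matrix(aperm(a, c(2, 1, 3)), d[2]), d[c(2, 1, 3)]), c(2, 1, 3))
  aperm(array(T3 %*% matrix(aperm(a, c(3, 1, 2)), d[3]), d[c(3, 1, 2)]), c(2, 3, 1))
}

#' Configuration of the dose-regression network
#'
#' The predictor is a compact voxel-wise regression network: a fixed
#' multi-scale 3D Gaussian context encoder turns the three input channels
#' into per-voxel features (each channel at its native resolution plus
#' smoothed copies at `sigmas_mm`), and a small fully-connected head (two
#' hidden layers) maps features to normalized dose. It is trained with
#' the Huber loss (`delta = 1`) on dose normalized by the case's maximum
#' prescription, using Adam on minibatches of in-body voxels; the returned
#' model is the checkpoint with the best validation loss.
#'
#' @param hidden integer vector of hidden-layer widths (default `c(32, 32)`).
#' @param sigmas_mm Gaussian context scales in mm (default `c(4, 8, 16)`).
#' @param delta Huber threshold (default 1).
#' @param epochs training epochs (default 30).
#' @param batch minibatch size in voxels (default 8192).
#' @param lr Adam learning rate (default 2e-3).
#' @param seed RNG seed; training is deterministic given the seed and data.
#' @param activation hidden-layer activation, `"relu"` (default) or
#'   `"tanh"`.
#' @return A `predictor_config`.
#' @export
predictor_config <- function(hidden = c(64L, 64L), sigmas_mm = c(2, 4, 8, 16),
                             delta = 1, epochs = 30L, batch = 8192L,
                             lr = 3e-3, seed = 1L,
                             activation = c("relu", "tanh")) {
  activation <- match.arg(activation)
  if (delta <= 0) stop("delta must be positive", call. = FALSE)
  if (length(hidden) < 1) stop("need at least one hidden layer", call. = FALSE)
  structure(list(hidden = as.integer(hidden), sigmas_mm = sigmas_mm,
                 delta = delta, epochs = as.integer(epochs),
                 batch = as.integer(batch), lr = lr, seed = as.integer(seed),
                 activation = activation),
            class = "predictor_config")
}

#' Per-voxel features of a channel stack
#'
#' @param stack a `channel_stack`.
#' @param sigmas_mm context scales (mm).
#' @return list with `X` (n-by-p feature matrix over in-body voxels), `idx`
#'   (linear indices of in-body voxels; the body is where the avoidance
#'   channel is positive), `dim`, `spacing_mm`, `origin_mm`, `dp_max_Gy`.
#' @export
featurize_stack <- function(stack, sigmas_mm = c(4, 8, 16)) {
  body <- stack$avoidance$values > 0
  idx <- which(body)
  sp <- stack$prescription$spacing_mm
  chans <- list(stack$prescription$values, stack$avoidance$values,
                stack$beam_trace$values)
  cols <- list()
  for (ch in chans) {
    cols[[length(cols) + 1]] <- ch[idx]
    for (s in sigmas_mm)
      cols[[length(cols) + 1]] <- smooth3d(ch, s, sp)[idx]
    # gradient magnitude (in 1/mm, scaled by spacing to O(1) units)
    cols[[length(cols) + 1]] <- grad_mag3d(ch, sp)[idx] * sp
  }
  list(X = do.call(cbind, cols), idx = idx, dim = dim(stack$prescription$values),
       spacing_mm = sp, origin_mm = stack$prescription$origin_mm,
       dp_max_Gy = stack$dp_max_Gy)
}

mlp_init <- function(p, hidden, activation = "relu") {
  sizes <- c(p, hidden, 1L)
  fan_sd <- if (activation == "relu") function(m) sqrt(2 / m) else function(m) sqrt(1 / m)
  W <- list(); b <- list()
  for (l in seq_len(length(sizes) - 1)) {
    W[[l]] <- matrix(stats::rnorm(sizes[l] * sizes[l + 1], sd = fan_sd(sizes[l])),
                     sizes[l], sizes[l + 1])
    b[[l]] <- numeric(sizes[l + 1])
  }
  list(W = W, b = b)
}

mlp_forward <- function(theta, X, keep = FALSE, activation = "relu") {
  L <- length(theta$W)
  a <- X; acts <- list(a)
  for (l in seq_len(L)) {
    z <- a %*% theta$W[[l]]
    z <- sweep(z, 2, theta$b[[l]], "+")
    a <- if (l < L) {
      if (activation == "relu") pmax(z, 0) else tanh(z)
    } else z
    if (keep) acts[[l + 1]] <- a
  }
  if (keep) list(out = as.numeric(a), acts = acts) else as.numeric(a)
}

mlp_backward <- function(theta, acts, dout, activation = "relu") {
  L <- length(theta$W)
  gW <- vector("list", L); gb <- vector("list", L)
  delta <- matrix(dout, ncol = 1)
  for (l in L:1) {
    a_in <- acts[[l]]
    gW[[l]] <- crossprod(a_in, delta)
    gb[[l]] <- colSums(delta)
    if (l > 1) {
      dact <- if (activation == "relu") (acts[[l]] > 0) * 1 else 1 - acts[[l]]^2
      delta <- (delta %*% t(theta$W[[l]])) * dact
    }
  }
  list(W = gW, b = gb)
}

#' Train the dose-regression network
#'
#' @param train list of training entries, each
#'   `list(stack = channel_stack, label = volume_grid)` with labels in Gy
#'   (normalized internally by each case's `dp_max_Gy`).
#' @param cfg a [predictor_config()].
#' @param val optional validation entries in the same form; when omitted, the
#'   last training case is held out for checkpoint selection if more than one
#'   case is available, otherwise the training pool itself is used.
#' @param verbose print per-epoch losses.
#' @return A `dose_predictor`: weights of the best-validation checkpoint,
#'   feature/normalization conventions, and `history` (per-epoch training and
#'   validation loss).
#' @export
train_predictor <- function(train, cfg = predictor_config(), val = NULL,
                            verbose = FALSE) {
  if (length(train) < 1) stop("empty training manifest", call. = FALSE)
  pool <- function(entries) {
    Xs <- list(); ys <- list()
    for (e in entries) {
      f <- featurize_stack(e$stack, cfg$sigmas_mm)
      lab <- if (is_volume_grid(e$label)) e$label$values else e$label
      Xs[[length(Xs) + 1]] <- f$X
      ys[[length(ys) + 1]] <- lab[f$idx] / f$dp_max_Gy
    }
    list(X = do.call(rbind, Xs), y = unlist(ys))
  }
  if (is.null(val)) {
    if (length(train) > 1) {
      val <- train[length(train)]
      train <- train[-length(train)]
    } else val <- train
  }
  tr <- pool(train); va <- pool(val)
  n <- nrow(tr$X); p <- ncol(tr$X)
  with_seed(cfg$seed, {
    theta <- mlp_init(p, cfg$hidden, cfg$activation)
    mom <- list(W = lapply(theta$W, function(w) w * 0),
                b = lapply(theta$b, function(b) b * 0))
    vel <- mom
    beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8; t_adam <- 0
    best <- list(loss = Inf, theta = theta, epoch = 0L)
    hist <- data.frame(epoch = integer(), train_loss = numeric(),
                       val_loss = numeric())
    steps <- max(1L, ceiling(n / cfg$batch))
    for (ep in seq_len(cfg$epochs)) {
      # cosine decay from lr to lr/10 over the training budget
      lr_ep <- cfg$lr * (0.55 + 0.45 * cos(pi * (ep - 1) / max(1, cfg$epochs - 1)))
      perm <- sample.int(n)
      for (s in seq_len(steps)) {
        rows <- perm[((s - 1) * cfg$batch + 1):min(s * cfg$batch, n)]
        Xb <- tr$X[rows, , drop = FALSE]; yb <- tr$y[rows]
        fw <- mlp_forward(theta, Xb, keep = TRUE, cfg$activation)
        r <- fw$out - yb
        if (any(!is.finite(r))) stop("non-finite training loss; aborting", call. = FALSE)
        dout <- huber_grad(r, cfg$delta) / length(r)
        g <- mlp_backward(theta, fw$acts, dout, cfg$activation)
        t_adam <- t_adam + 1
        for (l in seq_along(theta$W)) {
          mom$W[[l]] <- beta1 * mom$W[[l]] + (1 - beta1) * g$W[[l]]
          vel$W[[l]] <- beta2 * vel$W[[l]] + (1 - beta2) * g$W[[l]]^2
          mhat <- mom$W[[l]] / (1 - beta1^t_adam)
          vhat <- vel$W[[l]] / (1 - beta2^t_adam)
          theta$W[[l]] <- theta$W[[l]] - lr_ep * mhat / (sqrt(vhat) + eps)
          mom$b[[l]] <- beta1 * mom$b[[l]] + (1 - beta1) * g$b[[l]]
          vel$b[[l]] <- beta2 * vel$b[[l]] + (1 - beta2) * g$b[[l]]^2
          mbh <- mom$b[[l]] / (1 - beta1^t_adam)
          vbh <- vel$b[[l]] / (1 - beta2^t_adam)
          theta$b[[l]] <- theta$b[[l]] - lr_ep * mbh / (sqrt(vbh) + eps)
        }
      }
      tl <- huber_loss(mlp_forward(theta, tr$X, activation = cfg$activation), tr$y, cfg$delta)
      vl <- huber_loss(mlp_forward(theta, va$X, activation = cfg$activation), va$y, cfg$delta)
      hist <- rbind(hist, data.frame(epoch = ep, train_loss = tl, val_loss = vl))
      if (vl < best$loss) best <- list(loss = vl, theta = theta, epoch = ep)
      if (verbose) message(sprintf("epoch %3d  train %.3e  val %.3e", ep, tl, vl))
    }
    structure(list(theta = best$theta, cfg = cfg, best_epoch = best$epoch,
                   val_loss = best$loss, history = hist, n_features = p),
              class = "dose_predictor")
  })
}

#' Predict a dose distribution from a channel stack
#'
#' Pure function of the trained weights and the input channels. Negative
#' network outputs are clipped to zero; voxels outside the body are zero.
#'
#' @param model a `dose_predictor`.
#' @param stack a `channel_stack`.
#' @return list with `normalized` (dose / dp_max, `volume_grid`) and
#'   `dose_Gy` (`volume_grid`).
#' @export
predict_dose <- function(model, stack) {
  f <- featurize_stack(stack, model$cfg$sigmas_mm)
  if (ncol(f$X) != model$n_features)
    stop("channel stack does not match the model's feature configuration", call. = FALSE)
  yhat <- pmax(mlp_forward(model$theta, f$X, activation = model$cfg$activation), 0)
  arr <- array(0, f$dim)
  arr[f$idx] <- yhat
  normalized <- volume_grid(arr, f$spacing_mm, f$origin_mm)
  gy <- normalized; gy$values <- gy$values * f$dp_max_Gy
  list(normalized = normalized, dose_Gy = gy)
}

#' @export
print.dose_predictor <- function(x, ...) {
  cat(sprintf("dose_predictor: %d features -> %s -> 1; best epoch %d (val loss %.3e)\n",
              x$n_features, paste(x$cfg$hidden, collapse = "-"),
              x$best_epoch, x$val_loss))
  invisible(x)
}

#' Save / load a trained predictor as JSON
#'
#' @param model a `dose_predictor`.
#' @param path JSON file path.
#' @return `save_predictor`: `path` invisibly; `load_predictor`: the model.
#' @export
save_predictor <- function(model, path) {
  obj <- list(W = lapply(model$theta$W, function(w) list(dim = dim(w), x = as.numeric(w))),
              b = model$theta$b,
              cfg = unclass(model$cfg), best_epoch = model$best_epoch,
              val_loss = model$val_loss, n_features = model$n_features)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_predictor
#' @export
load_predictor <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = FALSE)
  W <- lapply(o$W, function(w)
    matrix(unlist(w$x), unlist(w$dim)[1], unlist(w$dim)[2]))
  b <- lapply(o$b, function(x) as.numeric(unlist(x)))
  cfgl <- o$cfg
  cfg <- predictor_config(hidden = unlist(cfgl$hidden),
                          sigmas_mm = unlist(cfgl$sigmas_mm),
                          delta = cfgl$delta, epochs = cfgl$epochs,
                          batch = cfgl$batch, lr = cfgl$lr, seed = cfgl$seed,
                          activation = cfgl$activation)
  structure(list(theta = list(W = W, b = b), cfg = cfg,
                 best_epoch = o$best_epoch, val_loss = o$val_loss,
                 history = NULL, n_features = o$n_features),
            class = "dose_predictor")
}
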