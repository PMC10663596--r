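# Two-stage reconstruction + discrimination network. The reconstruction
# network (a plain convolutional autoencoder from the DAE family) is trained
# to denoise synthetically corrupted inputs back to the clean volume; the
# discrimination network, a small 3D U-Net, takes the channelwise
# concatenation of corrupted input and reconstruction and emits one logit
# per voxel. The sigmoid of the logits is the anomaly map — no residual is
# computed.

#' RecDiscNet configuration
#'
#' Optimizer, batch size and epoch count follow the DAE recipe. The loss
#' weights are `bce_weight` (amplifies the discrimination term) and
#' `pos_weight` (weights the positive class to compensate for the class
#' imbalance between patch and non-patch voxels); `pos_weight = "auto"`
#' uses the per-volume ratio of negative to positive in-brain voxels.
#'
#' @param bce_weight positive scalar multiplying the BCE term.
#' @param pos_weight positive-class weight, or `"auto"` (n_neg / n_pos).
#' @param latent_dim,channels reconstruction-net architecture, as
#'   [dae_config()].
#' @param disc_channels widths of the two U-Net encoder scales.
#' @param epochs,batch_size,lr,lr_decay optimization hyperparameters.
#' @param negative_slope LeakyReLU negative slope.
#' @param mode `"joint"` optimizes the summed loss end-to-end;
#'   `"sequential"` trains the reconstruction net first, then the
#'   discriminator with the reconstruction frozen.
#' @param augment_n corrupted copies precomputed per training subject.
#' @param seed integer seed.
#' @return An object of class `recdisc_config`.
#' @export
recdisc_config <- function(bce_weight = 1, pos_weight = "auto",
                           latent_dim = 128L,
                           channels = c(32L, 64L, 128L, 256L),
                           disc_channels = c(32L, 64L),
                           epochs = 500L, batch_size = 4L,
                           lr = 1e-4, lr_decay = 0.95,
                           negative_slope = 0.01,
                           mode = c("joint", "sequential"),
                           augment_n = 4L,
                           seed = 1L) {
  if (bce_weight <= 0) stop("bce_weight must be > 0", call. = FALSE)
  if (!identical(pos_weight, "auto") && pos_weight <= 0)
    stop("pos_weight must be > 0", call. = FALSE)
  structure(list(bce_weight = bce_weight, pos_weight = pos_weight,
                 latent_dim = as.integer(latent_dim),
                 channels = as.integer(channels),
                 disc_channels = as.integer(disc_channels),
                 epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 lr = lr, lr_decay = lr_decay, negative_slope = negative_slope,
                 mode = match.arg(mode), augment_n = as.integer(augment_n),
                 seed = as.integer(seed)),
            class = "recdisc_config")
}

# log(sigmoid(y)) and log(1 - sigmoid(y)) via softplus, safe for any logit.
log_sigmoid <- function(y) -log1p(exp(-abs(y))) + pmin(y, 0)
log_one_minus_sigmoid <- function(y) -log1p(exp(-abs(y))) + pmin(-y, 0)

#' Composite RecDisc loss: reconstruction MSE plus weighted BCE
#'
#' `MSE(clean, reconstruction) + w * [ -(1/n) sum_i (p1 yhat_i log s(y_i)
#' + (1 - yhat_i) log(1 - s(y_i))) ]` where `s` is the sigmoid, `yhat` the
#' artificial groundtruth and `n` the number of evaluated (in-brain)
#' voxels. Evaluated in log-sum-exp form so saturated logits stay finite.
#' With `pos_weight = 1, bce_weight = 1` this is exactly MSE + standard
#' mean BCE.
#'
#' @param clean_input,reconstruction equal-shaped 4D arrays.
#' @param logits 3D array of discriminator logits.
#' @param target 3D array of 0/1 (or logical) artificial groundtruth.
#' @param bce_weight,pos_weight loss weights.
#' @param mask optional 3D logical array restricting the evaluated voxels
#'   (both terms); default: all voxels.
#' @return scalar loss.
#' @export
recdisc_loss <- function(clean_input, reconstruction, logits, target,
                         bce_weight = 1, pos_weight = 1, mask = NULL) {
  if (length(clean_input) != length(reconstruction))
    stop("clean_input and reconstruction shapes differ", call. = FALSE)
  if (length(logits) != length(target))
    stop("logits and target shapes differ", call. = FALSE)
  tgt <- as.numeric(target)
  y <- as.numeric(logits)
  if (is.null(mask)) {
    sel <- rep(TRUE, length(y))
  } else {
    sel <- as.vector(mask)
  }
  n <- sum(sel)
  bce <- -(1 / n) * sum(pos_weight * tgt[sel] * log_sigmoid(y[sel]) +
                          (1 - tgt[sel]) * log_one_minus_sigmoid(y[sel]))
  if (is.null(mask)) {
    mse <- mean((clean_input - reconstruction)^2)
  } else {
    n_ch <- length(clean_input) / length(mask)
    selc <- rep(as.vector(mask), n_ch)
    mse <- mean((as.numeric(clean_input)[selc] -
                   as.numeric(reconstruction)[selc])^2)
  }
  mse + bce_weight * bce
}

# ---- discriminator: 2-scale 3D U-Net -------------------------------------
build_disc <- function(config, input_shape, in_channels) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(config$seed + 7L)
  f <- config$disc_channels
  g0 <- max(4L, f[1] %/% 2L)          # full-resolution head width
  pad_shape <- stride_compatible_shape(input_shape, 2L)
  half <- pad_shape %/% 2L
  quarter <- half %/% 2L
  # spatial context (3^3 kernels) lives at half/quarter resolution; the
  # full-resolution head mixes channels pointwise (1^3), which keeps the
  # im2col working set small at the native grid
  geoms <- list(
    d1 = conv_geom(pad_shape, in_channels, 3L, 2L, 1L),      # -> half, f1
    d2 = conv_geom(half, f[1], 3L, 2L, 1L),                  # -> quarter, f2
    bn = conv_geom(quarter, f[2], 3L, 1L, 1L),               # -> quarter, f2
    u1 = conv_geom(half, f[1], 3L, 2L, 1L),                  # convT: quarter -> half
    c1 = conv_geom(half, 2L * f[1], 3L, 1L, 1L),             # -> half, f1
    u2 = conv_geom(pad_shape, g0, 3L, 2L, 1L),               # convT: half -> full
    c2 = conv_geom(pad_shape, g0 + in_channels, 1L, 1L, 0L), # -> full, g0
    out = conv_geom(pad_shape, g0, 1L, 1L, 0L))              # -> full, 1
  params <- list(
    d1_W = he_init(geoms$d1$K, f[1], geoms$d1$K), d1_b = numeric(f[1]),
    d2_W = he_init(geoms$d2$K, f[2], geoms$d2$K), d2_b = numeric(f[2]),
    bn_W = he_init(geoms$bn$K, f[2], geoms$bn$K), bn_b = numeric(f[2]),
    u1_W = he_init(geoms$u1$K, f[2], f[2] * 8), u1_b = numeric(f[1]),
    c1_W = he_init(geoms$c1$K, f[1], geoms$c1$K), c1_b = numeric(f[1]),
    u2_W = he_init(geoms$u2$K, f[1], f[1] * 8), u2_b = numeric(g0),
    c2_W = he_init(geoms$c2$K, g0, geoms$c2$K), c2_b = numeric(g0),
    out_W = he_init(geoms$out$K, 1L, geoms$out$K), out_b = numeric(1L))
  list(geoms = geoms, params = params, pad_shape = pad_shape,
       input_shape = as.integer(input_shape), in_channels = in_channels,
       f = f, g0 = g0, slope = config$negative_slope)
}

disc_forward <- function(disc, x) {
  p <- disc$params; g <- disc$geoms; sl <- disc$slope
  xp <- pad_to_shape(x, disc$pad_shape)
  cache <- list(xp = xp)
  step <- function(h, W, b, geom, tag, norm = TRUE) {
    cv <- conv_fwd(h, p[[W]], p[[b]], geom)
    if (norm) {
      no <- inorm_fwd(cv$y)
      a <- lrelu_fwd(no$y, sl)
      cache[[tag]] <<- list(cols = cv$cols, pre = no$y, xhat = no$xhat,
                            istd = no$istd, norm = TRUE)
    } else {
      a <- lrelu_fwd(cv$y, sl)
      cache[[tag]] <<- list(cols = cv$cols, pre = cv$y, norm = FALSE)
    }
    a
  }
  e1 <- step(xp, "d1_W", "d1_b", g$d1, "d1")
  e2 <- step(e1, "d2_W", "d2_b", g$d2, "d2")
  b <- step(e2, "bn_W", "bn_b", g$bn, "bn")
  ct1 <- convt_fwd(b, p$u1_W, p$u1_b, g$u1)
  no1 <- inorm_fwd(ct1$y); a1 <- lrelu_fwd(no1$y, sl)
  cache$u1 <- list(X = ct1$X, pre = no1$y, xhat = no1$xhat, istd = no1$istd)
  c1in <- abind4(a1, e1)
  c1 <- step(c1in, "c1_W", "c1_b", g$c1, "c1")
  ct2 <- convt_fwd(c1, p$u2_W, p$u2_b, g$u2)
  no2 <- inorm_fwd(ct2$y); a2 <- lrelu_fwd(no2$y, sl)
  cache$u2 <- list(X = ct2$X, pre = no2$y, xhat = no2$xhat, istd = no2$istd)
  c2in <- abind4(a2, xp)
  c2 <- step(c2in, "c2_W", "c2_b", g$c2, "c2", norm = FALSE)
  lg <- conv_fwd(c2, p$out_W, p$out_b, g$out)
  cache$out <- list(cols = lg$cols)
  logits_pad <- lg$y
  logits <- array(logits_pad[seq_len(disc$input_shape[1]),
                             seq_len(disc$input_shape[2]),
                             seq_len(disc$input_shape[3]), 1],
                  disc$input_shape)
  list(logits = logits, logits_pad = logits_pad, cache = cache,
       acts = list(e1 = e1, e2 = e2, b = b, a1 = a1, c1in = c1in, c1 = c1,
                   a2 = a2, c2in = c2in, c2 = c2))
}

# dy_logits: gradient wrt cropped logits (3D). Returns grads and the
# gradient wrt the (unpadded) discriminator input.
disc_backward <- function(disc, fw, dy_logits) {
  p <- disc$params; g <- disc$geoms; sl <- disc$slope
  cache <- fw$cache; acts <- fw$acts
  grads <- list()
  dlp <- array(0, dim(fw$logits_pad))
  dlp[seq_len(disc$input_shape[1]), seq_len(disc$input_shape[2]),
      seq_len(disc$input_shape[3]), 1] <- dy_logits
  bw <- conv_bwd(dlp, cache$out$cols, p$out_W, g$out)
  grads$out_W <- bw$dW; grads$out_b <- bw$db
  dc2 <- bw$dx
  back_conv <- function(dh, tag, W, geom, pre_act) {
    cc <- cache[[tag]]
    dh <- lrelu_bwd(dh, cc$pre, sl)
    if (isTRUE(cc$norm)) dh <- inorm_bwd(dh, cc$xhat, cc$istd)
    conv_bwd(dh, cc$cols, p[[W]], geom)
  }
  bw <- back_conv(dc2, "c2", "c2_W", g$c2)
  grads$c2_W <- bw$dW; grads$c2_b <- bw$db
  dc2in <- bw$dx
  f1 <- disc$f[1]; g0 <- disc$g0
  da2 <- dc2in[, , , seq_len(g0), drop = FALSE]
  dxp <- dc2in[, , , g0 + seq_len(disc$in_channels), drop = FALSE]
  dh <- lrelu_bwd(da2, cache$u2$pre, sl)
  dh <- inorm_bwd(dh, cache$u2$xhat, cache$u2$istd)
  bw <- convt_bwd(dh, cache$u2$X, p$u2_W, g$u2)
  grads$u2_W <- bw$dW; grads$u2_b <- bw$db
  dc1 <- bw$dx
  bw <- back_conv(dc1, "c1", "c1_W", g$c1)
  grads$c1_W <- bw$dW; grads$c1_b <- bw$db
  dc1in <- bw$dx
  da1 <- dc1in[, , , seq_len(f1), drop = FALSE]
  de1_skip <- dc1in[, , , f1 + seq_len(f1), drop = FALSE]
  dh <- lrelu_bwd(da1, cache$u1$pre, sl)
  dh <- inorm_bwd(dh, cache$u1$xhat, cache$u1$istd)
  bw <- convt_bwd(dh, cache$u1$X, p$u1_W, g$u1)
  grads$u1_W <- bw$dW; grads$u1_b <- bw$db
  db_ <- bw$dx
  bw <- back_conv(db_, "bn", "bn_W", g$bn)
  grads$bn_W <- bw$dW; grads$bn_b <- bw$db
  de2 <- bw$dx
  bw <- back_conv(de2, "d2", "d2_W", g$d2)
  grads$d2_W <- bw$dW; grads$d2_b <- bw$db
  de1 <- bw$dx + de1_skip
  bw <- back_conv(de1, "d1", "d1_W", g$d1)
  grads$d1_W <- bw$dW; grads$d1_b <- bw$db
  dxp_total <- bw$dx + dxp
  dx <- dxp_total[seq_len(disc$input_shape[1]), seq_len(disc$input_shape[2]),
                  seq_len(disc$input_shape[3]), , drop = FALSE]
  list(grads = grads, dx = dx)
}

# concatenate two (X,Y,Z,C) arrays along the channel axis
abind4 <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1:3], da[4] + db[4]))
  out[, , , seq_len(da[4])] <- a
  out[, , , da[4] + seq_len(db[4])] <- b
  out
}

#' Build the RecDiscNet model pair
#'
#' @param config a [recdisc_config()].
#' @param input_shape spatial grid (length 3).
#' @param in_channels diffusion channel count C; the discriminator consumes
#'   2C channels (input concatenated with reconstruction) and emits one
#'   logit channel at input resolution.
#' @return An object of class `recdisc_model` with elements `recon_net` (a
#'   plain `dae_model`) and `disc_net`.
#' @export
build_recdisc <- function(config, input_shape, in_channels) {
  stopifnot(inherits(config, "recdisc_config"))
  rcfg <- dae_config(latent_dim = config$latent_dim,
                     output_activation = "sigmoid",
                     kl_weight = 0, negative_slope = config$negative_slope,
                     epochs = config$epochs, batch_size = config$batch_size,
                     lr = config$lr, lr_decay = config$lr_decay,
                     channels = config$channels, variational = FALSE,
                     seed = config$seed)
  recon_net <- build_dae(rcfg, input_shape, in_channels)
  disc_net <- build_disc(config, input_shape, 2L * in_channels)
  structure(list(recon_net = recon_net, disc_net = disc_net, config = config,
                 input_shape = as.integer(input_shape),
                 in_channels = as.integer(in_channels)),
            class = "recdisc_model")
}

#' @export
print.recdisc_model <- function(x, ...) {
  cat("<recdisc_model> reconstruction ", paste(x$config$channels, collapse = "-"),
      " / latent ", x$config$latent_dim,
      "; discriminator U-Net ", paste(x$config$disc_channels, collapse = "-"),
      "\n  input ", paste(x$input_shape, collapse = " x "), " x ",
      x$in_channels, " -> disc input ", 2L * x$in_channels,
      " channels, 1 logit channel\n", sep = "")
  invisible(x)
}

# One forward pass of the full two-stage model on a corrupted input.
recdisc_forward <- function(model, x_corrupt) {
  fw_r <- dae_forward(model$recon_net, x_corrupt, sample = FALSE)
  disc_in <- abind4(x_corrupt, fw_r$recon)
  fw_d <- disc_forward(model$disc_net, disc_in)
  list(recon = fw_r$recon, logits = fw_d$logits, fw_r = fw_r, fw_d = fw_d)
}

#' Train the RecDiscNet
#'
#' Each training subject is expanded to `augment_n` corrupted copies via
#' [augment()] (fresh per-epoch resampling optional). The reconstruction
#' target is the clean volume; the discrimination target is the artificial
#' groundtruth. Joint mode backpropagates the summed loss through both
#' networks (the discriminator's input gradient reaches the reconstruction
#' net through the concatenation); sequential mode trains reconstruction
#' first, then the discriminator with reconstruction frozen. Loss terms are
#' computed over in-brain voxels only.
#'
#' @param cohort list of healthy normalized [dwi_volume()]s (or
#'   `simulate_dwi()` results).
#' @param spec a [noise_spec()] describing the injected appearances.
#' @param config a [recdisc_config()].
#' @param fold optional list with `train` / `val` index vectors.
#' @param resample_each_epoch draw fresh corruptions per epoch instead of a
#'   fixed precomputed set.
#' @param verbose print per-epoch losses?
#' @return An object of class `recdisc_fit`.
#' @export
train_recdisc <- function(cohort, spec, config, fold = NULL,
                          resample_each_epoch = FALSE, verbose = FALSE) {
  vols <- lapply(cohort, function(s) if (inherits(s, "dwi_volume")) s else s$volume)
  n <- length(vols)
  if (is.null(fold)) {
    n_val <- max(1L, ceiling(n / 5))
    fold <- list(train = seq_len(n - n_val), val = seq(n - n_val + 1L, n))
  }
  shape <- dim(vols[[1]]$signal)[1:3]
  n_ch <- dim(vols[[1]]$signal)[4]
  model <- build_recdisc(config, shape, n_ch)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(config$seed + 11L)
  make_items <- function(idx, n_aug) {
    out <- list()
    for (j in idx) {
      cors <- augment(vols[[j]], spec, n = n_aug)
      for (cv in cors)
        out[[length(out) + 1L]] <-
          list(x = cv$volume$signal, clean = vols[[j]]$signal,
               gt = cv$artificial_groundtruth$voxels,
               bmask = brain_mask(vols[[j]]))
    }
    out
  }
  val_items <- make_items(fold$val, max(1L, config$augment_n %/% 2L))
  train_items <- if (resample_each_epoch) NULL else
    make_items(fold$train, config$augment_n)
  opt_r <- adam_init(model$recon_net$params)
  opt_d <- adam_init(model$disc_net$params)
  seq_split <- floor(config$epochs / 2)
  item_pass <- function(it, train_recon, train_disc) {
    fw <- recdisc_forward(model, it$x)
    sel <- as.vector(it$bmask)
    n_vox <- sum(sel)
    selc <- rep(sel, n_ch)
    tgt <- as.numeric(it$gt)
    y <- as.numeric(fw$logits)
    p1 <- if (identical(config$pos_weight, "auto")) {
      npos <- sum(tgt[sel])
      if (npos > 0) (n_vox - npos) / npos else 1
    } else config$pos_weight
    loss <- recdisc_loss(it$clean, fw$recon, fw$logits, it$gt,
                         config$bce_weight, p1, it$bmask)
    if (!is.finite(loss)) stop("training diverged (non-finite loss)", call. = FALSE)
    s <- sigmoid(y)
    dy <- numeric(length(y))
    dy[sel] <- config$bce_weight / n_vox *
      (p1 * tgt[sel] * (s[sel] - 1) + (1 - tgt[sel]) * s[sel])
    dy <- array(dy, dim(fw$logits))
    grads <- list(r = NULL, d = NULL)
    if (train_disc) {
      bwd <- disc_backward(model$disc_net, fw$fw_d, dy)
      grads$d <- bwd$grads
      d_recon_from_disc <- bwd$dx[, , , n_ch + seq_len(n_ch), drop = FALSE]
    } else d_recon_from_disc <- 0
    if (train_recon) {
      d_recon <- array(0, dim(fw$recon))
      dv <- 2 * (as.numeric(fw$recon) - as.numeric(it$clean)) / sum(selc)
      dv[!selc] <- 0
      d_recon <- array(dv, dim(fw$recon))
      if (train_disc && config$mode == "joint")
        d_recon <- d_recon + d_recon_from_disc
      grads$r <- dae_backward(model$recon_net, fw$fw_r, d_recon)
    }
    list(loss = loss, grads = grads)
  }
  val_loss_fn <- function() {
    mean(vapply(val_items, function(it) {
      fw <- recdisc_forward(model, it$x)
      p1 <- if (identical(config$pos_weight, "auto")) {
        sel <- as.vector(it$bmask)
        npos <- sum(as.numeric(it$gt)[sel])
        if (npos > 0) (sum(sel) - npos) / npos else 1
      } else config$pos_weight
      recdisc_loss(it$clean, fw$recon, fw$logits, it$gt,
                   config$bce_weight, p1, it$bmask)
    }, numeric(1)))
  }
  history <- data.frame(epoch = integer(), lr = numeric(),
                        train_loss = numeric(), val_loss = numeric())
  best_val <- Inf
  best <- list(r = model$recon_net$params, d = model$disc_net$params)
  for (ep in seq_len(config$epochs)) {
    lr_ep <- config$lr * config$lr_decay^(ep - 1)
    items <- if (resample_each_epoch) make_items(fold$train, config$augment_n)
             else train_items
    train_recon <- config$mode == "joint" || ep <= seq_split
    train_disc <- config$mode == "joint" || ep > seq_split
    ord <- sample(seq_along(items))
    batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
    tr_loss <- 0
    for (bt in batches) {
      acc_r <- NULL; acc_d <- NULL
      for (j in bt) {
        res <- item_pass(items[[j]], train_recon, train_disc)
        tr_loss <- tr_loss + res$loss
        if (!is.null(res$grads$r))
          acc_r <- if (is.null(acc_r)) res$grads$r else
            mapply(`+`, acc_r, res$grads$r, SIMPLIFY = FALSE)
        if (!is.null(res$grads$d))
          acc_d <- if (is.null(acc_d)) res$grads$d else
            mapply(`+`, acc_d, res$grads$d, SIMPLIFY = FALSE)
      }
      if (!is.null(acc_r)) {
        acc_r <- lapply(acc_r, function(g) g / length(bt))
        st <- adam_step(model$recon_net$params, acc_r, opt_r, lr_ep)
        model$recon_net$params <- st$params; opt_r <- st$state
      }
      if (!is.null(acc_d)) {
        acc_d <- lapply(acc_d, function(g) g / length(bt))
        st <- adam_step(model$disc_net$params, acc_d, opt_d, lr_ep)
        model$disc_net$params <- st$params; opt_d <- st$state
      }
    }
    tr_loss <- tr_loss / length(items)
    vl <- val_loss_fn()
    history <- rbind(history, data.frame(epoch = ep, lr = lr_ep,
                                         train_loss = tr_loss, val_loss = vl))
    if (vl < best_val) {
      best_val <- vl
      best <- list(r = model$recon_net$params, d = model$disc_net$params)
    }
    if (verbose)
      message(sprintf("[recdisc] epoch %3d lr %.2e train %.6f val %.6f",
                      ep, lr_ep, tr_loss, vl))
  }
  model$recon_net$params <- best$r
  model$disc_net$params <- best$d
  structure(list(model = model, history = history, fold = fold,
                 best_val_loss = best_val, spec = spec),
            class = "recdisc_fit")
}

#' @export
print.recdisc_fit <- function(x, ...) {
  cat("<recdisc_fit> ", nrow(x$history), " epoch(s); best validation loss ",
      signif(x$best_val_loss, 5), "\n", sep = "")
  invisible(x)
}

#' Score a volume with a trained RecDiscNet
#'
#' The anomaly map is the voxelwise sigmoid of the discriminator logits
#' (range \[0, 1\]); no residual computation is involved. Inference is
#' deterministic.
#'
#' @param fit a `recdisc_fit` (or bare `recdisc_model`).
#' @param vol a normalized [dwi_volume()] (possibly corrupted or lesioned)
#'   or a 4D array.
#' @return An [anomaly_map()] with `score_range = c(0, 1)`.
#' @export
score_recdisc <- function(fit, vol) {
  model <- if (inherits(fit, "recdisc_fit")) fit$model else fit
  x <- if (inherits(vol, "dwi_volume")) vol$signal else as.array(vol)
  if (!identical(dim(x)[1:3], as.integer(model$input_shape)) ||
      dim(x)[4] != model$in_channels)
    stop("input shape does not match training geometry", call. = FALSE)
  fw <- recdisc_forward(model, x)
  anomaly_map(sigmoid(fw$logits), score_range = c(0, 1),
              source_model = "recdisc")
}
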