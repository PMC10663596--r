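# Convolutional (variational) autoencoder with a linear latent space.
# Encoder: strided 3D convolutions, each normalized then LeakyReLU(0.01).
# Latent: flat vector of size n with mean and log-variance heads (the
# variational case) or a single linear head (plain autoencoder, used as the
# RecDisc reconstruction network). Decoder mirrors the encoder with
# transposed convolutions; the output layer uses a sigmoid or linear
# activation and matches the input channel count.

#' DAE configuration
#'
#' Defaults follow the published training recipe: KL weight
#' `1.22e-5`, LeakyReLU negative slope 0.01, 500 epochs, batch size 4,
#' per-epoch learning-rate decay 0.95, Adam. The initial learning rate and
#' the exact layer widths are reimplementation choices (the original
#' architecture table is not reproduced here); both are configurable.
#'
#' @param latent_dim linear latent space size; the published grid considered
#'   16, 32, 64, 128, 256 and 512.
#' @param output_activation `"sigmoid"` (input range \[0, 1\]) or
#'   `"linear"`.
#' @param kl_weight weight of the KL divergence term.
#' @param negative_slope LeakyReLU negative slope.
#' @param epochs,batch_size,lr,lr_decay optimization hyperparameters.
#' @param channels encoder stage widths (decoder mirrors them); one strided
#'   convolution per entry, so the grid must be padded to a multiple of
#'   `2^length(channels)`.
#' @param variational `FALSE` builds a plain autoencoder (no KL, no
#'   sampling).
#' @param seed integer seed for weight init and shuffling.
#' @return An object of class `dae_config`.
#' @export
dae_config <- function(latent_dim = 128L,
                       output_activation = c("sigmoid", "linear"),
                       kl_weight = 1.22e-5,
                       negative_slope = 0.01,
                       epochs = 500L, batch_size = 4L,
                       lr = 1e-4, lr_decay = 0.95,
                       channels = c(32L, 64L, 128L, 256L),
                       variational = TRUE,
                       seed = 1L) {
  structure(list(latent_dim = as.integer(latent_dim),
                 output_activation = match.arg(output_activation),
                 kl_weight = kl_weight, negative_slope = negative_slope,
                 epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 lr = lr, lr_decay = lr_decay,
                 channels = as.integer(channels),
                 variational = isTRUE(variational),
                 seed = as.integer(seed)),
            class = "dae_config")
}

#' Eq.-style composite VAE loss: reconstruction MSE plus weighted KL
#'
#' `MSE + w * [ -(1/2)(1/n) sum_j (1 + log S_j - mu_j^2 - S_j) ]` with
#' `S_j = exp(log_var_j)`; `n` is the latent size. With `kl_weight = 0`
#' this is exactly the MSE.
#'
#' @param input,reconstruction equal-shaped numeric arrays.
#' @param mu,log_var latent posterior mean and log-variance vectors.
#' @param kl_weight KL weight.
#' @return scalar loss.
#' @export
dae_loss <- function(input, reconstruction, mu, log_var, kl_weight = 1.22e-5) {
  if (!identical(dim(input), dim(reconstruction)) &&
      length(input) != length(reconstruction))
    stop("input and reconstruction shapes differ", call. = FALSE)
  if (any(!is.finite(mu)) || any(!is.finite(log_var)))
    stop("non-finite latent posterior", call. = FALSE)
  n <- length(mu)
  mse <- mean((input - reconstruction)^2)
  kl <- -0.5 / n * sum(1 + log_var - mu^2 - exp(log_var))
  mse + kl_weight * kl
}

#' Build a (variational) autoencoder model
#'
#' @param config a [dae_config()].
#' @param input_shape spatial grid (length 3); padded internally to the
#'   nearest stride-compatible grid, and outputs are cropped back.
#' @param in_channels number of diffusion channels C.
#' @return An object of class `dae_model` holding parameters and geometry.
#' @export
build_dae <- function(config, input_shape, in_channels) {
  stopifnot(inherits(config, "dae_config"))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  n_st <- length(config$channels)
  pad_shape <- stride_compatible_shape(input_shape, n_st)
  shapes <- list(pad_shape)
  for (i in seq_len(n_st)) shapes[[i + 1]] <- shapes[[i]] %/% 2L
  chans <- c(in_channels, config$channels)
  enc_geoms <- lapply(seq_len(n_st), function(i)
    conv_geom(shapes[[i]], chans[i], k = 3L, stride = 2L, pad = 1L))
  n_flat <- prod(shapes[[n_st + 1]]) * chans[n_st + 1]
  params <- list()
  for (i in seq_len(n_st)) {
    g <- enc_geoms[[i]]
    params[[paste0("enc", i, "_W")]] <- he_init(g$K, chans[i + 1], g$K)
    params[[paste0("enc", i, "_b")]] <- numeric(chans[i + 1])
  }
  params$mu_W <- matrix(rnorm(n_flat * config$latent_dim, 0, sqrt(1 / n_flat)),
                        n_flat, config$latent_dim)
  params$mu_b <- numeric(config$latent_dim)
  if (config$variational) {
    params$lv_W <- matrix(rnorm(n_flat * config$latent_dim, 0, 0.01 * sqrt(1 / n_flat)),
                          n_flat, config$latent_dim)
    params$lv_b <- numeric(config$latent_dim)
  }
  params$dec0_W <- matrix(rnorm(config$latent_dim * n_flat, 0,
                                sqrt(1 / config$latent_dim)),
                          config$latent_dim, n_flat)
  params$dec0_b <- numeric(n_flat)
  # decoder convT stage i upsamples shapes[[i+1]] -> shapes[[i]]; its
  # geometry is the matching downsampling conv's geometry
  dec_geoms <- list()
  for (i in rev(seq_len(n_st))) {
    out_ch <- chans[i]           # in_channels for the last stage
    g <- conv_geom(shapes[[i]], out_ch, k = 3L, stride = 2L, pad = 1L)
    dec_geoms[[i]] <- g
    fan_in <- chans[i + 1] * ceiling(3 / 2)^3
    params[[paste0("dec", i, "_W")]] <-
      he_init(g$K, chans[i + 1], fan_in)
    params[[paste0("dec", i, "_b")]] <- numeric(out_ch)
  }
  structure(list(config = config, input_shape = as.integer(input_shape),
                 pad_shape = pad_shape, in_channels = as.integer(in_channels),
                 shapes = shapes, chans = chans, n_stages = n_st,
                 n_flat = n_flat, enc_geoms = enc_geoms, dec_geoms = dec_geoms,
                 params = params),
            class = "dae_model")
}

#' @export
print.dae_model <- function(x, ...) {
  cat("<dae_model> ", if (x$config$variational) "variational" else "plain",
      " autoencoder\n", sep = "")
  cat("  input : ", paste(x$input_shape, collapse = " x "), " x ",
      x$in_channels, " (padded to ", paste(x$pad_shape, collapse = " x "),
      ")\n", sep = "")
  cat("  stages: ", paste(x$config$channels, collapse = "-"),
      "  latent: ", x$config$latent_dim,
      "  output: ", x$config$output_activation, "\n", sep = "")
  cat("  parameters: ", format(sum(vapply(x$params, length, 1L)),
                               big.mark = ","), "\n", sep = "")
  invisible(x)
}

#' Number of trainable parameters
#' @param model a model object with a `params` list.
#' @return integer count.
#' @export
n_parameters <- function(model) sum(vapply(model$params, length, 1L))

# Full forward pass. `sample = TRUE` draws z = mu + eps * exp(log_var / 2);
# inference uses the posterior mean. Returns recon (cropped to the original
# grid), mu / log_var and caches for backprop.
dae_forward <- function(model, x, sample = FALSE, eps = NULL) {
  cfg <- model$config
  p <- model$params
  h <- pad_to_shape(x, model$pad_shape)
  cache <- list(x_pad = h)
  for (i in seq_len(model$n_stages)) {
    cv <- conv_fwd(h, p[[paste0("enc", i, "_W")]], p[[paste0("enc", i, "_b")]],
                   model$enc_geoms[[i]])
    no <- inorm_fwd(cv$y)
    a <- lrelu_fwd(no$y, cfg$negative_slope)
    cache[[paste0("e", i)]] <- list(cols = cv$cols, pre = no$y,
                                    xhat = no$xhat, istd = no$istd)
    h <- a
  }
  flat <- as.vector(h)
  mu <- dense_fwd(flat, p$mu_W, p$mu_b)
  if (cfg$variational) {
    log_var <- dense_fwd(flat, p$lv_W, p$lv_b)
    log_var <- pmin(pmax(log_var, -15), 15)
    if (sample) {
      if (is.null(eps)) eps <- rnorm(cfg$latent_dim)
      z <- mu + eps * exp(0.5 * log_var)
    } else {
      eps <- numeric(cfg$latent_dim)
      z <- mu
    }
  } else {
    log_var <- NULL; eps <- NULL; z <- mu
  }
  d0 <- dense_fwd(z, p$dec0_W, p$dec0_b)
  a0 <- lrelu_fwd(d0, cfg$negative_slope)
  h <- array(a0, c(model$shapes[[model$n_stages + 1]],
                   model$chans[model$n_stages + 1]))
  cache$flat <- flat; cache$z <- z; cache$eps <- eps
  cache$log_var <- log_var; cache$d0 <- d0
  for (i in rev(seq_len(model$n_stages))) {
    ct <- convt_fwd(h, p[[paste0("dec", i, "_W")]], p[[paste0("dec", i, "_b")]],
                    model$dec_geoms[[i]])
    if (i > 1L) {
      no <- inorm_fwd(ct$y)
      a <- lrelu_fwd(no$y, cfg$negative_slope)
      cache[[paste0("d", i)]] <- list(X = ct$X, pre = no$y,
                                      xhat = no$xhat, istd = no$istd)
      h <- a
    } else {
      cache[[paste0("d", i)]] <- list(X = ct$X, pre = ct$y)
      h <- if (cfg$output_activation == "sigmoid") sigmoid(ct$y) else ct$y
    }
  }
  recon_pad <- h
  recon <- array(crop_to_shape(recon_pad, model$input_shape),
                 c(model$input_shape, model$in_channels))
  list(recon = recon, recon_pad = recon_pad, mu = mu, log_var = log_var,
       cache = cache)
}

# Backward pass. d_recon is the loss gradient wrt the cropped output;
# d_mu / d_log_var carry extra (KL) gradients on the latent heads.
dae_backward <- function(model, fwd, d_recon, d_mu = NULL, d_log_var = NULL) {
  cfg <- model$config
  p <- model$params
  cache <- fwd$cache
  grads <- list()
  dh <- array(0, dim(fwd$recon_pad))
  dh[seq_len(model$input_shape[1]), seq_len(model$input_shape[2]),
     seq_len(model$input_shape[3]), ] <- d_recon
  if (cfg$output_activation == "sigmoid") {
    s <- sigmoid(cache$d1$pre)
    dh <- dh * s * (1 - s)
  }
  for (i in seq_len(model$n_stages)) {
    cc <- cache[[paste0("d", i)]]
    if (i > 1L) {
      dh <- lrelu_bwd(dh, cc$pre, cfg$negative_slope)
      dh <- inorm_bwd(dh, cc$xhat, cc$istd)
    }
    bw <- convt_bwd(dh, cc$X, p[[paste0("dec", i, "_W")]], model$dec_geoms[[i]])
    grads[[paste0("dec", i, "_W")]] <- bw$dW
    grads[[paste0("dec", i, "_b")]] <- bw$db
    dh <- bw$dx
  }
  da0 <- as.vector(dh)
  dd0 <- lrelu_bwd(da0, cache$d0, cfg$negative_slope)
  bw0 <- dense_bwd(dd0, cache$z, p$dec0_W)
  grads$dec0_W <- bw0$dW; grads$dec0_b <- bw0$db
  dz <- bw0$dx
  dmu_total <- dz
  if (!is.null(d_mu)) dmu_total <- dmu_total + d_mu
  dflat <- numeric(model$n_flat)
  if (cfg$variational) {
    dlv_total <- dz * cache$eps * 0.5 * exp(0.5 * cache$log_var)
    if (!is.null(d_log_var)) dlv_total <- dlv_total + d_log_var
    bwlv <- dense_bwd(dlv_total, cache$flat, p$lv_W)
    grads$lv_W <- bwlv$dW; grads$lv_b <- bwlv$db
    dflat <- dflat + bwlv$dx
  }
  bwmu <- dense_bwd(dmu_total, cache$flat, p$mu_W)
  grads$mu_W <- bwmu$dW; grads$mu_b <- bwmu$db
  dflat <- dflat + bwmu$dx
  dh <- array(dflat, c(model$shapes[[model$n_stages + 1]],
                       model$chans[model$n_stages + 1]))
  for (i in rev(seq_len(model$n_stages))) {
    cc <- cache[[paste0("e", i)]]
    dh <- lrelu_bwd(dh, cc$pre, cfg$negative_slope)
    dh <- inorm_bwd(dh, cc$xhat, cc$istd)
    bw <- conv_bwd(dh, cc$cols, p[[paste0("enc", i, "_W")]], model$enc_geoms[[i]])
    grads[[paste0("enc", i, "_W")]] <- bw$dW
    grads[[paste0("enc", i, "_b")]] <- bw$db
    dh <- bw$dx
  }
  grads
}

#' Train the DAE on healthy volumes
#'
#' Plain autoencoding of clean healthy volumes (the denoising behavior at
#' test time comes from out-of-distribution inputs). Adam with per-epoch
#' learning-rate decay `lr * lr_decay^epoch`; the checkpoint minimizing
#' validation loss is kept. Padding voxels never enter the loss (outputs
#' are cropped to the original grid before the MSE).
#'
#' @param cohort list of normalized [dwi_volume()]s (or `simulate_dwi()`
#'   results).
#' @param config a [dae_config()].
#' @param fold optional list with integer vectors `train` and `val`
#'   (indices into `cohort`); default: last ceiling(n/5) subjects validate.
#' @param verbose print per-epoch losses?
#' @return An object of class `dae_fit`: the trained model (best-validation
#'   weights), the loss history data.frame, and fold bookkeeping.
#' @export
train_dae <- function(cohort, config, fold = NULL, verbose = FALSE) {
  vols <- lapply(cohort, function(s) if (inherits(s, "dwi_volume")) s else s$volume)
  xs <- lapply(vols, function(v) v$signal)
  n <- length(xs)
  if (is.null(fold)) {
    n_val <- max(1L, ceiling(n / 5))
    fold <- list(train = seq_len(n - n_val), val = seq(n - n_val + 1L, n))
  }
  shape <- dim(xs[[1]])[1:3]
  n_ch <- dim(xs[[1]])[4]
  model <- build_dae(config, shape, n_ch)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(config$seed + 1L)
  opt <- adam_init(model$params)
  n_elem <- prod(dim(xs[[1]]))
  kl_grads <- function(mu, lv) {
    n_lat <- length(mu)
    list(d_mu = config$kl_weight * mu / n_lat,
         d_lv = config$kl_weight * (exp(lv) - 1) / (2 * n_lat))
  }
  item_loss <- function(x, fw) {
    if (config$variational)
      dae_loss(x, fw$recon, fw$mu, fw$log_var, config$kl_weight)
    else mean((x - fw$recon)^2)
  }
  history <- data.frame(epoch = integer(), lr = numeric(),
                        train_loss = numeric(), val_loss = numeric())
  best_val <- Inf; best_params <- model$params
  for (ep in seq_len(config$epochs)) {
    lr_ep <- config$lr * config$lr_decay^(ep - 1)
    ord <- sample(fold$train)
    batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
    tr_loss <- 0
    for (bt in batches) {
      acc <- NULL
      bl <- 0
      for (j in bt) {
        x <- xs[[j]]
        fw <- dae_forward(model, x, sample = config$variational)
        loss <- item_loss(x, fw)
        if (!is.finite(loss))
          stop("training diverged (non-finite loss) at epoch ", ep, call. = FALSE)
        d_recon <- 2 * (fw$recon - x) / n_elem
        if (config$variational) {
          kg <- kl_grads(fw$mu, fw$log_var)
          g <- dae_backward(model, fw, d_recon, kg$d_mu, kg$d_lv)
        } else {
          g <- dae_backward(model, fw, d_recon)
        }
        acc <- if (is.null(acc)) g else mapply(`+`, acc, g, SIMPLIFY = FALSE)
        bl <- bl + loss
      }
      acc <- lapply(acc, function(gr) gr / length(bt))
      st <- adam_step(model$params, acc, opt, lr_ep)
      model$params <- st$params; opt <- st$state
      tr_loss <- tr_loss + bl
    }
    tr_loss <- tr_loss / length(fold$train)
    val_loss <- mean(vapply(fold$val, function(j) {
      fw <- dae_forward(model, xs[[j]], sample = FALSE)
      item_loss(xs[[j]], fw)
    }, numeric(1)))
    history <- rbind(history, data.frame(epoch = ep, lr = lr_ep,
                                         train_loss = tr_loss,
                                         val_loss = val_loss))
    if (val_loss < best_val) { best_val <- val_loss; best_params <- model$params }
    if (verbose)
      message(sprintf("[dae] epoch %3d lr %.2e train %.6f val %.6f",
                      ep, lr_ep, tr_loss, val_loss))
  }
  model$params <- best_params
  structure(list(model = model, history = history, fold = fold,
                 best_val_loss = best_val),
            class = "dae_fit")
}

#' @export
print.dae_fit <- function(x, ...) {
  cat("<dae_fit> ", nrow(x$history), " epoch(s); best validation loss ",
      signif(x$best_val_loss, 5), "\n", sep = "")
  invisible(x)
}

#' Reconstruct a volume through a trained autoencoder
#'
#' Deterministic inference: the posterior mean is used, no latent sampling,
#' so repeated calls give identical output.
#'
#' @param fit a `dae_fit` (or bare `dae_model`).
#' @param vol a normalized [dwi_volume()] or 4D array with the training
#'   geometry.
#' @return 4D reconstruction array with the input's shape.
#' @export
reconstruct <- function(fit, vol) {
  model <- if (inherits(fit, "dae_fit")) fit$model else fit
  x <- if (inherits(vol, "dwi_volume")) vol$signal else as.array(vol)
  if (!identical(dim(x)[1:3], as.integer(model$input_shape)) ||
      dim(x)[4] != model$in_channels)
    stop("input shape ", paste(dim(x), collapse = "x"),
         " does not match training geometry ",
         paste(c(model$input_shape, model$in_channels), collapse = "x"),
         call. = FALSE)
  dae_forward(model, x, sample = FALSE)$recon
}
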