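# The convolution engine underpins both models; its backward passes are
# checked against central finite differences, and the forward convolution
# against a direct nested-loop evaluation.

conv_bruteforce <- function(x, W, b, k, stride, pad) {
  d <- dim(x); in_ch <- d[4]; out_ch <- ncol(W)
  pd <- d[1:3] + 2 * pad
  xp <- array(0, c(pd, in_ch))
  xp[pad + seq_len(d[1]), pad + seq_len(d[2]), pad + seq_len(d[3]), ] <- x
  out_sh <- (pd - k) %/% stride + 1
  y <- array(0, c(out_sh, out_ch))
  for (ox in seq_len(out_sh[1])) for (oy in seq_len(out_sh[2]))
    for (oz in seq_len(out_sh[3])) {
      bx <- (ox - 1) * stride; by <- (oy - 1) * stride; bz <- (oz - 1) * stride
      patch <- xp[bx + 1:k, by + 1:k, bz + 1:k, , drop = FALSE]
      for (oc in seq_len(out_ch))
        y[ox, oy, oz, oc] <- sum(patch * array(W[, oc], c(k, k, k, in_ch))) +
          b[oc]
    }
  y
}

test_that("gathered-GEMM convolution equals the nested-loop definition", {
  set.seed(1)
  for (case in list(list(sh = c(6, 6, 4), ic = 2, oc = 3, k = 3, s = 2, p = 1),
                    list(sh = c(5, 4, 4), ic = 3, oc = 2, k = 3, s = 1, p = 1),
                    list(sh = c(4, 4, 4), ic = 2, oc = 2, k = 1, s = 1, p = 0))) {
    g <- dwianomaly:::conv_geom(case$sh, case$ic, case$k, case$s, case$p)
    W <- matrix(rnorm(g$K * case$oc), g$K, case$oc)
    b <- rnorm(case$oc)
    x <- array(rnorm(prod(case$sh) * case$ic), c(case$sh, case$ic))
    got <- dwianomaly:::conv_fwd(x, W, b, g)$y
    want <- conv_bruteforce(x, W, b, case$k, case$s, case$p)
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("transposed convolution is the exact adjoint of convolution", {
  # <conv(x), y> must equal <x, convT(y)> for the same weights
  set.seed(2)
  sh <- c(6, 6, 4); ic <- 2; oc <- 3
  g <- dwianomaly:::conv_geom(sh, ic, 3, 2, 1)
  W <- matrix(rnorm(g$K * oc), g$K, oc)
  x <- array(rnorm(prod(sh) * ic), c(sh, ic))
  y <- array(rnorm(prod(g$out_shape) * oc), c(g$out_shape, oc))
  cx <- dwianomaly:::conv_fwd(x, W, numeric(oc), g)$y
  # convT with the same geometry maps y (small, oc ch) -> x grid (ic ch):
  # its weight is the conv weight, consumed transposed
  ty <- dwianomaly:::convt_fwd(y, W, numeric(ic), g)$y
  expect_equal(sum(cx * y), sum(x * ty), tolerance = 1e-9)
})

test_that("autoencoder backprop matches finite differences", {
  set.seed(3)
  cfg <- dae_config(latent_dim = 4L, channels = c(3L, 4L), seed = 2L)
  m <- build_dae(cfg, c(8, 8, 8), 2L)
  x <- array(runif(8 * 8 * 8 * 2), c(8, 8, 8, 2))
  eps <- rnorm(4)
  fw <- dwianomaly:::dae_forward(m, x, sample = TRUE, eps = eps)
  d_recon <- 2 * (fw$recon - x) / length(x)
  kw <- cfg$kl_weight
  g <- dwianomaly:::dae_backward(
    m, fw, d_recon, kw * fw$mu / 4, kw * (exp(fw$log_var) - 1) / 8)
  loss_at <- function(params) {
    m2 <- m; m2$params <- params
    fw2 <- dwianomaly:::dae_forward(m2, x, sample = TRUE, eps = eps)
    dae_loss(x, fw2$recon, fw2$mu, fw2$log_var, kw)
  }
  h <- 1e-5
  for (nm in c("enc1_W", "enc2_W", "mu_W", "lv_W", "dec0_W", "dec2_W",
               "dec1_W", "dec1_b")) {
    i <- sample(length(m$params[[nm]]), 1)
    p <- m$params
    p[[nm]][i] <- p[[nm]][i] + h; lp <- loss_at(p)
    p[[nm]][i] <- p[[nm]][i] - 2 * h; lm <- loss_at(p)
    num <- (lp - lm) / (2 * h)
    expect_equal(g[[nm]][i], num, tolerance = 1e-4,
                 label = paste("analytic grad", nm))
  }
})

test_that("discriminator and joint-path backprop match finite differences", {
  set.seed(4)
  cfg <- recdisc_config(latent_dim = 4L, channels = c(3L, 4L),
                        disc_channels = c(4L, 6L), seed = 3L)
  m <- build_recdisc(cfg, c(8, 8, 8), 2L)
  x <- array(runif(8 * 8 * 8 * 2), c(8, 8, 8, 2))
  clean <- array(runif(8 * 8 * 8 * 2), c(8, 8, 8, 2))
  gt <- array(runif(8 * 8 * 8) < 0.1, c(8, 8, 8))
  bmask <- array(runif(8 * 8 * 8) < 0.8, c(8, 8, 8))
  p1 <- 3; w <- 1.5
  loss_at <- function(mm) {
    fw <- dwianomaly:::recdisc_forward(mm, x)
    recdisc_loss(clean, fw$recon, fw$logits, gt, w, p1, bmask)
  }
  fw <- dwianomaly:::recdisc_forward(m, x)
  sel <- as.vector(bmask); n_vox <- sum(sel); selc <- rep(sel, 2)
  tgt <- as.numeric(gt); y <- as.numeric(fw$logits)
  s <- 1 / (1 + exp(-y))
  dy <- numeric(length(y))
  dy[sel] <- w / n_vox * (p1 * tgt[sel] * (s[sel] - 1) + (1 - tgt[sel]) * s[sel])
  bwd <- dwianomaly:::disc_backward(m$disc_net, fw$fw_d,
                                    array(dy, dim(fw$logits)))
  dv <- 2 * (as.numeric(fw$recon) - as.numeric(clean)) / sum(selc)
  dv[!selc] <- 0
  d_recon <- array(dv, dim(fw$recon)) + bwd$dx[, , , 3:4, drop = FALSE]
  gr <- dwianomaly:::dae_backward(m$recon_net, fw$fw_r, d_recon)
  h <- 1e-5
  for (nm in c("d1_W", "d2_W", "bn_W", "u1_W", "c1_W", "u2_W", "c2_W",
               "out_W", "out_b")) {
    i <- sample(length(m$disc_net$params[[nm]]), 1)
    m2 <- m
    m2$disc_net$params[[nm]][i] <- m2$disc_net$params[[nm]][i] + h
    lp <- loss_at(m2)
    m2$disc_net$params[[nm]][i] <- m2$disc_net$params[[nm]][i] - 2 * h
    lm <- loss_at(m2)
    num <- (lp - lm) / (2 * h)
    expect_equal(bwd$grads[[nm]][i], num, tolerance = 1e-4,
                 label = paste("disc grad", nm))
  }
  for (nm in c("enc1_W", "mu_W", "dec0_W", "dec1_W")) {
    i <- sample(length(m$recon_net$params[[nm]]), 1)
    m2 <- m
    m2$recon_net$params[[nm]][i] <- m2$recon_net$params[[nm]][i] + h
    lp <- loss_at(m2)
    m2$recon_net$params[[nm]][i] <- m2$recon_net$params[[nm]][i] - 2 * h
    lm <- loss_at(m2)
    num <- (lp - lm) / (2 * h)
    expect_equal(gr[[nm]][i], num, tolerance = 1e-4,
                 label = paste("recon grad", nm))
  }
})
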