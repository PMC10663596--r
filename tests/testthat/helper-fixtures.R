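# Shared fixtures, generated once per test run and cached. All phantom
# fixtures use the desk-scale study conditions: 32 x 32 x 20 grid, 8
# diffusion channels, b = 1000 s/mm^2, Rician noise sigma = 0.02.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_env))
    assign(name, builder(), envir = .fixture_env)
  get(name, envir = .fixture_env)
}

healthy_volume <- function() {
  fixture("healthy_volume", function() simulate_dwi(phantom_config(seed = 11L)))
}

lesioned_volume <- function() {
  fixture("lesioned_volume", function() {
    simulate_dwi(phantom_config(
      seed = 12L,
      lesion = lesion_spec(center = c(16, 16, 10), semi_axes = c(5, 4, 3.5))))
  })
}

small_cohort <- function() {
  fixture("small_cohort", function() make_cohort(6, phantom_config(), seed = 21L))
}

# tiny architectures used for fast unit tests
tiny_dae_config <- function(...) {
  args <- utils::modifyList(
    list(latent_dim = 8L, channels = c(6L, 8L), epochs = 8L,
         batch_size = 2L, lr = 3e-3, lr_decay = 0.97, seed = 5L),
    list(...))
  do.call(dae_config, args)
}

tiny_recdisc_config <- function(...) {
  args <- utils::modifyList(
    list(latent_dim = 8L, channels = c(6L, 8L), disc_channels = c(6L, 8L),
         epochs = 6L, batch_size = 2L, lr = 2e-3, lr_decay = 0.97,
         augment_n = 2L, seed = 5L),
    list(...))
  do.call(recdisc_config, args)
}

# independent brute-force oracles -------------------------------------------

# O(n^2) Mann-Whitney AUC: fraction of (positive, negative) pairs ranked
# correctly, ties counting one half.
auc_bruteforce <- function(scores, labels) {
  pos <- scores[labels]; neg <- scores[!labels]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

# brute-force binary erosion/dilation with a full cube of half-width r
morph_bruteforce <- function(m, r, op = c("erode", "dilate")) {
  op <- match.arg(op)
  d <- dim(m)
  out <- array(FALSE, d)
  for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3])) {
    xs <- max(1, x - r):min(d[1], x + r)
    ys <- max(1, y - r):min(d[2], y + r)
    zs <- max(1, z - r):min(d[3], z + r)
    nb <- m[xs, ys, zs]
    full <- length(xs) == 2 * r + 1 && length(ys) == 2 * r + 1 &&
      length(zs) == 2 * r + 1
    out[x, y, z] <- if (op == "erode") full && all(nb) else any(nb)
  }
  out
}

# brute-force sliding-window mean maximum (valid positions only)
pooled_max_bruteforce <- function(arr, k) {
  d <- dim(arr)
  best <- -Inf
  for (x in seq_len(d[1] - k + 1)) for (y in seq_len(d[2] - k + 1))
    for (z in seq_len(d[3] - k + 1)) {
      best <- max(best, mean(arr[x:(x + k - 1), y:(y + k - 1), z:(z + k - 1)]))
    }
  best
}

# exhaustive Otsu: maximize between-class variance over all histogram cuts
otsu_bruteforce <- function(v, n_bins) {
  rng <- range(v)
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1)
  bin <- pmin(findInterval(v, edges, rightmost.closed = TRUE), n_bins)
  mids <- (edges[-1] + edges[-length(edges)]) / 2
  best <- -Inf; best_t <- NA
  for (t in seq_len(n_bins - 1)) {
    lo <- bin <= t; n0 <- sum(lo); n1 <- sum(!lo)
    if (n0 == 0 || n1 == 0) next
    w0 <- n0 / length(v); w1 <- 1 - w0
    mu0 <- mean(mids[bin[lo]]); mu1 <- mean(mids[bin[!lo]])
    bcv <- w0 * w1 * (mu0 - mu1)^2
    if (bcv > best + 1e-15) { best <- bcv; best_t <- edges[t + 1] }
  }
  best_t
}
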