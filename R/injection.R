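# Just-out-of-distribution appearance injection: healthy volumes are
# corrupted with ellipsoidal noise patches whose voxel values are drawn from
# simple parametric distributions anchored to the subject's own brain signal
# statistics. The replaced voxel set doubles as the artificial groundtruth
# used to train the discrimination network. The recipe is deliberately
# scanner- and tumor-independent.

#' Noise specification for synthetic corruption
#'
#' @param family `"normal"`, `"uniform"` or `"mix"` (resolved per patch).
#' @param mean_mode `"full"` (patch mean = brain mean) or `"half"` (half the
#'   brain mean).
#' @param structure spatial/channel structure of the noise block:
#'   `"random"` (iid per voxel and channel), `"directional"` (one draw per
#'   channel, constant over space), `"isotropic"` (one draw per voxel,
#'   constant across channels) or `"mix"` (resolved per patch).
#' @param uniform_width `"sigma"`: uniform values span `mean +/- sigma/2`
#'   (total width = one brain-signal standard deviation, the default
#'   reading of the recipe) or `"two-sigma"`: `mean +/- sigma`.
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(family = c("normal", "uniform", "mix"),
                       mean_mode = c("full", "half"),
                       structure = c("random", "directional", "isotropic", "mix"),
                       uniform_width = c("sigma", "two-sigma")) {
  structure(list(family = match.arg(family),
                 mean_mode = match.arg(mean_mode),
                 structure = match.arg(structure),
                 uniform_width = match.arg(uniform_width)),
            class = "noise_spec")
}

#' Pooled brain-signal statistics
#'
#' Mean and standard deviation of all in-brain signal values pooled over
#' channels; these anchor the injected noise distributions. Computed per
#' subject. CSF counts as brain tissue by default.
#'
#' @param vol a normalized [dwi_volume()].
#' @param include_csf include CSF/ventricle voxels in the pool?
#' @return list with `mu` and `sigma` (population standard deviation).
#' @export
brain_statistics <- function(vol, include_csf = TRUE) {
  labels <- vol$tissue_mask
  sel <- if (include_csf) labels != TISSUE_BACKGROUND
         else labels == TISSUE_WM | labels == TISSUE_GM
  if (!any(sel)) stop("brain mask is empty", call. = FALSE)
  n_ch <- dim(vol$signal)[4]
  vals <- as.vector(vol$signal)[rep(as.vector(sel), n_ch)]
  mu <- mean(vals)
  list(mu = mu, sigma = sqrt(mean((vals - mu)^2)))
}

# Resolve "mix" choices to concrete family/structure for one patch.
resolve_noise_spec <- function(spec) {
  fam <- spec$family
  if (fam == "mix") fam <- sample(c("normal", "uniform"), 1L)
  struct <- spec$structure
  if (struct == "mix")
    struct <- sample(c("random", "directional", "isotropic"), 1L)
  list(family = fam, mean_mode = spec$mean_mode, structure = struct,
       uniform_width = spec$uniform_width)
}

#' Sample one noise block
#'
#' Draws the replacement values for a patch of `n_voxels` voxels across
#' `n_channels` channels. The normal family uses `N(m, sigma^2)`; the
#' uniform family `U(m - w/2, m + w/2)` with `w` = `sigma` (default) or
#' `2 sigma`; `m` is `mu` (`full`) or `mu / 2` (`half`). Structure controls
#' broadcasting: `random` draws independently per (voxel, channel),
#' `directional` draws once per channel and broadcasts over voxels,
#' `isotropic` draws once per voxel and broadcasts across channels.
#'
#' @param n_voxels,n_channels block dimensions.
#' @param spec a [noise_spec()]; `"mix"` entries are resolved internally.
#' @param mu,sigma brain-signal statistics from [brain_statistics()].
#' @param clip clip values to \[0, 1\] (the model input range)? Set `FALSE`
#'   to inspect the raw distribution.
#' @return `n_voxels` x `n_channels` numeric matrix.
#' @export
sample_noise_block <- function(n_voxels, n_channels, spec, mu, sigma,
                               clip = TRUE) {
  stopifnot(sigma >= 0)
  rs <- if (spec$family == "mix" || spec$structure == "mix")
    resolve_noise_spec(spec) else spec
  m <- if (rs$mean_mode == "half") mu / 2 else mu
  halfwidth <- if (rs$uniform_width == "sigma") sigma / 2 else sigma
  draw <- function(n) {
    if (rs$family == "normal") rnorm(n, m, sigma)
    else runif(n, m - halfwidth, m + halfwidth)
  }
  block <- switch(rs$structure,
    random = matrix(draw(n_voxels * n_channels), n_voxels, n_channels),
    directional = matrix(draw(n_channels), n_voxels, n_channels, byrow = TRUE),
    isotropic = matrix(draw(n_voxels), n_voxels, n_channels))
  if (clip) block <- pmin(pmax(block, 0), 1)
  attr(block, "resolved") <- rs
  block
}

#' Draw a patch plan
#'
#' The number of ellipsoidal patches is 0, 1 or 2 with probabilities 0.2,
#' 0.6 and 0.2. Each patch has a center drawn uniformly from in-brain
#' voxels, semi-axes drawn from `size_range`, and a uniform random 3D
#' orientation (ZYZ Euler angles with the sine-corrected middle angle).
#' Degenerate draws (any semi-axis < 1 voxel) are re-drawn and counted.
#'
#' @param vol a [dwi_volume()].
#' @param spec a [noise_spec()]; `"mix"` entries are resolved per patch.
#' @param size_range semi-axis range in voxels; default `c(2, 8)` scaled by
#'   `mean(grid) / 28` so patch size tracks the grid.
#' @return An object of class `patch_plan`: list with `n_patches` and
#'   `patches` (each with `center`, `semi_axes`, `rotation`, `noise`).
#' @export
sample_patch_plan <- function(vol, spec, size_range = NULL) {
  gs <- dim(vol$signal)[1:3]
  if (is.null(size_range)) size_range <- c(2, 8) * mean(gs) / 28
  n_patches <- sample(0:2, 1L, prob = c(0.2, 0.6, 0.2))
  bm <- which(brain_mask(vol))
  if (length(bm) == 0L) stop("brain mask is empty", call. = FALSE)
  redraws <- 0L
  patches <- lapply(seq_len(n_patches), function(i) {
    repeat {
      axes <- runif(3, size_range[1], size_range[2])
      if (all(axes >= 1)) break
      redraws <<- redraws + 1L
    }
    ctr_flat <- sample(bm, 1L)
    ctr <- arrayInd(ctr_flat, gs)[1, ]
    rot <- c(runif(1, 0, 2 * pi), acos(runif(1, -1, 1)), runif(1, 0, 2 * pi))
    list(center = as.numeric(ctr), semi_axes = axes, rotation = rot,
         noise = resolve_noise_spec(spec))
  })
  structure(list(n_patches = n_patches, patches = patches,
                 redraws = redraws, size_range = size_range),
            class = "patch_plan")
}

#' Corrupt a healthy volume with out-of-distribution patches
#'
#' Draws a patch plan, rasterizes each ellipsoid (a voxel is inside iff the
#' rotated quadratic form is <= 1), clips patches to the brain mask
#' (centers are in-brain; painted voxels never include background), and
#' replaces the signal at patch voxels with values from
#' [sample_noise_block()] — the same spatial support across all channels.
#' Replaced voxels define the artificial groundtruth.
#'
#' @inheritParams sample_patch_plan
#' @param stats optional precomputed [brain_statistics()] result.
#' @return An object of class `corrupted_volume`: list with `volume` (the
#'   corrupted [dwi_volume()]), `artificial_groundtruth` (a
#'   [lesion_mask()]), and `plan`.
#' @export
corrupt <- function(vol, spec, size_range = NULL, stats = NULL) {
  if (is.null(stats)) stats <- brain_statistics(vol)
  gs <- dim(vol$signal)[1:3]
  n_ch <- dim(vol$signal)[4]
  plan <- sample_patch_plan(vol, spec, size_range)
  sig <- vol$signal
  gt <- array(FALSE, gs)
  bm <- brain_mask(vol)
  sig_mat <- matrix(sig, prod(gs), n_ch)
  for (p in plan$patches) {
    vox <- which(ellipsoid_mask(gs, p$center, p$semi_axes, p$rotation) & bm)
    if (length(vox) == 0L) next
    block <- sample_noise_block(length(vox), n_ch, structure(p$noise, class = "noise_spec"),
                                stats$mu, stats$sigma, clip = TRUE)
    sig_mat[vox, ] <- block
    gt[vox] <- TRUE
  }
  out <- vol
  out$signal <- array(sig_mat, c(gs, n_ch))
  structure(list(volume = out,
                 artificial_groundtruth = lesion_mask(gt, "artificial"),
                 plan = plan),
            class = "corrupted_volume")
}

#' Fourfold corruption augmentation
#'
#' Expands one healthy subject into four independently corrupted inputs
#' (different patch plans over the same underlying volume).
#'
#' @inheritParams corrupt
#' @param n number of corrupted copies (default 4).
#' @return list of `n` [corrupt()] results.
#' @export
augment <- function(vol, spec, size_range = NULL, n = 4L) {
  stats <- brain_statistics(vol)
  lapply(seq_len(n), function(i) corrupt(vol, spec, size_range, stats = stats))
}
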