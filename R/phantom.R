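# Synthetic single-shell dMRI phantom: nested-ellipsoid brain geometry,
# tissue-dependent diffusion tensors (anisotropic WM with a concentric-shell
# tangent fiber field, isotropic GM/CSF), Rician magnitude noise, optional
# tumor-like lesion with altered diffusivity. Used as a stand-in training and
# evaluation cohort where no real acquisitions are available.

#' Phantom configuration
#'
#' @param grid_shape integer length-3; voxel counts per axis (each >= 16).
#' @param n_channels number of diffusion-weighted directions (>= 6).
#' @param bval diffusion weighting in s/mm^2.
#' @param tissue_geometry list of ellipsoid fractions of the half-grid:
#'   `brain` (outer brain surface), `wm` (WM core), `ventricle` (CSF
#'   ellipsoid semi-axes fraction) and `ventricle_offset` (lateral offset
#'   fraction of the two ventricles).
#' @param tensor_params per-tissue mean diffusivity `md` (mm^2/s) and
#'   fractional anisotropy `fa` in \[0, 1).
#' @param noise_sigma Rician noise scale as a fraction of the unweighted
#'   signal S0 (default 0.02).
#' @param lesion optional [lesion_spec()].
#' @param seed integer RNG seed.
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(grid_shape = c(32L, 32L, 20L),
                           n_channels = 8L,
                           bval = 1000,
                           tissue_geometry = list(brain = 0.92, wm = 0.62,
                                                  ventricle = c(0.10, 0.16, 0.18),
                                                  ventricle_offset = 0.18),
                           tensor_params = list(
                             WM  = list(md = 0.75e-3, fa = 0.75),
                             GM  = list(md = 0.85e-3, fa = 0.10),
                             CSF = list(md = 3.0e-3,  fa = 0.0)),
                           noise_sigma = 0.02,
                           lesion = NULL,
                           seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3L)
  if (any(grid_shape < 16L))
    stop("grid_shape components must be >= 16", call. = FALSE)
  if (n_channels < 6L) stop("n_channels must be >= 6", call. = FALSE)
  for (tp in tensor_params) {
    if (tp$md <= 0) stop("per-tissue diffusivities must be positive", call. = FALSE)
    if (tp$fa < 0 || tp$fa >= 1) stop("FA must lie in [0, 1)", call. = FALSE)
  }
  structure(list(grid_shape = grid_shape, n_channels = as.integer(n_channels),
                 bval = bval, tissue_geometry = tissue_geometry,
                 tensor_params = tensor_params, noise_sigma = noise_sigma,
                 lesion = lesion, seed = as.integer(seed)),
            class = "phantom_config")
}

#' Lesion specification for the phantom
#'
#' An ellipsoidal region with altered diffusivity: mean diffusivity is
#' multiplied by `md_multiplier` (tumor/edema typically increase MD) and
#' fractional anisotropy by `fa_multiplier` (infiltration degrades
#' anisotropy).
#'
#' @param center voxel coordinates (length 3); must fall inside the brain.
#' @param semi_axes ellipsoid semi-axes in voxels (length 3).
#' @param rotation Euler angles (radians, ZYZ), length 3.
#' @param md_multiplier positive MD scale factor (default 1.8).
#' @param fa_multiplier positive FA scale factor (default 0.3).
#' @return An object of class `lesion_spec`.
#' @export
lesion_spec <- function(center, semi_axes, rotation = c(0, 0, 0),
                        md_multiplier = 1.8, fa_multiplier = 0.3) {
  stopifnot(length(center) == 3L, length(semi_axes) == 3L)
  if (md_multiplier <= 0 || fa_multiplier <= 0)
    stop("lesion multipliers must be > 0", call. = FALSE)
  structure(list(center = as.numeric(center),
                 semi_axes = as.numeric(semi_axes),
                 rotation = as.numeric(rotation),
                 md_multiplier = md_multiplier,
                 fa_multiplier = fa_multiplier),
            class = "lesion_spec")
}

#' Quasi-uniform single-shell gradient table
#'
#' One b ~ 0 entry plus `n_channels` unit directions laid out by a spherical
#' Fibonacci spiral on the upper hemisphere (antipodally non-redundant: no
#' direction is the negation of another), optionally randomly rotated.
#'
#' @param n_channels number of diffusion directions (>= 6).
#' @param bval shell b-value in s/mm^2.
#' @param seed optional seed for the random global rotation; `NULL` keeps the
#'   canonical orientation.
#' @return list with `bvals` (length `n_channels + 1`, first entry 0) and
#'   `bvecs` ((`n_channels + 1`) x 3; first row zero).
#' @export
make_gradient_table <- function(n_channels, bval = 1000, seed = NULL) {
  if (n_channels < 6L) stop("n_channels must be >= 6", call. = FALSE)
  n <- as.integer(n_channels)
  i <- seq_len(n)
  z <- (i - 0.5) / n            # upper hemisphere only -> antipodally distinct
  phi <- i * pi * (3 - sqrt(5)) # golden angle
  r <- sqrt(pmax(0, 1 - z^2))
  dirs <- cbind(r * cos(phi), r * sin(phi), z)
  if (!is.null(seed)) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(seed)
    rot <- random_rotation()
    dirs <- dirs %*% t(rot)
  }
  dirs <- dirs / sqrt(rowSums(dirs^2))
  list(bvals = c(0, rep(bval, n)), bvecs = rbind(c(0, 0, 0), dirs))
}

# Save/restore global RNG state so seeded helpers don't perturb callers.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

# Uniform random rotation matrix (via QR of a Gaussian matrix, det +1).
random_rotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  q <- qr.Q(qr_)
  d <- diag(sign(diag(qr.R(qr_))))
  q <- q %*% d
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# Rotation matrix from ZYZ Euler angles.
euler_rotation <- function(a, b, g) {
  rz <- function(t) matrix(c(cos(t), sin(t), 0, -sin(t), cos(t), 0, 0, 0, 1), 3, 3)
  ry <- function(t) matrix(c(cos(t), 0, -sin(t), 0, 1, 0, sin(t), 0, cos(t)), 3, 3)
  rz(a) %*% ry(b) %*% rz(g)
}

# Axially symmetric eigenvalues from mean diffusivity and fractional
# anisotropy: lambda1 = md (1 + 2 a), lambda23 = md (1 - a) with
# a = fa / sqrt(3 - 2 fa^2), which preserves MD exactly.
tensor_eigenvalues <- function(md, fa) {
  a <- fa / sqrt(3 - 2 * fa^2)
  c(l1 = md * (1 + 2 * a), l23 = md * (1 - a))
}

# Voxel-center coordinates relative to grid center, one row per voxel.
voxel_offsets <- function(grid_shape) {
  ctr <- (grid_shape + 1) / 2
  gx <- seq_len(grid_shape[1]) - ctr[1]
  gy <- seq_len(grid_shape[2]) - ctr[2]
  gz <- seq_len(grid_shape[3]) - ctr[3]
  cbind(rep(gx, times = grid_shape[2] * grid_shape[3]),
        rep(rep(gy, each = grid_shape[1]), times = grid_shape[3]),
        rep(gz, each = grid_shape[1] * grid_shape[2]))
}

# Rasterize an ellipsoid: TRUE where the rotated, scaled quadratic form <= 1.
ellipsoid_mask <- function(grid_shape, center, semi_axes, rotation = c(0, 0, 0)) {
  ctr <- (grid_shape + 1) / 2
  off <- voxel_offsets(grid_shape)
  off <- sweep(off, 2, center - ctr, `-`)
  rot <- euler_rotation(rotation[1], rotation[2], rotation[3])
  local <- off %*% rot              # rotate into ellipsoid frame
  q <- (local[, 1] / semi_axes[1])^2 + (local[, 2] / semi_axes[2])^2 +
    (local[, 3] / semi_axes[3])^2
  array(q <= 1, grid_shape)
}

# Nested-ellipsoid tissue labels: GM shell around a WM core, two CSF
# ventricles carved out of the WM, background outside the brain surface.
phantom_labels <- function(config) {
  gs <- config$grid_shape
  tg <- config$tissue_geometry
  ctr <- (gs + 1) / 2
  half <- gs / 2
  brain <- ellipsoid_mask(gs, ctr, tg$brain * half)
  wm <- ellipsoid_mask(gs, ctr, tg$wm * half)
  voff <- tg$ventricle_offset * gs[1]
  vsz <- tg$ventricle * half
  v1 <- ellipsoid_mask(gs, ctr + c(voff, 0, 0), vsz)
  v2 <- ellipsoid_mask(gs, ctr - c(voff, 0, 0), vsz)
  labels <- array(TISSUE_BACKGROUND, gs)
  labels[brain] <- TISSUE_GM
  labels[wm] <- TISSUE_WM
  labels[(v1 | v2) & brain] <- TISSUE_CSF
  labels
}

# Per-voxel diffusion tensors as the 6 unique components (xx, yy, zz, xy,
# xz, yz), each an array over the grid. WM principal directions are tangents
# to concentric shells (azimuthal about the z axis); GM/CSF are isotropic up
# to their configured (small) FA along the same field.
phantom_tensors <- function(config, labels, lesion_mask_arr = NULL) {
  gs <- config$grid_shape
  nvox <- prod(gs)
  off <- voxel_offsets(gs)
  # azimuthal tangent e1 = z_hat x r_hat (degenerate on the axis -> x_hat)
  ex <- -off[, 2]; ey <- off[, 1]; ez <- numeric(nvox)
  nrm <- sqrt(ex^2 + ey^2)
  deg <- nrm < 1e-8
  ex[deg] <- 1; ey[deg] <- 0
  nrm[deg] <- 1
  ex <- ex / nrm; ey <- ey / nrm
  md <- numeric(nvox); fa <- numeric(nvox)
  for (tl in list(list(TISSUE_WM, "WM"), list(TISSUE_GM, "GM"),
                  list(TISSUE_CSF, "CSF"))) {
    sel <- as.vector(labels == tl[[1]])
    md[sel] <- config$tensor_params[[tl[[2]]]]$md
    fa[sel] <- config$tensor_params[[tl[[2]]]]$fa
  }
  if (!is.null(lesion_mask_arr)) {
    sel <- as.vector(lesion_mask_arr) & as.vector(labels != TISSUE_BACKGROUND)
    md[sel] <- md[sel] * config$lesion$md_multiplier
    fa[sel] <- pmin(fa[sel] * config$lesion$fa_multiplier, 0.99)
  }
  a <- fa / sqrt(3 - 2 * fa^2)
  l1 <- md * (1 + 2 * a)
  l23 <- md * (1 - a)
  dl <- l1 - l23
  # D = l23 I + (l1 - l23) e1 e1^T
  list(xx = array(l23 + dl * ex * ex, gs),
       yy = array(l23 + dl * ey * ey, gs),
       zz = array(l23 + dl * ez * ez, gs),
       xy = array(dl * ex * ey, gs),
       xz = array(dl * ex * ez, gs),
       yz = array(dl * ey * ez, gs))
}

# Analytic noiseless attenuation exp(-b g' D g) for one direction.
tensor_attenuation <- function(tens, g, bval) {
  exp(-bval * (g[1]^2 * tens$xx + g[2]^2 * tens$yy + g[3]^2 * tens$zz +
                 2 * g[1] * g[2] * tens$xy + 2 * g[1] * g[3] * tens$xz +
                 2 * g[2] * g[3] * tens$yz))
}

#' Simulate a diffusion-weighted phantom volume
#'
#' Generates tissue labels, evaluates the single-tensor signal
#' `S0 exp(-b g' D g)` per direction, applies Rician magnitude noise of
#' scale `noise_sigma`, then normalizes with the b0-ratio convention (the
#' noisy b0 channel is consumed). If `config$lesion` is set, the lesion
#' region uses tensors with multiplied MD / scaled FA and is returned as a
#' groundtruth [lesion_mask()].
#'
#' @param config a [phantom_config()].
#' @return list with elements `volume` (a normalized [dwi_volume()]) and
#'   `groundtruth` (a [lesion_mask()]; empty when no lesion is configured).
#' @export
simulate_dwi <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  gs <- config$grid_shape
  labels <- phantom_labels(config)
  gt_arr <- NULL
  if (!is.null(config$lesion)) {
    les <- config$lesion
    ctr_vox <- round(les$center)
    inside <- labels[ctr_vox[1], ctr_vox[2], ctr_vox[3]] != TISSUE_BACKGROUND
    if (!inside)
      stop("lesion center lies outside the brain label region", call. = FALSE)
    gt_arr <- ellipsoid_mask(gs, les$center, les$semi_axes, les$rotation) &
      (labels != TISSUE_BACKGROUND)
  }
  tens <- phantom_tensors(config, labels, gt_arr)
  # canonical (unrotated) gradient layout so a cohort shares one protocol
  gtab <- make_gradient_table(config$n_channels, config$bval, seed = NULL)
  n_all <- config$n_channels + 1L
  sig <- array(0, c(gs, n_all))
  bmask <- labels != TISSUE_BACKGROUND
  for (i in seq_len(n_all)) {
    s <- if (gtab$bvals[i] <= B0_TOLERANCE) array(1, gs)
         else tensor_attenuation(tens, gtab$bvecs[i, ], gtab$bvals[i])
    s[!bmask] <- 0
    if (config$noise_sigma > 0) {
      n1 <- array(rnorm(prod(gs), 0, config$noise_sigma), gs)
      n2 <- array(rnorm(prod(gs), 0, config$noise_sigma), gs)
      s <- sqrt((s + n1)^2 + n2^2)   # Rician magnitude
      s[!bmask] <- 0
    }
    sig[, , , i] <- s
  }
  raw <- dwi_volume(sig, gtab$bvals, gtab$bvecs, labels,
                    subject_id = paste0("phantom-", config$seed))
  vol <- normalize_attenuation(raw, "b0-ratio")
  gt <- if (is.null(gt_arr))
    lesion_mask(array(FALSE, gs), threshold_method = "groundtruth")
  else lesion_mask(gt_arr, threshold_method = "groundtruth")
  list(volume = vol, groundtruth = gt)
}

#' Generate a cohort of phantom subjects
#'
#' Per-subject jitter is applied to the tissue geometry (ellipsoid fractions,
#' +/- 5%), the noise scale (+/- 20%) and, for lesioned cohorts, the lesion
#' center/semi-axes/orientation, emulating anatomical variability across
#' subjects scanned with a fixed protocol. Deterministic under `seed`.
#'
#' @param n_subjects number of subjects (>= 1).
#' @param config_template a [phantom_config()] used as the base recipe.
#' @param seed integer master seed.
#' @param lesioned if `TRUE`, every subject receives a jittered lesion
#'   (template's `lesion` or a default deep-WM lesion).
#' @return list of per-subject lists with `volume` and `groundtruth`.
#' @export
make_cohort <- function(n_subjects, config_template = phantom_config(),
                        seed = 1L, lesioned = FALSE) {
  stopifnot(n_subjects >= 1)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  subj_seeds <- sample.int(.Machine$integer.max %/% 2L, n_subjects)
  lapply(seq_len(n_subjects), function(i) {
    set.seed(subj_seeds[i])
    cfg <- config_template
    tg <- cfg$tissue_geometry
    tg$brain <- min(tg$brain * runif(1, 0.95, 1.05), 0.98)
    tg$wm <- tg$wm * runif(1, 0.95, 1.05)
    cfg$tissue_geometry <- tg
    cfg$noise_sigma <- cfg$noise_sigma * runif(1, 0.8, 1.2)
    if (lesioned) {
      les <- cfg$lesion
      if (is.null(les)) {
        gs <- cfg$grid_shape
        les <- lesion_spec(center = (gs + 1) / 2, semi_axes = c(5, 4, 3.5))
      }
      ctr <- les$center + runif(3, -2.5, 2.5) * c(1, 1, 0.6)
      les <- lesion_spec(center = ctr,
                         semi_axes = pmax(les$semi_axes * runif(3, 0.8, 1.25), 1.5),
                         rotation = runif(3, 0, 2 * pi),
                         md_multiplier = les$md_multiplier,
                         fa_multiplier = les$fa_multiplier)
      cfg$lesion <- les
    } else {
      cfg$lesion <- NULL
    }
    cfg$seed <- subj_seeds[i]
    res <- simulate_dwi(cfg)
    res$volume$subject_id <- sprintf("sub-%03d", i)
    res
  })
}
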