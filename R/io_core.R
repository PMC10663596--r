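#' @keywords internal
#' @import stats
#' @import utils
#' @import graphics
"_PACKAGE"

# Tissue label conventions used throughout: 0 background, 1 white matter,
# 2 gray matter, 3 CSF / ventricle.
TISSUE_BACKGROUND <- 0L
TISSUE_WM <- 1L
TISSUE_GM <- 2L
TISSUE_CSF <- 3L

# b-values at or below this (s/mm^2) count as unweighted (b ~ 0) channels.
B0_TOLERANCE <- 50

#' Construct a diffusion-weighted volume
#'
#' A `dwi_volume` bundles a 4D diffusion-attenuated signal (X, Y, Z, C with C
#' diffusion channels), its gradient table, a voxel size and a tissue label
#' mask (0 = background, 1 = WM, 2 = GM, 3 = CSF/ventricle). Signal values
#' are expected to be normalized attenuations in \[0, 1\]; see
#' [normalize_attenuation()].
#'
#' @param signal 4D numeric array, dimensions (X, Y, Z, C).
#' @param bvals numeric vector of per-channel b-values (s/mm^2), length C.
#' @param bvecs C x 3 matrix of gradient directions; rows with `bvals` above
#'   the b0 tolerance must have unit norm.
#' @param tissue_mask 3D integer array of tissue labels matching the spatial
#'   shape of `signal`.
#' @param voxel_size voxel edge lengths in mm (length 1 or 3).
#' @param subject_id opaque identifier carried through logs and reports.
#' @param normalized normalization state: `NA` (raw), `"b0-ratio"` or
#'   `"global-max"`.
#' @return An object of class `dwi_volume`.
#' @export
dwi_volume <- function(signal, bvals, bvecs, tissue_mask,
                       voxel_size = 2.4, subject_id = "subject",
                       normalized = NA_character_) {
  signal <- as.array(signal)
  if (length(dim(signal)) != 4L)
    stop("`signal` must be a 4D array (X, Y, Z, C); got ",
         length(dim(signal)), " dimensions", call. = FALSE)
  n_ch <- dim(signal)[4]
  bvals <- as.numeric(bvals)
  bvecs <- as.matrix(bvecs)
  if (length(bvals) != n_ch)
    stop("gradient table mismatch on channel axis: image has ", n_ch,
         " channels but bvals has ", length(bvals), call. = FALSE)
  if (nrow(bvecs) != n_ch || ncol(bvecs) != 3L)
    stop("gradient table mismatch: bvecs must be ", n_ch,
         " x 3; got ", nrow(bvecs), " x ", ncol(bvecs), call. = FALSE)
  if (anyNA(signal) || any(!is.finite(signal))) {
    n_bad <- sum(!is.finite(signal))
    stop("signal contains ", n_bad, " non-finite voxel value(s)", call. = FALSE)
  }
  tissue_mask <- as.array(tissue_mask)
  if (!identical(dim(tissue_mask), dim(signal)[1:3]))
    stop("tissue_mask spatial shape ", paste(dim(tissue_mask), collapse = "x"),
         " does not match signal ", paste(dim(signal)[1:3], collapse = "x"),
         call. = FALSE)
  storage.mode(tissue_mask) <- "integer"
  dw <- bvals > B0_TOLERANCE
  if (any(dw)) {
    nrm <- sqrt(rowSums(bvecs[dw, , drop = FALSE]^2))
    if (any(abs(nrm - 1) > 1e-4))
      stop("bvecs rows with b > ", B0_TOLERANCE, " s/mm^2 must be unit norm",
           call. = FALSE)
  }
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3L)
  structure(
    list(signal = signal, bvals = bvals, bvecs = bvecs,
         tissue_mask = tissue_mask, voxel_size = as.numeric(voxel_size),
         subject_id = as.character(subject_id),
         normalized = normalized),
    class = "dwi_volume")
}

#' @export
print.dwi_volume <- function(x, ...) {
  d <- dim(x$signal)
  cat("<dwi_volume> ", x$subject_id, "\n", sep = "")
  cat("  grid    : ", paste(d[1:3], collapse = " x "), " voxels, ",
      d[4], " channel(s)\n", sep = "")
  cat("  b-values: ", paste(unique(round(x$bvals)), collapse = ", "),
      " s/mm^2\n", sep = "")
  cat("  tissue  : WM ", sum(x$tissue_mask == TISSUE_WM),
      " | GM ", sum(x$tissue_mask == TISSUE_GM),
      " | CSF ", sum(x$tissue_mask == TISSUE_CSF), " voxels\n", sep = "")
  cat("  normalized: ", ifelse(is.na(x$normalized), "no", x$normalized),
      "\n", sep = "")
  invisible(x)
}

#' Does the volume carry an unweighted (b ~ 0) channel?
#' @param vol a [dwi_volume()].
#' @return logical scalar.
#' @export
has_b0 <- function(vol) any(vol$bvals <= B0_TOLERANCE)

#' Logical mask of in-brain voxels (any non-background tissue label)
#' @param vol a [dwi_volume()] or a 3D tissue label array.
#' @return 3D logical array.
#' @export
brain_mask <- function(vol) {
  labels <- if (inherits(vol, "dwi_volume")) vol$tissue_mask else as.array(vol)
  labels != TISSUE_BACKGROUND
}

#' Evaluation mask: white and gray matter only
#'
#' Scoring and thresholding are confined to parenchyma: CSF/ventricles and
#' background are excluded, mirroring evaluation restricted to white or gray
#' matter in registered diffusion space.
#'
#' @inheritParams brain_mask
#' @return 3D logical array, `TRUE` only where the label is WM or GM.
#' @export
evaluation_mask <- function(vol) {
  labels <- if (inherits(vol, "dwi_volume")) vol$tissue_mask else as.array(vol)
  labels == TISSUE_WM | labels == TISSUE_GM
}

#' Read a diffusion-weighted dataset from disk
#'
#' Loads a NIfTI 4D image, FSL-style `.bval`/`.bvec` text files (b-values on
#' one line; gradient directions as three rows) and a NIfTI tissue label
#' volume, and validates them into a [dwi_volume()].
#'
#' @param path_image path to the 4D NIfTI image.
#' @param path_bval,path_bvec paths to the FSL gradient table files.
#' @param path_mask path to the NIfTI tissue label volume.
#' @param subject_id identifier stored on the volume.
#' @return A validated [dwi_volume()].
#' @export
read_dwi <- function(path_image, path_bval, path_bvec, path_mask,
                     subject_id = sub("\\.nii(\\.gz)?$", "", basename(path_image))) {
  for (p in c(path_image, path_bval, path_bvec, path_mask))
    if (!file.exists(p)) stop("file not found: ", p, call. = FALSE)
  img <- RNifti::readNifti(path_image)
  arr <- as.array(img)
  if (length(dim(arr)) == 3L) dim(arr) <- c(dim(arr), 1L)
  bvals <- scan(path_bval, quiet = TRUE)
  bvec_rows <- as.matrix(read.table(path_bvec))
  if (nrow(bvec_rows) != 3L)
    stop("bvec file must have 3 rows (FSL convention); got ",
         nrow(bvec_rows), call. = FALSE)
  bvecs <- t(bvec_rows)
  mask <- as.array(RNifti::readNifti(path_mask))
  vol <- dwi_volume(arr, bvals, bvecs, mask, subject_id = subject_id)
  attr(vol, "affine") <- RNifti::xform(img)
  vol
}

#' Write a diffusion-weighted dataset to disk
#'
#' Writes `<prefix>.nii.gz`, `<prefix>.bval`, `<prefix>.bvec` (FSL 3-row
#' layout) and `<prefix>_labels.nii.gz`.
#'
#' @param vol a [dwi_volume()].
#' @param prefix output path prefix.
#' @return The prefix, invisibly.
#' @export
write_dwi <- function(vol, prefix) {
  dir.create(dirname(prefix), showWarnings = FALSE, recursive = TRUE)
  RNifti::writeNifti(RNifti::asNifti(vol$signal), paste0(prefix, ".nii.gz"))
  writeLines(paste(format(vol$bvals, trim = TRUE), collapse = " "),
             paste0(prefix, ".bval"))
  write.table(t(vol$bvecs), paste0(prefix, ".bvec"),
              row.names = FALSE, col.names = FALSE)
  RNifti::writeNifti(RNifti::asNifti(vol$tissue_mask),
                     paste0(prefix, "_labels.nii.gz"))
  invisible(prefix)
}

#' Normalize diffusion signal to attenuations in \[0, 1\]
#'
#' The models consume attenuation values in \[0, 1\] (sigmoid-output networks
#' require this). `b0-ratio` divides every diffusion-weighted channel by the
#' unweighted (b ~ 0) channel inside the brain mask and clips to \[0, 1\];
#' any b0 channels are consumed in the process and dropped from the output,
#' so the result carries only the C diffusion-weighted channels that the
#' networks see. `global-max` divides all channels by the maximum in-brain
#' value (also dropping b0 channels for a consistent contract).
#'
#' @param vol a raw [dwi_volume()].
#' @param mode `"b0-ratio"` (default when a b0 channel exists) or
#'   `"global-max"`.
#' @return A normalized [dwi_volume()] with only diffusion-weighted channels.
#' @export
normalize_attenuation <- function(vol,
                                  mode = if (has_b0(vol)) "b0-ratio" else "global-max") {
  mode <- match.arg(mode, c("b0-ratio", "global-max"))
  is_b0 <- vol$bvals <= B0_TOLERANCE
  bmask <- brain_mask(vol)
  sig <- vol$signal
  d <- dim(sig)
  if (mode == "b0-ratio") {
    if (!any(is_b0))
      stop("b0-ratio normalization requires at least one b ~ 0 channel",
           call. = FALSE)
    b0 <- if (sum(is_b0) == 1L) sig[, , , which(is_b0)] else
      apply(sig[, , , is_b0, drop = FALSE], 1:3, mean)
    n_zero <- sum(b0 <= 0 & bmask)
    if (n_zero > 0)
      message("normalize_attenuation [", vol$subject_id, "]: ", n_zero,
              " zero-valued b0 voxel(s) inside brain mask; clipped")
    denom <- pmax(b0, .Machine$double.eps)
    keep <- which(!is_b0)
    out <- sig[, , , keep, drop = FALSE]
    for (k in seq_along(keep)) {
      ch <- out[, , , k]
      ch <- ch / denom
      ch[!bmask] <- 0
      out[, , , k] <- pmin(pmax(ch, 0), 1)
    }
  } else {
    keep <- which(!is_b0)
    if (length(keep) == 0L) keep <- seq_len(d[4])
    out <- sig[, , , keep, drop = FALSE]
    mx <- max(apply(out, 4, function(ch) max(ch[bmask])))
    if (mx <= 0) mx <- 1
    for (k in seq_along(keep)) {
      ch <- out[, , , k] / mx
      ch[!bmask] <- 0
      out[, , , k] <- pmin(pmax(ch, 0), 1)
    }
  }
  dwi_volume(out, vol$bvals[keep], vol$bvecs[keep, , drop = FALSE],
             vol$tissue_mask, voxel_size = vol$voxel_size,
             subject_id = vol$subject_id, normalized = mode)
}

#' Construct an anomaly map
#'
#' A 3D scalar field of per-voxel anomaly scores. Residual-based maps have
#' declared range \[0, Inf); discriminator probability maps \[0, 1\]. Voxels
#' excluded from evaluation are `NA`.
#'
#' @param scores 3D numeric array of nonnegative scores (`NA` = excluded).
#' @param score_range length-2 numeric, declared score range.
#' @param source_model identifier of the producing model (`"dae"`,
#'   `"recdisc"`, ...).
#' @param provenance free-form list recording processing steps.
#' @return An object of class `anomaly_map`.
#' @export
anomaly_map <- function(scores, score_range = c(0, Inf),
                        source_model = "unknown", provenance = list()) {
  scores <- as.array(scores)
  if (length(dim(scores)) != 3L)
    stop("`scores` must be a 3D array", call. = FALSE)
  finite <- scores[!is.na(scores)]
  if (any(finite < 0))
    stop("anomaly scores must be nonnegative", call. = FALSE)
  if (is.finite(score_range[2]) && any(finite > score_range[2] + 1e-9))
    stop("anomaly scores exceed declared range [",
         score_range[1], ", ", score_range[2], "]", call. = FALSE)
  structure(list(scores = scores, score_range = score_range,
                 source_model = source_model, provenance = provenance),
            class = "anomaly_map")
}

#' @export
print.anomaly_map <- function(x, ...) {
  s <- x$scores[!is.na(x$scores)]
  cat("<anomaly_map> source: ", x$source_model,
      "  grid: ", paste(dim(x$scores), collapse = " x "), "\n", sep = "")
  cat("  scored voxels: ", length(s), "  range: [",
      signif(min(s), 4), ", ", signif(max(s), 4), "]\n", sep = "")
  invisible(x)
}

#' Construct a binary lesion mask
#'
#' @param voxels 3D logical array of segmented voxels.
#' @param threshold_method method that produced it (`"fixed"`, `"otsu"`,
#'   `"pooled_max"`, `"youden"`, `"dice_optimal"`, `"groundtruth"`, ...).
#' @param threshold_value numeric threshold applied, if any.
#' @param postprocessed has morphological opening been applied?
#' @return An object of class `lesion_mask`.
#' @export
lesion_mask <- function(voxels, threshold_method = "groundtruth",
                        threshold_value = NA_real_, postprocessed = FALSE) {
  voxels <- as.array(voxels)
  if (length(dim(voxels)) != 3L)
    stop("`voxels` must be a 3D array", call. = FALSE)
  storage.mode(voxels) <- "logical"
  voxels[is.na(voxels)] <- FALSE
  structure(list(voxels = voxels, threshold_method = threshold_method,
                 threshold_value = threshold_value,
                 postprocessed = postprocessed),
            class = "lesion_mask")
}

#' @export
print.lesion_mask <- function(x, ...) {
  cat("<lesion_mask> ", sum(x$voxels), " voxel(s); method: ",
      x$threshold_method,
      if (!is.na(x$threshold_value))
        paste0(" (T = ", signif(x$threshold_value, 4), ")"),
      if (x$postprocessed) "; opened" else "", "\n", sep = "")
  invisible(x)
}

#' Write an anomaly map or mask as NIfTI
#'
#' The file inherits the reference volume's geometry. Masks are stored as
#' 0/1 integers, maps as floats (out-of-mask `NA` stored as -1).
#'
#' @param x an [anomaly_map()] or [lesion_mask()].
#' @param reference a [dwi_volume()] providing the target geometry.
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_map <- function(x, reference, path) {
  arr <- if (inherits(x, "anomaly_map")) x$scores
         else if (inherits(x, "lesion_mask")) x$voxels
         else as.array(x)
  ref_shape <- dim(reference$signal)[1:3]
  if (!identical(dim(arr), ref_shape))
    stop("map shape ", paste(dim(arr), collapse = "x"),
         " does not match reference ", paste(ref_shape, collapse = "x"),
         call. = FALSE)
  if (inherits(x, "lesion_mask")) {
    out <- array(0L, dim(arr)); out[arr] <- 1L
  } else {
    out <- arr
    out[is.na(out)] <- -1
  }
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  RNifti::writeNifti(RNifti::asNifti(out), path)
  invisible(path)
}

#' @rdname write_map
#' @export
write_mask <- write_map

#' Read an anomaly map written by [write_map()]
#' @param path NIfTI path.
#' @inheritParams anomaly_map
#' @return An [anomaly_map()]; stored -1 values become `NA`.
#' @export
read_map <- function(path, score_range = c(0, Inf), source_model = "unknown") {
  arr <- as.array(RNifti::readNifti(path))
  arr[arr < 0] <- NA_real_
  anomaly_map(arr, score_range = score_range, source_model = source_model)
}

#' Read a binary mask written by [write_mask()]
#' @param path NIfTI path.
#' @return A [lesion_mask()].
#' @export
read_mask <- function(path) {
  arr <- as.array(RNifti::readNifti(path))
  lesion_mask(arr > 0.5, threshold_method = "file")
}
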