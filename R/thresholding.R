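# Threshold selection (fixed, Otsu, pooled-maximum, Youden, Dice-optimal),
# binarization, and 3D morphological opening. The two supervised methods
# (Youden, Dice-optimal) require a groundtruth mask and exist only to
# compare model architectures on equal footing.

masked_scores <- function(map) {
  s <- if (inherits(map, "anomaly_map")) map$scores else as.array(map)
  s[!is.na(s)]
}

# Candidate cuts for supervised threshold scans: midpoints between
# consecutive unique score values (exact below `max_exact` voxels, else a
# quantile grid). Binarization uses strict ">", so a midpoint cut cleanly
# separates its neighbors.
candidate_thresholds <- function(values, max_exact = 1e5, grid_size = 512L) {
  u <- sort(unique(values))
  if (length(u) > max_exact)
    u <- unique(quantile(values, probs = seq(0, 1, length.out = grid_size),
                         names = FALSE, type = 7))
  if (length(u) == 1L) return(u)
  c(u[1] - 1, (u[-length(u)] + u[-1]) / 2)
}

#' Pre-fixed classification threshold per model family
#'
#' 0.5 for the RecDiscNet (halving the \[0, 1\] discrimination output
#' range) and 0.3 for the DAE (sensitive to small residual deviations).
#'
#' @param model_kind `"recdisc"` or `"dae"`.
#' @param value optional override, passed through unchanged.
#' @return scalar threshold.
#' @export
fixed_threshold <- function(model_kind = c("recdisc", "dae"), value = NULL) {
  if (!is.null(value)) return(value)
  switch(match.arg(model_kind), recdisc = 0.5, dae = 0.3)
}

#' Otsu's threshold over the masked score histogram
#'
#' Builds an `n_bins` histogram over the masked score range and returns the
#' bin edge maximizing the between-class variance
#' `w0 w1 (mu0 - mu1)^2`; ties resolve to the lowest qualifying edge.
#'
#' @param map an [anomaly_map()] (possibly restricted) or numeric values.
#' @param n_bins histogram bin count (default 256).
#' @return scalar threshold.
#' @export
otsu_threshold <- function(map, n_bins = 256L) {
  v <- masked_scores(map)
  if (length(unique(v)) < 2L)
    stop("Otsu threshold requires at least 2 distinct score values",
         call. = FALSE)
  rng <- range(v)
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  counts <- tabulate(pmin(findInterval(v, edges, rightmost.closed = TRUE),
                          n_bins), nbins = n_bins)
  mids <- (edges[-1] + edges[-length(edges)]) / 2
  w <- counts / sum(counts)
  cw0 <- cumsum(w)
  cmu <- cumsum(w * mids)
  mu_tot <- cmu[n_bins]
  w0 <- cw0[-n_bins]
  w1 <- 1 - w0
  mu0 <- cmu[-n_bins] / w0
  mu1 <- (mu_tot - cmu[-n_bins]) / w1
  bcv <- w0 * w1 * (mu0 - mu1)^2
  bcv[!is.finite(bcv)] <- -Inf
  t_idx <- which.max(bcv)            # which.max takes the first (lowest) tie
  edges[t_idx + 1L]
}

# 3D summed-area table lookup of window sums: sums of all k^3 windows at
# valid positions (no padding).
cumsum3 <- function(a) {
  a <- apply(a, c(2, 3), cumsum)                    # along axis 1
  a <- aperm(apply(a, c(1, 3), cumsum), c(2, 1, 3)) # along axis 2
  aperm(apply(a, c(1, 2), cumsum), c(2, 3, 1))      # along axis 3
}

window_means_3d <- function(arr, k) {
  d <- dim(arr)
  cs <- cumsum3(arr)
  # pad the cumulative table with a leading zero plane per axis
  csp <- array(0, d + 1L)
  csp[-1, -1, -1] <- cs
  nx <- d[1] - k + 1L; ny <- d[2] - k + 1L; nz <- d[3] - k + 1L
  i0 <- seq_len(nx); j0 <- seq_len(ny); l0 <- seq_len(nz)
  i1 <- i0 + k; j1 <- j0 + k; l1 <- l0 + k
  s <- csp[i1, j1, l1, drop = FALSE] -
    csp[i0, j1, l1, drop = FALSE] - csp[i1, j0, l1, drop = FALSE] -
    csp[i1, j1, l0, drop = FALSE] +
    csp[i0, j0, l1, drop = FALSE] + csp[i0, j1, l0, drop = FALSE] +
    csp[i1, j0, l0, drop = FALSE] - csp[i0, j0, l0, drop = FALSE]
  s / k^3
}

#' Pooled-maximum threshold
#'
#' `T = max(I * f_local)`: the map is pooled with a cubic local-average
#' kernel of edge length `kernel` and the global maximum of the pooled
#' image is the threshold. Only fully supported (valid) window positions
#' are considered — no padding, so the maximum is never diluted at the
#' brain edge. Unscored (`NA`) voxels count as 0 in the average.
#'
#' @param map an [anomaly_map()] or 3D array.
#' @param kernel window edge length in voxels (16 at full acquisition
#'   scale; scale down proportionally for smaller grids).
#' @param mode `"sliding"` (stride 1, default) or `"block"`
#'   (non-overlapping windows).
#' @return scalar threshold.
#' @export
pooled_max_threshold <- function(map, kernel = 16L, mode = c("sliding", "block")) {
  mode <- match.arg(mode)
  s <- if (inherits(map, "anomaly_map")) map$scores else as.array(map)
  s[is.na(s)] <- 0
  d <- dim(s)
  k <- as.integer(kernel)
  if (any(d < k))
    stop("map extent ", paste(d, collapse = "x"),
         " is smaller than the pooling kernel ", k, call. = FALSE)
  wm <- window_means_3d(s, k)
  if (mode == "block") {
    ix <- seq(1L, d[1] - k + 1L, by = k)
    iy <- seq(1L, d[2] - k + 1L, by = k)
    iz <- seq(1L, d[3] - k + 1L, by = k)
    wm <- wm[ix, iy, iz, drop = FALSE]
  }
  max(wm)
}

# TPR/FPR at every candidate cut, vectorized: with scores sorted
# decreasing, position i gives the operating point of threshold just below
# score_(i).
roc_curve_points <- function(scores, labels) {
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  tp <- cumsum(y); fp <- cumsum(!y)
  n_pos <- tp[length(tp)]; n_neg <- fp[length(fp)]
  keep <- c(s[-1] != s[-length(s)], TRUE)  # last index of each tied block
  data.frame(threshold = s[keep], tpr = tp[keep] / n_pos,
             fpr = fp[keep] / n_neg)
}

#' Youden's-index threshold (supervised)
#'
#' Scans all candidate cuts (midpoints between consecutive unique scores)
#' and returns the one maximizing `J = TPR - FPR`; ties resolve to the
#' lowest threshold (highest sensitivity). For perfectly separated classes
#' this is the midpoint of the gap.
#'
#' @param map an [anomaly_map()] or numeric scores (`NA` excluded).
#' @param groundtruth a [lesion_mask()] or logical array/vector aligned
#'   with the scores.
#' @return scalar threshold.
#' @export
youden_threshold <- function(map, groundtruth) {
  v <- align_scores_labels(map, groundtruth)
  if (!any(v$y) || all(v$y))
    stop("groundtruth must contain both classes", call. = FALSE)
  cand <- candidate_thresholds(v$s)
  j <- vapply(cand, function(t) {
    pred <- v$s > t
    mean(pred[v$y]) - mean(pred[!v$y])
  }, numeric(1))
  cand[which.max(j)]
}

#' Dice-optimal threshold (supervised)
#'
#' Exhaustive scan over candidate cuts maximizing the Dice coefficient of
#' the un-postprocessed binarization against the groundtruth.
#'
#' @inheritParams youden_threshold
#' @return scalar threshold.
#' @export
dice_optimal_threshold <- function(map, groundtruth) {
  v <- align_scores_labels(map, groundtruth)
  if (!any(v$y) || all(v$y))
    stop("groundtruth must contain both classes", call. = FALSE)
  cand <- candidate_thresholds(v$s)
  d <- vapply(cand, function(t) {
    pred <- v$s > t
    denom <- sum(pred) + sum(v$y)
    if (denom == 0) 1 else 2 * sum(pred & v$y) / denom
  }, numeric(1))
  cand[which.max(d)]
}

# Extract aligned (scores, labels) vectors from map-like and mask-like
# inputs, dropping unscored voxels.
align_scores_labels <- function(map, groundtruth) {
  s <- if (inherits(map, "anomaly_map")) as.vector(map$scores) else
    as.vector(unclass(map))
  y <- if (inherits(groundtruth, "lesion_mask")) as.vector(groundtruth$voxels)
       else as.logical(as.vector(groundtruth))
  if (length(s) != length(y))
    stop("scores and groundtruth lengths differ", call. = FALSE)
  keep <- !is.na(s)
  list(s = s[keep], y = y[keep])
}

#' Binarize an anomaly map at a threshold
#'
#' A voxel is positive iff its score is strictly greater than `T`;
#' unscored (`NA`) voxels are always negative.
#'
#' @param map an [anomaly_map()].
#' @param threshold scalar cut.
#' @param method label recorded in the mask provenance.
#' @return A [lesion_mask()].
#' @export
binarize <- function(map, threshold, method = "fixed") {
  stopifnot(inherits(map, "anomaly_map"))
  vox <- map$scores > threshold
  vox[is.na(vox)] <- FALSE
  lesion_mask(vox, threshold_method = method, threshold_value = threshold)
}

# Binary erosion by a k^3 cube: minimum over all shifts in the structuring
# element (out-of-bounds treated as background).
shift_mask <- function(m, dx, dy, dz, fill) {
  d <- dim(m)
  out <- array(fill, d)
  sx <- max(1, 1 + dx):min(d[1], d[1] + dx)
  sy <- max(1, 1 + dy):min(d[2], d[2] + dy)
  sz <- max(1, 1 + dz):min(d[3], d[3] + dz)
  out[sx, sy, sz] <- m[sx - dx, sy - dy, sz - dz]
  out
}

erode3 <- function(m, r) {
  out <- m
  for (dx in -r:r) for (dy in -r:r) for (dz in -r:r) {
    if (dx == 0 && dy == 0 && dz == 0) next
    out <- out & shift_mask(m, dx, dy, dz, FALSE)
  }
  out
}

dilate3 <- function(m, r) {
  out <- m
  for (dx in -r:r) for (dy in -r:r) for (dz in -r:r) {
    if (dx == 0 && dy == 0 && dz == 0) next
    out <- out | shift_mask(m, dx, dy, dz, FALSE)
  }
  out
}

#' Morphological opening of a binary lesion mask
#'
#' Erosion followed by dilation with a full cubic structuring element
#' (default side length 3), removing isolated misclassified voxels while
#' preserving solid structures. Idempotent and anti-extensive.
#'
#' @param mask a [lesion_mask()] or 3D logical array.
#' @param side structuring-element edge length (odd; default 3).
#' @return An opened [lesion_mask()] with `postprocessed = TRUE`.
#' @export
morphological_opening <- function(mask, side = 3L) {
  m <- if (inherits(mask, "lesion_mask")) mask$voxels else as.array(mask) > 0
  r <- (as.integer(side) - 1L) %/% 2L
  opened <- dilate3(erode3(m, r), r)
  lesion_mask(opened,
              threshold_method = if (inherits(mask, "lesion_mask"))
                mask$threshold_method else "unknown",
              threshold_value = if (inherits(mask, "lesion_mask"))
                mask$threshold_value else NA_real_,
              postprocessed = TRUE)
}

#' Select a threshold by any of the five strategies
#'
#' Convenience dispatcher used by the evaluation harness and the CLI.
#'
#' @param map an [anomaly_map()].
#' @param method one of `"fixed"`, `"otsu"`, `"pooled_max"`, `"youden"`,
#'   `"dice_optimal"`.
#' @param model_kind for `"fixed"`: `"dae"` or `"recdisc"`.
#' @param groundtruth required for the supervised methods.
#' @param kernel pooled-max kernel edge length.
#' @param n_bins Otsu bin count.
#' @param value fixed-threshold override.
#' @return scalar threshold.
#' @export
select_threshold <- function(map,
                             method = c("fixed", "otsu", "pooled_max",
                                        "youden", "dice_optimal"),
                             model_kind = "dae", groundtruth = NULL,
                             kernel = 16L, n_bins = 256L, value = NULL) {
  method <- match.arg(method)
  if (method %in% c("youden", "dice_optimal") && is.null(groundtruth))
    stop("supervised method '", method, "' requires a groundtruth mask",
         call. = FALSE)
  switch(method,
         fixed = fixed_threshold(model_kind, value),
         otsu = otsu_threshold(map, n_bins),
         pooled_max = pooled_max_threshold(map, kernel),
         youden = youden_threshold(map, groundtruth),
         dice_optimal = dice_optimal_threshold(map, groundtruth))
}
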