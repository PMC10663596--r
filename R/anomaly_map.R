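# Residual-map construction and evaluation-mask restriction. The DAE
# anomaly score at a voxel is the absolute value of the channel-summed
# signed residual — summing before taking the absolute value lets
# zero-mean per-channel noise cancel, which a per-channel |.| would not.

#' Channel-summed absolute residual map
#'
#' `score(v) = | sum_c (output(v, c) - input(v, c)) |`: signed residuals
#' are summed over the C diffusion channels first, and the absolute value
#' is taken after the summation (not per channel).
#'
#' @param input,output equal-shaped 4D arrays (or [dwi_volume()] /
#'   reconstruction pairs).
#' @return An [anomaly_map()] with `score_range = c(0, Inf)` and the channel
#'   count recorded in its provenance.
#' @export
residual_map <- function(input, output) {
  x <- if (inherits(input, "dwi_volume")) input$signal else as.array(input)
  y <- as.array(output)
  if (!identical(dim(x), dim(y)))
    stop("input shape ", paste(dim(x), collapse = "x"),
         " does not match output ", paste(dim(y), collapse = "x"),
         call. = FALSE)
  d <- dim(x)
  delta <- matrix(y - x, prod(d[1:3]), d[4])
  scores <- array(abs(rowSums(delta)), d[1:3])
  anomaly_map(scores, score_range = c(0, Inf), source_model = "dae",
              provenance = list(channels = d[4], op = "abs-after-sum"))
}

#' Restrict an anomaly map to an evaluation mask
#'
#' Scores outside the mask become `NA` and are excluded from every
#' downstream metric and threshold. Idempotent.
#'
#' @param map an [anomaly_map()].
#' @param mask 3D logical array (e.g. from [evaluation_mask()]).
#' @return The restricted [anomaly_map()].
#' @export
restrict_map <- function(map, mask) {
  stopifnot(inherits(map, "anomaly_map"))
  mask <- as.array(mask)
  if (!identical(dim(mask), dim(map$scores)))
    stop("mask shape does not match map", call. = FALSE)
  if (!any(mask)) stop("evaluation mask is empty", call. = FALSE)
  s <- map$scores
  s[!mask] <- NA_real_
  anomaly_map(s, map$score_range, map$source_model,
              c(map$provenance, list(restricted = sum(mask))))
}

#' Min-max rescale anomaly scores to \[0, 1\]
#'
#' Rescaling is computed over the scored (non-`NA`) voxels. It is strictly
#' monotone, so ranking metrics (AUC) are unchanged; it makes fixed
#' thresholds comparable across subjects for unbounded residual maps.
#'
#' @param map an [anomaly_map()].
#' @return The rescaled [anomaly_map()] with `score_range = c(0, 1)`.
#' @export
normalize_scores <- function(map) {
  stopifnot(inherits(map, "anomaly_map"))
  s <- map$scores
  v <- s[!is.na(s)]
  rng <- range(v)
  if (diff(rng) == 0)
    stop("cannot min-max normalize a constant map", call. = FALSE)
  s <- (s - rng[1]) / diff(rng)
  anomaly_map(s, c(0, 1), map$source_model,
              c(map$provenance, list(minmax = rng)))
}

#' Quick-look section plot of an anomaly map
#'
#' @param x an [anomaly_map()].
#' @param z axial slice index (default: middle slice).
#' @param ... passed to [graphics::image()].
#' @export
plot.anomaly_map <- function(x, z = NULL, ...) {
  if (is.null(z)) z <- ceiling(dim(x$scores)[3] / 2)
  sl <- x$scores[, , z]
  graphics::image(sl, useRaster = TRUE, asp = 1, axes = FALSE,
                  main = paste0(x$source_model, " anomaly map, slice z=", z),
                  ...)
  invisible(x)
}
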