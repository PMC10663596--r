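# Masked Dice and ROC/AUC metrics, anomaly-score density summaries, and the
# k-fold cross-validation harness (7 folds over 28 healthy subjects in the
# reference setting).

as_mask_array <- function(x) {
  if (inherits(x, "lesion_mask")) x$voxels else as.array(x) > 0
}

#' Dice coefficient between two binary masks
#'
#' `2 |A n B| / (|A| + |B|)` over the evaluation mask. Two empty masks have
#' Dice 1 by convention (degenerate but possible on lesion-free phantoms).
#'
#' @param a,b [lesion_mask()]s or logical arrays.
#' @param eval_mask optional 3D logical array restricting the comparison.
#' @return scalar in \[0, 1\].
#' @export
dice <- function(a, b, eval_mask = NULL) {
  av <- as_mask_array(a); bv <- as_mask_array(b)
  if (!identical(dim(av), dim(bv)))
    stop("mask shapes differ", call. = FALSE)
  if (!is.null(eval_mask)) {
    sel <- as.vector(eval_mask)
    av <- as.vector(av)[sel]; bv <- as.vector(bv)[sel]
  }
  denom <- sum(av) + sum(bv)
  if (denom == 0) return(1)
  2 * sum(av & bv) / denom
}

#' ROC curve and AUC of an anomaly map against a groundtruth
#'
#' Voxels are pooled over the evaluation mask within one subject. AUC uses
#' the rank (Mann-Whitney) formulation, so ties are handled by rank
#' averaging; this equals the trapezoidal area under the ROC curve.
#'
#' @param map an [anomaly_map()] or numeric scores.
#' @param groundtruth a [lesion_mask()] or logical array.
#' @param eval_mask optional 3D logical array; only voxels inside it (and
#'   scored, i.e. non-`NA`) are compared.
#' @param subject_id used in error messages.
#' @return list with `roc` (data.frame threshold/tpr/fpr) and `auc`.
#' @export
roc_auc <- function(map, groundtruth, eval_mask = NULL,
                    subject_id = "subject") {
  s <- if (inherits(map, "anomaly_map")) as.vector(map$scores) else
    as.vector(unclass(map))
  y <- as.vector(as_mask_array(groundtruth))
  if (length(s) != length(y))
    stop("scores and groundtruth lengths differ", call. = FALSE)
  keep <- !is.na(s)
  if (!is.null(eval_mask)) keep <- keep & as.vector(eval_mask)
  s <- s[keep]; y <- y[keep]
  n_pos <- sum(y); n_neg <- sum(!y)
  if (n_pos == 0L || n_neg == 0L)
    stop("groundtruth for ", subject_id,
         " contains a single class inside the evaluation mask", call. = FALSE)
  r <- rank(s)                       # average ranks on ties
  auc <- (sum(r[y]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  list(roc = roc_curve_points(s, y), auc = auc)
}

#' Class-conditional anomaly-score densities
#'
#' Kernel density estimates of the anomaly scores inside and outside the
#' groundtruth, plus the difference of class means as a separation
#' statistic. Accepts one subject or lists of subjects (pooled).
#'
#' @param maps an [anomaly_map()] or list of maps.
#' @param groundtruths matching [lesion_mask()] or list.
#' @param eval_mask optional mask (or list) restricting the voxels.
#' @return An object of class `score_density`: data.frame `values`
#'   (score, class), the two `density` objects and `separation`.
#' @export
score_density <- function(maps, groundtruths, eval_mask = NULL) {
  if (inherits(maps, "anomaly_map")) maps <- list(maps)
  if (!is.list(groundtruths) || inherits(groundtruths, "lesion_mask"))
    groundtruths <- list(groundtruths)
  if (!is.null(eval_mask) && !is.list(eval_mask)) eval_mask <- list(eval_mask)
  les <- c(); hea <- c()
  for (i in seq_along(maps)) {
    s <- as.vector(maps[[i]]$scores)
    y <- as.vector(as_mask_array(groundtruths[[i]]))
    keep <- !is.na(s)
    if (!is.null(eval_mask)) keep <- keep & as.vector(eval_mask[[i]])
    les <- c(les, s[keep & y]); hea <- c(hea, s[keep & !y])
  }
  structure(list(values = data.frame(
    score = c(les, hea),
    class = rep(c("lesion", "healthy"), c(length(les), length(hea)))),
    density_lesion = if (length(les) > 1) stats::density(les) else NULL,
    density_healthy = if (length(hea) > 1) stats::density(hea) else NULL,
    separation = mean(les) - mean(hea)),
    class = "score_density")
}

#' @export
print.score_density <- function(x, ...) {
  cat("<score_density> lesion voxels: ", sum(x$values$class == "lesion"),
      "; healthy voxels: ", sum(x$values$class == "healthy"),
      "\n  class-mean separation: ", signif(x$separation, 4), "\n", sep = "")
  invisible(x)
}

#' @export
plot.score_density <- function(x, ...) {
  dl <- x$density_lesion; dh <- x$density_healthy
  graphics::plot(dh, col = "steelblue", lwd = 2,
                 main = "Anomaly-score densities",
                 xlab = "anomaly score", ...)
  if (!is.null(dl)) graphics::lines(dl, col = "firebrick", lwd = 2)
  graphics::legend("topright", c("healthy", "lesion"),
                   col = c("steelblue", "firebrick"), lwd = 2, bty = "n")
  invisible(x)
}

#' Random fold assignment for cross-validation
#'
#' Subjects are assigned to `n_folds` random subsets with sizes differing
#' by at most one; each fold serves once as the validation set.
#'
#' @param n_subjects number of subjects.
#' @param n_folds number of folds (default 7).
#' @param seed RNG seed.
#' @return An object of class `fold_split`: integer vector `assignments`
#'   (subject -> fold) plus bookkeeping.
#' @export
fold_split <- function(n_subjects, n_folds = 7L, seed = 1L) {
  if (n_subjects < n_folds)
    stop("need at least one subject per fold: ", n_subjects, " subjects for ",
         n_folds, " folds", call. = FALSE)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  base <- rep(seq_len(n_folds), length.out = n_subjects)
  assignments <- base[sample.int(n_subjects)]
  structure(list(n_subjects = as.integer(n_subjects),
                 n_folds = as.integer(n_folds),
                 assignments = assignments, seed = as.integer(seed)),
            class = "fold_split")
}

#' Train/validation indices for one fold
#' @param split a [fold_split()].
#' @param fold fold index (validation fold).
#' @return list with integer vectors `train` and `val`.
#' @export
fold_indices <- function(split, fold) {
  stopifnot(inherits(split, "fold_split"), fold >= 1, fold <= split$n_folds)
  list(train = which(split$assignments != fold),
       val = which(split$assignments == fold))
}

#' Cross-validated training and evaluation harness
#'
#' Trains one model per fold on the healthy cohort (checkpoints chosen by
#' validation loss), then scores held-out evaluation subjects: evaluation
#' subject `i` is assigned round-robin to fold `1 + (i - 1) mod n_folds`
#' and scored once by that fold's model. Per-subject Dice (raw and
#' post-processed) and AUC are aggregated as unweighted mean +/- population
#' standard deviation.
#'
#' @param cohort list of healthy subjects ([dwi_volume()]s or
#'   `simulate_dwi()` results).
#' @param eval_set list of evaluation subjects, each a list with `volume`
#'   and `groundtruth` (e.g. lesioned [make_cohort()] output; for the
#'   RecDisc view of corruption detection, [corrupt()] results also work).
#' @param model `"dae"` or `"recdisc"`.
#' @param config a [dae_config()] or [recdisc_config()].
#' @param spec [noise_spec()] (RecDisc only).
#' @param threshold_method threshold strategy for the binary metrics.
#' @param kernel pooled-max kernel edge length.
#' @param n_folds,seed cross-validation bookkeeping.
#' @param opening_side structuring-element size for post-processing.
#' @return An object of class `metric_report`.
#' @export
crossvalidate <- function(cohort, eval_set, model = c("dae", "recdisc"),
                          config, spec = NULL,
                          threshold_method = "pooled_max", kernel = 16L,
                          n_folds = 7L, seed = 1L, opening_side = 3L) {
  model <- match.arg(model)
  split <- fold_split(length(cohort), n_folds, seed)
  fits <- vector("list", n_folds)
  for (f in seq_len(n_folds)) {
    idx <- fold_indices(split, f)
    fits[[f]] <- if (model == "dae")
      train_dae(cohort, config, fold = idx)
    else train_recdisc(cohort, spec, config, fold = idx)
  }
  rows <- lapply(seq_along(eval_set), function(i) {
    f <- 1L + (i - 1L) %% n_folds
    subj <- eval_set[[i]]
    vol <- subj$volume
    gt <- subj$groundtruth %||% subj$artificial_groundtruth
    emask <- evaluation_mask(vol)
    map <- if (model == "dae") {
      rec <- reconstruct(fits[[f]], vol)
      normalize_scores(restrict_map(residual_map(vol$signal, rec), emask))
    } else {
      restrict_map(score_recdisc(fits[[f]], vol), emask)
    }
    thr <- select_threshold(map, threshold_method, model_kind = model,
                            groundtruth = gt, kernel = kernel)
    bin <- binarize(map, thr, method = threshold_method)
    post <- morphological_opening(bin, opening_side)
    auc <- roc_auc(map, gt, eval_mask = emask,
                   subject_id = vol$subject_id)$auc
    data.frame(subject = vol$subject_id, fold = f,
               method = threshold_method, threshold = thr,
               dice_raw = dice(bin, gt, emask),
               dice_post = dice(post, gt, emask),
               auc = auc)
  })
  per_subject <- do.call(rbind, rows)
  metric_report(per_subject, split = split, model = model)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Assemble a metric report from per-subject rows
#'
#' Aggregates (mean +/- population SD) are always recomputed from the
#' per-subject table, so they stay consistent with it.
#'
#' @param per_subject data.frame with columns subject, method, threshold,
#'   dice_raw, dice_post, auc (and optionally fold).
#' @param split optional [fold_split()] bookkeeping.
#' @param model model label.
#' @return An object of class `metric_report`.
#' @export
metric_report <- function(per_subject, split = NULL, model = "unknown") {
  pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
  agg <- data.frame(
    metric = c("dice_raw", "dice_post", "auc"),
    mean = c(mean(per_subject$dice_raw), mean(per_subject$dice_post),
             mean(per_subject$auc)),
    sd = c(pop_sd(per_subject$dice_raw), pop_sd(per_subject$dice_post),
           pop_sd(per_subject$auc)))
  structure(list(per_subject = per_subject, aggregate = agg,
                 split = split, model = model),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat("<metric_report> model: ", x$model, " (", nrow(x$per_subject),
      " subject(s))\n", sep = "")
  for (i in seq_len(nrow(x$aggregate)))
    cat(sprintf("  %-10s %.3f +/- %.2f\n", x$aggregate$metric[i],
                x$aggregate$mean[i], x$aggregate$sd[i]))
  invisible(x)
}

#' @export
as.data.frame.metric_report <- function(x, ...) x$per_subject
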