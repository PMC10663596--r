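# Desk-scale end-to-end study: train both anomaly-detection models on a
# synthetic healthy cohort and evaluate them on held-out lesioned (DAE) and
# corrupted (RecDisc) phantoms. This mirrors the full-scale experimental
# design — 28 healthy training subjects, evaluation restricted to WM/GM,
# pooled-maximum thresholding, morphological post-processing — at a grid
# and epoch budget that runs on one CPU.

#' Run the phantom-scale anomaly-detection study end to end
#'
#' Generates a healthy training cohort and held-out evaluation phantoms,
#' trains the denoising VAE and the RecDiscNet, and computes the headline
#' metrics: per-subject lesion AUC and pooled-max/postprocessed Dice for
#' the DAE, and corruption AUC plus in/out-of-patch mean probability for
#' the RecDiscNet.
#'
#' The defaults are the desk-scale study conditions: 32 x 32 x 20 voxel
#' phantoms with 8 diffusion channels, 28 healthy subjects, a 16-dim
#' latent / 8-16 channel DAE trained 50 epochs, a RecDiscNet trained 12
#' epochs with mix/half injection and x4 augmentation, and a pooled-max
#' kernel of 8 voxels.
#'
#' @param seed master seed for all randomness.
#' @param n_train healthy training subjects.
#' @param n_eval held-out evaluation subjects (lesioned and corrupted).
#' @param dae_epochs,recdisc_epochs training epochs per model.
#' @param kernel pooled-max kernel edge length at phantom scale.
#' @param spec injection recipe for the RecDiscNet.
#' @param config_template [phantom_config()] template for all subjects.
#' @param verbose print training progress?
#' @return list with `dae` and `recdisc` per-subject data.frames, the two
#'   fits, and a `summary` named vector of the headline numbers.
#' @export
phantom_study <- function(seed = 1L, n_train = 28L, n_eval = 6L,
                          dae_epochs = 50L, recdisc_epochs = 12L,
                          kernel = 8L,
                          spec = noise_spec("mix", "half", "mix"),
                          config_template = phantom_config(),
                          verbose = FALSE) {
  seed <- as.integer(seed)
  cohort <- make_cohort(n_train, config_template, seed = seed)
  lesioned <- make_cohort(n_eval, config_template, seed = seed + 1000L,
                          lesioned = TRUE)

  dae_cfg <- dae_config(latent_dim = 16L, channels = c(8L, 16L),
                        epochs = dae_epochs, batch_size = 4L,
                        lr = 3e-3, lr_decay = 0.97, seed = seed)
  dae_fit <- train_dae(cohort, dae_cfg, verbose = verbose)
  dae_rows <- do.call(rbind, lapply(lesioned, function(s) {
    emask <- evaluation_mask(s$volume)
    rec <- reconstruct(dae_fit, s$volume)
    map <- normalize_scores(restrict_map(residual_map(s$volume$signal, rec),
                                         emask))
    thr <- pooled_max_threshold(map, kernel)
    bin <- binarize(map, thr, method = "pooled_max")
    post <- morphological_opening(bin)
    data.frame(subject = s$volume$subject_id,
               threshold = thr,
               dice_raw = dice(bin, s$groundtruth, emask),
               dice_post = dice(post, s$groundtruth, emask),
               auc = roc_auc(map, s$groundtruth, emask,
                             subject_id = s$volume$subject_id)$auc)
  }))

  rd_cfg <- recdisc_config(latent_dim = 16L, channels = c(8L, 16L),
                           disc_channels = c(8L, 16L),
                           epochs = recdisc_epochs, batch_size = 4L,
                           lr = 2e-3, lr_decay = 0.97, augment_n = 4L,
                           seed = seed)
  rd_fit <- train_recdisc(cohort, spec, rd_cfg, verbose = verbose)
  heldout <- make_cohort(n_eval, config_template, seed = seed + 2000L)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed + 3000L)
  rd_rows <- do.call(rbind, lapply(heldout, function(s) {
    cv <- corrupt(s$volume, spec)
    while (sum(cv$artificial_groundtruth$voxels &
                 evaluation_mask(s$volume)) == 0)
      cv <- corrupt(s$volume, spec)
    emask <- evaluation_mask(s$volume)
    map <- score_recdisc(rd_fit, cv$volume)
    gt <- cv$artificial_groundtruth$voxels
    bm <- brain_mask(s$volume)
    thr <- fixed_threshold("recdisc")
    bin <- binarize(restrict_map(map, emask), thr)
    data.frame(subject = s$volume$subject_id,
               auc = roc_auc(restrict_map(map, emask),
                             cv$artificial_groundtruth, emask,
                             subject_id = s$volume$subject_id)$auc,
               p_in = mean(map$scores[gt]),
               p_out = mean(map$scores[bm & !gt]),
               dice_fixed = dice(bin, cv$artificial_groundtruth, emask))
  }))

  summary_vec <- c(dae_auc = mean(dae_rows$auc),
                   dae_dice_pooledmax_raw = mean(dae_rows$dice_raw),
                   dae_dice_pooledmax_post = mean(dae_rows$dice_post),
                   recdisc_auc = mean(rd_rows$auc),
                   recdisc_inpatch_prob = mean(rd_rows$p_in),
                   recdisc_outpatch_prob = mean(rd_rows$p_out),
                   recdisc_dice_fixed = mean(rd_rows$dice_fixed))
  list(dae = dae_rows, recdisc = rd_rows,
       dae_fit = dae_fit, recdisc_fit = rd_fit,
       summary = summary_vec,
       conditions = list(seed = seed, n_train = n_train, n_eval = n_eval,
                         grid = config_template$grid_shape,
                         channels = config_template$n_channels,
                         kernel = kernel))
}
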