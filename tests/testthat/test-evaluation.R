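test_that("Dice handles identity, disjoint, partial overlap and emptiness", {
  d <- c(8, 8, 4)
  a <- array(FALSE, d); a[1:5, 1:5, 1] <- TRUE
  expect_equal(dice(a, a), 1)
  b <- array(FALSE, d); b[6:8, 6:8, 2] <- TRUE
  expect_equal(dice(a, b), 0)
  # |A| = |B| = 100 with overlap 50 -> 0.5
  a2 <- array(FALSE, d); a2[seq_len(100)] <- TRUE
  b2 <- array(FALSE, d); b2[51:150] <- TRUE
  expect_equal(dice(a2, b2), 0.5)
  expect_equal(dice(array(FALSE, d), array(FALSE, d)), 1)
  # restriction: voxels outside the evaluation mask are invisible
  em <- array(FALSE, d); em[1:5, 1:5, 1] <- TRUE
  expect_equal(dice(a, b, em), 0)   # inside em only a has voxels
  em2 <- array(FALSE, d); em2[, , 3:4] <- TRUE
  expect_equal(dice(a, b, em2), 1)  # both empty inside em2
})

test_that("AUC equals the O(n^2) Mann-Whitney oracle including ties", {
  # perfect separation
  s <- c(rep(0.1, 15), rep(0.9, 15))
  y <- c(rep(FALSE, 15), rep(TRUE, 15))
  expect_equal(roc_auc(s, y)$auc, 1)
  # all-tied scores -> 0.5 by the rank-averaging convention
  expect_equal(roc_auc(rep(0.5, 30), y)$auc, 0.5)
  # toy instances vs brute force, with deliberate ties from rounding
  set.seed(60)
  for (i in 1:10) {
    s <- round(runif(30), 1)
    y <- runif(30) < 0.4
    if (!any(y) || all(y)) next
    expect_equal(roc_auc(s, y)$auc, auc_bruteforce(s, y), tolerance = 1e-12)
  }
  # invariance under strictly monotone transforms
  s <- runif(50); y <- runif(50) < 0.5
  if (any(y) && !all(y)) {
    expect_equal(roc_auc(exp(3 * s), y)$auc, roc_auc(s, y)$auc,
                 tolerance = 1e-12)
  }
  expect_error(roc_auc(runif(10), rep(TRUE, 10), subject_id = "sub-9"),
               "sub-9")
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(61)
  s <- runif(200); y <- runif(200) < 0.3
  want <- as.numeric(pROC::auc(pROC::roc(response = y, predictor = s,
                                         quiet = TRUE, direction = "<")))
  expect_equal(roc_auc(s, y)$auc, want, tolerance = 1e-9)
})

test_that("score densities separate classes and integrate to one", {
  d <- c(8, 8, 4)
  gt <- array(FALSE, d); gt[1:3, 1:3, 1:2] <- TRUE
  sc <- array(0.1, d); sc[gt] <- 0.9
  sd_ <- score_density(anomaly_map(sc), lesion_mask(gt))
  expect_equal(sd_$separation, 0.8, tolerance = 1e-12)
  # densities integrate to ~1
  dl <- sd_$density_lesion
  expect_equal(sum(dl$y) * diff(dl$x[1:2]), 1, tolerance = 0.01)
  # random scores: separation near zero
  set.seed(62)
  sc2 <- array(runif(prod(d)), d)
  gt2 <- array(runif(prod(d)) < 0.5, d)
  sd2 <- score_density(anomaly_map(sc2), lesion_mask(gt2))
  expect_lt(abs(sd2$separation), 0.1)
})

test_that("7-fold split of 28 subjects gives four subjects per fold", {
  sp <- fold_split(28, 7, seed = 3)
  expect_equal(as.numeric(table(sp$assignments)), rep(4, 7))
  # each subject validated exactly once across the folds
  seen <- integer(28)
  for (f in 1:7) {
    idx <- fold_indices(sp, f)
    expect_length(intersect(idx$train, idx$val), 0)
    expect_equal(sort(c(idx$train, idx$val)), 1:28)
    seen[idx$val] <- seen[idx$val] + 1L
  }
  expect_true(all(seen == 1L))
  # determinism and unequal-n balance
  expect_identical(fold_split(28, 7, seed = 3)$assignments, sp$assignments)
  sp2 <- fold_split(30, 7, seed = 1)
  expect_lte(diff(range(table(sp2$assignments))), 1)
  expect_error(fold_split(5, 7), "at least one subject")
})

test_that("metric report aggregates recompute from per-subject rows", {
  rows <- data.frame(subject = sprintf("s%02d", 1:6), fold = rep(1:3, 2),
                     method = "pooled_max", threshold = runif(6),
                     dice_raw = runif(6), dice_post = runif(6),
                     auc = runif(6))
  rep_ <- metric_report(rows, model = "dae")
  pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
  for (m in c("dice_raw", "dice_post", "auc")) {
    row <- rep_$aggregate[rep_$aggregate$metric == m, ]
    expect_equal(row$mean, mean(rows[[m]]), tolerance = 1e-12)
    expect_equal(row$sd, pop_sd(rows[[m]]), tolerance = 1e-12)
  }
})

test_that("the cross-validation harness trains per fold and scores eval subjects", {
  cohort <- small_cohort()
  eval_set <- fixture("tiny_eval_set", function() {
    make_cohort(2, phantom_config(), seed = 71L, lesioned = TRUE)
  })
  cfg <- tiny_dae_config(epochs = 4L)
  rep_ <- crossvalidate(cohort, eval_set, model = "dae", config = cfg,
                        threshold_method = "pooled_max", kernel = 8L,
                        n_folds = 3L, seed = 4L)
  expect_s3_class(rep_, "metric_report")
  expect_equal(nrow(rep_$per_subject), 2L)
  expect_true(all(rep_$per_subject$fold %in% 1:3))
  expect_true(all(rep_$per_subject$auc >= 0 & rep_$per_subject$auc <= 1))
  # aggregates consistent with rows
  expect_equal(rep_$aggregate$mean[rep_$aggregate$metric == "auc"],
               mean(rep_$per_subject$auc), tolerance = 1e-12)
})
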