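test_that("fixed thresholds follow the model family with override", {
  expect_equal(fixed_threshold("recdisc"), 0.5)
  expect_equal(fixed_threshold("dae"), 0.3)
  expect_equal(fixed_threshold("dae", value = 0.42), 0.42)
})

test_that("Otsu separates a bimodal sample and matches exhaustive search", {
  v <- c(rep(0.1, 100), rep(0.9, 100))
  t_bi <- otsu_threshold(v, n_bins = 64)
  expect_gt(t_bi, 0.1); expect_lt(t_bi, 0.9)
  set.seed(50)
  for (i in 1:5) {
    v <- runif(64)
    expect_equal(otsu_threshold(v, n_bins = 32),
                 otsu_bruteforce(v, 32), tolerance = 1e-12)
  }
  # translation invariance up to bin width
  v <- runif(200)
  t0 <- otsu_threshold(v, 128)
  t1 <- otsu_threshold(v + 5, 128)
  expect_lt(abs((t1 - 5) - t0), diff(range(v)) / 128 + 1e-12)
  expect_error(otsu_threshold(rep(0.5, 10)), "distinct")
})

test_that("pooled-max threshold equals brute-force window means", {
  # constant map: every window mean is the constant
  expect_equal(pooled_max_threshold(array(0.7, c(6, 6, 6)), 4), 0.7)
  # single hot voxel in a zero map, k = 2: the best 2^3 window mean is 1/8
  m <- array(0, c(6, 6, 6)); m[3, 3, 3] <- 1
  expect_equal(pooled_max_threshold(m, 2), 1 / 8)
  set.seed(51)
  arr <- array(runif(8 * 7 * 6), c(8, 7, 6))
  expect_equal(pooled_max_threshold(arr, 4),
               pooled_max_bruteforce(arr, 4), tolerance = 1e-10)
  # bounds: <= global max, >= any single window mean (e.g. the corner one)
  expect_lte(pooled_max_threshold(arr, 4), max(arr))
  expect_gte(pooled_max_threshold(arr, 4), mean(arr[1:4, 1:4, 1:4]))
  expect_error(pooled_max_threshold(array(0, c(3, 3, 3)), 4), "smaller")
})

test_that("Youden threshold maximizes TPR - FPR like an exhaustive scan", {
  # perfectly separated classes: gap midpoint
  s <- c(rep(0.2, 10), rep(0.8, 10))
  y <- c(rep(FALSE, 10), rep(TRUE, 10))
  expect_equal(youden_threshold(s, y), 0.5)
  # 20-voxel toy set vs brute force over all candidate cuts
  set.seed(52)
  for (i in 1:10) {
    s <- round(runif(20), 2)
    y <- runif(20) < 0.4
    if (!any(y) || all(y)) next
    cand <- dwianomaly:::candidate_thresholds(s)
    j <- vapply(cand, function(t) {
      pred <- s > t
      tpr <- sum(pred & y) / sum(y)
      fpr <- sum(pred & !y) / sum(!y)
      tpr - fpr
    }, numeric(1))
    t_got <- youden_threshold(s, y)
    expect_equal(t_got, cand[which.max(j)])
  }
  # label-independent scores give J close to 0 at any threshold
  set.seed(53)
  s <- runif(5000); y <- runif(5000) < 0.5
  t_r <- youden_threshold(s, y)
  pred <- s > t_r
  expect_lt(abs(mean(pred[y]) - mean(pred[!y])), 0.08)
})

test_that("Dice-optimal threshold matches brute force and bounds all cuts", {
  s <- c(rep(0.1, 8), rep(0.9, 8))
  y <- c(rep(FALSE, 8), rep(TRUE, 8))
  t0 <- dice_optimal_threshold(s, y)
  pred <- s > t0
  expect_equal(2 * sum(pred & y) / (sum(pred) + sum(y)), 1)
  set.seed(54)
  for (i in 1:10) {
    s <- round(runif(30), 2)
    y <- runif(30) < 0.3
    if (!any(y) || all(y)) next
    cand <- dwianomaly:::candidate_thresholds(s)
    d <- vapply(cand, function(t) {
      pred <- s > t
      den <- sum(pred) + sum(y)
      if (den == 0) 1 else 2 * sum(pred & y) / den
    }, numeric(1))
    t_got <- dice_optimal_threshold(s, y)
    pred <- s > t_got
    got_d <- 2 * sum(pred & y) / (sum(pred) + sum(y))
    expect_equal(got_d, max(d), tolerance = 1e-12)
  }
})

test_that("binarization is monotone in the threshold and mask-aware", {
  set.seed(55)
  d <- c(6, 6, 4)
  scores <- array(runif(prod(d)), d)
  mask <- array(runif(prod(d)) < 0.7, d)
  map <- restrict_map(anomaly_map(scores), mask)
  expect_equal(sum(binarize(map, 2)$voxels), 0)
  expect_identical(binarize(map, -1)$voxels, mask)
  b1 <- binarize(map, 0.3)$voxels
  b2 <- binarize(map, 0.6)$voxels
  expect_true(all(b1[b2]))          # higher threshold nests inside lower
})

test_that("morphological opening matches the brute-force cube oracle", {
  d <- c(9, 9, 9)
  # isolated voxel is removed
  m <- array(FALSE, d); m[5, 5, 5] <- TRUE
  expect_equal(sum(morphological_opening(lesion_mask(m))$voxels), 0)
  # solid 5^3 cube is preserved
  m2 <- array(FALSE, d); m2[3:7, 3:7, 3:7] <- TRUE
  op2 <- morphological_opening(lesion_mask(m2))
  expect_identical(op2$voxels, m2)
  expect_identical(morph_bruteforce(morph_bruteforce(m2, 1, "erode"), 1,
                                    "dilate"), m2)
  # random masks: equality with erosion-then-dilation brute force,
  # idempotence, anti-extensivity, never growing the foreground
  set.seed(56)
  for (i in 1:3) {
    m3 <- array(runif(prod(d)) < 0.45, d)
    got <- morphological_opening(lesion_mask(m3))$voxels
    want <- morph_bruteforce(morph_bruteforce(m3, 1, "erode"), 1, "dilate")
    expect_identical(got, want)
    expect_identical(morphological_opening(lesion_mask(got))$voxels, got)
    expect_true(all(m3[got]))
    expect_lte(sum(got), sum(m3))
  }
  expect_true(morphological_opening(lesion_mask(m2))$postprocessed)
})
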