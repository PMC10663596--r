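test_that("gradient tables have one b0 plus unit, well-spread directions", {
  gt <- make_gradient_table(6)
  expect_length(gt$bvals, 7)
  expect_equal(gt$bvals[1], 0)
  nrm <- sqrt(rowSums(gt$bvecs[-1, ]^2))
  expect_equal(nrm, rep(1, 6), tolerance = 1e-12)
  # the reference acquisition layout: 64 directions at b = 1000
  gt64 <- make_gradient_table(64, 1000)
  expect_length(gt64$bvals, 65)
  expect_true(all(gt64$bvals[-1] == 1000))
  # min pairwise angular distance > 0, including antipodal identification
  d <- gt64$bvecs[-1, ]
  cosang <- abs(tcrossprod(d))
  diag(cosang) <- 0
  expect_true(max(cosang) < 1 - 1e-6)
})

test_that("isotropic tensors give direction-independent signal", {
  cfg <- phantom_config(seed = 2L, noise_sigma = 0,
                        tensor_params = list(
                          WM = list(md = 1e-3, fa = 0),
                          GM = list(md = 1e-3, fa = 0),
                          CSF = list(md = 1e-3, fa = 0)))
  vol <- simulate_dwi(cfg)$volume
  bm <- brain_mask(vol)
  sig <- matrix(vol$signal, ncol = dim(vol$signal)[4])
  rng <- apply(sig[as.vector(bm), ], 1, function(x) diff(range(x)))
  expect_true(max(rng) < 1e-12)
  expect_equal(mean(sig[as.vector(bm), 1]), exp(-1000 * 1e-3), tolerance = 1e-10)
})

test_that("anisotropic WM attenuates most along the principal eigenvector", {
  cfg <- phantom_config(seed = 2L, noise_sigma = 0)
  vol <- simulate_dwi(cfg)$volume
  lab <- vol$tissue_mask
  gt <- make_gradient_table(cfg$n_channels, cfg$bval)
  dirs <- gt$bvecs[-1, ]
  ctr <- (dim(lab) + 1) / 2
  wm <- which(lab == 1L)
  set.seed(1)
  for (flat in sample(wm, 10)) {
    v <- arrayInd(flat, dim(lab))[1, ]
    e1 <- c(-(v[2] - ctr[2]), v[1] - ctr[1], 0)
    if (sqrt(sum(e1^2)) < 1e-8) next
    e1 <- e1 / sqrt(sum(e1^2))
    align <- abs(dirs %*% e1)
    s <- vol$signal[v[1], v[2], v[3], ]
    # signal ordering is inverse to alignment with the fiber direction
    expect_lt(s[which.max(align)], s[which.min(align)])
  }
})

test_that("phantoms are deterministic under seed and vary across seeds", {
  a <- simulate_dwi(phantom_config(seed = 9L))
  b <- simulate_dwi(phantom_config(seed = 9L))
  c <- simulate_dwi(phantom_config(seed = 10L))
  expect_identical(a$volume$signal, b$volume$signal)
  expect_false(identical(a$volume$signal, c$volume$signal))
})

test_that("increasing md_multiplier strictly decreases mean lesion signal", {
  les <- function(mult) {
    cfg <- phantom_config(seed = 4L, noise_sigma = 0,
                          lesion = lesion_spec(c(16, 16, 10), c(5, 4, 3),
                                               md_multiplier = mult))
    res <- simulate_dwi(cfg)
    mean(res$volume$signal[rep(res$groundtruth$voxels,
                               dim(res$volume$signal)[4])])
  }
  m <- vapply(c(1, 1.4, 1.8, 2.4), les, numeric(1))
  expect_true(all(diff(m) < 0))
})

test_that("lesions outside the brain are rejected", {
  cfg <- phantom_config(seed = 4L,
                        lesion = lesion_spec(c(1, 1, 1), c(3, 3, 3)))
  expect_error(simulate_dwi(cfg), "outside the brain")
})

test_that("cohorts are reproducible, distinct across subjects and seeds", {
  co1 <- make_cohort(3, phantom_config(), seed = 31L)
  co2 <- make_cohort(3, phantom_config(), seed = 31L)
  co3 <- make_cohort(3, phantom_config(), seed = 32L)
  expect_length(co1, 3)
  expect_identical(co1[[2]]$volume$signal, co2[[2]]$volume$signal)
  expect_false(identical(co1[[1]]$volume$signal, co1[[2]]$volume$signal))
  expect_false(identical(co1[[1]]$volume$signal, co3[[1]]$volume$signal))
  # all signals normalized
  for (s in co1) expect_true(all(s$volume$signal >= 0 & s$volume$signal <= 1))
  # lesioned cohorts carry nonempty groundtruth inside the brain
  col <- make_cohort(2, phantom_config(), seed = 33L, lesioned = TRUE)
  for (s in col) {
    expect_gt(sum(s$groundtruth$voxels), 0)
    expect_true(all(brain_mask(s$volume)[s$groundtruth$voxels]))
  }
})
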