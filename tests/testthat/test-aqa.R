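# Quality network: nuance computation, CAM, the loss family and the MOS
# normalisation bridge.

test_that("nuance maps are absolute differences with the expected algebra", {
  a <- rand_batch(16, 1, seed = 1)
  b <- rand_batch(16, 1, seed = 2)
  expect_true(all(compute_nuance(a, a) == 0))
  expect_equal(compute_nuance(a, b), compute_nuance(b, a))
  x <- array(0.3, c(2, 2, 3)); y <- array(0.7, c(2, 2, 3))
  expect_equal(compute_nuance(x, y), array(0.4, c(2, 2, 3)))
  expect_error(compute_nuance(a, rand_batch(8, 1)), "mismatch")
})

test_that("vectorised CAM equals an explicit double-loop oracle", {
  set.seed(20)
  for (rep in 1:5) {
    feats <- array(rnorm(4 * 4 * 8), c(4, 4, 8))
    w <- rnorm(8)
    raw <- matrix(0, 4, 4)
    for (x in 1:4) for (y in 1:4) for (j in 1:8)
      raw[x, y] <- raw[x, y] + w[j] * feats[x, y, j]
    got <- compute_cam(feats, w)
    want <- (raw - min(raw)) / (max(raw) - min(raw))
    expect_equal(got, want, tolerance = 1e-6)
  }
})

test_that("CAM handles the single-channel and cancellation cases", {
  f1 <- array(matrix(1:16, 4), c(4, 4, 1))
  got <- compute_cam(f1, 1)
  expect_equal(got, (f1[, , 1] - 1) / 15)
  # two identical channels with opposite weights cancel: constant map -> zeros
  f2 <- array(rep(rnorm(16), 2), c(4, 4, 2))
  expect_true(all(compute_cam(f2, c(1, -1)) == 0))
  expect_error(compute_cam(f2, c(1, 2, 3)), "channel count")
})

test_that("attention loss is an L1 mean with the expected bounds", {
  a <- matrix(0.2, 4, 4); b <- matrix(0.5, 4, 4)
  expect_equal(loss_cam(a, a), 0)
  expect_equal(loss_cam(a, b), 0.3)
  set.seed(4)
  x <- array(runif(4 * 4 * 3), c(4, 4, 3)); y <- array(runif(4 * 4 * 3), c(4, 4, 3))
  expect_lte(loss_cam(x, y), 1)
  expect_error(loss_cam(a, matrix(0, 2, 2)), "mismatch")
})

test_that("the sigmoid map and quality loss match closed forms", {
  expect_equal(sigmoid_map(0), 0.5)
  expect_equal(sigmoid_map(log(3)), 0.75)
  xs <- withr::with_seed(5, rnorm(20))
  expect_equal(sigmoid_map(xs) + sigmoid_map(-xs), rep(1, 20))
  expect_equal(loss_quality(0, 1), log(2), tolerance = 1e-9)
  # at q_t = 0.5 the loss is minimised at q_pre = 0 with value log 2
  grid <- seq(-3, 3, by = 0.01)
  vals <- vapply(grid, function(q) loss_quality(q, 0.5), numeric(1))
  expect_equal(grid[which.min(vals)], 0)
  expect_equal(min(vals), log(2), tolerance = 1e-4)
  # stationarity: gradient sigma(q) - q_t vanishes when target matches
  q <- 0.7; t_ <- sigmoid_map(q)
  expect_equal(sigmoid_map(q) - t_, 0)
  expect_error(loss_quality(0, 1.2), "\\[0, 1\\]")
})

test_that("the combined objective weights its parts", {
  expect_equal(loss_aqa(0.3, 0.7, phi = 1), 1.0)
  expect_equal(loss_aqa(0.3, 0.7, phi = 0), 0.7)
  expect_error(loss_aqa(0.1, 0.1, phi = -1), "non-negative")
})

test_that("MOS normalisation round-trips and composes with the weight", {
  expect_equal(normalize_mos(3), 0.5)
  expect_equal(denormalize_mos(0.5), 3)
  expect_equal(normalize_mos(c(1, 5)), c(0, 1))
  expect_equal(denormalize_mos(normalize_mos(c(1.7, 4.2))), c(1.7, 4.2))
  s <- seq(0, 1, by = 0.05)
  expect_identical(quality_weight(denormalize_mos(s)), as.integer(s >= 0.5))
  expect_error(normalize_mos(0.5), "\\[1, 5\\]")
  expect_error(denormalize_mos(2), "\\[0, 1\\]")
})

test_that("quality prediction is deterministic and shape-checked", {
  aqa <- build_aqa(aqa_config(128, stem_channels = 2, width_factor = 1 / 16,
                              fc_hidden = 8), f_last_channels = 8, seed = 6)
  x <- rand_batch(128, 2, seed = 6)
  su <- rand_batch(128, 2, seed = 7)
  fl <- withr::with_seed(8, array(runif(32 * 32 * 8 * 2), c(32, 32, 8, 2)))
  p1 <- predict_quality(aqa, x, su, fl)
  p2 <- predict_quality(aqa, x, su, fl)
  expect_identical(p1$q_pre, p2$q_pre)
  expect_length(p1$q_pre, 2)
  expect_true(all(is.finite(p1$q_pre)))
  expect_identical(dim(p1$f_cam), c(4L, 4L, 2L))   # 128 px through 5 pools
  expect_true(all(p1$f_cam >= 0 & p1$f_cam <= 1))
  expect_true(all(p1$mos >= 1 & p1$mos <= 5))
  expect_error(predict_quality(aqa, x, su), "f_last")
})

test_that("the trunk-only ablation needs no warehouse features", {
  aqa <- build_aqa(aqa_config(64, stem_channels = 2, width_factor = 1 / 16,
                              fc_hidden = 8, use_f_last = FALSE, use_cam = FALSE),
                   seed = 7)
  x <- rand_batch(64, 2, seed = 9)
  p <- predict_quality(aqa, x, array(0, dim(x)))
  expect_length(p$q_pre, 2)
  expect_true(all(is.finite(p$q_pre)))
})

test_that("the combined loss sends nonzero gradients into both stems", {
  aqa <- build_aqa(aqa_config(32, stem_channels = 2, width_factor = 1 / 32,
                              fc_hidden = 4), f_last_channels = 4, seed = 8)
  n <- 2L
  x <- rand_batch(32, n, seed = 10)
  su <- rand_batch(32, n, seed = 11)
  fl <- withr::with_seed(12, array(runif(8 * 8 * 4 * n), c(8, 8, 4, n)))
  fgt <- withr::with_seed(13, array(runif(4 * 4 * n), c(4, 4, n)))
  r <- fuseqa:::aqa_forward(aqa, x, su, fl, train = TRUE)
  bk <- fuseqa:::aqa_backward(r$aqa, (r$q_sigmoid - c(0.1, 0.9)) / n, fgt, phi = 1)
  expect_gt(sum(bk$aqa$stem_org$conv$grads$w^2), 0)
  expect_gt(sum(bk$aqa$stem_sub$conv$grads$w^2), 0)
  expect_gt(sum(bk$aqa$trunk$c1$grads$w^2), 0)
  expect_gt(sum(abs(bk$d_i_sub)), 0)
})
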