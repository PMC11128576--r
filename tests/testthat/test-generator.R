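# Generator architecture contracts and its objective components.

test_that("encoder blocks halve the resolution and trace to the warehouse", {
  blk <- withr::with_seed(1, new_down_block(3L, 32L, stride = 2L))
  x <- rand_batch(128, 1, seed = 1)
  y <- down_block(x, blk, train = TRUE)
  expect_identical(dim(y), c(64L, 64L, 32L, 1L))
  # three stride-2 blocks bring 256 px down to 32 px
  b2 <- withr::with_seed(2, new_down_block(32L, 32L, stride = 2L))
  b3 <- withr::with_seed(3, new_down_block(32L, 32L, stride = 2L))
  z <- down_block(down_block(down_block(rand_batch(256, 1, seed = 2), blk,
                                        train = TRUE), b2, train = TRUE),
                  b3, train = TRUE)
  expect_identical(dim(z)[1:2], c(32L, 32L))
  expect_error(down_block(rand_batch(32, 1)[1:31, , , , drop = FALSE], blk),
               "even spatial size")
})

test_that("a zero-weight residual refinement is the identity", {
  blk <- withr::with_seed(1, new_down_block(2L, 2L, stride = 1L))
  for (nm in c("c1", "c2", "c3")) {
    blk$res$layers[[nm]]$params$w[] <- 0
    blk$res$layers[[nm]]$params$b[] <- 0
  }
  x <- withr::with_seed(5, array(rnorm(8 * 8 * 2 * 2), c(8, 8, 2, 2)))
  got <- fuseqa:::seq_fwd(list(blk$res), x, train = TRUE)$out
  expect_equal(got, x)
})

test_that("feature-warehouse blocks preserve 32x32 shape through five repeats", {
  blk <- withr::with_seed(2, new_ufw_block(64L, 32L))
  x <- withr::with_seed(6, array(rnorm(32 * 32 * 64 * 1), c(32, 32, 64, 1)))
  y <- ufw_block(x, blk, train = TRUE)
  expect_identical(dim(y), dim(x))
  z <- x
  blocks <- withr::with_seed(3, lapply(1:5, function(i) new_ufw_block(64L, 32L)))
  for (b in blocks) z <- ufw_block(z, b, train = TRUE)
  expect_identical(dim(z), dim(x))
  expect_error(ufw_block(array(0, c(16, 16, 64, 1)), blk), "32x32")
})

test_that("a zeroed feature-warehouse block passes its input through", {
  blk <- withr::with_seed(2, new_ufw_block(4L, 8L))
  for (nm in names(blk$layers)) {
    if (!is.null(blk$layers[[nm]]$params$w)) {
      blk$layers[[nm]]$params$w[] <- 0
      blk$layers[[nm]]$params$b[] <- 0
    }
  }
  x <- withr::with_seed(7, array(rnorm(8 * 8 * 4 * 2), c(8, 8, 4, 2)))
  expect_equal(ufw_block(x, blk, train = TRUE), x)
})

test_that("the generator maps 128x128x3 to 128x128x3 inside (0, 1)", {
  gen <- build_generator(generator_config(128, base_channels = 4), seed = 9)
  x <- rand_batch(128, 1, seed = 9)
  y1 <- generate(gen, x)
  expect_identical(dim(y1), c(128L, 128L, 3L, 1L))
  expect_true(all(y1 > 0 & y1 < 1))
  expect_identical(dim(attr(y1, "f_last")), c(32L, 32L, 8L, 1L))
  # deterministic in inference mode
  y2 <- generate(gen, x)
  expect_identical(as.vector(y1), as.vector(y2))
  # single-image input keeps its shape
  xi <- array(x[, , , 1], c(128, 128, 3))
  yi <- generate(gen, xi)
  expect_identical(dim(yi), c(128L, 128L, 3L))
  expect_error(generate(gen, rand_batch(64, 1)), "128x128x3")
})

test_that("the decoder upsamples exactly twice across its four layers", {
  gen <- build_generator(generator_config(128, base_channels = 4), seed = 1)
  ups <- vapply(gen$dec, function(l) !is.null(l$up), logical(1))
  expect_identical(unname(ups), c(TRUE, TRUE, FALSE, FALSE))
  # spatial trace 32 -> 64 -> 128 -> 128 -> 128
  x <- withr::with_seed(1, array(rnorm(32 * 32 * 8), c(32, 32, 8, 1)))
  sizes <- integer(0)
  for (l in gen$dec) {
    x <- fuseqa:::seq_fwd(l, x, train = TRUE)$out
    sizes <- c(sizes, dim(x)[1])
  }
  expect_identical(sizes, c(64L, 128L, 128L, 128L))
})

test_that("content loss matches closed forms and a loop oracle", {
  a <- array(0.5, c(4, 4, 3)); b <- array(0.25, c(4, 4, 3))
  expect_equal(loss_content(a, a), 0)
  expect_equal(loss_content(a, b), 0.0625)
  x <- rand_batch(8, 2, seed = 11); y <- rand_batch(8, 2, seed = 12)
  expect_equal(loss_content(x, y), loop_mse(x, y), tolerance = 1e-6)
  expect_error(loss_content(a, array(0, c(5, 5, 3))), "mismatch")
})

test_that("generator objective evaluates its closed forms", {
  i <- rand_batch(8, 2, seed = 13)
  # D fixed at 0.5 and perfect content: log(0.5)
  v <- loss_generator(c(0.5, 0.5), i, i, theta = 0.5)
  expect_equal(as.numeric(v), log(0.5), tolerance = 1e-9)
  # theta = 0 removes the content term
  j <- rand_batch(8, 2, seed = 14)
  v0 <- loss_generator(c(0.3, 0.7), i, j, theta = 0)
  expect_equal(as.numeric(v0), mean(log(1 - c(0.3, 0.7))), tolerance = 1e-9)
  expect_equal(attr(loss_generator(c(0.5, 0.5), i, j), "content"),
               loss_content(i, j))
  expect_error(loss_generator(c(1.2, 0.5), i, i), "\\(0, 1\\)")
})

test_that("content loss backpropagates a nonzero gradient into the encoder", {
  gen <- build_generator(generator_config(32, base_channels = 2,
                                          n_ufw_repeats = 1), seed = 2)
  x <- rand_batch(32, 2, seed = 15)
  gt <- rand_batch(32, 2, seed = 16)
  r <- fuseqa:::generator_forward(gen, x, train = TRUE)
  bk <- fuseqa:::generator_backward(r$gen, 2 * (r$i_hq - gt) / 2)
  expect_gt(sum(bk$gen$enc$d1$conv$grads$w^2), 0)
  expect_gt(sum(bk$gen$dec$u4$conv$grads$w^2), 0)
})
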