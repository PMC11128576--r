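# Reference-hallucination generator: a down-sampling residual encoder, a
# stack of multi-scale feature-warehouse blocks at quarter resolution, and an
# up-sampling decoder with a sigmoid output. Given a fused image of arbitrary
# quality it produces a best-quality version of the same scene, whose
# per-pixel difference from the input ("nuance") is the reference information
# the quality network consumes.

#' Generator configuration
#'
#' The encoder runs three blocks (conv 3x3 -> LeakyReLU -> batch norm ->
#' residual refinement); the first two halve the resolution, the third works
#' at constant resolution, so a `size` input reaches `size/4` before the
#' feature-warehouse stage. Five feature-warehouse repeats operate there, and
#' a four-layer decoder (the first two layers upsample x2) restores the full
#' resolution. All kernels are 3x3.
#'
#' @param size Input image side (default 128).
#' @param base_channels Encoder width; channel plan is
#'   `3 -> b -> 2b -> 2b` (encoder), `2b` throughout the warehouse stage,
#'   `2b -> 2b -> b -> b/2 -> 3` (decoder).
#' @param n_ufw_repeats Number of feature-warehouse repeats (default 5).
#' @param leaky_slope LeakyReLU negative slope.
#' @param theta Weight of the content (MSE) term in the generator objective.
#' @param use_ufw Include the feature-warehouse stage? (`FALSE` gives the
#'   plain encoder-decoder ablation.)
#' @return A `generator_config` list.
#' @export
generator_config <- function(size = 128L, base_channels = 32L,
                             n_ufw_repeats = 5L, leaky_slope = 0.2,
                             theta = 0.5, use_ufw = TRUE) {
  stopifnot(size %% 4 == 0, base_channels >= 2, theta >= 0)
  structure(list(size = as.integer(size),
                 base_channels = as.integer(base_channels),
                 n_ufw_repeats = as.integer(n_ufw_repeats),
                 leaky_slope = leaky_slope, theta = theta,
                 ufw_size = as.integer(size) %/% 4L,
                 use_ufw = isTRUE(use_ufw)),
            class = "generator_config")
}

#' Create a down-sampling encoder block
#'
#' conv(3x3, `stride`) -> LeakyReLU -> batch norm -> residual refinement
#' (three 3x3 convs with an identity skip). With `stride = 2` the spatial
#' size halves; input spatial size must then be even.
#'
#' @param cin,cout Input/output channels.
#' @param stride Convolution stride (2 halves the resolution).
#' @param slope LeakyReLU negative slope.
#' @return Block parameters for [down_block()].
#' @export
new_down_block <- function(cin, cout, stride = 2L, slope = 0.2) {
  list(conv = layer_conv(cin, cout, stride = stride),
       act = layer_lrelu(slope), bn = layer_bn(cout), res = layer_res3(cout, slope))
}

#' Apply a down-sampling encoder block
#'
#' @param x Input batch, `(H, W, C, N)` array (or a single `(H, W, C)` image).
#' @param params Block from [new_down_block()].
#' @param train Batch-norm mode.
#' @return Output feature map array.
#' @export
down_block <- function(x, params, train = FALSE) {
  x <- as_batch(x)
  if (params$conv$stride == 2L && (dim(x)[1] %% 2L || dim(x)[2] %% 2L))
    stop("down_block with stride 2 needs an even spatial size, got ",
         dim(x)[1], "x", dim(x)[2])
  seq_fwd(params, x, train)$out
}

#' Create a multi-scale feature-warehouse block
#'
#' @param channels Channel count (preserved by the block).
#' @param size Working resolution (input and output are `size x size`).
#' @param slope LeakyReLU negative slope.
#' @return Block parameters for [ufw_block()].
#' @export
new_ufw_block <- function(channels, size = 32L, slope = 0.2) {
  layer_ufw(channels, size, slope)
}

#' Apply a feature-warehouse block
#'
#' Three parallel scale branches (full, half and quarter resolution via
#' average pooling, each conv -> LeakyReLU -> batch norm), upsampled back,
#' concatenated, merged by a 3x3 conv, and added to the block input.
#' Input must match the block's working resolution and channel count.
#'
#' @inheritParams down_block
#' @param params Block from [new_ufw_block()].
#' @return Output feature map, same shape as the input.
#' @export
ufw_block <- function(x, params, train = FALSE) {
  x <- as_batch(x)
  layer_fwd(params, x, train)$out
}

as_batch <- function(x) {
  if (is.matrix(x)) x <- array(x, c(dim(x), 1))
  if (length(dim(x)) == 3) x <- array(x, c(dim(x), 1))
  if (length(dim(x)) != 4) stop("expected an (H, W, C) image or (H, W, C, N) batch")
  x
}

#' Build a generator
#'
#' @param cfg A [generator_config()].
#' @param seed Integer seed for weight initialisation.
#' @return A `fq_generator` object.
#' @export
build_generator <- function(cfg = generator_config(), seed = 1L) {
  b <- cfg$base_channels
  withr::with_seed(as.integer(seed), {
    enc <- list(d1 = new_down_block(3L, b, 2L, cfg$leaky_slope),
                d2 = new_down_block(b, 2L * b, 2L, cfg$leaky_slope),
                d3 = new_down_block(2L * b, 2L * b, 1L, cfg$leaky_slope))
    ufw <- if (cfg$use_ufw)
      lapply(seq_len(cfg$n_ufw_repeats),
             function(i) layer_ufw(2L * b, cfg$ufw_size, cfg$leaky_slope))
    else list()
    c4 <- max(3L, b %/% 2L)
    dec <- list(
      u1 = list(up = layer_upsample(2L), conv = layer_conv(2L * b, 2L * b),
                bn = layer_bn(2L * b), act = layer_lrelu(cfg$leaky_slope)),
      u2 = list(up = layer_upsample(2L), conv = layer_conv(2L * b, b),
                bn = layer_bn(b), act = layer_lrelu(cfg$leaky_slope)),
      u3 = list(conv = layer_conv(b, c4), bn = layer_bn(c4),
                act = layer_lrelu(cfg$leaky_slope)),
      u4 = list(conv = layer_conv(c4, 3L), bn = layer_bn(3L),
                act = layer_sigmoid()))
    structure(list(cfg = cfg, enc = enc, ufw = ufw, dec = dec),
              class = "fq_generator")
  })
}

#' @export
print.fq_generator <- function(x, ...) {
  cat(sprintf(paste0("<fq_generator> %dx%d input, base %d channels, ",
                     "%d feature-warehouse repeats at %dx%d\n"),
              x$cfg$size, x$cfg$size, x$cfg$base_channels,
              if (x$cfg$use_ufw) x$cfg$n_ufw_repeats else 0L,
              x$cfg$ufw_size, x$cfg$ufw_size))
  invisible(x)
}

# full forward pass; returns updated generator (caches for backward),
# output image batch and the last warehouse-stage feature map (F_last)
generator_forward <- function(gen, x, train = TRUE) {
  for (i in seq_along(gen$enc)) {
    r <- seq_fwd(gen$enc[[i]], x, train)
    gen$enc[[i]] <- r$layers
    x <- r$out
  }
  for (i in seq_along(gen$ufw)) {
    r <- layer_fwd(gen$ufw[[i]], x, train)
    gen$ufw[[i]] <- r$layer
    x <- r$out
  }
  f_last <- x
  for (i in seq_along(gen$dec)) {
    r <- seq_fwd(gen$dec[[i]], x, train)
    gen$dec[[i]] <- r$layers
    x <- r$out
  }
  list(gen = gen, i_hq = x, f_last = f_last)
}

generator_backward <- function(gen, d_ihq) {
  for (i in rev(seq_along(gen$dec))) {
    r <- seq_bwd(gen$dec[[i]], d_ihq)
    gen$dec[[i]] <- r$layers
    d_ihq <- r$dx
  }
  for (i in rev(seq_along(gen$ufw))) {
    r <- layer_bwd(gen$ufw[[i]], d_ihq)
    gen$ufw[[i]] <- r$layer
    d_ihq <- r$dx
  }
  for (i in rev(seq_along(gen$enc))) {
    r <- seq_bwd(gen$enc[[i]], d_ihq)
    gen$enc[[i]] <- r$layers
    d_ihq <- r$dx
  }
  list(gen = gen, dx = d_ihq)
}

generator_adam <- function(gen, lr, t) {
  for (i in seq_along(gen$enc)) gen$enc[[i]] <- adam_step_layers(gen$enc[[i]], lr, t)
  gen$ufw <- adam_step_layers(gen$ufw, lr, t)
  for (i in seq_along(gen$dec)) gen$dec[[i]] <- adam_step_layers(gen$dec[[i]], lr, t)
  gen
}

#' Hallucinate the best-quality version of a fused image
#'
#' Runs the generator in inference mode. The input must match the configured
#' resolution and have three channels with values in `[0, 1]`; the output has
#' the same shape with values in `(0, 1)` (sigmoid output layer). The feature
#' map of the last warehouse repeat is attached as attribute `f_last` for the
#' quality network.
#'
#' @param gen A [build_generator()] object.
#' @param x `(H, W, 3)` image or `(H, W, 3, N)` batch.
#' @return Generated image(s), same shape as `x`, with attribute `f_last`.
#' @export
generate <- function(gen, x) {
  single <- length(dim(x)) == 3
  x <- as_batch(x)
  if (dim(x)[1] != gen$cfg$size || dim(x)[2] != gen$cfg$size || dim(x)[3] != 3)
    stop(sprintf("generator expects %dx%dx3 input, got %dx%dx%d",
                 gen$cfg$size, gen$cfg$size, dim(x)[1], dim(x)[2], dim(x)[3]))
  r <- generator_forward(gen, x, train = FALSE)
  out <- if (single) array(r$i_hq, dim(r$i_hq)[1:3]) else r$i_hq
  attr(out, "f_last") <- r$f_last
  out
}

#' Content loss: mean squared error to the group reference
#'
#' @param i_hq Generated image(s).
#' @param i_gt Ground-truth reference image(s), same shape.
#' @return Mean over all pixels, channels and batch of `(i_hq - i_gt)^2`.
#' @export
loss_content <- function(i_hq, i_gt) {
  if (!identical(dim(as_batch(i_hq)), dim(as_batch(i_gt))))
    stop("shape mismatch between generated and reference images")
  mean((i_hq - i_gt)^2)
}

#' Generator adversarial objective
#'
#' `mean(log(1 - d_fake)) + theta * loss_content(i_hq, i_gt)`: the generator
#' minimises this, pushing the discriminator's score on generated images up
#' while staying close to the reference in MSE. Scores are epsilon-clamped
#' before the log.
#'
#' @param d_fake Discriminator scores on generated images, in `(0, 1)`.
#' @param i_hq,i_gt Generated and reference image batches.
#' @param theta Content-term weight (default 0.5).
#' @param eps Log clamping epsilon.
#' @return Scalar objective with components as attributes `adversarial` and
#'   `content`.
#' @export
loss_generator <- function(d_fake, i_hq, i_gt, theta = 0.5, eps = 1e-7) {
  if (any(!is.finite(d_fake)) || any(d_fake <= 0) || any(d_fake >= 1))
    stop("discriminator scores must lie in (0, 1)")
  adv <- mean(log(pmax(1 - d_fake, eps)))
  l1 <- loss_content(i_hq, i_gt)
  out <- adv + theta * l1
  attr(out, "adversarial") <- adv
  attr(out, "content") <- l1
  out
}
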