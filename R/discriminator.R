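# Discriminator: four 3x3/stride-2/pad-1 conv layers (each halving both
# spatial dimensions), LeakyReLU + batch norm, then an independent classifier
# conv, global average pooling and a sigmoid, giving one realness score per
# image. Its adversarial objective carries a per-sample binary quality weight
# derived from the quality network's score on the generated image.

#' Discriminator configuration
#'
#' @param size Input image side (default 128).
#' @param base_channels Width of the first layer; channel plan
#'   `3 -> b -> 2b -> 4b -> 8b` over the four feature layers.
#' @param leaky_slope LeakyReLU negative slope.
#' @return A `discriminator_config` list.
#' @export
discriminator_config <- function(size = 128L, base_channels = 32L,
                                 leaky_slope = 0.2) {
  stopifnot(size %% 16 == 0, base_channels >= 2)
  structure(list(size = as.integer(size),
                 base_channels = as.integer(base_channels),
                 leaky_slope = leaky_slope),
            class = "discriminator_config")
}

#' Build a discriminator
#'
#' @param cfg A [discriminator_config()].
#' @param seed Integer seed for weight initialisation.
#' @return A `fq_discriminator` object.
#' @export
build_discriminator <- function(cfg = discriminator_config(), seed = 1L) {
  b <- cfg$base_channels
  widths <- c(3L, b, 2L * b, 4L * b, 8L * b)
  withr::with_seed(as.integer(seed), {
    layers <- list()
    for (i in 1:4) {
      layers[[paste0("c", i)]] <- layer_conv(widths[i], widths[i + 1], stride = 2L)
      layers[[paste0("a", i)]] <- layer_lrelu(cfg$leaky_slope)
      layers[[paste0("n", i)]] <- layer_bn(widths[i + 1])
    }
    layers$classifier <- layer_conv(widths[5], 1L, stride = 1L)
    structure(list(cfg = cfg, layers = layers), class = "fq_discriminator")
  })
}

#' @export
print.fq_discriminator <- function(x, ...) {
  cat(sprintf("<fq_discriminator> %dx%d input, widths %s\n",
              x$cfg$size, x$cfg$size,
              paste(x$cfg$base_channels * c(1, 2, 4, 8), collapse = "/")))
  invisible(x)
}

# forward with caches; returns per-sample scores in (0, 1)
disc_forward <- function(disc, x, train = TRUE) {
  r <- seq_fwd(disc$layers, x, train)
  disc$layers <- r$layers
  logits <- gap_fwd(r$out)[, 1]              # N
  disc$logit_dim <- dim(r$out)
  scores <- 1 / (1 + exp(-logits))
  disc$scores <- scores
  list(disc = disc, scores = scores)
}

# dscore: gradient of the objective w.r.t. the scores (length N)
disc_backward <- function(disc, dscore) {
  dlogit <- dscore * disc$scores * (1 - disc$scores)
  dmap <- gap_bwd(matrix(dlogit, ncol = 1), disc$logit_dim)
  r <- seq_bwd(disc$layers, dmap)
  disc$layers <- r$layers
  list(disc = disc, dx = r$dx)
}

disc_adam <- function(disc, lr, t) {
  disc$layers <- adam_step_layers(disc$layers, lr, t)
  disc
}

#' Score images with the discriminator
#'
#' @param disc A [build_discriminator()] object.
#' @param x `(H, W, 3)` image or `(H, W, 3, N)` batch at the configured size.
#' @return Numeric vector of realness scores in `(0, 1)`, one per image.
#' @export
discriminate <- function(disc, x) {
  x <- as_batch(x)
  if (dim(x)[1] != disc$cfg$size || dim(x)[2] != disc$cfg$size || dim(x)[3] != 3)
    stop(sprintf("discriminator expects %dx%dx3 input, got %dx%dx%d",
                 disc$cfg$size, disc$cfg$size, dim(x)[1], dim(x)[2], dim(x)[3]))
  disc_forward(disc, x, train = FALSE)$scores
}

#' Binary diagnostic-quality weight from a MOS-scale score
#'
#' Images whose predicted MOS clears 3 are considered diagnostically safe;
#' the adversarial objective treats them as acceptable targets. Returns 1
#' where `score >= 3`, else 0.
#'
#' @param score Predicted quality on the 1-5 MOS scale (vectorised).
#' @return Integer vector of 0/1 weights.
#' @export
quality_weight <- function(score) {
  if (any(!is.finite(score))) stop("quality score must be finite")
  as.integer(score >= 3)
}

#' Quality-weighted discriminator objective
#'
#' `mean(log(d_real)) + mean(log(1 - |d_fake - w|))`, epsilon-clamped inside
#' the logs. The per-sample weight `w` sets the score the discriminator is
#' rewarded for assigning to a generated image: with `w = 0` the fake term is
#' the plain adversarial `log(1 - d_fake)` (push unsafe generations towards
#' 0), while with `w = 1` it becomes `log(d_fake)`, rewarding the
#' discriminator for accepting a diagnostically safe generated image as real.
#' The discriminator takes an ascent step on this objective.
#'
#' @param d_real Scores on reference images, in `(0, 1)`.
#' @param d_fake Scores on generated images, in `(0, 1)`.
#' @param w Per-sample weights in `{0, 1}` (scalar recycled).
#' @param eps Log clamping epsilon.
#' @return Scalar objective (to be maximised).
#' @export
loss_discriminator <- function(d_real, d_fake, w = 1, eps = 1e-7) {
  if (length(w) == 1) w <- rep(w, length(d_fake))
  if (length(d_fake) != length(w)) stop("`w` must match the fake batch size")
  if (!all(w %in% c(0, 1))) stop("weights must be 0 or 1")
  mean(log(pmax(d_real, eps))) + mean(log(pmax(1 - abs(d_fake - w), eps)))
}
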