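# Attention-supervised quality network: dual stems (the fused image under
# assessment and its nuance map each get their own 3x3 conv), a VGG11-style
# conv trunk on the concatenated stems, global average pooling, concatenation
# with the channel-pooled generator warehouse features, and a two-layer fully
# connected head producing a raw quality score. A class-activation map built
# from the head's weights over the last conv features is supervised against a
# ground-truth attention map (here: the synthetic severity map).

#' Quality-network configuration
#'
#' The trunk follows the VGG11 conv plan (eight 3x3 conv stages, max pooling
#' after stages 1, 2, 4, 6 and 8) with widths scaled by `width_factor`.
#' Pooling stops once the spatial size reaches `min_spatial`, so the
#' class-activation map never degenerates below `min_spatial^2` pixels
#' (for 128-pixel input all five pools fire and the map is 4x4).
#'
#' @param size Input image side.
#' @param stem_channels Channels of each input stem conv.
#' @param width_factor Multiplier on the VGG11 widths (64, 128, 256, 256,
#'   512, 512, 512, 512); use small values for desk-scale training.
#' @param fc_hidden Hidden units of the fully connected head.
#' @param phi Weight of the attention (CAM) loss in the combined objective.
#' @param leaky_slope LeakyReLU negative slope.
#' @param use_f_last Concatenate the generator's warehouse features before
#'   the head? (`FALSE` gives the trunk-only ablation.)
#' @param use_cam Supervise the class-activation map?
#' @param min_spatial Smallest spatial size the trunk pools down to.
#' @return An `aqa_config` list.
#' @export
aqa_config <- function(size = 128L, stem_channels = 16L, width_factor = 1,
                       fc_hidden = 64L, phi = 1, leaky_slope = 0.2,
                       use_f_last = TRUE, use_cam = TRUE, min_spatial = 4L) {
  stopifnot(phi >= 0, size >= 32, stem_channels >= 1)
  widths <- pmax(4L, as.integer(round(width_factor * c(64L, 128L, 256L, 256L,
                                                       512L, 512L, 512L, 512L))))
  pool_stage <- c(1L, 2L, 4L, 6L, 8L)
  sp <- as.integer(size)
  pool_after <- logical(8)
  for (i in 1:8) {
    if (i %in% pool_stage && sp > min_spatial) {
      pool_after[i] <- TRUE
      sp <- sp %/% 2L
    }
  }
  structure(list(size = as.integer(size), stem_channels = as.integer(stem_channels),
                 widths = widths, pool_after = pool_after, cam_size = sp,
                 fc_hidden = as.integer(fc_hidden), phi = phi,
                 leaky_slope = leaky_slope, use_f_last = isTRUE(use_f_last),
                 use_cam = isTRUE(use_cam), min_spatial = as.integer(min_spatial)),
            class = "aqa_config")
}

#' Build a quality network
#'
#' @param cfg An [aqa_config()].
#' @param f_last_channels Channel count of the generator warehouse features
#'   (ignored when `cfg$use_f_last` is `FALSE`).
#' @param seed Integer seed for weight initialisation.
#' @return An `fq_aqa` object.
#' @export
build_aqa <- function(cfg = aqa_config(), f_last_channels = 64L, seed = 1L) {
  withr::with_seed(as.integer(seed), {
    s <- cfg$stem_channels
    stem_org <- list(conv = layer_conv(3L, s), act = layer_lrelu(cfg$leaky_slope))
    stem_sub <- list(conv = layer_conv(3L, s), act = layer_lrelu(cfg$leaky_slope))
    trunk <- list()
    cin <- 2L * s
    for (i in 1:8) {
      trunk[[paste0("c", i)]] <- layer_conv(cin, cfg$widths[i])
      trunk[[paste0("a", i)]] <- layer_lrelu(cfg$leaky_slope)
      trunk[[paste0("n", i)]] <- layer_bn(cfg$widths[i])
      if (cfg$pool_after[i]) trunk[[paste0("p", i)]] <- layer_maxpool2()
      cin <- cfg$widths[i]
    }
    k_t <- cfg$widths[8]
    k_u <- if (cfg$use_f_last) as.integer(f_last_channels) else 0L
    head <- list(fc1 = layer_fc(k_t + k_u, cfg$fc_hidden),
                 a = layer_lrelu(cfg$leaky_slope),
                 fc2 = layer_fc(cfg$fc_hidden, 1L))
    structure(list(cfg = cfg, stem_org = stem_org, stem_sub = stem_sub,
                   trunk = trunk, head = head, k_t = k_t, k_u = k_u),
              class = "fq_aqa")
  })
}

#' @export
print.fq_aqa <- function(x, ...) {
  cat(sprintf(paste0("<fq_aqa> %dx%d input, trunk widths %s, CAM %dx%d, ",
                     "warehouse features %s\n"),
              x$cfg$size, x$cfg$size, paste(x$cfg$widths, collapse = "/"),
              x$cfg$cam_size, x$cfg$cam_size,
              if (x$cfg$use_f_last) sprintf("%d channels", x$k_u) else "off"))
  invisible(x)
}

#' Nuance map between a hallucinated reference and the image under test
#'
#' Element-wise absolute difference `|i_hq - i_org|`: zero exactly where the
#' two images agree, symmetric in its arguments, and bounded by `[0, 1]` for
#' inputs in `[0, 1]`.
#'
#' @param i_hq,i_org Arrays of identical shape with values in `[0, 1]`.
#' @return The nuance map, same shape.
#' @export
compute_nuance <- function(i_hq, i_org) {
  if (!identical(dim(i_hq), dim(i_org)))
    stop("shape mismatch between generated and original images")
  abs(i_hq - i_org)
}

# effective head weights over the spatially-resolved trunk channels:
# the linear composition of the two fully connected layers, restricted to the
# trunk block of the concatenated feature vector
cam_weights <- function(aqa) {
  w1t <- aqa$head$fc1$params$w[seq_len(aqa$k_t), , drop = FALSE]  # k_t x m
  drop(w1t %*% aqa$head$fc2$params$w)                             # k_t
}

#' Class activation map from conv features and channel weights
#'
#' `cam(x, y) = sum_j w_j * f_j(x, y)`, min-max normalised to `[0, 1]`.
#' A constant raw map (no spatial preference) normalises to all zeros.
#'
#' @param features `h x w x k` feature array.
#' @param weights Numeric vector of length `k`.
#' @return `h x w` map in `[0, 1]`.
#' @export
compute_cam <- function(features, weights) {
  d <- dim(features)
  if (length(d) != 3 || d[3] != length(weights))
    stop("`weights` length must match the feature channel count")
  raw <- matrix(matrix(features, d[1] * d[2], d[3]) %*% weights, d[1], d[2])
  rng <- max(raw) - min(raw)
  if (rng <= 0) return(matrix(0, d[1], d[2]))
  (raw - min(raw)) / rng
}

# batched CAM with cache for backward: F (h, w, k, N) -> list(norm (h,w,N),
# raw, rng, minv)
cam_batch <- function(feats, weights) {
  d <- dim(feats)
  fm <- matrix(feats, d[1] * d[2], d[3] * d[4])
  raw <- array(0, c(d[1], d[2], d[4]))
  for (n in seq_len(d[4])) {
    cols <- (n - 1L) * d[3] + seq_len(d[3])
    raw[, , n] <- matrix(fm[, cols] %*% weights, d[1], d[2])
  }
  minv <- apply(raw, 3, min)
  rng <- apply(raw, 3, max) - minv
  norm <- raw
  for (n in seq_len(d[4])) {
    norm[, , n] <- if (rng[n] > 0) (raw[, , n] - minv[n]) / rng[n] else 0
  }
  list(norm = norm, raw = raw, rng = rng, minv = minv)
}

#' Attention supervision loss (mean absolute error)
#'
#' @param f_cam Predicted attention maps in `[0, 1]` (`h x w` or `h x w x N`).
#' @param f_gt Ground-truth maps, same shape.
#' @return Mean absolute difference.
#' @export
loss_cam <- function(f_cam, f_gt) {
  if (!identical(dim(f_cam), dim(f_gt)))
    stop("shape mismatch between predicted and ground-truth attention maps")
  mean(abs(f_cam - f_gt))
}

#' Logistic squashing of a raw quality score
#'
#' @param q_pre Raw score(s).
#' @return `1 / (1 + exp(-q_pre))`, in `(0, 1)`.
#' @export
sigmoid_map <- function(q_pre) 1 / (1 + exp(-q_pre))

#' Quality regression loss (cross-entropy against a normalised MOS target)
#'
#' Binary cross-entropy with a continuous target:
#' `-(q_t * log(sigma(q_pre)) + (1 - q_t) * log(1 - sigma(q_pre)))`,
#' averaged over the batch. Minimised exactly when `sigma(q_pre) = q_t`.
#'
#' @param q_pre Raw score(s).
#' @param q_t Target(s) in `[0, 1]` (normalised MOS).
#' @return Mean loss (non-negative).
#' @export
loss_quality <- function(q_pre, q_t) {
  if (any(q_t < 0 | q_t > 1)) stop("`q_t` must lie in [0, 1]")
  # numerically stable BCE-with-logits
  mean(pmax(q_pre, 0) - q_pre * q_t + log1p(exp(-abs(q_pre))))
}

#' Combined quality-network objective
#'
#' @param l_cam Attention loss component.
#' @param l_qa Quality regression component.
#' @param phi Attention weight (>= 0).
#' @return `phi * l_cam + l_qa`.
#' @export
loss_aqa <- function(l_cam, l_qa, phi = 1) {
  if (phi < 0) stop("`phi` must be non-negative")
  phi * l_cam + l_qa
}

#' Map a MOS in `[1, 5]` to the unit interval (and back)
#'
#' `normalize_mos` applies `(mos - 1) / 4`; `denormalize_mos` inverts it with
#' `1 + 4 * s`. A MOS of 3 (the diagnostic-safety threshold) maps to 0.5.
#'
#' @param mos MOS values in `[1, 5]`.
#' @return Values in `[0, 1]`.
#' @export
normalize_mos <- function(mos) {
  if (any(!is.finite(mos)) || any(mos < 1 | mos > 5))
    stop("`mos` must lie in [1, 5]")
  (mos - 1) / 4
}

#' @rdname normalize_mos
#' @param score01 Values in `[0, 1]`.
#' @export
denormalize_mos <- function(score01) {
  if (any(!is.finite(score01)) || any(score01 < 0 | score01 > 1))
    stop("`score01` must lie in [0, 1]")
  1 + 4 * score01
}

# full forward pass with caches. i_org/i_sub: (H, W, 3, N); f_last:
# (h, w, k_u, N) or NULL. Returns scores, CAM and the caches backward needs.
aqa_forward <- function(aqa, i_org, i_sub, f_last = NULL, train = TRUE) {
  ro <- seq_fwd(aqa$stem_org, i_org, train); aqa$stem_org <- ro$layers
  rs <- seq_fwd(aqa$stem_sub, i_sub, train); aqa$stem_sub <- rs$layers
  x <- cat_channels(ro$out, rs$out)
  rt <- seq_fwd(aqa$trunk, x, train); aqa$trunk <- rt$layers
  feats <- rt$out                               # (h', w', k_t, N)
  aqa$feat_dim <- dim(feats)
  pooled_t <- gap_fwd(feats)                    # N x k_t
  if (aqa$cfg$use_f_last) {
    if (is.null(f_last))
      stop("warehouse features (f_last) required; build with use_f_last = FALSE for the trunk-only ablation")
    aqa$flast_dim <- dim(f_last)
    pooled_u <- gap_fwd(f_last)                 # N x k_u
    conca <- cbind(pooled_t, pooled_u)
  } else {
    conca <- pooled_t
  }
  rh <- seq_fwd(aqa$head, conca, train); aqa$head <- rh$layers
  q_pre <- drop(rh$out)
  w_eff <- cam_weights(aqa)
  cam <- cam_batch(feats, w_eff)
  aqa$cache_feats <- feats
  aqa$cache_cam <- cam
  list(aqa = aqa, q_pre = q_pre, q_sigmoid = sigmoid_map(q_pre),
       f_cam = cam$norm, f_conca = conca, feats = feats)
}

# backward for phi * L_CAM + L_QA (or arbitrary upstream gradients):
# dq_pre length N; f_gt (h, w, N) or NULL disables the attention path.
# Returns gradients w.r.t. the two input images (for generator coupling).
aqa_backward <- function(aqa, dq_pre, f_gt = NULL, phi = 1) {
  rh <- seq_bwd(aqa$head, matrix(dq_pre, ncol = 1))
  aqa$head <- rh$layers
  dconca <- rh$dx                                # N x (k_t + k_u)
  dfeats <- gap_bwd(dconca[, seq_len(aqa$k_t), drop = FALSE], aqa$feat_dim)
  dflast <- NULL
  if (aqa$cfg$use_f_last && aqa$k_u > 0) {
    dflast <- gap_bwd(dconca[, aqa$k_t + seq_len(aqa$k_u), drop = FALSE],
                      aqa$flast_dim)
  }
  if (!is.null(f_gt) && phi > 0) {
    cam <- aqa$cache_cam
    d <- aqa$feat_dim
    npix <- d[1] * d[2] * d[4]
    dnorm <- phi * sign(cam$norm - f_gt) / npix   # (h, w, N)
    w_eff <- cam_weights(aqa)
    dw_eff <- numeric(aqa$k_t)
    for (n in seq_len(d[4])) {
      if (cam$rng[n] <= 0) next
      draw <- dnorm[, , n] / cam$rng[n]           # normalisation detached
      for (j in seq_len(d[3])) {
        dfeats[, , j, n] <- dfeats[, , j, n] + draw * w_eff[j]
      }
      fm <- matrix(aqa$cache_feats[, , , n], d[1] * d[2], d[3])
      dw_eff <- dw_eff + drop(crossprod(fm, as.vector(draw)))
    }
    # product rule through w_eff = W1[trunk,] %*% W2
    w1t <- aqa$head$fc1$params$w[seq_len(aqa$k_t), , drop = FALSE]
    w2 <- aqa$head$fc2$params$w
    aqa$head$fc1$grads$w[seq_len(aqa$k_t), ] <-
      aqa$head$fc1$grads$w[seq_len(aqa$k_t), ] + dw_eff %*% t(w2)
    aqa$head$fc2$grads$w <- aqa$head$fc2$grads$w + t(w1t) %*% dw_eff
  }
  rt <- seq_bwd(aqa$trunk, dfeats)
  aqa$trunk <- rt$layers
  halves <- split_channels(rt$dx, rep(aqa$cfg$stem_channels, 2))
  bo <- seq_bwd(aqa$stem_org, halves[[1]]); aqa$stem_org <- bo$layers
  bs <- seq_bwd(aqa$stem_sub, halves[[2]]); aqa$stem_sub <- bs$layers
  list(aqa = aqa, d_i_org = bo$dx, d_i_sub = bs$dx, d_f_last = dflast)
}

aqa_adam <- function(aqa, lr, t) {
  aqa$stem_org <- adam_step_layers(aqa$stem_org, lr, t)
  aqa$stem_sub <- adam_step_layers(aqa$stem_sub, lr, t)
  aqa$trunk <- adam_step_layers(aqa$trunk, lr, t)
  aqa$head <- adam_step_layers(aqa$head, lr, t)
  aqa
}

#' Predict the quality of fused images
#'
#' Runs the quality network in inference mode on the image under assessment,
#' its nuance map, and (unless disabled) the generator's warehouse features.
#'
#' @param aqa A [build_aqa()] object.
#' @param i_org `(H, W, 3)` image or `(H, W, 3, N)` batch.
#' @param i_sub Nuance map(s) from [compute_nuance()], same shape.
#' @param f_last Warehouse feature batch (attribute `f_last` of
#'   [generate()]); required unless the network was built with
#'   `use_f_last = FALSE`.
#' @return List with `q_pre` (raw scores), `q_sigmoid` (scores in `(0, 1)`),
#'   `mos` (denormalised to the 1-5 scale) and `f_cam` (attention maps,
#'   `h x w x N`).
#' @export
predict_quality <- function(aqa, i_org, i_sub, f_last = NULL) {
  i_org <- as_batch(i_org); i_sub <- as_batch(i_sub)
  if (!identical(dim(i_org), dim(i_sub)))
    stop("shape mismatch between image and nuance map")
  r <- aqa_forward(aqa, i_org, i_sub, f_last, train = FALSE)
  list(q_pre = r$q_pre, q_sigmoid = r$q_sigmoid,
       mos = denormalize_mos(r$q_sigmoid), f_cam = r$f_cam)
}
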