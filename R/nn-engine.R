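# Minimal CNN engine: explicit forward/backward passes over a small set of
# layer types, batched as (H, W, C, N) double arrays. Convolution, pooling and
# upsampling run in compiled code (src/tensor_ops.cpp); the rest is vectorised
# R. Layers are plain lists; a "network" is a named list of layers/sub-chains.
# Nothing here is exported: the networks built on top are the public surface.

he_init <- function(fan_in, n) {
  stats::rnorm(n, sd = sqrt(2 / fan_in))
}

layer_conv <- function(cin, cout, k = 3L, stride = 1L, pad = 1L, zero_init = FALSE) {
  w <- if (zero_init) matrix(0, k * k * cin, cout) else
    matrix(he_init(k * k * cin, k * k * cin * cout), k * k * cin, cout)
  list(type = "conv", params = list(w = w, b = numeric(cout)),
       stride = as.integer(stride), pad = as.integer(pad),
       cin = cin, cout = cout, k = as.integer(k))
}

layer_bn <- function(c, momentum = 0.9, eps = 1e-5) {
  list(type = "bn", params = list(gamma = rep(1, c), beta = numeric(c)),
       running_mean = numeric(c), running_var = rep(1, c),
       momentum = momentum, eps = eps, c = c)
}

layer_lrelu <- function(slope = 0.2) list(type = "lrelu", slope = slope, params = list())
layer_sigmoid <- function() list(type = "sigmoid", params = list())
layer_maxpool2 <- function() list(type = "maxpool2", params = list())
layer_avgpool <- function(f) list(type = "avgpool", f = as.integer(f), params = list())
layer_upsample <- function(f) list(type = "upsample", f = as.integer(f), params = list())

layer_fc <- function(nin, nout) {
  list(type = "fc",
       params = list(w = matrix(he_init(nin, nin * nout), nin, nout), b = numeric(nout)),
       nin = nin, nout = nout)
}

# residual refinement block: three channel-preserving 3x3 convs with leaky
# ReLUs, plus an identity skip. Zero weights make it an exact identity.
layer_res3 <- function(c, slope = 0.2) {
  list(type = "res3", slope = slope, params = list(),
       layers = list(c1 = layer_conv(c, c), a1 = layer_lrelu(slope),
                     c2 = layer_conv(c, c), a2 = layer_lrelu(slope),
                     c3 = layer_conv(c, c)))
}

# multi-scale feature-warehouse block at a fixed working resolution `size`:
# three parallel branches at size, size/2 and size/4 (average pooling in,
# nearest-neighbour upsampling out), each conv -> LeakyReLU -> BN, fused by
# channel concatenation and a 3x3 merge conv, with an identity skip from
# block input to output. The merge conv is zero-initialised so a fresh block
# starts as the identity.
layer_ufw <- function(c, size, slope = 0.2) {
  stopifnot(size %% 4 == 0)
  list(type = "ufw", size = as.integer(size), c = c, params = list(),
       layers = list(
         b1_conv = layer_conv(c, c), b1_act = layer_lrelu(slope), b1_bn = layer_bn(c),
         b2_conv = layer_conv(c, c), b2_act = layer_lrelu(slope), b2_bn = layer_bn(c),
         b3_conv = layer_conv(c, c), b3_act = layer_lrelu(slope), b3_bn = layer_bn(c),
         merge = layer_conv(3 * c, c, zero_init = TRUE)))
}

cat_channels <- function(...) {
  xs <- list(...)
  d <- dim(xs[[1]])
  cs <- vapply(xs, function(x) dim(x)[3], integer(1))
  out <- array(0, c(d[1], d[2], sum(cs), d[4]))
  at <- 0L
  for (x in xs) {
    cc <- dim(x)[3]
    out[, , at + seq_len(cc), ] <- x
    at <- at + cc
  }
  out
}

split_channels <- function(x, sizes) {
  at <- 0L
  lapply(sizes, function(cc) {
    idx <- at + seq_len(cc)
    at <<- at + cc
    x[, , idx, , drop = FALSE]
  })
}

# ---- forward/backward dispatch -------------------------------------------

layer_fwd <- function(layer, x, train = TRUE) {
  out <- switch(layer$type,
    conv = {
      layer$cache <- x
      cpp_conv2d_fwd(x, layer$params$w, layer$params$b, layer$stride, layer$pad)
    },
    bn = {
      if (train) {
        mo <- cpp_channel_moments(x)
        mu <- mo$mean
        v <- mo$var
        layer$running_mean <- layer$momentum * layer$running_mean + (1 - layer$momentum) * mu
        layer$running_var <- layer$momentum * layer$running_var + (1 - layer$momentum) * v
      } else {
        mu <- layer$running_mean
        v <- layer$running_var
      }
      inv_sd <- 1 / sqrt(v + layer$eps)
      layer$cache <- list(x = x, mu = mu, inv_sd = inv_sd, train = train)
      cpp_bn_fwd(x, layer$params$gamma, layer$params$beta, mu, inv_sd)
    },
    lrelu = {
      layer$cache <- x
      cpp_lrelu_fwd(x, layer$slope)
    },
    sigmoid = {
      y <- 1 / (1 + exp(-x))
      layer$cache <- y
      y
    },
    maxpool2 = {
      r <- cpp_maxpool2_fwd(x)
      layer$cache <- r$argmax
      r$y
    },
    avgpool = cpp_avgpool_fwd(x, layer$f),
    upsample = cpp_upsample_fwd(x, layer$f),
    fc = {
      layer$cache <- x
      sweep(x %*% layer$params$w, 2, layer$params$b, "+")
    },
    res3 = {
      r <- seq_fwd(layer$layers, x, train)
      layer$layers <- r$layers
      r$out + x
    },
    ufw = {
      s <- dim(x)[1]
      if (s != layer$size || dim(x)[2] != layer$size)
        stop(sprintf("feature-warehouse block expects %dx%d input, got %dx%d",
                     layer$size, layer$size, dim(x)[1], dim(x)[2]))
      L <- layer$layers
      f1 <- layer_fwd(L$b1_conv, x, train); L$b1_conv <- f1$layer
      f1 <- layer_fwd(L$b1_act, f1$out, train); L$b1_act <- f1$layer
      f1 <- layer_fwd(L$b1_bn, f1$out, train); L$b1_bn <- f1$layer
      x2 <- cpp_avgpool_fwd(x, 2L)
      f2 <- layer_fwd(L$b2_conv, x2, train); L$b2_conv <- f2$layer
      f2 <- layer_fwd(L$b2_act, f2$out, train); L$b2_act <- f2$layer
      f2 <- layer_fwd(L$b2_bn, f2$out, train); L$b2_bn <- f2$layer
      x3 <- cpp_avgpool_fwd(x, 4L)
      f3 <- layer_fwd(L$b3_conv, x3, train); L$b3_conv <- f3$layer
      f3 <- layer_fwd(L$b3_act, f3$out, train); L$b3_act <- f3$layer
      f3 <- layer_fwd(L$b3_bn, f3$out, train); L$b3_bn <- f3$layer
      up2 <- cpp_upsample_fwd(f2$out, 2L)
      up4 <- cpp_upsample_fwd(f3$out, 4L)
      cc <- cat_channels(f1$out, up2, up4)
      fm <- layer_fwd(L$merge, cc, train); L$merge <- fm$layer
      layer$layers <- L
      fm$out + x
    },
    stop("unknown layer type: ", layer$type))
  list(layer = layer, out = out)
}

layer_bwd <- function(layer, dout) {
  dx <- switch(layer$type,
    conv = {
      g <- cpp_conv2d_bwd(layer$cache, layer$params$w, dout, layer$stride, layer$pad)
      layer$grads <- list(w = g$dw, b = g$db)
      g$dx
    },
    bn = {
      cc <- layer$cache
      g <- cpp_bn_bwd(cc$x, dout, layer$params$gamma, cc$mu, cc$inv_sd,
                      as.integer(cc$train))
      layer$grads <- list(gamma = g$dgamma, beta = g$dbeta)
      g$dx
    },
    lrelu = cpp_lrelu_bwd(layer$cache, dout, layer$slope),
    sigmoid = dout * layer$cache * (1 - layer$cache),
    maxpool2 = cpp_maxpool2_bwd(layer$cache, dout),
    avgpool = cpp_avgpool_bwd(dout, layer$f),
    upsample = cpp_upsample_bwd(dout, layer$f),
    fc = {
      layer$grads <- list(w = crossprod(layer$cache, dout), b = colSums(dout))
      dout %*% t(layer$params$w)
    },
    res3 = {
      r <- seq_bwd(layer$layers, dout)
      layer$layers <- r$layers
      r$dx + dout
    },
    ufw = {
      L <- layer$layers
      bm <- layer_bwd(L$merge, dout); L$merge <- bm$layer
      parts <- split_channels(bm$dx, rep(layer$c, 3))
      b1 <- layer_bwd(L$b1_bn, parts[[1]]); L$b1_bn <- b1$layer
      b1 <- layer_bwd(L$b1_act, b1$dx); L$b1_act <- b1$layer
      b1 <- layer_bwd(L$b1_conv, b1$dx); L$b1_conv <- b1$layer
      d2 <- cpp_upsample_bwd(parts[[2]], 2L)
      b2 <- layer_bwd(L$b2_bn, d2); L$b2_bn <- b2$layer
      b2 <- layer_bwd(L$b2_act, b2$dx); L$b2_act <- b2$layer
      b2 <- layer_bwd(L$b2_conv, b2$dx); L$b2_conv <- b2$layer
      d3 <- cpp_upsample_bwd(parts[[3]], 4L)
      b3 <- layer_bwd(L$b3_bn, d3); L$b3_bn <- b3$layer
      b3 <- layer_bwd(L$b3_act, b3$dx); L$b3_act <- b3$layer
      b3 <- layer_bwd(L$b3_conv, b3$dx); L$b3_conv <- b3$layer
      layer$layers <- L
      b1$dx + cpp_avgpool_bwd(b2$dx, 2L) + cpp_avgpool_bwd(b3$dx, 4L) + dout
    },
    stop("unknown layer type: ", layer$type))
  list(layer = layer, dx = dx)
}

seq_fwd <- function(layers, x, train = TRUE) {
  for (i in seq_along(layers)) {
    r <- layer_fwd(layers[[i]], x, train)
    layers[[i]] <- r$layer
    x <- r$out
  }
  list(layers = layers, out = x)
}

seq_bwd <- function(layers, dout) {
  for (i in rev(seq_along(layers))) {
    r <- layer_bwd(layers[[i]], dout)
    layers[[i]] <- r$layer
    dout <- r$dx
  }
  list(layers = layers, dx = dout)
}

# ---- global average pooling over space ------------------------------------

gap_fwd <- function(x) {
  d <- dim(x)
  m <- matrix(x, d[1] * d[2], d[3] * d[4])
  matrix(colMeans(m), d[3], d[4]) |> t()  # N x C
}

gap_bwd <- function(dpooled, d) {
  # dpooled: N x C; returns (H, W, C, N)
  array(rep(t(dpooled), each = d[1] * d[2]) / (d[1] * d[2]), d)
}

# ---- Adam -----------------------------------------------------------------

adam_step_layers <- function(layers, lr, t, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    if (!is.null(l$layers)) {
      l$layers <- adam_step_layers(l$layers, lr, t, beta1, beta2, eps)
    }
    if (length(l$params) && !is.null(l$grads)) {
      if (is.null(l$adam)) l$adam <- lapply(l$params, function(p) list(m = p * 0, v = p * 0))
      for (nm in names(l$params)) {
        g <- l$grads[[nm]]
        st <- l$adam[[nm]]
        st$m <- beta1 * st$m + (1 - beta1) * g
        st$v <- beta2 * st$v + (1 - beta2) * g^2
        mhat <- st$m / (1 - beta1^t)
        vhat <- st$v / (1 - beta2^t)
        l$params[[nm]] <- l$params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
        l$adam[[nm]] <- st
      }
      l$grads <- NULL
    }
    layers[[i]] <- l
  }
  layers
}

# strip caches/grads for compact serialization
strip_layers <- function(layers) {
  for (i in seq_along(layers)) {
    layers[[i]]$cache <- NULL
    layers[[i]]$grads <- NULL
    if (!is.null(layers[[i]]$layers)) layers[[i]]$layers <- strip_layers(layers[[i]]$layers)
  }
  layers
}

param_l2 <- function(layers) {
  s <- 0
  for (l in layers) {
    if (length(l$params)) s <- s + sum(vapply(l$params, function(p) sum(p^2), numeric(1)))
    if (!is.null(l$layers)) s <- s + param_l2(l$layers)
  }
  s
}
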