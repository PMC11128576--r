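# Joint training of generator, discriminator and quality network. Each batch
# alternates D -> G -> AQA: the discriminator ascends its quality-weighted
# objective, the generator descends its adversarial + content (+ perceptual
# coupling) objective, and the quality network descends its attention +
# regression loss on nuance maps formed with the just-updated generator.

#' Training configuration
#'
#' Defaults are desk-scale: small network widths and 200 epochs so a full
#' run fits on one CPU core in minutes. The optimiser protocol is Adam with
#' an initial learning rate of 2e-4 decayed by 0.95 every 20 batches; the
#' loss weights are `theta = 0.5` (generator content term), `phi = 1`
#' (attention supervision) and `gamma = 0.01` (perceptual coupling of the
#' generator to the quality network).
#'
#' The four `use_*` switches form the ablation ladder: all off except the
#' quality network = plain VGG-style regressor; `use_gan` adds the
#' hallucinated reference and nuance input; `use_ufw` adds the multi-scale
#' feature warehouse; `use_perceptual` adds the quality weighting of the
#' discriminator and the gamma coupling; `use_cam` adds attention
#' supervision.
#'
#' @param epochs Training epochs.
#' @param batch_size Images per batch.
#' @param lr0 Initial Adam learning rate.
#' @param decay,decay_every Multiplicative LR decay applied every
#'   `decay_every` batches.
#' @param theta,phi,gamma Loss weights (see above).
#' @param n_folds Folds for [five_fold_split()].
#' @param seed Master seed (weights, shuffling, evaluation resampling).
#' @param checkpoint_metric Validation metric that selects the best epoch
#'   (`"srcc"` or `"plcc"`).
#' @param use_gan,use_ufw,use_perceptual,use_cam Ablation switches.
#' @param gen_base_channels,disc_base_channels Network widths.
#' @param stem_channels,width_factor,fc_hidden Quality-network widths.
#' @param n_ufw_repeats Feature-warehouse repeats.
#' @param eval_repeats Evaluation resampling repeats (see
#'   [evaluate_model()]).
#' @return A `train_config` list.
#' @export
train_config <- function(epochs = 200L, batch_size = 16L, lr0 = 2e-4,
                         decay = 0.95, decay_every = 20L,
                         theta = 0.5, phi = 1, gamma = 0.01,
                         n_folds = 5L, seed = 1L,
                         checkpoint_metric = c("srcc", "plcc"),
                         use_gan = TRUE, use_ufw = TRUE,
                         use_perceptual = TRUE, use_cam = TRUE,
                         gen_base_channels = 4L, disc_base_channels = 4L,
                         stem_channels = 2L, width_factor = 1 / 32,
                         fc_hidden = 8L, n_ufw_repeats = 5L,
                         eval_repeats = 1L) {
  stopifnot(lr0 > 0, decay > 0, decay <= 1, gamma >= 0, phi >= 0, theta >= 0,
            epochs >= 1, batch_size >= 2)
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 lr0 = lr0, decay = decay, decay_every = as.integer(decay_every),
                 theta = theta, phi = phi, gamma = gamma,
                 n_folds = as.integer(n_folds), seed = as.integer(seed),
                 checkpoint_metric = match.arg(checkpoint_metric),
                 use_gan = isTRUE(use_gan), use_ufw = isTRUE(use_ufw),
                 use_perceptual = isTRUE(use_perceptual), use_cam = isTRUE(use_cam),
                 gen_base_channels = as.integer(gen_base_channels),
                 disc_base_channels = as.integer(disc_base_channels),
                 stem_channels = as.integer(stem_channels),
                 width_factor = width_factor, fc_hidden = as.integer(fc_hidden),
                 n_ufw_repeats = as.integer(n_ufw_repeats),
                 eval_repeats = as.integer(eval_repeats)),
            class = "train_config")
}

#' Learning-rate schedule
#'
#' `lr0 * decay^floor(batch_index / decay_every)`.
#'
#' @param batch_index Zero-based global batch counter (vectorised).
#' @param cfg A [train_config()].
#' @return Learning rate(s).
#' @export
lr_schedule <- function(batch_index, cfg = train_config()) {
  if (any(batch_index < 0)) stop("`batch_index` must be non-negative")
  cfg$lr0 * cfg$decay^floor(batch_index / cfg$decay_every)
}

#' Grouped k-fold split
#'
#' Partitions group ids (never individual images) into `n_folds` folds whose
#' sizes differ by at most one, so no scene contributes to both sides of a
#' split. Deterministic given the seed.
#'
#' @param groups List of `fq_group` (or a vector of group ids).
#' @param seed Integer seed for the shuffle.
#' @param n_folds Number of folds (default 5).
#' @return List of `n_folds` elements, each `list(train_ids, test_ids)`.
#' @export
five_fold_split <- function(groups, seed = 1L, n_folds = 5L) {
  ids <- if (is.list(groups))
    vapply(groups, function(g) as.integer(g$group_id), integer(1))
  else as.integer(groups)
  if (length(ids) < n_folds)
    stop("need at least ", n_folds, " groups, got ", length(ids))
  shuffled <- withr::with_seed(as.integer(seed), sample(ids))
  fold_of <- rep(seq_len(n_folds), length.out = length(shuffled))
  lapply(seq_len(n_folds), function(k) {
    list(train_ids = sort(shuffled[fold_of != k]),
         test_ids = sort(shuffled[fold_of == k]))
  })
}

#' Per-network objectives from loss components
#'
#' Pure arithmetic combiner: the discriminator ascends `l_d`; the generator
#' descends `l_adv + theta * l_content + gamma * l_r` (where `l_r` is the
#' quality-network loss evaluated on generated images); the quality network
#' descends `phi * l_cam + l_qa`. With `gamma = 0` the generator objective
#' reduces to the plain adversarial + content form.
#'
#' @param components Named list with `l_d`, `l_adv`, `l_content`, `l_r`,
#'   `l_cam`, `l_qa` (missing entries default to 0).
#' @param cfg A [train_config()] supplying `theta`, `phi`, `gamma`.
#' @return Named list `d_objective`, `g_objective`, `aqa_objective`.
#' @export
total_loss <- function(components, cfg = train_config()) {
  get0c <- function(nm) if (is.null(components[[nm]])) 0 else components[[nm]]
  for (nm in c("l_d", "l_adv", "l_content", "l_r", "l_cam", "l_qa"))
    if (!is.finite(get0c(nm)))
      stop("non-finite loss component: ", nm)
  list(d_objective = get0c("l_d"),
       g_objective = get0c("l_adv") + cfg$theta * get0c("l_content") +
         cfg$gamma * get0c("l_r"),
       aqa_objective = cfg$phi * get0c("l_cam") + get0c("l_qa"))
}

# ---- data staging ---------------------------------------------------------

# stack a list of groups into dense arrays for the training loop
stage_groups <- function(groups, cam_size, use_cam) {
  imgs <- purrr::list_flatten(purrr::map(groups, "variants"))
  size <- dim(imgs[[1]]$pixels)[1]
  n <- length(imgs)
  x <- array(0, c(size, size, 3, n))
  gt <- array(0, c(size, size, 3, n))
  fgt <- if (use_cam) array(0, c(cam_size, cam_size, n)) else NULL
  mos <- numeric(n)
  gid <- integer(n); vid <- integer(n)
  i <- 0L
  for (g in groups) {
    ref <- group_reference_image(g)
    for (v in g$variants) {
      i <- i + 1L
      x[, , , i] <- v$pixels
      gt[, , , i] <- ref$pixels
      mos[i] <- v$mos
      gid[i] <- g$group_id; vid[i] <- v$variant_id
      if (use_cam) {
        sm <- v$severity_map
        if (is.null(sm)) sm <- matrix(0, size, size)
        f <- cpp_avgpool_fwd(array(sm, c(size, size, 1, 1)),
                             as.integer(size / cam_size))[, , 1, 1]
        rng <- max(f) - min(f)
        fgt[, , i] <- if (rng > 0) (f - min(f)) / rng else 0
      }
    }
  }
  list(x = x, gt = gt, f_gt = fgt, mos = mos, q_t = normalize_mos(mos),
       group_id = gid, variant_id = vid, n = n, size = size)
}

cat_batch <- function(a, b) {
  d <- dim(a)
  out <- array(0, c(d[1], d[2], d[3], d[4] + dim(b)[4]))
  out[, , , seq_len(d[4])] <- a
  out[, , , d[4] + seq_len(dim(b)[4])] <- b
  out
}

# quality-network forward on generated images (treated as their own
# best-quality version: zero nuance), giving the per-sample diagnostic weight
perceptual_weights <- function(aqa, i_hq, f_last) {
  zeros <- array(0, dim(i_hq))
  r <- aqa_forward(aqa, i_hq, zeros,
                   if (aqa$cfg$use_f_last) f_last else NULL, train = FALSE)
  quality_weight(denormalize_mos(r$q_sigmoid))
}

# ---- the fit --------------------------------------------------------------

#' Train the full quality-assessment model
#'
#' Runs the alternating D/G/AQA scheme with Adam and the decaying learning
#' rate, evaluating on `val_groups` at the end of every epoch and retaining
#' the checkpoint with the best validation rank correlation.
#'
#' @param train_groups List of `fq_group` used for training.
#' @param cfg A [train_config()].
#' @param val_groups Held-out groups for per-epoch validation (optional but
#'   needed for checkpoint selection).
#' @param verbose Print a progress line per epoch?
#' @return An `fq_fit`: the trained networks (`generator`, `discriminator`,
#'   `aqa`), the best-epoch checkpoint (`best`), a per-epoch `log` tibble and
#'   the configuration.
#' @export
fit_quality_model <- function(train_groups, cfg = train_config(),
                              val_groups = NULL, verbose = FALSE) {
  if (length(train_groups) == 0) stop("empty training fold")
  eps <- 1e-7
  aqa_cfg0 <- aqa_config(size = dim(train_groups[[1]]$variants[[1]]$pixels)[1],
                         stem_channels = cfg$stem_channels,
                         width_factor = cfg$width_factor,
                         fc_hidden = cfg$fc_hidden, phi = cfg$phi,
                         use_f_last = cfg$use_gan, use_cam = cfg$use_cam)
  size <- aqa_cfg0$size
  tr <- stage_groups(train_groups, aqa_cfg0$cam_size, cfg$use_cam)
  va <- if (!is.null(val_groups)) stage_groups(val_groups, aqa_cfg0$cam_size, FALSE)
  gen <- disc <- NULL
  if (cfg$use_gan) {
    gen <- build_generator(
      generator_config(size, cfg$gen_base_channels,
                       n_ufw_repeats = cfg$n_ufw_repeats,
                       theta = cfg$theta, use_ufw = cfg$use_ufw),
      seed = cfg$seed)
    disc <- build_discriminator(
      discriminator_config(size, cfg$disc_base_channels), seed = cfg$seed + 1L)
  }
  aqa <- build_aqa(aqa_cfg0,
                   f_last_channels = 2L * cfg$gen_base_channels,
                   seed = cfg$seed + 2L)
  n_batches <- tr$n %/% cfg$batch_size
  if (n_batches == 0) stop("training fold smaller than one batch")
  log_rows <- vector("list", cfg$epochs)
  best <- list(metric = -Inf, epoch = NA_integer_)
  t_global <- 0L
  withr::with_seed(cfg$seed + 3L, {
    for (epoch in seq_len(cfg$epochs)) {
      order_idx <- sample.int(tr$n)
      ep <- list(l_d = 0, l_adv = 0, l_content = 0, l_cam = 0, l_qa = 0)
      for (b in seq_len(n_batches)) {
        idx <- order_idx[((b - 1L) * cfg$batch_size + 1L):(b * cfg$batch_size)]
        lr <- lr_schedule(t_global, cfg)
        t_global <- t_global + 1L
        nb <- length(idx)
        x_org <- tr$x[, , , idx, drop = FALSE]
        q_t <- tr$q_t[idx]
        i_sub <- NULL; f_last <- NULL
        if (cfg$use_gan) {
          x_gt <- tr$gt[, , , idx, drop = FALSE]
          gf <- generator_forward(gen, x_org, train = TRUE)
          i_hq <- gf$i_hq
          w <- if (cfg$use_perceptual)
            perceptual_weights(aqa, i_hq, gf$f_last) else rep(1L, nb)
          # --- discriminator ascent on the quality-weighted objective
          dfwd <- disc_forward(disc, cat_batch(x_gt, i_hq), train = TRUE)
          disc <- dfwd$disc
          d_real <- dfwd$scores[seq_len(nb)]
          d_fake <- dfwd$scores[nb + seq_len(nb)]
          l_d <- loss_discriminator(d_real, d_fake, w, eps)
          if (!is.finite(l_d)) stop("non-finite discriminator loss")
          dscore <- c(1 / (pmax(d_real, eps) * nb),
                      -sign(d_fake - w) / (pmax(1 - abs(d_fake - w), eps) * nb))
          dbk <- disc_backward(disc, -dscore)  # Adam minimises
          disc <- disc_adam(dbk$disc, lr, t_global)
          # --- generator descent
          dfwd2 <- disc_forward(disc, i_hq, train = TRUE)
          disc <- dfwd2$disc
          d_fake2 <- dfwd2$scores
          l_adv <- mean(log(pmax(1 - d_fake2, eps)))
          l_content <- loss_content(i_hq, x_gt)
          if (!is.finite(l_adv) || !is.finite(l_content))
            stop("non-finite generator loss")
          dbk2 <- disc_backward(disc, -1 / (pmax(1 - d_fake2, eps) * nb))
          disc <- dbk2$disc  # gradients are overwritten at the next D step
          # content gradient normalised per sample (the content objective
          # averages per-image squared error over the batch, not over pixels),
          # so theta = 0.5 balances it against the adversarial term
          d_ihq <- dbk2$dx + cfg$theta * 2 * (i_hq - x_gt) / nb
          if (cfg$use_perceptual && cfg$gamma > 0) {
            i_sub_g <- abs(i_hq - x_org)
            pf <- aqa_forward(aqa, x_org, i_sub_g,
                              if (aqa$cfg$use_f_last) gf$f_last else NULL,
                              train = FALSE)
            dq <- cfg$gamma * (pf$q_sigmoid - q_t) / nb
            pb <- aqa_backward(pf$aqa, dq,
                               if (cfg$use_cam) tr$f_gt[, , idx, drop = FALSE] else NULL,
                               phi = cfg$gamma * cfg$phi)
            d_ihq <- d_ihq + pb$d_i_sub * sign(i_hq - x_org)
          }
          gbk <- generator_backward(gf$gen, d_ihq)
          gen <- generator_adam(gbk$gen, lr, t_global)
          # --- nuance with the just-updated generator, in inference mode so
          # the quality network trains on the same input distribution it is
          # validated on (running batch-norm statistics)
          gf2 <- generator_forward(gen, x_org, train = FALSE)
          i_sub <- abs(gf2$i_hq - x_org)
          f_last <- gf2$f_last
          ep$l_d <- ep$l_d + l_d; ep$l_adv <- ep$l_adv + l_adv
          ep$l_content <- ep$l_content + l_content
        } else {
          i_sub <- array(0, dim(x_org))
        }
        # --- quality network descent
        af <- aqa_forward(aqa, x_org, i_sub,
                          if (aqa$cfg$use_f_last) f_last else NULL, train = TRUE)
        l_qa <- loss_quality(af$q_pre, q_t)
        l_cam <- if (cfg$use_cam)
          loss_cam(af$f_cam, tr$f_gt[, , idx, drop = FALSE]) else 0
        if (!is.finite(l_qa) || !is.finite(l_cam))
          stop("non-finite quality-network loss")
        dq <- (af$q_sigmoid - q_t) / nb
        abk <- aqa_backward(af$aqa, dq,
                            if (cfg$use_cam) tr$f_gt[, , idx, drop = FALSE] else NULL,
                            phi = cfg$phi)
        aqa <- aqa_adam(abk$aqa, lr, t_global)
        ep$l_qa <- ep$l_qa + l_qa; ep$l_cam <- ep$l_cam + l_cam
      }
      for (nm in names(ep)) ep[[nm]] <- ep[[nm]] / n_batches
      row <- tibble::tibble(epoch = epoch, lr = lr_schedule(t_global - 1L, cfg),
                            loss_d = ep$l_d, loss_g_adv = ep$l_adv,
                            loss_g_content = ep$l_content,
                            loss_cam = ep$l_cam, loss_qa = ep$l_qa,
                            val_plcc = NA_real_, val_srcc = NA_real_,
                            val_krcc = NA_real_, val_rmse = NA_real_,
                            val_gen_mse = NA_real_)
      if (!is.null(va)) {
        vm <- validate_epoch(gen, aqa, va, cfg)
        row$val_plcc <- vm$plcc; row$val_srcc <- vm$srcc
        row$val_krcc <- vm$krcc; row$val_rmse <- vm$rmse
        row$val_gen_mse <- vm$gen_mse
        metric <- vm[[cfg$checkpoint_metric]]
        if (is.finite(metric) && metric > best$metric) {
          best <- list(metric = metric, epoch = epoch,
                       generator = strip_model(gen), aqa = strip_model(aqa))
        }
      }
      log_rows[[epoch]] <- row
      if (verbose)
        message(sprintf("epoch %3d  qa %.4f  cam %.4f  content %.5f  srcc %s",
                        epoch, ep$l_qa, ep$l_cam, ep$l_content,
                        formatC(row$val_srcc, digits = 3, format = "f")))
    }
  })
  structure(list(generator = strip_model(gen), discriminator = strip_model(disc),
                 aqa = strip_model(aqa), best = best,
                 log = purrr::list_rbind(log_rows), cfg = cfg),
            class = "fq_fit")
}

strip_model <- function(m) {
  if (is.null(m)) return(NULL)
  m$cache_feats <- NULL; m$cache_cam <- NULL
  for (f in c("enc", "dec")) if (!is.null(m[[f]]))
    m[[f]] <- lapply(m[[f]], strip_layers)
  for (f in c("ufw", "layers", "trunk", "head", "stem_org", "stem_sub"))
    if (!is.null(m[[f]])) m[[f]] <- strip_layers(m[[f]])
  m
}

# held-out metrics for one epoch: predicted MOS vs true MOS, plus generator
# reconstruction MSE against the group references
validate_epoch <- function(gen, aqa, va, cfg) {
  pred <- predict_staged(gen, aqa, va, cfg)
  m <- tryCatch(compute_metrics(pred$predicted, va$mos),
                error = function(e) tibble::tibble(plcc = NA_real_, srcc = NA_real_,
                                                   krcc = NA_real_, rmse = NA_real_))
  list(plcc = m$plcc, srcc = m$srcc, krcc = m$krcc, rmse = m$rmse,
       gen_mse = pred$gen_mse)
}

# inference over a staged dataset in chunks; returns predicted MOS (1-5) and
# mean generator MSE to the references
predict_staged <- function(gen, aqa, st, cfg, chunk = 32L) {
  n <- st$n
  predicted <- numeric(n)
  gen_mse <- if (!is.null(gen)) 0 else NA_real_
  at <- 1L
  while (at <= n) {
    idx <- at:min(n, at + chunk - 1L)
    x <- st$x[, , , idx, drop = FALSE]
    if (!is.null(gen)) {
      gf <- generator_forward(gen, x, train = FALSE)
      i_sub <- abs(gf$i_hq - x)
      f_last <- if (aqa$cfg$use_f_last) gf$f_last else NULL
      gen_mse <- gen_mse + sum((gf$i_hq - st$gt[, , , idx, drop = FALSE])^2)
    } else {
      i_sub <- array(0, dim(x))
      f_last <- NULL
    }
    r <- aqa_forward(aqa, x, i_sub, f_last, train = FALSE)
    predicted[idx] <- denormalize_mos(r$q_sigmoid)
    at <- at + chunk
  }
  if (!is.null(gen)) gen_mse <- gen_mse / length(st$x)
  list(predicted = predicted, gen_mse = gen_mse)
}

#' @export
print.fq_fit <- function(x, ...) {
  cat(sprintf("<fq_fit> %d epochs", nrow(x$log)))
  if (!is.na(x$best$epoch))
    cat(sprintf(", best %s %.4f at epoch %d", x$cfg$checkpoint_metric,
                x$best$metric, x$best$epoch))
  cat("\n")
  invisible(x)
}

#' Save / load a trained model
#'
#' @param fit An `fq_fit`.
#' @param path Destination file.
#' @export
save_model <- function(fit, path) saveRDS(fit, path)

#' @rdname save_model
#' @export
load_model <- function(path) readRDS(path)
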