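# Protocol components: learning-rate schedule, grouped cross-validation,
# objective composition, and the training loop contract.

test_that("learning rate decays by 0.95 every 20 batches", {
  cfg <- train_config()
  expect_equal(lr_schedule(0, cfg), 2e-4)
  expect_equal(lr_schedule(19, cfg), 2e-4)
  expect_equal(lr_schedule(20, cfg), 2e-4 * 0.95)
  expect_equal(lr_schedule(39, cfg), 2e-4 * 0.95)
  expect_equal(lr_schedule(40, cfg), 2e-4 * 0.95^2)
  expect_error(lr_schedule(-1, cfg), "non-negative")
})

test_that("grouped five-fold split partitions 129 groups as 26/26/26/26/25", {
  folds <- five_fold_split(1:129, seed = 4)
  sizes <- sort(vapply(folds, function(f) length(f$test_ids), integer(1)))
  expect_identical(sizes, c(25L, 26L, 26L, 26L, 26L))
  all_test <- sort(unlist(lapply(folds, `[[`, "test_ids")))
  expect_identical(all_test, 1:129)
  for (f in folds) {
    expect_length(intersect(f$train_ids, f$test_ids), 0)
    expect_identical(sort(c(f$train_ids, f$test_ids)), 1:129)
  }
  expect_identical(five_fold_split(1:129, seed = 4), folds)
  expect_false(identical(five_fold_split(1:129, seed = 5), folds))
  expect_error(five_fold_split(1:4, seed = 1), "at least 5")
})

test_that("objective composition reduces to the plain GAN form at gamma 0", {
  comp <- list(l_d = -1.2, l_adv = -0.7, l_content = 0.04, l_r = 0.5,
               l_cam = 0.3, l_qa = 0.6)
  cfg0 <- train_config(gamma = 0)
  out0 <- total_loss(comp, cfg0)
  expect_equal(out0$g_objective, comp$l_adv + 0.5 * comp$l_content)
  cfg1 <- train_config()  # gamma = 0.01 default
  out1 <- total_loss(comp, cfg1)
  expect_equal(out1$g_objective, comp$l_adv + 0.5 * comp$l_content + 0.01 * comp$l_r)
  expect_equal(out1$aqa_objective, 1 * comp$l_cam + comp$l_qa)
  expect_equal(out1$d_objective, comp$l_d)
  expect_error(total_loss(list(l_d = NaN), cfg1), "l_d")
})

test_that("a tiny run completes, logs per epoch, and is reproducible", {
  groups <- tiny_groups()
  cfg <- train_config(epochs = 3, batch_size = 16, seed = 11)
  f1 <- fit_quality_model(groups[1:4], cfg, val_groups = groups[5:6])
  expect_s3_class(f1, "fq_fit")
  expect_identical(nrow(f1$log), 3L)
  expect_true(all(is.finite(f1$log$loss_qa)))
  expect_true(all(is.finite(f1$log$val_srcc)))
  # best checkpoint attains the maximum logged validation SRCC
  expect_equal(f1$best$metric, max(f1$log$val_srcc))
  expect_identical(f1$best$epoch, which.max(f1$log$val_srcc))
  # identical config + seed reproduces the log exactly
  f2 <- fit_quality_model(groups[1:4], cfg, val_groups = groups[5:6])
  expect_identical(f1$log, f2$log)
  expect_error(fit_quality_model(list(), cfg), "empty training fold")
})

test_that("one alternation updates all three parameter sets", {
  groups <- tiny_groups()
  cfg <- train_config(epochs = 1, batch_size = 16, seed = 12)
  aqa_cfg <- aqa_config(32, stem_channels = cfg$stem_channels,
                                 width_factor = cfg$width_factor,
                                 fc_hidden = cfg$fc_hidden)
  gen0 <- build_generator(generator_config(32, cfg$gen_base_channels,
                                           n_ufw_repeats = cfg$n_ufw_repeats),
                          seed = cfg$seed)
  disc0 <- build_discriminator(discriminator_config(32, cfg$disc_base_channels),
                               seed = cfg$seed + 1L)
  aqa0 <- build_aqa(aqa_cfg, f_last_channels = 2L * cfg$gen_base_channels,
                    seed = cfg$seed + 2L)
  f <- fit_quality_model(groups[1:4], cfg)
  expect_false(isTRUE(all.equal(fuseqa:::param_l2(f$generator$dec$u4),
                                fuseqa:::param_l2(gen0$dec$u4))))
  expect_false(isTRUE(all.equal(fuseqa:::param_l2(f$discriminator$layers),
                                fuseqa:::param_l2(disc0$layers))))
  expect_false(isTRUE(all.equal(fuseqa:::param_l2(f$aqa$trunk),
                                fuseqa:::param_l2(aqa0$trunk))))
})

test_that("the ablation ladder is constructible from config switches", {
  cfgs <- list(
    vgg_only = train_config(use_gan = FALSE, use_ufw = FALSE,
                            use_perceptual = FALSE, use_cam = FALSE),
    gan = train_config(use_ufw = FALSE, use_perceptual = FALSE,
                       use_cam = FALSE),
    gan_ufw = train_config(use_perceptual = FALSE, use_cam = FALSE),
    gan_ufw_perc = train_config(use_cam = FALSE),
    full = train_config())
  flags <- t(vapply(cfgs, function(cfg)
    c(cfg$use_gan, cfg$use_ufw, cfg$use_perceptual, cfg$use_cam), logical(4)))
  expect_identical(unname(rowSums(flags)), c(0, 1, 2, 3, 4))
  # each rung only adds components
  for (i in 2:5) expect_true(all(flags[i - 1, ] <= flags[i, ]))
})

test_that("models survive a save/load round trip", {
  groups <- tiny_groups()
  cfg <- train_config(epochs = 1, batch_size = 16, seed = 13,
                      use_gan = FALSE, use_cam = FALSE)
  f <- fit_quality_model(groups[1:4], cfg, val_groups = groups[5:6])
  path <- withr::local_tempfile(fileext = ".rds")
  save_model(f, path)
  g <- load_model(path)
  e1 <- evaluate_model(f, groups[5:6])
  e2 <- evaluate_model(g, groups[5:6])
  expect_identical(e1$metrics, e2$metrics)
})
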