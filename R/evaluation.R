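# Correlation/error metrics between predicted quality and MOS, model
# evaluation with optional resampling, and the train-fraction sweep.

#' Correlation and error metrics for predicted quality scores
#'
#' PLCC is the Pearson correlation, SRCC the Spearman rank correlation
#' (average ranks for ties), KRCC the Kendall tau-b, and RMSE the root mean
#' squared error on the 1-5 MOS scale. Constant inputs make the correlations
#' undefined and raise an error rather than returning 0.
#'
#' @param predicted Predicted scores (1-5 scale).
#' @param mos Ground-truth MOS, same length (>= 3).
#' @return One-row tibble with `plcc`, `srcc`, `krcc`, `rmse`, `n`.
#' @export
compute_metrics <- function(predicted, mos) {
  if (length(predicted) != length(mos))
    stop("`predicted` and `mos` must have the same length")
  if (length(mos) < 3) stop("need at least 3 observations")
  if (any(!is.finite(predicted)) || any(!is.finite(mos)))
    stop("inputs must be finite")
  if (stats::sd(predicted) == 0 || stats::sd(mos) == 0)
    stop("correlation undefined for a constant input vector")
  tibble::tibble(
    plcc = stats::cor(predicted, mos),
    srcc = stats::cor(predicted, mos, method = "spearman"),
    krcc = stats::cor(predicted, mos, method = "kendall"),
    rmse = sqrt(mean((predicted - mos)^2)),
    n = length(mos))
}

#' Evaluate a trained model on held-out groups
#'
#' Predicts a denormalised MOS for every image of the test groups with the
#' best-epoch checkpoint (falling back to the final state when no validation
#' ran during training) and computes PLCC/SRCC/KRCC/RMSE. With
#' `repeats > 1`, metrics are averaged over that many resampled 80% subsets
#' of the test images (seeded), which smooths metric estimates on small test
#' sets.
#'
#' @param fit An `fq_fit` from [fit_quality_model()].
#' @param test_groups Held-out `fq_group` list (disjoint from training).
#' @param repeats Resampling repeats (default from the fit's config).
#' @param seed Seed for the resampling draws.
#' @param use_best Use the best-epoch checkpoint when available?
#' @return An `fq_eval`: `metrics` (one-row tibble), `per_image` tibble
#'   (`group_id`, `variant_id`, `mos`, `predicted`) and `repeats`.
#' @export
evaluate_model <- function(fit, test_groups, repeats = NULL, seed = 1L,
                           use_best = TRUE) {
  if (length(test_groups) == 0) stop("empty test set")
  if (is.null(repeats)) repeats <- fit$cfg$eval_repeats
  gen <- fit$generator; aqa <- fit$aqa
  if (use_best && !is.na(fit$best$epoch)) {
    gen <- fit$best$generator; aqa <- fit$best$aqa
  }
  cam_size <- aqa$cfg$cam_size
  st <- stage_groups(test_groups, cam_size, FALSE)
  pred <- predict_staged(gen, aqa, st, fit$cfg)
  per_image <- tibble::tibble(group_id = st$group_id, variant_id = st$variant_id,
                              mos = st$mos, predicted = pred$predicted)
  if (repeats <= 1) {
    metrics <- compute_metrics(per_image$predicted, per_image$mos)
  } else {
    k <- max(3L, floor(0.8 * nrow(per_image)))
    reps <- withr::with_seed(as.integer(seed), {
      purrr::map(seq_len(repeats), function(r) {
        take <- sample.int(nrow(per_image), k)
        compute_metrics(per_image$predicted[take], per_image$mos[take])
      })
    }) |> purrr::list_rbind()
    metrics <- dplyr::summarise(reps, dplyr::across(c(plcc, srcc, krcc, rmse), mean))
    metrics$n <- nrow(per_image)
  }
  structure(list(metrics = metrics, per_image = per_image,
                 repeats = repeats, gen_mse = pred$gen_mse),
            class = "fq_eval")
}

#' @export
print.fq_eval <- function(x, ...) {
  cat(sprintf("<fq_eval> n = %d images%s\n", nrow(x$per_image),
              if (x$repeats > 1) sprintf(" (metrics averaged over %d resamples)",
                                         x$repeats) else ""))
  cat(sprintf("  PLCC %.4f  SRCC %.4f  KRCC %.4f  RMSE %.4f\n",
              x$metrics$plcc, x$metrics$srcc, x$metrics$krcc, x$metrics$rmse))
  invisible(x)
}

#' Training-fraction sweep
#'
#' Trains one model per requested training fraction on a group-level split
#' and evaluates on the complementary groups, producing a table of metric
#' values versus training-set size.
#'
#' @param groups Full list of `fq_group`.
#' @param fractions Training fractions, each strictly inside (0, 1).
#' @param cfg A [train_config()] used for every run.
#' @param seed Seed for the group shuffle (the same shuffle is reused across
#'   fractions so the splits are nested).
#' @param verbose Passed to [fit_quality_model()].
#' @return Tibble with one row per fraction: `fraction`, `n_train_groups`,
#'   `n_test_groups`, `plcc`, `srcc`, `krcc`, `rmse`.
#' @export
split_sweep <- function(groups, fractions, cfg = train_config(), seed = 1L,
                        verbose = FALSE) {
  n <- length(groups)
  shuffled <- withr::with_seed(as.integer(seed), sample(groups))
  purrr::map(fractions, function(f) {
    if (f <= 0 || f >= 1) stop("training fraction must lie strictly in (0, 1)")
    k <- as.integer(round(f * n))
    if (k < 1 || k >= n)
      stop("fraction ", f, " leaves an empty training or test side")
    train <- shuffled[seq_len(k)]
    test <- shuffled[(k + 1):n]
    m <- fit_quality_model(train, cfg, val_groups = test, verbose = verbose)
    ev <- evaluate_model(m, test, seed = seed)
    tibble::tibble(fraction = f, n_train_groups = k,
                   n_test_groups = as.integer(n - k),
                   plcc = ev$metrics$plcc, srcc = ev$metrics$srcc,
                   krcc = ev$metrics$krcc, rmse = ev$metrics$rmse)
  }) |> purrr::list_rbind()
}

# ---- broom-style accessors ------------------------------------------------

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy the per-epoch training log
#'
#' @param x An `fq_fit`.
#' @param ... Unused.
#' @return The per-epoch log tibble (losses, learning rate, validation
#'   metrics).
#' @exportS3Method generics::tidy
tidy.fq_fit <- function(x, ...) x$log

#' One-row summary of a fit
#'
#' @param x An `fq_fit`.
#' @param ... Unused.
#' @return Tibble with epochs trained, best epoch and best validation
#'   metrics.
#' @exportS3Method generics::glance
glance.fq_fit <- function(x, ...) {
  bl <- if (!is.na(x$best$epoch)) x$log[x$best$epoch, ] else x$log[nrow(x$log), ]
  tibble::tibble(epochs = nrow(x$log), best_epoch = x$best$epoch,
                 val_plcc = bl$val_plcc, val_srcc = bl$val_srcc,
                 val_krcc = bl$val_krcc, val_rmse = bl$val_rmse,
                 val_gen_mse = bl$val_gen_mse)
}

#' Per-image predictions of an evaluation
#'
#' @param x An `fq_eval`.
#' @param ... Unused.
#' @return Tibble with one row per test image.
#' @exportS3Method generics::tidy
tidy.fq_eval <- function(x, ...) x$per_image

#' One-row metric summary of an evaluation
#'
#' @param x An `fq_eval`.
#' @param ... Unused.
#' @return One-row tibble of PLCC/SRCC/KRCC/RMSE and `n`.
#' @exportS3Method generics::glance
glance.fq_eval <- function(x, ...) x$metrics

#' Training curves
#'
#' Loss components and validation rank correlation per epoch.
#'
#' @param object An `fq_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.fq_fit <- function(object, ...) {
  long <- tidyr::pivot_longer(object$log,
                              dplyr::any_of(c("loss_qa", "loss_cam",
                                              "loss_g_content", "val_srcc")),
                              names_to = "series", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$value,
                                     colour = .data$series)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::facet_wrap(~series, scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL, colour = NULL,
                  title = "Training losses and validation SRCC") +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}

#' Predicted score versus MOS scatter
#'
#' @param object An `fq_eval`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.fq_eval <- function(object, ...) {
  ggplot2::ggplot(object$per_image,
                  ggplot2::aes(x = .data$mos, y = .data$predicted)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::coord_cartesian(xlim = c(1, 5), ylim = c(1, 5)) +
    ggplot2::labs(x = "radiologist-style MOS", y = "predicted MOS",
                  title = sprintf("SRCC %.3f, PLCC %.3f",
                                  object$metrics$srcc, object$metrics$plcc)) +
    ggplot2::theme_minimal()
}

#' Metric-versus-training-fraction plot for a sweep table
#'
#' @param sweep Output of [split_sweep()].
#' @return A ggplot object.
#' @export
plot_sweep <- function(sweep) {
  long <- tidyr::pivot_longer(sweep, c("plcc", "srcc", "krcc", "rmse"),
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$fraction, y = .data$value)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "training fraction", y = NULL,
                  title = "Held-out performance vs training-set size") +
    ggplot2::theme_minimal()
}
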