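#' Generate a synthetic structural/functional source-image pair
#'
#' Emulates one co-registered multimodal acquisition: a structural modality
#' (piecewise-smooth anatomy with sharp edges, like MR/CT) and a functional
#' modality (a smooth, low-frequency uptake field concentrated in a random
#' lesion region, like PET/SPECT). The two single-channel images are the raw
#' material that the fusion-variant synthesiser degrades at graded severities.
#'
#' @param group_seed Integer seed; the pair is a pure function of it.
#' @param size Image side in pixels; must be a power of two, at least 32.
#' @return A list with `structural` and `functional`, each a `size x size`
#'   matrix of intensities in `[0, 1]`, plus `lesion_mask` (logical matrix).
#' @export
generate_source_pair <- function(group_seed, size = 128L) {
  if (!is.numeric(size) || length(size) != 1 || size < 32 ||
      bitwAnd(as.integer(size), as.integer(size) - 1L) != 0L) {
    stop("`size` must be a power of two >= 32, got ", size)
  }
  size <- as.integer(size)
  withr::with_seed(as.integer(group_seed), {
    gx <- matrix(rep(seq_len(size), each = size), size, size)  # column index
    gy <- matrix(rep(seq_len(size), times = size), size, size) # row index
    # structural: dark background, 4-7 sharp-edged ellipses + 1-2 rotated
    # rectangles, mild fine-grained texture
    s <- matrix(stats::runif(1, 0.05, 0.15), size, size)
    for (i in seq_len(sample(4:7, 1))) {
      cx <- stats::runif(1, 0.2, 0.8) * size; cy <- stats::runif(1, 0.2, 0.8) * size
      a <- stats::runif(1, 0.08, 0.3) * size; b <- stats::runif(1, 0.08, 0.3) * size
      th <- stats::runif(1, 0, pi)
      xr <- (gx - cx) * cos(th) + (gy - cy) * sin(th)
      yr <- -(gx - cx) * sin(th) + (gy - cy) * cos(th)
      inside <- (xr / a)^2 + (yr / b)^2 <= 1
      s[inside] <- stats::runif(1, 0.3, 0.95)
    }
    for (i in seq_len(sample(1:2, 1))) {
      cx <- stats::runif(1, 0.25, 0.75) * size; cy <- stats::runif(1, 0.25, 0.75) * size
      a <- stats::runif(1, 0.05, 0.2) * size; b <- stats::runif(1, 0.05, 0.2) * size
      th <- stats::runif(1, 0, pi)
      xr <- abs((gx - cx) * cos(th) + (gy - cy) * sin(th))
      yr <- abs(-(gx - cx) * sin(th) + (gy - cy) * cos(th))
      inside <- xr <= a & yr <= b
      s[inside] <- stats::runif(1, 0.3, 0.95)
    }
    s <- s + matrix(stats::rnorm(size^2, sd = 0.02), size, size)
    # functional: gaussian uptake blobs concentrated inside one lesion ellipse
    lcx <- stats::runif(1, 0.3, 0.7) * size; lcy <- stats::runif(1, 0.3, 0.7) * size
    la <- stats::runif(1, 0.12, 0.25) * size; lb <- stats::runif(1, 0.12, 0.25) * size
    lesion <- ((gx - lcx) / la)^2 + ((gy - lcy) / lb)^2 <= 1
    f <- matrix(0.05, size, size)
    for (i in seq_len(sample(3:5, 1))) {
      repeat {
        bx <- lcx + stats::rnorm(1, sd = la / 2)
        by <- lcy + stats::rnorm(1, sd = lb / 2)
        if (bx >= 1 && bx <= size && by >= 1 && by <= size) break
      }
      sg <- stats::runif(1, 0.05, 0.12) * size
      amp <- stats::runif(1, 0.5, 1)
      f <- f + amp * exp(-((gx - bx)^2 + (gy - by)^2) / (2 * sg^2))
    }
    list(structural = pmin(pmax(s, 0), 1),
         functional = pmin(pmax(f, 0), 1),
         lesion_mask = lesion)
  })
}

# map a single-channel functional image to pseudo-colour (hot-style LUT),
# as PET/SPECT overlays are usually displayed
functional_to_rgb <- function(f) {
  r <- pmin(1, 3 * f)
  g <- pmin(1, pmax(0, 3 * f - 1))
  b <- pmin(1, pmax(0, 3 * f - 2))
  array(c(r, g, b), c(nrow(f), ncol(f), 3))
}

# weighted pixel fusion of a source pair; w_struct is the structural weight.
# colour groups render the functional channel through the pseudo-colour LUT.
fuse_pair <- function(pair, w_struct = 0.5, color = TRUE) {
  s3 <- array(pair$structural, c(dim(pair$structural), 3))
  f3 <- if (color) functional_to_rgb(pair$functional) else
    array(pair$functional, c(dim(pair$functional), 3))
  pmin(pmax(w_struct * s3 + (1 - w_struct) * f3, 0), 1)
}

# separable gaussian blur applied per channel (reflective edges)
gaussian_blur <- function(x, sigma) {
  if (sigma <= 0) return(x)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(-r:r)^2 / (2 * sigma^2))
  k <- k / sum(k)
  blur1 <- function(m) {
    n <- nrow(m)
    idx <- pmin(pmax(outer(seq_len(n), -r:r, "+"), 1L), n)
    out <- matrix(0, n, ncol(m))
    for (j in seq_along(k)) out <- out + k[j] * m[idx[, j], , drop = FALSE]
    out
  }
  if (length(dim(x)) == 2) return(t(blur1(t(blur1(x)))))
  for (c in seq_len(dim(x)[3])) x[, , c] <- t(blur1(t(blur1(x[, , c]))))
  x
}

#' Synthesize graded-quality fusion variants of one source pair
#'
#' Emulates a bank of fusion algorithms of uneven quality: each variant is the
#' clean weighted fusion of the pair degraded by a severity-controlled mixture
#' of modality-weight imbalance, gaussian blur, local detail loss inside a
#' random patch, and additive noise. Severity 0 reproduces the clean fusion
#' exactly. A per-pixel severity map records the applied degradation (the
#' patch region carries extra severity) and later serves as the ground-truth
#' attention target for the quality network.
#'
#' @param pair Output of [generate_source_pair()].
#' @param n_variants Number of variants; must equal `length(severity_grid)`.
#' @param severity_grid Distinct severities in `[0, 1]`, one per variant.
#' @param variant_seed Integer seed controlling noise and patch placement.
#' @param color Render the functional modality in pseudo-colour?
#' @param group_id Group id stamped on each variant.
#' @return List of fused-image records (`fq_image`): fields `pixels`
#'   (`H x W x 3` in `[0,1]`), `group_id`, `variant_id` (0-based), `mos`,
#'   `severity`, `severity_map`.
#' @export
synthesize_fusion_variants <- function(pair, n_variants, severity_grid,
                                       variant_seed, color = TRUE,
                                       group_id = 0L) {
  if (length(severity_grid) == 0) stop("`severity_grid` must be non-empty")
  if (n_variants != length(severity_grid))
    stop("`n_variants` must equal length(severity_grid)")
  if (anyDuplicated(severity_grid)) stop("severities must be distinct")
  if (any(severity_grid < 0 | severity_grid > 1))
    stop("severities must lie in [0, 1]")
  size <- nrow(pair$structural)
  withr::with_seed(as.integer(variant_seed), {
    lapply(seq_along(severity_grid), function(i) {
      s <- severity_grid[i]
      # patch geometry is drawn per variant so detail loss is not co-located
      ps <- max(4L, as.integer(size / 4))
      px <- sample.int(size - ps + 1L, 1)
      py <- sample.int(size - ps + 1L, 1)
      img <- fuse_pair(pair, w_struct = 0.5 + 0.25 * s, color = color)
      if (s > 0) {
        img <- gaussian_blur(img, sigma = 2 * s)
        heavy <- gaussian_blur(img, sigma = 3)
        rows <- py:(py + ps - 1L); cols <- px:(px + ps - 1L)
        img[rows, cols, ] <- (1 - s) * img[rows, cols, ] + s * heavy[rows, cols, ]
        img <- img + array(stats::rnorm(length(img), sd = 0.06 * s), dim(img))
        img <- pmin(pmax(img, 0), 1)
      }
      smap <- matrix(s, size, size)
      if (s > 0) smap[py:(py + ps - 1L), px:(px + ps - 1L)] <- min(1, 1.5 * s)
      new_fq_image(pixels = img, group_id = as.integer(group_id),
                   variant_id = i - 1L, mos = assign_mos(s),
                   severity = s, severity_map = smap)
    })
  })
}

new_fq_image <- function(pixels, group_id, variant_id, mos,
                         severity = NA_real_, severity_map = NULL) {
  structure(list(pixels = pixels, group_id = group_id,
                 variant_id = variant_id, mos = mos, severity = severity,
                 severity_map = severity_map),
            class = "fq_image")
}

#' @export
print.fq_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<fq_image> group %d variant %d, %dx%dx%d, MOS %.3f\n",
              x$group_id, x$variant_id, d[1], d[2], d[3], x$mos))
  invisible(x)
}

#' Map distortion severity to a mean opinion score
#'
#' Linear map from severity in `[0, 1]` to the radiologist MOS scale
#' `[1, 5]`: `mos = 5 - 4 * severity`, optionally perturbed by bounded
#' gaussian rater noise and clipped back into range. With noise off the map
#' is strictly decreasing, so within-group MOS ranking mirrors inverse
#' severity ranking exactly — which is what makes ranking recovery testable.
#'
#' @param severity Numeric vector in `[0, 1]`.
#' @param noise_sd Rater-noise standard deviation on the MOS scale (default 0).
#' @return MOS values in `[1, 5]`.
#' @export
assign_mos <- function(severity, noise_sd = 0) {
  if (any(!is.finite(severity)) || any(severity < 0 | severity > 1))
    stop("`severity` must lie in [0, 1]")
  mos <- 5 - 4 * severity
  if (noise_sd > 0) mos <- mos + stats::rnorm(length(mos), sd = noise_sd)
  pmin(pmax(mos, 1), 5)
}

#' Select the reference variant of a group (highest MOS, random tie-break)
#'
#' The variant with the highest MOS is the group's ground-truth reference;
#' when several variants tie at the maximum, one is drawn uniformly at random
#' under `tie_seed`.
#'
#' @param group An `fq_group`, or a list of `fq_image` records.
#' @param tie_seed Integer seed for the tie-break draw.
#' @return The selected `variant_id`.
#' @export
select_reference <- function(group, tie_seed = 0L) {
  variants <- if (inherits(group, "fq_group")) group$variants else group
  if (length(variants) == 0) stop("group has no variants")
  mos <- vapply(variants, function(v) v$mos, numeric(1))
  ids <- vapply(variants, function(v) v$variant_id, integer(1))
  top <- ids[mos >= max(mos) - 1e-12]
  if (length(top) == 1) return(top)
  withr::with_seed(as.integer(tie_seed), top[sample.int(length(top), 1)])
}

new_fq_group <- function(group_id, variants, reference_variant_id) {
  structure(list(group_id = group_id, variants = variants,
                 reference_variant_id = reference_variant_id),
            class = "fq_group")
}

#' @export
print.fq_group <- function(x, ...) {
  cat(sprintf("<fq_group> id %d: %d variants, reference variant %d\n",
              x$group_id, length(x$variants), x$reference_variant_id))
  invisible(x)
}

#' Synthesize a full group-structured dataset in memory
#'
#' Builds `n_groups` scenes, each with `n_variants` graded-quality fusion
#' variants and a designated reference (highest MOS, random tie-break). The
#' default shape mirrors a fusion-quality database: ~93% colour groups, 10
#' variants per group, 128-pixel images, MOS in `[1, 5]` monotone in the
#' distortion severity.
#'
#' @param n_groups Number of scene groups (>= 1).
#' @param n_variants Variants per group.
#' @param size Image side (power of two >= 32).
#' @param seed Master seed; everything is a pure function of it.
#' @param severity_grid Severities used within each group (distinct, in
#'   `[0, 1]`); default evenly spaced over `[0, 1]`.
#' @param color_fraction Fraction of colour groups (rest grayscale).
#' @param mos_noise_sd Optional rater noise on the MOS scale (default 0).
#' @return List of `fq_group`.
#' @export
synthesize_groups <- function(n_groups, n_variants = 10L, size = 128L, seed = 1L,
                              severity_grid = NULL,
                              color_fraction = 120 / 129, mos_noise_sd = 0) {
  if (n_groups < 1) stop("`n_groups` must be >= 1")
  if (is.null(severity_grid)) severity_grid <- seq(0, 1, length.out = n_variants)
  n_color <- round(color_fraction * n_groups)
  lapply(seq_len(n_groups), function(g) {
    gseed <- as.integer(seed) + 7919L * g
    pair <- generate_source_pair(gseed, size)
    variants <- synthesize_fusion_variants(
      pair, n_variants, severity_grid, variant_seed = gseed + 1L,
      color = g <= n_color, group_id = g)
    if (mos_noise_sd > 0) {
      variants <- withr::with_seed(gseed + 2L, lapply(variants, function(v) {
        v$mos <- assign_mos(v$severity, noise_sd = mos_noise_sd)
        v
      }))
    }
    new_fq_group(g, variants, select_reference(variants, tie_seed = gseed + 3L))
  })
}

#' Write a synthetic dataset to disk (PNG images + CSV manifest)
#'
#' Materialises [synthesize_groups()] as 8-bit PNGs with a CSV manifest
#' (`file_path, group_id, variant_id, mos, is_reference, severity_path`) and
#' a YAML metadata sidecar recording image size, channel policy and the
#' generator seed. Grayscale groups are stored with the gray channel
#' replicated to three channels, so every image loads as `H x W x 3`.
#'
#' @param out_dir Output directory (created if needed).
#' @param n_groups,n_variants,size,seed,severity_grid,color_fraction,mos_noise_sd
#'   Passed to [synthesize_groups()].
#' @return The manifest as a tibble (invisibly also written to
#'   `out_dir/manifest.csv`), with attribute `manifest_path`.
#' @export
build_dataset <- function(out_dir, n_groups, n_variants = 10L, size = 128L,
                          seed = 1L, severity_grid = NULL,
                          color_fraction = 120 / 129, mos_noise_sd = 0) {
  groups <- synthesize_groups(n_groups, n_variants, size, seed,
                              severity_grid, color_fraction, mos_noise_sd)
  ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  dir.create(file.path(out_dir, "images"), showWarnings = FALSE)
  dir.create(file.path(out_dir, "severity"), showWarnings = FALSE)
  rows <- purrr::map(groups, function(g) {
    purrr::map(g$variants, function(v) {
      img_rel <- sprintf("images/g%03d_v%d.png", g$group_id, v$variant_id)
      sev_rel <- sprintf("severity/g%03d_v%d.png", g$group_id, v$variant_id)
      png::writePNG(v$pixels, file.path(out_dir, img_rel))
      png::writePNG(v$severity_map, file.path(out_dir, sev_rel))
      tibble::tibble(file_path = img_rel, group_id = g$group_id,
                     variant_id = v$variant_id, mos = v$mos,
                     is_reference = v$variant_id == g$reference_variant_id,
                     severity_path = sev_rel)
    }) |> purrr::list_rbind()
  }) |> purrr::list_rbind()
  readr::write_csv(rows, file.path(out_dir, "manifest.csv"))
  yaml::write_yaml(list(size = as.integer(size), channels = 3L,
                        channel_policy = "grayscale replicated to 3 channels",
                        seed = as.integer(seed), n_groups = as.integer(n_groups),
                        n_variants = as.integer(n_variants)),
                   file.path(out_dir, "metadata.yaml"))
  attr(rows, "manifest_path") <- file.path(out_dir, "manifest.csv")
  rows
}

#' Load a dataset written by [build_dataset()]
#'
#' Reads the manifest, validates group structure (no duplicate
#' (group, variant) pairs, exactly one reference per group) and reconstructs
#' the image groups with pixels in `[0, 1]`.
#'
#' @param manifest_path Path to `manifest.csv`.
#' @return List of `fq_group`.
#' @export
load_dataset <- function(manifest_path) {
  if (!file.exists(manifest_path)) stop("manifest not found: ", manifest_path)
  man <- readr::read_csv(manifest_path, show_col_types = FALSE)
  needed <- c("file_path", "group_id", "variant_id", "mos", "is_reference")
  if (!all(needed %in% names(man)))
    stop("malformed manifest: missing columns ",
         paste(setdiff(needed, names(man)), collapse = ", "))
  if (anyDuplicated(man[c("group_id", "variant_id")]))
    stop("malformed manifest: duplicate (group_id, variant_id) rows")
  nref <- tapply(man$is_reference, man$group_id, sum)
  if (any(nref != 1))
    stop("malformed manifest: each group must have exactly one reference (group ",
         paste(names(nref)[nref != 1], collapse = ", "), ")")
  base <- dirname(manifest_path)
  lapply(split(man, man$group_id), function(gm) {
    gm <- gm[order(gm$variant_id), ]
    variants <- purrr::pmap(gm, function(file_path, group_id, variant_id, mos,
                                         is_reference, severity_path = NA, ...) {
      path <- file.path(base, file_path)
      if (!file.exists(path)) stop("image file missing: ", path)
      px <- png::readPNG(path)
      if (length(dim(px)) == 2) px <- array(px, c(dim(px), 3))
      if (dim(px)[3] == 4) px <- px[, , 1:3]
      if (dim(px)[3] == 1) px <- array(px[, , 1], c(dim(px)[1:2], 3))
      smap <- NULL
      if (!is.na(severity_path) && nzchar(severity_path)) {
        spath <- file.path(base, severity_path)
        if (!file.exists(spath)) stop("severity map missing: ", spath)
        smap <- png::readPNG(spath)
        if (length(dim(smap)) == 3) smap <- smap[, , 1]
      }
      new_fq_image(px, as.integer(group_id), as.integer(variant_id), mos,
                   severity_map = smap)
    })
    ref <- gm$variant_id[gm$is_reference]
    new_fq_group(as.integer(gm$group_id[1]), variants, as.integer(ref))
  }) |> unname()
}

# convenience accessors used across modules
group_reference_image <- function(group) {
  ids <- vapply(group$variants, function(v) v$variant_id, integer(1))
  group$variants[[which(ids == group$reference_variant_id)]]
}

groups_to_manifest_tbl <- function(groups) {
  purrr::map(groups, function(g) {
    tibble::tibble(
      group_id = g$group_id,
      variant_id = vapply(g$variants, function(v) v$variant_id, integer(1)),
      mos = vapply(g$variants, function(v) v$mos, numeric(1)),
      severity = vapply(g$variants, function(v) v$severity, numeric(1)),
      is_reference = variant_id == g$reference_variant_id)
  }) |> purrr::list_rbind()
}
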