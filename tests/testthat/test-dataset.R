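# Synthetic dataset generator: determinism, monotone quality structure,
# reference selection and the on-disk round trip.

test_that("source pairs are deterministic, seed-sensitive and validated", {
  a <- generate_source_pair(7, 128)
  b <- generate_source_pair(7, 128)
  expect_identical(a$structural, b$structural)
  expect_identical(a$functional, b$functional)
  expect_true(all(a$structural >= 0 & a$structural <= 1))
  expect_true(all(a$functional >= 0 & a$functional <= 1))
  d <- generate_source_pair(8, 128)
  expect_gt(max(abs(a$structural - d$structural)), 0)
  expect_error(generate_source_pair(1, 31), "power of two")
  expect_error(generate_source_pair(1, 48), "power of two")
})

test_that("fusion variants degrade monotonically with severity", {
  pair <- generate_source_pair(3, 64)
  v0 <- synthesize_fusion_variants(pair, 1, 0, variant_seed = 9)
  clean <- fuseqa:::fuse_pair(pair, 0.5, color = TRUE)
  expect_identical(v0[[1]]$pixels, clean)
  expect_true(all(v0[[1]]$severity_map == 0))
  vs <- synthesize_fusion_variants(pair, 3, c(0, 0.5, 1), variant_seed = 9)
  mse <- vapply(vs, function(v) mean((v$pixels - clean)^2), numeric(1))
  expect_true(all(diff(mse) > 0))
  v10 <- synthesize_fusion_variants(pair, 10, seq(0, 1, length.out = 10),
                                    variant_seed = 9)
  expect_length(v10, 10)
  for (i in 1:9) for (j in (i + 1):10)
    expect_gt(max(abs(v10[[i]]$pixels - v10[[j]]$pixels)), 0)
  expect_error(synthesize_fusion_variants(pair, 0, numeric(0), 1), "non-empty")
  expect_error(synthesize_fusion_variants(pair, 2, c(0.3, 0.3), 1), "distinct")
})

test_that("severity maps to MOS linearly with clipping", {
  expect_equal(assign_mos(0), 5)
  expect_equal(assign_mos(1), 1)
  expect_equal(assign_mos(0.5), 3)
  expect_equal(assign_mos(c(0.25, 0.75)), c(4, 2))
  expect_error(assign_mos(-0.1), "\\[0, 1\\]")
  expect_error(assign_mos(1.3), "\\[0, 1\\]")
  # with noise off the within-group ranking is exactly inverse severity
  sev <- withr::with_seed(2, runif(10))
  expect_identical(order(assign_mos(sev)), order(-sev))
  noisy <- withr::with_seed(3, assign_mos(rep(0.5, 500), noise_sd = 0.5))
  expect_true(all(noisy >= 1 & noisy <= 5))
  expect_gt(stats::sd(noisy), 0)
})

test_that("reference selection takes the highest MOS with seeded tie-break", {
  mk <- function(mos) lapply(seq_along(mos), function(i)
    fuseqa:::new_fq_image(array(0, c(4, 4, 3)), 1L, i - 1L, mos[i]))
  expect_identical(select_reference(mk(c(2, 5, 3))), 1L)
  expect_identical(select_reference(mk(c(4))), 0L)
  tied <- mk(c(5, 5, 3))
  pick1 <- select_reference(tied, tie_seed = 11)
  expect_identical(select_reference(tied, tie_seed = 11), pick1)
  expect_true(pick1 %in% c(0L, 1L))
  picks <- vapply(1:40, function(s) select_reference(tied, tie_seed = s),
                  integer(1))
  expect_setequal(unique(picks), c(0L, 1L))
  expect_error(select_reference(list()), "no variants")
})

test_that("group synthesis obeys the group-integrity invariants", {
  groups <- tiny_groups()
  man <- fuseqa:::groups_to_manifest_tbl(groups)
  expect_identical(nrow(man), 60L)
  expect_identical(sum(man$is_reference), 6L)
  for (g in groups) {
    mos <- vapply(g$variants, `[[`, numeric(1), "mos")
    ref <- fuseqa:::group_reference_image(g)
    expect_equal(ref$mos, max(mos))
    expect_true(all(vapply(g$variants, `[[`, integer(1), "group_id") == g$group_id))
  }
})

test_that("a dataset round-trips through PNG + CSV within quantisation", {
  dir <- withr::local_tempdir()
  man <- build_dataset(dir, n_groups = 3, n_variants = 4, size = 32, seed = 5)
  expect_identical(nrow(man), 12L)
  expect_identical(sum(man$is_reference), 3L)
  groups <- load_dataset(file.path(dir, "manifest.csv"))
  mem <- synthesize_groups(3, 4, 32, seed = 5)
  expect_length(groups, 3)
  for (k in 1:3) {
    expect_identical(groups[[k]]$reference_variant_id,
                     mem[[k]]$reference_variant_id)
    for (v in 1:4) {
      expect_lt(max(abs(groups[[k]]$variants[[v]]$pixels -
                          mem[[k]]$variants[[v]]$pixels)), 1 / 255)
      expect_equal(groups[[k]]$variants[[v]]$mos, mem[[k]]$variants[[v]]$mos)
    }
  }
  # identical config + seed => byte-identical manifests
  dir2 <- withr::local_tempdir()
  build_dataset(dir2, n_groups = 3, n_variants = 4, size = 32, seed = 5)
  expect_identical(readLines(file.path(dir, "manifest.csv")),
                   readLines(file.path(dir2, "manifest.csv")))
})

test_that("malformed manifests are rejected with specific errors", {
  dir <- withr::local_tempdir()
  build_dataset(dir, n_groups = 2, n_variants = 3, size = 32, seed = 1)
  path <- file.path(dir, "manifest.csv")
  man <- readr::read_csv(path, show_col_types = FALSE)
  # two references in one group
  bad <- man
  bad$is_reference[bad$group_id == 1] <- TRUE
  p1 <- file.path(dir, "bad1.csv"); readr::write_csv(bad, p1)
  expect_error(load_dataset(p1), "exactly one reference")
  # duplicate (group, variant)
  bad2 <- man; bad2$variant_id[2] <- bad2$variant_id[1]
  p2 <- file.path(dir, "bad2.csv"); readr::write_csv(bad2, p2)
  expect_error(load_dataset(p2), "duplicate")
  # missing image file: error names the path
  bad3 <- man; bad3$file_path[1] <- "images/nothere.png"
  p3 <- file.path(dir, "bad3.csv"); readr::write_csv(bad3, p3)
  expect_error(load_dataset(p3), "nothere.png")
  expect_error(load_dataset(file.path(dir, "absent.csv")), "not found")
  expect_error(build_dataset(dir, n_groups = 0, size = 32, seed = 1), ">= 1")
})
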