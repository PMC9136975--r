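test_that("unit patches have the configured size and background statistics", {
  cfg_full <- imaging_config("full")
  p <- make_unit_patch(TRUE, cfg_full, seed = 1)
  expect_equal(dim(p$pixels), c(101L, 101L))   # default library crop size

  cfg <- fix_noisy()$cfg
  pe <- make_unit_patch(FALSE, cfg, seed = 2)
  expect_equal(dim(pe$pixels), c(9L, 9L))
  # background-only patch: mean within 5 sigma of the background level
  sd_mean <- cfg$background_noise_sd / sqrt(length(pe$pixels))
  expect_lt(abs(mean(pe$pixels) - cfg$background_level), 5 * sd_mean)

  # filled patches clearly exceed background in their interior
  pf <- make_unit_patch(TRUE, cfg, seed = 3)
  expect_gt(mean(pf$pixels[4:6, 4:6]), cfg$background_level + 0.3)
})

test_that("noiseless filled patches are exact centered constant squares", {
  cfg <- fix_noiseless()$cfg
  p <- make_unit_patch(TRUE, cfg, seed = 5)
  vals <- sort(unique(round(as.vector(p$pixels), 10)))
  expect_length(vals, 2L)                          # background and fill only
  expect_equal(vals[1], cfg$background_level)
  expect_equal(vals[2], cfg$background_level + cfg$fill_intensity_range[1])
  # mask is the centered square |u| <= 0.8 (rows/cols 2..8 of 9)
  bright <- p$pixels > cfg$background_level
  expect_equal(sum(bright), 49L)
  expect_true(all(bright[2:8, 2:8]))
})

test_that("patch libraries are seeded, sized, and non-degenerate", {
  cfg <- fix_noisy()$cfg
  lib1 <- build_patch_library(30, cfg, seed = 7)
  lib2 <- build_patch_library(30, cfg, seed = 7)
  expect_length(lib1$filled, 30L)
  expect_length(lib1$empty, 30L)
  expect_identical(lib1$filled[[17]]$pixels, lib2$filled[[17]]$pixels)
  # nonzero edge roughness: no two filled patches are pixel-identical
  mats <- vapply(lib1$filled, function(p) p$pixels, lib1$filled[[1]]$pixels)
  expect_equal(anyDuplicated(apply(mats, 3, paste, collapse = ",")), 0L)
})

test_that("channel composition places signal only at matching cells", {
  nl <- fix_noiseless()
  cfg_full <- imaging_config("full")
  expect_equal(cfg_full$canvas, c(648L, 692L))   # 692 x 648 (w x h) image

  # all-NONE code: every cell interior is indistinguishable from background
  empty <- matrix_code(matrix(0L, 7, 7))
  img <- compose_channel_image(empty, "ECFP", nl$lib, nl$cfg, seed = 1)
  stats <- grid_cell_stats(img, nl$layout)
  expect_true(all(abs(stats - nl$cfg$background_level) < 1e-12))

  # one EGFP cell at grid row 4, col 4 (0-based (3,3)): its interior mean
  # is the unique maximum
  cells <- matrix(0L, 7, 7); cells[4, 4] <- code_symbols[["EGFP"]]
  img <- compose_channel_image(matrix_code(cells), "EGFP", nl$lib, nl$cfg,
                               seed = 2)
  stats <- grid_cell_stats(img, nl$layout)
  expect_equal(which.max(stats), (4L - 1L) * 7L + 4L)   # row-major index
  expect_equal(sum(stats > nl$cfg$background_level + 0.1), 1L)
  # the other channels see an empty grid
  img_other <- compose_channel_image(matrix_code(cells), "MKATE2", nl$lib,
                                     nl$cfg, seed = 2)
  expect_true(all(grid_cell_stats(img_other, nl$layout) <
                    nl$cfg$background_level + 0.1))
})

test_that("rendering a code yields three consistent channel rasters", {
  nl <- fix_noiseless()
  m <- random_code(7, seed = 31)
  set1 <- render_code(m, nl$lib, nl$cfg, seed = 5)
  expect_named(set1$channels, c("ECFP", "EGFP", "MKATE2"))
  expect_length(concat_key(encode_channels(set1$truth))$bits, 147)

  # per-channel foreground cell count equals the symbol count in the code
  thr <- nl$cfg$background_level + 0.5 * nl$cfg$fill_intensity_range[1]
  for (ch in channel_order) {
    stats <- grid_cell_stats(set1$channels[[ch]], nl$layout)
    expect_equal(sum(stats > thr), sum(m$cells == code_symbols[[ch]]))
  }

  # bit-for-bit reproducibility under the same seed
  set2 <- render_code(m, nl$lib, nl$cfg, seed = 5)
  for (ch in channel_order)
    expect_identical(set1$channels[[ch]], set2$channels[[ch]])
})

test_that("datasets carry matching truths and a stable manifest", {
  ns <- fix_noisy()
  d1 <- generate_dataset(6, ns$lib, ns$cfg, seed = 41)
  d2 <- generate_dataset(6, ns$lib, ns$cfg, seed = 41)
  expect_length(d1$items, 6L)
  expect_equal(d1$manifest$config_hash, d2$manifest$config_hash)
  expect_identical(d1$items[[3]]$raster, d2$items[[3]]$raster)
  expect_equal(vapply(d1$items, `[[`, "", "channel")[1:3],
               c("ECFP", "EGFP", "MKATE2"))
  for (it in d1$items) expect_length(it$key$bits, 49)

  dc <- generate_dataset(2, ns$lib, ns$cfg, seed = 42, mode = "code")
  expect_s3_class(dc$items[[1]]$images, "code_image_set")
  expect_length(dc$items[[1]]$key$bits, 147)
})

test_that("intensity degradation scales foreground linearly and only foreground", {
  nl <- fix_noiseless()
  m <- random_code(7, seed = 51)
  img <- compose_channel_image(m, "ECFP", nl$lib, nl$cfg, seed = 6)
  bg <- nl$cfg$background_level

  expect_equal(degrade_intensity(img, 1), img)
  flat <- degrade_intensity(img, 0)
  expect_true(all(abs(flat - bg) < 1e-12))

  half <- degrade_intensity(img, 0.5)
  fg <- img > bg
  expect_equal(half[fg] - bg, (img[fg] - bg) / 2)
  expect_equal(half[!fg], img[!fg])
  expect_error(degrade_intensity(img, 1.5), "fraction")

  # render-time degradation: contrast is proportional to the fraction
  cfg75 <- nl$cfg; cfg75$intensity_fraction <- 0.75
  img75 <- compose_channel_image(m, "ECFP", nl$lib, cfg75, seed = 6)
  s100 <- grid_cell_stats(img, nl$layout)
  s75 <- grid_cell_stats(img75, nl$layout)
  expect_equal(s75 - bg, (s100 - bg) * 0.75, tolerance = 1e-10)
})

test_that("grid geometry errors on layouts that cannot fit", {
  expect_error(imaging_config("desk", unit_active_side = 20L),
               "overflows canvas")
  expect_error(imaging_config("desk", intensity_fraction = 1.2), "intensity")
  cfg <- fix_noisy()$cfg
  lib101 <- build_patch_library(2, imaging_config("full"), seed = 1)
  expect_error(compose_channel_image(random_code(7, seed = 1), "ECFP",
                                     lib101, cfg), "patch side")
})

test_that("rasters round-trip through image files at format precision", {
  ns <- fix_noisy()
  img <- compose_channel_image(random_code(7, seed = 61), "EGFP",
                               ns$lib, ns$cfg, seed = 7)
  tol <- c(".png" = 1 / 255, ".tif" = 1 / 65535)  # 8-bit PNG, 16-bit TIFF
  for (ext in names(tol)) {
    path <- tempfile(fileext = ext)
    write_raster(img, path)
    back <- read_raster(path)
    expect_equal(dim(back), dim(img))
    expect_lt(max(abs(back - img)), tol[[ext]] + 1e-9)
  }
})
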