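test_that("preprocessing preserves constants, kills impulses, keeps CNR", {
  cfg <- seg_config()
  const <- matrix(0.4, 32, 32)
  expect_identical(preprocess_slice(const, cfg), const)
  imp <- matrix(0, 21, 21)
  imp[11, 11] <- 1
  expect_equal(max(preprocess_slice(imp, cfg)), 0)
  expect_error(preprocess_slice(matrix(1.5, 4, 4), cfg), "\\[0, 1\\]")
  # shell/background separability (Fisher criterion against the truth
  # mask) does not decrease
  st <- small_stack(noise = noise_model(seed = 2))
  s <- (length(st$slices) + 1L) %/% 2L
  img <- st$slices[[s]]
  tm <- st$truth_masks[[s]]
  fisher <- function(im) {
    (mean(im[tm]) - mean(im[!tm]))^2 / (var(im[tm]) + var(im[!tm]))
  }
  expect_gte(fisher(preprocess_slice(img, cfg)), fisher(img))
})

test_that("featureless slices give empty masks", {
  cfg <- seg_config()
  expect_false(any(segment_slice(matrix(0.3, 64, 64), cfg)$mask))
  # lumen + tissue but no hyperechoic object
  img <- rbind(matrix(0.05, 30, 64), matrix(0.30, 34, 64))
  expect_false(any(segment_slice(img, cfg)$mask))
})

test_that("segmentation recovers the truth masks on rendered slices", {
  # noise-free: near-perfect overlap
  st0 <- small_stack(noise = zero_noise())
  expect_gte(stack_dice(st0), 0.95)
  # default noise, seed 1: still a solid overlap
  st1 <- small_stack(noise = noise_model(seed = 1))
  expect_gte(stack_dice(st1), 0.80)
})

test_that("thresholds select the hyperechoic class on noise-free renders", {
  st <- small_stack(noise = zero_noise())
  s <- (length(st$slices) + 1L) %/% 2L
  img <- st$slices[[s]]
  for (cfg in list(seg_config(threshold_mode = "otsu"),
                   seg_config(threshold_mode = "quantile", quantile = 0.95))) {
    m <- segment_slice(preprocess_slice(img, cfg), cfg)
    expect_true(any(m$mask))
    expect_gte(mean(img[m$mask]), 0.90 - 0.05)
  }
})

test_that("Dice against truth does not improve with heavier speckle", {
  ph <- small_phantom(2.0, 0.1)
  g3 <- scan_geometry(3, slice_spacing = 0.25,
                      image_rows = 140, image_cols = 192,
                      origin = c(ph$center_xy[1] - 191 * 0.025,
                                 ph$center_xy[2] - 0.25, 0))
  sc <- make_scene(ph)
  scales <- c(0.15, 0.30, 0.60)
  mean_dice <- vapply(scales, function(sp) {
    mean(vapply(1:10, function(seed) {
      st <- render_stack(sc, g3, noise_model(speckle_scale = sp, seed = seed))
      stack_dice(st)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_dice) <= 0))
})

test_that("extraction modes behave on canonical masks", {
  cfg_all <- seg_config(extraction_mode = "all")
  cfg_cl <- seg_config(extraction_mode = "centerline")
  cfg_oe <- seg_config(extraction_mode = "outer_edge")
  # full disk: centerline concentrates at the center ridge
  n <- 61
  d <- sqrt(outer((1:n - 31)^2, (1:n - 31)^2, "+"))
  disk <- d <= 20
  ctr <- extract_shell_points(slice_mask(disk), cfg_cl)
  expect_true(all(sqrt((ctr[, 1] - 30)^2 + (ctr[, 2] - 30)^2) <= 3))
  # annulus band 3.0-3.2 mm at 0.05 mm/px: centerline at 3.1 +/- one pixel
  nn <- 256
  dmm <- 0.05 * sqrt(outer((1:nn - 129)^2, (1:nn - 129)^2, "+"))
  band <- dmm >= 3.0 & dmm <= 3.2
  cl <- extract_shell_points(slice_mask(band), cfg_cl)
  r_cl <- 0.05 * sqrt((cl[, 1] - 128)^2 + (cl[, 2] - 128)^2)
  expect_true(all(abs(r_cl - 3.1) <= 0.05 + 1e-9))
  # outer edge sits at the outer boundary
  oe <- extract_shell_points(slice_mask(band), cfg_oe)
  r_oe <- 0.05 * sqrt((oe[, 1] - 128)^2 + (oe[, 2] - 128)^2)
  expect_true(all(r_oe >= 3.1))
  expect_true(all(r_oe <= 3.2 + 0.05))
  # one-pixel arc: centerline returns the arc itself; outer edge may drop
  # the few staircase pixels whose rounded outward step lands on the arc
  arc <- matrix(FALSE, 41, 41)
  th <- seq(0, pi / 2, length.out = 60)
  arc[cbind(21 + round(15 * sin(th)), 21 + round(15 * cos(th)))] <- TRUE
  ref <- extract_shell_points(slice_mask(arc), cfg_all)
  got_cl <- extract_shell_points(slice_mask(arc), cfg_cl)
  expect_identical(got_cl[order(got_cl[, 1], got_cl[, 2]), ],
                   ref[order(ref[, 1], ref[, 2]), ])
  got_oe <- extract_shell_points(slice_mask(arc), cfg_oe)
  expect_true(all(arc[got_oe + 1]))
  expect_gte(nrow(got_oe), 0.9 * nrow(ref))
  # consistency: centerline is a subset of the mask and never larger
  m_all <- extract_shell_points(slice_mask(band), cfg_all)
  expect_lte(nrow(cl), nrow(m_all))
  expect_true(all(band[cl + 1]))
  # empty mask gives an empty list
  expect_identical(nrow(extract_shell_points(slice_mask(matrix(FALSE, 4, 4)),
                                             cfg_cl)), 0L)
})

test_that("segmentation config validates its fields", {
  expect_error(seg_config(quantile = 0.4), "quantile")
  expect_error(seg_config(quantile = 1), "quantile")
  expect_error(seg_config(denoise_radius = -1), ">= 0")
  expect_error(seg_config(extraction_mode = "ridge"), "arg")
})
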