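test_that("phantom and scene constructors enforce their invariants", {
  expect_error(lesion_phantom(0), "positive")
  expect_error(lesion_phantom(-2), "positive")
  expect_error(lesion_phantom(3, -0.1), "non-negative")
  expect_error(lesion_phantom(3, cap_fraction = 0), "cap_fraction")
  expect_error(lesion_phantom(3, cap_fraction = 1.2), "cap_fraction")
  # the four phantom sizes of the validation series all construct
  for (r in c(2.0, 2.5, 3.0, 3.5)) {
    expect_s3_class(make_scene(lesion_phantom(r)), "acoustic_scene")
  }
  expect_error(make_scene(lesion_phantom(3), echo_levels = c(0.3, 0.05, 0.9)),
               "ordered")
  expect_error(make_scene(lesion_phantom(3), echo_levels = c(0.1, 0.5, 1.4)),
               "\\[0, 1\\]")
  expect_error(scan_geometry(10, slice_spacing = 0), "positive")
})

test_that("scene query returns the shell level on the membrane mid-surface", {
  ph <- lesion_phantom(3.0, 0.2, center_xy = c(5, 1), base_height = 7)
  sc <- make_scene(ph)
  mid <- 3.1  # tumor_radius + shell_thickness / 2
  # a point at distance `mid` from the center, above the base plane
  p_shell <- c(5, 1, 7) + mid * c(sin(0.4), 0, -cos(0.4))
  p_lumen <- c(5, 1, 7) + 4.5 * c(sin(0.4), 0, -cos(0.4))
  p_tumor <- c(5, 1, 7) + 1.0 * c(sin(0.4), 0, -cos(0.4))
  p_deep  <- c(5, 1, 7.5)
  got <- scene_intensity(sc, rbind(p_shell, p_lumen, p_tumor, p_deep))
  expect_equal(got, c(0.90, 0.05, 0.30, 0.30))
})

test_that("analytic shell sections follow the sphere-plane closed form", {
  ph <- lesion_phantom(3.0, 0.2)
  sec <- analytic_shell_section(ph, 0)
  expect_equal(sec$inner, 3.0)
  expect_equal(sec$outer, 3.2)
  expect_null(analytic_shell_section(ph, 3.2))   # tangent plane
  expect_null(analytic_shell_section(ph, 4.0))
  # zero-thickness shell, offset 1.8: sqrt(9 - 3.24) = 2.4
  sec2 <- analytic_shell_section(lesion_phantom(3.0, 0), 1.8)
  expect_equal(sec2$outer, 2.4)
  # plane between tumor and outer sphere cuts a full disk
  sec3 <- analytic_shell_section(ph, 3.1)
  expect_equal(sec3$inner, 0)
})

test_that("rendered slices match the analytic cross-section", {
  ph <- small_phantom(3.0, 0.2)
  g <- small_geometry(ph)
  sc <- make_scene(ph)
  # a slice plane beyond the shell: uniform tissue/lumen, empty mask
  rs_off <- render_slice(sc, g, 0L)
  expect_false(any(rs_off$mask))
  expect_setequal(unique(as.vector(rs_off$image)), c(0.05, 0.30))
  # central slice: mask pixel radii span [inner, outer] of the d = 0 section
  mid_idx <- (g$num_slices - 1L) %/% 2L
  rs <- render_slice(sc, g, mid_idx)
  expect_true(any(rs$mask))
  px <- which(rs$mask, arr.ind = TRUE) - 1
  w <- pixel_to_world(px[, 1], px[, 2], mid_idx, g)
  d_inplane <- sqrt((w[, 1] - ph$center_xy[1])^2 + (w[, 3] - ph$base_height)^2)
  half_diag <- 0.5 * sqrt(g$pixel_spacing_row^2 + g$pixel_spacing_col^2)
  expect_true(all(d_inplane >= 3.0 - half_diag))
  expect_true(all(d_inplane <= 3.2 + half_diag))
  expect_error(render_slice(sc, g, g$num_slices), "out of range")
})

test_that("truth masks stay within half a pixel diagonal of the analytic band", {
  for (t in c(0, 0.1)) {
    ph <- small_phantom(2.5, t)
    g <- small_geometry(ph)
    sc <- make_scene(ph)
    half_diag <- 0.5 * sqrt(g$pixel_spacing_row^2 + g$pixel_spacing_col^2)
    ro <- shell_outer_radius(ph)
    for (s in seq_len(g$num_slices) - 1L) {
      rs <- render_slice(sc, g, s)
      if (!any(rs$mask)) next
      px <- which(rs$mask, arr.ind = TRUE) - 1
      w <- pixel_to_world(px[, 1], px[, 2], s, g)
      rho <- sqrt((w[, 1] - ph$center_xy[1])^2 + (w[, 2] - ph$center_xy[2])^2 +
                    (w[, 3] - ph$base_height)^2)
      # 3D distance to the annulus solid between the tumor and outer spheres
      gap <- pmax(ph$tumor_radius - rho, rho - ro, 0)
      expect_true(all(gap <= half_diag + 1e-12))
    }
  }
})

test_that("zero noise reproduces the noise-free renders exactly", {
  ph <- small_phantom()
  g <- small_geometry(ph)
  sc <- make_scene(ph)
  st <- render_stack(sc, g, zero_noise())
  for (s in seq_len(g$num_slices)) {
    rs <- render_slice(sc, g, s - 1L)
    expect_identical(st$slices[[s]], rs$image)
    expect_identical(st$truth_masks[[s]], rs$mask)
  }
  # intensity ordering is exact at the configured levels
  img <- st$slices[[(g$num_slices + 1L) %/% 2L]]
  expect_setequal(unique(as.vector(img)), c(0.05, 0.30, 0.90))
})

test_that("stacks are deterministic in the seed and noisier than their masks", {
  a <- small_stack(noise = noise_model(seed = 7))
  b <- small_stack(noise = noise_model(seed = 7))
  c <- small_stack(noise = noise_model(seed = 8))
  expect_identical(a$slices, b$slices)
  expect_false(identical(a$slices, c$slices))
  # hyperechoic contrast survives the noise on every shell-bearing slice
  for (s in seq_along(a$slices)) {
    tm <- a$truth_masks[[s]]
    if (!any(tm)) next
    expect_gt(mean(a$slices[[s]][tm]), mean(a$slices[[s]][!tm]))
  }
})

test_that("render_stack does not disturb the caller's RNG stream", {
  set.seed(99)
  before <- runif(1)
  set.seed(99)
  invisible(small_stack(noise = noise_model(seed = 3)))
  expect_identical(runif(1), before)
})

test_that("slice coverage of the shell cap has no gap larger than the spacing", {
  ph <- small_phantom(3.0, 0.1)
  g <- small_geometry(ph)
  st <- render_stack(make_scene(ph), g, zero_noise())
  has <- which(vapply(st$truth_masks, any, logical(1)))
  ys <- g$origin[2] + (has - 1) * g$slice_spacing
  expect_true(all(diff(ys) <= g$slice_spacing + 1e-12))
  # the covered span reaches within one spacing of the shell's extent
  ro <- shell_outer_radius(ph)
  expect_lt(abs(min(ys) - (ph$center_xy[2] - ro)), g$slice_spacing)
  expect_lt(abs(max(ys) - (ph$center_xy[2] + ro)), g$slice_spacing)
})
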