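test_that("algebraic sphere fit is exact on canonical points and rejects degeneracy", {
  P <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0), c(0, 0, 1))
  est <- fit_sphere_lsq(P)
  expect_equal(est$radius, 1, tolerance = 1e-12)
  expect_equal(est$center, c(0, 0, 0), tolerance = 1e-12)
  expect_equal(est$rms_residual, 0, tolerance = 1e-12)
  expect_error(fit_sphere_lsq(P[1:3, ]), "degenerate")
  flat <- cbind(matrix(runif(40), ncol = 2), 0)
  expect_error(fit_sphere_lsq(flat), "degenerate")
})

test_that("sphere fit recovers a noisy hemisphere within 1%", {
  pts <- sphere_cap_samples(500, radius = 3, center = c(1, -2, 0.5),
                            cos_max = 0, sigma = 0.02, seed = 21)
  est <- fit_sphere_lsq(pts)
  expect_lt(abs(est$radius - 3) / 3, 0.01)
})

test_that("local PCA radii are exact on spheres, flag planes, and split fused caps", {
  # exactness within 1e-6 relative for several neighbourhood sizes
  pts <- sphere_cap_samples(600, radius = 2.7, center = c(3, 1, -2),
                            cos_max = 0.1, seed = 5)
  for (k in c(20, 60, 150)) {
    lr <- local_pca_radius(pts, k = k)
    expect_true(all(is.finite(lr)))
    expect_lt(max(abs(lr - 2.7) / 2.7), 1e-6)
  }
  # exact plane: flagged flat (infinite radius), excluded from aggregation
  set.seed(8)
  plane <- cbind(runif(200), runif(200), 0.25)
  lp <- local_pca_radius(plane, k = 15)
  expect_true(all(!is.na(lp)))
  expect_true(all(is.infinite(lp)))
  # two disjoint caps of radii 2 and 3: bimodal local radii
  cap2 <- sphere_cap_samples(700, radius = 2, center = c(0, 0, 0),
                             cos_max = 0.5, seed = 31)
  cap3 <- sphere_cap_samples(700, radius = 3, center = c(20, 0, 0),
                             cos_max = 0.5, seed = 32)
  lr2 <- local_pca_radius(rbind(cap2, cap3), k = 40)
  grp <- rep(c(2, 3), each = 700)
  expect_lt(max(abs(lr2[grp == 2] - 2)), 1e-6)
  expect_lt(max(abs(lr2[grp == 3] - 3)), 1e-6)
  expect_error(local_pca_radius(cap2, k = 700), "smaller")
  expect_error(local_pca_radius(cap2, k = 5), "at least 10")
})

test_that("local and global estimates agree on single-sphere caps", {
  # cap covering well over 30% of the hemisphere, light noise
  pts <- sphere_cap_samples(1500, radius = 3.2, cos_max = 0.4,
                            sigma = 0.005, seed = 13)
  cloud <- point_cloud(pts)
  eg <- estimate_radius(cloud, method = "global_sphere")
  el <- estimate_radius(cloud, method = "local_pca", k = 150)
  expect_lt(abs(el$radius - eg$radius) / eg$radius, 0.01)
  # and exactly (1e-6) on noise-free samples
  pts0 <- sphere_cap_samples(1000, radius = 3.2, cos_max = 0.2, seed = 14)
  cl0 <- point_cloud(pts0)
  e0g <- estimate_radius(cl0, method = "global_sphere", outliers = FALSE)
  e0l <- estimate_radius(cl0, method = "local_pca", k = 100, outliers = FALSE)
  expect_lt(abs(e0l$radius - e0g$radius) / e0g$radius, 1e-6)
})

test_that("estimates are invariant under rigid motion and equivariant under scaling", {
  pts <- sphere_cap_samples(800, radius = 2.4, cos_max = 0.3,
                            sigma = 0.01, seed = 17)
  cloud <- point_cloud(pts)
  base <- estimate_radius(cloud, method = "local_pca", k = 100)
  # a rotation about an arbitrary axis plus a translation
  th <- 0.83
  ax <- c(1, 2, 0.5) / sqrt(5.25)
  K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0), 3, 3)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
  moved <- point_cloud(sweep(pts %*% t(R), 2, c(5, -3, 11), "+"))
  est_m <- estimate_radius(moved, method = "local_pca", k = 100)
  expect_lt(abs(est_m$radius - base$radius) / base$radius, 1e-9)
  est_g <- estimate_radius(cloud, method = "global_sphere")
  est_gm <- estimate_radius(moved, method = "global_sphere")
  expect_lt(abs(est_gm$radius - est_g$radius) / est_g$radius, 1e-9)
  # scaling all coordinates scales the estimate (exact up to the
  # convergence jitter of the local refinement)
  for (s in c(0.5, 3)) {
    est_s <- estimate_radius(point_cloud(pts * s), method = "local_pca",
                             k = 100)
    expect_equal(est_s$radius, s * base$radius, tolerance = 1e-8)
  }
})

test_that("degenerate clouds raise degenerate-fit errors with diagnostics", {
  expect_error(estimate_radius(point_cloud(matrix(numeric(0), ncol = 3))),
               "empty")
  few <- point_cloud(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)))
  expect_error(estimate_radius(few, outliers = FALSE), "degenerate")
})

test_that("shell correction shifts the estimate by exactly the half band", {
  pts <- sphere_cap_samples(600, radius = 3.05, cos_max = 0.2, seed = 19)
  cloud <- point_cloud(pts)
  plain <- estimate_radius(cloud, method = "global_sphere")
  corr <- estimate_radius(cloud, method = "global_sphere",
                          shell_correction = 0.05)
  expect_equal(plain$radius - corr$radius, 0.05, tolerance = 1e-12)
  expect_equal(corr$shell_correction, 0.05)
})
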