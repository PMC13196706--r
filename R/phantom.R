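#' Hemispherical lesion phantom with a conformal hyperechoic shell
#'
#' Describes the ground-truth geometry used by the synthetic B-mode renderer:
#' a hemispherical tumor of radius `tumor_radius` protruding from a flat
#' tissue plane into the lumen, wrapped by a thin echogenic shell. The shell
#' occupies the spherical annulus between `tumor_radius` and
#' `tumor_radius + shell_thickness` above the base plane, restricted to the
#' cap fraction measured from the apex.
#'
#' `shell_thickness` models the thickness of the echogenic interface layer
#' that B-mode resolves (the strong reflection at the tumor/air-cavity
#' boundary), not the full physical substrate of the device.
#'
#' @param tumor_radius Tumor (lesion) radius in mm; must be positive.
#' @param shell_thickness Echogenic shell thickness in mm; non-negative.
#' @param center_xy Planar (x, y) position of the hemisphere center in mm.
#' @param base_height Depth (z, along the image rows) of the flat tissue
#'   plane in mm. The hemisphere protrudes toward the probe, i.e. toward
#'   smaller z.
#' @param cap_fraction Portion of the hemisphere covered by the shell,
#'   measured from the apex, in `(0, 1]`. `1` is a full hemispherical wrap.
#' @return An object of class `lesion_phantom`.
#' @seealso [make_scene()], [default_scan_geometry()], [analytic_shell_section()]
#' @export
#' @examples
#' lesion_phantom(3.0)
lesion_phantom <- function(tumor_radius, shell_thickness = 0.1,
                           center_xy = c(6.4, 0), base_height = 8,
                           cap_fraction = 1) {
  if (!is.numeric(tumor_radius) || length(tumor_radius) != 1L ||
      !is.finite(tumor_radius) || tumor_radius <= 0) {
    stop("'tumor_radius' must be a single positive number (mm)")
  }
  if (!is.numeric(shell_thickness) || length(shell_thickness) != 1L ||
      !is.finite(shell_thickness) || shell_thickness < 0) {
    stop("'shell_thickness' must be a single non-negative number (mm)")
  }
  if (length(center_xy) != 2L || !all(is.finite(center_xy))) {
    stop("'center_xy' must be two finite coordinates (mm)")
  }
  if (!is.finite(base_height)) stop("'base_height' must be finite")
  if (!is.finite(cap_fraction) || cap_fraction <= 0 || cap_fraction > 1) {
    stop("'cap_fraction' must lie in (0, 1]")
  }
  structure(
    list(tumor_radius = as.numeric(tumor_radius),
         shell_thickness = as.numeric(shell_thickness),
         center_xy = as.numeric(center_xy),
         base_height = as.numeric(base_height),
         cap_fraction = as.numeric(cap_fraction)),
    class = "lesion_phantom"
  )
}

#' @export
print.lesion_phantom <- function(x, ...) {
  cat(sprintf(
    "<lesion_phantom> tumor radius %.3g mm, shell %.3g mm, cap fraction %.2f\n",
    x$tumor_radius, x$shell_thickness, x$cap_fraction))
  invisible(x)
}

#' Outer radius of the shell annulus
#' @param phantom A [lesion_phantom()].
#' @return Tumor radius plus shell thickness, mm.
#' @export
shell_outer_radius <- function(phantom) {
  phantom$tumor_radius + phantom$shell_thickness
}

#' Scan geometry of a parallel-slice B-mode acquisition
#'
#' Parallel slice planes orthogonal to the scan (y) axis, each sampled on a
#' regular `image_rows` x `image_cols` pixel grid. See the package help for
#' the pixel-to-world convention (0-based indices).
#'
#' @param num_slices Number of slices; at least 1.
#' @param slice_spacing Distance between adjacent slice planes, mm.
#' @param pixel_spacing_row,pixel_spacing_col In-plane pixel pitch, mm.
#' @param image_rows,image_cols Image dimensions in pixels.
#' @param origin World position (mm) of pixel (0, 0) in slice 0.
#' @return An object of class `scan_geometry`.
#' @export
scan_geometry <- function(num_slices, slice_spacing = 0.25,
                          pixel_spacing_row = 0.05, pixel_spacing_col = 0.05,
                          image_rows = 256, image_cols = 256,
                          origin = c(0, 0, 0)) {
  num_slices <- as.integer(num_slices)
  if (is.na(num_slices) || num_slices < 1L) stop("'num_slices' must be >= 1")
  sp <- c(slice_spacing, pixel_spacing_row, pixel_spacing_col)
  if (!all(is.finite(sp)) || any(sp <= 0)) {
    stop("all spacings must be positive and finite (mm)")
  }
  if (image_rows < 1 || image_cols < 1) stop("image dimensions must be >= 1")
  if (length(origin) != 3L || !all(is.finite(origin))) {
    stop("'origin' must be three finite coordinates (mm)")
  }
  structure(
    list(num_slices = num_slices, slice_spacing = as.numeric(slice_spacing),
         pixel_spacing_row = as.numeric(pixel_spacing_row),
         pixel_spacing_col = as.numeric(pixel_spacing_col),
         image_rows = as.integer(image_rows),
         image_cols = as.integer(image_cols),
         origin = as.numeric(origin)),
    class = "scan_geometry"
  )
}

#' Default scan geometry covering a phantom
#'
#' Centers the lateral field of view and the slice span on the phantom and
#' chooses enough equally spaced slices to cover the shell plus a margin,
#' never fewer than `min_slices`. Defaults follow a high-frequency linear
#' probe: 0.05 mm pixels on a 256 x 256 grid, 0.25 mm slice spacing.
#'
#' @param phantom A [lesion_phantom()].
#' @inheritParams scan_geometry
#' @param margin Extra lateral coverage beyond the shell on each side, mm.
#' @param min_slices Lower bound on the slice count.
#' @return A [scan_geometry()].
#' @export
default_scan_geometry <- function(phantom, slice_spacing = 0.25,
                                  pixel_spacing_row = 0.05,
                                  pixel_spacing_col = 0.05,
                                  image_rows = 256, image_cols = 256,
                                  margin = 0.5, min_slices = 15) {
  half_span <- shell_outer_radius(phantom) + margin
  half_n <- ceiling(half_span / slice_spacing)
  num_slices <- max(as.integer(min_slices), 2L * as.integer(half_n) + 1L)
  origin <- c(
    phantom$center_xy[1] - (image_cols - 1) / 2 * pixel_spacing_col,
    phantom$center_xy[2] - (num_slices - 1) / 2 * slice_spacing,
    0
  )
  geom <- scan_geometry(num_slices, slice_spacing, pixel_spacing_row,
                        pixel_spacing_col, image_rows, image_cols, origin)
  # the field of view must contain the whole shell cap
  zmax <- origin[3] + (image_rows - 1) * pixel_spacing_row
  xmin <- origin[1]
  xmax <- origin[1] + (image_cols - 1) * pixel_spacing_col
  ro <- shell_outer_radius(phantom)
  if (phantom$base_height > zmax || phantom$base_height - ro < origin[3] ||
      phantom$center_xy[1] - ro < xmin || phantom$center_xy[1] + ro > xmax) {
    stop("field of view does not cover the phantom; enlarge the image or ",
         "move the phantom")
  }
  geom
}

#' B-mode degradation model for the synthetic renderer
#'
#' All parameters default to a moderately noisy high-frequency B-mode
#' acquisition; a model with every parameter zero reproduces the noise-free
#' render exactly. The realization is fully determined by `seed`.
#'
#' @param speckle_scale Relative standard deviation of the mean-one
#'   multiplicative gamma speckle (shape `1/speckle_scale^2`). 0 disables.
#' @param psf_sigma Gaussian point-spread sigma, mm.
#' @param additive_sigma Additive Gaussian noise sigma, intensity fraction.
#' @param attenuation Residual depth attenuation after gain compensation,
#'   per mm of imaging depth.
#' @param seed Integer RNG seed.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(speckle_scale = 0.3, psf_sigma = 0.05,
                        additive_sigma = 0.02, attenuation = 0.03,
                        seed = 1L) {
  v <- c(speckle_scale, psf_sigma, additive_sigma, attenuation)
  if (!all(is.finite(v)) || any(v < 0)) {
    stop("noise parameters must be non-negative and finite")
  }
  structure(
    list(speckle_scale = as.numeric(speckle_scale),
         psf_sigma = as.numeric(psf_sigma),
         additive_sigma = as.numeric(additive_sigma),
         attenuation = as.numeric(attenuation),
         seed = as.integer(seed)),
    class = "noise_model"
  )
}

#' Noise-free acoustic scene of a wrapped lesion
#'
#' Builds the queryable 3D echogenicity field: lumen above the tissue plane,
#' tissue below it and inside the tumor, and a bright shell annulus between
#' `tumor_radius` and the shell outer radius above the base plane, restricted
#' to the wrapped cap. The three echo levels must be strictly ordered
#' lumen < tissue < shell.
#'
#' @param phantom A [lesion_phantom()].
#' @param echo_levels Named or positional intensities `c(lumen, tissue,
#'   shell)`, each in `[0, 1]`, strictly increasing.
#' @return An object of class `acoustic_scene`.
#' @export
make_scene <- function(phantom,
                       echo_levels = c(lumen = 0.05, tissue = 0.30,
                                       shell = 0.90)) {
  stopifnot(inherits(phantom, "lesion_phantom"))
  if (length(echo_levels) != 3L || !all(is.finite(echo_levels))) {
    stop("'echo_levels' must be three finite intensities")
  }
  lv <- as.numeric(echo_levels)
  if (any(lv < 0) || any(lv > 1)) stop("echo levels must lie in [0, 1]")
  if (!(lv[1] < lv[2] && lv[2] < lv[3])) {
    stop("echo levels must be strictly ordered lumen < tissue < shell")
  }
  structure(
    list(phantom = phantom,
         echo_levels = c(lumen = lv[1], tissue = lv[2], shell = lv[3])),
    class = "acoustic_scene"
  )
}

#' Region membership of 3D points in an acoustic scene
#'
#' @param scene An [make_scene()] scene.
#' @param points N x 3 matrix of world coordinates, mm.
#' @param membrane_halfwidth Half-width of the rendered shell membrane around
#'   its mid-surface, mm. Defaults to half the shell thickness; renderers
#'   widen it to the resolution limit so a zero-thickness membrane still
#'   reflects.
#' @return Integer vector: 0 lumen, 1 tissue, 2 shell.
#' @export
scene_region <- function(scene, points,
                         membrane_halfwidth =
                           scene$phantom$shell_thickness / 2) {
  ph <- scene$phantom
  points <- matrix(as.numeric(points), ncol = 3L)
  dx <- points[, 1] - ph$center_xy[1]
  dy <- points[, 2] - ph$center_xy[2]
  dz <- points[, 3] - ph$base_height
  rho <- sqrt(dx^2 + dy^2 + dz^2)
  mid <- ph$tumor_radius + ph$shell_thickness / 2
  above <- points[, 3] <= ph$base_height + 1e-12
  # polar cosine from the apex direction (toward the probe)
  cos_apex <- ifelse(rho > 0, -dz / rho, 1)
  in_cap <- cos_apex >= (1 - ph$cap_fraction) - 1e-12
  shell <- abs(rho - mid) <= membrane_halfwidth + 1e-12 & above & in_cap
  tissue <- !shell & (!above | rho <= ph$tumor_radius)
  out <- integer(nrow(points))
  out[tissue] <- 1L
  out[shell] <- 2L
  out
}

#' Echogenicity of 3D points in an acoustic scene
#'
#' @inheritParams scene_region
#' @return Intensities in `[0, 1]`, one per point.
#' @export
scene_intensity <- function(scene, points,
                            membrane_halfwidth =
                              scene$phantom$shell_thickness / 2) {
  unname(scene$echo_levels[scene_region(scene, points,
                                        membrane_halfwidth) + 1L])
}

#' Analytic cross-section of the shell annulus
#'
#' Exact in-plane radii of the intersection between the shell annulus (the
#' solid between the tumor sphere and the shell outer sphere) and a plane at
#' signed distance `plane_offset` from the sphere center along the scan axis.
#' Serves as the geometric oracle for segmentation and reconstruction tests.
#'
#' @param phantom A [lesion_phantom()].
#' @param plane_offset Signed plane distance from the sphere center, mm.
#' @return `NULL` when the plane misses the shell, otherwise
#'   `list(inner, outer)` in mm (inner is 0 when the plane no longer cuts the
#'   tumor sphere).
#' @export
analytic_shell_section <- function(phantom, plane_offset) {
  stopifnot(inherits(phantom, "lesion_phantom"))
  d2 <- plane_offset^2
  ro <- shell_outer_radius(phantom)
  if (d2 >= ro^2) return(NULL)
  inner2 <- phantom$tumor_radius^2 - d2
  list(inner = if (inner2 > 0) sqrt(inner2) else 0,
       outer = sqrt(ro^2 - d2))
}

#' Render one noise-free B-mode slice
#'
#' Samples the scene at pixel centers on the requested slice plane. The truth
#' mask marks pixels whose centers fall in the shell membrane; the membrane
#' half-width is never narrower than half the smaller in-plane pixel pitch,
#' so arbitrarily thin shells still produce a one-pixel band.
#'
#' @param scene An [make_scene()] scene.
#' @param geometry A [scan_geometry()].
#' @param slice_index 0-based slice index.
#' @return `list(image, mask)`: intensity matrix in `[0, 1]` and logical
#'   truth mask, both `image_rows` x `image_cols`.
#' @export
render_slice <- function(scene, geometry, slice_index) {
  stopifnot(inherits(scene, "acoustic_scene"),
            inherits(geometry, "scan_geometry"))
  slice_index <- as.integer(slice_index)
  if (is.na(slice_index) || slice_index < 0L ||
      slice_index >= geometry$num_slices) {
    stop("'slice_index' out of range [0, num_slices)")
  }
  nr <- geometry$image_rows
  nc <- geometry$image_cols
  xs <- geometry$origin[1] + (seq_len(nc) - 1) * geometry$pixel_spacing_col
  zs <- geometry$origin[3] + (seq_len(nr) - 1) * geometry$pixel_spacing_row
  y <- geometry$origin[2] + slice_index * geometry$slice_spacing
  pts <- cbind(rep(xs, each = nr), y, rep(zs, times = nc))
  hw <- max(scene$phantom$shell_thickness / 2,
            0.5 * min(geometry$pixel_spacing_row, geometry$pixel_spacing_col))
  region <- scene_region(scene, pts, membrane_halfwidth = hw)
  lv <- unname(scene$echo_levels)
  list(image = matrix(lv[region + 1L], nrow = nr, ncol = nc),
       mask = matrix(region == 2L, nrow = nr, ncol = nc))
}

#' Ordered B-mode slice stack
#'
#' @param slices List of intensity matrices in `[0, 1]`, one per slice.
#' @param geometry A [scan_geometry()] with `num_slices == length(slices)`.
#' @param truth_masks Optional list of logical matrices aligned pixelwise
#'   with `slices`.
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(slices, geometry, truth_masks = NULL) {
  stopifnot(inherits(geometry, "scan_geometry"), is.list(slices))
  if (length(slices) != geometry$num_slices) {
    stop("length(slices) must equal geometry$num_slices")
  }
  dims <- c(geometry$image_rows, geometry$image_cols)
  ok <- vapply(slices, function(s) identical(dim(s), as.integer(dims)),
               logical(1))
  if (!all(ok)) stop("all slices must be image_rows x image_cols matrices")
  if (!is.null(truth_masks)) {
    if (length(truth_masks) != length(slices)) {
      stop("truth_masks must align with slices")
    }
    okm <- vapply(truth_masks,
                  function(s) identical(dim(s), as.integer(dims)),
                  logical(1))
    if (!all(okm)) stop("all truth masks must match the slice dimensions")
  }
  structure(list(slices = slices, geometry = geometry,
                 truth_masks = truth_masks),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  g <- x$geometry
  cat(sprintf("<image_stack> %d slices of %d x %d px (%.3g x %.3g mm/px, %.3g mm apart)%s\n",
              g$num_slices, g$image_rows, g$image_cols, g$pixel_spacing_row,
              g$pixel_spacing_col, g$slice_spacing,
              if (is.null(x$truth_masks)) "" else ", with truth masks"))
  invisible(x)
}

# Run code with a private, seeded RNG stream; the caller's RNG state is
# untouched.
with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Render a full synthetic B-mode stack with speckle and blur
#'
#' Per slice: noise-free render, Gaussian point-spread blur, mean-one
#' multiplicative gamma speckle, exponential depth attenuation, additive
#' Gaussian noise, and clipping to `[0, 1]`. Truth masks are kept noise-free.
#' The same `(scene, geometry, noise)` triple always yields a bitwise
#' identical stack.
#'
#' @param scene An [make_scene()] scene.
#' @param geometry A [scan_geometry()].
#' @param noise A [noise_model()]; all-zero parameters reproduce the
#'   noise-free renders exactly.
#' @return An [image_stack()] carrying the phantom and noise model as
#'   attributes `phantom` and `noise`.
#' @export
render_stack <- function(scene, geometry, noise = noise_model()) {
  stopifnot(inherits(noise, "noise_model"))
  nr <- geometry$image_rows
  nc <- geometry$image_cols
  depth <- geometry$origin[3] + (seq_len(nr) - 1) * geometry$pixel_spacing_row
  atten <- exp(-noise$attenuation * depth)
  shape <- if (noise$speckle_scale > 0) 1 / noise$speckle_scale^2 else NA_real_
  slices <- vector("list", geometry$num_slices)
  masks <- vector("list", geometry$num_slices)
  with_seed(noise$seed, {
    for (s in seq_len(geometry$num_slices)) {
      rs <- render_slice(scene, geometry, s - 1L)
      img <- rs$image
      if (noise$psf_sigma > 0) {
        img <- gaussian_blur(img,
                             sigma_row = noise$psf_sigma / geometry$pixel_spacing_row,
                             sigma_col = noise$psf_sigma / geometry$pixel_spacing_col)
      }
      if (noise$speckle_scale > 0) {
        img <- img * matrix(rgamma(nr * nc, shape = shape, rate = shape),
                            nrow = nr)
      }
      if (noise$attenuation > 0) img <- img * atten
      if (noise$additive_sigma > 0) {
        img <- img + matrix(rnorm(nr * nc, sd = noise$additive_sigma),
                            nrow = nr)
      }
      slices[[s]] <- pmin(pmax(img, 0), 1)
      masks[[s]] <- rs$mask
    }
  })
  out <- image_stack(slices, geometry, truth_masks = masks)
  attr(out, "phantom") <- scene$phantom
  attr(out, "noise") <- noise
  out
}

#' Convenience generator: phantom to noisy stack in one call
#'
#' @param tumor_radius Tumor radius, mm.
#' @param shell_thickness Shell thickness, mm.
#' @param noise A [noise_model()].
#' @param ... Passed to [default_scan_geometry()].
#' @return An [image_stack()] with truth masks and phantom attribute.
#' @export
simulate_stack <- function(tumor_radius, shell_thickness = 0.1,
                           noise = noise_model(), ...) {
  phantom <- lesion_phantom(tumor_radius, shell_thickness)
  geometry <- default_scan_geometry(phantom, ...)
  render_stack(make_scene(phantom), geometry, noise)
}
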