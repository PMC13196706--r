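# Shared fixtures, built in code. The "small" world is a downscaled scan
# (9.6 x 7 mm field, same pixel pitch as the default geometry) so module
# tests stay fast; acceptance tests use the full default geometry.

small_phantom <- function(tumor_radius = 2.5, shell_thickness = 0.1,
                          cap_fraction = 1) {
  lesion_phantom(tumor_radius, shell_thickness, center_xy = c(4.8, 0),
                 base_height = 6, cap_fraction = cap_fraction)
}

small_geometry <- function(phantom, ...) {
  default_scan_geometry(phantom, image_rows = 140, image_cols = 192,
                        margin = 0.4, ...)
}

small_stack <- function(tumor_radius = 2.5, shell_thickness = 0.1,
                        noise = noise_model(), ...) {
  ph <- small_phantom(tumor_radius, shell_thickness)
  render_stack(make_scene(ph), small_geometry(ph, ...), noise)
}

zero_noise <- function(seed = 1L) noise_model(0, 0, 0, 0, seed = seed)

# Uniform samples of a spherical cap: polar cosine from the cap axis drawn
# uniformly in [cos_max, 1] (area-uniform), azimuth uniform.
sphere_cap_samples <- function(n, radius = 3, center = c(0, 0, 0),
                               cos_max = 0, sigma = 0, seed = 1) {
  stopifnot(cos_max >= -1, cos_max < 1)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  u <- runif(n, cos_max, 1)
  phi <- runif(n, 0, 2 * pi)
  s <- sqrt(1 - u^2)
  pts <- radius * cbind(s * cos(phi), s * sin(phi), u)
  if (sigma > 0) pts <- pts + matrix(rnorm(3 * n, sd = sigma), ncol = 3)
  sweep(pts, 2, center, "+")
}

# pooled Dice between segmented and truth masks over every slice of a stack
stack_dice <- function(stack, config = seg_config()) {
  tp <- fp <- fn <- 0
  for (s in seq_along(stack$slices)) {
    tm <- stack$truth_masks[[s]]
    m <- segment_slice(preprocess_slice(stack$slices[[s]], config), config,
                       s - 1L)
    tp <- tp + sum(m$mask & tm)
    fp <- fp + sum(m$mask & !tm)
    fn <- fn + sum(!m$mask & tm)
  }
  2 * tp / (2 * tp + fp + fn)
}
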