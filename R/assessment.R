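#' Pipeline configuration
#'
#' Nested configuration for the full estimation chain. Unknown keys in any
#' section are rejected, so typos fail loudly.
#'
#' @param seg A [seg_config()].
#' @param outlier List with `k` and `n_sigma` for [remove_outliers()].
#' @param curvature List with `method` (`"local_pca"` or `"global_sphere"`)
#'   and neighbourhood size `k`.
#' @param shell_correction Length subtracted from the fitted radius to
#'   convert a band-midline radius into a lesion-surface radius, mm.
#'   0 (off) by default.
#' @param verbose Emit per-stage messages.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(seg = seg_config(),
                            outlier = list(k = 8L, n_sigma = 2.0),
                            curvature = list(method = "local_pca", k = 150L),
                            shell_correction = 0,
                            verbose = FALSE) {
  stopifnot(inherits(seg, "seg_config"))
  check_keys <- function(x, allowed, what) {
    extra <- setdiff(names(x), allowed)
    if (length(extra)) {
      stop(sprintf("unknown %s key(s): %s", what,
                   paste(extra, collapse = ", ")))
    }
  }
  check_keys(outlier, c("k", "n_sigma"), "outlier")
  check_keys(curvature, c("method", "k"), "curvature")
  outlier <- utils::modifyList(list(k = 8L, n_sigma = 2.0), outlier)
  curvature <- utils::modifyList(list(method = "local_pca", k = 150L),
                                 curvature)
  if (!curvature$method %in% c("local_pca", "global_sphere")) {
    stop("curvature$method must be 'local_pca' or 'global_sphere'")
  }
  if (!is.numeric(shell_correction) || shell_correction < 0) {
    stop("'shell_correction' must be a non-negative length (mm)")
  }
  structure(list(seg = seg, outlier = outlier, curvature = curvature,
                 shell_correction = as.numeric(shell_correction),
                 verbose = isTRUE(verbose)),
            class = "pipeline_config")
}

#' Run the full estimation pipeline on one stack
#'
#' Segmentation of every slice, shell-point extraction, 3D reconstruction,
#' statistical outlier removal, and curvature-radius estimation. The result
#' is a pure function of the stack and the configuration (no randomness).
#'
#' @param stack An [image_stack()].
#' @param config A [pipeline_config()].
#' @return A [radius_estimate()] with diagnostic attributes `cloud` (the
#'   reconstructed [point_cloud()] before outlier removal) and `masks` (the
#'   per-slice [slice_mask()] list).
#' @export
run_pipeline <- function(stack, config = pipeline_config()) {
  stopifnot(inherits(stack, "image_stack"), inherits(config, "pipeline_config"))
  say <- function(...) if (config$verbose) message(sprintf(...))
  masks <- vector("list", length(stack$slices))
  n_px <- 0L
  for (s in seq_along(stack$slices)) {
    img <- preprocess_slice(stack$slices[[s]], config$seg)
    m <- segment_slice(img, config$seg, slice_index = s - 1L)
    m$shell_pixels <- extract_shell_points(m, config$seg)
    n_px <- n_px + nrow(m$shell_pixels)
    masks[[s]] <- m
  }
  say("segmentation: %d shell pixels over %d slices", n_px, length(masks))
  if (n_px == 0L) {
    stop("no hyperechoic object detected in any slice")
  }
  cloud <- build_point_cloud(masks, stack$geometry)
  say("reconstruction: %d points", nrow(cloud$points))
  est <- estimate_radius(cloud,
                         method = config$curvature$method,
                         k = config$curvature$k,
                         outliers = TRUE,
                         outlier_k = config$outlier$k,
                         outlier_nsigma = config$outlier$n_sigma,
                         shell_correction = config$shell_correction)
  say("estimate: %.3f mm from %d points (rms %.4f mm)",
      est$radius, est$n_points_used, est$rms_residual)
  attr(est, "cloud") <- cloud
  attr(est, "masks") <- masks
  est
}

#' Relative radius error
#'
#' `|estimated - true| / true`, as a fraction.
#'
#' @param true_radius True radius, mm; must be positive.
#' @param estimated_radius Estimated radius, mm (vectorized).
#' @return Relative error fraction(s).
#' @export
relative_error <- function(true_radius, estimated_radius) {
  if (any(!is.finite(true_radius)) || any(true_radius <= 0)) {
    stop("'true_radius' must be positive")
  }
  abs(estimated_radius - true_radius) / true_radius
}

#' Mean relative error in percent
#'
#' Arithmetic mean of per-pair relative errors, times 100. This is the
#' summary used to score phantom-recovery runs; report it rounded to one
#' decimal.
#'
#' @param true_radii,estimated_radii Paired radii, mm.
#' @return Mean relative error, percent (unrounded).
#' @export
mean_relative_error <- function(true_radii, estimated_radii) {
  if (length(true_radii) < 1L ||
      length(true_radii) != length(estimated_radii)) {
    stop("need at least one (true, estimated) pair of equal length")
  }
  mean(relative_error(true_radii, estimated_radii)) * 100
}

#' Longitudinal series of radius estimates
#'
#' @param timepoints Strictly increasing times (days).
#' @param radii Estimated radii, mm, one per timepoint.
#' @param labels Optional free-text labels.
#' @return An object of class `longitudinal_series`.
#' @export
longitudinal_series <- function(timepoints, radii, labels = NULL) {
  if (length(timepoints) != length(radii)) {
    stop("'timepoints' and 'radii' must have equal length")
  }
  if (any(diff(timepoints) <= 0)) {
    stop("'timepoints' must be strictly increasing")
  }
  if (!is.null(labels) && length(labels) != length(radii)) {
    stop("'labels' must align with 'radii'")
  }
  structure(list(timepoints = as.numeric(timepoints),
                 radii = as.numeric(radii), labels = labels),
            class = "longitudinal_series")
}

#' Trend of a longitudinal radius series
#'
#' Total change (last minus first), successive per-interval deltas, and a
#' direction call with a stability band: changes within `+/- stability_band`
#' are "stable", larger decreases "shrinking", larger increases "growing".
#'
#' @param series A [longitudinal_series()] (at least two timepoints).
#' @param stability_band Half-width of the stable band, mm.
#' @return `list(total_change, deltas, direction, interval_direction)`.
#' @export
longitudinal_trend <- function(series, stability_band = 0.1) {
  stopifnot(inherits(series, "longitudinal_series"))
  if (length(series$radii) < 2L) {
    stop("need at least two timepoints for a trend")
  }
  classify <- function(d) {
    ifelse(d < -stability_band, "shrinking",
           ifelse(d > stability_band, "growing", "stable"))
  }
  deltas <- diff(series$radii)
  total <- series$radii[length(series$radii)] - series$radii[1]
  list(total_change = total,
       deltas = deltas,
       direction = classify(total),
       interval_direction = classify(deltas))
}

#' Phantom recovery study
#'
#' Generates a synthetic stack for every (tumor radius, seed) combination,
#' runs the full pipeline, and tabulates estimates and relative errors —
#' the desk-scale stand-in for scanning physical phantoms of known size.
#'
#' @param radii Tumor radii, mm.
#' @param seeds Noise seeds, one stack per (radius, seed) pair.
#' @param shell_thickness Shell thickness of every phantom, mm.
#' @param noise A [noise_model()]; its `seed` field is replaced per run.
#' @param config A [pipeline_config()].
#' @param ... Passed to [default_scan_geometry()].
#' @return `data.frame(tumor_radius, seed, estimate, rel_error_pct,
#'   n_points)`.
#' @export
phantom_recovery_study <- function(radii = c(2.0, 2.5, 3.0, 3.5),
                                   seeds = 1:5, shell_thickness = 0.1,
                                   noise = noise_model(),
                                   config = pipeline_config(), ...) {
  grid <- expand.grid(tumor_radius = radii, seed = seeds,
                      KEEP.OUT.ATTRS = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    r <- grid$tumor_radius[i]
    noise$seed <- as.integer(grid$seed[i])
    stack <- simulate_stack(r, shell_thickness, noise, ...)
    est <- run_pipeline(stack, config)
    data.frame(tumor_radius = r, seed = grid$seed[i],
               estimate = est$radius,
               rel_error_pct = relative_error(r, est$radius) * 100,
               n_points = est$n_points_used)
  })
  do.call(rbind, res)
}

#' Write CSV + JSON reports for a set of estimates
#'
#' One CSV row per stack (truth when known, estimate, residual, point count,
#' method); when two or more rows carry a truth, summary rows with the mean
#' and median relative error (percent) are appended. The JSON file carries
#' the full table.
#'
#' @param results Data frame with at least columns `estimate`; optional
#'   `label`, `truth`, `n_points`, `rms_residual`, `method`.
#' @param csv_path,json_path Output paths (`NULL` skips that format).
#' @return Invisibly, the augmented table written to CSV.
#' @export
generate_report <- function(results, csv_path = NULL, json_path = NULL) {
  stopifnot(is.data.frame(results), "estimate" %in% names(results))
  tab <- data.frame(
    label = if ("label" %in% names(results)) as.character(results$label)
            else sprintf("stack_%02d", seq_len(nrow(results))),
    truth = if ("truth" %in% names(results)) results$truth else NA_real_,
    estimate = results$estimate,
    residual = if ("truth" %in% names(results))
                 results$estimate - results$truth else NA_real_,
    n_points = if ("n_points" %in% names(results)) results$n_points
               else NA_integer_,
    rms_residual = if ("rms_residual" %in% names(results))
                     results$rms_residual else NA_real_,
    method = if ("method" %in% names(results)) results$method
             else NA_character_,
    stringsAsFactors = FALSE
  )
  known <- !is.na(tab$truth)
  if (sum(known) >= 2L) {
    mre <- mean_relative_error(tab$truth[known], tab$estimate[known])
    med <- median(relative_error(tab$truth[known],
                                 tab$estimate[known])) * 100
    tab <- rbind(tab,
                 data.frame(label = "mean_relative_error_pct", truth = NA,
                            estimate = mre, residual = NA, n_points = NA,
                            rms_residual = NA, method = NA),
                 data.frame(label = "median_relative_error_pct", truth = NA,
                            estimate = med, residual = NA, n_points = NA,
                            rms_residual = NA, method = NA))
  }
  if (!is.null(csv_path)) {
    ok <- tryCatch({
      write.csv(tab, csv_path, row.names = FALSE)
      TRUE
    }, error = function(e) FALSE, warning = function(w) FALSE)
    if (!ok) stop("cannot write report to '", csv_path, "'")
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(tab, json_path, dataframe = "rows", digits = NA,
                         na = "null", pretty = TRUE)
  }
  invisible(tab)
}

#' Read back a CSV report
#'
#' @param csv_path Path written by [generate_report()].
#' @return `list(table, summary)`: the per-stack rows and the summary rows.
#' @export
read_report <- function(csv_path) {
  tab <- read.csv(csv_path, stringsAsFactors = FALSE)
  is_summary <- grepl("_pct$", tab$label)
  list(table = tab[!is_summary, , drop = FALSE],
       summary = tab[is_summary, , drop = FALSE])
}
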