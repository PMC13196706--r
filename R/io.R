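# Plain-text stack, point-cloud and sidecar I/O.
#
# Stacks are stored as one ASCII PGM (P2) file per slice plus a JSON sidecar
# with the scan geometry and, when known, the phantom ground truth and noise
# model; truth masks are a parallel set of PGM files. Text formats keep the
# fixtures and outputs portable and diffable.

write_pgm <- function(mat, path, maxval = 65535L) {
  q <- round(pmin(pmax(mat, 0), 1) * maxval)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", sprintf("%d %d", ncol(q), nrow(q)),
               as.character(maxval)), con)
  writeLines(apply(q, 1, paste, collapse = " "), con)
}

read_pgm <- function(path) {
  toks <- scan(path, what = character(), quiet = TRUE, comment.char = "#")
  if (toks[1] != "P2") stop("'", path, "' is not an ASCII PGM (P2) file")
  nc <- as.integer(toks[2])
  nr <- as.integer(toks[3])
  maxval <- as.numeric(toks[4])
  vals <- as.numeric(toks[-(1:4)])
  if (length(vals) != nr * nc) stop("corrupt PGM: wrong pixel count")
  matrix(vals, nrow = nr, ncol = nc, byrow = TRUE) / maxval
}

#' Write an image stack as per-slice ASCII PGM plus a JSON sidecar
#'
#' Creates `slice_###.pgm` (16-bit quantized intensities), optional
#' `mask_###.pgm` truth masks, and `stack.json` describing the scan
#' geometry, and the phantom and noise model when the stack carries them.
#'
#' @param stack An [image_stack()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, `dir`.
#' @seealso [read_image_stack()]
#' @export
write_image_stack <- function(stack, dir) {
  stopifnot(inherits(stack, "image_stack"))
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE)) {
    stop("cannot create '", dir, "'")
  }
  for (s in seq_along(stack$slices)) {
    write_pgm(stack$slices[[s]], file.path(dir, sprintf("slice_%03d.pgm", s)))
    if (!is.null(stack$truth_masks)) {
      write_pgm(stack$truth_masks[[s]] * 1,
                file.path(dir, sprintf("mask_%03d.pgm", s)), maxval = 1L)
    }
  }
  side <- list(geometry = unclass(stack$geometry))
  ph <- attr(stack, "phantom")
  nz <- attr(stack, "noise")
  if (!is.null(ph)) side$phantom <- unclass(ph)
  if (!is.null(nz)) side$noise <- unclass(nz)
  jsonlite::write_json(side, file.path(dir, "stack.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read an image stack written by [write_image_stack()]
#'
#' @param dir Directory holding `slice_###.pgm` files and `stack.json`.
#' @return An [image_stack()]; phantom and noise attributes are restored
#'   when present in the sidecar.
#' @export
read_image_stack <- function(dir) {
  side_path <- file.path(dir, "stack.json")
  if (!file.exists(side_path)) stop("no stack.json sidecar in '", dir, "'")
  side <- jsonlite::read_json(side_path, simplifyVector = TRUE)
  g <- side$geometry
  geometry <- scan_geometry(g$num_slices, g$slice_spacing,
                            g$pixel_spacing_row, g$pixel_spacing_col,
                            g$image_rows, g$image_cols, g$origin)
  slices <- lapply(seq_len(geometry$num_slices), function(s) {
    read_pgm(file.path(dir, sprintf("slice_%03d.pgm", s)))
  })
  mask_files <- file.path(dir, sprintf("mask_%03d.pgm",
                                       seq_len(geometry$num_slices)))
  masks <- NULL
  if (all(file.exists(mask_files))) {
    masks <- lapply(mask_files, function(f) read_pgm(f) > 0.5)
  }
  out <- image_stack(slices, geometry, truth_masks = masks)
  if (!is.null(side$phantom)) {
    p <- side$phantom
    attr(out, "phantom") <- lesion_phantom(p$tumor_radius, p$shell_thickness,
                                           p$center_xy, p$base_height,
                                           p$cap_fraction)
  }
  if (!is.null(side$noise)) {
    z <- side$noise
    attr(out, "noise") <- noise_model(z$speckle_scale, z$psf_sigma,
                                      z$additive_sigma, z$attenuation,
                                      z$seed)
  }
  out
}

#' Write a point cloud as whitespace-separated XYZ text
#'
#' Columns `x y z slice` in mm (slice is the 0-based source slice index).
#'
#' @param cloud A [point_cloud()].
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_point_cloud <- function(cloud, path) {
  stopifnot(inherits(cloud, "point_cloud"))
  df <- data.frame(x = cloud$points[, 1], y = cloud$points[, 2],
                   z = cloud$points[, 3], slice = cloud$source_slice)
  utils::write.table(format(df, digits = 12, scientific = FALSE,
                            trim = TRUE),
                     path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a point cloud written by [write_point_cloud()]
#'
#' @param path XYZ text file.
#' @return A [point_cloud()].
#' @export
read_point_cloud <- function(path) {
  df <- utils::read.table(path, header = TRUE)
  point_cloud(as.matrix(df[, c("x", "y", "z")]),
              if ("slice" %in% names(df)) df$slice else integer(nrow(df)))
}
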