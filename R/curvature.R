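#' Curvature-radius estimate of the wrapped shell
#'
#' Container for the sensing readout: the aggregate curvature radius of the
#' reconstructed shell surface, with fit diagnostics.
#'
#' @param radius Estimated radius, mm (after any shell correction).
#' @param center Fitted sphere center, mm.
#' @param method `"global_sphere"` or `"local_pca"`.
#' @param local_radii Per-point local radii, mm (`local_pca` only).
#' @param rms_residual RMS distance residual of the global sphere fit, mm.
#' @param n_points_used Number of points contributing to the estimate.
#' @param shell_correction Half-band correction subtracted, mm (0 when off).
#' @return An object of class `radius_estimate`.
#' @export
radius_estimate <- function(radius, center, method, local_radii = NULL,
                            rms_residual = NA_real_, n_points_used = NA_integer_,
                            shell_correction = 0) {
  if (!is.finite(radius) || radius <= 0) {
    stop("degenerate fit: estimated radius is not a positive number")
  }
  structure(
    list(radius = as.numeric(radius), center = as.numeric(center),
         method = method, local_radii = local_radii,
         rms_residual = as.numeric(rms_residual),
         n_points_used = as.integer(n_points_used),
         shell_correction = as.numeric(shell_correction)),
    class = "radius_estimate"
  )
}

#' @export
print.radius_estimate <- function(x, ...) {
  cat(sprintf(
    "<radius_estimate> %.3f mm (%s, %d points, rms residual %.4f mm)\n",
    x$radius, x$method, x$n_points_used, x$rms_residual))
  invisible(x)
}

as_points <- function(cloud) {
  if (inherits(cloud, "point_cloud")) cloud$points
  else matrix(as.numeric(cloud), ncol = 3L)
}

#' Algebraic least-squares sphere fit
#'
#' Linear (Coope/Kasa) formulation: from `|x|^2 = 2 c . x + (r^2 - |c|^2)`
#' the center and radius solve an ordinary least-squares system. Exact on
#' noise-free sphere samples; raises a degenerate-fit error for fewer than
#' four points or (near-)coplanar configurations.
#'
#' @param cloud A [point_cloud()] or N x 3 matrix, mm.
#' @return A [radius_estimate()] with method `"global_sphere"`.
#' @export
fit_sphere_lsq <- function(cloud) {
  P <- as_points(cloud)
  if (nrow(P) < 4L) stop("degenerate fit: need at least 4 points")
  A <- cbind(2 * P, 1)
  b <- rowSums(P^2)
  qa <- qr(A)
  if (qa$rank < 4L) {
    stop("degenerate fit: points are coplanar or otherwise rank-deficient")
  }
  beta <- qr.coef(qa, b)
  center <- beta[1:3]
  r2 <- beta[4] + sum(center^2)
  if (!is.finite(r2) || r2 <= 0) stop("degenerate fit: non-positive radius")
  r <- sqrt(r2)
  resid <- sqrt(rowSums(sweep(P, 2, center)^2)) - r
  radius_estimate(r, center, "global_sphere",
                  rms_residual = sqrt(mean(resid^2)),
                  n_points_used = nrow(P))
}

#' Local curvature radii by PCA-framed osculating-sphere fits
#'
#' For every point, the principal components of its `k`-nearest-neighbour
#' patch give the local surface normal (smallest component). The osculating
#' sphere is then fitted with its center constrained to the normal line
#' through the point, using the same linear algebraic formulation as
#' [fit_sphere_lsq()], and refined by a few damped Gauss-Newton steps on the
#' geometric distance (accepted only while the RMS residual decreases),
#' which makes the fit exact on noise-free sphere samples regardless of the
#' PCA normal's sampling error. Flat patches (no measurable height above the
#' tangent plane) are flagged `Inf`; rank-deficient patches are `NA` and
#' skipped by aggregation.
#'
#' @param cloud A [point_cloud()] or N x 3 matrix, mm.
#' @param k Neighbourhood size; `10 <= k < N`.
#' @return Numeric vector of per-point local radii, mm (`Inf` flat, `NA`
#'   skipped).
#' @export
local_pca_radius <- function(cloud, k = 150L) {
  P <- as_points(cloud)
  n <- nrow(P)
  k <- as.integer(k)
  if (k < 10L) stop("'k' must be at least 10")
  if (k >= n) stop("'k' must be smaller than the number of points")
  nn <- cpp_knn(P, k)$idx
  scale <- sqrt(sum((apply(P, 2, max) - apply(P, 2, min))^2))
  if (scale == 0) scale <- 1
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    X <- P[c(i, nn[i, ]), , drop = FALSE]
    Xc <- sweep(X, 2, colMeans(X))
    ev <- eigen(crossprod(Xc), symmetric = TRUE)
    if (ev$values[2] <= 1e-12 * max(ev$values[1], 1e-300)) next  # collinear
    nrm <- ev$vectors[, 3]
    D <- sweep(X, 2, P[i, ])
    h <- drop(D %*% nrm)
    if (max(abs(h)) < 1e-9 * scale) {
      out[i] <- Inf  # flat patch: no height above the tangent plane
      next
    }
    # constrained algebraic fit: center on the normal line through the point
    beta <- tryCatch(qr.solve(cbind(2 * h, 1), rowSums(D^2)),
                     error = function(e) NULL)
    if (is.null(beta)) next
    r2 <- beta[2] + beta[1]^2
    if (!is.finite(r2) || r2 <= 0) next
    center <- P[i, ] + beta[1] * nrm
    r_i <- sqrt(r2)
    # geometric Gauss-Newton refinement, step accepted only on improvement
    rms <- function(ctr, r) {
      sqrt(mean((sqrt(rowSums(sweep(X, 2, ctr)^2)) - r)^2))
    }
    cur <- rms(center, r_i)
    for (iter in 1:20) {
      V <- sweep(X, 2, center)
      dst <- sqrt(rowSums(V^2))
      if (any(dst < 1e-12 * scale)) break
      J <- cbind(-V / dst, -1)
      f <- dst - r_i
      step <- tryCatch(qr.solve(J, -f), error = function(e) NULL)
      if (is.null(step) || !all(is.finite(step))) break
      # backtracking line search: accept the first damped step that improves
      improved <- FALSE
      for (lam in 2^-(0:5)) {
        cand_c <- center + lam * step[1:3]
        cand_r <- r_i + lam * step[4]
        if (cand_r <= 0) next
        cand <- rms(cand_c, cand_r)
        if (is.finite(cand) && cand < cur) {
          center <- cand_c
          r_i <- cand_r
          cur <- cand
          improved <- TRUE
          break
        }
      }
      if (!improved || cur < 1e-14 * scale) break
    }
    out[i] <- r_i
  }
  out
}

#' Estimate the wrap curvature radius from a point cloud
#'
#' The sensing readout. Optionally removes statistical outliers, then either
#' fits one global algebraic sphere (`"global_sphere"`) or aggregates the
#' local PCA radii by their median (`"local_pca"`, the default — the median
#' is robust to residual artifacts and to flat-region remnants). Local radii
#' larger than ten times the cloud's bounding-box diagonal are treated as
#' flat and excluded. An optional shell correction (half the band thickness)
#' is subtracted to convert a band-midline radius into a lesion-surface
#' radius; it is off (0) by default.
#'
#' @param cloud A [point_cloud()].
#' @param method `"local_pca"` or `"global_sphere"`.
#' @param k Neighbourhood size for the local method.
#' @param outliers Remove statistical outliers first (logical).
#' @param outlier_k,outlier_nsigma Parameters of [remove_outliers()].
#' @param shell_correction Length subtracted from the fitted radius, mm.
#' @return A [radius_estimate()].
#' @export
estimate_radius <- function(cloud, method = c("local_pca", "global_sphere"),
                            k = 150L, outliers = TRUE, outlier_k = 8L,
                            outlier_nsigma = 2.0, shell_correction = 0) {
  method <- match.arg(method)
  stopifnot(inherits(cloud, "point_cloud"))
  if (nrow(cloud$points) == 0L) stop("degenerate fit: empty point cloud")
  if (outliers) cloud <- remove_outliers(cloud, outlier_k, outlier_nsigma)
  global <- fit_sphere_lsq(cloud)
  n <- nrow(cloud$points)
  if (method == "local_pca" && n > max(k, 10L)) {
    lr <- local_pca_radius(cloud, k = min(k, n - 1L))
    bbox_diag <- sqrt(sum((apply(cloud$points, 2, max) -
                             apply(cloud$points, 2, min))^2))
    valid <- is.finite(lr) & lr <= 10 * bbox_diag
    if (!any(valid)) stop("degenerate fit: no valid local radii")
    radius_estimate(median(lr[valid]) - shell_correction, global$center,
                    "local_pca", local_radii = lr,
                    rms_residual = global$rms_residual,
                    n_points_used = sum(valid),
                    shell_correction = shell_correction)
  } else {
    radius_estimate(global$radius - shell_correction, global$center,
                    "global_sphere", rms_residual = global$rms_residual,
                    n_points_used = n, shell_correction = shell_correction)
  }
}
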