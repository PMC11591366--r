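#' Least-squares sphere fit
#'
#' Fits a sphere to 3D points by minimising the sum of squared geometric
#' (orthogonal) residuals `(||p - c|| - r)^2`. An algebraic (Coope-style)
#' linear least-squares fit provides the initial estimate; Gauss-Newton
#' iterations with step halving refine it to the geometric optimum. The
#' geometric fit is unbiased for partial-coverage data such as a fiducial
#' marker seen from one side only.
#'
#' @param points Points on the sphere surface (matrix, [point_cloud], or
#'   [trimesh] whose vertices are used).
#' @param fixed_radius Optional known radius (mm); only the centre is then
#'   estimated, and 3 non-collinear points suffice.
#' @param tol Convergence tolerance on the parameter step (mm).
#' @param max_iter Maximum Gauss-Newton iterations.
#' @return Object of class `sphere_fit`: `center` (mm), `radius` (mm),
#'   `rms_residual` (mm), `n_points`, `iterations`, `converged`.
#' @examples
#' p <- rbind(c(14, 0, 0), c(-14, 0, 0), c(0, 14, 0),
#'            c(0, -14, 0), c(0, 0, 14), c(0, 0, -14))
#' fit_sphere(sweep(p, 2, c(10, -5, 3), "+"))
#' @export
fit_sphere <- function(points, fixed_radius = NULL, tol = 1e-10,
                       max_iter = 100L) {
  p <- as_points3(points)
  n <- nrow(p)
  need <- if (is.null(fixed_radius)) 4L else 3L
  if (n < need)
    stop_validation(sprintf("sphere fit needs at least %d points", need))
  ctr <- colMeans(p)
  pc <- sweep(p, 2, ctr)
  sv <- svd(pc, nu = 0)$d
  if (is.null(fixed_radius)) {
    if (sv[3] < 1e-8 * max(sv[1], 1))
      stop_geometry("points are coplanar or degenerate: sphere is not identifiable")
    # algebraic init: ||p||^2 = 2 p.c + (r^2 - ||c||^2)
    B <- cbind(2 * p, 1)
    f <- rowSums(p^2)
    w <- qr.solve(B, f)
    c0 <- w[1:3]
    r0 <- sqrt(max(w[4] + sum(c0^2), .Machine$double.eps))
  } else {
    if (sv[2] < 1e-8 * max(sv[1], 1))
      stop_geometry("points are collinear: sphere centre is not identifiable")
    if (fixed_radius <= 0) stop_validation("fixed_radius must be positive")
    # init: centroid pushed along the smallest principal direction
    normal <- svd(pc, nv = 3)$v[, 3]
    dbar <- mean(sqrt(rowSums(pc^2)))
    h <- sqrt(max(fixed_radius^2 - dbar^2, 0))
    c0 <- ctr + h * normal
    r0 <- fixed_radius
  }

  theta <- c(c0, if (is.null(fixed_radius)) r0)
  rss <- function(th) {
    cc <- th[1:3]
    r <- if (is.null(fixed_radius)) th[4] else fixed_radius
    d <- sqrt(rowSums(sweep(p, 2, cc)^2))
    sum((d - r)^2)
  }
  cur <- rss(theta)
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    cc <- theta[1:3]
    r <- if (is.null(fixed_radius)) theta[4] else fixed_radius
    diff <- sweep(p, 2, cc)
    d <- sqrt(rowSums(diff^2))
    if (any(d < 1e-12))
      stop_numerical("a data point coincides with the sphere centre")
    u <- diff / d
    res <- d - r
    J <- if (is.null(fixed_radius)) cbind(-u, -1) else -u
    step <- tryCatch(qr.solve(J, -res), error = function(e)
      stop_numerical(sprintf("sphere fit normal equations singular: %s",
                             conditionMessage(e))))
    lambda <- 1
    repeat {
      cand <- theta + lambda * step
      new <- rss(cand)
      if (new <= cur || lambda < 1e-8) break
      lambda <- lambda / 2
    }
    moved <- sqrt(sum((lambda * step)^2))
    theta <- theta + lambda * step
    cur <- rss(theta)
    if (moved < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged)
    stop_numerical(sprintf(
      "sphere fit did not converge in %d iterations (last step %.3g mm, rms %.3g mm)",
      max_iter, moved, sqrt(cur / n)))
  center <- theta[1:3]
  radius <- if (is.null(fixed_radius)) theta[4] else fixed_radius
  if (radius <= 0) stop_numerical("sphere fit produced a non-positive radius")
  structure(list(center = center, radius = radius,
                 rms_residual = sqrt(cur / n), n_points = n,
                 iterations = it, converged = converged),
            class = "sphere_fit")
}

#' @export
print.sphere_fit <- function(x, ...) {
  cat(sprintf(
    "sphere_fit: center (%.4f, %.4f, %.4f) mm, radius %.4f mm, rms residual %.3g mm (n = %d)\n",
    x$center[1], x$center[2], x$center[3], x$radius, x$rms_residual,
    x$n_points))
  invisible(x)
}

#' Labelled set of fitted fiducial markers for one scan
#'
#' @param fits Named list of [fit_sphere] results; names are marker labels.
#' @param scan_id Identifier of the scan the markers belong to.
#' @return Object of class `marker_set`.
#' @export
marker_set <- function(fits, scan_id = "scan") {
  if (!is.list(fits) || length(fits) == 0L ||
      !all(vapply(fits, inherits, TRUE, "sphere_fit")))
    stop_validation("fits must be a non-empty list of sphere_fit objects")
  labels <- names(fits)
  if (is.null(labels) || anyDuplicated(labels) || any(!nzchar(labels)))
    stop_validation("marker labels must be unique and non-empty")
  structure(list(markers = fits, scan_id = scan_id), class = "marker_set")
}

#' @export
print.marker_set <- function(x, ...) {
  cat(sprintf("marker_set '%s': %d markers (%s)\n", x$scan_id,
              length(x$markers), paste(names(x$markers), collapse = ", ")))
  invisible(x)
}

marker_centers <- function(set) {
  m <- t(vapply(set$markers, `[[`, numeric(3), "center"))
  rownames(m) <- names(set$markers)
  m
}

#' Read pre-fit marker centres from CSV
#'
#' Expected columns: `label`, `x_mm`, `y_mm`, `z_mm`. Each row becomes a
#' degenerate `sphere_fit` (radius `NA`, residual 0) usable for registration.
#'
#' @param path CSV path.
#' @param scan_id Scan identifier.
#' @return A [marker_set].
#' @export
read_marker_csv <- function(path, scan_id = "scan") {
  if (!file.exists(path)) stop_io(sprintf("marker file not found: %s", path))
  df <- utils::read.csv(path)
  need <- c("label", "x_mm", "y_mm", "z_mm")
  if (!all(need %in% names(df)))
    stop_io(sprintf("marker CSV must have columns %s", paste(need, collapse = ", ")))
  fits <- lapply(seq_len(nrow(df)), function(i) {
    structure(list(center = as.numeric(df[i, c("x_mm", "y_mm", "z_mm")]),
                   radius = NA_real_, rms_residual = 0, n_points = NA_integer_,
                   iterations = 0L, converged = TRUE), class = "sphere_fit")
  })
  names(fits) <- as.character(df$label)
  marker_set(fits, scan_id)
}
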