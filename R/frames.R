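#' Total-least-squares plane fit
#'
#' Fits a plane through 3D points by principal components: the plane passes
#' through the centroid with normal along the smallest principal direction
#' of the centred points (orthogonal-distance regression).
#'
#' @param points `n x 3` matrix or [point_cloud], `n >= 3`, non-collinear.
#' @param orient Optional reference direction; the normal is flipped, if
#'   needed, to have a positive dot product with it.
#' @return Object of class `plane_fit`: `point` (centroid), `normal`
#'   (unit), `rms_residual` (mm).
#' @export
fit_plane <- function(points, orient = NULL) {
  p <- as_points3(points)
  if (nrow(p) < 3L) stop_validation("plane fit needs at least 3 points")
  ctr <- colMeans(p)
  pc <- sweep(p, 2, ctr)
  s <- svd(pc, nu = 0)
  if (s$d[2] < 1e-9 * max(s$d[1], 1))
    stop_geometry("points are collinear: plane is not identifiable")
  normal <- s$v[, 3]
  if (!is.null(orient) && sum(normal * orient) < 0) normal <- -normal
  structure(list(point = ctr, normal = normal,
                 rms_residual = sqrt(mean((pc %*% normal)^2))),
            class = "plane_fit")
}

#' @export
print.plane_fit <- function(x, ...) {
  cat(sprintf("plane_fit: normal (%.4f, %.4f, %.4f), rms residual %.3g mm\n",
              x$normal[1], x$normal[2], x$normal[3], x$rms_residual))
  invisible(x)
}

#' Anatomical coordinate frame of the knee
#'
#' Orthonormal right-handed frame with axes medial-to-lateral (`axis_ml`),
#' posterior-to-anterior (`axis_ap`), and distal-to-proximal (`axis_pd`),
#' with `ml x ap = pd`.
#'
#' @param origin Frame origin (mm).
#' @param axis_ml,axis_ap,axis_pd Unit axis vectors.
#' @param side `"right"` or `"left"`.
#' @return Object of class `anatomical_frame`.
#' @export
anatomical_frame <- function(origin, axis_ml, axis_ap, axis_pd,
                             side = c("right", "left")) {
  side <- match.arg(side)
  A <- cbind(axis_ml, axis_ap, axis_pd)
  if (max(abs(crossprod(A) - diag(3))) > 1e-9)
    stop_validation("frame axes are not orthonormal")
  if (max(abs(cross3(axis_ml, axis_ap) - axis_pd)) > 1e-9)
    stop_validation("frame is not right-handed (ml x ap != pd)")
  structure(list(origin = as.numeric(origin), axis_ml = as.numeric(axis_ml),
                 axis_ap = as.numeric(axis_ap), axis_pd = as.numeric(axis_pd),
                 side = side),
            class = "anatomical_frame")
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

unit3 <- function(v) v / sqrt(sum(v^2))

#' @export
print.anatomical_frame <- function(x, ...) {
  cat(sprintf("anatomical_frame (%s knee)\n", x$side))
  cat(sprintf("  origin (%.3f, %.3f, %.3f) mm\n", x$origin[1], x$origin[2], x$origin[3]))
  cat(sprintf("  ML (%.4f, %.4f, %.4f)\n", x$axis_ml[1], x$axis_ml[2], x$axis_ml[3]))
  cat(sprintf("  AP (%.4f, %.4f, %.4f)\n", x$axis_ap[1], x$axis_ap[2], x$axis_ap[3]))
  cat(sprintf("  PD (%.4f, %.4f, %.4f)\n", x$axis_pd[1], x$axis_pd[2], x$axis_pd[3]))
  invisible(x)
}

#' Build the standard anatomical planes from landmark patches
#'
#' Operationalises the standard-plane construction: spheres are
#' least-squares fit to the two posterior condylar patches and the
#' medial-to-lateral (ML) axis is the line through their centres, so the
#' standard sagittal plane (normal = ML) superimposes the posterior femoral
#' condyles. The standard axial plane is normal to the sagittal plane and
#' parallel to the medial tibial plateau: its normal is the component of
#' the plateau plane normal orthogonal to ML. The AP axis is the cross
#' product of the axial normal with ML, oriented anteriorly using the
#' trochlea-side reference; the coronal plane normal is the AP axis, and
#' PD completes the right-handed triad. The origin is the midpoint of the
#' two condylar sphere centres.
#'
#' For a left knee the ML axis is negated (so the frame stays right-handed
#' with AP anterior and PD proximal on mirrored anatomy).
#'
#' @param condyle_medial,condyle_lateral Posterior condylar surface patches
#'   (point clouds or `n x 3` matrices).
#' @param medial_plateau Medial tibial plateau patch.
#' @param anterior_ref A point (or patch, whose centroid is used) on the
#'   anterior/trochlear side, fixing the AP sign.
#' @param side `"right"` or `"left"`.
#' @param max_condyle_residual Quality gate (mm) on the condylar sphere-fit
#'   RMS residuals.
#' @param min_angle_deg Minimum angle between the ML axis and the plateau
#'   normal before the construction is declared degenerate.
#' @return An [anatomical_frame]; attributes `condyle_fits` (the two sphere
#'   fits) and `plateau_fit` carry the intermediate fits.
#' @export
build_standard_frame <- function(condyle_medial, condyle_lateral,
                                 medial_plateau, anterior_ref,
                                 side = c("right", "left"),
                                 max_condyle_residual = 1.0,
                                 min_angle_deg = 10) {
  side <- match.arg(side)
  fit_med <- fit_sphere(condyle_medial)
  fit_lat <- fit_sphere(condyle_lateral)
  if (fit_med$rms_residual > max_condyle_residual ||
      fit_lat$rms_residual > max_condyle_residual)
    stop_geometry(sprintf(
      "condylar sphere fit residual exceeds %.2f mm (medial %.3f, lateral %.3f): patch is not spherical enough",
      max_condyle_residual, fit_med$rms_residual, fit_lat$rms_residual))
  ml <- unit3(fit_lat$center - fit_med$center)
  if (side == "left") ml <- -ml
  plat <- fit_plane(medial_plateau)
  np <- plat$normal
  sin_angle <- sqrt(max(0, 1 - sum(np * ml)^2))
  if (asin(min(1, sin_angle)) < min_angle_deg * pi / 180)
    stop_geometry("plateau normal is nearly parallel to the ML axis: axial plane is degenerate")
  axial_n <- unit3(np - sum(np * ml) * ml)
  ap <- unit3(cross3(axial_n, ml))
  origin <- (fit_med$center + fit_lat$center) / 2
  aref <- colMeans(as_points3(anterior_ref, "anterior_ref"))
  if (sum(ap * (aref - origin)) < 0) ap <- -ap
  pd <- cross3(ml, ap)
  fr <- anatomical_frame(origin, ml, ap, pd, side)
  attr(fr, "condyle_fits") <- list(medial = fit_med, lateral = fit_lat)
  attr(fr, "plateau_fit") <- plat
  fr
}

#' Rigid transform from world coordinates into a frame
#'
#' In frame coordinates the ML, AP, PD axes map to +x, +y, +z and the frame
#' origin to (0, 0, 0).
#'
#' @param frame An [anatomical_frame].
#' @return A [rigid_transform].
#' @export
frame_transform <- function(frame) {
  R <- t(cbind(frame$axis_ml, frame$axis_ap, frame$axis_pd))
  rigid_transform(R, -as.numeric(R %*% frame$origin))
}

#' Express geometry in an anatomical frame
#'
#' @param x [trimesh], [point_cloud], or points.
#' @param frame An [anatomical_frame].
#' @return `x` expressed in frame coordinates (x = ML, y = AP, z = PD).
#' @export
to_frame <- function(x, frame) {
  apply_transform(frame_transform(frame), x)
}

#' @rdname to_frame
#' @export
from_frame <- function(x, frame) {
  apply_transform(invert_transform(frame_transform(frame)), x)
}
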