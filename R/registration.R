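#' Rigid transform (rotation + translation)
#'
#' Proper rigid motions only: the rotation must be orthonormal with
#' determinant +1 (reflections are rejected). Applied as `x' = R x + t`.
#'
#' @param rotation 3x3 rotation matrix.
#' @param translation Length-3 translation (mm).
#' @return Object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  translation <- as.numeric(translation)
  if (!all(dim(rotation) == c(3, 3)) || length(translation) != 3L)
    stop_validation("rotation must be 3x3 and translation length 3")
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-9)
    stop_validation("rotation matrix is not orthonormal")
  if (abs(det(rotation) - 1) > 1e-9)
    stop_validation("rotation has det != +1 (reflections are forbidden)")
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  ang <- rotation_angle(x$rotation) * 180 / pi
  cat(sprintf("rigid_transform: rotation %.3f deg, translation (%.3f, %.3f, %.3f) mm\n",
              ang, x$translation[1], x$translation[2], x$translation[3]))
  invisible(x)
}

# rotation angle in radians; atan2 form is stable near zero, where
# acos((trace - 1) / 2) loses half the significant digits
rotation_angle <- function(R) {
  s <- sqrt(sum(c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1],
                  R[2, 1] - R[1, 2])^2)) / 2
  atan2(s, (sum(diag(R)) - 1) / 2)
}

#' Apply a rigid transform to points, a point cloud, or a mesh
#'
#' @param transform A [rigid_transform].
#' @param x Points (`n x 3` or length 3), [point_cloud], or [trimesh].
#' @return Object of the same kind as `x`, transformed.
#' @export
apply_transform <- function(transform, x) {
  stopifnot(inherits(transform, "rigid_transform"))
  tf <- function(p) sweep(p %*% t(transform$rotation), 2,
                          transform$translation, "+")
  if (inherits(x, "trimesh")) {
    x$vertices <- tf(x$vertices)
    return(x)
  }
  if (inherits(x, "point_cloud")) return(point_cloud(tf(x$points)))
  drop_vec <- is.null(dim(x))
  out <- tf(as_points3(x))
  if (drop_vec) out <- drop(out)
  out
}

#' Compose and invert rigid transforms
#'
#' `compose_transforms(b, a)` is the transform that applies `a` first and
#' then `b`.
#'
#' @param b,a,transform [rigid_transform] objects.
#' @return A [rigid_transform].
#' @export
compose_transforms <- function(b, a) {
  rigid_transform(b$rotation %*% a$rotation,
                  as.numeric(b$rotation %*% a$translation) + b$translation)
}

#' @rdname compose_transforms
#' @export
invert_transform <- function(transform) {
  rigid_transform(t(transform$rotation),
                  -as.numeric(t(transform$rotation) %*% transform$translation))
}

#' Serialize a rigid transform as a 4x4 homogeneous matrix
#'
#' @param transform A [rigid_transform].
#' @return 4x4 numeric matrix.
#' @export
transform_matrix <- function(transform) {
  m <- diag(4)
  m[1:3, 1:3] <- transform$rotation
  m[1:3, 4] <- transform$translation
  m
}

#' @rdname transform_matrix
#' @param m A 4x4 homogeneous matrix (row-major list form also accepted).
#' @export
transform_from_matrix <- function(m) {
  m <- matrix(as.numeric(unlist(m)), 4, 4, byrow = !is.matrix(m))
  rigid_transform(m[1:3, 1:3], m[1:3, 4])
}

#' Least-squares rigid registration of paired points (Kabsch/SVD)
#'
#' Estimates the proper rigid motion (rotation + translation, no scale)
#' minimising the sum of squared distances between transformed source points
#' and their corresponding targets, via SVD of the cross-covariance of the
#' centred point sets, with the determinant correction that forbids
#' reflections. The root-mean-square fiducial registration error (FRE) over
#' the input correspondences is reported; a warning is emitted when it
#' exceeds `fre_warn` (a configuration-quality flag, roughly twice a good
#' scanner's per-scan precision).
#'
#' @param source,target Corresponding points, `n x 3` with `n >= 3`
#'   (row names, if present, give the correspondence labels).
#' @param fre_warn FRE threshold (mm) above which a quality warning is
#'   emitted.
#' @return Object of class `registration`: `transform` ([rigid_transform]),
#'   `fre_rms` (mm), `correspondence` (data frame of paired labels).
#' @export
estimate_rigid_transform <- function(source, target, fre_warn = 0.2) {
  src <- as_points3(source, "source")
  tgt <- as_points3(target, "target")
  if (nrow(src) != nrow(tgt))
    stop_validation("source and target must have the same number of points")
  if (nrow(src) < 3L)
    stop_validation("rigid registration needs at least 3 point pairs")
  sc <- colMeans(src)
  tc <- colMeans(tgt)
  X <- sweep(src, 2, sc)
  Y <- sweep(tgt, 2, tc)
  if (svd(X, nu = 0)$d[2] < 1e-9 * max(svd(X, nu = 0)$d[1], 1))
    stop_geometry("source points are collinear: rotation is not identifiable")
  H <- crossprod(X, Y) # 3x3 cross-covariance
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  t <- tc - as.numeric(R %*% sc)
  tf <- rigid_transform(R, t)
  resid <- apply_transform(tf, src) - tgt
  fre <- sqrt(mean(rowSums(resid^2)))
  if (fre > fre_warn)
    warning(sprintf("fiducial registration error %.3f mm exceeds %.3f mm: check marker configuration",
                    fre, fre_warn))
  labs_s <- rownames(source)
  labs_t <- rownames(target)
  corr <- data.frame(
    source = if (is.null(labs_s)) as.character(seq_len(nrow(src))) else labs_s,
    target = if (is.null(labs_t)) as.character(seq_len(nrow(tgt))) else labs_t
  )
  structure(list(transform = tf, fre_rms = fre, correspondence = corr),
            class = "registration")
}

#' @export
print.registration <- function(x, ...) {
  cat(sprintf("registration over %d fiducials: FRE %.4g mm\n",
              nrow(x$correspondence), x$fre_rms))
  print(x$transform)
  invisible(x)
}

#' Match fiducial markers between two scans
#'
#' If the two marker sets share at least three labels, markers are paired by
#' label. Otherwise correspondence is recovered geometrically: the pairing
#' of the smaller set into the larger that minimises the RMS discrepancy
#' between the inter-centre distance matrices, searched exhaustively
#' (practical for the 6-8 markers typically attached per bone). A tie
#' between the best and second-best assignment within `ambiguity_tol`
#' signals a symmetric marker layout and raises an ambiguity error.
#'
#' @param set_a,set_b [marker_set] objects with at least 3 markers each.
#' @param ambiguity_tol Residual gap (mm) below which two assignments are
#'   considered indistinguishable.
#' @return Data frame with columns `label_a`, `label_b`, and attribute
#'   `residual` (mm, RMS distance-matrix discrepancy; 0 for label matching).
#' @export
match_markers <- function(set_a, set_b, ambiguity_tol = 0.05) {
  stopifnot(inherits(set_a, "marker_set"), inherits(set_b, "marker_set"))
  la <- names(set_a$markers)
  lb <- names(set_b$markers)
  if (length(la) < 3L || length(lb) < 3L)
    stop_validation("marker matching needs at least 3 markers in each set")
  common <- intersect(la, lb)
  if (length(common) >= 3L) {
    out <- data.frame(label_a = common, label_b = common)
    attr(out, "residual") <- 0
    return(out)
  }
  ca <- marker_centers(set_a)
  cb <- marker_centers(set_b)
  swap <- nrow(ca) > nrow(cb)
  if (swap) { tmp <- ca; ca <- cb; cb <- tmp }
  n <- nrow(ca)
  m <- nrow(cb)
  if (m > 8L)
    stop_validation("exhaustive marker matching is limited to 8 markers")
  da <- as.matrix(stats::dist(ca))
  db <- as.matrix(stats::dist(cb))
  perms <- permutations_of(m)
  best <- Inf
  second <- Inf
  best_asgn <- NULL
  seen <- new.env(hash = TRUE)
  for (k in seq_len(nrow(perms))) {
    asgn <- perms[k, 1:n] # which rows of cb each row of ca maps to
    key <- paste(asgn, collapse = ",")
    if (!is.null(seen[[key]])) next
    seen[[key]] <- TRUE
    resid <- sqrt(mean((da - db[asgn, asgn, drop = FALSE])[upper.tri(da)]^2))
    if (resid < best) {
      second <- best
      best <- resid
      best_asgn <- asgn
    } else if (resid < second) {
      second <- resid
    }
  }
  if (is.finite(second) && (second - best) < ambiguity_tol)
    stop_ambiguity(sprintf(
      "marker correspondence is ambiguous: two assignments differ by %.4f mm in distance-matrix residual",
      second - best))
  labels_a <- rownames(ca)
  labels_b <- rownames(cb)[best_asgn]
  out <- if (swap) data.frame(label_a = labels_b, label_b = labels_a)
         else data.frame(label_a = labels_a, label_b = labels_b)
  attr(out, "residual") <- best
  out
}

permutations_of <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- permutations_of(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- setdiff(seq_len(n), i)
    cbind(i, matrix(rest[sub], nrow(sub)))
  }))
}

#' Register one scan's marker set to another
#'
#' Matches markers (by label or geometry) and estimates the rigid transform
#' taking `set_a` marker centres onto `set_b` marker centres.
#'
#' @inheritParams match_markers
#' @param fre_warn See [estimate_rigid_transform()].
#' @return A `registration` whose `correspondence` holds the marker pairing.
#' @export
register_marker_sets <- function(set_a, set_b, ambiguity_tol = 0.05,
                                 fre_warn = 0.2) {
  pairing <- match_markers(set_a, set_b, ambiguity_tol)
  ca <- marker_centers(set_a)[pairing$label_a, , drop = FALSE]
  cb <- marker_centers(set_b)[pairing$label_b, , drop = FALSE]
  reg <- estimate_rigid_transform(ca, cb, fre_warn = fre_warn)
  reg$correspondence <- data.frame(label_a = pairing$label_a,
                                   label_b = pairing$label_b)
  reg
}

#' Carry a registration over to the with-cartilage model
#'
#' The two-scan design registers the without-cartilage models; the same
#' transform is then applied to the with-cartilage model of the same bone so
#' that both surfaces live in one frame and thickness can be measured by
#' closest-point distance.
#'
#' @param reg_without A `registration` (or bare [rigid_transform]).
#' @param mesh_with_cartilage [trimesh] to transform.
#' @return The transformed [trimesh]; faces unchanged.
#' @export
propagate_to_cartilage_model <- function(reg_without, mesh_with_cartilage) {
  tf <- if (inherits(reg_without, "registration")) reg_without$transform
        else reg_without
  stopifnot(inherits(tf, "rigid_transform"))
  apply_transform(tf, mesh_with_cartilage)
}
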