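#' Subregion definition parameters
#'
#' The three dimensionless constants of the condylar subregion procedure:
#' the weight-bearing region extends `wb_fraction` (default 60%) of the
#' anterior-posterior distance from the trochlear lowest point to the most
#' posterior point of the cartilage; its central `ap_band_fraction` (default
#' one third) in the AP direction is retained; and the medio-lateral width
#' is reduced to `ml_width_fraction` (default 15%) of the total ML cartilage
#' width, centred at the retained region's centroid.
#'
#' @param wb_fraction Weight-bearing fraction of the trochlea-to-posterior
#'   AP distance, in (0, 1].
#' @param ap_band_fraction Central AP band fraction, in (0, 1].
#' @param ml_width_fraction ML width fraction of total width W, in (0, 1].
#' @return Object of class `subregion_spec`.
#' @export
subregion_spec <- function(wb_fraction = 0.60, ap_band_fraction = 1 / 3,
                           ml_width_fraction = 0.15) {
  vals <- c(wb_fraction, ap_band_fraction, ml_width_fraction)
  if (any(!is.finite(vals)) || any(vals <= 0) || any(vals > 1))
    stop_validation("subregion fractions must lie in (0, 1]")
  structure(list(wb_fraction = wb_fraction,
                 ap_band_fraction = ap_band_fraction,
                 ml_width_fraction = ml_width_fraction),
            class = "subregion_spec")
}

condyle_side_idx <- function(mesh, split, condyle) {
  x <- mesh$vertices[, 1]
  if (condyle == "medial") which(x < split) else which(x >= split)
}

#' Measure the cartilage extent landmarks
#'
#' On a cartilage-surface mesh expressed in the anatomical frame (x = ML,
#' y = AP, z = PD), finds the lowest (most distal) point of the trochlear
#' region, the most posterior point of each condyle, the total
#' medio-lateral cartilage width `W` (max minus min ML coordinate over all
#' cartilage vertices), and the weight-bearing extents `L_med`, `L_lat`
#' (`wb_fraction` times the AP distance from the trochlear lowest point to
#' each condyle's most posterior point). Ties at extrema are broken by the
#' lowest vertex index.
#'
#' @param cartilage_mesh [trimesh] in the anatomical frame.
#' @param trochlea_idx Vertex indices of the trochlear region (supplied by
#'   the user or the phantom generator; not auto-detected).
#' @param condyle_split ML coordinate separating the medial (x < split)
#'   from the lateral condyle. Defaults to the ML coordinate of the
#'   trochlear lowest point.
#' @param spec A [subregion_spec].
#' @return Object of class `cartilage_extent` with fields
#'   `trochlear_lowest_point`, `most_posterior_point_medial`,
#'   `most_posterior_point_lateral`, `W`, `L_med`, `L_lat`,
#'   `condyle_split`.
#' @export
measure_cartilage_extent <- function(cartilage_mesh, trochlea_idx,
                                     condyle_split = NULL,
                                     spec = subregion_spec()) {
  stopifnot(inherits(cartilage_mesh, "trimesh"))
  v <- cartilage_mesh$vertices
  trochlea_idx <- as.integer(trochlea_idx)
  if (length(trochlea_idx) == 0L || any(trochlea_idx < 1L) ||
      any(trochlea_idx > nrow(v)))
    stop_validation("trochlea_idx must be valid vertex indices")
  tl <- trochlea_idx[which.min(v[trochlea_idx, 3])]
  trochlear_lowest <- v[tl, ]
  if (is.null(condyle_split)) condyle_split <- trochlear_lowest[1]
  out <- list(trochlear_lowest_point = trochlear_lowest,
              condyle_split = condyle_split)
  for (condyle in c("medial", "lateral")) {
    idx <- condyle_side_idx(cartilage_mesh, condyle_split, condyle)
    if (length(idx) == 0L)
      stop_validation(sprintf("no cartilage vertices on the %s side of the split", condyle))
    mp <- idx[which.min(v[idx, 2])]
    out[[paste0("most_posterior_point_", condyle)]] <- v[mp, ]
    out[[if (condyle == "medial") "L_med" else "L_lat"]] <-
      spec$wb_fraction * (trochlear_lowest[2] - v[mp, 2])
  }
  out$W <- max(v[, 1]) - min(v[, 1])
  if (out$W <= 0 || out$L_med <= 0 || out$L_lat <= 0)
    stop_geometry("degenerate cartilage extent (non-positive W or L)")
  structure(out, class = "cartilage_extent")
}

#' @export
print.cartilage_extent <- function(x, ...) {
  cat(sprintf("cartilage_extent: W %.2f mm, L_med %.2f mm, L_lat %.2f mm\n",
              x$W, x$L_med, x$L_lat))
  cat(sprintf("  trochlear lowest point (%.2f, %.2f, %.2f), split at ML %.2f\n",
              x$trochlear_lowest_point[1], x$trochlear_lowest_point[2],
              x$trochlear_lowest_point[3], x$condyle_split))
  invisible(x)
}

new_subregion <- function(idx, condyle, flexion, centroid, bounds) {
  structure(list(vertex_indices = idx, condyle = condyle, flexion = flexion,
                 centroid = centroid, bounds = bounds),
            class = "subregion")
}

#' @export
print.subregion <- function(x, ...) {
  cat(sprintf("subregion: %s condyle, %s flexion, %d vertices\n",
              x$condyle, x$flexion, length(x$vertex_indices)))
  invisible(x)
}

#' Distal (0-degree flexion) condylar subregion
#'
#' Three-stage selection on a condyle of the cartilage surface in the
#' anatomical frame: (1) the weight-bearing strip, vertices with AP
#' coordinate between the trochlear lowest point and `L_c` posterior of it;
#' (2) the central third (in AP) of that strip; (3) a medio-lateral trim to
#' `ml_width_fraction` of the total width `W`, centred at the retained
#' vertices' ML centroid.
#'
#' @param cartilage_mesh [trimesh] in the anatomical frame.
#' @param extent A [measure_cartilage_extent] result.
#' @param spec A [subregion_spec].
#' @param condyle `"medial"` or `"lateral"`.
#' @return A `subregion`; its `bounds` record the AP interval of the
#'   central band and the ML interval of the final trim (closed intervals).
#' @export
subregion_0deg <- function(cartilage_mesh, extent, spec = subregion_spec(),
                           condyle = c("medial", "lateral")) {
  condyle <- match.arg(condyle)
  stopifnot(inherits(extent, "cartilage_extent"))
  v <- cartilage_mesh$vertices
  y_t <- extent$trochlear_lowest_point[2]
  L <- if (condyle == "medial") extent$L_med else extent$L_lat
  cidx <- condyle_side_idx(cartilage_mesh, extent$condyle_split, condyle)
  # (1) weight-bearing strip
  strip <- cidx[v[cidx, 2] >= y_t - L & v[cidx, 2] <= y_t]
  if (length(strip) == 0L)
    stop_geometry(sprintf("empty %s 0-degree subregion at stage 'weight-bearing strip'", condyle))
  # (2) central AP band; the band has length ap_band_fraction * L, centred
  half_rem <- (1 - spec$ap_band_fraction) / 2
  ap_lo <- y_t - L * (1 - half_rem)
  ap_hi <- y_t - L * half_rem
  band <- strip[v[strip, 2] >= ap_lo & v[strip, 2] <= ap_hi]
  if (length(band) == 0L)
    stop_geometry(sprintf("empty %s 0-degree subregion at stage 'central AP band'", condyle))
  # (3) ML trim about the band centroid
  cen <- colMeans(v[band, , drop = FALSE])
  half_w <- spec$ml_width_fraction * extent$W / 2
  ml_lo <- cen[1] - half_w
  ml_hi <- cen[1] + half_w
  final <- band[v[band, 1] >= ml_lo & v[band, 1] <= ml_hi]
  if (length(final) == 0L)
    stop_geometry(sprintf("empty %s 0-degree subregion at stage 'medio-lateral trim'", condyle))
  new_subregion(final, condyle, "0deg",
                centroid = colMeans(v[final, , drop = FALSE]),
                bounds = list(ap = c(ap_lo, ap_hi), ml = c(ml_lo, ml_hi)))
}

#' Posterior (90-degree flexion) condylar subregion
#'
#' Centred about the condyle's most posterior cartilage point: (1) vertices
#' whose proximal-distal coordinate lies within half of `length_from_0deg`
#' of the most posterior point's PD coordinate, restricted to the posterior
#' aspect (AP coordinate below `posterior_cutoff_ap`, by default the
#' condylar sphere-centre AP, i.e. the frame origin); (2) the same
#' medio-lateral trim as at 0 degrees.
#'
#' @inheritParams subregion_0deg
#' @param length_from_0deg Band length (mm); by contract the AP length of
#'   the same condyle's 0-degree subregion, i.e. `ap_band_fraction * L_c`.
#' @param posterior_cutoff_ap AP coordinate of the anterior cutoff.
#' @return A `subregion` with PD, AP-cutoff, and ML bounds recorded.
#' @export
subregion_90deg <- function(cartilage_mesh, extent, spec = subregion_spec(),
                            condyle = c("medial", "lateral"),
                            length_from_0deg = NULL,
                            posterior_cutoff_ap = 0) {
  condyle <- match.arg(condyle)
  stopifnot(inherits(extent, "cartilage_extent"))
  L <- if (condyle == "medial") extent$L_med else extent$L_lat
  if (is.null(length_from_0deg))
    length_from_0deg <- spec$ap_band_fraction * L
  if (!is.finite(length_from_0deg) || length_from_0deg <= 0)
    stop_validation("length_from_0deg must be positive")
  v <- cartilage_mesh$vertices
  mp <- if (condyle == "medial") extent$most_posterior_point_medial
        else extent$most_posterior_point_lateral
  cidx <- condyle_side_idx(cartilage_mesh, extent$condyle_split, condyle)
  pd_lo <- mp[3] - length_from_0deg / 2
  pd_hi <- mp[3] + length_from_0deg / 2
  band <- cidx[v[cidx, 3] >= pd_lo & v[cidx, 3] <= pd_hi &
                 v[cidx, 2] <= posterior_cutoff_ap]
  if (length(band) == 0L)
    stop_geometry(sprintf("empty %s 90-degree subregion at stage 'posterior PD band'", condyle))
  cen <- colMeans(v[band, , drop = FALSE])
  half_w <- spec$ml_width_fraction * extent$W / 2
  ml_lo <- cen[1] - half_w
  ml_hi <- cen[1] + half_w
  final <- band[v[band, 1] >= ml_lo & v[band, 1] <= ml_hi]
  if (length(final) == 0L)
    stop_geometry(sprintf("empty %s 90-degree subregion at stage 'medio-lateral trim'", condyle))
  new_subregion(final, condyle, "90deg",
                centroid = colMeans(v[final, , drop = FALSE]),
                bounds = list(pd = c(pd_lo, pd_hi),
                              ap_max = posterior_cutoff_ap,
                              ml = c(ml_lo, ml_hi)))
}

#' Export a subregion as JSON
#'
#' @param subregion A `subregion`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_subregion_json <- function(subregion, path) {
  jsonlite::write_json(
    list(condyle = subregion$condyle, flexion = subregion$flexion,
         vertex_indices = subregion$vertex_indices,
         centroid = subregion$centroid, bounds = subregion$bounds),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
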