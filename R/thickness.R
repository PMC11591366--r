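#' Closest-point cartilage thickness over a subregion
#'
#' For each subregion vertex on the cartilage surface, thickness is the
#' nearest-point distance to the bone (cartilage-free) surface, both models
#' having been registered into one frame beforehand. Points farther than
#' `max_valid` from the bone are flagged invalid (mismatched geometry, e.g.
#' cartilage over an unscanned region) and excluded from the summary
#' statistics, which use the arithmetic mean and sample (n-1) standard
#' deviation.
#'
#' @param cartilage_mesh [trimesh] of the with-cartilage surface.
#' @param bone_mesh [trimesh] of the without-cartilage surface, same frame.
#' @param subregion A `subregion` indexing `cartilage_mesh` vertices.
#' @param max_valid Validity ceiling (mm, default 10).
#' @return Object of class `thickness_map`: `subregion`, per-point
#'   `thickness` (mm, aligned to `subregion$vertex_indices`), logical
#'   `valid`, `mean`, `sd`, `n_valid`, and the query `points`.
#' @export
compute_thickness_map <- function(cartilage_mesh, bone_mesh, subregion,
                                  max_valid = 10) {
  stopifnot(inherits(cartilage_mesh, "trimesh"),
            inherits(bone_mesh, "trimesh"),
            inherits(subregion, "subregion"))
  idx <- subregion$vertex_indices
  if (any(idx < 1L) || any(idx > n_vertices(cartilage_mesh)))
    stop_validation("subregion indices do not fit the cartilage mesh")
  q <- cartilage_mesh$vertices[idx, , drop = FALSE]
  d <- mesh_closest_points(q, bone_mesh)$distance
  valid <- d <= max_valid
  if (sum(valid) < 10L)
    stop_geometry(sprintf(
      "insufficient coverage: only %d valid thickness points (< 10) in the %s %s subregion",
      sum(valid), subregion$condyle, subregion$flexion))
  structure(list(subregion = subregion, thickness = d, valid = valid,
                 mean = mean(d[valid]), sd = stats::sd(d[valid]),
                 n_valid = sum(valid), points = q),
            class = "thickness_map")
}

#' @export
print.thickness_map <- function(x, ...) {
  cat(sprintf(
    "thickness_map (%s condyle, %s): mean %.2f mm, sd %.2f mm (%d valid / %d points)\n",
    x$subregion$condyle, x$subregion$flexion, x$mean, x$sd, x$n_valid,
    length(x$thickness)))
  invisible(x)
}

#' @export
summary.thickness_map <- function(object, ...) {
  s <- subregion_stats(object)
  cat(sprintf("%s condyle, %s flexion: %.1f (%.1f) mm over %d points\n",
              object$subregion$condyle, object$subregion$flexion,
              s$mean_rounded, s$sd_rounded, object$n_valid))
  invisible(s)
}

#' @export
plot.thickness_map <- function(x, ...) {
  graphics::hist(x$thickness[x$valid], breaks = 20,
                 main = sprintf("Cartilage thickness (%s, %s)",
                                x$subregion$condyle, x$subregion$flexion),
                 xlab = "thickness (mm)", ...)
  graphics::abline(v = x$mean, lty = 2)
  invisible(x)
}

#' Mean and standard deviation of a thickness map
#'
#' Recomputes the summary from the per-point list (valid points only), and
#' also reports values rounded to 0.1 mm, the convention used for study
#' tables.
#'
#' @param map A `thickness_map` (or bare numeric vector of thicknesses).
#' @return List with `mean`, `sd`, `mean_rounded`, `sd_rounded`, `n`.
#' @export
subregion_stats <- function(map) {
  t_valid <- if (inherits(map, "thickness_map")) map$thickness[map$valid]
             else as.numeric(map)
  if (length(t_valid) < 2L)
    stop_validation("thickness statistics need at least 2 valid points")
  m <- mean(t_valid)
  s <- stats::sd(t_valid)
  list(mean = m, sd = s, mean_rounded = round(m, 1), sd_rounded = round(s, 1),
       n = length(t_valid))
}

#' Study-level summary of subregion thickness means
#'
#' Takes a table of per-specimen subregion statistics (four subregions per
#' specimen: medial/lateral condyle at 0/90 degrees of flexion) and
#' reproduces the study-table summaries: per-subregion column means over
#' specimens, the overall mean (mean of the four column means), and the
#' extreme cells, all reported to 0.1 mm.
#'
#' @param per_specimen_stats Data frame with columns `specimen`, `condyle`
#'   (`"medial"`/`"lateral"`), `flexion` (`"0deg"`/`"90deg"`), `mean_mm`,
#'   and optionally `sd_mm`.
#' @return Object of class `study_summary`: `cells` (input table),
#'   `column_means` (named, rounded to 0.1 mm), `column_means_raw`,
#'   `overall_mean`, `min_cell`, `max_cell`.
#' @export
summarize_study <- function(per_specimen_stats) {
  df <- as.data.frame(per_specimen_stats)
  need <- c("specimen", "condyle", "flexion", "mean_mm")
  if (!all(need %in% names(df)))
    stop_validation(sprintf("study table must have columns %s",
                            paste(need, collapse = ", ")))
  df$condyle <- as.character(df$condyle)
  df$flexion <- as.character(df$flexion)
  if (!all(df$condyle %in% c("medial", "lateral")) ||
      !all(df$flexion %in% c("0deg", "90deg")))
    stop_validation("condyle must be medial/lateral and flexion 0deg/90deg")
  # column order: medial 0, lateral 0, medial 90, lateral 90
  cols <- data.frame(condyle = c("medial", "lateral", "medial", "lateral"),
                     flexion = c("0deg", "0deg", "90deg", "90deg"))
  key <- paste(df$condyle, df$flexion)
  for (sp in unique(df$specimen)) {
    have <- key[df$specimen == sp]
    want <- paste(cols$condyle, cols$flexion)
    if (!setequal(have, want) || length(have) != 4L)
      stop_validation(sprintf("specimen '%s' must have exactly the 4 subregion cells", sp))
  }
  col_raw <- vapply(seq_len(nrow(cols)), function(i) {
    mean(df$mean_mm[df$condyle == cols$condyle[i] & df$flexion == cols$flexion[i]])
  }, numeric(1))
  names(col_raw) <- paste(cols$condyle, cols$flexion, sep = "_")
  overall <- mean(col_raw)
  imin <- which.min(df$mean_mm)
  imax <- which.max(df$mean_mm)
  cell_info <- function(i) list(specimen = df$specimen[i],
                                condyle = df$condyle[i],
                                flexion = df$flexion[i],
                                mean_mm = df$mean_mm[i])
  structure(list(cells = df,
                 column_means = round(col_raw, 1),
                 column_means_raw = col_raw,
                 overall_mean = round(overall, 1),
                 overall_mean_raw = overall,
                 min_cell = cell_info(imin),
                 max_cell = cell_info(imax)),
            class = "study_summary")
}

#' @export
print.study_summary <- function(x, ...) {
  cat("study summary (mm, rounded to 0.1):\n")
  cm <- x$column_means
  cat(sprintf("  column means: medial 0deg %.1f | lateral 0deg %.1f | medial 90deg %.1f | lateral 90deg %.1f\n",
              cm["medial_0deg"], cm["lateral_0deg"], cm["medial_90deg"],
              cm["lateral_90deg"]))
  cat(sprintf("  overall mean of column means: %.1f\n", x$overall_mean))
  cat(sprintf("  thinnest cell: %.1f (%s, %s, %s)\n", x$min_cell$mean_mm,
              x$min_cell$specimen, x$min_cell$condyle, x$min_cell$flexion))
  cat(sprintf("  thickest cell: %.1f (%s, %s, %s)\n", x$max_cell$mean_mm,
              x$max_cell$specimen, x$max_cell$condyle, x$max_cell$flexion))
  invisible(x)
}

#' Two-scan thickness precision propagation
#'
#' Thickness is the difference of two independent surface measurements, so
#' its precision is `sigma_t = sqrt(sigma^2 + sigma^2) = sqrt(2) * sigma`,
#' where `sigma` is the precision of an individual scan. Optionally reports
#' the relative error against a reference thickness.
#'
#' @param sigma_scan Single-scan precision (mm), `>= 0`.
#' @param reference_thickness Optional reference thickness (mm) for the
#'   relative error.
#' @return Object of class `precision_model`: `sigma_scan`,
#'   `sigma_thickness`, and (if a reference is given) `relative_error`.
#' @examples
#' propagate_precision(0.087) # sigma_t = 0.123 mm
#' @export
propagate_precision <- function(sigma_scan, reference_thickness = NULL) {
  if (!is.finite(sigma_scan) || sigma_scan < 0)
    stop_validation("sigma_scan must be a non-negative number")
  out <- list(sigma_scan = sigma_scan,
              sigma_thickness = sqrt(2) * sigma_scan)
  if (!is.null(reference_thickness)) {
    if (reference_thickness <= 0)
      stop_validation("reference_thickness must be positive")
    out$reference_thickness <- reference_thickness
    out$relative_error <- out$sigma_thickness / reference_thickness
  }
  structure(out, class = "precision_model")
}

#' @export
print.precision_model <- function(x, ...) {
  cat(sprintf("precision_model: sigma_scan %.3f mm -> sigma_thickness %.3f mm\n",
              x$sigma_scan, x$sigma_thickness))
  if (!is.null(x$relative_error))
    cat(sprintf("  relative error vs %.2f mm reference: %.1f%%\n",
                x$reference_thickness, 100 * x$relative_error))
  invisible(x)
}

#' Export a thickness map as CSV
#'
#' Columns: `vertex_index`, `x`, `y`, `z`, `thickness_mm`, `valid`.
#'
#' @param map A `thickness_map`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_thickness_csv <- function(map, path) {
  df <- data.frame(vertex_index = map$subregion$vertex_indices,
                   x = map$points[, 1], y = map$points[, 2],
                   z = map$points[, 3], thickness_mm = map$thickness,
                   valid = map$valid)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
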