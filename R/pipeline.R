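# High-level orchestration of the two-scan workflow, plus the cmd_*
# functions behind the inst/cli/cartscan.R command-line driver.

#' Register the with-cartilage scan onto the without-cartilage scan
#'
#' Fits a sphere to every fiducial marker cloud in both scans, establishes
#' marker correspondence, estimates the rigid transform taking the
#' with-cartilage scan's marker centres onto the without-cartilage scan's,
#' and applies it to the with-cartilage surface so both surfaces share one
#' frame.
#'
#' @param scan_with,scan_without Lists with elements `mesh` ([trimesh]) and
#'   `markers` (named list of [point_cloud]), as produced by
#'   [simulate_two_scans()].
#' @param marker_radius Optional known marker radius (mm) passed to the
#'   sphere fits.
#' @return List: `registration`, `cartilage` (the transformed with-cartilage
#'   mesh), `bone` (the without-cartilage mesh), `marker_sets`.
#' @export
align_scans <- function(scan_with, scan_without, marker_radius = NULL) {
  fit_set <- function(scan, id) {
    if (is.null(scan$markers) || length(scan$markers) < 3L)
      stop_validation(sprintf("scan '%s' needs at least 3 marker clouds", id))
    fits <- lapply(scan$markers, fit_sphere, fixed_radius = marker_radius)
    marker_set(fits, id)
  }
  set_a <- fit_set(scan_with, "with_cartilage")
  set_b <- fit_set(scan_without, "without_cartilage")
  reg <- register_marker_sets(set_a, set_b)
  list(registration = reg,
       cartilage = propagate_to_cartilage_model(reg, scan_with$mesh),
       bone = scan_without$mesh,
       marker_sets = list(with_cartilage = set_a, without_cartilage = set_b))
}

#' Condylar thickness measurement over the four standard subregions
#'
#' Runs the anatomical stages on a registered surface pair: builds the
#' standard anatomical frame from the landmark patches, expresses both
#' surfaces in it, measures the cartilage extent, extracts the medial and
#' lateral subregions at 0 and 90 degrees of flexion, and computes the four
#' closest-point thickness maps.
#'
#' @param cartilage_mesh,bone_mesh Registered [trimesh] pair (one frame).
#' @param patches List with `posterior_medial`, `posterior_lateral`,
#'   `trochlea` (vertex index sets into `cartilage_mesh`), `plateau`
#'   ([point_cloud] of the medial tibial plateau), and optionally
#'   `anterior_ref` (defaults to the trochlear patch centroid).
#' @param side `"right"` or `"left"`.
#' @param spec A [subregion_spec].
#' @param max_valid Thickness validity ceiling (mm).
#' @return Object of class `thickness_study`: `frame`, `extent`, `maps`
#'   (named list of four `thickness_map`s), `table` (per-subregion mean/SD
#'   data frame, mm).
#' @export
measure_condyle_thickness <- function(cartilage_mesh, bone_mesh, patches,
                                      side = "right",
                                      spec = subregion_spec(),
                                      max_valid = 10) {
  need <- c("posterior_medial", "posterior_lateral", "trochlea", "plateau")
  if (!all(need %in% names(patches)))
    stop_validation(sprintf("patches must contain %s",
                            paste(need, collapse = ", ")))
  v <- cartilage_mesh$vertices
  aref <- patches$anterior_ref
  if (is.null(aref))
    aref <- colMeans(v[patches$trochlea, , drop = FALSE])
  frame <- build_standard_frame(
    v[patches$posterior_medial, , drop = FALSE],
    v[patches$posterior_lateral, , drop = FALSE],
    patches$plateau, aref, side = side)
  cart_f <- to_frame(cartilage_mesh, frame)
  bone_f <- to_frame(bone_mesh, frame)
  extent <- measure_cartilage_extent(cart_f, patches$trochlea, spec = spec)
  maps <- list()
  for (condyle in c("medial", "lateral")) {
    s0 <- subregion_0deg(cart_f, extent, spec, condyle)
    len <- diff(s0$bounds$ap)
    s90 <- subregion_90deg(cart_f, extent, spec, condyle,
                           length_from_0deg = len)
    maps[[paste0(condyle, "_0deg")]] <-
      compute_thickness_map(cart_f, bone_f, s0, max_valid)
    maps[[paste0(condyle, "_90deg")]] <-
      compute_thickness_map(cart_f, bone_f, s90, max_valid)
  }
  tab <- do.call(rbind, lapply(maps, function(m)
    data.frame(condyle = m$subregion$condyle, flexion = m$subregion$flexion,
               mean_mm = m$mean, sd_mm = m$sd, n_points = m$n_valid)))
  rownames(tab) <- NULL
  structure(list(frame = frame, extent = extent, maps = maps, table = tab,
                 cartilage = cart_f, bone = bone_f),
            class = "thickness_study")
}

#' @export
print.thickness_study <- function(x, ...) {
  cat("thickness_study (mm):\n")
  tab <- x$table
  for (i in seq_len(nrow(tab)))
    cat(sprintf("  %-7s %-6s %.1f (%.1f)  n = %d\n", tab$condyle[i],
                tab$flexion[i], round(tab$mean_mm[i], 1),
                round(tab$sd_mm[i], 1), tab$n_points[i]))
  invisible(x)
}

# ---- command wrappers ---------------------------------------------------
# Thin, file-oriented entry points used by inst/cli/cartscan.R. Each takes
# a config list (or a YAML path when the yaml package is available) and
# writes its outputs under config$output_dir.

read_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop_io(sprintf("config file not found: %s", config))
    if (!requireNamespace("yaml", quietly = TRUE))
      stop_io("reading YAML configs requires the 'yaml' package")
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop_validation("config must be a list or YAML path")
  config
}

out_path <- function(config, name) {
  dir <- config$output_dir %||% "."
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  file.path(dir, name)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

config_spec <- function(config) {
  subregion_spec(
    wb_fraction = config$wb_fraction %||% 0.60,
    ap_band_fraction = config$ap_band_fraction %||% (1 / 3),
    ml_width_fraction = config$ml_width_fraction %||% 0.15)
}

#' Command backends for the command-line driver
#'
#' `cmd_phantom` generates a seeded phantom pair with markers and writes
#' PLY surfaces, marker clouds, patch indices, and a truth JSON.
#' `cmd_register` fits and matches the fiducial markers of the two scans
#' and writes the registered with-cartilage mesh plus a JSON report (4x4
#' matrix, FRE, correspondence). `cmd_thickness` runs the anatomical
#' pipeline on a registered pair and writes per-point CSVs and a
#' study-table-style summary CSV. `cmd_summarize` aggregates a study table
#' CSV. `cmd_deviation` compares a list of meshes pairwise.
#'
#' @param config A named list (or path to a YAML file) of inputs; see the
#'   command-line help in `inst/cli/cartscan.R` for the keys.
#' @return The principal result object of each command, invisibly; outputs
#'   are written to `config$output_dir`.
#' @name cmd
NULL

#' @rdname cmd
#' @export
cmd_phantom <- function(config) {
  config <- read_config(config)
  if (is.null(config$seed)) stop_validation("cmd_phantom requires a seed")
  ph <- make_bicondylar_phantom(
    condyle_radius = config$condyle_radius %||% 25,
    condyle_separation = config$condyle_separation %||% 44,
    t0 = config$t0 %||% 2, a = config$a %||% 0,
    step_deg = config$step_deg %||% 2.5)
  ph <- add_markers(ph, n_markers = config$n_markers %||% 7)
  scans <- simulate_two_scans(
    ph, sigma = config$sigma %||% 0.087,
    inter_scan_transform = if (is.null(config$transform)) rigid_transform()
      else transform_from_matrix(config$transform),
    seed = config$seed)
  write_mesh(scans$scan_with$mesh, out_path(config, "scan_with_cartilage.ply"))
  write_mesh(scans$scan_without$mesh, out_path(config, "scan_without_cartilage.ply"))
  for (lab in names(scans$scan_with$markers)) {
    utils::write.csv(
      data.frame(scans$scan_with$markers[[lab]]$points),
      out_path(config, sprintf("marker_with_%s.csv", lab)), row.names = FALSE)
    utils::write.csv(
      data.frame(scans$scan_without$markers[[lab]]$points),
      out_path(config, sprintf("marker_without_%s.csv", lab)), row.names = FALSE)
  }
  jsonlite::write_json(
    list(kind = ph$params$kind, params = ph$params,
         marker_centers_a = ph$markers$centers,
         thickness_range = range(ph$thickness),
         patches = lapply(ph$patches[c("trochlea", "posterior_medial",
                                       "posterior_lateral")], as.integer),
         seed = config$seed),
    out_path(config, "phantom_truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(ph)
}

#' @rdname cmd
#' @export
cmd_register <- function(config) {
  config <- read_config(config)
  for (key in c("mesh_with", "mesh_without"))
    if (is.null(config[[key]]) || !file.exists(config[[key]]))
      stop_io(sprintf("missing input mesh '%s': %s", key,
                      config[[key]] %||% "<unset>"))
  scan_with <- list(mesh = read_mesh(config$mesh_with),
                    markers = read_marker_clouds(config$markers_with))
  scan_without <- list(mesh = read_mesh(config$mesh_without),
                       markers = read_marker_clouds(config$markers_without))
  res <- align_scans(scan_with, scan_without,
                     marker_radius = config$marker_radius)
  write_mesh(res$cartilage, out_path(config, "cartilage_registered.ply"))
  jsonlite::write_json(
    list(matrix = transform_matrix(res$registration$transform),
         fre_rms_mm = res$registration$fre_rms,
         correspondence = res$registration$correspondence),
    out_path(config, "registration.json"), auto_unbox = TRUE, digits = NA)
  invisible(res)
}

read_marker_clouds <- function(paths) {
  if (is.null(paths)) return(NULL)
  out <- lapply(paths, function(p) {
    if (!file.exists(p)) stop_io(sprintf("marker cloud file not found: %s", p))
    if (grepl("\\.ply$", p, ignore.case = TRUE))
      point_cloud(read_mesh(p)$vertices)
    else point_cloud(as.matrix(utils::read.csv(p)))
  })
  names(out) <- if (!is.null(names(paths))) names(paths)
                else sub("\\.[^.]+$", "", basename(unlist(paths)))
  out
}

#' @rdname cmd
#' @export
cmd_thickness <- function(config) {
  config <- read_config(config)
  spec <- config_spec(config)
  cart <- read_mesh(config$mesh_cartilage)
  bone <- read_mesh(config$mesh_bone)
  patches <- jsonlite::read_json(config$patches, simplifyVector = TRUE)
  patches$plateau <- point_cloud(as.matrix(utils::read.csv(config$plateau)))
  study <- measure_condyle_thickness(cart, bone, patches,
                                     side = config$side %||% "right",
                                     spec = spec,
                                     max_valid = config$max_valid %||% 10)
  for (nm in names(study$maps))
    write_thickness_csv(study$maps[[nm]],
                        out_path(config, sprintf("thickness_%s.csv", nm)))
  tab <- study$table
  tab$mean_mm <- round(tab$mean_mm, 1)
  tab$sd_mm <- round(tab$sd_mm, 1)
  utils::write.csv(tab, out_path(config, "thickness_summary.csv"),
                   row.names = FALSE)
  invisible(study)
}

#' @rdname cmd
#' @export
cmd_summarize <- function(config) {
  config <- read_config(config)
  if (is.null(config$table) || !file.exists(config$table))
    stop_io(sprintf("study table not found: %s", config$table %||% "<unset>"))
  summ <- summarize_study(utils::read.csv(config$table))
  jsonlite::write_json(
    list(column_means = as.list(summ$column_means),
         overall_mean = summ$overall_mean,
         min_cell = summ$min_cell, max_cell = summ$max_cell),
    out_path(config, "study_summary.json"), auto_unbox = TRUE, digits = NA)
  invisible(summ)
}

#' @rdname cmd
#' @export
cmd_deviation <- function(config) {
  config <- read_config(config)
  if (is.null(config$meshes) || length(config$meshes) < 2L)
    stop_validation("cmd_deviation needs at least 2 meshes")
  meshes <- lapply(unlist(config$meshes), read_mesh)
  rep <- pairwise_repeatability(meshes,
                                symmetric = isTRUE(config$symmetric))
  write_deviation_csv(rep, out_path(config, "deviation.csv"))
  jsonlite::write_json(
    list(mean_rmsd_mm = rep$mean_rmsd, mean_ad_mm = rep$mean_ad,
         n_comparisons = nrow(rep$pairs)),
    out_path(config, "deviation.json"), auto_unbox = TRUE, digits = NA)
  invisible(rep)
}
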