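# End-to-end orchestration: simulate/load -> z-filter -> dual fit ->
# mother assignment -> plane extraction -> orientation -> probability map ->
# profile fits -> geometry report. All randomness flows from one master
# seed via fixed offsets, so a run is a pure function of its configuration.

#' Assemble a run configuration
#'
#' Either `simulate` (a list with `preset`, `n_particles`, optional
#' `params`, optional `noise`) or `volumes` + `seeds` (paths readable by
#' [read_volume()] / [read_seeds()]) must be supplied. Unknown keys are
#' rejected so typos cannot silently fall back to defaults.
#'
#' @param simulate synthetic-input description (see [generate_dataset()]).
#' @param volumes character vector of TIFF paths.
#' @param seeds path to a seed CSV.
#' @param fit_channel,reference_channel,query_channel 0-based channel roles;
#'   `reference_channel = NULL` switches mother assignment to brightness.
#' @param detection a [detection_params()].
#' @param upsample,grid_half plane resampling controls
#'   (see [extract_aligned_plane()]).
#' @param profile_components,profile_trim_px,profile_broad_bg profile-fit
#'   controls for the query channel (see [fit_profile()]).
#' @param profile_window_nm perpendicular averaging half-width for axis
#'   profiles (see [axis_profile()]); the vertical profile additionally
#'   windows to the fitted mother-satellite extent plus 150 nm.
#' @param mc_n Monte Carlo replicates for profile errors.
#' @param rng_seed master seed.
#' @param out_dir optional output directory for report and intermediates.
#' @return list of class `spa_run_config`.
#' @export
run_config <- function(simulate = NULL, volumes = NULL, seeds = NULL,
                       fit_channel = 0L, reference_channel = 1L,
                       query_channel = 1L,
                       detection = detection_params(),
                       upsample = 4L, grid_half = 320L,
                       profile_components = 1L, profile_trim_px = 0L,
                       profile_broad_bg = FALSE, profile_window_nm = 300,
                       mc_n = 100L, rng_seed = 1L, out_dir = NULL) {
  if (is.null(simulate) && (is.null(volumes) || is.null(seeds)))
    stop("config needs either `simulate` or `volumes` + `seeds`")
  structure(list(simulate = simulate, volumes = volumes, seeds = seeds,
                 fit_channel = as.integer(fit_channel),
                 reference_channel = if (is.null(reference_channel)) NULL
                                     else as.integer(reference_channel),
                 query_channel = as.integer(query_channel),
                 detection = detection, upsample = as.integer(upsample),
                 grid_half = as.integer(grid_half),
                 profile_components = as.integer(profile_components),
                 profile_trim_px = as.integer(profile_trim_px),
                 profile_broad_bg = isTRUE(profile_broad_bg),
                 profile_window_nm = as.numeric(profile_window_nm),
                 mc_n = as.integer(mc_n),
                 rng_seed = as.integer(rng_seed), out_dir = out_dir),
            class = "spa_run_config")
}

#' Load a run configuration from YAML
#'
#' @param path YAML file whose keys match the [run_config()] arguments.
#' @return a `spa_run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  unknown <- setdiff(names(y), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  if (!is.null(y$detection)) y$detection <- do.call(detection_params,
                                                    y$detection)
  do.call(run_config, y)
}

#' Execute the full single-particle-averaging pipeline
#'
#' @param config a [run_config()] (or path to a YAML config).
#' @return object of class `spa_run_report`: per-particle `fits` table,
#'   `counts` (detected/used and every rejection class), the accumulated
#'   `map`, `profiles` (query x/y and fit-channel x fits), `geometry`
#'   (separation, intensity ratio, bend angle with Monte Carlo errors) and
#'   the fully-resolved `config`.
#' @export
run_spa <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "spa_run_config"))

  if (!is.null(config$simulate)) {
    sim <- config$simulate
    dataset <- generate_dataset(sim$preset, sim$n_particles,
                                rng_seed = config$rng_seed,
                                params = sim$params %||% list(),
                                noise = sim$noise)
  } else {
    missing_files <- config$volumes[!file.exists(config$volumes)]
    if (length(missing_files))
      stop("missing input volume(s): ",
           paste(missing_files, collapse = ", "))
    seeds <- read_seeds(config$seeds)
    vols <- lapply(config$volumes, read_volume)
    names(vols) <- vapply(vols, `[[`, character(1), "image_id")
    dataset <- lapply(seeds, function(sp) {
      v <- vols[[sp$image_id]]
      if (is.null(v)) stop("seed row references unknown image_id ",
                           sp$image_id)
      list(volume = v, seed_pair = sp, truth = NULL)
    })
  }

  rejections <- character(0)
  planes <- list()
  fit_rows <- list()
  for (rec in dataset) {
    vol <- rec$volume; sp <- rec$seed_pair
    id <- vol$image_id
    zp <- extract_z_profile(vol, config$fit_channel, sp$mother_seed,
                            config$detection$box)
    if (!passes_z_filter(zp)) { rejections[id] <- "z_edge"; next }
    fit <- fit_dual_spot(vol, sp)
    if (!fit$converged) { rejections[id] <- "non_converged"; next }
    if (fit$degenerate) { rejections[id] <- "degenerate"; next }
    ref_center <- NULL
    if (!is.null(config$reference_channel)) {
      rf <- fit_single_spot(vol, config$reference_channel, sp$mother_seed)
      if (rf$converged) ref_center <- rf$spot$center
    }
    particle <- assign_mother(fit, ref_center)
    plane <- tryCatch(
      extract_aligned_plane(vol, particle, upsample = config$upsample,
                            grid_half = config$grid_half),
      error = function(e) NULL)
    if (is.null(plane)) { rejections[id] <- "tilt"; next }
    plane <- orient_plane(plane, config$query_channel,
                          config$reference_channel)
    if (!plane$orientation_ok) { rejections[id] <- "orientation"; next }
    planes[[length(planes) + 1L]] <- plane
    fit_rows[[length(fit_rows) + 1L]] <- data.frame(
      image_id = id,
      separation_nm = distance_3d(particle$mother_center,
                                  particle$distal_center),
      intensity_ratio = particle$mother_amplitude /
        particle$distal_amplitude,
      mother_rule = particle$mother_rule,
      sigma_xy_nm = fit$spot_a$sigma_lateral,
      sigma_z_nm = fit$spot_a$sigma_axial,
      background = fit$background,
      residual_variance = fit$residual_variance)
  }
  if (length(planes) == 0L)
    stop("no usable particles after filtering (",
         length(rejections), " rejection(s))")
  fits <- do.call(rbind, fit_rows)
  map <- accumulate_map(planes)

  seed_off <- function(k) (config$rng_seed + k) %% .Machine$integer.max
  win <- config$profile_window_nm
  prof_fit_x <- fit_profile(axis_profile(map, config$fit_channel, "x",
                                         normalize = "coverage",
                                         window_nm = win),
                            n_components = 2L, mc_n = config$mc_n,
                            mc_seed = seed_off(101L))
  # vertical profile averaged over the mother-satellite extent only
  sep_est <- abs(diff(prof_fit_x$components$center))
  win_y <- sep_est / 2 + 150
  prof_query_x <- fit_profile(axis_profile(map, config$query_channel, "x",
                                           normalize = "coverage",
                                           window_nm = win),
                              n_components = config$profile_components,
                              trim_px = if (config$profile_components == 1L)
                                config$profile_trim_px else 0L,
                              broad_bg = config$profile_broad_bg,
                              mc_n = config$mc_n,
                              mc_seed = seed_off(102L))
  prof_query_y <- fit_profile(axis_profile(map, config$query_channel, "y",
                                           normalize = "coverage",
                                           window_nm = win_y),
                              n_components = 1L, mc_n = config$mc_n,
                              mc_seed = seed_off(103L))

  sep_map <- diff(prof_fit_x$components$center)
  ratio_map <- prof_fit_x$components$amplitude[1] /
    prof_fit_x$components$amplitude[2]
  mother_pt <- c(prof_fit_x$components$center[1], 0)
  distal_pt <- c(prof_fit_x$components$center[2], 0)
  middle_pt <- c(prof_query_x$components$center[1],
                 prof_query_y$components$center[1])
  bend <- bend_angle(mother_pt, middle_pt, distal_pt)
  geometry <- list(
    separation_map_nm = sep_map,
    separation_map_sd_nm = sqrt(sum(prof_fit_x$errors[
      c("center_1", "center_2")]^2)),
    separation_fit_mean_nm = mean(fits$separation_nm),
    intensity_ratio_map = ratio_map,
    intensity_ratio_fit_mean = mean(fits$intensity_ratio),
    bend_deg = bend,
    landmarks = list(mother = mother_pt, middle = middle_pt,
                     distal = distal_pt))

  counts <- list(
    detected = length(dataset),
    used = length(planes),
    rejected = as.list(table(unname(rejections))))
  report <- structure(list(fits = fits, counts = counts, map = map,
                           profiles = list(fit_x = prof_fit_x,
                                           query_x = prof_query_x,
                                           query_y = prof_query_y),
                           geometry = geometry, config = config,
                           rejections = rejections),
                      class = "spa_run_report")
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

#' @export
print.spa_run_report <- function(x, ...) {
  cat("<spa_run_report>\n")
  cat(sprintf("  particles: %d used / %d detected\n", x$counts$used,
              x$counts$detected))
  g <- x$geometry
  cat(sprintf("  separation (map fit): %.1f nm (sd %.1f)\n",
              g$separation_map_nm, g$separation_map_sd_nm))
  cat(sprintf("  intensity ratio (map fit): %.2f\n", g$intensity_ratio_map))
  cat(sprintf("  bend angle: %.1f deg\n", g$bend_deg))
  invisible(x)
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$fits, file.path(out_dir, "fits.csv"),
                   row.names = FALSE)
  prof_export <- lapply(report$profiles, function(p)
    list(components = p$components, offset = p$offset,
         errors = as.list(p$errors), residual_variance = p$residual_variance))
  jsonlite::write_json(
    list(geometry = report$geometry[setdiff(names(report$geometry),
                                            "landmarks")],
         counts = report$counts, profiles = prof_export),
    file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA)
  map <- report$map
  map_vol <- spa_volume(array(map$grid,
                              dim = c(dim(map$grid)[1], 1L,
                                      dim(map$grid)[2], dim(map$grid)[3])),
                        c(map$pixel_size, map$pixel_size, map$pixel_size),
                        channel_labels = map$channel_labels,
                        image_id = "probability_map")
  write_volume(map_vol, file.path(out_dir, "map.tiff"))
  jsonlite::write_json(
    list(n_particles = map$n_particles, pixel_size = map$pixel_size,
         particle_ids = map$particle_ids),
    file.path(out_dir, "map_meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
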