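# Ground-truthed synthetic scene generation.
#
# Emulates SIM-reconstructed two-color volumes of diffraction-limited
# particles: anisotropic Gaussian PSF (defaults sigma_xy = 50 nm, FWHM ~118
# nm; sigma_z = 130 nm, FWHM ~306 nm), 40 nm lateral voxels, 125 nm axial
# step, additive Gaussian noise over a constant background. Presets mirror
# the canonical mother/satellite geometries: a two-spot pair with a
# fiducial, a bent three-point bridge, a line-source bridge and a single
# spot. Everything is a pure function of (spec, seed).

scene_defaults <- function() {
  list(volume_shape = c(channels = 2L, nz = 15L, ny = 64L, nx = 64L),
       voxel_size = c(dz = 125, dy = 40, dx = 40),
       psf_sigma_xy = 50, psf_sigma_z = 130,
       background = c(10, 10),
       noise_sd = 2,
       mother_amplitude = 100,
       intensity_ratio = 1.9,
       separation = 225,
       bend_deg = 17,
       line_length = 160,
       line_intensity = 60000,
       query_offset = c(12, 15),
       max_tilt_deg = 30,
       center_jitter_px = 2,
       fiducial_amplitude = 100)
}

#' Build a synthetic scene specification
#'
#' Presets (channel 0 is always the fit channel):
#' * `pair`: two spots (mother/satellite, amplitude ratio
#'   `intensity_ratio`) in channel 0 and a single fiducial spot at the
#'   mother in channel 1.
#' * `bent_triplet`: the two-spot pair in channel 0 plus a query emitter in
#'   channel 1 at the bridge midpoint, displaced along the pole axis so the
#'   mother-middle-distal bend equals `bend_deg`.
#' * `line_bridge`: the pair in channel 0 plus a uniform line source of
#'   length `line_length` along the mother-satellite axis in channel 1.
#' * `offset_pair`: the pair in channel 0 and a copy in channel 1 shifted by
#'   `query_offset` = (dx, dy) nm in the particle frame.
#' * `single`: one spot in channel 0, fiducial at the same place in
#'   channel 1 (separation undefined).
#'
#' The particle axis direction is drawn uniformly in-plane with a z-tilt
#' uniform in `[0, max_tilt_deg]`; the particle center jitters by up to
#' `center_jitter_px` around the volume center.
#'
#' @param preset one of `"pair"`, `"bent_triplet"`, `"line_bridge"`,
#'   `"offset_pair"`, `"single"`.
#' @param params named list overriding any of the defaults (see
#'   `spasim:::scene_defaults()`).
#' @param rng_seed integer; identical (preset, params, seed) give identical
#'   scenes.
#' @param image_id identifier for the rendered volume.
#' @return object of class `spa_scene_spec` with `emitters`, `truth`, and
#'   all imaging parameters resolved.
#' @export
make_scene <- function(preset = c("pair", "bent_triplet", "line_bridge",
                                  "offset_pair", "single"),
                       params = list(), rng_seed = 1L,
                       image_id = paste0(preset, "_", rng_seed)) {
  preset <- match.arg(preset)
  p <- utils::modifyList(scene_defaults(), params)
  unknown <- setdiff(names(params), names(scene_defaults()))
  if (length(unknown))
    stop("unknown scene parameter(s): ", paste(unknown, collapse = ", "))
  old <- .Random.seed_get(); on.exit(.Random.seed_set(old))
  set.seed(as.integer(rng_seed))
  vs <- p$voxel_size; sh <- p$volume_shape
  center <- c((sh[["nx"]] - 1) / 2 * vs[["dx"]],
              (sh[["ny"]] - 1) / 2 * vs[["dy"]],
              (sh[["nz"]] - 1) / 2 * vs[["dz"]])
  jit <- stats::runif(3, -1, 1) *
    c(p$center_jitter_px * vs[["dx"]], p$center_jitter_px * vs[["dy"]],
      0.5 * vs[["dz"]])
  center <- center + jit
  theta <- stats::runif(1, 0, 2 * pi)
  tilt <- stats::runif(1, 0, p$max_tilt_deg) * pi / 180
  u <- c(cos(theta) * cos(tilt), sin(theta) * cos(tilt), sin(tilt))
  zhat <- c(0, 0, 1)
  v <- zhat - sum(zhat * u) * u
  v <- v / sqrt(sum(v^2))
  d <- p$separation
  mother <- center - d / 2 * u
  distal <- center + d / 2 * u
  A_m <- p$mother_amplitude
  A_d <- A_m / p$intensity_ratio
  pt <- function(channel, pos, amplitude)
    list(channel = channel, type = "point", pos = pos,
         amplitude = amplitude)
  seg <- function(channel, from, to, total_intensity)
    list(channel = channel, type = "segment", from = from, to = to,
         total_intensity = total_intensity)
  emitters <- switch(preset,
    pair = list(pt(0L, mother, A_m), pt(0L, distal, A_d),
                pt(1L, mother, p$fiducial_amplitude)),
    bent_triplet = {
      h <- d / 2 * tan(p$bend_deg / 2 * pi / 180)
      middle <- (mother + distal) / 2 + h * v
      list(pt(0L, mother, A_m), pt(0L, distal, A_d), pt(1L, middle, A_m))
    },
    line_bridge = {
      half_l <- p$line_length / 2
      mid <- (mother + distal) / 2
      list(pt(0L, mother, A_m), pt(0L, distal, A_d),
           seg(1L, mid - half_l * u, mid + half_l * u, p$line_intensity))
    },
    offset_pair = {
      off <- p$query_offset[1] * u + p$query_offset[2] * v
      list(pt(0L, mother, A_m), pt(0L, distal, A_d),
           pt(1L, mother + off, A_m), pt(1L, distal + off, A_d))
    },
    single = list(pt(0L, center, A_m),
                  pt(1L, center, p$fiducial_amplitude)))
  truth <- list(
    preset = preset,
    mother = if (preset == "single") center else mother,
    distal = if (preset == "single") NULL else distal,
    separation = if (preset == "single") NA_real_ else d,
    intensity_ratio = if (preset == "single") NA_real_
                      else p$intensity_ratio,
    bend_deg = if (preset == "bent_triplet") p$bend_deg else NA_real_,
    query_offset = if (preset == "offset_pair") p$query_offset else NULL,
    u = u, v = v, tilt_deg = tilt * 180 / pi,
    center = center)
  structure(c(p, list(preset = preset, emitters = emitters, truth = truth,
                      rng_seed = as.integer(rng_seed),
                      image_id = image_id)),
            class = "spa_scene_spec")
}

#' Render a scene specification into a volume
#'
#' Point emitters contribute `A exp(-dx^2/2s_xy^2 - dy^2/2s_xy^2
#' - dz^2/2s_z^2)` in physical units; segments are integrated numerically
#' with `n_segment_samples` point sources whose summed voxel flux equals the
#' segment's `total_intensity`. Background is added per channel and Gaussian
#' noise is drawn from the scene seed, so rendering is deterministic.
#'
#' @param spec a [make_scene()] result.
#' @param noise override the scene noise SD (e.g. `0` for a noiseless
#'   render).
#' @param n_segment_samples point samples per line segment (>= 64).
#' @return list with `volume` (a [spa_volume()]) and `truth` (ground-truth
#'   record, including seed-friendly pixel positions).
#' @export
render_scene <- function(spec, noise = NULL, n_segment_samples = 64L) {
  stopifnot(inherits(spec, "spa_scene_spec"))
  sh <- spec$volume_shape; vs <- spec$voxel_size
  nx <- sh[["nx"]]; ny <- sh[["ny"]]; nz <- sh[["nz"]]
  xs <- (0:(nx - 1)) * vs[["dx"]]
  ys <- (0:(ny - 1)) * vs[["dy"]]
  zs <- (0:(nz - 1)) * vs[["dz"]]
  sxy <- spec$psf_sigma_xy; sz <- spec$psf_sigma_z
  data <- array(0, dim = c(sh[["channels"]], nz, ny, nx))
  add_point <- function(ch, pos, peak) {
    ex <- exp(-(xs - pos[1])^2 / (2 * sxy^2))
    ey <- exp(-(ys - pos[2])^2 / (2 * sxy^2))
    ez <- exp(-(zs - pos[3])^2 / (2 * sz^2))
    data[ch + 1L, , , ] <<- data[ch + 1L, , , ] + peak * (ez %o% ey %o% ex)
  }
  voxel_vol <- vs[["dx"]] * vs[["dy"]] * vs[["dz"]]
  for (e in spec$emitters) {
    if (e$type == "point") {
      add_point(e$channel, e$pos, e$amplitude)
    } else {
      ns <- max(64L, as.integer(n_segment_samples))
      ts <- (seq_len(ns) - 0.5) / ns
      flux_per_sample <- e$total_intensity / ns
      peak <- flux_per_sample * voxel_vol / ((2 * pi)^1.5 * sxy^2 * sz)
      for (t in ts)
        add_point(e$channel, e$from + t * (e$to - e$from), peak)
    }
  }
  bg <- rep_len(spec$background, sh[["channels"]])
  for (ch in seq_len(sh[["channels"]]))
    data[ch, , , ] <- data[ch, , , ] + bg[ch]
  sd_noise <- if (is.null(noise)) spec$noise_sd else noise
  if (sd_noise > 0) {
    old <- .Random.seed_get(); on.exit(.Random.seed_set(old))
    set.seed(spec$rng_seed + 1e6L)
    data <- data + array(stats::rnorm(length(data), sd = sd_noise),
                         dim = dim(data))
    data <- pmax(data, 0)
  }
  vol <- spa_volume(data, vs, channel_labels =
                      paste0("ch", seq_len(sh[["channels"]]) - 1L),
                    image_id = spec$image_id)
  truth <- spec$truth
  truth$mother_px <- truth$mother[1:2] / vs[c("dx", "dy")]
  if (!is.null(truth$distal))
    truth$distal_px <- truth$distal[1:2] / vs[c("dx", "dy")]
  truth$noise_sd <- sd_noise
  list(volume = vol, truth = truth)
}

#' Generate a reproducible synthetic dataset
#'
#' `n` independent scenes with per-scene seeds derived deterministically
#' from `rng_seed`; seed pairs are the true lateral spot positions perturbed
#' by up to +/- 1 px uniform jitter, emulating manual clicking.
#'
#' @param preset scene preset (see [make_scene()]).
#' @param n_particles number of scenes.
#' @param rng_seed master seed.
#' @param params overrides forwarded to [make_scene()].
#' @param noise optional noise override forwarded to [render_scene()].
#' @return list of records, each with `volume`, `seed_pair` (`NULL` for the
#'   `single` preset), `truth`, `scene`.
#' @export
generate_dataset <- function(preset, n_particles, rng_seed = 1L,
                             params = list(), noise = NULL) {
  stopifnot(n_particles >= 1)
  old <- .Random.seed_get(); on.exit(.Random.seed_set(old))
  set.seed(as.integer(rng_seed))
  scene_seeds <- sample.int(2^30, n_particles)
  jitters <- matrix(stats::runif(4 * n_particles, -1, 1), ncol = 4)
  lapply(seq_len(n_particles), function(i) {
    spec <- make_scene(preset, params, rng_seed = scene_seeds[i],
                       image_id = sprintf("%s_%03d", preset, i))
    sc <- render_scene(spec, noise = noise)
    sp <- NULL
    if (spec$preset != "single") {
      sp <- seed_pair(image_id = spec$image_id, fit_channel = 0L,
                      reference_channel = 1L,
                      mother_seed = sc$truth$mother_px + jitters[i, 1:2],
                      distal_seed = sc$truth$distal_px + jitters[i, 3:4])
    }
    list(volume = sc$volume, seed_pair = sp, truth = sc$truth, scene = spec)
  })
}

#' Write a ground-truth record as a JSON sidecar
#'
#' @param truth a truth record from [render_scene()].
#' @param path output JSON path.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
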