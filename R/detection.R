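#' Detection parameters
#'
#' Defaults reproduce the semi-automated spindle-pole-body screen: blur the
#' sum projection with a 1-px Gaussian, keep maxima above 15% of the blurred
#' maximum that are at least 30 px from any brighter accepted maximum, and
#' inspect 30x30-px z-profiles.
#'
#' @param blur_sigma Gaussian blur SD in pixels (>= 0).
#' @param threshold_fraction fraction of the blurred-image maximum, in (0,1).
#' @param min_distance minimum Euclidean distance between accepted maxima,
#'   pixels.
#' @param box lateral window size for z-profiles, pixels.
#' @return list of class `spa_detection_params`.
#' @export
detection_params <- function(blur_sigma = 1, threshold_fraction = 0.15,
                             min_distance = 30, box = 30) {
  stopifnot(blur_sigma >= 0, threshold_fraction > 0, threshold_fraction < 1,
            min_distance > 0, box >= 3)
  structure(list(blur_sigma = blur_sigma,
                 threshold_fraction = threshold_fraction,
                 min_distance = min_distance, box = as.integer(box)),
            class = "spa_detection_params")
}

#' Sum projection of one channel along z
#'
#' @param volume a [spa_volume()].
#' @param channel 0-based channel index.
#' @return matrix (y, x), `out[y, x] = sum_z data[channel, z, y, x]`.
#' @export
sum_project <- function(volume, channel) {
  channel <- check_channel(volume, channel)
  d <- dim(volume$data)
  ch <- array(volume$data[channel + 1L, , , ], dim = d[2:4])
  apply(ch, c(2, 3), sum)
}

#' Find candidate particles on a projection image
#'
#' Blurs the projection, then greedily accepts local maxima in descending
#' blurred-intensity order: a maximum is kept iff it exceeds
#' `threshold_fraction` of the blurred-image maximum and lies at least
#' `min_distance` px (Euclidean) from every previously accepted maximum.
#' Ties in value are broken by (y, x) lexicographic order. A constant image
#' yields no candidates.
#'
#' @param projection numeric matrix (y, x), all finite.
#' @param params a [detection_params()].
#' @return data.frame with 0-based `x`, `y` and blurred `peak_value`, in
#'   acceptance order (possibly 0 rows).
#' @export
find_candidates <- function(projection, params = detection_params()) {
  stopifnot(is.matrix(projection), all(is.finite(projection)))
  empty <- data.frame(x = numeric(0), y = numeric(0),
                      peak_value = numeric(0))
  if (diff(range(projection)) == 0) return(empty)
  b <- gaussian_blur2d(projection, params$blur_sigma)
  thr <- params$threshold_fraction * max(b)
  lm <- local_maxima(b)
  keep <- which(lm & b > thr, arr.ind = TRUE)
  if (nrow(keep) == 0L) return(empty)
  vals <- b[keep]
  # descending value, ties by (y, x) lexicographic
  ord <- order(-vals, keep[, 1], keep[, 2])
  ys <- keep[ord, 1] - 1L; xs <- keep[ord, 2] - 1L; vals <- vals[ord]
  acc_x <- numeric(0); acc_y <- numeric(0); acc_v <- numeric(0)
  for (i in seq_along(vals)) {
    if (length(acc_x) == 0L ||
        all((acc_x - xs[i])^2 + (acc_y - ys[i])^2 >=
            params$min_distance^2)) {
      acc_x <- c(acc_x, xs[i]); acc_y <- c(acc_y, ys[i])
      acc_v <- c(acc_v, vals[i])
    }
  }
  data.frame(x = acc_x, y = acc_y, peak_value = acc_v)
}

local_maxima <- function(m) {
  ny <- nrow(m); nx <- ncol(m)
  pad <- matrix(-Inf, ny + 2L, nx + 2L)
  pad[2:(ny + 1L), 2:(nx + 1L)] <- m
  res <- matrix(TRUE, ny, nx)
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    res <- res & (m >= pad[(2:(ny + 1L)) + dy, (2:(nx + 1L)) + dx])
  }
  res
}

#' Extract a boxed z-profile at a lateral position
#'
#' Sums intensities over a `box` x `box` lateral window (start index
#' `round(center) - box/2`, clipped at the borders) for every slice.
#'
#' @param volume a [spa_volume()].
#' @param channel 0-based channel index.
#' @param xy `(x, y)` 0-based lateral pixel position.
#' @param box window size in pixels.
#' @return numeric vector, one summed intensity per slice.
#' @export
extract_z_profile <- function(volume, channel, xy, box = 30) {
  channel <- check_channel(volume, channel)
  d <- dim(volume$data)
  half <- as.integer(box) %/% 2L
  x0 <- as.integer(round(xy[1])) - half; y0 <- as.integer(round(xy[2])) - half
  xs <- max(x0, 0L):min(x0 + box - 1L, d[4] - 1L)
  ys <- max(y0, 0L):min(y0 + box - 1L, d[3] - 1L)
  if (xy[1] < 0 || xy[1] > d[4] - 1L || xy[2] < 0 || xy[2] > d[3] - 1L)
    stop("xy outside lateral image bounds")
  sub <- volume$data[channel + 1L, , ys + 1L, xs + 1L, drop = FALSE]
  apply(array(sub, dim = dim(sub)[2:4]), 1, sum)
}

#' Axial edge filter for candidate particles
#'
#' Fits a 1D Gaussian (amplitude, center, sigma, offset) to the z-profile and
#' rejects the particle when the fitted center falls within one slice of the
#' first or last slice (a truncated particle) or when the fit fails.
#'
#' @param profile numeric vector of per-slice intensities, length >= 3.
#' @return `TRUE` if the particle is axially well contained.
#' @export
passes_z_filter <- function(profile) {
  n <- length(profile)
  if (n < 3L) stop("z-profile must have at least 3 slices")
  fit <- fit_gauss1d(profile)
  if (!isTRUE(fit$converged) || !is.finite(fit$center)) return(FALSE)
  fit$center >= 1 && fit$center <= n - 2
}

#' Run detection over a whole volume channel
#'
#' Convenience wrapper: sum projection, candidate search, z-profile
#' extraction and edge filtering.
#'
#' @inheritParams sum_project
#' @param params a [detection_params()].
#' @return data.frame with columns `image_id`, `channel`, `x`, `y`,
#'   `peak_value`, `z_edge_ok`.
#' @export
detect_particles <- function(volume, channel, params = detection_params()) {
  proj <- sum_project(volume, channel)
  cand <- find_candidates(proj, params)
  z_ok <- vapply(seq_len(nrow(cand)), function(i) {
    prof <- extract_z_profile(volume, channel,
                              c(cand$x[i], cand$y[i]), params$box)
    passes_z_filter(prof)
  }, logical(1))
  data.frame(image_id = rep(volume$image_id, nrow(cand)),
             channel = rep(as.integer(channel), nrow(cand)),
             cand, z_edge_ok = z_ok)
}
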