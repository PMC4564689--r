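# Constrained single- and dual-spot 3D Gaussian fitting.
#
# All centers and widths are in nm (position = 0-based voxel index times
# spacing), so voxel anisotropy cannot bias distances. Optimization is
# box-constrained nonlinear least squares (PORT/nlminb): lateral centers are
# confined to +/- 2 px around the picked seeds and axial centers to +/- 2
# slices around the 3x3 z-profile initialization, mirroring the guards used
# against dramatic misfits in sparse two-spot images.

# parameter layout: B, then per spot (A, cx, cy, cz), then sigma_xy, sigma_z
spot_par_names <- function(nspots) {
  c("background",
    unlist(lapply(seq_len(nspots), function(k)
      paste0(c("amplitude", "cx", "cy", "cz"), "_", k))),
    "sigma_xy", "sigma_z")
}

model_spots <- function(par, grid, nspots) {
  sxy <- par[length(par) - 1L]; sz <- par[length(par)]
  m <- array(par[1], dim = c(length(grid$z), length(grid$y), length(grid$x)))
  for (k in seq_len(nspots)) {
    o <- 1L + 4L * (k - 1L)
    ex <- exp(-(grid$x - par[o + 2L])^2 / (2 * sxy^2))
    ey <- exp(-(grid$y - par[o + 3L])^2 / (2 * sxy^2))
    ez <- exp(-(grid$z - par[o + 4L])^2 / (2 * sz^2))
    m <- m + par[o + 1L] * (ez %o% ey %o% ex)
  }
  m
}

crop_volume <- function(volume, channel, seeds_px, margin = 15L) {
  d <- dim(volume$data)
  xr <- range(round(vapply(seeds_px, `[`, numeric(1), 1)))
  yr <- range(round(vapply(seeds_px, `[`, numeric(1), 2)))
  xs <- max(xr[1] - margin, 0):min(xr[2] + margin, d[4] - 1L)
  ys <- max(yr[1] - margin, 0):min(yr[2] + margin, d[3] - 1L)
  zs <- 0:(d[2] - 1L)
  data <- array(volume$data[channel + 1L, zs + 1L, ys + 1L, xs + 1L],
                dim = c(length(zs), length(ys), length(xs)))
  vs <- volume$voxel_size
  list(data = data,
       origin = c(z = zs[1], y = ys[1], x = xs[1]),
       grid = list(z = zs * vs[1], y = ys * vs[2], x = xs * vs[3]),
       voxel_size = vs)
}

#' Initialize the axial center of a spot
#'
#' Returns the slice maximizing the 3x3 lateral intensity sum centered at
#' `round(xy)`; ties break toward the smaller slice index.
#'
#' @param volume a [spa_volume()].
#' @param channel 0-based channel index.
#' @param xy `(x, y)` 0-based lateral pixels.
#' @return 0-based slice index.
#' @export
init_axial_center <- function(volume, channel, xy) {
  channel <- check_channel(volume, channel)
  d <- dim(volume$data)
  cx <- as.integer(round(xy[1])); cy <- as.integer(round(xy[2]))
  xs <- max(cx - 1L, 0L):min(cx + 1L, d[4] - 1L)
  ys <- max(cy - 1L, 0L):min(cy + 1L, d[3] - 1L)
  sub <- volume$data[channel + 1L, , ys + 1L, xs + 1L, drop = FALSE]
  prof <- apply(array(sub, dim = dim(sub)[2:4]), 1, sum)
  which.max(prof) - 1L
}

# gradient of the residual sum of squares; separable structure keeps every
# term a cheap triple contraction
spot_grad <- function(par, grid, nspots, data) {
  sxy <- par[length(par) - 1L]; sz <- par[length(par)]
  nz <- length(grid$z); ny <- length(grid$y); nx <- length(grid$x)
  r <- model_spots(par, grid, nspots) - data
  rm2 <- matrix(r, nz * ny, nx)
  contract <- function(a, b, c)
    sum(a * (matrix(rm2 %*% c, nz, ny) %*% b))
  g <- numeric(length(par))
  g[1] <- 2 * sum(r)
  for (k in seq_len(nspots)) {
    o <- 1L + 4L * (k - 1L)
    A <- par[o + 1L]
    dx <- grid$x - par[o + 2L]; dy <- grid$y - par[o + 3L]
    dz <- grid$z - par[o + 4L]
    ex <- exp(-dx^2 / (2 * sxy^2)); ey <- exp(-dy^2 / (2 * sxy^2))
    ez <- exp(-dz^2 / (2 * sz^2))
    g[o + 1L] <- 2 * contract(ez, ey, ex)
    g[o + 2L] <- 2 * A * contract(ez, ey, ex * dx / sxy^2)
    g[o + 3L] <- 2 * A * contract(ez, ey * dy / sxy^2, ex)
    g[o + 4L] <- 2 * A * contract(ez * dz / sz^2, ey, ex)
    g[length(par) - 1L] <- g[length(par) - 1L] +
      2 * A * (contract(ez, ey, ex * dx^2 / sxy^3) +
               contract(ez, ey * dy^2 / sxy^3, ex))
    g[length(par)] <- g[length(par)] +
      2 * A * contract(ez * dz^2 / sz^3, ey, ex)
  }
  g
}

run_spot_fit <- function(crop, nspots, p0, lower, upper,
                         iter_max = 1000, rel_tol = 1e-10) {
  obj <- function(p) sum((model_spots(p, crop$grid, nspots) - crop$data)^2)
  grad <- function(p) spot_grad(p, crop$grid, nspots, crop$data)
  accept <- function(fit)
    fit$convergence == 0 ||
      grepl(paste0("relative convergence|X-convergence|",
                   "singular convergence|absolute function convergence"),
            fit$message %||% "") ||
      fit$objective <= 1e-8 * sum(crop$data^2)  # numerically perfect fit
  start <- p0
  fit <- NULL; ok <- FALSE
  # up to two restarts: the PORT algorithm occasionally stalls with a
  # "false convergence" diagnostic just short of the optimum
  for (attempt in 1:3) {
    fit <- tryCatch(
      stats::nlminb(start, obj, gradient = grad,
                    scale = 1 / pmax(abs(start), 1),
                    lower = lower, upper = upper,
                    control = list(iter.max = iter_max,
                                   eval.max = 10 * iter_max,
                                   rel.tol = rel_tol)),
      error = function(e) NULL)
    if (is.null(fit)) {
      resid <- crop$data - model_spots(start, crop$grid, nspots)
      return(list(par = start, converged = FALSE, rss = sum(resid^2),
                  residual_variance = mean(resid^2)))
    }
    ok <- accept(fit)
    if (ok) break
    start <- fit$par
  }
  resid <- crop$data - model_spots(fit$par, crop$grid, nspots)
  list(par = fit$par, converged = ok,
       rss = fit$objective,
       residual_variance = mean(resid^2))
}

spot_from_par <- function(par, k, vs) {
  o <- 1L + 4L * (k - 1L)
  list(amplitude = par[o + 1L],
       center = c(x = par[o + 2L], y = par[o + 3L], z = par[o + 4L]),
       sigma_lateral = par[length(par) - 1L],
       sigma_axial = par[length(par)])
}

#' Fit a single 3D Gaussian spot
#'
#' Least-squares fit of `B + A exp(-dx^2/2s_xy^2 - dy^2/2s_xy^2
#' - dz^2/2s_z^2)` over a crop around the seed (all z slices, +/- 15 px
#' laterally), with the lateral center constrained to seed +/- 2 px and the
#' axial center to its 3x3 z-profile initialization +/- 2 slices.
#'
#' @param volume a [spa_volume()].
#' @param channel 0-based channel index.
#' @param seed `(x, y)` 0-based lateral pixels.
#' @param margin lateral crop margin in pixels.
#' @return object of class `spa_spot_fit`: `spot` (amplitude, center nm,
#'   sigma_lateral, sigma_axial), `background`, `residual_variance`,
#'   `converged`, `crop_origin`, plus the crop needed for Monte Carlo
#'   refitting.
#' @export
fit_single_spot <- function(volume, channel, seed, margin = 15L) {
  channel <- check_channel(volume, channel)
  vs <- volume$voxel_size
  crop <- crop_volume(volume, channel, list(seed), margin)
  z0 <- init_axial_center(volume, channel, seed)
  B0 <- stats::quantile(crop$data, 0.1, names = FALSE)
  A0 <- max(max(crop$data) - B0, 1e-6)
  p0 <- c(B0, A0, seed[1] * vs[3], seed[2] * vs[2], z0 * vs[1],
          1.2 * vs[3], 1.0 * vs[1])
  nz <- dim(crop$data)[1]
  lower <- c(-Inf, 1e-9,
             (seed[1] - 2) * vs[3], (seed[2] - 2) * vs[2],
             max(z0 - 2, 0) * vs[1], 0.2 * vs[3], 0.2 * vs[1])
  upper <- c(Inf, Inf,
             (seed[1] + 2) * vs[3], (seed[2] + 2) * vs[2],
             min(z0 + 2, nz - 1) * vs[1], 20 * vs[3], 10 * vs[1])
  res <- run_spot_fit(crop, 1L, p0, lower, upper)
  structure(list(
    spot = spot_from_par(res$par, 1L, vs),
    background = res$par[1],
    residual_variance = res$residual_variance,
    converged = res$converged,
    crop_origin = crop$origin,
    seed = seed, channel = channel, voxel_size = vs,
    par = stats::setNames(res$par, spot_par_names(1L)),
    init = p0, lower = lower, upper = upper,
    nspots = 1L, crop = crop), class = "spa_spot_fit")
}

#' Fit the sum of two constrained 3D Gaussians
#'
#' Joint fit of two spots sharing lateral and axial widths over one constant
#' background, the per-particle model for a mother/satellite pair. Lateral
#' centers are constrained to their seeds +/- 2 px; axial centers are
#' initialized from 3x3 z-profiles and constrained +/- 2 slices. `spot_a`
#' always corresponds to `mother_seed`.
#'
#' @param volume a [spa_volume()].
#' @param seedpair a [seed_pair()] (uses its `fit_channel`).
#' @param margin lateral crop margin in pixels beyond the seed bounding box.
#' @param shared_widths if `FALSE`, each spot gets its own sigma pair
#'   (parameters `sigma_xy_2`, `sigma_z_2` appended).
#' @return object of class `spa_dual_fit` with `spot_a`, `spot_b`,
#'   `background`, `residual_variance`, `converged`, `degenerate`,
#'   `crop_origin`, `seeds`, and refit state for [monte_carlo_errors()].
#' @export
fit_dual_spot <- function(volume, seedpair, margin = 15L,
                          shared_widths = TRUE) {
  stopifnot(inherits(seedpair, "spa_seed_pair"))
  channel <- check_channel(volume, seedpair$fit_channel)
  vs <- volume$voxel_size
  seeds <- list(seedpair$mother_seed, seedpair$distal_seed)
  crop <- crop_volume(volume, channel, seeds, margin)
  nz <- dim(crop$data)[1]
  z0 <- vapply(seeds, function(s) init_axial_center(volume, channel, s),
               numeric(1))
  B0 <- stats::quantile(crop$data, 0.1, names = FALSE)
  peak_near <- function(s, z) {
    d <- dim(volume$data)
    xs <- max(round(s[1]) - 1, 0):min(round(s[1]) + 1, d[4] - 1)
    ys <- max(round(s[2]) - 1, 0):min(round(s[2]) + 1, d[3] - 1)
    max(volume$data[channel + 1L, z + 1L, ys + 1L, xs + 1L])
  }
  A0 <- vapply(1:2, function(k) max(peak_near(seeds[[k]], z0[k]) - B0, 1e-6),
               numeric(1))
  p0 <- c(B0,
          A0[1], seeds[[1]][1] * vs[3], seeds[[1]][2] * vs[2], z0[1] * vs[1],
          A0[2], seeds[[2]][1] * vs[3], seeds[[2]][2] * vs[2], z0[2] * vs[1],
          1.2 * vs[3], 1.0 * vs[1])
  cb <- function(k, i, side) {  # center bound for spot k, lateral axis i
    s <- seeds[[k]][i]
    (s + side * 2) * vs[4 - i]  # i=1 -> dx (vs[3]), i=2 -> dy (vs[2])
  }
  lower <- c(-Inf,
             1e-9, cb(1, 1, -1), cb(1, 2, -1), max(z0[1] - 2, 0) * vs[1],
             1e-9, cb(2, 1, -1), cb(2, 2, -1), max(z0[2] - 2, 0) * vs[1],
             0.2 * vs[3], 0.2 * vs[1])
  upper <- c(Inf,
             Inf, cb(1, 1, 1), cb(1, 2, 1), min(z0[1] + 2, nz - 1) * vs[1],
             Inf, cb(2, 1, 1), cb(2, 2, 1), min(z0[2] + 2, nz - 1) * vs[1],
             20 * vs[3], 10 * vs[1])
  res <- run_spot_fit(crop, 2L, p0, lower, upper)
  ctr <- function(k) spot_from_par(res$par, k, vs)$center
  sep_px <- sqrt(sum(((ctr(1) - ctr(2)) / vs[c(3, 2, 1)])^2))
  structure(list(
    spot_a = spot_from_par(res$par, 1L, vs),
    spot_b = spot_from_par(res$par, 2L, vs),
    background = res$par[1],
    residual_variance = res$residual_variance,
    converged = res$converged,
    degenerate = sep_px < 0.5,
    crop_origin = crop$origin,
    seeds = seedpair, channel = channel, voxel_size = vs,
    par = stats::setNames(res$par, spot_par_names(2L)),
    init = p0, lower = lower, upper = upper,
    nspots = 2L, crop = crop), class = "spa_dual_fit")
}

#' @export
print.spa_dual_fit <- function(x, ...) {
  cat("<spa_dual_fit>", if (x$converged) "converged" else "NOT converged",
      if (x$degenerate) "(degenerate)" else "", "\n")
  fmt <- function(s) sprintf("A=%.3g center=(%.1f, %.1f, %.1f) nm",
                             s$amplitude, s$center[1], s$center[2],
                             s$center[3])
  cat("  mother   :", fmt(x$spot_a), "\n")
  cat("  distal   :", fmt(x$spot_b), "\n")
  cat(sprintf("  sigma_xy = %.1f nm, sigma_z = %.1f nm, B = %.3g, s2 = %.3g\n",
              x$spot_a$sigma_lateral, x$spot_a$sigma_axial, x$background,
              x$residual_variance))
  invisible(x)
}

#' Monte Carlo parameter uncertainties for a spot fit
#'
#' Synthesizes `n` replicates of the fitted model plus i.i.d. Gaussian noise
#' with the variance indicated by the fit residuals, refits each from the
#' original initialization under the original constraints, and reports the
#' per-parameter standard deviation. Replicates that fail to converge are
#' excluded and counted; more than 10% failures flags the estimate
#' unreliable.
#'
#' @param fit a `spa_spot_fit` or `spa_dual_fit`.
#' @param n number of replicates (default 100).
#' @param rng_seed integer seed; identical inputs give identical output.
#' @return object of class `spa_mc_errors`: named `sd` vector, `n_replicates`,
#'   `n_failed`, `unreliable`, `rng_seed`.
#' @export
monte_carlo_errors <- function(fit, n = 100, rng_seed = 1L) {
  stopifnot(inherits(fit, c("spa_spot_fit", "spa_dual_fit")))
  if (!isTRUE(fit$converged)) stop("fit did not converge")
  nm <- spot_par_names(fit$nspots)
  s2 <- fit$residual_variance
  if (s2 <= 0) {
    return(structure(list(sd = stats::setNames(rep(0, length(nm)), nm),
                          n_replicates = n, n_failed = 0L,
                          unreliable = FALSE, rng_seed = rng_seed),
                     class = "spa_mc_errors"))
  }
  model <- model_spots(unname(fit$par), fit$crop$grid, fit$nspots)
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old))
  set.seed(as.integer(rng_seed))
  pars <- matrix(NA_real_, n, length(nm))
  ok <- logical(n)
  crop <- fit$crop
  for (i in seq_len(n)) {
    crop$data <- model + array(stats::rnorm(length(model), sd = sqrt(s2)),
                               dim = dim(model))
    r <- run_spot_fit(crop, fit$nspots, fit$init, fit$lower, fit$upper)
    ok[i] <- r$converged
    if (r$converged) pars[i, ] <- r$par
  }
  n_failed <- sum(!ok)
  sds <- apply(pars[ok, , drop = FALSE], 2, stats::sd)
  structure(list(sd = stats::setNames(sds, nm), n_replicates = n,
                 n_failed = n_failed, unreliable = n_failed > 0.1 * n,
                 rng_seed = rng_seed), class = "spa_mc_errors")
}

.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_set <- function(seed) {
  if (is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", seed, envir = globalenv())
}

#' Mother/distal integrated-intensity ratio
#'
#' With shared widths the amplitude ratio equals the integrated-intensity
#' ratio.
#'
#' @param fit a converged `spa_dual_fit`.
#' @return `A_mother / A_distal`.
#' @export
intensity_ratio <- function(fit) {
  stopifnot(inherits(fit, "spa_dual_fit"))
  if (!isTRUE(fit$converged) || isTRUE(fit$degenerate))
    stop("degenerate or non-converged fit: intensity ratio undefined")
  a <- fit$spot_a$amplitude; b <- fit$spot_b$amplitude
  if (b <= 1e-9 * a)
    stop("degenerate fit: distal amplitude is (near) zero")
  a / b
}
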