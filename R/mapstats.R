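# Quantification of probability maps: axis profiles, multi-Gaussian
# decomposition with Monte Carlo errors, width conversions, geometry and
# contour outlines.

#' Average intensity profile of a map along one axis
#'
#' @param map a `spa_map`.
#' @param channel 0-based channel index.
#' @param axis `"x"` (mother-satellite) or `"y"` (pole).
#' @param normalize `"none"`: plain mean over the perpendicular axis;
#'   `"coverage"`: mean over the samples that actually fell inside their
#'   source volumes (out-of-volume samples are zero-filled in the fixed-size
#'   grid and would otherwise imprint the coverage footprint on the
#'   profile). Positions with no coverage give `NA`.
#' @param window_nm optional half-width (nm): only perpendicular positions
#'   within `|perp| <= window_nm` enter the average. The fixed-size map
#'   extends far beyond any real distribution, and averaging metres of pure
#'   background into a profile only dilutes the signal.
#' @return data.frame with `position` (nm) and `value` (mean over the
#'   perpendicular axis).
#' @export
axis_profile <- function(map, channel, axis = c("x", "y"),
                         normalize = c("none", "coverage"),
                         window_nm = NULL) {
  axis <- match.arg(axis)
  normalize <- match.arg(normalize)
  stopifnot(inherits(map, "spa_map"))
  nc <- dim(map$grid)[1]
  if (channel < 0 || channel >= nc) stop("invalid channel")
  m <- map$grid[channel + 1L, , ]
  cov <- map$coverage
  if (!is.null(window_nm)) {
    perp <- map_axis_nm(map, if (axis == "x") "y" else "x")
    keep <- abs(perp) <= window_nm
    if (axis == "x") { m <- m[keep, , drop = FALSE]
                       cov <- cov[keep, , drop = FALSE] }
    else             { m <- m[, keep, drop = FALSE]
                       cov <- cov[, keep, drop = FALSE] }
  }
  if (normalize == "none") {
    val <- if (axis == "x") colMeans(m) else rowMeans(m)
  } else {
    num <- if (axis == "x") colSums(m) else rowSums(m)
    den <- if (axis == "x") colSums(cov) else rowSums(cov)
    val <- ifelse(den > 0, num / den * map$n_particles, NA_real_)
  }
  data.frame(position = map_axis_nm(map, axis), value = val)
}

profile_model <- function(p, x, n_components, broad_bg) {
  y <- rep(p[1], length(x))
  for (k in seq_len(n_components)) {
    o <- 1L + 3L * (k - 1L)
    y <- y + p[o + 1L] * exp(-(x - p[o + 2L])^2 / (2 * p[o + 3L]^2))
  }
  if (broad_bg) {
    o <- 1L + 3L * n_components
    sig_max <- max(p[1L + 3L * (seq_len(n_components) - 1L) + 3L])
    sb <- p[o + 2L] * sig_max   # broad sigma as multiple of widest peak
    y <- y + p[o + 1L] * exp(-x^2 / (2 * sb^2))
  }
  y
}

init_profile_components <- function(x, y, n_components) {
  off0 <- min(y)
  yc <- pmax(y - off0, 0)
  if (n_components == 1L) {
    c0 <- x[which.max(y)]
    s0 <- if (sum(yc) > 0)
      sqrt(sum(yc * (x - sum(yc * x) / sum(yc))^2) / sum(yc))
    else diff(range(x)) / 4
    return(list(offset = off0, amp = max(yc), center = c0,
                sigma = max(s0, diff(x)[1])))
  }
  # two components: peaks of the left and right halves about the centroid
  mid <- if (sum(yc) > 0) sum(yc * x) / sum(yc) else stats::median(x)
  left <- x <= mid
  c1 <- x[left][which.max(y[left])]
  c2 <- x[!left][which.max(y[!left])]
  s0 <- max(abs(c2 - c1) / 4, diff(x)[1])
  list(offset = off0, amp = c(max(yc[left]), max(yc[!left])),
       center = c(c1, c2), sigma = c(s0, s0))
}

#' Multi-Gaussian decomposition of an axis profile
#'
#' Least-squares fit of one or two Gaussian components plus a constant
#' offset, optionally with a third broad component fixed at the profile
#' center (x = 0) whose width is bounded below at 1.5x the widest peak --
#' the remedy for half-bridge-spanning background in pore-protein profiles.
#' For single-peak x profiles a fixed number of pixels is conventionally
#' trimmed from either end to avoid mis-fitting variable background
#' (`trim_px = 30` in the published protocol). Parameter uncertainties are
#' Monte Carlo SDs: refits of `mc_n` replicates of the fitted model plus
#' Gaussian noise matched to the residual variance.
#'
#' @param profile data.frame with `position` (nm) and `value`, as returned
#'   by [axis_profile()], or a bare numeric vector (positions default to
#'   0-based indices).
#' @param n_components 1 or 2 Gaussian peaks.
#' @param trim_px pixels removed from each end before fitting.
#' @param broad_bg add the broad centered component.
#' @param mc_n Monte Carlo replicates (0 skips error estimation).
#' @param mc_seed RNG seed for the Monte Carlo errors.
#' @return object of class `spa_profile_fit`: `components` data.frame
#'   (`center`, `sigma`, `fwhm`, `amplitude`, sorted by center), `offset`,
#'   `broad` (or NULL), `errors` (named SD vector), `converged`,
#'   `collapsed`, `residual_variance`, `trim_px`, `n_components`.
#' @export
fit_profile <- function(profile, n_components = 1L, trim_px = 0L,
                        broad_bg = FALSE, mc_n = 100L, mc_seed = 1L) {
  if (is.numeric(profile))
    profile <- data.frame(position = seq_along(profile) - 1,
                          value = profile)
  x <- profile$position; y <- profile$value
  ok <- is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (trim_px > 0) {
    keep <- seq(trim_px + 1L, length(x) - trim_px)
    x <- x[keep]; y <- y[keep]
  }
  n_par <- 1L + 3L * n_components + if (broad_bg) 2L else 0L
  if (length(x) < 5L * n_par)
    stop("profile too short after trimming for ", n_par, " parameters")
  ini <- init_profile_components(x, y, n_components)
  pitch <- diff(x)[1]
  p0 <- c(ini$offset, rbind(ini$amp, ini$center, ini$sigma))
  lo <- c(-Inf, rep(c(1e-12, min(x), pitch / 4), n_components))
  hi <- c(Inf, rep(c(Inf, max(x), diff(range(x))), n_components))
  if (broad_bg) {
    p0 <- c(p0, max(ini$amp) / 4, 3)
    lo <- c(lo, 0, 1.5)
    hi <- c(hi, Inf, 50)
  }
  obj <- function(p) sum((profile_model(p, x, n_components, broad_bg) - y)^2)
  fit <- nlminb_ls(p0, obj, lo, hi, iter_max = 500, rel_tol = 1e-12)
  build <- function(p, conv) {
    centers <- p[1L + 3L * (seq_len(n_components) - 1L) + 2L]
    ord <- order(centers)
    comp <- data.frame(
      center = p[1L + 3L * (ord - 1L) + 2L],
      sigma = p[1L + 3L * (ord - 1L) + 3L],
      amplitude = p[1L + 3L * (ord - 1L) + 1L])
    comp$fwhm <- fwhm_from_sigma(comp$sigma)
    broad <- NULL
    if (broad_bg) {
      o <- 1L + 3L * n_components
      sb <- p[o + 2L] * max(comp$sigma)
      broad <- list(center = 0, sigma = sb, fwhm = fwhm_from_sigma(sb),
                    amplitude = p[o + 1L])
    }
    resid <- y - profile_model(p, x, n_components, broad_bg)
    collapsed <- n_components == 2L &&
      abs(diff(comp$center)) < pitch
    list(comp = comp, broad = broad, offset = p[1],
         rss = sum(resid^2), residual_variance = mean(resid^2),
         collapsed = collapsed, conv = conv, par = p)
  }
  base <- build(fit$par, fit$converged)
  errors <- NULL
  if (mc_n > 0 && base$residual_variance > 0) {
    model0 <- profile_model(fit$par, x, n_components, broad_bg)
    old <- .Random.seed_get(); on.exit(.Random.seed_set(old))
    set.seed(as.integer(mc_seed))
    reps <- matrix(NA_real_, mc_n, length(fit$par))
    for (i in seq_len(mc_n)) {
      yi <- model0 + stats::rnorm(length(x),
                                  sd = sqrt(base$residual_variance))
      ri <- nlminb_ls(p0, function(p)
        sum((profile_model(p, x, n_components, broad_bg) - yi)^2),
        lo, hi, iter_max = 500, rel_tol = 1e-12)
      if (ri$converged) reps[i, ] <- ri$par
    }
    ok <- stats::complete.cases(reps)
    sds <- apply(reps[ok, , drop = FALSE], 2, stats::sd)
    nm <- c("offset",
            unlist(lapply(seq_len(n_components), function(k)
              paste0(c("amplitude", "center", "sigma"), "_", k))),
            if (broad_bg) c("broad_amplitude", "broad_sigma_mult"))
    errors <- stats::setNames(sds, nm)
  } else if (mc_n > 0) {
    errors <- stats::setNames(rep(0, length(fit$par)), NULL)
  }
  structure(list(components = base$comp, offset = base$offset,
                 broad = base$broad, errors = errors,
                 converged = base$conv, collapsed = base$collapsed,
                 rss = base$rss, residual_variance = base$residual_variance,
                 trim_px = as.integer(trim_px),
                 n_components = as.integer(n_components),
                 par = fit$par, positions = x, values = y,
                 broad_bg = broad_bg), class = "spa_profile_fit")
}

#' @export
print.spa_profile_fit <- function(x, ...) {
  cat("<spa_profile_fit>", x$n_components, "component(s)",
      if (!is.null(x$broad)) "+ broad background" else "", "\n")
  for (i in seq_len(nrow(x$components)))
    cat(sprintf("  peak %d: center %.1f nm, FWHM %.1f nm, amplitude %.3g\n",
                i, x$components$center[i], x$components$fwhm[i],
                x$components$amplitude[i]))
  invisible(x)
}

#' Width conversions for Gaussian components
#'
#' `fwhm_from_sigma()` returns `2 sqrt(2 ln 2) sigma` (~= 2.35 sigma);
#' `ci95_from_fwhm()` returns the width containing the central 95% of a
#' Gaussian's integral, `2 z_{0.975} / (2 sqrt(2 ln 2))` times the FWHM
#' (~= 1.7x).
#'
#' @param sigma Gaussian standard deviation (nm), > 0.
#' @return width in nm.
#' @export
fwhm_from_sigma <- function(sigma) {
  if (any(sigma <= 0)) stop("sigma must be positive")
  2 * sqrt(2 * log(2)) * sigma
}

#' @rdname fwhm_from_sigma
#' @param fwhm full width at half maximum (nm), > 0.
#' @export
ci95_from_fwhm <- function(fwhm) {
  if (any(fwhm <= 0)) stop("fwhm must be positive")
  (2 * stats::qnorm(0.975) / (2 * sqrt(2 * log(2)))) * fwhm
}

#' Euclidean distance between 3D positions (nm)
#'
#' @param p,q numeric positions of equal length in physical units.
#' @return distance in nm.
#' @export
distance_3d <- function(p, q) {
  stopifnot(length(p) == length(q))
  sqrt(sum((as.numeric(p) - as.numeric(q))^2))
}

#' Bend angle at the middle of three landmarks
#'
#' Deviation from collinearity at `middle`:
#' `180 - angle(mother - middle, distal - middle)` degrees, in [0, 180).
#' Invariant under rotation, translation and uniform scaling.
#'
#' @param mother,middle,distal 2D or 3D positions (nm).
#' @return bend angle in degrees.
#' @export
bend_angle <- function(mother, middle, distal) {
  pad <- function(p) { p <- as.numeric(p); c(p, rep(0, 3 - length(p))) }
  a <- pad(mother) - pad(middle); b <- pad(distal) - pad(middle)
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) stop("coincident landmark points")
  ang <- acos(pmin(pmax(sum(a * b) / (na * nb), -1), 1)) * 180 / pi
  180 - ang
}

#' Threshold contour outlines of map distributions
#'
#' Each channel is thresholded at `threshold_fraction` of its maximum and the
#' resulting level set outlined. Channels with two peaks (an interior
#' x-profile minimum between two fitted centers) are split at that minimum
#' and each side outlined against its own maximum, so the weaker
#' distribution is not swallowed by the brighter one.
#'
#' @param map a `spa_map` (register maps first when overlaying several).
#' @param channels 0-based channel indices (default: all).
#' @param threshold_fraction level as a fraction of the (per-distribution)
#'   maximum, in (0,1).
#' @return object of class `spa_contour_set`: per channel a list of
#'   outlines, each a data.frame of `x`, `y` map coordinates in nm, plus the
#'   peak position and threshold level used.
#' @export
contour_set <- function(map, channels = NULL, threshold_fraction = 0.75) {
  stopifnot(inherits(map, "spa_map"),
            threshold_fraction > 0, threshold_fraction < 1)
  nc <- dim(map$grid)[1]
  if (is.null(channels)) channels <- seq_len(nc) - 1L
  x_nm <- map_axis_nm(map, "x"); y_nm <- map_axis_nm(map, "y")
  out <- list()
  for (ch in channels) {
    m <- map$grid[ch + 1L, , ]
    if (diff(range(m)) == 0) stop("flat channel ", ch, ": no contour")
    regions <- list(seq_len(ncol(m)))
    # detect a two-peak structure on the x profile
    prof <- colMeans(m)
    pf <- tryCatch(fit_profile(data.frame(position = x_nm, value = prof),
                               n_components = 2L, mc_n = 0L),
                   error = function(e) NULL)
    if (!is.null(pf) && isTRUE(pf$converged) && !pf$collapsed) {
      c1 <- pf$components$center[1]; c2 <- pf$components$center[2]
      between <- which(x_nm > c1 & x_nm < c2)
      if (length(between) > 2) {
        split_at <- between[which.min(prof[between])]
        interior_min <- prof[split_at] < prof[between[1]] &&
          prof[split_at] < prof[between[length(between)]]
        if (interior_min)
          regions <- list(seq_len(split_at), seq(split_at, ncol(m)))
      }
    }
    outlines <- list()
    for (reg in regions) {
      sub <- m[, reg, drop = FALSE]
      level <- threshold_fraction * max(sub)
      peak <- which(sub == max(sub), arr.ind = TRUE)[1, ]
      cl <- grDevices::contourLines(x = x_nm[reg], y = y_nm,
                                    z = t(sub), levels = level)
      if (length(cl) == 0) next
      # keep outline(s) enclosing the region's peak pixel
      px <- x_nm[reg][peak[2]]; py <- y_nm[peak[1]]
      enclosing <- Filter(function(cc)
        point_in_polygon(px, py, cc$x, cc$y), cl)
      if (length(enclosing) == 0) enclosing <- cl[1]
      for (cc in enclosing)
        outlines[[length(outlines) + 1L]] <-
          list(outline = data.frame(x = cc$x, y = cc$y),
               peak = c(x = px, y = py), level = level)
    }
    out[[paste0("ch", ch)]] <- outlines
  }
  structure(list(channels = out, threshold_fraction = threshold_fraction),
            class = "spa_contour_set")
}

point_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  j <- n
  inside <- FALSE
  for (i in seq_len(n)) {
    if ((vy[i] > py) != (vy[j] > py) &&
        px < (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i])
      inside <- !inside
    j <- i
  }
  inside
}

#' Display rendering of a 2D image
#'
#' 2x bilinear upsampling followed by a Gaussian blur of sigma 0.8 output
#' pixels -- presentation only, never used upstream of quantitation.
#'
#' @param image numeric matrix.
#' @return matrix of twice the size in each dimension.
#' @export
render_display <- function(image) {
  stopifnot(is.matrix(image))
  up <- bilinear_upsample2x(image)
  gaussian_blur2d(up, 0.8)
}

bilinear_upsample2x <- function(m) {
  up1 <- function(mm) {
    n <- nrow(mm)
    src <- (seq_len(2L * n) - 0.5) / 2 - 0.5   # center-aligned mapping
    lo <- pmin(pmax(floor(src), 0), n - 1)
    hi <- pmin(lo + 1, n - 1)
    t <- src - lo
    t[src < 0] <- 0; t[src > n - 1] <- 0
    (1 - t) * mm[lo + 1, , drop = FALSE] + t * mm[hi + 1, , drop = FALSE]
  }
  t(up1(t(up1(m))))
}

#' Classify a crop as containing one or two foci
#'
#' Replaces visual 3D inspection: returns `"two"` iff the dual fit reduces
#' the residual sum of squares over the single fit by more than an F-ratio
#' criterion (4 extra parameters) and the fitted separation exceeds one
#' lateral pixel.
#'
#' @param fit_single a `spa_spot_fit` on the crop.
#' @param fit_dual a `spa_dual_fit` on the same crop.
#' @param alpha F-test significance threshold.
#' @return list with `call` (`"one"`/`"two"`), `p_value`, `f_stat`,
#'   `separation_px`, `reliable`.
#' @export
classify_foci <- function(fit_single, fit_dual, alpha = 0.01) {
  stopifnot(inherits(fit_single, "spa_spot_fit"),
            inherits(fit_dual, "spa_dual_fit"))
  if (!isTRUE(fit_single$converged) || !isTRUE(fit_dual$converged))
    return(list(call = "one", p_value = NA_real_, f_stat = NA_real_,
                separation_px = NA_real_, reliable = FALSE))
  n <- length(fit_dual$crop$data)
  rss1 <- fit_single$residual_variance * length(fit_single$crop$data)
  rss2 <- fit_dual$residual_variance * n
  df_extra <- 4
  p2 <- length(fit_dual$par)
  f_stat <- ((rss1 - rss2) / df_extra) / (rss2 / (n - p2))
  p_value <- if (f_stat > 0)
    stats::pf(f_stat, df_extra, n - p2, lower.tail = FALSE) else 1
  vs <- fit_dual$voxel_size
  sep_px <- sqrt(sum(((fit_dual$spot_a$center - fit_dual$spot_b$center) /
                      vs[c(3, 2, 1)])^2))
  call <- if (p_value < alpha && sep_px > 1) "two" else "one"
  list(call = call, p_value = p_value, f_stat = f_stat,
       separation_px = sep_px, reliable = TRUE)
}
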