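# Gaussian helpers shared by detection, fitting and map statistics.

#' Gaussian blur of a 2D image
#'
#' Separable Gaussian convolution with reflective boundary handling, the
#' standard pre-filter for maxima detection on sum projections.
#'
#' @param img numeric matrix (y, x).
#' @param sigma standard deviation in pixels; `0` returns `img` unchanged.
#' @return blurred matrix of the same shape.
#' @export
gaussian_blur2d <- function(img, sigma) {
  stopifnot(is.matrix(img), sigma >= 0)
  if (sigma == 0) return(img)
  r <- max(1L, ceiling(4 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k <- k / sum(k)
  img <- blur1d(img, k, r)          # along columns (y)
  t(blur1d(t(img), k, r))           # along rows (x)
}

blur1d <- function(m, k, r) {
  n <- nrow(m)
  idx <- seq_len(n)
  out <- matrix(0, n, ncol(m))
  for (j in seq_along(k)) {
    off <- j - r - 1L
    src <- idx + off
    # reflect indices at the borders (abc|cba style)
    src <- ifelse(src < 1L, 1L - (src - 1L) - 1L, src)
    src <- ifelse(src > n, n - (src - n) + 1L, src)
    src <- pmin(pmax(src, 1L), n)
    out <- out + k[j] * m[src, , drop = FALSE]
  }
  out
}

# Box-constrained least-squares driver. nlminb's convergence code 1 covers
# benign "evaluation limit" as well as genuine failures, so acceptance is
# decided from the diagnostic message.
nlminb_ls <- function(p0, obj, lower, upper, iter_max = 500,
                      rel_tol = 1e-10) {
  fit <- tryCatch(
    stats::nlminb(p0, obj, lower = lower, upper = upper,
                  control = list(iter.max = iter_max,
                                 eval.max = 10 * iter_max,
                                 rel.tol = rel_tol)),
    error = function(e) NULL)
  if (is.null(fit))
    return(list(par = p0, objective = NA_real_, converged = FALSE))
  ok <- fit$convergence == 0 ||
    grepl(paste0("relative convergence|X-convergence|singular convergence|",
                 "absolute function convergence"),
          fit$message %||% "")
  list(par = fit$par, objective = fit$objective, converged = ok)
}

gauss1d_model <- function(p, x) {
  # p = (offset, amp1, center1, sigma1, amp2, center2, sigma2, ...)
  y <- rep(p[1], length(x))
  ncomp <- (length(p) - 1L) %/% 3L
  for (k in seq_len(ncomp)) {
    a <- p[1 + 3 * (k - 1) + 1]; c0 <- p[1 + 3 * (k - 1) + 2]
    s <- p[1 + 3 * (k - 1) + 3]
    y <- y + a * exp(-(x - c0)^2 / (2 * s^2))
  }
  y
}

#' Fit a single 1D Gaussian with constant offset
#'
#' Least-squares fit of `offset + A exp(-(x - c)^2 / (2 s^2))` by
#' box-constrained quasi-Newton minimization. Used for z-profile edge
#' filtering and fiducial registration.
#'
#' @param y profile values.
#' @param x positions (default 0-based indices).
#' @param center_bounds optional `(lo, hi)` constraint on the center.
#' @return list with `amplitude`, `center`, `sigma`, `offset`, `converged`,
#'   `rss`, `residual_variance`.
#' @export
fit_gauss1d <- function(y, x = seq_along(y) - 1, center_bounds = NULL) {
  stopifnot(length(y) == length(x), length(y) >= 3)
  # normalize the intensity scale: large offsets (e.g. summed background of
  # a 30x30 window) otherwise stall the optimizer short of formal
  # convergence
  y_min <- min(y); y_scale <- diff(range(y))
  if (y_scale <= 0) y_scale <- max(abs(y_min), 1)
  y <- (y - y_min) / y_scale
  off0 <- min(y)
  amp0 <- max(y) - off0
  if (amp0 <= 0) amp0 <- max(abs(y), 1e-6)
  c0 <- x[which.max(y)]
  w <- pmax(y - off0, 0)
  s0 <- if (sum(w) > 0) sqrt(sum(w * (x - sum(w * x) / sum(w))^2) / sum(w))
        else diff(range(x)) / 4
  s0 <- max(s0, diff(range(x)) / length(x) / 2, 1e-3)
  p0 <- c(off0, amp0, c0, s0)
  lo <- c(-Inf, 1e-12, if (is.null(center_bounds)) min(x) else
          center_bounds[1], 1e-6)
  hi <- c(Inf, Inf, if (is.null(center_bounds)) max(x) else
          center_bounds[2], diff(range(x)) * 2 + 1)
  obj <- function(p) sum((gauss1d_model(p, x) - y)^2)
  fit <- nlminb_ls(p0, obj, lo, hi)
  if (!is.finite(fit$objective))
    return(list(amplitude = NA_real_, center = NA_real_, sigma = NA_real_,
                offset = NA_real_, converged = FALSE, rss = NA_real_,
                residual_variance = NA_real_))
  p <- fit$par
  list(amplitude = p[2] * y_scale, center = p[3], sigma = p[4],
       offset = p[1] * y_scale + y_min,
       converged = fit$converged || fit$objective < 1e-20,
       rss = fit$objective * y_scale^2,
       residual_variance = fit$objective * y_scale^2 / length(y))
}
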