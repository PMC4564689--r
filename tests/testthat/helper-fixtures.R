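# Shared fixtures and independent oracles. Everything here is built in code
# at test time; the rendering helpers below are deliberately written
# independently of the package's own generator so recovery tests close the
# loop against a second implementation.

# direct (loop-free but independent) render of point emitters into a
# (channel, z, y, x) array; spots: list(list(channel, pos_nm = c(x,y,z), A))
oracle_render <- function(shape, voxel_size, spots, background = 0,
                          sigma_xy = 50, sigma_z = 130) {
  nc <- shape[1]; nz <- shape[2]; ny <- shape[3]; nx <- shape[4]
  dz <- voxel_size[1]; dy <- voxel_size[2]; dx <- voxel_size[3]
  data <- array(background, dim = shape)
  for (s in spots) {
    ex <- exp(-((0:(nx - 1)) * dx - s$pos[1])^2 / (2 * sigma_xy^2))
    ey <- exp(-((0:(ny - 1)) * dy - s$pos[2])^2 / (2 * sigma_xy^2))
    ez <- exp(-((0:(nz - 1)) * dz - s$pos[3])^2 / (2 * sigma_z^2))
    contrib <- s$A * (ez %o% ey %o% ex)
    data[s$channel + 1, , , ] <- data[s$channel + 1, , , ] + contrib
  }
  data
}

oracle_volume <- function(shape, voxel_size, spots, background = 0,
                          sigma_xy = 50, sigma_z = 130, image_id = "fix") {
  spa_volume(oracle_render(shape, voxel_size, spots, background,
                           sigma_xy, sigma_z),
             voxel_size, image_id = image_id)
}

# render an isolated 2D Gaussian spot into a matrix (0-based px center)
oracle_spot_image <- function(ny, nx, cx, cy, peak, sigma = 2) {
  ex <- exp(-((0:(nx - 1)) - cx)^2 / (2 * sigma^2))
  ey <- exp(-((0:(ny - 1)) - cy)^2 / (2 * sigma^2))
  peak * (ey %o% ex)
}

# brute-force O(n^2) detection oracle: same rules, naive implementation
oracle_candidates <- function(projection, params) {
  b <- gaussian_blur2d(projection, params$blur_sigma)
  if (diff(range(projection)) == 0)
    return(data.frame(x = numeric(0), y = numeric(0),
                      peak_value = numeric(0)))
  thr <- params$threshold_fraction * max(b)
  ny <- nrow(b); nx <- ncol(b)
  xs <- c(); ys <- c(); vals <- c()
  for (y in seq_len(ny)) for (x in seq_len(nx)) {
    v <- b[y, x]
    if (v <= thr) next
    is_max <- TRUE
    for (dy in -1:1) for (dx in -1:1) {
      if (dy == 0 && dx == 0) next
      yy <- y + dy; xx <- x + dx
      if (yy >= 1 && yy <= ny && xx >= 1 && xx <= nx &&
          b[yy, xx] > v) is_max <- FALSE
    }
    if (is_max) { xs <- c(xs, x - 1); ys <- c(ys, y - 1); vals <- c(vals, v) }
  }
  if (length(vals) == 0)
    return(data.frame(x = numeric(0), y = numeric(0),
                      peak_value = numeric(0)))
  ord <- order(-vals, ys, xs)
  xs <- xs[ord]; ys <- ys[ord]; vals <- vals[ord]
  ax <- c(); ay <- c(); av <- c()
  for (i in seq_along(vals)) {
    if (length(ax) == 0 ||
        all(sqrt((ax - xs[i])^2 + (ay - ys[i])^2) >= params$min_distance)) {
      ax <- c(ax, xs[i]); ay <- c(ay, ys[i]); av <- c(av, vals[i])
    }
  }
  data.frame(x = ax, y = ay, peak_value = av)
}

# build a spa_map directly from a function z(x_nm, y_nm) per channel
oracle_map <- function(fun_list, half = 160, pixel_size = 10,
                       n_particles = 1) {
  n <- 2 * half + 1
  pos <- (seq_len(n) - 1 - half) * pixel_size
  grids <- lapply(fun_list, function(f) outer(pos, pos, function(y, x)
    rep_len(f(x, y), length(x))))
  grid <- array(0, dim = c(length(fun_list), n, n))
  for (i in seq_along(grids)) grid[i, , ] <- grids[[i]]
  structure(list(grid = grid, coverage = matrix(n_particles, n, n),
                 n_particles = n_particles, pixel_size = pixel_size,
                 origin = c(x = half, y = half),
                 particle_ids = "synthetic",
                 channel_labels = paste0("ch", seq_along(fun_list) - 1),
                 y_shift = 0), class = "spa_map")
}

# particle record without going through a fit (for pure-geometry tests)
oracle_particle <- function(mother, distal, image_id = "fix") {
  structure(list(image_id = image_id, mother_center = mother,
                 distal_center = distal, mother_amplitude = 2,
                 distal_amplitude = 1, mother_rule = "seed-order",
                 tie = FALSE, fit = NULL, reference_center = NULL),
            class = "spa_particle")
}
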