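test_that("axis profiles average the map along the perpendicular axis", {
  sep_fun <- function(x, y) 3 + 20 * exp(-x^2 / (2 * 90^2)) *
    exp(-y^2 / (2 * 50^2))
  m <- oracle_map(list(sep_fun))
  px <- axis_profile(m, 0, "x")
  # separable map: x profile proportional to the generating x Gaussian
  gx <- exp(-px$position^2 / (2 * 90^2))
  resid <- lm(px$value ~ gx)$residuals
  expect_lt(max(abs(resid)), 1e-6 * max(px$value))
  flat <- oracle_map(list(function(x, y) 7))
  expect_equal(unique(axis_profile(flat, 0, "y")$value), 7)
  # two-peak map: profile maxima at the planted centers
  two <- oracle_map(list(function(x, y)
    exp(-((x + 110)^2 + y^2) / (2 * 60^2)) +
      0.5 * exp(-((x - 110)^2 + y^2) / (2 * 60^2))))
  pr <- axis_profile(two, 0, "x")
  pk1 <- pr$position[which.max(pr$value)]
  expect_lte(abs(pk1 + 110), two$pixel_size)
  expect_error(axis_profile(two, 3, "x"), "invalid channel")
})

test_that("profile fits recover components, trimming and the broad term", {
  x <- seq(-1500, 1500, by = 10)
  # noiseless single Gaussian, sigma 40
  y1 <- 2 + 30 * exp(-(x - 25)^2 / (2 * 40^2))
  f1 <- fit_profile(data.frame(position = x, value = y1), 1, mc_n = 0)
  expect_equal(f1$components$center, 25, tolerance = 1e-3)
  expect_equal(f1$components$fwhm, 2 * sqrt(2 * log(2)) * 40,
               tolerance = 1e-3)
  # two peaks at +/-112.5 under 1% noise
  set.seed(5)
  y2 <- 40 * exp(-(x + 112.5)^2 / (2 * 60^2)) +
    21 * exp(-(x - 112.5)^2 / (2 * 60^2)) + rnorm(length(x), 0, 0.4)
  f2 <- fit_profile(data.frame(position = x, value = y2), 2, mc_n = 0)
  expect_equal(f2$components$center, c(-112.5, 112.5), tolerance = 2)
  # trimming drops the stated number of edge pixels
  f_trim <- fit_profile(data.frame(position = x, value = y1), 1,
                        trim_px = 30, mc_n = 0)
  expect_equal(length(f_trim$positions), length(x) - 60)
  # broad plateau: without the third component the fit is much worse
  y3 <- y2 - pmin(0, 0) + 12 * exp(-x^2 / (2 * 400^2))
  fb_off <- fit_profile(data.frame(position = x, value = y3), 2,
                        broad_bg = FALSE, mc_n = 0)
  fb_on <- fit_profile(data.frame(position = x, value = y3), 2,
                       broad_bg = TRUE, mc_n = 0)
  expect_gt(fb_off$rss, 5 * fb_on$rss)
  expect_gte(fb_on$broad$sigma, 1.5 * max(fb_on$components$sigma) - 1e-6)
  # Monte Carlo errors: deterministic, positive, sane scale
  fmc1 <- fit_profile(data.frame(position = x, value = y2), 2,
                      mc_n = 30, mc_seed = 11)
  fmc2 <- fit_profile(data.frame(position = x, value = y2), 2,
                      mc_n = 30, mc_seed = 11)
  expect_identical(fmc1$errors, fmc2$errors)
  expect_true(all(fmc1$errors >= 0))
  expect_lt(fmc1$errors[["center_1"]], 5)
  expect_error(fit_profile(data.frame(position = 1:10, value = 1:10), 2),
               "too short")
})

test_that("width conversions match the normal-distribution closed forms", {
  expect_equal(signif(fwhm_from_sigma(1), 3), 2.35)
  expect_equal(fwhm_from_sigma(40), 94.19, tolerance = 1e-3)
  expect_equal(fwhm_from_sigma(1), 2 * sqrt(2 * log(2)), tolerance = 1e-9)
  expect_equal(signif(ci95_from_fwhm(1), 2), 1.7)
  expect_equal(ci95_from_fwhm(100), 166.5, tolerance = 1e-3)
  # closed-form identity: ci95(fwhm(sigma)) is the central-95% width
  expect_equal(ci95_from_fwhm(fwhm_from_sigma(1)), 2 * qnorm(0.975),
               tolerance = 1e-9)
  expect_error(fwhm_from_sigma(0), "positive")
  expect_error(ci95_from_fwhm(-1), "positive")
})

test_that("distances and bend angles are exact and invariant", {
  expect_equal(distance_3d(c(0, 0, 0), c(3, 4, 0)), 5)
  expect_equal(distance_3d(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(distance_3d(c(10, 20, 30), c(-10, -20, -30)), 74.83,
               tolerance = 1e-3)
  expect_equal(bend_angle(c(0, 0), c(1, 0), c(2, 0)), 0)
  expect_equal(bend_angle(c(0, 0), c(1, 0), c(1, 1)), 90)
  expect_equal(bend_angle(c(-100, 0), c(0, 20), c(100, 0)), 22.62,
               tolerance = 1e-2)
  expect_error(bend_angle(c(0, 0), c(0, 0), c(1, 1)), "coincident")
  # invariance under rotation + translation + scaling
  set.seed(3)
  for (i in 1:10) {
    pts <- matrix(rnorm(9), 3)
    base <- bend_angle(pts[1, ], pts[2, ], pts[3, ])
    th <- runif(1, 0, 2 * pi)
    R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3)
    s <- runif(1, 0.1, 10); t <- rnorm(3)
    tr <- function(p) s * as.numeric(R %*% p) + t
    expect_equal(bend_angle(tr(pts[1, ]), tr(pts[2, ]), tr(pts[3, ])),
                 base, tolerance = 1e-8)
  }
})

test_that("75% contours outline each distribution independently", {
  sigma <- 80
  iso <- oracle_map(list(function(x, y)
    50 * exp(-(x^2 + y^2) / (2 * sigma^2))))
  cs <- contour_set(iso, threshold_fraction = 0.75)
  out <- cs$channels$ch0[[1]]$outline
  radii <- sqrt(out$x^2 + out$y^2)
  expect_equal(mean(radii), sigma * sqrt(-2 * log(0.75)),
               tolerance = iso$pixel_size / (sigma * sqrt(-2 * log(0.75))))
  expect_lt(max(radii) - min(radii), 2 * iso$pixel_size)
  # mirror-symmetric map gives a mirror-symmetric contour
  expect_lt(abs(mean(out$x)), iso$pixel_size)
  # two peaks with 2:1 amplitudes: both outlined at their own 75% level
  two <- oracle_map(list(function(x, y)
    60 * exp(-((x + 110)^2 + y^2) / (2 * 50^2)) +
      30 * exp(-((x - 110)^2 + y^2) / (2 * 50^2))))
  cs2 <- contour_set(two, threshold_fraction = 0.75)
  outs <- cs2$channels$ch0
  expect_gte(length(outs), 2)
  cx <- vapply(outs, function(o) mean(o$outline$x), numeric(1))
  expect_true(any(abs(cx + 110) < 20) && any(abs(cx - 110) < 20))
  # weak peak contour sits at 0.75 * 30, not 0.75 * 60
  weak <- outs[[which.min(abs(cx - 110))]]
  expect_equal(weak$level, 0.75 * 30, tolerance = 0.05 * 30)
  expect_error(contour_set(oracle_map(list(function(x, y) 1))), "flat")
})

test_that("display rendering doubles the grid and conserves mass", {
  img <- matrix(runif(30 * 20), 30, 20)
  out <- render_display(img)
  expect_equal(dim(out), c(60, 40))
  const <- render_display(matrix(4, 16, 16))
  expect_equal(unique(round(as.numeric(const), 9)), 4)
  # centred delta: integral (sum x pixel area 1/4) preserved
  delta <- matrix(0, 21, 21); delta[11, 11] <- 12
  expect_equal(sum(render_display(delta)) / 4, 12, tolerance = 1e-6)
})

test_that("the two-foci classifier separates one from two emitters", {
  vs <- c(125, 40, 40)
  one <- oracle_volume(c(1, 9, 40, 40), vs,
                       list(list(channel = 0,
                                 pos = c(20 * 40, 20 * 40, 4 * 125),
                                 A = 100)), background = 10)
  # add mild noise so the F statistic is finite
  set.seed(2)
  one$data <- one$data + array(rnorm(length(one$data), 0, 2),
                               dim = dim(one$data))
  fs <- fit_single_spot(one, 0, c(20, 20))
  fd <- fit_dual_spot(one, seed_pair("x", 0L, NULL, c(19, 20), c(21, 20)))
  expect_equal(classify_foci(fs, fd)$call, "one")
  # two emitters 225 nm apart at 2% noise
  rec <- generate_dataset("pair", 1, rng_seed = 6)[[1]]
  fs2 <- fit_single_spot(rec$volume, 0, rec$seed_pair$mother_seed)
  fd2 <- fit_dual_spot(rec$volume, rec$seed_pair)
  cls <- classify_foci(fs2, fd2)
  expect_equal(cls$call, "two")
  expect_lt(cls$p_value, 0.01)
  # sub-pixel separation is gated to "one"
  rec3 <- generate_dataset("pair", 1, rng_seed = 6,
                           params = list(separation = 20))[[1]]
  fs3 <- fit_single_spot(rec3$volume, 0, rec3$seed_pair$mother_seed)
  fd3 <- fit_dual_spot(rec3$volume, rec3$seed_pair)
  expect_equal(classify_foci(fs3, fd3)$call, "one")
})

test_that("a line source is broader along x than a point source", {
  ds_line <- generate_dataset("line_bridge", 4, rng_seed = 13)
  ds_pt <- generate_dataset("bent_triplet", 4, rng_seed = 13,
                            params = list(bend_deg = 0))
  width_of <- function(ds) {
    planes <- lapply(ds, function(rec) {
      f <- fit_dual_spot(rec$volume, rec$seed_pair)
      orient_plane(extract_aligned_plane(rec$volume, assign_mother(f)),
                   1, NULL)
    })
    m <- accumulate_map(planes)
    fit_profile(axis_profile(m, 1, "x", normalize = "coverage",
                             window_nm = 300), 1, mc_n = 0)$components$fwhm
  }
  expect_gt(width_of(ds_line), width_of(ds_pt))
})
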