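test_that("motion variance is recovered from Brownian tracks", {
  # quick recovery check (the full 50-replicate version runs with the
  # acceptance checks)
  est <- vapply(1:10, function(i) {
    estimate_motion_variance(mk_bm_track(500, 2000, 20, seed = i), 20)
  }, numeric(1))
  expect_lt(median(abs(est - 2000) / 2000), 0.15)
})

test_that("a perfectly linear constant-speed track has near-zero variance", {
  tr <- mk_track((0:99) * 100, (0:99) * 50)
  expect_lt(estimate_motion_variance(tr, 0.001), 0.1)
})

test_that("variance estimation is translation invariant", {
  tr <- mk_bm_track(200, 2000, 20, seed = 3)
  shifted <- tr
  shifted$x <- tr$x + 1e6
  shifted$y <- tr$y + 1e6
  expect_equal(estimate_motion_variance(tr, 20),
               estimate_motion_variance(shifted, 20), tolerance = 1e-6)
})

test_that("variance estimation rejects tracks with too few fixes", {
  expect_error(estimate_motion_variance(mk_track(c(0, 1), c(0, 1)), 20), ">= 3")
})

test_that("every occurrence raster carries unit mass", {
  for (seed in 1:3) {
    tr <- mk_bm_track(40, 2000, 20, seed = seed)
    r <- occurrence_distribution(tr, bbmm_params(motion_variance = 2000))
    expect_equal(sum(r$mass), 1, tolerance = 1e-6)
    expect_true(all(r$mass >= 0))
  }
})

test_that("pairs with lag above max_lag contribute no density", {
  # same track with and without a 12-h gap bridged: the gapped pair must be
  # skipped, so deleting it entirely changes nothing
  tt <- t0_utc + c(0, 4, 8, 20, 24, 28) * 3600
  x <- c(0, 300, 500, 5000, 5300, 5500)
  y <- c(0, 100, 250, 4000, 4100, 4300)
  tr <- track("a", tt, x, y)
  g <- bbmm_grid(-2000, -2000, 8000, 7000, 50)
  p <- bbmm_params(motion_variance = 2000, max_lag = 9)
  r_full <- occurrence_distribution(tr, p, g)
  # build the two halves separately and merge with duration weights
  r1 <- occurrence_distribution(track("a", tt[1:3], x[1:3], y[1:3]), p, g)
  r2 <- occurrence_distribution(track("a", tt[4:6], x[4:6], y[4:6]), p, g)
  merged <- prob_raster(g, r1$mass * 8 + r2$mass * 8)
  expect_equal(r_full$mass, merged$mass, tolerance = 1e-6)
})

test_that("a track with no pair within max lag is rejected", {
  tr <- track("a", t0_utc + c(0, 24, 48) * 3600, c(0, 100, 200), c(0, 0, 0))
  expect_error(occurrence_distribution(tr, bbmm_params(motion_variance = 100)),
               "max lag")
})

test_that("uniform-density contours keep the minimal prefix of tied cells", {
  r <- mk_raster(matrix(1, 10, 10))
  cr <- contour_region(r, 0.95)
  expect_equal(sum(cr$mask), 95)
  expect_equal(cr$area_km2, 0.2375)
  # the design alternative admits every tied cell
  cr_all <- contour_region(r, 0.95, ties = "all")
  expect_equal(sum(cr_all$mask), 100)
})

test_that("a single-cell raster contours to that cell", {
  w <- matrix(0, 5, 5); w[3, 3] <- 1
  cr <- contour_region(mk_raster(w), 0.95)
  expect_equal(sum(cr$mask), 1)
  expect_true(cr$mask[3, 3])
  expect_equal(cr$area_km2, 2500 / 1e6)
})

test_that("isotropic Gaussian contours match the analytic 95% disc", {
  g <- bbmm_grid(-3000, -3000, 3000, 3000, 50)
  xc <- seasonlap:::grid_xc(g); yc <- seasonlap:::grid_yc(g)
  sd <- 500
  w <- outer(dnorm(xc, 0, sd), dnorm(yc, 0, sd))
  r <- prob_raster(g, w)
  cr <- contour_region(r, 0.95)
  r95 <- sqrt(qchisq(0.95, 2)) * sd
  # boundary cells of the kept set lie within one cell of the analytic radius
  edge <- which(cr$mask, arr.ind = TRUE)
  dists <- sqrt(xc[edge[, 1]]^2 + yc[edge[, 2]]^2)
  expect_lt(max(dists), r95 + g$res)
  expect_equal(cr$area_km2, pi * r95^2 / 1e6, tolerance = 0.02)
})

test_that("contours are monotone in level", {
  tr <- mk_bm_track(30, 2000, 20, seed = 9)
  r <- occurrence_distribution(tr, bbmm_params(motion_variance = 2000))
  c50 <- contour_region(r, 0.5)
  c95 <- contour_region(r, 0.95)
  expect_true(all(c95$mask[c50$mask]))
  expect_gte(c50$mass, 0.5)
  expect_gte(c95$mass, 0.95)
})

test_that("halving the resolution changes smooth contour areas by under 2%", {
  tr <- mk_bm_track(60, 4000, 25, seed = 12, interval_h = 4)
  a <- vapply(c(50, 25), function(res) {
    r <- occurrence_distribution(tr, bbmm_params(motion_variance = 4000,
                                                 resolution = res))
    contour_region(r, 0.95)$area_km2
  }, numeric(1))
  expect_lt(abs(a[1] - a[2]) / a[2], 0.02)
})

test_that("region polygons close and enclose the mask area", {
  w <- matrix(0, 6, 6); w[2:4, 2:5] <- 1; w[3, 3] <- 0  # ring with a hole
  r <- mk_raster(w)
  cr <- contour_region(r, 0.9, ties = "all")
  polys <- region_polygons(cr)
  expect_gte(length(polys), 2)  # shell + hole
  for (p in polys) expect_equal(p[1, ], p[nrow(p), ])
  # shoelace: net signed area of all rings = cell count * cell area
  shoelace <- function(p) {
    n <- nrow(p) - 1
    sum(p[1:n, 1] * p[2:(n + 1), 2] - p[2:(n + 1), 1] * p[1:n, 2]) / 2
  }
  expect_equal(abs(sum(vapply(polys, shoelace, numeric(1)))),
               sum(cr$mask) * 50^2)
})

test_that("ascii-grid round trip preserves the raster", {
  tr <- mk_bm_track(20, 2000, 20, seed = 5)
  r <- occurrence_distribution(tr, bbmm_params(motion_variance = 2000))
  f <- tempfile(fileext = ".asc")
  write_ascii_grid(r, f)
  r2 <- read_ascii_grid(f)
  expect_equal(r2$mass, r$mass, tolerance = 1e-6)
  expect_equal(r2$grid$x0, r$grid$x0)
  unlink(f)
})
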