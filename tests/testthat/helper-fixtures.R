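# shared fixture builders (all data generated in code)

t0_utc <- as.POSIXct("2020-02-13", tz = "UTC")

# regular-interval track from coordinate vectors
mk_track <- function(x, y, interval_h = 4, start = t0_utc, id = "a",
                     species = "deer", sex = "F", pack = NA_character_) {
  track(id, start + (seq_along(x) - 1) * interval_h * 3600, x, y,
        species = species, sex = sex, pack = pack)
}

# pure Brownian-motion track observed with GPS error
mk_bm_track <- function(n, sigma2m, delta, interval_h = 4, seed = 1) {
  withr::with_seed(seed, {
    steps <- matrix(stats::rnorm(2 * (n - 1), 0, sqrt(sigma2m * interval_h)), ncol = 2)
    pos <- apply(rbind(c(0, 0), steps), 2, cumsum)
    obs <- pos + matrix(stats::rnorm(2 * n, 0, delta), ncol = 2)
    mk_track(obs[, 1], obs[, 2], interval_h)
  })
}

# stationary white-noise track, optionally with a linear-ramp mean shift
mk_wn_track <- function(n, sigma = 100, seed = 1, shift = 0,
                        t1_day = 120, dt_day = 10, interval_h = 4) {
  withr::with_seed(seed, {
    t <- t0_utc + (0:(n - 1)) * interval_h * 3600
    tn <- as.numeric(t)
    t1 <- as.numeric(t0_utc) + t1_day * 86400
    w <- pmin(1, pmax(0, (tn - t1) / (dt_day * 86400)))
    track("w", t, w * shift + stats::rnorm(n, 0, sigma),
          stats::rnorm(n, 0, sigma), species = "wolf", pack = "NE")
  })
}

# tiny raster on an explicit grid from a matrix of weights
mk_raster <- function(w, res = 50, x0 = 0, y0 = 0) {
  g <- bbmm_grid(x0, y0, x0 + nrow(w) * res, y0 + ncol(w) * res, res)
  prob_raster(g, w)
}

# rectangular contour region from cell index ranges on a grid
mk_region <- function(g, ix, iy, level = 0.95) {
  mask <- matrix(FALSE, g$nx, g$ny)
  mask[ix, iy] <- TRUE
  structure(list(grid = g, mask = mask, level = level, mass = level,
                 area_km2 = sum(mask) * g$res^2 / 1e6),
            class = "contour_region")
}

# reduced synthetic world used by end-to-end tests
mini_world_config <- function(wolf_fall_shift = 0, n_wolves = 8) {
  population_config(
    n_deer_migratory = 8, n_deer_resident = 4,
    n_moose_nomadic = 1, n_moose_migratory = 1, n_moose_resident = 1,
    n_wolves = n_wolves, years = 1, wolf_fall_shift = wolf_fall_shift)
}
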