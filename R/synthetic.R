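#' Specification of one simulated animal
#'
#' Describes the movement process of a single collared animal. Within-range
#' movement is a discrete Ornstein-Uhlenbeck (OU) process around the active
#' range center: the OU process is stationary (so it produces a bounded home
#' range) and has an analytic transition density, which makes the generator
#' testable against closed-form expectations. During range-to-range
#' transitions the center travels along `corridor_waypoints` at
#' `transit_speed` while the OU deviation keeps fluctuating around it.
#'
#' @param id animal id.
#' @param species `"deer"`, `"moose"` or `"wolf"`.
#' @param sex `"F"` or `"M"`.
#' @param pack wolf pack label (`"NE"`, `"NW"`, `"SW"`, `"FL"`) or `NA`.
#' @param strategy `"migratory"` (2-3 range centers), `"resident"` (exactly
#'   1) or `"nomadic"` (>= 4).
#' @param range_centers list of `c(x, y)` centers in meters.
#' @param range_sd stationary OU standard deviation per coordinate (m).
#' @param ou_timescale OU relaxation timescale (h).
#' @param depart_day_mean,depart_day_sd numeric vectors, one entry per
#'   center-to-center transition: mean and SD of the departure day
#'   (day-of-monitoring-year, origin 13 February).
#' @param transit_speed speed of the range center during transitions (m/h).
#' @param corridor_waypoints list of `c(x, y)` waypoints threaded between
#'   the first two centers during migration (reversed on return); empty for
#'   straight-line transits.
#' @param monitor_start,monitor_end `POSIXct` monitoring window (UTC).
#' @param fix_interval fix interval (h), > 0.
#' @param dropout_prob i.i.d. probability that a scheduled fix is missing.
#' @param mortality_time optional `POSIXct`; after it the animal is dead and
#'   the collar records stationary fixes (5 m GPS jitter) at the death site.
#' @param season_offsets optional named list mapping season name to a
#'   `c(dx, dy)` activity-center offset (m), applied within the (single)
#'   range of a resident animal; used to emulate territorial predators that
#'   redistribute inside their territory seasonally.
#' @param season_windows [season_windows()] used to resolve `season_offsets`
#'   (defaults to [default_season_windows()]).
#'
#' @return an object of class `"agent_spec"`.
#' @export
agent_spec <- function(id, species, strategy, range_centers,
                       sex = "F", pack = NA_character_,
                       range_sd = 600, ou_timescale = 12,
                       depart_day_mean = numeric(0), depart_day_sd = numeric(0),
                       transit_speed = 100, corridor_waypoints = list(),
                       monitor_start = as.POSIXct("2020-02-13", tz = "UTC"),
                       monitor_end = as.POSIXct("2021-02-12", tz = "UTC"),
                       fix_interval = 4, dropout_prob = 0.05,
                       mortality_time = NULL, season_offsets = NULL,
                       season_windows = NULL) {
  species <- match.arg(species, c("deer", "moose", "wolf"))
  strategy <- match.arg(strategy, c("migratory", "resident", "nomadic"))
  n_centers <- length(range_centers)
  ok <- switch(strategy,
               migratory = n_centers >= 2 && n_centers <= 3,
               resident  = n_centers == 1,
               nomadic   = n_centers >= 4)
  if (!ok) stop(sprintf("strategy '%s' incompatible with %d range centers", strategy, n_centers))
  stopifnot(fix_interval > 0, dropout_prob >= 0, dropout_prob < 1,
            range_sd > 0, ou_timescale > 0,
            length(depart_day_mean) == length(depart_day_sd))
  structure(list(
    id = as.character(id), species = species, sex = sex, pack = pack,
    strategy = strategy, range_centers = range_centers, range_sd = range_sd,
    ou_timescale = ou_timescale, depart_day_mean = depart_day_mean,
    depart_day_sd = depart_day_sd, transit_speed = transit_speed,
    corridor_waypoints = corridor_waypoints,
    monitor_start = monitor_start, monitor_end = monitor_end,
    fix_interval = fix_interval, dropout_prob = dropout_prob,
    mortality_time = mortality_time, season_offsets = season_offsets,
    season_windows = season_windows
  ), class = "agent_spec")
}

# piecewise-linear center path: data.frame(t_start, t_end, x0, y0, x1, y1)
# plus the migration-event truth table
build_center_path <- function(spec, depart_times) {
  centers <- spec$range_centers
  segs <- list()
  events <- list()
  t_cur <- spec$monitor_start
  c_idx <- 1L
  if (nrow(depart_times) > 0) {
    for (k in seq_len(nrow(depart_times))) {
      dep <- depart_times$depart[k]
      to <- depart_times$to_center[k]
      if (dep <= t_cur) next
      # dwell at current center
      segs[[length(segs) + 1L]] <- data.frame(
        t0 = t_cur, t1 = dep,
        x0 = centers[[c_idx]][1], y0 = centers[[c_idx]][2],
        x1 = centers[[c_idx]][1], y1 = centers[[c_idx]][2])
      # transit path through waypoints (only between centers 1 and 2)
      pts <- list(centers[[c_idx]])
      use_corridor <- length(spec$corridor_waypoints) > 0 &&
        ((c_idx == 1L && to == 2L) || (c_idx == 2L && to == 1L))
      if (use_corridor) {
        wps <- spec$corridor_waypoints
        if (c_idx == 2L) wps <- rev(wps)
        pts <- c(pts, wps)
      }
      pts <- c(pts, list(centers[[to]]))
      tt <- dep
      for (j in seq_len(length(pts) - 1L)) {
        d <- sqrt(sum((pts[[j + 1L]] - pts[[j]])^2))
        dt_h <- d / spec$transit_speed
        segs[[length(segs) + 1L]] <- data.frame(
          t0 = tt, t1 = tt + dt_h * 3600,
          x0 = pts[[j]][1], y0 = pts[[j]][2],
          x1 = pts[[j + 1L]][1], y1 = pts[[j + 1L]][2])
        tt <- tt + dt_h * 3600
      }
      events[[length(events) + 1L]] <- data.frame(
        id = spec$id, event = k, season = depart_times$season[k],
        depart = dep, arrive = tt,
        from_center = c_idx, to_center = to)
      c_idx <- to
      t_cur <- tt
    }
  }
  segs[[length(segs) + 1L]] <- data.frame(
    t0 = t_cur, t1 = spec$monitor_end + 1,
    x0 = centers[[c_idx]][1], y0 = centers[[c_idx]][2],
    x1 = centers[[c_idx]][1], y1 = centers[[c_idx]][2])
  list(path = do.call(rbind, segs),
       events = if (length(events)) do.call(rbind, events) else NULL)
}

# evaluate the center path at POSIXct times
center_at <- function(path, times) {
  tn <- as.numeric(times)
  i <- findInterval(tn, as.numeric(path$t0))
  i[i < 1L] <- 1L
  span <- as.numeric(path$t1)[i] - as.numeric(path$t0)[i]
  a <- ifelse(span > 0, pmin(1, pmax(0, (tn - as.numeric(path$t0)[i]) / span)), 0)
  cbind(x = path$x0[i] + a * (path$x1[i] - path$x0[i]),
        y = path$y0[i] + a * (path$y1[i] - path$y0[i]))
}

# draw departure schedule for a spec: one row per transition, repeated yearly
draw_departures <- function(spec) {
  n_trans <- length(spec$depart_day_mean)
  if (n_trans == 0L) return(data.frame())
  yrs <- unique(study_year(seq(spec$monitor_start, spec$monitor_end, by = "1 day")))
  rows <- list()
  for (yr in yrs) {
    origin <- as.POSIXct(sprintf("%d-02-13", yr), tz = "UTC")
    for (k in seq_len(n_trans)) {
      day <- stats::rnorm(1, spec$depart_day_mean[k], spec$depart_day_sd[k])
      dep <- origin + day * 86400
      if (dep < spec$monitor_start || dep > spec$monitor_end) next
      if (spec$strategy == "migratory") {
        n_c <- length(spec$range_centers)
        # odd transitions go out (1 -> 2); even return (2 -> 1), or to the
        # alternate third center in the final year when range fidelity is low
        to <- if (k %% 2L == 1L) 2L else if (n_c == 3L && yr == max(yrs)) 3L else 1L
        season <- if (k %% 2L == 1L) "spring" else "fall"
      } else { # nomadic: walk through the centers in order, cycling
        to <- (k %% length(spec$range_centers)) + 1L
        season <- NA_character_
      }
      rows[[length(rows) + 1L]] <- data.frame(depart = dep, to_center = to, season = season)
    }
  }
  if (!length(rows)) return(data.frame())
  out <- do.call(rbind, rows)
  out <- out[order(out$depart), , drop = FALSE]
  # keep transitions consistent: drop consecutive moves to the same center
  keep <- c(TRUE, diff(out$to_center) != 0)
  out[keep, , drop = FALSE]
}

#' Simulate one GPS track
#'
#' Simulates the collar record of a single animal from its [agent_spec()]:
#' an OU deviation process superimposed on a piecewise-linear range-center
#' path, sampled on the fix grid, thinned by i.i.d. dropouts, and (if the
#' spec has a `mortality_time`) followed by stationary post-mortality fixes
#' at the death site. Identical seeds give identical tracks.
#'
#' @param spec an [agent_spec()].
#' @param seed integer seed.
#' @return a [track()] with attribute `"truth"`: a list with the realized
#'   migration `events` table (depart/arrive times) and `centers`.
#' @export
simulate_track <- function(spec, seed) {
  stopifnot(inherits(spec, "agent_spec"))
  if (as.numeric(spec$monitor_end - spec$monitor_start, units = "hours") < spec$fix_interval) {
    stop("monitoring window shorter than one fix interval")
  }
  withr::with_seed(seed, {
    times <- seq(spec$monitor_start, spec$monitor_end, by = spec$fix_interval * 3600)
    deps <- draw_departures(spec)
    cp <- build_center_path(spec, deps)
    ctr <- center_at(cp$path, times)
    # seasonal within-territory redistribution for territorial residents
    if (!is.null(spec$season_offsets)) {
      sw <- spec$season_windows
      if (is.null(sw)) sw <- default_season_windows()
      seas <- season_of(times, sw)
      for (s in names(spec$season_offsets)) {
        idx <- seas == s
        ctr[idx, 1] <- ctr[idx, 1] + spec$season_offsets[[s]][1]
        ctr[idx, 2] <- ctr[idx, 2] + spec$season_offsets[[s]][2]
      }
    }
    n <- length(times)
    dt <- spec$fix_interval
    a <- exp(-dt / spec$ou_timescale)
    innov_sd <- spec$range_sd * sqrt(1 - a^2)
    dev <- matrix(0, n, 2)
    dev[1, ] <- stats::rnorm(2, 0, spec$range_sd)
    ex <- stats::rnorm(n - 1, 0, innov_sd)
    ey <- stats::rnorm(n - 1, 0, innov_sd)
    for (i in seq_len(n - 1L)) {
      dev[i + 1L, 1] <- dev[i, 1] * a + ex[i]
      dev[i + 1L, 2] <- dev[i, 2] * a + ey[i]
    }
    x <- ctr[, 1] + dev[, 1]
    y <- ctr[, 2] + dev[, 2]
    # mortality: collar keeps transmitting from the death site
    mort <- spec$mortality_time
    if (!is.null(mort) && mort < spec$monitor_end) {
      dead <- times >= mort
      i0 <- which(dead)[1]
      x[dead] <- x[i0] + stats::rnorm(sum(dead), 0, 5)
      y[dead] <- y[i0] + stats::rnorm(sum(dead), 0, 5)
    }
    keep <- stats::runif(n) >= spec$dropout_prob
    keep[1] <- TRUE
    tr <- track(spec$id, times[keep], x[keep], y[keep],
                species = spec$species, sex = spec$sex, pack = spec$pack)
    attr(tr, "truth") <- list(events = cp$events, centers = spec$range_centers,
                              strategy = spec$strategy, mortality = mort)
    tr
  })
}

#' Population configuration for the synthetic study system
#'
#' Defaults emulate the study system the analysis is designed for: a
#' corridor-sharing, partially migratory deer population (two thirds
#' migratory), a mostly nomadic/resident moose population, and a small set
#' of territorial wolf packs arranged around the deer corridor. Deer spring
#' departures are synchronous (small SD, mid April); fall departures are
#' asynchronous (large SD, late October). Median migratory deer displacement
#' is ~17 km and migratory moose ~5 km along straight-line transits.
#'
#' @param n_deer_migratory,n_deer_resident,n_moose_nomadic,n_moose_migratory,
#'   n_moose_resident,n_wolves population counts.
#' @param years monitoring duration in whole monitoring years (13 Feb start).
#' @param start first day of monitoring (`POSIXct`).
#' @param spring_mean,spring_sd,fall_mean,fall_sd deer departure-day
#'   distributions (day-of-monitoring-year).
#' @param deer_range_sd,moose_range_sd,wolf_range_sd OU stationary SDs (m).
#' @param wolf_floater_sd OU SD of the floating (non-pack) wolf (m).
#' @param wolf_fall_shift meters by which wolf activity centers move toward
#'   the deer winter range during fall migration (0 = strictly stationary
#'   territories, the null regime).
#' @param dropout_prob per-fix dropout probability.
#' @param fix_interval fix interval (h).
#' @return a list of class `"population_config"`.
#' @export
population_config <- function(n_deer_migratory = 20, n_deer_resident = 10,
                              n_moose_nomadic = 5, n_moose_migratory = 1,
                              n_moose_resident = 4, n_wolves = 6,
                              years = 2,
                              start = as.POSIXct("2020-02-13", tz = "UTC"),
                              spring_mean = 60, spring_sd = 3,
                              fall_mean = 257, fall_sd = 12,
                              deer_range_sd = 600, moose_range_sd = 800,
                              wolf_range_sd = 2500, wolf_floater_sd = 6500,
                              wolf_fall_shift = 0,
                              dropout_prob = 0.05, fix_interval = 4) {
  cfg <- as.list(environment())
  cfg$end <- start + years * 365 * 86400 - 86400
  # shared geometry (m): winter hub SW, summer hub NE, dog-leg corridor
  cfg$deer_winter_hub <- c(6000, 4000)
  cfg$deer_summer_hub <- c(16000, 17500)
  cfg$corridor_waypoints <- list(c(9500, 8000), c(12000, 12500))
  # pack territories sit along successive portions of the deer corridor
  cfg$wolf_pack_centers <- list(NE = c(15000, 16500), NW = c(10500, 10500),
                                SW = c(7000, 5500), FL = c(11000, 11000))
  class(cfg) <- "population_config"
  cfg
}

#' Simulate a full study population
#'
#' Builds [agent_spec()]s from a [population_config()], simulates every
#' track, and returns the tracks together with a ground-truth ledger used by
#' parameter-recovery tests. The fraction of migratory deer in the ledger
#' equals the configured fraction exactly (counts are deterministic; only
#' within-strategy realizations are random).
#'
#' @param config a [population_config()].
#' @param seed integer seed; every agent gets a derived sub-seed.
#' @return list with `tracks` (named list of tracks) and `ledger` (list with
#'   `agents` data.frame and `events` data.frame of true migration timings).
#' @export
simulate_population <- function(config, seed) {
  stopifnot(inherits(config, "population_config"))
  n_total <- config$n_deer_migratory + config$n_deer_resident +
    config$n_moose_nomadic + config$n_moose_migratory + config$n_moose_resident +
    config$n_wolves
  if (n_total == 0) stop("population config requests zero agents")
  specs <- list()
  withr::with_seed(seed, {
    jitter2 <- function(sd) stats::rnorm(2, 0, sd)
    # --- deer ---
    for (i in seq_len(config$n_deer_migratory)) {
      w <- config$deer_winter_hub + jitter2(1200)
      s <- config$deer_summer_hub + jitter2(1200)
      specs[[length(specs) + 1L]] <- agent_spec(
        id = sprintf("deer_m%02d", i), species = "deer", strategy = "migratory",
        sex = sample(c("F", "M"), 1), range_centers = list(w, s),
        range_sd = config$deer_range_sd, ou_timescale = 12,
        depart_day_mean = c(config$spring_mean, config$fall_mean),
        depart_day_sd = c(config$spring_sd, config$fall_sd),
        transit_speed = 100, corridor_waypoints = config$corridor_waypoints,
        monitor_start = config$start, monitor_end = config$end,
        fix_interval = config$fix_interval, dropout_prob = config$dropout_prob)
    }
    for (i in seq_len(config$n_deer_resident)) {
      hub <- if (i %% 2L == 0L) config$deer_winter_hub else config$deer_summer_hub
      specs[[length(specs) + 1L]] <- agent_spec(
        id = sprintf("deer_r%02d", i), species = "deer", strategy = "resident",
        sex = sample(c("F", "M"), 1), range_centers = list(hub + jitter2(2000)),
        range_sd = config$deer_range_sd, ou_timescale = 12,
        monitor_start = config$start, monitor_end = config$end,
        fix_interval = config$fix_interval, dropout_prob = config$dropout_prob)
    }
    # --- moose ---
    for (i in seq_len(config$n_moose_nomadic)) {
      base <- c(stats::runif(1, 4000, 18000), stats::runif(1, 4000, 18000))
      n_c <- sample(4:5, 1)
      # distinct home ranges: rejection-sample centers >= 6 km apart
      centers <- list(base + jitter2(3500))
      while (length(centers) < n_c) {
        cand <- base + jitter2(5000)
        dmin <- min(vapply(centers, function(c0) sqrt(sum((c0 - cand)^2)), numeric(1)))
        if (dmin >= 6000) centers[[length(centers) + 1L]] <- cand
      }
      span_d <- as.numeric(config$end - config$start, units = "days")
      # irregular switch days, but every dwell long enough (>= 40 d) to
      # register as a distinct home range rather than a stopover
      repeat {
        gaps <- sort(stats::runif(n_c - 1L, 40, span_d - 40))
        if (n_c == 2L || min(diff(gaps)) >= 40) break
      }
      specs[[length(specs) + 1L]] <- agent_spec(
        id = sprintf("moose_n%02d", i), species = "moose", strategy = "nomadic",
        sex = sample(c("F", "M"), 1), range_centers = centers,
        range_sd = config$moose_range_sd, ou_timescale = 18,
        depart_day_mean = gaps %% 365, depart_day_sd = rep(2, n_c - 1L),
        transit_speed = 200,
        monitor_start = config$start, monitor_end = config$end,
        fix_interval = config$fix_interval, dropout_prob = config$dropout_prob)
    }
    for (i in seq_len(config$n_moose_migratory)) {
      w <- c(7000, 9000) + jitter2(1500)
      s <- w + c(3000, 4000)  # ~5 km displacement, no shared corridor
      specs[[length(specs) + 1L]] <- agent_spec(
        id = sprintf("moose_m%02d", i), species = "moose", strategy = "migratory",
        sex = sample(c("F", "M"), 1), range_centers = list(w, s),
        range_sd = config$moose_range_sd, ou_timescale = 18,
        depart_day_mean = c(config$spring_mean + 10, config$fall_mean),
        depart_day_sd = c(6, 10), transit_speed = 150,
        monitor_start = config$start, monitor_end = config$end,
        fix_interval = config$fix_interval, dropout_prob = config$dropout_prob)
    }
    for (i in seq_len(config$n_moose_resident)) {
      base <- c(stats::runif(1, 5000, 17000), stats::runif(1, 5000, 17000))
      specs[[length(specs) + 1L]] <- agent_spec(
        id = sprintf("moose_r%02d", i), species = "moose", strategy = "resident",
        sex = sample(c("F", "M"), 1), range_centers = list(base),
        range_sd = config$moose_range_sd, ou_timescale = 18,
        monitor_start = config$start, monitor_end = config$end,
        fix_interval = config$fix_interval, dropout_prob = config$dropout_prob)
    }
    # --- wolves: territorial residents around the corridor ---
    pack_seq <- rep(c("NE", "NW", "SW", "FL"), length.out = config$n_wolves)
    for (i in seq_len(config$n_wolves)) {
      pk <- pack_seq[i]
      ctr <- config$wolf_pack_centers[[pk]] + jitter2(800)
      sdv <- if (pk == "FL") config$wolf_floater_sd else config$wolf_range_sd
      offs <- NULL
      if (config$wolf_fall_shift > 0 && pk != "FL") {
        # shift activity toward the deer winter hub during fall migration
        dir <- config$deer_winter_hub - ctr
        dir <- dir / sqrt(sum(dir^2))
        offs <- list(fall = dir * config$wolf_fall_shift)
      }
      specs[[length(specs) + 1L]] <- agent_spec(
        id = sprintf("wolf_%02d", i), species = "wolf", strategy = "resident",
        sex = sample(c("F", "M"), 1), pack = pk, range_centers = list(ctr),
        range_sd = sdv, ou_timescale = 8,
        monitor_start = config$start, monitor_end = config$end,
        fix_interval = config$fix_interval, dropout_prob = config$dropout_prob,
        season_offsets = offs)
    }
  })
  sub_seeds <- (seed + 1000L * seq_along(specs)) %% .Machine$integer.max
  tracks <- list()
  agents <- list()
  events <- list()
  for (i in seq_along(specs)) {
    sp <- specs[[i]]
    tr <- simulate_track(sp, sub_seeds[i])
    tracks[[sp$id]] <- tr
    truth <- attr(tr, "truth")
    agents[[i]] <- data.frame(
      id = sp$id, species = sp$species, sex = sp$sex, pack = sp$pack,
      strategy = sp$strategy, n_centers = length(sp$range_centers),
      center_x = sp$range_centers[[1]][1], center_y = sp$range_centers[[1]][2],
      stringsAsFactors = FALSE)
    if (!is.null(truth$events)) events[[length(events) + 1L]] <- truth$events
  }
  ledger <- list(
    agents = do.call(rbind, agents),
    events = if (length(events)) do.call(rbind, events) else NULL,
    centers = lapply(specs, function(s) s$range_centers),
    specs = specs
  )
  names(ledger$centers) <- vapply(specs, `[[`, "", "id")
  list(tracks = tracks, ledger = ledger)
}
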