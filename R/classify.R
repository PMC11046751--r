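#' Net squared displacement
#'
#' Squared Euclidean distance of every fix from the first fix, in km^2.
#' NSD plateaus identify residency; a double plateau identifies migration.
#'
#' @param tr a [track()].
#' @export
nsd <- function(tr) {
  if (nrow(tr) == 0L) stop("empty track")
  ((tr$x - tr$x[1])^2 + (tr$y - tr$y[1])^2) / 1e6
}

#' Segment-detection settings
#'
#' @param min_separation minimum distance between distinct range centers (m).
#' @param min_dwell minimum dwell for a home-range segment (days); shorter
#'   occupied runs flanked by travel are stopovers.
#' @param min_stop minimum dwell for a stopover (days).
#' @param settle_window window for the settledness statistic (h).
#' @param max_cluster_fixes subsample cap for center discovery.
#' @export
segment_params <- function(min_separation = 2500, min_dwell = 30,
                           min_stop = 1, settle_window = 48,
                           max_cluster_fixes = 1200) {
  structure(as.list(environment()), class = "segment_params")
}

#' Detect home-range occupancy segments and stopovers
#'
#' Automates the visual identification of home ranges from location maps and
#' NSD graphs: range centers are discovered by average-linkage clustering of
#' "settled" fixes (fixes whose surrounding `settle_window` of positions
#' stays within half the separation scale), every fix is assigned to its
#' nearest center (or to transit), and maximal temporal runs within one
#' center become segments. Runs of at least `min_dwell` days are home-range
#' segments; shorter occupied runs are stopovers.
#'
#' @param tr a censored, regularized [track()].
#' @param params a [segment_params()].
#' @return data.frame with one row per segment: `cluster, start, end,
#'   duration_days, cx, cy, n_fixes, kind` (`"range"` or `"stopover"`).
#' @export
detect_segments <- function(tr, params = segment_params()) {
  n <- nrow(tr)
  if (n < 3L) return(data.frame())
  tn <- as.numeric(tr$timestamp)
  half_sep <- params$min_separation / 2
  # settledness: max distance to the local window mean
  win <- params$settle_window * 3600
  settled <- logical(n)
  j0 <- 1L; j1 <- 1L
  for (i in seq_len(n)) {
    while (tn[j0] < tn[i] - win / 2) j0 <- j0 + 1L
    while (j1 < n && tn[j1 + 1L] <= tn[i] + win / 2) j1 <- j1 + 1L
    xs <- tr$x[j0:j1]; ys <- tr$y[j0:j1]
    settled[i] <- max(sqrt((xs - mean(xs))^2 + (ys - mean(ys))^2)) < half_sep
  }
  if (!any(settled)) return(data.frame())
  idx <- which(settled)
  if (length(idx) > params$max_cluster_fixes) {
    idx <- idx[round(seq(1, length(idx), length.out = params$max_cluster_fixes))]
  }
  pts <- cbind(tr$x[idx], tr$y[idx])
  if (length(idx) > 1L) {
    hc <- stats::hclust(stats::dist(pts), method = "average")
    cl <- stats::cutree(hc, h = params$min_separation)
  } else cl <- 1L
  centers <- do.call(rbind, lapply(split(seq_along(cl), cl), function(ii) {
    colMeans(pts[ii, , drop = FALSE])
  }))
  # assign every fix to the nearest center within min_separation, else transit
  d2 <- outer(tr$x, centers[, 1], "-")^2 + outer(tr$y, centers[, 2], "-")^2
  nearest <- max.col(-d2)
  assign <- ifelse(sqrt(d2[cbind(seq_len(n), nearest)]) <= params$min_separation,
                   nearest, NA_integer_)
  # smooth: flip runs < 24 h that are sandwiched between one same assignment
  r <- rle(assign)
  if (length(r$lengths) > 2L) {
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in 2:(length(r$lengths) - 1L)) {
      dur_h <- (tn[ends[k]] - tn[starts[k]]) / 3600
      same <- identical(r$values[k - 1L], r$values[k + 1L])
      if (dur_h < 24 && same && !identical(r$values[k], r$values[k - 1L])) {
        assign[starts[k]:ends[k]] <- r$values[k - 1L]
      }
    }
  }
  r <- rle(assign)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  segs <- list()
  for (k in seq_along(r$lengths)) {
    if (is.na(r$values[k])) next
    dur_d <- (tn[ends[k]] - tn[starts[k]]) / 86400
    if (dur_d < params$min_stop) next
    ii <- starts[k]:ends[k]
    segs[[length(segs) + 1L]] <- data.frame(
      cluster = r$values[k],
      start = tr$timestamp[starts[k]], end = tr$timestamp[ends[k]],
      duration_days = dur_d,
      cx = mean(tr$x[ii]), cy = mean(tr$y[ii]),
      n_fixes = length(ii),
      kind = if (dur_d >= params$min_dwell) "range" else "stopover",
      stringsAsFactors = FALSE)
  }
  if (!length(segs)) return(data.frame())
  out <- do.call(rbind, segs)
  # merge consecutive range segments in the same cluster separated only by
  # stopover-length noise in the same cluster
  rownames(out) <- NULL
  out
}

# first sustained upward crossing of `thresh` by the series r(tn),
# linearly interpolated between the bracketing fixes; NA if none
first_crossing <- function(tn, r, thresh) {
  n <- length(r)
  above <- r > thresh
  for (i in seq_len(n - 1L)) {
    nxt <- above[i + 1L] && (i + 2L > n || above[i + 2L])
    if (!above[i] && nxt) {
      return(tn[i] + (thresh - r[i]) / (r[i + 1L] - r[i]) * (tn[i + 1L] - tn[i]))
    }
  }
  NA_real_
}

# estimate the true start and end of one range transition. Radial distance
# from the source (target) centroid grows (shrinks) at the travel speed on
# the first (last) leg of the travel path whatever its heading, so the times
# at which the smoothed radius crosses two nearby thresholds just outside
# the range cloud extrapolate linearly to the zero-radius boundary without
# assuming a known speed. Two residual biases remain and largely cancel:
# the animal trails its moving range center by part of its positional
# autocorrelation timescale (a late bias), while noise makes the first
# sustained crossing fire slightly before the underlying mean does (an
# early bias). The correction is bounded by the known direction of the
# raw-boundary bias (the last in-cluster fix is late for departures and
# early for arrivals, by about separation / speed), and falls back to the
# raw boundary when the transit is too short to measure.
refine_transition <- function(tr, seg_a, seg_b, min_separation) {
  out <- list(depart = seg_a$end, arrive = seg_b$start)
  ca <- c(seg_a$cx, seg_a$cy); cb <- c(seg_b$cx, seg_b$cy)
  D <- sqrt(sum((cb - ca)^2))
  ratio <- 1.4
  if (!is.finite(D) || D <= 2 * ratio * min_separation) return(out)
  sel <- which(tr$timestamp >= seg_a$start & tr$timestamp <= seg_b$end)
  tn <- as.numeric(tr$timestamp[sel])
  # 3-fix moving average tames the positional noise before the crossings
  smooth3 <- function(v) {
    n <- length(v)
    (v + c(v[1], v[-n]) + c(v[-1], v[n])) / 3
  }
  xs <- smooth3(tr$x[sel]); ys <- smooth3(tr$y[sel])
  r_a <- sqrt((xs - ca[1])^2 + (ys - ca[2])^2)
  r_b <- sqrt((xs - cb[1])^2 + (ys - cb[2])^2)
  extrapolate <- function(tt, rr) {
    t1 <- first_crossing(tt, rr, min_separation)
    t2 <- first_crossing(tt, rr, ratio * min_separation)
    if (is.na(t1) || is.na(t2) || t2 <= t1) return(NA_real_)
    t1 - (t2 - t1) / (ratio - 1)
  }
  raw_dep <- as.numeric(seg_a$end); raw_arr <- as.numeric(seg_b$start)
  dep <- extrapolate(tn, r_a)
  # arrival: same construction on the time-reversed approach to the target
  arr_rev <- extrapolate(-rev(tn), rev(r_b))
  arr <- if (is.na(arr_rev)) NA_real_ else -arr_rev
  if (!is.na(dep)) {
    dep <- min(max(dep, as.numeric(seg_a$start), raw_dep - 3 * 86400), raw_dep)
    out$depart <- as.POSIXct(dep, tz = "UTC", origin = "1970-01-01")
  }
  if (!is.na(arr)) {
    arr <- max(min(arr, as.numeric(seg_b$end), raw_arr + 3 * 86400), raw_arr,
               as.numeric(out$depart) + 1)
    out$arrive <- as.POSIXct(arr, tz = "UTC", origin = "1970-01-01")
  }
  out
}

#' Extract migration events from a segment table
#'
#' A migration event is a transition between two home-range ("range")
#' segments in different clusters; stopover segments between them attach to
#' the event. Departure is the end of the source segment (day granularity:
#' the last day in the source range); arrival is the start of the target
#' segment. Events are labeled spring (departure February-July of the
#' monitoring year) or fall.
#'
#' @param segments output of [detect_segments()].
#' @return data.frame with one row per event: `depart, arrive, from_cluster,
#'   to_cluster, season, year, n_stopovers`.
#' When the source track is supplied, the raw segment boundaries are refined
#' by backcasting: fixes only leave the source cluster once they are
#' `min_separation` away from its center, so the last in-segment fix lags
#' the true start of the range shift by about (separation / travel speed).
#' Regressing transit progress (projection onto the source-to-target axis)
#' on time and extrapolating to zero (respectively full) progress removes
#' that lag without assuming a known travel speed.
#'
#' @param tr optionally, the track the segments came from (enables boundary
#'   backcasting).
#' @param min_separation the separation scale used in [detect_segments()];
#'   only used for backcasting.
#' @export
migration_events <- function(segments, tr = NULL, min_separation = 2500) {
  rng <- segments[segments$kind == "range", , drop = FALSE]
  if (nrow(rng) < 2L) return(data.frame())
  events <- list()
  for (k in seq_len(nrow(rng) - 1L)) {
    if (rng$cluster[k] == rng$cluster[k + 1L]) next
    dep <- rng$end[k]; arr <- rng$start[k + 1L]
    if (!is.null(tr)) {
      ref <- refine_transition(tr, rng[k, ], rng[k + 1L, ], min_separation)
      dep <- ref$depart; arr <- ref$arrive
    }
    stops <- segments$kind == "stopover" &
      segments$start >= dep & segments$end <= arr
    doy <- study_doy(dep)
    events[[length(events) + 1L]] <- data.frame(
      depart = dep, arrive = arr,
      from_cluster = rng$cluster[k], to_cluster = rng$cluster[k + 1L],
      season = if (doy < 150) "spring" else "fall",  # mid-July split from 13 Feb
      year = study_year(dep),
      n_stopovers = sum(stops), stringsAsFactors = FALSE)
  }
  if (!length(events)) return(data.frame())
  do.call(rbind, events)
}

#' Classify movement strategy
#'
#' One home range => resident; 2-3 distinct ranges with movement between
#' them => migratory; >= 4 distinct ranges visited at irregular intervals
#' (no repeated seasonal back-shift between the same two centers) =>
#' nomadic; monitoring spans shorter than one migration season => unknown.
#' When an animal makes several round trips, its migration is the movement
#' period associated with the longest stay.
#'
#' @param segments output of [detect_segments()].
#' @param monitoring_span monitored duration in days.
#' @param min_span_days minimum span needed to assess status (days).
#' @return list with `status` (`"migratory"`, `"resident"`, `"nomadic"`,
#'   `"unknown"`) and `displacement_km` (migratory only, else `NA`).
#' @export
classify_movement <- function(segments, monitoring_span, min_span_days = 60) {
  if (monitoring_span < min_span_days || nrow(segments) == 0L ||
      !any(segments$kind == "range")) {
    return(list(status = "unknown", displacement_km = NA_real_))
  }
  rng <- segments[segments$kind == "range", , drop = FALSE]
  n_clusters <- length(unique(rng$cluster))
  if (n_clusters == 1L) return(list(status = "resident", displacement_km = NA_real_))
  if (n_clusters >= 4L) {
    # nomadic unless the animal repeatedly shifts back and forth between the
    # same two centers (which would be migration plus noise)
    pairs <- paste(pmin(rng$cluster[-nrow(rng)], rng$cluster[-1L]),
                   pmax(rng$cluster[-nrow(rng)], rng$cluster[-1L]))
    if (max(table(pairs)) < 2L) {
      return(list(status = "nomadic", displacement_km = NA_real_))
    }
  }
  list(status = "migratory", displacement_km = displacement_km(rng))
}

#' Seasonal displacement of a migratory animal
#'
#' Euclidean distance between the arithmetic centroids of the winter and
#' summer ranges, in km. With multiple years and no range fidelity the
#' per-transition displacements are averaged.
#'
#' @param rng the `"range"` rows of a segment table.
#' @export
displacement_km <- function(rng) {
  if (nrow(rng) < 2L) stop("displacement requires >= 2 range segments")
  # centroid of each cluster, weighted by fixes
  agg <- do.call(rbind, lapply(split(rng, rng$cluster), function(g) {
    data.frame(cluster = g$cluster[1],
               cx = sum(g$cx * g$n_fixes) / sum(g$n_fixes),
               cy = sum(g$cy * g$n_fixes) / sum(g$n_fixes))
  }))
  # mean displacement over the consecutive distinct-range transitions
  d <- numeric(0)
  for (k in seq_len(nrow(rng) - 1L)) {
    if (rng$cluster[k] == rng$cluster[k + 1L]) next
    a <- agg[agg$cluster == rng$cluster[k], ]
    b <- agg[agg$cluster == rng$cluster[k + 1L], ]
    d <- c(d, sqrt((a$cx - b$cx)^2 + (a$cy - b$cy)^2) / 1000)
  }
  mean(d)
}

#' Migration-timing quantile table
#'
#' Per season: the 5% and 25% quantiles of departure days, mean departure,
#' mean arrival, and the 75% and 95% quantiles of arrival days. Quantiles
#' are empirical with linear interpolation (R type 7). Days are
#' day-of-monitoring-year (origin 13 February); formatted dates accompany
#' them. Seasons with no events are omitted.
#'
#' @param events data.frame with columns `depart`, `arrive` (`POSIXct`) and
#'   `season` (`"spring"`/`"fall"`).
#' @return data.frame, one row per season, with numeric day columns
#'   `start05, start25, start_mean, finish_mean, finish75, finish95` and
#'   matching `*_date` labels.
#' @export
timing_table <- function(events) {
  if (nrow(events) == 0L) stop("no migration events")
  rows <- lapply(c("spring", "fall"), function(s) {
    ev <- events[events$season == s, , drop = FALSE]
    if (nrow(ev) == 0L) return(NULL)
    dep <- study_doy(ev$depart)
    arr <- study_doy(ev$arrive)
    q <- function(v, p) unname(stats::quantile(v, p, type = 7))
    data.frame(
      season = s, n = nrow(ev),
      start05 = q(dep, .05), start25 = q(dep, .25),
      start_mean = mean(dep), finish_mean = mean(arr),
      finish75 = q(arr, .75), finish95 = q(arr, .95),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  origin_doy <- date_to_doy("13 February")
  for (col in c("start05", "start25", "start_mean", "finish_mean", "finish75", "finish95")) {
    out[[paste0(col, "_date")]] <-
      doy_to_date((origin_doy - 1 + round(out[[col]])) %% 365 + 1)
  }
  out
}

#' Season windows
#'
#' A partition of the calendar year into spring migration, summer, fall
#' migration and winter. Windows are stored as inclusive day-of-year ranges
#' on a 365-day template (29 February folds into 28 February); winter wraps
#' the year boundary.
#'
#' @param spring_start,spring_end,fall_start,fall_end dates as `"4 April"`
#'   style labels or `Date`s.
#' @return data.frame of class `"season_windows"`.
#' @export
season_windows <- function(spring_start, spring_end, fall_start, fall_end) {
  sdoy <- vapply(list(spring_start, spring_end, fall_start, fall_end),
                 date_to_doy, numeric(1))
  if (!(sdoy[1] <= sdoy[2] && sdoy[2] < sdoy[3] && sdoy[3] <= sdoy[4])) {
    stop("migration windows overlap or are out of order")
  }
  out <- data.frame(
    season = c("spring", "summer", "fall", "winter"),
    start_doy = c(sdoy[1], sdoy[2] + 1, sdoy[3], (sdoy[4] %% 365) + 1),
    end_doy = c(sdoy[2], sdoy[3] - 1, sdoy[4], sdoy[1] - 1),
    stringsAsFactors = FALSE)
  out$start_date <- doy_to_date(out$start_doy)
  out$end_date <- doy_to_date((out$end_doy - 1) %% 365 + 1)
  class(out) <- c("season_windows", "data.frame")
  out
}

#' Delineate analysis seasons from migration timing
#'
#' Spring migration runs from the 25% departure quantile to the 75% arrival
#' quantile of spring events; fall likewise. Summer is the gap between
#' spring and fall migration, winter the wrapped remainder. Both migration
#' rows must be present.
#'
#' @param timing output of [timing_table()].
#' @export
define_seasons <- function(timing) {
  sp <- timing[timing$season == "spring", ]
  fa <- timing[timing$season == "fall", ]
  if (nrow(sp) == 0L || nrow(fa) == 0L) stop("both spring and fall timing rows required")
  origin <- date_to_doy("13 February")
  to_date <- function(doy_study) {
    as.Date("2018-12-31") + ((origin - 1 + round(doy_study)) %% 365 + 1)
  }
  season_windows(to_date(sp$start25), to_date(sp$finish75),
                 to_date(fa$start25), to_date(fa$finish75))
}

#' Default season windows for the study system
#'
#' The worked example: spring migration 4 April-2 May, summer 3 May-9
#' October, fall migration 10 October-28 November, winter 29 November-3
#' April.
#' @export
default_season_windows <- function() {
  season_windows("4 April", "2 May", "10 October", "28 November")
}

#' Season membership of timestamps
#'
#' @param timestamps `POSIXct` vector.
#' @param windows a [season_windows()].
#' @return character vector of season labels.
#' @export
season_of <- function(timestamps, windows) {
  doy <- calendar_doy(timestamps)
  out <- rep(NA_character_, length(doy))
  for (k in seq_len(nrow(windows))) {
    s <- windows$start_doy[k]; e <- windows$end_doy[k]
    inside <- if (s <= e) doy >= s & doy <= e else doy >= s | doy <= e
    out[inside] <- windows$season[k]
  }
  out
}

#' Classify a whole population of tracks
#'
#' Runs [detect_segments()] and [classify_movement()] per animal and
#' collects migration events for the timing table.
#'
#' @param tracks named list of tracks (post-QC).
#' @param params a [segment_params()], or a named list of them keyed by
#'   species. The separation scale must track the species' home-range scale
#'   (about four times the within-range positional SD), so territorial
#'   predators default to a much larger separation than ungulates.
#' @return list with `status` (data.frame: id, species, status,
#'   displacement_km), `events` (migration events with ids and species), and
#'   `segments` (named list of per-animal segment tables).
#' @export
classify_population <- function(tracks, params = NULL) {
  if (is.null(params)) {
    params <- list(deer = segment_params(min_separation = 2500),
                   moose = segment_params(min_separation = 3200),
                   wolf = segment_params(min_separation = 10000))
  }
  status <- list(); events <- list(); seg_list <- list()
  for (id in names(tracks)) {
    tr <- tracks[[id]]
    pars <- if (inherits(params, "segment_params")) params
            else params[[tr$species[1]]]
    if (is.null(pars)) pars <- segment_params()
    span <- as.numeric(max(tr$timestamp) - min(tr$timestamp), units = "days")
    segs <- detect_segments(tr, pars)
    cls <- classify_movement(segs, span)
    status[[id]] <- data.frame(
      id = id, species = tr$species[1], sex = tr$sex[1], pack = tr$pack[1],
      status = cls$status, displacement_km = cls$displacement_km,
      stringsAsFactors = FALSE)
    seg_list[[id]] <- segs
    if (cls$status == "migratory") {
      ev <- migration_events(segs, tr, pars$min_separation)
      if (nrow(ev)) {
        ev$id <- id; ev$species <- tr$species[1]
        events[[id]] <- ev
      }
    }
  }
  list(status = do.call(rbind, status),
       events = if (length(events)) do.call(rbind, events) else data.frame(),
       segments = seg_list)
}
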