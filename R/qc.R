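#' Quality-control configuration
#'
#' Thresholds for track regularization and anomaly censoring. Defaults are
#' the standard collar-screening values for 4-h ungulate/wolf data: fixes
#' faster than 10.8 km/h between consecutive 4-h relocations are implausible;
#' a terminal run moving < 50 m over >= 48 h marks a mortality; fixes with a
#' first-passage time <= 1 h through a 300-m circle combined with a
#' 179-181 degree turn are out-and-back spikes.
#'
#' @param target_interval regular fix interval (h).
#' @param snap_tolerance max offset of an original fix from its grid slot (h).
#' @param vmax maximum plausible speed (km/h).
#' @param fpt_radius first-passage-time circle radius (m).
#' @param fpt_max FPT censoring threshold (h).
#' @param turn_lo,turn_hi relative turning-angle band (degrees, absolute
#'   angle convention in \[0, 180\]: 180 is an exact reversal, so the
#'   nominal 179-181 band maps to \[179, 180\]).
#' @param mortality_window minimum duration of a terminal stationary run (h).
#' @param mortality_dist maximum total movement within that run (m).
#' @export
qc_config <- function(target_interval = 4, snap_tolerance = 1, vmax = 10.8,
                      fpt_radius = 300, fpt_max = 1,
                      turn_lo = 179, turn_hi = 181,
                      mortality_window = 48, mortality_dist = 50) {
  stopifnot(vmax > 0, turn_lo < turn_hi, fpt_radius > 0, target_interval > 0)
  structure(as.list(environment()), class = "qc_config")
}

#' Regularize a track to a common fix interval
#'
#' Snaps fixes onto a regular time grid anchored at the first fix: each grid
#' slot takes the nearest original fix within `snap_tolerance`, empty slots
#' are dropped, and no original fix is used twice.
#'
#' @param tr a [track()].
#' @param cfg a [qc_config()].
#' @return the regularized track (a subsequence of the input rows).
#' @export
regularize <- function(tr, cfg = qc_config()) {
  tn <- as.numeric(tr$timestamp)
  if (is.unsorted(tn, strictly = TRUE)) stop("track must be strictly time-ordered")
  step <- cfg$target_interval * 3600
  tol <- cfg$snap_tolerance * 3600
  slots <- round((tn - tn[1]) / step)
  offset <- abs(tn - (tn[1] + slots * step))
  ok <- offset <= tol
  # one fix per slot: keep the nearest
  keep <- rep(FALSE, length(tn))
  for (s in unique(slots[ok])) {
    cand <- which(slots == s & ok)
    keep[cand[which.min(offset[cand])]] <- TRUE
  }
  track_slice(tr, keep)
}

#' Censor post-mortality locations
#'
#' If the track ends with a run of fixes whose total spatial extent is below
#' `mortality_dist` and whose duration is at least `mortality_window`, the
#' run is removed (the animal is considered dead from its start). Interior
#' low-movement runs are retained: resting behavior is not censored.
#'
#' @inheritParams regularize
#' @export
censor_mortality <- function(tr, cfg = qc_config()) {
  n <- nrow(tr)
  if (n < 2L) return(tr)
  tn <- as.numeric(tr$timestamp)
  # longest terminal run with all points within mortality_dist of each other
  start <- n
  for (i in rev(seq_len(n - 1L))) {
    xs <- tr$x[i:n]; ys <- tr$y[i:n]
    ext <- max(sqrt((xs - xs[1])^2 + (ys - ys[1])^2))
    if (ext < cfg$mortality_dist) start <- i else break
  }
  if (start < n) {
    dur_h <- (tn[n] - tn[start]) / 3600
    if (dur_h >= cfg$mortality_window) {
      return(track_slice(tr, seq_len(start - 1L)))
    }
  }
  tr
}

#' Censor implausible movement speeds
#'
#' Removes any fix whose incoming straight-line speed from the previous
#' retained fix over one consecutive interval exceeds `vmax`; speeds are
#' recomputed after each removal until no fix violates the threshold
#' (the later fix of an offending pair is dropped).
#'
#' @inheritParams regularize
#' @export
filter_speed <- function(tr, cfg = qc_config()) {
  repeat {
    n <- nrow(tr)
    if (n < 2L) return(tr)
    d <- sqrt(diff(tr$x)^2 + diff(tr$y)^2) / 1000           # km
    dt <- lag_hours(tr$timestamp)                           # h
    v <- d / dt
    bad <- which(v > cfg$vmax)
    if (!length(bad)) return(tr)
    tr <- track_slice(tr, -(bad[1] + 1L))
  }
}

#' First passage time through a circle around each fix
#'
#' For each fix, the time the trajectory takes to cross a circle of `radius`
#' centered on it: the time to first exit going forward plus the time to
#' first exit going backward, with the crossing instant linearly
#' interpolated along the straight segment on which the exit occurs. If the
#' circle is never exited on one side (track ends inside), the FPT is
#' censored (`NA`).
#'
#' @param tr a [track()].
#' @param radius circle radius (m), > 0.
#' @return numeric vector of FPTs in hours (`NA` = censored).
#' @export
first_passage_time <- function(tr, radius) {
  if (radius <= 0) stop("radius must be positive")
  n <- nrow(tr)
  tn <- as.numeric(tr$timestamp)
  x <- tr$x; y <- tr$y
  exit_time <- function(i, idx) {
    # walk segments in direction given by index sequence idx; return hours
    # from fix i to the interpolated circle crossing, or NA
    for (k in seq_len(length(idx) - 1L)) {
      a <- idx[k]; b <- idx[k + 1L]
      da <- sqrt((x[a] - x[i])^2 + (y[a] - y[i])^2)
      db <- sqrt((x[b] - x[i])^2 + (y[b] - y[i])^2)
      if (db > radius) {
        # crossing lies on segment a->b: solve |p(a) + s*(p(b)-p(a)) - p(i)| = r
        px <- x[a] - x[i]; py <- y[a] - y[i]
        dx <- x[b] - x[a]; dy <- y[b] - y[a]
        A <- dx^2 + dy^2
        B <- 2 * (px * dx + py * dy)
        C <- px^2 + py^2 - radius^2
        disc <- B^2 - 4 * A * C
        s <- if (A > 0 && disc >= 0) (-B + sqrt(disc)) / (2 * A) else 1
        s <- min(max(s, 0), 1)
        t_cross <- tn[a] + s * (tn[b] - tn[a])
        return(abs(t_cross - tn[i]) / 3600)
      }
    }
    NA_real_
  }
  vapply(seq_len(n), function(i) {
    fwd <- if (i < n) exit_time(i, i:n) else NA_real_
    bwd <- if (i > 1L) exit_time(i, i:1) else NA_real_
    fwd + bwd
  }, numeric(1))
}

# relative turning angle at each interior fix, absolute degrees in [0, 180]
turning_angle <- function(tr) {
  n <- nrow(tr)
  ang <- rep(NA_real_, n)
  if (n < 3L) return(ang)
  dx <- diff(tr$x); dy <- diff(tr$y)
  h1 <- atan2(dy[-(n - 1L)], dx[-(n - 1L)])
  h2 <- atan2(dy[-1L], dx[-1L])
  rel <- abs((h2 - h1 + pi) %% (2 * pi) - pi) * 180 / pi
  ang[2:(n - 1L)] <- rel
  ang
}

#' Censor out-and-back spike fixes
#'
#' Removes fixes that combine a small first passage time (rare usage of the
#' location) with a near-reversal turning angle (a direct route to and from
#' the location) -- the signature of a positional spike. Both conditions are
#' required; censored (`NA`) FPTs never trigger removal.
#'
#' @inheritParams regularize
#' @export
filter_fpt_turn <- function(tr, cfg = qc_config()) {
  fpt <- first_passage_time(tr, cfg$fpt_radius)
  ang <- turning_angle(tr)
  # absolute-angle convention: the nominal band [turn_lo, turn_hi] around a
  # 180-degree reversal collapses to [turn_lo, 180]
  bad <- !is.na(fpt) & fpt <= cfg$fpt_max &
    !is.na(ang) & ang >= cfg$turn_lo & ang <= pmin(cfg$turn_hi, 180)
  track_slice(tr, !bad)
}

#' Full QC pass
#'
#' Mortality censoring, regularization, the speed filter, and the
#' FPT/turning-angle filter, in that order (mortality is screened first,
#' mirroring pre-import screening of collar data).
#'
#' @inheritParams regularize
#' @export
qc_track <- function(tr, cfg = qc_config()) {
  tr <- censor_mortality(tr, cfg)
  tr <- regularize(tr, cfg)
  tr <- filter_speed(tr, cfg)
  filter_fpt_turn(tr, cfg)
}
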