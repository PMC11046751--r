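test_that("NSD is zero at the first fix and quadratic on a straight path", {
  tr <- mk_track((0:99) * 400, rep(0, 100))
  v <- nsd(tr)
  expect_equal(v[1], 0)
  tt <- seq_along(v) - 1
  fit <- lm(v ~ I(tt^2))
  expect_gt(suppressWarnings(summary(fit))$r.squared, 0.999)
})

test_that("NSD plateaus at twice the squared stationary SD on an OU track", {
  spec <- agent_spec("d", "deer", "resident", list(c(0, 0)), range_sd = 600,
                     dropout_prob = 0, monitor_end = t0_utc + 499 * 4 * 3600)
  tr <- simulate_track(spec, 41)
  # NSD is relative to the first fix; E[NSD] = 2*sd^2 + |first-fix deviation|^2
  d0 <- tr$x[1]^2 + tr$y[1]^2
  expected <- (2 * 600^2 + d0) / 1e6
  expect_equal(mean(nsd(tr)[-(1:50)]), expected, tolerance = 0.25)
})

test_that("segments recover a two-range migration with its stopover", {
  spec <- agent_spec("d", "deer", "migratory",
                     list(c(0, 0), c(12000, 9000)), range_sd = 500,
                     depart_day_mean = 100, depart_day_sd = 0.5,
                     transit_speed = 60,  # ~2.5 days in transit
                     dropout_prob = 0, monitor_end = t0_utc + 220 * 86400)
  tr <- simulate_track(spec, 6)
  segs <- detect_segments(tr, segment_params(min_separation = 2000))
  rng <- segs[segs$kind == "range", ]
  expect_equal(nrow(rng), 2)
  expect_lt(abs(rng$cx[1] - 0), 200)
  expect_lt(sqrt((rng$cx[2] - 12000)^2 + (rng$cy[2] - 9000)^2), 300)
  ev <- migration_events(segs)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$season, "spring")
  # departure detected within 2 days of the truth
  expect_lt(abs(as.numeric(ev$depart - (t0_utc + 100 * 86400), units = "days")), 2)
})

test_that("a resident track yields one segment spanning the monitoring period", {
  spec <- agent_spec("d", "deer", "resident", list(c(3000, 3000)),
                     dropout_prob = 0, monitor_end = t0_utc + 120 * 86400)
  tr <- simulate_track(spec, 8)
  segs <- detect_segments(tr, segment_params(min_separation = 2500))
  expect_equal(sum(segs$kind == "range"), 1)
  expect_gt(segs$duration_days[1], 115)
})

test_that("short monitoring yields unknown; five centers yield nomadic", {
  expect_equal(classify_movement(data.frame(), 10)$status, "unknown")
  segs <- data.frame(cluster = 1:5,
                     start = t0_utc + (0:4) * 60 * 86400,
                     end = t0_utc + (0:4) * 60 * 86400 + 50 * 86400,
                     duration_days = 50, cx = (1:5) * 5000, cy = 0,
                     n_fixes = 100, kind = "range")
  expect_equal(classify_movement(segs, 330)$status, "nomadic")
})

test_that("repeated back-shifts between two centers remain migratory", {
  segs <- data.frame(cluster = c(1, 2, 1, 2),
                     start = t0_utc + c(0, 100, 200, 300) * 86400,
                     end = t0_utc + c(90, 190, 290, 360) * 86400,
                     duration_days = c(90, 90, 90, 60),
                     cx = c(0, 10000, 0, 10000), cy = 0,
                     n_fixes = 500, kind = "range")
  cls <- classify_movement(segs, 400)
  expect_equal(cls$status, "migratory")
  expect_equal(cls$displacement_km, 10)
})

test_that("displacement follows centroid geometry and multi-year averaging", {
  seg2 <- data.frame(cluster = c(1, 2), cx = c(0, 3000), cy = c(0, 4000),
                     n_fixes = c(10, 10), kind = "range")
  expect_equal(displacement_km(seg2), 5)
  seg_same <- data.frame(cluster = c(1, 2), cx = c(0, 0), cy = c(0, 0),
                         n_fixes = c(10, 10), kind = "range")
  expect_equal(displacement_km(seg_same), 0)
  # two transitions with 10 and 14 km displacements average to 12
  seg3 <- data.frame(cluster = c(1, 2, 3), cx = c(0, 10000, 10000),
                     cy = c(0, 0, 14000), n_fixes = 10, kind = "range")
  expect_equal(displacement_km(seg3), 12)
})

test_that("classification is invariant to rigid motions of the coordinates", {
  spec <- agent_spec("d", "deer", "migratory", list(c(0, 0), c(14000, 8000)),
                     depart_day_mean = c(60, 250), depart_day_sd = c(2, 5),
                     dropout_prob = 0, monitor_end = t0_utc + 364 * 86400)
  tr <- simulate_track(spec, 10)
  cls1 <- classify_movement(detect_segments(tr, segment_params(2500)),
                            monitoring_span = 364)
  th <- 0.7
  tr2 <- tr
  tr2$x <- cos(th) * tr$x - sin(th) * tr$y + 5e5
  tr2$y <- sin(th) * tr$x + cos(th) * tr$y - 2e5
  cls2 <- classify_movement(detect_segments(tr2, segment_params(2500)),
                            monitoring_span = 364)
  expect_equal(cls1$status, cls2$status)
  expect_equal(cls1$displacement_km, cls2$displacement_km, tolerance = 1e-6)
})

test_that("timing table quantiles follow the linear-interpolation rule", {
  # degenerate: all departures on the same day
  ev <- data.frame(depart = rep(t0_utc + 100 * 86400, 4),
                   arrive = rep(t0_utc + 110 * 86400, 4),
                   season = "spring")
  tt <- timing_table(ev)
  expect_equal(tt$start05, 100)
  expect_equal(tt$start25, 100)
  # hand-computed type-7 quantile: arrivals {110, 112, 118, 140} days;
  # 75% quantile = 118 + 0.25*(140-118) = 123.5
  ev2 <- data.frame(depart = t0_utc + c(100, 101, 102, 103) * 86400,
                    arrive = t0_utc + c(110, 112, 118, 140) * 86400,
                    season = "fall")
  tt2 <- timing_table(ev2)
  expect_equal(tt2$finish75, 123.5)
  expect_equal(tt2$start_mean, 101.5)
})

test_that("timing quantiles converge to the generating distribution's", {
  # spring departures N(day 105, sd 2): the 25% quantile is 103.65
  withr::with_seed(5, {
    dep <- stats::rnorm(60, 105, 2)
  })
  ev <- data.frame(depart = t0_utc + dep * 86400,
                   arrive = t0_utc + (dep + 8) * 86400, season = "spring")
  tt <- timing_table(ev)
  expect_lt(abs(tt$start25 - (105 + stats::qnorm(0.25) * 2)), 1.5)
})

test_that("the published quartile dates reproduce the published season windows", {
  origin <- as.numeric(t0_utc)
  mk_doy <- function(lbl) {
    (seasonlap:::date_to_doy(lbl) - seasonlap:::date_to_doy("13 February")) %% 365
  }
  timing <- data.frame(
    season = c("spring", "fall"), n = 1,
    start05 = 0, start_mean = 0, finish_mean = 0, finish95 = 0,
    start25 = c(mk_doy("4 April"), mk_doy("10 October")),
    finish75 = c(mk_doy("2 May"), mk_doy("28 November")))
  sw <- define_seasons(timing)
  expect_equal(sw$start_date[sw$season == "summer"], "03 May")
  expect_equal(sw$end_date[sw$season == "summer"], "09 October")
  expect_equal(sw$start_date[sw$season == "fall"], "10 October")
  expect_equal(sw$end_date[sw$season == "fall"], "28 November")
  expect_equal(sw$start_date[sw$season == "winter"], "29 November")
  expect_equal(sw$end_date[sw$season == "winter"], "03 April")
})

test_that("season windows partition the full year with no gaps or overlaps", {
  for (sw in list(default_season_windows(),
                  season_windows("1 March", "30 April", "1 September", "15 December"))) {
    len <- ifelse(sw$end_doy >= sw$start_doy,
                  sw$end_doy - sw$start_doy + 1,
                  365 - sw$start_doy + 1 + sw$end_doy)
    expect_equal(sum(len), 365)
    # every calendar day maps to exactly one season
    days <- as.POSIXct(sprintf("2021-01-01"), tz = "UTC") + (0:364) * 86400
    expect_false(any(is.na(season_of(days, sw))))
  }
  # leap years map 29 Feb into the same season as 28 Feb
  leap <- as.POSIXct(c("2020-02-28", "2020-02-29"), tz = "UTC")
  sw <- default_season_windows()
  expect_equal(season_of(leap, sw)[1], season_of(leap, sw)[2])
})

test_that("season membership boundaries are inclusive as published", {
  sw <- default_season_windows()
  d <- as.POSIXct(c("2020-10-09", "2020-10-10", "2020-05-03", "2020-05-02"),
                  tz = "UTC")
  expect_equal(season_of(d, sw), c("summer", "fall", "summer", "spring"))
})

test_that("overlapping migration windows are rejected", {
  timing <- data.frame(season = c("spring", "fall"), start25 = c(50, 40),
                       finish75 = c(80, 70), n = 1, start05 = 0,
                       start_mean = 0, finish_mean = 0, finish95 = 0)
  expect_error(define_seasons(timing), "overlap|order")
})
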