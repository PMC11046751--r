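test_that("regularize snaps to the grid anchored at the first fix", {
  tr <- track("a", t0_utc + c(0, 0.25, 4.0) * 3600, c(0, 10, 20), c(0, 0, 0))
  out <- regularize(tr, qc_config(target_interval = 4, snap_tolerance = 1))
  expect_equal(as.numeric(out$timestamp - t0_utc, units = "hours"), c(0, 4))
  expect_equal(out$x, c(0, 20))
})

test_that("an already-regular track is unchanged by regularize", {
  tr <- mk_track(1:20, 1:20)
  expect_equal(as.data.frame(regularize(tr)), as.data.frame(tr))
})

test_that("a 15-min track over 24 h regularizes to 7 four-hour fixes", {
  tr <- mk_track(0:96, rep(0, 97), interval_h = 0.25, species = "moose")
  out <- regularize(tr, qc_config(target_interval = 4, snap_tolerance = 1))
  expect_equal(nrow(out), 7)
})

test_that("unordered input is rejected", {
  tr <- mk_track(1:5, 1:5)
  tr2 <- tr[c(1, 3, 2, 4, 5), ]
  class(tr2) <- c("track", "data.frame")
  expect_error(regularize(tr2), "ordered")
})

test_that("terminal stationary runs are censored as mortality", {
  # 20 moving fixes then 14 fixes inside a 30-m disc (56 h)
  withr::with_seed(1, {
    x <- c(cumsum(rnorm(20, 0, 300)), rep(0, 14) + runif(14, 0, 15))
    y <- c(cumsum(rnorm(20, 0, 300)), rep(0, 14) + runif(14, 0, 15))
  })
  tr <- mk_track(x, y)
  out <- censor_mortality(tr)
  expect_equal(nrow(out), 20)
})

test_that("interior resting runs are retained", {
  withr::with_seed(2, {
    x <- c(cumsum(rnorm(10, 0, 300)), rep(500, 13), cumsum(rnorm(10, 0, 300)) + 500)
    y <- c(cumsum(rnorm(10, 0, 300)), rep(500, 13), cumsum(rnorm(10, 0, 300)) + 500)
  })
  tr <- mk_track(x, y)
  expect_equal(nrow(censor_mortality(tr)), nrow(tr))
})

test_that("a constantly moving track is unchanged by mortality censoring", {
  tr <- mk_track(seq(0, 10000, by = 500), seq(0, 10000, by = 500))
  expect_equal(nrow(censor_mortality(tr)), 21)
})

test_that("speed filter removes fixes above 10.8 km/h and keeps those below", {
  # consecutive 4-h fixes 45 km apart: 11.25 km/h -> removed
  tr <- mk_track(c(0, 45000, 45000), c(0, 0, 0))
  expect_equal(nrow(filter_speed(tr)), 2)
  # 43 km in 4 h: 10.75 km/h -> retained
  tr2 <- mk_track(c(0, 43000, 43000), c(0, 0, 0))
  expect_equal(nrow(filter_speed(tr2)), 3)
  # stationary track unchanged
  tr3 <- mk_track(rep(0, 10), rep(0, 10))
  expect_equal(nrow(filter_speed(tr3)), 10)
})

test_that("speed filter is a fixpoint (idempotent)", {
  withr::with_seed(3, {
    x <- cumsum(rnorm(50, 0, 20000))
    y <- cumsum(rnorm(50, 0, 20000))
  })
  tr <- mk_track(x, y)
  once <- filter_speed(tr)
  twice <- filter_speed(once)
  expect_identical(as.data.frame(once), as.data.frame(twice))
})

test_that("FPT equals 2r/v on a straight constant-speed path", {
  v <- 500  # m/h
  tr <- mk_track((0:20) * v * 4, rep(0, 21))
  fpt <- first_passage_time(tr, 300)
  inner <- 5:17
  expect_equal(fpt[inner], rep(2 * 300 / v, length(inner)), tolerance = 1e-8)
})

test_that("FPT is censored when the circle is never exited", {
  tr <- mk_track(c(0, 10, -10, 5, -5), c(0, 5, -5, 10, -10))
  fpt <- first_passage_time(tr, 300)
  expect_true(all(is.na(fpt)))
  expect_error(first_passage_time(tr, -1), "positive")
})

test_that("FPT matches a brute-force segment-walk oracle on an OU track", {
  spec <- agent_spec("d", "deer", "resident", list(c(0, 0)), range_sd = 400,
                     dropout_prob = 0, monitor_end = t0_utc + 199 * 4 * 3600)
  tr <- simulate_track(spec, 21)
  r <- 300
  # oracle: plain loop over segments with explicit chord intersection
  oracle_one_side <- function(i, dir) {
    n <- nrow(tr)
    tn <- as.numeric(tr$timestamp)
    seqi <- if (dir > 0) i:n else i:1
    for (k in seq_len(length(seqi) - 1)) {
      a <- seqi[k]; b <- seqi[k + 1]
      pb <- c(tr$x[b] - tr$x[i], tr$y[b] - tr$y[i])
      if (sqrt(sum(pb^2)) > r) {
        pa <- c(tr$x[a] - tr$x[i], tr$y[a] - tr$y[i])
        d <- pb - pa
        A <- sum(d^2); B <- 2 * sum(pa * d); C <- sum(pa^2) - r^2
        s <- (-B + sqrt(B^2 - 4 * A * C)) / (2 * A)
        return(abs((tn[a] + s * (tn[b] - tn[a])) - tn[i]) / 3600)
      }
    }
    NA_real_
  }
  oracle <- vapply(seq_len(nrow(tr)), function(i) {
    oracle_one_side(i, +1) + oracle_one_side(i, -1)
  }, numeric(1))
  expect_equal(first_passage_time(tr, r), oracle, tolerance = 1e-10)
})

test_that("FPT/turn filter removes spikes but keeps transits and loiterers", {
  # base path moving steadily east at 500 m per 4-h step, with an injected
  # exact out-and-back 4-km spike after fix 10 (1000 m/h through the 300-m
  # circle -> FPT 0.6 h; exact reversal -> turn 180 degrees)
  x <- (0:19) * 500; y <- rep(0, 20)
  xsp <- c(x[1:10], x[10], x[10:20])
  ysp <- c(y[1:10], 4000, y[10:20])
  tr <- mk_track(xsp, ysp)
  out <- filter_fpt_turn(tr, qc_config(fpt_radius = 300, fpt_max = 1,
                                       turn_lo = 179))
  # the spike has FPT < 1 h and a 180-degree turn
  expect_equal(nrow(out), 21)
  expect_false(4000 %in% out$y)
  # fast straight transit: small FPT but straight angle -> retained
  tr2 <- mk_track((0:9) * 3000, rep(0, 10))
  expect_equal(nrow(filter_fpt_turn(tr2)), 10)
  # slow loiterer: reversal angles but large FPT -> retained
  tr3 <- mk_track(c(0, 50, 0, 50, 0, 50), rep(0, 6))
  expect_equal(nrow(filter_fpt_turn(tr3)), 6)
})

test_that("QC output is always a subsequence of its input", {
  spec <- agent_spec("d", "deer", "resident", list(c(0, 0)),
                     monitor_end = t0_utc + 30 * 86400)
  tr <- simulate_track(spec, 31)
  out <- qc_track(tr)
  key_in <- paste(tr$timestamp, tr$x, tr$y)
  key_out <- paste(out$timestamp, out$x, out$y)
  expect_true(all(key_out %in% key_in))
  expect_false(is.unsorted(out$timestamp))
})

test_that("clean synthetic tracks lose under 1% of fixes at default thresholds", {
  cfg <- population_config(n_deer_migratory = 3, n_deer_resident = 2,
                           n_moose_nomadic = 1, n_moose_migratory = 0,
                           n_moose_resident = 1, n_wolves = 2, years = 1)
  sim <- simulate_population(cfg, 17)
  frac_lost <- vapply(sim$tracks, function(tr) {
    1 - nrow(qc_track(tr)) / nrow(tr)
  }, numeric(1))
  expect_lt(max(frac_lost), 0.01)
})
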