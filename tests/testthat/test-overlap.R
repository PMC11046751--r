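test_that("corridor inclusion uses a >= rule on the fraction of fixes", {
  g <- bbmm_grid(0, 0, 10000, 10000, 100)
  corridor <- mk_region(g, 1:50, 1:100)  # western half
  mk_wolf <- function(id, n_in, n_out) {
    mk_track(c(rep(2000, n_in), rep(8000, n_out)),
             rep(5000, n_in + n_out), id = id, species = "wolf")
  }
  tracks <- list(none = mk_wolf("none", 0, 100),
                 under = mk_wolf("under", 49, 951),
                 at = mk_wolf("at", 50, 950),
                 all = mk_wolf("all", 100, 0))
  kept <- corridor_filter(tracks, corridor, 0.05)
  expect_identical(kept, c("at", "all"))
})

test_that("wolf-seasons below 50 locations are dropped at the boundary", {
  sw <- default_season_windows()
  # 49 summer fixes: dropped; 50: retained (daily fixes in July-August)
  jul <- as.POSIXct("2020-07-01", tz = "UTC")
  tr49 <- track("w", jul + (0:48) * 86400, rnorm(49), rnorm(49))
  tr50 <- track("w", jul + (0:49) * 86400, rnorm(50), rnorm(50))
  expect_equal(length(season_filter(tr49, sw)), 0)
  expect_equal(names(season_filter(tr50, sw)), "summer.2020")
})

test_that("proportional overlap matches exact geometry", {
  g <- bbmm_grid(0, 0, 1000, 1000, 50)
  wolf <- mk_region(g, 1:10, 1:10)
  expect_equal(proportional_overlap(wolf, mk_region(g, 1:20, 1:20)), 1.0)
  expect_equal(proportional_overlap(wolf, mk_region(g, 15:20, 15:20)), 0.0)
  expect_equal(proportional_overlap(wolf, mk_region(g, 1:10, 1:5)), 0.5)
  empty <- mk_region(g, integer(0), integer(0))
  expect_error(proportional_overlap(empty, wolf), "zero-area")
})

test_that("proportional overlap is monotone in the prey region", {
  g <- bbmm_grid(0, 0, 1000, 1000, 50)
  wolf <- mk_region(g, 3:12, 3:12)
  p <- vapply(seq(2, 20, by = 2), function(k) {
    proportional_overlap(wolf, mk_region(g, 1:k, 1:k))
  }, numeric(1))
  expect_true(all(diff(p) >= 0))
})

test_that("the capped logit matches its closed form", {
  expect_equal(logit_cap(0.5), 0)
  expect_equal(logit_cap(1.0), log(0.975 / 0.025))
  expect_equal(logit_cap(1.0), 3.6636, tolerance = 1e-4)
  expect_equal(logit_cap(0.0), -logit_cap(1.0))
  expect_equal(logit_cap(0.3), log(0.3 / 0.7))
})

test_that("pack assignment applies the strict floater threshold", {
  expect_equal(assign_pack(600, "SW"), "FL")
  expect_equal(assign_pack(561, "SW"), "SW")
  expect_equal(assign_pack(80, "SW"), "SW")
})

test_that("OLS coefficients equal a hand-solved normal-equations oracle", {
  rec <- data.frame(
    logit_value = c(-1.2, 0.4, -0.3, 0.9, -0.8, 0.1),
    season = c("winter", "fall", "winter", "fall", "summer", "summer"),
    sex = c("F", "F", "M", "M", "F", "M"),
    pack = c("FL", "FL", "NE", "NE", "NE", "FL"))
  fit <- fit_overlap_model(rec)
  # independent oracle: explicit design matrix and solve(X'X, X'y)
  X <- cbind(1,
             fall = as.numeric(rec$season == "fall"),
             summer = as.numeric(rec$season == "summer"),
             sexM = as.numeric(rec$sex == "M"),
             packNE = as.numeric(rec$pack == "NE"))
  beta <- solve(t(X) %*% X, t(X) %*% rec$logit_value)
  got <- fit$table$estimate[match(
    c("(Intercept)", "seasonfall", "seasonsummer", "sexM", "packNE"),
    fit$table$term)]
  expect_equal(got, as.vector(beta), tolerance = 1e-10)
})

test_that("identical responses yield zero slopes", {
  rec <- data.frame(logit_value = rep(1.3, 8),
                    season = rep(c("winter", "fall"), 4),
                    sex = rep(c("F", "M"), each = 4),
                    pack = c("FL", "NE", "NE", "FL", "FL", "NE", "NE", "FL"))
  fit <- suppressWarnings(fit_overlap_model(rec))  # perfect-fit warning
  slopes <- fit$table$estimate[fit$table$term != "(Intercept)"]
  expect_equal(slopes, rep(0, length(slopes)), tolerance = 1e-12)
  expect_equal(fit$table$estimate[fit$table$term == "(Intercept)"], 1.3)
})

test_that("a true seasonal effect is recovered with nominal coverage", {
  hits <- 0
  for (i in 1:60) {
    withr::with_seed(5000 + i, {
      n <- 100
      season <- sample(c("winter", "fall", "summer", "spring"), n, replace = TRUE)
      sex <- sample(c("F", "M"), n, replace = TRUE)
      pack <- sample(c("FL", "NE", "NW", "SW"), n, replace = TRUE)
      y <- 1.5 * (season == "fall") + 0.3 * (sex == "M") + rnorm(n, 0, 1)
    })
    fit <- fit_overlap_model(data.frame(logit_value = y, season, sex, pack))
    row <- fit$table[fit$table$term == "seasonfall", ]
    if (abs(row$estimate - 1.5) <= 2 * row$se) hits <- hits + 1
  }
  expect_gte(hits / 60, 0.93)
})

test_that("rank-deficient designs are rejected with the offending term", {
  rec <- data.frame(logit_value = rnorm(8),
                    season = rep(c("winter", "fall"), 4),
                    sex = rep(c("F", "M"), 4),
                    pack = rep(c("FL", "NE"), 4))  # sex == pack -> aliased
  expect_error(fit_overlap_model(rec), "rank-deficient")
})

test_that("Mann-Whitney matches the worked example and its symmetries", {
  mw <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(mw$W, 0)
  expect_equal(mw$p_value, 0.1)
  expect_equal(mw$method, "exact")
  expect_equal(mw$W + mw$W_b, 9)
  same <- mann_whitney(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$p_value, 1, tolerance = 1e-12)
})

test_that("exact Mann-Whitney p equals a brute-force permutation oracle", {
  perm_oracle <- function(a, b) {
    pooled <- c(a, b); nA <- length(a)
    rk <- rank(pooled)
    u_of <- function(idx) sum(rk[idx]) - nA * (nA + 1) / 2
    combos <- utils::combn(length(pooled), nA)
    us <- apply(combos, 2, u_of)
    mu <- mean(us)
    obs <- abs(u_of(seq_len(nA)) - mu)
    mean(abs(us - mu) >= obs - 1e-9)
  }
  withr::with_seed(77, {
    for (rep in 1:12) {
      nA <- sample(2:5, 1); nB <- sample(2:5, 1)
      # draw from a small integer pool to force ties
      a <- sample(1:6, nA, replace = TRUE)
      b <- sample(1:6, nB, replace = TRUE)
      mw <- mann_whitney(a, b)
      expect_equal(mw$p_value, perm_oracle(a, b),
                   info = paste("a =", paste(a, collapse = ","),
                                "b =", paste(b, collapse = ",")))
    }
  })
})

test_that("tie-free exact p agrees with the base wilcox.test", {
  withr::with_seed(42, {
    a <- rnorm(6); b <- rnorm(7) + 0.5
  })
  mw <- mann_whitney(a, b)
  wt <- stats::wilcox.test(a, b, exact = TRUE, correct = FALSE)
  expect_equal(mw$W, unname(wt$statistic))
  expect_equal(mw$p_value, wt$p.value, tolerance = 1e-12)
})

test_that("large samples fall back to the tie-corrected normal approximation", {
  withr::with_seed(8, {
    a <- sample(1:10, 25, replace = TRUE)
    b <- sample(1:10, 25, replace = TRUE) + 1
  })
  mw <- mann_whitney(a, b)
  expect_equal(mw$method, "normal")
  wt <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE, correct = TRUE))
  expect_equal(mw$p_value, wt$p.value, tolerance = 1e-9)
})
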