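#' Corridor-inclusion filter for predators
#'
#' A wolf is retained only if at least `min_frac` of all its recorded
#' locations fall inside the 95% deer-migration-corridor boundary; wolves
#' below the threshold are dispersers or hold ranges away from the corridor
#' and are excluded from the overlap analysis.
#'
#' @param tracks named list of wolf tracks.
#' @param corridor a [contour_region()].
#' @param min_frac inclusion threshold (fraction of fixes, `>=` rule).
#' @return character vector of retained wolf ids.
#' @export
corridor_filter <- function(tracks, corridor, min_frac = 0.05) {
  keep <- vapply(tracks, function(tr) {
    mean(region_contains(corridor, tr$x, tr$y)) >= min_frac
  }, logical(1))
  names(tracks)[keep]
}

#' Split a track into wolf-season subsets
#'
#' Fixes are assigned to seasons (and monitoring years); subsets with fewer
#' than `min_locs` locations (about one week of 4-h monitoring) are dropped.
#'
#' @param tr a [track()].
#' @param windows a [season_windows()].
#' @param min_locs minimum locations per wolf-season (`>=` rule).
#' @return named list of tracks, keys `"<season>.<year>"`.
#' @export
season_filter <- function(tr, windows, min_locs = 50) {
  seas <- season_of(tr$timestamp, windows)
  yr <- study_year(tr$timestamp)
  key <- paste(seas, yr, sep = ".")
  out <- list()
  for (k in unique(key)) {
    idx <- key == k
    if (sum(idx) >= min_locs) out[[k]] <- track_slice(tr, idx)
  }
  out
}

#' Proportional overlap of a predator region with a prey region
#'
#' Area of the intersection divided by the predator region's area, computed
#' exactly on the shared cell grid; in \[0, 1\].
#'
#' @param wolf_region,prey_region [contour_region()]s on the same grid.
#' @export
proportional_overlap <- function(wolf_region, prey_region) {
  nw <- sum(wolf_region$mask)
  if (nw == 0L) stop("zero-area predator region")
  mask_overlap_cells(wolf_region, prey_region) / nw
}

#' Capped logit transform for bounded proportions
#'
#' Proportions above `hi` or below `lo` are capped before the logit so that
#' complete (or zero) overlap stays finite.
#'
#' @param p proportion(s) in \[0, 1\].
#' @param lo,hi caps.
#' @export
logit_cap <- function(p, lo = 0.025, hi = 0.975) {
  q <- pmin(pmax(p, lo), hi)
  log(q / (1 - q))
}

#' Assign a wolf's pack covariate
#'
#' Wolves whose year-round 95% range exceeds `area_threshold` are floaters
#' (`"FL"`) regardless of geography; otherwise the observed geographic pack
#' label is kept (strict `>` rule at the threshold).
#'
#' @param area_km2 year-round 95% range area (km^2).
#' @param observed_pack geographic pack label.
#' @param area_threshold floater threshold (km^2).
#' @export
assign_pack <- function(area_km2, observed_pack, area_threshold = 561) {
  ifelse(area_km2 > area_threshold, "FL", observed_pack)
}

#' Fit one seasonal overlap model
#'
#' Ordinary least squares of logit proportional overlap on season, sex and
#' pack (all categorical), with winter, female and FL as the reference
#' levels. One model is fitted per prey distribution.
#'
#' @param records data.frame with columns `logit_value`, `season`, `sex`,
#'   `pack`.
#' @param covariates nuisance covariates to include beside season.
#' @return list of class `"overlap_fit"`: `table` (term, estimate, se,
#'   p_value), and the underlying `lm` fit.
#' @export
fit_overlap_model <- function(records, covariates = c("sex", "pack")) {
  stopifnot(all(c("logit_value", "season", "sex", "pack") %in% names(records)))
  if (length(unique(records$season)) < 2L) stop("need >= 2 seasons represented")
  records$season <- stats::relevel(factor(records$season), ref = "winter")
  records$sex <- stats::relevel(factor(records$sex), ref = "F")
  if ("FL" %in% records$pack) {
    records$pack <- stats::relevel(factor(records$pack), ref = "FL")
  } else records$pack <- factor(records$pack)
  form <- stats::reformulate(c("season", covariates), response = "logit_value")
  # drop constant covariates rather than fit a rank-deficient design
  for (v in covariates) {
    if (length(unique(records[[v]])) < 2L) form <- stats::update(form, paste("~ . -", v))
  }
  fit <- stats::lm(form, data = records)
  if (any(is.na(stats::coef(fit)))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("rank-deficient design; offending term(s): ", paste(bad, collapse = ", "))
  }
  sm <- summary(fit)$coefficients
  list(table = data.frame(term = rownames(sm), estimate = sm[, 1],
                          se = sm[, 2], p_value = sm[, 4],
                          row.names = NULL, stringsAsFactors = FALSE),
       fit = fit)
}

# exact conditional distribution of the rank-sum statistic over all
# choose(n, nA) group assignments, via dynamic programming on doubled
# midranks (integer-valued); equivalent to full enumeration.
mw_exact_dist <- function(ranks2, nA) {
  n <- length(ranks2)
  maxs <- sum(sort(ranks2, decreasing = TRUE)[seq_len(nA)])
  # f[a+1, s+1] = number of size-a subsets with doubled rank sum s
  f <- matrix(0, nA + 1L, maxs + 1L)
  f[1L, 1L] <- 1
  for (r in ranks2) {
    amax <- nA
    for (a in rev(seq_len(amax))) {
      src <- f[a, ]
      if (all(src == 0)) next
      shifted <- c(rep(0, r), src)[seq_len(maxs + 1L)]
      f[a + 1L, ] <- f[a + 1L, ] + shifted
    }
  }
  f[nA + 1L, ]
}

#' Mann-Whitney rank test with midranks and exact ties handling
#'
#' Returns the Mann-Whitney U statistic for the first group (rank sum of A
#' minus its minimum, midranks for ties) and a two-sided p-value. For small
#' samples (`nA * nB <= exact_limit`) the p-value is exact, computed from
#' the full conditional permutation distribution of the statistic given the
#' observed values; otherwise a normal approximation with tie correction and
#' continuity correction is used. Both group orientations are reported.
#'
#' @param a,b numeric vectors.
#' @param exact_limit threshold on `nA * nB` for the exact computation.
#' @return list: `W` (U for the first group), `W_b` (other orientation),
#'   `p_value`, `method`.
#' @export
mann_whitney <- function(a, b, exact_limit = 400) {
  nA <- length(a); nB <- length(b)
  if (nA == 0L || nB == 0L) stop("both groups must be nonempty")
  pooled <- c(a, b)
  rk <- rank(pooled)  # midranks
  wA <- sum(rk[seq_len(nA)]) - nA * (nA + 1) / 2
  wB <- nA * nB - wA
  if (nA * nB <= exact_limit) {
    ranks2 <- as.integer(round(2 * rk))
    f <- mw_exact_dist(ranks2, nA)
    total <- sum(f)
    s2 <- seq_along(f) - 1L  # doubled rank sums
    u2 <- s2 - nA * (nA + 1)  # doubled U values
    mu2 <- sum(u2 * f) / total
    obs <- abs(2 * wA - mu2)
    p <- sum(f[abs(u2 - mu2) >= obs - 1e-9]) / total
    method <- "exact"
  } else {
    mu <- nA * nB / 2
    ties <- table(rk)
    n <- nA + nB
    sig2 <- nA * nB / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    z <- (abs(wA - mu) - 0.5) / sqrt(sig2)
    p <- 2 * stats::pnorm(z, lower.tail = FALSE)
    method <- "normal"
  }
  list(W = wA, W_b = wB, p_value = min(1, p), method = method)
}

#' Build the wolf-season overlap record table
#'
#' Applies the corridor and season filters, computes each retained
#' wolf-season's 95% UD region, its proportional overlap with every prey
#' distribution, the capped logit, and the pack covariate (floaters
#' reassigned by year-round range area).
#'
#' @param wolf_tracks named list of wolf tracks (post-QC).
#' @param distributions output of [build_all_distributions()].
#' @param windows a [season_windows()].
#' @param params a [bbmm_params()].
#' @param min_frac corridor-inclusion threshold.
#' @param min_locs wolf-season location floor.
#' @param level UD contour level.
#' @param seasonal optional [seasonal_rasters()] output; matching wolf-season
#'   rasters are reused instead of being refitted.
#' @return data.frame of overlap records (one row per wolf-season x prey).
#' @export
overlap_records <- function(wolf_tracks, distributions, windows,
                            params = bbmm_params(), min_frac = 0.05,
                            min_locs = 50, level = 0.95, seasonal = NULL) {
  dist <- distributions$distributions
  if (is.null(dist$corridor)) stop("corridor distribution missing; build it first")
  keep_ids <- corridor_filter(wolf_tracks, dist$corridor$contour95, min_frac)
  prey_keys <- c(moose = "moose", corridor = "corridor", deer = "deer",
                 deer_migratory = "deer_migratory", deer_resident = "deer_resident")
  rows <- list()
  for (id in keep_ids) {
    tr <- wolf_tracks[[id]]
    # year-round range area for the pack covariate
    yr_region <- tryCatch({
      ud <- occurrence_distribution(tr, params)
      contour_region(ud, level)
    }, error = function(e) NULL)
    if (is.null(yr_region)) next
    pack <- assign_pack(yr_region$area_km2, tr$pack[1])
    subsets <- season_filter(tr, windows, min_locs)
    for (key in names(subsets)) {
      sub <- subsets[[key]]
      parts <- strsplit(key, ".", fixed = TRUE)[[1]]
      season <- parts[1]
      cached <- NULL
      if (!is.null(seasonal) && nrow(seasonal$meta)) {
        hit <- which(seasonal$meta$id == id & seasonal$meta$season == season &
                       seasonal$meta$year == parts[2])
        if (length(hit) == 1L) cached <- seasonal$rasters[[hit]]
      }
      region <- tryCatch({
        ud <- if (!is.null(cached)) cached else occurrence_distribution(sub, params)
        contour_region(ud, level)
      }, error = function(e) NULL)
      if (is.null(region)) next
      for (pk in names(prey_keys)) {
        prey_name <- if (pk == "corridor") "corridor" else paste(prey_keys[[pk]], season, sep = ".")
        prey <- dist[[prey_name]]
        if (is.null(prey)) next
        p <- proportional_overlap(region, prey$contour95)
        rows[[length(rows) + 1L]] <- data.frame(
          id = id, season = season, year = strsplit(key, ".", fixed = TRUE)[[1]][2],
          prey = pk, proportion = p, logit_value = logit_cap(p),
          sex = tr$sex[1], pack = pack, n_locations = nrow(sub),
          wolf_area_km2 = region$area_km2, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) return(data.frame())
  do.call(rbind, rows)
}

#' Fit the five per-prey overlap models
#'
#' In small samples the nuisance covariates can be aliased with each other
#' (e.g. one wolf per pack makes sex a linear combination of pack); each
#' model is then refitted with a reduced nuisance set (pack only, sex only,
#' then season only) so the seasonal contrasts of interest stay estimable.
#'
#' @param records output of [overlap_records()].
#' @return named list of [fit_overlap_model()] results (one per prey label
#'   present in the records).
#' @export
fit_all_overlap_models <- function(records) {
  out <- list()
  for (pk in unique(records$prey)) {
    rec <- records[records$prey == pk, , drop = FALSE]
    fit <- NULL
    for (cov in list(c("sex", "pack"), "pack", "sex", character(0))) {
      fit <- tryCatch(fit_overlap_model(rec, covariates = cov),
                      error = function(e) NULL)
      if (!is.null(fit)) break
    }
    out[[pk]] <- fit
  }
  out
}
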