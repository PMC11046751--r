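#' Cell-wise mean of probability rasters
#'
#' Arithmetic mean of the cell masses, renormalized to total mass 1. All
#' rasters must sit on the same resolution lattice (which every grid built
#' by [bbmm_grid()] at a given resolution does); extents may differ, and the
#' result covers their union. No resampling is ever performed.
#'
#' @param rasters list of [prob_raster()]s.
#' @export
mean_merge <- function(rasters) {
  if (!length(rasters)) stop("mean_merge of an empty list")
  g <- union_grid(lapply(rasters, `[[`, "grid"))
  acc <- matrix(0, g$nx, g$ny)
  for (r in rasters) acc <- accumulate_block(acc, g, r$mass, r$grid)
  prob_raster(g, acc / length(rasters))
}

# count of cells in the intersection of two region masks (lattice-aligned)
mask_overlap_cells <- function(a, b) {
  if (!same_lattice(a$grid, b$grid)) stop("regions on different lattices")
  off <- grid_offset(a$grid, b$grid)
  ixa <- seq_len(b$grid$nx) + off["ix"]
  iya <- seq_len(b$grid$ny) + off["iy"]
  ok_x <- which(ixa >= 1L & ixa <= a$grid$nx)
  ok_y <- which(iya >= 1L & iya <= a$grid$ny)
  if (!length(ok_x) || !length(ok_y)) return(0L)
  sum(a$mask[ixa[ok_x], iya[ok_y], drop = FALSE] &
        b$mask[ok_x, ok_y, drop = FALSE])
}

#' Hierarchical population-level seasonal distribution
#'
#' Three-level merge of individual-season rasters: (1) individuals within a
#' season-year are averaged into a season-year population distribution, then
#' (2, 3) season-year distributions are averaged across years into the final
#' population-level distribution. The hierarchy matters: a year with many
#' individuals carries the same weight as a year with one.
#'
#' @param rasters list of [prob_raster()]s.
#' @param animal,year character/integer vectors parallel to `rasters`.
#' @param level contour level for the attached boundary.
#' @return list of class `"distribution_set"`: `raster`, `contour95`,
#'   `n_individuals`, `n_years`, and the per-year rasters (`year_rasters`).
#' @export
build_population_distribution <- function(rasters, animal, year, level = 0.95) {
  stopifnot(length(rasters) >= 1L, length(animal) == length(rasters),
            length(year) == length(rasters))
  yr_r <- lapply(split(seq_along(rasters), as.character(year)), function(ii) {
    mean_merge(rasters[ii])
  })
  final <- mean_merge(yr_r)
  structure(list(raster = final, contour95 = contour_region(final, level),
                 n_individuals = length(unique(animal)),
                 n_years = length(yr_r), year_rasters = yr_r),
            class = "distribution_set")
}

#' Migration corridor distribution
#'
#' Merges the spring and fall season-year population distributions within
#' each year, then across years; the corridor is a single non-seasonal
#' distribution. Both seasons must be represented.
#'
#' @param spring_year_rasters,fall_year_rasters named lists of season-year
#'   population rasters keyed by year.
#' @param level contour level.
#' @export
build_corridor <- function(spring_year_rasters, fall_year_rasters, level = 0.95) {
  if (!length(spring_year_rasters) || !length(fall_year_rasters)) {
    stop("corridor requires both spring and fall season-year rasters")
  }
  yrs <- union(names(spring_year_rasters), names(fall_year_rasters))
  yr_merged <- lapply(yrs, function(y) {
    both <- c(spring_year_rasters[y], fall_year_rasters[y])
    mean_merge(both[!vapply(both, is.null, logical(1))])
  })
  final <- mean_merge(yr_merged)
  structure(list(raster = final, contour95 = contour_region(final, level),
                 n_individuals = NA_integer_, n_years = length(yrs),
                 year_rasters = yr_merged, non_seasonal = TRUE),
            class = "distribution_set")
}

#' Overlap between two contour regions
#'
#' Area of the intersection divided by, under the default, the smaller
#' region's area (alternatives: the union's area, or the mean of the two
#' areas). Computed exactly on the shared cell grid. Symmetric in its
#' arguments under every denominator.
#'
#' @param a,b [contour_region()]s on the same grid.
#' @param denominator `"smaller"`, `"union"` or `"mean"`.
#' @return overlap fraction in \[0, 1\].
#' @export
corridor_similarity <- function(a, b, denominator = c("smaller", "union", "mean")) {
  denominator <- match.arg(denominator)
  na <- sum(a$mask); nb <- sum(b$mask)
  if (na == 0L || nb == 0L) stop("zero-area region")
  ni <- mask_overlap_cells(a, b)
  den <- switch(denominator,
                smaller = min(na, nb),
                union = sum(a$mask | b$mask),
                mean = (na + nb) / 2)
  ni / den
}

#' Corridor-use raster
#'
#' Per cell, the fraction of migratory individuals whose migration-period
#' region covers the cell -- the footprint-stacking summary used to display
#' the proportion of the migratory population traversing each area.
#'
#' @param regions list of individual [contour_region()]s on a shared grid.
#' @return list with the grid and a `use` matrix of fractions in \[0, 1\].
#' @export
corridor_use <- function(regions) {
  if (!length(regions)) stop("no regions")
  g <- union_grid(lapply(regions, `[[`, "grid"))
  acc <- matrix(0, g$nx, g$ny)
  for (r in regions) acc <- accumulate_block(acc, g, r$mask + 0, r$grid)
  list(grid = g, use = acc / length(regions))
}

#' Individual-season rasters for a set of tracks
#'
#' Splits each track by season (and monitoring year), keeps animal-season-
#' year subsets with at least `min_fixes` usable fixes (a bridge needs a
#' pair), and fits one occurrence distribution per subset on the shared
#' grid. Motion variance is estimated per individual per season.
#'
#' @param tracks named list of tracks.
#' @param windows a [season_windows()].
#' @param params a [bbmm_params()].
#' @param min_fixes minimum fixes per animal-season-year.
#' @param grid optional explicit [bbmm_grid()]; by default each raster gets
#'   its own lattice-aligned local grid (merging handles extents).
#' @return data.frame-like list: `meta` (id, season, year, n_fixes) and
#'   `rasters` (parallel list of [prob_raster()]s).
#' @export
seasonal_rasters <- function(tracks, windows, params = bbmm_params(),
                             min_fixes = 2, grid = NULL) {
  meta <- list(); rasters <- list()
  for (id in names(tracks)) {
    tr <- tracks[[id]]
    seas <- season_of(tr$timestamp, windows)
    yr <- study_year(tr$timestamp)
    for (key in unique(paste(seas, yr))) {
      idx <- paste(seas, yr) == key
      if (sum(idx) < max(min_fixes, 3L)) next
      sub <- track_slice(tr, idx)
      lags <- lag_hours(sub$timestamp)
      if (!any(lags <= params$max_lag)) next
      r <- tryCatch(occurrence_distribution(sub, params, grid), error = function(e) NULL)
      if (is.null(r)) next
      meta[[length(meta) + 1L]] <- data.frame(
        id = id, species = tr$species[1],
        season = strsplit(key, " ")[[1]][1],
        year = strsplit(key, " ")[[1]][2],
        n_fixes = sum(idx), stringsAsFactors = FALSE)
      rasters[[length(rasters) + 1L]] <- r
    }
  }
  list(meta = if (length(meta)) do.call(rbind, meta) else data.frame(),
       rasters = rasters)
}

#' All 21 population-level distributions
#'
#' Builds the final seasonal distributions for the five populations (wolf,
#' moose, composite deer, migratory deer, resident deer) across the four
#' seasons, plus the non-seasonal deer migration corridor: 21 distributions
#' in total. Deer subsets come from the movement-status table; the corridor
#' merges the migratory-deer spring and fall season-year distributions.
#'
#' @param seasonal output of [seasonal_rasters()] for all animals.
#' @param status movement-status table (id, species, status).
#' @param level contour level.
#' @return list with `distributions` (named `population.season` list of
#'   distribution sets, plus `corridor`), and `manifest` (data.frame).
#' @export
build_all_distributions <- function(seasonal, status, level = 0.95) {
  meta <- seasonal$meta
  pop_of <- function(i) {
    sp <- meta$species[i]
    if (sp != "deer") return(sp)
    st <- status$status[match(meta$id[i], status$id)]
    if (identical(st, "migratory")) "deer_migratory"
    else if (identical(st, "resident")) "deer_resident"
    else NA_character_
  }
  base_pop <- vapply(seq_len(nrow(meta)), pop_of, character(1))
  out <- list(); manifest <- list()
  mig_year_rasters <- list(spring = list(), fall = list())
  pops <- list(wolf = which(meta$species == "wolf"),
               moose = which(meta$species == "moose"),
               deer = which(meta$species == "deer" & !is.na(base_pop)),
               deer_migratory = which(base_pop == "deer_migratory"),
               deer_resident = which(base_pop == "deer_resident"))
  for (pop in names(pops)) {
    for (s in c("winter", "spring", "summer", "fall")) {
      ii <- pops[[pop]][meta$season[pops[[pop]]] == s]
      if (!length(ii)) next
      ds <- build_population_distribution(seasonal$rasters[ii],
                                          meta$id[ii], meta$year[ii], level)
      out[[paste(pop, s, sep = ".")]] <- ds
      manifest[[length(manifest) + 1L]] <- data.frame(
        population = pop, season = s, year = "all",
        n_individuals = ds$n_individuals, stringsAsFactors = FALSE)
      if (pop == "deer_migratory" && s %in% c("spring", "fall")) {
        mig_year_rasters[[s]] <- ds$year_rasters
      }
    }
  }
  if (length(mig_year_rasters$spring) && length(mig_year_rasters$fall)) {
    out$corridor <- build_corridor(mig_year_rasters$spring, mig_year_rasters$fall, level)
    manifest[[length(manifest) + 1L]] <- data.frame(
      population = "deer_migratory", season = "migration", year = "all",
      n_individuals = NA_integer_, stringsAsFactors = FALSE)
  }
  list(distributions = out, manifest = do.call(rbind, manifest))
}
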