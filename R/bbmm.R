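#' Shared analysis grid
#'
#' A planar raster grid: origin (lower-left corner of cell \[1,1\]),
#' square cell size in meters, and dimensions. The origin is snapped down to
#' the resolution lattice so independently-built rasters align and can be
#' merged without resampling.
#'
#' @param xmin,ymin,xmax,ymax bounding box (m).
#' @param resolution cell size (m), > 0.
#' @export
bbmm_grid <- function(xmin, ymin, xmax, ymax, resolution = 50) {
  stopifnot(resolution > 0, xmax > xmin, ymax > ymin)
  x0 <- floor(xmin / resolution) * resolution
  y0 <- floor(ymin / resolution) * resolution
  nx <- ceiling((xmax - x0) / resolution)
  ny <- ceiling((ymax - y0) / resolution)
  structure(list(x0 = x0, y0 = y0, nx = as.integer(nx), ny = as.integer(ny),
                 res = resolution), class = "bbmm_grid")
}

#' Grid covering a set of tracks with a margin
#'
#' @param tracks list of tracks.
#' @param margin margin beyond the bounding box (m); should exceed ~3 bridge
#'   SDs so no density mass is clipped.
#' @param resolution cell size (m).
#' @export
grid_for_tracks <- function(tracks, margin = 2000, resolution = 50) {
  if (inherits(tracks, "track")) tracks <- list(tracks)
  xs <- unlist(lapply(tracks, `[[`, "x"))
  ys <- unlist(lapply(tracks, `[[`, "y"))
  bbmm_grid(min(xs) - margin, min(ys) - margin,
            max(xs) + margin, max(ys) + margin, resolution)
}

# cell centers along each axis
grid_xc <- function(g) g$x0 + (seq_len(g$nx) - 0.5) * g$res
grid_yc <- function(g) g$y0 + (seq_len(g$ny) - 0.5) * g$res

# cell index of points; NA outside. Closed lower edge, half-open upper.
grid_cell <- function(g, x, y) {
  ix <- floor((x - g$x0) / g$res) + 1L
  iy <- floor((y - g$y0) / g$res) + 1L
  bad <- ix < 1L | ix > g$nx | iy < 1L | iy > g$ny
  ix[bad] <- NA_integer_; iy[bad] <- NA_integer_
  cbind(ix = ix, iy = iy)
}

same_grid <- function(a, b) {
  isTRUE(all.equal(c(a$x0, a$y0, a$res), c(b$x0, b$y0, b$res))) &&
    a$nx == b$nx && a$ny == b$ny
}

# two grids on the same resolution lattice (origins congruent modulo res)?
# Because bbmm_grid() snaps origins down to the lattice, any two grids built
# through it at the same resolution are compatible and can be combined by
# integer cell offsets with no resampling.
same_lattice <- function(a, b) {
  if (abs(a$res - b$res) > 1e-9) return(FALSE)
  ox <- (a$x0 - b$x0) / a$res
  oy <- (a$y0 - b$y0) / a$res
  abs(ox - round(ox)) < 1e-6 && abs(oy - round(oy)) < 1e-6
}

# smallest grid covering both (same lattice required)
union_grid <- function(grids) {
  g1 <- grids[[1]]
  for (g in grids[-1]) if (!same_lattice(g1, g)) stop("grid lattice mismatch")
  x0 <- min(vapply(grids, `[[`, 0, "x0"))
  y0 <- min(vapply(grids, `[[`, 0, "y0"))
  x1 <- max(vapply(grids, function(g) g$x0 + g$nx * g$res, 0))
  y1 <- max(vapply(grids, function(g) g$y0 + g$ny * g$res, 0))
  structure(list(x0 = x0, y0 = y0,
                 nx = as.integer(round((x1 - x0) / g1$res)),
                 ny = as.integer(round((y1 - y0) / g1$res)),
                 res = g1$res), class = "bbmm_grid")
}

# integer cell offset of grid b's origin within grid a
grid_offset <- function(a, b) {
  c(ix = as.integer(round((b$x0 - a$x0) / a$res)),
    iy = as.integer(round((b$y0 - a$y0) / a$res)))
}

# add matrix `m` on grid `gm` into accumulator `acc` on grid `gacc`
accumulate_block <- function(acc, gacc, m, gm) {
  off <- grid_offset(gacc, gm)
  ix <- seq_len(nrow(m)) + off["ix"]
  iy <- seq_len(ncol(m)) + off["iy"]
  ok_x <- ix >= 1L & ix <= gacc$nx
  ok_y <- iy >= 1L & iy <= gacc$ny
  acc[ix[ok_x], iy[ok_y]] <- acc[ix[ok_x], iy[ok_y]] + m[ok_x, ok_y, drop = FALSE]
  acc
}

#' Probability raster
#'
#' Per-cell probability mass on a [bbmm_grid()]; total mass 1 (+- 1e-6).
#'
#' @param grid a [bbmm_grid()].
#' @param mass `nx` x `ny` matrix of non-negative cell masses.
#' @export
prob_raster <- function(grid, mass) {
  stopifnot(inherits(grid, "bbmm_grid"),
            nrow(mass) == grid$nx, ncol(mass) == grid$ny,
            all(mass >= 0))
  tot <- sum(mass)
  if (tot <= 0) stop("raster has no mass")
  structure(list(grid = grid, mass = mass / tot), class = "prob_raster")
}

#' @export
print.prob_raster <- function(x, ...) {
  cat(sprintf("<prob_raster> %d x %d cells @ %g m, mass %.6f\n",
              x$grid$nx, x$grid$ny, x$grid$res, sum(x$mass)))
  invisible(x)
}

#' BBMM parameters
#'
#' @param motion_variance Brownian motion variance sigma^2_m (m^2/h); `NA`
#'   means estimate from the track.
#' @param location_error_sd GPS location error SD delta (m).
#' @param max_lag maximum lag between paired fixes (h); longer gaps are
#'   skipped so that a single missed relocation does not bridge unrelated
#'   positions.
#' @param resolution grid cell size (m).
#' @param n_quad time-quadrature points per bridge segment.
#' @export
bbmm_params <- function(motion_variance = NA_real_, location_error_sd = 20,
                        max_lag = 9, resolution = 50, n_quad = 10) {
  stopifnot(is.na(motion_variance) || motion_variance >= 0,
            max_lag > 0, resolution > 0, n_quad >= 2)
  structure(as.list(environment()), class = "bbmm_params")
}

#' Estimate the Brownian motion variance
#'
#' Leave-one-out maximum likelihood: each even-indexed fix is modeled as a
#' draw from the Brownian-bridge normal density implied by its two
#' neighbors -- mean on the connecting line at time fraction
#' `alpha = (t - t0)/(t1 - t0)`, per-coordinate variance
#' `T * alpha * (1-alpha) * sigma2m + ((1-alpha)^2 + alpha^2) * delta^2` --
#' and `sigma2m` maximizes the product of those densities (1-D bounded
#' optimization on a log grid then golden-section refinement via
#' `stats::optimize`).
#'
#' @param tr a [track()].
#' @param location_error_sd GPS error SD delta (m).
#' @param max_lag maximum neighbor-to-neighbor lag (h); triplets spanning
#'   longer gaps are excluded.
#' @return estimated sigma^2_m in m^2/h.
#' @export
estimate_motion_variance <- function(tr, location_error_sd = 20, max_lag = 9) {
  n <- nrow(tr)
  if (n < 3L) stop("need >= 3 fixes")
  tn <- as.numeric(tr$timestamp) / 3600   # hours
  mid <- seq(2L, n - 1L, by = 2L)
  a_i <- mid - 1L; b_i <- mid + 1L
  Tt <- tn[b_i] - tn[a_i]
  ok <- Tt <= 2 * max_lag & Tt > 0
  if (!any(ok)) stop("no usable triplets within max lag")
  mid <- mid[ok]; a_i <- a_i[ok]; b_i <- b_i[ok]; Tt <- Tt[ok]
  alpha <- (tn[mid] - tn[a_i]) / Tt
  mx <- tr$x[a_i] + alpha * (tr$x[b_i] - tr$x[a_i])
  my <- tr$y[a_i] + alpha * (tr$y[b_i] - tr$y[a_i])
  rx <- tr$x[mid] - mx; ry <- tr$y[mid] - my
  err_var <- ((1 - alpha)^2 + alpha^2) * location_error_sd^2
  bridge_t <- Tt * alpha * (1 - alpha)
  negll <- function(s2) {
    v <- bridge_t * s2 + err_var
    sum(log(v) + (rx^2 + ry^2) / (2 * v))
  }
  # bracket on a log grid, then refine
  grid <- 10^seq(-3, 7, by = 0.5)
  vals <- vapply(grid, negll, numeric(1))
  k <- which.min(vals)
  lo <- grid[max(1L, k - 1L)]; hi <- grid[min(length(grid), k + 1L)]
  stats::optimize(negll, c(lo, hi))$minimum
}

# Gauss-Legendre nodes/weights on (0, 1)
gauss_legendre01 <- function(n) {
  # Golub-Welsch via the symmetric tridiagonal Jacobi matrix
  k <- seq_len(n - 1L)
  b <- k / sqrt(4 * k^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(k, k + 1L)] <- b
  J[cbind(k + 1L, k)] <- b
  e <- eigen(J, symmetric = TRUE)
  x <- e$values
  w <- 2 * e$vectors[1, ]^2
  list(nodes = (x + 1) / 2, weights = w / 2)
}

#' Brownian bridge occurrence distribution
#'
#' For each consecutive pair of fixes with lag <= `max_lag`, the Brownian
#' bridge's time-integrated normal density is accumulated onto the grid by
#' Gauss-Legendre quadrature in time (`n_quad` points per segment); segments
#' are weighted by their duration and the raster is normalized to total
#' mass 1. At quadrature fraction `a` the density is isotropic normal with
#' mean on the connecting line and per-coordinate variance
#' `T*a*(1-a)*sigma2m + ((1-a)^2 + a^2)*delta^2`. Each Gaussian is evaluated
#' on a local window of +-4.5 SD and integrated per cell via the error
#' function, so mass is conserved to well under 1e-6.
#'
#' @param tr a [track()].
#' @param params a [bbmm_params()]; if `motion_variance` is `NA` it is
#'   estimated with [estimate_motion_variance()].
#' @param grid a [bbmm_grid()]; default covers the track with a margin.
#' @return a [prob_raster()].
#' @export
occurrence_distribution <- function(tr, params = bbmm_params(), grid = NULL) {
  s2 <- params$motion_variance
  if (is.na(s2)) s2 <- estimate_motion_variance(tr, params$location_error_sd, params$max_lag)
  delta <- params$location_error_sd
  tn <- as.numeric(tr$timestamp) / 3600
  lags <- diff(tn)
  use <- which(lags <= params$max_lag & lags > 0)
  if (!length(use)) stop("no consecutive pair within max lag")
  if (is.null(grid)) {
    margin <- 4.5 * sqrt(max(lags[use]) / 4 * s2 + delta^2) + 3 * delta
    grid <- grid_for_tracks(tr, margin = max(margin, 250), resolution = params$resolution)
  }
  gq <- gauss_legendre01(params$n_quad)
  # flatten all (segment, quadrature-node) Gaussians, then accumulate in the
  # compiled kernel (exact per-cell normal integrals on a +-4.5 SD window)
  a <- gq$nodes
  Tt <- lags[use]
  mx <- as.vector(outer(tr$x[use], rep(1, length(a))) +
                    outer(tr$x[use + 1L] - tr$x[use], a))
  my <- as.vector(outer(tr$y[use], rep(1, length(a))) +
                    outer(tr$y[use + 1L] - tr$y[use], a))
  vv <- as.vector(outer(Tt, a * (1 - a)) * s2 +
                    rep(((1 - a)^2 + a^2) * delta^2, each = length(use)))
  wv <- as.vector(outer(Tt, gq$weights))   # duration weighting
  mass <- matrix(0, grid$nx, grid$ny)
  .accumulate_gaussians(mass, grid$x0, grid$y0, grid$res, mx, my, sqrt(vv), wv)
  prob_raster(grid, mass)
}

#' Probability contour region
#'
#' The smallest set of grid cells whose cumulative mass reaches `level`:
#' cells are sorted by mass descending and the minimal prefix kept. Cells
#' tied at the cutoff mass are, by default, admitted only as far as needed
#' (deterministic row-major order), so the uniform-density case yields
#' exactly `ceiling(level * n)` cells; `ties = "all"` admits every tied cell
#' (mass may then exceed `level`).
#'
#' @param raster a [prob_raster()].
#' @param level probability level in (0, 1).
#' @param ties `"minimal"` or `"all"`.
#' @return object of class `"contour_region"`: the grid, a logical cell
#'   mask, the level, the enclosed mass, and the area in km^2.
#' @export
contour_region <- function(raster, level = 0.95, ties = c("minimal", "all")) {
  stopifnot(level > 0, level < 1)
  ties <- match.arg(ties)
  m <- as.vector(raster$mass)
  if (sum(m > 0) == 0L) stop("degenerate raster: no cell carries mass")
  ord <- order(m, decreasing = TRUE)  # stable: ties in cell-index order
  cum <- cumsum(m[ord])
  k <- which(cum >= level - 1e-12)[1]
  if (is.na(k)) k <- length(ord)
  if (ties == "all") {
    cutoff <- m[ord[k]]
    k <- max(which(m[ord] >= cutoff))
  }
  mask <- matrix(FALSE, raster$grid$nx, raster$grid$ny)
  mask[ord[seq_len(k)]] <- TRUE
  structure(list(grid = raster$grid, mask = mask, level = level,
                 mass = cum[k],
                 area_km2 = k * raster$grid$res^2 / 1e6),
            class = "contour_region")
}

#' @export
print.contour_region <- function(x, ...) {
  cat(sprintf("<contour_region> level %.2f, %d cells, %.3f km^2, mass %.4f\n",
              x$level, sum(x$mask), x$area_km2, x$mass))
  invisible(x)
}

#' Point-in-region test
#'
#' Regions are closed: a point in any cell of the mask (cell membership:
#' closed lower edge) counts as inside.
#'
#' @param region a [contour_region()].
#' @param x,y point coordinates (m).
#' @return logical vector.
#' @export
region_contains <- function(region, x, y) {
  ij <- grid_cell(region$grid, x, y)
  inside <- rep(FALSE, length(x))
  ok <- !is.na(ij[, 1])
  inside[ok] <- region$mask[ij[ok, , drop = FALSE]]
  inside
}

#' Boundary polygons of a contour region
#'
#' Traces the exterior edges of the kept cell set into closed rings
#' (rectilinear polygons; holes are rings wound opposite to their shell).
#' Used for plain-text export of region outlines.
#'
#' @param region a [contour_region()].
#' @return list of matrices with columns x, y (closed rings).
#' @export
region_polygons <- function(region) {
  g <- region$grid; m <- region$mask
  res <- g$res
  # collect boundary edges as directed segments keeping region on the left
  edges <- list()
  idx <- which(m, arr.ind = TRUE)
  for (r in seq_len(nrow(idx))) {
    i <- idx[r, 1]; j <- idx[r, 2]
    x0 <- g$x0 + (i - 1) * res; y0 <- g$y0 + (j - 1) * res
    if (j == 1L || !m[i, j - 1L])      edges[[length(edges) + 1L]] <- c(x0, y0, x0 + res, y0)
    if (i == g$nx || !m[i + 1L, j])    edges[[length(edges) + 1L]] <- c(x0 + res, y0, x0 + res, y0 + res)
    if (j == g$ny || !m[i, j + 1L])    edges[[length(edges) + 1L]] <- c(x0 + res, y0 + res, x0, y0 + res)
    if (i == 1L || !m[i - 1L, j])      edges[[length(edges) + 1L]] <- c(x0, y0 + res, x0, y0)
  }
  if (!length(edges)) return(list())
  E <- do.call(rbind, edges)
  from <- paste(E[, 1], E[, 2]); to <- paste(E[, 3], E[, 4])
  nxt <- split(seq_len(nrow(E)), from)
  used <- rep(FALSE, nrow(E))
  rings <- list()
  for (e0 in seq_len(nrow(E))) {
    if (used[e0]) next
    ring <- list(E[e0, 1:2])
    cur <- e0
    repeat {
      used[cur] <- TRUE
      ring[[length(ring) + 1L]] <- E[cur, 3:4]
      cand <- nxt[[to[cur]]]
      cand <- cand[!used[cand]]
      if (!length(cand)) break
      cur <- cand[1]
    }
    rings[[length(rings) + 1L]] <- do.call(rbind, ring)
  }
  lapply(rings, function(r) { colnames(r) <- c("x", "y"); r })
}

#' Write a probability raster as an ESRI-ASCII grid
#'
#' @param raster a [prob_raster()].
#' @param path output file.
#' @export
write_ascii_grid <- function(raster, path) {
  g <- raster$grid
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", g$nx), sprintf("nrows %d", g$ny),
    sprintf("xllcorner %.3f", g$x0), sprintf("yllcorner %.3f", g$y0),
    sprintf("cellsize %.3f", g$res), "NODATA_value -9999"), con)
  # ESRI-ASCII rows run north to south
  for (j in rev(seq_len(g$ny))) {
    writeLines(paste(formatC(raster$mass[, j], format = "g", digits = 8),
                     collapse = " "), con)
  }
  invisible(path)
}

#' Read an ESRI-ASCII grid into a probability raster
#' @param path file written by [write_ascii_grid()].
#' @export
read_ascii_grid <- function(path) {
  hdr <- readLines(path, n = 6L)
  val <- function(k) as.numeric(strsplit(hdr[k], " +")[[1]][2])
  nx <- as.integer(val(1)); ny <- as.integer(val(2))
  g <- structure(list(x0 = val(3), y0 = val(4), nx = nx, ny = ny, res = val(5)),
                 class = "bbmm_grid")
  dat <- scan(path, skip = 6L, quiet = TRUE)
  m <- matrix(dat, nrow = ny, ncol = nx, byrow = TRUE)
  prob_raster(g, t(m[rev(seq_len(ny)), , drop = FALSE]))
}
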