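#' GPS relocation tracks
#'
#' A track is a time-ordered table of relocations for a single animal with
#' identity covariates. Coordinates are planar meters in an arbitrary local
#' projection; at the spatial scale of a single study area (a few tens of km)
#' planar distances are used throughout and no geodesy is performed.
#'
#' @param id animal identifier (scalar character).
#' @param timestamp `POSIXct` (UTC) fix times, strictly increasing.
#' @param x,y numeric coordinates in meters.
#' @param species one of `"deer"`, `"moose"`, `"wolf"`.
#' @param sex `"F"` or `"M"`.
#' @param pack pack label (`"NE"`, `"NW"`, `"SW"`, `"FL"`) or `NA` for
#'   non-territorial species.
#'
#' @return A `data.frame` of class `"track"` with columns
#'   `id, species, sex, pack, timestamp, x, y`.
#' @export
track <- function(id, timestamp, x, y, species = "deer", sex = "F", pack = NA_character_) {
  stopifnot(length(id) == 1L, inherits(timestamp, "POSIXct"),
            length(timestamp) == length(x), length(x) == length(y))
  if (is.unsorted(as.numeric(timestamp), strictly = TRUE)) {
    stop("track timestamps must be strictly increasing")
  }
  out <- data.frame(
    id = as.character(id),
    species = as.character(species),
    sex = as.character(sex),
    pack = as.character(pack),
    timestamp = timestamp,
    x = as.numeric(x),
    y = as.numeric(y),
    stringsAsFactors = FALSE
  )
  class(out) <- c("track", "data.frame")
  out
}

#' @export
print.track <- function(x, ...) {
  cat(sprintf("<track> %s (%s), %d fixes, %s .. %s\n",
              x$id[1], x$species[1], nrow(x),
              format(min(x$timestamp)), format(max(x$timestamp))))
  invisible(x)
}

as_track <- function(df) {
  stopifnot(all(c("id", "species", "sex", "pack", "timestamp", "x", "y") %in% names(df)))
  df <- df[order(df$timestamp), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("track", "data.frame")
  df
}

# subset rows of a track, preserving class
track_slice <- function(tr, keep) {
  out <- tr[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("track", "data.frame")
  out
}

#' Read and write delimited track tables
#'
#' Tracks are exchanged as tab-separated text with columns
#' `id, species, sex, pack, timestamp (ISO-8601 UTC), x_m, y_m`.
#'
#' @param tracks list of [track()] objects (or one track).
#' @param path file path.
#' @export
write_tracks <- function(tracks, path) {
  if (inherits(tracks, "track")) tracks <- list(tracks)
  df <- do.call(rbind, lapply(tracks, as.data.frame))
  df$timestamp <- format(df$timestamp, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  names(df)[names(df) == "x"] <- "x_m"
  names(df)[names(df) == "y"] <- "y_m"
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_tracks
#' @return `read_tracks()` returns a named list of tracks, one per animal id.
#' @export
read_tracks <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                          colClasses = c(pack = "character"))
  df$timestamp <- as.POSIXct(df$timestamp, format = "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  names(df)[names(df) == "x_m"] <- "x"
  names(df)[names(df) == "y_m"] <- "y"
  split_df <- split(df, df$id)
  lapply(split_df, as_track)
}

# hours between consecutive timestamps
lag_hours <- function(timestamp) {
  diff(as.numeric(timestamp)) / 3600
}

# Day-of-monitoring-year: days elapsed since the most recent 13 February
# (the monitoring-year origin; first fractional day = 0).
study_doy <- function(timestamp) {
  lt <- as.POSIXlt(timestamp, tz = "UTC")
  yr <- lt$year + 1900L
  feb13 <- as.POSIXct(sprintf("%d-02-13", yr), tz = "UTC")
  before <- timestamp < feb13
  feb13[before] <- as.POSIXct(sprintf("%d-02-13", yr[before] - 1L), tz = "UTC")
  as.numeric(timestamp - feb13, units = "days")
}

# Monitoring year label: the calendar year containing the most recent 13 Feb.
study_year <- function(timestamp) {
  lt <- as.POSIXlt(timestamp, tz = "UTC")
  yr <- lt$year + 1900L
  feb13 <- as.POSIXct(sprintf("%d-02-13", yr), tz = "UTC")
  ifelse(timestamp < feb13, yr - 1L, yr)
}

# Calendar day-of-year on a fixed non-leap template (29 Feb maps to 28 Feb),
# so season windows partition exactly 365 days in every year.
calendar_doy <- function(timestamp) {
  lt <- as.POSIXlt(timestamp, tz = "UTC")
  mon <- lt$mon + 1L
  mday <- lt$mday
  mday[mon == 2L & mday == 29L] <- 28L
  cum <- c(0L, cumsum(c(31L, 28L, 31L, 30L, 31L, 30L, 31L, 31L, 30L, 31L, 30L)))
  cum[mon] + mday
}

# doy (1..365, non-leap template) -> "d Month" label
doy_to_date <- function(doy) {
  format(as.Date("2018-12-31") + doy, "%d %B")
}

# "4 April"-style label or Date -> non-leap doy
date_to_doy <- function(date) {
  if (!inherits(date, "Date")) {
    date <- as.Date(paste(date, "2019"), format = "%d %B %Y")
  }
  calendar_doy(as.POSIXct(as.character(date), tz = "UTC"))
}
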