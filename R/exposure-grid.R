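# Daily exposure surface on a regular lat/lon centroid grid.
#
# Internally a grid is a list:
#   cells : data.frame(cell_id, lat, lon), sorted lexicographically by
#           (lat, lon) so that ties in the nearest-neighbour search resolve
#           to the lexicographically smallest centroid,
#   dates : sorted Date vector,
#   tmax, tdew, hmax : numeric matrices [cell, date]; NA marks a cell-day the
#           grid does not cover (queried NAs are an error, never silent),
#   humidity : "rh" or "dewpoint", recording what the source supplied.

#' Build a daily exposure grid from long-format weather data
#'
#' @param data Data frame with columns `date` (Date or ISO-8601 character),
#'   `lat`, `lon` (WGS84 decimal degrees of cell centroids), `tmax_c` (daily
#'   maximum air temperature, degC) and either `rh_pct` (mean relative
#'   humidity, percent) or `tdew_c` (mean dew point, degC).
#' @param check_regular If `TRUE`, assert the centroids lie on a regular
#'   1/16-degree lattice in both axes.
#' @return An object of class `exposure_grid` carrying the derived daily
#'   maximum Humidex (`hmax`) for every covered cell-day.
#' @export
exposure_grid <- function(data, check_regular = FALSE) {
  need <- c("date", "lat", "lon", "tmax_c")
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols)) {
    stop("exposure_grid: missing columns: ", paste(missing_cols, collapse = ", "))
  }
  has_rh <- "rh_pct" %in% names(data)
  has_td <- "tdew_c" %in% names(data)
  if (!has_rh && !has_td) {
    stop("exposure_grid: need a humidity column, either rh_pct or tdew_c")
  }
  date <- as.Date(data$date)
  key <- paste(data$lat, data$lon, date)
  if (anyDuplicated(key)) stop("exposure_grid: duplicate (cell, date) rows")

  cells <- unique(data.frame(lat = data$lat, lon = data$lon))
  cells <- cells[order(cells$lat, cells$lon), , drop = FALSE]
  cells <- data.frame(cell_id = seq_len(nrow(cells)),
                      lat = cells$lat, lon = cells$lon)
  if (check_regular) {
    step <- 1 / 16
    for (ax in c("lat", "lon")) {
      u <- sort(unique(cells[[ax]]))
      if (length(u) > 1 && any(abs(diff(u) %% step) > 1e-9 &
                               abs(diff(u) %% step - step) > 1e-9)) {
        stop("exposure_grid: centroid spacing along ", ax,
             " is not a multiple of 1/16 degree")
      }
    }
  }
  dates <- sort(unique(date))

  ci <- match(paste(data$lat, data$lon), paste(cells$lat, cells$lon))
  di <- match(date, dates)
  dims <- c(nrow(cells), length(dates))
  tmax <- matrix(NA_real_, dims[1], dims[2])
  tmax[cbind(ci, di)] <- data$tmax_c
  tdew <- matrix(NA_real_, dims[1], dims[2])
  if (has_td) {
    tdew[cbind(ci, di)] <- data$tdew_c
    humidity <- "dewpoint"
  } else {
    tdew[cbind(ci, di)] <- dewpoint_from_rh(data$tmax_c, data$rh_pct)
    humidity <- "rh"
  }
  hmax <- matrix(NA_real_, dims[1], dims[2])
  ok <- !is.na(tmax)
  hmax[ok] <- humidex(tmax[ok], pmin(tdew[ok], tmax[ok]))

  structure(
    list(cells = cells, dates = dates, tmax = tmax, tdew = tdew,
         hmax = hmax, humidity = humidity),
    class = "exposure_grid"
  )
}

#' @export
print.exposure_grid <- function(x, ...) {
  cat("Daily exposure grid:", nrow(x$cells), "cells x", length(x$dates),
      "days\n")
  cat("  dates    :", format(min(x$dates)), "to", format(max(x$dates)), "\n")
  cat("  lat range:", paste(range(x$cells$lat), collapse = " to "), "\n")
  cat("  lon range:", paste(range(x$cells$lon), collapse = " to "), "\n")
  cat("  humidity supplied as:",
      if (x$humidity == "rh") "relative humidity" else "dew point", "\n")
  invisible(x)
}

#' Read a long-format exposure grid CSV
#'
#' Expects header `date,lat,lon,tmax_c,rh_pct` or `date,lat,lon,tmax_c,tdew_c`
#' (ISO-8601 dates, WGS84 decimal degrees). An `hmax` column, if present, is
#' ignored and recomputed.
#'
#' @param path File path.
#' @param ... Passed to [exposure_grid()].
#' @return An `exposure_grid`.
#' @export
read_grid_csv <- function(path, ...) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  exposure_grid(df, ...)
}

#' Write an exposure grid as long-format CSV
#'
#' Emits the input dialect (`date,lat,lon,tmax_c,<humidity>`) plus the derived
#' `hmax` column, one row per covered cell-day.
#'
#' @param grid An `exposure_grid`.
#' @param path Output file path.
#' @export
write_grid_csv <- function(grid, path) {
  df <- as.data.frame(grid)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
as.data.frame.exposure_grid <- function(x, ...) {
  idx <- which(!is.na(x$tmax), arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  df <- data.frame(
    date = x$dates[idx[, 2]],
    lat = x$cells$lat[idx[, 1]],
    lon = x$cells$lon[idx[, 1]],
    tmax_c = x$tmax[idx],
    tdew_c = x$tdew[idx],
    hmax = x$hmax[idx]
  )
  df
}

#' Nearest grid cell to a point
#'
#' Finds, for each query point, the grid cell whose centroid minimises the
#' Euclidean distance in raw (lat, lon) degree space. Ties resolve to the
#' lexicographically smallest (lat, lon) centroid. At mid-latitudes the cell
#' anisotropy (about 7.0 x 4.5 km for a 1/16-degree cell) makes degree-space
#' and projected-space neighbours almost always identical.
#'
#' @param lat,lon Numeric vectors of query coordinates (recycled to common
#'   length).
#' @param grid An `exposure_grid`.
#' @return Integer vector of `cell_id`s.
#' @export
nearest_cell <- function(lat, lon, grid) {
  stopifnot(inherits(grid, "exposure_grid"))
  if (nrow(grid$cells) == 0L) stop("nearest_cell: empty grid")
  n <- max(length(lat), length(lon))
  lat <- rep_len(lat, n)
  lon <- rep_len(lon, n)
  clat <- grid$cells$lat
  clon <- grid$cells$lon
  ulat <- sort(unique(clat))
  ulon <- sort(unique(clon))
  if (length(ulat) * length(ulon) == length(clat)) {
    # complete rectangular lattice: the axes separate, and per-axis nearest
    # with ties to the smaller coordinate reproduces the lexicographic rule
    li <- .nearest_axis(lat, ulat)
    lo <- .nearest_axis(lon, ulon)
    idx <- (li - 1L) * length(ulon) + lo
  } else {
    idx <- integer(n)
    chunk <- max(1L, floor(1e7 / length(clat)))
    for (s in seq(1L, n, by = chunk)) {
      i <- s:min(s + chunk - 1L, n)
      d2 <- outer(lat[i], clat, "-")^2 + outer(lon[i], clon, "-")^2
      # cells are stored lexicographically, so "first" implements the tie rule
      idx[i] <- max.col(-d2, ties.method = "first")
    }
  }
  grid$cells$cell_id[idx]
}

# Index of the nearest value in sorted u; exact midpoints go to the smaller.
.nearest_axis <- function(x, u) {
  if (length(u) == 1L) return(rep(1L, length(x)))
  mid <- (u[-1] + u[-length(u)]) / 2
  findInterval(x, mid, left.open = TRUE) + 1L
}

# Internal vectorised lookup of a grid matrix; errors name the missing key.
.grid_lookup <- function(grid, cell_id, date, what = "hmax") {
  date <- as.Date(date)
  ci <- match(cell_id, grid$cells$cell_id)
  di <- match(as.numeric(date), as.numeric(grid$dates))
  bad <- is.na(ci) | is.na(di)
  if (!any(bad)) {
    v <- grid[[what]][cbind(ci, di)]
    bad <- is.na(v)
  }
  if (any(bad)) {
    k <- which(bad)[1]
    stop(sprintf("no %s value for cell %s on %s", what,
                 as.character(cell_id[k]), format(date[k])))
  }
  v
}

#' Daily maximum Humidex for a cell-day
#'
#' Looks up the derived daily maximum Humidex. A (cell, date) pair the grid
#' does not cover is an error naming the offending key, never a silent `NA`.
#'
#' @param grid An `exposure_grid`.
#' @param cell_id Cell identifier(s) as returned by [nearest_cell()].
#' @param date Date(s).
#' @return Numeric vector of Humidex values.
#' @export
daily_max_humidex <- function(grid, cell_id, date) {
  .grid_lookup(grid, cell_id, date, "hmax")
}
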