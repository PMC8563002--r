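#' Define a regular latitude/longitude grid
#'
#' A `grid_spec` fixes the spatial extent, the cell size and the monthly
#' calendar of a gridded field, mirroring the conventions of global
#' chemical-transport-model output (coarse grids of a few degrees) and
#' satellite products (fine grids of a few hundredths of a degree). Cell
#' centres are at `lat_min + (i - 1/2) * resolution` and analogously for
#' longitude.
#'
#' @param lat_min,lat_max,lon_min,lon_max Grid extent in decimal degrees.
#' @param resolution Cell size in degrees; the extents must be an integer
#'   number of cells. A single value is used for both axes.
#' @param n_months Number of monthly time steps (at least 12 so that an
#'   annual mean is defined).
#' @param start_year,start_month Calendar position of the first time step.
#' @return An object of class `grid_spec`.
#' @examples
#' g <- grid_spec(-10, 10, 0, 25, resolution = 2.5, n_months = 24)
#' g
#' @export
grid_spec <- function(lat_min, lat_max, lon_min, lon_max, resolution,
                      n_months = 12L, start_year = 2000L, start_month = 1L) {
  if (resolution <= 0) stopf("resolution must be > 0")
  n_lat <- (lat_max - lat_min) / resolution
  n_lon <- (lon_max - lon_min) / resolution
  if (abs(n_lat - round(n_lat)) > 1e-8 || abs(n_lon - round(n_lon)) > 1e-8)
    stopf("grid extent is not an integer number of cells at resolution %g", resolution)
  if (n_lat < 1 || n_lon < 1) stopf("grid extent is empty")
  if (n_months < 12L) stopf("n_months must be >= 12 (got %d)", n_months)
  structure(list(
    lat_min = lat_min, lat_max = lat_max,
    lon_min = lon_min, lon_max = lon_max,
    resolution = resolution,
    n_lat = as.integer(round(n_lat)), n_lon = as.integer(round(n_lon)),
    n_months = as.integer(n_months),
    start_year = as.integer(start_year), start_month = as.integer(start_month)
  ), class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("grid_spec: %d x %d cells at %g deg, lat [%g, %g], lon [%g, %g]\n",
              x$n_lat, x$n_lon, x$resolution, x$lat_min, x$lat_max,
              x$lon_min, x$lon_max))
  cat(sprintf("  %d monthly steps from %d-%02d\n", x$n_months,
              x$start_year, x$start_month))
  invisible(x)
}

grid_lat_centers <- function(g) g$lat_min + (seq_len(g$n_lat) - 0.5) * g$resolution
grid_lon_centers <- function(g) g$lon_min + (seq_len(g$n_lon) - 0.5) * g$resolution

## absolute month index (since Jan 2000) of each time slice
grid_month_index <- function(g) {
  ym_index(g$start_year, g$start_month) + seq_len(g$n_months) - 1L
}

#' Gridded scalar field
#'
#' Container for a monthly (3-d array `lat x lon x month`) or annual
#' (matrix `lat x lon`) scalar field on a [grid_spec()], carrying the
#' variable name and units.
#'
#' @param values Numeric array: `n_lat x n_lon` (annual field) or
#'   `n_lat x n_lon x n_months` (monthly field).
#' @param grid A [grid_spec()].
#' @param variable Variable name, e.g. `"pm25_on"`.
#' @param units Units string, e.g. `"ug/m3"`.
#' @param period For annual fields, the calendar year; `NULL` for monthly.
#' @return An object of class `grid_field`.
#' @export
grid_field <- function(values, grid, variable = "value", units = "",
                       period = NULL) {
  stopifnot(inherits(grid, "grid_spec"))
  d <- dim(values)
  if (is.null(d) || !(length(d) %in% c(2L, 3L)))
    stopf("values must be a 2-d (annual) or 3-d (monthly) array")
  if (d[1L] != grid$n_lat || d[2L] != grid$n_lon)
    stopf("values shape (%d x %d) does not match grid (%d x %d)",
          d[1L], d[2L], grid$n_lat, grid$n_lon)
  if (length(d) == 3L && d[3L] != grid$n_months)
    stopf("monthly field has %d slices but grid has %d months", d[3L], grid$n_months)
  structure(list(values = values, grid = grid, variable = variable,
                 units = units, period = period),
            class = "grid_field")
}

is_monthly <- function(f) length(dim(f$values)) == 3L

#' @export
print.grid_field <- function(x, ...) {
  kind <- if (is_monthly(x)) sprintf("monthly (%d steps)", dim(x$values)[3L])
          else sprintf("annual (%s)", x$period %||% "?")
  cat(sprintf("grid_field '%s' [%s], %s, %d x %d cells, range [%.3g, %.3g]\n",
              x$variable, x$units, kind, x$grid$n_lat, x$grid$n_lon,
              min(x$values, na.rm = TRUE), max(x$values, na.rm = TRUE)))
  invisible(x)
}

same_grid <- function(a, b) {
  ga <- a$grid; gb <- b$grid
  isTRUE(all.equal(ga[c("lat_min", "lat_max", "lon_min", "lon_max",
                        "resolution")],
                   gb[c("lat_min", "lat_max", "lon_min", "lon_max",
                        "resolution")], tolerance = 1e-10))
}

## row/col of the cell containing a point; NA outside the extent
grid_cell_of <- function(g, lat, lon) {
  i <- floor((lat - g$lat_min) / g$resolution) + 1
  j <- floor((lon - g$lon_min) / g$resolution) + 1
  i[lat < g$lat_min | lat > g$lat_max] <- NA
  j[lon < g$lon_min | lon > g$lon_max] <- NA
  i <- pmin(pmax(i, 1), g$n_lat)
  j <- pmin(pmax(j, 1), g$n_lon)
  cbind(row = as.integer(i), col = as.integer(j))
}

## monthly series at a point, as a vector indexed by absolute month
field_series_at <- function(f, lat, lon) {
  rc <- grid_cell_of(f$grid, lat, lon)
  if (anyNA(rc)) return(rep(NA_real_, f$grid$n_months))
  f$values[rc[1L], rc[2L], ]
}

#' Write / read a gridded field as long-format CSV
#'
#' Plain-text interchange format for gridded fields: one row per cell (and
#' month for monthly fields), with grid metadata in commented header lines
#' so that a round trip preserves the object.
#'
#' @param field A [grid_field()].
#' @param path Output path.
#' @return `write_grid_csv` returns `path` invisibly; `read_grid_csv`
#'   returns the reconstructed [grid_field()].
#' @export
write_grid_csv <- function(field, path) {
  g <- field$grid
  hdr <- sprintf(
    "# grid_field variable=%s units=%s lat_min=%g lat_max=%g lon_min=%g lon_max=%g resolution=%g n_months=%d start_year=%d start_month=%d period=%s",
    field$variable, field$units, g$lat_min, g$lat_max, g$lon_min, g$lon_max,
    g$resolution, g$n_months, g$start_year, g$start_month,
    if (is.null(field$period)) "NA" else as.character(field$period))
  if (is_monthly(field)) {
    d <- dim(field$values)
    df <- data.frame(
      row = rep(seq_len(d[1L]), times = d[2L] * d[3L]),
      col = rep(rep(seq_len(d[2L]), each = d[1L]), times = d[3L]),
      month = rep(seq_len(d[3L]), each = d[1L] * d[2L]),
      value = as.vector(field$values))
  } else {
    d <- dim(field$values)
    df <- data.frame(
      row = rep(seq_len(d[1L]), times = d[2L]),
      col = rep(seq_len(d[2L]), each = d[1L]),
      month = NA_integer_,
      value = as.vector(field$values))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_grid_csv
#' @param path Path of a CSV written by `write_grid_csv`.
#' @export
read_grid_csv <- function(path) {
  hdr <- readLines(path, n = 1L)
  if (!startsWith(hdr, "# grid_field")) stopf("not a grid_field CSV: %s", path)
  kv <- strsplit(sub("^# grid_field ", "", hdr), " ")[[1L]]
  kv <- strsplit(kv, "=", fixed = TRUE)
  meta <- setNames(lapply(kv, `[`, 2L), vapply(kv, `[`, "", 1L))
  num <- function(k) as.numeric(meta[[k]])
  g <- grid_spec(num("lat_min"), num("lat_max"), num("lon_min"),
                 num("lon_max"), num("resolution"), as.integer(num("n_months")),
                 as.integer(num("start_year")), as.integer(num("start_month")))
  df <- utils::read.csv(path, comment.char = "#")
  monthly <- !all(is.na(df$month))
  if (monthly) {
    arr <- array(NA_real_, c(g$n_lat, g$n_lon, g$n_months))
    arr[cbind(df$row, df$col, df$month)] <- df$value
  } else {
    arr <- matrix(NA_real_, g$n_lat, g$n_lon)
    arr[cbind(df$row, df$col)] <- df$value
  }
  per <- meta[["period"]]
  grid_field(arr, g, variable = meta[["variable"]], units = meta[["units"]],
             period = if (identical(per, "NA")) NULL else as.integer(per))
}
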