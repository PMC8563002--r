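#' Generate paired fire-on / fire-off PM2.5 simulations and companion fields
#'
#' Emulates the output of two chemical-transport-model runs that differ only
#' in whether landscape-fire emissions are switched on, together with the
#' burned-area mask and the meteorological covariates used downstream. The
#' fire-off run is a smooth regional background with mild seasonality and
#' multiplicative noise; the fire-on run adds, inside each fire region and
#' during its active months, a non-negative fire contribution, so that
#' `PM_on >= PM_off >= 0` holds everywhere by construction.
#'
#' @param grid A [grid_spec()] (typically coarse, a few degrees).
#' @param fire_regions List of regions; each is a list with elements
#'   `lat` (length-2 range), `lon` (length-2 range), `months` (calendar
#'   months 1-12 in which the region burns) and `intensity` (flat PM2.5
#'   contribution, ug/m3, added inside the box during active months).
#'   Regions may overlap. An empty list produces `PM_on == PM_off`.
#' @param seed Integer seed; the same seed reproduces the fields bit for bit.
#' @param background Mean background PM2.5 (ug/m3) of the fire-off run.
#' @param background_noise_sd Lognormal sd of cell-level background noise.
#' @return A list of [grid_field()]s: `pm_on`, `pm_off`, `burned_area`
#'   (fraction, positive only inside active regions), `temperature` (deg C)
#'   and `humidity` (percent relative humidity).
#' @examples
#' g <- grid_spec(-10, 10, 10, 35, resolution = 2.5, n_months = 24)
#' reg <- list(list(lat = c(-5, 5), lon = c(15, 30), months = 6:9,
#'                  intensity = 10))
#' f <- generate_ctm_fields(g, reg, seed = 1)
#' all(f$pm_on$values >= f$pm_off$values)
#' @export
generate_ctm_fields <- function(grid, fire_regions = list(), seed = 1L,
                                background = 15, background_noise_sd = 0.2) {
  stopifnot(inherits(grid, "grid_spec"))
  lat <- grid_lat_centers(grid)
  lon <- grid_lon_centers(grid)
  for (r in fire_regions) {
    if (r$lat[1L] < grid$lat_min || r$lat[2L] > grid$lat_max ||
        r$lon[1L] < grid$lon_min || r$lon[2L] > grid$lon_max)
      stopf("fire region [%g,%g]x[%g,%g] outside grid extent",
            r$lat[1L], r$lat[2L], r$lon[1L], r$lon[2L])
  }
  if (length(fire_regions) == 0L)
    fs_log("no fire regions: fire fraction will be identically zero")
  mon_cal <- (index_ym(grid_month_index(grid)))$month

  with_seed(seed, {
    nm <- grid$n_months
    ## spatial background: latitudinal gradient plus fixed cell-level noise
    sp <- outer(1 - 0.3 * (abs(lat) / 90), rep(1, grid$n_lon)) *
      matrix(exp(rnorm(grid$n_lat * grid$n_lon, -background_noise_sd^2 / 2,
                       background_noise_sd)), grid$n_lat, grid$n_lon)
    seas <- 1 + 0.15 * sin(2 * pi * (mon_cal - 1) / 12)
    off <- array(0, c(grid$n_lat, grid$n_lon, nm))
    for (t in seq_len(nm)) off[, , t] <- background * sp * seas[t]

    fire <- array(0, c(grid$n_lat, grid$n_lon, nm))
    burned <- array(0, c(grid$n_lat, grid$n_lon, nm))
    for (r in fire_regions) {
      in_lat <- lat >= r$lat[1L] & lat <= r$lat[2L]
      in_lon <- lon >= r$lon[1L] & lon <= r$lon[2L]
      active <- mon_cal %in% r$months
      if (!any(in_lat) || !any(in_lon) || !any(active)) next
      fire[in_lat, in_lon, active] <- fire[in_lat, in_lon, active] + r$intensity
      frac <- r$burned_fraction %||% 0.2
      burned[in_lat, in_lon, active] <- pmax(burned[in_lat, in_lon, active], frac)
    }

    tmp <- array(0, c(grid$n_lat, grid$n_lon, nm))
    hum <- array(0, c(grid$n_lat, grid$n_lon, nm))
    for (t in seq_len(nm)) {
      tmp[, , t] <- outer(28 - 0.35 * abs(lat), rep(1, grid$n_lon)) +
        3 * sin(2 * pi * (mon_cal[t] - 1) / 12) +
        matrix(rnorm(grid$n_lat * grid$n_lon, 0, 0.5), grid$n_lat, grid$n_lon)
      hum[, , t] <- pmin(pmax(
        outer(70 - 0.1 * abs(lat), rep(1, grid$n_lon)) -
          8 * sin(2 * pi * (mon_cal[t] - 1) / 12) +
          matrix(rnorm(grid$n_lat * grid$n_lon, 0, 2), grid$n_lat, grid$n_lon),
        5), 100)
    }

    list(
      pm_on = grid_field(off + fire, grid, "pm25_on", "ug/m3"),
      pm_off = grid_field(off, grid, "pm25_off", "ug/m3"),
      burned_area = grid_field(burned, grid, "burned_area", "fraction"),
      temperature = grid_field(tmp, grid, "temperature", "deg C"),
      humidity = grid_field(hum, grid, "humidity", "percent")
    )
  })
}

#' Generate a synthetic satellite annual PM2.5 product
#'
#' Emulates a satellite-derived annual-mean PM2.5 field as a multiplicatively
#' biased, lognormally noised copy of a truth field:
#' `satellite = bias * truth * exp(noise)`, `noise ~ N(0, noise_sd^2)`.
#' With `bias = 1, noise_sd = 0` the product equals the truth and the
#' downstream bias-correction rate is identically 1.
#'
#' @param truth Annual-mean [grid_field()] on the fine grid (the "real"
#'   surface concentration the satellite observes).
#' @param bias Multiplicative bias (> 0) of the product.
#' @param noise_sd Standard deviation of the lognormal noise (>= 0).
#' @param seed Integer seed.
#' @return An annual [grid_field()], strictly positive wherever truth is.
#' @export
generate_satellite_product <- function(truth, bias = 1, noise_sd = 0,
                                       seed = 1L) {
  stopifnot(inherits(truth, "grid_field"))
  if (is_monthly(truth)) stopf("truth must be an annual field")
  if (bias <= 0) stopf("bias must be > 0")
  if (noise_sd < 0) stopf("noise_sd must be >= 0")
  with_seed(seed, {
    noise <- if (noise_sd > 0)
      matrix(rnorm(length(truth$values), 0, noise_sd), nrow(truth$values))
    else 0
    grid_field(bias * truth$values * exp(noise), truth$grid,
               variable = "pm25_satellite", units = truth$units,
               period = truth$period)
  })
}

#' Annual mean of a monthly field
#'
#' Arithmetic mean over the monthly slices of one calendar year (or over all
#' available months of a partial year, which is logged).
#'
#' @param field Monthly [grid_field()].
#' @param year Calendar year to average.
#' @return Annual [grid_field()].
#' @export
annual_mean <- function(field, year) {
  stopifnot(is_monthly(field))
  idx <- grid_month_index(field$grid)
  ym <- index_ym(idx)
  sel <- ym$year == year
  if (!any(sel)) stopf("year %d not covered by field", year)
  if (sum(sel) < 12L)
    fs_log(sprintf("partial year %d: annual mean over %d months", year, sum(sel)))
  vals <- apply(field$values[, , sel, drop = FALSE], c(1L, 2L), mean)
  grid_field(vals, field$grid, variable = paste0(field$variable, "_annual"),
             units = field$units, period = year)
}
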