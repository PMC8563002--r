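#' Fire-attributable fraction of simulated PM2.5
#'
#' The monthly fraction of PM2.5 attributable to landscape fires, from the
#' paired fire-on/fire-off simulations: `rho = (PM_on - PM_off) / PM_on`.
#' Cells with `PM_on = 0` are defined as `rho = 0`, and values are clamped
#' to `[0, 1]` (transport chemistry can make `off` exceed `on` in isolated
#' cells; a fraction outside the unit interval is physically
#' uninterpretable). The number of clamped cells is attached as attribute
#' `"n_clamped"` and logged.
#'
#' @param pm_on,pm_off Monthly [grid_field()]s on the same grid.
#' @return Monthly [grid_field()] `rho` in `[0, 1]`.
#' @examples
#' g <- grid_spec(0, 2, 0, 2, 2, n_months = 12)
#' on <- grid_field(array(10, c(1, 1, 12)), g)
#' off <- grid_field(array(8, c(1, 1, 12)), g)
#' fire_fraction(on, off)$values[1, 1, 1]  # 0.2
#' @export
fire_fraction <- function(pm_on, pm_off) {
  stopifnot(inherits(pm_on, "grid_field"), inherits(pm_off, "grid_field"))
  if (!same_grid(pm_on, pm_off) ||
      !identical(dim(pm_on$values), dim(pm_off$values)))
    stopf("pm_on and pm_off are on different grids or periods")
  on <- pm_on$values
  rho <- (on - pm_off$values) / ifelse(on == 0, 1, on)
  rho[on == 0] <- 0
  n_clamp <- sum(rho < 0 | rho > 1, na.rm = TRUE)
  if (n_clamp > 0) fs_log(sprintf("fire_fraction: clamped %d cells to [0,1]",
                                  n_clamp))
  rho <- pmin(pmax(rho, 0), 1)
  out <- grid_field(rho, pm_on$grid, variable = "fire_fraction",
                    units = "fraction")
  attr(out, "n_clamped") <- n_clamp
  out
}

#' Inverse-distance-weighted downscaling to a finer grid
#'
#' Each fine cell takes the weighted mean of the `k` nearest coarse cell
#' centres with weights `d^(-power)`, distances measured along great
#' circles (the grids span the tropics, so planar distance would distort
#' longitudes). A fine cell whose centre coincides with a coarse centre
#' takes that cell's value exactly.
#'
#' @param coarse A [grid_field()] (monthly or annual).
#' @param target A [grid_spec()] with finer resolution.
#' @param power Positive IDW exponent (default 2, standard practice).
#' @param k Number of nearest coarse neighbours (default 4).
#' @return A [grid_field()] on `target` with the same time dimension.
#' @export
idw_downscale <- function(coarse, target, power = 2, k = 4L) {
  stopifnot(inherits(coarse, "grid_field"), inherits(target, "grid_spec"))
  if (k < 1L) stopf("k must be >= 1")
  if (power <= 0) stopf("power must be > 0")
  gc <- coarse$grid
  if (target$resolution >= gc$resolution)
    stopf("target resolution (%g) must be finer than source (%g)",
          target$resolution, gc$resolution)
  cc <- expand.grid(lat = grid_lat_centers(gc), lon = grid_lon_centers(gc))
  fc <- expand.grid(lat = grid_lat_centers(target),
                    lon = grid_lon_centers(target))
  k <- min(k, nrow(cc))
  ## great-circle distances fine x coarse (grids are small enough to hold
  ## the full matrix)
  D <- geosphere::distm(cbind(fc$lon, fc$lat), cbind(cc$lon, cc$lat),
                        fun = geosphere::distHaversine)
  nn <- t(apply(D, 1L, function(d) order(d)[seq_len(k)]))
  dd <- matrix(D[cbind(rep(seq_len(nrow(D)), k), as.vector(nn))], ncol = k)
  w <- dd^(-power)
  exact <- dd[, 1L] < 1e-6
  w[exact, ] <- 0
  w[exact, 1L] <- 1
  w <- w / rowSums(w)

  interp_one <- function(vals) {
    v <- as.vector(vals)           # coarse values in lat-major order
    rowSums(matrix(v[as.vector(nn)], ncol = k) * w)
  }
  if (is_monthly(coarse)) {
    nm <- dim(coarse$values)[3L]
    out <- array(0, c(target$n_lat, target$n_lon, nm))
    for (t in seq_len(nm)) out[, , t] <- interp_one(coarse$values[, , t])
  } else {
    out <- matrix(interp_one(coarse$values), target$n_lat, target$n_lon)
  }
  grid_field(out, target, variable = coarse$variable, units = coarse$units,
             period = coarse$period)
}

#' Annual bias-correction rate from a satellite product
#'
#' The per-cell ratio of the satellite annual-mean PM2.5 to the annual mean
#' of the simulated fire-on PM2.5:
#' `eta = satellite / mean_month(PM_on)`. Cells whose denominator is below
#' `eps` get `eta = 1` (the ratio is undefined there), values are clamped
#' to `[0.1, 10]` to cap the influence of pathological cells (counts
#' logged), and missing satellite cells propagate as missing `eta`.
#'
#' @param satellite Annual [grid_field()] on the fine grid.
#' @param pm_on_monthly Monthly [grid_field()] on the fine grid covering
#'   the satellite year (all of its months are averaged; for a partial
#'   year the mean over available months is used and logged).
#' @param year Calendar year to correct (defaults to `satellite$period`).
#' @param eps Denominator threshold for the `eta = 1` fallback.
#' @param clamp Length-2 clamping range.
#' @return Annual [grid_field()] `eta` with attributes `n_clamped`,
#'   `n_fallback`.
#' @export
bias_rate <- function(satellite, pm_on_monthly, year = NULL, eps = 1e-6,
                      clamp = c(0.1, 10)) {
  stopifnot(inherits(satellite, "grid_field"),
            inherits(pm_on_monthly, "grid_field"))
  if (!same_grid(satellite, pm_on_monthly))
    stopf("satellite and simulation are on different grids")
  year <- year %||% satellite$period
  if (is.null(year)) stopf("no year given and satellite has no period")
  ann <- annual_mean(pm_on_monthly, year)
  denom <- ann$values
  eta <- satellite$values / ifelse(denom < eps, 1, denom)
  n_fallback <- sum(denom < eps & !is.na(satellite$values))
  eta[denom < eps] <- 1
  eta[is.na(satellite$values)] <- NA_real_
  n_clamp <- sum(eta < clamp[1L] | eta > clamp[2L], na.rm = TRUE)
  if (n_fallback > 0 || n_clamp > 0)
    fs_log(sprintf("bias_rate %d: %d fallback cells, %d clamped", year,
                   n_fallback, n_clamp))
  eta <- pmin(pmax(eta, clamp[1L]), clamp[2L])
  out <- grid_field(eta, satellite$grid, variable = "bias_rate",
                    units = "ratio", period = year)
  attr(out, "n_clamped") <- n_clamp
  attr(out, "n_fallback") <- n_fallback
  out
}

#' Split bias-corrected PM2.5 into fire and non-fire components
#'
#' Applies the annual bias-correction rate to the monthly simulation and
#' partitions it by the fire fraction:
#' `fire = eta * rho * PM_on`, `nonfire = eta * (1 - rho) * PM_on`, so that
#' `fire + nonfire = eta * PM_on` holds exactly at every cell and month.
#' Missing `eta` propagates to both components.
#'
#' @param eta Annual [grid_field()] from [bias_rate()] (broadcast over the
#'   months of its year), or a monthly field already aligned with `pm_on`.
#' @param rho Monthly fire fraction from [fire_fraction()].
#' @param pm_on Monthly fire-on simulation on the same grid.
#' @return A `fire_split` list: `fire_pm`, `nonfire_pm`, `rho`, `eta`.
#' @export
split_fire_pm <- function(eta, rho, pm_on) {
  stopifnot(inherits(eta, "grid_field"), inherits(rho, "grid_field"),
            inherits(pm_on, "grid_field"))
  if (!same_grid(rho, pm_on) || !same_grid(eta, pm_on))
    stopf("eta, rho and pm_on must share one grid")
  nm <- dim(pm_on$values)[3L]
  ev <- eta$values
  if (length(dim(ev)) == 2L) {
    ## broadcast the annual rate over the months of its year; other months
    ## (if present) are left missing, as they are uncorrected
    yr <- eta$period
    idx <- index_ym(grid_month_index(pm_on$grid))
    sel <- if (is.null(yr)) rep(TRUE, nm) else idx$year == yr
    ea <- array(NA_real_, dim(pm_on$values))
    for (t in which(sel)) ea[, , t] <- ev
    ev <- ea
  }
  fire <- ev * rho$values * pm_on$values
  nonfire <- ev * (1 - rho$values) * pm_on$values
  structure(list(
    fire_pm = grid_field(fire, pm_on$grid, "fire_pm25", "ug/m3"),
    nonfire_pm = grid_field(nonfire, pm_on$grid, "nonfire_pm25", "ug/m3"),
    rho = rho, eta = eta), class = "fire_split")
}

#' Gestational window average of a monthly series
#'
#' Arithmetic mean of the `window` months strictly preceding the birth
#' month (the birth month itself is excluded; there is no day-level
#' resolution). If any month of the window is outside the series the
#' exposure is missing and the record later fails the inclusion criteria.
#'
#' @param series Numeric monthly series.
#' @param birth Index of the birth month within `series`.
#' @param window Window length in months: 3, 6 or 9.
#' @return The window mean, or `NA` if the window is incomplete.
#' @examples
#' gestational_window(1:12, birth = 12, window = 9)  # mean(3:11) = 7
#' @export
gestational_window <- function(series, birth, window = 9L) {
  if (!window %in% c(3L, 6L, 9L)) stopf("window must be 3, 6 or 9 months")
  idx <- (birth - window):(birth - 1L)
  if (any(idx < 1L) || any(idx > length(series))) return(NA_real_)
  v <- series[idx]
  if (anyNA(v)) return(NA_real_)
  mean(v)
}

#' Transported-smoke indicator
#'
#' A record's fire-sourced PM2.5 is classified as smoke transported from
#' other locations when the burned area at its own pixel is zero in every
#' month of the gestational window (local fires would register burned
#' area).
#'
#' @param burned_series Monthly burned-area series at the record's pixel.
#' @param birth Index of the birth month within the series.
#' @param window Gestation window length (months).
#' @return `TRUE` (all-zero burned area: transported), `FALSE`, or `NA` if
#'   the burned-area window is incomplete.
#' @export
transported_flag <- function(burned_series, birth, window = 9L) {
  idx <- (birth - window):(birth - 1L)
  if (any(idx < 1L) || any(idx > length(burned_series))) return(NA)
  v <- burned_series[idx]
  if (anyNA(v)) return(NA)
  all(v == 0)
}

#' Run the full exposure-assessment chain
#'
#' Convenience wrapper: fire fraction on the coarse grid, IDW downscaling
#' of the fraction and the fire-on simulation to the fine grid, annual bias
#' correction against the satellite product, and the fire/non-fire split.
#'
#' @param ctm Output of [generate_ctm_fields()] (coarse monthly fields).
#' @param satellite Annual [grid_field()] on the fine grid, or a list of
#'   annual fields (one per calendar year covered by the simulation; years
#'   without a satellite field are left uncorrected, i.e. missing).
#' @param fine_grid [grid_spec()] of the satellite product.
#' @param power,k IDW parameters (see [idw_downscale()]).
#' @return A `fire_split` on the fine grid, with the downscaled meteorology
#'   attached as `temperature`, `humidity`, `burned_area`.
#' @export
exposure_chain <- function(ctm, satellite, fine_grid, power = 2, k = 4L) {
  rho_c <- fire_fraction(ctm$pm_on, ctm$pm_off)
  rho_f <- idw_downscale(rho_c, fine_grid, power = power, k = k)
  on_f <- idw_downscale(ctm$pm_on, fine_grid, power = power, k = k)
  if (inherits(satellite, "grid_field")) satellite <- list(satellite)
  ## one annual bias-correction rate per satellite year, assembled into a
  ## monthly rate field (uncorrected months stay missing)
  ev <- array(NA_real_, dim(on_f$values))
  yrs <- index_ym(grid_month_index(fine_grid))$year
  for (s in satellite) {
    yr <- s$period %||% yrs[1L]
    e1 <- bias_rate(s, on_f, year = yr)
    for (t in which(yrs == yr)) ev[, , t] <- e1$values
  }
  eta <- grid_field(ev, fine_grid, variable = "bias_rate", units = "ratio")
  sp <- split_fire_pm(eta, rho_f, on_f)
  sp$temperature <- idw_downscale(ctm$temperature, fine_grid, power, k)
  sp$humidity <- idw_downscale(ctm$humidity, fine_grid, power, k)
  sp$burned_area <- idw_downscale(ctm$burned_area, fine_grid, power, k)
  sp
}
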