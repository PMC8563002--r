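mk_field <- function(vals, g) grid_field(vals, g)

test_that("fire fraction handles direct, degenerate and clamped cells", {
  g <- grid_spec(0, 5, 0, 5, 2.5, n_months = 12)
  on <- array(10, c(2, 2, 12)); off <- array(8, c(2, 2, 12))
  off[1, 1, ] <- 10   # no fire contribution
  on[2, 2, 1] <- 0; off[2, 2, 1] <- 0  # degenerate cell
  off[1, 2, 2] <- 12  # chemistry artefact: off > on -> clamp to 0
  rho <- fire_fraction(mk_field(on, g), mk_field(off, g))
  expect_equal(rho$values[2, 1, 1], 0.2)
  expect_equal(rho$values[1, 1, 3], 0)
  expect_equal(rho$values[2, 2, 1], 0)
  expect_equal(rho$values[1, 2, 2], 0)
  expect_gte(attr(rho, "n_clamped"), 1)
  expect_true(all(rho$values >= 0 & rho$values <= 1))
  g2 <- grid_spec(0, 5, 0, 10, 2.5, n_months = 12)
  expect_error(fire_fraction(mk_field(on, g),
                             mk_field(array(8, c(2, 4, 12)), g2)),
               "different grids")
})

test_that("IDW reproduces symmetry, coincidence and constant-field cases", {
  ## grid symmetric about the equator, so a fine centre at (0, 5) is
  ## genuinely equidistant (great-circle) from the four coarse centres
  g <- grid_spec(-5, 5, 0, 10, 5, n_months = 12)
  vals <- matrix(c(1, 3, 2, 4), 2, 2)  # centres at (+-2.5, 2.5/7.5)
  f <- grid_field(vals, g, period = 2000L)
  tgt <- grid_spec(-5, 5, 0, 10, 2, n_months = 12)
  d <- idw_downscale(f, tgt, power = 2, k = 4)
  expect_equal(d$values[3, 3], mean(vals), tolerance = 1e-12)
  ## fine cell centred exactly on a coarse centre takes its value: with
  ## resolution 1/3 the 8th fine centre is at -2.5, a coarse centre
  tgt2 <- grid_spec(-5, 5, 0, 10, 1 / 3, n_months = 12)
  d2 <- idw_downscale(f, tgt2, power = 2, k = 4)
  expect_equal(d2$values[8, 8], vals[1, 1])
  ## constant field stays constant at any resolution
  fc <- grid_field(matrix(7, 2, 2), g, period = 2000L)
  dc <- idw_downscale(fc, tgt2, power = 2, k = 4)
  expect_equal(range(dc$values), c(7, 7), tolerance = 1e-12)
  expect_error(idw_downscale(f, tgt, k = 0), "k must be")
  expect_error(idw_downscale(f, g), "finer")
})

test_that("IDW agrees with an all-pairs brute-force oracle to 1e-12", {
  set.seed(11)
  g <- grid_spec(-10, 10, 0, 25, 2.5, n_months = 12)
  vals <- matrix(runif(8 * 10, 2, 30), 8, 10)
  f <- grid_field(vals, g, period = 2000L)
  tgt <- grid_spec(-10, 10, 0, 25, 1.25, n_months = 12)
  d <- idw_downscale(f, tgt, power = 2, k = 4)
  o <- oracle_idw(vals, grid_lat_centers(g), grid_lon_centers(g),
                  grid_lat_centers(tgt), grid_lon_centers(tgt),
                  power = 2, k = 4)
  expect_lt(max(abs(d$values - o) / abs(o)), 1e-12)
})

test_that("bias rate follows the ratio definition with fallback and clamps", {
  g <- grid_spec(0, 5, 0, 5, 2.5, n_months = 12)
  on <- array(10, c(2, 2, 12))
  on[2, 2, ] <- 0                       # zero denominator cell
  sat <- matrix(12, 2, 2)
  sat[1, 2] <- NA                       # satellite gap
  sat[2, 1] <- 500                      # pathological cell -> clamp at 10
  eta <- bias_rate(grid_field(sat, g, period = 2000L), mk_field(on, g))
  expect_equal(eta$values[1, 1], 1.2)
  expect_equal(eta$values[2, 2], 1)     # fallback
  expect_true(is.na(eta$values[1, 2])) # missing propagates
  expect_equal(eta$values[2, 1], 10)    # clamped
  expect_equal(attr(eta, "n_fallback"), 1)
  expect_gte(attr(eta, "n_clamped"), 1)
  ## identity: satellite equal to the annual mean gives eta = 1
  sat1 <- matrix(10, 2, 2)
  on1 <- array(10, c(2, 2, 12))
  eta1 <- bias_rate(grid_field(sat1, g, period = 2000L), mk_field(on1, g))
  expect_equal(unname(eta1$values), matrix(1, 2, 2))
})

test_that("fire/non-fire split conserves eta * PM_on to 1e-10", {
  g <- grid_spec(0, 5, 0, 5, 2.5, n_months = 12)
  set.seed(3)
  on <- array(runif(2 * 2 * 12, 1, 30), c(2, 2, 12))
  rho <- array(runif(2 * 2 * 12), c(2, 2, 12))
  eta <- matrix(runif(4, 0.5, 2), 2, 2)
  sp <- split_fire_pm(grid_field(eta, g, period = 2000L),
                      grid_field(rho, g), grid_field(on, g))
  target <- sweep(on, c(1, 2), eta, `*`)
  expect_lt(max(abs(sp$fire_pm$values + sp$nonfire_pm$values - target) /
                  target), 1e-10)
  ## direct numbers: eta 1.2, rho 0.25, on 10 -> fire 3, nonfire 9
  sp2 <- split_fire_pm(grid_field(matrix(1.2, 2, 2), g, period = 2000L),
                       grid_field(array(0.25, c(2, 2, 12)), g),
                       grid_field(array(10, c(2, 2, 12)), g))
  expect_equal(sp2$fire_pm$values[1, 1, 1], 3)
  expect_equal(sp2$nonfire_pm$values[1, 1, 1], 9)
  ## limits
  sp0 <- split_fire_pm(grid_field(matrix(1.2, 2, 2), g, period = 2000L),
                       grid_field(array(0, c(2, 2, 12)), g),
                       grid_field(array(10, c(2, 2, 12)), g))
  expect_true(all(sp0$fire_pm$values == 0))
  expect_true(all(sp0$nonfire_pm$values == 12))
})

test_that("scale equivariance: scaling inputs by c scales fire PM by c", {
  g <- toy_grid()
  ctm <- generate_ctm_fields(g, toy_region(), seed = 4)
  fine <- grid_spec(-10, 10, 10, 35, 1.25, g$n_months)
  on_f <- idw_downscale(ctm$pm_on, fine)
  yrs <- unique(index_ym(grid_month_index(fine))$year)
  sat <- lapply(yrs, function(y) annual_mean(on_f, y))
  sp1 <- exposure_chain(ctm, sat, fine)
  cc <- 2.5
  ctm2 <- ctm
  ctm2$pm_on$values <- cc * ctm$pm_on$values
  ctm2$pm_off$values <- cc * ctm$pm_off$values
  sat2 <- lapply(sat, function(s) { s$values <- cc * s$values; s })
  sp2 <- exposure_chain(ctm2, sat2, fine)
  expect_equal(sp2$rho$values, sp1$rho$values, tolerance = 1e-12)
  expect_equal(sp2$eta$values, sp1$eta$values, tolerance = 1e-12)
  expect_equal(sp2$fire_pm$values, cc * sp1$fire_pm$values,
               tolerance = 1e-12)
})

test_that("noise-free satellite round trip gives fire = rho * PM_on exactly", {
  g <- toy_grid()
  ctm <- generate_ctm_fields(g, toy_region(), seed = 5)
  fine <- grid_spec(-10, 10, 10, 35, 1.25, g$n_months)
  on_f <- idw_downscale(ctm$pm_on, fine)
  yrs <- unique(index_ym(grid_month_index(fine))$year)
  sat <- lapply(yrs, function(y)
    generate_satellite_product(annual_mean(on_f, y), bias = 1, noise_sd = 0,
                               seed = 1))
  sp <- exposure_chain(ctm, sat, fine)
  rho_f <- idw_downscale(fire_fraction(ctm$pm_on, ctm$pm_off), fine)
  expect_equal(sp$fire_pm$values, rho_f$values * on_f$values,
               tolerance = 1e-12)
})

test_that("gestational windows average the months strictly before birth", {
  expect_equal(gestational_window(1:12, birth = 12, window = 9), 7)
  expect_equal(gestational_window(rep(4.2, 24), birth = 20, window = 3), 4.2)
  ## monotone series: shorter window sits later, so has a larger mean
  s <- 1:24
  w3 <- gestational_window(s, 20, 3)
  w9 <- gestational_window(s, 20, 9)
  expect_gt(w3, w9)
  ## incomplete window -> missing
  expect_true(is.na(gestational_window(1:12, birth = 5, window = 9)))
  expect_error(gestational_window(1:12, 12, window = 5), "window")
})

test_that("transported flag is true only for all-zero burned-area windows", {
  b <- rep(0, 24)
  expect_true(transported_flag(b, birth = 20, window = 9))
  b[15] <- 0.3
  expect_false(transported_flag(b, birth = 20, window = 9))
  expect_false(transported_flag(b, birth = 16, window = 9))  # straddles it
  expect_true(is.na(transported_flag(b, birth = 5, window = 9)))
})

test_that("bias-corrected totals track the synthetic satellite truth (r > 0.9)", {
  g <- toy_grid(n_months = 12)
  ctm <- generate_ctm_fields(g, toy_region(), seed = 6)
  fine <- grid_spec(-10, 10, 10, 35, 1.25, 12)
  on_f <- idw_downscale(ctm$pm_on, fine)
  truth <- annual_mean(on_f, 2000L)
  sat <- generate_satellite_product(truth, bias = 1.1, noise_sd = 0.1,
                                    seed = 2)
  sp <- exposure_chain(ctm, sat, fine)
  total_ann <- apply(sp$fire_pm$values + sp$nonfire_pm$values, c(1, 2), mean)
  expect_gt(cor(as.vector(total_ann), as.vector(sat$values)), 0.9)
})
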