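test_that("identity lag basis reproduces nine free lag coefficients", {
  co <- generate_cohort(scenario_config(n_families = 2000, seed = 5))
  b <- retained(co)
  lags <- co$fire_lags[as.integer(rownames(b)), 1:9]
  dl <- distributed_lag_fit(b, lags, basis = "identity",
                            adjust = "unadjusted")
  ## oracle: explicit nine-regressor fixed-effects fit
  dm <- list(y = b$birthweight, X = lags, group = b$group_id,
             outcome = "birthweight")
  colnames(dm$X) <- paste0("fire_pm", 1:9)
  f9 <- fe_ols(dm)
  expect_equal(dl$effects$estimate, f9$coefficients$estimate,
               tolerance = 1e-8)
  expect_equal(dl$cumulative, sum(f9$coefficients$estimate),
               tolerance = 1e-8)
})

test_that("a constant lag basis collapses to the window-average model", {
  co <- generate_cohort(scenario_config(n_families = 2000, seed = 16))
  b <- retained(co)
  lags <- co$fire_lags[as.integer(rownames(b)), 1:9]
  dl <- distributed_lag_fit(b, lags, basis = "ns", df = 1L,
                            adjust = "unadjusted")
  fw <- fe_ols(build_design(b, outcome = "birthweight",
                            adjust = "unadjusted"))
  ## cumulative effect over the window equals the window-mean coefficient
  expect_equal(dl$cumulative, fw$beta, tolerance = 1e-8)
  ## each lag carries 1/9 of it
  expect_equal(dl$effects$estimate, rep(fw$beta / 9, 9), tolerance = 1e-8)
})

test_that("equal per-lag truth accumulates to the configured total effect", {
  cfg <- scenario_config(n_families = 25000, seed = 29)
  co <- generate_cohort(cfg)
  b <- retained(co)
  lags <- co$fire_lags[as.integer(rownames(b)), 1:9]
  ## truth: -2.17 on the 9-month mean == -2.17/9 per lag-month sum
  dl <- distributed_lag_fit(b, lags, basis = "ns", df = 4L,
                            adjust = "partial")
  expect_lt(abs(dl$cumulative - (-2.17)), 3 * dl$cumulative_se + 1e-9)
  ## spline-basis per-lag effects hover around -2.17/9
  expect_lt(abs(mean(dl$effects$estimate) - (-2.17 / 9)),
            3 * mean(dl$effects$se))
})

test_that("nonlinear fit nests the linear truth and rejects degenerate input", {
  co <- generate_cohort(scenario_config(n_families = 8000, seed = 10))
  b <- retained(co)
  nl <- nonlinear_fit(b, k = 8, adjust = "partial")
  ## the anchored fitted curve should contain the anchored straight line
  ## with the headline slope inside its pointwise CI nearly everywhere
  fw <- fe_ols(build_design(b, outcome = "birthweight", adjust = "partial"))
  line <- fw$beta * nl$curve$exposure
  inside <- mean(line >= nl$curve$lo & line <= nl$curve$hi)
  expect_gt(inside, 0.9)
  expect_error(nonlinear_fit(b[1:40, ], k = 50, adjust = "partial"),
               "distinct exposure")
})

test_that("a saturating exposure-response is recovered near the plateau", {
  ## the far tail of the curve is identified by chaining within-family
  ## contrasts, so this designed experiment uses a generous within-family
  ## exposure spread
  cfg <- scenario_config(n_families = 25000, seed = 61, true_effect_bw = 0,
                         exposure_sd_within = 5)
  co <- generate_cohort(cfg)
  b0 <- co$births
  sat_curve <- function(x) -60 * (1 - exp(-x / 8))
  ## inject the nonlinear truth on top of the effect-free birthweights
  b0$birthweight <- b0$birthweight + sat_curve(b0$fire_pm) -
    ave(sat_curve(b0$fire_pm), b0$mother_id)
  gr <- build_groups(b0)
  nl <- nonlinear_fit(gr$births, k = 10, adjust = "partial")
  truth25 <- sat_curve(25) - sat_curve(0)
  at25 <- nl$curve[which.min(abs(nl$curve$exposure - 25)), ]
  expect_lt(abs(at25$estimate - truth25) / abs(truth25), 0.15)
})

test_that("a constant baseline basis collapses to the headline estimator", {
  co <- generate_cohort(scenario_config(n_families = 3000, seed = 18))
  b <- retained(co)
  bv <- baseline_varying_fit(b, anchors = c(2800, 3200), df = 1L,
                             adjust = "unadjusted")
  fw <- fe_ols(build_design(b, outcome = "birthweight",
                            adjust = "unadjusted"))
  expect_equal(bv$at_anchors$beta, rep(fw$beta, 2), tolerance = 1e-6)
})

test_that("anchors outside the observed baseline range are refused", {
  co <- generate_cohort(scenario_config(n_families = 500, seed = 19))
  b <- retained(co)
  expect_error(baseline_varying_fit(b, anchors = c(100, 3000)),
               "outside the observed")
})

test_that("a piecewise-linear baseline truth matches a stratified oracle", {
  truth_slope <- function(yb) ifelse(yb < 2800, -8, -2)
  cfg <- scenario_config(n_families = 25000, seed = 77,
                         baseline_dist = c(1800, 3800),
                         baseline_effect_curve = function(yb)
                           -truth_slope(yb) / yb * 100)
  co <- generate_cohort(cfg)
  b <- retained(co)
  bv <- baseline_varying_fit(b, anchors = c(2300, 3400), df = 6,
                             adjust = "partial")
  ## oracle: separate fixed-effects fits in baseline strata far from the
  ## breakpoint
  for (i in 1:2) {
    lohi <- list(c(1900, 2700), c(2900, 3700))[[i]]
    sub <- b[b$ybar >= lohi[1] & b$ybar <= lohi[2], , drop = FALSE]
    fo <- fe_ols(build_design(sub, outcome = "birthweight",
                              adjust = "partial"))
    expect_lt(abs(bv$at_anchors$beta[i] - fo$beta),
              3 * sqrt(bv$at_anchors$se[i]^2 + fo$se^2))
  }
})

test_that("anchored baseline truths are recovered at the published anchors", {
  anch <- cbind(c(1500, 2000, 2500, 3000), c(1.47, 0.54, 0.16, 0.03))
  cfg <- scenario_config(n_families = 20000, seed = 9,
                         baseline_effect_curve = anch,
                         baseline_dist = c(1200, 4500))
  co <- generate_cohort(cfg)
  b <- retained(co)
  bv <- baseline_varying_fit(b, adjust = "partial")
  for (i in 1:4) {
    expect_lt(abs(bv$at_anchors$relative_reduction_pct[i] - anch[i, 2]),
              3 * bv$at_anchors$se[i] / anch[i, 1] * 100 + 1e-9)
  }
})
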