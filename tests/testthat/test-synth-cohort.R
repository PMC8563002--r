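test_that("scenario_config validates its invariants", {
  expect_error(scenario_config(n_families = 1), "n_families")
  expect_error(scenario_config(exposure_sd_within = 0), "SDs")
  expect_error(scenario_config(p_lbw = 0.01, p_vlbw = 0.02), "p_vlbw")
  cfg <- scenario_config(group_size_mode = "ratio")
  expect_equal(cfg$mean_children, 227948 / 109137)
})

test_that("group sizes follow a truncated Poisson tuned to the target mean", {
  gs <- firesib:::group_size_dist(2.13)
  expect_equal(gs$mean, 2.13, tolerance = 1e-8)
  expect_true(all(gs$sizes >= 2))
  expect_equal(sum(gs$prob), 1)
  ## sd lands near the published 0.36 (one-parameter family: mean only)
  expect_lt(abs(gs$sd - 0.36), 0.05)
})

test_that("the generated cohort is deterministic given a seed", {
  a <- generate_cohort(scenario_config(n_families = 300, seed = 12))
  b <- generate_cohort(scenario_config(n_families = 300, seed = 12))
  expect_identical(a$births, b$births)
  expect_identical(a$fire_lags, b$fire_lags)
  d <- generate_cohort(scenario_config(n_families = 300, seed = 13))
  expect_false(identical(a$births$birthweight, d$births$birthweight))
})

test_that("records satisfy structural invariants", {
  co <- generate_cohort(scenario_config(n_families = 500, seed = 6))
  b <- co$births
  expect_true(all(table(b$mother_id) >= 2))
  expect_true(all(b$fire_pm > 0))
  bidx <- firesib:::ym_index(b$birth_year, b$birth_month)
  sidx <- firesib:::ym_index(b$survey_year, b$survey_month)
  expect_true(all(sidx - bidx >= 0 & sidx - bidx <= 60))
  ## sibling spacing at least 12 months
  sp <- tapply(bidx, b$mother_id, function(v) min(diff(sort(v))))
  expect_true(all(sp >= 12))
  ## stored 9-month exposure equals the window mean of the monthly series
  expect_equal(cohort_gestational_exposure(co, 9L), b$fire_pm,
               tolerance = 1e-12)
  ## and agrees with the per-record scalar window operation
  i <- c(1L, 17L, 101L)
  for (ix in i) {
    series <- rev(co$fire_lags[ix, ])   # months b-12 .. b-1
    expect_equal(gestational_window(series, birth = 13L, window = 9L),
                 b$fire_pm[ix], tolerance = 1e-12)
  }
  ## threshold mode: outcome labels are the birthweight indicators
  expect_equal(b$lbw, as.integer(b$birthweight < 2500))
  expect_equal(b$vlbw, as.integer(b$birthweight < 1500))
})

test_that("a null scenario yields a within-family slope near zero", {
  cfg <- scenario_config(n_families = 4000, seed = 31, true_effect_bw = 0,
                         covar_effects_bw = c(sex_male = 0))
  co <- generate_cohort(cfg)
  b <- retained(co)
  f <- fe_ols(build_design(b, outcome = "birthweight",
                           adjust = "unadjusted"))
  expect_lt(abs(f$beta), 3 * f$se)
})

test_that("exposure and birthweight calibration meet the descriptive targets", {
  ## moderately sized draw; the acceptance suite re-checks at 50k families
  co <- generate_cohort(scenario_config(n_families = 20000, seed = 8))
  b <- retained(co)
  de <- decompose_variance(b$fire_pm, b$group_id)
  db <- decompose_variance(b$birthweight, b$group_id)
  expect_lt(abs(mean(b$fire_pm) - 4.29) / 4.29, 0.02)
  expect_lt(abs(de$between_sd - 5.30) / 5.30, 0.03)
  expect_lt(abs(de$within_sd - 1.59) / 1.59, 0.03)
  expect_lt(abs(db$between_sd - 613) / 613, 0.03)
  expect_lt(abs(db$within_sd - 386) / 386, 0.03)
  ## variance recombination on the generated data
  expect_equal(de$total_sd^2, de$between_sd^2 + de$within_sd^2,
               tolerance = 1e-10)
})

test_that("direct-logit mode draws outcomes at the calibrated prevalences", {
  co <- generate_cohort(scenario_config(n_families = 20000, seed = 14,
                                        outcome_mode = "direct-logit"))
  b <- co$births
  n <- nrow(b)
  expect_lt(abs(mean(b$lbw) - 31854 / 227948),
            3 * sqrt(0.14 * 0.86 / n) + 0.003)  # family clustering widens SE
  expect_lt(abs(mean(b$vlbw) - 2912 / 227948),
            3 * sqrt(0.0128 * 0.987 / n) + 0.0012)
})

test_that("a per-record effect function is honoured (effect modification)", {
  cfg <- scenario_config(n_families = 6000, seed = 15,
                         true_effect_bw = function(df)
                           ifelse(df$employment == 1, -3, -1))
  co <- generate_cohort(cfg)
  expect_equal(unique(co$truth$slope[co$births$employment == 1]), -3)
  expect_equal(unique(co$truth$slope[co$births$employment == 0]), -1)
})
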