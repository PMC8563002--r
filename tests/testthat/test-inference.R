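library(survival)

test_that("design matrix bookkeeping: adjustment sets, df and degeneracies", {
  co <- generate_cohort(scenario_config(n_families = 300, seed = 2))
  b <- retained(co)
  d0 <- build_design(b, outcome = "birthweight", adjust = "unadjusted")
  expect_equal(colnames(d0$X), "fire_pm")
  dp <- build_design(b, outcome = "birthweight", adjust = "partial")
  expect_setequal(colnames(dp$X), c("fire_pm", "maternal_age", "sex_male",
                                    "multiple_birth", "nonfire_pm"))
  df <- build_design(b, outcome = "birthweight", adjust = "full")
  expect_equal(sum(startsWith(colnames(df$X), "temperature_s")), 3)
  expect_equal(sum(startsWith(colnames(df$X), "month_s")), 4)
  expect_equal(sum(startsWith(colnames(df$X), "year_s")), 5)
  ## a 6-distinct-value column supports a 5-df basis of 5 columns
  b2 <- b; b2$birth_order <- ((seq_len(nrow(b)) - 1L) %% 6L) + 1L
  df2 <- build_design(b2, outcome = "birthweight", adjust = "full")
  expect_equal(sum(startsWith(colnames(df2$X), "birth_order_s")), 5)
  ## df beyond the distinct values is an error naming the column
  b3 <- b; b3$temperature <- round(b3$temperature) %% 2
  expect_error(build_design(b3, outcome = "birthweight", adjust = "full"),
               "temperature")
  ## a constant spline input is dropped with a log entry
  b4 <- b; b4$temperature <- 25
  df4 <- build_design(b4, outcome = "birthweight", adjust = "full")
  expect_false(any(startsWith(colnames(df4$X), "temperature")))
  expect_true("temperature" %in% df4$dropped)
})

test_that("fe_ols solves a noiseless two-group toy exactly", {
  dm <- list(y = c(100, 98, 200, 194), X = cbind(fire_pm = c(0, 1, 2, 5)),
             group = c(1, 1, 2, 2), outcome = "birthweight")
  f <- fe_ols(dm)
  expect_equal(f$beta, -2, tolerance = 1e-12)
  expect_equal(f$n_informative_groups, 2)
})

test_that("demeaned OLS equals the dummy-variable (LSDV) oracle to 1e-10", {
  td <- toy_sib_data(G = 40, seed = 42)
  dm <- list(y = td$df$y, X = cbind(fire_pm = td$df$x, z = td$df$z),
             group = td$df$group, outcome = "y")
  f <- fe_ols(dm)
  lsdv <- coef(lm(y ~ x + z + factor(group), data = td$df))
  expect_equal(f$beta, unname(lsdv["x"]), tolerance = 1e-10)
  expect_equal(f$coefficients$estimate[2], unname(lsdv["z"]),
               tolerance = 1e-10)
  ## classical SEs also agree with the dummy regression
  se_lm <- summary(lm(y ~ x + z + factor(group),
                      data = td$df))$coefficients["x", "Std. Error"]
  expect_equal(f$coefficients$se_classical[1], unname(se_lm),
               tolerance = 1e-8)
})

test_that("group-constant confounding cannot move the within estimator", {
  td <- toy_sib_data(G = 30, seed = 7)
  dm <- list(y = td$df$y, X = cbind(fire_pm = td$df$x, z = td$df$z),
             group = td$df$group, outcome = "y")
  f0 <- fe_ols(dm)
  ## add an arbitrary group-constant shift to the response
  shift <- rnorm(30, 0, 500)[td$df$group]
  dm$y <- td$df$y + shift
  f1 <- fe_ols(dm)
  expect_equal(f1$beta, f0$beta, tolerance = 1e-10)
  ## a group-constant covariate is collinear after demeaning and dropped
  dm$X <- cbind(dm$X, gconst = rnorm(30)[td$df$group])
  f2 <- fe_ols(dm)
  expect_equal(f2$beta, f0$beta, tolerance = 1e-10)
  expect_false("gconst" %in% f2$coefficients$term)
})

test_that("fe_ols refuses unidentified designs", {
  dm <- list(y = rnorm(6), X = cbind(fire_pm = rep(1:3, each = 2)),
             group = rep(1:3, each = 2), outcome = "y")
  expect_error(fe_ols(dm), "unidentified")
})

test_that("conditional logit: symmetric discordant pairs give beta = 0", {
  dm <- list(y = c(1, 0, 0, 1), X = cbind(fire_pm = c(2, 1, 2, 1)),
             group = c(1, 1, 2, 2), outcome = "lbw")
  f <- conditional_logit(dm)
  expect_equal(f$beta, 0, tolerance = 1e-8)
  expect_equal(f$excess_risk_pct, 0, tolerance = 1e-6)
})

test_that("conditional logit matches the enumerated-likelihood oracle to 1e-6", {
  set.seed(19)
  G <- 60
  sz <- sample(2:3, G, TRUE)
  id <- rep(seq_len(G), sz)
  x <- rnorm(length(id), 0, 1.5)
  y <- rbinom(length(id), 1, plogis(rnorm(G)[id] + 0.6 * x))
  dm <- list(y = y, X = cbind(fire_pm = x), group = id, outcome = "lbw")
  f <- conditional_logit(dm)
  ## independent oracle: golden-section maximization of the explicitly
  ## enumerated conditional likelihood
  opt <- optimize(function(b) oracle_clogit_loglik(b, y, x, id),
                  c(-5, 5), maximum = TRUE, tol = 1e-9)
  expect_equal(f$beta, opt$maximum, tolerance = 1e-6)
  expect_equal(f$loglik, opt$objective, tolerance = 1e-8)
})

test_that("conditional logit agrees with survival::clogit on mixed groups", {
  set.seed(23)
  G <- 250
  sz <- sample(2:4, G, TRUE)
  id <- rep(seq_len(G), sz)
  n <- length(id)
  x <- rnorm(n); z <- rbinom(n, 1, 0.4)
  y <- rbinom(n, 1, plogis(rnorm(G)[id] + 0.7 * x - 0.4 * z))
  dm <- list(y = y, X = cbind(fire_pm = x, z = z), group = id,
             outcome = "lbw")
  f <- conditional_logit(dm)
  cf <- survival::clogit(y ~ x + z + survival::strata(id))
  expect_equal(f$coefficients$estimate, unname(coef(cf)), tolerance = 1e-7)
  expect_equal(f$coefficients$se, unname(sqrt(diag(vcov(cf)))),
               tolerance = 1e-7)
})

test_that("concordant groups drop out and all-concordant data errors", {
  dm <- list(y = c(1, 1, 0, 1), X = cbind(fire_pm = rnorm(4)),
             group = c(1, 1, 2, 2), outcome = "lbw")
  f <- conditional_logit(dm)
  expect_equal(f$n_informative_groups, 1)
  expect_equal(f$n_concordant, 1)
  dm2 <- list(y = c(1, 1, 0, 0), X = cbind(fire_pm = rnorm(4)),
              group = c(1, 1, 2, 2), outcome = "lbw")
  expect_error(conditional_logit(dm2), "discordant")
})

test_that("perfect separation is flagged, not silently reported", {
  ## every case sits at the higher exposure: the likelihood is monotone
  dm <- list(y = rep(c(1, 0), 20),
             X = cbind(fire_pm = rep(c(2, 1), 20)),
             group = rep(1:20, each = 2), outcome = "lbw")
  f <- conditional_logit(dm)
  expect_true(f$separated)
  expect_false(f$converged)
  expect_true(is.nan(f$beta))
})

test_that("excess risk transform matches the published arithmetic", {
  expect_equal(excess_risk(0), 0)
  expect_equal(excess_risk(log(1.1168)), 11.68)
  expect_equal(excess_risk(log(1.0280)), 2.80)
})

test_that("threshold-mode LBW association carries the sign of the continuous effect", {
  co <- generate_cohort(scenario_config(n_families = 20000, seed = 27,
                                        true_effect_bw = -40))
  b <- retained(co)
  fb <- fe_ols(build_design(b, outcome = "birthweight", adjust = "partial"))
  fl <- conditional_logit(build_design(b, outcome = "lbw",
                                       adjust = "partial"))
  expect_lt(fb$beta, 0)
  expect_gt(fl$beta, 0)   # harmful exposure raises LBW odds
})

test_that("duplicated strata give a null interaction; real contrast is detected", {
  td <- toy_sib_data(G = 60, seed = 3)
  two <- rbind(cbind(td$df, stratum = "a"),
               cbind(transform(td$df, group = group + 1000),
                     stratum = "b"))
  two$group_id <- two$group
  two$fire_pm <- two$x
  two$birthweight <- two$y
  si <- subgroup_interaction(two, "stratum", outcome = "birthweight",
                             adjust = "unadjusted")
  expect_lt(abs(si$interaction_estimates[[1]]), 1e-8)
  expect_gt(si$p_heterogeneity, 0.99)
  expect_equal(si$strata$a$beta, si$strata$b$beta)

  ## constructed stratum effects -1 vs -3 at a decent sample size
  cfg <- scenario_config(n_families = 12000, seed = 44,
                         true_effect_bw = function(df)
                           ifelse(df$employment == 1, -3, -1))
  co <- generate_cohort(cfg)
  b <- retained(co)
  si2 <- subgroup_interaction(b, "employment", outcome = "birthweight",
                              adjust = "partial")
  est <- si2$strata[["1"]]$beta - si2$strata[["0"]]$beta
  se2 <- sqrt(si2$strata[["1"]]$se^2 + si2$strata[["0"]]$se^2)
  expect_lt(abs(est - (-2)), 3 * se2)
  expect_equal(unname(si2$interaction_estimates[1]), est, tolerance = 0.3)
})
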