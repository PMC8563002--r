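#' Subgroup (effect-modification) analysis by interaction
#'
#' Estimates stratum-specific exposure effects and tests their equality.
#' The joint model augments the design with exposure-by-stratum
#' interaction columns (and stratum main-effect indicators where they vary
#' within a family); the heterogeneity test is a Wald chi-square on the
#' interaction terms, using the cluster-robust covariance for the Gaussian
#' model and the observed-information covariance for the conditional
#' logit. Per-stratum effects come from separate fits restricted to each
#' stratum; strata without informative groups are omitted with a warning.
#'
#' @param births Retained cohort rows (with `group_id`).
#' @param modifier Name of a categorical column (constant within each
#'   record) defining the strata.
#' @param outcome,adjust Passed to [build_design()].
#' @param ... Passed to [build_design()].
#' @return List of class `fs_interaction`: `strata` (named list of
#'   `fs_fit`), `interaction_estimates`, `p_heterogeneity`, `df`.
#' @export
subgroup_interaction <- function(births, modifier,
                                 outcome = "birthweight",
                                 adjust = "full", ...) {
  mod <- factor(births[[modifier]])
  if (nlevels(mod) < 2L) stopf("modifier '%s' has a single level", modifier)
  gaussian <- outcome == "birthweight"

  ## per-stratum fits
  strata <- list()
  for (lev in levels(mod)) {
    sub <- births[mod == lev, , drop = FALSE]
    fit <- tryCatch({
      dm <- build_design(sub, outcome = outcome, adjust = adjust, ...)
      if (gaussian) fe_ols(dm) else conditional_logit(dm)
    }, error = function(e) {
      warning(sprintf("stratum '%s' omitted: %s", lev, conditionMessage(e)),
              call. = FALSE)
      NULL
    })
    if (!is.null(fit)) strata[[lev]] <- fit
  }

  ## joint model with interaction columns
  dm <- build_design(births, outcome = outcome, adjust = adjust, ...)
  ## build_design may drop incomplete cases; align the modifier with the
  ## rows that survived
  modc <- droplevels(mod[dm$rows])
  x <- dm$X[, 1L]
  inter <- sapply(levels(modc)[-1L], function(lev) x * (modc == lev))
  colnames(inter) <- paste0("x_", levels(modc)[-1L])
  main <- sapply(levels(modc)[-1L], function(lev) as.numeric(modc == lev))
  colnames(main) <- paste0("m_", levels(modc)[-1L])
  dm2 <- dm
  dm2$X <- cbind(dm$X, main, inter)
  fit2 <- if (gaussian) fe_ols(dm2) else conditional_logit(dm2)

  keep <- intersect(colnames(inter), fit2$coefficients$term)
  if (length(keep) == 0L) stopf("all interaction terms were dropped")
  idx <- match(keep, fit2$coefficients$term)
  bi <- fit2$coefficients$estimate[idx]
  Vi <- fit2$vcov[keep, keep, drop = FALSE]
  stat <- tryCatch(as.numeric(t(bi) %*% solve(Vi, bi)),
                   error = function(e) NA_real_)
  pval <- if (is.na(stat)) NA_real_ else pchisq(stat, df = length(bi),
                                                lower.tail = FALSE)
  structure(list(strata = strata,
                 interaction_estimates = setNames(bi, keep),
                 wald_stat = stat, df = length(bi), p_heterogeneity = pval,
                 joint_fit = fit2),
            class = "fs_interaction")
}

#' @export
print.fs_interaction <- function(x, ...) {
  cat(sprintf("effect modification: Wald chi2 = %.3g on %d df, p = %.3g\n",
              x$wald_stat, x$df, x$p_heterogeneity))
  for (nm in names(x$strata)) {
    f <- x$strata[[nm]]
    cat(sprintf("  %s: beta = %.4g (95%% CI %.4g to %.4g)\n", nm, f$beta,
                f$ci95[1L], f$ci95[2L]))
  }
  invisible(x)
}
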