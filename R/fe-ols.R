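## least squares via normal equations with rank detection on the
## correlation-scaled Gram matrix; returns kept columns, coefficients and
## (X'X)^-1 for the kept set
fe_solve <- function(Xd, yd, tol = 1e-9) {
  p <- ncol(Xd)
  XtX <- crossprod(Xd)
  d <- sqrt(diag(XtX))
  nz <- which(d > max(d) * 1e-14)
  C <- XtX[nz, nz, drop = FALSE] / outer(d[nz], d[nz])
  qC <- qr(C, tol = tol)
  keep <- sort(nz[qC$pivot[seq_len(qC$rank)]])
  dropped <- setdiff(seq_len(p), keep)
  A <- XtX[keep, keep, drop = FALSE]
  ch <- chol(A)
  XtX_inv <- chol2inv(ch)
  beta <- XtX_inv %*% crossprod(Xd[, keep, drop = FALSE], yd)
  list(beta = as.vector(beta), keep = keep, dropped = dropped,
       XtX_inv = XtX_inv)
}

## within-group demeaning of a matrix (population group means)
demean_by <- function(M, group) {
  M <- as.matrix(M)
  n_g <- tabulate(group)
  gm <- rowsum(M, group, reorder = TRUE) / n_g[sort(unique(group))]
  M - gm[match(group, sort(unique(group))), , drop = FALSE]
}

#' Within-group (fixed-effects) Gaussian regression
#'
#' Estimates the sibling-matched linear model by demeaning the response,
#' the exposure and the covariates within each mother's group and running
#' ordinary least squares on the deviations. The point estimates equal the
#' least-squares-dummy-variable estimator (one intercept per group), but
#' the group intercepts are never materialized, so the fit scales to
#' hundreds of thousands of groups. Groups without internal exposure
#' variation contribute nothing to the exposure estimate.
#'
#' Standard errors: the headline SE is group-clustered robust (mothers are
#' the sampling unit) with the CR1 small-sample factor
#' `G/(G-1) * (N-1)/(N-k)`; the absorbed group intercepts are nested within
#' the clusters and therefore not counted in `k`. Classical
#' (homoskedastic) SEs -- which do count the intercepts in the residual
#' degrees of freedom -- are reported alongside.
#'
#' @param design An [build_design()] result (or any list with `y`, `X`,
#'   `group`).
#' @param se Which SE to use for the headline confidence interval.
#' @return An `fs_fit` with the exposure coefficient as `beta` (g per
#'   ug/m3), its `se`, `ci95`, the full coefficient table, and counts of
#'   records, groups and informative groups.
#' @export
fe_ols <- function(design, se = c("cluster", "classical")) {
  se <- match.arg(se)
  y <- design$y; X <- design$X; group <- design$group
  stopifnot(length(y) == nrow(X), length(group) == length(y))
  Xd <- demean_by(X, group)
  yd <- as.vector(demean_by(y, group))
  wvar <- colSums(Xd^2)
  if (wvar[1L] <= 0)
    stopf("effect unidentified: no within-group exposure variation")
  ## solve by normal equations (the demeaned design is dense but modest in
  ## columns); collinear columns identified on the scaled Gram matrix
  sol <- fe_solve(Xd, yd)
  if (!(1L %in% sol$keep))
    stopf("effect unidentified: exposure collinear after demeaning")
  if (length(sol$dropped))
    fs_log(sprintf("fe_ols: dropping %d collinear column(s): %s",
                   length(sol$dropped),
                   paste(colnames(Xd)[sol$dropped], collapse = ", ")))
  Xd <- Xd[, sol$keep, drop = FALSE]
  beta <- sol$beta
  res <- yd - Xd %*% beta
  N <- length(y)
  G <- length(unique(group))
  K <- ncol(Xd) + G
  df <- N - K
  if (df <= 0) stopf("no residual degrees of freedom")
  XtX_inv <- sol$XtX_inv
  sigma2 <- sum(res^2) / df
  V_cl0 <- XtX_inv %*% crossprod(rowsum(Xd * as.vector(res), group)) %*% XtX_inv
  ## CR1 small-sample factor; the absorbed group intercepts are nested
  ## within the clusters, so they are not counted in the correction
  V_cl <- V_cl0 * (G / (G - 1)) * ((N - 1) / (N - ncol(Xd)))
  V_cls <- sigma2 * XtX_inv
  dimnames(V_cl) <- dimnames(V_cls) <- list(colnames(Xd), colnames(Xd))
  se_cl <- sqrt(diag(V_cl)); se_cls <- sqrt(diag(V_cls))
  ses <- if (se == "cluster") se_cl else se_cls

  ## groups with internal exposure variation
  ex_dev <- Xd[, 1L]
  inform <- sum(rowsum(ex_dev^2, group) > 1e-12)

  coefs <- data.frame(term = colnames(Xd), estimate = as.vector(beta),
                      se_cluster = se_cl, se_classical = se_cls,
                      row.names = NULL)
  new_fs_fit(model = "fe_ols", outcome = design$outcome %||% "y",
             beta = beta[[1L]], se = ses[[1L]],
             coefficients = coefs, vcov = if (se == "cluster") V_cl else V_cls,
             n_records = N, n_groups = G, n_informative_groups = inform,
             sigma = sqrt(sigma2), converged = TRUE,
             exposure = design$exposure %||% colnames(Xd)[1L])
}

new_fs_fit <- function(model, outcome, beta, se, coefficients, vcov,
                       n_records, n_groups, n_informative_groups,
                       converged = TRUE, excess_risk_pct = NULL,
                       sigma = NULL, exposure = "fire_pm", extra = list()) {
  ci <- beta + c(-1, 1) * 1.96 * se
  structure(c(list(model = model, outcome = outcome, beta = beta, se = se,
                   ci95 = ci, coefficients = coefficients, vcov = vcov,
                   n_records = n_records, n_groups = n_groups,
                   n_informative_groups = n_informative_groups,
                   converged = converged, excess_risk_pct = excess_risk_pct,
                   sigma = sigma, exposure = exposure), extra),
            class = "fs_fit")
}

#' @export
print.fs_fit <- function(x, ...) {
  unit <- if (x$model == "fe_ols") "g" else "log-odds"
  cat(sprintf("%s fit of %s: beta = %.4g %s per ug/m3 (se %.3g, 95%% CI %.4g to %.4g)\n",
              x$model, x$outcome, x$beta, unit, x$se, x$ci95[1L], x$ci95[2L]))
  if (!is.null(x$excess_risk_pct))
    cat(sprintf("  excess risk: %.3f%% per ug/m3\n", x$excess_risk_pct))
  cat(sprintf("  %d records, %d groups (%d informative)%s\n", x$n_records,
              x$n_groups, x$n_informative_groups,
              if (isTRUE(x$converged)) "" else "  [NOT CONVERGED]"))
  invisible(x)
}

#' Excess risk from a log-odds coefficient
#'
#' Percentage change in the odds of the outcome per 1 ug/m3 of exposure,
#' `(exp(beta) - 1) * 100`. This sign convention makes a harmful
#' coefficient (`beta > 0`) a positive excess risk, matching the reported
#' positive excess risks for LBW and VLBW.
#'
#' @param beta Log-odds coefficient per unit exposure.
#' @return Excess risk in percent.
#' @examples
#' excess_risk(log(1.1168))  # 11.68
#' @export
excess_risk <- function(beta) (exp(beta) - 1) * 100
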