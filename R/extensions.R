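#' Distributed-lag model over the gestational window
#'
#' Re-expresses the exposure effect as a smooth function of the monthly lag
#' (1..9 months before birth) via a cross-basis: the nine monthly lag
#' exposures are projected on a lag basis `B` (a natural cubic spline over
#' lag with an explicit constant column by default, or the identity for an
#' audit fit), and the projected columns enter the within-group regression.
#' Per-lag effects are `B theta` with delta-method standard errors, and the
#' cumulative effect over the window is their sum. With the identity basis
#' the model is exactly nine free lag coefficients; with a constant basis
#' it collapses to the window-average model (up to the factor 9).
#'
#' @param births Retained cohort rows (with `group_id`).
#' @param lags Matrix of monthly exposures, one column per lag 1..9 before
#'   the birth month (e.g. `cohort$fire_lags[, 1:9]` aligned to the
#'   retained rows).
#' @param basis `"ns"` (natural cubic spline over lag, `df` columns
#'   including the constant) or `"identity"`.
#' @param df Dimension of the spline lag basis (including its constant).
#' @param adjust,outcome,... Passed to [build_design()] for the covariate
#'   part.
#' @return List of class `fs_dlm`: per-lag `effects` (with `se`, `lo`,
#'   `hi`), `cumulative` (+ `cumulative_se`), and the underlying `fs_fit`.
#' @export
distributed_lag_fit <- function(births, lags, basis = c("ns", "identity"),
                                df = 4L, outcome = "birthweight",
                                adjust = "full", ...) {
  basis <- match.arg(basis)
  lags <- as.matrix(lags)
  if (ncol(lags) != 9L) stopf("lags must have 9 columns (lags 1..9)")
  if (nrow(lags) != nrow(births)) stopf("lags rows must match births rows")
  B <- if (basis == "identity") diag(9L)
       else if (df == 1L) matrix(1, 9L, 1L)   # constant basis: window model
       else cbind(1, splines::ns(1:9, df = df - 1L))
  colnames(B) <- paste0("lagbasis", seq_len(ncol(B)))

  dm <- build_design(births, outcome = outcome, adjust = adjust, ...)
  Z <- lags[dm$rows, , drop = FALSE] %*% B
  colnames(Z) <- colnames(B)
  ## replace the window-mean exposure column by the cross-basis columns
  dm$X <- cbind(Z, dm$X[, -1L, drop = FALSE])
  fit <- fe_ols(dm)

  nb <- ncol(B)
  idx <- match(colnames(B), fit$coefficients$term)
  if (anyNA(idx))
    warning("reduced rank: collinear lag-basis column(s) dropped ",
            "(constant exposure over lags?)", call. = FALSE)
  theta <- numeric(nb)
  Vt <- matrix(0, nb, nb)
  ok <- which(!is.na(idx))
  theta[ok] <- fit$coefficients$estimate[idx[ok]]
  Vt[ok, ok] <- fit$vcov[idx[ok], idx[ok]]
  eff <- as.vector(B %*% theta)
  se <- sqrt(pmax(diag(B %*% Vt %*% t(B)), 0))
  cum <- sum(eff)
  cum_se <- sqrt(max(as.numeric(t(colSums(B)) %*% Vt %*% colSums(B)), 0))
  structure(list(
    effects = data.frame(lag = 1:9, estimate = eff, se = se,
                         lo = eff - 1.96 * se, hi = eff + 1.96 * se),
    cumulative = cum, cumulative_se = cum_se,
    basis = basis, fit = fit), class = "fs_dlm")
}

#' @export
print.fs_dlm <- function(x, ...) {
  cat(sprintf("distributed-lag fit (%s basis): cumulative %.4g (se %.3g) over lags 1..9\n",
              x$basis, x$cumulative, x$cumulative_se))
  print(x$effects, digits = 3, row.names = FALSE)
  invisible(x)
}

## thin-plate spline basis of a single covariate via mgcv, with the
## identifiability constraint absorbed (no intercept column)
tp_basis <- function(x, k) {
  sm <- mgcv::smoothCon(mgcv::s(x, bs = "tp", k = k),
                        data = data.frame(x = x), absorb.cons = TRUE)[[1L]]
  list(X = sm$X, sm = sm)
}

#' Nonlinear exposure-response curve within sibling groups
#'
#' Replaces the linear exposure term by a fixed-dimension thin-plate spline
#' basis whose columns are demeaned within each sibling group, so the curve
#' is identified purely by within-family exposure contrasts (the exact
#' nonlinear analogue of the fixed-effects model). The penalty weight is
#' chosen by generalized cross-validation over a log-spaced grid (set
#' `lambda = 0` for an unpenalized fixed-df fit). The fitted curve is
#' anchored to a zero effect at zero exposure; monotonicity is not
#' imposed.
#'
#' @param births Retained cohort rows.
#' @param k Basis dimension of the thin-plate spline.
#' @param lambda Penalty weight; `NULL` (default) selects it by GCV.
#' @param grid_points Number of exposure values at which to evaluate the
#'   curve.
#' @param outcome,adjust,... Passed to [build_design()].
#' @return List of class `fs_curve`: data.frame `curve` (`exposure`,
#'   `estimate`, `lo`, `hi`), `lambda`, `edf`.
#' @export
nonlinear_fit <- function(births, k = 10L, lambda = NULL,
                          grid_points = 100L, outcome = "birthweight",
                          adjust = "full", ...) {
  dm <- build_design(births, outcome = outcome, adjust = adjust, ...)
  x <- dm$X[, 1L]
  if (length(unique(x)) < k)
    stopf("fewer distinct exposure values (%d) than basis dimension (%d)",
          length(unique(x)), k)
  tb <- tp_basis(x, k)
  Xs <- cbind(tb$X, dm$X[, -1L, drop = FALSE])
  Xd <- demean_by(Xs, dm$group)
  yd <- as.vector(demean_by(dm$y, dm$group))
  ns_basis <- ncol(tb$X)
  S <- matrix(0, ncol(Xs), ncol(Xs))
  S[seq_len(ns_basis), seq_len(ns_basis)] <- tb$sm$S[[1L]]

  fit_pen <- function(lam) {
    A <- crossprod(Xd) + lam * S
    Ainv <- tryCatch(solve(A), error = function(e) NULL)
    if (is.null(Ainv)) return(NULL)
    beta <- Ainv %*% crossprod(Xd, yd)
    fitted <- Xd %*% beta
    rss <- sum((yd - fitted)^2)
    edf <- sum(diag(Ainv %*% crossprod(Xd)))
    list(beta = beta, Ainv = Ainv, rss = rss, edf = edf,
         gcv = length(yd) * rss / (length(yd) - edf)^2)
  }
  if (is.null(lambda)) {
    lgrid <- 10^seq(-2, 8, length.out = 25)
    fits <- lapply(lgrid, fit_pen)
    ok <- !vapply(fits, is.null, TRUE)
    gcvs <- vapply(fits[ok], `[[`, 0, "gcv")
    lambda <- lgrid[ok][which.min(gcvs)]
    best <- fits[ok][[which.min(gcvs)]]
  } else best <- fit_pen(lambda)
  if (is.null(best)) stopf("penalized fit failed")

  G <- length(unique(dm$group))
  sigma2 <- best$rss / (length(yd) - best$edf - G)
  Vb <- sigma2 * best$Ainv %*% crossprod(Xd) %*% best$Ainv

  xg <- seq(min(x), max(x), length.out = grid_points)
  Bg <- mgcv::PredictMat(tb$sm, data.frame(x = xg))
  B0 <- mgcv::PredictMat(tb$sm, data.frame(x = 0))
  Ba <- Bg - matrix(B0, nrow(Bg), ncol(Bg), byrow = TRUE)
  bs <- best$beta[seq_len(ns_basis)]
  Vs <- Vb[seq_len(ns_basis), seq_len(ns_basis), drop = FALSE]
  est <- as.vector(Ba %*% bs)
  sec <- sqrt(pmax(rowSums((Ba %*% Vs) * Ba), 0))
  structure(list(curve = data.frame(exposure = xg, estimate = est,
                                    lo = est - 1.96 * sec,
                                    hi = est + 1.96 * sec),
                 lambda = lambda, edf = best$edf,
                 n_records = length(yd), n_groups = G),
            class = "fs_curve")
}

#' @export
print.fs_curve <- function(x, ...) {
  cat(sprintf("nonlinear exposure-response: edf %.2f (lambda %.3g), %d records\n",
              x$edf, x$lambda, x$n_records))
  rng <- range(x$curve$exposure)
  at <- x$curve[which.min(abs(x$curve$exposure - rng[2L])), ]
  cat(sprintf("  effect at %.3g ug/m3: %.4g (95%% CI %.4g to %.4g)\n",
              at$exposure, at$estimate, at$lo, at$hi))
  invisible(x)
}

#' Baseline-varying exposure effect
#'
#' Fits the transformed sibling model in which the exposure coefficient is
#' a smooth function of the family-level mean birthweight: the response is
#' the within-family birthweight deviation and the exposure enters through
#' interaction columns (natural-spline basis in the family mean, including
#' a constant) multiplied by the exposure deviation from its family mean.
#' Because the exposure deviations sum to zero within each family, these
#' interaction columns are orthogonal to the family intercepts, which are
#' thereby absorbed rather than re-estimated; covariates are demeaned
#' within family. With a constant baseline basis the model collapses to
#' the headline fixed-effects fit. Identification comes solely from
#' within-family exposure contrasts interacting with the between-family
#' baseline, so the curve is reported only inside the observed baseline
#' range (no extrapolation).
#'
#' @param births Retained cohort rows, including the family mean
#'   birthweight column `ybar` (added by [build_groups()]).
#' @param anchors Baselines (g) at which to evaluate the effect.
#' @param df Dimension of the baseline basis (including its constant).
#' @param adjust,... Passed to [build_design()].
#' @return List of class `fs_vcurve`: data.frame `at_anchors` with the
#'   absolute effect `beta` (g per ug/m3), the relative effect
#'   `beta / ybar * 100` (% per ug/m3), its negation
#'   `relative_reduction_pct`, and pointwise 95% CIs; plus the spline fit
#'   internals.
#' @export
baseline_varying_fit <- function(births, anchors = c(1500, 2000, 2500, 3000),
                                 df = 5L, adjust = "full", ...) {
  if (is.null(births$ybar)) stopf("births must carry ybar (see build_groups)")
  dm <- build_design(births, outcome = "birthweight", adjust = adjust, ...)
  yb <- births$ybar[dm$rows]
  rng <- range(yb)
  bad <- anchors < rng[1L] | anchors > rng[2L]
  if (any(bad))
    stopf("anchor(s) %s outside the observed baseline range [%.0f, %.0f]",
          paste(anchors[bad], collapse = ", "), rng[1L], rng[2L])
  x <- dm$X[, 1L]
  xd <- as.vector(demean_by(x, dm$group))
  NB <- if (df > 1L) splines::ns(yb, df = df - 1L) else NULL
  W <- if (is.null(NB)) matrix(xd) else cbind(1, NB) * xd
  colnames(W) <- paste0("bbasis", seq_len(ncol(W)))
  Z <- if (ncol(dm$X) > 1L) demean_by(dm$X[, -1L, drop = FALSE], dm$group)
       else NULL
  yd <- as.vector(demean_by(dm$y, dm$group))
  XX <- cbind(W, Z)
  qrX <- qr(XX)
  rank <- qrX$rank
  if (rank < ncol(XX)) {
    keep <- sort(qrX$pivot[seq_len(rank)])
    if (!all(seq_len(ncol(W)) %in% keep))
      stopf("baseline basis collinear: curve unidentified")
    XX <- XX[, keep, drop = FALSE]
    qrX <- qr(XX)
  }
  beta <- qr.coef(qrX, yd)
  res <- yd - XX %*% beta
  N <- length(yd); G <- length(unique(dm$group))
  dfres <- N - ncol(XX) - G
  piv <- qrX$pivot
  XtX_inv <- matrix(0, ncol(XX), ncol(XX))
  XtX_inv[piv, piv] <- chol2inv(qr.R(qrX))
  ## cluster-robust over families
  Vc <- XtX_inv %*% crossprod(rowsum(XX * as.vector(res), dm$group)) %*%
    XtX_inv * (G / (G - 1)) * ((N - 1) / (N - ncol(XX)))

  nb <- ncol(W)
  th <- beta[seq_len(nb)]
  Vt <- Vc[seq_len(nb), seq_len(nb), drop = FALSE]
  Ba <- if (is.null(NB)) matrix(1, length(anchors), 1L)
        else cbind(1, stats::predict(NB, anchors))
  bhat <- as.vector(Ba %*% th)
  sec <- sqrt(pmax(rowSums((Ba %*% Vt) * Ba), 0))
  at <- data.frame(ybar = anchors, beta = bhat, se = sec,
                   lo = bhat - 1.96 * sec, hi = bhat + 1.96 * sec,
                   relative_pct = bhat / anchors * 100,
                   relative_reduction_pct = -bhat / anchors * 100,
                   rel_lo = (bhat - 1.96 * sec) / anchors * 100,
                   rel_hi = (bhat + 1.96 * sec) / anchors * 100)
  structure(list(at_anchors = at, theta = th, vcov_theta = Vt,
                 basis = NB, range = rng, n_records = N, n_groups = G),
            class = "fs_vcurve")
}

#' @export
print.fs_vcurve <- function(x, ...) {
  cat(sprintf("baseline-varying effect (%d records, %d groups):\n",
              x$n_records, x$n_groups))
  print(x$at_anchors[, c("ybar", "beta", "relative_reduction_pct",
                         "rel_lo", "rel_hi")],
        digits = 3, row.names = FALSE)
  invisible(x)
}
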