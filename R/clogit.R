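#' Conditional (fixed-effects) logistic regression for sibling groups
#'
#' Maximizes the exact conditional likelihood of the sibling-matched logit
#' model: each group's fixed effect is eliminated by conditioning on its
#' number of cases, so for a group `g` with `k_g` cases among `n_g`
#' siblings the contribution is
#' `exp(sum_{cases} x'b) / sum_{|S| = k_g} exp(sum_{S} x'b)`,
#' the sum running over all case-subsets of size `k_g`. Groups with no
#' outcome variation (all cases or all controls) carry no information and
#' drop out (their count is logged). This avoids the incidental-parameter
#' bias of estimating one intercept per group and is feasible here because
#' sibling groups are small.
#'
#' Estimation is Newton-Raphson with the analytic gradient and observed
#' information (with step halving); standard errors come from the inverse
#' observed information at the maximum. Apparent separation (the estimate
#' diverging) is flagged and reported as a non-finite estimate.
#'
#' @param design A [build_design()] result with a binary response
#'   (`lbw`/`vlbw`), or any list with `y` (0/1), `X`, `group`.
#' @param max_iter,tol Newton iteration controls.
#' @return An `fs_fit`; `beta` is the exposure log-odds slope per ug/m3 and
#'   `excess_risk_pct` its [excess_risk()] transform.
#' @export
conditional_logit <- function(design, max_iter = 50L, tol = 1e-10) {
  y <- design$y; X <- as.matrix(design$X); group <- design$group
  stopifnot(all(y %in% c(0, 1)))
  p <- ncol(X)

  ## keep informative (discordant) groups only
  ksum <- as.vector(rowsum(y, group))
  nsum <- as.vector(rowsum(rep(1L, length(y)), group))
  gids <- sort(unique(group))
  disc <- gids[ksum > 0 & ksum < nsum]
  n_concord <- length(gids) - length(disc)
  if (length(disc) == 0L)
    stopf("no discordant groups: conditional likelihood is uninformative")
  fs_log(sprintf("conditional_logit: %d concordant group(s) drop out",
                 n_concord))
  sel <- group %in% disc
  y <- y[sel]; X <- X[sel, , drop = FALSE]; group <- group[sel]

  ## organize by stratum of (group size, case count): groups in a stratum
  ## share the subset-enumeration structure, so the likelihood, gradient
  ## and information are computed by dense matrix algebra per stratum
  ord <- order(group)
  y <- y[ord]; X <- X[ord, , drop = FALSE]; group <- group[ord]
  gidx <- match(group, unique(group))
  n_g <- tabulate(gidx)
  k_g <- as.vector(rowsum(y, gidx))
  first <- cumsum(c(1L, head(n_g, -1L)))
  strata <- split(seq_along(n_g), paste(n_g, k_g))

  make_stratum <- function(gs) {
    n <- n_g[gs[1L]]; k <- k_g[gs[1L]]
    S <- combn(n, k)
    Sind <- matrix(0, n, ncol(S))
    Sind[cbind(as.vector(S), rep(seq_len(ncol(S)), each = k))] <- 1
    rows <- as.vector(outer(0:(n - 1L), first[gs], "+"))   # n x m, column-major
    m <- length(gs)
    Xa <- array(X[rows, , drop = FALSE], c(n, m, p))
    ya <- matrix(y[rows], n, m)
    ## case-sum of covariates per group: m x p
    case_sum <- vapply(seq_len(p), function(j)
      colSums(matrix(Xa[, , j], n, m) * ya), numeric(m))
    list(n = n, k = k, m = m, Sind = Sind, Xa = Xa,
         case_sum = matrix(case_sum, ncol = p))
  }
  st <- lapply(strata, make_stratum)

  eval_all <- function(beta) {
    ll <- 0; grad <- numeric(p); info <- matrix(0, p, p)
    for (s in st) {
      eta <- matrix(0, s$n, s$m)
      for (j in seq_len(p))
        eta <- eta + matrix(s$Xa[, , j], s$n, s$m) * beta[j]
      E <- crossprod(eta, s$Sind)              # m x nsub subset linear preds
      Emax <- apply(E, 1L, max)
      Wraw <- exp(E - Emax)
      denom <- rowSums(Wraw)
      W <- Wraw / denom
      ll <- ll + sum(rowSums(s$case_sum * matrix(beta, s$m, p, byrow = TRUE))) -
        sum(Emax + log(denom))
      A <- lapply(seq_len(p), function(j)
        crossprod(matrix(s$Xa[, , j], s$n, s$m), s$Sind))
      mean_s <- vapply(A, function(a) rowSums(W * a), numeric(s$m))
      mean_s <- matrix(mean_s, ncol = p)
      grad <- grad + colSums(s$case_sum - mean_s)
      for (j in seq_len(p)) for (l in j:p) {
        v <- sum(rowSums(W * A[[j]] * A[[l]]) - mean_s[, j] * mean_s[, l])
        info[j, l] <- info[j, l] + v
        if (l > j) info[l, j] <- info[l, j] + v
      }
    }
    list(ll = ll, grad = grad, info = info)
  }

  beta <- numeric(p)
  conv <- FALSE
  ev <- eval_all(beta)
  for (it in seq_len(max_iter)) {
    step <- tryCatch(solve(ev$info, ev$grad), error = function(e) NULL)
    if (is.null(step)) break
    lambda <- 1
    repeat {
      cand <- beta + lambda * step
      ev2 <- eval_all(cand)
      if (ev2$ll >= ev$ll - 1e-12 || lambda < 1e-6) break
      lambda <- lambda / 2
    }
    moved <- max(abs(cand - beta))
    beta <- cand; ev <- ev2
    if (max(abs(ev$grad)) < tol * max(1, abs(ev$ll)) || moved < 1e-12) {
      conv <- TRUE
      break
    }
  }
  ## the conditional likelihood attains its supremum 0 only when every
  ## discordant group is predicted perfectly, i.e. under separation
  separated <- ev$ll > -1e-8 * length(disc) || any(!is.finite(beta)) ||
    max(abs(beta)) > 30
  V <- tryCatch(solve(ev$info), error = function(e) matrix(NA_real_, p, p))
  dimnames(V) <- list(colnames(X), colnames(X))
  ses <- sqrt(diag(V))
  if (separated) {
    beta <- rep(NaN, p)
    fs_log("conditional_logit: apparent separation; estimate non-finite")
  }
  coefs <- data.frame(term = colnames(X), estimate = beta, se = ses,
                      row.names = NULL)
  new_fs_fit(model = "conditional_logit",
             outcome = design$outcome %||% "y",
             beta = beta[1L], se = ses[1L], coefficients = coefs, vcov = V,
             n_records = length(design$y),
             n_groups = length(gids),
             n_informative_groups = length(disc),
             converged = conv && !separated,
             excess_risk_pct = if (is.finite(beta[1L])) excess_risk(beta[1L])
                               else NaN,
             exposure = design$exposure %||% colnames(X)[1L],
             extra = list(loglik = ev$ll, n_concordant = n_concord,
                          separated = separated))
}
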