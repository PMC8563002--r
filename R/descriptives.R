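#' Between/within-group variance decomposition
#'
#' Decomposes the variance of a variable over matched sibling groups into a
#' between-group and a within-group component, using population
#' (denominator `N`) variances so that the identity
#' `between + within = total` holds exactly:
#' `between = sum_g n_g (m_g - m)^2 / N`,
#' `within = sum_g sum_j (x_gj - m_g)^2 / N`.
#' Group means are unweighted within each group; the between component
#' weights groups by size.
#'
#' @param x Numeric vector.
#' @param group Group index, same length as `x`; every group must have at
#'   least 2 members.
#' @return A list of class `fs_decomp`: `total_sd`, `between_sd`,
#'   `within_sd` (units of `x`) and `between_share`, `within_share`
#'   (percent of total variance).
#' @examples
#' d <- decompose_variance(c(1, 3, 5, 7), c(1, 1, 2, 2))
#' c(d$between_sd, d$within_sd, d$total_sd)  # 2, 1, sqrt(5)
#' @export
decompose_variance <- function(x, group) {
  stopifnot(length(x) == length(group), !anyNA(x))
  n_g <- table(group)
  if (any(n_g < 2L)) stopf("every group must have >= 2 members")
  N <- length(x)
  gm <- tapply(x, group, mean)
  m <- mean(x)
  between <- sum(as.vector(n_g) * (as.vector(gm) - m)^2) / N
  within <- sum((x - as.vector(gm)[match(group, names(gm))])^2) / N
  total <- between + within
  structure(list(total_sd = sqrt(total), between_sd = sqrt(between),
                 within_sd = sqrt(within),
                 between_share = 100 * between / total,
                 within_share = 100 * within / total,
                 n = N, n_groups = length(n_g)),
            class = "fs_decomp")
}

#' @export
print.fs_decomp <- function(x, ...) {
  cat(sprintf("total SD %.4g | between %.4g (%.1f%%) | within %.4g (%.1f%%)\n",
              x$total_sd, x$between_sd, x$between_share, x$within_sd,
              x$within_share))
  invisible(x)
}

#' Total, between-group and within-group correlations
#'
#' Pearson correlations of two paired variables in three dimensions:
#' `r_total` on the raw pairs, `r_between` on the group means (one point
#' per group, unweighted; a size-weighted version is also reported), and
#' `r_within` on the within-group deviations. The between dimension
#' reflects spatial contrasts between families; the within dimension
#' reflects temporal contrasts between siblings.
#'
#' @param x,y Numeric vectors.
#' @param group Group index; every group must have >= 2 members.
#' @return List with `r_total`, `r_between`, `r_between_weighted`,
#'   `r_within` (any correlation undefined because a component has zero
#'   variance is `NA`).
#' @export
group_correlations <- function(x, y, group) {
  stopifnot(length(x) == length(y), length(x) == length(group))
  n_g <- table(group)
  if (any(n_g < 2L)) stopf("every group must have >= 2 members")
  safe_cor <- function(a, b, w = NULL) {
    if (sd(a) == 0 || sd(b) == 0) return(NA_real_)
    if (is.null(w)) stats::cor(a, b)
    else {
      wm <- function(v) sum(w * v) / sum(w)
      ca <- a - wm(a); cb <- b - wm(b)
      sum(w * ca * cb) / sqrt(sum(w * ca^2) * sum(w * cb^2))
    }
  }
  gx <- tapply(x, group, mean); gy <- tapply(y, group, mean)
  dx <- x - as.vector(gx)[match(group, names(gx))]
  dy <- y - as.vector(gy)[match(group, names(gy))]
  list(r_total = safe_cor(x, y),
       r_between = safe_cor(as.vector(gx), as.vector(gy)),
       r_between_weighted = safe_cor(as.vector(gx), as.vector(gy),
                                     w = as.vector(n_g)),
       r_within = if (sd(dx) == 0 || sd(dy) == 0) NA_real_
                  else stats::cor(dx, dy))
}

#' Descriptive decomposition table for a sibling cohort
#'
#' Reproduces the descriptive table of the sibling-matched design:
#' between/within-group SDs and variance shares of birthweight and
#' gestational fire-sourced PM2.5, plus their total, between and within
#' correlations.
#'
#' @param births Retained cohort (e.g. `build_groups(...)$births`) with
#'   columns `birthweight`, `fire_pm` and `group_id`.
#' @return A data.frame in the published table's layout (rows total /
#'   between / within).
#' @export
table1 <- function(births) {
  db <- decompose_variance(births$birthweight, births$group_id)
  de <- decompose_variance(births$fire_pm, births$group_id)
  rr <- group_correlations(births$birthweight, births$fire_pm,
                           births$group_id)
  data.frame(
    dimension = c("total", "between_groups", "within_groups"),
    birthweight_sd = c(db$total_sd, db$between_sd, db$within_sd),
    birthweight_share_pct = c(100, db$between_share, db$within_share),
    fire_pm_sd = c(de$total_sd, de$between_sd, de$within_sd),
    fire_pm_share_pct = c(100, de$between_share, de$within_share),
    correlation = c(rr$r_total, rr$r_between, rr$r_within))
}
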