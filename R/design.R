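#' Build the regression design for the sibling-matched models
#'
#' Assembles the response, the exposure column and the adjustment
#' covariates of the fixed-effects model. The full adjustment set is:
#' maternal age, child sex, multiple birth, non-fire-sourced PM2.5, natural
#' cubic spline terms of birth order (5 df), temperature (3 df), humidity
#' (3 df), calendar year (5 df) and month-of-year index (4 df), and a
#' spatiotemporal effect encoded as country x calendar-year indicator
#' cells. Spline knots sit at equally spaced quantiles (boundary knots at
#' the data range); a cyclic month basis is available behind
#' `cyclic_month`. Cells collinear with the mother fixed effect (or with
#' other columns) are removed later, inside the estimators, with a log
#' entry.
#'
#' Only complete cases enter the design (counts logged); constant
#' covariates are dropped with a log entry, and a spline request whose df
#' exceeds the number of distinct values is an error naming the column.
#'
#' @param births Retained cohort rows (see [build_groups()]), including a
#'   `group_id` column.
#' @param outcome `"birthweight"`, `"lbw"` or `"vlbw"`.
#' @param adjust Adjustment set: `"full"`, `"partial"` (maternal age, sex,
#'   multiple birth, non-fire PM2.5) or `"unadjusted"` (exposure only).
#' @param exposure Name of the exposure column (default `fire_pm`).
#' @param spline_df Named degrees of freedom for the spline terms.
#' @param cyclic_month Use a periodic (cyclic) basis for the month index
#'   instead of the default non-cyclic natural spline.
#' @return An object of class `fs_design`: `y`, `X` (exposure in the first
#'   column), `group`, `outcome`, bookkeeping of dropped columns and
#'   complete-case counts.
#' @export
build_design <- function(births,
                         outcome = c("birthweight", "lbw", "vlbw"),
                         adjust = c("full", "partial", "unadjusted"),
                         exposure = "fire_pm",
                         spline_df = c(birth_order = 5L, temperature = 3L,
                                       humidity = 3L, year = 5L, month = 4L),
                         cyclic_month = FALSE) {
  outcome <- match.arg(outcome)
  adjust <- match.arg(adjust)
  if (is.null(births$group_id)) stopf("births must carry a group_id column")

  used <- c(outcome, exposure, "group_id")
  if (adjust != "unadjusted")
    used <- c(used, "maternal_age", "sex", "multiple_birth", "nonfire_pm")
  if (adjust == "full")
    used <- c(used, "birth_order", "temperature", "humidity", "birth_year",
              "birth_month", "country")
  cc <- complete.cases(births[, intersect(used, names(births)), drop = FALSE])
  if (!all(cc)) fs_log(sprintf("build_design: %d incomplete cases dropped",
                               sum(!cc)))
  d <- births[cc, , drop = FALSE]

  dropped <- character(0)
  cols <- list()
  add_linear <- function(cols, v, nm) {
    if (length(unique(v)) < 2L) {
      dropped <<- c(dropped, nm)
      fs_log("build_design: dropping constant column ", nm)
      return(cols)
    }
    cols[[nm]] <- matrix(v, ncol = 1L, dimnames = list(NULL, nm))
    cols
  }
  add_spline <- function(cols, v, nm, df, cyclic = FALSE) {
    nu <- length(unique(v))
    if (nu < 2L) {
      dropped <<- c(dropped, nm)
      fs_log("build_design: dropping constant spline term ", nm)
      return(cols)
    }
    if (df > nu)
      stopf("spline term '%s': %d df requested but only %d distinct values",
            nm, df, nu)
    B <- if (cyclic) {
      ## periodic basis: sine/cosine pairs up to the requested df
      k <- seq_len(ceiling(df / 2))
      M <- do.call(cbind, lapply(k, function(j)
        cbind(sin(2 * pi * j * v / 12), cos(2 * pi * j * v / 12))))
      M[, seq_len(df), drop = FALSE]
    } else suppressWarnings(splines::ns(v, df = df))
    colnames(B) <- paste0(nm, "_s", seq_len(ncol(B)))
    cols[[nm]] <- B
    cols
  }

  cols[[exposure]] <- matrix(d[[exposure]], ncol = 1L,
                             dimnames = list(NULL, exposure))
  if (adjust != "unadjusted") {
    cols <- add_linear(cols, d$maternal_age, "maternal_age")
    cols <- add_linear(cols, as.numeric(d$sex == "male"), "sex_male")
    cols <- add_linear(cols, d$multiple_birth, "multiple_birth")
    cols <- add_linear(cols, d$nonfire_pm, "nonfire_pm")
  }
  if (adjust == "full") {
    cols <- add_spline(cols, d$birth_order, "birth_order",
                       spline_df[["birth_order"]])
    cols <- add_spline(cols, d$temperature, "temperature",
                       spline_df[["temperature"]])
    cols <- add_spline(cols, d$humidity, "humidity", spline_df[["humidity"]])
    cols <- add_spline(cols, d$birth_year, "year", spline_df[["year"]])
    cols <- add_spline(cols, d$birth_month, "month", spline_df[["month"]],
                       cyclic = cyclic_month)
    cy <- interaction(d$country, d$birth_year, drop = TRUE)
    if (nlevels(cy) > 1L) {
      CY <- stats::model.matrix(~ cy)[, -1L, drop = FALSE]
      colnames(CY) <- paste0("cty_", levels(cy)[-1L])
      cols[["country_year"]] <- CY
    } else dropped <- c(dropped, "country_year")
  }
  X <- do.call(cbind, cols)
  structure(list(y = d[[outcome]], X = X, group = d$group_id,
                 outcome = outcome, adjust = adjust, exposure = exposure,
                 dropped = dropped, n = nrow(d), rows = which(cc),
                 n_dropped_cases = sum(!cc)),
            class = "fs_design")
}

#' @export
print.fs_design <- function(x, ...) {
  cat(sprintf("fs_design: outcome %s, %s adjustment, %d records, %d columns\n",
              x$outcome, x$adjust, x$n, ncol(x$X)))
  if (length(x$dropped)) cat("  dropped:", paste(x$dropped, collapse = ", "), "\n")
  invisible(x)
}
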