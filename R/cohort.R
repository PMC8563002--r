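#' Apply the study inclusion criteria to birth records
#'
#' A record is valid when it has (1) a valid birthweight, (2) GPS
#' coordinates, (3) a valid birthdate not after the survey date and within
#' the 5-year recall window, and (4) valid environmental exposure values
#' (satellite coverage gaps and incomplete gestational windows surface here
#' as missing exposure). Validation never throws: every record receives a
#' verdict plus reason codes, so exclusions are fully accounted.
#'
#' Birthweight validity is operationalized as 500-6500 g (plausibility
#' bounds; reported birthweights outside them are treated as data errors).
#'
#' @param births Data frame with columns `birthweight`, `lat`, `lon`,
#'   `birth_year`, `birth_month`, `survey_year`, `survey_month`, `fire_pm`,
#'   `nonfire_pm`, `temperature`, `humidity`.
#' @param bw_range Plausibility bounds for birthweight (g).
#' @return A data.frame with logical `valid` and character `reasons`
#'   (comma-separated codes among `no_birthweight`, `no_gps`,
#'   `bad_birthdate`, `no_exposure`).
#' @export
validate_records <- function(births, bw_range = c(500, 6500)) {
  n <- nrow(births)
  bad_bw <- is.na(births$birthweight) | births$birthweight < bw_range[1L] |
    births$birthweight > bw_range[2L]
  no_gps <- is.na(births$lat) | is.na(births$lon)
  bidx <- ym_index(births$birth_year, births$birth_month)
  sidx <- ym_index(births$survey_year, births$survey_month)
  recall <- sidx - bidx
  bad_date <- is.na(bidx) | is.na(sidx) | recall < 0L | recall > 60L
  no_exp <- is.na(births$fire_pm) | is.na(births$nonfire_pm) |
    is.na(births$temperature) | is.na(births$humidity)
  reasons <- character(n)
  add <- function(reasons, flag, code)
    ifelse(flag, ifelse(reasons == "", code, paste(reasons, code, sep = ",")),
           reasons)
  reasons <- add(reasons, bad_bw, "no_birthweight")
  reasons <- add(reasons, no_gps, "no_gps")
  reasons <- add(reasons, bad_date, "bad_birthdate")
  reasons <- add(reasons, no_exp, "no_exposure")
  data.frame(valid = reasons == "", reasons = reasons,
             stringsAsFactors = FALSE)
}

#' Build sibling groups from validated records
#'
#' Keeps all valid records of mothers with at least two valid records; the
#' mother is the matching unit. Mothers left with fewer than two valid
#' records are excluded (their records are reported, never silently
#' dropped), so `records_in = records_retained + sum(per-reason
#' exclusions)`.
#'
#' @param births Birth records (one row per livebirth) with `mother_id` and
#'   `child_index`.
#' @param validity Optional result of [validate_records()]; computed if
#'   missing.
#' @return A list of class `fs_groups`: `births` (retained rows, with a
#'   `group_id` column and family mean birthweight `ybar`), `groups`
#'   (per-group summary), and `exclusions` (named counts by reason,
#'   including `singleton_mother`).
#' @export
build_groups <- function(births, validity = NULL) {
  if (anyDuplicated(births[c("mother_id", "child_index")]))
    stopf("duplicate (mother_id, child_index) records")
  if (is.null(validity)) validity <- validate_records(births)
  stopifnot(nrow(validity) == nrow(births))
  valid <- validity$valid
  keep_m <- names(which(table(births$mother_id[valid]) >= 2L))
  retained <- valid & births$mother_id %in% keep_m
  excl <- table(unlist(strsplit(validity$reasons[!valid], ",")))
  excl <- c(as.list(excl),
            singleton_mother = sum(valid & !retained))
  if (sum(retained) == 0L) warning("no sibling groups could be formed")
  out <- births[retained, , drop = FALSE]
  out$group_id <- match(out$mother_id, unique(out$mother_id))
  ybar <- tapply(out$birthweight, out$group_id, mean)
  out$ybar <- as.vector(ybar)[out$group_id]
  groups <- data.frame(group_id = as.integer(names(table(out$group_id))),
                       n = as.integer(table(out$group_id)),
                       ybar = as.vector(ybar))
  structure(list(births = out, groups = groups,
                 exclusions = excl,
                 n_in = nrow(births), n_retained = nrow(out)),
            class = "fs_groups")
}

#' @export
print.fs_groups <- function(x, ...) {
  cat(sprintf("fs_groups: %d records retained of %d, in %d sibling groups\n",
              x$n_retained, x$n_in, nrow(x$groups)))
  if (length(x$exclusions))
    cat("  exclusions:", paste(names(x$exclusions), unlist(x$exclusions),
                               sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Label binary birthweight outcomes
#'
#' Low birthweight is a birthweight strictly below 2500 g and very low
#' birthweight strictly below 1500 g (the standard clinical thresholds), so
#' `vlbw` implies `lbw`.
#'
#' @param births Data frame with a `birthweight` column (g).
#' @return The data frame with (re)computed integer `lbw` and `vlbw`
#'   columns.
#' @export
label_outcomes <- function(births) {
  births$lbw <- as.integer(births$birthweight < 2500)
  births$vlbw <- as.integer(births$birthweight < 1500)
  births
}
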