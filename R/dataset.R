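#' Read and write longitudinal dosing/concentration tables
#'
#' The on-disk layout is a NONMEM-style event CSV with one row per dose or
#' observation and columns `ID`, `TIME` (h), `AMT` (mg, dose rows), `DUR`
#' (h, infusion duration), `DV` (mg/L, observation rows), `MDV`, `AGE`,
#' `SEX` (1 = male), `TBW` (kg), `SCR`, `SCR_UNIT` (`mg/dL` or `umol/L`),
#' `ICU` (0/1) and optionally `SHOCK`, `MOF`. Rows with a missing `DV` are
#' dose events; rows with a missing `AMT` are observations.
#'
#' @param path File path.
#' @return `read_dataset()` returns the event data frame after validation.
#' @export
read_dataset <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  validate_dataset(df)
  df
}

#' @rdname read_dataset
#' @param data An event data frame as produced by [generate_cohort()].
#' @export
write_dataset <- function(data, path) {
  validate_dataset(data)
  write.csv(data, path, row.names = FALSE, na = "")
  invisible(path)
}

required_columns <- c("ID", "TIME", "AMT", "DUR", "DV", "MDV", "AGE",
                      "SEX", "TBW", "SCR", "SCR_UNIT", "ICU")

validate_dataset <- function(df) {
  missing_cols <- setdiff(required_columns, names(df))
  if (length(missing_cols))
    stop("dataset lacks required columns: ",
         paste(missing_cols, collapse = ", "))
  if (any(!is.finite(df$TIME)) || any(df$TIME < 0))
    stop("TIME must be non-negative")
  bad_unit <- setdiff(unique(df$SCR_UNIT), c("mg/dL", "umol/L"))
  if (length(bad_unit))
    stop("unknown SCR_UNIT: ", paste(bad_unit, collapse = ", "))
  is_dose <- !is.na(df$AMT)
  is_obs <- !is.na(df$DV) & df$MDV == 0
  if (any(is_dose & is_obs))
    stop("rows cannot be both dose and observation")
  invisible(df)
}

#' Parse an event table into per-subject records
#'
#' Splits the event layout into one record per subject holding covariates,
#' the dosing history and the observations. Serum creatinine is converted
#' to mg/dL, and the subject's creatinine clearance is the mean of the
#' per-row Cockcroft-Gault values over all of that subject's records (the
#' admission-mean convention).
#'
#' @param data An event data frame (see [read_dataset()]).
#' @return A list of class `pk_subjects`; each element has `id`, `covs`
#'   (age, male, tbw, icu, shock, mof, clcr), `doses` and `obs`.
#' @export
as_subjects <- function(data) {
  if (inherits(data, "pk_subjects")) return(data)
  validate_dataset(data)
  ids <- unique(data$ID)
  out <- vector("list", length(ids))
  n_empty <- 0L
  for (k in seq_along(ids)) {
    d <- data[data$ID == ids[k], , drop = FALSE]
    clcr_rows <- cockcroft_gault(d$AGE, d$SEX, d$TBW, d$SCR, d$SCR_UNIT)
    dose_rows <- d[!is.na(d$AMT), , drop = FALSE]
    obs_rows <- d[!is.na(d$DV) & d$MDV == 0, , drop = FALSE]
    if (nrow(obs_rows) == 0) n_empty <- n_empty + 1L
    dur <- dose_rows$DUR
    dur[is.na(dur)] <- 1
    out[[k]] <- list(
      id = ids[k],
      covs = list(age = d$AGE[1], male = d$SEX[1] == 1, tbw = d$TBW[1],
                  icu = d$ICU[1] == 1,
                  shock = if ("SHOCK" %in% names(d)) d$SHOCK[1] == 1 else FALSE,
                  mof = if ("MOF" %in% names(d)) d$MOF[1] == 1 else FALSE,
                  clcr = mean(clcr_rows)),
      doses = dose_events(dose_rows$TIME, dose_rows$AMT, dur),
      obs = data.frame(time = obs_rows$TIME, dv = obs_rows$DV))
  }
  if (n_empty > 0)
    warning(n_empty, " subject(s) have no observations; ",
            "they are excluded from fitting")
  structure(out, class = "pk_subjects")
}

# covariate data frame across subjects (one row each)
subject_covariates <- function(subjects) {
  do.call(rbind, lapply(subjects, function(s)
    data.frame(id = s$id, age = s$covs$age, male = s$covs$male,
               tbw = s$covs$tbw, icu = s$covs$icu, shock = s$covs$shock,
               mof = s$covs$mof, clcr = s$covs$clcr)))
}

# flatten subjects into the CSR arrays consumed by the C++ FOCE evaluator;
# subjects without observations are dropped
flatten_subjects <- function(subjects) {
  keep <- vapply(subjects, function(s) nrow(s$obs) > 0, logical(1))
  subjects <- subjects[keep]
  obs_n <- vapply(subjects, function(s) nrow(s$obs), integer(1))
  dose_n <- vapply(subjects, function(s) nrow(s$doses), integer(1))
  list(subjects = subjects,
       obs_time = unlist(lapply(subjects, function(s) s$obs$time)),
       obs_y = unlist(lapply(subjects, function(s) s$obs$dv)),
       obs_ptr = c(0L, cumsum(obs_n)),
       dose_time = unlist(lapply(subjects, function(s) s$doses$start_time)),
       dose_amt = unlist(lapply(subjects, function(s) s$doses$amount)),
       dose_dur = unlist(lapply(subjects, function(s) s$doses$duration)),
       dose_ptr = c(0L, cumsum(dose_n)),
       covs = subject_covariates(subjects))
}
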