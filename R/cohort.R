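#' Virtual cohort specification
#'
#' Describes the demographic, dosing and sampling design of a virtual
#' therapeutic-drug-monitoring cohort: a mixed ward/ICU adult population
#' with renal function spanning severe impairment to augmented renal
#' clearance, intermittent q12h infusions, and sparse sampling concentrated
#' 5-12 h after the start of an infusion.
#'
#' @param n_subjects Number of subjects.
#' @param icu_fraction,male_fraction Bernoulli probabilities for ICU
#'   admission and male sex.
#' @param age_mean,age_sd Age distribution (years), truncated at 18.
#' @param tbw_mean,tbw_sd Total body weight (kg), truncated at 35.
#' @param clcr_range Range (mL/min) over which each subject's target
#'   creatinine clearance is drawn log-uniformly; the log scale keeps the
#'   augmented-renal tail populated.
#' @param samples_per_subject Named probability vector over the number of
#'   concentration samples per subject; the `"4+"` class draws uniformly
#'   from 4-6 samples.
#' @param sampling_windows Data frame with columns `lower`, `upper` (h after
#'   the start of the reference infusion) and `prob`.
#' @param lloq Lower limit of quantification (mg/L); simulated observations
#'   are floored here (0 disables censoring).
#' @param seed Default RNG seed used by [generate_cohort()].
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects, icu_fraction, male_fraction,
                        age_mean, age_sd, tbw_mean, tbw_sd, clcr_range,
                        samples_per_subject, sampling_windows,
                        lloq = 0, seed = NULL) {
  stopifnot(n_subjects >= 1, age_sd > 0, tbw_sd > 0)
  if (icu_fraction < 0 || icu_fraction > 1 ||
      male_fraction < 0 || male_fraction > 1)
    stop("fractions must lie in [0, 1]")
  if (length(clcr_range) != 2 || clcr_range[1] <= 0 ||
      clcr_range[2] <= clcr_range[1])
    stop("clcr_range must be an increasing positive pair")
  if (abs(sum(samples_per_subject) - 1) > 1e-8)
    stop("samples_per_subject probabilities must sum to 1")
  if (abs(sum(sampling_windows$prob) - 1) > 1e-8)
    stop("sampling_windows probabilities must sum to 1")
  if (lloq < 0) stop("lloq must be non-negative")
  structure(list(n_subjects = n_subjects, icu_fraction = icu_fraction,
                 male_fraction = male_fraction, age_mean = age_mean,
                 age_sd = age_sd, tbw_mean = tbw_mean, tbw_sd = tbw_sd,
                 clcr_range = clcr_range,
                 samples_per_subject = samples_per_subject,
                 sampling_windows = sampling_windows,
                 lloq = lloq, seed = seed),
            class = "cohort_spec")
}

#' Default virtual cohort design
#'
#' The packaged design: 209 subjects, 39.2% ICU, 60.3% male, age
#' 66.0 +/- 16.4 years, weight 63.4 +/- 12.9 kg, creatinine clearance
#' spanning 18.4-390.7 mL/min, sparse sampling (about half the subjects
#' contribute a single level; around 424 samples in total) concentrated in
#' the 5-12 h post-infusion window.
#'
#' @param n_subjects Number of subjects (default 209).
#' @param seed Default RNG seed stored in the spec.
#' @return A [cohort_spec()].
#' @export
default_cohort_spec <- function(n_subjects = 209, seed = NULL) {
  cohort_spec(
    n_subjects = n_subjects,
    icu_fraction = 0.392,
    male_fraction = 0.603,
    age_mean = 66.0, age_sd = 16.4,
    tbw_mean = 63.4, tbw_sd = 12.9,
    clcr_range = c(18.4, 390.7),
    samples_per_subject = c("1" = 0.493, "2" = 0.239, "3" = 0.139,
                            "4+" = 0.129),
    sampling_windows = data.frame(
      lower = c(0.5, 3, 5, 12, 24),
      upper = c(3, 5, 12, 24, 48),
      prob = c(0.059, 0.038, 0.693, 0.177, 0.033)),
    lloq = 0, seed = seed)
}

# truncated-normal draws via inverse CDF so the number of uniforms consumed
# is deterministic (one per subject)
rtnorm_lower <- function(n, mean, sd, lower) {
  p0 <- stats::pnorm((lower - mean) / sd)
  mean + sd * stats::qnorm(p0 + runif(n) * (1 - p0))
}

# clinician-like maintenance dose heuristic: 15 mg/kg q12h scaled by renal
# band, rounded to 250 mg and clipped to the 250-2500 mg practical range
heuristic_dose <- function(tbw, clcr) {
  band <- ifelse(clcr < 30, 0.25, ifelse(clcr < 60, 0.5,
                 ifelse(clcr < 130, 1, 1.3)))
  pmin(pmax(round(15 * tbw * band / 250) * 250, 250), 2500)
}

#' Generate a virtual cohort with simulated concentrations
#'
#' Simulates covariates, dosing histories and observed concentrations from a
#' population model. Subjects receive q12h infusions for 4-8 doses; sampling
#' times are drawn as offsets from the start of the final infusion so that
#' the time-after-dose distribution matches the design windows. Observations
#' are the model prediction times `(1 + eps)` with proportional noise
#' `eps ~ N(0, sigma2)`, floored at the assay quantification limit.
#'
#' All draws come from one RNG stream in a fixed order (sex, ICU, shock/MOF,
#' age, weight, target CLcr, samples per subject, doses per subject,
#' sampling windows and offsets, then per-subject eta and per-observation
#' eps), so a fixed seed reproduces the cohort exactly.
#'
#' @param spec A [cohort_spec()].
#' @param model A [pop_model()] used as simulation truth.
#' @param seed RNG seed; defaults to `spec$seed`. `NULL` leaves the RNG
#'   state untouched.
#' @return A data frame in the longitudinal event layout of
#'   [read_dataset()] (one row per dose or observation), with the true
#'   random effects in `attr(, "eta")`.
#' @export
generate_cohort <- function(spec, model = vanco_model(), seed = spec$seed) {
  stopifnot(inherits(spec, "cohort_spec"), inherits(model, "pop_model"))
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  n <- spec$n_subjects

  ## covariates, fixed draw order
  male <- rbinom(n, 1, spec$male_fraction)
  icu <- rbinom(n, 1, spec$icu_fraction)
  shock <- rbinom(n, 1, ifelse(icu == 1, 0.43, 0.04))
  mof <- rbinom(n, 1, ifelse(icu == 1, 0.07, 0.008))
  age <- rtnorm_lower(n, spec$age_mean, spec$age_sd, 18)
  tbw <- rtnorm_lower(n, spec$tbw_mean, spec$tbw_sd, 35)
  clcr <- exp(runif(n, log(spec$clcr_range[1]), log(spec$clcr_range[2])))
  # back-solve serum creatinine so Cockcroft-Gault reproduces the target
  scr <- (140 - age) * tbw * ifelse(male == 1, 1, 0.85) / (72 * clcr)

  ## design
  n_samp <- sample.int(length(spec$samples_per_subject), n, replace = TRUE,
                       prob = spec$samples_per_subject)
  n_samp <- ifelse(n_samp == length(spec$samples_per_subject),
                   3 + sample.int(3, n, replace = TRUE), n_samp)
  n_dose <- 3 + sample.int(5, n, replace = TRUE)  # 4-8 q12h doses
  dose_amt <- heuristic_dose(tbw, clcr)

  win <- spec$sampling_windows
  rows <- vector("list", n)
  eta <- cbind(eta1 = rnorm(n, 0, sqrt(model$omega2_cl)),
               eta2 = rnorm(n, 0, sqrt(model$omega2_vc)))
  for (i in seq_len(n)) {
    k <- n_dose[i]
    dtimes <- 12 * (seq_len(k) - 1)
    dur <- if (dose_amt[i] >= 1500) 2 else 1
    w <- sample.int(nrow(win), n_samp[i], replace = TRUE, prob = win$prob)
    offs <- runif(n_samp[i], win$lower[w], win$upper[w])
    otimes <- sort(dtimes[k] + offs)
    ev <- dose_events(dtimes, rep(dose_amt[i], k), rep(dur, k))
    p <- realize_individual(clcr[i], icu[i] == 1, model,
                            eta[i, 1], eta[i, 2])
    f <- concentration(otimes, ev, p)
    dv <- pmax(f * (1 + rnorm(n_samp[i], 0, sqrt(model$sigma2))), spec$lloq)
    rows[[i]] <- data.frame(
      ID = i,
      TIME = c(dtimes, otimes),
      AMT = c(rep(dose_amt[i], k), rep(NA_real_, n_samp[i])),
      DUR = c(rep(dur, k), rep(NA_real_, n_samp[i])),
      DV = c(rep(NA_real_, k), dv),
      MDV = c(rep(1L, k), rep(0L, n_samp[i])),
      AGE = age[i], SEX = male[i], TBW = tbw[i],
      SCR = scr[i], SCR_UNIT = "mg/dL", ICU = icu[i],
      SHOCK = shock[i], MOF = mof[i])
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "eta") <- eta
  attr(out, "true_clcr") <- clcr
  out
}
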