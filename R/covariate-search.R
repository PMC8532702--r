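#' Covariate candidates for stepwise model building
#'
#' @param parameter `"cl"` or `"vc"`.
#' @param covariate Covariate name (`clcr`, `age`, `tbw`, `male`, `icu`,
#'   `shock`, `mof`).
#' @param form Functional form: a continuous form (`linear`, `power`,
#'   `exponential`, `saturable`) for continuous covariates or `"shift"` for
#'   booleans.
#' @return A one-row candidate data frame.
#' @export
covariate_candidate <- function(parameter, covariate, form) {
  stopifnot(parameter %in% c("cl", "vc"))
  if (form == "shift" && !covariate %in% boolean_covariates)
    stop("categorical shift requires a boolean covariate")
  if (form != "shift" && covariate %in% boolean_covariates)
    stop("continuous form ", form, " incompatible with boolean covariate ",
         covariate)
  data.frame(parameter = parameter, covariate = covariate, form = form)
}

#' Default candidate set
#'
#' The covariates screened in the reference analysis: renal function
#' (saturable form on clearance), age, weight, sex, ICU admission and the
#' shock / multiple-organ-failure diagnoses, on both clearance and central
#' volume.
#'
#' @return Data frame of candidates.
#' @export
default_candidates <- function() {
  rbind(covariate_candidate("cl", "clcr", "saturable"),
        covariate_candidate("cl", "age", "linear"),
        covariate_candidate("cl", "tbw", "power"),
        covariate_candidate("cl", "male", "shift"),
        covariate_candidate("cl", "icu", "shift"),
        covariate_candidate("cl", "shock", "shift"),
        covariate_candidate("vc", "icu", "shift"),
        covariate_candidate("vc", "tbw", "power"),
        covariate_candidate("vc", "male", "shift"),
        covariate_candidate("vc", "shock", "shift"),
        covariate_candidate("vc", "mof", "shift"))
}

# degrees of freedom a candidate adds to the model
candidate_df <- function(cand) {
  if (cand$form == "saturable") 2L else 1L
}

# try to extend a structure by one candidate; NULL if incompatible with the
# current occupancy (e.g. a second continuous form on the same parameter)
apply_candidate <- function(structure, cand) {
  blk <- structure[[cand$parameter]]
  if (cand$form == "shift") {
    if (cand$parameter == "vc" && blk$form == "const") {
      blk$form <- "shift"
      blk$covariate <- cand$covariate
    } else if (cand$covariate %in% c(blk$shifts, blk$covariate)) {
      return(NULL)
    } else {
      blk$shifts <- c(blk$shifts, cand$covariate)
    }
  } else {
    if (blk$form != "const") return(NULL)  # continuous slot occupied
    blk$form <- cand$form
    blk$covariate <- cand$covariate
  }
  structure[[cand$parameter]] <- blk
  structure
}

# remove a previously included candidate
drop_candidate <- function(structure, cand) {
  blk <- structure[[cand$parameter]]
  if (cand$form == "shift") {
    if (identical(blk$covariate, cand$covariate) && blk$form == "shift") {
      blk$form <- "const"
      blk$covariate <- NULL
    } else {
      blk$shifts <- setdiff(blk$shifts, cand$covariate)
    }
  } else {
    blk$form <- "const"
    blk$covariate <- NULL
  }
  structure[[cand$parameter]] <- blk
  structure
}

#' Stepwise covariate search
#'
#' Forward inclusion followed by backward elimination against the base
#' (covariate-free) model. At each forward round every remaining compatible
#' candidate is fitted; the best candidate enters if its OFV drop exceeds
#' the chi-square 0.05 critical value for the number of parameters it adds
#' (3.84 for one parameter). From the resulting full model, candidates are
#' removed one at a time; a candidate is retained only if its removal
#' raises the OFV by more than the chi-square 0.001 critical value (10.83
#' for one parameter). Candidate fits that fail are logged and treated as
#' not significant.
#'
#' @param data Event data frame or `pk_subjects` list.
#' @param candidates Candidate data frame (see [covariate_candidate()]).
#' @param n_compartments Structural model for the search (default 2).
#' @param control Passed to [fit_popmodel()].
#' @param forward_alpha,backward_alpha Significance levels for the two
#'   phases (defaults 0.05 and 0.001).
#' @return List with the final `structure`, the final `fit`, the included
#'   `selected` candidates and the audit `trail` data frame recording every
#'   tested step's OFV and decision.
#' @export
covariate_search <- function(data, candidates = default_candidates(),
                             n_compartments = 2, control = list(),
                             forward_alpha = 0.05, backward_alpha = 0.001) {
  subjects <- as_subjects(data)
  base_struct <- model_structure(n_compartments, cl = list(form = "const"),
                                 vc = list(form = "const"))
  current <- fit_popmodel(subjects, base_struct, control = control)
  struct <- base_struct
  included <- candidates[0, ]
  trail <- list()
  note <- function(phase, step, cand, ofv, delta, decision)
    trail[[length(trail) + 1]] <<- data.frame(
      phase = phase, step = step,
      candidate = if (is.null(cand)) "base"
                  else paste0(cand$parameter, "~", cand$covariate,
                              "(", cand$form, ")"),
      ofv = ofv, delta_ofv = delta, decision = decision)
  note("forward", 0L, NULL, current$ofv, NA, "base model")

  remaining <- candidates
  step <- 0L
  repeat {
    step <- step + 1L
    best <- NULL
    for (k in seq_len(nrow(remaining))) {
      cand <- remaining[k, ]
      st <- apply_candidate(struct, cand)
      if (is.null(st)) next
      ft <- tryCatch(fit_popmodel(subjects, st, control = control),
                     error = function(e) NULL)
      if (is.null(ft)) {
        note("forward", step, cand, NA, NA, "fit failed")
        next
      }
      delta <- current$ofv - ft$ofv
      crit <- stats::qchisq(1 - forward_alpha, candidate_df(cand))
      sig <- delta > crit
      note("forward", step, cand, ft$ofv, delta,
           if (sig) "significant" else "not significant")
      if (sig && (is.null(best) || delta > best$delta))
        best <- list(cand = cand, fit = ft, st = st, delta = delta, k = k)
    }
    if (is.null(best)) break
    struct <- best$st
    current <- best$fit
    included <- rbind(included, best$cand)
    remaining <- remaining[-best$k, ]
    note("forward", step, best$cand, current$ofv, best$delta, "ADDED")
  }

  ## backward elimination from the full model
  step <- 0L
  repeat {
    step <- step + 1L
    if (nrow(included) == 0) break
    worst <- NULL
    for (k in seq_len(nrow(included))) {
      cand <- included[k, ]
      st <- drop_candidate(struct, cand)
      ft <- tryCatch(fit_popmodel(subjects, st, control = control),
                     error = function(e) NULL)
      if (is.null(ft)) {
        note("backward", step, cand, NA, NA, "removal fit failed; retained")
        next
      }
      delta <- ft$ofv - current$ofv  # OFV increase on removal
      crit <- stats::qchisq(1 - backward_alpha, candidate_df(cand))
      retain <- delta > crit
      note("backward", step, cand, ft$ofv, delta,
           if (retain) "retained" else "removable")
      if (!retain && (is.null(worst) || delta < worst$delta))
        worst <- list(cand = cand, fit = ft, st = st, delta = delta, k = k)
    }
    if (is.null(worst)) break
    struct <- worst$st
    current <- worst$fit
    included <- included[-worst$k, ]
    note("backward", step, worst$cand, current$ofv, worst$delta, "REMOVED")
  }

  list(structure = struct, fit = current, selected = included,
       trail = do.call(rbind, trail))
}
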