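#' Dosing regimen
#'
#' @param dose Dose per administration (mg).
#' @param interval Dosing interval (h); one of 8, 12 or 24.
#' @param infusion_duration Infusion duration (h). Defaults to 1 h, or 2 h
#'   for doses of 1500 mg and above (usual rate-limited vancomycin practice).
#' @return An object of class `regimen`.
#' @export
regimen <- function(dose, interval, infusion_duration = NULL) {
  if (!is.numeric(dose) || dose <= 0) stop("dose must be positive")
  if (!interval %in% c(8, 12, 24)) stop("interval must be 8, 12 or 24 h")
  if (is.null(infusion_duration))
    infusion_duration <- if (dose >= 1500) 2 else 1
  if (infusion_duration <= 0 || infusion_duration >= interval)
    stop("infusion_duration must lie in (0, interval)")
  structure(list(dose = dose, interval = interval,
                 infusion_duration = infusion_duration), class = "regimen")
}

#' @export
print.regimen <- function(x, ...) {
  cat(sprintf("%g mg q%gh (%g-h infusion)\n", x$dose, x$interval,
              x$infusion_duration))
  invisible(x)
}

#' Dose-event table
#'
#' @param start_time Infusion start times (h).
#' @param amount Dose amounts (mg).
#' @param duration Zero-order infusion durations (h).
#' @return A data frame of dose events sorted by start time.
#' @export
dose_events <- function(start_time, amount, duration) {
  if (any(duration <= 0)) stop("infusion duration must be positive")
  if (any(amount <= 0)) stop("dose amount must be positive")
  d <- data.frame(start_time = start_time, amount = amount,
                  duration = duration)
  d[order(d$start_time), , drop = FALSE]
}

#' Central-compartment concentration under intermittent infusion
#'
#' Closed-form superposition of zero-order-infusion two-compartment
#' solutions. With micro-constants \eqn{k_{10} = CL/V_c},
#' \eqn{k_{12} = Q/V_c}, \eqn{k_{21} = Q/V_p}, the hybrid rate constants
#' \eqn{\alpha,\beta} are the roots of
#' \eqn{\lambda^2 - (k_{10}+k_{12}+k_{21})\lambda + k_{10}k_{21} = 0};
#' each finite infusion is the difference of two never-ending-infusion
#' responses. `q = 0` gives the one-compartment model; the repeated-root
#' case \eqn{\alpha \approx \beta} uses the analytic limit form.
#'
#' @param t Times (h) at which to evaluate; vectorized.
#' @param events A [dose_events()] data frame.
#' @param p A `pk_parameters` object (scalar parameters).
#' @return Concentrations (mg/L), zero before the first infusion starts.
#' @export
#' @examples
#' p <- realize_individual(clcr = 90, icu = FALSE)
#' ev <- dose_events(c(0, 12), c(1000, 1000), c(1, 1))
#' concentration(c(1, 6, 12, 13), ev, p)
concentration <- function(t, events, p) {
  stopifnot(inherits(p, "pk_parameters"))
  if (any(t < 0)) stop("t must be non-negative")
  events <- dose_events(events$start_time, events$amount, events$duration)
  cpp_conc(as.numeric(t), as.numeric(events$start_time),
           as.numeric(events$amount), as.numeric(events$duration),
           p$cl[1], p$vc[1], p$q[1], p$vp[1])
}

# hybrid rate constants and bolus coefficients; list(lambda, coef) with
# C_bolus(t) = dose * sum(coef * exp(-lambda * t))
macro_constants <- function(p) {
  k10 <- p$cl / p$vc
  if (p$q <= 0) return(list(lambda = k10, coef = 1 / p$vc, repeated = FALSE))
  k12 <- p$q / p$vc
  k21 <- p$q / p$vp
  s <- k10 + k12 + k21
  sq <- sqrt(max(s^2 - 4 * k10 * k21, 0))
  a <- (s + sq) / 2
  b <- (s - sq) / 2
  if (a - b < 1e-9 * a)
    return(list(lambda = c(a, b), coef = NA, repeated = TRUE))
  list(lambda = c(a, b),
       coef = c((a - k21) / (p$vc * (a - b)), (k21 - b) / (p$vc * (a - b))),
       repeated = FALSE)
}

#' Steady-state daily exposure (AUC24)
#'
#' For linear kinetics the steady-state 24-h area under the curve is exactly
#' the daily dose divided by clearance, independent of the compartmental
#' volumes.
#'
#' @param reg A [regimen()].
#' @param p A `pk_parameters` object (vectorized over `cl`).
#' @return AUC over 24 h at steady state (mg h/L).
#' @export
auc24_steady_state <- function(reg, p) {
  stopifnot(inherits(reg, "regimen"))
  (24 / reg$interval) * reg$dose / p$cl
}

#' Steady-state trough concentration
#'
#' Concentration at the end of the dosing interval at steady state, from the
#' geometric-series accumulation of each bi-exponential term: every
#' exponential \eqn{e^{-\lambda t}} accumulates by the factor
#' \eqn{1/(1 - e^{-\lambda \tau})} under repeated dosing with interval
#' \eqn{\tau}. In the degenerate repeated-root case the interdose
#' superposition series is summed directly to convergence.
#'
#' @param reg A [regimen()].
#' @param p A `pk_parameters` object (scalar parameters).
#' @return Trough concentration (mg/L) just before the next dose.
#' @export
trough_steady_state <- function(reg, p) {
  stopifnot(inherits(reg, "regimen"))
  tau <- reg$interval
  dur <- reg$infusion_duration
  rate <- reg$dose / dur
  mc <- macro_constants(list(cl = p$cl[1], vc = p$vc[1], q = p$q[1],
                             vp = p$vp[1]))
  if (isTRUE(mc$repeated)) {
    # direct superposition sum, converging geometrically
    ev <- dose_events(0, reg$dose, dur)
    pk <- pk_parameters(p$cl[1], p$vc[1], p$q[1], p$vp[1])
    total <- 0
    for (k in 0:2000) {
      inc <- concentration(tau + k * tau, ev, pk)
      total <- total + inc
      if (inc < 1e-12 * max(total, 1e-300)) break
    }
    return(total)
  }
  lam <- mc$lambda
  co <- mc$coef
  sum(rate * co / lam * (1 - exp(-lam * dur)) * exp(-lam * (tau - dur)) /
        (1 - exp(-lam * tau)))
}
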