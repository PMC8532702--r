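#' Population pharmacokinetic model parameters
#'
#' Container for the fixed effects, inter-individual variances and residual
#' variance of the vancomycin population model. Clearance follows a saturable
#' (Hill-type) function of creatinine clearance,
#' \deqn{CL = CL_{max} \cdot CLcr^s / (CG_{50}^s + CLcr^s) \cdot e^{\eta_1},}
#' the central volume takes distinct typical values for ICU and non-ICU
#' patients (\eqn{V_c \cdot e^{\eta_2}}), and inter-compartmental clearance
#' \eqn{Q} and peripheral volume \eqn{V_p} are common to all subjects.
#' Residual variability is proportional: \eqn{y = f (1 + \epsilon)},
#' \eqn{\epsilon \sim N(0, \sigma^2)}.
#'
#' @param cl_max Theoretical maximum clearance (L/h).
#' @param cg50 Creatinine clearance at which clearance reaches half of
#'   `cl_max` (mL/min).
#' @param s Dimensionless steepness (Hill) exponent.
#' @param vc_non_icu,vc_icu Typical central volume of distribution (L) for
#'   general-ward and intensive-care patients.
#' @param q Inter-compartmental clearance (L/h).
#' @param vp Peripheral volume of distribution (L).
#' @param omega2_cl,omega2_vc Variances of the lognormal inter-individual
#'   random effects on clearance and central volume.
#' @param sigma2 Variance of the proportional residual error.
#'
#' @return An object of class `pop_model` (a named list).
#' @seealso [vanco_model()] for the packaged adult vancomycin estimates.
#' @export
pop_model <- function(cl_max, cg50, s, vc_non_icu, vc_icu, q, vp,
                      omega2_cl = 0, omega2_vc = 0, sigma2 = 0) {
  th <- c(cl_max = unname(cl_max), cg50 = unname(cg50), s = unname(s),
          vc_non_icu = unname(vc_non_icu), vc_icu = unname(vc_icu),
          q = unname(q), vp = unname(vp))
  if (any(!is.finite(th)) || any(th <= 0))
    stop("all fixed-effect parameters must be positive and finite")
  vr <- c(omega2_cl = omega2_cl, omega2_vc = omega2_vc, sigma2 = sigma2)
  if (any(!is.finite(vr)) || any(vr < 0))
    stop("variance components must be non-negative")
  structure(c(as.list(th), as.list(vr)), class = "pop_model")
}

#' Reference adult vancomycin population model
#'
#' The packaged estimates for intravenous vancomycin in adult patients with
#' creatinine clearance between roughly 18 and 390 mL/min: maximum clearance
#' 5.58 L/h reached half-maximally at CLcr = 93.8 mL/min with steepness 1.5,
#' central volume 8.02 L (ward) or 35.7 L (ICU), Q = 2.66 L/h, Vp = 36.8 L,
#' IIV variances 0.0771 (CL) and 0.223 (Vc), proportional residual variance
#' 0.0466.
#'
#' @return A [pop_model()] object.
#' @export
#' @examples
#' m <- vanco_model()
#' clearance_typical(130, m)  # ~3.46 L/h at the augmented-renal threshold
vanco_model <- function() {
  pop_model(cl_max = 5.58, cg50 = 93.8, s = 1.5,
            vc_non_icu = 8.02, vc_icu = 35.7, q = 2.66, vp = 36.8,
            omega2_cl = 0.0771, omega2_vc = 0.223, sigma2 = 0.0466)
}

#' @export
print.pop_model <- function(x, ...) {
  cat("Vancomycin population PK model (2-compartment, saturable CLcr on CL)\n")
  cat(sprintf("  CLmax %.3g L/h, CG50 %.3g mL/min, s %.3g\n",
              x$cl_max, x$cg50, x$s))
  cat(sprintf("  Vc %.3g L (non-ICU) / %.3g L (ICU), Q %.3g L/h, Vp %.3g L\n",
              x$vc_non_icu, x$vc_icu, x$q, x$vp))
  cat(sprintf("  omega2: CL %.4g, Vc %.4g; sigma2 %.4g\n",
              x$omega2_cl, x$omega2_vc, x$sigma2))
  invisible(x)
}

#' Cockcroft-Gault creatinine clearance
#'
#' \eqn{CLcr = (140 - age) \cdot TBW / (72 \cdot SCr)} mL/min with SCr in
#' mg/dL, multiplied by 0.85 for women. Serum creatinine reported in
#' micromol/L is converted at 88.4 micromol/L per mg/dL; the unit must be
#' given explicitly so that the conversion is never silent.
#'
#' @param age Age in years (adults; >= 18).
#' @param sex `"male"`/`"female"` (or 1/0 coded, 1 = male).
#' @param tbw Total body weight (kg).
#' @param scr Serum creatinine.
#' @param scr_unit `"mg/dL"` or `"umol/L"`, recycled as needed.
#' @return Creatinine clearance in mL/min. Vectorized over all arguments.
#' @export
#' @examples
#' cockcroft_gault(40, "male", 72, 1.0, "mg/dL")   # 100 mL/min
#' cockcroft_gault(40, "female", 72, 88.4, "umol/L")  # 85 mL/min
cockcroft_gault <- function(age, sex, tbw, scr, scr_unit = "mg/dL") {
  if (is.character(sex) || is.factor(sex)) {
    sex <- as.character(sex)
    if (!all(sex %in% c("male", "female")))
      stop("sex must be 'male' or 'female' (or 0/1 with 1 = male)")
    male <- sex == "male"
  } else {
    male <- as.numeric(sex) == 1
  }
  scr_unit <- rep_len(as.character(scr_unit), length(scr))
  known <- scr_unit %in% c("mg/dL", "umol/L")
  if (!all(known))
    stop("unknown SCR unit: ", paste(unique(scr_unit[!known]), collapse = ", "))
  scr_mgdl <- ifelse(scr_unit == "umol/L", scr / 88.4, scr)
  if (any(!is.finite(scr_mgdl)) || any(scr_mgdl <= 0))
    stop("serum creatinine must be positive")
  if (any(!is.finite(tbw)) || any(tbw <= 0))
    stop("total body weight must be positive")
  if (any(age < 18)) warning("Cockcroft-Gault applied to age < 18 years")
  (140 - age) * tbw / (72 * scr_mgdl) * ifelse(male, 1, 0.85)
}

#' Typical vancomycin clearance at a given creatinine clearance
#'
#' Saturable covariate model
#' \eqn{CL_{max} CLcr^s / (CG_{50}^s + CLcr^s)}: strictly increasing in CLcr,
#' asymptoting at `cl_max`, with half-maximum exactly at `cg50`.
#'
#' @param clcr Creatinine clearance (mL/min); vectorized.
#' @param model A [pop_model()].
#' @return Typical clearance (L/h).
#' @export
clearance_typical <- function(clcr, model = vanco_model()) {
  if (any(!is.finite(clcr)) || any(clcr <= 0))
    stop("clcr must be positive")
  model$cl_max * clcr^model$s / (model$cg50^model$s + clcr^model$s)
}

#' Typical central volume of distribution
#'
#' @param icu Logical (vectorized): admitted to intensive care?
#' @param model A [pop_model()].
#' @return Typical central volume (L).
#' @export
vc_typical <- function(icu, model = vanco_model()) {
  ifelse(as.logical(icu), model$vc_icu, model$vc_non_icu)
}

#' Individual pharmacokinetic parameters
#'
#' Applies the covariate model and the lognormal inter-individual random
#' effects: \eqn{CL_i = CL_{typ} e^{\eta_1}}, \eqn{V_{c,i} = V_c e^{\eta_2}};
#' Q and Vp are copied from the population values.
#'
#' @param clcr Creatinine clearance (mL/min).
#' @param icu Logical ICU flag.
#' @param model A [pop_model()].
#' @param eta1,eta2 Random-effect values (0 gives the typical subject).
#' @return A list of class `pk_parameters` with elements `cl`, `vc`, `q`,
#'   `vp`; with vector input, each element is a vector.
#' @export
realize_individual <- function(clcr, icu, model = vanco_model(),
                               eta1 = 0, eta2 = 0) {
  if (any(!is.finite(eta1)) || any(!is.finite(eta2)))
    stop("eta values must be finite")
  p <- list(cl = clearance_typical(clcr, model) * exp(eta1),
            vc = vc_typical(icu, model) * exp(eta2),
            q = rep_len(model$q, max(length(clcr), length(icu))),
            vp = rep_len(model$vp, max(length(clcr), length(icu))))
  class(p) <- "pk_parameters"
  p
}

#' @rdname realize_individual
#' @param cl,vc,q,vp Directly specified individual parameters (L/h, L).
#' @export
pk_parameters <- function(cl, vc, q, vp) {
  if (any(c(cl, vc, vp) <= 0) || any(q < 0))
    stop("pk parameters must be positive (q may be zero)")
  structure(list(cl = cl, vc = vc, q = q, vp = vp), class = "pk_parameters")
}
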