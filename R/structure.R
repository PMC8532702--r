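#' Structural and covariate model specification
#'
#' Describes a candidate nonlinear mixed-effects model: the number of
#' disposition compartments and the covariate model on clearance and central
#' volume. Continuous covariate forms on clearance are `"const"` (no
#' covariate), `"linear"`, `"power"`, `"exponential"` (each centred at the
#' dataset median) and `"saturable"` (Hill); boolean covariates enter as
#' categorical shifts. The central volume supports `"const"`, a `"shift"`
#' on a boolean covariate, or `"power"` on a continuous one. Lognormal
#' inter-individual random effects are always placed on clearance and
#' central volume, with a proportional residual error.
#'
#' @param n_compartments 1 or 2.
#' @param cl,vc Lists `list(form, covariate, shifts)` for the clearance and
#'   central-volume covariate models. `shifts` is a character vector of
#'   boolean covariate names entering as multiplicative ratios.
#' @return An object of class `model_structure`.
#' @export
#' @examples
#' # the reference vancomycin model: saturable CLcr on CL, ICU on Vc
#' model_structure()
#' # covariate-free two-compartment base model
#' model_structure(cl = list(form = "const"), vc = list(form = "const"))
model_structure <- function(n_compartments = 2,
                            cl = list(form = "saturable", covariate = "clcr"),
                            vc = list(form = "shift", covariate = "icu")) {
  cl <- modifyList(list(form = "const", covariate = NULL,
                        shifts = character()), cl)
  vc <- modifyList(list(form = "const", covariate = NULL,
                        shifts = character()), vc)
  if (!n_compartments %in% c(1, 2))
    stop("n_compartments must be 1 or 2")
  if (!cl$form %in% c("const", "linear", "power", "exponential", "saturable"))
    stop("unknown clearance covariate form: ", cl$form)
  if (!vc$form %in% c("const", "shift", "power"))
    stop("unknown central-volume covariate form: ", vc$form)
  if (cl$form != "const" && is.null(cl$covariate))
    stop("cl covariate form ", cl$form, " needs a covariate")
  if (vc$form != "const" && is.null(vc$covariate))
    stop("vc covariate form ", vc$form, " needs a covariate")
  structure(list(n_compartments = n_compartments, cl = cl, vc = vc),
            class = "model_structure")
}

#' @export
print.model_structure <- function(x, ...) {
  blk <- function(b) {
    base <- if (b$form == "const") "typical value"
      else paste0(b$form, "(", b$covariate, ")")
    if (length(b$shifts))
      base <- paste0(base, " * shifts[", paste(b$shifts, collapse = ","), "]")
    base
  }
  cat(sprintf("%d-compartment model; CL: %s; Vc: %s\n", x$n_compartments,
              blk(x$cl), blk(x$vc)))
  invisible(x)
}

boolean_covariates <- c("male", "icu", "shock", "mof")

# parameter table: name, transform ("log"/"id"), init; driven by structure
# and the covariate summary of the data
par_table <- function(structure, covs, inits = NULL) {
  rows <- list()
  add <- function(name, transform, init)
    rows[[length(rows) + 1]] <<- data.frame(name = name,
                                            transform = transform,
                                            init = init)
  med <- function(v) stats::median(covs[[v]])
  cl <- structure$cl
  switch(cl$form,
    const = add("cl", "log", 3),
    saturable = {
      add("cl_max", "log", 6)
      add("cg50", "log", med(cl$covariate))
      add("s", "log", 1)
    },
    linear = { add("cl", "log", 3); add("cl_slope", "id", 0.001) },
    power = { add("cl", "log", 3); add("cl_pwr", "id", 0.5) },
    exponential = { add("cl", "log", 3); add("cl_expo", "id", 0.001) })
  for (z in cl$shifts) add(paste0("cl_", z, "_ratio"), "log", 1)
  vc <- structure$vc
  if (vc$form == "const") {
    add("vc", "log", 20)
  } else if (vc$form == "shift" && identical(vc$covariate, "icu")) {
    add("vc_non_icu", "log", 12)
    add("vc_icu", "log", 30)
  } else if (vc$form == "shift") {
    add("vc", "log", 20)
    add(paste0("vc_", vc$covariate, "_ratio"), "log", 1.5)
  } else {  # power
    add("vc", "log", 20)
    add("vc_pwr", "id", 0.5)
  }
  for (z in vc$shifts) add(paste0("vc_", z, "_ratio"), "log", 1)
  if (structure$n_compartments == 2) {
    add("q", "log", 3)
    add("vp", "log", 30)
  }
  tab <- do.call(rbind, rows)
  if (!is.null(inits)) {
    hit <- intersect(names(inits), tab$name)
    tab$init[match(hit, tab$name)] <- unlist(inits[hit])
  }
  tab
}

# map named natural-scale theta + per-subject covariates to typical
# (cl, vc, q, vp) vectors
typical_values <- function(theta, structure, covs) {
  n <- nrow(covs)
  med <- function(v) stats::median(covs[[v]])
  cl <- structure$cl
  cl_typ <- switch(cl$form,
    const = rep(theta[["cl"]], n),
    saturable = {
      x <- covs[[cl$covariate]]
      theta[["cl_max"]] * x^theta[["s"]] /
        (theta[["cg50"]]^theta[["s"]] + x^theta[["s"]])
    },
    linear = {
      x <- covs[[cl$covariate]]
      theta[["cl"]] * pmax(1 + theta[["cl_slope"]] * (x - med(cl$covariate)),
                           1e-3)
    },
    power = {
      x <- covs[[cl$covariate]]
      theta[["cl"]] * (x / med(cl$covariate))^theta[["cl_pwr"]]
    },
    exponential = {
      x <- covs[[cl$covariate]]
      theta[["cl"]] * exp(theta[["cl_expo"]] * (x - med(cl$covariate)))
    })
  for (z in cl$shifts)
    cl_typ <- cl_typ * theta[[paste0("cl_", z, "_ratio")]]^as.numeric(covs[[z]])
  vc <- structure$vc
  vc_typ <- if (vc$form == "const") {
    rep(theta[["vc"]], n)
  } else if (vc$form == "shift" && identical(vc$covariate, "icu")) {
    ifelse(covs$icu, theta[["vc_icu"]], theta[["vc_non_icu"]])
  } else if (vc$form == "shift") {
    theta[["vc"]] *
      theta[[paste0("vc_", vc$covariate, "_ratio")]]^as.numeric(covs[[vc$covariate]])
  } else {
    x <- covs[[vc$covariate]]
    theta[["vc"]] * (x / med(vc$covariate))^theta[["vc_pwr"]]
  }
  for (z in vc$shifts)
    vc_typ <- vc_typ * theta[[paste0("vc_", z, "_ratio")]]^as.numeric(covs[[z]])
  if (structure$n_compartments == 2) {
    list(cl = cl_typ, vc = vc_typ,
         q = rep(theta[["q"]], n), vp = rep(theta[["vp"]], n))
  } else {
    list(cl = cl_typ, vc = vc_typ, q = rep(0, n), vp = rep(1, n))
  }
}
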