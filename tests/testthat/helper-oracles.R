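# Independent numerical oracles used across the suite.

# Stiff-safe numerical integration of the two-compartment infusion ODE
# system; the reference for the closed-form concentration solution.
ode_conc <- function(times, doses, cl, vc, q, vp) {
  rate_fun <- function(t) {
    r <- 0
    for (k in seq_len(nrow(doses)))
      if (t >= doses$start_time[k] &&
          t < doses$start_time[k] + doses$duration[k])
        r <- r + doses$amount[k] / doses$duration[k]
    r
  }
  derivs <- function(t, y, parms) {
    k10 <- cl / vc
    k12 <- if (q > 0) q / vc else 0
    k21 <- if (q > 0) q / vp else 0
    list(c(rate_fun(t) - (k10 + k12) * y[1] + k21 * y[2],
           k12 * y[1] - k21 * y[2]))
  }
  grid <- sort(unique(c(0, doses$start_time,
                        doses$start_time + doses$duration, times)))
  out <- deSolve::ode(c(0, 0), grid, derivs, NULL, method = "lsoda",
                      rtol = 1e-11, atol = 1e-11)
  stats::approx(out[, 1], out[, 2], xout = times)$y / vc
}

# Exact marginal -2 log-likelihood by adaptive Gauss-Hermite quadrature
# (mode-centred, Hessian-scaled); independent of the FOCE linearization.
agq_ofv <- function(subjects, model, n_nodes = 15) {
  gh <- pracma::gaussHermite(n_nodes)
  w <- c(model$omega2_cl, model$omega2_vc)
  total <- 0
  for (s in subjects) {
    clt <- clearance_typical(s$covs$clcr, model)
    vct <- vc_typical(s$covs$icu, model)
    g <- function(eta) {
      p <- pk_parameters(clt * exp(eta[1]), vct * exp(eta[2]),
                         model$q, model$vp)
      f <- pmax(concentration(s$obs$time, s$doses, p), 1e-10)
      -sum(dnorm(s$obs$dv, f, sqrt(model$sigma2) * f, log = TRUE)) -
        dnorm(eta[1], 0, sqrt(w[1]), log = TRUE) -
        dnorm(eta[2], 0, sqrt(w[2]), log = TRUE)
    }
    opt <- stats::optim(c(0, 0), g, method = "BFGS")
    H <- pracma::hessian(g, opt$par)
    Cl <- t(chol(solve(H)))
    L <- 0
    for (i in seq_len(n_nodes)) for (j in seq_len(n_nodes)) {
      z <- c(gh$x[i], gh$x[j])
      eta <- opt$par + sqrt(2) * as.vector(Cl %*% z)
      L <- L + gh$w[i] * gh$w[j] * exp(-g(eta) + sum(z^2))
    }
    total <- total - 2 * log(L * 2 * prod(diag(Cl)))
  }
  total
}

# named fixed-effect vector of the reference model, as fit_popmodel names it
ref_theta <- function(model = vanco_model()) {
  c(cl_max = model$cl_max, cg50 = model$cg50, s = model$s,
    vc_non_icu = model$vc_non_icu, vc_icu = model$vc_icu,
    q = model$q, vp = model$vp)
}

# bootstrap percentile 95% CIs of the reference analysis, used as recovery
# bands for simulation-based checks
ref_ci <- list(cl_max = c(4.26, 8.52), cg50 = c(66.99, 178.63),
               s = c(1.16, 1.95), vc_non_icu = c(4.90, 11.80),
               vc_icu = c(26.68, 48.37))

# small rich-sampling cohort: denser designs than the sparse default, for
# estimation tests that need well-identified subjects
rich_cohort <- function(n_subjects, model = vanco_model(), seed = 1,
                        obs_times = c(1.5, 3, 6, 11.5, 30, 47.5),
                        n_doses = 4, interval = 12) {
  set.seed(seed)
  clcr <- exp(runif(n_subjects, log(20), log(350)))
  icu <- rbinom(n_subjects, 1, 0.4)
  eta1 <- rnorm(n_subjects, 0, sqrt(model$omega2_cl))
  eta2 <- rnorm(n_subjects, 0, sqrt(model$omega2_vc))
  age <- runif(n_subjects, 30, 85)
  tbw <- runif(n_subjects, 45, 95)
  male <- rbinom(n_subjects, 1, 0.6)
  scr <- (140 - age) * tbw * ifelse(male == 1, 1, 0.85) / (72 * clcr)
  rows <- lapply(seq_len(n_subjects), function(i) {
    dtimes <- interval * (seq_len(n_doses) - 1)
    ev <- dose_events(dtimes, rep(1000, n_doses), rep(1, n_doses))
    p <- realize_individual(clcr[i], icu[i] == 1, model, eta1[i], eta2[i])
    f <- concentration(obs_times, ev, p)
    dv <- f * (1 + rnorm(length(obs_times), 0, sqrt(model$sigma2)))
    data.frame(ID = i, TIME = c(dtimes, obs_times),
               AMT = c(rep(1000, n_doses), rep(NA, length(obs_times))),
               DUR = c(rep(1, n_doses), rep(NA, length(obs_times))),
               DV = c(rep(NA, n_doses), dv),
               MDV = c(rep(1L, n_doses), rep(0L, length(obs_times))),
               AGE = age[i], SEX = male[i], TBW = tbw[i], SCR = scr[i],
               SCR_UNIT = "mg/dL", ICU = icu[i], SHOCK = 0L, MOF = 0L)
  })
  do.call(rbind, rows)
}
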