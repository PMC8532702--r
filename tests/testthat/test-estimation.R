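# The FOCE-I objective is validated against exact marginal likelihoods and
# its own analytic limits; fits are validated by simulation recovery.

test_that("FOCE-I objective matches adaptive Gauss-Hermite quadrature", {
  skip_if_not_installed("pracma")
  m <- vanco_model()
  th <- ref_theta(m)
  # sparse 3-subject cohort
  d3 <- generate_cohort(default_cohort_spec(n_subjects = 3), seed = 31)
  foce <- foce_objective(d3, model_structure(), th,
                         c(m$omega2_cl, m$omega2_vc), m$sigma2)
  exact <- agq_ofv(as_subjects(d3), m)
  expect_lt(abs(foce - exact), 0.5)
  # 10-subject cohort
  d10 <- generate_cohort(default_cohort_spec(n_subjects = 10), seed = 32)
  foce10 <- foce_objective(d10, model_structure(), th,
                           c(m$omega2_cl, m$omega2_vc), m$sigma2)
  exact10 <- agq_ofv(as_subjects(d10), m)
  expect_lt(abs(foce10 - exact10), 1)
})

test_that("zero-variance limit reduces to the naive-pooled -2 log-likelihood", {
  m <- vanco_model()
  d <- generate_cohort(default_cohort_spec(n_subjects = 12), seed = 33)
  subs <- as_subjects(d)
  ofv <- foce_objective(subs, model_structure(), ref_theta(m), c(0, 0),
                        m$sigma2)
  pooled <- sum(vapply(subs, function(s) {
    p <- realize_individual(s$covs$clcr, s$covs$icu, m)
    f <- concentration(s$obs$time, s$doses, p)
    -2 * sum(dnorm(s$obs$dv, f, sqrt(m$sigma2) * f, log = TRUE))
  }, 0))
  expect_equal(ofv, pooled, tolerance = 1e-8)
})

test_that("objective is additive over subjects and order-invariant", {
  m <- vanco_model()
  th <- ref_theta(m)
  w <- c(m$omega2_cl, m$omega2_vc)
  d <- generate_cohort(default_cohort_spec(n_subjects = 8), seed = 34)
  ofv1 <- foce_objective(d, model_structure(), th, w, m$sigma2)
  dup <- d
  dup$ID <- dup$ID + 1000
  ofv2 <- foce_objective(rbind(d, dup), model_structure(), th, w, m$sigma2)
  expect_equal(ofv2, 2 * ofv1, tolerance = 1e-8)
  # permuting subject order leaves the OFV unchanged
  perm <- d[order(-d$ID, d$TIME), ]
  expect_equal(foce_objective(perm, model_structure(), th, w, m$sigma2),
               ofv1, tolerance = 1e-8)
})

test_that("objective is invariant to consistent time-unit rescaling", {
  m <- vanco_model()
  d <- generate_cohort(default_cohort_spec(n_subjects = 8), seed = 35)
  th <- ref_theta(m)
  ofv1 <- foce_objective(d, model_structure(), th,
                         c(m$omega2_cl, m$omega2_vc), m$sigma2)
  # express time in days: rates CL and Q scale by 24
  d2 <- d
  d2$TIME <- d$TIME / 24
  d2$DUR <- d$DUR / 24
  th2 <- th
  th2[c("cl_max", "q")] <- th[c("cl_max", "q")] * 24
  ofv2 <- foce_objective(d2, model_structure(), th2,
                         c(m$omega2_cl, m$omega2_vc), m$sigma2)
  expect_equal(ofv2, ofv1, tolerance = 1e-6)
})

test_that("a single densely sampled noise-free subject is fit exactly", {
  set.seed(36)
  p_true <- pk_parameters(2.5, 20, 3, 35)
  ev <- dose_events(c(0, 12, 24), rep(1000, 3), rep(1, 3))
  tt <- seq(0.5, 48, by = 1)
  f <- concentration(tt, ev, p_true)
  d <- data.frame(ID = 1, TIME = c(ev$start_time, tt),
                  AMT = c(ev$amount, rep(NA, length(tt))),
                  DUR = c(ev$duration, rep(NA, length(tt))),
                  DV = c(rep(NA, 3), f * (1 + rnorm(length(tt), 0, 1e-4))),
                  MDV = c(rep(1L, 3), rep(0L, length(tt))),
                  AGE = 50, SEX = 1, TBW = 70, SCR = 1, SCR_UNIT = "mg/dL",
                  ICU = 0)
  fit <- fit_popmodel(d, model_structure(2, cl = list(form = "const"),
                                         vc = list(form = "const")),
                      inits = list(omega2_cl = 1e-6, omega2_vc = 1e-6,
                                   sigma2 = 1e-6),
                      control = list(hessian = FALSE))
  expect_equal(unname(fit$theta["cl"]), p_true$cl, tolerance = 1e-3)
  expect_equal(unname(fit$theta["vc"]), p_true$vc, tolerance = 1e-3)
  expect_equal(unname(fit$theta["q"]), p_true$q, tolerance = 1e-2)
  expect_equal(unname(fit$theta["vp"]), p_true$vp, tolerance = 1e-2)
})

test_that("refitting from a solution is a fixed point of the optimizer", {
  d <- rich_cohort(25, seed = 37)
  fit <- fit_popmodel(d, control = list(hessian = FALSE))
  refit <- fit_popmodel(d, inits = c(as.list(fit$theta),
                                     list(omega2_cl = fit$omega2[[1]],
                                          omega2_vc = fit$omega2[[2]],
                                          sigma2 = fit$sigma2)),
                        control = list(hessian = FALSE, pooled = FALSE))
  expect_lt(abs(refit$ofv - fit$ofv), 1e-3)
  expect_equal(fit$aic, fit$ofv + 2 * fit$n_par)
})

test_that("structural comparison selects the data-generating compartment count", {
  # rich early+late sampling separates distribution and elimination phases
  d <- rich_cohort(60, seed = 38)
  cmp <- compare_structures(d, control = list(hessian = FALSE))
  expect_equal(cmp$selected, "two_cpt")
  expect_equal(cmp$two_cpt$aic, cmp$two_cpt$ofv + 2 * cmp$two_cpt$n_par)
  # one-compartment truth: q = 0 nested limit
  m1 <- pop_model(5.58, 93.8, 1.5, 25, 35, q = 1e-6, vp = 30,
                  omega2_cl = 0.0771, omega2_vc = 0.1, sigma2 = 0.02)
  d1 <- rich_cohort(40, model = m1, seed = 39)
  cmp1 <- compare_structures(d1, control = list(hessian = FALSE))
  expect_true(cmp1$selected == "one_cpt" ||
                abs(cmp1$one_cpt$aic - cmp1$two_cpt$aic) <= 2)
})

test_that("the saturable clearance-CLcr form wins on saturable-truth data", {
  d <- rich_cohort(80, seed = 40)
  tab <- compare_cl_forms(d, control = list(hessian = FALSE))
  expect_true(all(is.finite(tab$ofv)))
  expect_equal(tab$form[1], "saturable")
})

test_that("stepwise search recovers true covariates and rejects absent ones", {
  cands <- rbind(covariate_candidate("cl", "clcr", "saturable"),
                 covariate_candidate("cl", "age", "linear"),
                 covariate_candidate("vc", "icu", "shift"),
                 covariate_candidate("vc", "shock", "shift"))
  d <- rich_cohort(60, seed = 41)
  res <- covariate_search(d, cands, control = list(hessian = FALSE))
  got <- paste(res$selected$parameter, res$selected$covariate)
  expect_true("cl clcr" %in% got)
  expect_true("vc icu" %in% got)
  expect_s3_class(res$trail, "data.frame")
  expect_true(any(res$trail$phase == "backward"))

  # covariate-free truth: constant CL (cg50 << clcr range), no ICU shift
  m0 <- pop_model(3, 1e-4, 1, 20, 20, 2.66, 36.8,
                  omega2_cl = 0.0771, omega2_vc = 0.1, sigma2 = 0.0466)
  null_hits <- vapply(1:3, function(s) {
    d0 <- rich_cohort(50, model = m0, seed = 500 + s)
    r0 <- covariate_search(d0, cands, control = list(hessian = FALSE))
    nrow(r0$selected)
  }, 0)
  expect_gte(sum(null_hits == 0), 2)
})

test_that("simulation from the reference truth recovers its fixed effects", {
  d <- generate_cohort(default_cohort_spec(), seed = 42)
  fit <- fit_popmodel(d)
  expect_true(fit$converged)
  expect_true(all(is.finite(fit$rse)))
  for (nm in names(ref_ci)) {
    expect_gt(fit$theta[[nm]], ref_ci[[nm]][1] * 0.9)
    expect_lt(fit$theta[[nm]], ref_ci[[nm]][2] * 1.1)
  }
  # empirical Bayes estimates are finite and centred near zero
  expect_true(all(is.finite(fit$eta)))
  expect_lt(abs(mean(fit$eta[, 1])), 0.15)
})
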