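# one shared fit of the default-design cohort, reused across the file
shared <- local({
  d <- generate_cohort(default_cohort_spec(), seed = 77)
  list(data = d, fit = fit_popmodel(d, control = list(hessian = FALSE)))
})

# build a pk_fit shell at user-chosen parameters without optimizing, for
# limit-case diagnostics
fit_at <- function(data, theta, omega2, sigma2,
                   structure = model_structure()) {
  fl <- vancopk:::flatten_subjects(as_subjects(data))
  res <- vancopk:::foce_eval(fl, structure, theta, omega2, sigma2,
                             want_diag = TRUE)
  structure(list(theta = theta,
                 omega2 = setNames(omega2, c("omega2_cl", "omega2_vc")),
                 sigma2 = sigma2, ofv = res$ofv, eta = res$eta,
                 converged = TRUE, structure = structure,
                 subjects = fl$subjects, flat = fl),
            class = "pk_fit")
}

test_that("conditional weighted residuals are calibrated under the true model", {
  g <- gof(shared$fit)
  expect_equal(nrow(g), sum(shared$data$MDV == 0))
  expect_true(all(g$tad >= 0))
  expect_lt(abs(mean(g$cwres)), 0.1)
  expect_gt(sd(g$cwres), 0.85)
  expect_lt(sd(g$cwres), 1.15)
  # individual predictions track the data more closely than population ones
  expect_lt(mean((g$dv - g$ipred)^2), mean((g$dv - g$pred)^2))
})

test_that("in the noise-free limit ipred equals the data and cwres vanishes", {
  m <- vanco_model()
  m0 <- pop_model(m$cl_max, m$cg50, m$s, m$vc_non_icu, m$vc_icu, m$q, m$vp)
  d <- generate_cohort(default_cohort_spec(n_subjects = 10), m0, seed = 51)
  f <- fit_at(d, ref_theta(m), c(1e-10, 1e-10), 1e-10)
  g <- gof(f)
  expect_equal(g$ipred, g$dv, tolerance = 1e-6)
  expect_lt(max(abs(g$cwres)), 0.01)
})

test_that("cwres is invariant to the concentration unit", {
  m <- vanco_model()
  d <- generate_cohort(default_cohort_spec(n_subjects = 15), seed = 52)
  g1 <- gof(fit_at(d, ref_theta(m), c(m$omega2_cl, m$omega2_vc), m$sigma2))
  # rescale to ug/L: amounts and observations 1000-fold
  d2 <- d
  d2$AMT <- d$AMT * 1000
  d2$DV <- d$DV * 1000
  g2 <- gof(fit_at(d2, ref_theta(m), c(m$omega2_cl, m$omega2_vc), m$sigma2))
  expect_equal(g2$cwres, g1$cwres, tolerance = 1e-6)
})

test_that("subject-resampling bootstrap is reproducible and summarized", {
  d <- rich_cohort(30, seed = 53)
  b1 <- pk_bootstrap(d, n_replicates = 8, seed = 7,
                     control = list(hessian = FALSE))
  b2 <- pk_bootstrap(d, n_replicates = 8, seed = 7,
                     control = list(hessian = FALSE))
  expect_identical(b1$indices, b2$indices)
  expect_identical(b1$summary, b2$summary)
  expect_gt(b1$success_rate, 0.5)
  expect_true(all(b1$summary$ci_lo <= b1$summary$median))
  expect_true(all(b1$summary$median <= b1$summary$ci_hi))
  expect_error(pk_bootstrap(d, n_replicates = 0), "at least 1")
})

test_that("bootstrap medians of the reference cohort stay in published bands", {
  b <- pk_bootstrap(shared$data, n_replicates = 10, seed = 54,
                    control = list(hessian = FALSE))
  med <- b$summary$median[b$summary$parameter == "cl_max"]
  expect_gt(med, ref_ci$cl_max[1])
  expect_lt(med, ref_ci$cl_max[2])
})

test_that("the pc-VPC self-covers data simulated from the fitted model", {
  v <- pc_vpc(shared$fit, n_sim = 200, bins = 8, seed = 55)
  expect_true(all(v$sim_lo <= v$sim_hi))
  # percentile ordering within each bin
  for (b in unique(v$bin)) {
    ob <- v$observed[v$bin == b][order(v$percentile[v$bin == b])]
    expect_true(all(diff(ob) >= 0))
  }
  expect_gte(attr(v, "coverage"), 0.8)
})

test_that("degenerate VPC inputs behave as limits dictate", {
  small <- local({
    d <- generate_cohort(default_cohort_spec(n_subjects = 20), seed = 56)
    m <- vanco_model()
    fit_at(d, ref_theta(m), c(m$omega2_cl, m$omega2_vc), m$sigma2)
  })
  v1 <- pc_vpc(small, n_sim = 1, bins = 4, seed = 57)
  expect_equal(v1$sim_lo, v1$sim_hi)  # a single replicate has no spread
  # binning is deterministic given the data and bin count
  va <- pc_vpc(small, n_sim = 5, bins = 4, seed = 58)
  vb <- pc_vpc(small, n_sim = 5, bins = 4, seed = 59)
  expect_identical(va[c("bin", "tad_lo", "tad_hi", "n")],
                   vb[c("bin", "tad_lo", "tad_hi", "n")])
  expect_identical(va$observed, vb$observed)
})
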