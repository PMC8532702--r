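test_that("Monte Carlo PTA agrees with the semianalytic integral", {
  combos <- list(list(st = c(15, 29), reg = regimen(250, 24)),
                 list(st = c(60, 89), reg = regimen(1250, 24)),
                 list(st = c(150, 179), reg = regimen(1000, 12)),
                 list(st = c(90, 119), reg = regimen(750, 12)))
  for (cb in combos) {
    mc <- simulate_pta(cb$st, cb$reg, n_sim = 10000, seed = 61)
    exact <- pta_semianalytic_auc(cb$st, cb$reg)
    expect_lt(abs(mc$pta - exact), 3 * max(mc$se, 1e-4))
    # binomial error bound at n = 10000
    expect_lte(mc$se, 0.005)
  }
})

test_that("degenerate PTA limits are exact", {
  m <- vanco_model()
  # deterministic model, near-point stratum: attainment is all-or-nothing
  m0 <- pop_model(m$cl_max, m$cg50, m$s, m$vc_non_icu, m$vc_icu, m$q, m$vp,
                  omega2_cl = 0, omega2_vc = 0, sigma2 = 0)
  p_in <- simulate_pta(c(60, 60.001), regimen(1000, 24), model = m0,
                       n_sim = 500, seed = 62)
  expect_true(p_in$pta %in% c(0, 1))
  # a regimen far above the window for every plausible draw
  p_hi <- simulate_pta(c(15, 29), regimen(2500, 8), n_sim = 10000, seed = 63)
  expect_equal(p_hi$pta, 0)
  # vacuous target
  wide <- exposure_target("auc24", 1e-9, 1e15)
  expect_equal(simulate_pta(c(60, 89), regimen(1000, 12), wide,
                            n_sim = 100, seed = 64)$pta, 1)
  expect_equal(pta_semianalytic_auc(c(60, 89), regimen(1000, 12), wide), 1,
               tolerance = 1e-6)
  expect_error(simulate_pta(c(60, 89), regimen(1000, 12), n_sim = 0),
               "n_sim")
})

test_that("deterministic-clearance limit equals the interval measure", {
  m <- vanco_model()
  m0 <- pop_model(m$cl_max, m$cg50, m$s, m$vc_non_icu, m$vc_icu, m$q, m$vp)
  # clcr interval mapping into the window, compared against brute force
  st <- c(30, 60)
  reg <- regimen(750, 24)
  exact <- pta_semianalytic_auc(st, reg, model = m0)
  grid <- seq(st[1], st[2], length.out = 200001)
  auc <- 750 / clearance_typical(grid, m0)
  expect_equal(exact, mean(auc >= 400 & auc <= 650), tolerance = 1e-3)
})

test_that("daily-exposure PTA depends on clearance only", {
  # identical seeds: ICU status and the volume parameters cannot matter
  a <- simulate_pta(c(90, 119), regimen(750, 12), icu = FALSE, seed = 65)
  b <- simulate_pta(c(90, 119), regimen(750, 12), icu = TRUE, seed = 65)
  expect_equal(a$pta, b$pta)
  m2 <- pop_model(5.58, 93.8, 1.5, vc_non_icu = 16, vc_icu = 70, q = 5,
                  vp = 80, omega2_cl = 0.0771, omega2_vc = 0.223,
                  sigma2 = 0.0466)
  c2 <- simulate_pta(c(90, 119), regimen(750, 12), model = m2, seed = 65)
  expect_equal(a$pta, c2$pta)
})

test_that("trough attainment uses the full disposition model", {
  tgt <- exposure_target("trough", 10, 20)
  a <- simulate_pta(c(60, 89), regimen(1000, 12), tgt, icu = FALSE,
                    n_sim = 4000, seed = 66)
  b <- simulate_pta(c(60, 89), regimen(1000, 12), tgt, icu = TRUE,
                    n_sim = 4000, seed = 66)
  expect_true(a$pta > 0 && a$pta < 1)
  expect_false(isTRUE(all.equal(a$pta, b$pta)))  # Vc shifts the trough
})

test_that("PTA is unimodal in daily dose over a fixed stratum", {
  daily <- sort(unique(default_grid()$daily_dose))
  # the AUC24 target depends on daily dose alone: evaluate q24 equivalents
  pta <- vapply(daily, function(dd)
    pta_semianalytic_auc(c(60, 89), regimen(dd, 24)), 0)
  peak <- which.max(pta)
  expect_true(all(diff(pta[seq_len(peak)]) >= -1e-12))
  expect_true(all(diff(pta[peak:length(pta)]) <= 1e-12))
})

test_that("regimen recommendation respects ties and grid structure", {
  # singleton grid returns its only regimen
  g1 <- default_grid(doses = 750, intervals = 12)
  r1 <- recommend_regimens(default_strata()[3, , drop = FALSE], g1,
                           n_sim = 2000, seed = 67)
  expect_equal(r1$dose, 750)
  expect_equal(r1$interval, 12)
  # equal daily dose means identical attainment under common random
  # numbers; the tie goes to the smaller infusion per administration
  g2 <- default_grid(doses = c(1000, 2000), intervals = c(12, 24))
  r2 <- recommend_regimens(data.frame(lower = 150, upper = 179,
                                      label = "150-179"),
                           g2, n_sim = 5000, seed = 68)
  all_pta <- attr(r2, "all_pta")
  tied <- all_pta[all_pta$daily_dose == 2000, ]
  expect_equal(length(unique(tied$pta)), 1)
  expect_equal(r2$dose, 1000)
  expect_equal(r2$interval, 12)
})
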