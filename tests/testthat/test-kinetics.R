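test_that("closed-form concentrations match stiff ODE integration", {
  skip_if_not_installed("deSolve")
  cases <- list(
    list(p = pk_parameters(2.79, 8.02, 2.66, 36.8),
         ev = dose_events(c(0, 12, 24), c(1000, 1000, 500), c(1, 1, 2))),
    list(p = pk_parameters(5.5, 35.7, 2.66, 36.8),
         ev = dose_events(c(0, 8, 16), c(2000, 2000, 2000), c(2, 2, 2))),
    list(p = pk_parameters(0.45, 8.02, 2.66, 36.8),
         ev = dose_events(0, 250, 1)),
    # one-compartment limit
    list(p = pk_parameters(3, 30, 0, 1),
         ev = dose_events(c(0, 24), c(1500, 1500), c(2, 2))))
  times <- c(0.25, 0.999, 1.5, 3, 7.77, 12, 18, 25.5, 40, 72)
  for (cs in cases) {
    a <- concentration(times, cs$ev, cs$p)
    b <- ode_conc(times, cs$ev, cs$p$cl, cs$p$vc, cs$p$q, cs$p$vp)
    expect_lt(max(abs(a - b) / pmax(abs(b), 1e-9)), 1e-6)
  }
})

test_that("concentration is zero pre-dose, linear in dose, superposable", {
  p <- pk_parameters(2.8, 8, 2.66, 36.8)
  ev <- dose_events(c(5, 17), c(750, 750), c(1, 1))
  expect_equal(concentration(c(0, 2, 4.99), ev, p), c(0, 0, 0))
  t <- c(6, 10, 20, 30)
  ev2 <- dose_events(ev$start_time, 2 * ev$amount, ev$duration)
  expect_equal(concentration(t, ev2, p), 2 * concentration(t, ev, p))
  # superposition of separate event lists
  evA <- dose_events(5, 750, 1)
  evB <- dose_events(17, 750, 1)
  expect_equal(concentration(t, evA, p) + concentration(t, evB, p),
               concentration(t, ev, p))
  expect_true(all(concentration(seq(0, 48, 0.5), ev, p) >= 0))
  expect_error(concentration(-1, ev, p), "non-negative")
})

test_that("q = 0 collapses to the one-compartment infusion solution", {
  p <- pk_parameters(3, 30, 0, 1)
  k <- p$cl / p$vc
  rate <- 1500 / 2
  ev <- dose_events(0, 1500, 2)
  t_in <- 1.2
  t_out <- 9
  expect_equal(concentration(t_in, ev, p),
               rate / (p$vc * k) * (1 - exp(-k * t_in)))
  expect_equal(concentration(t_out, ev, p),
               rate / (p$vc * k) * (1 - exp(-k * 2)) * exp(-k * (t_out - 2)))
})

test_that("near-degenerate equal hybrid rate constants use the limit form", {
  # k10 == k21 with k12 -> 0 forces alpha ~ beta; the profile must agree
  # with the one-compartment solution the limit represents
  vc <- 10; cl <- 1; q <- 1e-21; vp <- q / (cl / vc)
  p <- pk_parameters(cl, vc, q, vp)
  p1 <- pk_parameters(cl, vc, 0, 1)
  ev <- dose_events(0, 1000, 1)
  t <- c(0.5, 1, 5, 12, 24)
  expect_equal(concentration(t, ev, p), concentration(t, ev, p1),
               tolerance = 1e-8)
})

test_that("steady-state AUC24 equals daily dose over clearance", {
  expect_equal(auc24_steady_state(regimen(500, 24), pk_parameters(1, 8, 2, 30)),
               500)
  expect_equal(auc24_steady_state(regimen(750, 12), pk_parameters(3, 8, 2, 30)),
               500)
  # numeric-integration oracle: trapezoid over one day at cycle 20
  p <- pk_parameters(2.79, 8.02, 2.66, 36.8)
  reg <- regimen(1000, 12)
  ev <- dose_events(12 * (0:41), rep(1000, 42), rep(1, 42))
  tt <- seq(20 * 24, 21 * 24, by = 0.01)
  cc <- concentration(tt, ev, p)
  auc_num <- sum((cc[-1] + cc[-length(cc)]) / 2 * diff(tt))
  expect_equal(auc24_steady_state(reg, p), auc_num, tolerance = 0.005)
})

test_that("closed-form steady-state trough matches long simulation", {
  p <- pk_parameters(2.79, 8.02, 2.66, 36.8)
  for (reg in list(regimen(1000, 12), regimen(2000, 24), regimen(500, 8))) {
    n <- 60
    ev <- dose_events(reg$interval * (0:(n - 1)), rep(reg$dose, n),
                      rep(reg$infusion_duration, n))
    sim <- concentration(n * reg$interval, ev, p)
    expect_equal(trough_steady_state(reg, p), sim, tolerance = 0.001)
  }
  # one-compartment branch
  p1 <- pk_parameters(3, 30, 0, 1)
  reg <- regimen(1000, 12)
  ev <- dose_events(12 * (0:59), rep(1000, 60), rep(1, 60))
  expect_equal(trough_steady_state(reg, p1), concentration(720, ev, p1),
               tolerance = 0.001)
})

test_that("trough falls with longer intervals and vanishes at high clearance", {
  p <- pk_parameters(2.79, 8.02, 2.66, 36.8)
  troughs <- vapply(c(8, 12, 24),
                    function(tau) trough_steady_state(regimen(750, tau), p), 0)
  expect_true(all(diff(troughs) < 0))
  expect_lt(trough_steady_state(regimen(750, 12),
                                pk_parameters(5e4, 8.02, 2.66, 36.8)), 1e-6)
})
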