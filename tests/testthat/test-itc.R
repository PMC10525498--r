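# ITC simulation: power trace physics, instrument response, baseline
# correction, per-injection heats and enthalpy estimation.

prdx1_trace <- function() cached("prdx1_trace",
                                 simulate_itc(itc_protocol(),
                                              kinetic_parameters()))

test_that("protocol and trace validation", {
  expect_error(itc_protocol(n_injections = 0), "at least one injection")
  expect_error(itc_protocol(injection_volume = -1), "positive")
  expect_error(power_trace(c(0, 1, 3), c(0, 0, 0)), "uniform")
  expect_error(instrument_model(response_time = -1), ">= 0")
})

test_that("dissociation injections are endothermic and post-CTC heats collapse", {
  tr <- prdx1_trace()
  expect_true(all(tr$power <= 1e-9))   # endothermic-negative convention
  h <- injection_heats(tr)$heat_ucal
  # early injections (dilute cell) release nearly equal heats; the n = 5
  # equilibrium is soft, so the decline pre-transition is gradual
  pre <- h[2:5]
  expect_lt(stats::sd(pre) / abs(mean(pre)), 0.10)
  # the heat per injection shrinks steadily as the cell fills towards the
  # transition, collapsing to a small fraction of the early heats
  expect_true(all(diff(abs(h[2:length(h)])) < 0))
  expect_lt(max(abs(utils::tail(h, 3))), 0.2 * abs(mean(pre)))
})

test_that("energy bookkeeping: integrated heat equals enthalpy times moles dissociated", {
  # fine sampling: the power jumps at injections make the trapezoidal
  # quadrature first-order accurate at the boundaries
  pro <- itc_protocol(n_injections = 8)
  tr <- simulate_itc(pro, kinetic_parameters(), sampling_interval = 0.02)
  sp <- attr(tr, "species")
  # reaction-only change in dimer amount = final - initial - injected
  nd_end <- sp$dimer[nrow(sp)] * sp$volume[nrow(sp)] / 1000
  nd_0 <- pro$syringe_total_dimer * pro$injection_volume / 1000  # compensation
  eq_s <- equilibrium_distribution(pro$syringe_total_dimer, 1.1)
  injected <- pro$n_injections * eq_s[["dimer"]] * pro$injection_volume / 1000
  dimers_formed <- nd_end - nd_0 - injected          # nmol, by dissociation
  total_heat <- sum(injection_heats(tr)$heat_ucal)   # ucal
  expect_equal(total_heat, -dimers_formed * pro$delta_H,
               tolerance = 5e-3)
})

test_that("instrument response: identity, step response, area preservation", {
  t_grid <- seq(0, 100, 0.01)
  u <- ifelse(t_grid >= 1 & t_grid < 2, 1, 0) * (1 - abs(t_grid - 1.5) * 2)
  u <- pmax(u, 0)                 # unit triangular pulse, area 0.25
  trc <- power_trace(t_grid, u)
  # tau = 0: identity
  expect_equal(apply_instrument_response(trc, instrument_model(0))$power, u)
  # step input -> (1 - exp(-t/tau)) rise, exact for piecewise-constant input
  step <- power_trace(seq(0, 50, 0.5), rep(1, 101))
  resp <- apply_instrument_response(step, instrument_model(4))
  expect_equal(resp$power, 1 - exp(-step$time / 4), tolerance = 1e-10)
  # area preserved for any tau once the output has decayed
  for (tau in c(0.5, 2, 5)) {
    y <- apply_instrument_response(trc, instrument_model(tau))
    a_in <- sum(diff(t_grid) * (utils::head(u, -1) + utils::tail(u, -1)) / 2)
    a_out <- sum(diff(t_grid) * (utils::head(y$power, -1) +
                                   utils::tail(y$power, -1)) / 2)
    # exact continuous relation: a_out = a_in - tau * y(T); y(T) ~ 0 here
    expect_equal(a_out, a_in, tolerance = 1e-5)
    expect_lt(tau * abs(y$power[length(y$power)]) / a_in, 1e-6)
  }
  # offset and drift are added on the measured scale
  off <- apply_instrument_response(trc, instrument_model(0, 2, 0.1))
  expect_equal(off$power, u + 2 + 0.1 * t_grid)
})

test_that("baseline correction: no-op on clean traces, exact offset removal", {
  tr <- prdx1_trace()
  corr <- baseline_correct(tr)
  # the PRDX1 protocol rests at baseline between injections: correction
  # leaves per-injection heats nearly unchanged
  h0 <- injection_heats(tr)$heat_ucal
  h1 <- injection_heats(corr)$heat_ucal
  expect_equal(h1[2:8], h0[2:8], tolerance = 0.02)
  # a constant offset is absorbed exactly
  shifted <- power_trace(tr$time, tr$power + 3.7,
                         attr(tr, "injection_times"))
  expect_equal(baseline_correct(shifted)$power, corr$power,
               tolerance = 1e-9)
  one_win <- power_trace(0:10, rep(0, 11), injection_times = 0)
  expect_error(baseline_correct(one_win), "two inter-injection windows")
})

test_that("per-injection heats partition the trace integral", {
  tr <- prdx1_trace()
  h <- injection_heats(tr)
  expect_equal(nrow(h), attr(tr, "protocol")$n_injections)
  total <- sum(diff(tr$time) * (utils::head(tr$power, -1) +
                                  utils::tail(tr$power, -1)) / 2)
  expect_equal(sum(h$heat_ucal), total, tolerance = 1e-9)
  zero <- power_trace(0:100, rep(0, 101), injection_times = c(0, 50))
  expect_true(all(injection_heats(zero)$heat_ucal == 0))
})

test_that("enthalpy recovery from the maximum injection heat", {
  tr <- prdx1_trace()
  pro <- attr(tr, "protocol")
  est <- estimate_enthalpy(injection_heats(tr), pro)
  expect_equal(est, pro$delta_H, tolerance = 0.05)
  # linearity in delta_H
  pro2 <- itc_protocol(delta_H = 312, n_injections = 6)
  tr2 <- simulate_itc(pro2, kinetic_parameters())
  est2 <- estimate_enthalpy(injection_heats(tr2), pro2)
  expect_equal(est2 / est, 2, tolerance = 0.02)
  # an uninformative (all-zero) trace is rejected
  zero <- power_trace(0:400, rep(0, 401), injection_times = c(0, 200))
  expect_error(estimate_enthalpy(injection_heats(zero), pro),
               "undetermined")
})

test_that("power traces round-trip through CSV", {
  tr <- simulate_itc(itc_protocol(n_injections = 3),
                     kinetic_parameters())
  path <- tempfile(fileext = ".csv")
  write_power_trace(tr, path)
  back <- read_power_trace(path)
  expect_equal(back$time, tr$time)
  expect_equal(back$power, tr$power, tolerance = 1e-9)
  expect_equal(attr(back, "injection_times"),
               attr(tr, "injection_times"))
})
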