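# Mass-action rates, equilibria, time courses, dilution and the
# oxidation-state metrics.

test_that("mass-action rates follow the dissociation/association laws", {
  net <- assoc_only_network()
  dec0 <- reduced_decamer_id()
  p <- kinetic_parameters(koff = 0.055, Kd_app = 1.1)
  v <- mass_action_rates(stats::setNames(c(1, 2), c("Prx_SH_SH", dec0)),
                         p, net)
  expect_equal(unname(v["assoc"]), 0.05 * 1^5)
  expect_equal(unname(v["diss"]), 0.055 * 2)
  # at equilibrium the two fluxes balance (the kon = koff/Kd identity)
  eq <- equilibrium_distribution(2, 1.1)
  v_eq <- mass_action_rates(stats::setNames(eq, c("Prx_SH_SH", dec0)),
                            p, net)
  expect_equal(unname(v_eq["assoc"]), unname(v_eq["diss"]),
               tolerance = 1e-10)
  expect_error(mass_action_rates(stats::setNames(c(-1, 1),
                                                 c("Prx_SH_SH", dec0)),
                                 p, net), "negative")
})

test_that("equilibrium distribution: limits, defining relation, C_0.5", {
  expect_equal(equilibrium_distribution(0), c(dimer = 0, decamer = 0))
  # dilution limit: everything dimeric
  lo <- equilibrium_distribution(1e-4)
  expect_equal(lo[["dimer"]], 1e-4, tolerance = 1e-6)
  # defining relation d^5 / c = Kd to 1e-10 relative
  for (tot in c(0.5, 1.37, 10, 450)) {
    eq <- equilibrium_distribution(tot, 1.1)
    expect_equal(eq[["dimer"]]^5 / eq[["decamer"]], 1.1, tolerance = 1e-10)
    expect_equal(eq[["dimer"]] + 5 * eq[["decamer"]], tot,
                 tolerance = 1e-12)
  }
  # C_0.5: half the subunits decameric at ~1.36-1.37 uM (Kd 1.1 uM^4),
  # cross-checked by an independent bisection on the half-subunit condition
  f_dec <- function(tot) {
    eq <- equilibrium_distribution(tot, 1.1)
    5 * eq[["decamer"]] / tot
  }
  lohi <- c(0.5, 5)
  for (i in 1:60) {
    mid <- mean(lohi)
    if (f_dec(mid) < 0.5) lohi[1] <- mid else lohi[2] <- mid
  }
  expect_equal(c_half(1.1), mean(lohi), tolerance = 1e-8)
  expect_gt(c_half(1.1), 1.36)
  expect_lt(c_half(1.1), 1.38)
})

test_that("decamer fraction is monotone in total Prx", {
  tots <- 10^seq(-2, 2.5, length.out = 40)
  fr <- vapply(tots, function(tt) {
    eq <- equilibrium_distribution(tt, 1.1)
    5 * eq[["decamer"]] / tt
  }, 0)
  expect_true(all(diff(fr) > -1e-12))
})

test_that("time courses: equilibrium fixed point and subunit conservation", {
  net <- assoc_only_network()
  dec0 <- reduced_decamer_id()
  p <- kinetic_parameters()
  eq <- equilibrium_distribution(2, p$Kd_app)
  st <- stats::setNames(eq, c("Prx_SH_SH", dec0))
  tr <- simulate_timecourse(st, p, net, seq(0, 1000, 10))
  expect_equal(tr$Prx_SH_SH, rep(eq[["dimer"]], nrow(tr)), tolerance = 1e-7)
  # conservation along a strongly relaxing trajectory
  st2 <- stats::setNames(c(2, 0), c("Prx_SH_SH", dec0))
  tr2 <- simulate_timecourse(st2, p, net, seq(0, 200, 1))
  subs <- 2 * tr2$Prx_SH_SH + 10 * tr2[[dec0]]
  expect_lt(max(abs(subs - subs[1])) / subs[1], 1e-6)
  expect_error(simulate_timecourse(st, p, net, c(0, 1, 1)), "increasing")
})

test_that("oxidative challenge dissociates the decamer pool into bridged dimers", {
  p <- default_params()
  net <- net_single()
  dec0 <- reduced_decamer_id()
  st <- c(H2O2 = 50, stats::setNames(2, dec0))
  tr <- simulate_timecourse(st, p, net, seq(0, 20, 0.1))
  expect_lt(tr[[dec0]][nrow(tr)], 1e-8)
  dec_cols <- grep("^Dec__", names(tr), value = TRUE)
  expect_lt(sum(tr[nrow(tr), dec_cols]), 1e-6)
  ss_dimers <- tr$Prx_SH_SS + tr$Prx_SOH_SS
  expect_gt(ss_dimers[nrow(tr)], 1)
  # subunits conserved through the cascade
  state_cols <- setdiff(names(tr), "time")
  subs <- apply(tr[, state_cols], 1, function(row)
    subunit_total(stats::setNames(as.numeric(row), state_cols)))
  expect_lt(max(abs(subs - subs[1])) / subs[1], 1e-6)
})

test_that("dilution re-equilibration timing", {
  p <- default_params()
  # below the CTC: effectively already at equilibrium
  expect_equal(dilution_reequilibration(0.1, 10, p), 0,
               ignore_attr = TRUE)
  # 1 uM: identical relaxation times after 10x and 50x dilution
  t10 <- dilution_reequilibration(1, 10, p)
  t50 <- dilution_reequilibration(1, 50, p)
  expect_equal(t10, t50, tolerance = 0.02, ignore_attr = TRUE)
  # concentrated solutions: the stronger dilution takes strictly longer
  for (tot in c(10, 100, 450)) {
    a <- dilution_reequilibration(tot, 10, p)
    b <- dilution_reequilibration(tot, 50, p)
    expect_gt(b, a * 1.5)
  }
  expect_error(dilution_reequilibration(1, 0.5, p), "dilution_factor")
})

test_that("state fractions implement the bridge-count partition", {
  expect_equal(state_fractions(c(Prx_SH_SH = 2))$f_no_SS, 1)
  sf <- state_fractions(c(SH_SS = 1, SS_SOOH = 1))
  expect_equal(sf$f_one_SS, 1)
  expect_equal(sf$f_SOOH_and_SS, 0.5)
  expect_equal(sf$f_no_SS + sf$f_two_SS, 0)
  set.seed(3)
  x <- stats::setNames(stats::runif(10),
                       prxcycle:::.dimer_species(site_states()))
  sf2 <- state_fractions(x)
  expect_equal(sf2$f_no_SS + sf2$f_one_SS + sf2$f_two_SS, 1,
               tolerance = 1e-12)
  expect_error(state_fractions(c(Prx_SH_SH = 0)), "zero dimer pool")
})

test_that("disequilibrium ratio and hetero-oxidised fraction", {
  eq <- equilibrium_distribution(2, 1.1)
  expect_equal(disequilibrium_ratio(eq[["dimer"]], eq[["decamer"]], 1.1), 1,
               tolerance = 1e-9)
  q1 <- disequilibrium_ratio(0.5, 0.1, 1.1)
  expect_equal(disequilibrium_ratio(1, 0.1, 1.1) / q1, 32)
  expect_error(disequilibrium_ratio(1, 0, 1.1), "undefined")

  expect_equal(hetero_oxidised_reduced_fraction(c(SH_SH = 1)), 0)
  expect_equal(hetero_oxidised_reduced_fraction(c(SH_SOH = 1)), 1)
  expect_equal(hetero_oxidised_reduced_fraction(c(SH_SH = 1, SH_SOH = 1)),
               1 / 3)
  expect_error(hetero_oxidised_reduced_fraction(c(SOH_SS = 1)), "undefined")
})

test_that("under oxidative load the association reaction falls out of equilibrium", {
  p <- paper_repro_params()
  mixed <- decamerise_model(dimer_cycle_reactions(), p)
  dec0 <- reduced_decamer_id()
  eq <- equilibrium_distribution(2, p$Kd_app)
  st <- c(stats::setNames(eq, c("Prx_SH_SH", dec0)), H2O2 = 5)
  tr <- simulate_timecourse(st, p, mixed, seq(0, 0.3, 0.003))
  q <- disequilibrium_ratio(tr$Prx_SH_SH[nrow(tr)], tr[[dec0]][nrow(tr)],
                            p$Kd_app)
  expect_gt(q, 1)
})
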