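# HRP competition and NADPH-linked assay simulations and their analyses.

hrp_pair <- function() cached("hrp_pair", {
  par <- paper_repro_params()
  cfg <- hrp_assay_config()
  list(full = simulate_hrp_assay(cfg, par, "full_activity_dimer_only"),
       mixed = simulate_hrp_assay(cfg, par, "mixed_dimer_decamer"),
       par = par, cfg = cfg)
})

nadph_pair <- function() cached("nadph_pair", {
  par <- paper_repro_params()
  cfg <- nadph_assay_config()
  list(full = simulate_nadph_assay(cfg, par, "full_activity_dimer_only"),
       mixed = simulate_nadph_assay(cfg, par, "mixed_dimer_decamer"),
       par = par, cfg = cfg)
})

test_that("compound-I absorbance follows the extinction arithmetic", {
  # 1 uM compound I -> dA398 = 4.2e4 * 1 cm * 1e-6 M = 0.042
  hp <- hrp_pair()
  ctrl <- hp$full$traces[["0"]]
  expect_equal(hp$full$delta_max, 0.042 * hp$cfg$H2O2_init,
               tolerance = 1e-4)
  expect_equal(ctrl$dA398[nrow(ctrl)] / ctrl$CpdI[nrow(ctrl)], 0.042)
  # k_HRP has no safe default
  expect_error(simulate_hrp_assay(hrp_assay_config(),
                                  kinetic_parameters(),
                                  "full_activity_dimer_only"), "k_HRP")
})

test_that("fractional-inhibition algebra", {
  # delta_obs = delta_max everywhere -> kPrx = 0
  fi0 <- fractional_inhibition_k(c(`1` = 0.042, `2` = 0.042), 0.042, 17, 5)
  expect_equal(fi0$k_through_origin, 0)
  # single point at delta_max / 2 -> kPrx * Prx = kHRP * HRP exactly
  fi1 <- fractional_inhibition_k(c(`2` = 0.021), 0.042, 17, 5)
  expect_equal(fi1$k_through_origin * 2, 17 * 5)
  expect_error(fractional_inhibition_k(c(`1` = 0), 0.042, 17, 5),
               "outcompetition")
})

test_that("the mixed dimer-decamer model shows the inhibition-like effect", {
  hp <- hrp_pair()
  # larger dA398 (less H2O2 consumed by Prx) for every Prx concentration
  expect_true(all(hp$mixed$delta_obs > hp$full$delta_obs))
  # cumulative H2O2 consumption ordering at every shared time point
  for (nm in names(hp$full$traces))
    expect_true(all(hp$mixed$traces[[nm]]$h2o2_consumed <=
                      hp$full$traces[[nm]]$h2o2_consumed + 1e-9))
  # the derived rate constants order the same way
  kf <- fractional_inhibition_k(hp$full$delta_obs, hp$full$delta_max,
                                hp$par$k_HRP, hp$cfg$HRP_init)
  km <- fractional_inhibition_k(hp$mixed$delta_obs, hp$mixed$delta_max,
                                hp$par$k_HRP, hp$cfg$HRP_init)
  expect_gt(kf$k_through_origin, km$k_through_origin)
  # the mixed model's fractional-inhibition line has a positive x-intercept
  # (apparent inhibited Prx), the signature of the dimer-decamer equilibrium
  expect_gt(km$x_intercept, 0)
})

test_that("competition bookkeeping: H2O2 consumed = compound I + site oxidations", {
  hp <- hrp_pair()
  for (variant in c("full", "mixed")) {
    tr <- hp[[variant]]$traces[["1.7"]]
    last <- tr[nrow(tr), ]
    state <- stats::setNames(as.numeric(last), names(last))
    oxidised <- prxcycle:::.oxidised_site_total(state)
    expect_equal(hp$cfg$H2O2_init - last$H2O2, last$CpdI + oxidised,
                 tolerance = 1e-6)
  }
})

test_that("a competitor with HRP-like kinetics is recovered exactly", {
  # two irreversible second-order consumers share the peroxide linearly,
  # so the fractional-inhibition transform returns the competitor's k
  k_comp <- 40
  net <- reaction_network(
    data.frame(id = c("HRP", "CpdI", "Comp", "CompOx", "H2O2", "H2O"),
               role = c("assay", "assay", "assay", "assay", "small",
                        "small")),
    list(list(id = "hrp", kind = "assay_step", rate_ref = "k_HRP",
              factor = 1L, reactants = c(HRP = 1, H2O2 = 1),
              products = c(CpdI = 1, H2O = 1)),
         list(id = "comp", kind = "assay_step", rate_ref = "k_SOH_decamer",
              factor = 1L, reactants = c(Comp = 1, H2O2 = 1),
              products = c(CompOx = 1, H2O = 1))))
  # trace amounts of peroxide keep both competitors effectively constant
  # (pseudo-first-order), the regime in which the transform is exact
  par <- kinetic_parameters(k_HRP = 17, k_SOH_decamer = k_comp)
  dobs <- vapply(c(0, 0.5, 1, 2), function(C) {
    st <- c(H2O2 = 0.01, HRP = 5, Comp = C)
    tr <- simulate_timecourse(st, par, net, seq(0, 0.5, 0.005))
    0.042 * tr$CpdI[nrow(tr)]
  }, 0)
  fi <- fractional_inhibition_k(stats::setNames(dobs[-1], c(0.5, 1, 2)),
                                dobs[1], 17, 5)
  expect_equal(fi$k_through_origin, k_comp, tolerance = 1e-3)
  expect_equal(fi$k_free_intercept, k_comp, tolerance = 1e-3)
})

test_that("stopped-flow dilution at t0 raises apparent activity over a pre-equilibrated start", {
  par <- paper_repro_params()
  cfg_eq <- hrp_assay_config(prx_total_series = 1)
  cfg_dil <- hrp_assay_config(prx_total_series = 1,
                              pre_equilibrated = FALSE,
                              dilution_factor_at_t0 = 10)
  d_eq <- simulate_hrp_assay(cfg_eq, par, "mixed_dimer_decamer")$delta_obs
  d_dil <- simulate_hrp_assay(cfg_dil, par, "mixed_dimer_decamer")$delta_obs
  # the freshly diluted stock is still decamer-rich, hence more active:
  # smaller compound-I signal
  expect_gt(d_eq[[1]], d_dil[[1]])
})

test_that("NADPH assay: flux ceiling, electron bookkeeping, variant ordering", {
  np <- nadph_pair()
  for (variant in c("full", "mixed")) {
    tr <- np[[variant]]$trace
    # NADPH is non-increasing and bounded by the peroxide ceiling
    expect_true(all(diff(tr$NADPH) <= 1e-9))
    expect_lte(max(tr$delta_NADPH), np$cfg$H2O2 + 1e-6)
    # electrons balance: H2O2 consumed = oxidised sites + Trx_ox + NADPH used
    last <- tr[nrow(tr), ]
    state <- stats::setNames(as.numeric(last), names(last))
    oxidised <- prxcycle:::.oxidised_site_total(state)
    expect_equal(np$cfg$H2O2 - last$H2O2,
                 oxidised + last$Trx_ox + last$delta_NADPH,
                 tolerance = 1e-6)
  }
  # shallower initial slope for the mixed model
  k_full <- initial_rate_kcat(np$full)
  k_mixed <- initial_rate_kcat(np$mixed)
  expect_gt(k_full, k_mixed)
  # peroxide-free control: NADPH stays flat
  ctrl <- simulate_nadph_assay(nadph_assay_config(H2O2 = 0), np$par,
                               "full_activity_dimer_only")
  expect_equal(range(ctrl$trace$NADPH), c(150, 150), tolerance = 1e-9)
})

test_that("initial-rate analysis implements its definition", {
  # synthetic linear trace, slope 1 uM/s, 0.5 uM Prx -> kcat = 2 s^-1
  tr <- data.frame(time = seq(0, 10, 0.1), NADPH = 150 - seq(0, 10, 0.1))
  expect_equal(initial_rate_kcat(tr, prx_total = 0.5), 2,
               ignore_attr = TRUE)
})
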