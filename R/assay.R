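# In-silico peroxidase assays: HRP competition (compound-I absorbance) and
# NADPH-linked (Trx/TRR-coupled), for the full-activity dimer-only and the
# mixed-activity dimer-decamer model variants.

ASSAY_VARIANTS <- c("full_activity_dimer_only", "mixed_dimer_decamer")

#' Configuration of a simulated HRP competition assay
#'
#' @param HRP_init HRP concentration (uM).
#' @param H2O2_init Hydrogen peroxide (uM).
#' @param prx_total_series Total Prx concentrations to assay (uM, dimer
#'   units); 0 need not be included -- a Prx-free control is always run.
#' @param epsilon_398 Compound-I extinction coefficient (M^-1 cm^-1).
#' @param path_length Light path (cm).
#' @param pre_equilibrated Start from the dimer/decamer equilibrium
#'   (`TRUE`) or apply `dilution_factor_at_t0` to a pre-equilibrated stock
#'   at t = 0 (stopped-flow scenario).
#' @param dilution_factor_at_t0 Optional dilution factor applied at t = 0.
#' @param t_end,n_steps Simulation horizon (s) and output resolution.
#' @return Object of class `prx_hrp_config`.
#' @export
hrp_assay_config <- function(HRP_init = 5, H2O2_init = 1,
                             prx_total_series = c(0.4, 0.8, 1.3, 1.7),
                             epsilon_398 = 4.2e4, path_length = 1,
                             pre_equilibrated = TRUE,
                             dilution_factor_at_t0 = NULL,
                             t_end = 0.5, n_steps = 500) {
  stopifnot(HRP_init > 0, H2O2_init > 0, all(prx_total_series >= 0),
            epsilon_398 > 0, path_length > 0, t_end > 0)
  structure(as.list(environment()), class = "prx_hrp_config")
}

#' Configuration of a simulated NADPH-linked peroxidase assay
#'
#' Defaults reproduce the whole-system assay conditions: 50 uM Trx, 0.5 uM
#' TRR with kcat 10 s^-1, 5 uM H2O2 and 150 uM NADPH.
#'
#' @param Trx,TRR Thioredoxin / thioredoxin reductase (uM).
#' @param kcat_TRR TRR turnover number (s^-1).
#' @param H2O2,NADPH Initial concentrations (uM).
#' @param prx_total Total Prx (uM, dimer units).
#' @param t_end,n_steps Simulation horizon (s) and output resolution.
#' @return Object of class `prx_nadph_config`.
#' @export
nadph_assay_config <- function(Trx = 50, TRR = 0.5, kcat_TRR = 10,
                               H2O2 = 5, NADPH = 150, prx_total = 1,
                               t_end = 60, n_steps = 1200) {
  stopifnot(Trx > 0, TRR > 0, kcat_TRR > 0, H2O2 >= 0, NADPH > 0,
            prx_total > 0)
  structure(as.list(environment()), class = "prx_nadph_config")
}

# Prx part of an assay model for a given variant.
.prx_variant_network <- function(variant, include_trx = FALSE,
                                 params = kinetic_parameters(),
                                 mode = "single_SS") {
  variant <- match.arg(variant, ASSAY_VARIANTS)
  if (variant == "full_activity_dimer_only") {
    dimer_cycle_reactions(include_trx = include_trx,
                          sulfenilation_ref = "k_SOH_decamer")
  } else {
    decamerise_model(
      dimer_cycle_reactions(include_trx = include_trx,
                            sulfenilation_ref = "k_SOH_dimer"),
      params, mode = mode)
  }
}

# Initial Prx speciation for a variant (named concentration vector).
.prx_initial_state <- function(variant, prx_total, params,
                               dilution_factor = NULL) {
  if (prx_total == 0) return(numeric(0))
  if (variant == "full_activity_dimer_only")
    return(c(Prx_SH_SH = prx_total))
  if (is.null(dilution_factor)) {
    eq <- equilibrium_distribution(prx_total, params$Kd_app, params$n)
  } else {
    eq <- equilibrium_distribution(prx_total * dilution_factor,
                                   params$Kd_app, params$n) / dilution_factor
  }
  st <- c(eq[["dimer"]], eq[["decamer"]])
  names(st) <- c("Prx_SH_SH", .decamer_id(rep(1L, 10)))
  st
}

#' Simulate an HRP competition assay
#'
#' Runs the competition between HRP (forming compound I from H2O2) and Prx
#' for hydrogen peroxide across the configured Prx series, together with a
#' Prx-free control, and reports `dA398(t) = eps398 * l * [compound I]`.
#'
#' @param config [hrp_assay_config()].
#' @param params [kinetic_parameters()]; `k_HRP` must be set (it is
#'   literature-sourced, see [paper_repro_params()]).
#' @param variant `"full_activity_dimer_only"` or `"mixed_dimer_decamer"`.
#' @param mode Decamer enumeration mode for the mixed variant.
#' @return Object of class `prx_hrp_assay`: per-concentration trajectories
#'   (`$traces`, each with `time`, species columns, `dA398` and cumulative
#'   `h2o2_consumed`), the end-point `delta_obs` vector, `delta_max`, and
#'   the configuration used.
#' @export
simulate_hrp_assay <- function(config, params = kinetic_parameters(),
                               variant = ASSAY_VARIANTS, mode = "single_SS") {
  variant <- match.arg(variant)
  if (is.null(params$k_HRP))
    stop("k_HRP is not set; the HRP rate constant has no safe default and ",
         "must be supplied (see paper_repro_params())", call. = FALSE)
  prx_net <- .prx_variant_network(variant, include_trx = FALSE,
                                  params = params, mode = mode)
  hrp_net <- reaction_network(
    .mk_species(c("HRP", "CpdI", SMALL_SPECIES), c("assay", "assay",
                                                   "small", "small")),
    list(.rxn("hrp_cpd1", "assay_step", "k_HRP", 1,
              c(HRP = 1, H2O2 = 1), c(CpdI = 1, H2O = 1))))
  net <- merge_networks(prx_net, hrp_net)
  t_grid <- seq(0, config$t_end, length.out = config$n_steps + 1)
  run_one <- function(prx_total) {
    st <- c(H2O2 = config$H2O2_init, HRP = config$HRP_init,
            .prx_initial_state(variant, prx_total, params,
                               if (!config$pre_equilibrated)
                                 config$dilution_factor_at_t0))
    tr <- simulate_timecourse(st, params, net, t_grid)
    tr$dA398 <- config$epsilon_398 * config$path_length * tr$CpdI * 1e-6
    tr$h2o2_consumed <- config$H2O2_init - tr$H2O2
    tr
  }
  prx_series <- config$prx_total_series[config$prx_total_series > 0]
  traces <- c(list(`0` = run_one(0)),
              stats::setNames(lapply(prx_series, run_one),
                              as.character(prx_series)))
  delta <- vapply(traces, function(tr) tr$dA398[nrow(tr)], 0)
  structure(list(traces = traces,
                 delta_obs = delta[-1],
                 delta_max = delta[[1]],
                 prx_total = prx_series,
                 variant = variant, config = config, params = params),
            class = "prx_hrp_assay")
}

#' Prx rate constant by fractional-inhibition analysis
#'
#' Transforms end-point compound-I absorbances into an apparent second-order
#' Prx rate constant via the competition relation
#' `kPrx * Prx = kHRP * HRP * (dmax - dobs) / dobs`, fitting the right-hand
#' side against the Prx concentration.  Both the through-origin and the
#' free-intercept linear fits are reported.
#'
#' @param delta_obs_by_prx Named numeric vector of end-point dA398 values;
#'   names are the Prx concentrations (uM).
#' @param delta_max Control (Prx-free) dA398.
#' @param k_HRP HRP rate constant (uM^-1 s^-1).
#' @param HRP_init HRP concentration (uM).
#' @return List with `k_through_origin`, `k_free_intercept`, `intercept`,
#'   `x_intercept` and the transformed `points`.
#' @export
fractional_inhibition_k <- function(delta_obs_by_prx, delta_max, k_HRP,
                                    HRP_init) {
  prx <- as.numeric(names(delta_obs_by_prx))
  keep <- prx > 0
  prx <- prx[keep]; dobs <- as.numeric(delta_obs_by_prx)[keep]
  if (!length(prx))
    stop("at least one Prx concentration > 0 is required", call. = FALSE)
  if (any(dobs <= 0))
    stop("delta_obs = 0 (total outcompetition of HRP); the fractional-",
         "inhibition transform is undefined", call. = FALSE)
  y <- k_HRP * HRP_init * (delta_max - dobs) / dobs
  k_origin <- sum(prx * y) / sum(prx^2)
  if (length(prx) >= 2) {
    fit <- stats::lm(y ~ prx)
    k_free <- unname(stats::coef(fit)[2])
    icpt <- unname(stats::coef(fit)[1])
  } else {
    k_free <- NA_real_; icpt <- NA_real_
  }
  list(k_through_origin = k_origin, k_free_intercept = k_free,
       intercept = icpt,
       x_intercept = if (is.finite(k_free) && k_free != 0) -icpt / k_free
                     else NA_real_,
       points = data.frame(prx = prx, y = y))
}

#' Simulate an NADPH-linked peroxidase assay
#'
#' Links Prx disulphide reduction to NADPH oxidation through thioredoxin and
#' thioredoxin reductase (saturating TRR turnover in the small-KM limit).
#'
#' @param config [nadph_assay_config()].
#' @param params [kinetic_parameters()]; Trx/TRR constants are taken from
#'   the config.
#' @param variant Model variant, as in [simulate_hrp_assay()].
#' @param mode Decamer enumeration mode for the mixed variant.
#' @return Object of class `prx_nadph_assay` with the trajectory (`$trace`,
#'   including `NADPH` and `delta_NADPH`), the variant tag and the
#'   configuration.
#' @export
simulate_nadph_assay <- function(config, params = kinetic_parameters(),
                                 variant = ASSAY_VARIANTS,
                                 mode = "single_SS") {
  variant <- match.arg(variant)
  if (is.null(params$k_trx_red) || is.null(config$kcat_TRR))
    stop("Trx/TRR rate constants are required for the NADPH assay",
         call. = FALSE)
  params$TRR <- config$TRR
  params$kcat_TRR <- config$kcat_TRR
  prx_net <- .prx_variant_network(variant, include_trx = TRUE,
                                  params = params, mode = mode)
  trr_net <- reaction_network(
    .mk_species(c("Trx_red", "Trx_ox", "NADPH", "NADP"),
                c("redox", "redox", "redox", "redox")),
    list(.rxn("trr", "trr_turnover", "kcat_TRR", 1,
              c(Trx_ox = 1, NADPH = 1), c(Trx_red = 1, NADP = 1))))
  net <- merge_networks(prx_net, trr_net)
  t_grid <- seq(0, config$t_end, length.out = config$n_steps + 1)
  st <- c(H2O2 = config$H2O2, NADPH = config$NADPH, Trx_red = config$Trx,
          .prx_initial_state(variant, config$prx_total, params))
  tr <- simulate_timecourse(st, params, net, t_grid)
  tr$delta_NADPH <- config$NADPH - tr$NADPH
  structure(list(trace = tr, variant = variant, config = config,
                 params = params),
            class = "prx_nadph_assay")
}

#' Catalytic rate constant from initial-rate analysis of an NADPH trace
#'
#' The initial-rate window starts where the NADPH consumption rate is
#' maximal (the end of the brief Trx-activation lag) and extends forward as
#' long as a linear fit keeps R^2 >= `r2_min` (minimum 5 points).  The
#' turnover number is the fitted NADPH consumption rate per total Prx,
#' `kcat = -slope / [Prx total]` with the total in dimer units.
#'
#' @param result A `prx_nadph_assay` (or a data frame with `time` and
#'   `NADPH` columns).
#' @param prx_total Total Prx (uM, dimer units); taken from the result's
#'   config when omitted.
#' @param r2_min Linearity threshold.
#' @return `kcat` (s^-1); attributes `slope` (uM/s), `window` (number of
#'   points used) and `t_start` (window start, s).
#' @export
initial_rate_kcat <- function(result, prx_total = NULL, r2_min = 0.999) {
  tr <- if (inherits(result, "prx_nadph_assay")) result$trace else result
  if (is.null(prx_total)) prx_total <- result$config$prx_total
  t <- tr$time; y <- tr$NADPH
  n <- length(t)
  i0 <- which.max(-diff(y) / diff(t))
  if (n - i0 + 1L < 5L)
    stop("no linear initial-rate window (immediate saturation); ",
         "initial-rate analysis not applicable", call. = FALSE)
  best <- 0L
  for (m in (i0 + 4L):n) {
    idx <- i0:m
    fit <- stats::lm.fit(cbind(1, t[idx]), y[idx])
    ss_res <- sum(fit$residuals^2)
    ss_tot <- sum((y[idx] - mean(y[idx]))^2)
    r2 <- if (ss_tot == 0) 1 else 1 - ss_res / ss_tot
    if (r2 >= r2_min) best <- m else break
  }
  if (best < i0 + 4L)
    stop("no linear initial-rate window (immediate saturation); ",
         "initial-rate analysis not applicable", call. = FALSE)
  idx <- i0:best
  fit <- stats::lm.fit(cbind(1, t[idx]), y[idx])
  slope <- fit$coefficients[2]
  out <- unname(-slope / prx_total)
  attr(out, "slope") <- unname(slope)
  attr(out, "window") <- length(idx)
  attr(out, "t_start") <- t[i0]
  out
}

# internal: total oxidation events recorded in a state (SOH + SS sites,
# in uM of sites), counting decamer and dimer species.
.oxidised_site_total <- function(state) {
  tot <- 0
  for (nm in names(state)) {
    sites <- if (grepl("^Dec__", nm)) {
      unlist(strsplit(sub("^Dec__", "", nm), "__|_"))
    } else if (grepl("^Prx_", nm)) {
      unlist(strsplit(sub("^Prx_", "", nm), "_"))
    } else next
    tot <- tot + sum(sites %in% c("SOH", "SS")) * state[[nm]]
  }
  tot
}
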