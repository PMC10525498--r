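# Mass-action kinetics: parameters, ODE compilation, time courses,
# equilibria and oxidation-state metrics.

#' Kinetic parameters of the Prx dimer-decamer model
#'
#' Units are fixed package-wide: concentrations in uM, time in s, volumes in
#' uL, amounts in nmol.  `kon` has units uM^(1-n) s^-1 and `Kd_app` uM^(n-1)
#' for association exponent `n` (five dimers per association event by
#' default).  When `kon` is not supplied it is tethered to the dissociation
#' constant as `kon = koff / Kd_app`.  The dimer sulfenilation constant
#' defaults to 1/100 of the decamer constant, reflecting the 100-fold lower
#' peroxidase activity of dimeric Prx.
#'
#' @param koff Decamer dissociation rate constant (s^-1).
#' @param Kd_app Apparent dissociation constant of the 5 dimer <-> decamer
#'   equilibrium (uM^(n-1)).
#' @param n Association exponent (dimers per association event).
#' @param kon Association rate constant; `NULL` tethers it to
#'   `koff / Kd_app`.
#' @param k_SOH_decamer Sulfenilation rate constant of decameric Prx
#'   (uM^-1 s^-1).
#' @param k_SOH_dimer Sulfenilation rate constant of dimeric Prx; `NULL`
#'   gives `k_SOH_decamer / 100`.
#' @param k_SS_condensation Disulphide (condensation) rate constant (s^-1).
#' @param k_diss_oxidised Single-step dissociation rate constant of bridged
#'   decamers (s^-1); chosen to far exceed the other rates in the system.
#' @param k_trx_red Prx-SS reduction by thioredoxin (uM^-1 s^-1).
#' @param kcat_TRR Thioredoxin-reductase turnover number (s^-1).
#' @param TRR Thioredoxin-reductase concentration (uM).
#' @param KM_TRR_Trx,KM_TRR_NADPH Michaelis constants of the TRR turnover
#'   step (uM); the small defaults give the saturating small-KM limit.
#' @param k_HRP HRP + H2O2 -> compound I rate constant (uM^-1 s^-1); no
#'   default -- must be supplied (literature-sourced) for HRP assays.
#' @param k_sulfinilation SOH hyperoxidation rate constant (uM^-1 s^-1).
#' @param k_srx Sulfiredoxin-mediated SOOH reduction (s^-1, simplified
#'   first-order).
#' @return Object of class `prx_params` (a validated named list).
#' @export
kinetic_parameters <- function(koff = 0.055, Kd_app = 1.1, n = 5,
                               kon = NULL,
                               k_SOH_decamer = 100, k_SOH_dimer = NULL,
                               k_SS_condensation = 1.7,
                               k_diss_oxidised = 100,
                               k_trx_red = 0.21, kcat_TRR = 10, TRR = 0,
                               KM_TRR_Trx = 1e-3, KM_TRR_NADPH = 1e-3,
                               k_HRP = NULL,
                               k_sulfinilation = 0.012, k_srx = 3e-3) {
  if (is.null(kon)) kon <- koff / Kd_app
  if (is.null(k_SOH_dimer)) k_SOH_dimer <- k_SOH_decamer / 100
  p <- list(koff = koff, Kd_app = Kd_app, n = n, kon = kon,
            k_SOH_decamer = k_SOH_decamer, k_SOH_dimer = k_SOH_dimer,
            k_SS_condensation = k_SS_condensation,
            k_diss_oxidised = k_diss_oxidised,
            k_trx_red = k_trx_red, kcat_TRR = kcat_TRR, TRR = TRR,
            KM_TRR_Trx = KM_TRR_Trx, KM_TRR_NADPH = KM_TRR_NADPH,
            k_HRP = k_HRP,
            k_sulfinilation = k_sulfinilation, k_srx = k_srx)
  num <- p[!vapply(p, is.null, TRUE)]
  if (any(vapply(num, function(x) !is.numeric(x) || x < 0, TRUE)))
    stop("all kinetic parameters must be non-negative numbers",
         call. = FALSE)
  structure(p, class = "prx_params")
}

#' @export
print.prx_params <- function(x, ...) {
  cat("<prx_params>\n")
  for (nm in names(x))
    if (!is.null(x[[nm]])) cat(sprintf("  %-18s %g\n", nm, x[[nm]]))
  invisible(x)
}

# --- ODE compilation -----------------------------------------------------

# Compile a network + parameters into vectors/matrices for fast mass-action
# rate evaluation.  Each mass-action reaction may involve at most two
# distinct reactant species (with integer powers); `trr_turnover` reactions
# use a saturating rate law and are handled separately.
.compile_network <- function(network, params) {
  ids <- network$species$id
  nr <- length(network$reactions)
  k <- numeric(nr); i1 <- integer(nr); p1 <- numeric(nr)
  i2 <- integer(nr); p2 <- numeric(nr)
  trr <- logical(nr)
  S <- matrix(0, length(ids), nr, dimnames = list(ids, NULL))
  for (j in seq_len(nr)) {
    r <- network$reactions[[j]]
    base <- params[[r$rate_ref]]
    if (is.null(base))
      stop("rate constant ", sQuote(r$rate_ref), " is not set; supply it ",
           "via kinetic_parameters()", call. = FALSE)
    k[j] <- base * r$factor
    re <- r$reactants
    if (length(re) > 2L)
      stop("reaction ", r$id, " has more than two distinct reactants",
           call. = FALSE)
    i1[j] <- match(names(re)[1], ids); p1[j] <- re[[1]]
    if (length(re) == 2L) { i2[j] <- match(names(re)[2], ids); p2[j] <- re[[2]] }
    S[names(re), j] <- S[names(re), j] - re
    S[names(r$products), j] <- S[names(r$products), j] + r$products
    trr[j] <- identical(r$kind, "trr_turnover")
  }
  list(ids = ids, k = k, i1 = i1, p1 = p1, i2 = i2, p2 = p2, S = S,
       trr = trr, params = params)
}

.rates_compiled <- function(cm, conc) {
  v <- cm$k * conc[cm$i1]^cm$p1
  j2 <- which(cm$i2 > 0L)
  if (length(j2)) v[j2] <- v[j2] * conc[cm$i2[j2]]^cm$p2[j2]
  jt <- which(cm$trr)
  if (length(jt)) {
    p <- cm$params
    s1 <- conc[cm$i1[jt]]; s2 <- conc[cm$i2[jt]]
    v[jt] <- p$kcat_TRR * p$TRR *
      s1 / (s1 + p$KM_TRR_Trx) * s2 / (s2 + p$KM_TRR_NADPH)
  }
  v
}

#' Mass-action reaction rates of a network at a given state
#'
#' Dissociation is first order in the decamer (`v = koff [decamer]`),
#' association is `kon [dimer]^n`, and every other reaction is elementary
#' mass action scaled by its statistical factor.
#'
#' @param state Named concentration vector (uM) covering the network's
#'   species (absent species default to 0).
#' @param params [kinetic_parameters()].
#' @param network A `prx_network`.
#' @return Named vector of reaction rates (uM/s).
#' @export
mass_action_rates <- function(state, params, network) {
  if (any(state < 0))
    stop("negative concentration(s): ",
         paste(names(state)[state < 0], collapse = ", "), call. = FALSE)
  conc <- stats::setNames(numeric(nrow(network$species)), network$species$id)
  conc[names(state)] <- state
  v <- .rates_compiled(.compile_network(network, params), conc)
  stats::setNames(v, vapply(network$reactions, `[[`, "", "id"))
}

#' Total Prx subunits in a state
#'
#' @param state Named concentration vector (uM).
#' @return Subunit-weighted total (uM of monomer): 2 per dimer species, 10
#'   per decamer species.
#' @export
subunit_total <- function(state) {
  w <- vapply(names(state), .subunits_of, 0L)
  sum(w * state)
}

#' Simulate a reaction-network time course
#'
#' Stiff-capable integration (deSolve `lsoda`) of the mass-action ODE system
#' of a network, with optional instantaneous events.
#'
#' @param state0 Named initial concentration vector (uM); species not named
#'   start at 0.
#' @param params [kinetic_parameters()].
#' @param network A `prx_network`.
#' @param t_grid Increasing output time grid (s).
#' @param events Optional data frame with columns `var`, `time`, `value`,
#'   `method` (as in [deSolve::lsoda()] events).
#' @param rtol,atol Integration tolerances (defaults 1e-8 / 1e-12 uM).
#' @return Data frame: `time` plus one concentration column per species.
#' @export
simulate_timecourse <- function(state0, params, network, t_grid,
                                events = NULL, rtol = 1e-8, atol = 1e-12) {
  if (is.unsorted(t_grid, strictly = TRUE))
    stop("t_grid must be strictly increasing", call. = FALSE)
  cm <- .compile_network(network, params)
  y0 <- stats::setNames(numeric(length(cm$ids)), cm$ids)
  y0[names(state0)] <- state0
  deriv <- function(t, y, p) {
    v <- .rates_compiled(cm, pmax(y, 0))
    list(as.vector(cm$S %*% v))
  }
  ev <- if (!is.null(events)) list(data = events) else NULL
  out <- deSolve::lsoda(y0, t_grid, deriv, parms = NULL,
                        rtol = rtol, atol = atol, events = ev)
  if (attr(out, "istate")[1] < 0)
    stop("integrator failure at t = ", max(out[, 1]),
         "; last state: ", paste(round(out[nrow(out), -1], 6), collapse = ", "),
         call. = FALSE)
  as.data.frame(out)
}

# --- dimer/decamer equilibrium ------------------------------------------

#' Equilibrium distribution between Prx dimers and decamers
#'
#' Solves `d + n c = total` with `d^n / c = Kd_app` for the unique
#' non-negative root (concentrations of free dimer `d` and decamer `c`, with
#' `total` in dimer units).  Bracketed root-finding on the dimer variable
#' followed by Newton polishing; the defining relation holds to ~1e-12
#' relative.
#'
#' @param total_prx_dimer_units Total Prx (uM, dimer units).
#' @param Kd_app Apparent dissociation constant (uM^(n-1)).
#' @param n Association exponent.
#' @return Named vector `c(dimer = , decamer = )` in uM.
#' @export
equilibrium_distribution <- function(total_prx_dimer_units, Kd_app = 1.1,
                                     n = 5) {
  total <- total_prx_dimer_units
  stopifnot(total >= 0, Kd_app > 0, n > 1)
  if (total == 0) return(c(dimer = 0, decamer = 0))
  f <- function(d) d + n * exp(n * log(d) - log(Kd_app)) - total
  d <- stats::uniroot(f, c(total * 1e-12, total), tol = 1e-15 * total)$root
  for (i in 1:5) {  # Newton polish
    cd <- exp(n * log(d) - log(Kd_app))
    fd <- d + n * cd - total
    fpd <- 1 + n^2 * cd / d
    d <- max(d - fd / fpd, .Machine$double.xmin)
  }
  c(dimer = d, decamer = (total - d) / n)
}

#' Total Prx at which half the subunits are decameric
#'
#' Derived diagnostic: the dimer-unit concentration `C_0.5` at which half of
#' all Prx subunits reside in decamers, `2 (Kd_app / n)^(1/(n-1))`.
#'
#' @inheritParams equilibrium_distribution
#' @return `C_0.5` in uM (dimer units).
#' @export
c_half <- function(Kd_app = 1.1, n = 5) 2 * (Kd_app / n)^(1 / (n - 1))

#' Disequilibrium ratio Q/Kd of the dimer-decamer reaction
#'
#' @param dimer,decamer Concentrations (uM).
#' @inheritParams equilibrium_distribution
#' @return `(dimer^n / decamer) / Kd_app`; 1 at equilibrium.
#' @export
disequilibrium_ratio <- function(dimer, decamer, Kd_app = 1.1, n = 5) {
  if (any(decamer <= 0))
    stop("disequilibrium ratio is undefined at zero decamer concentration",
         call. = FALSE)
  exp(n * log(dimer) - log(decamer) - log(Kd_app))
}

# internal: association/dissociation-only ODE in concentrations
# y = c(dimer, decamer); supports the phenomenological exponent n via
# log-space evaluation of [dimer]^n.
.assoc_diss_deriv <- function(t, y, p) {
  d <- max(y[1], 0); cc <- max(y[2], 0)
  va <- if (d > 0) exp(log(p$kon) + p$n * log(d)) else 0
  vd <- p$koff * cc
  list(c(p$n * (vd - va), va - vd))
}

.simulate_assoc_diss <- function(d0, c0, params, times,
                                 rtol = 1e-10, atol = 1e-14) {
  out <- deSolve::lsoda(c(d = d0, c = c0), times, .assoc_diss_deriv,
                        parms = params, rtol = rtol, atol = atol)
  as.data.frame(out)
}

#' Time for a diluted Prx solution to re-equilibrate
#'
#' Computes the pre-dilution dimer/decamer equilibrium, divides both
#' concentrations by the dilution factor, simulates the relaxation under
#' association/dissociation kinetics, and returns the first time from which
#' the trajectory stays within `tolerance` of the post-dilution equilibrium.
#' Closeness is measured as the remaining fraction of the initial
#' displacement: `max_i |x_i(t) - x_i(inf)| / max_i |x_i(0) - x_i(inf)|`.
#'
#' @param initial_total Pre-dilution total Prx (uM, dimer units).
#' @param dilution_factor Dilution factor (> 1).
#' @param params [kinetic_parameters()].
#' @param tolerance Remaining-displacement fraction defining equilibrium
#'   (default 0.01, i.e. within 1%).
#' @param horizon Simulation horizon (s).
#' @return Time to equilibrium (s); attribute `"trajectory"` carries the
#'   simulated relaxation.
#' @export
dilution_reequilibration <- function(initial_total, dilution_factor,
                                     params = kinetic_parameters(),
                                     tolerance = 0.01, horizon = 2000) {
  if (dilution_factor <= 1)
    stop("dilution_factor must be > 1", call. = FALSE)
  eq0 <- equilibrium_distribution(initial_total, params$Kd_app, params$n)
  d0 <- eq0[["dimer"]] / dilution_factor
  c0 <- eq0[["decamer"]] / dilution_factor
  eqf <- equilibrium_distribution(initial_total / dilution_factor,
                                  params$Kd_app, params$n)
  gap0 <- max(abs(d0 - eqf[["dimer"]]), abs(c0 - eqf[["decamer"]]))
  if (gap0 <= tolerance * initial_total / dilution_factor) {
    # displacement negligible on the scale of the diluted pool
    out <- 0
    attr(out, "trajectory") <- NULL
    return(out)
  }
  times <- unique(c(0, 10^seq(-4, log10(horizon), length.out = 3000)))
  tr <- .simulate_assoc_diss(d0, c0, params, times)
  rem <- pmax(abs(tr$d - eqf[["dimer"]]), abs(tr$c - eqf[["decamer"]])) / gap0
  ok <- rev(cumprod(rev(rem <= tolerance))) == 1  # within tol, sustained
  if (!any(ok))
    stop("no re-equilibration within horizon = ", horizon, " s (remaining ",
         "fraction ", signif(rem[length(rem)], 3), ")", call. = FALSE)
  t_eq <- tr$time[which(ok)[1]]
  attr(t_eq, "trajectory") <- tr
  t_eq
}

# --- oxidation-state metrics --------------------------------------------

.dimer_conc_vector <- function(x) {
  labs <- .dimer_species(c("SH", "SOH", "SS", "SOOH"))
  out <- stats::setNames(numeric(length(labs)), labs)
  nm <- sub("^Prx_", "", names(x))
  unknown <- setdiff(nm, labs)
  if (length(unknown))
    stop("unknown dimer species: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  out[nm] <- out[nm] + as.numeric(x)
  out
}

#' Oxidation-state fractions of the Prx dimer population
#'
#' Partitions the dimer pool by disulphide-bridge count and reports the
#' sulfinic-site fractions: `f_no_SS` (no bridge), `f_one_SS` (exactly one),
#' `f_two_SS` (two), `f_SOOH_no_SS` (bridge-free dimers with a sulfinic
#' site) and `f_SOOH_and_SS` (bridged dimers with a sulfinic site).  All are
#' fractions of the total dimer concentration.
#'
#' @param dimer_concentrations Named vector of canonical dimer
#'   concentrations (uM); names may carry the `Prx_` prefix; absent species
#'   count as 0.
#' @return Named list of the five fractions.
#' @export
state_fractions <- function(dimer_concentrations) {
  x <- .dimer_conc_vector(dimer_concentrations)
  total <- sum(x)
  if (total <= 0)
    stop("state fractions are undefined for a zero dimer pool",
         call. = FALSE)
  n_ss <- vapply(names(x), function(l)
    sum(unlist(strsplit(l, "_")) == "SS"), 0L)
  has_soo <- vapply(names(x), function(l)
    any(unlist(strsplit(l, "_")) == "SOOH"), TRUE)
  list(
    f_no_SS       = sum(x[n_ss == 0]) / total,
    f_one_SS      = sum(x[n_ss == 1]) / total,
    f_two_SS      = sum(x[n_ss == 2]) / total,
    f_SOOH_no_SS  = sum(x[n_ss == 0 & has_soo]) / total,
    f_SOOH_and_SS = sum(x[n_ss >= 1 & has_soo]) / total)
}

#' Fraction of reduced sites residing in hetero-oxidised dimers
#'
#' Hetero-oxidised dimers (one reduced site paired with an oxidised one)
#' cannot join decamers, so their reduced sites carry the low dimer-level
#' activity.  Returns the fraction of all SH sites whose partner site is not
#' SH.
#'
#' @inheritParams state_fractions
#' @return A fraction in [0, 1].
#' @export
hetero_oxidised_reduced_fraction <- function(dimer_concentrations) {
  x <- .dimer_conc_vector(dimer_concentrations)
  n_sh <- vapply(names(x), function(l)
    sum(unlist(strsplit(l, "_")) == "SH"), 0L)
  total_sh <- sum(n_sh * x)
  if (total_sh <= 0)
    stop("no reduced (SH) sites present; fraction undefined", call. = FALSE)
  hetero_sh <- sum(x[n_sh == 1])
  hetero_sh / total_sh
}
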