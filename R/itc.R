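# Simulation of multi-injection ITC dilution experiments of decamer
# dissociation: injection events with volume tracking, chemical power,
# first-order instrument response, baseline correction and per-injection
# heats.

#' ITC dilution protocol
#'
#' Defaults reproduce the simulated PRDX1 protocol: 1.6 uL injections every
#' 200 s of a 51 uM (total dimer) pre-equilibrated Prx stock into an
#' initially 1400 uL cell, with a dissociation enthalpy of 156 kcal per mol
#' of dimer.  With `first_injection_compensation` the cell starts with one
#' injection's worth of fully dissociated dimers, standing in for the
#' syringe-diffusion loss of the (conventionally discarded) first injection.
#'
#' @param injection_volume uL per injection.
#' @param injection_interval s between injections.
#' @param n_injections Number of injections (>= 1).
#' @param cell_volume_initial Initial cell volume (uL).
#' @param syringe_total_dimer Total Prx in the syringe (uM, dimer units).
#' @param delta_H Dissociation enthalpy (kcal per mol dimer).
#' @param first_injection_compensation Logical.
#' @return Object of class `prx_itc_protocol`.
#' @export
itc_protocol <- function(injection_volume = 1.6, injection_interval = 200,
                         n_injections = 35, cell_volume_initial = 1400,
                         syringe_total_dimer = 51, delta_H = 156,
                         first_injection_compensation = TRUE) {
  if (n_injections < 1)
    stop("a protocol needs at least one injection", call. = FALSE)
  vals <- c(injection_volume, injection_interval, cell_volume_initial,
            syringe_total_dimer, delta_H)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("protocol parameters must be positive", call. = FALSE)
  structure(list(injection_volume = injection_volume,
                 injection_interval = injection_interval,
                 n_injections = as.integer(n_injections),
                 cell_volume_initial = cell_volume_initial,
                 syringe_total_dimer = syringe_total_dimer,
                 delta_H = delta_H,
                 first_injection_compensation =
                   isTRUE(first_injection_compensation)),
            class = "prx_itc_protocol")
}

#' Instrument response model
#'
#' First-order low-pass response with time constant `response_time`
#' (`tau = 0` is an ideal instrument), plus an affine baseline
#' `offset + drift * t`.
#'
#' @param response_time Time constant tau (s, >= 0).
#' @param baseline_offset Power offset (ucal/s).
#' @param drift_slope Baseline drift (ucal/s per s).
#' @return Object of class `prx_instrument`.
#' @export
instrument_model <- function(response_time = 10, baseline_offset = 0,
                             drift_slope = 0) {
  if (response_time < 0) stop("response_time must be >= 0", call. = FALSE)
  structure(list(response_time = response_time,
                 baseline_offset = baseline_offset,
                 drift_slope = drift_slope),
            class = "prx_instrument")
}

#' Power trace container
#'
#' @param time Uniform time grid (s).
#' @param power Power samples (ucal/s); endothermic dissociation is
#'   negative.
#' @param injection_times Injection time stamps (s).
#' @return A data frame of class `prx_power_trace` with attributes
#'   `injection_times` and `units`.
#' @export
power_trace <- function(time, power, injection_times = numeric(0)) {
  stopifnot(length(time) == length(power), all(is.finite(power)))
  dt <- diff(time)
  if (length(dt) && max(abs(dt - dt[1])) > 1e-8 * dt[1])
    stop("power traces require a uniform time grid", call. = FALSE)
  structure(data.frame(time = time, power = power),
            injection_times = injection_times,
            units = "ucal_per_s",
            class = c("prx_power_trace", "data.frame"))
}

.trace_dt <- function(trace) trace$time[2] - trace$time[1]

#' Simulate the chemical power trace of an ITC dilution experiment
#'
#' The syringe holds the dimer/decamer equilibrium at the syringe
#' concentration (a concentrated, hence overwhelmingly decameric, stock).
#' Each injection instantaneously adds the corresponding amounts and
#' increases the cell volume; between injections the association/
#' dissociation kinetics relax the cell contents.  The chemical power is
#' `P(t) = n (v_ass - v_diss) V dH` (ucal/s) -- the net rate of dimer
#' consumption times the per-dimer enthalpy -- so net dissociation
#' (endothermic) is negative.  The association exponent `n` may be the
#' mechanistic 5 or the phenomenological 130; `[dimer]^n` is evaluated in
#' log space.
#'
#' @param protocol [itc_protocol()].
#' @param params [kinetic_parameters()].
#' @param sampling_interval Output sampling interval (s).
#' @return A [power_trace()] with attributes `species` (data frame of time,
#'   dimer and decamer concentration, volume), `protocol` and `params`.
#' @export
simulate_itc <- function(protocol, params = kinetic_parameters(),
                         sampling_interval = 1) {
  pr <- protocol
  eq_s <- equilibrium_distribution(pr$syringe_total_dimer, params$Kd_app,
                                   params$n)
  V <- pr$cell_volume_initial
  nd <- 0; nc <- 0                       # amounts, nmol
  if (pr$first_injection_compensation)
    nd <- pr$syringe_total_dimer * pr$injection_volume / 1000
  seg_t <- seq(0, pr$injection_interval, by = sampling_interval)
  if (seg_t[length(seg_t)] < pr$injection_interval)
    seg_t <- c(seg_t, pr$injection_interval)
  time <- numeric(0); dimer <- numeric(0); decamer <- numeric(0)
  vol <- numeric(0)
  for (k in seq_len(pr$n_injections)) {
    nd <- nd + eq_s[["dimer"]] * pr$injection_volume / 1000
    nc <- nc + eq_s[["decamer"]] * pr$injection_volume / 1000
    V <- V + pr$injection_volume
    tr <- .simulate_assoc_diss(nd / V * 1000, nc / V * 1000, params, seg_t)
    keep <- if (k == pr$n_injections) seq_len(nrow(tr))
            else seq_len(nrow(tr) - 1L)
    time <- c(time, tr$time[keep] + (k - 1) * pr$injection_interval)
    dimer <- c(dimer, tr$d[keep]); decamer <- c(decamer, tr$c[keep])
    vol <- c(vol, rep(V, length(keep)))
    nd <- tr$d[nrow(tr)] * V / 1000
    nc <- tr$c[nrow(tr)] * V / 1000
  }
  va <- ifelse(dimer > 0, exp(log(params$kon) + params$n * log(dimer)), 0)
  vd <- params$koff * decamer
  # uM/s * uL = pmol/s of net dimer consumption; times kcal/mol gives
  # 1e-3 ucal/s
  p_chem <- params$n * (va - vd) * vol * pr$delta_H / 1000
  out <- power_trace(time, p_chem,
                     injection_times = (seq_len(pr$n_injections) - 1) *
                       pr$injection_interval)
  attr(out, "species") <- data.frame(time = time, dimer = dimer,
                                     decamer = decamer, volume = vol)
  attr(out, "protocol") <- pr
  attr(out, "params") <- params
  out
}

#' Apply the instrument response to a chemical power trace
#'
#' First-order low-pass filtering `dm/dt = (P - m)/tau` (exact first-order-
#' hold discretisation on the uniform grid), then the affine baseline
#' `offset + drift * t`.  With zero offset/drift the integrated heat is
#' preserved up to the filter state remaining at the end of the trace.
#'
#' @param trace A [power_trace()].
#' @param instrument An [instrument_model()].
#' @return A [power_trace()] on the same grid.
#' @export
apply_instrument_response <- function(trace, instrument = instrument_model()) {
  tau <- instrument$response_time
  u <- trace$power
  if (tau == 0) {
    m <- u
  } else {
    dt <- .trace_dt(trace)
    a <- exp(-dt / tau)
    b1 <- 1 - a
    b2 <- 1 - tau / dt * (1 - a)   # first-order hold weights
    m <- numeric(length(u))
    m[1] <- 0
    for (k in seq_len(length(u) - 1L))
      m[k + 1] <- m[k] * a + u[k] * b1 + (u[k + 1] - u[k]) * b2
  }
  m <- m + instrument$baseline_offset + instrument$drift_slope * trace$time
  out <- power_trace(trace$time, m, attr(trace, "injection_times"))
  for (at in c("species", "protocol", "params"))
    attr(out, at) <- attr(trace, at)
  out
}

.window_bounds <- function(trace) {
  it <- attr(trace, "injection_times")
  t_end <- trace$time[length(trace$time)]
  bounds <- sort(unique(c(it, t_end + .trace_dt(trace))))
  bounds <- bounds[bounds > trace$time[1] | bounds == trace$time[1]]
  if (bounds[1] > trace$time[1]) bounds <- c(trace$time[1], bounds)
  bounds
}

#' Baseline-correct a power trace
#'
#' Anchors the baseline in the final fraction of each inter-injection
#' window (where the signal is expected to have returned to baseline),
#' connects the anchor points piecewise-linearly and subtracts.  When the
#' injection period is too short for the trace to reach baseline, the
#' subtracted baseline tracks the sagging signal and the correction can
#' locally flip the sign of the trace -- the mechanism behind the apparent
#' exothermic peak at the critical transition concentration.
#'
#' @param trace A [power_trace()] with injection times.
#' @param anchor_fraction Final fraction of each window used as anchor.
#' @return Corrected [power_trace()]; attribute `"baseline"` carries the
#'   subtracted baseline.
#' @export
baseline_correct <- function(trace, anchor_fraction = 0.1) {
  bounds <- .window_bounds(trace)
  n_win <- length(bounds) - 1L
  if (n_win < 2L)
    stop("baseline correction needs at least two inter-injection windows",
         call. = FALSE)
  at <- numeric(n_win); av <- numeric(n_win)
  for (w in seq_len(n_win)) {
    lo <- bounds[w]; hi <- bounds[w + 1L]
    sel <- trace$time >= hi - anchor_fraction * (hi - lo) & trace$time < hi
    if (!any(sel)) sel <- which.max(trace$time[trace$time < hi])
    at[w] <- mean(trace$time[sel]); av[w] <- mean(trace$power[sel])
  }
  bl <- stats::approx(at, av, xout = trace$time, rule = 2)$y
  out <- power_trace(trace$time, trace$power - bl,
                     attr(trace, "injection_times"))
  attr(out, "baseline") <- bl
  for (a in c("species", "protocol", "params"))
    attr(out, a) <- attr(trace, a)
  out
}

.trapz <- function(x, y) sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)

#' Heat released per injection
#'
#' Trapezoidal area of the power trace between consecutive injections (the
#' final window runs to the end of the trace).
#'
#' @param trace A [power_trace()] with injection times.
#' @return Data frame with columns `injection`, `t_start` and `heat_ucal`.
#' @export
injection_heats <- function(trace) {
  bounds <- .window_bounds(trace)
  n_win <- length(bounds) - 1L
  heats <- numeric(n_win)
  for (w in seq_len(n_win)) {
    sel <- trace$time >= bounds[w] & trace$time <= bounds[w + 1L]
    heats[w] <- .trapz(trace$time[sel], trace$power[sel])
  }
  data.frame(injection = seq_len(n_win), t_start = bounds[-length(bounds)],
             heat_ucal = heats)
}

#' Estimate the dissociation enthalpy from per-injection heats
#'
#' Uses the maximum-magnitude injection heat, assuming that injection's
#' decamer content dissociated completely:
#' `dH = max |q| / (moles of dimer delivered per injection)`.
#'
#' @param heats Output of [injection_heats()].
#' @param protocol The [itc_protocol()] that produced the trace.
#' @return Estimated enthalpy (kcal per mol dimer).
#' @export
estimate_enthalpy <- function(heats, protocol) {
  q <- max(abs(heats$heat_ucal))
  nmol <- protocol$syringe_total_dimer * protocol$injection_volume / 1000
  if (q < 1e-9 * nmol)
    stop("all injection heats are ~0; enthalpy is undetermined ",
         "(no informative pre-transition injection)", call. = FALSE)
  q / nmol   # ucal / nmol == kcal / mol
}

# --- trace I/O -----------------------------------------------------------

#' Write a power trace as two-column CSV
#'
#' Injection times and units are stored in `#` comment headers.
#'
#' @param trace A [power_trace()].
#' @param path Output path.
#' @export
write_power_trace <- function(trace, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# prxcycle power trace",
               "# units: ucal_per_s",
               paste0("# injection_times: ",
                      paste(attr(trace, "injection_times"), collapse = ","))),
             con)
  writeLines("time_s,power_ucal_per_s", con)
  writeLines(sprintf("%.10g,%.10g", trace$time, trace$power), con)
  invisible(path)
}

#' Read a power trace written by [write_power_trace()]
#'
#' @param path CSV path.
#' @return A [power_trace()].
#' @export
read_power_trace <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  inj <- numeric(0)
  m <- grep("^# injection_times:", hdr, value = TRUE)
  if (length(m)) {
    body <- trimws(sub("^# injection_times:", "", m[1]))
    if (nzchar(body)) inj <- as.numeric(strsplit(body, ",")[[1]])
  }
  df <- utils::read.csv(text = lines[!grepl("^#", lines)])
  power_trace(df[[1]], df[[2]], injection_times = inj)
}
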