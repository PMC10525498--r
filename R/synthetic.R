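# Synthetic "external-looking" inputs: digitised-style ITC thermograms and
# assay traces with controlled noise, plus sidecar ground truth for recovery
# tests.

#' Specification of a synthetic digitised ITC thermogram
#'
#' @param protocol [itc_protocol()].
#' @param params [kinetic_parameters()] (the generating ground truth).
#' @param instrument [instrument_model()].
#' @param noise_sd Gaussian noise standard deviation, as a fraction of the
#'   peak absolute power.
#' @param drift_slope Linear baseline drift (ucal/s per s) added on top of
#'   the instrument's own drift.
#' @param sampling_interval Sampling interval (s).
#' @param seed Integer seed; mandatory when `noise_sd > 0`.
#' @return Object of class `prx_synth_itc_spec`.
#' @export
synthetic_itc_spec <- function(protocol = itc_protocol(),
                               params = kinetic_parameters(),
                               instrument = instrument_model(),
                               noise_sd = 0.02, drift_slope = 0,
                               sampling_interval = 1, seed = NULL) {
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (noise_sd > 0 && is.null(seed))
    stop("a seed is mandatory for noisy synthetic traces", call. = FALSE)
  structure(list(protocol = protocol, params = params,
                 instrument = instrument, noise_sd = noise_sd,
                 drift_slope = drift_slope,
                 sampling_interval = sampling_interval, seed = seed),
            class = "prx_synth_itc_spec")
}

#' Generate a synthetic measured-scale ITC power trace
#'
#' Chemical simulation, instrument convolution, then seeded Gaussian noise
#' and optional extra drift.  The same spec (and seed) always yields the
#' identical trace.
#'
#' @param spec [synthetic_itc_spec()].
#' @return List with `trace` (a [power_trace()]) and `truth` (the generating
#'   parameters, protocol, instrument and seed).
#' @export
make_synthetic_itc <- function(spec) {
  stopifnot(inherits(spec, "prx_synth_itc_spec"))
  chem <- simulate_itc(spec$protocol, spec$params,
                       sampling_interval = spec$sampling_interval)
  meas <- apply_instrument_response(chem, spec$instrument)
  p <- meas$power
  if (spec$noise_sd > 0) {
    set.seed(spec$seed)
    p <- p + stats::rnorm(length(p), 0, spec$noise_sd * max(abs(p)))
  }
  p <- p + spec$drift_slope * meas$time
  trace <- power_trace(meas$time, p, attr(meas, "injection_times"))
  truth <- list(koff = spec$params$koff, kon = spec$params$kon,
                Kd_app = spec$params$Kd_app, n = spec$params$n,
                delta_H = spec$protocol$delta_H,
                noise_sd = spec$noise_sd, seed = spec$seed,
                response_time = spec$instrument$response_time)
  list(trace = trace, truth = truth)
}

#' Write a synthetic ITC trace and its ground truth to disk
#'
#' @param spec [synthetic_itc_spec()].
#' @param trace_path CSV output for the trace.
#' @param truth_path JSON sidecar for the generating parameters (consumed
#'   only by tests, never by the analysis path).
#' @return `trace_path`, invisibly.
#' @export
write_synthetic_itc <- function(spec, trace_path, truth_path = NULL) {
  out <- make_synthetic_itc(spec)
  write_power_trace(out$trace, trace_path)
  if (!is.null(truth_path))
    jsonlite::write_json(out$truth, truth_path, auto_unbox = TRUE,
                         digits = NA)
  invisible(trace_path)
}

#' Generate assay fixture files
#'
#' Writes CSV fixtures in the dialects the analysis functions read: for
#' `"hrp"`, a per-concentration end-point table (including the Prx-free
#' control) plus the compound-I traces; for `"nadph"`, the NADPH time
#' course.  A JSON sidecar records the generating configuration.
#'
#' @param kind `"hrp"` or `"nadph"`.
#' @param variant Model variant (see [simulate_hrp_assay()]).
#' @param seed Integer seed (recorded; the assay simulations themselves are
#'   deterministic).
#' @param dir Output directory.
#' @param params [kinetic_parameters()]; `k_HRP` required for `"hrp"`.
#' @param config Optional assay config (defaults per kind).
#' @return Named list of written paths, invisibly.
#' @export
make_assay_fixture <- function(kind = c("hrp", "nadph"),
                               variant = ASSAY_VARIANTS, seed = 1L,
                               dir = tempdir(), params = NULL,
                               config = NULL) {
  kind <- match.arg(kind)
  variant <- match.arg(variant)
  if (is.null(params)) params <- paper_repro_params()
  paths <- list()
  if (kind == "hrp") {
    if (is.null(config)) config <- hrp_assay_config()
    res <- simulate_hrp_assay(config, params, variant)
    endpoints <- data.frame(
      prx_total_uM = c(0, res$prx_total),
      delta_A398 = c(res$delta_max, unname(res$delta_obs)))
    p1 <- file.path(dir, paste0("hrp_endpoints_", variant, ".csv"))
    utils::write.csv(endpoints, p1, row.names = FALSE)
    long <- do.call(rbind, lapply(names(res$traces), function(nm) {
      tr <- res$traces[[nm]]
      data.frame(prx_total_uM = as.numeric(nm), time = tr$time,
                 dA398 = tr$dA398)
    }))
    p2 <- file.path(dir, paste0("hrp_traces_", variant, ".csv"))
    utils::write.csv(long, p2, row.names = FALSE)
    paths <- list(endpoints = p1, traces = p2)
    truth <- list(kind = kind, variant = variant, seed = seed,
                  k_HRP = params$k_HRP, HRP_init = config$HRP_init,
                  H2O2_init = config$H2O2_init)
  } else {
    if (is.null(config)) config <- nadph_assay_config()
    res <- simulate_nadph_assay(config, params, variant)
    p1 <- file.path(dir, paste0("nadph_trace_", variant, ".csv"))
    utils::write.csv(res$trace[, c("time", "NADPH")], p1, row.names = FALSE)
    paths <- list(trace = p1)
    truth <- list(kind = kind, variant = variant, seed = seed,
                  prx_total = config$prx_total, H2O2 = config$H2O2)
  }
  pt <- file.path(dir, paste0(kind, "_truth_", variant, ".json"))
  jsonlite::write_json(truth, pt, auto_unbox = TRUE, digits = NA)
  paths$truth <- pt
  invisible(paths)
}
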