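#' Specification of a synthetic stopped-flow titration
#'
#' Forward model for ATP-induced actomyosin dissociation monitored by pyrene
#' fluorescence in the presence of competing ADP. At each ADP concentration
#' the trace is A_f exp(-k_f t) + A_s exp(-k_s t) + C + noise with the fast
#' phase slowed by competitive inhibition, k_f = k0 / (1 + [ADP]/K_ADP). At
#' [ADP] = 0 the slow amplitude is set to 0 (single-exponential condition,
#' as in the zero-ADP control).
#'
#' @param adp_concentrations ADP grid, uM (default the experimental grid
#'   0-640 uM).
#' @param k0 fast-phase rate at zero ADP, 1/s.
#' @param K_ADP_true ground-truth apparent ADP affinity, uM.
#' @param slow_rate slow-phase rate, 1/s; must stay below the fast rate at
#'   the highest ADP concentration for the phases to be separable.
#' @param fast_amplitude,slow_amplitude,offset signal units.
#' @param noise_sd additive i.i.d. Gaussian noise SD, signal units. The
#'   default is 1% of the fast-phase amplitude.
#' @param n_points,duration samples per trace and trace length (s).
#' @param atp ATP concentration recorded in the metadata, uM.
#' @param seed integer RNG seed.
#' @export
stopped_flow_spec <- function(adp_concentrations = c(0, 20, 40, 80, 160,
                                                     320, 640),
                              k0 = 100, K_ADP_true = 46.46, slow_rate = 1.5,
                              fast_amplitude = 0.7, slow_amplitude = 0.2,
                              offset = 0.1, noise_sd = 0.007,
                              n_points = 400, duration = 2, atp = 25,
                              seed = 1L) {
  stopifnot(k0 > 0, K_ADP_true > 0, slow_rate > 0,
            all(adp_concentrations >= 0), is_count(n_points), duration > 0,
            noise_sd >= 0)
  kf_min <- k0 / (1 + max(adp_concentrations) / K_ADP_true)
  if (kf_min <= slow_rate)
    stop("phases not separable: fast rate at the highest [ADP] (",
         signif(kf_min, 3), "/s) does not exceed the slow rate")
  structure(list(adp_concentrations = adp_concentrations, k0 = k0,
                 K_ADP_true = K_ADP_true, slow_rate = slow_rate,
                 fast_amplitude = fast_amplitude,
                 slow_amplitude = slow_amplitude, offset = offset,
                 noise_sd = noise_sd, n_points = as.integer(n_points),
                 duration = duration, atp = atp, seed = as.integer(seed)),
            class = "stopped_flow_spec")
}

#' Fluorescence trace container
#'
#' @param time strictly increasing time base, s (>= 20 points).
#' @param signal fluorescence, arbitrary units.
#' @param adp,atp condition, uM.
#' @param replicate replicate identifier.
#' @param warning optional character flag recorded by the generator (e.g.
#'   marginal phase separability).
#' @export
fluorescence_trace <- function(time, signal, adp = 0, atp = 25,
                               replicate = 1L, warning = NULL) {
  stopifnot(length(time) == length(signal), length(time) >= 20L,
            all(diff(time) > 0))
  structure(list(time = time, signal = signal,
                 meta = list(adp = adp, atp = atp, replicate = replicate,
                             warning = warning)),
            class = "fluorescence_trace")
}

#' @export
print.fluorescence_trace <- function(x, ...) {
  cat(sprintf("fluorescence_trace: %d points over %.3g s, [ADP] = %g uM\n",
              length(x$time), max(x$time), x$meta$adp))
  invisible(x)
}

#' Generate synthetic stopped-flow traces
#'
#' Realizes a [stopped_flow_spec()] as one trace per ADP concentration. If
#' the fast and slow phases are marginally separable (fast rate below three
#' times the slow rate at the highest ADP), the affected traces carry a
#' warning flag in their metadata.
#'
#' @param spec a [stopped_flow_spec()].
#' @return list of [fluorescence_trace()] objects, one per [ADP], with the
#'   ground-truth fast rates attached as attribute `k_fast_true`.
#' @export
generate_stopped_flow_traces <- function(spec) {
  stopifnot(inherits(spec, "stopped_flow_spec"))
  tgrid <- seq(0, spec$duration, length.out = spec$n_points)
  kf <- spec$k0 / (1 + spec$adp_concentrations / spec$K_ADP_true)
  traces <- with_seed(spec$seed, {
    lapply(seq_along(spec$adp_concentrations), function(i) {
      adp <- spec$adp_concentrations[i]
      As <- if (adp == 0) 0 else spec$slow_amplitude
      mu <- spec$fast_amplitude * exp(-kf[i] * tgrid) +
        As * exp(-spec$slow_rate * tgrid) + spec$offset
      flag <- if (kf[i] < 3 * spec$slow_rate)
        "fast/slow rate ratio < 3: phases marginally separable" else NULL
      fluorescence_trace(tgrid, mu + rnorm(length(tgrid), 0, spec$noise_sd),
                         adp = adp, atp = spec$atp, warning = flag)
    })
  })
  attr(traces, "k_fast_true") <- kf
  traces
}

#' Write / read a fluorescence trace as CSV with a JSON metadata sidecar
#'
#' The CSV holds `time, signal`; the sidecar (same path with `.json`
#' appended) holds the condition metadata.
#'
#' @param trace a [fluorescence_trace()].
#' @param file CSV path.
#' @export
write_trace_csv <- function(trace, file) {
  utils::write.csv(data.frame(time = trace$time, signal = trace$signal),
                   file, row.names = FALSE)
  jsonlite::write_json(trace$meta[!vapply(trace$meta, is.null, logical(1L))],
                       paste0(file, ".json"), auto_unbox = TRUE)
  invisible(file)
}

#' @rdname write_trace_csv
#' @export
read_trace_csv <- function(file) {
  df <- utils::read.csv(file)
  meta <- if (file.exists(paste0(file, ".json")))
    jsonlite::read_json(paste0(file, ".json"), simplifyVector = TRUE)
  else list(adp = 0, atp = 25, replicate = 1L)
  fluorescence_trace(df$time, df$signal, adp = meta$adp %||% 0,
                     atp = meta$atp %||% 25,
                     replicate = meta$replicate %||% 1L)
}
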