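#' Specification of a synthetic myofibril force trace
#'
#' Piecewise forward model of a calcium activation/relaxation cycle:
#' baseline; exponential force development
#' F = baseline + F_ss (1 - exp(-k_ACT (t - t_act))); plateau; from the
#' relaxation switch, a linear slow phase of slope -k_REL_slow * F_ss
#' lasting t_REL_slow; then exponential decay back to baseline at
#' k_REL_fast. Gaussian noise is added and the solution-switch times are
#' stored as event markers.
#'
#' @param F_ss steady-state (plateau) force above baseline, instrument
#'   units.
#' @param k_ACT activation rate, 1/s.
#' @param k_REL_slow_true normalized slow-phase slope, 1/s.
#' @param t_REL_slow_true slow-phase duration, s.
#' @param k_REL_fast_true fast-phase rate, 1/s (must exceed the slow rate).
#' @param baseline resting force.
#' @param activation_time,relaxation_time solution-switch times, s.
#' @param duration total trace length, s; default runs well past the fast
#'   relaxation.
#' @param noise_sd additive Gaussian noise SD, force units.
#' @param sample_rate Hz.
#' @param pCa,genotype,atp,adp condition metadata (e.g. pCa `"5.6"` or
#'   `"5.6ADP"`, nucleotide mix in mM).
#' @param seed integer RNG seed.
#' @export
force_trace_spec <- function(F_ss = 100, k_ACT = 4, k_REL_slow_true = 0.5,
                             t_REL_slow_true = 0.2, k_REL_fast_true = 8,
                             baseline = 0, activation_time = 0.5,
                             relaxation_time = 3, duration = NULL,
                             noise_sd = 0, sample_rate = 1000,
                             pCa = "5.6", genotype = "WT",
                             atp = 5, adp = 0, seed = 1L) {
  stopifnot(F_ss > 0, k_ACT > 0, k_REL_slow_true > 0, t_REL_slow_true > 0,
            k_REL_fast_true > 0, relaxation_time > activation_time,
            sample_rate > 0, noise_sd >= 0)
  if (k_REL_slow_true * t_REL_slow_true >= 1)
    stop("k_REL_slow * t_REL_slow must stay below 1 ",
         "(force must remain positive through the linear phase)")
  if (k_REL_fast_true <= k_REL_slow_true)
    stop("fast relaxation rate must exceed the slow-phase rate")
  if (is.null(duration))
    duration <- relaxation_time + t_REL_slow_true + 6 / k_REL_fast_true + 0.5
  structure(list(F_ss = F_ss, k_ACT = k_ACT,
                 k_REL_slow_true = k_REL_slow_true,
                 t_REL_slow_true = t_REL_slow_true,
                 k_REL_fast_true = k_REL_fast_true, baseline = baseline,
                 activation_time = activation_time,
                 relaxation_time = relaxation_time, duration = duration,
                 noise_sd = noise_sd, sample_rate = sample_rate,
                 pCa = pCa, genotype = genotype, atp = atp, adp = adp,
                 seed = as.integer(seed)),
            class = "force_trace_spec")
}

#' ADP-challenge preset applied to a force-trace spec
#'
#' Encodes the qualitative effect of replacing half the nucleotide pool with
#' ADP as ground-truth parameter changes: both relaxation rates halved, the
#' slow-phase duration doubled, activation slowed by 30%, steady-state force
#' unchanged. The condition metadata becomes pCa "5.6ADP" with a 2.5/2.5 mM
#' ATP/ADP mix.
#'
#' @param spec a [force_trace_spec()].
#' @return a modified [force_trace_spec()].
#' @export
adp_challenge <- function(spec) {
  stopifnot(inherits(spec, "force_trace_spec"))
  spec$k_REL_slow_true <- spec$k_REL_slow_true / 2
  spec$k_REL_fast_true <- spec$k_REL_fast_true / 2
  spec$t_REL_slow_true <- spec$t_REL_slow_true * 2
  spec$k_ACT <- spec$k_ACT * 0.7
  spec$duration <- spec$relaxation_time + spec$t_REL_slow_true +
    6 / spec$k_REL_fast_true + 0.5
  spec$pCa <- "5.6ADP"
  spec$atp <- 2.5
  spec$adp <- 2.5
  spec
}

#' Myofibril force trace container
#'
#' @param time s.
#' @param force instrument units.
#' @param events data frame with columns `label` (`"activate"`/`"relax"`)
#'   and `time`; activation must precede relaxation and both must lie in the
#'   time range.
#' @param condition list of metadata (pCa, genotype, atp, adp, ...).
#' @export
force_trace <- function(time, force, events, condition = list()) {
  stopifnot(length(time) == length(force), all(diff(time) > 0),
            is.data.frame(events), all(c("label", "time") %in% names(events)))
  ta <- events$time[events$label == "activate"]
  tr <- events$time[events$label == "relax"]
  if (length(ta) && length(tr) && any(tr <= max(ta) & tr <= min(ta)))
    stop("activation must precede relaxation")
  if (any(events$time < min(time) | events$time > max(time)))
    stop("events must lie within the time range")
  if (identical(condition$pCa, "5.6ADP") &&
      (!identical(condition$atp, 2.5) || !identical(condition$adp, 2.5)))
    stop("pCa 5.6ADP implies a 2.5 mM ATP / 2.5 mM ADP nucleotide mix")
  structure(list(time = time, force = force, events = events,
                 condition = condition),
            class = "force_trace")
}

#' @export
print.force_trace <- function(x, ...) {
  cat(sprintf("force_trace: %d samples over %.3g s, pCa %s, %s\n",
              length(x$time), max(x$time),
              x$condition$pCa %||% "?", x$condition$genotype %||% ""))
  invisible(x)
}

event_time <- function(trace, label) {
  t <- trace$events$time[trace$events$label == label]
  if (!length(t)) stop("trace has no '", label, "' event")
  t[1L]
}

#' Generate a synthetic myofibril force trace
#'
#' @param spec a [force_trace_spec()].
#' @return a [force_trace()] with `activate` and `relax` event markers and
#'   the ground-truth parameters attached as attribute `truth`.
#' @export
generate_force_trace <- function(spec) {
  stopifnot(inherits(spec, "force_trace_spec"))
  tt <- seq(0, spec$duration, by = 1 / spec$sample_rate)
  ta <- spec$activation_time; tr <- spec$relaxation_time
  f <- rep(spec$baseline, length(tt))
  rise <- tt >= ta & tt < tr
  f[rise] <- spec$baseline +
    spec$F_ss * (1 - exp(-spec$k_ACT * (tt[rise] - ta)))
  F_rel <- spec$baseline + spec$F_ss * (1 - exp(-spec$k_ACT * (tr - ta)))
  t_trans <- tr + spec$t_REL_slow_true
  lin <- tt >= tr & tt < t_trans
  f[lin] <- F_rel - spec$k_REL_slow_true * spec$F_ss * (tt[lin] - tr)
  F_trans <- F_rel - spec$k_REL_slow_true * spec$F_ss * spec$t_REL_slow_true
  decay <- tt >= t_trans
  f[decay] <- spec$baseline + (F_trans - spec$baseline) *
    exp(-spec$k_REL_fast_true * (tt[decay] - t_trans))
  if (spec$noise_sd > 0)
    f <- with_seed(spec$seed, f + rnorm(length(f), 0, spec$noise_sd))
  trace <- force_trace(tt, f,
                       data.frame(label = c("activate", "relax"),
                                  time = c(ta, tr)),
                       condition = list(pCa = spec$pCa,
                                        genotype = spec$genotype,
                                        atp = spec$atp, adp = spec$adp))
  attr(trace, "truth") <- spec[c("F_ss", "k_ACT", "k_REL_slow_true",
                                 "t_REL_slow_true", "k_REL_fast_true",
                                 "baseline")]
  trace
}

#' Write / read a force trace as CSV with a JSON events sidecar
#'
#' @param trace a [force_trace()].
#' @param file CSV path (`time, force`); events and condition go to
#'   `<file>.json`.
#' @export
write_force_csv <- function(trace, file) {
  utils::write.csv(data.frame(time = trace$time, force = trace$force),
                   file, row.names = FALSE)
  jsonlite::write_json(list(events = trace$events,
                            condition = trace$condition),
                       paste0(file, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(file)
}

#' @rdname write_force_csv
#' @export
read_force_csv <- function(file) {
  df <- utils::read.csv(file)
  side <- jsonlite::read_json(paste0(file, ".json"), simplifyVector = TRUE)
  force_trace(df$time, df$force, as.data.frame(side$events),
              condition = as.list(side$condition))
}
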