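# Dead time of the solution switch (s); samples this close after a switch
# are excluded from fit windows.
SWITCH_DEAD_TIME <- 0.005

#' Average sequential activation traces
#'
#' Traces are aligned on their activation events (time shifted so the
#' activation switch is at the first trace's activation time), interpolated
#' onto the first trace's time base, and averaged pointwise. Conditions must
#' match.
#'
#' @param traces list of [force_trace()] objects of the same condition.
#' @return a [force_trace()].
#' @export
average_activations <- function(traces) {
  stopifnot(length(traces) >= 1L)
  c0 <- traces[[1L]]$condition
  same <- vapply(traces, function(tr)
    identical(tr$condition$pCa, c0$pCa) &&
      identical(tr$condition$genotype, c0$genotype) &&
      identical(tr$condition$atp, c0$atp) &&
      identical(tr$condition$adp, c0$adp), logical(1L))
  if (!all(same)) stop("traces have mismatched conditions")
  tb <- traces[[1L]]$time
  ta0 <- event_time(traces[[1L]], "activate")
  sig <- rowMeans(vapply(traces, function(tr) {
    shift <- event_time(tr, "activate") - ta0
    approx(tr$time - shift, tr$force, xout = tb, rule = 2L)$y
  }, numeric(length(tb))))
  force_trace(tb, sig, traces[[1L]]$events, condition = c0)
}

#' Steady-state force of an activation
#'
#' Mean force over a window immediately preceding the relaxation switch,
#' minus the pre-activation baseline (so a uniform baseline shift leaves the
#' result unchanged).
#'
#' @param trace a [force_trace()] with `activate` and `relax` events.
#' @param window plateau window length before the relax event, s.
#' @return baseline-subtracted steady-state force.
#' @export
steady_state_force <- function(trace, window = 0.5) {
  ta <- event_time(trace, "activate")
  tr <- event_time(trace, "relax")
  if (tr - window < ta)
    stop("plateau window extends before the activation event")
  plateau <- trace$force[trace$time >= tr - window & trace$time <= tr]
  base <- trace$force[trace$time < ta - SWITCH_DEAD_TIME]
  if (!length(base)) base <- trace$force[trace$time < ta]
  mean(plateau) - mean(base)
}

#' Activation rate from the force rise
#'
#' Fits F = base + F_ss (1 - exp(-k (t - t_act))) between the activation
#' switch (plus the solution dead time) and the relaxation switch, with
#' multi-start rate initialization.
#'
#' @param trace a [force_trace()].
#' @return fitted rate k_ACT, 1/s, with the full fit in attribute `fit`.
#' @export
fit_kact <- function(trace) {
  ta <- event_time(trace, "activate")
  tr <- event_time(trace, "relax")
  keep <- trace$time >= ta + SWITCH_DEAD_TIME &
    trace$time <= tr - SWITCH_DEAD_TIME
  d <- data.frame(t = trace$time[keep] - ta, y = trace$force[keep])
  base0 <- mean(trace$force[trace$time < ta - SWITCH_DEAD_TIME])
  if (!is.finite(base0)) base0 <- d$y[1L]
  F0 <- max(d$y) - base0
  starts <- lapply(rate_grid(max(d$t), n = 7L), function(k)
    list(base = base0, Fss = F0, k = k))
  fit <- best_nls(y ~ base + Fss * (1 - exp(-k * t)), d, starts,
                  lower = c(base = -Inf, Fss = 1e-12, k = 1e-9))
  if (is.null(fit)) stop("activation fit failed to converge")
  coef(fit)[["k"]]
}

# Variable-projection exponential-decay fit y ~ B + A exp(-k (t - t0)):
# for each k the linear pair (A, B) is solved in closed form, and k is
# optimized on a log scale. Returns list(k, A, B, sse).
fit_decay_segment <- function(t, y, t0, k_range = c(1e-3, 2000)) {
  solve_lin <- function(k) {
    e <- exp(-k * (t - t0))
    X <- cbind(e, 1)
    f <- lm.fit(X, y)
    list(A = f$coefficients[1L], B = f$coefficients[2L],
         sse = sum(f$residuals^2))
  }
  opt <- optimize(function(logk) solve_lin(exp(logk))$sse,
                  log(k_range), tol = 1e-10)
  k <- exp(opt$minimum)
  c(list(k = k), solve_lin(k))
}

#' Decompose biphasic myofibril relaxation
#'
#' Two-segment change-point fit starting at the relaxation switch: a linear
#' slow phase followed by an exponential fast phase decaying to the final
#' baseline. The transition time is chosen on a candidate grid to minimize
#' the total squared residual (both segments refit per candidate), which
#' makes the estimator directly checkable against an exhaustive scan.
#' Reported quantities: `k_REL_slow` = |linear slope| / force at relaxation
#' onset (above baseline), so the slow rate is invariant to force-unit
#' rescaling; `t_REL_slow` = transition minus switch time; `k_REL_fast` =
#' fitted exponential rate.
#'
#' @param trace a [force_trace()] with a `relax` event.
#' @param search_window candidate transition offsets after the relax event,
#'   s (default 10 ms to 1 s).
#' @param candidate_step spacing of the candidate grid, s (snapped to whole
#'   samples).
#' @return object of class `relaxation_decomposition`: list with
#'   `k_REL_slow`, `t_REL_slow`, `k_REL_fast`, `transition_time`,
#'   `residuals` (per-segment SSE), `monophasic`, `onset_force`, `baseline`.
#' @export
decompose_relaxation <- function(trace, search_window = c(0.01, 1),
                                 candidate_step = 0.005) {
  tr <- event_time(trace, "relax")
  tt <- trace$time; ff <- trace$force
  tail_win <- tt >= max(tt) - 0.2
  baseline <- mean(ff[tail_win])
  onset <- mean(ff[tt >= tr - 0.05 & tt <= tr]) - baseline
  noise_sd <- sd(diff(ff[tail_win])) / sqrt(2)
  if (is.finite(noise_sd) && noise_sd > 0 && onset <= 3 * noise_sd)
    stop("force at the relaxation onset is within noise of baseline")
  seg_idx <- which(tt >= tr + SWITCH_DEAD_TIME)
  ts <- tt[seg_idx]; ys <- ff[seg_idx]
  dt <- median(diff(ts))
  step <- max(1L, round(candidate_step / dt))
  hi <- min(search_window[2L], max(ts) - tr - 10 * dt)
  cand <- ts[ts > tr + search_window[1L] - 1e-12 & ts <= tr + hi]
  cand <- cand[seq(1L, length(cand), by = step)]
  if (!length(cand)) stop("no candidate transition points in the window")
  best <- NULL
  for (tc in cand) {
    i1 <- ts <= tc
    if (sum(i1) < 3L || sum(!i1) < 5L) next
    l1 <- lm.fit(cbind(1, ts[i1] - tr), ys[i1])
    sse1 <- sum(l1$residuals^2)
    f2 <- fit_decay_segment(ts[!i1], ys[!i1], tc)
    tot <- sse1 + f2$sse
    if (is.null(best) || tot < best$tot)
      best <- list(tc = tc, slope = l1$coefficients[2L], sse1 = sse1,
                   f2 = f2, tot = tot)
  }
  if (is.null(best)) stop("relaxation too short to decompose")
  # monophasic check: does the interior change point beat single-segment fits?
  lin_all <- lm.fit(cbind(1, ts - tr), ys)
  exp_all <- fit_decay_segment(ts, ys, tr)
  mono <- best$tot >= min(sum(lin_all$residuals^2), exp_all$sse) - 1e-12
  structure(list(k_REL_slow = unname(abs(best$slope)) / onset,
                 t_REL_slow = best$tc - tr,
                 k_REL_fast = best$f2$k,
                 transition_time = best$tc,
                 residuals = c(slow = best$sse1, fast = best$f2$sse),
                 total_sse = best$tot,
                 monophasic = mono, onset_force = onset,
                 baseline = baseline),
            class = "relaxation_decomposition")
}

#' @export
print.relaxation_decomposition <- function(x, ...) {
  cat(sprintf(paste0("relaxation_decomposition: k_slow = %.4g /s over ",
                     "%.3g s, k_fast = %.4g /s%s\n"),
              x$k_REL_slow, x$t_REL_slow, x$k_REL_fast,
              if (x$monophasic) " [flagged monophasic]" else ""))
  invisible(x)
}

#' Build a mechanics table from per-myofibril measurements
#'
#' Convenience assembler: applies [steady_state_force()], [fit_kact()] and
#' [decompose_relaxation()] to each trace and rows up the results with the
#' genotype/solution labels.
#'
#' @param traces list of [force_trace()] objects.
#' @return data frame with columns `genotype`, `solution`, `force`, `k_ACT`,
#'   `k_REL_slow`, `t_REL_slow`, `k_REL_fast`.
#' @export
mechanics_table <- function(traces) {
  do.call(rbind, lapply(traces, function(tr) {
    dec <- decompose_relaxation(tr)
    data.frame(genotype = tr$condition$genotype %||% NA_character_,
               solution = tr$condition$pCa %||% NA_character_,
               force = steady_state_force(tr),
               k_ACT = fit_kact(tr),
               k_REL_slow = dec$k_REL_slow,
               t_REL_slow = dec$t_REL_slow,
               k_REL_fast = dec$k_REL_fast)
  }))
}

#' Two-way comparison of myofibril mechanics
#'
#' Type-II sums-of-squares two-way ANOVA (robust to the unbalanced group
#' sizes typical of myofibril data) with genotype, solution and their
#' interaction, plus Tukey-adjusted pairwise contrasts between the factor
#' cells.
#'
#' @param table data frame with `genotype` and `solution` factors and the
#'   response column (e.g. from [mechanics_table()]).
#' @param response name of the response column.
#' @return list with `anova` (data frame: term, F, p), `contrasts` (emmeans
#'   pairwise summary) and the fitted `model`.
#' @export
compare_mechanics <- function(table, response) {
  stopifnot(response %in% names(table),
            all(c("genotype", "solution") %in% names(table)))
  table$genotype <- factor(table$genotype)
  table$solution <- factor(table$solution)
  cells <- table(table$genotype, table$solution)
  if (any(cells < 2L))
    stop("every genotype x solution cell needs >= 2 observations")
  fml <- stats::reformulate(c("genotype", "solution", "genotype:solution"),
                            response)
  fit <- lm(fml, data = table)
  aov2 <- car::Anova(fit, type = 2)
  an <- data.frame(term = rownames(aov2), F = aov2$`F value`,
                   p = aov2$`Pr(>F)`)
  an <- an[an$term != "Residuals", ]
  emm <- emmeans::emmeans(fit, ~ genotype * solution)
  ctr <- summary(emmeans::contrast(emm, method = "pairwise"))
  list(anova = an, contrasts = ctr, model = fit)
}
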