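mk_trace <- function(f, tmax = 2, n = 200, adp = 0, atp = 25) {
  tt <- seq(0, tmax, length.out = n)
  fluorescence_trace(tt, f(tt), adp = adp, atp = atp)
}

test_that("trace averaging is pointwise and rejects mixed conditions", {
  tr <- mk_trace(function(t) 2 * exp(-3 * t) + 1)
  avg <- average_traces(list(tr, tr, tr))
  expect_equal(avg$signal, tr$signal)
  up <- mk_trace(function(t) 1 + sin(t))
  dn <- mk_trace(function(t) 1 - sin(t))
  expect_equal(average_traces(list(up, dn))$signal,
               rep(1, length(up$time)))
  other <- mk_trace(function(t) exp(-t), adp = 40)
  expect_error(average_traces(list(tr, other)), "mixed")

  # averaging n noisy replicates shrinks the residual SD ~ 1/sqrt(n)
  set.seed(2)
  noisy <- lapply(1:16, function(i)
    mk_trace(function(t) 2 * exp(-3 * t) + 1 + rnorm(length(t), 0, 0.05)))
  avg16 <- average_traces(noisy)
  resid1 <- sd(noisy[[1]]$signal - tr$signal)
  resid16 <- sd(avg16$signal - tr$signal)
  expect_equal(resid16 / resid1, 1 / 4, tolerance = 0.35)
})

test_that("single-exponential fits invert noiseless traces exactly", {
  tr <- mk_trace(function(t) 2 * exp(-3 * t) + 1)
  fit <- fit_single_exponential(tr)
  expect_equal(fit$phases$rate, 3, tolerance = 1e-6)
  expect_equal(fit$phases$amplitude, 2, tolerance = 1e-6)
  expect_equal(fit$offset, 1, tolerance = 1e-6)
  expect_lt(fit$residual_norm, 1e-6)
  # time rescaling t -> 2t halves the rate
  tr2 <- fluorescence_trace(tr$time * 2, tr$signal)
  expect_equal(fit_single_exponential(tr2)$phases$rate, 1.5,
               tolerance = 1e-6)
})

test_that("single-exponential rate SE has near-nominal coverage at 1% noise", {
  hits <- 0L
  set.seed(7)
  for (i in 1:100) {
    tr <- mk_trace(function(t) 1 * exp(-5 * t) + 0.2 +
                     rnorm(length(t), 0, 0.01), tmax = 1.5)
    fit <- fit_single_exponential(tr)
    if (abs(fit$phases$rate - 5) <= 2 * fit$phases$rate_se) hits <- hits + 1L
  }
  expect_gte(hits, 90)
})

test_that("double-exponential fits recover well-separated phases", {
  tr <- mk_trace(function(t) 0.7 * exp(-50 * t) + 0.2 * exp(-5 * t) + 0.1,
                 tmax = 1, n = 400)
  fit <- fit_double_exponential(tr)
  expect_equal(fit$phases$rate, c(50, 5), tolerance = 1e-5)
  expect_equal(fit$phases$amplitude, c(0.7, 0.2), tolerance = 1e-4)
  expect_equal(fit$offset, 0.1, tolerance = 1e-5)
  expect_null(fit$warning)

  # single-exponential input degenerates to a tiny slow amplitude
  single <- mk_trace(function(t) 1 * exp(-20 * t) + 0.1, n = 400)
  dfit <- fit_double_exponential(single)
  expect_lt(min(abs(dfit$phases$amplitude)), 0.01)
})

test_that("generator obeys the competitive-inhibition forward model", {
  spec <- stopped_flow_spec(K_ADP_true = 50, k0 = 100, noise_sd = 0,
                            seed = 1)
  traces <- generate_stopped_flow_traces(spec)
  kf <- attr(traces, "k_fast_true")
  expect_equal(kf[1], 100) # [ADP] = 0 -> k0 exactly
  expect_equal(kf[spec$adp_concentrations == 40],
               100 / (1 + 40 / 50))
  # at [ADP] = K_ADP the fast rate is exactly k0/2
  spec2 <- stopped_flow_spec(adp_concentrations = c(0, 50, 100, 200, 400),
                             K_ADP_true = 50, noise_sd = 0)
  kf2 <- attr(generate_stopped_flow_traces(spec2), "k_fast_true")
  expect_equal(kf2[2], 50)
  # zero-ADP trace is single-exponential (slow amplitude dropped)
  t0 <- traces[[1]]
  fit0 <- fit_single_exponential(t0)
  expect_lt(fit0$residual_norm, 1e-8)
  # determinism under the seed
  tr_a <- generate_stopped_flow_traces(stopped_flow_spec(seed = 33))
  tr_b <- generate_stopped_flow_traces(stopped_flow_spec(seed = 33))
  expect_identical(lapply(tr_a, `[[`, "signal"),
                   lapply(tr_b, `[[`, "signal"))
  # non-separable phase structure is rejected up front
  expect_error(stopped_flow_spec(slow_rate = 50), "separable")
})

test_that("noise-free titrations are fit exactly end to end", {
  spec <- stopped_flow_spec(K_ADP_true = 40, noise_sd = 0, seed = 1)
  curve <- fit_adp_titration(generate_stopped_flow_traces(spec))
  expect_equal(curve$krel[1], 1)
  kfit <- fit_kadp(curve)
  expect_equal(kfit$K_ADP, 40, tolerance = 1e-4)
  # fitted model passes through (0, 1) and predicts 0.5 at K_ADP
  expect_equal(1 / (1 + 0 / kfit$K_ADP), 1)
  expect_equal(1 / (1 + kfit$K_ADP / kfit$K_ADP), 0.5)
})

test_that("K_ADP fit equals a fine grid-search oracle", {
  set.seed(11)
  adp <- c(0, 20, 40, 80, 160, 320, 640)
  krel <- 1 / (1 + adp / 46.46) + c(0, rnorm(6, 0, 0.01))
  curve <- binding_curve(adp, krel)
  kfit <- fit_kadp(curve)
  grid <- seq(0.01, 1000, by = 0.01)
  sse <- vapply(grid, function(K) sum((krel - 1 / (1 + adp / K))^2),
                numeric(1))
  expect_equal(kfit$K_ADP, grid[which.min(sse)], tolerance = 2e-4)
})

test_that("relative rates and binding-curve preconditions behave", {
  expect_equal(relative_kobs(100, 100), 1)
  expect_equal(relative_kobs(50, 100), 0.5)
  expect_equal(relative_kobs(37.3, 91.1), 37.3 / 91.1)
  expect_error(relative_kobs(10, 0), "positive")
  expect_error(fit_kadp(binding_curve(c(0, 10, 20), c(1, 0.8, 0.6))),
               "4 distinct")
  expect_warning(fit_kadp(binding_curve(c(0, 10, 20, 40, 80),
                                        c(1, 0.5, 0.9, 0.4, 0.2))),
                 "monotone")
})

test_that("rates are invariant to uniform amplitude rescaling", {
  spec <- stopped_flow_spec(K_ADP_true = 60, noise_sd = 0, seed = 3)
  tr <- generate_stopped_flow_traces(spec)[[4]]
  f1 <- fit_double_exponential(tr)
  scaled <- fluorescence_trace(tr$time, tr$signal * 7.5,
                               adp = tr$meta$adp)
  f2 <- fit_double_exponential(scaled)
  expect_equal(f2$phases$rate, f1$phases$rate, tolerance = 1e-6)
  expect_equal(f2$phases$amplitude, 7.5 * f1$phases$amplitude,
               tolerance = 1e-6)
})

test_that("median end-to-end K_ADP recovery error stays under 5%", {
  rec <- kadp_recovery_experiment(46.46, n_repeats = 100, seed = 202)
  rel_err <- abs(rec$estimates - 46.46) / 46.46
  expect_lt(median(rel_err), 0.05)
})

test_that("trace CSV round-trips with metadata sidecar", {
  tr <- mk_trace(function(t) exp(-2 * t) + 0.3, adp = 80)
  f <- tempfile(fileext = ".csv")
  write_trace_csv(tr, f)
  back <- read_trace_csv(f)
  expect_equal(back$signal, tr$signal, tolerance = 1e-12)
  expect_equal(back$meta$adp, 80)
})
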