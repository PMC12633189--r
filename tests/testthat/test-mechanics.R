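test_that("force-trace generator honours its invariants and determinism", {
  expect_error(force_trace_spec(k_REL_slow_true = 2, t_REL_slow_true = 0.6),
               "positive")
  expect_error(force_trace_spec(k_REL_fast_true = 0.2,
                                k_REL_slow_true = 0.5), "exceed")
  expect_error(force_trace_spec(relaxation_time = 0.2,
                                activation_time = 0.5))
  a <- generate_force_trace(force_trace_spec(noise_sd = 2, seed = 10))
  b <- generate_force_trace(force_trace_spec(noise_sd = 2, seed = 10))
  expect_identical(a$force, b$force)
})

test_that("steady-state force is baseline-subtracted and exact", {
  tr <- generate_force_trace(force_trace_spec(noise_sd = 0, F_ss = 100))
  expect_equal(steady_state_force(tr), 100, tolerance = 1e-3)
  shifted <- force_trace(tr$time, tr$force + 10, tr$events, tr$condition)
  expect_equal(steady_state_force(shifted), steady_state_force(tr),
               tolerance = 1e-12)
  # brute-force window mean oracle on a noisy trace
  nz <- generate_force_trace(force_trace_spec(noise_sd = 2, seed = 3))
  trel <- nz$events$time[nz$events$label == "relax"]
  tact <- nz$events$time[nz$events$label == "activate"]
  manual <- mean(nz$force[nz$time >= trel - 0.5 & nz$time <= trel]) -
    mean(nz$force[nz$time < tact - 0.005])
  expect_equal(steady_state_force(nz), manual, tolerance = 1e-12)
  expect_error(steady_state_force(nz, window = 5), "window")
})

test_that("activation fits are exact, shift-invariant and noise-robust", {
  tr <- generate_force_trace(force_trace_spec(noise_sd = 0, k_ACT = 4))
  expect_equal(unname(fit_kact(tr)), 4, tolerance = 1e-6)
  # shifting the whole trace in time leaves k unchanged
  sh <- force_trace(tr$time + 1.5, tr$force,
                    data.frame(label = tr$events$label,
                               time = tr$events$time + 1.5), tr$condition)
  expect_equal(unname(fit_kact(sh)), 4, tolerance = 1e-6)

  set.seed(88)
  errs <- replicate(60, {
    k_true <- runif(1, 2, 8)
    spec <- force_trace_spec(k_ACT = k_true, noise_sd = 2,
                             seed = sample.int(1e6, 1))
    abs(fit_kact(generate_force_trace(spec)) - k_true) / k_true
  })
  expect_lt(median(errs), 0.05)
})

test_that("relaxation decomposition inverts noiseless generator traces", {
  spec <- force_trace_spec(k_REL_slow_true = 0.5, t_REL_slow_true = 0.2,
                           k_REL_fast_true = 8, noise_sd = 0)
  dec <- decompose_relaxation(generate_force_trace(spec))
  expect_equal(dec$k_REL_slow, 0.5, tolerance = 1e-3)
  expect_equal(dec$t_REL_slow, 0.2, tolerance = 1e-9)
  expect_equal(dec$k_REL_fast, 8, tolerance = 1e-6)
  expect_lt(dec$total_sse, 1e-10)
  expect_false(dec$monophasic)
})

test_that("noiseless inversion is machine-exact across a parameter sweep", {
  set.seed(17)
  for (i in 1:30) {
    ks <- runif(1, 0.2, 1)
    tslow <- sample(seq(0.05, 0.4, by = 0.005), 1)
    kf <- runif(1, 4, 15)
    if (ks * tslow >= 1 || kf <= ks) next
    spec <- force_trace_spec(F_ss = runif(1, 50, 200), k_REL_slow_true = ks,
                             t_REL_slow_true = tslow, k_REL_fast_true = kf,
                             noise_sd = 0)
    dec <- decompose_relaxation(generate_force_trace(spec))
    expect_lt(dec$total_sse, 1e-8)
    expect_equal(dec$t_REL_slow, tslow, tolerance = 1e-9)
    expect_equal(dec$k_REL_fast, kf, tolerance = 1e-4)
    expect_equal(dec$k_REL_slow, ks, tolerance = 5e-3)
  }
})

test_that("decomposition scales correctly with force units and F_ss", {
  base <- force_trace_spec(noise_sd = 0)
  tr1 <- generate_force_trace(base)
  d1 <- decompose_relaxation(tr1)
  # doubling F_ss doubles the force but leaves every rate unchanged
  big <- base; big$F_ss <- 200
  tr2 <- generate_force_trace(big)
  d2 <- decompose_relaxation(tr2)
  expect_equal(steady_state_force(tr2), 2 * steady_state_force(tr1),
               tolerance = 1e-3)
  expect_equal(d2$k_REL_slow, d1$k_REL_slow, tolerance = 1e-6)
  expect_equal(d2$k_REL_fast, d1$k_REL_fast, tolerance = 1e-6)
  expect_equal(unname(fit_kact(tr2)), unname(fit_kact(tr1)),
               tolerance = 1e-6)
  # rescaling instrument units (x0.01) leaves the normalized slope alone
  sc <- force_trace(tr1$time, tr1$force * 0.01, tr1$events, tr1$condition)
  expect_equal(decompose_relaxation(sc)$k_REL_slow, d1$k_REL_slow,
               tolerance = 1e-9)
})

test_that("change point equals the exhaustive-scan oracle under noise", {
  spec <- force_trace_spec(noise_sd = 2, t_REL_slow_true = 0.25, seed = 51)
  tr <- generate_force_trace(spec)
  dec <- decompose_relaxation(tr)
  oracle <- bf_changepoint(tr)
  expect_equal(dec$transition_time, oracle$transition_time)
})

test_that("ADP-challenge preset doubles the slow-phase duration", {
  base <- force_trace_spec(noise_sd = 0.5, seed = 14)
  ctrl <- decompose_relaxation(generate_force_trace(base))
  adp <- decompose_relaxation(generate_force_trace(adp_challenge(base)))
  expect_equal(adp$t_REL_slow / ctrl$t_REL_slow, 2, tolerance = 0.1)
  expect_equal(adp$k_REL_fast / ctrl$k_REL_fast, 0.5, tolerance = 0.1)
})

test_that("activation averaging aligns events and rejects mismatches", {
  base <- force_trace_spec(noise_sd = 0)
  tr <- generate_force_trace(base)
  expect_equal(average_activations(list(tr, tr))$force, tr$force)
  # pure-noise offsets shrink by ~1/sqrt(2)
  n1 <- generate_force_trace(force_trace_spec(noise_sd = 3, seed = 1))
  n2 <- generate_force_trace(force_trace_spec(noise_sd = 3, seed = 2))
  avg <- average_activations(list(n1, n2))
  resid_one <- sd(n1$force - tr$force)
  resid_avg <- sd(avg$force - tr$force)
  expect_equal(resid_avg / resid_one, 1 / sqrt(2), tolerance = 0.1)
  other <- generate_force_trace(adp_challenge(base))
  expect_error(average_activations(list(tr, other)), "mismatch")
})

test_that("two-way ANOVA matches manual sums of squares on balanced data", {
  set.seed(4)
  tab <- expand.grid(genotype = c("WT", "MUT"),
                     solution = c("5.6", "5.6ADP"),
                     rep = 1:6)
  tab$force <- rnorm(nrow(tab), 100, 10) +
    ifelse(tab$genotype == "MUT", 25, 0)
  res <- compare_mechanics(tab, "force")
  # balanced design: type-II equals classical aov sums of squares
  a <- summary(stats::aov(force ~ genotype * solution, data = tab))[[1]]
  expect_equal(res$anova$F,
               a$`F value`[1:3], tolerance = 1e-10)
  expect_lt(res$anova$p[res$anova$term == "genotype"], 0.001)
  expect_gt(nrow(res$contrasts), 1)
  # empty/thin cells are rejected
  thin <- tab[!(tab$genotype == "WT" & tab$solution == "5.6ADP"), ]
  expect_error(compare_mechanics(thin, "force"), "cell")
})

test_that("null simulations keep type-I error near nominal with 13-15/cell", {
  set.seed(12)
  pvals <- replicate(1000, {
    n <- c(15, 13, 15, 13)
    tab <- data.frame(
      genotype = rep(c("WT", "MUT", "WT", "MUT"), n),
      solution = rep(c("A", "A", "B", "B"), n),
      y = rnorm(sum(n)))
    fit <- lm(y ~ genotype * solution, data = tab)
    car::Anova(fit, type = 2)["genotype", "Pr(>F)"]
  })
  rate <- mean(pvals < 0.05)
  expect_gte(rate, 0.03)
  expect_lte(rate, 0.07)
})

test_that("an injected 5-SD genotype effect is detected essentially always", {
  set.seed(9)
  hits <- replicate(100, {
    tab <- data.frame(
      genotype = rep(c("WT", "MUT", "WT", "MUT"), c(15, 13, 15, 13)),
      solution = rep(c("A", "A", "B", "B"), c(15, 13, 15, 13)),
      y = rnorm(56))
    tab$y <- tab$y + ifelse(tab$genotype == "MUT", 5, 0)
    fit <- lm(y ~ genotype * solution, data = tab)
    car::Anova(fit, type = 2)["genotype", "Pr(>F)"] < 0.001
  })
  expect_gte(mean(hits), 0.99)
})

test_that("force CSV + events sidecar round-trips", {
  tr <- generate_force_trace(force_trace_spec(noise_sd = 1, seed = 77))
  f <- tempfile(fileext = ".csv")
  write_force_csv(tr, f)
  back <- read_force_csv(f)
  expect_equal(back$force, tr$force, tolerance = 1e-9)
  expect_equal(back$events$time, tr$events$time)
  expect_equal(back$condition$pCa, tr$condition$pCa)
})
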