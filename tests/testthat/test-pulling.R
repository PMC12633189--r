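mk_ens <- function(finals, lambda = c(0, 0.5, 1), temperature = 310) {
  W <- t(vapply(finals, function(w) w * lambda / max(lambda),
                numeric(length(lambda))))
  work_ensemble(lambda, W, temperature = temperature)
}

test_that("work resampling interpolates linearly and anchors at zero", {
  log1 <- data.frame(lambda = c(0, 1), W = c(0, 10))
  ens <- resample_work(list(log1), grid_step = 0.5)
  expect_equal(ens$W[1, ], c(0, 5, 10))
  # identity when already on the grid
  log2 <- data.frame(lambda = seq(0, 1, 0.1), W = seq(0, 20, 2))
  expect_equal(resample_work(list(log2), 0.1)$W[1, ], seq(0, 20, 2))
  # irregular log against base approx oracle
  set.seed(5)
  lam <- sort(c(0, runif(30, 0, 2), 2))
  wv <- cumsum(abs(rnorm(length(lam))))
  wv <- wv - wv[1]
  ens3 <- resample_work(list(data.frame(lambda = lam, W = wv)), 0.1)
  oracle <- approx(lam, wv, xout = ens3$lambda)$y
  expect_equal(ens3$W[1, ], oracle - oracle[1], tolerance = 1e-12)
  # logs with different ranges truncate with warning
  expect_warning(resample_work(list(log1,
                                    data.frame(lambda = c(0, 0.8),
                                               W = c(0, 8))), 0.1),
                 "truncated")
})

test_that("mean work and fold difference reproduce the worked figures", {
  ens <- mk_ens(c(50, 66))
  mw <- mean_work(ens)
  expect_equal(mw$mean_final, 58)
  expect_equal(mw$sd_final, sd(c(50, 66)))
  same <- mk_ens(c(60, 60))
  expect_equal(mean_work(same)$sd_final, 0)
  wt <- mk_ens(c(50, 66)) # mean 58
  mut <- mk_ens(c(82, 96)) # mean 89
  expect_equal(work_fold_difference(wt, mut)$fold, 1.5)
})

test_that("Welch comparison of final works behaves and matches manual", {
  a <- mk_ens(c(10, 12, 14))
  res <- compare_work(a, a)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)

  set.seed(9)
  big_a <- mk_ens(rnorm(60, 50, 2))
  big_b <- mk_ens(rnorm(60, 60, 2)) # 5 SD separation
  expect_lt(compare_work(big_a, big_b)$p_value, 1e-10)

  # manual Welch computation oracle
  x <- c(19, 22, 24, 27); y <- c(28, 31, 33, 35, 36)
  manual_t <- (mean(x) - mean(y)) /
    sqrt(var(x) / length(x) + var(y) / length(y))
  res2 <- compare_work(mk_ens(x), mk_ens(y))
  expect_equal(res2$statistic, manual_t, tolerance = 1e-12)

  deg <- compare_work(mk_ens(c(5, 5)), mk_ens(c(7, 7)))
  expect_true(deg$degenerate)
  expect_true(is.na(deg$p_value))
})

test_that("Jarzynski estimator matches closed forms and Jensen bound", {
  ens <- mk_ens(c(30, 30, 30))
  prof <- jarzynski_profile(ens)
  expect_equal(prof$dF, ens$W[1, ], tolerance = 1e-10)

  kT <- KB * 310
  two <- mk_ens(c(0, 2 * kT))
  prof2 <- jarzynski_profile(two)
  expect_equal(prof2$dF[3] / kT, -log((1 + exp(-2)) / 2), tolerance = 1e-10)
  expect_equal(prof2$dF[3] / kT, 0.566, tolerance = 1e-3)

  # direct-average oracle, Jensen inequality, reorder invariance
  set.seed(3)
  W <- t(replicate(25, cumsum(abs(rnorm(10)))))
  W <- cbind(0, W)
  ens3 <- work_ensemble(seq(0, 1, 0.1) * 10, W, temperature = 310)
  p3 <- jarzynski_profile(ens3)
  for (j in c(2, 6, 11))
    expect_equal(p3$dF[j], bf_jarzynski(W[, j], kT), tolerance = 1e-10)
  expect_true(all(p3$dF <= p3$mean_W + 1e-12))
  expect_equal(p3$dF[1], 0)
  shuf <- work_ensemble(ens3$lambda, W[sample(25), ], temperature = 310)
  expect_equal(jarzynski_profile(shuf)$dF, p3$dF)

  expect_warning(jarzynski_profile(mk_ens(5)), "single replicate")
})

test_that("representative trajectory is the L2-nearest replicate", {
  ens <- mk_ens(c(30, 30, 30))
  prof <- jarzynski_profile(ens)
  expect_equal(representative_trajectory(ens, prof), 1L) # tie -> first

  set.seed(8)
  W <- rbind(0.9 * c(0, 1, 2), c(0, 1.4, 2.9), c(0, 0.7, 1.2))
  e2 <- work_ensemble(c(0, 1, 2), W, temperature = 310)
  p2 <- jarzynski_profile(e2)
  # exhaustive scan oracle
  d2 <- apply(W, 1, function(w) sum((w - p2$dF)^2))
  expect_equal(representative_trajectory(e2, p2), unname(which.min(d2)))
  # a replicate exactly equal to the profile wins
  W3 <- rbind(W, p2$dF)
  e3 <- work_ensemble(c(0, 1, 2), W3, temperature = 310)
  expect_equal(representative_trajectory(e3, p2), 4L)
})

test_that("contact timelines filter by presence and count probabilities", {
  tgrid <- 5
  all_on <- matrix(1, 2, tgrid, dimnames = list(c("c1", "c2"), NULL))
  reps <- replicate(10, all_on, simplify = FALSE)
  tl <- contact_timeline(reps)
  expect_equal(tl$retained, c("c1", "c2"))
  expect_true(all(tl$probability == 1))

  # a contact present in only half the replicates is filtered at 0.9
  half <- lapply(1:10, function(r) {
    m <- all_on
    if (r <= 5) m["c2", ] <- 0
    m
  })
  tl2 <- contact_timeline(half)
  expect_equal(tl2$retained, "c1")

  # brute-force probability counting on a random ensemble
  set.seed(60)
  rnd <- replicate(60, matrix(rbinom(3 * 8, 1, 0.95), 3, 8,
                              dimnames = list(paste0("c", 1:3), NULL)),
                   simplify = FALSE)
  tl3 <- contact_timeline(rnd, presence_threshold = 0.9)
  for (cc in tl3$retained) for (tt in 1:8) {
    manual <- mean(sapply(rnd, function(m) m[cc, tt] != 0))
    expect_equal(unname(tl3$probability[cc, tt]), manual)
  }
})

test_that("Langevin ensembles honour quasi-static and flat-potential limits", {
  # stiff spring, slow pull on a harmonic surface: <W> ~ dF = k d^2 / 2
  spec <- pulling_spec(pulling_potential("harmonic", k = 2),
                       spring_constant = 500, pull_speed = 1,
                       end_position = 2, n_replicates = 12, seed = 4)
  ens <- generate_pulling_ensemble(spec)
  expect_equal(ens$dF_analytic, 4)
  mw <- mean_work(ens)
  expect_equal(mw$mean_final, 4, tolerance = 0.15)
  # second law on the ensemble mean
  expect_gte(mw$mean_final, ens$dF_analytic - 2 * mw$sd_final / sqrt(12))

  # flat potential: dF = 0 and the Jarzynski estimate approaches it
  flat <- generate_pulling_ensemble(
    pulling_spec(pulling_potential("flat"), end_position = 2,
                 pull_speed = 2, n_replicates = 40, seed = 6))
  expect_equal(flat$dF_analytic, 0)
  pf <- jarzynski_profile(flat)
  expect_lt(abs(pf$dF[length(pf$dF)]), 3 * KB * 310)
  expect_true(all(pf$dF <= pf$mean_W + 1e-9))
})

test_that("double-well pulls dissipate and reproducibility holds", {
  pot <- pulling_potential("double_well", height = 3, half_width = 1.5)
  spec <- pulling_spec(pot, start_position = -1.5, end_position = 1.5,
                       pull_speed = 10, n_replicates = 20, seed = 12)
  ens <- generate_pulling_ensemble(spec)
  # dF from numerical quadrature of the guided Boltzmann weight
  dfq <- stiff_spring_profile(pot, c(-1.5, 1.5), 100, 310)[2]
  expect_gt(mean_work(ens)$mean_final, dfq) # dissipated work positive
  expect_equal(ens$dF_analytic, 0, tolerance = 1e-10)

  ens2 <- generate_pulling_ensemble(spec)
  expect_identical(ens$W, ens2$W)
})

test_that("unstable or sloppy integrator setups are flagged", {
  expect_error(generate_pulling_ensemble(
    pulling_spec(pulling_potential("flat"), spring_constant = 100,
                 timestep = 2, friction = 50, end_position = 1,
                 pull_speed = 100, n_replicates = 2)),
    "unstable")
  expect_warning(generate_pulling_ensemble(
    pulling_spec(pulling_potential("flat"), spring_constant = 0.05,
                 pull_speed = 50, end_position = 30, friction = 200,
                 n_replicates = 2, seed = 1)),
    "lag|track")
})

test_that("steering bookkeeping converts distances to durations", {
  sched <- steering_schedule(c(3.6, 4.4))
  expect_equal(sched$duration_ns, c(10.8, 10))
  expect_equal(sched$pull_distance, c(10.8, 10))
  expect_error(steering_schedule(15))
})

test_that("work TSV round-trips through resample_work", {
  ens <- mk_ens(c(10, 20, 30))
  f <- tempfile(fileext = ".tsv")
  write_work_tsv(ens, f)
  back <- resample_work(read_work_tsv(f), grid_step = 0.5)
  expect_equal(back$W, unname(ens$W), tolerance = 1e-12)
})
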