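# Brute-force reference implementations, kept deliberately naive and
# independent of the package's vectorized code paths.

R_GAS <- 1.98720425864083
KB <- 1.98720425864083e-3

# Torsion via the determinant form atan2(|b2| b1.(b2 x b3), (b1 x b2).(b2 x b3))
bf_dihedral <- function(p1, p2, p3, p4) {
  cr <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                         a[3] * b[1] - a[1] * b[3],
                         a[1] * b[2] - a[2] * b[1])
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  atan2(sqrt(sum(b2^2)) * sum(b1 * cr(b2, b3)),
        sum(cr(b1, b2) * cr(b2, b3))) * 180 / pi
}

# Per-frame residue contact check by explicit pair loops.
bf_contact_fraction <- function(traj, ra, rb, cutoff = 5) {
  top <- traj$topology
  ia <- which(top$resid == ra & top$heavy)
  ib <- which(top$resid == rb & top$heavy)
  hits <- 0L
  for (f in seq_len(n_frames(traj))) {
    inc <- FALSE
    for (i in ia) for (j in ib) {
      d <- sqrt(sum((traj$coords[f, i, ] - traj$coords[f, j, ])^2))
      if (d <= cutoff) inc <- TRUE
    }
    if (inc) hits <- hits + 1L
  }
  hits / n_frames(traj)
}

bf_com_distance <- function(traj, ia, ib) {
  m <- traj$topology$mass
  sapply(seq_len(n_frames(traj)), function(f) {
    ca <- c(0, 0, 0); cb <- c(0, 0, 0)
    for (i in ia) ca <- ca + m[i] * traj$coords[f, i, ]
    for (i in ib) cb <- cb + m[i] * traj$coords[f, i, ]
    sqrt(sum((ca / sum(m[ia]) - cb / sum(m[ib]))^2))
  })
}

# Pairwise Coulomb + Lennard-Jones, looped atom by atom.
bf_lie <- function(traj, resid, lig_idx, cutoff = Inf) {
  top <- traj$topology
  rows <- which(top$resid == resid)
  elec <- vdw <- numeric(n_frames(traj))
  for (f in seq_len(n_frames(traj))) {
    for (i in rows) for (j in lig_idx) {
      r <- sqrt(sum((traj$coords[f, i, ] - traj$coords[f, j, ])^2))
      if (r > cutoff) next
      elec[f] <- elec[f] + 332.0636 * top$charge[i] * top$charge[j] / r
      sig <- (top$sigma[i] + top$sigma[j]) / 2
      eps <- sqrt(top$epsilon[i] * top$epsilon[j])
      vdw[f] <- vdw[f] + 4 * eps * ((sig / r)^12 - (sig / r)^6)
    }
  }
  c(electrostatic = mean(elec), vdw = mean(vdw),
    combined = mean(elec) + mean(vdw))
}

# Direct Jarzynski average without the log-sum-exp reduction.
bf_jarzynski <- function(W_col, kT) -kT * log(mean(exp(-W_col / kT)))

# Exhaustive change-point scan sharing the candidate grid of
# decompose_relaxation but refitting each candidate from scratch with nls
# machinery independent of fit_decay_segment's variable projection.
bf_changepoint <- function(trace, search_window = c(0.01, 1),
                           candidate_step = 0.005) {
  tr <- trace$events$time[trace$events$label == "relax"][1]
  keep <- trace$time >= tr + 0.005
  ts <- trace$time[keep]; ys <- trace$force[keep]
  dt <- median(diff(ts))
  step <- max(1L, round(candidate_step / dt))
  hi <- min(search_window[2], max(ts) - tr - 10 * dt)
  cand <- ts[ts > tr + search_window[1] - 1e-12 & ts <= tr + hi]
  cand <- cand[seq(1L, length(cand), by = step)]
  best_tc <- NA_real_; best_sse <- Inf
  for (tc in cand) {
    i1 <- ts <= tc
    if (sum(i1) < 3L || sum(!i1) < 5L) next
    sse1 <- sum(resid(lm(ys[i1] ~ ts[i1]))^2)
    sse2 <- tryCatch({
      d2 <- data.frame(t = ts[!i1] - tc, y = ys[!i1])
      ks <- exp(seq(log(0.05), log(500), length.out = 12))
      best <- Inf
      for (k0 in ks) {
        f <- tryCatch(suppressWarnings(minpack.lm::nlsLM(
          y ~ B + A * exp(-k * t), d2,
          start = list(A = d2$y[1], k = k0, B = min(d2$y)),
          control = minpack.lm::nls.lm.control(maxiter = 300))),
          error = function(e) NULL)
        if (!is.null(f)) best <- min(best, sum(resid(f)^2))
      }
      best
    }, error = function(e) Inf)
    if (sse1 + sse2 < best_sse) { best_sse <- sse1 + sse2; best_tc <- tc }
  }
  list(transition_time = best_tc, sse = best_sse)
}

# A free-form random coordinate trajectory (no schedules) for oracle tests.
random_toy_traj <- function(n_frames = 20, n_res = 3, atoms_per_res = 2,
                            seed = 1, charged = TRUE) {
  set.seed(seed)
  n_at <- n_res * atoms_per_res
  top <- data.frame(name = paste0("A", seq_len(n_at)),
                    element = sample(c("C", "N", "O"), n_at, replace = TRUE),
                    resid = rep(seq_len(n_res), each = atoms_per_res),
                    resname = "RES",
                    charge = if (charged) runif(n_at, -1, 1) else 0,
                    sigma = runif(n_at, 2.5, 4),
                    epsilon = runif(n_at, 0.05, 0.3))
  coords <- array(runif(n_frames * n_at * 3, 0, 10),
                  c(n_frames, n_at, 3))
  md_trajectory(coords, top)
}
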