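#' One-dimensional potentials for toy pulling simulations
#'
#' Energy surfaces U(q) (kcal/mol as a function of the reaction coordinate
#' in A) used by [generate_pulling_ensemble()]. Available forms:
#' `"flat"` (U = 0), `"harmonic"` (U = k/2 (q - center)^2),
#' `"double_well"` (U = height ((q/half_width)^2 - 1)^2, minima at
#' +/- half_width with a barrier of `height` at q = 0), and `"tabulated"`
#' (values on a grid, interpolated).
#'
#' @param type one of `"flat"`, `"harmonic"`, `"double_well"`, `"tabulated"`.
#' @param k,center harmonic stiffness (kcal/mol/A^2) and minimum position.
#' @param height,half_width double-well barrier height (kcal/mol) and
#'   half-separation of the minima (A).
#' @param q,U grid and energies for the tabulated form.
#' @return object of class `pulling_potential` with callable `U` and `dU`.
#' @export
pulling_potential <- function(type = c("flat", "harmonic", "double_well",
                                       "tabulated"),
                              k = 1, center = 0, height = 3, half_width = 2,
                              q = NULL, U = NULL) {
  type <- match.arg(type)
  obj <- switch(type,
    flat = list(code = 0L, params = numeric(0L),
                U = function(x) rep(0, length(x)),
                dU = function(x) rep(0, length(x))),
    harmonic = list(code = 1L, params = c(k, center),
                    U = function(x) 0.5 * k * (x - center)^2,
                    dU = function(x) k * (x - center)),
    double_well = list(code = 2L, params = c(height, half_width),
                       U = function(x) height * ((x / half_width)^2 - 1)^2,
                       dU = function(x)
                         height * 4 * (x / half_width) *
                           ((x / half_width)^2 - 1) / half_width),
    tabulated = {
      stopifnot(!is.null(q), !is.null(U), length(q) == length(U))
      sf <- stats::splinefun(q, U, method = "natural")
      list(code = 3L, params = numeric(0L), grid_q = q,
           U = function(x) sf(x), dU = function(x) sf(x, deriv = 1L))
    })
  obj$type <- type
  if (is.null(obj$grid_q)) obj$grid_q <- numeric(0L)
  structure(obj, class = "pulling_potential")
}

#' Specification of a steered-pulling ensemble
#'
#' Parameters for an overdamped Langevin particle in a 1-D potential,
#' dragged by a stiff harmonic guide whose centre moves at constant speed
#' from `start_position` to `end_position` -- a desk-scale surrogate for
#' steering a ligand out of its binding pocket along a centre-of-mass
#' reaction coordinate. The guide-work integral accumulated along the pull
#' is the per-replicate work curve.
#'
#' @param potential a [pulling_potential()].
#' @param spring_constant guide stiffness kappa_s, kcal/mol/A^2. The default
#'   100 is stiff enough that the stiff-spring interpretation of the free
#'   energy profile holds.
#' @param pull_speed steering speed v, A/ns (1 A/ns default).
#' @param start_position,end_position guide-centre endpoints, A.
#' @param temperature K.
#' @param friction drag coefficient zeta of the overdamped dynamics,
#'   kcal mol^-1 ps A^-2; larger values give slower diffusion and more
#'   dissipation at a given speed.
#' @param timestep Euler-Maruyama step, ps.
#' @param n_replicates independent pulls.
#' @param equilibration_time ps spent equilibrating at the start position
#'   before pulling.
#' @param seed integer RNG seed.
#' @export
pulling_spec <- function(potential = pulling_potential("flat"),
                         spring_constant = 100, pull_speed = 1,
                         start_position = 0, end_position = 14.4,
                         temperature = 310, friction = 50, timestep = 0.02,
                         n_replicates = 60, equilibration_time = 10,
                         seed = 1L) {
  stopifnot(inherits(potential, "pulling_potential"),
            end_position > start_position, spring_constant > 0,
            pull_speed > 0, timestep > 0, friction > 0,
            is_count(n_replicates), temperature > 0)
  structure(list(potential = potential, spring_constant = spring_constant,
                 pull_speed = pull_speed, start_position = start_position,
                 end_position = end_position, temperature = temperature,
                 friction = friction, timestep = timestep,
                 n_replicates = as.integer(n_replicates),
                 equilibration_time = equilibration_time,
                 seed = as.integer(seed)),
            class = "pulling_spec")
}

#' Generate a steered-pulling work ensemble
#'
#' Integrates `n_replicates` overdamped Langevin trajectories coupled to the
#' moving harmonic guide, accumulating external work
#' W(t) = sum kappa_s (lambda(t) - q(t)) v dt, and resamples the work curves
#' onto a common reaction-coordinate grid. The analytic stiff-spring ground
#' truth Delta F = U(end) - U(start) is recorded in the result.
#'
#' Unstable integrator parameters (dt (kappa_s + max U'') / zeta >= 2) are
#' rejected; a guide too soft to track the pull (mean lag over the final
#' stretch above 3 thermal widths) raises a warning.
#'
#' @param spec a [pulling_spec()].
#' @param grid_step resampling step along the reaction coordinate, A.
#' @return a [work_ensemble()] with attribute `raw` holding the per-frame
#'   logs (list of data frames `lambda`, `W`, `q`).
#' @export
generate_pulling_ensemble <- function(spec, grid_step = 0.1) {
  stopifnot(inherits(spec, "pulling_spec"))
  pot <- spec$potential
  v_ps <- spec$pull_speed / 1000 # A/ns -> A/ps
  dt <- spec$timestep
  span <- spec$end_position - spec$start_position
  n_steps <- ceiling(span / (v_ps * dt))
  # stability: fastest deterministic relaxation must be resolved
  qq <- seq(spec$start_position - 1, spec$end_position + 1, length.out = 400L)
  upp <- max(abs(diff(pot$dU(qq)) / diff(qq)))
  k_tot <- spec$spring_constant + upp
  if (dt * k_tot / spec$friction >= 2)
    stop(sprintf(paste0("unstable integrator: dt * (kappa_s + max U'')/zeta ",
                        "= %.2f >= 2; reduce timestep below %.4g ps"),
                 dt * k_tot / spec$friction, 2 * spec$friction / k_tot))
  save_every <- max(1L, floor(grid_step / 5 / (v_ps * dt)))
  grid_du <- if (pot$code == 3L) pot$dU(pot$grid_q) else numeric(0L)
  sim <- with_seed(spec$seed,
    langevin_pull_cpp(spec$n_replicates, spec$start_position, v_ps, dt,
                      as.integer(n_steps), as.integer(save_every),
                      spec$spring_constant, spec$friction,
                      KB_KCAL * spec$temperature, pot$code, pot$params,
                      pot$grid_q, grid_du,
                      as.integer(ceiling(spec$equilibration_time / dt))))
  lag <- sim$lambda - colMeans(sim$q)
  tail_idx <- seq(floor(length(lag) * 0.75), length(lag))
  thermal_width <- sqrt(KB_KCAL * spec$temperature / spec$spring_constant)
  if (mean(lag[tail_idx]) > 3 * thermal_width)
    warning(sprintf(paste0("guide too soft to track the pull: mean lag ",
                           "%.3f A exceeds 3 thermal widths (%.3f A)"),
                    mean(lag[tail_idx]), 3 * thermal_width))
  logs <- lapply(seq_len(spec$n_replicates), function(r)
    data.frame(lambda = sim$lambda, W = sim$W[r, ], q = sim$q[r, ]))
  ens <- resample_work(logs, grid_step = grid_step,
                       temperature = spec$temperature)
  ens$dF_analytic <- unname(pot$U(spec$end_position) -
                              pot$U(spec$start_position))
  attr(ens, "raw") <- logs
  ens
}

#' Stiff-spring free-energy profile by direct quadrature
#'
#' Exact F(lambda) = -kT ln int exp(-(U(q) + kappa_s/2 (q - lambda)^2)/kT) dq
#' (anchored to 0 at the first lambda), the equilibrium profile the guide
#' actually samples. Used as an independent oracle for the Jarzynski
#' estimator on toy surfaces.
#'
#' @param potential a [pulling_potential()].
#' @param lambda guide positions, A.
#' @param spring_constant kcal/mol/A^2.
#' @param temperature K.
#' @return numeric vector F(lambda) in kcal/mol, 0 at `lambda[1]`.
#' @export
stiff_spring_profile <- function(potential, lambda, spring_constant = 100,
                                 temperature = 310) {
  kT <- KB_KCAL * temperature
  f <- vapply(lambda, function(l) {
    -kT * log(integrate(function(q)
      exp(-(potential$U(q) + spring_constant / 2 * (q - l)^2) / kT),
      lower = l - 20, upper = l + 20, rel.tol = 1e-9)$value)
  }, numeric(1L))
  f - f[1L]
}

#' Steered-run bookkeeping
#'
#' Given a starting reaction-coordinate value (typically the modal
#' ligand-pocket distance), the final centre-of-mass distance and the
#' steering speed, computes the pull distance and production duration.
#'
#' @param start_distance starting distance, A.
#' @param target_distance final distance, A.
#' @param speed steering speed, A/ns.
#' @return data frame with `start`, `target`, `speed`, `pull_distance` (A)
#'   and `duration_ns`.
#' @examples
#' steering_schedule(c(3.6, 4.4)) # 10.8 and 10 ns at 1 A/ns to 14.4 A
#' @export
steering_schedule <- function(start_distance, target_distance = 14.4,
                              speed = 1) {
  stopifnot(all(target_distance > start_distance), speed > 0)
  data.frame(start = start_distance, target = target_distance, speed = speed,
             pull_distance = target_distance - start_distance,
             duration_ns = (target_distance - start_distance) / speed)
}
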