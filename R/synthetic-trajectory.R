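#' Specification for a toy bead trajectory
#'
#' Describes a synthetic "pocket + ligand" system whose residue contacts and
#' ligand dihedral distribution are prescribed exactly, so that every
#' trajectory descriptor can be validated against known ground truth. The
#' geometry is deliberately simple: pseudo-residues are beads on a line that
#' approach within 3 A of their partner during scheduled contact intervals
#' (otherwise they sit >= 9 A apart), and the first four ligand atoms form a
#' chain whose torsion angle follows a per-frame state schedule with von
#' Mises jitter.
#'
#' @param n_frames number of frames to generate.
#' @param residues list of per-residue atom tables, each a data frame with
#'   columns `name`, `element` and optionally `charge`, `sigma`, `epsilon`.
#'   See [toy_residue()].
#' @param ligand atom table (same columns) with at least 4 atoms; the first
#'   four define the scheduled dihedral.
#' @param contact_schedule data frame with columns `res_a`, `res_b`, `from`,
#'   `to` (1-based inclusive frame range) and optionally `contact` (default
#'   `TRUE`). Overlapping `TRUE`/`FALSE` intervals for the same pair are
#'   contradictory and rejected.
#' @param dihedral_states data frame with columns `mean` (degrees) and
#'   `kappa` (von Mises concentration; `Inf` locks the angle).
#' @param dihedral_schedule data frame with columns `state`, `from`, `to`
#'   assigning a state to each frame interval; frames not covered use state 1.
#' @param frame_interval ps between frames.
#' @param seed integer RNG seed; identical seeds give bit-identical output.
#' @return object of class `toy_trajectory_spec`.
#' @export
toy_trajectory_spec <- function(n_frames = 100,
                                residues = list(toy_residue(), toy_residue()),
                                ligand = toy_ligand(),
                                contact_schedule = NULL,
                                dihedral_states = data.frame(mean = 0,
                                                             kappa = Inf),
                                dihedral_schedule = NULL,
                                frame_interval = 10,
                                seed = 1L) {
  stopifnot(is_count(n_frames), length(residues) >= 1L,
            is.data.frame(ligand), nrow(ligand) >= 4L)
  if (!is.null(contact_schedule)) {
    cs <- contact_schedule
    stopifnot(all(c("res_a", "res_b", "from", "to") %in% names(cs)))
    if (is.null(cs$contact)) cs$contact <- TRUE
    if (any(cs$from < 1L | cs$to > n_frames | cs$from > cs$to))
      stop("contact_schedule intervals must lie within [1, n_frames]")
    if (any(cs$res_a < 1L | cs$res_b < 1L |
            cs$res_a > length(residues) | cs$res_b > length(residues)))
      stop("contact_schedule refers to unknown residues")
    key <- paste(pmin(cs$res_a, cs$res_b), pmax(cs$res_a, cs$res_b))
    for (k in unique(key)) {
      rows <- cs[key == k, ]
      if (nrow(rows) > 1L) {
        for (i in seq_len(nrow(rows) - 1L)) for (j in (i + 1L):nrow(rows)) {
          overlap <- rows$from[i] <= rows$to[j] && rows$from[j] <= rows$to[i]
          if (overlap && rows$contact[i] != rows$contact[j])
            stop("contradictory contact schedule for residue pair ", k,
                 ": overlapping in- and out-of-contact intervals")
        }
      }
    }
    contact_schedule <- cs
  }
  if (!is.null(dihedral_schedule)) {
    ds <- dihedral_schedule
    stopifnot(all(c("state", "from", "to") %in% names(ds)))
    if (any(ds$from < 1L | ds$to > n_frames | ds$from > ds$to))
      stop("dihedral_schedule intervals must lie within [1, n_frames]")
    if (any(ds$state < 1L | ds$state > nrow(dihedral_states)))
      stop("dihedral_schedule refers to unknown states")
  }
  structure(list(n_frames = as.integer(n_frames), residues = residues,
                 ligand = ligand, contact_schedule = contact_schedule,
                 dihedral_states = dihedral_states,
                 dihedral_schedule = dihedral_schedule,
                 frame_interval = frame_interval, seed = as.integer(seed)),
            class = "toy_trajectory_spec")
}

#' @rdname toy_trajectory_spec
#' @param n_atoms atoms in the pseudo-residue.
#' @param charge,sigma,epsilon per-atom partial charge (e) and Lennard-Jones
#'   parameters (A, kcal/mol), recycled across atoms.
#' @export
toy_residue <- function(n_atoms = 2, charge = 0, sigma = 3.4, epsilon = 0.1) {
  data.frame(name = paste0("C", seq_len(n_atoms)), element = "C",
             charge = rep_len(charge, n_atoms),
             sigma = rep_len(sigma, n_atoms),
             epsilon = rep_len(epsilon, n_atoms))
}

#' @rdname toy_trajectory_spec
#' @export
toy_ligand <- function(charge = 0, sigma = 3.4, epsilon = 0.1) {
  data.frame(name = c("O1B", "PB", "O3A", "PA"),
             element = c("O", "P", "O", "P"),
             charge = rep_len(charge, 4L), sigma = rep_len(sigma, 4L),
             epsilon = rep_len(epsilon, 4L))
}

# Best-Fisher (1979) rejection sampler for the von Mises distribution.
# mu in radians; kappa >= 0 (Inf returns mu exactly).
rvonmises <- function(n, mu, kappa) {
  if (!is.finite(kappa)) return(rep(mu, n))
  if (kappa < 1e-8) return(runif(n, -pi, pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      u <- runif(3L)
      z <- cos(pi * u[1L])
      f <- (1 + r * z) / (r + z)
      cc <- kappa * (r - f)
      if (cc * (2 - cc) - u[2L] > 0 || log(cc / u[2L]) + 1 - cc >= 0) {
        out[i] <- mu + sign(u[3L] - 0.5) * acos(pmin(1, pmax(-1, f)))
        break
      }
    }
  }
  atan2(sin(out), cos(out))
}

# Place the fourth atom of a chain given three positions, bond length r,
# bond angle theta (rad) at p3, and torsion phi (rad) about p2->p3.
place_by_torsion <- function(p1, p2, p3, r = 1.5,
                             theta = 109.47 * pi / 180, phi = 0) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  bc <- b2 / vnorm(b2)
  n <- vcross(b1, b2)
  n <- n / vnorm(n)
  m <- vcross(n, bc)
  d <- r * c(-cos(theta), sin(theta) * cos(phi), sin(theta) * sin(phi))
  p3 + bc * d[1L] + m * d[2L] + n * d[3L]
}

#' Generate a toy trajectory with prescribed contacts and dihedrals
#'
#' Realizes a [toy_trajectory_spec()] as coordinate frames: contacting
#' residue pairs are placed 3 A apart during their scheduled intervals (well
#' inside the 5 A heavy-atom criterion) and >= 9 A apart otherwise, and the
#' ligand's leading torsion angle is drawn per frame from the scheduled von
#' Mises state. The topology carries the partial charges and Lennard-Jones
#' parameters from the spec so interaction-energy code can be exercised.
#'
#' @param spec a [toy_trajectory_spec()].
#' @return an [md_trajectory()].
#' @export
generate_toy_trajectory <- function(spec) {
  stopifnot(inherits(spec, "toy_trajectory_spec"))
  nf <- spec$n_frames
  nres <- length(spec$residues)
  tops <- lapply(seq_len(nres), function(i) {
    r <- spec$residues[[i]]
    data.frame(name = r$name, element = r$element, resid = i,
               resname = "RES", charge = r$charge %||% 0,
               sigma = r$sigma %||% 3.4, epsilon = r$epsilon %||% 0.1)
  })
  lig <- spec$ligand
  tops[[nres + 1L]] <- data.frame(name = lig$name, element = lig$element,
                                  resid = nres + 1L, resname = "LIG",
                                  charge = lig$charge %||% 0,
                                  sigma = lig$sigma %||% 3.4,
                                  epsilon = lig$epsilon %||% 0.1)
  top <- do.call(rbind, tops)
  top$mass <- element_mass(top$element)
  na <- nrow(top)

  # per-frame torsion angles (radians)
  state_of <- rep(1L, nf)
  if (!is.null(spec$dihedral_schedule)) {
    for (i in seq_len(nrow(spec$dihedral_schedule))) {
      s <- spec$dihedral_schedule[i, ]
      state_of[s$from:s$to] <- as.integer(s$state)
    }
  }
  coords <- with_seed(spec$seed, {
    phi <- numeric(nf)
    for (st in seq_len(nrow(spec$dihedral_states))) {
      idx <- which(state_of == st)
      if (length(idx))
        phi[idx] <- rvonmises(length(idx),
                              spec$dihedral_states$mean[st] * pi / 180,
                              spec$dihedral_states$kappa[st])
    }
    arr <- array(NA_real_, c(nf, na, 3L))
    res_rows <- split(seq_len(na), top$resid)
    base_y <- 12 * (seq_len(nres) - 1)
    lig_origin <- c(50, 0, 0)
    for (f in seq_len(nf)) {
      centers <- cbind(0, base_y, 0)
      if (!is.null(spec$contact_schedule)) {
        cs <- spec$contact_schedule
        live <- cs$contact & cs$from <= f & f <= cs$to
        for (i in which(live))
          centers[cs$res_b[i], ] <- centers[cs$res_a[i], ] + c(0, 3, 0)
      }
      for (i in seq_len(nres)) {
        rows <- res_rows[[i]]
        off <- cbind(seq_along(rows) - 1, 0, 0)
        arr[f, rows, ] <- sweep(off, 2L, centers[i, ], "+")
      }
      # ligand chain with scheduled torsion
      p1 <- lig_origin
      p2 <- lig_origin + c(1.5, 0, 0)
      p3 <- p2 + 1.5 * c(-cos(109.47 * pi / 180), sin(109.47 * pi / 180), 0)
      p4 <- place_by_torsion(p1, p2, p3, phi = phi[f])
      pts <- rbind(p1, p2, p3, p4)
      rows <- res_rows[[nres + 1L]]
      if (length(rows) > 4L)
        pts <- rbind(pts, t(vapply(seq_len(length(rows) - 4L), function(k)
          lig_origin + c(0, -2 - 1.5 * k, 0), numeric(3L))))
      arr[f, rows, ] <- pts
    }
    arr
  })
  md_trajectory(coords, top, spec$frame_interval)
}
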