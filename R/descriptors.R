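#' Per-frame RMSD relative to a reference structure
#'
#' Each frame is optimally superposed (unweighted Kabsch) onto the reference
#' over the selected atoms before the root-mean-square deviation is taken,
#' so rigid-body motion does not contribute.
#'
#' @param traj an [md_trajectory()].
#' @param reference either a frame index into `traj` or an `n_atoms x 3`
#'   coordinate matrix (e.g. a minimized starting structure).
#' @param selection atoms to superpose and measure: indices, logical mask, or
#'   predicate `function(topology)`; default all atoms.
#' @return numeric vector, one RMSD (A) per frame.
#' @export
rmsd_to_reference <- function(traj, reference = 1L, selection = NULL) {
  sel <- resolve_selection(traj, selection)
  ref <- if (is.matrix(reference)) reference else frame_xyz(traj, reference)
  if (nrow(ref) != n_atoms(traj))
    stop("reference atom count does not match trajectory topology")
  vapply(seq_len(n_frames(traj)), function(f) {
    x <- superpose_onto(frame_xyz(traj, f), ref, sel)
    sqrt(mean(rowSums((x[sel, , drop = FALSE] -
                         ref[sel, , drop = FALSE])^2)))
  }, numeric(1L))
}

#' Per-atom root-mean-square fluctuation
#'
#' Two-pass procedure: frames are superposed on the average structure (itself
#' obtained after a first alignment to the raw mean), the mean is recomputed,
#' and each atom's RMS deviation from that mean is reported.
#'
#' @inheritParams rmsd_to_reference
#' @param align_selection atoms used for the superposition; defaults to
#'   `selection`. Useful when fluctuations of a mobile group should be
#'   measured in the frame of a rigid core.
#' @return numeric vector of RMSF values (A) for the selected atoms.
#' @export
rmsf <- function(traj, selection = NULL, align_selection = selection) {
  if (n_frames(traj) < 2L) stop("RMSF requires at least 2 frames")
  sel <- resolve_selection(traj, selection)
  asel <- resolve_selection(traj, align_selection)
  nf <- n_frames(traj)
  raw_mean <- apply(traj$coords, c(2L, 3L), mean)
  aligned <- array(NA_real_, dim(traj$coords))
  for (f in seq_len(nf))
    aligned[f, , ] <- superpose_onto(frame_xyz(traj, f), raw_mean, asel)
  avg <- apply(aligned, c(2L, 3L), mean)
  for (f in seq_len(nf))
    aligned[f, , ] <- superpose_onto(matrix(aligned[f, , ], ncol = 3L),
                                     avg, asel)
  avg <- apply(aligned, c(2L, 3L), mean)
  dev2 <- sapply(sel, function(a)
    mean(rowSums((matrix(aligned[, a, ], ncol = 3L) -
                    matrix(avg[a, ], nf, 3L, byrow = TRUE))^2)))
  setNames(sqrt(dev2), traj$topology$name[sel])
}

#' Fraction of frames in which residue pairs are in contact
#'
#' Two residues are in contact in a frame iff at least one pair of heavy
#' atoms between them lies within `cutoff` (default 5 A).
#'
#' @param traj an [md_trajectory()] whose topology flags heavy atoms.
#' @param cutoff heavy-atom distance criterion, A.
#' @param pairs optional two-column matrix/data frame of residue id pairs to
#'   restrict to; default all unordered pairs.
#' @return data frame with columns `res_a`, `res_b`, `fraction`.
#' @export
residue_contact_fractions <- function(traj, cutoff = 5, pairs = NULL) {
  top <- traj$topology
  if (!any(top$heavy)) stop("topology carries no heavy atoms")
  resids <- sort(unique(top$resid))
  heavy_rows <- lapply(resids, function(r)
    which(top$resid == r & top$heavy))
  names(heavy_rows) <- resids
  if (is.null(pairs)) {
    pairs <- t(utils::combn(resids, 2L))
  } else {
    pairs <- as.matrix(pairs)[, 1:2, drop = FALSE]
  }
  nf <- n_frames(traj)
  frac <- numeric(nrow(pairs))
  for (p in seq_len(nrow(pairs))) {
    ia <- heavy_rows[[as.character(pairs[p, 1L])]]
    ib <- heavy_rows[[as.character(pairs[p, 2L])]]
    if (!length(ia) || !length(ib)) next
    hits <- 0L
    for (f in seq_len(nf)) {
      a <- traj$coords[f, ia, , drop = FALSE]
      b <- traj$coords[f, ib, , drop = FALSE]
      if (min_pair_distance(a, b) <= cutoff) hits <- hits + 1L
    }
    frac[p] <- hits / nf
  }
  data.frame(res_a = pairs[, 1L], res_b = pairs[, 2L], fraction = frac)
}

# Minimum distance between two coordinate slabs (1 x n x 3 arrays).
min_pair_distance <- function(a, b) {
  am <- matrix(a, ncol = 3L)
  bm <- matrix(b, ncol = 3L)
  d2 <- outer(rowSums(am^2), rowSums(bm^2), "+") - 2 * tcrossprod(am, bm)
  sqrt(max(0, min(d2)))
}

#' Salt-bridge persistence between two residues
#'
#' A frame counts as bridged iff the minimum distance between side-chain
#' charged-group N/O atoms of the two residues is at most `cutoff`
#' (4.0 A by default, the standard structural-biology criterion). Charged
#' atoms are N/O atoms with a nonzero partial charge; the two residues must
#' carry groups of opposite sign.
#'
#' @param traj an [md_trajectory()] with partial charges in the topology.
#' @param res_a,res_b residue ids.
#' @param cutoff distance criterion, A.
#' @return fraction of frames in `[0, 1]`.
#' @export
salt_bridge_persistence <- function(traj, res_a, res_b, cutoff = 4) {
  top <- traj$topology
  grp <- function(r) which(top$resid == r &
                             toupper(top$element) %in% c("N", "O") &
                             !is.na(top$charge) & top$charge != 0)
  ia <- grp(res_a); ib <- grp(res_b)
  if (!length(ia) || !length(ib))
    stop("residue ", if (!length(ia)) res_a else res_b,
         " has no charged N/O atoms")
  if (sign(sum(top$charge[ia])) * sign(sum(top$charge[ib])) >= 0)
    stop("residues ", res_a, " and ", res_b,
         " do not carry opposite net charges")
  nf <- n_frames(traj)
  hits <- vapply(seq_len(nf), function(f)
    min_pair_distance(traj$coords[f, ia, , drop = FALSE],
                      traj$coords[f, ib, , drop = FALSE]) <= cutoff,
    logical(1L))
  mean(hits)
}

#' Dihedral angle specification
#'
#' @param label short label (e.g. `"theta1"`).
#' @param atoms character vector of four atom names, in order.
#' @export
dihedral_spec <- function(label, atoms) {
  stopifnot(length(atoms) == 4L, !anyDuplicated(atoms))
  structure(list(label = label, atoms = atoms), class = "dihedral_spec")
}

#' The six nucleotide torsions describing ADP geometry
#'
#' theta1..theta3 track the diphosphate, theta4/theta5 the ribose linkage and
#' theta6 the glycosidic (purine ring) orientation.
#'
#' @return list of [dihedral_spec()] objects named theta1..theta6.
#' @export
adp_dihedral_specs <- function() {
  defs <- list(theta1 = c("O1B", "PB", "O3A", "PA"),
               theta2 = c("PB", "O3A", "PA", "O5'"),
               theta3 = c("O3A", "PA", "O5'", "C5'"),
               theta4 = c("PA", "O5'", "C5'", "C4'"),
               theta5 = c("O5'", "C5'", "C4'", "O4'"),
               theta6 = c("O4'", "C1'", "N9", "C8"))
  mapply(dihedral_spec, names(defs), defs, SIMPLIFY = FALSE)
}

# Signed torsion (degrees, (-180, 180]) from four position rows.
torsion_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- vcross(b1, b2); n2 <- vcross(b2, b3)
  if (vnorm(n1) < 1e-10 || vnorm(n2) < 1e-10) return(NA_real_)
  ang <- atan2(sum(vcross(n1, n2) * (b2 / vnorm(b2))), sum(n1 * n2))
  deg <- ang * 180 / pi
  if (deg <= -180) deg <- deg + 360
  deg
}

#' Compute dihedral angle series
#'
#' Standard signed torsion from four atom positions, reported in degrees on
#' `(-180, 180]`. Frames with a collinear atom triplet (undefined torsion)
#' are flagged `NA`.
#'
#' @param traj an [md_trajectory()].
#' @param specs a single [dihedral_spec()] or a list of them. Atom names are
#'   resolved within `resid` when given.
#' @param resid optional residue id restricting the atom-name lookup.
#' @return data frame with one column per spec label, one row per frame.
#' @export
compute_dihedrals <- function(traj, specs, resid = NULL) {
  if (inherits(specs, "dihedral_spec")) specs <- list(specs)
  top <- traj$topology
  pool <- if (is.null(resid)) seq_len(nrow(top)) else which(top$resid %in% resid)
  out <- lapply(specs, function(sp) {
    idx <- vapply(sp$atoms, function(a) {
      hit <- pool[top$name[pool] == a]
      if (!length(hit)) stop("atom ", a, " not found in topology")
      hit[1L]
    }, integer(1L))
    vapply(seq_len(n_frames(traj)), function(f)
      torsion_angle(traj$coords[f, idx[1L], ], traj$coords[f, idx[2L], ],
                    traj$coords[f, idx[3L], ], traj$coords[f, idx[4L], ]),
      numeric(1L))
  })
  names(out) <- vapply(specs, `[[`, character(1L), "label")
  as.data.frame(out)
}
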