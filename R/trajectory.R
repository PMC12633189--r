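#' Molecular trajectory container
#'
#' Bundles an ordered set of coordinate frames with a per-atom topology. This
#' is the common currency of all trajectory descriptors: RMSD/RMSF, residue
#' contacts, dihedral maps, interaction energies, occupancy grids.
#'
#' @param coords numeric array of dimension `c(n_frames, n_atoms, 3)`, in
#'   Angstrom. A single frame may be given as an `n_atoms x 3` matrix.
#' @param topology data frame with one row per atom and columns `name`,
#'   `element`, `resid` (integer residue id), `resname`, and optionally
#'   `mass` (amu), `charge` (e), `sigma` (A), `epsilon` (kcal/mol). A logical
#'   `heavy` column is derived from `element` (everything but H).
#' @param frame_interval time between saved frames, ps.
#' @return An object of class `md_trajectory` with elements `coords`,
#'   `topology`, `frame_interval`.
#' @examples
#' top <- data.frame(name = c("C1", "C2"), element = "C",
#'                   resid = c(1L, 2L), resname = "TOY")
#' xyz <- array(0, c(3, 2, 3))
#' xyz[, 2, 1] <- 4 # atom 2 at x = 4 in every frame
#' traj <- md_trajectory(xyz, top)
#' n_frames(traj)
#' @export
md_trajectory <- function(coords, topology, frame_interval = 10) {
  if (is.matrix(coords)) coords <- array(coords, c(1L, dim(coords)))
  stopifnot(is.array(coords), length(dim(coords)) == 3L, dim(coords)[3L] == 3L)
  stopifnot(is.data.frame(topology), nrow(topology) == dim(coords)[2L])
  req <- c("name", "element", "resid", "resname")
  miss <- setdiff(req, names(topology))
  if (length(miss))
    stop("topology is missing columns: ", paste(miss, collapse = ", "))
  topology$resid <- as.integer(topology$resid)
  topology$heavy <- toupper(topology$element) != "H"
  for (col in c("mass", "charge", "sigma", "epsilon"))
    if (is.null(topology[[col]])) topology[[col]] <- NA_real_
  if (all(is.na(topology$mass)))
    topology$mass <- element_mass(topology$element)
  structure(list(coords = coords, topology = topology,
                 frame_interval = frame_interval),
            class = "md_trajectory")
}

#' @export
print.md_trajectory <- function(x, ...) {
  cat(sprintf("md_trajectory: %d frames x %d atoms (%d residues), %g ps/frame\n",
              n_frames(x), n_atoms(x), length(unique(x$topology$resid)),
              x$frame_interval))
  invisible(x)
}

#' @rdname md_trajectory
#' @param traj an `md_trajectory`.
#' @export
n_frames <- function(traj) dim(traj$coords)[1L]

#' @rdname md_trajectory
#' @export
n_atoms <- function(traj) dim(traj$coords)[2L]

element_mass <- function(el) {
  tab <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, P = 30.974,
           S = 32.06, MG = 24.305, NA. = 22.990, CL = 35.45, K = 39.098,
           FE = 55.845, ZN = 65.38)
  m <- tab[toupper(el)]
  m[is.na(m)] <- 12.0
  unname(m)
}

# Resolve an atom selection to integer indices. Accepts integer indices, a
# logical mask, a predicate function(topology) -> logical, or NULL (all).
resolve_selection <- function(traj, selection) {
  top <- traj$topology
  if (is.null(selection)) return(seq_len(nrow(top)))
  if (is.function(selection)) selection <- selection(top)
  if (is.logical(selection)) {
    stopifnot(length(selection) == nrow(top))
    selection <- which(selection)
  }
  selection <- as.integer(selection)
  if (!length(selection)) stop("empty atom selection")
  if (any(selection < 1L | selection > nrow(top)))
    stop("selection index out of range")
  selection
}

frame_xyz <- function(traj, i) {
  matrix(traj$coords[i, , ], ncol = 3L,
         dimnames = list(NULL, c("x", "y", "z")))
}

#' Read a topology from a PDB file
#'
#' Parses ATOM/HETATM records into the per-atom table used by
#' [md_trajectory()]. Partial charges and Lennard-Jones parameters are not
#' stored in PDB files and are left `NA`; attach them manually when computing
#' interaction energies.
#'
#' @param file path to a PDB file.
#' @return topology data frame (see [md_trajectory()]) with the PDB
#'   coordinates attached as attribute `"xyz"` (an `n x 3` matrix).
#' @export
read_pdb_topology <- function(file) {
  pdb <- bio3d::read.pdb(file)
  at <- pdb$atom
  top <- data.frame(name = at$elety,
                    element = ifelse(is.na(at$elesy) | at$elesy == "",
                                     substr(gsub("[0-9']", "", at$elety), 1, 1),
                                     at$elesy),
                    resid = as.integer(at$resno),
                    resname = at$resid,
                    stringsAsFactors = FALSE)
  top$mass <- element_mass(top$element)
  attr(top, "xyz") <- cbind(at$x, at$y, at$z)
  top
}

#' Read trajectory frames from a DCD file
#'
#' @param file path to a DCD trajectory.
#' @param topology topology data frame matching the atom count.
#' @param frame_interval ps between frames.
#' @return an [md_trajectory()].
#' @export
read_dcd_frames <- function(file, topology, frame_interval = 10) {
  m <- bio3d::read.dcd(file, verbose = FALSE)
  nf <- nrow(m)
  na <- ncol(m) / 3L
  coords <- array(NA_real_, c(nf, na, 3L))
  for (k in 1:3) coords[, , k] <- m[, seq(k, by = 3L, length.out = na),
                                    drop = FALSE]
  md_trajectory(coords, topology, frame_interval)
}

#' Read and write trajectory frames as delimited text
#'
#' The long format has one row per atom per frame with columns
#' `frame, atom, x, y, z` (tab-separated). This is the portable text fallback
#' for toy systems and fixtures.
#'
#' @param traj an [md_trajectory()].
#' @param file path of the TSV file.
#' @return `write_frames_tsv` returns `file` invisibly; `read_frames_tsv`
#'   returns an [md_trajectory()].
#' @export
write_frames_tsv <- function(traj, file) {
  nf <- n_frames(traj); na <- n_atoms(traj)
  df <- data.frame(frame = rep(seq_len(nf), each = na),
                   atom = rep(seq_len(na), nf),
                   x = as.vector(t(traj$coords[, , 1])),
                   y = as.vector(t(traj$coords[, , 2])),
                   z = as.vector(t(traj$coords[, , 3])))
  utils::write.table(df, file, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @rdname write_frames_tsv
#' @param topology topology data frame matching the atom count.
#' @param frame_interval ps between frames.
#' @export
read_frames_tsv <- function(file, topology, frame_interval = 10) {
  df <- utils::read.table(file, header = TRUE, sep = "\t")
  nf <- max(df$frame); na <- max(df$atom)
  df <- df[order(df$frame, df$atom), ]
  coords <- array(NA_real_, c(nf, na, 3L))
  coords[, , 1] <- matrix(df$x, nf, na, byrow = TRUE)
  coords[, , 2] <- matrix(df$y, nf, na, byrow = TRUE)
  coords[, , 3] <- matrix(df$z, nf, na, byrow = TRUE)
  md_trajectory(coords, topology, frame_interval)
}
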