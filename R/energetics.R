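#' Linear interaction energy between residues and a ligand group
#'
#' For each requested residue, sums pairwise vacuum Coulomb
#' (332.0636 q_i q_j / r kcal/mol) and Lennard-Jones
#' (4 eps [(sig/r)^12 - (sig/r)^6], Lorentz-Berthelot combining) energies
#' over all residue-ligand atom pairs in each frame, then averages over
#' frames. Electrostatic, van der Waals and combined means are all reported.
#'
#' @param traj an [md_trajectory()] whose topology carries `charge` and (for
#'   the van der Waals term) `sigma`/`epsilon`.
#' @param residues residue ids to evaluate; default all residues other than
#'   the ligand's.
#' @param ligand atom selection for the ligand group (indices, logical mask
#'   or predicate), e.g. `function(top) top$resname == "LIG"`.
#' @param ligand_label label stored in the output's `ligand` column.
#' @param cutoff pair-distance cutoff in A; `Inf` (default) evaluates all
#'   pairs, `10` mirrors a production nonbonded cutoff.
#' @param temperature simulation temperature (K), stored for downstream kT
#'   thresholding.
#' @return a `lie_table`: data frame with columns `resid`, `ligand`,
#'   `electrostatic`, `vdw`, `combined` (kcal/mol) and attribute
#'   `temperature`.
#' @export
linear_interaction_energy <- function(traj, residues = NULL, ligand,
                                      ligand_label = "LIG", cutoff = Inf,
                                      temperature = 310) {
  top <- traj$topology
  lig <- resolve_selection(traj, ligand)
  if (is.null(residues))
    residues <- setdiff(sort(unique(top$resid)), unique(top$resid[lig]))
  if (any(is.na(top$charge[lig])))
    stop("ligand atoms lack partial charges: ",
         paste(top$name[lig][is.na(top$charge[lig])], collapse = ", "))
  nf <- n_frames(traj)
  out <- lapply(residues, function(r) {
    rows <- which(top$resid == r)
    bad <- rows[is.na(top$charge[rows])]
    if (length(bad))
      stop("atoms without charges in residue ", r, ": ",
           paste(top$name[bad], collapse = ", "))
    qq <- outer(top$charge[rows], top$charge[lig])
    has_lj <- !any(is.na(top$sigma[rows])) && !any(is.na(top$epsilon[rows])) &&
      !any(is.na(top$sigma[lig])) && !any(is.na(top$epsilon[lig]))
    if (has_lj) {
      sig <- outer(top$sigma[rows], top$sigma[lig], function(a, b) (a + b) / 2)
      eps <- sqrt(outer(top$epsilon[rows], top$epsilon[lig]))
    }
    elec <- vdw <- numeric(nf)
    for (f in seq_len(nf)) {
      a <- matrix(traj$coords[f, rows, ], ncol = 3L)
      b <- matrix(traj$coords[f, lig, ], ncol = 3L)
      d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
      d <- sqrt(pmax(d2, 1e-12))
      ok <- d <= cutoff
      elec[f] <- sum(COULOMB_KCAL * qq[ok] / d[ok])
      if (has_lj) {
        s6 <- (sig[ok] / d[ok])^6
        vdw[f] <- sum(4 * eps[ok] * (s6^2 - s6))
      }
    }
    data.frame(resid = r, ligand = ligand_label,
               electrostatic = mean(elec), vdw = mean(vdw),
               combined = mean(elec) + mean(vdw))
  })
  res <- do.call(rbind, out)
  attr(res, "temperature") <- temperature
  class(res) <- c("lie_table", class(res))
  res
}

#' Select nucleotide-pocket residues by interaction-energy threshold
#'
#' Residues whose mean combined interaction energy with any of the supplied
#' ligand groups has magnitude at least `threshold_kt` times kT are selected
#' (kT at 310 K is about 0.616 kcal/mol). Tables for several ligand groups
#' (e.g. ADP and Mg) may be row-bound before calling; a residue qualifies if
#' it crosses the threshold with either group.
#'
#' @param table a `lie_table` from [linear_interaction_energy()] (or several
#'   row-bound together).
#' @param threshold_kt threshold in units of kT.
#' @param temperature K; defaults to the table's stored temperature.
#' @return sorted integer vector of residue ids.
#' @export
select_pocket_residues <- function(table, threshold_kt = 3,
                                   temperature = NULL) {
  if (!nrow(table)) return(integer(0L))
  temperature <- temperature %||% attr(table, "temperature") %||% 310
  thr <- threshold_kt * KB_KCAL * temperature
  sort(unique(table$resid[abs(table$combined) >= thr]))
}
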