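#' Centre-of-mass distance series between two atom groups
#'
#' Mass-weighted centres are computed per frame and their Euclidean distance
#' reported. This is the reaction coordinate used for steered ligand release.
#'
#' @param traj an [md_trajectory()] with masses in the topology.
#' @param group_a,group_b atom selections (indices, logical mask or
#'   predicate).
#' @return numeric vector of distances (A), one per frame.
#' @export
com_distance_series <- function(traj, group_a, group_b) {
  ia <- resolve_selection(traj, group_a)
  ib <- resolve_selection(traj, group_b)
  ma <- traj$topology$mass[ia]
  mb <- traj$topology$mass[ib]
  if (!sum(ma) || !sum(mb) || anyNA(c(ma, mb)))
    stop("groups must have positive total mass")
  vapply(seq_len(n_frames(traj)), function(f) {
    ca <- colSums(matrix(traj$coords[f, ia, ], ncol = 3L) * ma) / sum(ma)
    cb <- colSums(matrix(traj$coords[f, ib, ], ncol = 3L) * mb) / sum(mb)
    vnorm(ca - cb)
  }, numeric(1L))
}

#' Modal distance of a series
#'
#' Centre of the most populated histogram bin, with bins of width `bin`
#' centred on multiples of `bin` (so a series constant at 3.6 A reports
#' 3.6, not a shifted bin centre). Ties resolve to the smaller distance.
#'
#' @param series numeric distance series (A).
#' @param bin bin width (A).
#' @return modal distance (A).
#' @export
modal_distance <- function(series, bin = 0.1) {
  series <- series[!is.na(series)]
  if (!length(series)) stop("empty distance series")
  centers <- round(series / bin) * bin
  tab <- table(centers)
  cand <- as.numeric(names(tab)[tab == max(tab)])
  min(cand)
}

#' Select seed frames near a target reaction-coordinate value
#'
#' From each replicate's distance series, frames with
#' `|d - target| <= tolerance` qualify; up to `per_replicate` of them are
#' returned, chosen evenly spaced across the qualifying frames to avoid
#' temporal clustering. A replicate with no qualifying frame contributes
#' nothing and raises a warning.
#'
#' @param series_list named list of per-replicate distance series.
#' @param target target distance (A), typically the modal distance.
#' @param tolerance acceptance half-width (A).
#' @param per_replicate maximum seeds per replicate.
#' @return data frame with columns `replicate`, `frame`, `distance`; the
#'   total count is `nrow()` of the result.
#' @export
select_seed_frames <- function(series_list, target, tolerance = 0.1,
                               per_replicate = 20) {
  if (is.numeric(series_list)) series_list <- list(series_list)
  if (is.null(names(series_list)))
    names(series_list) <- seq_along(series_list)
  out <- lapply(names(series_list), function(rep) {
    d <- series_list[[rep]]
    q <- which(abs(d - target) <= tolerance)
    if (!length(q)) {
      warning("replicate ", rep, ": no frame within ", tolerance,
              " A of target ", target)
      return(NULL)
    }
    if (length(q) > per_replicate)
      q <- q[unique(round(seq(1L, length(q), length.out = per_replicate)))]
    data.frame(replicate = rep, frame = q, distance = d[q])
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(replicate = character(0L), frame = integer(0L),
                      distance = numeric(0L))
  out
}

#' Spatial occupancy grid of a ligand group
#'
#' Counts visits of the selected atoms to cubic voxels of edge `spacing`,
#' over a trajectory assumed already aligned on a reference selection. The
#' iso-level convention for rendering is mean + 2 SD over nonzero voxels.
#'
#' @param traj an [md_trajectory()].
#' @param group atom selection for the ligand group.
#' @param spacing voxel edge length (A).
#' @return object of class `occupancy_grid`: list with `origin`, `spacing`,
#'   `dim`, sparse `voxels` (data frame `ix, iy, iz, count`) and `iso_level`.
#' @export
occupancy_grid <- function(traj, group, spacing = 0.5) {
  idx <- resolve_selection(traj, group)
  pts <- do.call(rbind, lapply(seq_len(n_frames(traj)), function(f)
    matrix(traj$coords[f, idx, ], ncol = 3L)))
  origin <- floor(apply(pts, 2L, min) / spacing) * spacing
  iv <- floor(sweep(pts, 2L, origin) / spacing) + 1L
  key <- paste(iv[, 1L], iv[, 2L], iv[, 3L])
  tab <- table(key)
  ijk <- do.call(rbind, lapply(strsplit(names(tab), " "), as.integer))
  counts <- as.integer(tab)
  iso <- mean(counts) + 2 * (if (length(counts) > 1L) sd(counts) else 0)
  structure(list(origin = origin, spacing = spacing,
                 dim = apply(iv, 2L, max),
                 voxels = data.frame(ix = ijk[, 1L], iy = ijk[, 2L],
                                     iz = ijk[, 3L], count = counts),
                 iso_level = iso),
            class = "occupancy_grid")
}

#' Angle between two group-difference vectors
#'
#' For each frame, forms the vector from the centre of mass of `a_from` to
#' that of `a_to` (likewise for the second pair) and reports the angle
#' between the two vectors in degrees. Used e.g. for the orientation of the
#' myosin tail relative to the actin filament axis. Frames with a
#' zero-length vector are flagged `NA`.
#'
#' @param traj an [md_trajectory()].
#' @param a_from,a_to,b_from,b_to atom selections defining the two vectors.
#' @return numeric vector of angles (degrees), one per frame.
#' @export
group_vector_angle <- function(traj, a_from, a_to, b_from, b_to) {
  sels <- lapply(list(a_from, a_to, b_from, b_to),
                 resolve_selection, traj = traj)
  m <- traj$topology$mass
  com <- function(f, idx)
    colSums(matrix(traj$coords[f, idx, ], ncol = 3L) * m[idx]) / sum(m[idx])
  vapply(seq_len(n_frames(traj)), function(f) {
    v1 <- com(f, sels[[2L]]) - com(f, sels[[1L]])
    v2 <- com(f, sels[[4L]]) - com(f, sels[[3L]])
    n1 <- vnorm(v1); n2 <- vnorm(v2)
    if (n1 < 1e-10 || n2 < 1e-10) return(NA_real_)
    acos(pmin(1, pmax(-1, sum(v1 * v2) / (n1 * n2)))) * 180 / pi
  }, numeric(1L))
}
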