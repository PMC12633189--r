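#' Two-dimensional dihedral-angle histogram
#'
#' Ramachandran-style joint histogram of two torsion series over
#' `[-180, 180)^2` with half-open bins of width `bin` degrees (default 5,
#' giving a 72 x 72 grid). Pairs with an `NA` member are dropped.
#'
#' @param x,y angle series in degrees.
#' @param bin bin width in degrees; must divide 360 evenly.
#' @param labels length-2 character vector naming the axes.
#' @return object of class `dihedral_map` with elements `counts` (integer
#'   matrix), `probability`, `bin`, `labels`, `n`.
#' @export
dihedral_map <- function(x, y, bin = 5, labels = c("x", "y")) {
  stopifnot(length(x) == length(y))
  keep <- !(is.na(x) | is.na(y))
  x <- x[keep]; y <- y[keep]
  if (!length(x)) stop("empty angle series")
  if (abs(360 / bin - round(360 / bin)) > 1e-9)
    stop("bin width must divide 360 evenly")
  nb <- as.integer(round(360 / bin))
  # map to [-180, 180), then to bin index 1..nb
  wrap <- function(a) ((a + 180) %% 360) - 180
  ix <- pmin(nb, floor((wrap(x) + 180) / bin) + 1L)
  iy <- pmin(nb, floor((wrap(y) + 180) / bin) + 1L)
  counts <- matrix(0L, nb, nb)
  for (k in seq_along(ix))
    counts[ix[k], iy[k]] <- counts[ix[k], iy[k]] + 1L
  structure(list(counts = counts, probability = counts / length(x),
                 bin = bin, labels = labels, n = length(x)),
            class = "dihedral_map")
}

#' @export
print.dihedral_map <- function(x, ...) {
  cat(sprintf("dihedral_map %s vs %s: %dx%d bins of %g deg, n = %d\n",
              x$labels[1L], x$labels[2L], nrow(x$counts), ncol(x$counts),
              x$bin, x$n))
  cat(sprintf("  entropy %.3f cal/mol/K, coverage %.3f%%\n",
              conformational_entropy(x), percent_coverage(x)))
  invisible(x)
}

#' Conformational entropy of a dihedral map
#'
#' Gibbs entropy S = -R * sum p_i ln p_i over occupied bins of the joint
#' torsion histogram, with R = 1.987 cal mol^-1 K^-1 and 0 ln 0 = 0. A
#' ligand locked in a single bin scores 0; a uniform map scores R ln(n_bins).
#'
#' @param map a [dihedral_map()].
#' @return entropy in cal mol^-1 K^-1.
#' @export
conformational_entropy <- function(map) {
  stopifnot(inherits(map, "dihedral_map"))
  p <- map$probability[map$probability > 0]
  -R_CAL * sum(p * log(p))
}

#' Percent coverage of a dihedral map
#'
#' Share of bins visited at least once, as a percentage of all bins.
#'
#' @param map a [dihedral_map()].
#' @return coverage in percent, in `(0, 100]`.
#' @export
percent_coverage <- function(map) {
  stopifnot(inherits(map, "dihedral_map"))
  100 * sum(map$counts >= 1L) / length(map$counts)
}

#' Write a dihedral map as dense matrix text
#'
#' Header lines (prefixed `#`) record the axis labels and bin width; the body
#' is the tab-separated count matrix.
#'
#' @param map a [dihedral_map()].
#' @param file output path.
#' @export
write_dihedral_map <- function(map, file) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# axes: %s %s", map$labels[1L], map$labels[2L]),
               sprintf("# bin_deg: %g", map$bin),
               sprintf("# n: %d", map$n)), con)
  utils::write.table(map$counts, con, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  invisible(file)
}
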