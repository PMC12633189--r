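#' Work ensemble on a common reaction-coordinate grid
#'
#' Container for per-replicate external work curves W(lambda) at one
#' temperature. `W(lambda[1])` is 0 for every replicate and the grid is
#' strictly increasing.
#'
#' @param lambda ascending reaction-coordinate grid, A.
#' @param W matrix of work values, one row per replicate, kcal/mol.
#' @param temperature K.
#' @param label optional condition/genotype label.
#' @param dF_analytic optional known free-energy difference (ground truth
#'   for synthetic ensembles), kcal/mol.
#' @return object of class `work_ensemble`.
#' @export
work_ensemble <- function(lambda, W, temperature = 310, label = NULL,
                          dF_analytic = NULL) {
  W <- as.matrix(W)
  dimnames(W) <- NULL
  stopifnot(ncol(W) == length(lambda), all(diff(lambda) > 0))
  if (any(abs(W[, 1L]) > 1e-8))
    stop("work curves must be anchored to 0 at the first grid point")
  structure(list(lambda = lambda, W = W, temperature = temperature,
                 label = label, dF_analytic = dF_analytic),
            class = "work_ensemble")
}

#' @export
print.work_ensemble <- function(x, ...) {
  mw <- mean_work(x)
  cat(sprintf(paste0("work_ensemble%s: %d replicates, lambda %.2f..%.2f A, ",
                     "<W>(end) = %.2f +/- %.2f kcal/mol\n"),
              if (is.null(x$label)) "" else paste0(" [", x$label, "]"),
              nrow(x$W), min(x$lambda), max(x$lambda),
              mw$mean_final, mw$sd_final))
  invisible(x)
}

#' Resample raw work logs onto a common reaction-coordinate grid
#'
#' Linearly interpolates each replicate's (lambda, W) samples onto a shared
#' ascending grid and re-anchors W to 0 at the grid origin. Grid points not
#' covered by every log are dropped with a warning.
#'
#' @param logs list of per-replicate data frames with columns `lambda`, `W`.
#' @param grid_step grid spacing, A.
#' @param temperature K, stored in the ensemble.
#' @param label optional condition label.
#' @return a [work_ensemble()].
#' @export
resample_work <- function(logs, grid_step = 0.1, temperature = 310,
                          label = NULL) {
  stopifnot(length(logs) >= 1L)
  logs <- lapply(logs, function(l) l[order(l$lambda), , drop = FALSE])
  lo <- max(vapply(logs, function(l) min(l$lambda), numeric(1L)))
  hi <- min(vapply(logs, function(l) max(l$lambda), numeric(1L)))
  full_lo <- min(vapply(logs, function(l) min(l$lambda), numeric(1L)))
  full_hi <- max(vapply(logs, function(l) max(l$lambda), numeric(1L)))
  if (lo > full_lo + 1e-9 || hi < full_hi - 1e-9)
    warning("logs do not all cover the same lambda range; ",
            sprintf("grid truncated to [%.3f, %.3f]", lo, hi))
  # build the grid so the endpoint survives floating-point jitter in hi
  n_int <- floor((hi - lo) / grid_step + 1e-8)
  grid <- lo + (0:n_int) * grid_step
  grid[length(grid)] <- min(grid[length(grid)], hi)
  if (hi - grid[length(grid)] > 1e-6 * grid_step) grid <- c(grid, hi)
  W <- t(vapply(logs, function(l) {
    w <- approx(l$lambda, l$W, xout = grid, ties = "ordered")$y
    w - w[1L]
  }, numeric(length(grid))))
  work_ensemble(grid, W, temperature = temperature, label = label)
}

#' Mean and spread of the work along the pull
#'
#' @param ensemble a [work_ensemble()].
#' @return list with `mean_final`, `sd_final` (at the last grid point) and
#'   `mean_curve`, `sd_curve` along lambda.
#' @export
mean_work <- function(ensemble) {
  stopifnot(inherits(ensemble, "work_ensemble"))
  mc <- colMeans(ensemble$W)
  sc <- apply(ensemble$W, 2L, sd)
  list(mean_final = mc[length(mc)], sd_final = sc[length(sc)],
       mean_curve = mc, sd_curve = sc, lambda = ensemble$lambda)
}

#' Fold-difference in mean final work between two ensembles
#'
#' @param ens_a,ens_b [work_ensemble()] objects (numerator `ens_b`).
#' @param digits significant digits for the reported fold (2 by default,
#'   matching how such ratios are usually quoted).
#' @return named list with the two means and the (rounded) fold difference.
#' @export
work_fold_difference <- function(ens_a, ens_b, digits = 2) {
  ma <- mean_work(ens_a)$mean_final
  mb <- mean_work(ens_b)$mean_final
  list(mean_a = ma, mean_b = mb, fold = signif(mb / ma, digits))
}

#' Compare final pulling work between two ensembles
#'
#' Two-sided Welch (unequal-variance) t-test on the final-lambda work
#' values.
#'
#' @param ens_a,ens_b [work_ensemble()] objects with >= 2 replicates each.
#' @return list with `statistic`, `p_value`, `df`, `mean_a`, `mean_b` and
#'   `degenerate` (TRUE when both ensembles have zero variance, in which
#'   case the p-value is undefined and returned as NA).
#' @export
compare_work <- function(ens_a, ens_b) {
  wa <- ens_a$W[, ncol(ens_a$W)]
  wb <- ens_b$W[, ncol(ens_b$W)]
  stopifnot(length(wa) >= 2L, length(wb) >= 2L)
  if (var(wa) == 0 && var(wb) == 0)
    return(list(statistic = NA_real_, p_value = NA_real_, df = NA_real_,
                mean_a = mean(wa), mean_b = mean(wb), degenerate = TRUE))
  tt <- t.test(wa, wb, var.equal = FALSE)
  list(statistic = unname(tt$statistic), p_value = tt$p.value,
       df = unname(tt$parameter), mean_a = mean(wa), mean_b = mean(wb),
       degenerate = FALSE)
}

#' Jarzynski free-energy profile from a work ensemble
#'
#' Delta F(lambda) = -kT ln < exp(-W(lambda)/kT) >, evaluated with a
#' log-sum-exp reduction for numerical stability. By Jensen's inequality the
#' profile lies at or below the mean work pointwise. A single-replicate
#' ensemble degenerates to Delta F = W and raises a warning.
#'
#' @param ensemble a [work_ensemble()] with its temperature set.
#' @return object of class `free_energy_profile`: list with `lambda`, `dF`,
#'   `mean_W`, `sd_W`, `estimator`, `n_replicates`, `temperature`.
#' @export
jarzynski_profile <- function(ensemble) {
  stopifnot(inherits(ensemble, "work_ensemble"))
  kT <- KB_KCAL * ensemble$temperature
  n <- nrow(ensemble$W)
  if (n < 2L) warning("single replicate: Jarzynski average degenerates to W")
  dF <- vapply(seq_along(ensemble$lambda), function(j)
    -kT * log_mean_exp(-ensemble$W[, j] / kT), numeric(1L))
  mw <- mean_work(ensemble)
  structure(list(lambda = ensemble$lambda, dF = dF, mean_W = mw$mean_curve,
                 sd_W = mw$sd_curve, estimator = "jarzynski",
                 n_replicates = n, temperature = ensemble$temperature),
            class = "free_energy_profile")
}

#' @export
print.free_energy_profile <- function(x, ...) {
  cat(sprintf(paste0("free_energy_profile (%s, n = %d): ",
                     "dF(end) = %.3f kcal/mol, <W>(end) = %.3f kcal/mol\n"),
              x$estimator, x$n_replicates, x$dF[length(x$dF)],
              x$mean_W[length(x$mean_W)]))
  invisible(x)
}

#' Replicate closest to the free-energy profile
#'
#' Picks the replicate whose work curve minimizes the L2 distance to
#' Delta F(lambda); this realizes the "Jarzynski average trajectory" as an
#' actual member of the ensemble whose structures can be displayed. Ties
#' resolve to the lowest index.
#'
#' @param ensemble a [work_ensemble()].
#' @param profile the [jarzynski_profile()] computed from it.
#' @return replicate index (1-based).
#' @export
representative_trajectory <- function(ensemble, profile) {
  stopifnot(inherits(ensemble, "work_ensemble"),
            inherits(profile, "free_energy_profile"),
            ncol(ensemble$W) == length(profile$dF))
  d2 <- rowSums(sweep(ensemble$W, 2L, profile$dF)^2)
  which.min(d2)
}

#' Contact timeline across pulling replicates
#'
#' Filters contacts to those appearing at least once in at least
#' `presence_threshold` of the replicates, then reports, per retained
#' contact and time point, the fraction of replicates in which the contact
#' is present.
#'
#' @param series_list list of per-replicate logical (or 0/1) matrices,
#'   contacts x time, sharing dimensions and row names.
#' @param presence_threshold minimum fraction of replicates in which a
#'   contact must appear at least once to be retained.
#' @return object of class `contact_timeline`: list with `probability`
#'   (matrix, retained contacts x time), `retained`, `threshold`,
#'   `n_replicates`.
#' @export
contact_timeline <- function(series_list, presence_threshold = 0.9) {
  stopifnot(length(series_list) >= 1L)
  dims <- dim(series_list[[1L]])
  ok <- vapply(series_list, function(m) identical(dim(m), dims), logical(1L))
  if (!all(ok)) stop("replicate contact matrices must share dimensions")
  appear <- vapply(series_list, function(m) rowSums(m != 0) > 0,
                   logical(dims[1L]))
  appear <- matrix(appear, nrow = dims[1L])
  keep <- rowMeans(appear) >= presence_threshold
  prob <- Reduce(`+`, lapply(series_list, function(m) (m != 0) * 1)) /
    length(series_list)
  rn <- rownames(series_list[[1L]]) %||% as.character(seq_len(dims[1L]))
  rownames(prob) <- rn
  structure(list(probability = prob[keep, , drop = FALSE],
                 retained = rn[keep], threshold = presence_threshold,
                 n_replicates = length(series_list)),
            class = "contact_timeline")
}

#' Write a free-energy profile as TSV
#'
#' Columns: lambda, dF, mean_W, sd_W.
#'
#' @param profile a [free_energy_profile].
#' @param file output path.
#' @export
write_profile_tsv <- function(profile, file) {
  utils::write.table(
    data.frame(lambda = profile$lambda, dF = profile$dF,
               mean_W = profile$mean_W, sd_W = profile$sd_W),
    file, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Write a work ensemble as a long-format TSV (replicate, lambda, W)
#'
#' @param ensemble a [work_ensemble()].
#' @param file output path.
#' @export
write_work_tsv <- function(ensemble, file) {
  n <- nrow(ensemble$W)
  utils::write.table(
    data.frame(replicate = rep(seq_len(n), each = length(ensemble$lambda)),
               lambda = rep(ensemble$lambda, n),
               W = as.vector(t(ensemble$W))),
    file, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Read a long-format work TSV back into per-replicate logs
#'
#' @param file TSV with columns replicate, lambda, W.
#' @return list of data frames suitable for [resample_work()].
#' @export
read_work_tsv <- function(file) {
  df <- utils::read.table(file, header = TRUE, sep = "\t")
  lapply(split(df, df$replicate), function(d)
    data.frame(lambda = d$lambda, W = d$W))
}
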