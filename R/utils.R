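# Internal helpers shared across modules.

# Evaluate `code` under a given RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

# log(mean(exp(x))) without overflow; used by the Jarzynski estimator.
log_mean_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(mean(exp(x - m)))
}

vcross <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

vnorm <- function(a) sqrt(sum(a * a))

# Optimal rotation (Kabsch, unweighted) mapping centred coordinates P onto
# Q under right-multiplication of row vectors: minimizes ||P R - Q||_F.
# P, Q: n x 3 matrices already centred on their means.
kabsch_rotation <- function(P, Q) {
  H <- crossprod(P, Q)
  s <- svd(H)
  d <- sign(det(tcrossprod(s$u, s$v)))
  s$u %*% diag(c(1, 1, d)) %*% t(s$v)
}

# Superpose mobile (n x 3) onto ref (n x 3) using the selection rows `sel`;
# returns the transformed full coordinate set.
superpose_onto <- function(mobile, ref, sel = seq_len(nrow(mobile))) {
  cm <- colMeans(mobile[sel, , drop = FALSE])
  cr <- colMeans(ref[sel, , drop = FALSE])
  Pm <- sweep(mobile[sel, , drop = FALSE], 2L, cm)
  Pr <- sweep(ref[sel, , drop = FALSE], 2L, cr)
  Rm <- kabsch_rotation(Pm, Pr)
  sweep(sweep(mobile, 2L, cm) %*% Rm, 2L, cr, "+")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_count <- function(x) is.numeric(x) && length(x) == 1L &&
  is.finite(x) && x >= 1 && x == round(x)

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
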