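#' Posterior summaries of one voxel's samples
#'
#' Scalar parameters are summarised by their arithmetic posterior mean.
#' Orientations are summarised axially through [dyadic_mean()] — never by
#' averaging angles, which would be meaningless across the antipodal
#' symmetry of the model.
#'
#' @param samples a `"posterior_samples"` object from [run_mcmc()].
#' @return List with `mean` (named vector over all flat parameters), `dyads`
#'   (list of per-stick mean orientation unit vectors) and `dispersion`
#'   (per-stick largest dyadic-tensor eigenvalue, in `[1/3, 1]`).
#' @export
posterior_means <- function(samples) {
  stopifnot(inherits(samples, "posterior_samples"))
  S <- samples$samples
  if (nrow(S) < 1L) stop("no retained samples to summarise")
  m <- colMeans(S)
  L <- samples$L
  dyads <- vector("list", L)
  disp <- numeric(L)
  for (j in seq_len(L)) {
    X <- stick_direction(S[, 3L * j + 1L], S[, 3L * j + 2L])
    if (is.null(dim(X))) X <- matrix(X, 1L)
    dm <- dyadic_mean(X)
    dyads[[j]] <- dm$vector
    disp[j] <- dm$dispersion
  }
  list(mean = m, dyads = dyads, dispersion = disp)
}

#' Dyadic (axial) mean of orientation samples
#'
#' The mean orientation of axial data is the principal eigenvector of the
#' mean outer-product tensor `(1/n) sum_i x_i x_i^T`; its largest eigenvalue
#' measures concentration (1 for perfectly aligned samples, 1/3 in the
#' uniform limit). Sign-invariant by construction; the returned vector is
#' canonicalised to the z >= 0 hemisphere.
#'
#' @param x an `n x 3` matrix of unit vectors (or a single length-3 vector).
#' @return List with `vector` (unit 3-vector) and `dispersion` (scalar in
#'   `[1/3, 1]` for unit-vector input).
#' @examples
#' dyadic_mean(rbind(c(0, 0, 1), c(0, 0, -1)))
#' @export
dyadic_mean <- function(x) {
  if (is.null(dim(x))) x <- matrix(x, 1L)
  Tm <- crossprod(x) / nrow(x)
  ei <- eigen(Tm, symmetric = TRUE)
  v <- ei$vectors[, 1L]
  # canonical hemisphere: z > 0, ties broken on y then x
  if (v[3L] < 0 || (v[3L] == 0 && (v[2L] < 0 || (v[2L] == 0 && v[1L] < 0))))
    v <- -v
  list(vector = v, dispersion = ei$values[1L])
}

#' Angular error between two axes
#'
#' `acos(|u . v|)` in degrees — the axial angle, in `[0, 90]`, invariant to
#' the sign of either vector.
#'
#' @param u,v unit 3-vectors.
#' @return Angle in degrees.
#' @examples
#' angular_error(c(1, 0, 0), c(0, 1, 0))  # 90
#' @export
angular_error <- function(u, v) {
  acos(min(max(abs(sum(u * v)), 0), 1)) * 180 / pi
}

#' Minimum-assignment angular error for multi-fibre estimates
#'
#' Matches estimated dyads to ground-truth axes by the permutation minimising
#' the total angular error, and returns the per-truth-axis errors under that
#' assignment. This is the standard recovery metric for crossing-fibre
#' configurations, where stick labels are arbitrary.
#'
#' @param est list (or matrix rows) of estimated unit 3-vectors.
#' @param truth list (or matrix rows) of true unit 3-vectors, same length.
#' @return Numeric vector of angular errors (degrees), one per truth axis.
#' @export
assignment_angular_error <- function(est, truth) {
  as_list <- function(x) if (is.matrix(x)) asplit(x, 1) else x
  est <- as_list(est); truth <- as_list(truth)
  L <- length(truth)
  stopifnot(length(est) == L)
  errmat <- outer(seq_len(L), seq_len(L),
                  Vectorize(function(i, j) angular_error(truth[[i]], est[[j]])))
  perms <- all_permutations(L)
  costs <- vapply(perms, function(p) sum(errmat[cbind(seq_len(L), p)]), 0)
  best <- perms[[which.min(costs)]]
  errmat[cbind(seq_len(L), best)]
}

all_permutations <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (i in seq_len(n)) {
    for (p in all_permutations(n - 1L)) {
      rest <- seq_len(n)[-i]
      out[[length(out) + 1L]] <- c(i, rest[p])
    }
  }
  out
}
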