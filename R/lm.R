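#' Options for the Levenberg-Marquardt stage
#'
#' @param max_iter maximum number of damping cycles (each cycle solves one
#'   damped normal system and tests the step).
#' @param ftol relative sum-of-squares improvement below which an accepted
#'   step counts as convergence.
#' @param initial_lambda starting damping factor.
#' @param lambda_up multiplier applied to the damping after a rejected step
#'   (> 1).
#' @param lambda_down multiplier applied after an accepted step (in (0, 1)).
#' @return A list of class `"lm_options"`.
#' @export
lm_options <- function(max_iter = 200L, ftol = 1e-9, initial_lambda = 1e-3,
                       lambda_up = 10, lambda_down = 0.1) {
  stopifnot(max_iter >= 1, ftol > 0, initial_lambda > 0,
            lambda_up > 1, lambda_down > 0, lambda_down < 1)
  structure(list(max_iter = as.integer(max_iter), ftol = ftol,
                 initial_lambda = initial_lambda, lambda_up = lambda_up,
                 lambda_down = lambda_down),
            class = "lm_options")
}

#' Initial parameter guess from a log-linear diffusion tensor fit
#'
#' Seeds the nonlinear fit: `S0` is the mean of the b=0 signals; a diffusion
#' tensor is fitted by linear least squares to `log(S/S0)`, giving the
#' diffusivity (mean eigenvalue), the first stick orientation (principal
#' eigenvector) and `f_1` from the fractional anisotropy (clipped to
#' `[0.01, 0.95]`). Additional sticks start at the remaining eigenvectors
#' with `f_j = f_1 / (j + 1)`. If the tensor system is singular or produces
#' non-finite values, an isotropic fallback is used (`f_j = 0.05`,
#' orientations along the coordinate axes).
#'
#' @inheritParams bs_residuals
#' @param L number of sticks to initialise.
#' @return A [ball_stick()] parameter set.
#' @export
init_guess <- function(data, scheme, L = 1L) {
  stopifnot_scheme(scheme)
  if (length(data) != scheme$K)
    stop("'data' length does not match the scheme")
  if (any(!is.finite(data))) stop("'data' contains non-finite values")
  if (!any(scheme$b0))
    stop("initialisation requires at least one b=0 measurement")
  if (sum(!scheme$b0) < 6L)
    stop("initialisation requires at least 6 diffusion-weighted measurements")
  S0 <- mean(data[scheme$b0])
  if (S0 <= 0) S0 <- max(mean(abs(data)), 1e-6)

  dw <- !scheme$b0
  b <- scheme$bvals[dw]
  g <- scheme$bvecs[dw, , drop = FALSE]
  y <- log(pmax(data[dw], 1e-8 * S0) / S0)
  X <- -b * cbind(g[, 1]^2, g[, 2]^2, g[, 3]^2,
                  2 * g[, 1] * g[, 2], 2 * g[, 1] * g[, 3], 2 * g[, 2] * g[, 3])
  beta <- tryCatch(qr.solve(X, y), error = function(e) NULL)
  axes_fallback <- function(d0) {
    th <- c(pi / 2, pi / 2, 0)[seq_len(L)]
    ph <- c(0, pi / 2, 0)[seq_len(L)]
    ball_stick(S0, d0, f = rep(0.05, L), theta = th, phi = ph)
  }
  if (is.null(beta) || any(!is.finite(beta))) {
    adc <- mean(pmax(-y / b, 0))
    return(axes_fallback(max(adc, 1e-6)))
  }
  D <- matrix(c(beta[1], beta[4], beta[5],
                beta[4], beta[2], beta[6],
                beta[5], beta[6], beta[3]), 3, 3)
  ei <- eigen(D, symmetric = TRUE)
  lam <- pmax(ei$values, 0)          # descending
  md <- mean(lam)
  if (!is.finite(md) || md <= 0) return(axes_fallback(1e-6))
  fa <- sqrt(1.5 * sum((lam - md)^2) / max(sum(lam^2), 1e-30))
  f1 <- min(max(fa, 0.01), 0.95)
  f <- f1 / c(1, seq_len(max(L - 1L, 0L)) + 2L)[seq_len(L)]  # f1, f1/3, f1/4, ...
  if (sum(f) > 0.95) f <- f * 0.95 / sum(f)
  vecs <- ei$vectors[, seq_len(min(L, 3L)), drop = FALSE]
  th <- acos(pmin(pmax(vecs[3L, ], -1), 1))
  ph <- atan2(vecs[2L, ], vecs[1L, ])
  if (L > 3L) { # beyond the three eigenvectors: coordinate axes
    th <- c(th, rep(pi / 2, L - 3L)); ph <- c(ph, rep(0, L - 3L))
  }
  ball_stick(S0, max(md, 1e-6), f = f, theta = th[seq_len(L)],
             phi = ph[seq_len(L)])
}

# Constraint transforms: LM iterates in an unconstrained space u where
#   S0 = u1^2, d = u2^2, f_j = sin^2(u_fj); angles pass through.
to_unconstrained <- function(v, L) {
  u <- v
  u[1L] <- sqrt(v[1L]); u[2L] <- sqrt(v[2L])
  for (j in seq_len(L)) u[3L * j] <- asin(sqrt(min(max(v[3L * j], 0), 1)))
  u
}
to_constrained <- function(u, L) {
  v <- u
  v[1L] <- u[1L]^2; v[2L] <- u[2L]^2
  for (j in seq_len(L)) v[3L * j] <- sin(u[3L * j])^2
  v
}
# dp/du for the chain rule, same layout
transform_grad <- function(u, L) {
  g <- rep(1, length(u))
  g[1L] <- 2 * u[1L]; g[2L] <- 2 * u[2L]
  for (j in seq_len(L)) g[3L * j] <- sin(2 * u[3L * j])
  g
}
# keep sum(f) <= 1 by rescaling fractions of an accepted step
project_simplex <- function(v, L, cap = 0.9999) {
  idx <- 3L * seq_len(L)
  s <- sum(v[idx])
  if (s > cap) v[idx] <- v[idx] * cap / s
  v
}

#' Levenberg-Marquardt fit of the ball-and-stick model
#'
#' Stage one of the two-stage pipeline: a deterministic damped least-squares
#' fit minimising the sum of squared residuals, providing the MCMC starting
#' point. Constraints are enforced by optimising in a transformed space
#' (squared transforms keep `S0, d >= 0`; a squared-sine transform keeps each
#' `f_j` in `[0, 1]`; `sum(f) <= 1` by projection after accepted steps), so
#' the inner iteration is unconstrained. The accepted sum-of-squares sequence
#' is non-increasing by construction and is returned as a trace.
#'
#' @inheritParams init_guess
#' @param opts an [lm_options()] list.
#' @param init optional [ball_stick()] starting point; defaults to
#'   [init_guess()].
#' @return A list with `params` (fitted [ball_stick()]), `iterations`,
#'   `sum_sq` (final), `converged`, and `trace` (accepted sum-of-squares
#'   values, starting with the value at initialisation).
#' @examples
#' sch <- make_scheme(K = 32, bval = 1500, n_b0 = 2)
#' truth <- ball_stick(1000, 1e-3, f = 0.6, theta = pi / 3, phi = 0.4)
#' fit <- lm_fit(predict_signal(truth, sch), sch, L = 1)
#' fit$sum_sq
#' @export
lm_fit <- function(data, scheme, L = 1L, opts = lm_options(), init = NULL) {
  stopifnot_scheme(scheme)
  if (any(!is.finite(data))) stop("'data' contains non-finite values")
  if (scheme$K < 3L * L + 2L)
    stop("the scheme has fewer measurements than model parameters")
  if (is.null(init)) init <- init_guess(data, scheme, L)
  R <- 3L * L + 2L

  v <- pack_params(init)
  # nudge off constraint boundaries so the transform gradients are nonzero
  v[1L] <- max(v[1L], 1e-6)
  v[2L] <- max(v[2L], 1e-8)
  for (j in seq_len(L)) v[3L * j] <- min(max(v[3L * j], 1e-4), 0.9999)
  v <- project_simplex(v, L)
  u <- to_unconstrained(v, L)

  ss <- sum_sq(data - predict_signal_vec(v, L, scheme$bvals, scheme$bvecs))
  trace <- ss
  lambda <- opts$initial_lambda
  converged <- FALSE
  iter <- 0L
  ss_floor <- 1e-20 * max(sum(data^2), 1)  # numerically-perfect start
  if (ss <= ss_floor) converged <- TRUE
  while (!converged && iter < opts$max_iter) {
    iter <- iter + 1L
    p <- unpack_params(v, L)
    r <- data - predict_signal_vec(v, L, scheme$bvals, scheme$bvecs)
    Ju <- bs_jacobian(p, scheme) * rep(transform_grad(u, L), each = scheme$K)
    A <- crossprod(Ju)
    gvec <- crossprod(Ju, r)
    step <- tryCatch(
      solve(A + lambda * diag(diag(A) + 1e-12, R), gvec),
      error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) {
      lambda <- lambda * opts$lambda_up
      if (lambda > 1e12) break
      next
    }
    u_new <- u + drop(step)
    v_new <- project_simplex(to_constrained(u_new, L), L)
    ss_new <- sum_sq(data - predict_signal_vec(v_new, L, scheme$bvals, scheme$bvecs))
    if (is.finite(ss_new) && ss_new < ss) {
      rel <- (ss - ss_new) / max(ss, .Machine$double.xmin)
      u <- to_unconstrained(v_new, L)
      v <- v_new
      ss <- ss_new
      trace <- c(trace, ss)
      lambda <- max(lambda * opts$lambda_down, 1e-12)
      if (rel < opts$ftol || ss <= ss_floor) { converged <- TRUE; break }
    } else {
      lambda <- lambda * opts$lambda_up
      if (lambda > 1e12) { converged <- TRUE; break } # no improving direction left
    }
  }
  list(params = unpack_params(v, L), iterations = iter, sum_sq = ss,
       converged = converged, trace = trace)
}
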