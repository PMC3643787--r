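#' Ball-and-stick model parameters for one voxel
#'
#' The ball-and-stick model decomposes the voxel signal into one isotropic
#' compartment (the "ball") and `L` perfectly anisotropic compartments (the
#' "sticks"), whose orientations are the voxel's preferred diffusion
#' orientations. A parameter set holds the baseline signal `S0`, the
#' diffusivity `d` and, per stick, a volume fraction `f_j` and spherical
#' angles `theta_j` (polar) and `phi_j` (azimuth). The model has `R = 3L + 2`
#' free parameters.
#'
#' @param S0 baseline signal without diffusion weighting (intensity units, >= 0).
#' @param d diffusivity (mm^2/s, >= 0).
#' @param f numeric vector of stick volume fractions, each in `[0, 1]` with
#'   `sum(f) <= 1`; its length sets the number of sticks `L >= 1`.
#' @param theta,phi polar and azimuthal angles (radians) of each stick, same
#'   length as `f`. Angles are unconstrained; they are mapped onto the sphere
#'   by [stick_direction()] and the model depends on the orientation only
#'   through `(r . x)^2`, so antipodal directions are equivalent.
#' @return An object of class `"ball_stick"`.
#' @examples
#' p <- ball_stick(S0 = 1000, d = 1e-3, f = 0.7, theta = pi / 2, phi = 0)
#' @export
ball_stick <- function(S0, d, f, theta, phi) {
  L <- length(f)
  if (L < 1L) stop("at least one stick is required (L >= 1)")
  if (length(theta) != L || length(phi) != L)
    stop("'f', 'theta' and 'phi' must have one entry per stick")
  if (!is.finite(S0) || S0 < 0) stop("'S0' must be finite and >= 0")
  if (!is.finite(d) || d < 0) stop("'d' must be finite and >= 0")
  if (any(!is.finite(f)) || any(f < 0) || any(f > 1) || sum(f) > 1 + 1e-12)
    stop("volume fractions must lie in [0, 1] with sum(f) <= 1")
  structure(list(S0 = as.numeric(S0), d = as.numeric(d), f = as.numeric(f),
                 theta = as.numeric(theta), phi = as.numeric(phi), L = L),
            class = "ball_stick")
}

#' @export
print.ball_stick <- function(x, ...) {
  cat("Ball & stick parameters (L =", x$L, "):\n")
  cat("  S0 =", format(x$S0), "  d =", format(x$d), "mm^2/s\n")
  for (j in seq_len(x$L))
    cat(sprintf("  stick %d: f = %.4f, theta = %.4f, phi = %.4f\n",
                j, x$f[j], x$theta[j], x$phi[j]))
  invisible(x)
}

# Flat parameter vector layout (also the MCMC update order):
#   S0, d, then per stick (f_j, theta_j, phi_j).
param_names <- function(L) {
  c("S0", "d", as.vector(rbind(paste0("f", 1:L),
                               paste0("th", 1:L),
                               paste0("ph", 1:L))))
}

pack_params <- function(params) {
  v <- c(params$S0, params$d,
         as.vector(rbind(params$f, params$theta, params$phi)))
  names(v) <- param_names(params$L)
  v
}

unpack_params <- function(v, L) {
  idx <- 2L + 3L * (seq_len(L) - 1L)
  structure(list(S0 = v[[1L]], d = v[[2L]], f = unname(v[idx + 1L]),
                 theta = unname(v[idx + 2L]), phi = unname(v[idx + 3L]), L = L),
            class = "ball_stick")
}

#' Unit orientation vector of a stick
#'
#' Maps spherical angles onto the unit sphere:
#' `x = (sin(theta) cos(phi), sin(theta) sin(phi), cos(theta))`.
#' Vectorised over angles.
#'
#' @param theta polar angle(s), radians.
#' @param phi azimuthal angle(s), radians.
#' @return A length-3 unit vector, or an `n x 3` matrix for vector input.
#' @examples
#' stick_direction(pi / 2, 0)  # x axis
#' @export
stick_direction <- function(theta, phi) {
  st <- sin(theta)
  out <- cbind(st * cos(phi), st * sin(phi), cos(theta))
  if (nrow(out) == 1L) drop(out) else out
}

# Per-measurement signal for a flat parameter vector. Kept free of any matrix
# product so the serial R engine and the compiled batched engine perform the
# same scalar IEEE operations in the same order (see sum_sq for the reduction).
predict_signal_vec <- function(v, L, bvals, bvecs) {
  S0 <- v[[1L]]; d <- v[[2L]]
  # accumulated as e_iso + sum_j f_j (e_j - e_iso): algebraically the usual
  # (1 - sum f) e_iso + sum f_j e_j, but exactly S0 at b = 0 in floating point
  e_iso <- exp(-(bvals * d))
  acc <- e_iso
  for (j in seq_len(L)) {
    f <- v[[3L * j]]; th <- v[[3L * j + 1L]]; ph <- v[[3L * j + 2L]]
    st <- sin(th)
    x1 <- st * cos(ph); x2 <- st * sin(ph); x3 <- cos(th)
    dt <- bvecs[, 1L] * x1 + bvecs[, 2L] * x2 + bvecs[, 3L] * x3
    acc <- acc + f * (exp(-(bvals * d) * (dt * dt)) - e_iso)
  }
  S0 * acc
}

#' Forward ball-and-stick signal prediction
#'
#' Evaluates the multi-compartment signal equation
#' `S_i = S0 * ((1 - sum(f)) * exp(-b_i d) + sum_j f_j exp(-b_i d (r_i . x_j)^2))`
#' for every measurement of the scheme. At `b = 0` this reduces to `S0`
#' exactly, for any parameter set.
#'
#' @param params a [ball_stick()] parameter set.
#' @param scheme an [acquisition_scheme()].
#' @return Numeric vector of predicted signals, length `scheme$K`.
#' @examples
#' sch <- make_scheme(K = 12, bval = 1000, n_b0 = 1)
#' p <- ball_stick(1, 1e-3, f = 0.5, theta = pi / 2, phi = 0)
#' predict_signal(p, sch)
#' @export
predict_signal <- function(params, scheme) {
  stopifnot_scheme(scheme)
  predict_signal_vec(pack_params(params), params$L, scheme$bvals, scheme$bvecs)
}

#' Model residuals and their sum of squares
#'
#' `bs_residuals()` returns `data - predict_signal(params, scheme)`;
#' `sum_sq()` reduces a residual vector with a fixed sequential order (the
#' same reduction both execution engines use), so equal inputs give equal
#' sums regardless of engine.
#'
#' @inheritParams predict_signal
#' @param data observed signal vector, length `scheme$K`.
#' @return `bs_residuals()`: numeric residual vector; `sum_sq()`: scalar.
#' @export
bs_residuals <- function(params, scheme, data) {
  stopifnot_scheme(scheme)
  if (length(data) != scheme$K)
    stop("'data' has length ", length(data), " but the scheme has ",
         scheme$K, " measurements")
  data - predict_signal(params, scheme)
}

#' @rdname bs_residuals
#' @param r numeric residual vector.
#' @export
sum_sq <- function(r) sum(r * r)

#' Analytic Jacobian of the signal model
#'
#' Sensitivity matrix `dS_i / dp` for `p` in the flat parameter order
#' `(S0, d, f_1, theta_1, phi_1, ...)`. Used by the Levenberg-Marquardt
#' stage; tests cross-check it against central finite differences.
#'
#' @inheritParams predict_signal
#' @return `K x (3L + 2)` numeric matrix with parameter names as columns.
#' @export
bs_jacobian <- function(params, scheme) {
  stopifnot_scheme(scheme)
  b <- scheme$bvals; g <- scheme$bvecs
  S0 <- params$S0; d <- params$d; L <- params$L
  J <- matrix(0, scheme$K, 3L * L + 2L,
              dimnames = list(NULL, param_names(L)))
  e_iso <- exp(-b * d)
  fsum <- sum(params$f)
  acc <- (1 - fsum) * e_iso          # model / S0
  dS_dd <- -(b) * (1 - fsum) * e_iso # d(model/S0)/dd
  for (j in seq_len(L)) {
    f <- params$f[j]; th <- params$theta[j]; ph <- params$phi[j]
    st <- sin(th); ct <- cos(th); sp <- sin(ph); cp <- cos(ph)
    x <- c(st * cp, st * sp, ct)
    dx_dth <- c(ct * cp, ct * sp, -st)
    dx_dph <- c(-st * sp, st * cp, 0)
    dt <- g %*% x
    a <- dt^2
    e_j <- exp(-b * d * a)
    da_dth <- 2 * dt * (g %*% dx_dth)
    da_dph <- 2 * dt * (g %*% dx_dph)
    J[, 3L * j] <- S0 * (e_j - e_iso)                 # d/df_j
    J[, 3L * j + 1L] <- S0 * f * e_j * (-b * d) * da_dth
    J[, 3L * j + 2L] <- S0 * f * e_j * (-b * d) * da_dph
    dS_dd <- dS_dd + f * (-b * a) * e_j
    acc <- acc + f * e_j
  }
  J[, 1L] <- acc
  J[, 2L] <- S0 * dS_dd
  J
}
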