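# shared fixtures: small schemes, quick chain settings, random parameter draws

quick_opts <- function(burnin = 200L, njumps = 200L, sampleevery = 10L, ...) {
  mcmc_options(burnin = burnin, njumps = njumps, sampleevery = sampleevery, ...)
}

small_scheme <- function(K = 24L, bval = 1500, n_b0 = 2L) {
  make_scheme(K, bval, n_b0)
}

# random interior single-stick parameter set
random_params <- function(L = 1L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  f <- runif(L, 0.1, 0.8 / L)
  ball_stick(S0 = runif(1, 500, 1500), d = runif(1, 5e-4, 2e-3),
             f = f, theta = runif(L, 0.3, pi - 0.3), phi = runif(L, -pi, pi))
}

random_rotation <- function(seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  M <- matrix(rnorm(9), 3)
  qr.Q(qr(M)) * sign(det(qr.Q(qr(M))))
}

angles_from_vector <- function(x) {
  c(theta = acos(min(max(x[3], -1), 1)), phi = atan2(x[2], x[1]))
}
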