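#' Options for the random-walk Metropolis sampler
#'
#' Defaults follow the standard whole-brain analysis settings: a burn-in of
#' 3000 iterations and a thinning period of 25 samples, with 1250 post-burn-in
#' jumps so that 50 samples per parameter are retained.
#'
#' @param burnin iterations discarded before retention begins (>= 0).
#' @param njumps post-burn-in iterations (>= 0).
#' @param sampleevery thinning period: every `sampleevery`-th post-burn-in
#'   state is retained (>= 1). Retained samples = `floor(njumps / sampleevery)`.
#' @param proposal_sds optional per-parameter Normal proposal standard
#'   deviations in flat parameter order; `NULL` uses scale-aware defaults
#'   derived from the starting point.
#' @param adapt if `TRUE`, proposal standard deviations are rescaled every 40
#'   iterations during burn-in only (factor `accepted_fraction / 0.5`, clipped
#'   to `[0.5, 2]`) and frozen afterwards, keeping the stationary target exact.
#' @return A list of class `"mcmc_options"`.
#' @export
mcmc_options <- function(burnin = 3000L, njumps = 1250L, sampleevery = 25L,
                         proposal_sds = NULL, adapt = TRUE) {
  stopifnot(burnin >= 0, njumps >= 0, sampleevery >= 1)
  structure(list(burnin = as.integer(burnin), njumps = as.integer(njumps),
                 sampleevery = as.integer(sampleevery),
                 proposal_sds = proposal_sds, adapt = isTRUE(adapt)),
            class = "mcmc_options")
}

#' Pre-generated random stream for one MCMC run
#'
#' All Normal and Uniform draws an MCMC run will consume are generated up
#' front, indexed by (iteration, parameter). Both execution engines read the
#' same buffers in the same order, which is what makes serial and batched
#' runs directly comparable: two engines given the same stream must produce
#' the same chain.
#'
#' @param seed integer seed for R's Mersenne-Twister generator (inversion
#'   Normal method).
#' @param opts an [mcmc_options()] list; determines the number of iterations.
#' @param R number of model parameters (`3L + 2`).
#' @return An object of class `"random_stream"`: list with `seed`, `normals`
#'   and `uniforms` (each an `(burnin + njumps) x R` matrix, filled in
#'   iteration-major order).
#' @examples
#' st <- generate_stream(1, mcmc_options(burnin = 10, njumps = 10), R = 5)
#' dim(st$normals)
#' @export
generate_stream <- function(seed, opts, R) {
  niter <- opts$burnin + opts$njumps
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed), kind = "Mersenne-Twister", normal.kind = "Inversion")
  normals <- matrix(rnorm(niter * R), nrow = niter, ncol = R, byrow = TRUE)
  uniforms <- matrix(runif(niter * R), nrow = niter, ncol = R, byrow = TRUE)
  structure(list(seed = as.integer(seed), normals = normals, uniforms = uniforms,
                 rng = "Mersenne-Twister/Inversion"),
            class = "random_stream")
}

# Prior support check + orientation density on a flat parameter vector.
# Flat priors on S0 >= 0, d >= 0 and the volume-fraction simplex contribute
# zero; each stick contributes log|sin theta| (uniform on the sphere, extended
# periodically since angles are unconstrained). widen_f is the negative-control
# hook used by repeat_validation's "broken" engine.
log_prior_vec <- function(v, L, widen_f = 0) {
  if (v[[1L]] < 0 || v[[2L]] < 0) return(-Inf)
  fsum <- 0
  lp <- 0
  for (j in seq_len(L)) {
    f <- v[[3L * j]]
    if (f < -widen_f || f > 1 + widen_f) return(-Inf)
    fsum <- fsum + f
    s <- abs(sin(v[[3L * j + 1L]]))
    if (s <= 0) return(-Inf)
    lp <- lp + log(s)
  }
  if (fsum > 1 + widen_f) return(-Inf)
  lp
}

#' Log-prior of a ball-and-stick parameter set
#'
#' Returns `-Inf` outside the prior support (`f_j` outside `[0, 1]`,
#' `sum(f) > 1`, `d < 0` or `S0 < 0`); inside, the flat priors on `S0`, `d`
#' and `f` contribute zero and each stick orientation contributes
#' `log(sin(theta_j))`, the uniform-on-sphere density.
#'
#' @param params a [ball_stick()] parameter set.
#' @return A scalar, possibly `-Inf`.
#' @export
log_prior <- function(params) log_prior_vec(pack_params(params), params$L)

#' Marginalised Gaussian log-likelihood
#'
#' With Gaussian measurement noise of unknown variance carrying a
#' noninformative prior, the variance integrates out analytically and the
#' log-likelihood reduces (up to a constant) to
#' `-(K/2) * log(sum_sq(residuals))`, floored at `1e-12` on the sum of
#' squares so a perfect fit does not diverge.
#'
#' @inheritParams bs_residuals
#' @return A scalar log-likelihood.
#' @export
log_marginal_likelihood <- function(params, data, scheme) {
  stopifnot_scheme(scheme)
  if (scheme$K < 2L) stop("at least 2 measurements are required")
  if (any(!is.finite(data))) stop("'data' contains non-finite values")
  ss <- sum_sq(bs_residuals(params, scheme, data))
  -(scheme$K / 2) * log(max(ss, 1e-12))
}

loglik_vec <- function(v, L, data, bvals, bvecs, K) {
  s <- predict_signal_vec(v, L, bvals, bvecs)
  r <- data - s
  -(K / 2) * log(max(sum(r * r), 1e-12))
}

#' Single-parameter Metropolis update
#'
#' Proposes `p' = p + proposal_sd * normal_draw` for one parameter, evaluates
#' the change in log-posterior (log-prior plus marginalised log-likelihood)
#' and accepts iff `log(uniform_draw)` is below that change. Exactly one
#' Normal and one Uniform draw are consumed per call. The state carries the
#' cached log-prior and log-likelihood of the current parameters so a
#' rejection costs nothing to undo.
#'
#' @param state list with `v` (flat parameter vector), `lp` (log-prior) and
#'   `ll` (log-likelihood); as produced by `mcmc_state()`.
#' @param param_index which parameter (1-based, flat order) to update.
#' @param normal_draw,uniform_draw the pre-generated draws to consume.
#' @param proposal_sd standard deviation of the Normal proposal.
#' @inheritParams bs_residuals
#' @param L number of sticks.
#' @return The updated state list, with an `accepted` logical attached.
#' @export
metropolis_update <- function(state, param_index, normal_draw, uniform_draw,
                              proposal_sd, data, scheme, L) {
  stopifnot_scheme(scheme)
  v <- state$v
  v[param_index] <- v[param_index] + proposal_sd * normal_draw
  lpp <- log_prior_vec(v, L)
  if (is.finite(lpp)) {
    llp <- loglik_vec(v, L, data, scheme$bvals, scheme$bvecs, scheme$K)
    delta <- (lpp + llp) - (state$lp + state$ll)
  } else {
    delta <- -Inf
  }
  if (log(uniform_draw) < delta) {
    state$v <- v; state$lp <- lpp; state$ll <- llp
    state$accepted <- TRUE
  } else {
    state$accepted <- FALSE
  }
  state
}

#' @rdname metropolis_update
#' @param init a [ball_stick()] starting point inside the prior support.
#' @export
mcmc_state <- function(init, data, scheme) {
  v <- pack_params(init)
  list(v = v, lp = log_prior_vec(v, init$L),
       ll = loglik_vec(v, init$L, data, scheme$bvals, scheme$bvecs, scheme$K))
}

default_proposal_sds <- function(v, L) {
  sds <- numeric(3L * L + 2L)
  sds[1L] <- max(0.05 * v[1L], 1e-6)
  sds[2L] <- max(0.2 * v[2L], 1e-6)
  for (j in seq_len(L)) sds[3L * j + c(0L, 1L, 2L)] <- c(0.05, 0.1, 0.1)
  sds
}

# nudge an LM result (which may sit on a constraint boundary) strictly inside
# the prior support
project_into_support <- function(init) {
  v <- pack_params(init)
  L <- init$L
  v[1L] <- max(v[1L], 1e-6)
  v[2L] <- max(v[2L], 1e-8)
  for (j in seq_len(L)) {
    v[3L * j] <- min(max(v[3L * j], 1e-4), 1 - 1e-4)
    if (abs(sin(v[3L * j + 1L])) < 1e-6) v[3L * j + 1L] <- v[3L * j + 1L] + 1e-3
  }
  project_simplex(v, L, cap = 1 - 1e-4)
}

#' Run the random-walk Metropolis sampler for one voxel
#'
#' Stage two of the pipeline: starting from the Levenberg-Marquardt estimate,
#' all `R = 3L + 2` parameters are updated one at a time in a fixed order
#' (`S0`, `d`, then per stick `f`, `theta`, `phi`) in every iteration, using
#' the pre-generated draws of `stream`. Burn-in states are discarded and every
#' `sampleevery`-th post-burn-in state is retained. The run is a pure function
#' of its arguments: the same stream gives bitwise-identical chains, and the
#' serial and batched engines execute the same operations in the same order.
#'
#' @inheritParams bs_residuals
#' @param init a [ball_stick()] starting point; projected strictly inside the
#'   prior support if it sits on a boundary.
#' @param opts an [mcmc_options()] list.
#' @param stream a [generate_stream()] object with buffers of size
#'   `(burnin + njumps) x (3L + 2)`.
#' @param engine `"batched"` (compiled; per-gradient signal evaluations
#'   vectorised) or `"serial"` (plain-R reference implementation).
#' @return An object of class `"posterior_samples"`: list with `samples`
#'   (retained draws, `floor(njumps / sampleevery) x R`), `accept` (accepted
#'   proposals per parameter), `n_updates` (proposals per parameter),
#'   `final_state` (flat vector), `proposal_sds` (after any adaptation), `L`.
#' @examples
#' sch <- make_scheme(K = 16, bval = 1000, n_b0 = 1)
#' truth <- ball_stick(1, 1e-3, f = 0.6, theta = pi / 2, phi = 0)
#' y <- simulate_voxel(truth, sch, snr = 30, seed = 7)
#' op <- mcmc_options(burnin = 100, njumps = 100, sampleevery = 10)
#' st <- generate_stream(1, op, R = 5)
#' ps <- run_mcmc(y, sch, truth, op, st)
#' colMeans(ps$samples)
#' @export
run_mcmc <- function(data, scheme, init, opts = mcmc_options(),
                     stream = NULL, engine = c("batched", "serial")) {
  stopifnot_scheme(scheme)
  engine <- match.arg(engine)
  L <- init$L
  R <- 3L * L + 2L
  niter <- opts$burnin + opts$njumps
  if (is.null(stream)) stream <- generate_stream(1L, opts, R)
  if (nrow(stream$normals) < niter || ncol(stream$normals) != R ||
      nrow(stream$uniforms) < niter || ncol(stream$uniforms) != R)
    stop("random stream buffers do not cover ", niter, " iterations x ", R,
         " parameters")
  v0 <- project_into_support(init)
  sds <- opts$proposal_sds
  if (is.null(sds)) sds <- default_proposal_sds(v0, L)
  if (length(sds) != R) stop("'proposal_sds' must have one entry per parameter")

  res <- if (engine == "batched") {
    run_chain_cpp(data, scheme$bvals, scheme$bvecs, v0, L,
                  opts$burnin, opts$njumps, opts$sampleevery,
                  sds, opts$adapt, stream$normals, stream$uniforms)
  } else {
    run_chain_serial(data, scheme, v0, L, opts, sds, stream)
  }
  colnames(res$samples) <- param_names(L)
  names(res$final_state) <- param_names(L)
  structure(c(res, list(L = L, engine = engine, options = opts)),
            class = "posterior_samples")
}

# Plain-R reference engine. Mirrors run_chain_cpp operation for operation:
# any change here must be made there too.
run_chain_serial <- function(data, scheme, v0, L, opts, sds, stream,
                             widen_f = 0) {
  R <- 3L * L + 2L
  niter <- opts$burnin + opts$njumps
  bvals <- scheme$bvals; bvecs <- scheme$bvecs; K <- scheme$K
  cur <- v0
  lp <- log_prior_vec(cur, L, widen_f)
  ll <- loglik_vec(cur, L, data, bvals, bvecs, K)
  if (!is.finite(lp)) stop("starting point lies outside the prior support")
  nsamp <- opts$njumps %/% opts$sampleevery
  samples <- matrix(NA_real_, nsamp, R)
  acc_total <- integer(R)
  acc_win <- integer(R)
  k <- 0L
  normals <- stream$normals; uniforms <- stream$uniforms
  for (it in seq_len(niter)) {
    for (p in seq_len(R)) {
      prop <- cur
      prop[p] <- cur[p] + sds[p] * normals[it, p]
      lpp <- log_prior_vec(prop, L, widen_f)
      if (is.finite(lpp)) {
        llp <- loglik_vec(prop, L, data, bvals, bvecs, K)
        delta <- (lpp + llp) - (lp + ll)
      } else {
        delta <- -Inf
      }
      if (log(uniforms[it, p]) < delta) {
        cur <- prop; lp <- lpp; ll <- llp
        acc_total[p] <- acc_total[p] + 1L
        acc_win[p] <- acc_win[p] + 1L
      }
    }
    if (opts$adapt && it <= opts$burnin && it %% 40L == 0L) {
      fac <- pmin(pmax(acc_win / 20, 0.5), 2)
      sds <- sds * fac
      acc_win[] <- 0L
    }
    if (it > opts$burnin && (it - opts$burnin) %% opts$sampleevery == 0L) {
      k <- k + 1L
      samples[k, ] <- cur
    }
  }
  list(samples = samples, accept = acc_total, n_updates = rep(niter, R),
       final_state = cur, proposal_sds = sds)
}

#' Sample a scalar target with the same Metropolis kernel
#'
#' Validation utility: runs the package's random-walk Metropolis
#' accept/reject rule against an arbitrary one-dimensional log-density, so
#' the sampler can be checked on targets with known moments (e.g. a standard
#' Normal) independently of the diffusion model.
#'
#' @param log_target function of one numeric argument returning the
#'   log-density (up to a constant); may return `-Inf`.
#' @param init starting value with finite log-density.
#' @param n_iter number of iterations.
#' @param proposal_sd Normal proposal standard deviation.
#' @param seed integer seed for the pre-generated draw buffers.
#' @param burnin iterations discarded from the returned samples.
#' @return List with `samples` (length `n_iter - burnin`) and `accept_rate`.
#' @export
sample_scalar_target <- function(log_target, init, n_iter, proposal_sd,
                                 seed = 1L, burnin = 0L) {
  opts <- mcmc_options(burnin = 0L, njumps = n_iter, sampleevery = 1L,
                       adapt = FALSE)
  stream <- generate_stream(seed, opts, R = 1L)
  cur <- init
  lt <- log_target(cur)
  if (!is.finite(lt)) stop("'init' has non-finite log-density")
  out <- numeric(n_iter)
  acc <- 0L
  for (it in seq_len(n_iter)) {
    prop <- cur + proposal_sd * stream$normals[it, 1L]
    ltp <- log_target(prop)
    delta <- if (is.finite(ltp)) ltp - lt else -Inf
    if (log(stream$uniforms[it, 1L]) < delta) {
      cur <- prop; lt <- ltp; acc <- acc + 1L
    }
    out[it] <- cur
  }
  list(samples = out[(burnin + 1L):n_iter], accept_rate = acc / n_iter)
}

#' @export
print.posterior_samples <- function(x, ...) {
  cat("Posterior samples:", nrow(x$samples), "retained draws x",
      ncol(x$samples), "parameters (", x$engine, "engine )\n")
  cat("  acceptance rates:",
      paste(sprintf("%s %.2f", colnames(x$samples), x$accept / x$n_updates),
            collapse = ", "), "\n")
  invisible(x)
}
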