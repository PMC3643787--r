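#' Repeated-execution engine validation
#'
#' The engine-equivalence check that matters in practice: if two execution
#' engines implement the same sampler, then across many repeats with
#' independent seeds the distribution of each parameter's posterior mean
#' must be the same for both. Each engine is run `n_repeats` times on the
#' same voxel data (its own disjoint seed list by default), the per-repeat
#' posterior means are collected, and a two-sample Kolmogorov-Smirnov test
#' compares the two engines' distributions parameter by parameter.
#'
#' The `"broken"` engine label runs the serial sampler with a deliberately
#' widened prior support (volume fractions allowed outside `[0, 1]`) and
#' serves as a negative control: a validation procedure that cannot flag it
#' would be toothless.
#'
#' @inheritParams run_mcmc
#' @param L number of sticks.
#' @param n_repeats repeats per engine (>= 20).
#' @param engines length-2 character vector out of `"serial"`, `"batched"`,
#'   `"broken"`.
#' @param seeds optional list of two integer vectors (length `n_repeats`
#'   each), the stream seeds per engine; default disjoint consecutive
#'   blocks starting at `base_seed`.
#' @param base_seed first seed used when `seeds` is `NULL`.
#' @param lm_opts an [lm_options()] list for the shared starting point.
#' @return A data frame with one row per parameter: `parameter`, `ks_stat`,
#'   `p_value`, plus the engine pair as attributes.
#' @export
repeat_validation <- function(data, scheme, L = 1L, opts = mcmc_options(),
                              n_repeats = 50L,
                              engines = c("serial", "batched"),
                              seeds = NULL, base_seed = 1L,
                              lm_opts = lm_options()) {
  stopifnot_scheme(scheme)
  if (n_repeats < 20L) stop("'n_repeats' must be at least 20")
  if (length(engines) != 2L) stop("'engines' must name exactly two engines")
  R <- 3L * L + 2L
  if (is.null(seeds)) {
    seeds <- list(base_seed + seq_len(n_repeats) - 1L,
                  base_seed + n_repeats + seq_len(n_repeats) - 1L)
  }
  init <- lm_fit(data, scheme, L, lm_opts)$params

  run_engine <- function(engine, seed_vec) {
    means <- matrix(NA_real_, length(seed_vec), R)
    for (r in seq_along(seed_vec)) {
      stream <- generate_stream(seed_vec[r], opts, R)
      ps <- if (engine == "broken") {
        run_mcmc_broken(data, scheme, init, opts, stream)
      } else {
        run_mcmc(data, scheme, init, opts, stream, engine = engine)
      }
      means[r, ] <- colMeans(ps$samples)
    }
    means
  }
  m1 <- run_engine(engines[1L], seeds[[1L]])
  m2 <- run_engine(engines[2L], seeds[[2L]])
  ks <- lapply(seq_len(R), function(p)
    suppressWarnings(ks.test(m1[, p], m2[, p])))
  out <- data.frame(parameter = param_names(L),
                    ks_stat = vapply(ks, function(k) unname(k$statistic), 0),
                    p_value = vapply(ks, function(k) k$p.value, 0))
  attr(out, "engines") <- engines
  attr(out, "n_repeats") <- n_repeats
  out
}

# negative control: serial sampler with prior support widened on f
run_mcmc_broken <- function(data, scheme, init, opts, stream, widen_f = 0.3) {
  L <- init$L
  R <- 3L * L + 2L
  v0 <- project_into_support(init)
  sds <- opts$proposal_sds
  if (is.null(sds)) sds <- default_proposal_sds(v0, L)
  res <- run_chain_serial(data, scheme, v0, L, opts, sds, stream,
                          widen_f = widen_f)
  colnames(res$samples) <- param_names(L)
  structure(c(res, list(L = L, engine = "broken", options = opts)),
            class = "posterior_samples")
}
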