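test_that("log-prior encodes the support and the spherical orientation density", {
  bad <- ball_stick(1, 1e-3, f = 0.5, theta = 1, phi = 0)
  bad$f <- -0.1  # outside support, bypassing the constructor
  expect_identical(log_prior(bad), -Inf)
  over <- ball_stick(1, 1e-3, f = c(0.6, 0.3), theta = c(1, 1), phi = c(0, 1))
  over$f <- c(0.6, 0.5)
  expect_identical(log_prior(over), -Inf)
  expect_equal(log_prior(ball_stick(1, 1e-3, 0.5, pi / 2, 0)), 0)
  two <- ball_stick(1, 1e-3, c(0.3, 0.3), c(pi / 4, pi / 3), c(0, 0))
  expect_equal(log_prior(two), log(sin(pi / 4)) + log(sin(pi / 3)),
               tolerance = 1e-12)
})

test_that("marginalised likelihood follows its scaling identity and floor", {
  sch <- small_scheme()
  p <- random_params(seed = 7)
  y <- simulate_voxel(p, sch, snr = 10, seed = 8)
  ll <- log_marginal_likelihood(p, y, sch)
  # doubling every residual shifts the value by -(K/2) log 4
  y2 <- predict_signal(p, sch) + 2 * (y - predict_signal(p, sch))
  expect_equal(log_marginal_likelihood(p, y2, sch), ll - sch$K / 2 * log(4),
               tolerance = 1e-9)
  # perfect fit hits the floor
  expect_equal(log_marginal_likelihood(p, predict_signal(p, sch), sch),
               -(sch$K / 2) * log(1e-12))
  # two-line oracle
  expect_equal(ll, -(sch$K / 2) * log(sum((y - predict_signal(p, sch))^2)))
})

test_that("metropolis update accepts and rejects as the criterion dictates", {
  sch <- small_scheme()
  p <- random_params(seed = 9)
  y <- simulate_voxel(p, sch, snr = 20, seed = 10)
  st <- mcmc_state(p, y, sch)
  # zero-width proposal: delta = 0, always accepted, state numerically unchanged
  up <- metropolis_update(st, 3L, normal_draw = 1.7, uniform_draw = 0.999,
                          proposal_sd = 0, data = y, scheme = sch, L = 1L)
  expect_true(up$accepted)
  expect_identical(up$v, st$v)
  # proposal pushing f negative is rejected whatever the uniform draw
  dn <- -(p$f[1] + 0.2)
  up2 <- metropolis_update(st, 3L, normal_draw = dn, uniform_draw = 1e-300,
                           proposal_sd = 1, data = y, scheme = sch, L = 1L)
  expect_false(up2$accepted)
  expect_identical(up2$v, st$v)
})

test_that("pre-generated streams are reproducible and correctly sized", {
  op <- mcmc_options()  # burnin 3000, njumps 1250
  s1 <- generate_stream(11, op, R = 5)
  s2 <- generate_stream(11, op, R = 5)
  expect_identical(s1$normals, s2$normals)
  expect_identical(s1$uniforms, s2$uniforms)
  expect_identical(dim(s1$normals), c(4250L, 5L))  # (3000+1250) x R draws
  expect_identical(dim(s1$uniforms), c(4250L, 5L))
  # empirical moments within 4 standard errors of (0, 1)
  n <- length(s1$normals)
  expect_lt(abs(mean(s1$normals)), 4 / sqrt(n))
  expect_lt(abs(var(as.vector(s1$normals)) - 1), 4 * sqrt(2 / n))
})

test_that("chain retention arithmetic and reproducibility hold", {
  sch <- small_scheme()
  truth <- random_params(seed = 12)
  y <- simulate_voxel(truth, sch, snr = 25, seed = 13)
  init <- lm_fit(y, sch, 1)$params
  op0 <- mcmc_options(burnin = 50, njumps = 0, sampleevery = 5)
  ps0 <- run_mcmc(y, sch, init, op0, generate_stream(1, op0, 5))
  expect_identical(nrow(ps0$samples), 0L)
  expect_true(all(is.finite(ps0$final_state)))
  op <- quick_opts(njumps = 120, sampleevery = 25)
  st <- generate_stream(2, op, 5)
  ps1 <- run_mcmc(y, sch, init, op, st)
  ps2 <- run_mcmc(y, sch, init, op, st)
  expect_identical(nrow(ps1$samples), 4L)  # floor(120 / 25)
  expect_identical(ps1$samples, ps2$samples)
  # stream too short for the requested run
  expect_error(run_mcmc(y, sch, init, mcmc_options(burnin = 500), st),
               "stream")
})

test_that("retained samples never leave the prior support", {
  sch <- small_scheme()
  for (i in 1:5) {
    truth <- random_params(L = 2, seed = 70 + i)
    y <- simulate_voxel(truth, sch, snr = 10, seed = 80 + i)
    init <- lm_fit(y, sch, 2)$params
    op <- quick_opts()
    ps <- run_mcmc(y, sch, init, op, generate_stream(90 + i, op, 8))
    f <- ps$samples[, c("f1", "f2"), drop = FALSE]
    expect_true(all(f >= 0 & f <= 1))
    expect_true(all(rowSums(f) <= 1))
    expect_true(all(ps$samples[, "d"] >= 0) && all(ps$samples[, "S0"] >= 0))
    expect_true(all(ps$accept / ps$n_updates >= 0 & ps$accept / ps$n_updates <= 1))
  }
})

test_that("posterior spread shrinks as SNR grows", {
  sch <- make_scheme(32, 1500, 1)
  truth <- ball_stick(1000, 1e-3, f = 0.6, theta = pi / 3, phi = 0.2)
  op <- mcmc_options(burnin = 600, njumps = 600, sampleevery = 5)
  spread <- sapply(c(10, 30, 100), function(snr) {
    sds <- sapply(1:20, function(v) {
      y <- simulate_voxel(truth, sch, snr = snr, seed = 500 + v)
      init <- lm_fit(y, sch, 1)$params
      ps <- run_mcmc(y, sch, init, op, generate_stream(600 + v, op, 5))
      sd(ps$samples[, "f1"])
    })
    median(sds)
  })
  expect_true(all(diff(spread) < 0))
})

test_that("acceptance rates match an independent scalar reference chain", {
  # fixed proposal widths, no adaptation; reference chain written directly
  # from the posterior definition, run on its own seeds
  sch <- small_scheme()
  truth <- ball_stick(900, 1e-3, f = 0.55, theta = pi / 2.5, phi = 0.3)
  y <- simulate_voxel(truth, sch, snr = 20, seed = 123)
  init <- lm_fit(y, sch, 1)$params
  sds <- c(20, 1e-4, 0.05, 0.1, 0.1)
  op <- mcmc_options(burnin = 0, njumps = 2000, sampleevery = 10,
                     proposal_sds = sds, adapt = FALSE)
  pkg_rate <- mean(sapply(1:5, function(s) {
    ps <- run_mcmc(y, sch, init, op, generate_stream(s, op, 5))
    sum(ps$accept) / sum(ps$n_updates)
  }))
  ref_chain <- function(seed) {
    set.seed(seed)
    v <- ballstick:::project_into_support(init)
    lpost <- function(v) {
      if (any(v[3] < 0, v[3] > 1, v[1] < 0, v[2] < 0)) return(-Inf)
      s <- abs(sin(v[4])); if (s == 0) return(-Inf)
      pred <- v[1] * ((1 - v[3]) * exp(-sch$bvals * v[2]) +
        v[3] * exp(-sch$bvals * v[2] *
          (sch$bvecs %*% stick_direction(v[4], v[5]))^2))
      log(s) - sch$K / 2 * log(max(sum((y - pred)^2), 1e-12))
    }
    cur_lp <- lpost(v); acc <- 0
    for (it in 1:2000) for (p in 1:5) {
      w <- v; w[p] <- w[p] + rnorm(1, 0, sds[p])
      wlp <- lpost(w)
      if (runif(1) < exp(wlp - cur_lp)) { v <- w; cur_lp <- wlp; acc <- acc + 1 }
    }
    acc / 10000
  }
  ref_rate <- mean(sapply(101:105, ref_chain))
  expect_lt(abs(pkg_rate - ref_rate), 0.02)
})

test_that("the Metropolis kernel samples a standard Normal correctly", {
  r <- sample_scalar_target(function(x) -x^2 / 2, init = 0, n_iter = 50000,
                            proposal_sd = 2.4, seed = 31, burnin = 1000)
  expect_lt(abs(mean(r$samples)), 0.04)
  expect_lt(abs(var(r$samples) - 1), 0.08)
  expect_gt(r$accept_rate, 0.2)
  expect_lt(r$accept_rate, 0.7)
})
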