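test_that("posterior means average scalars and summarise orientations axially", {
  fake <- structure(list(
    samples = cbind(S0 = c(900, 1100), d = c(1e-3, 1.2e-3), f1 = c(0.2, 0.4),
                    th1 = c(pi / 2, pi / 2), ph1 = c(0, 0)),
    accept = rep(1L, 5), n_updates = rep(2L, 5), L = 1L),
    class = "posterior_samples")
  pm <- posterior_means(fake)
  expect_equal(unname(pm$mean[c("S0", "f1")]), c(1000, 0.3))
  expect_equal(abs(pm$dyads[[1]]), c(1, 0, 0), tolerance = 1e-12)
  one <- fake; one$samples <- fake$samples[1, , drop = FALSE]
  expect_equal(unname(posterior_means(one)$mean), unname(fake$samples[1, ]))
  none <- fake; none$samples <- fake$samples[0, , drop = FALSE]
  expect_error(posterior_means(none), "no retained samples")
  # direct recomputation on a long sample vector
  set.seed(4)
  big <- fake
  big$samples <- cbind(S0 = rnorm(1000, 1000), d = rnorm(1000, 1e-3, 1e-5),
                       f1 = runif(1000), th1 = runif(1000, 0, pi),
                       ph1 = runif(1000, -pi, pi))
  expect_equal(unname(posterior_means(big)$mean["f1"]),
               sum(big$samples[, "f1"]) / 1000)
})

test_that("dyadic mean is sign-invariant and detects isotropy", {
  v <- c(0.6, 0.8, 0) / 1
  d1 <- dyadic_mean(rbind(v, v, v))
  expect_equal(abs(d1$vector), abs(v), tolerance = 1e-12)
  expect_equal(d1$dispersion, 1, tolerance = 1e-12)
  d2 <- dyadic_mean(rbind(v, -v))
  expect_equal(abs(d2$vector), abs(v), tolerance = 1e-12)
  expect_equal(d2$dispersion, 1, tolerance = 1e-12)
  # uniform samples on the sphere: dispersion -> 1/3
  set.seed(5)
  z <- runif(10000, -1, 1); az <- runif(10000, 0, 2 * pi)
  X <- cbind(sqrt(1 - z^2) * cos(az), sqrt(1 - z^2) * sin(az), z)
  du <- dyadic_mean(X)
  expect_lt(abs(du$dispersion - 1 / 3), 0.02)
  # dispersion is invariant under global rotation of the samples
  Q <- random_rotation(seed = 6)
  set.seed(7)
  zc <- cbind(rnorm(500, 0, 0.1), rnorm(500, 0, 0.1), 1)
  zc <- zc / sqrt(rowSums(zc^2))
  expect_equal(dyadic_mean(zc %*% t(Q))$dispersion, dyadic_mean(zc)$dispersion,
               tolerance = 1e-9)
})

test_that("angular error is the axial angle in [0, 90] degrees", {
  u <- c(0, 0, 1)
  expect_equal(angular_error(u, u), 0)
  expect_equal(angular_error(u, -u), 0)
  expect_equal(angular_error(u, c(1, 0, 0)), 90)
  expect_equal(angular_error(u, c(0, sin(0.3), cos(0.3))), 0.3 * 180 / pi,
               tolerance = 1e-9)
  # minimum-assignment matching for crossing estimates ignores stick labels
  est <- list(c(0, 1, 0), c(1, 0, 0))
  truth <- list(c(1, 0, 0), c(0, 1, 0))
  expect_equal(assignment_angular_error(est, truth), c(0, 0))
})

test_that("phantom files round-trip exactly and gradient tables auto-orient", {
  dir <- withr::local_tempdir()
  ph <- make_phantom(canonical_phantom_spec(2, snr = 20, seed = 8),
                     make_scheme(12, 2000, 1))
  write_phantom(ph, dir)
  back <- read_inputs(file.path(dir, "data.nii.gz"),
                      file.path(dir, "mask.nii.gz"),
                      file.path(dir, "bvecs"), file.path(dir, "bvals"))
  expect_identical(back$data4d, unclass(ph$data))
  expect_identical(back$mask, ph$mask)
  expect_equal(back$scheme$bvecs, ph$scheme$bvecs, tolerance = 1e-12)
  # K x 3 layout reads the same as the written 3 x K layout
  write.table(ph$scheme$bvecs, file.path(dir, "bvecs_t"),
              row.names = FALSE, col.names = FALSE)
  sch_t <- read_bvals_bvecs(file.path(dir, "bvals"), file.path(dir, "bvecs_t"))
  expect_equal(sch_t$bvecs, back$scheme$bvecs, tolerance = 1e-12)
})

test_that("result maps are written with the contract names and shapes", {
  dir <- withr::local_tempdir()
  sch <- make_scheme(18, 2000, 1)
  ph <- make_phantom(canonical_phantom_spec(2, snr = 30, seed = 9), sch)
  op <- quick_opts(burnin = 100, njumps = 50, sampleevery = 10)
  res <- fit_volume(ph$data, ph$mask, ph$scheme, L = 2, mcmc_opts = op)
  files <- write_results(res, dir)
  expected <- c("mean_S0samples", "mean_dsamples",
                "mean_f1samples", "dyads1", "dispersion1",
                "mean_f2samples", "dyads2", "dispersion2")
  expect_setequal(basename(files), paste0(expected, ".nii.gz"))
  dy <- RNifti::readNifti(file.path(dir, "dyads1.nii.gz"))
  expect_identical(dim(dy), c(dim(ph$mask), 3L))
  md <- RNifti::readNifti(file.path(dir, "mean_dsamples.nii.gz"))
  pad3 <- function(d) c(d, rep(1L, 3 - length(d)))  # readers drop trailing 1s
  expect_identical(pad3(dim(md)), dim(ph$mask))
  expect_true(all(md[!ph$mask] == 0))
  # dyads unit-norm on the mask, dispersion within its bounds
  for (j in 1:2) {
    nrm <- sqrt(apply(res$dyads[[j]]^2, 1:3, sum))[ph$mask]
    expect_lt(max(abs(nrm - 1)), 1e-9)
    disp <- res$dispersion[[j]][ph$mask]
    expect_true(all(disp >= 1 / 3 - 1e-9 & disp <= 1 + 1e-9))
  }
})

test_that("the command-line interface runs the phantom and fit pipelines", {
  cli <- system.file("cli", "ballstick", package = "ballstick")
  skip_if(cli == "", "CLI script not installed")
  dir <- withr::local_tempdir()
  withr::local_envvar(R_LIBS = paste(.libPaths(), collapse = .Platform$path.sep))
  ph_dir <- file.path(dir, "phantom"); out_dir <- file.path(dir, "out")
  r1 <- system2("Rscript", c(cli, "phantom", "--n-per-region", "2",
                             "--snr", "30", "--K", "12", "--seed", "4",
                             "--out", ph_dir), stdout = TRUE, stderr = TRUE)
  expect_true(file.exists(file.path(ph_dir, "data.nii.gz")))
  r2 <- system2("Rscript", c(cli, "fit",
                             "--data", file.path(ph_dir, "data.nii.gz"),
                             "--mask", file.path(ph_dir, "mask.nii.gz"),
                             "--bvecs", file.path(ph_dir, "bvecs"),
                             "--bvals", file.path(ph_dir, "bvals"),
                             "--nfibres", "1", "--burnin", "100",
                             "--njumps", "50", "--sampleevery", "10",
                             "--seed", "1", "--out", out_dir),
                stdout = TRUE, stderr = TRUE)
  expect_true(file.exists(file.path(out_dir, "mean_f1samples.nii.gz")))
  img <- RNifti::readNifti(file.path(out_dir, "mean_f1samples.nii.gz"))
  expect_identical(prod(dim(img)), 6)
})
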