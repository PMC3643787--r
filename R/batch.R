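#' Options for volume-level execution
#'
#' @param batch_size voxels per Levenberg-Marquardt batch (default 64, the
#'   thread-block size found fastest in the decomposition this engine
#'   mirrors). A throughput knob only: results are identical for any value.
#' @param workers number of parallel slice workers (forked processes).
#' @param base_seed integer from which each voxel's random-stream seed is
#'   derived deterministically (base_seed + voxel linear index, modulo
#'   2^31 - 1), so per-voxel streams are distinct and reproducible and do
#'   not depend on batching or worker assignment.
#' @param engine `"batched"` or `"serial"`; passed to [run_mcmc()].
#' @param keep_samples if `TRUE`, retain every voxel's posterior sample
#'   matrix in the result (memory permitting).
#' @return A list of class `"batch_options"`.
#' @export
batch_options <- function(batch_size = 64L, workers = 1L, base_seed = 1L,
                          engine = c("batched", "serial"),
                          keep_samples = FALSE) {
  stopifnot(batch_size >= 1, workers >= 1)
  structure(list(batch_size = as.integer(batch_size),
                 workers = as.integer(workers),
                 base_seed = as.integer(base_seed),
                 engine = match.arg(engine),
                 keep_samples = isTRUE(keep_samples)),
            class = "batch_options")
}

#' Assign mask slices to workers
#'
#' Slices (third spatial axis) are the unit of distribution, as in
#' cluster-style voxelwise processing: each slice's voxels are independent,
#' so workers need never communicate. Slices with at least one masked voxel
#' are assigned greedily, largest masked-voxel count first, each to the
#' currently least-loaded worker.
#'
#' @param mask 3D logical array.
#' @param workers number of workers (>= 1).
#' @return List with `assignment` (integer vector over slices; worker index,
#'   `NA` for empty slices) and `load` (masked voxels per worker).
#' @examples
#' m <- array(TRUE, c(2, 2, 4))
#' partition_slices(m, 2)$load
#' @export
partition_slices <- function(mask, workers = 1L) {
  stopifnot(workers >= 1)
  counts <- apply(mask, 3, sum)
  nz <- which(counts > 0)
  assignment <- rep(NA_integer_, length(counts))
  load <- numeric(workers)
  for (s in nz[order(counts[nz], decreasing = TRUE)]) {
    w <- which.min(load)
    assignment[s] <- w
    load[w] <- load[w] + counts[s]
  }
  list(assignment = assignment, load = load)
}

voxel_seed <- function(base_seed, lin_index) {
  as.integer((as.numeric(base_seed) + lin_index) %% 2147483647)
}

# full pipeline for one voxel: LM init -> support projection -> stream -> MCMC
fit_voxel <- function(data, scheme, L, lm_opts, mcmc_opts, seed, engine) {
  fit <- lm_fit(data, scheme, L, lm_opts)
  stream <- generate_stream(seed, mcmc_opts, 3L * L + 2L)
  run_mcmc(data, scheme, fit$params, mcmc_opts, stream, engine = engine)
}

#' Fit the ball-and-stick model over a masked volume
#'
#' Runs the full two-stage pipeline (Levenberg-Marquardt initialisation,
#' then random-walk Metropolis MCMC) independently in every masked voxel and
#' assembles posterior summary maps. Voxels are processed in batches of
#' `batch_size` through the selected engine; slices are partitioned across
#' `workers` forked processes. Because every voxel derives its own random
#' stream from `base_seed` and its linear index, the result is invariant to
#' `batch_size`, `workers` and voxel ordering.
#'
#' @param data4d 4D numeric array (`X x Y x Z x K`).
#' @param mask 3D logical (or 0/1) array matching the spatial dimensions.
#' @param scheme an [acquisition_scheme()] with `K` measurements.
#' @param L number of sticks to fit.
#' @param lm_opts an [lm_options()] list.
#' @param mcmc_opts an [mcmc_options()] list.
#' @param batch_opts a [batch_options()] list.
#' @return An object of class `"volume_result"`: posterior-mean maps
#'   `mean_S0`, `mean_d`, per-stick `mean_f[[j]]`, dyad maps `dyads[[j]]`
#'   (`X x Y x Z x 3` unit vectors) and `dispersion[[j]]` (largest dyadic
#'   eigenvalue, in `[1/3, 1]`), the `mask`, and (optionally) per-voxel
#'   `samples`. Maps are zero outside the mask.
#' @examples
#' ph <- make_phantom(canonical_phantom_spec(2, snr = Inf),
#'                    make_scheme(16, 1500, 1))
#' op <- mcmc_options(burnin = 80, njumps = 40, sampleevery = 10)
#' res <- fit_volume(ph$data, ph$mask, ph$scheme, L = 1, mcmc_opts = op)
#' res$mean_f[[1]][, 2, 1]  # single-fibre column
#' @export
fit_volume <- function(data4d, mask, scheme, L = 1L, lm_opts = lm_options(),
                       mcmc_opts = mcmc_options(),
                       batch_opts = batch_options()) {
  stopifnot_scheme(scheme)
  dims <- dim(data4d)
  if (length(dims) != 4L) stop("'data4d' must be a 4D array")
  if (!identical(dim(mask), dims[1:3]))
    stop("'mask' dimensions do not match the spatial dimensions of 'data4d'")
  if (dims[4L] != scheme$K)
    stop("'data4d' has ", dims[4L], " volumes but the scheme has ", scheme$K,
         " measurements")
  mask <- array(as.logical(mask), dims[1:3])
  vox <- which(mask)
  if (length(vox) == 0L) {
    warning("empty mask: nothing to fit")
    return(empty_volume_result(dims[1:3], L, mask))
  }

  flat <- matrix(data4d, nrow = prod(dims[1:3]), ncol = dims[4L])
  slice_of <- rep(seq_len(dims[3L]), each = prod(dims[1:2]))

  process <- function(vidx) {
    out <- vector("list", length(vidx))
    for (start in seq(1L, length(vidx), by = batch_opts$batch_size)) {
      batch <- vidx[start:min(start + batch_opts$batch_size - 1L, length(vidx))]
      for (i in seq_along(batch)) {
        v <- batch[i]
        ps <- fit_voxel(flat[v, ], scheme, L, lm_opts, mcmc_opts,
                        voxel_seed(batch_opts$base_seed, v),
                        batch_opts$engine)
        out[[start + i - 1L]] <- summarise_voxel(ps, batch_opts$keep_samples)
      }
    }
    out
  }

  if (batch_opts$workers > 1L) {
    part <- partition_slices(mask, batch_opts$workers)
    groups <- lapply(seq_len(batch_opts$workers), function(w) {
      vox[part$assignment[slice_of[vox]] == w]
    })
    groups <- groups[vapply(groups, length, 1L) > 0L]
    pieces <- parallel::mclapply(groups, process,
                                 mc.cores = batch_opts$workers)
    per_vox <- vector("list", length(vox))
    names(per_vox) <- as.character(vox)
    for (g in seq_along(groups))
      per_vox[as.character(groups[[g]])] <- pieces[[g]]
    per_vox <- per_vox[as.character(vox)]
  } else {
    per_vox <- process(vox)
  }
  assemble_volume_result(per_vox, vox, dims[1:3], L, mask, batch_opts)
}

summarise_voxel <- function(ps, keep_samples) {
  pm <- posterior_means(ps)
  list(mean_S0 = pm$mean["S0"], mean_d = pm$mean["d"],
       mean_f = pm$mean[paste0("f", seq_len(ps$L))],
       dyads = pm$dyads, dispersion = pm$dispersion,
       samples = if (keep_samples) ps$samples else NULL)
}

empty_volume_result <- function(sdim, L, mask) {
  z3 <- array(0, sdim)
  structure(list(mean_S0 = z3, mean_d = z3,
                 mean_f = rep(list(z3), L),
                 dyads = rep(list(array(0, c(sdim, 3L))), L),
                 dispersion = rep(list(z3), L),
                 mask = mask, L = L, n_voxels = 0L, samples = NULL),
            class = "volume_result")
}

assemble_volume_result <- function(per_vox, vox, sdim, L, mask, batch_opts) {
  res <- empty_volume_result(sdim, L, mask)
  res$n_voxels <- length(vox)
  nvox3 <- prod(sdim)
  for (i in seq_along(vox)) {
    v <- vox[i]; s <- per_vox[[i]]
    res$mean_S0[v] <- s$mean_S0
    res$mean_d[v] <- s$mean_d
    for (j in seq_len(L)) {
      res$mean_f[[j]][v] <- s$mean_f[j]
      res$dyads[[j]][v + nvox3 * (0:2)] <- s$dyads[[j]]
      res$dispersion[[j]][v] <- s$dispersion[j]
    }
  }
  if (batch_opts$keep_samples) {
    res$samples <- lapply(per_vox, `[[`, "samples")
    names(res$samples) <- as.character(vox)
  }
  res
}

#' @export
print.volume_result <- function(x, ...) {
  cat("Ball & stick volume result:", x$n_voxels, "voxels fitted, L =", x$L, "\n")
  cat("  grid:", paste(dim(x$mean_d), collapse = " x "), "\n")
  invisible(x)
}

#' Per-voxel summary table of a volume result
#'
#' @param x a `"volume_result"`.
#' @param row.names,optional,... passed over from the generic (unused).
#' @return A data frame with one row per masked voxel: grid coordinates,
#'   posterior means and, per stick, dyad components and dispersion.
#' @export
as.data.frame.volume_result <- function(x, row.names = NULL, optional = FALSE,
                                        ...) {
  vox <- which(x$mask)
  ijk <- arrayInd(vox, dim(x$mask))
  nvox3 <- prod(dim(x$mask))
  out <- data.frame(i = ijk[, 1], j = ijk[, 2], k = ijk[, 3],
                    mean_S0 = x$mean_S0[vox], mean_d = x$mean_d[vox])
  for (jj in seq_len(x$L)) {
    out[[paste0("mean_f", jj)]] <- x$mean_f[[jj]][vox]
    d <- x$dyads[[jj]]
    out[[paste0("dyad", jj, "_x")]] <- d[vox]
    out[[paste0("dyad", jj, "_y")]] <- d[vox + nvox3]
    out[[paste0("dyad", jj, "_z")]] <- d[vox + 2 * nvox3]
    out[[paste0("dispersion", jj)]] <- x$dispersion[[jj]][vox]
  }
  out
}
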