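#' Read FSL-dialect gradient tables
#'
#' `bvals` is a whitespace-separated vector of b-values; `bvecs` holds the
#' gradient directions as either 3 rows x K columns (the common layout) or
#' K rows x 3 columns — the orientation is auto-detected from the shape.
#' Directions are taken in the image coordinate frame exactly as given: no
#' gradient-table reorientation of any kind is applied.
#'
#' @param bvals_path,bvecs_path paths to the text files.
#' @param b0_threshold b-values below this count as b=0 (default 50 s/mm^2).
#' @return An [acquisition_scheme()].
#' @export
read_bvals_bvecs <- function(bvals_path, bvecs_path, b0_threshold = 50) {
  bvals <- scan(bvals_path, quiet = TRUE)
  raw <- as.matrix(read.table(bvecs_path))
  if (nrow(raw) == 3L && ncol(raw) != 3L) raw <- t(raw)
  if (ncol(raw) != 3L)
    stop("'", bvecs_path, "' is neither 3 x K nor K x 3")
  if (nrow(raw) != length(bvals))
    stop("bvals lists ", length(bvals), " measurements but bvecs lists ",
         nrow(raw))
  acquisition_scheme(bvals, raw, b0_threshold = b0_threshold)
}

#' Read a diffusion dataset
#'
#' Loads the 4D diffusion-weighted volume, the 3D brain mask and the
#' gradient tables, checks that all dimensions agree, and returns them with
#' a normalised acquisition scheme.
#'
#' @param data_path path to the 4D NIfTI volume (.nii or .nii.gz).
#' @param mask_path path to the 3D NIfTI brain mask.
#' @param bvecs_path,bvals_path gradient table paths ([read_bvals_bvecs()]).
#' @return List with `data4d` (4D array), `mask` (3D logical array),
#'   `scheme` (an [acquisition_scheme()]) and `reference` (the mask NIfTI
#'   image, carrying the header geometry for output writing).
#' @export
read_inputs <- function(data_path, mask_path, bvecs_path, bvals_path) {
  img <- RNifti::readNifti(data_path)
  mask_img <- RNifti::readNifti(mask_path)
  data4d <- array(as.numeric(img), dim(img))
  if (length(dim(data4d)) != 4L)
    stop("'", data_path, "' is not a 4D volume")
  # NIfTI readers drop trailing singleton dimensions; restore a full 3D shape
  mdim <- dim(mask_img)
  if (length(mdim) > 3L) stop("'", mask_path, "' is not a 3D mask")
  mdim <- c(mdim, rep(1L, 3L - length(mdim)))
  mask <- array(as.numeric(mask_img) != 0, mdim)
  if (!identical(dim(mask), dim(data4d)[1:3]))
    stop("mask dimensions ", paste(dim(mask), collapse = "x"),
         " do not match data ", paste(dim(data4d)[1:3], collapse = "x"))
  scheme <- read_bvals_bvecs(bvals_path, bvecs_path)
  if (scheme$K != dim(data4d)[4L])
    stop("gradient tables list ", scheme$K, " measurements but the data has ",
         dim(data4d)[4L], " volumes")
  list(data4d = data4d, mask = mask, scheme = scheme, reference = mask_img)
}

#' Write posterior summary maps
#'
#' Writes the per-voxel posterior summaries as 32-bit float NIfTI volumes
#' with the reference image's header geometry, using the conventional
#' output names: `mean_S0samples`, `mean_dsamples`, `mean_f{j}samples`,
#' `dyads{j}` (4D, 3 components) and `dispersion{j}`.
#'
#' @param result a `"volume_result"` from [fit_volume()].
#' @param out_dir output directory (created if missing).
#' @param reference optional NIfTI image supplying the header geometry.
#' @return Invisibly, the vector of files written.
#' @export
write_results <- function(result, out_dir, reference = NULL) {
  stopifnot(inherits(result, "volume_result"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(arr, name) {
    path <- file.path(out_dir, paste0(name, ".nii.gz"))
    img <- if (is.null(reference)) RNifti::asNifti(arr)
           else RNifti::asNifti(arr, reference = reference)
    RNifti::writeNifti(img, path, datatype = "float")
    path
  }
  files <- c(wr(result$mean_S0, "mean_S0samples"),
             wr(result$mean_d, "mean_dsamples"))
  for (j in seq_len(result$L)) {
    files <- c(files,
               wr(result$mean_f[[j]], paste0("mean_f", j, "samples")),
               wr(result$dyads[[j]], paste0("dyads", j)),
               wr(result$dispersion[[j]], paste0("dispersion", j)))
  }
  invisible(files)
}

#' Write a synthetic phantom to disk
#'
#' Writes the phantom in exactly the formats [read_inputs()] consumes:
#' `data.nii.gz` (float64, so the round trip is exact), `mask.nii.gz`,
#' `bvals`/`bvecs` text files, and ground-truth sidecar volumes
#' (`truth_f{j}.nii.gz`, `truth_dyads{j}.nii.gz`, `truth_d.nii.gz`,
#' `truth_S0.nii.gz`).
#'
#' @param phantom output of [make_phantom()].
#' @param out_dir output directory (created if missing).
#' @return Invisibly, `out_dir`.
#' @export
write_phantom <- function(phantom, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  RNifti::writeNifti(RNifti::asNifti(phantom$data),
                     file.path(out_dir, "data.nii.gz"), datatype = "double")
  RNifti::writeNifti(RNifti::asNifti(phantom$mask + 0),
                     file.path(out_dir, "mask.nii.gz"), datatype = "uint8")
  writeLines(paste(phantom$scheme$bvals, collapse = " "),
             file.path(out_dir, "bvals"))
  write.table(t(phantom$scheme$bvecs), file.path(out_dir, "bvecs"),
              row.names = FALSE, col.names = FALSE)
  sdim <- dim(phantom$mask)
  L <- max(vapply(phantom$truth[!vapply(phantom$truth, is.null, TRUE)],
                  function(p) p$L, 1L))
  t_S0 <- array(0, sdim); t_d <- array(0, sdim)
  t_f <- rep(list(array(0, sdim)), L)
  t_dy <- rep(list(array(0, c(sdim, 3))), L)
  nvox3 <- prod(sdim)
  for (v in which(phantom$mask)) {
    p <- phantom$truth[[v]]
    t_S0[v] <- p$S0; t_d[v] <- p$d
    for (j in seq_len(p$L)) {
      t_f[[j]][v] <- p$f[j]
      t_dy[[j]][v + nvox3 * (0:2)] <- stick_direction(p$theta[j], p$phi[j])
    }
  }
  RNifti::writeNifti(RNifti::asNifti(t_S0),
                     file.path(out_dir, "truth_S0.nii.gz"), datatype = "double")
  RNifti::writeNifti(RNifti::asNifti(t_d),
                     file.path(out_dir, "truth_d.nii.gz"), datatype = "double")
  for (j in seq_len(L)) {
    RNifti::writeNifti(RNifti::asNifti(t_f[[j]]),
                       file.path(out_dir, paste0("truth_f", j, ".nii.gz")),
                       datatype = "double")
    RNifti::writeNifti(RNifti::asNifti(t_dy[[j]]),
                       file.path(out_dir, paste0("truth_dyads", j, ".nii.gz")),
                       datatype = "double")
  }
  invisible(out_dir)
}
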