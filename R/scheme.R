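#' Diffusion acquisition scheme
#'
#' Bundles the per-measurement b-values (s/mm^2), unit gradient directions and
#' b=0 flags that define a diffusion-weighted measurement design. Measurements
#' with `bvals < b0_threshold` are treated as unweighted (b=0): scanner b-value
#' tables rarely contain exact zeros.
#'
#' @param bvals numeric vector of b-values, one per measurement (s/mm^2).
#' @param bvecs numeric matrix of gradient directions, `length(bvals)` x 3
#'   (rows are measurements). Non-b0 rows must be unit vectors; rows deviating
#'   from unit norm by more than `1e-6` are renormalised with a warning.
#' @param b0_threshold b-values below this are flagged b=0 (default 50 s/mm^2).
#' @return An object of class `"acquisition_scheme"`: a list with elements
#'   `bvals`, `bvecs` (K x 3), `b0` (logical) and `K` (number of measurements).
#' @examples
#' sch <- acquisition_scheme(c(0, 1000, 1000),
#'                           rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)))
#' sch$K
#' @export
acquisition_scheme <- function(bvals, bvecs, b0_threshold = 50) {
  bvals <- as.numeric(bvals)
  bvecs <- as.matrix(bvecs)
  storage.mode(bvecs) <- "double"
  dimnames(bvecs) <- NULL
  if (ncol(bvecs) != 3L)
    stop("'bvecs' must have 3 columns (one gradient direction per row)")
  if (nrow(bvecs) != length(bvals))
    stop("'bvals' (", length(bvals), ") and 'bvecs' (", nrow(bvecs),
         " rows) describe different numbers of measurements")
  if (any(!is.finite(bvals)) || any(bvals < 0))
    stop("b-values must be finite and non-negative")
  b0 <- bvals < b0_threshold
  nrm <- sqrt(rowSums(bvecs^2))
  bad <- !b0 & abs(nrm - 1) > 1e-6
  if (any(bad)) {
    warning(sum(bad), " non-b0 gradient direction(s) were not unit-norm; renormalising")
    bvecs[bad, ] <- bvecs[bad, , drop = FALSE] / nrm[bad]
  }
  structure(list(bvals = bvals, bvecs = bvecs, b0 = b0, K = length(bvals)),
            class = "acquisition_scheme")
}

#' @export
print.acquisition_scheme <- function(x, ...) {
  cat("Acquisition scheme:", x$K, "measurements (", sum(x$b0), "b=0 )\n")
  if (any(!x$b0))
    cat("  b-values:", paste(unique(round(x$bvals[!x$b0])), collapse = ", "),
        "s/mm^2\n")
  invisible(x)
}

stopifnot_scheme <- function(scheme) {
  if (!inherits(scheme, "acquisition_scheme"))
    stop("'scheme' must be an acquisition_scheme object")
}
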