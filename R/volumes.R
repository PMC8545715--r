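#' @useDynLib poretomo, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm runif sd
#' @importFrom utils combn read.csv write.csv packageVersion
NULL

# Run expr with a local RNG stream seeded by `seed`, restoring any global
# .Random.seed afterwards. All stochastic operations in the package draw
# through this helper so nothing depends on (or disturbs) global RNG state.
with_local_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv(), inherits = FALSE)
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

check_dim3 <- function(x, what) {
  if (!is.array(x) || length(dim(x)) != 3) {
    stop(what, " must be a 3D array", call. = FALSE)
  }
}

#' Grayscale tomography volume
#'
#' Container for a reconstructed 3D scalar field (dimensionless reconstruction
#' intensity) together with the physical voxel edge length.
#'
#' @param values 3D numeric array of intensities.
#' @param voxel_edge_um Voxel edge length in micrometers (default 0.87, the
#'   resolution of the synchrotron scans this pipeline was designed around).
#' @return An object of class `grayscale_volume`.
#' @export
grayscale_volume <- function(values, voxel_edge_um = 0.87) {
  check_dim3(values, "values")
  stopifnot(voxel_edge_um > 0)
  structure(list(values = values, voxel_edge_um = voxel_edge_um),
            class = "grayscale_volume")
}

#' Quantized (16-bit signed integer) volume
#'
#' @param values 3D integer array; values must lie in \[-32768, 32767\].
#' @param voxel_edge_um Voxel edge length in micrometers.
#' @return An object of class `quantized_volume`.
#' @export
quantized_volume <- function(values, voxel_edge_um = 0.87) {
  check_dim3(values, "values")
  stopifnot(voxel_edge_um > 0)
  rng <- range(values)
  if (rng[1] < -32768 || rng[2] > 32767) {
    stop("quantized values outside 16-bit signed range", call. = FALSE)
  }
  storage.mode(values) <- "integer"
  structure(list(values = values, voxel_edge_um = voxel_edge_um),
            class = "quantized_volume")
}

#' Binary (pore/solid) volume
#'
#' The mask convention throughout the package is `TRUE` = pore (void),
#' `FALSE` = solid matrix.
#'
#' @param mask 3D logical array, `TRUE` = pore.
#' @param voxel_edge_um Voxel edge length in micrometers.
#' @return An object of class `binary_volume`.
#' @export
binary_volume <- function(mask, voxel_edge_um = 0.87) {
  check_dim3(mask, "mask")
  stopifnot(voxel_edge_um > 0, length(mask) >= 1)
  storage.mode(mask) <- "logical"
  structure(list(mask = mask, voxel_edge_um = voxel_edge_um),
            class = "binary_volume")
}

#' @export
print.grayscale_volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("grayscale_volume %d x %d x %d voxels, voxel edge %.3g um\n",
              d[1], d[2], d[3], x$voxel_edge_um))
  cat(sprintf("  intensity range [%.4g, %.4g]\n",
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
print.binary_volume <- function(x, ...) {
  d <- dim(x$mask)
  cat(sprintf("binary_volume %d x %d x %d voxels, voxel edge %.3g um\n",
              d[1], d[2], d[3], x$voxel_edge_um))
  cat(sprintf("  pore fraction %.4f\n", mean(x$mask)))
  invisible(x)
}

#' @export
print.quantized_volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("quantized_volume %d x %d x %d voxels (int16), voxel edge %.3g um\n",
              d[1], d[2], d[3], x$voxel_edge_um))
  invisible(x)
}
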