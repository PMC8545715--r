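#' Per-slice pore frequency curve along one axis
#'
#' Counts the pore voxels in every slice perpendicular to the chosen axis.
#' All segmented pore voxels are counted, regardless of the size of the pore
#' they belong to (unlike total porosity, which applies a minimum-size rule).
#' The resulting 1D curve is the measure fed to multifractal analysis.
#'
#' @param binary A [binary_volume()].
#' @param axis Axis index 1, 2 or 3; slices are taken perpendicular to it.
#' @return A `frequency_curve`: list with `counts` (integer per slice),
#'   `axis`, `slice_area_vox`, and `L` (number of slices).
#' @export
pore_frequency_curve <- function(binary, axis) {
  stopifnot(inherits(binary, "binary_volume"))
  if (!(axis %in% 1:3)) stop("axis must be 1, 2 or 3", call. = FALSE)
  d <- dim(binary$mask)
  counts <- as.integer(apply(binary$mask, axis, sum))
  structure(list(counts = counts, axis = axis,
                 slice_area_vox = prod(d[-axis]), L = d[axis]),
            class = "frequency_curve")
}

#' Construct a frequency curve from raw counts
#'
#' Wraps a plain vector of per-slice pore-voxel counts (e.g. a synthetic
#' measure or counts read from a CSV) as a `frequency_curve`.
#'
#' @param counts Nonnegative numeric vector, length >= 2.
#' @param slice_area_vox Voxels per slice (defaults to `max(counts)` when
#'   unknown; only used to express counts as slice porosities).
#' @param axis Axis label to carry along (default `NA`).
#' @return A `frequency_curve`.
#' @export
frequency_curve <- function(counts, slice_area_vox = max(counts), axis = NA) {
  counts <- as.numeric(counts)
  if (length(counts) < 2 || any(counts < 0) || any(!is.finite(counts))) {
    stop("counts must be >= 2 finite nonnegative values", call. = FALSE)
  }
  structure(list(counts = counts, axis = axis,
                 slice_area_vox = slice_area_vox, L = length(counts)),
            class = "frequency_curve")
}

#' @export
print.frequency_curve <- function(x, ...) {
  cat(sprintf("frequency_curve: %d slices along axis %s, mean count %.1f\n",
              x$L, as.character(x$axis), mean(x$counts)))
  invisible(x)
}

#' Range of per-slice porosity along a curve
#'
#' @param curve A `frequency_curve`.
#' @return Named numeric vector `c(min = , max = )` of slice porosities
#'   (counts divided by slice area).
#' @export
slice_porosity_range <- function(curve) {
  stopifnot(inherits(curve, "frequency_curve"))
  c(min = min(curve$counts), max = max(curve$counts)) / curve$slice_area_vox
}

#' Write / read a frequency curve as two-column CSV
#'
#' @param curve A `frequency_curve`.
#' @param path CSV path (columns: `slice`, `count`).
#' @return `path` invisibly (write); a `frequency_curve` (read).
#' @export
write_frequency_curve <- function(curve, path) {
  stopifnot(inherits(curve, "frequency_curve"))
  utils::write.csv(data.frame(slice = seq_along(curve$counts) - 1L,
                              count = curve$counts),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_frequency_curve
#' @param slice_area_vox Slice area in voxels to attach on read.
#' @export
read_frequency_curve <- function(path, slice_area_vox = NULL) {
  df <- utils::read.csv(path)
  frequency_curve(df$count,
                  slice_area_vox = if (is.null(slice_area_vox)) max(df$count)
                  else slice_area_vox)
}
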