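#' Quantize a grayscale volume to 16-bit signed integers
#'
#' Multiplies reconstruction intensities by `scale_factor` (default 100,000,
#' which maps typical phase-retrieved float intensities onto a displayable
#' integer range), rounds half away from zero, and clips to
#' \[-32768, 32767\].
#'
#' @param gray A [grayscale_volume()].
#' @param scale_factor Positive multiplier; default `1e5`.
#' @return A [quantized_volume()].
#' @examples
#' g <- grayscale_volume(array(1e-4, c(2, 2, 2)))
#' quantize(g)$values[1]  # 10
#' @export
quantize <- function(gray, scale_factor = 1e5) {
  stopifnot(inherits(gray, "grayscale_volume"))
  if (!is.numeric(scale_factor) || scale_factor <= 0) {
    stop("scale_factor must be > 0", call. = FALSE)
  }
  x <- gray$values * scale_factor
  x <- sign(x) * floor(abs(x) + 0.5)  # round half away from zero
  x <- pmin(pmax(x, -32768), 32767)
  quantized_volume(array(as.integer(x), dim(gray$values)), gray$voxel_edge_um)
}

#' Threshold segmentation into pore and solid
#'
#' Voxels with quantized value strictly greater than `threshold` are solid
#' (the denser carbon phase is brighter after reconstruction); all other
#' voxels are pore. The returned mask uses `TRUE` = pore.
#'
#' @param quant A [quantized_volume()].
#' @param threshold Integer threshold; default 8.
#' @return A [binary_volume()].
#' @export
segment <- function(quant, threshold = 8) {
  stopifnot(inherits(quant, "quantized_volume"))
  binary_volume(quant$values <= threshold, quant$voxel_edge_um)
}

#' Keep only the largest connected solid component
#'
#' All solid voxels outside the largest connected group of solid voxels are
#' reassigned to pore, removing isolated specks of apparent solid (noise or
#' debris) so that the retained solid represents one connected matrix. Pore
#' voxels are never modified. Components are compared by voxel count; an
#' exact tie is broken deterministically in favor of the component containing
#' the earliest voxel in array scan order.
#'
#' @param binary A [binary_volume()] (`TRUE` = pore).
#' @param connectivity Solid-phase neighborhood rule, 6 (faces) or
#'   26 (faces, edges and vertices; the default).
#' @return A [binary_volume()] with at most one solid component.
#' @export
retain_largest_solid <- function(binary, connectivity = 26) {
  stopifnot(inherits(binary, "binary_volume"))
  solid <- !binary$mask
  if (!any(solid)) {
    stop("no solid voxels: cannot identify a largest solid component",
         call. = FALSE)
  }
  labels <- label_components_cpp(as.vector(solid), dim(solid),
                                 as.integer(connectivity))
  sizes <- tabulate(labels)
  keep <- which.max(sizes)  # first maximum = earliest in scan order
  pore <- array(labels != keep, dim(solid))
  binary_volume(pore, binary$voxel_edge_um)
}

#' Crop a centered cubic region of interest
#'
#' Extracts a cube of side `roi_edge_vox` centered in the volume; with an odd
#' remainder the start index per axis is `floor((dim - edge) / 2)` (0-based),
#' i.e. the cube sits half a voxel toward the origin.
#'
#' @param binary A [binary_volume()].
#' @param roi_edge_vox Cube edge in voxels; must not exceed any dimension.
#' @return The cropped [binary_volume()].
#' @export
crop_center_roi <- function(binary, roi_edge_vox) {
  stopifnot(inherits(binary, "binary_volume"))
  d <- dim(binary$mask)
  e <- as.integer(roi_edge_vox)
  if (e < 1 || any(e > d)) {
    stop("roi_edge_vox must be in [1, min(dim)]", call. = FALSE)
  }
  start <- floor((d - e) / 2) + 1L  # 1-based
  binary_volume(binary$mask[start[1]:(start[1] + e - 1L),
                            start[2]:(start[2] + e - 1L),
                            start[3]:(start[3] + e - 1L), drop = FALSE],
                binary$voxel_edge_um)
}
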