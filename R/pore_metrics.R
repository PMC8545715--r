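#' Label connected pore components
#'
#' Connected-component labelling of the pore phase under a 6- or
#' 26-neighborhood. Labels are dense (1..K) and assigned in array scan order
#' of each component's first voxel, so labelling is deterministic.
#'
#' @param binary A [binary_volume()] (`TRUE` = pore).
#' @param connectivity 6 or 26 (default 26).
#' @return A `pore_label_field`: list with `labels` (3D integer array, 0 =
#'   solid), `volumes` (per-label voxel counts), `connectivity`, and
#'   `voxel_edge_um`.
#' @export
label_pores <- function(binary, connectivity = 26) {
  stopifnot(inherits(binary, "binary_volume"))
  if (!(connectivity %in% c(6, 26))) {
    stop("connectivity must be 6 or 26", call. = FALSE)
  }
  lab <- label_components_cpp(as.vector(binary$mask), dim(binary$mask),
                              as.integer(connectivity))
  K <- max(lab)
  volumes <- if (K == 0) numeric(0) else tabulate(lab, nbins = K)
  structure(list(labels = array(lab, dim(binary$mask)),
                 volumes = as.numeric(volumes),
                 connectivity = connectivity,
                 voxel_edge_um = binary$voxel_edge_um),
            class = "pore_label_field")
}

#' @export
print.pore_label_field <- function(x, ...) {
  cat(sprintf("pore_label_field: %d pores, %s pore voxels, connectivity %d\n",
              length(x$volumes), format(sum(x$volumes), big.mark = ","),
              x$connectivity))
  invisible(x)
}

#' Total porosity with a minimum pore size rule
#'
#' Fraction of ROI voxels belonging to pores of at least `min_volume_vox`
#' voxels. The default of 4 voxels discards components too small to be
#' resolved reliably at the scan resolution.
#'
#' @param labels A `pore_label_field` from [label_pores()].
#' @param min_volume_vox Minimum pore volume in voxels (default 4).
#' @return Porosity fraction in \[0, 1\].
#' @export
total_porosity <- function(labels, min_volume_vox = 4) {
  stopifnot(inherits(labels, "pore_label_field"), min_volume_vox >= 1)
  keep <- labels$volumes[labels$volumes >= min_volume_vox]
  sum(keep) / length(labels$labels)
}

#' Volume fraction of the largest pore (connectivity indicator)
#'
#' Ratio of the largest pore component's volume to the total pore volume
#' (all pores, no size filter). Values near 1 indicate that essentially all
#' pore space forms one connected network.
#'
#' @param labels A `pore_label_field`.
#' @return Fraction in (0, 1\].
#' @export
largest_pore_fraction <- function(labels) {
  stopifnot(inherits(labels, "pore_label_field"))
  if (length(labels$volumes) == 0) {
    stop("no pore components present", call. = FALSE)
  }
  max(labels$volumes) / sum(labels$volumes)
}

#' 3D perimeter (surface) voxel count of a pore mask
#'
#' Counts pore voxels having at least one face-adjacent (6-neighborhood)
#' neighbor that is not pore; the volume boundary counts as non-pore. This is
#' the 3D analogue of a 2D perimeter count on a binary image.
#'
#' @param mask 3D logical array of one pore (`TRUE` = pore voxel).
#' @return Perimeter voxel count.
#' @export
pore_surface_area <- function(mask) {
  check_dim3(mask, "mask")
  if (!any(mask)) stop("empty pore mask", call. = FALSE)
  perimeter_count_cpp(as.vector(mask), dim(mask))
}

#' Surface-area-to-volume ratio of a pore
#'
#' Perimeter voxel count divided by pore voxel count; dimensionless in voxel
#' units. Large values indicate a convoluted, far-from-spherical pore.
#'
#' @param mask 3D logical array of one pore.
#' @return Dimensionless ratio.
#' @export
surface_to_volume <- function(mask) {
  pore_surface_area(mask) / sum(mask)
}

#' Surface-to-volume ratio of the volume-equivalent sphere
#'
#' For a continuum sphere of the same volume (in voxel units), SA/V = 3/r
#' with r = (3 V / 4 pi)^(1/3). Used as the compactness baseline against
#' which measured pore SA/V is compared.
#'
#' @param volume_vox Pore volume in voxels, > 0.
#' @return Dimensionless ratio.
#' @export
sphere_equiv_sa_v <- function(volume_vox) {
  if (!is.numeric(volume_vox) || any(volume_vox <= 0)) {
    stop("volume_vox must be > 0", call. = FALSE)
  }
  r <- (3 * volume_vox / (4 * pi))^(1 / 3)
  3 / r
}

#' Convert voxel counts to physical volume
#'
#' @param voxels Voxel count (>= 0).
#' @param voxel_edge_um Voxel edge length in micrometers.
#' @return Volume in cubic millimeters.
#' @examples
#' physical_volume(1024^3, 0.87)  # ~0.707 mm^3
#' @export
physical_volume <- function(voxels, voxel_edge_um) {
  stopifnot(voxel_edge_um > 0)
  voxels * (voxel_edge_um * 1e-3)^3
}

#' Equivalent cube width of a pore volume
#'
#' Side length, in micrometers, of the cube with the same voxel volume:
#' a 43-voxel pore at 0.87 um voxels has an equivalent width of about 3 um.
#'
#' @param volume_vox Pore volume in voxels (>= 0).
#' @param voxel_edge_um Voxel edge length in micrometers.
#' @return Width in micrometers.
#' @export
equivalent_cube_width <- function(volume_vox, voxel_edge_um) {
  stopifnot(volume_vox >= 0, voxel_edge_um > 0)
  volume_vox^(1 / 3) * voxel_edge_um
}

#' Pore-network metrics of a binary ROI
#'
#' Computes the per-sample summary of the pore network: total porosity under
#' the minimum-size rule, largest-pore volume fraction (connectivity
#' indicator), largest-pore physical volume, measured and sphere-equivalent
#' surface-to-volume ratios of the largest pore, pore count, and the
#' fraction of non-largest pores below a small-pore volume cutoff.
#'
#' @param binary A [binary_volume()] ROI.
#' @param connectivity Pore-phase neighborhood rule (default 26).
#' @param min_volume_vox Minimum pore volume for total porosity (default 4).
#' @param small_pore_cutoff_vox Volume cutoff (voxels) for the isolated
#'   small-pore fraction (default 43, about a 3 um equivalent width at
#'   0.87 um voxels).
#' @return A `pore_metrics` list.
#' @export
pore_metrics <- function(binary, connectivity = 26, min_volume_vox = 4,
                         small_pore_cutoff_vox = 43) {
  stopifnot(inherits(binary, "binary_volume"))
  labels <- label_pores(binary, connectivity)
  if (length(labels$volumes) == 0) {
    stop("no pore components present", call. = FALSE)
  }
  largest <- which.max(labels$volumes)
  largest_mask <- labels$labels == largest
  non_largest <- labels$volumes[-largest]
  res <- list(
    total_porosity = total_porosity(labels, min_volume_vox),
    largest_pore_fraction = largest_pore_fraction(labels),
    largest_pore_volume_vox = labels$volumes[largest],
    largest_pore_volume_mm3 = physical_volume(labels$volumes[largest],
                                              binary$voxel_edge_um),
    largest_pore_sa_v = surface_to_volume(largest_mask),
    sphere_equiv_sa_v = sphere_equiv_sa_v(labels$volumes[largest]),
    n_pores = length(labels$volumes),
    isolated_small_pore_fraction = if (length(non_largest) > 0) {
      mean(non_largest < small_pore_cutoff_vox)
    } else NaN,
    connectivity = connectivity,
    min_volume_vox = min_volume_vox,
    small_pore_cutoff_vox = small_pore_cutoff_vox,
    voxel_edge_um = binary$voxel_edge_um
  )
  structure(res, class = "pore_metrics")
}

#' @export
print.pore_metrics <- function(x, ...) {
  cat("pore_metrics\n")
  cat(sprintf("  total porosity (>= %d vox):    %.4f\n",
              x$min_volume_vox, x$total_porosity))
  cat(sprintf("  largest-pore fraction:        %.4f\n",
              x$largest_pore_fraction))
  cat(sprintf("  largest-pore volume:          %.4g mm^3\n",
              x$largest_pore_volume_mm3))
  cat(sprintf("  largest-pore SA/V:            %.4f\n", x$largest_pore_sa_v))
  cat(sprintf("  sphere-equivalent SA/V:       %.5f\n", x$sphere_equiv_sa_v))
  cat(sprintf("  pores: %d; small-pore fraction (< %d vox): %.3f\n",
              x$n_pores, x$small_pore_cutoff_vox,
              x$isolated_small_pore_fraction))
  invisible(x)
}
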