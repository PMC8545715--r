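#' Synthetic porous-media phantom specification
#'
#' Describes a synthetic binary volume standing in for a segmented
#' microtomography scan. Two structures are supported: `"fragment_pack"`, a
#' packing of overlapping randomly oriented solid ellipsoids emulating the
#' disarranged wood-fragment morphology of pelletized char (approximately
#' isotropic), and `"tube_array"`, a solid block pierced by parallel
#' cylindrical pores on a regular grid, mimicking the strongly anisotropic
#' tracheid lumina of raw wood.
#'
#' @param shape Integer vector of 3 axis sizes (voxels), each >= 8.
#' @param target_porosity Pore-voxel fraction aimed for, in \[0, 1\]
#'   (`fragment_pack` only; default 0.577, the porosity regime of
#'   softwood-pellet char).
#' @param structure `"fragment_pack"` or `"tube_array"`.
#' @param tube_axis Axis (1, 2 or 3) the tubes run along (`tube_array`).
#' @param tube_radius_vox,tube_spacing_vox Tube radius and center-to-center
#'   spacing, in voxels; requires `tube_radius_vox < tube_spacing_vox / 2`.
#' @param fragment_size_vox Characteristic fragment diameter in voxels
#'   (`fragment_pack`; default 16, i.e. ~14 um at 0.87 um voxels, the scale
#'   of milled wood fragment features).
#' @param seed Integer seed controlling all random draws.
#' @param voxel_edge_um Voxel edge length in micrometers.
#' @return A `phantom_spec` list, validated.
#' @export
phantom_spec <- function(shape,
                         structure = c("fragment_pack", "tube_array"),
                         target_porosity = 0.577,
                         tube_axis = 3,
                         tube_radius_vox = 4,
                         tube_spacing_vox = 16,
                         fragment_size_vox = 16,
                         seed = 1,
                         voxel_edge_um = 0.87) {
  structure_type <- match.arg(structure)
  shape <- as.integer(shape)
  if (length(shape) != 3 || any(shape < 8)) {
    stop("shape must be 3 integers, each >= 8", call. = FALSE)
  }
  if (!is.numeric(target_porosity) || target_porosity < 0 ||
      target_porosity > 1) {
    stop("target_porosity must be in [0, 1]", call. = FALSE)
  }
  if (structure_type == "tube_array") {
    if (!(tube_axis %in% 1:3)) stop("tube_axis must be 1, 2 or 3", call. = FALSE)
    if (tube_radius_vox <= 0 || tube_spacing_vox <= 0 ||
        tube_radius_vox >= tube_spacing_vox / 2) {
      stop("need 0 < tube_radius_vox < tube_spacing_vox / 2", call. = FALSE)
    }
  } else {
    if (fragment_size_vox <= 0) stop("fragment_size_vox must be > 0", call. = FALSE)
  }
  base::structure(
    list(shape = shape, structure = structure_type,
         target_porosity = target_porosity, tube_axis = tube_axis,
         tube_radius_vox = tube_radius_vox,
         tube_spacing_vox = tube_spacing_vox,
         fragment_size_vox = fragment_size_vox, seed = as.integer(seed),
         voxel_edge_um = voxel_edge_um),
    class = "phantom_spec")
}

# Rasterize one solid ellipsoid into the logical `solid` array (TRUE = solid).
# center: length-3 numeric; semi: length-3 semi-axes; rot: 3x3 rotation.
add_ellipsoid <- function(solid, center, semi, rot) {
  d <- dim(solid)
  rmax <- max(semi)
  lo <- pmax(1L, floor(center - rmax))
  hi <- pmin(d, ceiling(center + rmax))
  if (any(lo > hi)) return(solid)
  xs <- lo[1]:hi[1]; ys <- lo[2]:hi[2]; zs <- lo[3]:hi[3]
  g <- as.matrix(expand.grid(x = xs, y = ys, z = zs))
  rel <- sweep(g, 2, center) %*% rot
  inside <- (rel[, 1] / semi[1])^2 + (rel[, 2] / semi[2])^2 +
    (rel[, 3] / semi[3])^2 <= 1
  if (any(inside)) {
    idx <- g[inside, , drop = FALSE]
    solid[idx[, 1] + d[1] * (idx[, 2] - 1L) +
            d[1] * d[2] * (idx[, 3] - 1L)] <- TRUE
  }
  solid
}

random_rotation <- function() {
  # QR of a Gaussian matrix gives a Haar-distributed orthogonal matrix
  m <- matrix(rnorm(9), 3, 3)
  qr_ <- qr(m)
  q <- qr.Q(qr_)
  q * rep(sign(diag(qr.R(qr_))), each = 3)
}

#' Generate a synthetic binary phantom volume
#'
#' For `fragment_pack`, solid ellipsoids with random centers, sizes and
#' orientations are deposited until the solid fraction reaches
#' `1 - target_porosity`; the stopping rule makes the achieved porosity exact
#' only to within about +/- 0.02. For `tube_array`, a fully solid block is
#' pierced by parallel cylindrical pores along `tube_axis` on a regular grid
#' with the given radius and spacing. Output is reproducible for a fixed seed.
#'
#' @param spec A [phantom_spec()].
#' @return A [binary_volume()] (`TRUE` = pore).
#' @examples
#' ph <- generate_phantom(phantom_spec(c(32, 32, 32), "tube_array"))
#' mean(ph$mask)  # ~ pi * r^2 / spacing^2
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$shape
  if (spec$structure == "tube_array") {
    s <- spec$tube_spacing_vox
    r <- spec$tube_radius_vox
    perp <- setdiff(1:3, spec$tube_axis)
    n1 <- d[perp[1]]; n2 <- d[perp[2]]
    c1 <- seq(s / 2, n1, by = s)
    c2 <- seq(s / 2, n2, by = s)
    u <- matrix(seq_len(n1), n1, n2)
    v <- matrix(seq_len(n2), n1, n2, byrow = TRUE)
    disk <- matrix(FALSE, n1, n2)
    for (a in c1) for (b in c2) {
      disk <- disk | ((u - a)^2 + (v - b)^2 <= r^2)
    }
    # replicate the disk pattern along the tube axis, then permute axes back
    ord <- c(perp, spec$tube_axis)
    arr <- array(disk, dim = c(n1, n2, d[spec$tube_axis]))
    mask <- aperm(arr, match(1:3, ord))
    return(binary_volume(mask, spec$voxel_edge_um))
  }
  # fragment_pack
  target_solid <- 1 - spec$target_porosity
  solid <- array(FALSE, d)
  n_total <- prod(d)
  if (target_solid > 0) {
    solid <- with_local_seed(spec$seed, {
      base_r <- spec$fragment_size_vox / 2
      max_iter <- 50 * ceiling(target_solid * n_total /
                                 (4 / 3 * pi * base_r^3) + 1)
      it <- 0
      while (sum(solid) / n_total < target_solid && it < max_iter) {
        it <- it + 1
        center <- runif(3, min = 1, max = d)
        semi <- base_r * runif(3, 0.5, 1.5)
        solid <- add_ellipsoid(solid, center, semi, random_rotation())
      }
      if (sum(solid) / n_total < target_solid - 0.02) {
        stop("fragment deposition failed to reach target solid fraction",
             call. = FALSE)
      }
      solid
    })
  }
  binary_volume(!solid, spec$voxel_edge_um)
}

#' Render a binary phantom as a noisy grayscale volume
#'
#' Emulates phase-retrieved reconstruction contrast: solid voxels take
#' `solid_level`, pore voxels `pore_level`, plus i.i.d. Gaussian noise. The
#' defaults are chosen so that the standard quantization (x 100,000) maps
#' solid to ~20 quantized units, safely above the segmentation threshold of 8.
#'
#' @param binary A [binary_volume()] (`TRUE` = pore).
#' @param solid_level,pore_level Intensity levels; must satisfy
#'   `solid_level > pore_level` (denser carbon is brighter).
#' @param noise_sd Gaussian noise standard deviation, `>= 0`.
#' @param seed Integer seed for the noise draw.
#' @return A [grayscale_volume()].
#' @export
render_grayscale <- function(binary, solid_level = 2e-4, pore_level = 0,
                             noise_sd = 0, seed = 1) {
  stopifnot(inherits(binary, "binary_volume"))
  if (!is.numeric(noise_sd) || noise_sd < 0) {
    stop("noise_sd must be >= 0", call. = FALSE)
  }
  if (solid_level <= pore_level) {
    stop("solid_level must exceed pore_level", call. = FALSE)
  }
  vals <- ifelse(binary$mask, pore_level, solid_level)
  vals <- array(vals, dim(binary$mask))
  if (noise_sd > 0) {
    vals <- vals + with_local_seed(seed, array(rnorm(length(vals), 0, noise_sd),
                                               dim(vals)))
  }
  grayscale_volume(vals, binary$voxel_edge_um)
}
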