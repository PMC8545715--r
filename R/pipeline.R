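#' Pipeline configuration
#'
#' Bundles every parameter of the analysis chain. Defaults are the reference
#' values of the workflow this package implements: quantization scale
#' 100,000; segmentation threshold 8; 26-neighborhood for both phases;
#' minimum pore volume 4 voxels; moment orders -9..9; dyadic levels 1..10;
#' R-squared acceptance 0.9; voxel edge 0.87 um.
#'
#' @param input A [phantom_spec()] or a path to a TIFF stack (file or
#'   directory of slices).
#' @param sample_id Free-form sample label.
#' @param group Free-form group label (e.g. production temperature).
#' @param scale_factor Quantization multiplier.
#' @param threshold Segmentation threshold (strict `>` selects solid).
#' @param solid_connectivity Neighborhood rule for solid-component retention.
#' @param pore_connectivity Neighborhood rule for pore labelling.
#' @param roi_edge_vox Centered ROI cube edge; `NULL` = no crop.
#' @param min_volume_vox Minimum pore volume for total porosity.
#' @param q_grid Moment orders for multifractal analysis.
#' @param k_range Dyadic levels; `NULL` = `1:min(10, log2(L))`.
#' @param r2_threshold R-squared acceptance threshold.
#' @param voxel_edge_um Voxel edge length in micrometers.
#' @param render_noise_sd For phantom inputs: Gaussian noise added when the
#'   phantom is passed through the grayscale/quantize/segment chain (default
#'   `1e-5`; set `NULL` to skip rendering and analyze the phantom mask
#'   directly).
#' @param homogeneity_threshold Max spectrum width still called homogeneous.
#' @param isotropy_threshold Max pairwise descriptor difference still called
#'   isotropic.
#' @param out_dir Output directory for artifacts; `NULL` = return only.
#' @param seed Integer seed for all stochastic stages.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(input, sample_id = "sample", group = "default",
                            scale_factor = 1e5, threshold = 8,
                            solid_connectivity = 26, pore_connectivity = 26,
                            roi_edge_vox = NULL, min_volume_vox = 4,
                            q_grid = -9:9, k_range = NULL, r2_threshold = 0.9,
                            voxel_edge_um = 0.87, render_noise_sd = 1e-5,
                            homogeneity_threshold = 0.15,
                            isotropy_threshold = 0.1,
                            out_dir = NULL, seed = 1) {
  structure(list(input = input, sample_id = sample_id, group = group,
                 scale_factor = scale_factor, threshold = threshold,
                 solid_connectivity = solid_connectivity,
                 pore_connectivity = pore_connectivity,
                 roi_edge_vox = roi_edge_vox, min_volume_vox = min_volume_vox,
                 q_grid = q_grid, k_range = k_range,
                 r2_threshold = r2_threshold, voxel_edge_um = voxel_edge_um,
                 render_noise_sd = render_noise_sd,
                 homogeneity_threshold = homogeneity_threshold,
                 isotropy_threshold = isotropy_threshold,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "pipeline_config")
}

config_manifest <- function(config) {
  m <- unclass(config)
  if (inherits(m$input, "phantom_spec")) {
    m$input <- c(list(kind = "phantom"), unclass(m$input))
  } else {
    m$input <- list(kind = "tiff", path = m$input)
  }
  m$package_version <- as.character(utils::packageVersion("poretomo"))
  m
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Run the full pore-structure analysis pipeline on one sample
#'
#' Chains input acquisition (phantom generation or TIFF ingestion),
#' segmentation (quantize, threshold, largest-solid retention, centered ROI
#' crop), pore-network metrics, per-axis frequency curves, and per-axis
#' multifractal analysis, and summarizes cross-axis homogeneity/isotropy.
#' When `out_dir` is set, all artifacts plus a manifest holding every
#' parameter and seed are written there; a rerun from the manifest is
#' bit-identical.
#'
#' @param config A [pipeline_config()].
#' @return A `pipeline_report`: list with `metrics` ([pore_metrics()]),
#'   `curves` (3 frequency curves), `spectra` (3 spectra), `isotropy`
#'   (see details), and `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  binary <- run_stage("input", {
    if (inherits(config$input, "phantom_spec")) {
      ph <- generate_phantom(config$input)
      if (!is.null(config$render_noise_sd)) {
        gray <- render_grayscale(ph, noise_sd = config$render_noise_sd,
                                 seed = config$seed + 1L)
        seg <- segment(quantize(gray, config$scale_factor), config$threshold)
        if (any(!seg$mask)) {
          seg <- retain_largest_solid(seg, config$solid_connectivity)
        }
        seg
      } else {
        ph
      }
    } else {
      vol <- read_volume(config$input, config$voxel_edge_um)
      if (inherits(vol, "binary_volume")) {
        vol
      } else {
        if (inherits(vol, "grayscale_volume")) {
          vol <- quantize(vol, config$scale_factor)
        }
        seg <- segment(vol, config$threshold)
        retain_largest_solid(seg, config$solid_connectivity)
      }
    }
  })
  if (!is.null(config$roi_edge_vox)) {
    binary <- run_stage("crop", crop_center_roi(binary, config$roi_edge_vox))
  }
  metrics <- run_stage("metrics",
                       pore_metrics(binary, config$pore_connectivity,
                                    config$min_volume_vox))
  curves <- lapply(1:3, function(a) {
    run_stage(paste0("curve_axis", a), pore_frequency_curve(binary, a))
  })
  spectra <- lapply(1:3, function(a) {
    run_stage(paste0("mfa_axis", a),
              run_multifractal(curves[[a]], config$q_grid, config$k_range,
                               config$r2_threshold))
  })
  isotropy <- run_stage("isotropy",
                        isotropy_report(curves, spectra,
                                        config$homogeneity_threshold,
                                        config$isotropy_threshold))
  manifest <- config_manifest(config)
  manifest$n_multifractal_analyses <- length(spectra)
  report <- structure(list(sample_id = config$sample_id, group = config$group,
                           metrics = metrics, curves = curves,
                           spectra = spectra, isotropy = isotropy,
                           manifest = manifest),
                      class = "pipeline_report")
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

# Descriptors feeding the isotropy verdict. The asymmetry A is reported but
# deliberately excluded: as a ratio of two spectrum-width differences it is
# ill-conditioned when the spectrum degenerates toward a point (the
# monofractal case), where tiny absolute fluctuations flip A by O(1).
descriptor_vector <- function(d) {
  c(delta_alpha = d$delta_alpha, D0_D2 = d$D0_D2,
    Dqmin_Dqmax = d$Dqmin_Dqmax)
}

#' Cross-axis homogeneity and isotropy summary
#'
#' Compares the three per-axis spectra and frequency curves. The sample is
#' called homogeneous when every axis' spectrum width (delta alpha) is below
#' `homogeneity_threshold`, and isotropic when the maximum pairwise absolute
#' difference of the shape descriptors (delta alpha, D0 - D2, Dqmin - Dqmax;
#' non-finite values are skipped) is below `isotropy_threshold`. The
#' asymmetry A is reported but not thresholded, because it is numerically
#' unstable for near-degenerate (monofractal) spectra. Both thresholds are
#' descriptive tool settings, not inferential tests.
#'
#' @param curves List of 3 frequency curves (axes 1..3).
#' @param spectra List of 3 `multifractal_spectrum` objects.
#' @param homogeneity_threshold,isotropy_threshold Verdict thresholds.
#' @return An `isotropy_report` list.
#' @export
isotropy_report <- function(curves, spectra, homogeneity_threshold = 0.15,
                            isotropy_threshold = 0.1) {
  stopifnot(length(curves) == 3, length(spectra) == 3)
  desc <- lapply(spectra, function(s) s$descriptors)
  if (any(vapply(desc, is.null, logical(1)))) {
    stop("spectrum descriptors unavailable on some axis (q = 0 rejected)",
         call. = FALSE)
  }
  curve_summary <- t(vapply(curves, function(cv) {
    rng <- slice_porosity_range(cv)
    c(mean_count = mean(cv$counts), sd_count = sd(cv$counts),
      min_slice_porosity = rng[["min"]], max_slice_porosity = rng[["max"]])
  }, numeric(4)))
  rownames(curve_summary) <- paste0("axis", 1:3)
  dv <- vapply(desc, descriptor_vector, numeric(3))
  pairs <- combn(3, 2)
  pair_diffs <- apply(pairs, 2, function(p) abs(dv[, p[1]] - dv[, p[2]]))
  colnames(pair_diffs) <- apply(pairs, 2, paste, collapse = "-")
  widths <- vapply(desc, function(d) d$delta_alpha, numeric(1))
  finite_diffs <- pair_diffs[is.finite(pair_diffs)]
  structure(list(
    descriptors = desc,
    curve_summary = curve_summary,
    pairwise_descriptor_diffs = pair_diffs,
    max_pairwise_diff = if (length(finite_diffs)) max(finite_diffs) else NA_real_,
    delta_alpha = widths,
    homogeneous = all(widths < homogeneity_threshold),
    isotropic = length(finite_diffs) > 0 &&
      max(finite_diffs) < isotropy_threshold,
    homogeneity_threshold = homogeneity_threshold,
    isotropy_threshold = isotropy_threshold
  ), class = "isotropy_report")
}

#' @export
print.isotropy_report <- function(x, ...) {
  cat("isotropy_report\n")
  cat(sprintf("  delta_alpha per axis: %s\n",
              paste(sprintf("%.4f", x$delta_alpha), collapse = ", ")))
  cat(sprintf("  max pairwise descriptor difference: %.4f\n",
              x$max_pairwise_diff))
  cat(sprintf("  homogeneous: %s (threshold %.3g); isotropic: %s (threshold %.3g)\n",
              x$homogeneous, x$homogeneity_threshold,
              x$isotropic, x$isotropy_threshold))
  invisible(x)
}

metrics_record <- function(report) {
  m <- report$metrics
  data.frame(sample = report$sample_id, group = report$group,
             total_porosity = m$total_porosity,
             largest_pore_fraction = m$largest_pore_fraction,
             largest_pore_volume_mm3 = m$largest_pore_volume_mm3,
             largest_pore_sa_v = m$largest_pore_sa_v,
             sphere_equiv_sa_v = m$sphere_equiv_sa_v)
}

write_report <- function(report, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  jsonlite::write_json(report$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  m <- report$metrics
  jsonlite::write_json(unclass(m), file.path(out_dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA)
  for (a in 1:3) {
    write_frequency_curve(report$curves[[a]],
                          file.path(out_dir, sprintf("curve_axis%d.csv", a)))
    write_spectrum(report$spectra[[a]],
                   file.path(out_dir, sprintf("spectrum_axis%d.csv", a)))
    jsonlite::write_json(report$spectra[[a]]$descriptors,
                         file.path(out_dir,
                                   sprintf("descriptors_axis%d.json", a)),
                         auto_unbox = TRUE, digits = NA)
  }
  iso <- report$isotropy
  jsonlite::write_json(
    list(delta_alpha = iso$delta_alpha,
         max_pairwise_diff = iso$max_pairwise_diff,
         homogeneous = iso$homogeneous, isotropic = iso$isotropic,
         homogeneity_threshold = iso$homogeneity_threshold,
         isotropy_threshold = iso$isotropy_threshold),
    file.path(out_dir, "isotropy.json"), auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("pipeline_report for sample '%s' (group '%s')\n",
              x$sample_id, x$group))
  print(x$metrics)
  print(x$isotropy)
  invisible(x)
}

#' Aggregate per-sample metrics into a cohort summary
#'
#' Computes arithmetic means and sample standard deviations (n - 1) of each
#' numeric metric, overall and per group. Accepts either a list of
#' `pipeline_report` / `pore_metrics`-like records or a data frame with one
#' row per sample (columns: `sample`, `group`, then numeric metrics). With a
#' single sample the standard deviation is reported as `NaN`.
#'
#' @param reports List of `pipeline_report` objects, or a data frame.
#' @return List with `n`, `overall` (data frame: metric, mean, sd) and
#'   `by_group` (data frame: group, metric, mean, sd).
#' @export
aggregate_samples <- function(reports) {
  df <- if (is.data.frame(reports)) {
    reports
  } else if (is.list(reports) && length(reports) > 0) {
    do.call(rbind, lapply(reports, metrics_record))
  } else {
    stop("reports must be a non-empty list or data frame", call. = FALSE)
  }
  if (nrow(df) == 0) stop("no samples to aggregate", call. = FALSE)
  num_cols <- names(df)[vapply(df, is.numeric, logical(1))]
  safe_sd <- function(x) if (length(x) < 2) NaN else sd(x)
  overall <- data.frame(
    metric = num_cols,
    mean = vapply(num_cols, function(cn) mean(df[[cn]]), numeric(1)),
    sd = vapply(num_cols, function(cn) safe_sd(df[[cn]]), numeric(1)),
    row.names = NULL)
  by_group <- NULL
  if ("group" %in% names(df)) {
    by_group <- do.call(rbind, lapply(split(df, df$group), function(g) {
      data.frame(group = g$group[1], metric = num_cols,
                 mean = vapply(num_cols, function(cn) mean(g[[cn]]), numeric(1)),
                 sd = vapply(num_cols, function(cn) safe_sd(g[[cn]]), numeric(1)),
                 row.names = NULL)
    }))
    rownames(by_group) <- NULL
  }
  list(n = nrow(df), overall = overall, by_group = by_group)
}
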