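test_that("quantize scales, rounds half away from zero, and clips", {
  g <- grayscale_volume(array(c(1e-4, 0, 1, -1, 8.5e-5, -8.5e-5, 4.9e-6, 0),
                              c(2, 2, 2)))
  q <- quantize(g)
  expect_identical(as.vector(q$values)[1:7],
                   c(10L, 0L, 32767L, -32768L, 9L, -9L, 0L))
  expect_error(quantize(g, scale_factor = 0), "scale_factor")
})

test_that("segment uses a strict greater-than rule, solid above threshold", {
  q9 <- quantized_volume(array(9L, c(4, 4, 4)))
  expect_equal(mean(segment(q9, 8)$mask), 0)   # all solid
  q8 <- quantized_volume(array(8L, c(4, 4, 4)))
  expect_equal(mean(segment(q8, 8)$mask), 1)   # boundary value is pore
})

test_that("retain_largest_solid keeps exactly the biggest solid component", {
  # two solid blobs of very different size: small one becomes pore
  mask <- array(TRUE, c(12, 12, 12))           # all pore
  mask[2:6, 2:6, 2:6] <- FALSE                 # 125-voxel solid blob
  mask[10:11, 10:11, 10] <- FALSE              # 4-voxel solid blob
  bv <- binary_volume(mask)
  out <- retain_largest_solid(bv)
  expect_equal(sum(!out$mask), 125)
  expect_true(all(out$mask[10:11, 10:11, 10]))
  # pore voxels are never modified
  expect_true(all(out$mask[bv$mask]))
  # idempotence and no increase of solid count
  expect_identical(retain_largest_solid(out)$mask, out$mask)
  expect_lte(sum(!out$mask), sum(!bv$mask))
  # single connected solid: identity
  one <- array(TRUE, c(6, 6, 6)); one[2:3, 2:3, 2:3] <- FALSE
  bv1 <- binary_volume(one)
  expect_identical(retain_largest_solid(bv1)$mask, bv1$mask)
  # equal-size blobs: the one with the earliest scan-order voxel is kept
  tie <- array(TRUE, c(10, 10, 10))
  tie[2:3, 2:3, 2:3] <- FALSE                  # 8 voxels, starts earlier
  tie[7:8, 7:8, 7:8] <- FALSE                  # 8 voxels
  kept <- retain_largest_solid(binary_volume(tie))
  expect_true(all(!kept$mask[2:3, 2:3, 2:3]))
  expect_true(all(kept$mask[7:8, 7:8, 7:8]))
  # degenerate input
  expect_error(retain_largest_solid(binary_volume(array(TRUE, c(4, 4, 4)))),
               "no solid")
})

test_that("crop_center_roi centers with the floor rule", {
  m <- array(FALSE, c(10, 10, 10)); m[1, 1, 1] <- TRUE
  expect_identical(crop_center_roi(binary_volume(m), 10)$mask, m)
  # 11^3 volume, edge 10: start index 0 (0-based), so voxel [1,1,1] survives
  m11 <- array(FALSE, c(11, 11, 11)); m11[1, 1, 1] <- TRUE
  cr <- crop_center_roi(binary_volume(m11), 10)
  expect_equal(dim(cr$mask), c(10, 10, 10))
  expect_true(cr$mask[1, 1, 1])
  # 12^3, edge 10: start index 1, voxel [2,2,2] maps to [1,1,1]
  m12 <- array(FALSE, c(12, 12, 12)); m12[2, 2, 2] <- TRUE
  expect_true(crop_center_roi(binary_volume(m12), 10)$mask[1, 1, 1])
  expect_error(crop_center_roi(binary_volume(m), 11), "roi_edge_vox")
  # porosity equals pore voxels / edge^3
  fp <- fragment_phantom_64(seed = 1)
  roi <- crop_center_roi(fp, 32)
  expect_equal(mean(roi$mask), sum(roi$mask) / 32^3)
  expect_gte(mean(roi$mask), 0); expect_lte(mean(roi$mask), 1)
})

test_that("1024^3 voxels at 0.87 um correspond to about 0.707 mm^3", {
  expect_equal(physical_volume(1024^3, 0.87), 0.707, tolerance = 0.001)
})

test_that("TIFF volumes round-trip bit-exactly for all three dtypes", {
  dir <- withr::local_tempdir()
  # float32: use float-exact values (dyadic rationals)
  vals <- array(sample(0:1023, 16^3, replace = TRUE) / 1024, c(16, 16, 16))
  g <- grayscale_volume(vals, voxel_edge_um = 2)
  f <- file.path(dir, "g.tif")
  write_volume(g, f)
  g2 <- read_volume(f, voxel_edge_um = 2)
  expect_s3_class(g2, "grayscale_volume")
  expect_identical(g2$values, g$values)
  # int16 with negative values
  qv <- quantized_volume(array(sample(-32768:32767, 5^3), c(5, 5, 5)))
  write_volume(qv, file.path(dir, "q.tif"))
  q2 <- read_volume(file.path(dir, "q.tif"))
  expect_s3_class(q2, "quantized_volume")
  expect_identical(q2$values, qv$values)
  # binary, directory layout
  bm <- binary_volume(array(sample(c(TRUE, FALSE), 8^3, replace = TRUE),
                            c(8, 8, 8)))
  bd <- file.path(dir, "slices")
  write_volume(bm, bd, layout = "directory")
  b2 <- read_volume(bd)
  expect_s3_class(b2, "binary_volume")
  expect_identical(b2$mask, bm$mask)
})

test_that("directory slices are read in ascending filename order", {
  dir <- withr::local_tempdir()
  # five single-slice files named s000..s004, written out of order
  for (k in sample(0:4)) {
    sl <- quantized_volume(array(k * 100L, c(6, 7, 1)))
    write_volume(sl, file.path(dir, sprintf("s%03d.tif", k)))
  }
  vol <- read_volume(dir)
  expect_equal(dim(vol$values), c(6, 7, 5))
  expect_equal(vol$values[1, 1, ], (0:4) * 100L)
})

test_that("malformed stacks raise format errors", {
  dir <- withr::local_tempdir()
  write_volume(quantized_volume(array(1L, c(4, 4, 1))),
               file.path(dir, "a.tif"))
  write_volume(quantized_volume(array(1L, c(5, 5, 1))),
               file.path(dir, "b.tif"))
  expect_error(read_volume(dir), "mixed shapes")
  dir2 <- withr::local_tempdir()
  write_volume(quantized_volume(array(1L, c(4, 4, 1))),
               file.path(dir2, "a.tif"))
  write_volume(grayscale_volume(array(1, c(4, 4, 1))),
               file.path(dir2, "b.tif"))
  expect_error(read_volume(dir2), "mixed data types")
  bad <- file.path(dir, "not.tif")
  writeBin(as.raw(1:64), bad)
  expect_error(read_volume(bad), "not a TIFF")
  expect_error(read_volume(file.path(dir, "absent.tif")), "does not exist")
})

test_that("written TIFF stacks are readable by an external TIFF library", {
  skip_if_not(nzchar(Sys.which("python")))
  has_tifffile <- tryCatch({
    system2("python", c("-c", shQuote("import tifffile")), stdout = FALSE,
            stderr = FALSE) == 0
  }, error = function(e) FALSE, warning = function(w) FALSE)
  skip_if_not(has_tifffile, "python tifffile not available")
  dir <- withr::local_tempdir()
  qv <- quantized_volume(array(seq_len(4 * 5 * 3) - 40L, c(4, 5, 3)))
  f <- file.path(dir, "x.tif")
  write_volume(qv, f)
  out <- system2("python", c("-c", shQuote(paste0(
    "import tifffile, numpy as np; a = tifffile.imread('", f, "'); ",
    "print(a.shape, a.dtype, int(a.sum()))"))), stdout = TRUE)
  # tifffile reads pages as (slices, rows, cols); our slices are (rows, cols)
  expect_match(out, "\\(3, 4, 5\\) int16")
  expect_match(out, as.character(sum(qv$values)))
})
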