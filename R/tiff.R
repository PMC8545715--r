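# Minimal baseline TIFF codec: uncompressed, single-sample grayscale,
# 8-bit unsigned / 16-bit signed / 32-bit float, multi-page or one file per
# slice. No TIFF library is assumed at run time; strips are read/written with
# readBin/writeBin. This covers exactly the layouts tomography pipelines
# exchange (tifffile/ImageJ-style stacks) and nothing more.

tiff_type_size <- c(`1` = 1, `2` = 1, `3` = 2, `4` = 4, `5` = 8)

read_tiff_value <- function(con, type, count, endian) {
  # reads `count` values of the given TIFF field type at current position
  if (type == 3) {
    readBin(con, "integer", n = count, size = 2, signed = FALSE,
            endian = endian)
  } else if (type == 4) {
    readBin(con, "integer", n = count, size = 4, endian = endian)
  } else if (type %in% c(1, 2)) {
    readBin(con, "integer", n = count, size = 1, signed = FALSE,
            endian = endian)
  } else {
    stop("unsupported TIFF field type: ", type, call. = FALSE)
  }
}

read_tiff_pages <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readChar(con, 2, useBytes = TRUE)
  endian <- if (identical(magic, "II")) "little" else if (identical(magic, "MM")) "big" else
    stop("not a TIFF file: ", path, call. = FALSE)
  forty_two <- readBin(con, "integer", size = 2, signed = FALSE, endian = endian)
  if (forty_two != 42) stop("not a TIFF file: ", path, call. = FALSE)
  ifd_offset <- readBin(con, "integer", size = 4, endian = endian)
  pages <- list()
  while (ifd_offset != 0) {
    seek(con, ifd_offset)
    n_entries <- readBin(con, "integer", size = 2, signed = FALSE,
                         endian = endian)
    tags <- list()
    for (i in seq_len(n_entries)) {
      tag <- readBin(con, "integer", size = 2, signed = FALSE, endian = endian)
      type <- readBin(con, "integer", size = 2, signed = FALSE, endian = endian)
      count <- readBin(con, "integer", size = 4, endian = endian)
      value_pos <- seek(con)
      total <- tiff_type_size[as.character(type)] * count
      if (is.na(total)) {
        seek(con, value_pos + 4)
        next
      }
      if (total <= 4) {
        val <- read_tiff_value(con, type, count, endian)
      } else {
        off <- readBin(con, "integer", size = 4, endian = endian)
        here <- seek(con)
        seek(con, off)
        val <- read_tiff_value(con, type, count, endian)
        seek(con, here)
      }
      seek(con, value_pos + 4)
      tags[[as.character(tag)]] <- val
    }
    ifd_offset <- readBin(con, "integer", size = 4, endian = endian)

    width <- tags[["256"]]; height <- tags[["257"]]
    if (is.null(width) || is.null(height)) {
      stop("TIFF page missing dimensions", call. = FALSE)
    }
    bits <- if (is.null(tags[["258"]])) 1 else tags[["258"]][1]
    compression <- if (is.null(tags[["259"]])) 1 else tags[["259"]]
    if (compression != 1) {
      stop("unsupported TIFF compression (only uncompressed supported)",
           call. = FALSE)
    }
    spp <- if (is.null(tags[["277"]])) 1 else tags[["277"]]
    if (spp != 1) stop("only single-sample grayscale TIFF supported", call. = FALSE)
    fmt <- if (is.null(tags[["339"]])) 1 else tags[["339"]][1]
    offsets <- tags[["273"]]
    counts <- tags[["279"]]
    if (is.null(offsets) || is.null(counts)) {
      stop("TIFF page missing strip layout", call. = FALSE)
    }
    n_pix <- as.numeric(width) * height
    size <- bits / 8
    vals <- numeric(0)
    for (s in seq_along(offsets)) {
      seek(con, offsets[s])
      n_here <- counts[s] / size
      chunk <- if (fmt == 3 && bits == 32) {
        readBin(con, "double", n = n_here, size = 4, endian = endian)
      } else if (fmt == 2 && bits == 16) {
        readBin(con, "integer", n = n_here, size = 2, signed = TRUE,
                endian = endian)
      } else if (fmt == 1 && bits == 8) {
        readBin(con, "integer", n = n_here, size = 1, signed = FALSE,
                endian = endian)
      } else if (fmt == 1 && bits == 16) {
        readBin(con, "integer", n = n_here, size = 2, signed = FALSE,
                endian = endian)
      } else {
        stop(sprintf("unsupported TIFF dtype (bits=%d, sample format=%d)",
                     bits, fmt), call. = FALSE)
      }
      vals <- c(vals, chunk)
    }
    if (length(vals) != n_pix) stop("TIFF strip data truncated", call. = FALSE)
    # TIFF stores row-major (rows = first array dim here)
    slice <- matrix(vals, nrow = height, ncol = width, byrow = TRUE)
    dtype <- if (fmt == 3) "float32" else if (fmt == 2) "int16" else
      if (bits == 8) "uint8" else "uint16"
    pages[[length(pages) + 1]] <- list(slice = slice, dtype = dtype)
  }
  pages
}

write_tiff_pages <- function(slices, path, dtype) {
  # slices: list of matrices (rows = image rows); dtype: uint8/int16/float32
  size <- switch(dtype, uint8 = 1L, int16 = 2L, float32 = 4L,
                 stop("unsupported dtype: ", dtype, call. = FALSE))
  fmt <- switch(dtype, uint8 = 1L, int16 = 2L, float32 = 3L)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("II", con, eos = NULL)
  writeBin(c(42L), con, size = 2, endian = "little")
  # first IFD offset placeholder, patched as we go: data blocks first
  header_pos <- seek(con)
  writeBin(0L, con, size = 4, endian = "little")
  offset <- 8L
  ifd_offsets <- integer(length(slices))
  data_offsets <- integer(length(slices))
  for (i in seq_along(slices)) {
    sl <- slices[[i]]
    data_offsets[i] <- offset
    v <- as.vector(t(sl))  # row-major
    if (dtype == "float32") {
      writeBin(as.numeric(v), con, size = 4, endian = "little")
    } else {
      writeBin(as.integer(v), con, size = size, endian = "little")
    }
    nbytes <- length(v) * size
    offset <- offset + nbytes
    ifd_offsets[i] <- offset
    # IFD: 10 entries
    h <- nrow(sl); w <- ncol(sl)
    writeBin(10L, con, size = 2, endian = "little")
    wr_entry <- function(tag, type, count, value) {
      writeBin(as.integer(tag), con, size = 2, endian = "little")
      writeBin(as.integer(type), con, size = 2, endian = "little")
      writeBin(as.integer(count), con, size = 4, endian = "little")
      if (type == 3) {
        writeBin(as.integer(value), con, size = 2, endian = "little")
        writeBin(0L, con, size = 2, endian = "little")
      } else {
        writeBin(as.integer(value), con, size = 4, endian = "little")
      }
    }
    wr_entry(256, 4, 1, w)
    wr_entry(257, 4, 1, h)
    wr_entry(258, 3, 1, size * 8L)
    wr_entry(259, 3, 1, 1)          # uncompressed
    wr_entry(262, 3, 1, 1)          # BlackIsZero
    wr_entry(273, 4, 1, data_offsets[i])
    wr_entry(277, 3, 1, 1)
    wr_entry(278, 4, 1, h)
    wr_entry(279, 4, 1, length(v) * size)
    wr_entry(339, 3, 1, fmt)
    next_ifd <- 0L  # patched below for all but last page
    writeBin(next_ifd, con, size = 4, endian = "little")
    offset <- offset + 2L + 10L * 12L + 4L
  }
  # patch the IFD chain
  seek(con, header_pos, rw = "write")
  writeBin(ifd_offsets[1], con, size = 4, endian = "little")
  if (length(slices) > 1) {
    for (i in seq_len(length(slices) - 1)) {
      # next-IFD pointer sits at the end of IFD i
      seek(con, ifd_offsets[i] + 2L + 10L * 12L, rw = "write")
      writeBin(ifd_offsets[i + 1], con, size = 4, endian = "little")
    }
  }
  invisible(path)
}

volume_to_slices <- function(values) {
  lapply(seq_len(dim(values)[3]), function(k) values[, , k])
}

#' Write a volume as a TIFF stack
#'
#' Grayscale volumes are written as 32-bit float, quantized volumes as 16-bit
#' signed integers, and binary volumes as 8-bit unsigned with 0 = solid and
#' 255 = pore. `layout = "multipage"` writes one multi-page file;
#' `layout = "directory"` writes one single-page file per slice, named
#' `slice_0000.tif`, `slice_0001.tif`, ... so that ascending filename order
#' is slice order.
#'
#' @param volume A [grayscale_volume()], [quantized_volume()] or
#'   [binary_volume()].
#' @param path Output file (multipage) or directory (directory layout).
#' @param layout `"multipage"` or `"directory"`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path, layout = c("multipage", "directory")) {
  layout <- match.arg(layout)
  if (inherits(volume, "binary_volume")) {
    values <- array(ifelse(volume$mask, 255L, 0L), dim(volume$mask))
    dtype <- "uint8"
  } else if (inherits(volume, "quantized_volume")) {
    values <- volume$values
    dtype <- "int16"
  } else if (inherits(volume, "grayscale_volume")) {
    values <- volume$values
    dtype <- "float32"
  } else {
    stop("unsupported volume class", call. = FALSE)
  }
  slices <- volume_to_slices(values)
  if (layout == "multipage") {
    write_tiff_pages(slices, path, dtype)
  } else {
    if (!dir.exists(path)) dir.create(path, recursive = TRUE)
    for (k in seq_along(slices)) {
      write_tiff_pages(slices[k],
                       file.path(path, sprintf("slice_%04d.tif", k - 1)),
                       dtype)
    }
  }
  invisible(path)
}

#' Read a volume from a TIFF stack
#'
#' Accepts either a multi-page TIFF file or a directory of single-page TIFF
#' files (slice order = ascending filename order). All slices must share
#' shape and data type; 8-bit unsigned stacks written by [write_volume()] for
#' binary masks are returned as a [binary_volume()] (value > 127 = pore),
#' 16-bit signed stacks as a [quantized_volume()], and 32-bit float stacks as
#' a [grayscale_volume()].
#'
#' @param path TIFF file or directory of TIFF slices.
#' @param voxel_edge_um Voxel edge length in micrometers to attach.
#' @return A volume object of the class matching the stored data type.
#' @export
read_volume <- function(path, voxel_edge_um = 0.87) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.tif{1,2}$",
                             ignore.case = TRUE, full.names = TRUE))
    if (length(files) == 0) stop("no TIFF slices in ", path, call. = FALSE)
    pages <- unlist(lapply(files, read_tiff_pages), recursive = FALSE)
  } else if (file.exists(path)) {
    pages <- read_tiff_pages(path)
  } else {
    stop("path does not exist: ", path, call. = FALSE)
  }
  dims <- vapply(pages, function(p) dim(p$slice), integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("TIFF slices have mixed shapes", call. = FALSE)
  }
  dtypes <- vapply(pages, function(p) p$dtype, character(1))
  if (length(unique(dtypes)) != 1) {
    stop("TIFF slices have mixed data types", call. = FALSE)
  }
  values <- array(0, c(dims[1, 1], dims[2, 1], length(pages)))
  for (k in seq_along(pages)) values[, , k] <- pages[[k]]$slice
  switch(dtypes[1],
         uint8 = binary_volume(values > 127, voxel_edge_um),
         int16 = quantized_volume(values, voxel_edge_um),
         float32 = grayscale_volume(values, voxel_edge_um),
         grayscale_volume(values, voxel_edge_um))
}
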