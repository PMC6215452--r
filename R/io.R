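#' Read and write image stacks
#'
#' Two formats are supported. Multi-page TIFF (`.tif`/`.tiff`): one page per
#' slice, 8-bit 0/255 for binary volumes and 16-bit for greyscale, with a
#' YAML sidecar (`<file>.meta.yaml`) carrying spacing, origin and the value
#' range (TIFF itself stores normalised values). MetaImage (`.mha`): a single
#' self-contained file with spacing and origin in the header; greyscale is
#' stored as double, binary as uchar. Round trips preserve the grid, spacing
#' and origin exactly (greyscale TIFF is quantised to 16 bits, so integer
#' grids in \[0, 65535\] round-trip bit-identically).
#'
#' @param vol a [voxel_volume()] or [binary_volume()].
#' @param path output path ending in `.tif`, `.tiff` or `.mha`.
#' @return `write_stack`: the path, invisibly. `read_stack`: the volume.
#' @export
write_stack <- function(vol, path) {
  ext <- tolower(tools::file_ext(path))
  binary <- inherits(vol, "binary_volume")
  if (ext %in% c("tif", "tiff")) {
    g <- vol$grid
    if (binary) {
      pages <- lapply(seq_len(dim(g)[1]), function(i) g[i, , ] + 0)
      tiff::writeTIFF(pages, path, bits.per.sample = 8L)
      rng <- c(0, 1)
    } else {
      if (all(g >= 0 & g <= 65535 & g == round(g))) {
        rng <- c(0, 65535)       # integer grids round-trip bit-identically
      } else {
        rng <- range(g)
        if (diff(rng) == 0) rng[2] <- rng[1] + 1
      }
      gn <- (g - rng[1]) / (rng[2] - rng[1])
      pages <- lapply(seq_len(dim(g)[1]), function(i) gn[i, , ])
      tiff::writeTIFF(pages, path, bits.per.sample = 16L)
    }
    yaml::write_yaml(list(kind = if (binary) "binary" else "greyscale",
                          dim = dim(g), spacing_mm = vol$spacing_mm,
                          origin_mm = vol$origin_mm,
                          value_min = rng[1], value_max = rng[2]),
                     paste0(path, ".meta.yaml"))
  } else if (ext == "mha") {
    write_mha(vol, path)
  } else stop("unsupported stack format: .", ext)
  invisible(path)
}

#' @param path input path.
#' @rdname write_stack
#' @export
read_stack <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    pages <- tiff::readTIFF(path, all = TRUE)
    if (length(unique(vapply(pages, function(p) paste(dim(p), collapse = "x"),
                             character(1)))) != 1)
      stop("inconsistent slice dimensions in ", path)
    side <- paste0(path, ".meta.yaml")
    if (file.exists(side)) {
      meta <- yaml::read_yaml(side)
    } else {
      warning("missing sidecar ", side, ": spacing defaults to 1 mm")
      meta <- list(kind = "greyscale", spacing_mm = c(1, 1, 1),
                   origin_mm = c(0, 0, 0), value_min = 0, value_max = 1)
    }
    d <- c(length(pages), dim(pages[[1]]))
    g <- array(0, d)
    for (i in seq_along(pages)) g[i, , ] <- pages[[i]]
    if (identical(meta$kind, "binary"))
      binary_volume(g > 0.5, unlist(meta$spacing_mm), unlist(meta$origin_mm))
    else
      voxel_volume(g * (meta$value_max - meta$value_min) + meta$value_min,
                   unlist(meta$spacing_mm), unlist(meta$origin_mm))
  } else if (ext == "mha") {
    read_mha(path)
  } else stop("unsupported stack format: .", ext)
}

# Minimal uncompressed MetaImage writer/reader. DimSize is written in array
# axis order (slice, row, col); data in R column-major order (axis 1 fastest).
write_mha <- function(vol, path) {
  binary <- inherits(vol, "binary_volume")
  d <- dim(vol$grid)
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- c("ObjectType = Image", "NDims = 3", "BinaryData = True",
           "BinaryDataByteOrderMSB = False",
           paste("DimSize =", paste(d, collapse = " ")),
           paste("ElementSpacing =", paste(vol$spacing_mm, collapse = " ")),
           paste("Offset =", paste(vol$origin_mm, collapse = " ")),
           paste("ElementType =", if (binary) "MET_UCHAR" else "MET_DOUBLE"),
           "ElementDataFile = LOCAL")
  writeLines(hdr, con)
  if (binary)
    writeBin(as.integer(vol$grid), con, size = 1)
  else
    writeBin(as.numeric(vol$grid), con, size = 8)
  invisible(path)
}

read_mha <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- list()
  repeat {
    line <- readLines(con, n = 1)
    if (length(line) == 0) stop("truncated MetaImage header")
    kv <- strsplit(line, "=", fixed = TRUE)[[1]]
    key <- trimws(kv[1])
    hdr[[key]] <- trimws(paste(kv[-1], collapse = "="))
    if (key == "ElementDataFile") break
  }
  d <- as.integer(strsplit(hdr$DimSize, " +")[[1]])
  sp <- as.numeric(strsplit(hdr$ElementSpacing, " +")[[1]])
  org <- if (!is.null(hdr$Offset))
    as.numeric(strsplit(hdr$Offset, " +")[[1]]) else c(0, 0, 0)
  n <- prod(d)
  if (identical(hdr$ElementType, "MET_UCHAR")) {
    g <- array(readBin(con, integer(), n, size = 1, signed = FALSE) > 0, d)
    binary_volume(g, sp, org)
  } else {
    g <- array(readBin(con, numeric(), n, size = 8), d)
    voxel_volume(g, sp, org)
  }
}

#' Write/read a VOI fabric table as CSV
#' @param tab a data.frame (e.g. from [batch_fabric()] or [ccp_pack()]).
#' @param path CSV path.
#' @return the path / the data.frame.
#' @export
write_table_csv <- function(tab, path) {
  utils::write.csv(as.data.frame(tab), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_table_csv
#' @export
read_table_csv <- function(path) utils::read.csv(path)
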