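#' Read and write image volumes
#'
#' Two on-disk formats are supported: MetaImage (`.mhd` header + `.raw`
#' data; spacing travels with the file) and TIFF stacks (one z-slice per
#' page; spacing must be supplied when reading). Gray8 volumes are stored as
#' unsigned 8-bit, raw volumes as 32-bit float.
#'
#' @param path file path (`.mhd` or `.tif`/`.tiff`).
#' @param volume an [ImageVolume-class].
#' @param spacing voxel spacing in mm, required when reading TIFF.
#' @param kind volume kind to stamp on a TIFF read (`"gray8"` or `"raw"`).
#' @return `readImageVolume` returns an [ImageVolume-class];
#'   `writeImageVolume` returns `path` invisibly.
#' @name volume-io
NULL

#' @rdname volume-io
#' @export
writeImageVolume <- function(volume, path) {
  stopifnot(is(volume, "ImageVolume"))
  ext <- tolower(tools::file_ext(path))
  if (ext == "mhd") {
    rawPath <- sub("\\.mhd$", ".raw", path, ignore.case = TRUE)
    type <- if (volume@kind == "gray8") "MET_UCHAR" else "MET_FLOAT"
    hdr <- c("ObjectType = Image", "NDims = 3", "BinaryData = True",
             "BinaryDataByteOrderMSB = False",
             paste("DimSize =", paste(dim(volume@data), collapse = " ")),
             paste("ElementSpacing =", paste(volume@spacing, collapse = " ")),
             paste("ElementType =", type),
             paste("ElementDataFile =", basename(rawPath)))
    writeLines(hdr, path)
    con <- file(rawPath, "wb"); on.exit(close(con))
    if (volume@kind == "gray8")
      writeBin(as.integer(volume@data), con, size = 1L)
    else
      writeBin(as.numeric(volume@data), con, size = 4L, endian = "little")
  } else if (ext %in% c("tif", "tiff")) {
    d <- dim(volume@data)
    mx <- if (volume@kind == "gray8") 255 else max(abs(volume@data), 1e-12)
    slices <- lapply(seq_len(d[3]), function(k)
      clamp(volume@data[, , k] / mx, 0, 1))
    tiff::writeTIFF(slices, path, bits.per.sample = 8L)
  } else stop("unsupported volume format: .", ext)
  invisible(path)
}

#' @rdname volume-io
#' @export
readImageVolume <- function(path, spacing = NULL, kind = "gray8") {
  ext <- tolower(tools::file_ext(path))
  if (ext == "mhd") {
    hdr <- readLines(path)
    getv <- function(key) {
      ln <- grep(paste0("^\\s*", key, "\\s*="), hdr, value = TRUE)
      if (!length(ln)) stop("MetaImage header missing ", key)
      trimws(sub("^[^=]*=", "", ln[1]))
    }
    d <- as.integer(strsplit(getv("DimSize"), "\\s+")[[1]])
    sp <- as.numeric(strsplit(getv("ElementSpacing"), "\\s+")[[1]])
    type <- getv("ElementType")
    rawPath <- file.path(dirname(path), getv("ElementDataFile"))
    con <- file(rawPath, "rb"); on.exit(close(con))
    n <- prod(d)
    x <- switch(type,
      MET_UCHAR = as.numeric(readBin(con, "integer", n, size = 1L,
                                     signed = FALSE)),
      MET_FLOAT = readBin(con, "numeric", n, size = 4L, endian = "little"),
      MET_SHORT = as.numeric(readBin(con, "integer", n, size = 2L,
                                     signed = TRUE, endian = "little")),
      stop("unsupported ElementType: ", type))
    imageVolume(array(x, dim = d), sp,
                kind = if (type == "MET_UCHAR") "gray8" else "raw")
  } else if (ext %in% c("tif", "tiff")) {
    if (is.null(spacing)) stop("spacing must be supplied when reading TIFF")
    slices <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(slices)) slices <- list(slices)
    arr <- array(0, dim = c(dim(slices[[1]]), length(slices)))
    for (k in seq_along(slices)) arr[, , k] <- slices[[k]] * 255
    arr <- roundHalfAway(arr)
    imageVolume(arr, spacing, kind = kind)
  } else stop("unsupported volume format: .", ext)
}

#' Read and write load-displacement curves as CSV
#'
#' Two-column CSV with header `displacement_mm` and either `load_kN` or
#' `load_N`; loads in newtons are converted to kN on read.
#'
#' @param path CSV file path.
#' @param curve a [LoadDisplacementCurve-class].
#' @param id specimen id for the curve read (default: file stem).
#' @return `readLoadCurve` returns a [LoadDisplacementCurve-class];
#'   `writeLoadCurve` returns `path` invisibly.
#' @name curve-io
NULL

#' @rdname curve-io
#' @export
readLoadCurve <- function(path, id = NULL) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"displacement_mm" %in% names(df))
    stop("curve CSV must have a 'displacement_mm' column: ", path)
  load <- if ("load_kN" %in% names(df)) df$load_kN
          else if ("load_N" %in% names(df)) df$load_N / 1000
          else stop("curve CSV must have a 'load_kN' or 'load_N' column: ", path)
  if (is.null(id)) id <- tools::file_path_sans_ext(basename(path))
  loadDisplacementCurve(df$displacement_mm, load, id = id)
}

#' @rdname curve-io
#' @export
writeLoadCurve <- function(curve, path) {
  stopifnot(is(curve, "LoadDisplacementCurve"))
  utils::write.csv(curveData(curve), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
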