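#' Read a raw voxel grid with sidecar metadata
#'
#' The canonical on-disk volume format: a headerless binary file of vertex
#' scalars plus a YAML (or JSON) sidecar declaring \code{extents} (vertex
#' counts), \code{spacing} (mm), \code{dtype} (\code{uint8}, \code{int16},
#' \code{uint16}, \code{float32} or \code{float64}), \code{byteOrder}
#' (\code{little}/\code{big}, default little) and \code{axisOrder} (a
#' permutation of \code{"xyz"} naming the fastest-varying axis first,
#' default \code{"xyz"}). The file's byte length must equal
#' \code{prod(extents) * sizeof(dtype)}.
#'
#' @param dataPath path to the raw binary file.
#' @param metaPath path to the YAML/JSON metadata sidecar.
#' @return A [ScalarVolume-class].
#' @seealso [writeRawVolume()]
#' @export
readRawVolume <- function(dataPath, metaPath) {
  if (!file.exists(dataPath)) stop("raw data file not found: ", dataPath)
  meta <- .readMeta(metaPath)
  ext <- as.integer(meta$extents)
  if (length(ext) != 3L) stop("metadata extents must have length 3")
  dt <- .dtypeInfo(meta$dtype)
  expected <- prod(ext) * dt$size
  actual <- file.size(dataPath)
  if (actual != expected)
    stop(sprintf(
      "corrupt raw volume: expected %d bytes (%d x %d x %d x %d-byte %s), found %d",
      expected, ext[1], ext[2], ext[3], dt$size, meta$dtype, actual))
  endian <- .byteOrder(meta)
  con <- file(dataPath, "rb")
  on.exit(close(con))
  vals <- readBin(con, what = dt$what, n = prod(ext), size = dt$size,
                  signed = dt$signed, endian = endian)
  axisOrder <- if (is.null(meta$axisOrder)) "xyz" else meta$axisOrder
  perm <- match(strsplit(axisOrder, "")[[1]], c("x", "y", "z"))
  if (length(perm) != 3L || anyNA(perm) || anyDuplicated(perm))
    stop("axisOrder must be a permutation of 'xyz'")
  a <- array(as.numeric(vals), dim = ext)
  if (!identical(perm, 1:3)) {
    # stored dims follow the declared order; bring them back to x, y, z
    a <- aperm(a, order(perm))
  }
  scalarVolume(a, spacing = as.numeric(meta$spacing))
}

#' Write a raw voxel grid with sidecar metadata
#'
#' Inverse of [readRawVolume()]; the round trip is bit-exact for values
#' representable in the chosen dtype.
#'
#' @param volume a [ScalarVolume-class].
#' @param dataPath output path for the raw binary file.
#' @param metaPath output path for the YAML sidecar.
#' @param dtype scalar type to store (default \code{float32}... use
#'   \code{float64} for lossless storage of arbitrary doubles).
#' @param byteOrder \code{"little"} (default) or \code{"big"}.
#' @return Invisibly, the two paths.
#' @export
writeRawVolume <- function(volume, dataPath, metaPath, dtype = "float64",
                           byteOrder = "little") {
  dt <- .dtypeInfo(dtype)
  ext <- dim(volume@values)
  con <- file(dataPath, "wb")
  vals <- as.vector(volume@values)
  if (dt$what == "integer") vals <- as.integer(round(vals))
  writeBin(vals, con, size = dt$size, endian = byteOrder)
  close(con)
  meta <- list(extents = as.integer(ext),
               spacing = as.numeric(volume@spacing),
               dtype = dtype, byteOrder = byteOrder, axisOrder = "xyz")
  yaml::write_yaml(meta, metaPath)
  invisible(c(dataPath, metaPath))
}

.readMeta <- function(metaPath) {
  if (!file.exists(metaPath)) stop("metadata file not found: ", metaPath)
  if (grepl("\\.json$", metaPath, ignore.case = TRUE)) {
    if (!requireNamespace("jsonlite", quietly = TRUE))
      stop("reading JSON metadata requires the jsonlite package")
    jsonlite::fromJSON(metaPath)
  } else {
    yaml::read_yaml(metaPath)
  }
}

.dtypeInfo <- function(dtype) {
  if (is.null(dtype)) stop("metadata must declare a dtype")
  switch(dtype,
    uint8   = list(what = "integer", size = 1L, signed = FALSE),
    int16   = list(what = "integer", size = 2L, signed = TRUE),
    uint16  = list(what = "integer", size = 2L, signed = FALSE),
    float32 = list(what = "numeric", size = 4L, signed = TRUE),
    float64 = list(what = "numeric", size = 8L, signed = TRUE),
    stop("unknown scalar dtype: ", dtype))
}

.byteOrder <- function(meta) {
  bo <- if (is.null(meta$byteOrder)) "little" else meta$byteOrder
  if (!bo %in% c("little", "big"))
    stop("byteOrder must be 'little' or 'big'")
  bo
}

#' Read a stack of 2D grayscale slices as a volume
#'
#' Slice files (PNG or TIFF, one per z-slice) sorted in natural filename
#' order (numeric runs compared as numbers, so \code{s2} precedes
#' \code{s10}) become \code{k = 0 .. Ez-1}. Pixel \code{[row, col]} of a
#' slice maps to vertex \code{(i = row-1, j = col-1)}. Color slices are
#' averaged to grayscale. Values keep the readers' [0, 1] scale.
#'
#' @param directory directory containing the slice files.
#' @param spacing numeric(3) vertex spacing in mm (slices carry no spacing).
#' @param pattern filename regex (default matches .png and .tif/.tiff).
#' @return A [ScalarVolume-class] with \code{Ez} = number of slices (>= 2).
#' @export
readSliceStack <- function(directory, spacing,
                           pattern = "\\.(png|tiff?)$") {
  files <- list.files(directory, pattern = pattern, ignore.case = TRUE,
                      full.names = TRUE)
  files <- files[naturalOrder(basename(files))]
  if (length(files) < 2L)
    stop("inconsistent stack: at least 2 slice files are required, found ",
         length(files))
  slices <- lapply(files, .readSlice)
  d <- dim(slices[[1]])
  for (s in seq_along(slices)) {
    if (!identical(dim(slices[[s]]), d))
      stop(sprintf("inconsistent stack: slice '%s' is %d x %d, expected %d x %d",
                   basename(files[s]), dim(slices[[s]])[1],
                   dim(slices[[s]])[2], d[1], d[2]))
  }
  a <- array(0, dim = c(d[1], d[2], length(slices)))
  for (s in seq_along(slices)) a[, , s] <- slices[[s]]
  scalarVolume(a, spacing = spacing)
}

.readSlice <- function(path) {
  img <- if (grepl("\\.png$", path, ignore.case = TRUE)) png::readPNG(path)
         else tiff::readTIFF(path)
  if (length(dim(img)) == 3L) img <- apply(img, c(1, 2), mean)
  img
}

#' Natural (numeric-aware) filename ordering
#'
#' Orders names so that embedded numbers compare as numbers: \code{s2} before
#' \code{s10}. Numeric runs are zero-padded to a fixed width and the padded
#' keys sorted lexicographically.
#'
#' @param names character vector.
#' @return integer permutation ordering \code{names} naturally.
#' @examples
#' naturalOrder(c("s10.png", "s2.png"))  # 2 1
#' @export
naturalOrder <- function(names) {
  keys <- vapply(names, function(nm) {
    m <- gregexpr("[0-9]+", nm)[[1]]
    if (m[1] == -1) return(nm)
    runs <- regmatches(nm, gregexpr("[0-9]+", nm))[[1]]
    padded <- sprintf("%020d", as.numeric(runs))
    out <- nm
    for (i in rev(seq_along(runs))) {
      start <- m[i]
      stop_ <- start + attr(m, "match.length")[i] - 1L
      out <- paste0(substr(out, 1, start - 1), padded[i],
                    substr(out, stop_ + 1, nchar(out)))
    }
    out
  }, character(1))
  order(keys)
}

#' Write a rendered image to PNG or PGM
#'
#' Pixel values are mapped linearly from \code{[0, maxValue]} to full scale
#' with clamping (the normalization maximum is configured, not auto-scaled,
#' so images are comparable across samplers and runs). PNG output is 8-bit
#' grayscale or RGB via the png package; \code{.pgm} writes the plain-text
#' P2 format at the requested bit depth.
#'
#' @param image numeric matrix (grayscale) or rows x cols x 3 array (RGB;
#'   PNG only), all values finite.
#' @param path output path ending in \code{.png} or \code{.pgm}.
#' @param maxValue value mapped to full scale (default 1).
#' @param bitDepth 8 or 16 (PGM only; PNG is written 8-bit).
#' @return Invisibly, \code{path}.
#' @export
writeImage <- function(image, path, maxValue = 1, bitDepth = 8L) {
  if (!all(is.finite(image)))
    stop("image contains non-finite pixel values")
  stopifnot(maxValue > 0)
  scaled <- pmin(pmax(image / maxValue, 0), 1)
  if (grepl("\\.pgm$", path, ignore.case = TRUE)) {
    if (length(dim(image)) == 3L) stop("PGM output is grayscale only")
    maxint <- if (bitDepth == 16L) 65535L else 255L
    q <- round(scaled * maxint)
    lines <- c("P2", paste(ncol(q), nrow(q)), as.character(maxint),
               apply(q, 1, paste, collapse = " "))
    writeLines(lines, path)
  } else {
    png::writePNG(scaled, target = path)
  }
  invisible(path)
}
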