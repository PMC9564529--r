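#' @include landscape-core.R
NULL

# ESRI ASCII grid: minimal text raster carrier. Header keys are parsed
# case-insensitively; values are written top row first (row-major, origin
# top-left), matching the package's grid convention.

read_ascii_grid <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 7) stopf("'%s' is not an ESRI ASCII grid", path)
  hdr <- list()
  i <- 1L
  while (i <= length(lines) &&
         grepl("^\\s*[A-Za-z_]+\\s+-?[0-9.eE+-]+\\s*$", lines[i])) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
    i <- i + 1L
  }
  for (key in c("ncols", "nrows"))
    if (is.null(hdr[[key]])) stopf("'%s': missing header '%s'", path, key)
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  if (length(vals) != nr * nc)
    stopf("'%s': expected %d values, found %d", path, nr * nc, length(vals))
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else NA_real_
  list(values = m, nodata = nodata,
       cellsize = if (!is.null(hdr$cellsize)) hdr$cellsize else 1)
}

write_ascii_grid <- function(m, path, nodata = .NODATA, cellsize = 1) {
  hdr <- c(sprintf("ncols %d", ncol(m)), sprintf("nrows %d", nrow(m)),
           "xllcorner 0", "yllcorner 0", sprintf("cellsize %g", cellsize),
           sprintf("NODATA_value %g", nodata))
  body <- apply(m, 1, function(r)
    paste(formatC(r, format = "g", digits = 15), collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

raster_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("asc", "txt")) "ascii"
  else if (ext %in% c("tif", "tiff")) "tiff"
  else stopf("unsupported raster extension '.%s' (use .asc or .tif)", ext)
}

#' Read a categorical land-use raster
#'
#' Reads a single-band integer raster (ESRI ASCII grid or single-band TIFF)
#' and remaps its codes to the canonical 1..6 classes. Any non-nodata code
#' absent from \code{classMap} is an error, never silently dropped.
#'
#' @param path raster path (.asc/.txt or .tif/.tiff).
#' @param classMap named integer vector mapping file codes to canonical codes
#'   1..6; names are the file codes. Default: identity on 1..6.
#' @param cellArea km2 per cell; if NA, the square of the ASCII-grid cellsize
#'   (interpreted in km) is used, or 1 for TIFF.
#' @param epoch year label stored on the grid.
#' @return a \linkS4class{LandUseGrid}.
#' @export
readLandUseGrid <- function(path, classMap = setNames(1:6, as.character(1:6)),
                            cellArea = NA_real_, epoch = "") {
  fmt <- raster_format(path)
  if (fmt == "ascii") {
    g <- read_ascii_grid(path)
    m <- g$values
    nodata <- g$nodata
    if (is.na(cellArea)) cellArea <- g$cellsize^2
  } else {
    v <- tiff::readTIFF(path, as.is = TRUE)
    if (length(dim(v)) == 3L) v <- v[, , 1]
    m <- v - 1L           # stored as code + 1; 0 = nodata
    nodata <- .NODATA
    if (is.na(cellArea)) cellArea <- 1
  }
  codes <- matrix(.NODATA, nrow(m), ncol(m))
  valid <- if (is.na(nodata)) !is.na(m) else (m != nodata & !is.na(m))
  fc <- as.character(as.integer(m[valid]))
  unknown <- setdiff(unique(fc), names(classMap))
  if (length(unknown))
    stopf("codes outside class map: %s", paste(unknown, collapse = ", "))
  codes[valid] <- as.integer(classMap[fc])
  LandUseGrid(codes, cellArea = cellArea, epoch = epoch)
}

#' Write a categorical land-use raster
#'
#' The ASCII writer round-trips codes bit-identically; the TIFF writer stores
#' code + 1 in an 8-bit band (0 = nodata), which also round-trips exactly.
#'
#' @param grid a \linkS4class{LandUseGrid}.
#' @param path destination (.asc/.txt or .tif/.tiff).
#' @return the path, invisibly.
#' @export
writeLandUseGrid <- function(grid, path) {
  fmt <- raster_format(path)
  codes <- landCodes(grid)
  if (fmt == "ascii") {
    write_ascii_grid(codes, path, nodata = .NODATA,
                     cellsize = sqrt(cellArea(grid)))
  } else {
    stored <- codes + 1L
    stored[codes == .NODATA] <- 0L
    tiff::writeTIFF(stored / 255, path, bits.per.sample = 8L)
  }
  invisible(path)
}

#' Read / write a continuous driver surface
#'
#' Driver rasters travel as one single-band ESRI ASCII grid per driver.
#'
#' @param path .asc path.
#' @return numeric matrix.
#' @export
readDriverSurface <- function(path) {
  g <- read_ascii_grid(path)
  m <- g$values
  if (!is.na(g$nodata)) m[m == g$nodata] <- NA_real_
  m
}

#' @rdname readDriverSurface
#' @param m numeric matrix to write.
#' @export
writeDriverSurface <- function(m, path) {
  m2 <- m
  m2[is.na(m2)] <- -9999
  write_ascii_grid(m2, path, nodata = -9999)
}

#' Read / write a red-line mask raster
#'
#' Masks travel as 0/1 ASCII grids.
#' @param path .asc path.
#' @return a \linkS4class{RedLineMask}.
#' @export
readRedLineMask <- function(path) {
  g <- read_ascii_grid(path)
  RedLineMask(g$values != 0)
}

#' @rdname readRedLineMask
#' @param mask a \linkS4class{RedLineMask} to write.
#' @export
writeRedLineMask <- function(mask, path) {
  write_ascii_grid(maskInside(mask) * 1L, path, nodata = -1)
}

#' Read / write an area vector as CSV
#'
#' CSV schema: \code{class,area_km2}, rows in canonical class order.
#'
#' @param path CSV path.
#' @return an \linkS4class{AreaVector}.
#' @export
readAreaVector <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("class", "area_km2") %in% names(df)))
    stopf("'%s' must have columns class,area_km2", path)
  idx <- match(.CLASS_LABELS, df$class)
  if (any(is.na(idx)))
    stopf("'%s' is missing classes: %s", path,
          paste(.CLASS_LABELS[is.na(idx)], collapse = ", "))
  AreaVector(df$area_km2[idx])
}

#' @rdname readAreaVector
#' @param x an \linkS4class{AreaVector} to write.
#' @export
writeAreaVector <- function(x, path) {
  write.csv(data.frame(class = names(areaKm2(x)), area_km2 = areaKm2(x),
                       row.names = NULL),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
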