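#' Georeferenced grid raster
#'
#' Minimal in-memory raster: a numeric matrix in map orientation (row 1 =
#' northernmost row), a cell size in metres and the lower-left corner of the
#' grid. `NA` is the nodata mask.
#'
#' @param values numeric matrix, row 1 = top of the map.
#' @param cell_size pixel edge length in metres (> 0).
#' @param xll,yll x/y of the lower-left corner of the lower-left pixel.
#' @return object of class `land_raster`.
#' @export
land_raster <- function(values, cell_size = 30, xll = 0, yll = 0) {
  stopifnot(is.matrix(values), cell_size > 0)
  structure(list(values = values, cell_size = cell_size,
                 xll = xll, yll = yll),
            class = "land_raster")
}

#' @export
print.land_raster <- function(x, ...) {
  v <- x$values[!is.na(x$values)]
  cat(sprintf("land_raster: %d x %d @ %gm, origin (%g, %g), %d nodata\n",
              nrow(x$values), ncol(x$values), x$cell_size, x$xll, x$yll,
              sum(is.na(x$values))))
  cat(sprintf("  values: %g .. %g (%d distinct)\n", min(v), max(v),
              length(unique(v))))
  invisible(x)
}

#' World coordinates to raster row/column
#'
#' Half-pixel-center registration: the centre of pixel (row r, col c) lies at
#' `x = xll + (c - 0.5) * cs`, `y = yll + (nrow - r + 0.5) * cs` (row 1 is
#' the top row).
#'
#' @param r a `land_raster`.
#' @param x,y numeric vectors of world coordinates.
#' @return matrix with columns `row`, `col` (NA when outside the grid).
#' @export
world_to_pixel <- function(r, x, y) {
  cs <- r$cell_size
  col <- floor((x - r$xll) / cs) + 1
  row <- nrow(r$values) - floor((y - r$yll) / cs)
  bad <- col < 1 | col > ncol(r$values) | row < 1 | row > nrow(r$values)
  col[bad] <- NA; row[bad] <- NA
  cbind(row = row, col = col)
}

#' Raster row/column to world coordinates of the pixel centre
#' @param r a `land_raster`.
#' @param row,col integer vectors.
#' @return matrix with columns `x`, `y`.
#' @export
pixel_to_world <- function(r, row, col) {
  cs <- r$cell_size
  cbind(x = r$xll + (col - 0.5) * cs,
        y = r$yll + (nrow(r$values) - row + 0.5) * cs)
}

#' Read an ESRI ASCII grid (.asc)
#'
#' Header keys `ncols`, `nrows`, `xllcorner`, `yllcorner`, `cellsize`,
#' optional `NODATA_value`; data rows follow in row-major order from the top
#' of the map.
#'
#' @param path file path.
#' @return a [land_raster()].
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- list()
  i <- 1
  while (grepl("^[[:alpha:]]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr)))
    stop("missing header keys: ", paste(setdiff(need, names(hdr)),
                                        collapse = ", "))
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  if (length(vals) != hdr$ncols * hdr$nrows)
    stop("data length does not match ncols * nrows")
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  if (!is.null(hdr$nodata_value)) m[m == hdr$nodata_value] <- NA
  land_raster(m, hdr$cellsize, hdr$xllcorner, hdr$yllcorner)
}

#' Write an ESRI ASCII grid (.asc)
#' @param r a [land_raster()].
#' @param path output path.
#' @param nodata nodata sentinel written for `NA` pixels.
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(r, path, nodata = -9999) {
  m <- r$values
  m[is.na(m)] <- nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste("ncols", ncol(m)), paste("nrows", nrow(m)),
               paste("xllcorner", r$xll), paste("yllcorner", r$yll),
               paste("cellsize", r$cell_size),
               paste("NODATA_value", nodata)), con)
  utils::write.table(m, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Land-cover class codes used by the synthetic landscape generator
#'
#' Named integer codes for the six cover types of the study system:
#' forest, wetland, urban, water, grassland, agriculture.
#' @return named integer vector.
#' @export
landcover_classes <- function() {
  c(forest = 1L, wetland = 2L, urban = 3L, water = 4L,
    grassland = 5L, agriculture = 6L)
}
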