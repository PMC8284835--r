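#' Land-cover class codes
#'
#' Integer codes used throughout the package for the seven land-cover classes
#' of a classified mosaic: 1 old-growth forest, 2 secondary forest,
#' 3 floodplain, 4 arboreal crop, 5 cattle pasture, 6 anthropogenic cover,
#' 7 water bodies.
#'
#' @format Named integer vector of length 7.
#' @export
land_cover_classes <- c(
  old_growth    = 1L,
  secondary     = 2L,
  floodplain    = 3L,
  arboreal_crop = 4L,
  pasture       = 5L,
  anthropogenic = 6L,
  water         = 7L
)

#' Habitat-quality ranking of the land-cover classes
#'
#' Seven-point ranking of matrix quality used by the edge-contrast metric:
#' 1 for the least suitable cover (water bodies) up to 7 for old-growth
#' forest. With the default class coding the rank of class code `k` is
#' `8 - k`.
#'
#' @return Named integer vector mapping class code (as name) to rank 1-7.
#' @export
#' @examples
#' quality_ranking()
quality_ranking <- function() {
  r <- 8L - land_cover_classes
  names(r) <- as.character(land_cover_classes)
  r
}

#' Construct a classified land-cover raster
#'
#' @param grid Integer matrix of class codes in 1..7. Row 1 is the northern
#'   (top) edge of the mosaic.
#' @param cell_size Cell edge length in metres (> 0).
#' @param origin Planar (x, y) of the lower-left corner, metres.
#' @return An object of class `land_cover_raster`.
#' @export
land_cover_raster <- function(grid, cell_size, origin = c(0, 0)) {
  grid <- as.matrix(grid)
  if (length(grid) == 0L) stop("grid must be non-empty")
  storage.mode(grid) <- "integer"
  if (anyNA(grid) || any(grid < 1L) || any(grid > 7L))
    stop("grid cells must hold class codes in 1..7")
  if (!is.numeric(cell_size) || length(cell_size) != 1L || cell_size <= 0)
    stop("cell_size must be a single positive number")
  if (length(origin) != 2L || !is.numeric(origin))
    stop("origin must be a numeric (x, y) pair")
  structure(
    list(grid = grid, cell_size = as.numeric(cell_size),
         origin = as.numeric(origin)),
    class = "land_cover_raster"
  )
}

#' @export
print.land_cover_raster <- function(x, ...) {
  cat(sprintf(
    "land_cover_raster: %d x %d cells, %.6g m cells (%.6g x %.6g km)\n",
    nrow(x$grid), ncol(x$grid), x$cell_size,
    ncol(x$grid) * x$cell_size / 1000, nrow(x$grid) * x$cell_size / 1000))
  tab <- table(factor(x$grid, levels = 1:7))
  prop <- round(100 * as.numeric(tab) / length(x$grid), 2)
  cat("class cover (%):", paste(sprintf("%d:%.2f", 1:7, prop), collapse = " "),
      "\n")
  invisible(x)
}

#' Planar coordinates of cell centres
#'
#' @param raster A `land_cover_raster`.
#' @param rows,cols Integer vectors of matrix indices (recycled together).
#' @return Two-column matrix of (x, y) centre coordinates in metres.
#' @keywords internal
cell_centres <- function(raster, rows, cols) {
  nr <- nrow(raster$grid)
  cbind(
    x = raster$origin[1] + (cols - 0.5) * raster$cell_size,
    y = raster$origin[2] + (nr - rows + 0.5) * raster$cell_size
  )
}

#' Write a land-cover raster as an ESRI ASCII grid
#'
#' Plain-text single-band grid: a six-line header (ncols, nrows, xllcorner,
#' yllcorner, cellsize, NODATA_value) followed by rows of integer codes from
#' the northern edge down.
#'
#' @param raster A `land_cover_raster`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(raster, path) {
  stopifnot(inherits(raster, "land_cover_raster"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", ncol(raster$grid)),
    sprintf("nrows %d", nrow(raster$grid)),
    sprintf("xllcorner %.10g", raster$origin[1]),
    sprintf("yllcorner %.10g", raster$origin[2]),
    sprintf("cellsize %.10g", raster$cell_size),
    "NODATA_value -9999"
  ), con)
  writeLines(apply(raster$grid, 1L, paste, collapse = " "), con)
  invisible(path)
}

#' Read a land-cover raster from an ESRI ASCII grid
#'
#' @param path File written by [write_ascii_grid()] (or any conforming
#'   integer-coded ASCII grid).
#' @return A `land_cover_raster`.
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1L
  while (grepl("^[A-Za-z_]", lines[i])) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
    i <- i + 1L
  }
  need <- c("ncols", "nrows", "cellsize")
  if (!all(need %in% names(hdr))) stop("malformed ASCII grid header")
  body <- lines[i:length(lines)]
  body <- body[nzchar(trimws(body))]
  if (length(body) != hdr$nrows) stop("ASCII grid row count mismatch")
  vals <- lapply(body, function(l) as.integer(strsplit(trimws(l), "\\s+")[[1]]))
  if (any(lengths(vals) != hdr$ncols)) stop("ASCII grid column count mismatch")
  grid <- do.call(rbind, vals)
  origin <- c(
    if (is.null(hdr$xllcorner)) 0 else hdr$xllcorner,
    if (is.null(hdr$yllcorner)) 0 else hdr$yllcorner
  )
  land_cover_raster(grid, hdr$cellsize, origin)
}
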