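# Digital elevation models: in-memory grid, bilinear lookup, synthetic
# generators, and ESRI ASCII grid I/O.

#' Construct an in-memory DEM grid
#'
#' @param x0,y0 coordinates of the lower-left corner of the raster, m.
#' @param cell cell size, meters (> 0).
#' @param z elevation matrix; `z[1, ]` is the southernmost row (smallest
#'   y), columns run west to east.
#' @param nodata marker value for missing cells.
#' @return an object of class `dem_grid`.
#' @export
dem_grid <- function(x0, y0, cell, z, nodata = -9999) {
  stopifnot(cell > 0, is.matrix(z))
  structure(list(x0 = x0, y0 = y0, cell = cell, z = z, nodata = nodata),
            class = "dem_grid")
}

#' @export
print.dem_grid <- function(x, ...) {
  cat(sprintf("<dem_grid> %d x %d cells of %g m at (%g, %g)\n",
              nrow(x$z), ncol(x$z), x$cell, x$x0, x$y0))
  invisible(x)
}

#' Bilinear elevation lookup
#'
#' Interpolates the four cell centers surrounding `(x, y)`. Queries
#' outside the raster extent, or touching a nodata cell, raise an error
#' (callers fall back to fixed-altitude mode).
#'
#' @param dem a `dem_grid`.
#' @param x,y query coordinates, meters.
#' @return elevation, meters.
#' @export
dem_elevation <- function(dem, x, y) {
  nx <- ncol(dem$z); ny <- nrow(dem$z)
  if (x < dem$x0 || x > dem$x0 + nx * dem$cell ||
      y < dem$y0 || y > dem$y0 + ny * dem$cell)
    stop("DEM query outside raster extent")
  # continuous index in cell-center units
  cx <- (x - dem$x0) / dem$cell + 0.5
  cy <- (y - dem$y0) / dem$cell + 0.5
  j0 <- min(max(floor(cx), 1), nx - 1); j1 <- j0 + 1
  i0 <- min(max(floor(cy), 1), ny - 1); i1 <- i0 + 1
  if (nx == 1) { j0 <- j1 <- 1 }
  if (ny == 1) { i0 <- i1 <- 1 }
  fx <- min(max(cx - j0, 0), 1)
  fy <- min(max(cy - i0, 0), 1)
  q <- dem$z[c(i0, i0, i1, i1), ][cbind(1:4, c(j0, j1, j0, j1))]
  if (any(q == dem$nodata)) stop("DEM query touches nodata cells")
  (1 - fy) * ((1 - fx) * q[1] + fx * q[2]) +
    fy * ((1 - fx) * q[3] + fx * q[4])
}

#' Generate a synthetic DEM
#'
#' Deterministic per seed. Styles: `flat` (constant `value`), `ramp`
#' (`value + slope * x`), `hills` (constant plus a sum of seeded Gaussian
#' bumps).
#'
#' @param extent length-2 or scalar extent in meters (x, y), rasters start
#'   at (0, 0).
#' @param style `"flat"`, `"ramp"` or `"hills"`.
#' @param seed RNG seed (hills style).
#' @param cell cell size, meters.
#' @param value base elevation, meters.
#' @param slope ramp slope, m elevation per m easting.
#' @param n_hills,hill_height,hill_width hills-style parameters.
#' @return a `dem_grid`.
#' @export
make_dem <- function(extent, style = c("flat", "ramp", "hills"), seed = 1,
                     cell = 30, value = 30, slope = 0.01, n_hills = 8,
                     hill_height = 80, hill_width = 800) {
  style <- match.arg(style)
  extent <- rep_len(extent, 2)
  nx <- max(2L, ceiling(extent[1] / cell))
  ny <- max(2L, ceiling(extent[2] / cell))
  xc <- (seq_len(nx) - 0.5) * cell
  yc <- (seq_len(ny) - 0.5) * cell
  z <- switch(style,
    flat = matrix(value, ny, nx),
    ramp = matrix(rep(value + slope * xc, each = ny), ny, nx),
    hills = {
      z <- matrix(value, ny, nx)
      with_seed(seed, {
        for (k in seq_len(n_hills)) {
          hx <- stats::runif(1, 0, extent[1])
          hy <- stats::runif(1, 0, extent[2])
          h <- stats::runif(1, 0.3, 1) * hill_height
          w <- stats::runif(1, 0.5, 1.5) * hill_width
          z <- z + h * exp(-(outer((yc - hy)^2, (xc - hx)^2, "+")) /
                             (2 * w^2))
        }
        z
      })
    })
  dem_grid(0, 0, cell, z)
}

#' Read an ESRI ASCII grid
#'
#' Expects coordinates in the local planar metric frame (meters);
#' geographic rasters must be projected beforehand.
#'
#' @param path file path.
#' @return a `dem_grid`.
#' @export
read_esri_ascii <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr)))
    stop("malformed ESRI ASCII grid header (need ",
         paste(need, collapse = ", "), ")")
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  if (length(vals) != hdr$ncols * hdr$nrows)
    stop("ESRI ASCII grid: expected ", hdr$ncols * hdr$nrows,
         " values, got ", length(vals))
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  m <- m[rev(seq_len(nrow(m))), , drop = FALSE]  # file rows run north->south
  dem_grid(hdr$xllcorner, hdr$yllcorner, hdr$cellsize, m,
           nodata = if (is.null(hdr$nodata_value)) -9999 else
             hdr$nodata_value)
}

#' Write a DEM as an ESRI ASCII grid
#'
#' @param dem a `dem_grid`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_esri_ascii <- function(dem, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("ncols %d", ncol(dem$z)),
               sprintf("nrows %d", nrow(dem$z)),
               sprintf("xllcorner %.6f", dem$x0),
               sprintf("yllcorner %.6f", dem$y0),
               sprintf("cellsize %.6f", dem$cell),
               sprintf("NODATA_value %g", dem$nodata)), con)
  m <- dem$z[rev(seq_len(nrow(dem$z))), , drop = FALSE]
  writeLines(apply(m, 1, function(r) paste(format(r, trim = TRUE),
                                           collapse = " ")), con)
  invisible(path)
}
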