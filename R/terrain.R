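## Terrain derivatives on the common grid: Horn slope/aspect and an exact
## Euclidean distance-to-features layer.

# Pad a matrix by replicating its border (Horn kernel needs a full 3x3
# window at edge cells).
pad_replicate <- function(m) {
  m <- rbind(m[1, , drop = FALSE], m, m[nrow(m), , drop = FALSE])
  cbind(m[, 1, drop = FALSE], m, m[, ncol(m), drop = FALSE])
}

# Horn (1981) 8-neighbour finite differences. Returns list(dzdx, dzdy) on
# the original grid; dzdx increases eastward, dzdy southward (row-major,
# rows increase southward). NA propagates through any window touching nodata.
horn_gradient <- function(dem) {
  z <- pad_replicate(dem$values)
  cs <- dem$grid$cell_size
  nr <- nrow(dem$values); nc <- ncol(dem$values)
  ri <- 2:(nr + 1); ci <- 2:(nc + 1)
  a <- z[ri - 1, ci - 1]; b <- z[ri - 1, ci]; c_ <- z[ri - 1, ci + 1]
  d <- z[ri, ci - 1];                          f <- z[ri, ci + 1]
  g <- z[ri + 1, ci - 1]; h <- z[ri + 1, ci]; i_ <- z[ri + 1, ci + 1]
  list(dzdx = ((c_ + 2 * f + i_) - (a + 2 * d + g)) / (8 * cs),
       dzdy = ((g + 2 * h + i_) - (a + 2 * b + c_)) / (8 * cs))
}

#' Slope from a digital elevation model
#'
#' Horn's 3x3 finite-difference method (the standard used by mainstream GIS
#' slope tools); border cells use edge replication. Elevation must be in the
#' same length units as the grid's cell size.
#'
#' @param dem a continuous [env_layer()] of elevations.
#' @param units currently only `"degrees"`.
#' @return an [env_layer()] named `"slope"`, values in \[0, 90).
#' @export
compute_slope <- function(dem, units = "degrees") {
  if (dem$kind != "continuous") stop("slope requires a continuous DEM layer")
  units <- match.arg(units, "degrees")
  gr <- horn_gradient(dem)
  slope <- atan(sqrt(gr$dzdx^2 + gr$dzdy^2)) * 180 / pi
  slope[is.na(dem$values)] <- NA    # the Horn kernel omits the center cell
  env_layer("slope", slope, dem$grid, "continuous")
}

#' Aspect from a digital elevation model
#'
#' Compass direction of the downslope vector, in degrees clockwise from
#' north, computed from the Horn gradient. Flat cells (zero gradient) are
#' flagged with the sentinel -1.
#'
#' @inheritParams compute_slope
#' @param flat_tol gradient magnitude below which a cell counts as flat.
#' @return an [env_layer()] named `"aspect"`: \[0, 360) or -1 for flat.
#' @export
compute_aspect <- function(dem, flat_tol = 1e-12) {
  if (dem$kind != "continuous") stop("aspect requires a continuous DEM layer")
  gr <- horn_gradient(dem)
  # downslope vector in (east, north) components: (-dzdx, +dzdy) since dzdy
  # is the southward derivative; compass angle = atan2(east, north).
  asp <- atan2(-gr$dzdx, gr$dzdy) * 180 / pi
  asp <- (asp + 360) %% 360
  flat <- sqrt(gr$dzdx^2 + gr$dzdy^2) < flat_tol
  asp[which(flat)] <- -1
  asp[is.na(dem$values)] <- NA
  env_layer("aspect", asp, dem$grid, "continuous")
}

#' Exact Euclidean distance to the nearest feature cell
#'
#' Distance (in map units) from every cell center to the nearest feature
#' cell center — exact minimisation over all features, not a chamfer
#' approximation.
#'
#' @param grid a [grid_spec()].
#' @param feature_cells non-empty integer vector of cell indices (e.g.
#'   rasterized roads).
#' @param name output layer name.
#' @return a continuous [env_layer()] of distances; 0 on feature cells.
#' @export
distance_to_features <- function(grid, feature_cells, name = "road_dist") {
  feature_cells <- unique(as.integer(feature_cells))
  if (length(feature_cells) == 0) stop("feature_cells must be non-empty")
  frc <- cell_to_rowcol(grid, feature_cells)
  nr <- grid$n_rows; nc <- grid$n_cols
  rows <- seq_len(nr); cols <- seq_len(nc)
  d2 <- matrix(Inf, nr, nc)
  for (f in seq_len(nrow(frc)))
    d2 <- pmin(d2, outer((rows - frc[f, "row"])^2, (cols - frc[f, "col"])^2, `+`))
  env_layer(name, sqrt(d2) * grid$cell_size, grid, "continuous")
}

#' Rasterize line segments onto grid cells
#'
#' Bresenham-style traversal of each segment expressed in cell coordinates;
#' used to turn road vectors (x1,y1,x2,y2 per row) into feature cells for
#' [distance_to_features()]. Endpoints outside the grid are clipped to it.
#'
#' @param grid a [grid_spec()].
#' @param segments data frame or matrix with columns x1, y1, x2, y2.
#' @return integer vector of unique cell indices touched.
#' @export
rasterize_segments <- function(grid, segments) {
  segments <- as.data.frame(segments)
  need <- c("x1", "y1", "x2", "y2")
  if (!all(need %in% names(segments))) stop("segments need columns x1,y1,x2,y2")
  to_rc <- function(x, y) {
    c(row = min(max(floor((grid$origin_y - y) / grid$cell_size) + 1, 1), grid$n_rows),
      col = min(max(floor((x - grid$origin_x) / grid$cell_size) + 1, 1), grid$n_cols))
  }
  cells <- integer(0)
  for (k in seq_len(nrow(segments))) {
    p0 <- to_rc(segments$x1[k], segments$y1[k])
    p1 <- to_rc(segments$x2[k], segments$y2[k])
    dr <- abs(p1["row"] - p0["row"]); dc <- abs(p1["col"] - p0["col"])
    n <- max(dr, dc)
    if (n == 0) {
      cells <- c(cells, rowcol_to_cell(grid, p0["row"], p0["col"]))
    } else {
      t <- seq(0, 1, length.out = n + 1)
      rr <- round(p0["row"] + t * (p1["row"] - p0["row"]))
      cc <- round(p0["col"] + t * (p1["col"] - p0["col"]))
      cells <- c(cells, rowcol_to_cell(grid, rr, cc))
    }
  }
  sort(unique(cells))
}
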