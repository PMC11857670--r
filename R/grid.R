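#' Grid geometry for aligned raster layers
#'
#' A `grid_spec` describes a regular, square-celled raster grid: dimensions,
#' cell size, the coordinate of the top-left corner, an opaque CRS tag, and
#' the nodata sentinel. Rows increase southward; all point-to-cell mapping
#' uses half-open cell intervals.
#'
#' @param n_rows,n_cols positive integers, grid dimensions.
#' @param cell_size positive cell edge length in map units (cells are square).
#' @param origin_x,origin_y map coordinates of the grid's top-left corner.
#' @param crs_tag opaque string passed through to outputs.
#' @param nodata_value sentinel for missing cells (default -9999).
#' @return an object of class `grid_spec`.
#' @export
grid_spec <- function(n_rows, n_cols, cell_size, origin_x = 0, origin_y = n_rows * cell_size,
                      crs_tag = "", nodata_value = -9999) {
  stopifnot(n_rows >= 1, n_cols >= 1, cell_size > 0)
  structure(list(
    n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
    cell_size = as.numeric(cell_size),
    origin_x = as.numeric(origin_x), origin_y = as.numeric(origin_y),
    crs_tag = as.character(crs_tag), nodata_value = as.numeric(nodata_value)
  ), class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("grid_spec: %d x %d cells, cell_size %g, origin (%g, %g)\n",
              x$n_rows, x$n_cols, x$cell_size, x$origin_x, x$origin_y))
  invisible(x)
}

#' Test whether two grid specs are aligned
#'
#' Aligned means every field except the CRS tag compares equal.
#' @param a,b `grid_spec` objects.
#' @return logical scalar.
#' @export
grids_aligned <- function(a, b) {
  isTRUE(a$n_rows == b$n_rows && a$n_cols == b$n_cols &&
           isTRUE(all.equal(a$cell_size, b$cell_size)) &&
           isTRUE(all.equal(a$origin_x, b$origin_x)) &&
           isTRUE(all.equal(a$origin_y, b$origin_y)) &&
           isTRUE(all.equal(a$nodata_value, b$nodata_value)))
}

#' A single environmental covariate raster
#'
#' @param name layer name (unique within a stack).
#' @param values numeric matrix `n_rows x n_cols`; `NA` marks nodata.
#' @param grid a [grid_spec()].
#' @param kind `"continuous"` or `"categorical"`. Categorical layers must
#'   hold integer codes (or `NA`).
#' @return an object of class `env_layer`.
#' @export
env_layer <- function(name, values, grid, kind = c("continuous", "categorical")) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("layer values must be numeric")
  if (nrow(values) != grid$n_rows || ncol(values) != grid$n_cols)
    stop(sprintf("layer '%s': values are %d x %d but grid is %d x %d",
                 name, nrow(values), ncol(values), grid$n_rows, grid$n_cols))
  fin <- values[!is.na(values)]
  if (any(!is.finite(fin))) stop(sprintf("layer '%s': non-finite values", name))
  if (kind == "categorical" && length(fin) && any(fin != round(fin)))
    stop(sprintf("layer '%s': categorical layers must contain integer codes", name))
  structure(list(name = as.character(name), kind = kind,
                 values = values, grid = grid),
            class = "env_layer")
}

#' @export
print.env_layer <- function(x, ...) {
  cat(sprintf("env_layer '%s' (%s): %d x %d, %d nodata cells\n",
              x$name, x$kind, nrow(x$values), ncol(x$values), sum(is.na(x$values))))
  invisible(x)
}

#' An aligned multi-layer environmental stack
#'
#' Layers must share one grid and have unique names. The valid mask marks
#' cells where every layer has data.
#'
#' @param layers list of [env_layer()] objects on one grid.
#' @return an object of class `env_stack` with elements `layers`, `grid`,
#'   `valid_mask` (logical matrix).
#' @export
env_stack <- function(layers) {
  stopifnot(length(layers) >= 1)
  nms <- vapply(layers, function(l) l$name, "")
  if (anyDuplicated(nms)) stop("duplicate layer names: ",
                               paste(unique(nms[duplicated(nms)]), collapse = ", "))
  grid <- layers[[1]]$grid
  for (l in layers[-1])
    if (!grids_aligned(l$grid, grid))
      stop(sprintf("layer '%s' is not aligned with the stack grid", l$name))
  valid <- Reduce(`&`, lapply(layers, function(l) !is.na(l$values)))
  names(layers) <- nms
  structure(list(layers = layers, grid = grid, valid_mask = valid),
            class = "env_stack")
}

#' @export
print.env_stack <- function(x, ...) {
  cat(sprintf("env_stack: %d layers on a %d x %d grid (%d valid cells)\n",
              length(x$layers), x$grid$n_rows, x$grid$n_cols, sum(x$valid_mask)))
  for (l in x$layers) cat(sprintf("  - %s (%s)\n", l$name, l$kind))
  invisible(x)
}

#' Layer names of a stack
#' @param stack an [env_stack()].
#' @return character vector.
#' @export
layer_names <- function(stack) names(stack$layers)

## ---- cell indexing -------------------------------------------------------
## Cells are numbered row-major, 1-based: index = (row - 1) * n_cols + col.

#' Convert between cell indices and row/column pairs
#' @param grid a [grid_spec()].
#' @param cells integer vector of row-major, 1-based cell indices.
#' @return `cell_to_rowcol`: 2-column matrix (row, col); `rowcol_to_cell`:
#'   integer vector of indices.
#' @export
cell_to_rowcol <- function(grid, cells) {
  cells <- as.integer(cells)
  if (any(cells < 1L | cells > grid$n_rows * grid$n_cols))
    stop("cell index out of grid")
  cbind(row = (cells - 1L) %/% grid$n_cols + 1L,
        col = (cells - 1L) %% grid$n_cols + 1L)
}

#' @rdname cell_to_rowcol
#' @param row,col integer vectors of 1-based row/column positions.
#' @export
rowcol_to_cell <- function(grid, row, col) {
  stopifnot(all(row >= 1L & row <= grid$n_rows), all(col >= 1L & col <= grid$n_cols))
  as.integer((row - 1L) * grid$n_cols + col)
}

#' Map point coordinates to containing cells
#'
#' Uses half-open intervals: a point on a cell's west/north edge belongs to
#' that cell. Points outside the grid get `NA`.
#'
#' @param grid a [grid_spec()].
#' @param x,y numeric coordinate vectors.
#' @return integer vector of cell indices (`NA` when off-grid).
#' @export
point_to_cell <- function(grid, x, y) {
  col <- floor((x - grid$origin_x) / grid$cell_size) + 1
  row <- floor((grid$origin_y - y) / grid$cell_size) + 1
  ok <- col >= 1 & col <= grid$n_cols & row >= 1 & row <= grid$n_rows &
    is.finite(col) & is.finite(row)
  out <- rep(NA_integer_, length(x))
  out[ok] <- as.integer((row[ok] - 1) * grid$n_cols + col[ok])
  out
}

#' Coordinates of cell centers
#' @inheritParams cell_to_rowcol
#' @return 2-column matrix (x, y) of cell-center coordinates.
#' @export
cell_center <- function(grid, cells) {
  rc <- cell_to_rowcol(grid, cells)
  cbind(x = grid$origin_x + (rc[, "col"] - 0.5) * grid$cell_size,
        y = grid$origin_y - (rc[, "row"] - 0.5) * grid$cell_size)
}

## ---- ASCII grid I/O ------------------------------------------------------

#' Read a raster layer from an ESRI ASCII grid file
#'
#' The plain-text `.asc` interchange format: a 6-line header (`ncols`,
#' `nrows`, `xllcorner`, `yllcorner`, `cellsize`, `NODATA_value`) followed
#' by rows of values, northernmost row first. The format carries no layer
#' semantics, so `name` and `kind` are supplied by the caller (or a stack
#' manifest).
#'
#' @param path file path.
#' @param name layer name; defaults to the file base name.
#' @param kind `"continuous"` or `"categorical"`.
#' @param crs_tag optional CRS string recorded on the grid.
#' @return an [env_layer()].
#' @export
read_ascii_raster <- function(path, name = NULL,
                              kind = c("continuous", "categorical"),
                              crs_tag = "") {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("cannot read raster: ", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 7) stop("not an ASCII grid (too short): ", path)
  hdr <- list()
  for (i in 1:6) {
    parts <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]
    if (length(parts) != 2) stop("malformed ASCII grid header line: ", lines[i])
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize", "nodata_value")
  if (!all(need %in% names(hdr))) stop("incomplete ASCII grid header in ", path)
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  vals <- scan(text = paste(lines[-(1:6)], collapse = "\n"), quiet = TRUE)
  if (length(vals) != nr * nc)
    stop(sprintf("ASCII grid %s: expected %d values, found %d", path, nr * nc, length(vals)))
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == hdr$nodata_value] <- NA
  grid <- grid_spec(nr, nc, hdr$cellsize,
                    origin_x = hdr$xllcorner,
                    origin_y = hdr$yllcorner + nr * hdr$cellsize,
                    crs_tag = crs_tag, nodata_value = hdr$nodata_value)
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  env_layer(name, m, grid, kind)
}

#' Write a raster layer as an ESRI ASCII grid file
#'
#' Values are written at full double precision so read/write round-trips are
#' bit-identical.
#'
#' @param layer an [env_layer()] (or a suitability map).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_ascii_raster <- function(layer, path) {
  g <- layer$grid
  m <- layer$values
  m[is.na(m)] <- g$nodata_value
  hdr <- c(sprintf("ncols %d", g$n_cols),
           sprintf("nrows %d", g$n_rows),
           sprintf("xllcorner %.10g", g$origin_x),
           sprintf("yllcorner %.10g", g$origin_y - g$n_rows * g$cell_size),
           sprintf("cellsize %.10g", g$cell_size),
           sprintf("NODATA_value %.10g", g$nodata_value))
  body <- apply(m, 1, function(r) paste(format(r, digits = 17, trim = TRUE,
                                               scientific = FALSE), collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

## ---- alignment -----------------------------------------------------------

#' Resample layers onto a common target grid
#'
#' Each source layer is resampled to `target` by looking up, for every target
#' cell center, the source cell whose center is nearest (`method =
#' "nearest"`) or by bilinear interpolation between the four surrounding
#' source cell centers (`method = "bilinear"`). Categorical layers are only
#' admissible with nearest-neighbour resampling.
#'
#' @param layers list of [env_layer()] objects (possibly on differing grids).
#' @param target a [grid_spec()]; every source extent must cover it.
#' @param method `"nearest"` or `"bilinear"`.
#' @return an [env_stack()] on `target`.
#' @export
align_stack <- function(layers, target, method = c("nearest", "bilinear")) {
  method <- match.arg(method)
  out <- lapply(layers, function(l) {
    if (l$kind == "categorical" && method != "nearest")
      stop(sprintf("categorical layer '%s' requires method = \"nearest\"", l$name))
    if (grids_aligned(l$grid, target)) {
      env_layer(l$name, l$values, target, l$kind)
    } else {
      env_layer(l$name, resample_values(l, target, method), target, l$kind)
    }
  })
  env_stack(out)
}

## Target cell centers expressed in fractional source row/col coordinates.
resample_values <- function(layer, target, method) {
  sg <- layer$grid
  tc_col <- target$origin_x + (seq_len(target$n_cols) - 0.5) * target$cell_size
  tc_row <- target$origin_y - (seq_len(target$n_rows) - 0.5) * target$cell_size
  # fractional source index of each target center (1-based, center-of-cell)
  fc <- (tc_col - sg$origin_x) / sg$cell_size + 0.5
  fr <- (sg$origin_y - tc_row) / sg$cell_size + 0.5
  eps <- 1e-9
  if (any(fc < 0.5 - eps | fc > sg$n_cols + 0.5 + eps) ||
      any(fr < 0.5 - eps | fr > sg$n_rows + 0.5 + eps))
    stop(sprintf("layer '%s' does not cover the target grid", layer$name))
  if (method == "nearest") {
    ic <- pmin(pmax(round(fc), 1L), sg$n_cols)
    ir <- pmin(pmax(round(fr), 1L), sg$n_rows)
    layer$values[ir, ic, drop = FALSE]
  } else {
    r0 <- pmin(pmax(floor(fr), 1L), sg$n_rows - 1L); r1 <- r0 + 1L
    c0 <- pmin(pmax(floor(fc), 1L), sg$n_cols - 1L); c1 <- c0 + 1L
    wr <- pmin(pmax(fr - r0, 0), 1); wc <- pmin(pmax(fc - c0, 0), 1)
    WR <- matrix(wr, target$n_rows, target$n_cols)
    WC <- matrix(wc, target$n_rows, target$n_cols, byrow = TRUE)
    v00 <- layer$values[r0, c0, drop = FALSE]
    v01 <- layer$values[r0, c1, drop = FALSE]
    v10 <- layer$values[r1, c0, drop = FALSE]
    v11 <- layer$values[r1, c1, drop = FALSE]
    (1 - WR) * ((1 - WC) * v00 + WC * v01) + WR * ((1 - WC) * v10 + WC * v11)
  }
}
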