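## Presence points, cell mapping, pseudo-absence sampling, and covariate
## extraction into a model design table.

#' Construct an occurrence set
#'
#' @param species species name.
#' @param presences data frame with columns `x`, `y`, `cell` (one row per
#'   retained presence record).
#' @param absences integer vector of pseudo-absence cell indices (may be
#'   empty before sampling).
#' @param seed integer seed used for absence generation (NA before).
#' @return an object of class `occurrence_set`.
#' @export
occurrence_set <- function(species, presences, absences = integer(0), seed = NA_integer_) {
  stopifnot(is.data.frame(presences), all(c("x", "y", "cell") %in% names(presences)))
  if (length(absences) && any(absences %in% presences$cell))
    stop("absences must be disjoint from presence cells")
  structure(list(species = as.character(species), presences = presences,
                 absences = as.integer(absences), seed = seed),
            class = "occurrence_set")
}

#' @export
print.occurrence_set <- function(x, ...) {
  cat(sprintf("occurrence_set '%s': %d presences, %d pseudo-absences (seed %s)\n",
              x$species, nrow(x$presences), length(x$absences),
              ifelse(is.na(x$seed), "unset", x$seed)))
  invisible(x)
}

#' Load presence records from CSV and snap them to grid cells
#'
#' The CSV must have columns `species`, `x`, `y` (raster CRS coordinates).
#' Points are mapped to their containing cell with half-open intervals;
#' points off the grid or on invalid cells are dropped and counted.
#'
#' @param path CSV path (or a data frame with the same columns).
#' @param grid a [grid_spec()].
#' @param valid_mask optional logical matrix; presences on invalid cells are
#'   dropped.
#' @param dedupe keep at most one presence per cell (first record wins);
#'   default TRUE to avoid pseudo-replication at camera stations.
#' @return named list of `occurrence_set` (presences only), one per species,
#'   each carrying a `drop_log` attribute with counts of discarded points.
#' @export
load_occurrences <- function(path, grid, valid_mask = NULL, dedupe = TRUE) {
  df <- if (is.data.frame(path)) path else utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("species", "x", "y")
  if (!all(need %in% names(df)))
    stop("occurrence table must have columns species,x,y")
  if (!is.numeric(df$x) || !is.numeric(df$y))
    stop("occurrence coordinates must be numeric")
  cells <- point_to_cell(grid, df$x, df$y)
  off_grid <- is.na(cells)
  invalid <- rep(FALSE, length(cells))
  if (!is.null(valid_mask)) {
    on <- !off_grid
    rc <- cbind((cells[on] - 1L) %/% grid$n_cols + 1L,
                (cells[on] - 1L) %% grid$n_cols + 1L)
    invalid[on] <- !valid_mask[rc]
  }
  ok <- !off_grid & !invalid
  out <- lapply(split(seq_len(nrow(df))[ok], df$species[ok]), function(idx) {
    pres <- data.frame(x = df$x[idx], y = df$y[idx], cell = cells[idx])
    dup <- 0L
    if (dedupe) {
      dup <- sum(duplicated(pres$cell))
      pres <- pres[!duplicated(pres$cell), , drop = FALSE]
    }
    os <- occurrence_set(df$species[idx][1], pres)
    attr(os, "drop_log") <- c(off_grid = sum(off_grid & df$species == df$species[idx][1]),
                              invalid = sum(invalid & df$species == df$species[idx][1]),
                              dedupe = dup)
    os
  })
  out
}

#' Sample pseudo-absence cells
#'
#' Draws `n` distinct cells uniformly without replacement from the valid
#' cells excluding presence cells; reproducible given `seed`.
#'
#' @param grid a [grid_spec()].
#' @param valid_mask logical matrix of usable cells.
#' @param presence_cells integer vector of cells to exclude.
#' @param n number of absences (conventionally equal to the presence count).
#' @param seed integer seed.
#' @return integer vector of `n` cell indices.
#' @export
sample_pseudo_absences <- function(grid, valid_mask, presence_cells, n, seed) {
  vm <- t(valid_mask)               # transpose: row-major cell numbering
  eligible <- which(as.vector(vm))
  eligible <- setdiff(eligible, as.integer(presence_cells))
  if (n > length(eligible))
    stop(sprintf("cannot draw %d absences from %d eligible cells", n, length(eligible)))
  with_seed(seed, sample(eligible, n, replace = FALSE))
}

#' Attach pseudo-absences to an occurrence set
#'
#' Convenience wrapper: samples presence-count-matched absences (the
#' convention of presence/background ensemble workflows) and records the seed.
#'
#' @param occ an `occurrence_set` with presences only.
#' @param stack an [env_stack()] supplying grid and valid mask.
#' @param seed integer seed.
#' @param n absence count; default matches the number of presence records.
#' @return the `occurrence_set` with `absences` and `seed` filled in.
#' @export
add_pseudo_absences <- function(occ, stack, seed, n = nrow(occ$presences)) {
  abs_cells <- sample_pseudo_absences(stack$grid, stack$valid_mask,
                                      occ$presences$cell, n, seed)
  occurrence_set(occ$species, occ$presences, abs_cells, seed)
}

#' Extract a model design table for a set of cells
#'
#' One row per cell. Continuous layers contribute their raw values;
#' a categorical layer is expanded to one-hot indicator columns
#' (`<layer>_<code>`) over the codes present in the full stack, so train and
#' prediction schemas agree. Column order is deterministic (stack order).
#'
#' @param cells integer vector of cell indices (must be valid cells).
#' @param stack an [env_stack()].
#' @param layers optional subset of layer names (default all).
#' @return data frame with attribute `continuous` naming the non-indicator
#'   columns.
#' @export
extract_covariates <- function(cells, stack, layers = NULL) {
  if (is.null(layers)) layers <- layer_names(stack)
  cells <- as.integer(cells)
  rc <- cell_to_rowcol(stack$grid, cells)
  if (any(!stack$valid_mask[rc])) stop("extract_covariates: cell on nodata")
  cols <- list(); cont <- character(0)
  for (nm in layers) {
    l <- stack$layers[[nm]]
    if (is.null(l)) stop("unknown layer: ", nm)
    v <- l$values[rc]
    if (l$kind == "continuous") {
      cols[[nm]] <- v
      cont <- c(cont, nm)
    } else {
      codes <- sort(unique(l$values[stack$valid_mask]))
      for (cd in codes) cols[[sprintf("%s_%d", nm, as.integer(cd))]] <- as.numeric(v == cd)
    }
  }
  out <- as.data.frame(cols, check.names = FALSE)
  attr(out, "continuous") <- cont
  out
}

#' Labelled design table for an occurrence set
#'
#' Rows are presences (label 1) followed by pseudo-absences (label 0);
#' classes are exactly balanced when absences were count-matched.
#'
#' @param occ an `occurrence_set` with absences attached.
#' @param stack an [env_stack()].
#' @param layers optional layer subset.
#' @return list with `X` (design data frame) and `y` (0/1 integer vector).
#' @export
design_table <- function(occ, stack, layers = NULL) {
  if (!length(occ$absences)) stop("occurrence set has no pseudo-absences")
  cells <- c(occ$presences$cell, occ$absences)
  X <- extract_covariates(cells, stack, layers)
  list(X = X, y = c(rep(1L, nrow(occ$presences)), rep(0L, length(occ$absences))),
       cells = cells)
}
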