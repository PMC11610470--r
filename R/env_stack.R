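# env_layers module: multivariate raster stacks, accessible areas (M),
# variable pre-filtering and point extraction.
#
# Grids follow the north-up raster convention: row 1 is the northernmost row,
# cells are addressed (row, col). A point (x, y) belongs to the half-open cell
# [x0 + (c-1)*s, x0 + c*s) x (ytop - r*s, ytop - (r-1)*s], where x0 is the
# west edge, ytop the north edge and s the cell size.

#' Construct an environmental raster stack for one time period
#'
#' An `env_stack` bundles co-registered single-variable grids for one climate
#' period (e.g. the 19 bioclimatic variables for 1950-1979) with a shared
#' geometry and a validity mask. The validity mask is the intersection of the
#' per-layer data masks: a cell is valid only when every variable has data
#' there.
#'
#' @param variables named list of numeric matrices (identical dimensions);
#'   `NA` encodes nodata. Variable order is preserved.
#' @param period_label character period tag, e.g. `"T1"`.
#' @param geometry list with `xll`, `yll` (south-west corner), `cellsize`,
#'   and optionally `crs`. Row/column counts come from the matrices.
#' @return an object of class `env_stack`.
#' @export
env_stack <- function(variables, period_label,
                      geometry = list(xll = 0, yll = 0, cellsize = 1,
                                      crs = "unspecified")) {
  if (!is.list(variables) || length(variables) < 1L)
    stop_arg("`variables` must be a non-empty named list of matrices")
  nm <- names(variables)
  if (is.null(nm) || any(nm == "") || anyDuplicated(nm))
    stop_arg("variable names must be unique and non-empty")
  dims <- dim(variables[[1L]])
  for (i in seq_along(variables)) {
    if (!is.matrix(variables[[i]]) || !is.numeric(variables[[i]]))
      stop_arg("variable '", nm[i], "' is not a numeric matrix")
    if (!identical(dim(variables[[i]]), dims))
      stop_arg("alignment error: variable '", nm[i], "' has dimensions ",
               paste(dim(variables[[i]]), collapse = "x"),
               ", expected ", paste(dims, collapse = "x"))
  }
  mask <- Reduce(`&`, lapply(variables, function(m) !is.na(m)))
  geometry$nrow <- dims[1L]
  geometry$ncol <- dims[2L]
  geometry$crs <- geometry$crs %||% "unspecified"
  structure(list(variables = variables, period = period_label,
                 geometry = geometry, mask = mask),
            class = "env_stack")
}

#' @export
print.env_stack <- function(x, ...) {
  g <- x$geometry
  cat(sprintf("env_stack '%s': %d variable(s), %d x %d cells (%d valid)\n",
              x$period, length(x$variables), g$nrow, g$ncol, sum(x$mask)))
  cat("  variables:", paste(names(x$variables), collapse = ", "), "\n")
  invisible(x)
}

n_cells <- function(stack) stack$geometry$nrow * stack$geometry$ncol

# (row, col) <-> linear cell index, row-major, 1-based
cell_index <- function(stack, row, col) (row - 1L) * stack$geometry$ncol + col
cell_rowcol <- function(stack, cell) {
  col <- (cell - 1L) %% stack$geometry$ncol + 1L
  row <- (cell - 1L) %/% stack$geometry$ncol + 1L
  cbind(row = row, col = col)
}

# Row-major linear indices of TRUE cells of a logical matrix
mask_cells <- function(mask) which(t(mask))

# Matrix of variable values (cells x variables) for given linear cell indices
cell_values <- function(stack, cells) {
  rc <- cell_rowcol(stack, cells)
  out <- vapply(stack$variables,
                function(m) m[cbind(rc[, "row"], rc[, "col"])],
                numeric(length(cells)))
  if (length(cells) == 1L) out <- matrix(out, nrow = 1L,
                                         dimnames = list(NULL, names(stack$variables)))
  out
}

# Cell-center coordinates for linear cell indices
cell_centers <- function(stack, cells) {
  g <- stack$geometry
  rc <- cell_rowcol(stack, cells)
  ytop <- g$yll + g$nrow * g$cellsize
  cbind(x = g$xll + (rc[, "col"] - 0.5) * g$cellsize,
        y = ytop - (rc[, "row"] - 0.5) * g$cellsize)
}

# Point coordinates -> (row, col); NA row/col for out-of-bounds points
point_to_rowcol <- function(stack, x, y) {
  g <- stack$geometry
  ytop <- g$yll + g$nrow * g$cellsize
  col <- floor((x - g$xll) / g$cellsize) + 1
  row <- floor((ytop - y) / g$cellsize) + 1
  # points exactly on the north/west edges belong to the first row/column
  row[y == ytop] <- 1
  bad <- col < 1 | col > g$ncol | row < 1 | row > g$nrow |
    !is.finite(x) | !is.finite(y)
  col[bad] <- NA_integer_
  row[bad] <- NA_integer_
  cbind(row = as.integer(row), col = as.integer(col))
}

same_geometry <- function(a, b) {
  ga <- a$geometry; gb <- b$geometry
  isTRUE(ga$nrow == gb$nrow) && isTRUE(ga$ncol == gb$ncol) &&
    isTRUE(all.equal(ga$xll, gb$xll)) && isTRUE(all.equal(ga$yll, gb$yll)) &&
    isTRUE(all.equal(ga$cellsize, gb$cellsize))
}

#' Load an environmental stack from single-variable raster files
#'
#' Reads one ESRI ASCII grid (`.asc`) per variable and assembles an
#' [env_stack()]. All layers must share the same geometry; a mismatch is an
#' alignment error naming the offending layer, never a silent resample.
#'
#' @param paths named character vector of file paths; names become variable
#'   names (basenames without extension when unnamed).
#' @param period_label character period tag.
#' @return an `env_stack`.
#' @seealso [read_asc()], [load_stack_manifest()]
#' @export
load_stack <- function(paths, period_label) {
  if (length(paths) < 1L) stop_arg("at least one raster path required")
  nm <- names(paths)
  if (is.null(nm)) nm <- sub("\\.[^.]*$", "", basename(paths))
  layers <- vector("list", length(paths))
  geom <- NULL
  for (i in seq_along(paths)) {
    r <- read_asc(paths[[i]])
    if (is.null(geom)) {
      geom <- r$geometry
    } else if (!(r$geometry$nrow == geom$nrow && r$geometry$ncol == geom$ncol &&
                 isTRUE(all.equal(r$geometry$xll, geom$xll)) &&
                 isTRUE(all.equal(r$geometry$yll, geom$yll)) &&
                 isTRUE(all.equal(r$geometry$cellsize, geom$cellsize)))) {
      stop_arg("alignment error: layer '", nm[i], "' (", paths[[i]],
               ") does not match the geometry of the first layer")
    }
    layers[[i]] <- r$data
  }
  names(layers) <- nm
  env_stack(layers, period_label, geom)
}

#' Load a two-period stack pair from a manifest file
#'
#' The manifest is a YAML file with one top-level key per period, each mapping
#' variable names to raster paths:
#' ```yaml
#' T1: {bio1: t1/bio1.asc, bio12: t1/bio12.asc}
#' T2: {bio1: t2/bio1.asc, bio12: t2/bio12.asc}
#' ```
#' Relative paths are resolved against the manifest's directory. Both periods
#' must list the same variables and share one geometry.
#'
#' @param path manifest file path.
#' @return named list of `env_stack`, one per period.
#' @export
load_stack_manifest <- function(path) {
  man <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  stacks <- lapply(names(man), function(per) {
    p <- unlist(man[[per]])
    abs <- ifelse(grepl("^(/|[A-Za-z]:)", p), p, file.path(base, p))
    names(abs) <- names(p)
    load_stack(abs, per)
  })
  names(stacks) <- names(man)
  if (length(stacks) >= 2L)
    for (i in 2:length(stacks))
      if (!same_geometry(stacks[[1L]], stacks[[i]]))
        stop_arg("alignment error: period '", names(stacks)[i],
                 "' geometry differs from period '", names(stacks)[1L], "'")
  vars1 <- names(stacks[[1L]]$variables)
  for (s in stacks[-1L])
    if (!setequal(vars1, names(s$variables)))
      stop_arg("periods list different variable sets")
  stacks
}

#' Define an accessible area (M)
#'
#' @param mask logical matrix, `TRUE` inside M; must be a subset of the
#'   stack's validity mask.
#' @param stack the `env_stack` M belongs to.
#' @param source_polygons identifiers of contributing ecoregions (optional).
#' @return object of class `accessible_area`.
#' @export
accessible_area <- function(mask, stack, source_polygons = integer(0)) {
  if (!identical(dim(mask), dim(stack$mask)))
    stop_arg("mask dimensions do not match the stack")
  mask <- mask & stack$mask   # M is always within valid data
  structure(list(mask = mask, geometry = stack$geometry,
                 source_polygons = source_polygons),
            class = "accessible_area")
}

#' @export
print.accessible_area <- function(x, ...) {
  cat(sprintf("accessible_area: %d cells (of %d grid cells)\n",
              sum(x$mask), length(x$mask)))
  invisible(x)
}

#' Accessible area covering the whole valid grid
#'
#' Convenience constructor for the synthetic-world setting where dispersal is
#' unconstrained and M equals the full valid grid.
#'
#' @param stack an `env_stack`.
#' @return an `accessible_area`.
#' @export
full_area <- function(stack) accessible_area(stack$mask, stack)

#' Delimit the accessible area (M) from ecoregions and occurrences
#'
#' M is the union of the cells of every ecoregion containing at least one
#' occurrence, intersected with the stack's validity mask — the standard
#' BAM-style accessibility delineation under the assumption that ecoregion
#' boundaries act as dispersal barriers. Ecoregions are supplied as a
#' co-registered integer raster of region identifiers. In synthetic mode
#' (`ecoregions = NULL`) M is a caller-specified rectangle, defaulting to the
#' full valid grid.
#'
#' @param stack an `env_stack`.
#' @param ecoregions integer matrix of region ids on the stack grid (`NA` =
#'   no region), or `NULL` for synthetic mode.
#' @param occurrences an `occurrence_set` on the same grid.
#' @param rectangle synthetic mode only: `c(row_min, row_max, col_min,
#'   col_max)`, or `NULL` for the full grid.
#' @return an `accessible_area`.
#' @export
clip_to_accessible_area <- function(stack, ecoregions, occurrences,
                                    rectangle = NULL) {
  if (nrow(occurrences$records) == 0L) stop_arg("occurrence set is empty")
  if (is.null(ecoregions)) {
    mask <- matrix(FALSE, stack$geometry$nrow, stack$geometry$ncol)
    if (is.null(rectangle)) {
      mask[] <- TRUE
    } else {
      mask[rectangle[1L]:rectangle[2L], rectangle[3L]:rectangle[4L]] <- TRUE
    }
    return(accessible_area(mask, stack))
  }
  if (!identical(dim(ecoregions), dim(stack$mask)))
    stop_arg("ecoregion raster does not match the stack grid")
  rc <- cbind(occurrences$records$row, occurrences$records$col)
  occupied <- unique(ecoregions[rc])
  occupied <- occupied[!is.na(occupied)]
  if (length(occupied) == 0L)
    stop_arg("empty-M error: no occurrence falls inside any ecoregion")
  mask <- matrix(ecoregions %in% occupied, nrow(ecoregions), ncol(ecoregions))
  accessible_area(mask, stack, source_polygons = sort(occupied))
}

#' Greedy Pearson pre-filter of correlated variables
#'
#' Computes pairwise Pearson correlations over the cells of the accessible
#' area and repeatedly drops, among the variables currently involved in a
#' pair with |r| above the threshold, the one with the highest mean absolute
#' correlation to the others (ties broken by input order), until no offending
#' pair remains. Zero-variance variables are dropped first with a warning.
#'
#' @param stack an `env_stack`.
#' @param area an `accessible_area` with at least 3 cells.
#' @param threshold maximum tolerated |r| (default 0.80).
#' @return character vector of retained variable names, in input order.
#' @export
select_uncorrelated_variables <- function(stack, area, threshold = 0.80) {
  if (length(stack$variables) < 2L)
    stop_arg("need at least 2 variables to screen correlations")
  cells <- mask_cells(area$mask)
  if (length(cells) < 3L) stop_arg("accessible area has fewer than 3 cells")
  vals <- cell_values(stack, cells)
  sds <- apply(vals, 2L, stats::sd)
  keep <- names(stack$variables)
  if (any(sds == 0 | is.na(sds))) {
    dropped <- keep[sds == 0 | is.na(sds)]
    warning("dropping constant variable(s): ", paste(dropped, collapse = ", "),
            call. = FALSE)
    keep <- setdiff(keep, dropped)
    if (length(keep) < 2L) return(keep)
    vals <- vals[, keep, drop = FALSE]
  }
  cm <- abs(stats::cor(vals))
  diag(cm) <- 0
  while (TRUE) {
    offend <- which(cm > threshold, arr.ind = TRUE)
    if (nrow(offend) == 0L) break
    involved <- sort(unique(as.vector(offend)))
    mean_r <- vapply(involved, function(i) mean(cm[i, -i]), numeric(1))
    # drop the highest mean |r|; on ties the later variable goes, so earlier
    # input order wins
    drop_i <- involved[order(-mean_r, -involved)][1L]
    cm <- cm[-drop_i, -drop_i, drop = FALSE]
    keep <- keep[-drop_i]
  }
  keep
}

#' Keep only a subset of variables in a stack
#'
#' @param stack an `env_stack`.
#' @param variables character vector of variable names to retain.
#' @return an `env_stack` restricted to `variables` (in the given order).
#' @export
subset_stack <- function(stack, variables) {
  missing <- setdiff(variables, names(stack$variables))
  if (length(missing))
    stop_arg("variables not in stack: ", paste(missing, collapse = ", "))
  env_stack(stack$variables[variables], stack$period, stack$geometry)
}

#' Extract per-point variable values from a stack
#'
#' Each point maps to the value of the cell containing it (half-open cell
#' convention). Points on nodata cells are flagged (`valid = FALSE`) and
#' carry `NA` values so downstream fitting can exclude them.
#'
#' @param stack an `env_stack`.
#' @param points two-column matrix or data.frame of x/y (lon/lat) coordinates.
#' @return data.frame with `point`, `row`, `col`, `cell`, `valid` and one
#'   column per variable.
#' @export
extract_values <- function(stack, points) {
  points <- as.matrix(points)
  rc <- point_to_rowcol(stack, points[, 1L], points[, 2L])
  oob <- which(is.na(rc[, "row"]))
  if (length(oob))
    stop_arg("bounds error: point(s) outside grid: index ",
             paste(oob, collapse = ", "))
  valid <- stack$mask[rc]
  cells <- cell_index(stack, rc[, "row"], rc[, "col"])
  vals <- cell_values(stack, cells)
  vals[!valid, ] <- NA_real_
  out <- data.frame(point = seq_len(nrow(points)), row = rc[, "row"],
                    col = rc[, "col"], cell = cells, valid = valid)
  cbind(out, as.data.frame(vals))
}
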