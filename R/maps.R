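# Suitability and binary map containers, the ten-percentile threshold and
# binarization.

#' Construct a suitability map
#'
#' @param grid numeric matrix on the stack geometry; values in \[0, 1\] where
#'   defined, `NA` elsewhere.
#' @param geometry grid geometry (as in [env_stack()]).
#' @param algorithm name of the producing algorithm.
#' @return object of class `suitability_map`.
#' @export
suitability_map <- function(grid, geometry, algorithm = "unknown") {
  rng <- range(grid, na.rm = TRUE)
  if (is.finite(rng[1L]) && (rng[1L] < -1e-9 || rng[2L] > 1 + 1e-9))
    stop_arg("suitability values outside [0, 1]")
  structure(list(grid = grid, geometry = geometry, algorithm = algorithm),
            class = "suitability_map")
}

# Assemble a suitability_map from per-cell predictions (row-major cells)
suitability_map_from_cells <- function(stack, cells, values, algorithm) {
  grid <- matrix(NA_real_, stack$geometry$nrow, stack$geometry$ncol)
  rc <- cell_rowcol(stack, cells)
  grid[rc] <- pmin(1, pmax(0, values))
  suitability_map(grid, stack$geometry, algorithm)
}

#' Ten-percentile presence threshold
#'
#' The threshold is the value at 0-based index `floor(0.1 * n)` of the
#' ascending sort of the calibration-presence suitabilities, so that
#' binarizing at `suitability >= threshold` retains at least 90% of the
#' calibration presences while trimming the lowest-scoring tail (guarding
#' against overprediction from erroneous records).
#'
#' @param suitability_at_presences numeric vector of suitability values at
#'   the calibration presence records.
#' @return the threshold (a value from the input).
#' @export
ten_percentile_threshold <- function(suitability_at_presences) {
  v <- suitability_at_presences
  if (length(v) == 0L) stop_arg("empty suitability vector")
  if (anyNA(v)) stop_arg("suitability vector contains NA")
  sort(v)[floor(0.1 * length(v)) + 1L]
}

#' Binarize a suitability map
#'
#' Cells with suitability at or above the threshold become presence (1),
#' below become absence (0); undefined cells stay `NA`.
#'
#' @param map a `suitability_map`.
#' @param threshold numeric threshold in \[0, 1\].
#' @return object of class `binary_map` with field `threshold_used`.
#' @export
binarize <- function(map, threshold) {
  if (threshold < 0 || threshold > 1) stop_arg("threshold must be in [0, 1]")
  grid <- ifelse(map$grid >= threshold, 1, 0)
  structure(list(grid = grid, geometry = map$geometry,
                 algorithm = map$algorithm, threshold_used = threshold),
            class = "binary_map")
}

#' @export
print.suitability_map <- function(x, ...) {
  cat(sprintf("suitability_map [%s]: %d defined cells, range %.3f-%.3f\n",
              x$algorithm, sum(!is.na(x$grid)),
              min(x$grid, na.rm = TRUE), max(x$grid, na.rm = TRUE)))
  invisible(x)
}

#' @export
print.binary_map <- function(x, ...) {
  cat(sprintf("binary_map [%s]: %d presence / %d absence cells (threshold %.4f)\n",
              x$algorithm, sum(x$grid == 1, na.rm = TRUE),
              sum(x$grid == 0, na.rm = TRUE), x$threshold_used))
  invisible(x)
}
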