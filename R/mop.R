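# mop_analysis module: Mobility-Oriented Parity. Quantifies the multivariate
# environmental similarity between a calibration (reference) scenario and a
# projection scenario, and maps cells requiring strict extrapolation — cells
# whose value on at least one variable lies outside the reference min-max.

#' Mobility-Oriented Parity analysis
#'
#' For each projection cell the MOP distance is the mean Euclidean distance
#' (in variable space) to its nearest `ceiling(reference_fraction * N_ref)`
#' reference cells. With `standardize = TRUE` (default) variables are scaled
#' to reference mean/SD so the distance is scale-free. Strict extrapolation
#' is flagged on the raw values via the range rule.
#'
#' @param reference,projection `env_stack`s sharing one variable set.
#' @param reference_fraction fraction of the reference cloud defining the
#'   nearest subset, in (0, 1\] (default 0.1, the common convention).
#' @param standardize scale variables to reference mean/SD before distances.
#' @param reference_area,projection_area optional `accessible_area`s
#'   restricting each scenario (default: each stack's full valid grid).
#' @return object of class `mop_result`: `distance_surface` (matrix, `NA`
#'   outside the projection domain), `strict_extrapolation_mask` (logical
#'   matrix) and `reference_fraction`.
#' @export
compute_mop <- function(reference, projection, reference_fraction = 0.1,
                        standardize = TRUE,
                        reference_area = full_area(reference),
                        projection_area = full_area(projection)) {
  if (!setequal(names(reference$variables), names(projection$variables)))
    stop_arg("reference and projection variable sets differ")
  if (reference_fraction <= 0 || reference_fraction > 1)
    stop_arg("reference_fraction must be in (0, 1]")
  vars <- sort(names(reference$variables))  # order-invariant distances
  ref_cells <- mask_cells(reference_area$mask)
  prj_cells <- mask_cells(projection_area$mask)
  if (length(ref_cells) < 1L) stop_arg("reference scenario has no valid cells")
  R <- cell_values(reference, ref_cells)[, vars, drop = FALSE]
  P <- cell_values(projection, prj_cells)[, vars, drop = FALSE]

  # range rule on raw values
  lo <- apply(R, 2L, min); hi <- apply(R, 2L, max)
  strict <- rowSums(sweep(P, 2L, lo, `<`) | sweep(P, 2L, hi, `>`)) > 0

  if (standardize) {
    mu <- colMeans(R)
    sd_ <- apply(R, 2L, stats::sd)
    sd_[sd_ == 0 | is.na(sd_)] <- 1
    R <- sweep(sweep(R, 2L, mu), 2L, sd_, `/`)
    P <- sweep(sweep(P, 2L, mu), 2L, sd_, `/`)
  }
  k <- ceiling(reference_fraction * nrow(R))
  rsq <- rowSums(R^2)
  dist_mean_k <- numeric(nrow(P))
  chunk <- max(1L, floor(2e6 / max(1L, nrow(R))))
  for (start in seq(1L, nrow(P), by = chunk)) {
    idx <- start:min(nrow(P), start + chunk - 1L)
    # squared cross-distances via the expansion |p-r|^2 = |p|^2 - 2 p.r + |r|^2
    D2 <- outer(rowSums(P[idx, , drop = FALSE]^2), rsq, `+`) -
      2 * P[idx, , drop = FALSE] %*% t(R)
    D2[D2 < 0] <- 0
    dist_mean_k[idx] <- apply(D2, 1L, function(row)
      mean(sqrt(sort.int(row, partial = k)[seq_len(k)])))
  }
  g <- projection$geometry
  surf <- matrix(NA_real_, g$nrow, g$ncol)
  mask <- matrix(FALSE, g$nrow, g$ncol)
  rc <- cell_rowcol(projection, prj_cells)
  surf[rc] <- dist_mean_k
  mask[rc] <- strict
  structure(list(distance_surface = surf, strict_extrapolation_mask = mask,
                 reference_fraction = reference_fraction, geometry = g),
            class = "mop_result")
}

#' Percentage of an area requiring strict extrapolation
#'
#' @param result a `mop_result`.
#' @param area an `accessible_area` (or the full valid grid) over which to
#'   report.
#' @return percentage in \[0, 100\]: 100 x strict-extrapolation cells inside
#'   the area / defined cells inside the area.
#' @export
strict_extrapolation_percentage <- function(result, area) {
  if (!identical(dim(result$distance_surface), dim(area$mask)))
    stop_arg("MOP result and area are not aligned")
  defined <- area$mask & !is.na(result$distance_surface)
  n <- sum(defined)
  if (n == 0L) stop_arg("empty area")
  100 * sum(result$strict_extrapolation_mask & defined) / n
}
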