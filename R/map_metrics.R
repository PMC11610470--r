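# map_metrics module: pixel-by-pixel comparison of binary maps, the four
# transfer indices, map similarity, and exact binomial validation.
#
# The four indices are implemented exactly as printed in the source protocol:
#   (1) TSS = a/(a+c) + d/(b+d) - 1
#   (2) OI  = a/(a+c)
#   (3) eq3_rate = b/(b+d)   (printed under the label "FNR")
#   (4) eq4_rate = c/(a+c)   (printed under the label "FPR")
# Note the printed labels are swapped relative to the usual definitions:
# b/(b+d) is a false-positive (commission) rate and c/(a+c) an omission
# rate. Both rates are therefore exposed under the neutral names eq3_rate /
# eq4_rate, with `fpr_commission` and `fnr_omission` aliases carrying the
# conventional meanings (fpr_commission = eq3_rate, fnr_omission = eq4_rate).

#' Pixel-wise confusion counts between two binary maps
#'
#' Counts are taken over cells defined in both maps and inside the
#' accessible area: `a` reference-present and comparison-present, `b`
#' reference-absent and comparison-present, `c` reference-present and
#' comparison-absent, `d` both absent.
#'
#' @param reference,comparison `binary_map`s on the same geometry.
#' @param area an `accessible_area`.
#' @return list of class `confusion_counts` with fields `a`, `b`, `c`, `d`.
#' @export
confusion_counts <- function(reference, comparison, area) {
  if (!identical(dim(reference$grid), dim(comparison$grid)) ||
      !identical(dim(reference$grid), dim(area$mask)))
    stop_arg("alignment error: maps/area differ in geometry")
  ok <- area$mask & !is.na(reference$grid) & !is.na(comparison$grid)
  if (!any(ok)) stop_arg("empty comparison domain")
  r <- reference$grid[ok]
  m <- comparison$grid[ok]
  structure(list(a = sum(r == 1 & m == 1), b = sum(r == 0 & m == 1),
                 c = sum(r == 1 & m == 0), d = sum(r == 0 & m == 0)),
            class = "confusion_counts")
}

#' Transfer metrics from confusion counts
#'
#' @param counts a `confusion_counts` (or list with `a`, `b`, `c`, `d`).
#' @return list of class `transfer_metrics`: `tss`, `oi`, `eq3_rate`,
#'   `eq4_rate`, `fpr_commission` (= eq3_rate), `fnr_omission` (= eq4_rate),
#'   and `similarity` = (a+d)/(a+b+c+d), the simple-agreement proportion used
#'   by the 70% control gate.
#' @export
transfer_metrics <- function(counts) {
  a <- counts$a; b <- counts$b; cc <- counts$c; d <- counts$d
  if (any(c(a, b, cc, d) < 0)) stop_arg("negative confusion count")
  if (a + cc == 0 || b + d == 0)
    stop_arg("undefined-metric error: a+c and b+d must both be positive")
  oi <- a / (a + cc)
  eq3 <- b / (b + d)
  eq4 <- cc / (a + cc)
  structure(list(tss = oi + d / (b + d) - 1,
                 oi = oi, eq3_rate = eq3, eq4_rate = eq4,
                 fpr_commission = eq3, fnr_omission = eq4,
                 similarity = (a + d) / (a + b + cc + d)),
            class = "transfer_metrics")
}

#' Exact binomial validation of a binary map
#'
#' Tests whether the validation presences hit the predicted-presence area
#' more often than expected if they fell at random on M. The null success
#' probability is the predicted area fraction (presence cells / defined M
#' cells) and the p-value the exact upper tail
#' `P(X >= n_hits | n, fraction)`. Validation points off M are excluded and
#' counted.
#'
#' @param map a `binary_map`.
#' @param validation_presences an `occurrence_set`.
#' @param area an `accessible_area`.
#' @return list of class `binomial_validation`: `n_validation`, `n_hits`,
#'   `predicted_area_fraction`, `p_value`, `n_excluded`.
#' @export
binomial_validation <- function(map, validation_presences, area) {
  defined <- area$mask & !is.na(map$grid)
  n_def <- sum(defined)
  if (n_def == 0L) stop_arg("empty accessible area")
  frac <- sum(map$grid == 1 & defined) / n_def
  rc <- cbind(validation_presences$records$row, validation_presences$records$col)
  on_m <- defined[rc]
  n_excluded <- sum(!on_m)
  rc <- rc[on_m, , drop = FALSE]
  n <- nrow(rc)
  if (n < 1L) stop_arg("no validation presence falls on the comparison domain")
  hits <- sum(map$grid[rc] == 1)
  p <- stats::pbinom(hits - 1, n, frac, lower.tail = FALSE)
  structure(list(n_validation = n, n_hits = hits,
                 predicted_area_fraction = frac, p_value = p,
                 n_excluded = n_excluded),
            class = "binomial_validation")
}
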