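# Native Bioclim climatic-envelope implementation.
#
# Scoring follows the tail-symmetric percentile convention: for each variable
# the cell value is placed on the mid-ECDF of the calibration presence values,
# p = (#{v < x} + #{v <= x}) / (2n); the per-variable score is
# s = 1 - 2*|p - 0.5| (1 at the median, tapering to ~0 at the envelope edges),
# with s = 0 outside the calibration [min, max]. Cell suitability is the
# minimum score across variables — the classical rectilinear envelope.

#' Fit a Bioclim envelope
#'
#' Stores the per-variable calibration presence value distributions (sorted
#' values, min and max). Presence-only: no absences are used.
#'
#' @param presence_values data.frame or matrix of per-record variable values
#'   (rows = presence records, columns = variables); at least 1 record and 1
#'   variable (2+ records for a non-degenerate envelope).
#' @return object of class `bioclim_envelope`.
#' @export
fit_bioclim <- function(presence_values) {
  pv <- as.matrix(presence_values)
  if (nrow(pv) < 1L || ncol(pv) < 1L)
    stop_arg("need at least one presence record and one variable")
  if (anyNA(pv)) stop_arg("presence values contain NA")
  vars <- colnames(pv)
  if (is.null(vars)) vars <- paste0("v", seq_len(ncol(pv)))
  env <- lapply(seq_len(ncol(pv)), function(j) {
    v <- sort(pv[, j])
    list(sorted = v, min = v[1L], max = v[length(v)])
  })
  names(env) <- vars
  structure(list(envelope = env, variables = vars, n = nrow(pv)),
            class = "bioclim_envelope")
}

# Tail-symmetric envelope score of values x for one variable's envelope
bioclim_score_1d <- function(x, env1) {
  n <- length(env1$sorted)
  leq <- findInterval(x, env1$sorted)
  less <- findInterval(x, env1$sorted, left.open = TRUE)
  p <- (less + leq) / (2 * n)
  s <- 1 - 2 * abs(p - 0.5)
  s[x < env1$min | x > env1$max] <- 0
  s
}

# Suitability of a values matrix (rows x variables) under the envelope
bioclim_suitability <- function(envelope, values) {
  values <- as.matrix(values)
  miss <- setdiff(envelope$variables, colnames(values))
  if (length(miss))
    stop_arg("missing variable(s): ", paste(miss, collapse = ", "))
  scores <- vapply(envelope$variables, function(v)
    bioclim_score_1d(values[, v], envelope$envelope[[v]]),
    numeric(nrow(values)))
  if (nrow(values) == 1L) scores <- matrix(scores, nrow = 1L)
  apply(scores, 1L, min)
}

#' Project a Bioclim envelope onto a stack
#'
#' @param envelope a `bioclim_envelope`.
#' @param stack an `env_stack` containing all envelope variables.
#' @param area `accessible_area` to restrict prediction to (default: full
#'   valid grid).
#' @return a `suitability_map`.
#' @export
predict_bioclim <- function(envelope, stack, area = full_area(stack)) {
  miss <- setdiff(envelope$variables, names(stack$variables))
  if (length(miss))
    stop_arg("stack lacks variable(s): ", paste(miss, collapse = ", "))
  cells <- mask_cells(area$mask)
  vals <- cell_values(stack, cells)
  suit <- bioclim_suitability(envelope, vals)
  suitability_map_from_cells(stack, cells, suit, algorithm = "bioclim")
}
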