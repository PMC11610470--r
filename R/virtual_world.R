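# virtual_world module: paired-period synthetic climates and virtual species
# with analytically known niches, so the full framework can be exercised and
# benchmarked without any external data.

#' Configuration for a paired-period synthetic climate
#'
#' @param nrow,ncol grid dimensions.
#' @param n_variables number of climate variables.
#' @param smoothness moving-average window half-width (cells) for spatial
#'   autocorrelation.
#' @param shift per-variable between-period shift, in units of the period-1
#'   SD of that variable (length `n_variables`, recycled from a scalar).
#' @param noise_sd SD of fresh period-2 noise, in period-1 SD units.
#' @param variable_correlation pairwise correlation among variables induced
#'   by a shared latent field (default 0.6 — bioclimatic variables derived
#'   from the same temperature/precipitation surfaces are strongly
#'   inter-correlated, though kept below the 0.8 screening threshold).
#' @param seed integer seed.
#' @return object of class `synthetic_climate_config`.
#' @export
synthetic_climate_config <- function(nrow = 60, ncol = 60, n_variables = 3,
                                     smoothness = 8, shift = 0,
                                     noise_sd = 0, variable_correlation = 0.6,
                                     seed = 1L) {
  if (nrow < 1 || ncol < 1) stop_arg("grid dimensions must be positive")
  if (smoothness < 1) stop_arg("smoothness must be >= 1")
  if (variable_correlation < 0 || variable_correlation >= 1)
    stop_arg("variable_correlation must be in [0, 1)")
  shift <- rep_len(shift, n_variables)
  structure(list(nrow = as.integer(nrow), ncol = as.integer(ncol),
                 n_variables = as.integer(n_variables),
                 smoothness = smoothness, shift = shift,
                 noise_sd = noise_sd,
                 variable_correlation = variable_correlation,
                 seed = as.integer(seed)),
            class = "synthetic_climate_config")
}

# Smoothed Gaussian random field: white noise box-averaged in both axes.
smooth_field <- function(nr, nc, half_width) {
  w <- 2L * as.integer(half_width) + 1L
  pad <- (w - 1L) / 2L
  z <- matrix(stats::rnorm((nr + 2L * pad) * (nc + 2L * pad)),
              nr + 2L * pad, nc + 2L * pad)
  kern <- rep(1 / w, w)
  z <- apply(z, 2L, function(col) stats::filter(col, kern, sides = 2))
  z <- t(apply(z, 1L, function(row) stats::filter(row, kern, sides = 2)))
  z <- z[(pad + 1L):(pad + nr), (pad + 1L):(pad + nc)]
  (z - mean(z)) / stats::sd(z)
}

#' Generate a pair of co-registered synthetic climate stacks
#'
#' Period-1 variables are spatially smoothed Gaussian random fields
#' (standardized to mean 0, SD 1), inter-correlated through a shared latent
#' field at the configured level. Period 2 is period 1 plus the configured
#' per-variable shift (in period-1 SD units) plus fresh spatial noise —
#' emulating a directional climate change of controllable magnitude between
#' two climatologies on one grid.
#'
#' @param config a [synthetic_climate_config()].
#' @return list with elements `T1` and `T2`, both `env_stack`s.
#' @export
generate_climate_pair <- function(config) {
  stopifnot(inherits(config, "synthetic_climate_config"))
  with_seed(config$seed, {
    rho <- config$variable_correlation
    shared <- smooth_field(config$nrow, config$ncol, config$smoothness)
    vars1 <- lapply(seq_len(config$n_variables), function(v) {
      f <- sqrt(rho) * shared + sqrt(1 - rho) *
        smooth_field(config$nrow, config$ncol, config$smoothness)
      (f - mean(f)) / stats::sd(f)
    })
    vars2 <- lapply(seq_len(config$n_variables), function(v) {
      f <- vars1[[v]]
      s1 <- stats::sd(f)
      out <- f + config$shift[v] * s1
      if (config$noise_sd > 0)
        out <- out + config$noise_sd * s1 *
          smooth_field(config$nrow, config$ncol, config$smoothness)
      out
    })
    names(vars1) <- names(vars2) <- paste0("bio", seq_len(config$n_variables))
    list(T1 = env_stack(vars1, "T1"), T2 = env_stack(vars2, "T2"))
  })
}

#' Define a virtual species with a Gaussian niche
#'
#' True suitability is the Gaussian product
#' `exp(-sum_v (x_v - mu_v)^2 / (2 sigma_v^2))` — a smooth bell-shaped
#' response on every variable, equal to 1 exactly at the niche centre. The
#' niche is fixed across periods (niche stability over the transfer window,
#' the framework's working assumption). `shape = "box"` gives a hard envelope
#' (1 inside `mu +/- sigma`, 0 outside) and `shape = "skew"` a skew-normal
#' response, for envelope-favourable and envelope-hostile niche geometries.
#'
#' @param mu numeric vector of niche centres (one per variable).
#' @param sigma numeric vector of niche widths (> 0).
#' @param shape `"gaussian"` (default), `"box"` or `"skew"`.
#' @param skew skewness parameter for `shape = "skew"`.
#' @return object of class `virtual_species`.
#' @export
virtual_species <- function(mu, sigma, shape = c("gaussian", "box", "skew"),
                            skew = 3) {
  shape <- match.arg(shape)
  if (length(mu) != length(sigma)) stop_arg("mu and sigma lengths differ")
  if (any(sigma <= 0)) stop_arg("sigma must be positive")
  structure(list(mu = mu, sigma = sigma, shape = shape, skew = skew),
            class = "virtual_species")
}

# True suitability of a values matrix (rows x variables)
true_suitability <- function(species, values) {
  values <- as.matrix(values)
  if (ncol(values) < length(species$mu))
    stop_arg("stack has fewer variables than the species niche")
  z <- sweep(values[, seq_along(species$mu), drop = FALSE], 2L, species$mu)
  z <- sweep(z, 2L, species$sigma, `/`)
  switch(species$shape,
    gaussian = exp(-rowSums(z^2) / 2),
    box = as.numeric(rowSums(abs(z) > 1) == 0),
    skew = {
      s <- exp(-rowSums(z^2) / 2) * apply(2 * stats::pnorm(species$skew * z),
                                          1L, prod)
      if (max(s) > 0) s / max(s) else s
    })
}

#' True suitability map of a virtual species
#'
#' @param species a [virtual_species()].
#' @param stack an `env_stack` with at least as many variables as the niche.
#' @return a `suitability_map` of the known truth.
#' @export
virtual_species_suitability <- function(species, stack) {
  cells <- mask_cells(stack$mask)
  vals <- cell_values(stack, cells)
  suitability_map_from_cells(stack, cells, true_suitability(species, vals),
                             "truth")
}

#' Sample virtual occurrences proportionally to suitability
#'
#' Draws `n` distinct cells with probability proportional to
#' `suitability x bias` (without replacement, so cell-level deduplication is
#' a no-op on synthetic data unless duplicates are injected deliberately).
#'
#' @param species a [virtual_species()].
#' @param stack an `env_stack`.
#' @param n number of occurrence cells.
#' @param bias_map optional non-negative matrix of sampling weights (e.g.
#'   roadside bias); default unbiased.
#' @param seed integer seed.
#' @param name species name for the resulting set.
#' @return an `occurrence_set`.
#' @export
sample_virtual_occurrences <- function(species, stack, n, bias_map = NULL,
                                       seed = 1L, name = "virtual") {
  cells <- mask_cells(stack$mask)
  w <- true_suitability(species, cell_values(stack, cells))
  if (!is.null(bias_map)) {
    rc <- cell_rowcol(stack, cells)
    w <- w * bias_map[rc]
  }
  if (all(w <= 0)) stop_arg("all sampling weights are zero")
  pos <- w > 0
  if (sum(pos) < n)
    stop_arg("capacity error: ", sum(pos), " cells with positive weight for n = ", n)
  drawn <- with_seed(seed, sample(cells[pos], n, prob = w[pos]))
  occ_from_cells(name, stack$period, stack, drawn)
}

#' Synthetic stand-in for the supplementary occurrence compilation
#'
#' Builds a raw (pre-deduplication) occurrence table whose per-species
#' bookkeeping reproduces the published margins of the real compilation of
#' Mexican endemic rodents: 117 species, of which 44 have at least 10 unique
#' localities in both periods, 14 are underrepresented in one period and 59
#' are insufficient in both, with the best-sampled species contributing 504
#' unique localities. The table is synthetic — species are labelled
#' `sp001..sp117` and coordinates are random grid cells — and exists so the
#' load/deduplicate/classify pipeline can be exercised end-to-end against
#' known totals; it carries no information about the real species.
#'
#' @param stack an `env_stack` defining the grid (needs >= 1100 valid cells).
#' @param seed integer seed.
#' @return data.frame with columns `species`, `longitude`, `latitude`,
#'   `period`, including injected within-cell duplicates and a few off-grid
#'   rows.
#' @export
synthetic_supp_occurrences <- function(stack, seed = 1L) {
  n_cells_needed <- 1100L
  cells <- mask_cells(stack$mask)
  if (length(cells) < n_cells_needed)
    stop_arg("grid too small for the synthetic compilation")
  with_seed(seed, {
    specs <- data.frame(species = sprintf("sp%03d", 1:117))
    # 44 sufficient (>=10 in both), 14 under in one, 59 insufficient in both
    n1 <- integer(117); n2 <- integer(117)
    n1[1:44] <- sample(10:40, 44, replace = TRUE)
    n2[1:44] <- sample(10:40, 44, replace = TRUE)
    # best-sampled species: 504 unique localities in total across periods
    n1[1L] <- 250L; n2[1L] <- 254L
    under_flip <- sample(c(TRUE, FALSE), 14, replace = TRUE)
    n1[45:58] <- ifelse(under_flip, sample(1:9, 14, replace = TRUE),
                        sample(10:30, 14, replace = TRUE))
    n2[45:58] <- ifelse(under_flip, sample(10:30, 14, replace = TRUE),
                        sample(1:9, 14, replace = TRUE))
    n1[59:117] <- sample(0:9, 59, replace = TRUE)
    n2[59:117] <- sample(1:9, 59, replace = TRUE)
    rows <- list()
    for (i in 1:117) {
      for (per in c("T1", "T2")) {
        k <- if (per == "T1") n1[i] else n2[i]
        if (k == 0L) next
        cc <- sample(cells, k)
        xy <- cell_centers(stack, cc)
        # jitter within the cell: same cell, different coordinates
        cs <- stack$geometry$cellsize
        rows[[length(rows) + 1L]] <- data.frame(
          species = specs$species[i],
          longitude = xy[, "x"] + stats::runif(k, -0.4, 0.4) * cs,
          latitude = xy[, "y"] + stats::runif(k, -0.4, 0.4) * cs,
          period = per)
        # inject duplicates for a third of the records of sufficient species
        if (i <= 44 && k >= 3) {
          dup <- seq_len(max(1L, k %/% 3L))
          rows[[length(rows) + 1L]] <- data.frame(
            species = specs$species[i],
            longitude = xy[dup, "x"], latitude = xy[dup, "y"], period = per)
        }
      }
    }
    tab <- do.call(rbind, rows)
    # a few off-grid rows that the loader must drop
    g <- stack$geometry
    off <- data.frame(species = specs$species[1:3],
                      longitude = g$xll - 10 * g$cellsize,
                      latitude = g$yll - 10 * g$cellsize,
                      period = "T1")
    rbind(tab, off)
  })
}
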