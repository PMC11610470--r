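# occurrences module: ingestion, cell-level deduplication, the 10-record
# sufficiency rule, pseudoabsence generation and 70/30 partitioning.

#' Construct an occurrence set
#'
#' Records are stored at cell resolution: "unique localities" are unique grid
#' cells at the working resolution, so duplicates within one cell collapse to
#' a single record.
#'
#' @param species species name.
#' @param period period label (`"T1"`, `"T2"`).
#' @param records data.frame with columns `lon`, `lat`, `row`, `col`, `cell`
#'   (one row per unique cell).
#' @param provenance optional free-text source tags.
#' @return object of class `occurrence_set`.
#' @export
occurrence_set <- function(species, period, records,
                           provenance = character(0)) {
  stopifnot(is.data.frame(records))
  if (anyDuplicated(records$cell))
    stop_arg("records share a cell index; deduplicate first")
  structure(list(species = species, period = period,
                 records = records, provenance = provenance),
            class = "occurrence_set")
}

#' @export
print.occurrence_set <- function(x, ...) {
  cat(sprintf("occurrence_set: %s [%s], %d unique localities\n",
              x$species, x$period, nrow(x$records)))
  invisible(x)
}

# Build an occurrence_set from linear cell indices
occ_from_cells <- function(species, period, stack, cells) {
  cells <- as.integer(cells)
  rc <- cell_rowcol(stack, cells)
  xy <- cell_centers(stack, cells)
  occurrence_set(species, period,
                 data.frame(lon = xy[, "x"], lat = xy[, "y"],
                            row = rc[, "row"], col = rc[, "col"], cell = cells))
}

#' Load, map to cells and deduplicate an occurrence table
#'
#' Raw records are assigned to the grid cell containing them; records sharing
#' a cell collapse to one; records falling off-grid, on nodata cells, with
#' unparseable coordinates, or with a period outside the configured labels
#' are dropped and counted. Years are mapped to period labels through
#' `period_bounds`.
#'
#' @param table data.frame with columns `species`, `longitude`, `latitude`,
#'   `period` (period labels or years).
#' @param stack an `env_stack` defining the grid (either period; geometries
#'   are shared).
#' @param period_bounds named list mapping period label to `c(first, last)`
#'   year, used when `period` holds years. Defaults to 1950-1979 (`T1`) and
#'   1980-2009 (`T2`).
#' @return list with `sets` (named list of `occurrence_set`, keys
#'   `"species|period"`) and `dropped` (named integer vector of drop counts
#'   by reason: `bad_coord`, `off_grid`, `nodata_cell`, `bad_period`,
#'   `duplicate`).
#' @export
load_and_deduplicate <- function(table, stack,
                                 period_bounds = list(T1 = c(1950, 1979),
                                                      T2 = c(1980, 2009))) {
  req <- c("species", "longitude", "latitude", "period")
  missing <- setdiff(req, names(table))
  if (length(missing))
    stop_arg("schema error: missing column(s): ", paste(missing, collapse = ", "))
  lon <- suppressWarnings(as.numeric(table$longitude))
  lat <- suppressWarnings(as.numeric(table$latitude))
  dropped <- c(bad_coord = 0L, off_grid = 0L, nodata_cell = 0L,
               bad_period = 0L, duplicate = 0L)

  bad <- !is.finite(lon) | !is.finite(lat)
  dropped["bad_coord"] <- sum(bad)

  # map period column: accept labels directly, else interpret as a year
  per_raw <- as.character(table$period)
  per <- rep(NA_character_, length(per_raw))
  per[per_raw %in% names(period_bounds)] <- per_raw[per_raw %in% names(period_bounds)]
  yr <- suppressWarnings(as.numeric(per_raw))
  for (lab in names(period_bounds)) {
    b <- period_bounds[[lab]]
    per[is.na(per) & is.finite(yr) & yr >= b[1L] & yr <= b[2L]] <- lab
  }
  bad_per <- is.na(per) & !bad
  dropped["bad_period"] <- sum(bad_per)
  keep <- !bad & !bad_per

  rc <- point_to_rowcol_safe(stack, lon[keep], lat[keep])
  off <- is.na(rc[, "row"])
  dropped["off_grid"] <- sum(off)
  idx <- which(keep)[!off]
  rc <- rc[!off, , drop = FALSE]
  nod <- !stack$mask[rc]
  dropped["nodata_cell"] <- sum(nod)
  idx <- idx[!nod]
  rc <- rc[!nod, , drop = FALSE]

  df <- data.frame(species = as.character(table$species)[idx],
                   period = per[idx],
                   lon = lon[idx], lat = lat[idx],
                   row = rc[, "row"], col = rc[, "col"],
                   cell = cell_index(stack, rc[, "row"], rc[, "col"]))
  sets <- list()
  for (key in unique(paste(df$species, df$period, sep = "|"))) {
    sub <- df[paste(df$species, df$period, sep = "|") == key, ]
    dup <- duplicated(sub$cell)
    dropped["duplicate"] <- dropped["duplicate"] + sum(dup)
    sub <- sub[!dup, ]
    sets[[key]] <- occurrence_set(sub$species[1L], sub$period[1L],
                                  sub[, c("lon", "lat", "row", "col", "cell")])
  }
  list(sets = sets, dropped = dropped)
}

# like point_to_rowcol but returns NA rows instead of raising a bounds error
point_to_rowcol_safe <- function(stack, x, y) {
  g <- stack$geometry
  ytop <- g$yll + g$nrow * g$cellsize
  col <- floor((x - g$xll) / g$cellsize) + 1
  row <- floor((ytop - y) / g$cellsize) + 1
  row[y == ytop] <- 1
  bad <- col < 1 | col > g$ncol | row < 1 | row > g$nrow
  col[bad] <- NA_integer_; row[bad] <- NA_integer_
  cbind(row = as.integer(row), col = as.integer(col))
}

#' Classify species by record sufficiency in both periods
#'
#' A species is `sufficient` when it has at least `minimum` unique localities
#' in each period, `insufficient_both` when below the minimum in both, and
#' `underrepresented_one_period` otherwise. Species absent from one period
#' count 0 there.
#'
#' @param sets named list of `occurrence_set` (keys `"species|period"`), or a
#'   data.frame with columns `species`, `n_T1`, `n_T2`.
#' @param minimum minimum unique localities per period (default 10).
#' @param periods the two period labels.
#' @return data.frame with `species`, `n_T1`, `n_T2`, `status`.
#' @export
classify_species_sufficiency <- function(sets, minimum = 10,
                                         periods = c("T1", "T2")) {
  if (is.data.frame(sets)) {
    counts <- sets
  } else {
    sp <- unique(vapply(sets, function(s) s$species, character(1)))
    counts <- data.frame(species = sp,
                         n_T1 = 0L, n_T2 = 0L, stringsAsFactors = FALSE)
    for (s in sets) {
      i <- match(s$species, counts$species)
      if (s$period == periods[1L]) counts$n_T1[i] <- nrow(s$records)
      if (s$period == periods[2L]) counts$n_T2[i] <- nrow(s$records)
    }
  }
  status <- ifelse(counts$n_T1 >= minimum & counts$n_T2 >= minimum, "sufficient",
            ifelse(counts$n_T1 < minimum & counts$n_T2 < minimum,
                   "insufficient_both", "underrepresented_one_period"))
  data.frame(species = counts$species, n_T1 = counts$n_T1,
             n_T2 = counts$n_T2, status = status, stringsAsFactors = FALSE)
}

#' Draw pseudoabsences within the accessible area
#'
#' Draws exactly as many cells as there are presences, uniformly without
#' replacement from the accessible area excluding presence cells — absence
#' stand-ins matched in number to the presence records, confined to M because
#' M is the modeling domain throughout.
#'
#' @param presences an `occurrence_set`.
#' @param area an `accessible_area`.
#' @param seed integer seed; identical seeds give identical draws.
#' @param stack the `env_stack` the area lives on (for cell coordinates).
#' @return an `occurrence_set` of pseudoabsence cells.
#' @export
generate_pseudoabsences <- function(presences, area, seed, stack) {
  n <- nrow(presences$records)
  candidates <- setdiff(mask_cells(area$mask), presences$records$cell)
  if (length(candidates) < n)
    stop_arg("capacity error: ", length(candidates),
             " candidate cells for ", n, " pseudoabsences")
  cells <- with_seed(seed, sample(candidates, n, replace = FALSE))
  out <- occ_from_cells(presences$species, presences$period, stack, cells)
  out$provenance <- "pseudoabsence"
  out
}

#' Split an occurrence set into calibration and validation subsets
#'
#' Uniform random assignment of `round(fraction * n)` records to calibration
#' and the remainder to validation. Presences and pseudoabsences are split
#' separately with the same fractions.
#'
#' @param occ an `occurrence_set` with at least 2 records.
#' @param fraction calibration fraction (default 0.7).
#' @param seed integer seed.
#' @return list with `calibration`, `validation` (both `occurrence_set`) and
#'   `seed`.
#' @export
partition_calibration_validation <- function(occ, fraction = 0.7, seed) {
  n <- nrow(occ$records)
  if (n < 2L) stop_arg("need at least 2 records to partition")
  n_cal <- as.integer(round(fraction * n))
  n_cal <- max(1L, min(n - 1L, n_cal))  # both parts non-empty
  idx <- with_seed(seed, sample.int(n, n_cal))
  mk <- function(rows) occurrence_set(occ$species, occ$period,
                                      occ$records[rows, , drop = FALSE],
                                      occ$provenance)
  list(calibration = mk(sort(idx)),
       validation = mk(sort(setdiff(seq_len(n), idx))),
       seed = seed)
}
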