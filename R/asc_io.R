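# Minimal reader/writer for the ESRI ASCII grid format (.asc) — the
# plain-text single-band raster interchange format. Header keys are accepted
# case-insensitively and in any order; xllcenter/yllcenter variants are
# converted to corner convention. Rows run north to south.

#' Read an ESRI ASCII grid
#'
#' @param path file path.
#' @return list with `data` (numeric matrix, row 1 = northernmost, `NA` for
#'   nodata) and `geometry` (`xll`, `yll`, `cellsize`, `nrow`, `ncol`).
#' @export
read_asc <- function(path) {
  if (!file.exists(path)) stop_arg("cannot read raster file: ", path)
  con <- file(path, "r"); on.exit(close(con))
  hdr <- list()
  repeat {
    pos <- seek(con)
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) stop_arg("unexpected end of file in ", path)
    tok <- strsplit(trimws(line), "\\s+")[[1L]]
    if (length(tok) == 2L && is.na(suppressWarnings(as.numeric(tok[1L])))) {
      hdr[[tolower(tok[1L])]] <- as.numeric(tok[2L])
    } else {
      seek(con, pos)
      break
    }
  }
  need <- c("ncols", "nrows")
  if (!all(need %in% names(hdr)))
    stop_arg("malformed .asc header in ", path)
  nc <- as.integer(hdr$ncols); nr <- as.integer(hdr$nrows)
  cs <- hdr$cellsize %||% 1
  xll <- hdr$xllcorner %||% (if (!is.null(hdr$xllcenter)) hdr$xllcenter - cs / 2 else 0)
  yll <- hdr$yllcorner %||% (if (!is.null(hdr$yllcenter)) hdr$yllcenter - cs / 2 else 0)
  vals <- scan(con, what = double(), n = nr * nc, quiet = TRUE)
  if (length(vals) != nr * nc)
    stop_arg("expected ", nr * nc, " cell values in ", path, ", got ",
             length(vals))
  if (!is.null(hdr$nodata_value)) vals[vals == hdr$nodata_value] <- NA_real_
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  list(data = m,
       geometry = list(xll = xll, yll = yll, cellsize = cs,
                       nrow = nr, ncol = nc, crs = "unspecified"))
}

#' Write a matrix as an ESRI ASCII grid
#'
#' @param data numeric matrix, row 1 = northernmost; `NA` written as nodata.
#' @param path output path.
#' @param geometry list with `xll`, `yll`, `cellsize`.
#' @param nodata nodata sentinel written to the file (default -9999).
#' @param digits significant digits to print (default 15, round-trip safe).
#' @export
write_asc <- function(data, path, geometry = list(xll = 0, yll = 0, cellsize = 1),
                      nodata = -9999, digits = 15) {
  stopifnot(is.matrix(data))
  if (any(data == nodata, na.rm = TRUE))
    stop_arg("data contains the nodata sentinel ", nodata)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(paste("ncols", ncol(data)),
               paste("nrows", nrow(data)),
               paste("xllcorner", format(geometry$xll, digits = digits)),
               paste("yllcorner", format(geometry$yll, digits = digits)),
               paste("cellsize", format(geometry$cellsize, digits = digits)),
               paste("NODATA_value", nodata)), con)
  out <- data
  out[is.na(out)] <- nodata
  for (r in seq_len(nrow(out)))
    writeLines(paste(format(out[r, ], digits = digits, trim = TRUE,
                            scientific = FALSE), collapse = " "), con)
  invisible(path)
}

#' Write every variable of a stack as ESRI ASCII grids
#'
#' Files are named `<prefix><variable>.asc`.
#'
#' @param stack an `env_stack`.
#' @param dir output directory (created if absent).
#' @param prefix filename prefix (default the period label plus `_`).
#' @return named character vector of written paths.
#' @export
write_stack <- function(stack, dir, prefix = paste0(stack$period, "_")) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- vapply(names(stack$variables), function(v) {
    p <- file.path(dir, paste0(prefix, v, ".asc"))
    m <- stack$variables[[v]]
    m[!stack$mask] <- NA_real_
    write_asc(m, p, stack$geometry)
    p
  }, character(1))
  paths
}
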