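#' Read and write plot inventory tables
#'
#' Plot inventories are RFC-4180 CSV files with one row per plot and the
#' mandatory columns `plot_id`, `age` (yr), `mean_dbh` (cm), `mean_height`
#' (cm), `density` (trees/100 m^2), `salinity` (ppt), `elevation` (m).
#' Additional columns (e.g. `region`, `G`, `root_Cr`) are read and written
#' unchanged. Numbers use the locale-independent decimal point.
#'
#' @param path CSV file path.
#' @param plots Plot data frame to write.
#' @return `read_plot_csv()` returns a data frame; `write_plot_csv()`
#'   returns `path` invisibly.
#' @export
read_plot_csv <- function(path) {
  need <- c("plot_id", "age", "mean_dbh", "mean_height", "density",
            "salinity", "elevation")
  df <- .read_checked_csv(path, need, numeric_cols = setdiff(need, "plot_id"))
  if (any(df$age < 1 | df$age > 150))
    stop("implausible plot age outside [1, 150] yr in ", path)
  df
}

#' @rdname read_plot_csv
#' @export
write_plot_csv <- function(plots, path) {
  need <- c("plot_id", "age", "mean_dbh", "mean_height", "density",
            "salinity", "elevation")
  miss <- setdiff(need, names(plots))
  if (length(miss)) stop("plot table lacks column(s): ",
                         paste(miss, collapse = ", "))
  utils::write.csv(plots, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write heavy-metal concentration tables
#'
#' Long-format CSV with mandatory columns `site_id`, `region`,
#' `compartment` (`soil`/`root`/`leaf`), `metal`, `conc` (mg/kg DW); one
#' row per (site, compartment, metal).
#'
#' @param path CSV file path.
#' @param table Heavy-metal data frame to write.
#' @return `read_hm_csv()` returns a data frame; `write_hm_csv()` returns
#'   `path` invisibly.
#' @export
read_hm_csv <- function(path) {
  df <- .read_checked_csv(path, c("site_id", "region", "compartment",
                                  "metal", "conc"), numeric_cols = "conc")
  bad <- setdiff(unique(df$compartment), c("soil", "root", "leaf"))
  if (length(bad)) stop("unknown compartment(s) in ", path, ": ",
                        paste(bad, collapse = ", "))
  .check_hm_table(df)
  df
}

#' @rdname read_hm_csv
#' @export
write_hm_csv <- function(table, path) {
  .check_hm_table(table)
  utils::write.csv(table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# shared CSV reader: mandatory columns, numeric coercion with the offending
# data line reported (header is line 1)
.read_checked_csv <- function(path, need, numeric_cols = character()) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", check.names = TRUE)
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("schema error in ", path, ": missing column(s) ",
         paste(miss, collapse = ", "))
  for (cl in intersect(numeric_cols, names(df))) {
    x <- suppressWarnings(as.numeric(df[[cl]]))
    bad <- which(is.na(x) & nzchar(df[[cl]]) & !is.na(df[[cl]]))
    if (length(bad))
      stop("malformed value in ", path, ", column '", cl,
           "', line ", bad[1] + 1L, ": '", df[[cl]][bad[1]], "'")
    df[[cl]] <- x
  }
  # remaining all-numeric-looking extra columns are converted too
  for (cl in setdiff(names(df), c(need, numeric_cols))) {
    x <- suppressWarnings(as.numeric(df[[cl]]))
    if (!anyNA(x[nzchar(df[[cl]])])) df[[cl]] <- x
  }
  df
}

#' Raster layer in ESRI ASCII grid form
#'
#' A minimal in-memory raster: a numeric matrix (row 1 = northernmost row,
#' matching the on-disk order of the ASCII format) plus the standard header
#' fields. `NA` cells are written as the nodata marker.
#'
#' @param data Numeric matrix.
#' @param cellsize Cell edge length (m).
#' @param xll,yll Coordinates of the lower-left corner.
#' @param nodata Nodata marker value used on disk.
#' @return An object of class `ascii_grid`.
#' @export
ascii_grid <- function(data, cellsize = 100, xll = 0, yll = 0,
                       nodata = -9999) {
  stopifnot(is.matrix(data), is.numeric(cellsize), cellsize > 0)
  structure(list(data = data, cellsize = cellsize, xll = xll, yll = yll,
                 nodata = nodata),
            class = "ascii_grid")
}

#' @export
print.ascii_grid <- function(x, ...) {
  cat(sprintf("ascii_grid: %d x %d cells of %g m (xll %g, yll %g), %d nodata\n",
              nrow(x$data), ncol(x$data), x$cellsize, x$xll, x$yll,
              sum(is.na(x$data))))
  invisible(x)
}

#' Read and write ESRI ASCII grid rasters
#'
#' Plain-text raster exchange format: a six-line header (`ncols`, `nrows`,
#' `xllcorner`, `yllcorner`, `cellsize`, `NODATA_value`) followed by
#' `nrows` rows of values, north first. The round trip preserves header
#' fields exactly and values to full printed precision; nodata cells map
#' to `NA` in memory.
#'
#' @param path File path.
#' @param grid An [ascii_grid()] object.
#' @return `read_ascii_grid()` returns an [ascii_grid()];
#'   `write_ascii_grid()` returns `path` invisibly.
#' @export
read_ascii_grid <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 6) stop("not an ASCII grid (fewer than 6 lines): ", path)
  hdr <- list()
  for (i in 1:6) {
    parts <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]
    if (length(parts) != 2)
      stop("malformed header line ", i, " in ", path)
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize",
            "nodata_value")
  miss <- setdiff(need, names(hdr))
  if (length(miss)) stop("ASCII grid header lacks: ",
                         paste(miss, collapse = ", "))
  vals <- scan(text = paste(lines[-(1:6)], collapse = "\n"), quiet = TRUE)
  if (length(vals) != hdr$ncols * hdr$nrows)
    stop("value count (", length(vals), ") does not match header ",
         hdr$nrows, " x ", hdr$ncols, " in ", path)
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  m[m == hdr$nodata_value] <- NA
  ascii_grid(m, cellsize = hdr$cellsize, xll = hdr$xllcorner,
             yll = hdr$yllcorner, nodata = hdr$nodata_value)
}

#' @rdname read_ascii_grid
#' @export
write_ascii_grid <- function(grid, path) {
  stopifnot(inherits(grid, "ascii_grid"))
  m <- grid$data
  m[is.na(m)] <- grid$nodata
  hdr <- c(paste("ncols", ncol(m)),
           paste("nrows", nrow(m)),
           paste("xllcorner", format(grid$xll, scientific = FALSE)),
           paste("yllcorner", format(grid$yll, scientific = FALSE)),
           paste("cellsize", format(grid$cellsize, scientific = FALSE)),
           paste("NODATA_value", format(grid$nodata, scientific = FALSE)))
  body <- apply(m, 1, function(r)
    paste(format(r, trim = TRUE, digits = 15, scientific = FALSE),
          collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}
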