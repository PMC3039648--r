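#' Write a landscape to a text grid file
#'
#' Three plain-text formats are supported:
#' \describe{
#'   \item{`"csv"`}{a bare CSV matrix, rows = y, columns = x; 2-D only.}
#'   \item{`"asc"`}{ESRI ASCII grid with the standard six-line header
#'     (`ncols`, `nrows`, `xllcorner`, `yllcorner`, `cellsize`,
#'     `NODATA_value`); 2-D only.}
#'   \item{`"flat"`}{N-dimensional flat text: first line the
#'     whitespace-separated extents, then one value per line in row-major
#'     order (last dimension fastest).}
#' }
#' Values are serialised with 17 significant digits, so `"csv"` and `"flat"`
#' round-trip bit-exactly through [read_grid()].  Binary landscapes are
#' written as 0/1.
#'
#' @param land an `fbm_landscape` or `fbm_binary_landscape`.
#' @param path output file path.
#' @param format one of `"csv"`, `"asc"`, `"flat"` (default guessed from the
#'   file extension, falling back to `"flat"`).
#' @return `path`, invisibly.
#' @export
write_grid <- function(land, path, format = NULL) {
  v <- grid_values(land)
  format <- grid_format(format, path)
  if (format %in% c("csv", "asc") && length(dim(v)) != 2L)
    stop("format '", format, "' requires a 2-D landscape (got ",
         length(dim(v)), " dimensions)")
  con <- file(path, "w")
  on.exit(close(con))
  if (format == "csv") {
    for (i in seq_len(nrow(v)))
      writeLines(paste(fmt17(v[i, ]), collapse = ","), con)
  } else if (format == "asc") {
    writeLines(c(paste("ncols", ncol(v)),
                 paste("nrows", nrow(v)),
                 "xllcorner 0", "yllcorner 0", "cellsize 1",
                 "NODATA_value -9999"), con)
    for (i in seq_len(nrow(v)))
      writeLines(paste(fmt17(v[i, ]), collapse = " "), con)
  } else {
    writeLines(paste(dim(v), collapse = " "), con)
    writeLines(fmt17(as.vector(aperm(v, rev(seq_along(dim(v)))))), con)
  }
  invisible(path)
}

fmt17 <- function(x) sprintf("%.17g", as.numeric(x))

grid_values <- function(land) {
  if (is_landscape(land)) land$values
  else if (inherits(land, "fbm_binary_landscape")) land$suitable + 0
  else if (is.numeric(land) && !is.null(dim(land))) land
  else stop("`land` must be a landscape object or a numeric array")
}

grid_format <- function(format, path) {
  if (is.null(format)) {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext == "csv") "csv" else if (ext == "asc") "asc" else "flat"
  }
  match.arg(format, c("csv", "asc", "flat"))
}

#' Read a landscape from a text grid file
#'
#' Inverse of [write_grid()] for the `"csv"` and `"flat"` formats (the ESRI
#' `"asc"` format is also readable; its header is parsed and discarded).
#' Malformed files raise a parse error naming the offending line.
#'
#' @param path input file path.
#' @param format one of `"csv"`, `"asc"`, `"flat"` (default guessed from the
#'   extension).
#' @return an `fbm_landscape` (aperiodic: periodicity metadata is not stored
#'   in grid files).
#' @export
read_grid <- function(path, format = NULL) {
  format <- grid_format(format, path)
  lines <- readLines(path)
  if (length(lines) == 0) stop("empty grid file: ", path)
  if (format == "csv") {
    rows <- strsplit(lines, ",", fixed = TRUE)
    ncols <- length(rows[[1]])
    for (i in seq_along(rows))
      if (length(rows[[i]]) != ncols)
        stop("parse error in ", path, " at line ", i, ": expected ", ncols,
             " values, found ", length(rows[[i]]))
    v <- parse_grid_numbers(unlist(rows), path, rep(seq_along(rows),
                                                    each = ncols))
    new_landscape(matrix(v, nrow = length(rows), byrow = TRUE))
  } else if (format == "asc") {
    if (length(lines) < 7) stop("parse error in ", path, ": truncated header")
    hdr <- strsplit(trimws(lines[1:6]), "\\s+")
    keys <- tolower(vapply(hdr, `[`, "", 1))
    if (!identical(keys[1:2], c("ncols", "nrows")))
      stop("parse error in ", path, " at line 1: not an ESRI ASCII header")
    nc <- as.integer(hdr[[1]][2]); nr <- as.integer(hdr[[2]][2])
    body <- strsplit(trimws(lines[-(1:6)]), "\\s+")
    if (length(body) != nr)
      stop("parse error in ", path, ": expected ", nr, " data rows, found ",
           length(body))
    for (i in seq_along(body))
      if (length(body[[i]]) != nc)
        stop("parse error in ", path, " at line ", i + 6, ": expected ", nc,
             " values, found ", length(body[[i]]))
    v <- parse_grid_numbers(unlist(body), path,
                            rep(seq_along(body) + 6, each = nc))
    new_landscape(matrix(v, nrow = nr, byrow = TRUE))
  } else {
    extent <- suppressWarnings(as.integer(strsplit(trimws(lines[1]),
                                                   "\\s+")[[1]]))
    if (anyNA(extent) || any(extent < 1))
      stop("parse error in ", path, " at line 1: invalid extent header")
    n_cells <- prod(extent)
    if (length(lines) - 1 != n_cells)
      stop("parse error in ", path, ": expected ", n_cells,
           " value lines, found ", length(lines) - 1)
    v <- parse_grid_numbers(lines[-1], path, seq_along(lines[-1]) + 1)
    a <- array(v, dim = rev(extent))
    new_landscape(aperm(a, rev(seq_along(extent))))
  }
}

parse_grid_numbers <- function(x, path, line_no) {
  v <- suppressWarnings(as.numeric(x))
  if (anyNA(v)) {
    bad <- which(is.na(v))[1]
    stop("parse error in ", path, " at line ", line_no[bad],
         ": not a number: '", x[bad], "'")
  }
  v
}
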