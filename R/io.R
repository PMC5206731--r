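## Plain-text input/output.
##
## The canonical fiber format is a delimited table with a header:
## fiber_id, z_index, vertex_index, x, y — one row per polyline vertex.
## Fiber-extraction output (e.g. CT-FIRE vertex lists) is converted to
## this format once; simulated fibers are written in it directly, so
## simulated and real data are interchangeable downstream.

.readDelim <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  l1 <- readLines(path, n = 1L)
  sep <- if (grepl("\t", l1)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep,
                    stringsAsFactors = FALSE)
}

#' Read a fiber table
#'
#' Reads the delimited fiber-vertex format (CSV or TSV, autodetected from
#' the header line): columns \code{fiber_id}, \code{z_index},
#' \code{vertex_index}, \code{x}, \code{y}, one row per vertex. Malformed
#' input — missing columns, non-numeric coordinates, fibers with fewer
#' than two vertices — raises an error naming the offending column, row or
#' fiber.
#'
#' @param path Path to the file.
#' @return A validated fiber table, rows ordered by z-index, fiber id and
#'   vertex index.
#' @seealso [writeFiberTable()], [checkFiberTable()]
#' @export
readFiberTable <- function(path) {
  tab <- .readDelim(path)
  missing <- setdiff(.FIBER_COLS, names(tab))
  if (length(missing))
    stop("fiber file ", path, " is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  for (col in c("x", "y")) {
    v <- suppressWarnings(as.numeric(tab[[col]]))
    bad <- which(is.na(v) & !is.na(tab[[col]]) | !is.finite(v))
    if (length(bad))
      stop("non-numeric '", col, "' in ", path, " at data row(s): ",
           paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
    tab[[col]] <- v
  }
  tab$z_index <- as.integer(tab$z_index)
  tab$vertex_index <- as.integer(tab$vertex_index)
  checkFiberTable(tab, allowEmpty = FALSE)
  tab[order(tab$z_index, tab$fiber_id, tab$vertex_index), , drop = FALSE]
}

#' Write a fiber table
#'
#' Writes the fiber-vertex format read by [readFiberTable()], with full
#' coordinate precision (round-trip lossless).
#'
#' @param fibers A fiber table.
#' @param path Output path; \code{.tsv} selects tab separation, anything
#'   else comma.
#' @return \code{path}, invisibly.
#' @export
writeFiberTable <- function(fibers, path) {
  checkFiberTable(fibers)
  out <- fibers[, .FIBER_COLS]
  out$x <- sprintf("%.17g", out$x)
  out$y <- sprintf("%.17g", out$y)
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  utils::write.table(out, path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read a boundary table
#'
#' Reads per-slice circular tumor boundaries: columns \code{z_index},
#' \code{cx}, \code{cy}, \code{r} (pixels).
#'
#' @param path Path to the file (CSV or TSV).
#' @return A \code{data.frame} with one row per z-slice.
#' @export
readBoundaryTable <- function(path) {
  tab <- .readDelim(path)
  need <- c("z_index", "cx", "cy", "r")
  missing <- setdiff(need, names(tab))
  if (length(missing))
    stop("boundary file ", path, " is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (any(!is.finite(tab$r) | tab$r <= 0))
    stop("boundary radii must be positive", call. = FALSE)
  if (anyDuplicated(tab$z_index))
    stop("duplicate z_index in boundary file ", path, call. = FALSE)
  tab$z_index <- as.integer(tab$z_index)
  tab
}

#' Write a vector field (or stack) as a table
#'
#' One row per grid cell: position, z-index, exclusion status, alignment
#' length, axial angle and segment count. Excluded cells keep their status
#' label and empty vector columns. Values are written at full precision,
#' so valid-cell lengths round-trip losslessly through
#' [readVectorFieldTable()].
#'
#' @param field A [VectorField-class] or [StackField-class].
#' @param path Output path; \code{.tsv} selects tab separation, anything
#'   else comma.
#' @return \code{path}, invisibly.
#' @export
writeVectorField <- function(field, path) {
  tab <- if (is(field, "StackField")) cells(field)
         else if (is(field, "VectorField"))
           cbind(field@cells, z_index = field@zIndex)
         else stop("'field' must be a VectorField or StackField",
                   call. = FALSE)
  out <- tab[, c("x", "y", "z_index", "status", "length", "angle",
                 "n_segments")]
  num <- function(v) ifelse(is.na(v), "", sprintf("%.17g", v))
  out$length <- num(out$length)
  out$angle <- num(out$angle)
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  utils::write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a vector-field table
#'
#' Reads the per-cell table written by [writeVectorField()] back into a
#' \code{data.frame} (it does not reconstruct the S4 field object).
#'
#' @param path Path to the file.
#' @return A \code{data.frame} with columns \code{x}, \code{y},
#'   \code{z_index}, \code{status}, \code{length}, \code{angle},
#'   \code{n_segments}.
#' @export
readVectorFieldTable <- function(path) {
  tab <- .readDelim(path)
  need <- c("x", "y", "z_index", "status", "length", "angle", "n_segments")
  missing <- setdiff(need, names(tab))
  if (length(missing))
    stop("field file ", path, " is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (!all(tab$status %in% .CELL_STATUSES))
    stop("unknown cell status in ", path, call. = FALSE)
  for (col in c("length", "angle")) tab[[col]] <- as.numeric(tab[[col]])
  tab
}
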