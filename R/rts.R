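#' Region-by-time series container
#'
#' A `region_ts` object holds a numeric matrix of signals with regions in
#' rows and time points in columns, together with region labels and a flag
#' recording whether the rows have been standardized (sample mean 0 with the
#' 1/T convention, sample variance 1 with the 1/(T-1) convention).  It is the
#' universal input of all connectivity estimators in this package.
#'
#' @param data numeric matrix, regions in rows, time points in columns.
#' @param region_ids character vector of region labels; defaults to the
#'   matrix rownames, or `"R1"`, `"R2"`, ... when those are absent.
#' @param standardized logical; set only if the rows are already z-scored.
#' @return an object of class `region_ts`.
#' @examples
#' x <- region_ts(matrix(rnorm(40), nrow = 4))
#' standardize(x)
#' @export
region_ts <- function(data, region_ids = NULL, standardized = FALSE) {
  if (!is.matrix(data)) data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (ncol(data) < 2L)
    stop("a region_ts needs at least 2 time points", call. = FALSE)
  if (!all(is.finite(data)))
    stop("non-finite values in time-series matrix", call. = FALSE)
  if (is.null(region_ids)) {
    region_ids <- rownames(data)
    if (is.null(region_ids)) region_ids <- paste0("R", seq_len(nrow(data)))
  }
  region_ids <- as.character(region_ids)
  if (length(region_ids) != nrow(data))
    stop("length(region_ids) must equal nrow(data)", call. = FALSE)
  if (anyDuplicated(region_ids))
    stop("region labels must be unique", call. = FALSE)
  rownames(data) <- region_ids
  x <- new_region_ts(data, standardized)
  if (standardized) check_standardized(x)
  x
}

# cheap internal constructor: no validation, used on hot paths
new_region_ts <- function(data, standardized = FALSE) {
  structure(list(data = data, region_ids = rownames(data),
                 standardized = isTRUE(standardized)),
            class = "region_ts")
}

check_standardized <- function(x, tol = 1e-10) {
  T <- ncol(x$data)
  mu <- rowMeans(x$data)
  v <- rowSums((x$data - mu)^2) / (T - 1)
  if (any(abs(mu) > tol) || any(abs(v - 1) > tol))
    stop("standardized flag set but rows are not z-scored", call. = FALSE)
  invisible(x)
}

#' @export
print.region_ts <- function(x, ...) {
  cat(sprintf("region_ts: %d regions x %d time points%s\n",
              nrow(x$data), ncol(x$data),
              if (x$standardized) " (standardized)" else ""))
  ids <- x$region_ids
  if (length(ids) > 8) ids <- c(ids[1:8], "...")
  cat("regions:", paste(ids, collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.region_ts <- function(x) dim(x$data)

#' Z-score the rows of a region-by-time series
#'
#' Each row is centred to sample mean zero (1/T convention) and scaled to
#' sample variance one (1/(T-1) convention).  These are the two conventions
#' under which all plug-in moment estimators of this package are defined; a
#' consequence is that the plug-in second moment of a row with itself equals
#' (T-1)/T rather than 1.  Standardizing an already standardized series is a
#' no-op.
#'
#' @param x a [region_ts()].
#' @return a standardized `region_ts`.
#' @export
standardize <- function(x) {
  stopifnot(inherits(x, "region_ts"))
  if (x$standardized) return(x)
  T <- ncol(x$data)
  d <- x$data - rowMeans(x$data)
  s2 <- rowSums(d^2) / (T - 1)
  if (any(s2 <= .Machine$double.eps * max(s2, 1))) {
    bad <- x$region_ids[s2 <= .Machine$double.eps * max(s2, 1)]
    stop("degenerate (constant) signal in region(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  new_region_ts(d / sqrt(s2), standardized = TRUE)
}

# standardize with a notice when the caller passed raw data to an estimator
need_standardized <- function(x) {
  stopifnot(inherits(x, "region_ts"))
  if (x$standardized) return(x)
  message("input was not standardized; z-scoring rows before estimation")
  standardize(x)
}

region_index <- function(x, labels) {
  idx <- match(as.character(labels), x$region_ids)
  if (anyNA(idx))
    stop("unknown region label(s): ",
         paste(labels[is.na(idx)], collapse = ", "), call. = FALSE)
  idx
}

#' Read a delimited region-by-time matrix
#'
#' Reads a TSV/CSV matrix of signals.  By default rows are regions and
#' columns are time points; transposed files are handled with
#' `regions_in_rows = FALSE`.  A leading header column/row of region labels
#' is detected automatically (any non-numeric first row).
#'
#' @param path file path.
#' @param regions_in_rows logical; `TRUE` (default) if the file stores one
#'   region per row.
#' @param sep field separator; `"auto"` picks tab for `.tsv`, comma for
#'   `.csv`, otherwise whitespace.
#' @param header logical or `"auto"`: whether the first row holds region
#'   labels (only meaningful with `regions_in_rows = FALSE`) or the first
#'   column does (with `regions_in_rows = TRUE`).
#' @return a [region_ts()].
#' @export
read_region_ts <- function(path, regions_in_rows = TRUE, sep = "auto",
                           header = "auto") {
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  if (identical(sep, "auto")) {
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  }
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty input file: ", path, call. = FALSE)
  cells <- strsplit(lines, sep, fixed = TRUE)
  nfield <- lengths(cells)
  if (length(unique(nfield)) != 1L)
    stop(sprintf("ragged rows in %s: line %d has %d fields, expected %d",
                 path, which(nfield != nfield[1])[1],
                 nfield[which(nfield != nfield[1])[1]], nfield[1]),
         call. = FALSE)
  first <- suppressWarnings(as.numeric(cells[[1]]))
  labels <- NULL
  if (identical(header, "auto")) header <- anyNA(first)
  if (isTRUE(header)) {
    # label row (time in rows layout) or label column (regions in rows)
    if (regions_in_rows) {
      labels <- vapply(cells, `[`, "", 1L)
      cells <- lapply(cells, `[`, -1L)
    } else {
      labels <- cells[[1]]
      cells <- cells[-1L]
    }
  } else if (regions_in_rows && anyNA(first)) {
    labels <- vapply(cells, `[`, "", 1L)
    cells <- lapply(cells, `[`, -1L)
  }
  num <- lapply(seq_along(cells), function(i) {
    v <- suppressWarnings(as.numeric(cells[[i]]))
    if (anyNA(v))
      stop(sprintf("non-numeric cell in %s at line %d", path, i),
           call. = FALSE)
    v
  })
  m <- do.call(rbind, num)
  if (!regions_in_rows) m <- t(m)
  region_ts(m, region_ids = labels)
}

#' Write a region-by-time matrix as TSV
#'
#' @param x a [region_ts()].
#' @param path output file path.
#' @param labels include the region labels as a first column.
#' @export
write_region_ts <- function(x, path, labels = TRUE) {
  stopifnot(inherits(x, "region_ts"))
  m <- format(x$data, digits = 10, trim = TRUE, scientific = FALSE)
  rows <- apply(m, 1L, paste, collapse = "\t")
  if (labels) rows <- paste(x$region_ids, rows, sep = "\t")
  writeLines(rows, path)
  invisible(path)
}
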