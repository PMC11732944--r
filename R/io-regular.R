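#' Read a regular labelled time-series file
#'
#' Reads the delimited dialect used by the standard equal-length
#' classification benchmarks: one series per row, the class label in the
#' first column, then `T` numeric observations; tab- or comma-separated.
#' Every row must parse to exactly `1 + T` fields — ragged rows, non-numeric
#' cells and missing-value tokens are errors reported with their row
#' number, never silently repaired.
#'
#' A multivariate dataset stored as one file per feature can be read by
#' passing several paths: the per-file label columns must agree and the
#' series are stacked into an `N x T x k` array.
#'
#' @param path character vector of one or more file paths (one per
#'   feature).
#' @param sep field separator; `"auto"` (default) tries tab, then comma.
#' @param missing_tokens strings that mark a missing value and trigger an
#'   error when encountered (default `"?"` and `"NA"`).
#' @return A list with `x` (`N x T` matrix, or `N x T x k` array for
#'   multiple files) and `y` (factor of labels as given in the file).
#' @export
read_regular <- function(path, sep = "auto", missing_tokens = c("?", "NA")) {
  one <- function(p) {
    lines <- readLines(p, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (!length(lines)) stop("file '", p, "' is empty", call. = FALSE)
    s <- sep
    if (identical(s, "auto"))
      s <- if (grepl("\t", lines[[1L]])) "\t" else ","
    cells <- strsplit(lines, s, fixed = TRUE)
    width <- lengths(cells)
    if (any(width != width[1L]))
      stop("ragged row ", which(width != width[1L])[1L], " in '", p,
           "': expected ", width[1L], " fields, found ",
           width[which(width != width[1L])[1L]], call. = FALSE)
    if (width[1L] < 2L)
      stop("rows in '", p, "' must contain a label and at least one ",
           "observation", call. = FALSE)
    lab <- vapply(cells, function(r) trimws(r[[1L]]), "")
    obs <- lapply(cells, function(r) trimws(r[-1L]))
    for (i in seq_along(obs)) {
      bad <- obs[[i]] %in% missing_tokens
      if (any(bad))
        stop("missing value token at row ", i, ", column ",
             which(bad)[1L] + 1L, call. = FALSE)
      v <- suppressWarnings(as.numeric(obs[[i]]))
      if (anyNA(v))
        stop("non-numeric cell at row ", i, ", column ",
             which(is.na(v))[1L] + 1L, call. = FALSE)
      obs[[i]] <- v
    }
    list(x = do.call(rbind, obs), y = factor(lab))
  }
  parts <- lapply(path, one)
  if (length(parts) == 1L) return(parts[[1L]])
  y <- parts[[1L]]$y
  for (p in parts[-1L])
    if (!identical(as.character(p$y), as.character(y)))
      stop("label columns disagree across per-feature files", call. = FALSE)
  dims <- vapply(parts, function(p) dim(p$x), integer(2L))
  if (any(dims[1L, ] != dims[1L, 1L]) || any(dims[2L, ] != dims[2L, 1L]))
    stop("per-feature files disagree in shape", call. = FALSE)
  x <- array(0, dim = c(dims[1L, 1L], dims[2L, 1L], length(parts)))
  for (f in seq_along(parts)) x[, , f] <- parts[[f]]$x
  list(x = x, y = y)
}

#' Write a regular labelled time-series file
#'
#' Inverse of [read_regular()] for the univariate case: label first, then
#' the observations, one series per line. Values are written with 17
#' significant digits so a round trip reproduces them exactly.
#'
#' @param x `N x T` numeric matrix.
#' @param y length-`N` label vector.
#' @param path output file path.
#' @param sep field separator (default tab).
#' @return `path`, invisibly.
#' @export
write_regular <- function(x, y, path, sep = "\t") {
  if (length(dim(x)) == 3L)
    stop("multivariate arrays are written one feature per file; ",
         "pass x[, , f]", call. = FALSE)
  stopifnot(nrow(x) == length(y))
  lines <- vapply(seq_len(nrow(x)), function(i)
    paste(c(as.character(y[i]),
            formatC(x[i, ], format = "g", digits = 17)),
          collapse = sep), "")
  writeLines(lines, path)
  invisible(path)
}
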