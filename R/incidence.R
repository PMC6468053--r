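#' Binary individual-by-resource incidence matrices
#'
#' An `incidence_matrix` is an integer 0/1 matrix whose rows are individual
#' consumers (one row per retained sample of an individual in a season) and
#' whose columns are food-item categories. Row and column names are mandatory
#' and unique. After pruning there are no all-zero rows or columns and the
#' matrix contains at least one link.
#'
#' @param x a numeric/logical matrix with unique dimnames, cells in `{0, 1}`.
#' @param prune drop all-zero rows and columns before validating?
#' @return An object of class `incidence_matrix` (an integer matrix).
#' @examples
#' m <- incidence_matrix(rbind(A = c(x = 1, y = 1), B = c(x = 0, y = 1)))
#' connectance(m)
#' @export
incidence_matrix <- function(x, prune = FALSE) {
  if (!is.matrix(x)) stop("`x` must be a matrix")
  if (is.logical(x)) x <- x + 0L
  if (!is.numeric(x)) stop("incidence cells must be numeric 0/1")
  bad <- which(!(x %in% c(0, 1)))
  if (length(bad)) {
    ij <- arrayInd(bad[1L], dim(x))
    stop(sprintf("non-binary cell %s at (row %d, col %d)",
                 format(x[bad[1L]]), ij[1L], ij[2L]))
  }
  mode(x) <- "integer"
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop("incidence matrix needs row (individual) and column (item) labels")
  if (prune) x <- x[rowSums(x) > 0L, colSums(x) > 0L, drop = FALSE]
  if (anyDuplicated(rownames(x))) stop("duplicated row (individual) labels")
  if (anyDuplicated(colnames(x))) stop("duplicated column (item) labels")
  if (nrow(x) == 0L || ncol(x) == 0L || sum(x) < 1L)
    stop("incidence matrix must contain at least one link")
  if (any(rowSums(x) == 0L)) stop("all-zero row after construction")
  if (any(colSums(x) == 0L)) stop("all-zero column after construction")
  structure(x, class = c("incidence_matrix", class(matrix())))
}

#' @export
print.incidence_matrix <- function(x, ...) {
  cat(sprintf("incidence_matrix: %d individuals x %d items, %d links (C = %.3f)\n",
              nrow(x), ncol(x), sum(x), connectance(x)))
  print(unclass(x), ...)
  invisible(x)
}

# Drop all-zero rows/columns without revalidating class (used on null draws).
prune_incidence <- function(x) {
  x[rowSums(x) > 0L, colSums(x) > 0L, drop = FALSE]
}

#' Write / read an incidence matrix as labeled CSV
#'
#' The on-disk format is a plain CSV whose first column holds individual ids
#' (header `individual`) and whose remaining headers are item labels.
#' `read_incidence(write_incidence(m, f))` is the identity: labels, order and
#' cells are preserved exactly.
#'
#' @param m an [incidence_matrix()].
#' @param path file path.
#' @return `write_incidence` returns `path` invisibly; `read_incidence`
#'   returns an [incidence_matrix()].
#' @export
write_incidence <- function(m, path) {
  stopifnot(inherits(m, "incidence_matrix"))
  df <- data.frame(individual = rownames(m), unclass(m),
                   check.names = FALSE, row.names = NULL)
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_incidence
#' @export
read_incidence <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  if (ncol(df) < 2L) stop("incidence CSV needs an id column plus item columns")
  if (anyDuplicated(names(df)[-1L]))
    stop("duplicated column label in ", path, ": ",
         names(df)[-1L][duplicated(names(df)[-1L])][1L])
  ids <- df[[1L]]
  if (anyDuplicated(ids)) stop("duplicated individual id: ",
                               ids[duplicated(ids)][1L])
  cells <- as.matrix(df[-1L])
  num <- suppressWarnings(matrix(as.numeric(cells), nrow(cells), ncol(cells)))
  bad <- which(is.na(num) | !(num %in% c(0, 1)))
  if (length(bad)) {
    ij <- arrayInd(bad[1L], dim(num))
    stop(sprintf("non-binary cell \"%s\" at (row %s, col %s)",
                 cells[bad[1L]], ids[ij[1L]], names(df)[-1L][ij[2L]]))
  }
  dimnames(num) <- list(ids, names(df)[-1L])
  incidence_matrix(num)
}
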