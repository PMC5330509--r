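# Species pairwise distance matrices: validation, construction, CSV io.

#' Construct and validate a species distance matrix
#'
#' Enforces the invariants every matrix entering the Mantel machinery must
#' satisfy: square with matching row/column species labels, symmetric to
#' 1e-12, non-negative, and exactly zero on the diagonal.
#'
#' @param m numeric matrix with species dimnames.
#' @return an object of class `dist_matrix` (a labelled matrix).
#' @export
dist_matrix <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) != ncol(m)) stop("distance matrix must be square")
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stop("distance matrix must carry species labels")
  if (!identical(rownames(m), colnames(m)))
    stop("row and column labels must match")
  if (any(!is.finite(m))) stop("distances must be finite")
  if (max(abs(m - t(m))) > 1e-12) stop("distance matrix must be symmetric")
  if (any(diag(m) != 0)) stop("diagonal must be exactly zero")
  if (any(m < 0)) stop("distances must be non-negative")
  structure(m, class = c("dist_matrix", "matrix", "array"))
}

#' Euclidean distances between species feature rows
#'
#' @param x species-by-feature numeric matrix (species rownames).
#' @return a [dist_matrix()].
#' @export
euclidean_distance <- function(x) {
  x <- as.matrix(x)
  if (is.null(rownames(x))) stop("feature matrix needs species rownames")
  m <- as.matrix(dist(x, method = "euclidean"))
  m <- (m + t(m)) / 2
  diag(m) <- 0
  dist_matrix(m)
}

#' Read / write a square distance matrix CSV
#'
#' The CSV stores species labels both as header and as the first column.
#'
#' @param path file path.
#' @return a [dist_matrix()].
#' @export
read_distance_matrix <- function(path) {
  raw <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  labels <- trimws(as.character(raw[[1L]]))
  m <- as.matrix(raw[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- labels
  colnames(m) <- trimws(colnames(m))
  m <- (m + t(m)) / 2   # absorb decimal-printing asymmetry
  diag(m) <- 0
  dist_matrix(m)
}

#' @rdname read_distance_matrix
#' @param x a `dist_matrix`.
#' @export
write_distance_matrix <- function(x, path) {
  stopifnot(inherits(x, "dist_matrix"))
  df <- data.frame(species = rownames(x), unclass(x), check.names = FALSE)
  write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

lower_tri <- function(m) m[lower.tri(m)]
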