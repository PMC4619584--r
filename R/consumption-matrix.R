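#' Weighted plant x frugivore consumption matrix
#'
#' The central data structure of the package: a non-negative numeric matrix
#' with plants as rows and frugivores as columns. Cell \eqn{X_{ij}} holds the
#' (estimated) number of fruits of plant *i* handled by frugivore *j*
#' (`scale = "counts"`), or the percentage of plant *i*'s handled fruits taken
#' by frugivore *j* (`scale = "percent"`, rows summing to 100).
#'
#' Row totals \eqn{A_i}, column totals \eqn{A_j}, the grand total \eqn{M} and
#' the fill \eqn{F} (number of non-zero cells) are available through
#' [matrix_marginals()].
#'
#' @param values numeric matrix or data frame of non-negative weights,
#'   plants as rows, frugivores as columns.
#' @param plant_labels,frugivore_labels optional character vectors of unique
#'   labels; default to the dimnames of `values` or `P1..`/`F1..`.
#' @param scale `"counts"` or `"percent"`.
#' @return an object of class `consumption_matrix` (a numeric matrix with a
#'   `scale` attribute).
#' @examples
#' m <- consumption_matrix(rbind(c(10, 0), c(5, 5)))
#' matrix_marginals(m)
#' @export
consumption_matrix <- function(values, plant_labels = NULL,
                               frugivore_labels = NULL,
                               scale = c("counts", "percent")) {
  scale <- match.arg(scale)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (any(!is.finite(values))) stop("matrix values must be finite", call. = FALSE)
  if (any(values < 0)) {
    bad <- which(values < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative value at row %d, column %d", bad[1], bad[2]),
         call. = FALSE)
  }
  plant_labels <- plant_labels %||% rownames(values) %||%
    paste0("P", seq_len(nrow(values)))
  frugivore_labels <- frugivore_labels %||% colnames(values) %||%
    paste0("F", seq_len(ncol(values)))
  plant_labels <- normalize_labels(plant_labels)
  frugivore_labels <- normalize_labels(frugivore_labels)
  if (anyDuplicated(plant_labels))
    stop("duplicate plant labels: ",
         paste(unique(plant_labels[duplicated(plant_labels)]), collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(frugivore_labels))
    stop("duplicate frugivore labels: ",
         paste(unique(frugivore_labels[duplicated(frugivore_labels)]),
               collapse = ", "), call. = FALSE)
  dimnames(values) <- list(plant_labels, frugivore_labels)
  if (scale == "percent") {
    rs <- rowSums(values)
    live <- rs > 0
    if (any(abs(rs[live] - 100) > 1e-6))
      stop("percent-scale rows must sum to 100 (off: ",
           paste(plant_labels[live][abs(rs[live] - 100) > 1e-6], collapse = ", "),
           ")", call. = FALSE)
  }
  structure(values, scale = scale, class = c("consumption_matrix", "matrix"))
}

#' @export
print.consumption_matrix <- function(x, ...) {
  mg <- matrix_marginals(x)
  cat(sprintf(
    "<consumption_matrix> %d plants x %d frugivores, scale = %s\n",
    nrow(x), ncol(x), attr(x, "scale")))
  cat(sprintf("  grand total M = %.6g, fill F = %d (connectance %.3f)\n",
              mg$M, mg$F, mg$F / (nrow(x) * ncol(x))))
  print(unclass(x)[, , drop = FALSE], ...)
  invisible(x)
}

#' @export
as.matrix.consumption_matrix <- function(x, ...) {
  y <- unclass(x)
  attr(y, "scale") <- NULL
  y
}

#' Subset a consumption matrix, keeping class and scale
#'
#' @param x a [consumption_matrix()].
#' @param i,j row/column indices.
#' @param drop ignored; dimensions are always kept.
#' @param ... unused.
#' @export
`[.consumption_matrix` <- function(x, i, j, ..., drop = FALSE) {
  y <- unclass(x)[i, j, drop = FALSE]
  structure(y, scale = attr(x, "scale"),
            class = c("consumption_matrix", "matrix"))
}

#' Marginal totals of a consumption matrix
#'
#' @param matrix a [consumption_matrix()] (any non-negative matrix accepted).
#' @return a list with `A_plant` (row totals), `A_frug` (column totals),
#'   grand total `M` and fill `F` (count of cells > 0).
#' @export
matrix_marginals <- function(matrix) {
  m <- as.matrix(matrix)
  list(A_plant = rowSums(m), A_frug = colSums(m),
       M = sum(m), F = sum(m > 0))
}

#' Scale flag of a consumption matrix
#' @param matrix a [consumption_matrix()].
#' @return `"counts"` or `"percent"`.
#' @export
matrix_scale <- function(matrix) attr(matrix, "scale") %||% "counts"

#' Normalize species labels
#'
#' Trims and collapses whitespace and unifies the spacing of `cf.`/`aff.`
#' qualifiers so labels match across tables.
#'
#' @param x character vector.
#' @return cleaned character vector.
#' @export
normalize_labels <- function(x) {
  x <- gsub("\\s+", " ", trimws(as.character(x)))
  gsub("\\b(cf|aff)\\.\\s*", "\\1. ", x)
}

#' Long-format view of a consumption matrix
#'
#' @param x a [consumption_matrix()].
#' @param ... unused.
#' @return a tibble with columns `plant`, `frugivore`, `weight`
#'   (zero cells included) -- ready for dplyr/ggplot2.
#' @exportS3Method generics::tidy
#' @export
tidy.consumption_matrix <- function(x, ...) {
  tibble::tibble(
    plant = rep(rownames(x), times = ncol(x)),
    frugivore = rep(colnames(x), each = nrow(x)),
    weight = as.vector(unclass(x))
  )
}

#' One-line summary of a consumption matrix
#'
#' @param x a [consumption_matrix()].
#' @param ... unused.
#' @return a one-row tibble: dimensions, grand total, fill, connectance.
#' @exportS3Method generics::glance
#' @export
glance.consumption_matrix <- function(x, ...) {
  mg <- matrix_marginals(x)
  tibble::tibble(
    n_plants = nrow(x), n_frugivores = ncol(x), scale = matrix_scale(x),
    total = mg$M, fill = mg$F, connectance = mg$F / (nrow(x) * ncol(x))
  )
}

#' Binarize a consumption matrix
#'
#' Presence/absence skeleton of the weighted web: a cell is 1 iff its weight
#' is strictly positive. No rounding threshold is applied, so arbitrarily
#' small percentages survive. All-zero rows or columns are reported in the
#' `empty` attribute and a warning.
#'
#' @param matrix a [consumption_matrix()].
#' @return a 0/1 integer matrix with the same dimnames; attribute `empty`
#'   lists all-zero row/column labels.
#' @examples
#' binarize(consumption_matrix(rbind(c(2.5, 0), c(1, 1))))
#' @export
binarize <- function(matrix) {
  m <- as.matrix(matrix)
  b <- (m > 0) * 1L
  dimnames(b) <- dimnames(m)
  empty <- list(plants = rownames(b)[rowSums(b) == 0],
                frugivores = colnames(b)[colSums(b) == 0])
  if (length(empty$plants) || length(empty$frugivores))
    warning("all-zero rows/columns: ",
            paste(unlist(empty), collapse = ", "), call. = FALSE)
  attr(b, "empty") <- empty
  b
}

#' Rescale each plant row to percentages
#'
#' Converts a count-scale matrix to the row-percentage form in which each
#' non-empty plant row sums to 100. Idempotent on percent input.
#'
#' @param matrix a [consumption_matrix()].
#' @return a percent-scale [consumption_matrix()].
#' @export
normalize_percent <- function(matrix) {
  m <- as.matrix(matrix)
  rs <- rowSums(m)
  live <- rs > 0
  m[live, ] <- 100 * m[live, , drop = FALSE] / rs[live]
  consumption_matrix(m, scale = "percent")
}

#' Read / write a consumption matrix as delimited text
#'
#' CSV with a header row of frugivore labels and the first column holding
#' plant labels. `read_matrix()` validates rectangularity, uniqueness and
#' non-negativity and reports offending coordinates.
#'
#' @param path file path.
#' @param scale scale flag to stamp on the result.
#' @param transpose if `TRUE` the file stores frugivores as rows and is
#'   transposed at ingest.
#' @return `read_matrix()`: a [consumption_matrix()]; `write_matrix()`:
#'   `path`, invisibly.
#' @export
read_matrix <- function(path, scale = c("counts", "percent"),
                        transpose = FALSE) {
  scale <- match.arg(scale)
  df <- readr::read_csv(path, col_types = readr::cols(
    .default = readr::col_character()))
  if (ncol(df) < 2) stop("matrix file needs a label column plus data columns",
                         call. = FALSE)
  labs <- df[[1]]
  vals <- as.matrix(df[, -1])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow = nrow(vals)))
  if (any(is.na(num))) {
    bad <- which(is.na(num), arr.ind = TRUE)[1, ]
    stop(sprintf("non-numeric or blank cell at row '%s', column '%s'",
                 labs[bad[1]], colnames(df)[-1][bad[2]]), call. = FALSE)
  }
  if (any(num < 0)) {
    bad <- which(num < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative value at row '%s', column '%s'",
                 labs[bad[1]], colnames(df)[-1][bad[2]]), call. = FALSE)
  }
  dimnames(num) <- list(labs, colnames(df)[-1])
  if (transpose) num <- t(num)
  consumption_matrix(num, scale = scale)
}

#' @rdname read_matrix
#' @param matrix a [consumption_matrix()] to write.
#' @export
write_matrix <- function(matrix, path) {
  m <- as.matrix(matrix)
  df <- tibble::as_tibble(m, .name_repair = "minimal")
  df <- dplyr::bind_cols(tibble::tibble(species = rownames(m)), df)
  readr::write_csv(df, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
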