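#' Cell-by-protein intensity matrix
#'
#' The central container of the package: a numeric matrix with cells in rows
#' and protein groups in columns, on the linear intensity scale, with `NA`
#' marking "not quantified" (missing is never zero; search engines do not
#' report true zero intensities). Each protein group carries a gene symbol,
#' used for cross-dataset joins with RNA count matrices.
#'
#' @param values numeric matrix, cells in rows, protein groups in columns.
#'   Row and column names are required and must be unique. Present values
#'   must be strictly positive.
#' @param genes character vector of gene symbols, one per protein group
#'   (recycled from column names when omitted).
#' @return an `intensity_matrix`: the matrix with a `genes` attribute.
#' @examples
#' m <- intensity_matrix(matrix(c(100, NA, 50, 200), nrow = 2,
#'                              dimnames = list(c("c1", "c2"), c("P1", "P2"))))
#' genes(m)
#' @export
intensity_matrix <- function(values, genes = NULL) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix (cells x protein groups)", call. = FALSE)
  }
  if (is.null(rownames(values))) {
    rownames(values) <- sprintf("cell%04d", seq_len(nrow(values)))
  }
  if (is.null(colnames(values))) {
    colnames(values) <- sprintf("PG%04d", seq_len(ncol(values)))
  }
  if (anyDuplicated(rownames(values))) {
    stop("duplicate cell identifiers", call. = FALSE)
  }
  if (anyDuplicated(colnames(values))) {
    stop("duplicate protein-group identifiers", call. = FALSE)
  }
  if (any(values <= 0, na.rm = TRUE)) {
    stop("present intensities must be strictly positive (missing is NA, not 0)",
         call. = FALSE)
  }
  genes <- genes %||% colnames(values)
  if (length(genes) != ncol(values)) {
    stop("`genes` must have one symbol per protein group", call. = FALSE)
  }
  genes <- as.character(genes)
  names(genes) <- colnames(values)
  structure(values, genes = genes, class = c("intensity_matrix", "matrix", "array"))
}

#' @export
`[.intensity_matrix` <- function(x, i, j, ..., drop = FALSE) {
  g <- attr(x, "genes")
  out <- NextMethod(drop = drop)
  if (is.matrix(out)) {
    attr(out, "genes") <- g[colnames(out)]
    class(out) <- c("intensity_matrix", "matrix", "array")
  }
  out
}

#' Gene symbols of an intensity matrix
#' @param m an [intensity_matrix()]
#' @return named character vector, one symbol per protein group.
#' @export
genes <- function(m) {
  attr(m, "genes") %||% colnames(m)
}

#' @export
print.intensity_matrix <- function(x, ...) {
  cat(sprintf("<intensity_matrix> %d cells x %d protein groups, %.1f%% complete\n",
              nrow(x), ncol(x),
              if (length(x)) 100 * mean(!is.na(x)) else 100))
  invisible(x)
}

#' Fraction of quantified entries
#'
#' @param m an [intensity_matrix()] or plain matrix with `NA` for missing.
#' @return scalar in \[0, 1\]; 1 for an empty matrix.
#' @export
completeness <- function(m) {
  if (length(m) == 0) {
    return(1)
  }
  mean(!is.na(m))
}

# Strip class/attributes down to a plain numeric matrix.
as_plain_matrix <- function(m) {
  out <- unclass(m)
  attr(out, "genes") <- NULL
  out
}
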