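#' Read a cell-by-protein intensity table
#'
#' Two layouts are supported. `wide`: first column `cell_id`, one column per
#' protein group, empty fields or `NA` meaning "not quantified". `long`: one
#' row per quantified entry with columns `cell_id`, `protein_group`, `gene`,
#' `intensity`; pairs absent from the file (or with an empty intensity
#' field) are missing. Because raw search output never reports a true zero
#' intensity, zeros are read as missing by default.
#'
#' @param path TSV file (tab-delimited, UTF-8, header row).
#' @param layout `"wide"` or `"long"`.
#' @param zero_as_missing treat 0 as missing (default `TRUE`).
#' @return an [intensity_matrix()].
#' @export
read_intensity_table <- function(path, layout = c("wide", "long"),
                                 zero_as_missing = TRUE) {
  layout <- match.arg(layout)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                          na.strings = c("", "NA"))
  if (layout == "wide") {
    if (names(df)[1] != "cell_id") {
      stop("wide layout requires the first column to be `cell_id`", call. = FALSE)
    }
    cells <- as.character(df[[1]])
    vals <- as.matrix(df[, -1, drop = FALSE])
    if (!is.numeric(vals)) {
      bad <- which(!vapply(df[-1], is.numeric, logical(1)))
      stop("non-numeric intensity in column(s): ",
           paste(names(df)[-1][bad], collapse = ", "), call. = FALSE)
    }
    rownames(vals) <- cells
    if (zero_as_missing) {
      vals[!is.na(vals) & vals == 0] <- NA_real_
    }
    return(intensity_matrix(vals))
  }
  need <- c("cell_id", "protein_group", "intensity")
  if (!all(need %in% names(df))) {
    stop("long layout requires columns cell_id, protein_group, intensity",
         call. = FALSE)
  }
  if (!is.numeric(df$intensity)) {
    bad <- which(is.na(suppressWarnings(as.numeric(df$intensity))) &
                   !is.na(df$intensity))
    stop("non-numeric intensity in row(s): ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(df[c("cell_id", "protein_group")])) {
    stop("duplicate (cell, protein) entries in long table", call. = FALSE)
  }
  cells <- unique(df$cell_id)
  prots <- unique(df$protein_group)
  vals <- matrix(NA_real_, nrow = length(cells), ncol = length(prots),
                 dimnames = list(cells, prots))
  vals[cbind(match(df$cell_id, cells), match(df$protein_group, prots))] <-
    df$intensity
  if (zero_as_missing) {
    vals[!is.na(vals) & vals == 0] <- NA_real_
  }
  gene_map <- NULL
  if ("gene" %in% names(df)) {
    first <- !duplicated(df$protein_group)
    gene_map <- df$gene[first]
    names(gene_map) <- df$protein_group[first]
    gene_map <- ifelse(is.na(gene_map[prots]), prots, gene_map[prots])
  }
  intensity_matrix(vals, genes = gene_map)
}

#' Write an intensity matrix as TSV
#'
#' @param m an [intensity_matrix()].
#' @param path output path.
#' @param layout `"wide"` (empty field = missing) or `"long"` (one row per
#'   quantified entry, with the gene symbol column).
#' @return `path`, invisibly.
#' @export
write_intensity_table <- function(m, path, layout = c("wide", "long")) {
  layout <- match.arg(layout)
  if (layout == "wide") {
    df <- data.frame(cell_id = rownames(m), as_plain_matrix(m),
                     check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                       na = "")
  } else {
    obs <- which(!is.na(as_plain_matrix(m)), arr.ind = TRUE)
    g <- genes(m)
    df <- data.frame(cell_id = rownames(m)[obs[, 1]],
                     protein_group = colnames(m)[obs[, 2]],
                     gene = unname(g[obs[, 2]]),
                     intensity = as_plain_matrix(m)[obs],
                     stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read a count matrix from Matrix Market files
#'
#' Reads the coordinate Matrix Market layout used throughout single-cell
#' genomics: an `.mtx` file plus plain-text feature and barcode lists.
#' Rows of the matrix are cells (barcodes) and columns are genes (features);
#' coordinates are 1-based per the Matrix Market standard, and entries
#' absent from the file are zero (observed zeros, not missing).
#'
#' @param mtx_path coordinate MatrixMarket file.
#' @param features_path one gene symbol per line.
#' @param barcodes_path one cell barcode per line.
#' @return integer matrix, cells x genes, with dimnames.
#' @export
read_mtx_counts <- function(mtx_path, features_path, barcodes_path) {
  mm <- Matrix::readMM(mtx_path)
  feats <- readLines(features_path)
  bars <- readLines(barcodes_path)
  if (nrow(mm) != length(bars)) {
    stop(sprintf("MTX declares %d rows but barcodes file lists %d cells",
                 nrow(mm), length(bars)), call. = FALSE)
  }
  if (ncol(mm) != length(feats)) {
    stop(sprintf("MTX declares %d columns but features file lists %d genes",
                 ncol(mm), length(feats)), call. = FALSE)
  }
  counts <- as.matrix(mm)
  if (any(counts < 0)) {
    stop("counts must be non-negative", call. = FALSE)
  }
  storage.mode(counts) <- "integer"
  dimnames(counts) <- list(bars, feats)
  counts
}

#' Write a count matrix as Matrix Market files
#'
#' @param counts integer matrix, cells x genes, with dimnames.
#' @param mtx_path,features_path,barcodes_path output paths.
#' @return `mtx_path`, invisibly.
#' @export
write_mtx_counts <- function(counts, mtx_path, features_path, barcodes_path) {
  Matrix::writeMM(Matrix::Matrix(counts, sparse = TRUE), mtx_path)
  writeLines(colnames(counts), features_path)
  writeLines(rownames(counts), barcodes_path)
  invisible(mtx_path)
}

#' Write generator ground truth as JSON
#'
#' @param truth the `truth` element of [generate_proteome_cohort()] output.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  # named vectors must become JSON objects, not arrays, to keep their names
  if (!is.null(truth$base_abundance_log10)) {
    truth$base_abundance_log10 <- as.list(truth$base_abundance_log10)
  }
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' Read generator ground truth from JSON
#'
#' @param path JSON file written by [write_ground_truth()].
#' @return list mirroring the generator's `truth` element.
#' @export
read_ground_truth <- function(path) {
  tr <- jsonlite::read_json(path, simplifyVector = TRUE)
  tr$cells <- as.data.frame(tr$cells, stringsAsFactors = FALSE)
  if (!is.null(tr$marker_effects)) {
    tr$marker_effects <- as.data.frame(tr$marker_effects, stringsAsFactors = FALSE)
  }
  tr
}
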