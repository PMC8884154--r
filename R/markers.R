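#' Built-in cell-cycle marker sets
#'
#' The three phase-specific marker protein sets used for gene-set cell-cycle
#' scoring of drug-arrested HeLa single-cell proteomes. They derive from
#' bulk cell-cycle proteomics fold-change rankings (top differentially
#' expressed proteins per phase, filtered for quantification coverage) and
#' are bundled verbatim: 14 G1 markers, 12 S markers and 12 G2/M markers.
#'
#' @return named list of three `marker_set` objects (`G1`, `S`, `G2M`).
#' @seealso [marker_set()], [score_gene_set()]
#' @examples
#' lengths(lapply(cell_cycle_markers(), `[[`, "genes"))
#' @export
cell_cycle_markers <- function() {
  list(
    G1 = marker_set("G1", c(
      "MARCKS", "KRT1", "HIST1H1E", "KRT18", "HNRNPA1", "CHCHD3", "CD44",
      "NASP", "TARDBP", "PODXL", "SUMO2", "STMN1", "TRIM28", "SPTAN1"
    )),
    S = marker_set("S", c(
      "NOLC1", "ATP2A2", "CANX", "TMX1", "CKB", "SLC25A3", "SLC16A1",
      "MT-CO2", "SRPRB", "CYB5R3", "LETM1", "ANP32B"
    )),
    G2M = marker_set("G2M", c(
      "TOP2A", "HMGB1", "EIF5B", "TMSB10", "EIF3D", "ANP32A", "RCC2",
      "FASN", "LUC7L2", "AARS", "KPNA2", "CKAP5"
    ))
  )
}

#' Construct a marker set
#'
#' A named cell-cycle phase with an ordered list of gene symbols.
#'
#' @param phase phase label, one of `"G1"`, `"S"`, `"G2M"` (other labels are
#'   allowed for user-defined sets).
#' @param genes non-empty character vector of unique gene symbols.
#' @return a `marker_set` (list with `phase` and `genes`).
#' @export
marker_set <- function(phase, genes) {
  if (length(genes) == 0) {
    stop("a marker set must contain at least one gene", call. = FALSE)
  }
  genes <- as.character(genes)
  if (anyDuplicated(toupper(trimws(genes)))) {
    stop("marker gene symbols must be unique within a set", call. = FALSE)
  }
  structure(list(phase = as.character(phase), genes = genes),
            class = "marker_set")
}

#' @export
print.marker_set <- function(x, ...) {
  cat(sprintf("<marker_set> %s: %d genes (%s, ...)\n", x$phase,
              length(x$genes), paste(utils::head(x$genes, 3), collapse = ", ")))
  invisible(x)
}

#' Read marker sets from a two-column TSV
#'
#' @param path TSV file with header columns `phase` and `gene`.
#' @return named list of `marker_set`, one per distinct phase, genes in file
#'   order.
#' @export
read_marker_sets <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("phase", "gene") %in% names(df))) {
    stop("marker file must have columns `phase` and `gene`", call. = FALSE)
  }
  phases <- unique(df$phase)
  out <- lapply(phases, function(p) marker_set(p, df$gene[df$phase == p]))
  names(out) <- phases
  out
}

#' Write marker sets to a two-column TSV
#'
#' @param sets named list of [marker_set()] objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_marker_sets <- function(sets, path) {
  df <- do.call(rbind, lapply(sets, function(s) {
    data.frame(phase = s$phase, gene = s$genes, stringsAsFactors = FALSE)
  }))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
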