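#' Build an annotated expression container
#'
#' Wraps a cells-by-genes matrix of log-normalized expression together with
#' per-cell patient, cell-type and treatment labels into a
#' \link[SingleCellExperiment]{SingleCellExperiment} (genes in rows, cells in
#' columns, assay \code{"logcounts"}), the container the rest of the package
#' consumes.
#'
#' @param values numeric matrix, cells in rows and genes in columns (the
#'   orientation of most flat-file exports), non-negative log-normalized
#'   expression. Column names are the gene identifiers.
#' @param patient,cell_type,treatment per-cell label vectors recycled to the
#'   number of cells.
#' @return a \code{SingleCellExperiment} with colData columns \code{patient},
#'   \code{cell_type}, \code{treatment}.
#' @export
annotated_expression <- function(values, patient, cell_type = "cancer",
                                 treatment = "irradiated") {
  values <- as.matrix(values)
  if (is.null(colnames(values))) {
    stop("'values' must have gene identifiers as column names")
  }
  if (anyDuplicated(colnames(values))) stop("gene identifiers must be unique")
  if (any(values < 0)) stop("log-normalized expression must be non-negative")
  n <- nrow(values)
  cd <- S4Vectors::DataFrame(
    patient   = rep_len(as.character(patient), n),
    cell_type = rep_len(as.character(cell_type), n),
    treatment = rep_len(as.character(treatment), n)
  )
  SingleCellExperiment::SingleCellExperiment(
    assays  = list(logcounts = t(values)),
    colData = cd
  )
}

# genes x cells expression matrix from an SCE (or a plain matrix passed
# through cells x genes -> transposed)
.expr_matrix <- function(x) {
  if (methods::is(x, "SummarizedExperiment")) {
    a <- SummarizedExperiment::assayNames(x)
    nm <- if ("logcounts" %in% a) "logcounts" else a[1]
    as.matrix(SummarizedExperiment::assay(x, nm))
  } else if (is.matrix(x)) {
    t(x)
  } else {
    stop("expected a SingleCellExperiment or a cells x genes matrix")
  }
}

.cell_labels <- function(x) {
  if (!methods::is(x, "SummarizedExperiment")) {
    stop("per-cell labels require a SingleCellExperiment input")
  }
  as.data.frame(SummarizedExperiment::colData(x))
}

# logical cell filter from a population spec: NULL (all cells), a character
# vector of cell_type values, or a logical/integer index vector
.population_cells <- function(x, population) {
  n <- ncol(.expr_matrix(x))
  if (is.null(population)) return(rep(TRUE, n))
  if (is.character(population)) {
    labs <- .cell_labels(x)
    if (!"cell_type" %in% names(labs)) stop("no cell_type labels present")
    return(labs$cell_type %in% population)
  }
  if (is.logical(population)) {
    if (length(population) != n) stop("logical population filter has wrong length")
    return(population)
  }
  if (is.numeric(population)) {
    keep <- rep(FALSE, n)
    keep[population] <- TRUE
    return(keep)
  }
  stop("unsupported population specification")
}
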