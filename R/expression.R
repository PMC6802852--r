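#' Construct an expression matrix
#'
#' The basic container of the package: a dense numeric matrix with cells in
#' rows and genes in columns, tagged with the unit its values are measured
#' in. All downstream functions take and return this class and check the
#' unit they require.
#'
#' @param values Numeric matrix (cells x genes) or a \pkg{Matrix} sparse
#'   matrix; coerced to a dense base matrix. Row names are cell ids, column
#'   names gene ids; both are mandatory.
#' @param unit One of \code{"counts"}, \code{"lognorm"}, \code{"fpkm"}.
#' @return An object of class \code{expr_matrix}: the matrix itself with a
#'   \code{unit} attribute.
#' @examples
#' m <- matrix(rpois(12, 5), nrow = 3,
#'             dimnames = list(paste0("c", 1:3), paste0("g", 1:4)))
#' em <- expr_matrix(m, "counts")
#' dim(em); expr_unit(em)
#' @export
expr_matrix <- function(values, unit = c("counts", "lognorm", "fpkm")) {
  unit <- match.arg(unit)
  if (inherits(values, "Matrix")) values <- as.matrix(values)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix (cells x genes)")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must carry cell ids as rownames and gene ids as colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate cell ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate gene ids: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]),
               collapse = ", "))
  if (!all(is.finite(values)))
    stop("expression values must all be finite")
  if (unit %in% c("counts", "fpkm") && any(values < 0))
    stop("negative values are not valid for unit '", unit, "'")
  structure(values, unit = unit, class = c("expr_matrix", "matrix", "array"))
}

#' @rdname expr_matrix
#' @param x An \code{expr_matrix}.
#' @export
expr_unit <- function(x) attr(x, "unit")

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d cells x %d genes [unit: %s]\n",
              nrow(x), ncol(x), expr_unit(x)))
  invisible(x)
}

# Subset while keeping class and unit; drops are never allowed.
#' @export
`[.expr_matrix` <- function(x, i, j, ...) {
  out <- NextMethod(drop = FALSE)
  structure(out, unit = attr(x, "unit"),
            class = c("expr_matrix", "matrix", "array"))
}

#' Construct a cell annotation table
#'
#' @param df Data frame with columns \code{cell_id}, \code{timepoint},
#'   optionally \code{condition} and \code{lineage}.
#' @param timepoint_levels Optional character vector giving the temporal
#'   order of the timepoint labels; defaults to their sorted unique values.
#' @return A data frame of class \code{cell_annotation} whose
#'   \code{timepoint} column is an ordered factor.
#' @export
cell_annotation <- function(df, timepoint_levels = NULL) {
  if (!all(c("cell_id", "timepoint") %in% names(df)))
    stop("annotation needs at least columns cell_id and timepoint")
  if (anyDuplicated(df$cell_id))
    stop("duplicate cell_id in annotation: ",
         paste(unique(df$cell_id[duplicated(df$cell_id)]), collapse = ", "))
  if (is.null(timepoint_levels)) {
    if (is.factor(df$timepoint)) timepoint_levels <- levels(df$timepoint)
    else timepoint_levels <- sort(unique(as.character(df$timepoint)))
  }
  if (!all(as.character(df$timepoint) %in% timepoint_levels))
    stop("timepoint values outside the declared level set")
  df$cell_id <- as.character(df$cell_id)
  df$timepoint <- factor(as.character(df$timepoint),
                         levels = timepoint_levels, ordered = TRUE)
  class(df) <- c("cell_annotation", "data.frame")
  df
}

#' Construct a named gene set
#'
#' @param name Set label (e.g. a lineage name such as \code{"TE"}).
#' @param genes Character vector of gene ids; duplicates are dropped.
#' @return An object of class \code{gene_set}.
#' @export
gene_set <- function(name, genes) {
  genes <- unique(as.character(genes))
  if (length(genes) == 0) stop("gene set '", name, "' is empty")
  structure(list(name = as.character(name), genes = genes),
            class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("gene_set '%s': %d genes\n", x$name, length(x$genes)))
  invisible(x)
}

#' Read an expression matrix from disk
#'
#' Two on-disk layouts are supported. \code{fmt = "mtx"} expects a
#' MatrixMarket coordinate file in the genes-x-cells orientation that
#' \code{\link{write_dataset}} (and most single-cell tools) emit, with
#' one-column sidecar files \code{genes.txt} and \code{cells.txt} next to
#' it; the matrix is transposed to cells-in-rows on load. \code{fmt = "tsv"}
#' expects a dense table whose first column holds cell ids and whose header
#' holds gene ids.
#'
#' @param path For \code{mtx}, the \code{.mtx} file or the directory that
#'   contains \code{matrix.mtx}; for \code{tsv}, the file itself.
#' @param fmt \code{"mtx"} or \code{"tsv"}.
#' @param unit Unit tag to attach to the values (the formats themselves do
#'   not record it).
#' @return An \code{\link{expr_matrix}}.
#' @export
read_expression <- function(path, fmt = c("mtx", "tsv"),
                            unit = c("counts", "lognorm", "fpkm")) {
  fmt <- match.arg(fmt)
  unit <- match.arg(unit)
  if (fmt == "mtx") {
    if (dir.exists(path)) path <- file.path(path, "matrix.mtx")
    if (!file.exists(path)) stop("no such file: ", path)
    dir <- dirname(path)
    gpath <- file.path(dir, "genes.txt")
    cpath <- file.path(dir, "cells.txt")
    for (p in c(gpath, cpath))
      if (!file.exists(p)) stop("missing sidecar file: ", p)
    m <- tryCatch(Matrix::readMM(path),
                  error = function(e) stop("malformed MatrixMarket file: ",
                                           conditionMessage(e)))
    genes <- readLines(gpath)
    cells <- readLines(cpath)
    if (anyDuplicated(genes))
      stop("duplicate gene ids in ", gpath)
    if (anyDuplicated(cells))
      stop("duplicate cell ids in ", cpath)
    if (nrow(m) != length(genes) || ncol(m) != length(cells))
      stop(sprintf(
        "matrix is %d x %d but sidecars list %d genes and %d cells",
        nrow(m), ncol(m), length(genes), length(cells)))
    m <- t(as.matrix(m))                      # to cells-in-rows
    dimnames(m) <- list(cells, genes)
    expr_matrix(m, unit)
  } else {
    tab <- utils::read.delim(path, check.names = FALSE,
                             stringsAsFactors = FALSE)
    if (ncol(tab) < 2)
      stop("TSV must have a cell-id column plus at least one gene column")
    cells <- as.character(tab[[1]])
    m <- as.matrix(tab[, -1, drop = FALSE])
    if (!is.numeric(m)) stop("non-numeric expression values in ", path)
    rownames(m) <- cells
    expr_matrix(m, unit)
  }
}

#' Read a cell annotation TSV
#'
#' Expects a header with columns \code{cell_id}, \code{timepoint} and
#' optionally \code{condition} and \code{lineage}.
#'
#' @inheritParams cell_annotation
#' @param path TSV file path.
#' @return A \code{\link{cell_annotation}} data frame.
#' @export
read_annotation <- function(path, timepoint_levels = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  cell_annotation(df, timepoint_levels)
}

#' Read a one-symbol-per-line gene list
#'
#' @param path Text file, one gene id per line; blank lines ignored.
#' @param name Set name; defaults to the file base name.
#' @return A \code{\link{gene_set}}.
#' @export
read_gene_list <- function(path, name = NULL) {
  if (is.null(name))
    name <- sub("\\.[^.]*$", "", basename(path))
  genes <- readLines(path)
  genes <- genes[nzchar(trimws(genes))]
  gene_set(name, trimws(genes))
}

# Align an annotation to a matrix: every cell of `expr` must be annotated.
# Returns the annotation subset in matrix row order.
align_annotation <- function(expr, ann) {
  idx <- match(rownames(expr), ann$cell_id)
  if (anyNA(idx)) {
    miss <- rownames(expr)[is.na(idx)][1:min(5, sum(is.na(idx)))]
    stop("cells missing from annotation: ", paste(miss, collapse = ", "))
  }
  out <- ann[idx, , drop = FALSE]
  rownames(out) <- NULL
  out
}
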