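## Expression matrix and gene-set I/O.
##
## Internal orientation is always genes x cells. Dense text matrices carry a
## header row of cell ids and a first column of gene ids; MatrixMarket
## triplets come with genes.tsv / barcodes.tsv sidecars.

#' Validate an expression matrix
#'
#' Checks the invariants of the genes x cells container: numeric,
#' nonnegative, with unique row (gene) and column (cell) identifiers.
#'
#' @param x Numeric matrix, genes in rows and cells in columns, with
#'   dimnames.
#' @return \code{x} invisibly, after stopping on any violation.
#' @export
validateExpression <- function(x) {
  if (!is.matrix(x) || !is.numeric(x))
    stop("expression data must be a numeric matrix")
  if (anyNA(x) || any(!is.finite(x)))
    stop("expression matrix contains missing or non-finite entries")
  if (any(x < 0))
    stop("expression matrix contains negative entries")
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop("expression matrix must carry gene (row) and cell (column) ids")
  if (anyDuplicated(rownames(x)))
    stop("gene identifiers are not unique")
  if (anyDuplicated(colnames(x)))
    stop("cell identifiers are not unique")
  invisible(x)
}

## Fraction of identifiers that look like cell barcodes / cell labels
## rather than gene symbols.
cellLikeScore <- function(ids) {
  barcode <- grepl("^[ACGTN]{6,}([-_][0-9]+)?$", ids)
  labelled <- grepl("^(cell|barcode|bc)[-_.]?[0-9]*$", ids,
                    ignore.case = TRUE)
  mean(barcode | labelled)
}

#' Read an expression matrix from delimited text or MatrixMarket files
#'
#' Supports a dense delimited matrix (header row of cell ids, first column
#' of gene ids; comma or tab separated, chosen by extension) or a
#' MatrixMarket coordinate file with \code{genes.tsv} and
#' \code{barcodes.tsv} sidecars in the same directory.
#'
#' The returned matrix is always genes x cells. For dense input the
#' orientation is resolved by \code{layoutHint}; with the default
#' \code{"auto"} the axis whose identifiers look like cell barcodes (or
#' "cell..." labels) becomes the columns, and if neither axis looks
#' cell-like the longer axis is taken to be genes.
#'
#' @param path Path to a \code{.csv}/\code{.tsv}/\code{.txt} matrix or a
#'   \code{.mtx} file.
#' @param layoutHint One of \code{"auto"}, \code{"genes_by_cells"},
#'   \code{"cells_by_genes"}.
#' @return A numeric genes x cells matrix with gene row names and cell
#'   column names.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' m <- matrix(0:5, 3, 2, dimnames = list(paste0("G", 1:3), c("c1", "c2")))
#' writeExpression(m, f)
#' x <- readExpression(f)
#' stopifnot(identical(dim(x), c(3L, 2L)))
#' @export
readExpression <- function(path,
                           layoutHint = c("auto", "genes_by_cells",
                                          "cells_by_genes")) {
  layoutHint <- match.arg(layoutHint)
  if (!file.exists(path)) stop("file not found: ", path)
  if (grepl("\\.mtx$", path, ignore.case = TRUE)) {
    x <- readExpressionMM(path)
  } else {
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
    df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1L,
                            check.names = FALSE, comment.char = "")
    x <- as.matrix(df)
    if (!is.numeric(x)) stop("non-numeric entries in ", path)
    if (layoutHint == "cells_by_genes") {
      x <- t(x)
    } else if (layoutHint == "auto") {
      rowsCellLike <- cellLikeScore(rownames(x))
      colsCellLike <- cellLikeScore(colnames(x))
      if (rowsCellLike > colsCellLike) {
        x <- t(x)
      } else if (rowsCellLike == colsCellLike && nrow(x) < ncol(x)) {
        # neither axis identifiable: assume the larger axis is genes
        x <- t(x)
      }
    }
  }
  validateExpression(x)
  x
}

readExpressionMM <- function(path) {
  m <- as.matrix(Matrix::readMM(path))
  dir <- dirname(path)
  genesFile <- file.path(dir, "genes.tsv")
  cellsFile <- file.path(dir, "barcodes.tsv")
  if (!file.exists(genesFile) || !file.exists(cellsFile))
    stop("MatrixMarket input needs genes.tsv and barcodes.tsv next to ", path)
  genes <- utils::read.table(genesFile, sep = "\t",
                             stringsAsFactors = FALSE)[[1L]]
  cells <- utils::read.table(cellsFile, sep = "\t",
                             stringsAsFactors = FALSE)[[1L]]
  if (length(genes) != nrow(m))
    stop("genes.tsv has ", length(genes), " entries but matrix has ",
         nrow(m), " rows")
  if (length(cells) != ncol(m))
    stop("barcodes.tsv has ", length(cells), " entries but matrix has ",
         ncol(m), " columns")
  dimnames(m) <- list(genes, cells)
  m
}

#' Write an expression matrix
#'
#' Dense delimited output (extension \code{.csv} or \code{.tsv}) or
#' MatrixMarket coordinate output (extension \code{.mtx}, with
#' \code{genes.tsv} and \code{barcodes.tsv} sidecars written alongside).
#'
#' @param x Genes x cells numeric matrix with dimnames.
#' @param path Output path; the extension selects the format.
#' @return \code{path}, invisibly.
#' @export
writeExpression <- function(x, path) {
  validateExpression(x)
  if (grepl("\\.mtx$", path, ignore.case = TRUE)) {
    Matrix::writeMM(Matrix::Matrix(x, sparse = TRUE), path)
    dir <- dirname(path)
    writeLines(rownames(x), file.path(dir, "genes.tsv"))
    writeLines(colnames(x), file.path(dir, "barcodes.tsv"))
  } else {
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
    df <- data.frame(gene = rownames(x), x, check.names = FALSE)
    utils::write.table(df, path, sep = sep, row.names = FALSE,
                       col.names = TRUE, quote = FALSE)
  }
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' GMT dialect: one set per non-blank line, tab-separated fields
#' \code{name}, \code{description}, then gene identifiers. Gene order is
#' preserved.
#'
#' @param path Path to a GMT file.
#' @return A [PathwayCollection-class].
#' @export
readGeneSets <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(PathwayCollection(list()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3L)
  if (length(bad))
    stop("GMT line ", bad[1L], " has fewer than 3 fields")
  nms <- vapply(fields, `[[`, character(1L), 1L)
  if (anyDuplicated(nms))
    stop("duplicate gene set name: ", nms[duplicated(nms)][1L])
  descs <- vapply(fields, `[[`, character(1L), 2L)
  sets <- lapply(fields, function(f) f[-(1:2)])
  names(sets) <- nms
  PathwayCollection(sets, descs)
}

#' Write gene sets to a GMT file
#'
#' @param gs A [PathwayCollection-class].
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
writeGeneSets <- function(gs, path) {
  stopifnot(is(gs, "PathwayCollection"))
  sets <- geneSets(gs)
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], gs@descriptions[i], sets[[i]]), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Read / write cluster labels
#'
#' Labels are stored as a two-column CSV (\code{cell_id}, \code{cluster}).
#'
#' @param path CSV path.
#' @return For \code{readLabels}, an integer vector of cluster labels named
#'   by cell id.
#' @export
readLabels <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = ",",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("label file needs columns cell_id, cluster")
  labels <- as.integer(df[[2L]])
  names(labels) <- as.character(df[[1L]])
  labels
}

#' @rdname readLabels
#' @param labels Integer vector of cluster labels, named by cell id (or
#'   accompanied by \code{cellIds}).
#' @param cellIds Optional cell identifiers overriding \code{names(labels)}.
#' @export
writeLabels <- function(labels, path, cellIds = NULL) {
  if (is.null(cellIds)) cellIds <- names(labels)
  if (is.null(cellIds)) cellIds <- paste0("cell", seq_along(labels))
  utils::write.table(
    data.frame(cell_id = cellIds, cluster = as.integer(labels)),
    path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}
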