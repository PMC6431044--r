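#' @useDynLib emptydrops, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
NULL

#' Extract a sparse count matrix from supported containers
#'
#' Accepts a \linkS4class{SingleCellExperiment} /
#' \linkS4class{SummarizedExperiment} (the \code{"counts"} assay, or the
#' first assay if none is named \code{"counts"}), or any base or
#' \pkg{Matrix} matrix, and returns a \code{dgCMatrix} of UMI counts with
#' genes in rows and barcodes in columns.
#'
#' @param x A matrix-like object or a SummarizedExperiment.
#' @return A \code{dgCMatrix}.
#' @export
counts_matrix <- function(x) {
    if (is(x, "SummarizedExperiment")) {
        nms <- SummarizedExperiment::assayNames(x)
        idx <- if ("counts" %in% nms) "counts" else 1L
        x <- SummarizedExperiment::assay(x, idx)
    }
    if (is.matrix(x)) {
        x <- Matrix::Matrix(x, sparse = TRUE)
    }
    if (!is(x, "Matrix")) {
        stop("unsupported count container: ", class(x)[1])
    }
    m <- as(as(as(x, "dMatrix"), "generalMatrix"), "CsparseMatrix")
    .validate_counts(m)
    m
}

.validate_counts <- function(m) {
    if (length(m@x)) {
        if (any(m@x < 0)) {
            stop("count matrix contains negative values")
        }
        if (any(m@x != floor(m@x))) {
            stop("count matrix contains non-integer values")
        }
    }
    if (!is.null(colnames(m)) && anyDuplicated(colnames(m))) {
        stop("duplicated barcode identifiers")
    }
    invisible(m)
}

.find_10x_file <- function(path, stems) {
    for (stem in stems) {
        for (f in c(stem, paste0(stem, ".gz"))) {
            full <- file.path(path, f)
            if (file.exists(full)) {
                return(full)
            }
        }
    }
    NULL
}

.read_tsv_plain <- function(path) {
    con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
    on.exit(close(con))
    utils::read.table(con, sep = "\t", header = FALSE, quote = "",
                      comment.char = "", stringsAsFactors = FALSE,
                      colClasses = "character")
}

#' Read an unfiltered 10X-format count matrix
#'
#' Reads the MatrixMarket sparse matrix plus barcode and gene annotation
#' files produced by CellRanger, in either the v2 layout
#' (\code{matrix.mtx}, \code{genes.tsv}, \code{barcodes.tsv}) or the v3
#' layout (\code{matrix.mtx.gz}, \code{features.tsv.gz},
#' \code{barcodes.tsv.gz}); plain and gzipped variants of either dialect
#' are accepted interchangeably.
#'
#' @param path Directory containing the three files.
#' @return A \linkS4class{SingleCellExperiment} with a \code{"counts"}
#'   assay (\code{dgCMatrix}), gene identifiers as row names (any further
#'   annotation columns in \code{rowData}), and barcodes as column names.
#' @details Gene annotation files may carry one or more columns
#'   (identifier, symbol, feature type); only the first is required.
#'   Duplicate gene identifiers are tolerated, duplicate barcodes are an
#'   error, as are negative or fractional matrix entries.
#' @examples
#' dir <- tempfile()
#' m <- Matrix::rsparsematrix(10, 4, 0.5, rand.x = function(n) rpois(n, 2) + 1)
#' dimnames(m) <- list(paste0("G", 1:10), paste0("BC", 1:4))
#' write_10x(m, dir)
#' sce <- read_10x(dir)
#' @export
read_10x <- function(path) {
    if (!dir.exists(path)) {
        stop("'", path, "' is not a directory")
    }
    mat_file <- .find_10x_file(path, "matrix.mtx")
    bc_file <- .find_10x_file(path, "barcodes.tsv")
    gene_file <- .find_10x_file(path, c("features.tsv", "genes.tsv"))
    if (is.null(mat_file) || is.null(bc_file) || is.null(gene_file)) {
        stop("directory must contain matrix.mtx, barcodes.tsv and ",
             "genes.tsv/features.tsv (optionally gzipped)")
    }

    if (grepl("\\.gz$", mat_file)) {
        tmp <- tempfile(fileext = ".mtx")
        on.exit(unlink(tmp))
        writeLines(readLines(gzfile(mat_file)), tmp)
        mat_file <- tmp
    }
    m <- Matrix::readMM(mat_file)
    # an entry-free MTX reads back as a pattern matrix; normalize class
    m <- as(as(as(m, "dMatrix"), "generalMatrix"), "CsparseMatrix")

    genes <- .read_tsv_plain(gene_file)
    barcodes <- .read_tsv_plain(bc_file)[[1]]
    if (nrow(genes) != nrow(m)) {
        stop("gene annotation rows (", nrow(genes),
             ") do not match matrix rows (", nrow(m), ")")
    }
    if (length(barcodes) != ncol(m)) {
        stop("barcode annotation rows (", length(barcodes),
             ") do not match matrix columns (", ncol(m), ")")
    }
    if (anyDuplicated(barcodes)) {
        stop("duplicated barcode identifiers")
    }
    rownames(m) <- genes[[1]]
    colnames(m) <- barcodes
    .validate_counts(m)

    rd <- S4Vectors::DataFrame(gene_id = genes[[1]])
    if (ncol(genes) >= 2) rd$symbol <- genes[[2]]
    if (ncol(genes) >= 3) rd$type <- genes[[3]]
    rownames(rd) <- NULL
    SingleCellExperiment::SingleCellExperiment(
        assays = list(counts = m), rowData = rd
    )
}

.write_lines_maybe_gz <- function(lines, path, gz) {
    con <- if (gz) gzfile(path, "wt") else file(path, "wt")
    on.exit(close(con))
    writeLines(lines, con)
}

#' Write a count matrix in 10X format
#'
#' Writes the MatrixMarket/TSV triplet read back by [read_10x()], either
#' in the v2 plain-text layout or the gzipped v3 layout.
#'
#' @param x Matrix-like object or SummarizedExperiment of UMI counts.
#' @param path Output directory (created if absent).
#' @param version `"2"` (plain `genes.tsv`) or `"3"` (gzipped
#'   `features.tsv.gz` with a feature-type column).
#' @param symbols,feature_type Optional gene symbols and feature type for
#'   the annotation file; defaults reuse the identifiers and
#'   `"Gene Expression"`.
#' @return Invisibly, the output directory.
#' @export
write_10x <- function(x, path, version = c("2", "3"), symbols = NULL,
                      feature_type = "Gene Expression") {
    version <- match.arg(version)
    m <- counts_matrix(x)
    gene_ids <- rownames(m)
    if (is.null(gene_ids)) gene_ids <- paste0("gene", seq_len(nrow(m)))
    barcodes <- colnames(m)
    if (is.null(barcodes)) barcodes <- paste0("barcode", seq_len(ncol(m)))
    if (is(x, "SummarizedExperiment") && is.null(symbols)) {
        rd <- SummarizedExperiment::rowData(x)
        if ("symbol" %in% colnames(rd)) symbols <- rd$symbol
    }
    if (is.null(symbols)) symbols <- gene_ids

    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    gz <- version == "3"
    mtx_tmp <- tempfile(fileext = ".mtx")
    Matrix::writeMM(m, mtx_tmp)
    mtx_lines <- readLines(mtx_tmp)
    unlink(mtx_tmp)
    .write_lines_maybe_gz(
        mtx_lines,
        file.path(path, if (gz) "matrix.mtx.gz" else "matrix.mtx"), gz
    )
    .write_lines_maybe_gz(
        barcodes,
        file.path(path, if (gz) "barcodes.tsv.gz" else "barcodes.tsv"), gz
    )
    if (gz) {
        gene_lines <- paste(gene_ids, symbols, feature_type, sep = "\t")
        .write_lines_maybe_gz(gene_lines, file.path(path, "features.tsv.gz"),
                              TRUE)
    } else {
        gene_lines <- paste(gene_ids, symbols, sep = "\t")
        .write_lines_maybe_gz(gene_lines, file.path(path, "genes.tsv"), FALSE)
    }
    invisible(path)
}

#' Drop genes with no counts in any barcode
#'
#' Genes observed in no droplet carry no information for distinguishing
#' barcodes and are removed before ambient profile estimation. The
#' barcode set (and hence every per-barcode total) is unchanged.
#'
#' @param x Matrix-like object or SummarizedExperiment.
#' @return Object of the same class restricted to genes with at least one
#'   nonzero count.
#' @export
filter_zero_genes <- function(x) {
    m <- counts_matrix(x)
    keep <- Matrix::rowSums(m) > 0
    x[keep, , drop = FALSE]
}

#' Write and read a barcode test table
#'
#' Serializes the per-barcode results of [empty_drops()] (or any data
#' frame with a `barcode` column) to a delimited text file; untested
#' barcodes keep explicit `NA` markers for their p-value and FDR. The
#' delimiter is a comma for `.csv` paths and a tab otherwise.
#'
#' @param table Data frame of per-barcode results.
#' @param path Output file path.
#' @return `write_results` invisibly returns `path`; `read_results`
#'   returns the data frame, with a round trip reproducing the table.
#' @export
write_results <- function(table, path) {
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
    utils::write.table(table, path, sep = sep, quote = FALSE,
                       row.names = FALSE, na = "NA")
    invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
    utils::read.table(path, sep = sep, header = TRUE, na.strings = "NA",
                      stringsAsFactors = FALSE)
}
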