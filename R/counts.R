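## Count-matrix plumbing: validation, normalization helpers, delimited I/O.
## Counts are plain numeric matrices with feature rownames and sample
## colnames; SummarizedExperiment inputs are unwrapped via assay().

#' Validate a count matrix
#'
#' Checks that `X` is a feature-by-sample matrix of non-negative integers
#' with no all-zero sample column (a sample with zero total depth carries
#' no information and breaks the depth-matching convention). All-zero
#' feature rows are allowed: they simply contribute zero to every type.
#'
#' @param X numeric matrix (features x samples), or a
#'   `SummarizedExperiment` whose first assay is used.
#' @param requireIntegers logical; demand integral entries (default TRUE).
#' @return the validated matrix, with dimnames filled in if missing.
#' @export
#' @examples
#' asCountMatrix(matrix(0:5, nrow = 2))
asCountMatrix <- function(X, requireIntegers = TRUE) {
  if (is(X, "SummarizedExperiment") &&
      requireNamespace("SummarizedExperiment", quietly = TRUE)) {
    X <- as.matrix(SummarizedExperiment::assay(X))
  }
  X <- as.matrix(X)
  if (!is.numeric(X)) stop("count matrix must be numeric")
  if (anyNA(X)) stop("count matrix contains missing values")
  if (any(X < 0)) {
    idx <- which(X < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative entry at row %d, column %d", idx[1], idx[2]))
  }
  if (requireIntegers && any(abs(X - round(X)) > 1e-8)) {
    idx <- which(abs(X - round(X)) > 1e-8, arr.ind = TRUE)[1, ]
    stop(sprintf("non-integer entry at row %d, column %d", idx[1], idx[2]))
  }
  zero <- colSums(X) == 0
  if (any(zero))
    stop("all-zero sample column(s): ",
         paste(if (is.null(colnames(X))) which(zero)
               else colnames(X)[zero], collapse = ", "))
  if (is.null(rownames(X)))
    rownames(X) <- paste0("feature", seq_len(nrow(X)))
  if (is.null(colnames(X)))
    colnames(X) <- paste0("sample", seq_len(ncol(X)))
  X
}

#' @keywords internal
normalizeColumns <- function(M) {
  cs <- colSums(M)
  cs[cs == 0] <- 1
  sweep(M, 2, cs, "/")
}

#' Read a count table
#'
#' Reads a delimited count table (first column feature IDs, header row
#' sample IDs) or a BIOM file, and validates it with [asCountMatrix()].
#'
#' @param path file path.
#' @param format `"tsv"`, `"csv"` or `"biom"` (requires the biomformat
#'   package). Default guesses from the file extension.
#' @return validated count matrix.
#' @export
readCounts <- function(path, format = c("auto", "tsv", "csv", "biom")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, csv = "csv", biom = "biom", "tsv")
  }
  if (format == "biom") {
    if (!requireNamespace("biomformat", quietly = TRUE))
      stop("reading BIOM files requires the biomformat package")
    b <- biomformat::read_biom(path)
    M <- as(biomformat::biom_data(b), "matrix")
    return(asCountMatrix(M))
  }
  sep <- if (format == "csv") "," else "\t"
  df <- read.delim(path, sep = sep, header = TRUE, row.names = 1,
                   check.names = FALSE)
  asCountMatrix(as.matrix(df))
}

#' Write a matrix as TSV with row and column labels
#'
#' @param M matrix with dimnames.
#' @param path output file.
#' @export
writeMatrix <- function(M, path) {
  df <- data.frame(id = rownames(M), M, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sample class labels
#'
#' Reads a two-column delimited file (sample ID, class label) and checks
#' it against a count matrix when one is given: every sample column must
#' have exactly one label and every class must be non-empty.
#'
#' @param path file path (TSV, with or without a header line).
#' @param counts optional count matrix to validate against.
#' @return named factor of class labels (names = sample IDs, in the order
#'   of `counts` when given).
#' @export
readLabels <- function(path, counts = NULL) {
  df <- read.delim(path, sep = "\t", header = FALSE,
                   colClasses = "character")
  if (nrow(df) && tolower(df[1, 1]) %in% c("sample", "sample_id", "id"))
    df <- df[-1, , drop = FALSE]
  if (ncol(df) < 2) stop("label file needs two columns: sample, class")
  labels <- stats::setNames(factor(df[[2]]), df[[1]])
  if (!is.null(counts)) {
    missing <- setdiff(colnames(counts), names(labels))
    if (length(missing))
      stop("samples missing from label file: ",
           paste(missing, collapse = ", "))
    labels <- labels[colnames(counts)]
    labels <- droplevels(labels)
  }
  if (any(table(labels) == 0)) stop("empty class in labels")
  labels
}

#' @keywords internal
checkPartition <- function(labels, n) {
  labels <- as.factor(labels)
  if (length(labels) != n)
    stop("need exactly one class label per sample")
  if (anyNA(labels)) stop("missing class labels")
  labels <- droplevels(labels)
  if (nlevels(labels) < 1 || any(table(labels) == 0))
    stop("every class must be non-empty")
  labels
}

## Align the rows of a type matrix with the rows of a count matrix by
## feature ID. Errors list the offending identifiers.
#' @keywords internal
alignFeatures <- function(Tm, X) {
  if (is.null(rownames(Tm)) || is.null(rownames(X)))
    return(if (nrow(Tm) == nrow(X)) X else
           stop("feature dimensions differ and no IDs to join on"))
  bad <- setdiff(rownames(X), rownames(Tm))
  bad2 <- setdiff(rownames(Tm), rownames(X))
  if (length(bad) || length(bad2))
    stop("feature IDs do not match: ",
         paste(head(c(bad, bad2), 10), collapse = ", "))
  X[rownames(Tm), , drop = FALSE]
}
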