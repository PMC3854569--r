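#' Construct an expression matrix
#'
#' Light container for a genes x conditions expression matrix carrying a
#' `scale_tag` recording what the values are: raw read counts (`"counts"`),
#' length- and depth-normalized values in reads per kilobase per million
#' mapped reads (`"normalized"`), or natural-log values (`"log"`).
#'
#' @param values Numeric matrix, rows = genes, columns = conditions. Row and
#'   column names are required and must be unique.
#' @param scale_tag One of `"counts"`, `"normalized"`, `"log"`.
#' @return An object of class `expr_matrix`: a list with elements `values`
#'   (the matrix) and `scale_tag`.
#' @export
expression_matrix <- function(values, scale_tag = c("counts", "normalized", "log")) {
  scale_tag <- match.arg(scale_tag)
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (is.null(rownames(values)) && nrow(values) > 0)
    stop("'values' must have gene identifiers as row names")
  if (is.null(colnames(values)))
    stop("'values' must have condition identifiers as column names")
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene identifiers: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate condition identifiers: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "))
  if (scale_tag != "log" && nrow(values) > 0 && any(values < 0, na.rm = TRUE))
    stop("counts and normalized expression values must be non-negative")
  if (anyNA(values))
    stop("expression values must not contain NA")
  structure(list(values = values, scale_tag = scale_tag), class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d genes x %d conditions [%s]\n",
              nrow(x$values), ncol(x$values), x$scale_tag))
  invisible(x)
}

#' Gene identifiers of an expression matrix
#' @param m An `expr_matrix`.
#' @return Character vector of gene ids (row order).
#' @export
gene_ids <- function(m) rownames(m$values)

#' Condition identifiers of an expression matrix
#' @param m An `expr_matrix`.
#' @return Character vector of condition ids (column order).
#' @export
condition_ids <- function(m) colnames(m$values)

#' Subset an expression matrix by gene and/or condition
#' @param m An `expr_matrix`.
#' @param genes,conditions Character vectors of identifiers to keep
#'   (default: all, in stored order).
#' @return A new `expr_matrix` with the same `scale_tag`.
#' @export
subset_genes <- function(m, genes = gene_ids(m), conditions = condition_ids(m)) {
  missing_g <- setdiff(genes, gene_ids(m))
  if (length(missing_g))
    stop("genes not in matrix: ", paste(utils::head(missing_g, 5), collapse = ", "))
  missing_c <- setdiff(conditions, condition_ids(m))
  if (length(missing_c))
    stop("conditions not in matrix: ", paste(utils::head(missing_c, 5), collapse = ", "))
  expression_matrix(m$values[genes, conditions, drop = FALSE], m$scale_tag)
}

#' Read a raw read-count matrix from a tab-delimited file
#'
#' Expects a header row of condition identifiers and a first column of gene
#' identifiers; remaining cells are non-negative counts. Row and column
#' ordering of the file is preserved.
#'
#' @param path Path to the tab-delimited file.
#' @return An `expr_matrix` with `scale_tag = "counts"`.
#' @export
load_counts <- function(path) {
  read_expression(path, "counts")
}

#' Read an expression matrix of any scale from a tab-delimited file
#'
#' Same layout as [load_counts()] but with an explicit `scale_tag`, e.g.
#' for reading back a written log-expression matrix.
#'
#' @param path Path to the tab-delimited file.
#' @param scale_tag One of `"counts"`, `"normalized"`, `"log"`.
#' @return An `expr_matrix`.
#' @export
read_expression <- function(path, scale_tag = c("counts", "normalized", "log")) {
  scale_tag <- match.arg(scale_tag)
  df <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                          colClasses = "character", stringsAsFactors = FALSE)
  if (ncol(df) < 2)
    stop("matrix file must have a gene-id column plus at least one condition column: ", path)
  ids <- df[[1]]
  conds <- colnames(df)[-1]
  if (anyDuplicated(ids))
    stop("duplicate gene identifiers in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  vals <- matrix(NA_real_, nrow = length(ids), ncol = length(conds),
                 dimnames = list(ids, conds))
  for (j in seq_along(conds)) {
    col <- suppressWarnings(as.numeric(df[[j + 1L]]))
    bad <- which(is.na(col) & !is.na(df[[j + 1L]]))
    if (length(bad))
      stop(sprintf("non-numeric value for gene '%s', condition '%s'",
                   ids[bad[1L]], conds[j]))
    vals[, j] <- col
  }
  expression_matrix(vals, scale_tag)
}

#' Write an expression matrix to a tab-delimited file
#'
#' Inverse of [load_counts()]: first column `gene_id`, then one column per
#' condition.
#'
#' @param m An `expr_matrix`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_expression <- function(m, path) {
  df <- data.frame(gene_id = gene_ids(m), m$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene-length table
#'
#' Two tab-delimited columns: gene id and length in base pairs.
#'
#' @param path Path to the table (header optional; detected from whether the
#'   second field of the first line is numeric).
#' @return Named numeric vector of lengths (bp).
#' @export
read_gene_lengths <- function(path) {
  first <- utils::read.delim(path, header = FALSE, nrows = 1,
                             colClasses = "character")
  has_header <- is.na(suppressWarnings(as.numeric(first[[2]])))
  df <- utils::read.delim(path, header = has_header, colClasses = "character")
  len <- suppressWarnings(as.numeric(df[[2]]))
  if (anyNA(len)) stop("non-numeric gene length in ", path)
  stats::setNames(len, df[[1]])
}

#' Read a transcription-factor table
#'
#' Tab-delimited, two or three columns: gene id, a flag or the family label,
#' optionally a family label in column three. Only rows listed are TFs.
#'
#' @param path Path to the table.
#' @return data.frame with columns `gene_id`, `tf_family`.
#' @export
read_tf_table <- function(path) {
  df <- utils::read.delim(path, header = FALSE, colClasses = "character",
                          comment.char = "#")
  fam <- if (ncol(df) >= 2) df[[ncol(df)]] else rep("", nrow(df))
  data.frame(gene_id = df[[1]], tf_family = fam, stringsAsFactors = FALSE)
}

#' Normalize raw counts to reads per kilobase per million mapped reads
#'
#' Each count is divided by the gene length in kilobases and by the library
#' size (total mapped reads of that condition) in millions:
#' `count / (length_bp/1000) / (library_size/1e6)`.
#'
#' @param counts An `expr_matrix` with `scale_tag = "counts"`.
#' @param gene_lengths Named numeric vector of gene lengths in bp; must cover
#'   every gene of `counts`.
#' @param library_sizes Named numeric vector of total mapped reads per
#'   condition. Defaults to the column sums of the count matrix.
#' @return An `expr_matrix` with `scale_tag = "normalized"`.
#' @export
rpkm_normalize <- function(counts, gene_lengths, library_sizes = NULL) {
  stopifnot(inherits(counts, "expr_matrix"))
  if (counts$scale_tag != "counts")
    stop("rpkm_normalize expects raw counts (scale_tag 'counts'), got '",
         counts$scale_tag, "'")
  if (is.null(library_sizes))
    library_sizes <- colSums(counts$values)
  miss_len <- setdiff(gene_ids(counts), names(gene_lengths))
  if (length(miss_len))
    stop("missing gene length for: ", paste(utils::head(miss_len, 10), collapse = ", "))
  miss_lib <- setdiff(condition_ids(counts), names(library_sizes))
  if (length(miss_lib))
    stop("missing library size for: ", paste(miss_lib, collapse = ", "))
  len <- gene_lengths[gene_ids(counts)]
  lib <- library_sizes[condition_ids(counts)]
  if (any(len <= 0)) stop("gene lengths must be positive")
  if (any(lib <= 0)) stop("library sizes must be positive")
  vals <- counts$values / (len / 1000) # recycles down columns (genes)
  vals <- sweep(vals, 2, lib / 1e6, "/")
  expression_matrix(vals, "normalized")
}

#' Natural-log transform of normalized expression values
#'
#' Applies `ln(value + pseudocount)` cell-wise so that expression values are
#' closer to Gaussian, as assumed by the regulatory-tree leaf model.
#'
#' @param m An `expr_matrix` with `scale_tag = "normalized"`.
#' @param pseudocount Non-negative offset added before the log; default 1 so
#'   that zero expression maps to zero.
#' @return An `expr_matrix` with `scale_tag = "log"`.
#' @export
log_transform <- function(m, pseudocount = 1) {
  stopifnot(inherits(m, "expr_matrix"))
  if (m$scale_tag != "normalized")
    stop("log_transform expects normalized values (scale_tag 'normalized'), got '",
         m$scale_tag, "'")
  if (pseudocount < 0) stop("pseudocount must be >= 0")
  if (nrow(m$values) > 0 && any(m$values + pseudocount <= 0))
    stop("log of non-positive value; increase the pseudocount")
  expression_matrix(log(m$values + pseudocount), "log")
}
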