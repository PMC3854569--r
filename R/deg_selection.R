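#' Define a two-group comparison
#'
#' @param name Label, e.g. `"12h_vs_mock"`.
#' @param group_a,group_b Disjoint, nonempty character vectors of condition
#'   identifiers (e.g. inoculated vs mock-inoculated replicates).
#' @return A `comparison` object.
#' @export
comparison <- function(name, group_a, group_b) {
  if (!length(group_a) || !length(group_b))
    stop("comparison groups must be nonempty")
  if (length(intersect(group_a, group_b)))
    stop("comparison groups must be disjoint")
  structure(list(name = name, group_a = as.character(group_a),
                 group_b = as.character(group_b)),
            class = "comparison")
}

#' Per-gene differential-expression p-values (pooled binomial test)
#'
#' A replicate-free stand-in for a dedicated count-based DE package: for each
#' gene the counts are pooled within each group and a two-sided exact
#' binomial test compares the group-A share of the gene's reads against the
#' share expected from the group library sizes. Genes with zero total count
#' get p = 1. Results from edgeR/DEGseq-style tools can be substituted via
#' [import_deg_table()].
#'
#' @param counts An `expr_matrix` with `scale_tag = "counts"`.
#' @param comp A [comparison()].
#' @return data.frame with columns `gene_id`, `p_value`.
#' @export
de_test <- function(counts, comp) {
  stopifnot(inherits(counts, "expr_matrix"), inherits(comp, "comparison"))
  if (counts$scale_tag != "counts")
    stop("de_test expects raw counts")
  miss <- setdiff(c(comp$group_a, comp$group_b), condition_ids(counts))
  if (length(miss))
    stop("comparison conditions absent from matrix: ", paste(miss, collapse = ", "))
  a <- round(rowSums(counts$values[, comp$group_a, drop = FALSE]))
  b <- round(rowSums(counts$values[, comp$group_b, drop = FALSE]))
  lib_a <- sum(counts$values[, comp$group_a, drop = FALSE])
  lib_b <- sum(counts$values[, comp$group_b, drop = FALSE])
  prob <- lib_a / (lib_a + lib_b)
  p <- vapply(seq_along(a), function(i) {
    n <- a[i] + b[i]
    if (n == 0) return(1)
    stats::binom.test(a[i], n, p = prob, alternative = "two.sided")$p.value
  }, numeric(1))
  data.frame(gene_id = gene_ids(counts), p_value = pmin(p, 1),
             stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg adjustment of p-values
#'
#' @param p Numeric vector of raw p-values in \[0, 1\].
#' @return Step-up adjusted p-values (monotone in rank, capped at 1).
#' @export
adjust_pvalues <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Assemble a differential-expression result
#'
#' @param name Comparison label.
#' @param gene_id Character vector of gene ids.
#' @param p_raw Raw p-values.
#' @param p_adj Adjusted p-values (default: BH adjustment of `p_raw`).
#' @param threshold Inclusive adjusted-p cutoff for selection; default 0.05.
#' @return A `deg_result`: list with `name`, `table` (gene_id, p_raw, p_adj),
#'   `threshold`, and `selected` (gene ids with `p_adj <= threshold`).
#' @export
deg_result <- function(name, gene_id, p_raw, p_adj = adjust_pvalues(p_raw),
                       threshold = 0.05) {
  stopifnot(length(gene_id) == length(p_raw), length(p_raw) == length(p_adj))
  tab <- data.frame(gene_id = as.character(gene_id), p_raw = p_raw,
                    p_adj = p_adj, stringsAsFactors = FALSE)
  structure(list(name = name, table = tab, threshold = threshold,
                 selected = tab$gene_id[tab$p_adj <= threshold]),
            class = "deg_result")
}

#' Re-apply a selection threshold to a DEG result
#' @param res A `deg_result`.
#' @param threshold New inclusive adjusted-p cutoff.
#' @return A `deg_result` with the new threshold applied.
#' @export
apply_threshold <- function(res, threshold) {
  deg_result(res$name, res$table$gene_id, res$table$p_raw, res$table$p_adj,
             threshold)
}

#' Run differential-expression selection for several comparisons
#'
#' @param counts An `expr_matrix` of raw counts.
#' @param comparisons List of [comparison()] objects.
#' @param threshold Inclusive adjusted-p cutoff (default 0.05).
#' @return Named list of `deg_result`, one per comparison.
#' @export
run_deg <- function(counts, comparisons, threshold = 0.05) {
  res <- lapply(comparisons, function(cmp) {
    tab <- de_test(counts, cmp)
    deg_result(cmp$name, tab$gene_id, tab$p_value, threshold = threshold)
  })
  stats::setNames(res, vapply(comparisons, `[[`, "", "name"))
}

#' Combine selected DEG sets across comparisons
#'
#' @param results List of `deg_result` objects (at least one).
#' @param mode `"per_group"` (list of each comparison's set), `"overlap"`
#'   (intersection across all comparisons) or `"union"`.
#' @return Character vector of gene ids, or a named list for `"per_group"`.
#' @export
select_degs <- function(results, mode = c("overlap", "union", "per_group")) {
  mode <- match.arg(mode)
  if (!length(results)) stop("need at least one deg_result")
  sets <- lapply(results, `[[`, "selected")
  switch(mode,
         per_group = sets,
         overlap = Reduce(intersect, sets),
         union = sort(unique(unlist(sets))))
}

#' Import an externally computed DEG table
#'
#' Lets users substitute adjusted p-values from a dedicated DE package
#' (e.g. an edgeR or DEGseq run) for the built-in pooled binomial test. The
#' file has two tab-delimited columns: gene id and adjusted p-value.
#'
#' @param path Path to the two-column file. A header line is detected from a
#'   non-numeric second field.
#' @param name Comparison label for the result.
#' @param threshold Inclusive adjusted-p cutoff; default 0.05.
#' @return A `deg_result` with `p_raw = p_adj =` the imported values.
#' @export
import_deg_table <- function(path, name = basename(path), threshold = 0.05) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  start <- 1L
  if (length(lines)) {
    f1 <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
    if (length(f1) >= 2 && is.na(suppressWarnings(as.numeric(f1[2]))))
      start <- 2L
  }
  ids <- character(0); ps <- numeric(0)
  for (i in seq_along(lines)) {
    if (i < start) next
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    p <- suppressWarnings(as.numeric(f[2]))
    if (length(f) < 2 || is.na(p) || p < 0 || p > 1)
      stop(sprintf("malformed DEG table row at line %d of %s", i, path))
    ids <- c(ids, f[1]); ps <- c(ps, p)
  }
  deg_result(name, ids, ps, p_adj = ps, threshold = threshold)
}
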