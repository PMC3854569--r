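# Serialization of fitted networks: JSON for the full object, DOT for
# individual trees, TSV for heatmap-ready module expression blocks.

tree_to_list <- function(tree) {
  if (tree$type == "leaf")
    return(list(type = "leaf", conditions = as.list(tree$conditions),
                mu = tree$mu, sigma = tree$sigma))
  list(type = "split", tf_id = tree$tf_id, query_state = tree$query_state,
       yes = tree_to_list(tree$yes), no = tree_to_list(tree$no))
}

#' Serialize a module network to JSON
#'
#' Writes modules, their gene memberships, regulatory trees (nested nodes
#' with leaf Gaussian parameters and condition partitions), the likelihood
#' trace and the fitting parameters. Deterministic: identical networks give
#' byte-identical files.
#'
#' @param net A `module_network`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_network_json <- function(net, path) {
  obj <- list(
    n_modules = length(net$modules),
    iterations_run = net$iterations_run,
    converged = net$converged,
    ll_trace = net$ll_trace,
    params = net$params[setdiff(names(net$params), "tf_ids")],
    candidate_tfs = net$params$tf_ids,
    modules = lapply(seq_along(net$modules), function(k)
      list(index = k,
           genes = net$modules[[k]]$genes,
           regulators = tree_regulators(net$modules[[k]]$tree),
           tree = tree_to_list(net$modules[[k]]$tree))))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Render a regulatory tree in Graphviz DOT format
#'
#' Internal nodes are labeled with the TF and the queried state
#' (highly/lowly expressed?); edges carry yes/no; leaves list their
#' conditions with the fitted Gaussian parameters.
#'
#' @param tree A `reg_tree`.
#' @param path Output path; `NULL` returns the DOT text.
#' @param name Graph name.
#' @return The DOT text, invisibly when written to a file.
#' @export
tree_to_dot <- function(tree, path = NULL, name = "regulatory_tree") {
  counter <- new.env(); counter$i <- 0L
  lines <- character(0)
  emit <- function(node) {
    counter$i <- counter$i + 1L
    id <- sprintf("n%d", counter$i)
    if (node$type == "leaf") {
      lab <- sprintf("%s\\nmu=%.3f sigma=%.3f",
                     paste(node$conditions, collapse = ","), node$mu, node$sigma)
      lines <<- c(lines, sprintf('  %s [shape=box, label="%s"];', id, lab))
    } else {
      lab <- sprintf("%s %s?", node$tf_id, node$query_state)
      lines <<- c(lines, sprintf('  %s [shape=ellipse, label="%s"];', id, lab))
      yid <- emit(node$yes); nid <- emit(node$no)
      lines <<- c(lines, sprintf('  %s -> %s [label="yes"];', id, yid),
                  sprintf('  %s -> %s [label="no"];', id, nid))
    }
    id
  }
  emit(tree)
  txt <- paste(c(sprintf("digraph %s {", name), lines, "}"), collapse = "\n")
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' Export a module's expression block for heatmap plotting
#'
#' Writes the module genes x conditions log-expression values as TSV, with
#' conditions ordered by the tree's leaf partition (leaves left to right) so
#' the blocks of the heatmap align with the tree structure.
#'
#' @param net A `module_network`.
#' @param m The `expr_matrix` the network was fitted on.
#' @param module Module index.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_module_heatmap_tsv <- function(net, m, module, path) {
  mod <- net$modules[[module]]
  conds <- unlist(lapply(tree_leaves(mod$tree), `[[`, "conditions"))
  df <- data.frame(gene_id = mod$genes,
                   m$values[mod$genes, conds, drop = FALSE],
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
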