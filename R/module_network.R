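#' Discretize one expression profile into activity states
#'
#' Maps a (log-scale) expression profile over all conditions to the three
#' activity levels of its gene: +1 (highly expressed), 0 (normal),
#' -1 (lowly expressed), by z-scoring against the profile's own mean and
#' standard deviation. Constant profiles get all-zero states.
#'
#' @param x Numeric vector of log expression values over conditions.
#' @param z_hi z-score at or above which the state is +1 (default +1).
#' @param z_lo z-score at or below which the state is -1 (default -1).
#' @return Integer vector over \{-1, 0, 1\}, same names as `x`.
#' @export
discretize_tf <- function(x, z_hi = 1, z_lo = -1) {
  s <- stats::sd(x)
  out <- rep(0L, length(x))
  if (is.finite(s) && s > 0) {
    z <- (x - mean(x)) / s
    out[z >= z_hi] <- 1L
    out[z <= z_lo] <- -1L
  }
  names(out) <- names(x)
  out
}

#' Discretize the profiles of a set of transcription factors
#'
#' @param m An `expr_matrix` (`scale_tag = "log"`) containing the TF rows.
#' @param tf_ids Character vector of TF gene ids (rows of `m`).
#' @param z_hi,z_lo Discretization thresholds, see [discretize_tf()].
#' @return A `tf_states` object: integer matrix over \{-1,0,1\}, rows = TFs,
#'   columns = conditions.
#' @export
discretize_states <- function(m, tf_ids, z_hi = 1, z_lo = -1) {
  stopifnot(inherits(m, "expr_matrix"))
  miss <- setdiff(tf_ids, gene_ids(m))
  if (length(miss))
    stop("TF rows absent from matrix: ", paste(utils::head(miss, 5), collapse = ", "))
  states <- t(vapply(tf_ids,
                     function(tf) discretize_tf(m$values[tf, ], z_hi, z_lo),
                     integer(ncol(m$values))))
  dimnames(states) <- list(tf_ids, condition_ids(m))
  structure(states, class = c("tf_states", "matrix"))
}

#' Log density of the Gaussian leaf model
#'
#' `ln[(1 / (sqrt(2*pi) * sigma)) * exp(-(x - mu)^2 / (2 sigma^2))]`, with
#' `sigma` clamped below at `sigma_floor` to keep the likelihood finite on
#' degenerate leaves.
#'
#' @param x Expression value(s), log scale.
#' @param mu Leaf mean.
#' @param sigma Leaf standard deviation.
#' @param sigma_floor Lower clamp for `sigma` (default 0.01 log-units).
#' @return Log density, vectorized over `x`.
#' @export
gaussian_log_density <- function(x, mu, sigma, sigma_floor = 0.01) {
  stats::dnorm(x, mean = mu, sd = pmax(sigma, sigma_floor), log = TRUE)
}

#' Fit a Gaussian leaf to pooled expression values
#'
#' `mu` is the mean and `sigma` the population standard deviation
#' (denominator n) of the pooled values of all module genes in the leaf's
#' conditions, floored at `sigma_floor`.
#'
#' @param values Numeric vector (nonempty).
#' @param sigma_floor Lower clamp for `sigma`.
#' @return List with `mu`, `sigma`.
#' @export
fit_leaf <- function(values, sigma_floor = 0.01) {
  if (!length(values)) stop("cannot fit a leaf to an empty value pool")
  mu <- mean(values)
  sigma <- sqrt(mean((values - mu)^2))
  list(mu = mu, sigma = max(sigma, sigma_floor))
}

# Log likelihood of a value pool under its own fitted leaf.
leaf_log_likelihood <- function(values, sigma_floor = 0.01) {
  f <- fit_leaf(values, sigma_floor)
  sum(gaussian_log_density(values, f$mu, f$sigma, sigma_floor))
}

#' Log likelihood of splitting a condition set in two
#'
#' Fits one Gaussian leaf per condition subset from the pooled values of the
#' module genes and sums the log densities of every gene expression value in
#' both subsets. This is the (log) likelihood the tree search maximizes when
#' choosing a TF query.
#'
#' @param x Numeric matrix: module genes x conditions (log scale).
#' @param cond_yes,cond_no Disjoint condition-id vectors covering `colnames(x)`.
#' @param sigma_floor Leaf sigma clamp.
#' @return Total log likelihood of the two-leaf model.
#' @export
split_log_likelihood <- function(x, cond_yes, cond_no, sigma_floor = 0.01) {
  stopifnot(length(cond_yes) > 0, length(cond_no) > 0)
  leaf_log_likelihood(as.vector(x[, cond_yes, drop = FALSE]), sigma_floor) +
    leaf_log_likelihood(as.vector(x[, cond_no, drop = FALSE]), sigma_floor)
}

#' Best transcription-factor split of a condition set
#'
#' Evaluates every candidate query (TF, high) and (TF, low) — "is this TF
#' highly (resp. lowly) expressed in the condition?" — and returns the
#' feasible query maximizing [split_log_likelihood()], provided it improves
#' on the unsplit single-leaf likelihood by more than `epsilon_gain`.
#' Exact likelihood ties are broken toward the lexicographically smallest
#' `(tf_id, query_state)` with `"high" < "low"`.
#'
#' @param x Module genes x conditions matrix (log scale).
#' @param conds Condition ids under consideration (columns of `x`).
#' @param states A `tf_states` matrix covering `conds`.
#' @param candidate_tfs TF ids allowed as regulators at this node.
#' @param min_leaf_conditions Minimum conditions on each side (default 2).
#' @param epsilon_gain Minimum log-likelihood gain to accept a split.
#' @param sigma_floor Leaf sigma clamp.
#' @return List `(tf_id, query_state, cond_yes, cond_no, log_lik, gain)`,
#'   or `NULL` when no feasible query improves on the unsplit leaf.
#' @export
best_split <- function(x, conds, states, candidate_tfs,
                       min_leaf_conditions = 2, epsilon_gain = 1e-6,
                       sigma_floor = 0.01) {
  if (!length(candidate_tfs)) return(NULL)
  base_ll <- leaf_log_likelihood(as.vector(x[, conds, drop = FALSE]), sigma_floor)
  best <- NULL
  for (tf in sort(candidate_tfs)) {
    st <- states[tf, conds]
    for (qs in c("high", "low")) {
      yes <- conds[st == (if (qs == "high") 1L else -1L)]
      no <- setdiff(conds, yes)
      if (length(yes) < min_leaf_conditions || length(no) < min_leaf_conditions)
        next
      ll <- split_log_likelihood(x[, conds, drop = FALSE], yes, no, sigma_floor)
      if (is.null(best) || ll > best$log_lik) # strict: first lexicographic wins ties
        best <- list(tf_id = tf, query_state = qs, cond_yes = yes,
                     cond_no = no, log_lik = ll, gain = ll - base_ll)
    }
  }
  if (is.null(best) || best$gain <= epsilon_gain) return(NULL)
  best
}

#' Build a regulatory decision tree for a module
#'
#' Greedy recursive construction: at each node the best TF query (by
#' [best_split()]) divides the conditions; each side is split further with
#' the remaining TFs until the depth limit, the minimum leaf size, or a
#' non-improving split stops the recursion. No TF is queried twice on one
#' root-to-leaf path. Leaves carry the Gaussian fitted to the pooled values
#' of the module's genes in the leaf's conditions.
#'
#' @param x Module genes x conditions matrix (log scale), or an
#'   `expr_matrix` restricted to the module.
#' @param states A `tf_states` matrix.
#' @param candidate_tfs TF ids allowed as regulators.
#' @param conds Conditions to cover (default: all columns of `x`).
#' @param max_depth Maximum number of queries on a path (default 3).
#' @param min_leaf_conditions Minimum conditions per leaf (default 2).
#' @param epsilon_gain Minimum gain to accept a split (default 1e-6).
#' @param sigma_floor Leaf sigma clamp (default 0.01).
#' @return A `reg_tree`: nested list; internal nodes
#'   `list(type = "split", tf_id, query_state, yes, no)`, leaves
#'   `list(type = "leaf", conditions, mu, sigma)`. Leaf condition sets
#'   partition `conds`.
#' @export
build_tree <- function(x, states, candidate_tfs, conds = NULL,
                       max_depth = 3, min_leaf_conditions = 2,
                       epsilon_gain = 1e-6, sigma_floor = 0.01) {
  if (inherits(x, "expr_matrix")) x <- x$values
  if (is.null(conds)) conds <- colnames(x)
  if (!nrow(x)) stop("cannot build a tree for an empty module")
  node <- function(conds, avail, depth) {
    sp <- if (depth < max_depth)
      best_split(x, conds, states, avail, min_leaf_conditions,
                 epsilon_gain, sigma_floor)
    else NULL
    if (is.null(sp)) {
      f <- fit_leaf(as.vector(x[, conds, drop = FALSE]), sigma_floor)
      return(list(type = "leaf", conditions = conds, mu = f$mu, sigma = f$sigma))
    }
    rest <- setdiff(avail, sp$tf_id)
    list(type = "split", tf_id = sp$tf_id, query_state = sp$query_state,
         yes = node(sp$cond_yes, rest, depth + 1L),
         no = node(sp$cond_no, rest, depth + 1L))
  }
  structure(node(conds, sort(unique(candidate_tfs)), 0L), class = "reg_tree")
}

#' Leaves of a regulatory tree
#' @param tree A `reg_tree`.
#' @return List of leaf nodes in yes-first depth-first order.
#' @export
tree_leaves <- function(tree) {
  if (tree$type == "leaf") return(list(tree))
  c(tree_leaves(tree$yes), tree_leaves(tree$no))
}

#' TFs queried anywhere in a tree
#' @param tree A `reg_tree`.
#' @return Character vector of TF ids (unique, in DFS order).
#' @export
tree_regulators <- function(tree) {
  if (tree$type == "leaf") return(character(0))
  unique(c(tree$tf_id, tree_regulators(tree$yes), tree_regulators(tree$no)))
}

#' Depth of a regulatory tree (0 = single leaf)
#' @param tree A `reg_tree`.
#' @return Integer depth.
#' @export
tree_depth <- function(tree) {
  if (tree$type == "leaf") return(0L)
  1L + max(tree_depth(tree$yes), tree_depth(tree$no))
}

# Per-condition leaf parameters: list(mu, sigma), each a vector named by
# condition, covering every condition the tree partitions.
tree_leaf_params <- function(tree) {
  leaves <- tree_leaves(tree)
  conds <- unlist(lapply(leaves, `[[`, "conditions"))
  mu <- unlist(lapply(leaves, function(l) rep(l$mu, length(l$conditions))))
  sigma <- unlist(lapply(leaves, function(l) rep(l$sigma, length(l$conditions))))
  list(mu = stats::setNames(mu, conds), sigma = stats::setNames(sigma, conds))
}

# Refit leaf Gaussians of a tree, keeping its topology and condition
# partition, from a (possibly different) gene value matrix.
refit_tree <- function(tree, x, sigma_floor = 0.01) {
  if (tree$type == "leaf") {
    f <- fit_leaf(as.vector(x[, tree$conditions, drop = FALSE]), sigma_floor)
    tree$mu <- f$mu; tree$sigma <- f$sigma
    return(tree)
  }
  tree$yes <- refit_tree(tree$yes, x, sigma_floor)
  tree$no <- refit_tree(tree$no, x, sigma_floor)
  tree
}

# Canonical topology signature: the nested yes/no condition partition,
# optionally with the (tf, state) queries. Distinct queries can induce the
# same condition split and are then likelihood-equivalent (the data cannot
# tell them apart), so structural comparisons default to the partition.
tree_signature <- function(tree, include_queries = FALSE) {
  if (tree$type == "leaf")
    return(paste0("{", paste(sort(tree$conditions), collapse = ","), "}"))
  if (include_queries)
    return(paste0("(", tree$tf_id, ":", tree$query_state,
                  " Y", tree_signature(tree$yes, TRUE),
                  " N", tree_signature(tree$no, TRUE), ")"))
  kids <- sort(c(tree_signature(tree$yes), tree_signature(tree$no)))
  paste0("(", kids[1], " | ", kids[2], ")")
}

#' Log likelihood of one gene's profile under a regulatory tree
#'
#' Sum over conditions of the Gaussian log density of the gene's value under
#' the leaf containing that condition (the log of the product of the
#' per-condition probabilities).
#'
#' @param gene_row Named numeric vector of log expression over conditions.
#' @param tree A `reg_tree` whose leaves cover those conditions.
#' @param sigma_floor Leaf sigma clamp.
#' @return Scalar log likelihood.
#' @export
gene_log_likelihood <- function(gene_row, tree, sigma_floor = 0.01) {
  p <- tree_leaf_params(tree)
  conds <- names(p$mu)
  sum(gaussian_log_density(gene_row[conds], p$mu, p$sigma, sigma_floor))
}

# Log likelihood of a whole gene matrix under a tree (pooled leaf model).
matrix_log_likelihood <- function(x, tree, sigma_floor = 0.01) {
  p <- tree_leaf_params(tree)
  conds <- names(p$mu)
  sum(gaussian_log_density(
    x[, conds, drop = FALSE],
    matrix(p$mu, nrow(x), length(conds), byrow = TRUE),
    matrix(p$sigma, nrow(x), length(conds), byrow = TRUE),
    sigma_floor))
}

#' Reassign genes to the trees that explain them best
#'
#' Each gene moves to the module whose regulatory tree gives its profile the
#' highest log likelihood; exact ties go to the lowest module index. Modules
#' left empty are dropped (with their trees) and the remaining modules are
#' reindexed.
#'
#' @param trees List of `reg_tree`, one per module.
#' @param m An `expr_matrix` (log scale) of the genes to assign.
#' @param sigma_floor Leaf sigma clamp.
#' @return List with `assignment` (named integer vector into the *kept*
#'   modules), `kept` (original indices of nonempty modules), and `ll`
#'   (genes x modules log-likelihood matrix, original module order).
#' @export
reassign_genes <- function(trees, m, sigma_floor = 0.01) {
  stopifnot(length(trees) >= 1)
  x <- m$values
  ll <- matrix(NA_real_, nrow(x), length(trees),
               dimnames = list(gene_ids(m), NULL))
  for (k in seq_along(trees)) {
    p <- tree_leaf_params(trees[[k]])
    conds <- names(p$mu)
    ll[, k] <- rowSums(gaussian_log_density(
      x[, conds, drop = FALSE],
      matrix(p$mu, nrow(x), length(conds), byrow = TRUE),
      matrix(p$sigma, nrow(x), length(conds), byrow = TRUE),
      sigma_floor))
  }
  raw <- max.col(ll, ties.method = "first")
  kept <- sort(unique(raw))
  remap <- stats::setNames(seq_along(kept), kept)
  list(assignment = stats::setNames(as.integer(remap[as.character(raw)]),
                                    gene_ids(m)),
       kept = kept, ll = ll)
}

#' Fit a gene regulatory module network
#'
#' The full inference procedure: discretize the candidate TFs' states,
#' initialize the gene partition with K-means, then alternate (1) greedy
#' regulatory-tree construction per module and (2) reassignment of every
#' gene to the tree maximizing its likelihood, until the assignment reaches
#' a fixed point (or `max_iter`). When refitting a module's tree, the
#' previous tree (leaf parameters refit to the current members) is retained
#' if the greedy search cannot match its likelihood, so the total data log
#' likelihood never decreases across iterations.
#'
#' @param m An `expr_matrix`, `scale_tag = "log"`, containing all genes to
#'   be modeled (TF rows included if they are to be modeled as targets too).
#' @param tf_ids Candidate regulator TFs; must be rows of the state source
#'   matrix (`states_from` or `m`).
#' @param K Number of initial clusters.
#' @param seed Integer seed (K-means initialization).
#' @param max_iter Iteration cap (default 50).
#' @param z_hi,z_lo Discretization thresholds.
#' @param max_depth,min_leaf_conditions,epsilon_gain,sigma_floor Tree
#'   parameters, see [build_tree()].
#' @param exclude_module_tfs When `TRUE` (default), a TF currently assigned
#'   to a module as a target is not allowed to regulate that same module's
#'   tree.
#' @param states_from Optional `expr_matrix` to take TF profiles from when
#'   the TFs are not rows of `m` (e.g. TF states from the full matrix while
#'   modeling DEGs only). Default: `m`.
#' @param nstart K-means restarts.
#' @return A `module_network`: list with `modules` (each
#'   `list(genes, tree)`), `assignment` (named integer vector), `states`,
#'   `iterations_run`, `converged`, `ll_trace` (total log likelihood after
#'   each reassignment; non-decreasing), and `params`.
#' @export
fit_module_network <- function(m, tf_ids, K, seed = 1L, max_iter = 50L,
                               z_hi = 1, z_lo = -1, max_depth = 3,
                               min_leaf_conditions = 2, epsilon_gain = 1e-6,
                               sigma_floor = 0.01,
                               exclude_module_tfs = TRUE,
                               states_from = NULL, nstart = 10L) {
  stopifnot(inherits(m, "expr_matrix"))
  if (m$scale_tag != "log")
    stop("fit_module_network expects log-scale values")
  src <- if (is.null(states_from)) m else states_from
  states <- discretize_states(src, tf_ids, z_hi, z_lo)
  init <- kmeans_cluster(m, K, seed = seed, nstart = nstart)
  assignment <- init$assignment
  x <- m$values
  trees <- vector("list", max(assignment))
  ll_trace <- numeric(0)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    new_trees <- vector("list", max(assignment))
    for (k in seq_len(max(assignment))) {
      members <- names(assignment)[assignment == k]
      xk <- x[members, , drop = FALSE]
      cands <- tf_ids
      if (exclude_module_tfs) cands <- setdiff(cands, members)
      tr <- build_tree(xk, states, cands, max_depth = max_depth,
                       min_leaf_conditions = min_leaf_conditions,
                       epsilon_gain = epsilon_gain, sigma_floor = sigma_floor)
      # keep the previous tree if (still valid here and) better: guarantees
      # a non-decreasing likelihood trace under greedy search
      prev <- if (k <= length(trees)) trees[[k]] else NULL
      if (!is.null(prev) && !any(tree_regulators(prev) %in%
                                 setdiff(tf_ids, cands))) {
        prev <- refit_tree(prev, xk, sigma_floor)
        if (matrix_log_likelihood(xk, prev, sigma_floor) >
            matrix_log_likelihood(xk, tr, sigma_floor))
          tr <- prev
      }
      new_trees[[k]] <- tr
    }
    re <- reassign_genes(new_trees, m, sigma_floor)
    ll_trace <- c(ll_trace, sum(apply(re$ll, 1, max)))
    new_assignment <- re$assignment
    trees <- new_trees[re$kept]
    same <- identical(
      unname(relabel_partition(new_assignment[names(assignment)])),
      unname(relabel_partition(assignment)))
    if (same) { # partition unchanged: fixed point
      assignment <- new_assignment
      converged <- TRUE
      break
    }
    assignment <- new_assignment
  }
  modules <- lapply(seq_along(trees), function(k)
    list(genes = names(assignment)[assignment == k], tree = trees[[k]]))
  if (length(modules) == 1)
    warning("all genes collapsed into a single module")
  structure(list(modules = modules, assignment = assignment, states = states,
                 iterations_run = iter, converged = converged,
                 ll_trace = ll_trace,
                 params = list(K = K, seed = seed, z_hi = z_hi, z_lo = z_lo,
                               max_depth = max_depth,
                               min_leaf_conditions = min_leaf_conditions,
                               epsilon_gain = epsilon_gain,
                               sigma_floor = sigma_floor,
                               exclude_module_tfs = exclude_module_tfs,
                               tf_ids = tf_ids)),
            class = "module_network")
}

# Canonical relabeling of a partition: clusters numbered by first appearance.
relabel_partition <- function(assignment) {
  labs <- unique(assignment)
  stats::setNames(match(assignment, labs), names(assignment))
}

#' @export
print.module_network <- function(x, ...) {
  cat(sprintf("module_network: %d modules over %d genes (%d iterations%s)\n",
              length(x$modules), length(x$assignment), x$iterations_run,
              if (x$converged) ", converged" else ""))
  for (k in seq_along(x$modules))
    cat(sprintf("  module %d: %d genes, tree depth %d, regulators: %s\n",
                k, length(x$modules[[k]]$genes), tree_depth(x$modules[[k]]$tree),
                paste(tree_regulators(x$modules[[k]]$tree), collapse = ", ")))
  invisible(x)
}
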