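# Synthetic module-structured expression data with planted ground truth.
# The generator emulates the structure the inference model assumes: each
# module's genes are driven by a small regulatory tree over discretized TF
# states, with Gaussian noise around leaf means; background genes carry no
# tree structure; decoy (non-DE) TFs exist for stability experiments.

# Sample a TF state vector and a consistent expression profile: states are
# drawn first, a profile is built around them (state * 2 + small noise) and
# accepted only if discretization recovers the states exactly.
sample_tf_profile <- function(n_conditions, z_hi, z_lo, p_active = 0.3,
                              max_tries = 200) {
  for (i in seq_len(max_tries)) {
    st <- sample(c(-1L, 0L, 1L), n_conditions, replace = TRUE,
                 prob = c(p_active, 1 - 2 * p_active, p_active))
    expr <- 2 * st + stats::rnorm(n_conditions, 0, 0.15)
    if (identical(unname(discretize_tf(expr, z_hi, z_lo)), st))
      return(list(states = st, expr = expr))
  }
  stop("could not sample a self-consistent TF profile")
}

# Build a planted tree of the requested depth over `conds`, querying
# tf_pool[level] at each level. Requires each side of a level-l split to
# keep at least min_leaf * 2^(depth - l) conditions so the full subtree
# fits. Returns NULL if infeasible with these states.
plant_tree <- function(conds, tf_pool, states, depth, min_leaf) {
  if (depth == 0 || !length(tf_pool))
    return(list(type = "leaf", conditions = conds, mu = NA_real_,
                sigma = NA_real_))
  tf <- tf_pool[1]
  need <- min_leaf * 2^(depth - 1)
  for (qs in sample(c("high", "low"))) {
    yes <- conds[states[tf, conds] == (if (qs == "high") 1L else -1L)]
    no <- setdiff(conds, yes)
    if (length(yes) < need || length(no) < need) next
    yes_t <- plant_tree(yes, tf_pool[-1], states, depth - 1, min_leaf)
    no_t <- plant_tree(no, tf_pool[-1], states, depth - 1, min_leaf)
    if (is.null(yes_t) || is.null(no_t)) next
    return(list(type = "split", tf_id = tf, query_state = qs,
                yes = yes_t, no = no_t))
  }
  NULL
}

# Assign hierarchical leaf means: the level-l branch contributes
# +/- separation * 2^(depth-l) / 2, so sibling leaves differ by the
# separation and the root split dominates. Minimum pairwise gap equals
# `separation`.
set_leaf_means <- function(tree, separation, sigma, depth, level = 1,
                           base = 0) {
  if (tree$type == "leaf") {
    tree$mu <- base
    tree$sigma <- sigma
    return(tree)
  }
  step <- separation * 2^(depth - level) / 2
  tree$yes <- set_leaf_means(tree$yes, separation, sigma, depth, level + 1,
                             base + step)
  tree$no <- set_leaf_means(tree$no, separation, sigma, depth, level + 1,
                            base - step)
  tree
}

#' Generate a synthetic dataset with a planted module network
#'
#' Draws self-consistent TF state/expression profiles, builds one random
#' regulatory tree per module from disjoint TF subsets, gives each leaf a
#' mean (hierarchically spaced, pairwise separation >= `leaf_mean_separation`)
#' and samples each module gene's expression from the leaf Gaussians with
#' standard deviation `leaf_sigma`. Background genes are diffuse: Gaussian
#' noise at three times the module noise level (at least 1 log-unit) around
#' a random module's mean profile, emulating the bulk of weakly co-varying
#' transcripts that follow no regulatory program tightly. Decoy TFs
#' (profiles drawn the same way but regulating nothing) model
#' non-differentially-expressed TFs for stability experiments. TF rows are part of the expression matrix, so
#' they are themselves clustered as target genes during fitting.
#'
#' @param n_modules Number of planted modules (default 5).
#' @param genes_per_module Genes per module (default 30).
#' @param n_background_genes Unstructured genes (default 30).
#' @param n_conditions Conditions (default 20); must satisfy
#'   `n_conditions >= 2^depth * min_leaf_conditions`.
#' @param n_tfs Regulator TFs; default `n_modules * depth` (disjoint per
#'   module); must be at least that.
#' @param n_decoy_tfs Non-regulating TFs (default 10).
#' @param leaf_mean_separation Minimum gap between leaf means, log units
#'   (default 4).
#' @param leaf_sigma Within-leaf standard deviation (default 0.5).
#' @param depth Planted tree depth (default 2).
#' @param min_leaf_conditions Minimum conditions per planted leaf
#'   (default 2).
#' @param z_hi,z_lo Discretization thresholds (defaults +1/-1).
#' @param seed Integer seed; regeneration with the same parameters is
#'   bit-identical.
#' @return A `synthetic_dataset`: list with `matrix` (`expr_matrix`, log
#'   scale), `truth_assignment` (named integer; 0 for background, TF and
#'   decoy rows), `truth_trees`, `tf_ids`, `decoy_tf_ids`, `tf_states`,
#'   and `params`.
#' @export
generate_planted_network <- function(n_modules = 5, genes_per_module = 30,
                                     n_background_genes = 30,
                                     n_conditions = 20,
                                     n_tfs = n_modules * depth,
                                     n_decoy_tfs = 10,
                                     leaf_mean_separation = 4,
                                     leaf_sigma = 0.5, depth = 2,
                                     min_leaf_conditions = 2,
                                     z_hi = 1, z_lo = -1, seed = 7L) {
  if (n_conditions < 2^depth * min_leaf_conditions)
    stop("infeasible: need n_conditions >= 2^depth * min_leaf_conditions (",
         2^depth * min_leaf_conditions, ")")
  if (n_tfs < n_modules * depth)
    stop("need at least n_modules * depth regulator TFs")
  set.seed(seed)
  conds <- sprintf("C%02d", seq_len(n_conditions))
  tf_ids <- sprintf("TF%02d", seq_len(n_tfs))
  decoy_ids <- if (n_decoy_tfs > 0) sprintf("NTF%02d", seq_len(n_decoy_tfs))
               else character(0)

  all_tfs <- c(tf_ids, decoy_ids)
  states <- matrix(0L, length(all_tfs), n_conditions,
                   dimnames = list(all_tfs, conds))
  tf_expr <- matrix(0, length(all_tfs), n_conditions,
                    dimnames = list(all_tfs, conds))

  trees <- vector("list", n_modules)
  for (mod in seq_len(n_modules)) {
    pool <- tf_ids[((mod - 1) * depth + 1):(mod * depth)]
    tree <- NULL
    for (try in seq_len(200)) {
      for (tf in pool) {
        prof <- sample_tf_profile(n_conditions, z_hi, z_lo)
        states[tf, ] <- prof$states
        tf_expr[tf, ] <- prof$expr
      }
      tree <- plant_tree(conds, pool, states, depth, min_leaf_conditions)
      if (!is.null(tree)) break
    }
    if (is.null(tree))
      stop("infeasible depth/condition combination for module ", mod)
    trees[[mod]] <- structure(
      set_leaf_means(tree, leaf_mean_separation, leaf_sigma, depth),
      class = "reg_tree")
  }
  for (tf in decoy_ids) {
    prof <- sample_tf_profile(n_conditions, z_hi, z_lo)
    states[tf, ] <- prof$states
    tf_expr[tf, ] <- prof$expr
  }

  gene_rows <- list()
  truth <- integer(0)
  for (mod in seq_len(n_modules)) {
    p <- tree_leaf_params(trees[[mod]])
    mu_j <- p$mu[conds]
    for (g in seq_len(genes_per_module)) {
      gid <- sprintf("M%d_G%03d", mod, g)
      gene_rows[[gid]] <- stats::rnorm(n_conditions, mu_j, leaf_sigma)
      truth[gid] <- mod
    }
  }
  # diffuse background genes: Gaussian noise at three times the module
  # noise level around a randomly chosen module's mean profile — the bulk
  # of weakly co-varying transcripts that follow no program tightly; they
  # scatter across modules instead of forming a separable block
  bg_sigma <- max(3 * leaf_sigma, 1)
  for (g in seq_len(n_background_genes)) {
    gid <- sprintf("BG_G%03d", g)
    src <- sample.int(n_modules, 1)
    mu_j <- tree_leaf_params(trees[[src]])$mu[conds]
    gene_rows[[gid]] <- stats::rnorm(n_conditions, mu_j, bg_sigma)
    truth[gid] <- 0L
  }
  for (tf in all_tfs) {
    gene_rows[[tf]] <- tf_expr[tf, ]
    truth[tf] <- 0L
  }
  vals <- do.call(rbind, gene_rows)
  colnames(vals) <- conds
  structure(list(matrix = expression_matrix(vals, "log"),
                 truth_assignment = truth,
                 truth_trees = trees,
                 tf_ids = tf_ids, decoy_tf_ids = decoy_ids,
                 tf_states = structure(states, class = c("tf_states", "matrix")),
                 params = list(n_modules = n_modules,
                               genes_per_module = genes_per_module,
                               n_background_genes = n_background_genes,
                               n_conditions = n_conditions, n_tfs = n_tfs,
                               n_decoy_tfs = n_decoy_tfs,
                               leaf_mean_separation = leaf_mean_separation,
                               leaf_sigma = leaf_sigma, depth = depth,
                               min_leaf_conditions = min_leaf_conditions,
                               z_hi = z_hi, z_lo = z_lo, seed = seed)),
            class = "synthetic_dataset")
}

#' Generate an RNA-Seq-like count matrix from a synthetic dataset
#'
#' Converts the log-scale planted expression into Poisson read counts: each
#' gene/condition rate is proportional to `exp(log expression)`, columns are
#' scaled to the requested library size, and an optional between-group rate
#' shift is planted in a subset of genes (the true DEGs), exercising the
#' differential-expression selection path.
#'
#' @param dataset A `synthetic_dataset`.
#' @param library_size Target total reads per condition (default 1e6).
#' @param seed Integer seed.
#' @param shift_genes Gene ids (or a count, drawn from the module genes) to
#'   receive a rate shift in `group_b`; default none.
#' @param shift_factor Multiplicative rate shift in `group_b` (default 1 =
#'   no differential expression).
#' @param group_a,group_b Condition-id vectors defining the two groups;
#'   default: first half vs second half of the conditions.
#' @return List with `counts` (`expr_matrix`, `scale_tag = "counts"`),
#'   `true_degs` (character vector), `comparison` (a [comparison()]), and
#'   `library_size`.
#' @export
generate_counts <- function(dataset, library_size = 1e6, seed = 1L,
                            shift_genes = character(0), shift_factor = 1,
                            group_a = NULL, group_b = NULL) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  if (library_size <= 0) stop("library_size must be > 0")
  m <- dataset$matrix
  conds <- condition_ids(m)
  if (is.null(group_a)) group_a <- conds[seq_len(floor(length(conds) / 2))]
  if (is.null(group_b)) group_b <- setdiff(conds, group_a)
  set.seed(seed)
  if (is.numeric(shift_genes) && length(shift_genes) == 1) {
    pool <- names(dataset$truth_assignment)[dataset$truth_assignment > 0]
    shift_genes <- sample(pool, shift_genes)
  }
  rate <- exp(m$values)
  if (shift_factor != 1 && length(shift_genes))
    rate[shift_genes, group_b] <- rate[shift_genes, group_b] * shift_factor
  rate <- sweep(rate, 2, colSums(rate), "/") * library_size
  counts <- matrix(stats::rpois(length(rate), lambda = rate),
                   nrow = nrow(rate), dimnames = dimnames(rate))
  true_degs <- if (shift_factor != 1) as.character(shift_genes) else character(0)
  list(counts = expression_matrix(counts, "counts"),
       true_degs = true_degs,
       comparison = comparison("group_a_vs_group_b", group_a, group_b),
       library_size = library_size)
}

#' Compare a fitted network with the planted truth
#'
#' Matches each planted module to the fitted module sharing the most genes,
#' computes the Rand index between the fitted and planted partitions of the
#' planted module genes (background and TF rows carry no truth label and
#' are excluded), and checks whether each planted tree's topology — query
#' structure and leaf condition partition — was recovered exactly by its
#' matched fitted module.
#'
#' @param net A `module_network`.
#' @param dataset The `synthetic_dataset` the matrix came from.
#' @return List with `rand` (Rand index on planted genes),
#'   `topology_recovered` (logical per planted module), and
#'   `all_topologies_recovered`.
#' @export
score_recovery <- function(net, dataset) {
  truth <- dataset$truth_assignment
  planted <- names(truth)[truth > 0]
  r <- rand_index(net$assignment[planted], truth[planted])$R
  topo <- vapply(seq_along(dataset$truth_trees), function(mod) {
    mg <- names(truth)[truth == mod]
    overlap <- vapply(net$modules, function(md)
      length(intersect(md$genes, mg)), integer(1))
    best <- which.max(overlap)
    identical(tree_signature(net$modules[[best]]$tree),
              tree_signature(dataset$truth_trees[[mod]]))
  }, logical(1))
  list(rand = r, topology_recovered = topo,
       all_topologies_recovered = all(topo))
}

#' Write the synthetic dataset's ground truth as JSON
#' @param dataset A `synthetic_dataset`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_truth_json <- function(dataset, path) {
  obj <- list(params = dataset$params,
              truth_assignment = as.list(dataset$truth_assignment),
              tf_ids = dataset$tf_ids,
              decoy_tf_ids = dataset$decoy_tf_ids,
              truth_trees = lapply(dataset$truth_trees, tree_to_list))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
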