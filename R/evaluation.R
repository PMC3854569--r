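#' Per-condition probability score of a module
#'
#' For condition j lying in tree leaf k with parameters (mu_k, sigma_k), the
#' score is `log p_j = sum_i [ -(x_ij - mu_k)^2 / (2 sigma_k^2) - ln sigma_k ]`
#' over the module's genes i — the summed per-gene Gaussian log terms with
#' the constant `-(1/2) ln 2 pi` per term dropped. Higher scores mean the
#' tree explains the genes' expression better.
#'
#' @param module A module: `list(genes, tree)` (an element of a
#'   `module_network$modules`).
#' @param m The `expr_matrix` (log scale) containing the module's genes.
#' @return List with `scores` (data.frame `condition`, `log_p`) and
#'   `mean_log_p` (mean over conditions).
#' @export
module_log_p <- function(module, m) {
  x <- m$values[module$genes, , drop = FALSE]
  p <- tree_leaf_params(module$tree)
  conds <- names(p$mu)
  log_p <- vapply(conds, function(j) {
    sum(-(x[, j] - p$mu[j])^2 / (2 * p$sigma[j]^2) - log(p$sigma[j]))
  }, numeric(1))
  list(scores = data.frame(condition = conds, log_p = unname(log_p),
                           stringsAsFactors = FALSE),
       mean_log_p = mean(log_p))
}

# Mean over modules of each module's mean log p (network-level score).
network_mean_log_p <- function(net, m) {
  mean(vapply(net$modules, function(mod) module_log_p(mod, m)$mean_log_p,
              numeric(1)))
}

#' Random-reassignment null distribution of a module's score
#'
#' Repeatedly draws the same number of genes at random (without replacement)
#' from a gene universe, places them on the module tree's fixed topology and
#' condition partition, refits the leaf Gaussians from the drawn genes, and
#' records the mean per-condition score. This is the "random genes, same
#' topology" null against which fitted modules are judged.
#'
#' @param module A module: `list(genes, tree)`.
#' @param m The `expr_matrix` (log scale); must contain the universe genes.
#' @param universe Gene-id set to draw from (typically all DEGs); must be at
#'   least as large as the module.
#' @param n_reps Number of random draws (default 1000).
#' @param seed Integer seed; the draw sequence is deterministic per seed.
#' @param sigma_floor Leaf sigma clamp used when refitting.
#' @return A `null_distribution`: list with `per_rep` (mean log p of each
#'   draw), `n_reps`, and `summary` (mean, sd, min, max of the draws).
#' @export
random_null <- function(module, m, universe, n_reps = 1000, seed = 1L,
                        sigma_floor = 0.01) {
  universe <- unique(universe)
  if (length(universe) < length(module$genes))
    stop("universe (", length(universe), ") smaller than module (",
         length(module$genes), ")")
  miss <- setdiff(universe, gene_ids(m))
  if (length(miss)) stop("universe genes absent from matrix")
  n_genes <- length(module$genes)
  leaves <- tree_leaves(module$tree)
  set.seed(seed)
  per_rep <- vapply(seq_len(n_reps), function(r) {
    draw <- sample(universe, n_genes)
    x <- m$values[draw, , drop = FALSE]
    lp_total <- 0
    n_cond <- 0L
    for (lf in leaves) {
      vals <- x[, lf$conditions, drop = FALSE]
      f <- fit_leaf(as.vector(vals), sigma_floor)
      lp <- colSums(-(vals - f$mu)^2 / (2 * f$sigma^2) - log(f$sigma))
      lp_total <- lp_total + sum(lp)
      n_cond <- n_cond + length(lf$conditions)
    }
    lp_total / n_cond
  }, numeric(1))
  structure(list(per_rep = per_rep, n_reps = n_reps,
                 summary = c(mean = mean(per_rep), sd = stats::sd(per_rep),
                             min = min(per_rep), max = max(per_rep))),
            class = "null_distribution")
}

#' Write a null distribution as TSV (histogram-ready)
#'
#' One row per random draw plus, when `breaks > 0`, a second block of
#' density-normalized bins (area 1) for histogram overlays.
#'
#' @param null A `null_distribution`.
#' @param path Output path.
#' @param breaks Number of histogram bins (0 = raw draws only).
#' @return Invisibly, `path`.
#' @export
write_null_tsv <- function(null, path, breaks = 0) {
  df <- data.frame(rep = seq_along(null$per_rep), mean_log_p = null$per_rep)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (breaks > 0) {
    h <- graphics::hist(null$per_rep, breaks = breaks, plot = FALSE)
    hb <- data.frame(bin_mid = h$mids, density = h$density)
    utils::write.table(hb, paste0(path, ".bins"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Rand index between two partitions
#'
#' Over all unordered pairs of the shared element set: `a` pairs together in
#' both partitions, `b` pairs apart in both, `c` together in X but apart in
#' Y, `d` apart in X but together in Y; `R = (a + b)/(a + b + c + d)`.
#'
#' @param x,y Named vectors of cluster labels over the same elements
#'   (n >= 2); names identify the elements.
#' @return A `rand_index_report`: list with counts `a`, `b`, `c`, `d` and
#'   the index `R`.
#' @export
rand_index <- function(x, y) {
  if (is.null(names(x)) || is.null(names(y)))
    stop("partitions must be named vectors")
  if (!setequal(names(x), names(y)))
    stop("partitions are over different element sets")
  els <- names(x)
  if (length(els) < 2) stop("need at least 2 elements")
  y <- y[els]
  same_x <- outer(x, x, "==")
  same_y <- outer(y, y, "==")
  ut <- upper.tri(same_x)
  a <- sum(same_x[ut] & same_y[ut])
  b <- sum(!same_x[ut] & !same_y[ut])
  cc <- sum(same_x[ut] & !same_y[ut])
  d <- sum(!same_x[ut] & same_y[ut])
  structure(list(a = a, b = b, c = cc, d = d,
                 R = (a + b) / (a + b + cc + d)),
            class = "rand_index_report")
}

# Module label of every regulator TF used in a network: the lowest-index
# module whose tree queries it. TFs not used map to nothing.
regulator_modules <- function(net) {
  out <- integer(0)
  for (k in seq_along(net$modules)) {
    for (tf in tree_regulators(net$modules[[k]]$tree))
      if (!tf %in% names(out)) out[tf] <- k
  }
  out
}

# Rand indices between two fitted networks: gene-gene co-membership,
# TF-TF co-regulation (over TFs used in both), and the combined TF-target
# relation (genes and shared TFs labeled jointly by module).
compare_networks <- function(net_a, net_b) {
  ga <- net_a$assignment; gb <- net_b$assignment
  common_genes <- intersect(names(ga), names(gb))
  r_gene <- rand_index(ga[common_genes], gb[common_genes])$R
  ra <- regulator_modules(net_a); rb <- regulator_modules(net_b)
  common_tfs <- intersect(names(ra), names(rb))
  r_tf <- if (length(common_tfs) >= 2)
    rand_index(ra[common_tfs], rb[common_tfs])$R else NA_real_
  joint_a <- c(ga[common_genes], stats::setNames(ra[common_tfs] + 0.5,
                                                 paste0("tf:", common_tfs)))
  joint_b <- c(gb[common_genes], stats::setNames(rb[common_tfs] + 0.5,
                                                 paste0("tf:", common_tfs)))
  r_joint <- rand_index(joint_a, joint_b)$R
  c(gene_gene = r_gene, tf_tf = r_tf, tf_target = r_joint)
}

#' Stability of the network under injection of non-DE transcription factors
#'
#' Regulators are normally restricted to differentially expressed TFs; this
#' probes how much the predicted module structure shifts when a growing
#' share of non-differentially-expressed TFs is added to the candidate
#' regulator list. For each fraction, the candidate list is augmented with
#' that share of `non_deg_tfs` (a fixed, seed-determined nested ordering),
#' the network is refit with the same seed, and the resulting TF-TF,
#' TF-target and gene-gene co-membership partitions are compared to the
#' 0%-injection baseline with the Rand index.
#'
#' @param m An `expr_matrix`, log scale.
#' @param deg_tfs Baseline (differentially expressed) candidate TF ids.
#' @param non_deg_tfs Pool of non-DE TF ids to inject.
#' @param fractions Fractions of the pool to inject (values in \[0, 1\]).
#' @param K,seed,... Passed to [fit_module_network()].
#' @return data.frame with one row per fraction: `fraction`, `n_injected`,
#'   `rand_gene_gene`, `rand_tf_tf`, `rand_tf_target`.
#' @export
tf_injection_stability <- function(m, deg_tfs, non_deg_tfs, fractions,
                                   K, seed = 1L, ...) {
  if (any(fractions < 0 | fractions > 1))
    stop("fractions must lie in [0, 1]")
  baseline <- fit_module_network(m, deg_tfs, K, seed = seed, ...)
  set.seed(seed + 1000L)
  pool <- sample(non_deg_tfs) # fixed nested injection order
  rows <- lapply(fractions, function(f) {
    n_add <- round(f * length(non_deg_tfs))
    if (n_add > length(pool)) {
      warning("fraction ", f, " exceeds available non-DE TFs; capped")
      n_add <- length(pool)
    }
    tfs <- c(deg_tfs, pool[seq_len(n_add)])
    net <- fit_module_network(m, tfs, K, seed = seed, ...)
    r <- compare_networks(baseline, net)
    data.frame(fraction = f, n_injected = n_add,
               rand_gene_gene = r[["gene_gene"]],
               rand_tf_tf = r[["tf_tf"]],
               rand_tf_target = r[["tf_target"]])
  })
  do.call(rbind, rows)
}

#' Robustness of modules to the DEG selection threshold
#'
#' Fits one network on the DEGs selected at a stricter adjusted-p cutoff and
#' one at a looser cutoff, then reports, for every stricter-cutoff module,
#' the best-matching looser-cutoff module by Jaccard overlap together with
#' the containment fraction (share of the stricter module inside the match).
#' Near-complete containment indicates the module structure is stable
#' against the threshold choice.
#'
#' @param m An `expr_matrix` (log scale) covering all candidate genes.
#' @param deg_results List of `deg_result` objects (one per comparison);
#'   DEG sets are the overlap (intersection) across comparisons at each
#'   cutoff.
#' @param thresholds Numeric pair `c(strict, loose)` of adjusted-p cutoffs.
#' @param tf_ids Candidate regulator TFs.
#' @param K,seed,... Passed to [fit_module_network()].
#' @return List with `report` (data.frame: one row per stricter module:
#'   `module`, `size`, `best_match`, `jaccard`, `containment`) and the two
#'   fitted networks `net_strict`, `net_loose`.
#' @export
threshold_robustness <- function(m, deg_results, thresholds, tf_ids, K,
                                 seed = 1L, ...) {
  stopifnot(length(thresholds) == 2)
  strict <- min(thresholds); loose <- max(thresholds)
  genes_at <- function(cutoff) {
    sets <- lapply(deg_results, function(r) apply_threshold(r, cutoff)$selected)
    Reduce(intersect, sets)
  }
  g_strict <- intersect(genes_at(strict), gene_ids(m))
  g_loose <- intersect(genes_at(loose), gene_ids(m))
  if (!length(g_strict)) stop("no DEGs at the stricter cutoff ", strict)
  if (!length(g_loose)) stop("no DEGs at the looser cutoff ", loose)
  net_s <- fit_module_network(subset_genes(m, g_strict), tf_ids,
                              min(K, length(g_strict)),
                              seed = seed, states_from = m, ...)
  net_l <- fit_module_network(subset_genes(m, g_loose), tf_ids,
                              min(K, length(g_loose)),
                              seed = seed, states_from = m, ...)
  rows <- lapply(seq_along(net_s$modules), function(k) {
    gs <- net_s$modules[[k]]$genes
    jac <- vapply(net_l$modules, function(ml)
      length(intersect(gs, ml$genes)) / length(union(gs, ml$genes)),
      numeric(1))
    best <- which.max(jac)
    data.frame(module = k, size = length(gs), best_match = best,
               jaccard = jac[best],
               containment = length(intersect(gs, net_l$modules[[best]]$genes)) /
                 length(gs))
  })
  list(report = do.call(rbind, rows), net_strict = net_s, net_loose = net_l)
}
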