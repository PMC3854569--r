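test_that("TF discretization thresholds on the profile's own z-scores", {
  expect_equal(discretize_tf(rep(3, 6)), rep(0L, 6))   # constant -> all normal

  # hand-computed z-scores on a 5-element vector: only x5 exceeds +1 sd
  x <- c(1, 2, 2, 2, 8)
  z <- (x - mean(x)) / sd(x)
  st <- discretize_tf(x)
  expect_equal(which(st == 1L), which(z >= 1))
  expect_equal(which(st == 1L), 5L)
  expect_equal(which(st == -1L), which(z <= -1))

  # negation swaps the +1 and -1 states
  expect_equal(discretize_tf(-x), -st)

  # matrix version carries dimnames and only {-1,0,1}
  m <- make_expr(rbind(x, c(0, 0, 5, 0, 0)), "log", genes = c("t1", "t2"))
  states <- discretize_states(m, c("t1", "t2"))
  expect_identical(rownames(states), c("t1", "t2"))
  expect_true(all(states %in% c(-1L, 0L, 1L)))
  expect_error(discretize_states(m, "t3"), "absent")
})

test_that("Gaussian leaf log density matches its closed forms", {
  expect_equal(gaussian_log_density(0, 0, 1), log(1 / sqrt(2 * pi)))
  expect_equal(gaussian_log_density(0, 0, 1), -0.9189385, tolerance = 1e-6)
  expect_equal(gaussian_log_density(1, 0, 1), -0.9189385 - 0.5,
               tolerance = 1e-6)
  # doubling sigma at the mean lowers the density by ln 2
  expect_equal(gaussian_log_density(0, 0, 1) - gaussian_log_density(0, 0, 2),
               log(2))
  # sigma below the floor is clamped
  expect_equal(gaussian_log_density(0, 0, 1e-9, sigma_floor = 0.01),
               gaussian_log_density(0, 0, 0.01))
})

test_that("leaf fitting uses the population sd with a floor", {
  f <- fit_leaf(c(1, 1, 1))
  expect_equal(f$mu, 1)
  expect_equal(f$sigma, 0.01)              # degenerate variance -> floor
  f2 <- fit_leaf(c(0, 2))
  expect_equal(f2$mu, 1)
  expect_equal(f2$sigma, 1)                # population sd, not sample sd
  set.seed(42)
  v <- rnorm(6)
  f3 <- fit_leaf(v)
  expect_equal(f3$mu, mean(v))
  expect_equal(f3$sigma, sqrt(mean((v - mean(v))^2)))
  expect_error(fit_leaf(numeric(0)), "empty")
})

test_that("split likelihood equals direct summation and favors true splits", {
  # single-gene, 4-condition toy: hand-computed sum of 4 log densities
  x <- matrix(c(1, 1.2, 5, 5.4), 1, 4,
              dimnames = list("g", c("c1", "c2", "c3", "c4")))
  got <- split_log_likelihood(x, c("c1", "c2"), c("c3", "c4"))
  expect_equal(got, oracle_split_ll(x, c("c1", "c2"), c("c3", "c4")))

  # with genuine two-state structure, the best split beats the merged leaf
  set.seed(5)
  x2 <- rbind(c(rnorm(4, 0, 0.2), rnorm(4, 6, 0.2)),
              c(rnorm(4, 0, 0.2), rnorm(4, 6, 0.2)))
  dimnames(x2) <- list(c("g1", "g2"), sprintf("c%d", 1:8))
  merged <- regmodnet:::leaf_log_likelihood(as.vector(x2))
  split <- split_log_likelihood(x2, sprintf("c%d", 1:4), sprintf("c%d", 5:8))
  expect_gt(split, merged)

  # genes constant within each subset: likelihood sits at the sigma floor
  x3 <- matrix(c(2, 2, 7, 7), 1, 4, dimnames = list("g", colnames(x)))
  ll3 <- split_log_likelihood(x3, c("c1", "c2"), c("c3", "c4"))
  expect_equal(ll3, 4 * gaussian_log_density(0, 0, 0.01))
})

test_that("best_split picks the dominating query and ties break lexicographically", {
  conds <- sprintf("c%d", 1:8)
  # TF1 'high' separates conditions into two zero-variance groups
  states <- rbind(t1 = c(1L, 1L, 1L, 1L, 0L, 0L, -1L, 0L),
                  t2 = c(1L, 0L, 1L, 0L, 1L, 0L, 1L, 0L))
  colnames(states) <- conds
  x <- matrix(rep(c(0, 0, 0, 0, 5, 5, 5, 5), 3), 3, 8, byrow = TRUE,
              dimnames = list(c("g1", "g2", "g3"), conds))
  sp <- best_split(x, conds, states, c("t1", "t2"))
  expect_equal(sp$tf_id, "t1")
  expect_equal(sp$query_state, "high")
  expect_setequal(sp$cond_yes, conds[1:4])

  # exact tie between two TFs with identical state rows: lower tf_id wins
  states2 <- rbind(ta = states["t1", ], tb = states["t1", ])
  colnames(states2) <- conds
  sp2 <- best_split(x, conds, states2, c("tb", "ta"))
  expect_equal(sp2$tf_id, "ta")

  # no candidate improves on the unsplit leaf -> NULL
  flat <- matrix(1, 2, 8, dimnames = list(c("g1", "g2"), conds))
  expect_null(best_split(flat, conds, states, c("t1", "t2")))
})

test_that("greedy search agrees with exhaustive enumeration on random instances", {
  for (s in 1:25) {
    inst <- random_split_instance(s)
    got <- best_split(inst$x, inst$conds, inst$states, inst$tfs)
    want <- oracle_best_split(inst$x, inst$conds, inst$states, inst$tfs)
    if (is.null(want)) {
      expect_null(got)
    } else {
      expect_equal(got$tf_id, want$tf)
      expect_equal(got$query_state, want$qs)
      expect_equal(got$log_lik, want$ll, tolerance = 1e-9)
    }
  }
})

test_that("tree construction respects depth, leaf-size and no-repeat constraints", {
  ds <- generate_planted_network(seed = 3)
  mod_genes <- names(ds$truth_assignment)[ds$truth_assignment == 1]
  x <- ds$matrix$values[mod_genes, ]
  tr <- build_tree(x, ds$tf_states, ds$tf_ids, max_depth = 1)
  expect_lte(length(tree_leaves(tr)), 2)       # max_depth=1 -> at most 2 leaves
  tr3 <- build_tree(x, ds$tf_states, ds$tf_ids, max_depth = 3)
  expect_lte(tree_depth(tr3), 3)
  # leaves partition the conditions
  leaves <- tree_leaves(tr3)
  conds <- unlist(lapply(leaves, `[[`, "conditions"))
  expect_setequal(conds, condition_ids(ds$matrix))
  expect_equal(anyDuplicated(conds), 0L)
  expect_true(all(lengths(lapply(leaves, `[[`, "conditions")) >= 2))
  # no TF repeated on a root-to-leaf path
  check_path <- function(node, seen) {
    if (node$type == "leaf") return(TRUE)
    if (node$tf_id %in% seen) return(FALSE)
    check_path(node$yes, c(seen, node$tf_id)) &&
      check_path(node$no, c(seen, node$tf_id))
  }
  expect_true(check_path(tr3, character(0)))

  # no TF improves at the root -> a single-leaf depth-0 tree
  flat <- matrix(0, 3, 20, dimnames = list(c("a", "b", "c"),
                                           condition_ids(ds$matrix)))
  tr0 <- build_tree(flat, ds$tf_states, ds$tf_ids)
  expect_equal(tr0$type, "leaf")
  expect_equal(tree_depth(tr0), 0L)
})

test_that("planted depth-2 trees are recovered from well-separated data", {
  ok <- 0
  for (s in 1:5) {
    ds <- generate_planted_network(seed = 400 + s)
    all_match <- TRUE
    for (mod in 1:5) {
      mg <- names(ds$truth_assignment)[ds$truth_assignment == mod]
      tr <- build_tree(ds$matrix$values[mg, ], ds$tf_states, ds$tf_ids,
                       max_depth = 2)
      if (!identical(regmodnet:::tree_signature(tr),
                     regmodnet:::tree_signature(ds$truth_trees[[mod]])))
        all_match <- FALSE
    }
    if (all_match) ok <- ok + 1
  }
  expect_gte(ok, 4)
})

test_that("gene likelihood sums per-condition leaf densities", {
  ds <- generate_planted_network(seed = 9)
  tr <- ds$truth_trees[[1]]
  p <- regmodnet:::tree_leaf_params(tr)
  conds <- names(p$mu)
  # gene exactly at every leaf mean with sigma = 1: -0.91894 per condition
  gene <- p$mu
  set_sigma1 <- function(node) {
    if (node$type == "leaf") { node$sigma <- 1; return(node) }
    node$yes <- set_sigma1(node$yes); node$no <- set_sigma1(node$no); node
  }
  trs <- set_sigma1(tr)
  expect_equal(gene_log_likelihood(gene, trs),
               length(conds) * log(1 / sqrt(2 * pi)))
  # adding a constant offset c lowers it by n * c^2 / 2 when all sigma = 1
  expect_equal(gene_log_likelihood(gene + 0.7, trs),
               gene_log_likelihood(gene, trs) - length(conds) * 0.7^2 / 2)
  # 4-condition toy equals hand-summed oracle densities
  x4 <- c(c1 = 0.3, c2 = -0.1, c3 = 2.2, c4 = 2.0)
  toy <- structure(list(type = "split", tf_id = "t", query_state = "high",
                        yes = list(type = "leaf", conditions = c("c1", "c2"),
                                   mu = 0.1, sigma = 0.5),
                        no = list(type = "leaf", conditions = c("c3", "c4"),
                                  mu = 2.1, sigma = 0.3)), class = "reg_tree")
  want <- oracle_log_density(0.3, 0.1, 0.5) + oracle_log_density(-0.1, 0.1, 0.5) +
    oracle_log_density(2.2, 2.1, 0.3) + oracle_log_density(2.0, 2.1, 0.3)
  expect_equal(gene_log_likelihood(x4, toy), want)
})

test_that("gene reassignment is an argmax with deterministic tie-breaks", {
  ds <- generate_planted_network(seed = 21)
  trees <- ds$truth_trees
  # genes sampled from module 1's leaves end up in module 1 (>= 95%)
  p <- regmodnet:::tree_leaf_params(trees[[1]])
  conds <- condition_ids(ds$matrix)
  set.seed(77)
  hits <- 0
  for (i in 1:100) {
    g <- rnorm(length(conds), p$mu[conds], 0.3)
    vals <- matrix(g, 1, length(conds), dimnames = list("probe", conds))
    re <- reassign_genes(trees, expression_matrix(vals, "log"))
    if (re$kept[re$assignment[["probe"]]] == 1) hits <- hits + 1
  }
  expect_gte(hits, 95)

  # identical trees: every gene goes to module 1 by the lowest-index rule
  re2 <- reassign_genes(list(trees[[1]], trees[[1]]), ds$matrix)
  expect_true(all(re2$assignment == 1L))
  expect_equal(re2$kept, 1L)

  # one gene, one module: unchanged
  one <- subset_genes(ds$matrix, "M1_G001")
  re3 <- reassign_genes(trees[1], one)
  expect_equal(unname(re3$assignment), 1L)
})

test_that("network fitting converges monotonically and deterministically", {
  ds <- generate_planted_network(seed = 31)
  net <- suppressWarnings(fit_module_network(ds$matrix, ds$tf_ids, K = 6,
                                             seed = 2, max_depth = 2))
  expect_true(net$converged)
  expect_lte(net$iterations_run, 50)
  expect_true(all(diff(net$ll_trace) >= -1e-8))
  # partition invariants
  expect_setequal(names(net$assignment), gene_ids(ds$matrix))
  expect_equal(sort(unique(net$assignment)), seq_along(net$modules))
  # bit-identical refit with the same seed
  net2 <- suppressWarnings(fit_module_network(ds$matrix, ds$tf_ids, K = 6,
                                              seed = 2, max_depth = 2))
  expect_identical(net$assignment, net2$assignment)
  expect_identical(net$ll_trace, net2$ll_trace)

  # no TF structure: flat states -> all trees depth 0
  flat_states_m <- make_expr(matrix(rep(c(0, 5), each = 10), 2, 10,
                                    byrow = TRUE), "log",
                             genes = c("t1", "g1"))
  netf <- suppressWarnings(fit_module_network(flat_states_m, "t1", K = 1,
                                              seed = 1))
  expect_true(all(vapply(netf$modules, function(md) tree_depth(md$tree),
                         integer(1)) == 0L))
})
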