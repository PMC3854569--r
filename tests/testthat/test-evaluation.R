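toy_module <- function() {
  conds <- c("c1", "c2", "c3", "c4")
  tree <- structure(list(type = "split", tf_id = "t", query_state = "high",
                         yes = list(type = "leaf", conditions = c("c1", "c2"),
                                    mu = 0, sigma = 1),
                         no = list(type = "leaf", conditions = c("c3", "c4"),
                                   mu = 5, sigma = 1)), class = "reg_tree")
  vals <- rbind(g1 = c(0, 0, 5, 5), g2 = c(0, 0, 5, 5), g3 = c(0, 0, 5, 5))
  colnames(vals) <- conds
  list(module = list(genes = c("g1", "g2", "g3"), tree = tree),
       m = expression_matrix(vals, "log"))
}

test_that("per-condition module score follows the summed Gaussian terms", {
  tm <- toy_module()
  # all genes at leaf means, sigma 1: both terms vanish, log_p = 0 everywhere
  lp <- module_log_p(tm$module, tm$m)
  expect_equal(lp$scores$log_p, rep(0, 4))
  expect_equal(lp$mean_log_p, 0)

  # n genes each one sigma from the mean: log_p = -n/2
  m2 <- expression_matrix(tm$m$values + 1, "log")
  lp2 <- module_log_p(tm$module, m2)
  expect_equal(lp2$scores$log_p, rep(-3 / 2, 4))

  # 3-gene toy with unequal values: hand-summed value per condition
  vals <- rbind(g1 = c(0.2, -0.3, 4.8, 5.1), g2 = c(0.1, 0, 5.2, 5),
                g3 = c(-0.2, 0.4, 4.9, 5.3))
  colnames(vals) <- c("c1", "c2", "c3", "c4")
  m3 <- expression_matrix(vals, "log")
  lp3 <- module_log_p(tm$module, m3)
  hand <- function(x, mu, s) sum(-(x - mu)^2 / (2 * s^2) - log(s))
  expect_equal(lp3$scores$log_p[1], hand(vals[, "c1"], 0, 1))
  expect_equal(lp3$scores$log_p[3], hand(vals[, "c3"], 5, 1))

  # moving any value away from its leaf mean strictly lowers the score
  worse <- vals; worse["g1", "c1"] <- worse["g1", "c1"] + 2
  expect_lt(module_log_p(tm$module, expression_matrix(worse, "log"))$scores$log_p[1],
            lp3$scores$log_p[1])
})

test_that("random-null draws are deterministic and refit on the fixed topology", {
  ds <- generate_planted_network(seed = 13)
  net <- suppressWarnings(fit_module_network(ds$matrix, ds$tf_ids, K = 6,
                                             seed = 1, max_depth = 2))
  mod <- net$modules[[1]]
  # universe = module genes only: every rep reproduces the refit observed score
  null_self <- random_null(mod, ds$matrix, mod$genes, n_reps = 5, seed = 4)
  refit <- regmodnet:::refit_tree(mod$tree, ds$matrix$values[mod$genes, ])
  obs <- module_log_p(list(genes = mod$genes, tree = refit), ds$matrix)
  expect_equal(null_self$per_rep, rep(obs$mean_log_p, 5))

  # same seed twice -> identical draws; different seed -> different
  u <- gene_ids(ds$matrix)
  n1 <- random_null(mod, ds$matrix, u, n_reps = 20, seed = 9)
  n2 <- random_null(mod, ds$matrix, u, n_reps = 20, seed = 9)
  expect_identical(n1$per_rep, n2$per_rep)
  expect_length(n1$per_rep, 20)

  # planted module beats every random draw
  expect_gt(module_log_p(mod, ds$matrix)$mean_log_p, max(n1$per_rep))
  expect_error(random_null(mod, ds$matrix, mod$genes[1:3], 5, 1), "smaller")
})

test_that("Rand index matches brute-force pair counting", {
  # identity
  x <- c(a = 1, b = 1, c = 2)
  expect_equal(rand_index(x, x)$R, 1.0)
  # full disagreement on two elements
  r0 <- rand_index(c(e1 = 1, e2 = 2), c(e1 = 1, e2 = 1))
  expect_equal(r0$R, 0.0)
  expect_equal(r0$d, 1)
  # X = {{1,2},{3}}, Y = {{1},{2,3}} -> R = 1/3
  r3 <- rand_index(c(`1` = 1, `2` = 1, `3` = 2), c(`1` = 1, `2` = 2, `3` = 2))
  expect_equal(r3$R, 1 / 3)
  expect_equal(unlist(r3[c("a", "b", "c", "d")]),
               c(a = 0, b = 1, c = 1, d = 1))

  # brute-force oracle on random partitions + symmetry + pair conservation
  set.seed(31)
  for (i in 1:10) {
    n <- sample(4:9, 1)
    x <- setNames(sample(1:3, n, replace = TRUE), paste0("e", 1:n))
    y <- setNames(sample(1:3, n, replace = TRUE), paste0("e", 1:n))
    pairs <- combn(names(x), 2)
    counts <- c(a = 0, b = 0, c = 0, d = 0)
    for (j in seq_len(ncol(pairs))) {
      p1 <- pairs[1, j]; p2 <- pairs[2, j]
      sx <- x[p1] == x[p2]; sy <- y[p1] == y[p2]
      counts[if (sx && sy) "a" else if (!sx && !sy) "b"
             else if (sx) "c" else "d"] <-
        counts[if (sx && sy) "a" else if (!sx && !sy) "b"
               else if (sx) "c" else "d"] + 1
    }
    r <- rand_index(x, y)
    expect_equal(unlist(r[c("a", "b", "c", "d")]), counts)
    expect_equal(r$a + r$b + r$c + r$d, choose(n, 2))
    expect_equal(rand_index(y, x)$R, r$R)
  }
  expect_error(rand_index(c(a = 1, b = 1), c(a = 1, z = 1)), "different element")
})

test_that("non-DE TF injection leaves the baseline intact and reports per fraction", {
  ds <- generate_planted_network(seed = 17)
  tab <- suppressWarnings(tf_injection_stability(
    ds$matrix, ds$tf_ids, ds$decoy_tf_ids, fractions = c(0, 0.5),
    K = 6, seed = 3, max_depth = 2))
  expect_equal(nrow(tab), 2)                     # one row per fraction
  expect_equal(tab$rand_gene_gene[tab$fraction == 0], 1.0)
  expect_equal(tab$rand_tf_target[tab$fraction == 0], 1.0)
  expect_equal(tab$n_injected, c(0, 5))
  expect_true(all(tab$rand_gene_gene >= 0 & tab$rand_gene_gene <= 1))
})

test_that("module structure is robust to the DEG threshold on planted subsets", {
  ds <- generate_planted_network(seed = 23)
  truth <- ds$truth_assignment
  planted <- names(truth)[truth > 0]
  # stricter cutoff keeps half of each planted module; looser keeps all
  p_adj <- setNames(rep(0.04, length(planted)), planted)
  for (mod in 1:5) {
    mg <- names(truth)[truth == mod]
    p_adj[mg[seq_len(15)]] <- 1e-6
  }
  dr <- deg_result("cmp", names(p_adj), p_adj, p_adj = p_adj)
  out <- suppressWarnings(threshold_robustness(
    ds$matrix, list(dr), thresholds = c(1e-4, 0.05), tf_ids = ds$tf_ids,
    K = 5, seed = 2, max_depth = 2))
  expect_equal(nrow(out$report), length(out$net_strict$modules))
  expect_true(all(out$report$containment >= 0.9))

  # identical cutoffs: identical networks, all overlaps 1
  out2 <- suppressWarnings(threshold_robustness(
    ds$matrix, list(dr), thresholds = c(0.05, 0.05), tf_ids = ds$tf_ids,
    K = 5, seed = 2, max_depth = 2))
  expect_true(all(out2$report$jaccard == 1))
  expect_error(suppressWarnings(threshold_robustness(
    ds$matrix, list(dr), thresholds = c(1e-9, 0.05), tf_ids = ds$tf_ids,
    K = 5, seed = 2)), "stricter cutoff")
})
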