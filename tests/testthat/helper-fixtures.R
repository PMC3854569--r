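# Shared fixtures, built in code at test time.

# Small expression matrix with explicit values.
make_expr <- function(values, scale_tag = "log",
                      genes = sprintf("g%d", seq_len(nrow(values))),
                      conds = sprintf("c%d", seq_len(ncol(values)))) {
  dimnames(values) <- list(genes, conds)
  expression_matrix(values, scale_tag)
}

# Write a counts TSV and return its path.
write_counts_file <- function(values, path = tempfile(fileext = ".tsv"),
                              genes = rownames(values),
                              conds = colnames(values)) {
  df <- data.frame(gene_id = genes, values, check.names = FALSE)
  colnames(df) <- c("gene_id", conds)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# Independent Gaussian log-density oracle (explicit formula, not dnorm).
oracle_log_density <- function(x, mu, sigma, sigma_floor = 0.01) {
  s <- max(sigma, sigma_floor)
  -0.5 * log(2 * pi) - log(s) - (x - mu)^2 / (2 * s^2)
}

# Oracle leaf fit: mean + population sd with floor.
oracle_fit <- function(v, sigma_floor = 0.01) {
  mu <- sum(v) / length(v)
  list(mu = mu, sigma = max(sqrt(sum((v - mu)^2) / length(v)), sigma_floor))
}

# Oracle two-leaf split log likelihood over a module gene matrix.
oracle_split_ll <- function(x, yes, no, sigma_floor = 0.01) {
  ll_side <- function(conds) {
    v <- as.vector(x[, conds, drop = FALSE])
    f <- oracle_fit(v, sigma_floor)
    sum(vapply(v, oracle_log_density, numeric(1), f$mu, f$sigma, sigma_floor))
  }
  ll_side(yes) + ll_side(no)
}

# Exhaustive enumeration of every (TF, high/low) query: the brute-force
# oracle best_split is checked against. Mirrors feasibility, gain and
# lexicographic tie-break rules independently of the package's search.
oracle_best_split <- function(x, conds, states, tfs, min_leaf = 2,
                              eps = 1e-6, sigma_floor = 0.01) {
  v <- as.vector(x[, conds, drop = FALSE])
  f <- oracle_fit(v, sigma_floor)
  base <- sum(vapply(v, oracle_log_density, numeric(1), f$mu, f$sigma,
                     sigma_floor))
  best <- NULL
  for (tf in sort(tfs)) for (qs in c("high", "low")) {
    yes <- conds[states[tf, conds] == (if (qs == "high") 1L else -1L)]
    no <- setdiff(conds, yes)
    if (length(yes) < min_leaf || length(no) < min_leaf) next
    ll <- oracle_split_ll(x[, conds, drop = FALSE], yes, no, sigma_floor)
    if (is.null(best) || ll > best$ll)
      best <- list(tf = tf, qs = qs, ll = ll)
  }
  if (is.null(best) || best$ll - base <= eps) return(NULL)
  best
}

# Random small instance for the split-search oracle test.
random_split_instance <- function(seed) {
  set.seed(seed)
  n_tf <- sample(1:3, 1); n_cond <- sample(5:8, 1); n_gene <- sample(2:6, 1)
  conds <- sprintf("c%d", 1:n_cond)
  tfs <- sprintf("t%d", 1:n_tf)
  states <- matrix(sample(c(-1L, 0L, 1L), n_tf * n_cond, replace = TRUE),
                   n_tf, n_cond, dimnames = list(tfs, conds))
  x <- matrix(rnorm(n_gene * n_cond), n_gene, n_cond,
              dimnames = list(sprintf("g%d", 1:n_gene), conds))
  list(x = x, conds = conds, states = states, tfs = tfs)
}
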