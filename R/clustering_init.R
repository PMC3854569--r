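#' K-means clustering of log-expression profiles
#'
#' Initial partition of (differentially expressed) genes into co-expression
#' clusters by Lloyd's K-means on the row vectors, Euclidean distance,
#' with random restarts keeping the lowest within-cluster sum of squares.
#'
#' @param m An `expr_matrix` with `scale_tag = "log"`.
#' @param K Number of clusters, `1 <= K <=` number of genes.
#' @param seed Integer seed; results are deterministic for a fixed seed.
#' @param nstart Number of random restarts (default 10).
#' @return A `gene_clustering`: list with `assignment` (named integer vector,
#'   cluster indices `1..K`), `K`, `avg_corr`, `avg_size`.
#' @export
kmeans_cluster <- function(m, K, seed = 1L, nstart = 10L) {
  stopifnot(inherits(m, "expr_matrix"))
  if (m$scale_tag != "log")
    stop("kmeans_cluster expects log-scale values")
  n <- nrow(m$values)
  if (K < 1) stop("K must be >= 1")
  if (K > n) stop("K (", K, ") exceeds the number of genes (", n, ")")
  if (K == n) {
    st0 <- cluster_stats(m, stats::setNames(seq_len(n), gene_ids(m)))
    return(structure(list(assignment = stats::setNames(seq_len(n), gene_ids(m)),
                          K = as.integer(K), avg_corr = st0$avg_corr,
                          avg_size = st0$avg_size),
                     class = "gene_clustering"))
  }
  n_distinct <- nrow(unique(m$values))
  if (K == 1 || K > n_distinct) {
    # fewer distinct profiles than centers: K-means is ill-posed; fall back
    # to grouping identical profiles (deterministic)
    if (K == 1) {
      assign <- stats::setNames(rep(1L, n), gene_ids(m))
    } else {
      key <- apply(m$values, 1, paste, collapse = "\r")
      assign <- stats::setNames(as.integer(factor(key, levels = unique(key))),
                                gene_ids(m))
    }
  } else {
    set.seed(seed)
    km <- suppressWarnings(
      stats::kmeans(m$values, centers = K, nstart = nstart, iter.max = 100))
    assign <- stats::setNames(as.integer(km$cluster), gene_ids(m))
  }
  st <- cluster_stats(m, assign)
  structure(list(assignment = assign, K = as.integer(K),
                 avg_corr = st$avg_corr, avg_size = st$avg_size),
            class = "gene_clustering")
}

#' Within-cluster correlation and size summary
#'
#' `avg_corr` is the mean over clusters of the mean pairwise Pearson
#' correlation among member expression profiles; singleton clusters
#' contribute 1. Pairs involving a zero-variance profile (undefined Pearson
#' correlation) contribute 0. `avg_size` is genes / clusters.
#'
#' @param m An `expr_matrix` whose rows cover the clustered genes.
#' @param assignment Named integer vector gene -> cluster index.
#' @return List with `avg_corr` and `avg_size`.
#' @export
cluster_stats <- function(m, assignment) {
  genes <- names(assignment)
  miss <- setdiff(genes, gene_ids(m))
  if (length(miss)) stop("assignment covers genes absent from matrix")
  ks <- sort(unique(assignment))
  corr_per_cluster <- vapply(ks, function(k) {
    members <- genes[assignment == k]
    if (length(members) == 1) return(1)
    x <- m$values[members, , drop = FALSE]
    cc <- suppressWarnings(stats::cor(t(x)))
    cc[is.na(cc)] <- 0          # zero-variance rows: correlation defined as 0
    mean(cc[upper.tri(cc)])
  }, numeric(1))
  list(avg_corr = mean(corr_per_cluster),
       avg_size = length(genes) / length(ks))
}

#' Choose the number of clusters from the correlation/size tradeoff
#'
#' Runs K-means over a range of K and records the average within-cluster
#' correlation and average cluster size for each K. Raising K raises the
#' correlation and shrinks the clusters; the chosen K is the knee of the
#' correlation curve — the point, after the region of most drastic change,
#' with maximum distance above the chord joining the curve's endpoints
#' (both axes min-max normalized). The full curve is returned so the
#' choice can be overridden.
#'
#' @param m An `expr_matrix`, `scale_tag = "log"`.
#' @param k_range Integer vector of candidate K (e.g. `2:10`), within
#'   `[2, n_genes]`.
#' @param seed Integer seed used for every K.
#' @param nstart Restarts per K (default 10).
#' @return List with `chosen_k` and `curve` (data.frame `K`, `avg_corr`,
#'   `avg_size`). If the range has fewer than 3 values the curvature is
#'   undefined: the midpoint is returned with a warning. If the correlation
#'   curve is flat (no structure), the smallest K is returned with a warning.
#' @export
select_k <- function(m, k_range, seed = 1L, nstart = 10L) {
  k_range <- sort(unique(as.integer(k_range)))
  if (any(k_range < 2) || any(k_range > nrow(m$values)))
    stop("k_range must lie within [2, number of genes]")
  curve <- data.frame(K = k_range, avg_corr = NA_real_, avg_size = NA_real_)
  for (i in seq_along(k_range)) {
    cl <- kmeans_cluster(m, k_range[i], seed = seed, nstart = nstart)
    curve$avg_corr[i] <- cl$avg_corr
    curve$avg_size[i] <- cl$avg_size
  }
  if (length(k_range) < 3) {
    warning("k_range too narrow for curvature selection; returning midpoint")
    chosen <- k_range[ceiling(length(k_range) / 2)]
  } else if (diff(range(curve$avg_corr)) < 1e-8) {
    warning("flat correlation curve (no cluster structure); returning smallest K")
    chosen <- k_range[1]
  } else {
    xn <- (k_range - min(k_range)) / diff(range(k_range))
    yn <- (curve$avg_corr - min(curve$avg_corr)) / diff(range(curve$avg_corr))
    chosen <- k_range[which.max(yn - xn)]
  }
  list(chosen_k = chosen, curve = curve)
}

#' Write a K-selection curve as TSV
#' @param curve data.frame from [select_k()]`$curve`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_k_curve <- function(curve, path) {
  utils::write.table(curve, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
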