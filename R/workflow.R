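# End-to-end orchestration: a declarative config drives the pipeline
# stages in order (normalize -> DEG selection -> K selection -> module
# network fitting -> null-model evaluation -> enrichment -> motif scan),
# each stage writing its outputs before the next begins. A single master
# seed deterministically derives per-stage seeds, so a rerun with the same
# config is bit-identical.

#' Default run configuration
#'
#' Returns the full configuration list with documented defaults; any subset
#' can be overridden via `...` or by loading a YAML file with
#' [read_run_config()].
#'
#' @param ... Named overrides of the defaults.
#' @return A `run_config` list.
#' @export
run_config <- function(...) {
  cfg <- list(
    counts = NULL,            # path to tab-delimited raw counts
    gene_lengths = NULL,      # path to gene-length table (bp)
    tf_table = NULL,          # path to TF table (gene_id [, family])
    go_annotations = NULL,    # path to GO annotation table
    genome_fasta = NULL,      # genome FASTA for upstream extraction
    features_gff = NULL,      # GFF3 gene features
    deg_tables = NULL,        # optional: externally computed DEG tables
    comparisons = NULL,       # list of list(name, group_a, group_b)
    deg_threshold = 0.05,     # inclusive adjusted-p cutoff
    deg_mode = "overlap",     # overlap | union across comparisons
    pseudocount = 1,
    K = NULL,                 # fixed cluster number; NULL = select from k_range
    k_range = c(2, 10),
    z_hi = 1, z_lo = -1,
    max_depth = 3, min_leaf_conditions = 2,
    epsilon_gain = 1e-6, sigma_floor = 0.01,
    exclude_module_tfs = TRUE,
    tf_families = NULL,       # prior-knowledge mode: restrict to families
    enrichment_cutoff = 0.01,
    upstream_length = 500,
    n_null_reps = 1000,
    max_iter = 50,
    seed = 1L)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stop("unknown config fields: ",
                            paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = "run_config")
}

#' Read a run configuration from YAML
#' @param path Path to a YAML file whose keys are [run_config()] fields.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}

#' Write a run configuration to YAML
#' @param config A `run_config`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config)[!vapply(config, is.null, logical(1))], path)
  invisible(path)
}

# Deterministic per-stage seed stream from the master seed.
stage_seed <- function(master, stage) {
  (as.integer(master) * 131L + match(stage, c("kmeans", "fit", "null",
                                              "stability", "counts"))) %% .Machine$integer.max
}

#' Run the full regulatory-module-network pipeline
#'
#' Executes, in order: count loading and RPKM-style normalization, log
#' transform, per-comparison differential-expression selection, cluster
#' number selection, module-network fitting on the selected DEGs,
#' null-model evaluation of every module, and (when annotation / sequence
#' inputs are present) GO enrichment and nodulin-motif scanning of each
#' module. Every stage's outputs are written to `out_dir` before the next
#' stage begins; reruns with the same config are byte-identical.
#'
#' @param config A `run_config`.
#' @param out_dir Output directory (created; existing files overwritten).
#' @return Invisibly, a list with the fitted `network`, the log `matrix`,
#'   the DEG results, and the paths written.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run.log")
  logf <- function(stage, ...) {
    cat(sprintf("[%s] %s\n", stage, paste0(...)), file = log_path,
        append = TRUE)
  }
  cat("", file = log_path)
  stage <- "load"
  result <- tryCatch({
    # --- load + normalize ---------------------------------------------
    if (is.null(config$counts)) stop("config$counts is required")
    counts <- load_counts(config$counts)
    logf(stage, "loaded ", length(gene_ids(counts)), " genes x ",
         length(condition_ids(counts)), " conditions")
    stage <- "normalize"
    lens <- if (!is.null(config$gene_lengths))
      read_gene_lengths(config$gene_lengths)
    else stats::setNames(rep(1000, nrow(counts$values)), gene_ids(counts))
    normalized <- rpkm_normalize(counts, lens)
    logm <- log_transform(normalized, config$pseudocount)
    write_expression(normalized, file.path(out_dir, "normalized.tsv"))
    write_expression(logm, file.path(out_dir, "log_expression.tsv"))
    logf(stage, "normalized (reads/KB/MB) and log-transformed")

    # --- DEG selection -------------------------------------------------
    stage <- "deg"
    if (!is.null(config$deg_tables)) {
      degs <- lapply(config$deg_tables, import_deg_table,
                     threshold = config$deg_threshold)
    } else {
      if (is.null(config$comparisons)) stop("config$comparisons is required")
      cmps <- lapply(config$comparisons, function(cm)
        comparison(cm$name, cm$group_a, cm$group_b))
      degs <- run_deg(counts, cmps, threshold = config$deg_threshold)
    }
    for (r in degs)
      utils::write.table(r$table, file.path(out_dir, paste0("deg_", r$name, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    selected <- select_degs(degs, config$deg_mode)
    writeLines(selected, file.path(out_dir, "deg_selected.txt"))
    logf(stage, length(selected), " genes selected (", config$deg_mode, ")")
    if (!length(selected)) stop("no differentially expressed genes selected")

    # --- TF candidates -------------------------------------------------
    stage <- "tfs"
    if (is.null(config$tf_table)) stop("config$tf_table is required")
    tfs <- read_tf_table(config$tf_table)
    if (!is.null(config$tf_families))
      tfs <- tfs[tfs$tf_family %in% config$tf_families, , drop = FALSE]
    # regulators restricted to differentially expressed TFs
    tf_ids <- intersect(tfs$gene_id, selected)
    logf(stage, length(tf_ids), " candidate regulator TFs")

    # --- clustering + K selection -------------------------------------
    stage <- "select_k"
    m_deg <- subset_genes(logm, intersect(selected, gene_ids(logm)))
    if (!is.null(config$K)) {
      K <- config$K
    } else {
      kr <- seq(max(2, config$k_range[1]),
                min(config$k_range[2], nrow(m_deg$values)))
      sel <- select_k(m_deg, kr, seed = stage_seed(config$seed, "kmeans"))
      write_k_curve(sel$curve, file.path(out_dir, "k_curve.tsv"))
      K <- sel$chosen_k
    }
    logf(stage, "K = ", K)

    # --- module network ------------------------------------------------
    stage <- "fit"
    net <- fit_module_network(
      m_deg, tf_ids, K, seed = stage_seed(config$seed, "fit"),
      max_iter = config$max_iter, z_hi = config$z_hi, z_lo = config$z_lo,
      max_depth = config$max_depth,
      min_leaf_conditions = config$min_leaf_conditions,
      epsilon_gain = config$epsilon_gain, sigma_floor = config$sigma_floor,
      exclude_module_tfs = config$exclude_module_tfs, states_from = logm)
    write_network_json(net, file.path(out_dir, "network.json"))
    for (k in seq_along(net$modules)) {
      tree_to_dot(net$modules[[k]]$tree,
                  file.path(out_dir, sprintf("module_%02d.dot", k)),
                  name = sprintf("module_%02d", k))
      write_module_heatmap_tsv(net, m_deg, k,
                               file.path(out_dir, sprintf("module_%02d_heatmap.tsv", k)))
    }
    logf(stage, length(net$modules), " modules, ", net$iterations_run,
         " iterations, converged = ", net$converged)

    # --- null-model evaluation ----------------------------------------
    stage <- "evaluate"
    eval_rows <- lapply(seq_along(net$modules), function(k) {
      obs <- module_log_p(net$modules[[k]], m_deg)
      null <- random_null(net$modules[[k]], m_deg, gene_ids(m_deg),
                          n_reps = config$n_null_reps,
                          seed = stage_seed(config$seed, "null") + k,
                          sigma_floor = config$sigma_floor)
      write_null_tsv(null, file.path(out_dir, sprintf("module_%02d_null.tsv", k)),
                     breaks = 30)
      data.frame(module = k, n_genes = length(net$modules[[k]]$genes),
                 mean_log_p = obs$mean_log_p,
                 null_mean = null$summary[["mean"]],
                 null_sd = null$summary[["sd"]],
                 null_max = null$summary[["max"]])
    })
    eval_tab <- do.call(rbind, eval_rows)
    utils::write.table(eval_tab, file.path(out_dir, "module_evaluation.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    logf(stage, "mean log p over modules = ",
         format(mean(eval_tab$mean_log_p)))

    # --- enrichment ----------------------------------------------------
    if (!is.null(config$go_annotations)) {
      stage <- "enrich"
      ann <- read_go_annotations(config$go_annotations)
      bg <- intersect(gene_ids(logm), unique(ann$gene_id))
      enr <- lapply(seq_along(net$modules), function(k) {
        mg <- intersect(net$modules[[k]]$genes, bg)
        if (!length(mg)) return(NULL)
        res <- enrichment_test(mg, ann, bg, p_cutoff = config$enrichment_cutoff)
        if (nrow(res)) cbind(module = k, res) else NULL
      })
      enr <- do.call(rbind, enr[!vapply(enr, is.null, logical(1))])
      if (!is.null(enr))
        utils::write.table(enr, file.path(out_dir, "enrichment.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      logf(stage, "enrichment rows: ", if (is.null(enr)) 0 else nrow(enr))
    }

    # --- motif scan ----------------------------------------------------
    if (!is.null(config$genome_fasta) && !is.null(config$features_gff)) {
      stage <- "motifs"
      ups <- extract_upstream(config$genome_fasta, config$features_gff,
                              config$upstream_length)
      Biostrings::writeXStringSet(ups, file.path(out_dir, "upstream.fasta"))
      scan <- scan_nodulin_motifs(ups)
      utils::write.table(scan$summary, file.path(out_dir, "motif_counts.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      if (nrow(scan$hits))
        utils::write.table(scan$hits, file.path(out_dir, "motif_hits.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      logf(stage, nrow(scan$hits), " motif hits")
    }

    list(network = net, matrix = m_deg, degs = degs, out_dir = out_dir)
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(result)
}
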