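#' Read a GO annotation table
#'
#' Tab-delimited columns: gene id, GO id, ontology (one of P, F, C:
#' biological process, molecular function, cellular component), term name.
#'
#' @param path Path to the table (header optional, detected from a first
#'   line whose second field starts with "GO:").
#' @return data.frame with columns `gene_id`, `go_id`, `ontology`, `term`.
#' @export
read_go_annotations <- function(path) {
  first <- utils::read.delim(path, header = FALSE, nrows = 1,
                             colClasses = "character")
  has_header <- !grepl("^GO:", first[[2]])
  df <- utils::read.delim(path, header = has_header, colClasses = "character")
  colnames(df) <- c("gene_id", "go_id", "ontology", "term")[seq_len(ncol(df))]
  if (ncol(df) < 4) df$term <- df$go_id
  if (!"ontology" %in% colnames(df)) df$ontology <- ""
  bad <- !df$ontology %in% c("P", "F", "C", "")
  if (any(bad)) stop("ontology must be one of P, F, C")
  df[, c("gene_id", "go_id", "ontology", "term")]
}

#' Hypergeometric GO-term enrichment of a module
#'
#' For every GO term annotated to at least one module gene, tests whether
#' the term is over-represented in the module relative to the background
#' with a one-sided hypergeometric upper-tail test: with N background genes,
#' K_bg of them carrying the term, and a module of n genes of which k carry
#' it, p = P(X >= k), X ~ Hypergeometric(N, K_bg, n). Raw p-values are
#' reported (no multiple-testing correction by default, optional BH).
#'
#' @param module_genes Character vector of module gene ids.
#' @param annotations data.frame as from [read_go_annotations()].
#' @param background Character vector of background gene ids (must contain
#'   the module genes). Default: all annotated genes.
#' @param p_cutoff Significance flag cutoff (default 0.01).
#' @param adjust Apply Benjamini-Hochberg to the term p-values (default
#'   FALSE; the flag then uses adjusted values).
#' @return data.frame, one row per term present in the module: `go_id`,
#'   `ontology`, `term`, `k`, `K_bg`, `n`, `N`, `p_value`, `significant`;
#'   sorted by `p_value`.
#' @export
enrichment_test <- function(module_genes, annotations,
                            background = unique(annotations$gene_id),
                            p_cutoff = 0.01, adjust = FALSE) {
  background <- unique(background)
  if (!length(background)) stop("empty background gene set")
  out <- setdiff(module_genes, background)
  if (length(out))
    stop("module genes outside the background: ",
         paste(utils::head(out, 5), collapse = ", "))
  ann <- annotations[annotations$gene_id %in% background, , drop = FALSE]
  ann <- unique(ann[, c("gene_id", "go_id", "ontology", "term")])
  N <- length(background)
  n <- length(unique(module_genes))
  mod_ann <- ann[ann$gene_id %in% module_genes, , drop = FALSE]
  if (!nrow(mod_ann))
    return(data.frame(go_id = character(0), ontology = character(0),
                      term = character(0), k = integer(0), K_bg = integer(0),
                      n = integer(0), N = integer(0), p_value = numeric(0),
                      significant = logical(0)))
  terms <- unique(mod_ann$go_id)
  rows <- lapply(terms, function(g) {
    sub <- ann[ann$go_id == g, , drop = FALSE]
    k <- length(unique(sub$gene_id[sub$gene_id %in% module_genes]))
    K_bg <- length(unique(sub$gene_id))
    p <- stats::phyper(k - 1, K_bg, N - K_bg, n, lower.tail = FALSE)
    data.frame(go_id = g, ontology = sub$ontology[1], term = sub$term[1],
               k = k, K_bg = K_bg, n = n, N = N, p_value = p,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  if (adjust) res$p_value <- stats::p.adjust(res$p_value, method = "BH")
  res$significant <- res$p_value < p_cutoff
  res[order(res$p_value, res$go_id), , drop = FALSE]
}

#' Extract upstream (promoter) sequences of genes
#'
#' For each gene feature, returns up to `length` bases of genomic sequence
#' immediately upstream of the coding start: for a forward-strand gene
#' starting at 1-based position s, positions `[max(1, s - length), s - 1]`;
#' for a reverse-strand gene ending at e, the reverse complement of
#' `[e + 1, e + length]`. Windows are truncated at contig ends. Genes on
#' contigs absent from the genome are skipped with a warning.
#'
#' @param genome A `DNAStringSet` or path to a FASTA file.
#' @param features A `GRanges` of gene features or path to a GFF3 file
#'   (features of type `gene`, or all features if none are genes; gene ids
#'   from the `ID` or `Name` attribute).
#' @param length Upstream window size in bp (default 500).
#' @return A `DNAStringSet` named by gene id.
#' @export
extract_upstream <- function(genome, features, length = 500) {
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  names(genome) <- sub("\\s.*$", "", names(genome))
  if (is.character(features)) features <- rtracklayer::import(features)
  if ("type" %in% colnames(S4Vectors::mcols(features)) &&
      any(features$type == "gene"))
    features <- features[features$type == "gene"]
  ids <- if (!is.null(features$ID)) as.character(features$ID)
         else as.character(features$Name)
  seqs <- character(0)
  skipped <- character(0)
  for (i in seq_along(features)) {
    chrom <- as.character(GenomicRanges::seqnames(features)[i])
    if (!chrom %in% names(genome)) {
      skipped <- c(skipped, ids[i])
      next
    }
    contig <- genome[[chrom]]
    clen <- Biostrings::nchar(contig)
    strand <- as.character(GenomicRanges::strand(features)[i])
    if (strand == "-") {
      e <- GenomicRanges::end(features)[i]
      from <- e + 1; to <- min(clen, e + length)
      s <- if (from > to) "" else as.character(
        Biostrings::reverseComplement(Biostrings::subseq(contig, from, to)))
    } else {
      st <- GenomicRanges::start(features)[i]
      from <- max(1, st - length); to <- st - 1
      s <- if (from > to) "" else
        as.character(Biostrings::subseq(contig, from, to))
    }
    seqs[ids[i]] <- s
  }
  if (length(skipped))
    warning("skipped genes on contigs absent from the genome: ",
            paste(utils::head(skipped, 5), collapse = ", "))
  Biostrings::DNAStringSet(seqs)
}

#' Scan upstream sequences for nodulin consensus motifs
#'
#' Counts all exact (overlapping) occurrences of the putative nodulin
#' consensus sequences NODCON1GM (`AAAGAT`) and NODCON2GM (`CTCTT`) in each
#' upstream sequence. Matching is case-insensitive; IUPAC ambiguity codes in
#' the subject never match. Each record is scanned independently (no hits
#' across record boundaries). The reverse-complement strand can optionally
#' be scanned too.
#'
#' @param upstream A named `DNAStringSet` (or named character vector) of
#'   upstream sequences, e.g. from [extract_upstream()].
#' @param scan_reverse Also scan the reverse-complement strand (default
#'   FALSE).
#' @param motifs Named character vector of motifs; defaults to the two
#'   nodulin consensus patterns.
#' @return List with `hits` (data.frame `gene_id`, `motif`, `strand`,
#'   `offset` — 0-based position in the upstream sequence) and `summary`
#'   (data.frame `gene_id`, one count column per motif, and `total`).
#' @export
scan_nodulin_motifs <- function(upstream, scan_reverse = FALSE,
                                motifs = c(NODCON1GM = "AAAGAT",
                                           NODCON2GM = "CTCTT")) {
  seqs <- toupper(as.character(upstream))
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  hit_rows <- list()
  for (g in names(seqs)) {
    if (!nchar(seqs[[g]])) next
    subj <- Biostrings::DNAString(seqs[[g]])
    strands <- list("+" = subj)
    if (scan_reverse) strands[["-"]] <- Biostrings::reverseComplement(subj)
    for (strand in names(strands)) {
      for (mn in names(motifs)) {
        mt <- Biostrings::matchPattern(motifs[[mn]], strands[[strand]],
                                       fixed = TRUE)
        if (length(mt))
          hit_rows[[length(hit_rows) + 1L]] <- data.frame(
            gene_id = g, motif = mn, strand = strand,
            offset = Biostrings::start(mt) - 1L, stringsAsFactors = FALSE)
      }
    }
  }
  hits <- if (length(hit_rows)) do.call(rbind, hit_rows)
          else data.frame(gene_id = character(0), motif = character(0),
                          strand = character(0), offset = integer(0))
  summary <- data.frame(gene_id = names(seqs), stringsAsFactors = FALSE)
  for (mn in names(motifs))
    summary[[mn]] <- vapply(summary$gene_id, function(g)
      sum(hits$gene_id == g & hits$motif == mn), integer(1))
  summary$total <- rowSums(summary[, names(motifs), drop = FALSE])
  rownames(summary) <- NULL
  list(hits = hits, summary = summary)
}
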