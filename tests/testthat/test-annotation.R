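make_annotations <- function(assign) {
  # assign: named list term -> gene ids
  do.call(rbind, lapply(names(assign), function(term)
    data.frame(gene_id = assign[[term]], go_id = term, ontology = "P",
               term = paste0("name_", term), stringsAsFactors = FALSE)))
}

test_that("hypergeometric enrichment matches the combinatorial closed forms", {
  bg <- paste0("g", 1:10)
  ann <- make_annotations(list(
    "GO:0000001" = paste0("g", 1:3),    # K_bg = 3
    "GO:0000002" = bg))                 # annotates every background gene
  mod <- paste0("g", 1:3)
  res <- enrichment_test(mod, ann, bg, p_cutoff = 0.01)
  # N=10, K=3, n=3, k=3: p = C(3,3) C(7,0) / C(10,3) = 1/120
  expect_equal(res$p_value[res$go_id == "GO:0000001"], 1 / 120)
  expect_true(res$significant[res$go_id == "GO:0000001"])
  # term covering the whole background cannot be enriched
  expect_equal(res$p_value[res$go_id == "GO:0000002"], 1.0)
  # term absent from the module is omitted
  ann2 <- rbind(ann, make_annotations(list("GO:0000003" = "g9")))
  res2 <- enrichment_test(mod, ann2, bg)
  expect_false("GO:0000003" %in% res2$go_id)
  expect_error(enrichment_test(mod, ann, character(0)), "background")
  expect_error(enrichment_test("gX", ann, bg), "outside")
})

test_that("hypergeometric p equals exhaustive enumeration for small backgrounds", {
  # enumerate all C(N, n) module draws and count those with >= k marked genes
  for (cfg in list(c(N = 8, K = 3, n = 4, k = 2), c(N = 10, K = 5, n = 3, k = 1),
                   c(N = 12, K = 4, n = 6, k = 3), c(N = 12, K = 6, n = 5, k = 5),
                   c(N = 7, K = 2, n = 2, k = 2))) {
    N <- cfg[["N"]]; K <- cfg[["K"]]; n <- cfg[["n"]]; k <- cfg[["k"]]
    bg <- paste0("g", seq_len(N))
    marked <- bg[seq_len(K)]
    draws <- combn(N, n)
    p_enum <- mean(apply(draws, 2, function(d) sum(bg[d] %in% marked) >= k))
    # construct a module realizing exactly k marked genes
    mod <- c(marked[seq_len(k)], setdiff(bg, marked)[seq_len(n - k)])
    ann <- make_annotations(list("GO:X" = marked))
    res <- enrichment_test(mod, ann, bg)
    expect_equal(res$p_value[res$go_id == "GO:X"], p_enum, tolerance = 1e-12)
  }
})

test_that("upstream windows honor strand, truncation and contig bounds", {
  genome_fa <- tempfile(fileext = ".fa")
  contig <- paste0(paste(rep("ACGT", 150), collapse = ""), "TTGGCC")  # 606 bp
  writeLines(c(">chr1 test contig", contig), genome_fa)
  gff <- tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\tsrc\tgene\t501\t550\t.\t+\t.\tID=gplus",
    "chr1\tsrc\tgene\t3\t40\t.\t+\t.\tID=gshort",
    "chr1\tsrc\tgene\t5\t12\t.\t-\t.\tID=gminus",
    "chr2\tsrc\tgene\t5\t12\t.\t+\t.\tID=gmissing"), gff)
  expect_warning(ups <- extract_upstream(genome_fa, gff, length = 500),
                 "gmissing")
  # + strand gene at 501 with length 500: positions 1..500
  expect_equal(as.character(ups[["gplus"]]), substr(contig, 1, 500))
  # + strand gene at 3: truncated to 2 bp
  expect_equal(as.character(ups[["gshort"]]), substr(contig, 1, 2))
  # - strand gene ending at 12: reverse complement of 13..512, hand-checked
  want <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(substr(contig, 13, 512))))
  expect_equal(as.character(ups[["gminus"]]), want)
  expect_false("gmissing" %in% names(ups))

  # - strand toy gene on a 20 bp contig: manual reverse complement window
  g2 <- tempfile(fileext = ".fa"); writeLines(c(">tiny", "ACGTACGTACGGTTCAAGGT"), g2)
  gff2 <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "tiny\tsrc\tgene\t4\t10\t.\t-\t.\tID=toy"), gff2)
  ups2 <- extract_upstream(g2, gff2, length = 6)
  # upstream of a minus gene ending at 10: bases 11..16 = GGTTCA, revcomp TGAACC
  expect_equal(as.character(ups2[["toy"]]), "TGAACC")
  expect_true(all(Biostrings::width(ups2) <= 6))
})

test_that("nodulin motif counting is exact, overlapping and case-insensitive", {
  scan <- scan_nodulin_motifs(c(s1 = "AAAGAT"))
  expect_equal(scan$summary$NODCON1GM, 1L)
  expect_equal(scan$summary$NODCON2GM, 0L)

  # overlapping occurrences all counted
  scan2 <- scan_nodulin_motifs(c(s1 = "CTCTTCTCTT"))
  expect_equal(scan2$summary$NODCON2GM, 2L)
  expect_equal(sort(scan2$hits$offset), c(0L, 5L))
  scan3 <- scan_nodulin_motifs(c(s1 = "CTCTCTT"))
  expect_equal(scan3$summary$NODCON2GM, 1L)
  expect_equal(scan3$hits$offset, 2L)

  # case-insensitive; ambiguity codes never match; per-record scanning
  expect_equal(scan_nodulin_motifs(c(s = "ctcttaaagat"))$summary$total, 2L)
  expect_equal(scan_nodulin_motifs(c(s = "CTCTN"))$summary$total, 0L)
  two <- scan_nodulin_motifs(c(a = "AAAG", b = "AT"))  # no cross-record hit
  expect_equal(sum(two$summary$total), 0L)

  # brute-force sliding-window oracle on random sequences
  set.seed(8)
  for (i in 1:5) {
    s <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE), collapse = "")
    got <- scan_nodulin_motifs(setNames(s, "r"))$summary
    brute <- function(pat) sum(vapply(
      seq_len(nchar(s) - nchar(pat) + 1),
      function(i) substr(s, i, i + nchar(pat) - 1) == pat, logical(1)))
    expect_equal(got$NODCON1GM, brute("AAAGAT"))
    expect_equal(got$NODCON2GM, brute("CTCTT"))
  }

  # optional reverse-strand scan finds the reverse complement
  rc <- scan_nodulin_motifs(c(s = "ATCTTT"), scan_reverse = TRUE)  # revcomp AAAGAT
  expect_equal(rc$summary$NODCON1GM, 1L)
  expect_equal(rc$hits$strand, "-")
})
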