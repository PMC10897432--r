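mk_gene <- function(id, start, end, strand, biotype = "protein_coding",
                    chrom = "chr1") {
  tibble::tibble(gene_id = id, chrom = chrom, start = as.integer(start),
                 end = as.integer(end), strand = strand, biotype = biotype)
}

test_that("TSS assignment honours the window, fraction and UTR rules", {
  ann <- toy_annotation(mk_gene("g1", 5000L, 7000L, "+"))
  p <- toy_peaks(c(4900L,   # 100 bp upstream: rule (b)
                   5400L,   # 20% into a 2 kb transcript: rule (c)
                   6500L,   # 75% in, 1.5 kb from TSS: fails all three
                   4400L),  # 600 bp upstream: outside the window
                 "+")
  out <- assign_tss(p, ann)
  expect_equal(out$assigned_gene, c("g1", "g1", NA, NA))
})

test_that("TSS assignment is strand-aware and works on the minus strand", {
  ann <- toy_annotation(mk_gene("g1", 5000L, 7000L, "-"))
  p <- toy_peaks(c(7100L, 6700L, 5400L, 6999L), c("-", "-", "-", "+"))
  out <- assign_tss(p, ann)
  # 100 bp upstream (rightward), 15% into the body, 80% in, wrong strand
  expect_equal(out$assigned_gene, c("g1", "g1", NA, NA))
})

test_that("the annotated 5' UTR assigns peaks beyond the windows", {
  tx <- tibble::tibble(tx_id = "t1", gene_id = "g1", chrom = "chr1",
                       start = 5000L, end = 15000L, strand = "+",
                       utr5_start = 5000L, utr5_end = 8100L)
  ann <- toy_annotation(mk_gene("g1", 5000L, 15000L, "+"), transcripts = tx)
  p <- toy_peaks(8000L, "+")  # 30% in and 3 kb from the TSS: only the UTR
  expect_equal(assign_tss(p, ann)$assigned_gene, "g1")
})

test_that("competing transcripts resolve by nearest TSS then gene id", {
  genes <- dplyr::bind_rows(mk_gene("gB", 4800L, 7000L, "+"),
                            mk_gene("gA", 5200L, 9000L, "+"))
  ann <- toy_annotation(genes)
  out <- assign_tss(toy_peaks(5150L, "+"), ann)
  expect_equal(out$assigned_gene, "gA")  # 50 bp vs 350 bp
  tie <- toy_annotation(dplyr::bind_rows(mk_gene("gZ", 5000L, 7000L, "+"),
                                         mk_gene("gA2", 5000L, 8000L, "+")))
  expect_equal(assign_tss(toy_peaks(5100L, "+"), tie)$assigned_gene, "gA2")
})

test_that("TSS categories follow the biotype lists and transcript rescue", {
  genes <- dplyr::bind_rows(
    mk_gene("pc", 1000L, 4000L, "+", "protein_coding"),
    mk_gene("lnc", 10000L, 13000L, "+", "antisense_long_non_coding_rna"),
    mk_gene("mir", 20000L, 23000L, "+", "miRNA"),
    mk_gene("odd", 30000L, 33000L, "+", "mystery_rna")
  )
  ann <- toy_annotation(genes)
  p <- toy_peaks(c(1000L, 10000L, 20000L, 30000L, 50000L, 60000L), "+")
  p <- assign_tss(p, ann)
  rtx <- tibble::tibble(tx_id = "r1", chrom = "chr1", start = 50030L,
                        end = 50500L, strand = "+")
  expect_warning(out <- categorize_tss(p, ann, rtx), "mystery_rna")
  expect_equal(out$category, c("mRNA", "lncRNA", "otherNcRNA", "otherNcRNA",
                               "putativeLncRNA", "unstable"))
})

test_that("every peak receives exactly one of the five categories", {
  withr::local_seed(12)
  biotypes <- c("protein_coding", "antisense_rna", "pseudogene", "miRNA",
                "small_nucleolar_rna", "long_noncoding_rna")
  genes <- tibble::tibble(
    gene_id = sprintf("g%03d", 1:40),
    chrom = "chr1",
    start = seq(1000L, by = 2000L, length.out = 40),
    end = seq(1000L, by = 2000L, length.out = 40) + 1500L,
    strand = sample(c("+", "-"), 40, replace = TRUE),
    biotype = sample(biotypes, 40, replace = TRUE)
  )
  ann <- toy_annotation(genes)
  p <- toy_peaks(sample.int(90000L, 300), sample(c("+", "-"), 300, TRUE))
  p$peak_id <- sprintf("pk%03d", seq_len(nrow(p)))
  out <- categorize_tss(assign_tss(p, ann), ann)
  expect_true(all(out$category %in% tss_categories()))
  expect_equal(sum(table(out$category)), 300L)
})

test_that("transcript filtering drops short/far candidates, keeps longest", {
  peaks <- toy_peaks(c(1000L, 5000L), "+")
  cand <- tibble::tibble(
    tx_id = c("short", "far", "a300", "a500"),
    chrom = "chr1",
    start = c(1000L, 5060L, 1010L, 1020L),
    end = c(1150L, 5400L, 1310L, 1520L),
    strand = "+"
  )
  out <- filter_transcripts(cand, peaks)
  expect_equal(out$tx_id, "a500")
})

test_that("ACR ladder applies priorities and matches the rule-order oracle", {
  genes <- mk_gene("g1", 1000L, 6000L, "+")
  ann <- toy_annotation(genes)
  peaks <- toy_peaks(c(1000L, 3000L), c("+", "-"), assigned_gene = "g1")
  te <- tibble::tibble(chrom = "chr1", start = 4000L, end = 4500L)
  acrs <- tibble::tibble(
    peak_id = sprintf("a%d", 1:4), chrom = "chr1",
    summit = c(900L,    # promoter window of the gene TSS (inside gene? no)
               4200L,   # inside gene AND TE -> TE
               2000L,   # inside gene only -> Intragenic
               50000L)  # open space -> Intergenic
  )
  out <- annotate_acr(acrs, ann, te, peaks)
  expect_equal(out$annotation, c("Promoter", "TE", "Intragenic", "Intergenic"))
  # summit inside gene AND inside a detected promoter window -> Promoter
  out2 <- annotate_acr(tibble::tibble(peak_id = "x", chrom = "chr1",
                                      summit = 3100L), ann, te, peaks)
  expect_equal(out2$annotation, "Promoter")

  withr::local_seed(13)
  for (k in 1:20) {
    racrs <- tibble::tibble(peak_id = sprintf("r%02d", 1:40), chrom = "chr1",
                            summit = sample.int(60000L, 40))
    got <- annotate_acr(racrs, ann, te, peaks)$annotation
    want <- acr_ladder_oracle(racrs, genes, te, peaks)
    expect_equal(got, want)
  }
})
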