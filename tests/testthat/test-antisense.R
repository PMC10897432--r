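as_setup <- function(gene_strand = "+") {
  genes <- tibble::tibble(gene_id = "g1", chrom = "chr1", start = 10000L,
                          end = 14000L, strand = gene_strand,
                          biotype = "protein_coding")
  toy_annotation(genes)
}

# peaks: one sense mRNA peak at the gene TSS plus one candidate nc peak
as_peaks <- function(nc_summit, nc_strand, ann) {
  g <- ann$genes
  tss <- if (g$strand == "+") g$start else g$end - 1L
  tibble::tibble(
    peak_id = c("sense", "anti"),
    chrom = "chr1",
    start = c(tss, nc_summit) - 75L,
    end = c(tss, nc_summit) + 76L,
    strand = c(g$strand, nc_strand),
    summit = c(tss, as.integer(nc_summit)),
    category = c("mRNA", "unstable"),
    assigned_gene = c("g1", NA)
  )
}

as_cpm <- function() toy_cpm(list(sense = c(40, 30, 20, 10, 5, 2),
                                  anti = c(5, 4, 3, 2, 1, 1)))

test_that("antisense pairing needs the opposite strand within body + 200 bp", {
  ann <- as_setup("+")
  inside <- find_antisense(as_peaks(11600L, "-", ann), ann, as_cpm(),
                           WT_SAMPLES)
  expect_equal(nrow(inside), 1L)
  expect_equal(inside$gene_id, "g1")
  expect_equal(inside$distance_from_gene_tss, 1600L)

  past_tts <- find_antisense(as_peaks(14149L, "-", ann), ann, as_cpm(),
                             WT_SAMPLES)
  expect_equal(nrow(past_tts), 1L)  # 150 bp downstream of the TTS

  too_far <- find_antisense(as_peaks(14250L, "-", ann), ann, as_cpm(),
                            WT_SAMPLES)
  expect_equal(nrow(too_far), 0L)  # 250 bp: outside the extension

  same_strand <- find_antisense(as_peaks(11600L, "+", ann), ann, as_cpm(),
                                WT_SAMPLES)
  expect_equal(nrow(same_strand), 0L)
})

test_that("antisense pairing works for minus-strand host genes", {
  ann <- as_setup("-")
  out <- find_antisense(as_peaks(12000L, "+", ann), ann, as_cpm(),
                        WT_SAMPLES)
  expect_equal(out$distance_from_gene_tss, 13999L - 12000L)
  ext <- find_antisense(as_peaks(9850L, "+", ann), ann, as_cpm(),
                        WT_SAMPLES)
  expect_equal(nrow(ext), 1L)  # 150 bp past the (leftward) TTS
})

test_that("overlapping hosts resolve to the nearest gene TSS and the
           representative sense peak is the highest expressed", {
  genes <- tibble::tibble(
    gene_id = c("far", "near"), chrom = "chr1",
    start = c(10000L, 11500L), end = c(20000L, 14000L), strand = "+",
    biotype = "protein_coding"
  )
  ann <- toy_annotation(genes)
  peaks <- tibble::tibble(
    peak_id = c("s_far_lo", "s_far_hi", "s_near", "anti"),
    chrom = "chr1",
    start = c(10000L, 10050L, 11500L, 12000L) - 75L,
    end = c(10000L, 10050L, 11500L, 12000L) + 76L,
    strand = c("+", "+", "+", "-"),
    summit = c(10000L, 10050L, 11500L, 12000L),
    category = c("mRNA", "mRNA", "mRNA", "unstable"),
    assigned_gene = c("far", "far", "near", NA)
  )
  cpm <- toy_cpm(list(s_far_lo = rep(5, 6), s_far_hi = rep(50, 6),
                      s_near = rep(8, 6), anti = rep(2, 6)))
  out <- find_antisense(peaks, ann, cpm, WT_SAMPLES)
  expect_equal(out$gene_id, "near")  # 500 bp vs 2 kb to the gene TSS
  # move the nc summit where only "far" hosts it: the representative sense
  # peak is far's highest-expressed assigned peak
  peaks2 <- peaks
  peaks2$summit[4] <- 10500L
  peaks2$start[4] <- 10500L - 75L
  peaks2$end[4] <- 10500L + 76L
  out2 <- find_antisense(peaks2, ann, cpm, WT_SAMPLES)
  expect_equal(out2$gene_id, "far")
  expect_equal(out2$sense_peak_id, "s_far_hi")
})

test_that("hosts without a detected sense TSS are dropped with a log entry", {
  ann <- as_setup("+")
  p <- as_peaks(11600L, "-", ann)
  p$assigned_gene[1] <- NA  # no detected sense TSS for g1
  expect_message(out <- find_antisense(p, ann, as_cpm(), WT_SAMPLES),
                 "dropped")
  expect_equal(nrow(out), 0L)
  expect_equal(attr(out, "dropped"), "g1")
})

test_that("proximal requires the first half of the body and > 1 kb from TTS", {
  pairs <- tibble::tibble(
    distance_from_gene_tss = c(1000L, 3500L, 600L, 2000L, 1999L),
    gene_length = c(4000L, 4000L, 1500L, 4000L, 4000L),
    distance_from_tts = c(3000L, 500L, 900L, 2000L, 1000L)
  )
  out <- classify_antisense(pairs)
  expect_equal(out$antisense_class,
               c("proximal",  # forced by the stated rule
                 "distal",    # second half
                 "distal",    # TTS clause fails (900 <= 1000)
                 "distal",    # exactly 50%: boundary goes distal
                 "distal"))   # exactly 1000 bp from TTS: boundary distal
})

test_that("classification is a total partition, stable under permutation", {
  withr::local_seed(17)
  L <- sample(seq(1500L, 6000L, 100L), 500, replace = TRUE)
  o <- vapply(L, function(l) sample.int(l + 200L, 1L) - 1L, integer(1))
  pairs <- tibble::tibble(distance_from_gene_tss = o, gene_length = L,
                          distance_from_tts = abs(L - 1L - o))
  out <- classify_antisense(pairs)
  expect_true(all(out$antisense_class %in% c("proximal", "distal")))
  perm <- sample.int(nrow(pairs))
  out2 <- classify_antisense(pairs[perm, ])
  expect_equal(out2$antisense_class, out$antisense_class[perm])
})

test_that("sense:antisense ratio uses masked maxima and flags zeros", {
  pairs <- tibble::tibble(sense_peak_id = c("s1", "s2", "s3"),
                          antisense_peak_id = c("a1", "a2", "a3"))
  cpm <- toy_cpm(list(s1 = c(40, 1, 1, 1, 1, 1), a1 = c(5, 2, 1, 1, 1, 1),
                      s2 = rep(7, 6), a2 = rep(7, 6),
                      s3 = rep(3, 6), a3 = rep(0, 6)))
  out <- sense_antisense_ratio(pairs, cpm, WT_SAMPLES)
  expect_equal(out$ratio_sense_over_antisense[1:2], c(8, 1))
  expect_true(is.na(out$ratio_sense_over_antisense[3]))
  expect_equal(out$ratio_defined, c(TRUE, TRUE, FALSE))
})

test_that("pair correlation handles perfect, inverted and constant profiles", {
  x <- c(1, 3, 2, 5, 4, 6)
  cpm <- toy_cpm(list(a = x, b = 2 * x + 1, c = mean(x) * 2 - x,
                      k = rep(4, 6)))
  pairs <- tibble::tibble(sense_peak_id = c("a", "a", "a"),
                          antisense_peak_id = c("b", "c", "k"))
  out <- pair_correlation(pairs, cpm, WT_SAMPLES)
  expect_equal(out$pearson_r, c(1, -1, NA_real_))
  expect_error(pair_correlation(pairs, cpm, WT_SAMPLES[1:2]), "3")
})

test_that("cluster enrichment reproduces the hand-computed statistic", {
  even <- cluster_enrichment(c(20, 20), c(100, 100), 0.2)
  expect_equal(unname(even$statistic), 0)
  expect_equal(even$p.value, 1)
  ex <- cluster_enrichment(c(30, 10), c(100, 100), 0.2)
  expect_equal(unname(ex$statistic), 10)
  expect_equal(unname(ex$parameter), 1)
  expect_error(cluster_enrichment(5, 10, 0.5), "at least 2")
  expect_error(cluster_enrichment(c(1, 1), c(10, 10), 0), "expected count")
})

test_that("cluster enrichment equals the textbook computation on random tables", {
  withr::local_seed(18)
  for (k in 1:100) {
    nk <- sample(2:8, 1)
    sizes <- sample(20:200, nk, replace = TRUE)
    frac <- runif(1, 0.05, 0.5)
    obs <- rbinom(nk, sizes, frac)
    got <- cluster_enrichment(obs, sizes, frac)
    want <- chisq_textbook(obs, frac * sizes)
    expect_equal(unname(got$statistic), want$stat)
    expect_equal(got$p.value, want$p)
  }
})

test_that("correlation partition respects the 0.5 / -0.25 bounds", {
  pairs <- tibble::tibble(pearson_r = c(0.6, -0.3, 0.1, NA, 0.5, -0.25))
  out <- partition_by_correlation(pairs)
  expect_equal(out$corr_group, c("positive", "negative", "other", "other",
                                 "other", "other"))
})
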