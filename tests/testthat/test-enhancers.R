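enh_annotation <- function() {
  genome_annotation(
    tibble::tibble(chrom = c("chr1", "chr2"), length = 100000L),
    tibble::tibble(gene_id = "g1", chrom = "chr1", start = 60000L,
                   end = 64000L, strand = "+", biotype = "protein_coding")
  )
}

test_that("nc-nc regions grow to 500 bp and wide pairs are kept", {
  ann <- enh_annotation()
  peaks <- toy_peaks(c(10000L, 10300L), c("-", "+"), "unstable")
  ncnc <- tibble::tibble(peak_a_id = "p001", peak_b_id = "p002",
                         chrom = "chr1", summit_a = 10000L,
                         summit_b = 10300L)
  out <- compile_enhancers(ncnc, NULL, peaks, ann)
  expect_equal(out$end - out$start, 500L)
  mid <- (out$start + out$end) / 2
  expect_equal(mid, (10000 + 10301) / 2, tolerance = 1)

  wide <- tibble::tibble(peak_a_id = "a", peak_b_id = "b", chrom = "chr1",
                         summit_a = 10000L, summit_b = 10799L)
  out2 <- compile_enhancers(wide, NULL, peaks, ann)
  expect_equal(out2$end - out2$start, 800L)
})

test_that("unidirectional sources give 500 bp centered regions", {
  ann <- enh_annotation()
  uni <- tibble::tibble(peak_id = "u1", chrom = "chr1", summit = 20000L)
  out <- compile_enhancers(NULL, uni, toy_peaks(500L, "+", "unstable"), ann)
  expect_equal(c(out$start, out$end), c(19750L, 20250L))
  expect_equal(out$source, "unidirectional_intergenic")
})

test_that("candidates overlapping pc promoter windows are trimmed or dropped", {
  ann <- enh_annotation()
  # pc peak at 60000 (+): promoter window [59600, 60101)
  pc <- toy_peaks(60000L, "+", "mRNA", assigned_gene = "g1")
  # candidate [59500, 60000): overlap leaves 100 bp -> dropped
  uni_drop <- tibble::tibble(peak_id = "u1", chrom = "chr1", summit = 59750L)
  expect_equal(nrow(compile_enhancers(NULL, uni_drop, pc, ann)), 0L)
  # candidate barely touching the window keeps its longest piece when the
  # remainder is still >= 500 bp
  ncnc <- tibble::tibble(peak_a_id = "a", peak_b_id = "b", chrom = "chr1",
                         summit_a = 58800L, summit_b = 59699L)
  out <- compile_enhancers(ncnc, NULL, pc, ann)
  expect_equal(nrow(out), 1L)
  expect_equal(out$end, 59600L)
  expect_gte(out$end - out$start, 500L)
})

test_that("regions past chromosome ends are clipped with a warning", {
  ann <- enh_annotation()
  uni <- tibble::tibble(peak_id = "u1", chrom = "chr1", summit = 99950L)
  expect_warning(out <- compile_enhancers(NULL, uni,
                                          toy_peaks(500L, "+", "unstable"),
                                          ann),
                 "clipped")
  # the clipped remainder falls under 500 bp and is dropped
  expect_equal(nrow(out), 0L)
})

test_that("activity sums both strands and is additive over partitions", {
  tr <- list(
    s1 = signal_track(tibble::tibble(
      chrom = "chr1", strand = c("+", "+", "-"),
      pos = c(1000L, 1200L, 1100L), value = c(5, 4, 3.5)
    )),
    s2 = empty_track()
  )
  enh <- tibble::tibble(enhancer_id = "e1", chrom = "chr1", start = 900L,
                        end = 1400L)
  act <- enhancer_activity(enh, tr)
  expect_equal(act["e1", "s1"], 12.5)
  expect_equal(act["e1", "s2"], 0)
  halves <- tibble::tibble(enhancer_id = c("h1", "h2"), chrom = "chr1",
                           start = c(900L, 1150L), end = c(1150L, 1400L))
  act_h <- enhancer_activity(halves, tr)
  expect_equal(sum(act_h[, "s1"]), act["e1", "s1"])
})

test_that("gene linking respects the 5 kb window and reports distances", {
  enh <- tibble::tibble(enhancer_id = "e1", chrom = "chr1", start = 10000L,
                        end = 10500L, source = "unidirectional_intergenic",
                        member_peaks = "u")
  peaks <- tibble::tibble(
    peak_id = c("near", "far", "inside"),
    chrom = "chr1",
    start = c(14000L, 17000L, 10100L) - 75L,
    end = c(14000L, 17000L, 10100L) + 76L,
    strand = "+",
    summit = c(14000L, 17000L, 10100L),
    category = "mRNA",
    assigned_gene = c("gn", "gf", "gi")
  )
  act <- matrix(c(1, 2, 3, 4, 5, 6), 1, dimnames = list("e1", WT_SAMPLES))
  cpm <- toy_cpm(list(near = c(2, 4, 6, 8, 10, 12), far = 1:6,
                      inside = rep(3, 6)))
  links <- enhancer_gene_correlations(enh, act, peaks, cpm, WT_SAMPLES)
  expect_setequal(links$gene_id, c("gn", "gi"))  # 6.5 kb gene excluded
  expect_equal(links$pearson_r[links$gene_id == "gn"], 1)
  expect_equal(links$distance[links$gene_id == "gi"], 0L)
  expect_true(is.na(links$pearson_r[links$gene_id == "gi"]))  # constant
})

test_that("target selection uses an inclusive 0.5 bound and deduplicates", {
  links <- tibble::tibble(
    enhancer_id = c("e1", "e2", "e3", "e4"),
    gene_id = c("g1", "g2", "g1", "g3"),
    pearson_r = c(0.5, 0.49, 0.6, NA)
  )
  expect_equal(select_target_genes(links), "g1")
  expect_equal(select_target_genes(links, r_min = 0.4), c("g1", "g2"))
})

test_that("the inter-chromosomal null is seeded and validates chromosomes", {
  withr::local_seed(41)
  enh <- tibble::tibble(
    enhancer_id = sprintf("e%02d", 1:6),
    chrom = rep(c("chr1", "chr2"), 3),
    start = seq(1000L, by = 2000L, length.out = 6),
    end = seq(1500L, by = 2000L, length.out = 6)
  )
  peaks <- toy_peaks(seq(500L, by = 3000L, length.out = 8), "+", "mRNA")
  peaks$chrom <- rep(c("chr1", "chr2"), 4)
  cpm <- matrix(runif(48, 1, 50), 8, 6,
                dimnames = list(peaks$peak_id, WT_SAMPLES))
  act <- matrix(runif(36, 1, 50), 6, 6,
                dimnames = list(enh$enhancer_id, WT_SAMPLES))
  r1 <- enhancer_null_correlations(enh, act, peaks, cpm, WT_SAMPLES,
                                   n_draws = 200, seed = 9)
  r2 <- enhancer_null_correlations(enh, act, peaks, cpm, WT_SAMPLES,
                                   n_draws = 200, seed = 9)
  expect_identical(r1, r2)
  expect_length(r1, 200L)
  expect_length(enhancer_null_correlations(enh, act, peaks, cpm, WT_SAMPLES,
                                           n_draws = 0, seed = 9), 0L)
  one_chr <- dplyr::mutate(enh, chrom = "chr1")
  one_pk <- dplyr::mutate(peaks, chrom = "chr1")
  expect_error(
    enhancer_null_correlations(one_chr, act, one_pk, cpm, WT_SAMPLES,
                               n_draws = 10, seed = 1),
    "2 chromosomes")
})

test_that("ranking is deterministic, disjoint and caps n", {
  enh <- tibble::tibble(enhancer_id = sprintf("e%02d", 1:10),
                        chrom = "chr1", start = 1:10 * 1000L,
                        end = 1:10 * 1000L + 600L)
  act <- matrix(c(10:1), 10, 1, dimnames = list(enh$enhancer_id, "L57"))
  expect_warning(rk <- rank_enhancers(enh, act, "L57", n = 500L), "capped")
  expect_equal(rk$top, sprintf("e%02d", 1:5))
  expect_equal(rk$bottom, sprintf("e%02d", 10:6))
  expect_length(intersect(rk$top, rk$bottom), 0L)
  perm <- sample.int(10)
  expect_warning(rk2 <- rank_enhancers(enh[perm, ], act, "L57", n = 500L))
  expect_equal(rk2$top, rk$top)
})
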