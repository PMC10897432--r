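test_that("summit is the maximum pileup with leftmost tie-break", {
  tr <- toy_track(c(10, 12, 20), c(5, 9, 3))
  expect_equal(find_summit(tr, "chr1", "+", 0, 100), 12L)
  tie <- toy_track(c(10, 12), c(5, 5))
  expect_equal(find_summit(tie, "chr1", "+", 0, 100), 10L)
  expect_error(find_summit(tr, "chr1", "-", 0, 100), "no signal")
})

test_that("width80 finds the smallest window holding 80% of read starts", {
  one <- toy_track(50, 10)
  expect_equal(width80(one, "chr1", "+", 0, 100), 1L)
  tr <- toy_track(c(100, 105, 110), c(50, 30, 20))
  expect_equal(width80(tr, "chr1", "+", 90, 120), 6L)
  ten <- toy_track(0:9, rep(1, 10))
  expect_equal(width80(ten, "chr1", "+", 0, 10), 8L)
})

test_that("width80 agrees with the O(N^2) brute-force oracle", {
  withr::local_seed(21)
  for (k in 1:200) {
    npos <- sample(1:30, 1)
    pos <- sort(sample.int(200L, npos))
    val <- sample(1:20, npos, replace = TRUE)
    tr <- toy_track(pos, val)
    expect_equal(width80(tr, "chr1", "+", 0, 201),
                 width80_bruteforce(pos, val))
  }
})

test_that("annotate_summits vectorizes and drops signal-free peaks", {
  tr <- toy_track(c(100, 105), c(5, 2))
  peaks <- tibble::tibble(peak_id = c("a", "b"), chrom = "chr1",
                          start = c(90L, 500L), end = c(120L, 530L),
                          strand = "+")
  expect_warning(out <- annotate_summits(peaks, tr), "no signal")
  expect_equal(out$peak_id, "a")
  expect_equal(out$summit, 100L)
})

test_that("TMM matches the edgeR oracle and honours its invariants", {
  skip_if_not_installed("edgeR")
  withr::local_seed(31)
  for (k in 1:20) {
    m <- matrix(stats::rnbinom(1200, mu = exp(runif(300, 1, 6)), size = 5),
                300, 4, dimnames = list(NULL, paste0("s", 1:4)))
    f_pkg <- tmm_normalize(m)$factors
    f_ref <- edgeR::calcNormFactors(edgeR::DGEList(counts = m))$samples$norm.factors
    expect_equal(unname(f_pkg), f_ref, tolerance = 1e-10)
  }
})

test_that("TMM gives unit factors for identical and proportional libraries", {
  a <- matrix(stats::rpois(200, 40), 100, 2,
              dimnames = list(NULL, c("x", "y")))
  a[, 2] <- a[, 1]
  expect_equal(unname(tmm_normalize(a)$factors), c(1, 1))
  b <- cbind(x = a[, 1], y = 2 * a[, 1])
  expect_equal(unname(tmm_normalize(b)$factors), c(1, 1))
})

test_that("TMM is scale-invariant and validates input", {
  withr::local_seed(5)
  m <- matrix(stats::rnbinom(900, mu = 60, size = 3), 300, 3,
              dimnames = list(NULL, c("a", "b", "c")))
  f1 <- tmm_normalize(m)$factors
  f2 <- tmm_normalize(m * 7L)$factors
  expect_equal(f1, f2, tolerance = 1e-9)
  expect_error(tmm_normalize(m[, 1, drop = FALSE]), "at least 2")
  m3 <- m
  m3[, 2] <- 0
  expect_error(tmm_normalize(m3), "all-zero sample")
})

test_that("CPM obeys count / (lib size x factor) x 1e6 and tidiers report it", {
  withr::local_seed(6)
  m <- matrix(stats::rnbinom(600, mu = 50, size = 4), 200, 3,
              dimnames = list(sprintf("f%03d", 1:200), c("a", "b", "c")))
  norm <- tmm_normalize(m)
  expect_equal(exp(mean(log(norm$factors))), 1, tolerance = 1e-9)
  expect_equal(norm$cpm[5, 2],
               m[5, 2] / (norm$lib_sizes[[2]] * norm$factors[[2]]) * 1e6)
  td <- tidy(norm)
  expect_equal(td$factor, unname(norm$factors))
  gl <- glance(norm)
  expect_equal(gl$n_features, 200L)
  expect_equal(gl$factor_geo_mean, 1, tolerance = 1e-9)
})

test_that("coefficient of variation uses n-1 sd and flags zero means", {
  m <- rbind(const = c(20, 20, 20), var = c(1, 2, 3), zero = c(0, 0, 0))
  cv <- feature_cv(m)
  expect_equal(unname(cv["const"]), 0)
  expect_equal(unname(cv["var"]), stats::sd(1:3) / 2)
  expect_true(is.na(cv["zero"]))
})

test_that("constitutive set filters on minimum CPM then keeps smallest CVs", {
  withr::local_seed(7)
  n <- 600L
  base <- runif(n, 60, 200)
  m <- sapply(1:6, function(s) base * (1 + rnorm(n, 0, 0.05 + (seq_len(n) / n) * 0.5)))
  rownames(m) <- sprintf("f%04d", seq_len(n))
  m <- pmax(m, 51)
  picked <- constitutive_features(m, min_cpm = 50, top_n = 500L)
  expect_length(picked, 500L)
  cv <- sort(feature_cv(m))
  expect_setequal(picked, names(cv)[1:500])

  low <- m
  low["f0001", 1] <- 49
  picked2 <- constitutive_features(low, min_cpm = 50, top_n = 500L)
  expect_false("f0001" %in% picked2)

  expect_warning(constitutive_features(m[1:10, ], min_cpm = 50, top_n = 500L),
                 "eligible")
})

test_that("heatmap rows are trimmed, rescaled and strand-subtracted", {
  # sense-only window: row in [0,1]; antisense-only: row in [-1,0]
  tr <- signal_track(tibble::tibble(
    chrom = "chr1", strand = c(rep("+", 3), rep("-", 2)),
    pos = c(100L, 101L, 104L, 200L, 203L), value = c(1, 5, 2, 4, 1)
  ))
  anchors <- tibble::tibble(chrom = "chr1", strand = "+",
                            anchor = c(102L, 201L, 500L))
  m <- heatmap_matrix(anchors, tr, flank = 5L)
  expect_true(all(m >= -1 & m <= 1))
  expect_true(all(m[1, ] >= 0))
  expect_true(all(m[2, ] <= 0))
  expect_equal(m[3, ], stats::setNames(rep(0, 11), colnames(m)))
})

test_that("heatmap trim/rescale matches a direct two-line recomputation", {
  v <- 0:9
  tr <- toy_track(100:109, v)
  m <- heatmap_matrix(tibble::tibble(chrom = "chr1", strand = "+",
                                     anchor = 104L),
                      tr, flank = 4L, trim_pct = 90)
  win <- track_window(tr, "chr1", "+", 100, 109)
  capped <- pmin(win, stats::quantile(win, 0.9, names = FALSE))
  oracle <- (capped - min(capped)) / (max(capped) - min(capped))
  expect_equal(unname(m[1, ]), oracle)
})

test_that("heatmap is invariant to spikes above the percentile cap", {
  withr::local_seed(8)
  pos <- 0:60
  val <- runif(61, 1, 10)
  val[31] <- 500  # already far above the 90th percentile cap
  anchor <- tibble::tibble(chrom = "chr1", strand = "+", anchor = 30L)
  m1 <- heatmap_matrix(anchor, toy_track(pos, val), flank = 30L)
  val2 <- val
  val2[31] <- val[31] * 10  # grows further above the cap: no effect
  m2 <- heatmap_matrix(anchor, toy_track(pos, val2), flank = 30L)
  expect_equal(m1, m2)
})

test_that("minus-strand windows are reversed and off-end windows flagged", {
  tr <- signal_track(
    tibble::tibble(chrom = "chr1", strand = "-", pos = c(48L, 50L),
                   value = c(1, 9)),
    chrom_lengths = c(chr1 = 60L)
  )
  m <- heatmap_matrix(tibble::tibble(chrom = "chr1", strand = "-",
                                     anchor = c(50L, 58L)),
                      tr, flank = 5L)
  # downstream of a minus-strand anchor is rightward after reversal
  expect_equal(unname(which.max(m[1, ])), 6L)  # summit at the anchor column
  expect_true(m[1, 8] > 0)             # the 48 bp hit lies downstream (+2)
  expect_equal(attr(m, "clipped"), c(FALSE, TRUE))
})
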