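pair_type_label <- function(cat_minus, cat_plus) {
  n_pc <- (cat_minus == "mRNA") + (cat_plus == "mRNA")
  c("ncTSS-ncTSS", "ncTSS-pcTSS", "pcTSS-pcTSS")[n_pc + 1L]
}

# all divergent candidate pairs (minus summit <= plus summit) up to max_dist
divergent_candidates <- function(peaks, max_dist) {
  assert_cols(peaks, c("peak_id", "chrom", "strand", "summit", "category"))
  minus <- peaks[peaks$strand == "-", ]
  plus <- peaks[peaks$strand == "+", ]
  cand <- dplyr::inner_join(
    dplyr::rename(minus[, c("peak_id", "chrom", "summit", "category")],
                  peak_a_id = "peak_id", summit_a = "summit",
                  category_a = "category"),
    dplyr::rename(plus[, c("peak_id", "chrom", "summit", "category")],
                  peak_b_id = "peak_id", summit_b = "summit",
                  category_b = "category"),
    by = "chrom", relationship = "many-to-many"
  )
  cand <- cand[cand$summit_a <= cand$summit_b &
                 cand$summit_b - cand$summit_a <= max_dist, , drop = FALSE]
  cand$inter_tss_distance <- cand$summit_b - cand$summit_a
  cand$pair_type <- pair_type_label(cand$category_a, cand$category_b)
  tibble::as_tibble(cand)
}

#' Detect bidirectional (divergent) promoter pairs
#'
#' Candidates are opposite-facing summit pairs - a minus-strand member at or
#' left of a plus-strand member (head-to-head, transcription pointing away) -
#' with inter-TSS distance (plus summit minus minus summit) at most
#' `bidir_max_dist` (500 bp). Each peak joins at most one pair: candidates
#' are accepted greedily by ascending distance, ties broken by the leftmost
#' minus-strand member. Pair types follow the members' categories (`mRNA`
#' counts as protein-coding, every other category as non-coding).
#'
#' @param peaks categorized TSS peaks with `summit`.
#' @param params an [analysis_params()].
#' @return Tibble with `peak_a_id` (minus member), `peak_b_id` (plus
#'   member), `pair_type` (`pcTSS-pcTSS`, `ncTSS-pcTSS`, `ncTSS-ncTSS`) and
#'   `inter_tss_distance`.
#' @export
find_bidirectional <- function(peaks, params = analysis_params()) {
  cand <- divergent_candidates(peaks, params$bidir_max_dist)
  cand <- cand[order(cand$inter_tss_distance, cand$chrom, cand$summit_a,
                     cand$peak_a_id, cand$peak_b_id), ]
  used <- character()
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    a <- cand$peak_a_id[i]
    b <- cand$peak_b_id[i]
    if (!(a %in% used) && !(b %in% used)) {
      keep[i] <- TRUE
      used <- c(used, a, b)
    }
  }
  out <- cand[keep, c("peak_a_id", "peak_b_id", "chrom", "summit_a",
                      "summit_b", "pair_type", "inter_tss_distance")]
  out[order(out$chrom, out$summit_a), ]
}

#' Correlation-versus-distance table for divergent candidates
#'
#' Enumerates all opposite-facing candidate pairs up to `max_dist` without
#' the 500 bp bidirectional cut and attaches the Pearson correlation between
#' member CPM profiles over the masked samples; smoothing/binning is left to
#' the plotting layer.
#'
#' @param peaks categorized TSS peaks with `summit`.
#' @param cpm CPM matrix with `peak_id` rownames.
#' @param mask non-mutant sample names.
#' @param max_dist maximum inter-TSS distance to enumerate (bp).
#' @return Tibble with `pair_type`, `inter_tss_distance`, `pearson_r`.
#' @export
correlation_distance_table <- function(peaks, cpm, mask, max_dist = 2000L) {
  cand <- divergent_candidates(peaks, max_dist)
  if (!nrow(cand)) {
    return(tibble::tibble(peak_a_id = character(), peak_b_id = character(),
                          pair_type = character(),
                          inter_tss_distance = integer(),
                          pearson_r = numeric()))
  }
  cand <- pair_correlation(cand, cpm, mask, cols = c("peak_a_id", "peak_b_id"))
  cand[, c("peak_a_id", "peak_b_id", "pair_type", "inter_tss_distance",
           "pearson_r")]
}

#' Expression ratio within a TSS pair
#'
#' Maximum CPM of the higher-expressing member divided by the maximum CPM of
#' the lower-expressing member over the masked samples (symmetric in member
#' order, always >= 1). Pairs whose lower maximum is 0 get `NA` and
#' `ratio_defined = FALSE`.
#'
#' @param pairs tibble with `peak_a_id`, `peak_b_id`.
#' @param cpm CPM matrix with `peak_id` rownames.
#' @param mask non-mutant sample names.
#' @return `pairs` with `max_cpm_ratio` and `ratio_defined`.
#' @export
max_cpm_ratio <- function(pairs, cpm, mask) {
  assert_cols(pairs, c("peak_a_id", "peak_b_id"))
  a <- unname(apply(cpm[pairs$peak_a_id, mask, drop = FALSE], 1L, max))
  b <- unname(apply(cpm[pairs$peak_b_id, mask, drop = FALSE], 1L, max))
  hi <- pmax(a, b)
  lo <- pmin(a, b)
  pairs$max_cpm_ratio <- ifelse(lo == 0, NA_real_, hi / lo)
  pairs$ratio_defined <- lo > 0
  pairs
}

#' Correlation groups of bidirectional pairs
#'
#' Splits pairs into `correlating` (r > bound), `anti-correlating`
#' (r < -bound) and `other` (including undefined correlations), reports the
#' median log2 expression ratio per group, and compares groups with
#' two-sided rank-sum tests under Holm correction. With all pairs in a
#' single group the comparison is skipped with a warning.
#'
#' @param pairs tibble with `pearson_r` and `max_cpm_ratio`.
#' @param bound strict group bound (default 0.25).
#' @return A list with `pairs` (input plus `corr_group`), `medians`
#'   (tibble of group medians of log2 ratio) and `tests` (tibble of
#'   pairwise Holm-adjusted rank-sum p-values, or NULL).
#' @export
corr_groups <- function(pairs, bound = 0.25) {
  assert_cols(pairs, c("pearson_r", "max_cpm_ratio"))
  pairs$corr_group <- dplyr::case_when(
    is.na(pairs$pearson_r) ~ "other",
    pairs$pearson_r > bound ~ "correlating",
    pairs$pearson_r < -bound ~ "anti-correlating",
    TRUE ~ "other"
  )
  ok <- !is.na(pairs$max_cpm_ratio)
  medians <- pairs[ok, ] |>
    dplyr::group_by(corr_group = .data$corr_group) |>
    dplyr::summarise(n = dplyr::n(),
                     median_log2_ratio = stats::median(log2(.data$max_cpm_ratio)),
                     .groups = "drop")
  groups <- unique(pairs$corr_group[ok])
  tests <- NULL
  if (length(groups) < 2L) {
    warning("all pairs fall in one correlation group; comparison skipped")
  } else {
    combos <- utils::combn(sort(groups), 2L)
    p <- apply(combos, 2L, function(g) {
      x <- log2(pairs$max_cpm_ratio[ok & pairs$corr_group == g[1]])
      y <- log2(pairs$max_cpm_ratio[ok & pairs$corr_group == g[2]])
      stats::wilcox.test(x, y, exact = FALSE)$p.value
    })
    tests <- tibble::tibble(group_a = combos[1, ], group_b = combos[2, ],
                            p_value = p,
                            p_adjusted = stats::p.adjust(p, method = "holm"))
  }
  list(pairs = pairs, medians = medians, tests = tests)
}

#' Strand-subtracted heatmap over TSS pairs
#'
#' Delegates to [heatmap_matrix()] with one window per pair, anchored on the
#' protein-coding member's summit for divergent (nc-pc) pairs and on the
#' pair midpoint for nc-nc and pc-pc pairs, rows ordered by ascending
#' inter-TSS distance.
#'
#' @param pairs output of [find_bidirectional()].
#' @param peaks the peak table the pairs refer to.
#' @param track a [signal_track()].
#' @param flank half-window size (bp).
#' @param trim_pct percentile cap, see [heatmap_matrix()].
#' @return A `signal_heatmap` matrix, rows sorted by distance.
#' @export
paired_heatmap <- function(pairs, peaks, track, flank = 1000L, trim_pct = 90) {
  assert_cols(pairs, c("peak_a_id", "peak_b_id", "pair_type",
                       "inter_tss_distance"))
  idx <- stats::setNames(seq_len(nrow(peaks)), peaks$peak_id)
  pairs <- pairs[order(pairs$inter_tss_distance, pairs$peak_a_id), ]
  anchors <- purrr::pmap_dfr(
    list(pairs$peak_a_id, pairs$peak_b_id, pairs$pair_type),
    function(a, b, type) {
      pa <- peaks[idx[a], ]
      pb <- peaks[idx[b], ]
      if (type == "ncTSS-pcTSS") {
        pc <- if (pa$category == "mRNA") pa else pb
        tibble::tibble(chrom = pc$chrom, strand = pc$strand, anchor = pc$summit)
      } else {
        tibble::tibble(chrom = pa$chrom, strand = "+",
                       anchor = as.integer((pa$summit + pb$summit) %/% 2))
      }
    }
  )
  heatmap_matrix(anchors, track, flank = flank, trim_pct = trim_pct)
}
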