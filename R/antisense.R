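#' Detect antisense TSSs of protein-coding genes
#'
#' Pairs each non-coding TSS peak whose summit lies on the antisense strand
#' of a protein-coding gene body (extended 200 bp past the TTS) with that
#' gene. A non-coding summit inside several gene bodies is paired with the
#' gene whose annotated TSS is closest to the summit. The gene's
#' representative sense TSS is its assigned peak with the highest maximum
#' CPM across the masked (non-mutant) samples; genes with no detected sense
#' TSS are dropped and reported in the `dropped` attribute.
#'
#' @param peaks categorized TSS peaks (after [assign_tss()] and
#'   [categorize_tss()]), with `summit`.
#' @param annotation a [genome_annotation()].
#' @param cpm CPM matrix with `peak_id` rownames.
#' @param mask character vector of non-mutant sample names.
#' @param params an [analysis_params()].
#' @return Tibble with one row per sense/antisense pair: `gene_id`,
#'   `sense_peak_id`, `antisense_peak_id`, `distance_from_gene_tss`,
#'   `distance_from_tts`, `gene_length`.
#' @export
find_antisense <- function(peaks, annotation, cpm, mask,
                           params = analysis_params()) {
  assert_cols(peaks, c("peak_id", "chrom", "strand", "summit", "category",
                       "assigned_gene"))
  genes <- annotation$genes[annotation$genes$biotype == "protein_coding", ]
  nc <- peaks[peaks$category != "mRNA", , drop = FALSE]
  ext <- params$antisense_tts_ext
  # representative sense peak per gene: highest max CPM over masked samples
  sense <- peaks[!is.na(peaks$assigned_gene) &
                   peaks$assigned_gene %in% genes$gene_id, ]
  sense$max_cpm <- if (nrow(sense)) {
    apply(cpm[sense$peak_id, mask, drop = FALSE], 1L, max)
  } else {
    numeric(0)
  }
  rep_sense <- sense |>
    dplyr::arrange(dplyr::desc(.data$max_cpm), .data$peak_id) |>
    dplyr::distinct(.data$assigned_gene, .keep_all = TRUE)
  rep_map <- stats::setNames(rep_sense$peak_id, rep_sense$assigned_gene)

  rows <- list()
  dropped <- character()
  for (i in seq_len(nrow(nc))) {
    s <- nc$summit[i]
    anti <- ifelse(genes$strand == "+", "-", "+")
    body_lo <- ifelse(genes$strand == "+", genes$start, genes$start - ext)
    body_hi <- ifelse(genes$strand == "+", genes$end + ext, genes$end)
    hit <- which(genes$chrom == nc$chrom[i] & nc$strand[i] == anti &
                   s >= body_lo & s < body_hi)
    if (!length(hit)) next
    g_tss <- tss_pos(genes$start[hit], genes$end[hit], genes$strand[hit])
    g <- hit[which.min(abs(s - g_tss))]
    gene_id <- genes$gene_id[g]
    if (is.na(rep_map[gene_id])) {
      dropped <- c(dropped, gene_id)
      next
    }
    t0 <- tss_pos(genes$start[g], genes$end[g], genes$strand[g])
    t1 <- tts_pos(genes$start[g], genes$end[g], genes$strand[g])
    rows[[length(rows) + 1L]] <- tibble::tibble(
      gene_id = gene_id,
      sense_peak_id = unname(rep_map[gene_id]),
      antisense_peak_id = nc$peak_id[i],
      distance_from_gene_tss = oriented_offset(s, t0, genes$strand[g]),
      distance_from_tts = abs(s - t1),
      gene_length = genes$end[g] - genes$start[g]
    )
  }
  out <- if (length(rows)) dplyr::bind_rows(rows) else tibble::tibble(
    gene_id = character(), sense_peak_id = character(),
    antisense_peak_id = character(), distance_from_gene_tss = integer(),
    distance_from_tts = integer(), gene_length = integer()
  )
  if (length(dropped)) {
    message(length(dropped), " antisense TSS(s) dropped: host gene without ",
            "a detected sense TSS")
  }
  attr(out, "dropped") <- unique(dropped)
  out
}

#' Classify antisense TSSs as proximal or distal
#'
#' Proximal when the antisense summit sits strictly within the first 50% of
#' the gene body (offset from the gene TSS `< 0.5 x` gene length) and
#' strictly more than 1 kb from the TTS; all others, including summits in
#' the 200 bp TTS extension, are distal. Boundary equalities resolve to
#' distal.
#'
#' @param pairs output of [find_antisense()].
#' @param params an [analysis_params()].
#' @return `pairs` with an `antisense_class` column (`proximal`/`distal`).
#' @export
classify_antisense <- function(pairs, params = analysis_params()) {
  assert_cols(pairs, c("distance_from_gene_tss", "distance_from_tts",
                       "gene_length"))
  pairs$antisense_class <- ifelse(
    pairs$distance_from_gene_tss < params$proximal_frac * pairs$gene_length &
      pairs$distance_from_tts > params$proximal_tts_min,
    "proximal", "distal"
  )
  pairs
}

#' Sense-to-antisense expression ratio
#'
#' Ratio of the maximum CPM of the sense TSS to the maximum CPM of the
#' antisense TSS across the masked (non-mutant) samples. Pairs whose
#' antisense maximum is 0 get `NA` and `ratio_defined = FALSE`.
#'
#' @param pairs output of [find_antisense()] (or downstream).
#' @param cpm CPM matrix with `peak_id` rownames.
#' @param mask non-mutant sample names.
#' @return `pairs` with `ratio_sense_over_antisense` and `ratio_defined`.
#' @export
sense_antisense_ratio <- function(pairs, cpm, mask) {
  assert_cols(pairs, c("sense_peak_id", "antisense_peak_id"))
  s <- unname(apply(cpm[pairs$sense_peak_id, mask, drop = FALSE], 1L, max))
  a <- unname(apply(cpm[pairs$antisense_peak_id, mask, drop = FALSE], 1L, max))
  pairs$ratio_sense_over_antisense <- ifelse(a == 0, NA_real_, s / a)
  pairs$ratio_defined <- a > 0
  pairs
}

#' Pearson correlation between pair members
#'
#' Sample Pearson correlation between the two members' CPM profiles over the
#' masked samples. Constant profiles give `NA` (the undefined flag); fewer
#' than three masked samples is an error.
#'
#' @param pairs tibble with two peak-id columns.
#' @param cpm CPM matrix with `peak_id` rownames.
#' @param mask non-mutant sample names.
#' @param cols names of the two peak-id columns.
#' @return `pairs` with a `pearson_r` column.
#' @export
pair_correlation <- function(pairs, cpm, mask,
                             cols = c("sense_peak_id", "antisense_peak_id")) {
  assert_cols(pairs, cols)
  if (length(mask) < 3L) stop("need at least 3 masked samples")
  sub <- cpm[, mask, drop = FALSE]
  pairs$pearson_r <- vapply(seq_len(nrow(pairs)), function(i) {
    safe_cor(sub[pairs[[cols[1]]][i], ], sub[pairs[[cols[2]]][i], ])
  }, numeric(1))
  pairs
}

#' Observed-vs-expected chi-square across expression clusters
#'
#' Compares the observed number of antisense TSSs per cluster with the
#' expected number (global antisense fraction x cluster size) using the
#' chi-square statistic `sum((obs - exp)^2 / exp)` on `k - 1` degrees of
#' freedom.
#'
#' @param observed integer vector of antisense counts per cluster.
#' @param sizes cluster sizes (> 0).
#' @param fraction global fraction of clustered TSSs that are antisense.
#' @return A list of class `htest` with `statistic`, `parameter` (df),
#'   `p.value`, `observed` and `expected`.
#' @export
cluster_enrichment <- function(observed, sizes, fraction) {
  if (length(observed) != length(sizes)) stop("observed/sizes length mismatch")
  if (length(observed) < 2L) stop("need at least 2 clusters (df would be 0)")
  if (any(sizes <= 0)) stop("cluster sizes must be positive")
  expected <- fraction * sizes
  if (any(expected == 0)) stop("expected count of 0 in some cluster")
  stat <- sum((observed - expected)^2 / expected)
  df <- length(observed) - 1L
  structure(
    list(statistic = c("X-squared" = stat), parameter = c(df = df),
         p.value = stats::pchisq(stat, df, lower.tail = FALSE),
         observed = observed, expected = expected,
         method = "Chi-square test of observed vs expected antisense counts",
         data.name = "observed antisense TSSs per cluster"),
    class = "htest"
  )
}

#' Partition pairs by correlation sign
#'
#' Adds a `corr_group` column: `positive` when `pearson_r > pos`, `negative`
#' when `pearson_r < neg`, otherwise (including undefined correlations)
#' `other`. Defaults match the sense/antisense analysis (r > 0.5 vs
#' r < -0.25); bidirectional promoter groups use `pos = 0.25`.
#'
#' @param pairs tibble with a `pearson_r` column.
#' @param pos,neg strict thresholds.
#' @return `pairs` with `corr_group`.
#' @export
partition_by_correlation <- function(pairs, pos = 0.5, neg = -0.25) {
  assert_cols(pairs, "pearson_r")
  pairs$corr_group <- dplyr::case_when(
    is.na(pairs$pearson_r) ~ "other",
    pairs$pearson_r > pos ~ "positive",
    pairs$pearson_r < neg ~ "negative",
    TRUE ~ "other"
  )
  pairs
}
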