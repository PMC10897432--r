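#' Density of sense:antisense expression ratios
#'
#' Log10-scale density of the per-pair ratio of maximum sense to maximum
#' antisense CPM, the summary whose genome-wide median is about 8:1.
#'
#' @param pairs output of [sense_antisense_ratio()].
#' @return A ggplot object.
#' @export
plot_ratio_density <- function(pairs) {
  assert_cols(pairs, "ratio_sense_over_antisense")
  df <- pairs[!is.na(pairs$ratio_sense_over_antisense), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$ratio_sense_over_antisense)) +
    ggplot2::geom_density() +
    ggplot2::geom_vline(
      xintercept = stats::median(df$ratio_sense_over_antisense),
      linetype = "dashed") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "max sense CPM / max antisense CPM", y = "density")
}

#' Pair correlation against inter-TSS distance
#'
#' @param candidates output of [correlation_distance_table()].
#' @return A ggplot object with a loess smooth per pair type.
#' @export
plot_correlation_distance <- function(candidates) {
  assert_cols(candidates, c("inter_tss_distance", "pearson_r", "pair_type"))
  df <- candidates[!is.na(candidates$pearson_r), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$inter_tss_distance,
                                   y = .data$pearson_r,
                                   colour = .data$pair_type)) +
    ggplot2::geom_point(alpha = 0.3, size = 0.8) +
    ggplot2::geom_smooth(method = "loess", formula = y ~ x, se = FALSE) +
    ggplot2::labs(x = "inter-TSS distance (bp)", y = "Pearson r",
                  colour = "pair type")
}

#' Observed enhancer-gene correlations against the inter-chromosomal null
#'
#' @param links output of [enhancer_gene_correlations()].
#' @param null_r vector from [enhancer_null_correlations()].
#' @param r_min the target-call threshold to mark.
#' @return A ggplot object with both densities.
#' @export
plot_enhancer_null <- function(links, null_r, r_min = 0.5) {
  df <- dplyr::bind_rows(
    tibble::tibble(r = links$pearson_r[!is.na(links$pearson_r)],
                   set = "intra-chromosomal (<= 5 kb)"),
    tibble::tibble(r = null_r[!is.na(null_r)], set = "inter-chromosomal null")
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$r, colour = .data$set)) +
    ggplot2::geom_density() +
    ggplot2::geom_vline(xintercept = r_min, linetype = "dashed") +
    ggplot2::labs(x = "Pearson r (enhancer activity vs pc TSS CPM)",
                  y = "density", colour = NULL)
}
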