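#' Classify features as exosome-sensitive or -insensitive
#'
#' Gates applied to a mutant-versus-wild-type differential table (positive
#' `log2fc` = higher in the mutant): `sensitive` when `log2fc >= 2`
#' (upregulated) and `qvalue < 0.05`; `insensitive` when `|log2fc| < 1`,
#' `qvalue > 0.05` and the feature's maximum expression exceeds 1 CPM
#' (csRNA-seq) or 0.1 TPM (total RNA-seq); everything else, including
#' `qvalue` exactly 0.05, is `unclassified`. The two gates are disjoint by
#' construction (`log2fc >= 2` vs `|log2fc| < 1`).
#'
#' @param de tibble from [read_de_table()]: `feature_id`, `log2fc`,
#'   `qvalue`, `max_expr`.
#' @param assay `"csRNA"` or `"totalRNA"` (selects the expression floor).
#' @param params an [analysis_params()].
#' @return `de` with a `call` column (`sensitive`/`insensitive`/
#'   `unclassified`).
#' @export
classify_exosome <- function(de, assay = c("csRNA", "totalRNA"),
                             params = analysis_params()) {
  assay <- match.arg(assay)
  assert_cols(de, c("feature_id", "log2fc", "qvalue", "max_expr"))
  if (any(de$qvalue < 0 | de$qvalue > 1)) stop("qvalue outside [0, 1]")
  floor_expr <- if (assay == "csRNA") params$exo_min_cpm else params$exo_min_tpm
  de$call <- dplyr::case_when(
    de$log2fc >= params$exo_lfc_sens & de$qvalue < params$exo_q ~ "sensitive",
    abs(de$log2fc) < params$exo_lfc_insens & de$qvalue > params$exo_q &
      de$max_expr > floor_expr ~ "insensitive",
    TRUE ~ "unclassified"
  )
  de
}

#' Hypergeometric overlap test between two feature sets
#'
#' Upper-tail probability of observing at least the given overlap when
#' drawing `|B|` features from a universe of `N` containing `|A|` marked
#' ones: `P(X >= overlap)` under Hypergeometric(N, |A|, |B|).
#'
#' @param set_a,set_b character vectors of feature ids (or their sizes, with
#'   `overlap` supplied).
#' @param universe universe size `N`.
#' @param overlap observed overlap; computed from the sets when they are
#'   given as vectors.
#' @return A list of class `htest` with the p-value and counts.
#' @export
exosome_overlap_test <- function(set_a, set_b, universe, overlap = NULL) {
  if (is.character(set_a) || is.character(set_b)) {
    overlap <- length(intersect(set_a, set_b))
    k_a <- length(unique(set_a))
    k_b <- length(unique(set_b))
  } else {
    k_a <- set_a
    k_b <- set_b
    if (is.null(overlap)) stop("overlap must be given with set sizes")
  }
  if (k_a > universe || k_b > universe) stop("set larger than universe")
  if (overlap > min(k_a, k_b)) stop("overlap exceeds the smaller set")
  if (overlap < k_a + k_b - universe) {
    stop("overlap smaller than forced by the universe size")
  }
  p <- stats::phyper(overlap - 1, k_a, universe - k_a, k_b,
                     lower.tail = FALSE)
  structure(
    list(statistic = c(overlap = overlap),
         parameter = c(N = universe, size_a = k_a, size_b = k_b),
         p.value = p,
         method = "Hypergeometric upper-tail overlap test",
         data.name = "feature set overlap"),
    class = "htest"
  )
}
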