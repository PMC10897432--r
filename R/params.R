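#' Analysis parameters
#'
#' All tunable thresholds of the pipeline in one place. Defaults are the
#' values used throughout the analysis: TSS-to-gene assignment windows
#' (500 bp upstream / 200 bp downstream of the annotated TSS, first 25% of
#' the transcript), the 200 bp TTS extension and proximal/distal rule for
#' antisense TSSs (first 50% of the gene body and > 1 kb from the TTS), the
#' 500 bp inter-TSS cap for bidirectional promoters, the 80% read-start
#' width, the 90th-percentile heatmap trim, transcript filters (>= 200 bp,
#' 5' end within 50 bp of a TSS peak), enhancer compilation (>= 500 bp
#' regions, 5 kb gene window, r >= 0.5 target call), correlation-group
#' bounds (+/- 0.25), exosome-sensitivity gates (|log2FC| >= 2 with
#' q < 0.05; insensitive |log2FC| < 1, q > 0.05 and minimum expression),
#' the constitutive-TSS selection (min 50 CPM, top 500 by CV), the ACR
#' promoter window (-400/+100 bp around a detected TSS) and the top/bottom
#' ranking size (500).
#'
#' @param ... named overrides for any default listed above.
#'
#' @return A named list of class `analysis_params`.
#' @examples
#' p <- analysis_params(bidir_max_dist = 400)
#' p$bidir_max_dist
#' @export
analysis_params <- function(...) {
  p <- list(
    assign_upstream    = 500L,
    assign_downstream  = 200L,
    assign_frac        = 0.25,
    antisense_tts_ext  = 200L,
    proximal_frac      = 0.5,
    proximal_tts_min   = 1000L,
    bidir_max_dist     = 500L,
    width_frac         = 0.8,
    heatmap_trim_pct   = 90,
    min_tx_len         = 200L,
    tx_tss_tol         = 50L,
    enhancer_min_width = 500L,
    enhancer_gene_window = 5000L,
    target_corr_min    = 0.5,
    corr_group_bound   = 0.25,
    exo_lfc_sens       = 2,
    exo_q              = 0.05,
    exo_lfc_insens     = 1,
    exo_min_cpm        = 1,
    exo_min_tpm        = 0.1,
    const_min_cpm      = 50,
    const_top_n        = 500L,
    acr_promoter_up    = 400L,
    acr_promoter_down  = 100L,
    rank_n             = 500L
  )
  dots <- list(...)
  bad <- setdiff(names(dots), names(p))
  if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
  p[names(dots)] <- dots
  dists <- c(
    "assign_upstream", "assign_downstream", "antisense_tts_ext",
    "proximal_tts_min", "bidir_max_dist", "min_tx_len", "tx_tss_tol",
    "enhancer_min_width", "enhancer_gene_window", "acr_promoter_up",
    "acr_promoter_down"
  )
  for (d in dists) {
    if (!is.numeric(p[[d]]) || length(p[[d]]) != 1L || p[[d]] <= 0 ||
        p[[d]] != as.integer(p[[d]])) {
      stop("parameter '", d, "' must be a positive integer distance")
    }
    p[[d]] <- as.integer(p[[d]])
  }
  for (f in c("assign_frac", "proximal_frac", "width_frac")) {
    if (!is.numeric(p[[f]]) || p[[f]] <= 0 || p[[f]] > 1) {
      stop("parameter '", f, "' must be a fraction in (0, 1]")
    }
  }
  structure(p, class = c("analysis_params", "list"))
}

#' Read or write analysis parameters as YAML
#'
#' @param path file path.
#' @param params an [analysis_params()] object.
#' @return `read_params()` returns an `analysis_params` object;
#'   `write_params()` returns `path` invisibly.
#' @export
read_params <- function(path) {
  do.call(analysis_params, yaml::read_yaml(path))
}

#' @rdname read_params
#' @export
write_params <- function(params, path) {
  yaml::write_yaml(unclass(params), path)
  invisible(path)
}
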