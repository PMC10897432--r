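# Biotype groups used for TSS category labels
LNC_BIOTYPES <- c(
  "antisense_long_non_coding_rna", "antisense_rna", "long_noncoding_rna",
  "novel_transcribed_region", "other_rna", "pseudogene",
  "transposable_element_gene"
)
SMALL_BIOTYPES <- c("miRNA", "pre_trna", "small_nuclear_rna",
                    "small_nucleolar_rna")

#' TSS categories
#'
#' The five labels a categorized peak can carry.
#' @return Character vector.
#' @export
tss_categories <- function() {
  c("mRNA", "lncRNA", "otherNcRNA", "putativeLncRNA", "unstable")
}

#' Assign TSS peaks to gene models
#'
#' A peak is assigned to a same-strand transcript when its summit is (a)
#' within the transcript's annotated 5' UTR, (b) between 500 bp upstream and
#' 200 bp downstream of the annotated TSS (in transcription orientation), or
#' (c) within the first 25% of the transcript length downstream of the
#' annotated TSS. When several transcripts match, the one whose annotated
#' TSS is nearest to the summit wins; remaining ties go to the
#' lexicographically smallest gene id. Unmatched peaks keep `NA`.
#'
#' @param peaks tibble with `peak_id`, `chrom`, `strand`, `summit`.
#' @param annotation a [genome_annotation()].
#' @param params an [analysis_params()].
#' @return `peaks` with `assigned_gene` and `assigned_tx` columns.
#' @export
assign_tss <- function(peaks, annotation, params = analysis_params()) {
  assert_cols(peaks, c("peak_id", "chrom", "strand", "summit"))
  tx <- annotation$transcripts
  tx$tss <- tss_pos(tx$start, tx$end, tx$strand)
  tx$len <- tx$end - tx$start
  hits <- dplyr::inner_join(
    dplyr::mutate(peaks[, c("peak_id", "chrom", "strand", "summit")],
                  .prow = dplyr::row_number()),
    tx, by = c("chrom", "strand"), relationship = "many-to-many"
  )
  o <- oriented_offset(hits$summit, hits$tss, hits$strand)
  in_utr <- !is.na(hits$utr5_start) & !is.na(hits$utr5_end) &
    hits$summit >= hits$utr5_start & hits$summit < hits$utr5_end
  in_window <- o >= -params$assign_upstream & o <= params$assign_downstream
  in_frac <- o >= 0 & o < params$assign_frac * hits$len
  hits <- hits[in_utr | in_window | in_frac, , drop = FALSE]
  hits$dist <- abs(hits$summit - hits$tss)
  best <- hits |>
    dplyr::arrange(.data$dist, .data$gene_id, .data$tx_id) |>
    dplyr::distinct(.data$.prow, .keep_all = TRUE)
  peaks$assigned_gene <- NA_character_
  peaks$assigned_tx <- NA_character_
  peaks$assigned_gene[best$.prow] <- best$gene_id
  peaks$assigned_tx[best$.prow] <- best$tx_id
  peaks
}

#' Label TSS peak categories
#'
#' Assigned peaks are labelled by the biotype of their gene: protein-coding
#' genes give `mRNA`; long non-coding biotypes (antisense lncRNA, lncRNA,
#' novel transcribed region, other RNA, pseudogene, TE gene) give `lncRNA`;
#' small-RNA biotypes (miRNA, pre-tRNA, snRNA, snoRNA) give `otherNcRNA`;
#' any other biotype falls back to `otherNcRNA` with a warning. Unassigned
#' peaks become `putativeLncRNA` when a reconstructed transcript starts
#' within `tx_tss_tol` (50 bp) of the summit on the same strand, and
#' `unstable` otherwise.
#'
#' @param peaks output of [assign_tss()].
#' @param annotation a [genome_annotation()].
#' @param transcripts optional tibble of reconstructed transcript candidates
#'   (`tx_id`, `chrom`, `start`, `end`, `strand`), e.g. from
#'   [filter_transcripts()].
#' @param params an [analysis_params()].
#' @return `peaks` with a `category` column.
#' @export
categorize_tss <- function(peaks, annotation, transcripts = NULL,
                           params = analysis_params()) {
  assert_cols(peaks, c("peak_id", "chrom", "strand", "summit", "assigned_gene"))
  biotype <- stats::setNames(annotation$genes$biotype, annotation$genes$gene_id)
  bt <- biotype[peaks$assigned_gene]
  category <- dplyr::case_when(
    is.na(peaks$assigned_gene) ~ NA_character_,
    bt == "protein_coding" ~ "mRNA",
    bt %in% LNC_BIOTYPES ~ "lncRNA",
    bt %in% SMALL_BIOTYPES ~ "otherNcRNA",
    TRUE ~ "otherNcRNA"
  )
  odd <- !is.na(bt) & !(bt %in% c("protein_coding", LNC_BIOTYPES, SMALL_BIOTYPES))
  if (any(odd)) {
    warning("biotype(s) outside the known lists labelled otherNcRNA: ",
            paste(unique(bt[odd]), collapse = ", "))
  }
  un <- which(is.na(category))
  if (length(un)) {
    near_tx <- rep(FALSE, length(un))
    if (!is.null(transcripts) && nrow(transcripts)) {
      t5 <- tss_pos(transcripts$start, transcripts$end, transcripts$strand)
      for (k in seq_along(un)) {
        i <- un[k]
        same <- transcripts$chrom == peaks$chrom[i] &
          transcripts$strand == peaks$strand[i]
        near_tx[k] <- any(same & abs(t5 - peaks$summit[i]) <= params$tx_tss_tol)
      }
    }
    category[un] <- ifelse(near_tx, "putativeLncRNA", "unstable")
  }
  peaks$category <- category
  peaks
}

#' Filter reconstructed transcript candidates
#'
#' Keeps candidates at least `min_tx_len` (200 bp) long whose 5' end lies
#' within `tx_tss_tol` (50 bp) of a same-strand TSS peak summit, then
#' resolves same-strand overlaps by keeping the longest candidate (ties to
#' the leftmost).
#'
#' @param candidates tibble with `tx_id`, `chrom`, `start`, `end`, `strand`.
#' @param peaks tibble of TSS peaks with `chrom`, `strand`, `summit`.
#' @param params an [analysis_params()].
#' @return Filtered candidate tibble.
#' @export
filter_transcripts <- function(candidates, peaks, params = analysis_params()) {
  assert_cols(candidates, c("tx_id", "chrom", "start", "end", "strand"))
  cand <- candidates[candidates$end - candidates$start >= params$min_tx_len, ,
                     drop = FALSE]
  if (!nrow(cand)) return(cand)
  t5 <- tss_pos(cand$start, cand$end, cand$strand)
  keep <- vapply(seq_len(nrow(cand)), function(i) {
    same <- peaks$chrom == cand$chrom[i] & peaks$strand == cand$strand[i]
    any(same & abs(peaks$summit - t5[i]) <= params$tx_tss_tol)
  }, logical(1))
  cand <- cand[keep, , drop = FALSE]
  if (nrow(cand) <= 1L) return(cand)
  cand <- cand[order(-(cand$end - cand$start), cand$start, cand$tx_id), ]
  accepted <- integer()
  for (i in seq_len(nrow(cand))) {
    overlaps <- FALSE
    for (j in accepted) {
      if (cand$chrom[i] == cand$chrom[j] && cand$strand[i] == cand$strand[j] &&
          cand$start[i] < cand$end[j] && cand$start[j] < cand$end[i]) {
        overlaps <- TRUE
        break
      }
    }
    if (!overlaps) accepted <- c(accepted, i)
  }
  out <- cand[sort(accepted), , drop = FALSE]
  out[order(out$chrom, out$start), ]
}

#' Annotate accessible chromatin regions by summit location
#'
#' Priority ladder applied to the ACR summit, later steps overwriting
#' earlier ones: (1) every peak starts `Intergenic`; (2) `Intragenic` when
#' the summit lies inside a gene detected in the csRNA-seq (a gene with at
#' least one assigned TSS peak); (3) `TE` when it lies inside a transposable
#' element interval; (4) `Promoter` when it lies in the promoter window
#' (-400 bp to +100 bp, transcription orientation) of any detected TSS peak
#' summit.
#'
#' @param acrs tibble with `peak_id`, `chrom`, `summit`.
#' @param annotation a [genome_annotation()].
#' @param te_intervals tibble with `chrom`, `start`, `end` (may be empty).
#' @param peaks categorized TSS peaks with `assigned_gene` and `summit`.
#' @param params an [analysis_params()].
#' @return `acrs` with an `annotation` column.
#' @export
annotate_acr <- function(acrs, annotation, te_intervals, peaks,
                         params = analysis_params()) {
  assert_cols(acrs, c("peak_id", "chrom", "summit"))
  label <- rep("Intergenic", nrow(acrs))
  detected_genes <- unique(peaks$assigned_gene[!is.na(peaks$assigned_gene)])
  g <- annotation$genes[annotation$genes$gene_id %in% detected_genes, ]
  up <- params$acr_promoter_up
  down <- params$acr_promoter_down
  for (i in seq_len(nrow(acrs))) {
    s <- acrs$summit[i]
    ch <- acrs$chrom[i]
    if (any(g$chrom == ch & s >= g$start & s < g$end)) label[i] <- "Intragenic"
    if (!is.null(te_intervals) && nrow(te_intervals) &&
        any(te_intervals$chrom == ch & s >= te_intervals$start &
              s < te_intervals$end)) {
      label[i] <- "TE"
    }
    o <- oriented_offset(s, peaks$summit, peaks$strand)
    if (any(peaks$chrom == ch & o >= -up & o <= down)) label[i] <- "Promoter"
  }
  acrs$annotation <- label
  acrs
}
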