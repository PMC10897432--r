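# pc promoter windows ([TSS-400, TSS+100] in transcription orientation) as
# 0-based half-open intervals, one per mRNA peak summit
pc_promoter_windows <- function(peaks, params) {
  pc <- peaks[peaks$category == "mRNA", , drop = FALSE]
  tibble::tibble(
    chrom = pc$chrom,
    start = ifelse(pc$strand == "+", pc$summit - params$acr_promoter_up,
                   pc$summit - params$acr_promoter_down),
    end = ifelse(pc$strand == "+", pc$summit + params$acr_promoter_down + 1L,
                 pc$summit + params$acr_promoter_up + 1L)
  )
}

# subtract a set of windows from [start, end); returns the longest remaining
# piece (ties leftmost) or NULL if nothing remains
trim_interval <- function(start, end, windows) {
  pieces <- list(c(start, end))
  for (i in seq_len(nrow(windows))) {
    ws <- windows$start[i]
    we <- windows$end[i]
    nxt <- list()
    for (p in pieces) {
      if (we <= p[1] || ws >= p[2]) {
        nxt[[length(nxt) + 1L]] <- p
        next
      }
      if (ws > p[1]) nxt[[length(nxt) + 1L]] <- c(p[1], ws)
      if (we < p[2]) nxt[[length(nxt) + 1L]] <- c(we, p[2])
    }
    pieces <- nxt
    if (!length(pieces)) return(NULL)
  }
  w <- vapply(pieces, function(p) p[2] - p[1], numeric(1))
  pieces[[which.max(w)]]
}

#' Compile candidate enhancer regions
#'
#' Candidates come from non-coding bidirectional (nc-nc) promoter pairs -
#' the region spanning both summits, grown symmetrically to at least
#' `enhancer_min_width` (500 bp) - and from intergenic non-coding
#' unidirectional TSSs - 500 bp centered on the summit. Candidates
#' overlapping a detected protein-coding promoter window (-400/+100 bp of an
#' mRNA peak summit) are trimmed away from it (the longest remaining piece
#' is kept) and dropped when less than 500 bp survives. Regions running off
#' a chromosome end are clipped with a warning.
#'
#' @param ncnc_pairs nc-nc rows of [find_bidirectional()] output.
#' @param uni_peaks tibble of intergenic unidirectional non-coding peaks
#'   (with `peak_id`, `chrom`, `summit`).
#' @param peaks the categorized TSS peak table (for promoter windows).
#' @param annotation a [genome_annotation()] (for chromosome bounds).
#' @param params an [analysis_params()].
#' @return Tibble with `enhancer_id`, `chrom`, `start`, `end`, `source`
#'   (`bidirectional_nc` / `unidirectional_intergenic`) and `member_peaks`
#'   (comma-separated peak ids).
#' @export
compile_enhancers <- function(ncnc_pairs, uni_peaks, peaks, annotation,
                              params = analysis_params()) {
  min_w <- params$enhancer_min_width
  cands <- list()
  if (!is.null(ncnc_pairs) && nrow(ncnc_pairs)) {
    assert_cols(ncnc_pairs, c("chrom", "summit_a", "summit_b", "peak_a_id",
                              "peak_b_id"))
    for (i in seq_len(nrow(ncnc_pairs))) {
      lo <- ncnc_pairs$summit_a[i]
      hi <- ncnc_pairs$summit_b[i] + 1L
      if (hi - lo < min_w) {
        mid <- (lo + hi) %/% 2L
        lo <- mid - min_w %/% 2L
        hi <- lo + min_w
      }
      cands[[length(cands) + 1L]] <- tibble::tibble(
        chrom = ncnc_pairs$chrom[i], start = lo, end = hi,
        source = "bidirectional_nc",
        member_peaks = paste(ncnc_pairs$peak_a_id[i], ncnc_pairs$peak_b_id[i],
                             sep = ",")
      )
    }
  }
  if (!is.null(uni_peaks) && nrow(uni_peaks)) {
    assert_cols(uni_peaks, c("peak_id", "chrom", "summit"))
    for (i in seq_len(nrow(uni_peaks))) {
      lo <- uni_peaks$summit[i] - min_w %/% 2L
      cands[[length(cands) + 1L]] <- tibble::tibble(
        chrom = uni_peaks$chrom[i], start = lo, end = lo + min_w,
        source = "unidirectional_intergenic",
        member_peaks = uni_peaks$peak_id[i]
      )
    }
  }
  if (!length(cands)) {
    return(tibble::tibble(enhancer_id = character(), chrom = character(),
                          start = integer(), end = integer(),
                          source = character(), member_peaks = character()))
  }
  out <- dplyr::bind_rows(cands)
  lens <- stats::setNames(annotation$chromosomes$length,
                          annotation$chromosomes$chrom)
  clip_lo <- out$start < 0
  clip_hi <- out$end > lens[out$chrom]
  if (any(clip_lo | clip_hi)) {
    warning(sum(clip_lo | clip_hi), " enhancer region(s) clipped to ",
            "chromosome bounds")
    out$start <- pmax(out$start, 0L)
    out$end <- pmin(out$end, unname(lens[out$chrom]))
  }
  prom <- pc_promoter_windows(peaks, params)
  kept <- purrr::map_dfr(seq_len(nrow(out)), function(i) {
    w <- prom[prom$chrom == out$chrom[i], , drop = FALSE]
    piece <- trim_interval(out$start[i], out$end[i], w)
    if (is.null(piece) || piece[2] - piece[1] < min_w) {
      return(tibble::tibble())
    }
    r <- out[i, ]
    r$start <- as.integer(piece[1])
    r$end <- as.integer(piece[2])
    r
  })
  if (!nrow(kept)) {
    return(tibble::tibble(enhancer_id = character(), chrom = character(),
                          start = integer(), end = integer(),
                          source = character(), member_peaks = character()))
  }
  kept <- kept[order(kept$chrom, kept$start), ]
  kept$enhancer_id <- sprintf("enh_%04d", seq_len(nrow(kept)))
  kept[, c("enhancer_id", "chrom", "start", "end", "source", "member_peaks")]
}

#' Per-sample enhancer activity
#'
#' Activity of a region in a sample is the sum of all signal over
#' `[start, end)` on both strands of that sample's (normalized) track.
#'
#' @param enhancers output of [compile_enhancers()].
#' @param tracks named list of [signal_track()]s, one per sample.
#' @return Numeric matrix, enhancers x samples, with `enhancer_id` rownames.
#' @export
enhancer_activity <- function(enhancers, tracks) {
  assert_cols(enhancers, c("enhancer_id", "chrom", "start", "end"))
  m <- vapply(tracks, function(tr) {
    vapply(seq_len(nrow(enhancers)), function(i) {
      track_sum(tr, enhancers$chrom[i], "+", enhancers$start[i], enhancers$end[i]) +
        track_sum(tr, enhancers$chrom[i], "-", enhancers$start[i], enhancers$end[i])
    }, numeric(1))
  }, numeric(nrow(enhancers)))
  if (nrow(enhancers) == 1L) {
    m <- matrix(m, nrow = 1L, dimnames = list(NULL, names(tracks)))
  }
  rownames(m) <- enhancers$enhancer_id
  m
}

#' Link enhancers to nearby protein-coding TSSs by correlation
#'
#' For every protein-coding TSS peak whose summit lies within
#' `enhancer_gene_window` (5 kb) of an enhancer's edges (distance 0 inside
#' the region), the Pearson correlation between the enhancer's activity and
#' the TSS CPM over the masked samples is computed.
#'
#' @param enhancers output of [compile_enhancers()].
#' @param activity matrix from [enhancer_activity()].
#' @param peaks categorized peak table (mRNA peaks are used).
#' @param cpm CPM matrix with `peak_id` rownames.
#' @param mask non-mutant sample names.
#' @param params an [analysis_params()].
#' @return Tibble with `enhancer_id`, `gene_id`, `peak_id`, `distance`,
#'   `pearson_r`.
#' @export
enhancer_gene_correlations <- function(enhancers, activity, peaks, cpm, mask,
                                       params = analysis_params()) {
  if (length(mask) < 3L) stop("need at least 3 masked samples")
  pc <- peaks[peaks$category == "mRNA" & !is.na(peaks$assigned_gene), ]
  links <- purrr::map_dfr(seq_len(nrow(enhancers)), function(i) {
    d <- pmax(0L, enhancers$start[i] - pc$summit,
              pc$summit - (enhancers$end[i] - 1L))
    near <- which(pc$chrom == enhancers$chrom[i] &
                    d <= params$enhancer_gene_window)
    if (!length(near)) return(tibble::tibble())
    act <- activity[enhancers$enhancer_id[i], mask]
    r <- row_cor(cpm[pc$peak_id[near], mask, drop = FALSE], act)
    tibble::tibble(
      enhancer_id = enhancers$enhancer_id[i],
      gene_id = pc$assigned_gene[near],
      peak_id = pc$peak_id[near],
      distance = d[near],
      pearson_r = r
    )
  })
  if (!nrow(links)) {
    links <- tibble::tibble(enhancer_id = character(), gene_id = character(),
                            peak_id = character(), distance = integer(),
                            pearson_r = numeric())
  }
  links
}

#' Inter-chromosomal null distribution of enhancer-gene correlations
#'
#' Draws `n_draws` uniform random (enhancer, protein-coding TSS) pairs
#' constrained to lie on different chromosomes and returns their Pearson
#' correlations; deterministic given `seed`.
#'
#' @inheritParams enhancer_gene_correlations
#' @param n_draws number of random pairs.
#' @param seed RNG seed.
#' @return Numeric vector of correlations (length `n_draws`; `NA` for
#'   degenerate constant profiles).
#' @export
enhancer_null_correlations <- function(enhancers, activity, peaks, cpm, mask,
                                       n_draws = 10000L, seed = 1L) {
  if (n_draws == 0L) return(numeric())
  pc <- peaks[peaks$category == "mRNA", ]
  cross_ok <- vapply(unique(enhancers$chrom),
                     function(ch) any(pc$chrom != ch), logical(1))
  if (length(unique(c(enhancers$chrom, pc$chrom))) < 2L || !all(cross_ok)) {
    stop("inter-chromosomal null needs at least 2 chromosomes")
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  ei <- sample.int(nrow(enhancers), n_draws, replace = TRUE)
  gi <- vapply(ei, function(i) {
    ok <- which(pc$chrom != enhancers$chrom[i])
    ok[sample.int(length(ok), 1L)]
  }, integer(1))
  act <- activity[, mask, drop = FALSE]
  sub <- cpm[, mask, drop = FALSE]
  vapply(seq_len(n_draws), function(k) {
    safe_cor(act[enhancers$enhancer_id[ei[k]], ], sub[pc$peak_id[gi[k]], ])
  }, numeric(1))
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Select enhancer target genes
#'
#' Protein-coding TSSs with a correlation of `r_min` (0.5) or greater to a
#' nearby enhancer, deduplicated.
#'
#' @param links output of [enhancer_gene_correlations()].
#' @param r_min inclusive correlation threshold.
#' @return Character vector of gene ids.
#' @export
select_target_genes <- function(links, r_min = 0.5) {
  assert_cols(links, c("gene_id", "pearson_r"))
  sort(unique(links$gene_id[!is.na(links$pearson_r) &
                              links$pearson_r >= r_min]))
}

#' Rank enhancers by activity in one sample
#'
#' Orders enhancers by activity in `sample` (descending, ties by id) and
#' returns the disjoint top-`n` and bottom-`n` sets; `n` is capped at half
#' the number of enhancers with a warning.
#'
#' @param enhancers output of [compile_enhancers()].
#' @param activity matrix from [enhancer_activity()].
#' @param sample sample name to rank in.
#' @param n set size.
#' @return A list with character vectors `top` and `bottom`.
#' @export
rank_enhancers <- function(enhancers, activity, sample, n = 500L) {
  ids <- enhancers$enhancer_id
  act <- activity[ids, sample]
  if (n > floor(length(ids) / 2)) {
    n <- floor(length(ids) / 2)
    warning("n capped at ", n, " (half the enhancer count)")
  }
  ord <- ids[order(-act, ids)]
  list(top = ord[seq_len(n)], bottom = rev(ord)[seq_len(n)])
}
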