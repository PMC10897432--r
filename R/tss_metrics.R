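#' Summit and 80%-width of a TSS peak
#'
#' `find_summit()` returns the single position of maximal read-start pileup
#' within `[start, end)` (ties broken leftmost). `width80()` returns the
#' length in bp of the smallest contiguous window inside the peak holding at
#' least `ceiling(fraction * N)` of the `N` read starts; among equal-length
#' minima the leftmost wins.
#'
#' @param track a [signal_track()] of 5' read-start counts.
#' @param chrom,strand,start,end the peak interval.
#' @param fraction fraction of read starts the window must contain.
#' @return `find_summit()` a 0-based position; `width80()` an integer bp.
#' @examples
#' tr <- signal_track(tibble::tibble(
#'   chrom = "c", strand = "+",
#'   pos = c(100L, 105L, 110L), value = c(50, 30, 20)
#' ))
#' find_summit(tr, "c", "+", 90, 120) # 100
#' width80(tr, "c", "+", 90, 120)     # 6
#' @export
find_summit <- function(track, chrom, strand, start, end) {
  s <- track_sparse(track, chrom, strand, start, end)
  if (!length(s$pos)) stop("no signal in peak ", chrom, ":", start, "-", end)
  s$pos[which.max(s$val)]
}

#' @rdname find_summit
#' @export
width80 <- function(track, chrom, strand, start, end, fraction = 0.8) {
  s <- track_sparse(track, chrom, strand, start, end)
  if (!length(s$pos)) stop("no signal in peak ", chrom, ":", start, "-", end)
  target <- ceiling(fraction * sum(s$val))
  cs <- c(0, cumsum(s$val))
  best <- Inf
  j <- 1L
  n <- length(s$pos)
  for (i in seq_len(n)) {
    if (j < i) j <- i
    while (j <= n && cs[j + 1L] - cs[i] < target) j <- j + 1L
    if (j > n) break
    w <- s$pos[j] - s$pos[i] + 1L
    if (w < best) best <- w
  }
  if (!is.finite(best)) best <- s$pos[n] - s$pos[1] + 1L
  as.integer(best)
}

#' Add summit and width columns to a peak table
#'
#' Vectorized application of [find_summit()] and [width80()] over a peak
#' tibble. Peaks with no signal in the track are dropped with a warning.
#'
#' @param peaks tibble with `peak_id`, `chrom`, `start`, `end`, `strand`.
#' @param track a [signal_track()] (typically all samples merged).
#' @param fraction width fraction, see [width80()].
#' @return `peaks` with `summit` and `width80` columns.
#' @export
annotate_summits <- function(peaks, track, fraction = 0.8) {
  assert_cols(peaks, c("peak_id", "chrom", "start", "end", "strand"))
  res <- purrr::pmap(
    list(peaks$chrom, peaks$strand, peaks$start, peaks$end),
    function(chrom, strand, start, end) {
      s <- track_sparse(track, chrom, strand, start, end)
      if (!length(s$pos)) return(c(NA_integer_, NA_integer_))
      c(find_summit(track, chrom, strand, start, end),
        width80(track, chrom, strand, start, end, fraction))
    }
  )
  peaks$summit <- vapply(res, `[[`, integer(1), 1L)
  peaks$width80 <- vapply(res, `[[`, integer(1), 2L)
  drop <- is.na(peaks$summit)
  if (any(drop)) {
    warning(sum(drop), " peak(s) with no signal dropped")
    peaks <- peaks[!drop, ]
  }
  peaks
}

#' Count read starts per peak and sample
#'
#' @param peaks tibble with `peak_id`, `chrom`, `start`, `end`, `strand`.
#' @param tracks named list of [signal_track()]s, one per sample.
#' @return Integer-valued matrix, peaks x samples.
#' @export
quantify_peaks <- function(peaks, tracks) {
  assert_cols(peaks, c("peak_id", "chrom", "start", "end", "strand"))
  m <- vapply(tracks, function(tr) {
    purrr::pmap_dbl(
      list(peaks$chrom, peaks$strand, peaks$start, peaks$end),
      function(chrom, strand, start, end) track_sum(tr, chrom, strand, start, end)
    )
  }, numeric(nrow(peaks)))
  if (nrow(peaks) == 1L) m <- matrix(m, nrow = 1L, dimnames = list(NULL, names(tracks)))
  rownames(m) <- peaks$peak_id
  m
}

# TMM factor for one sample against the reference, from the published
# definition: two-sided trimming of M (log ratio) at 30% and A (mean log
# abundance) at 5%, inverse approximate-asymptotic-variance weights.
tmm_pair_factor <- function(obs, ref, n_obs, n_ref,
                            logratio_trim = 0.3, sum_trim = 0.05) {
  log_r <- log2((obs / n_obs) / (ref / n_ref))
  abs_e <- (log2(obs / n_obs) + log2(ref / n_ref)) / 2
  v <- (n_obs - obs) / n_obs / obs + (n_ref - ref) / n_ref / ref
  fin <- is.finite(log_r) & is.finite(abs_e)
  log_r <- log_r[fin]; abs_e <- abs_e[fin]; v <- v[fin]
  if (max(abs(log_r)) < 1e-6) return(1)
  n <- length(log_r)
  lo_l <- floor(n * logratio_trim) + 1
  hi_l <- n + 1 - lo_l
  lo_s <- floor(n * sum_trim) + 1
  hi_s <- n + 1 - lo_s
  keep <- rank(log_r) >= lo_l & rank(log_r) <= hi_l &
    rank(abs_e) >= lo_s & rank(abs_e) <= hi_s
  f <- sum(log_r[keep] / v[keep], na.rm = TRUE) / sum(1 / v[keep], na.rm = TRUE)
  if (is.na(f)) f <- 0
  2^f
}

#' TMM normalization
#'
#' Trimmed-mean-of-M-values between-library normalization, computed from the
#' definition: the reference is the sample whose 75th count quantile (scaled
#' by library size) is closest to the mean across samples; per sample the
#' scaling factor is the weighted mean of M-values after trimming 30% on M
#' and 5% on A, with inverse approximate asymptotic variances as weights;
#' factors are rescaled to geometric mean 1. CPM for feature i in sample j is
#' `count / (library size x factor) x 1e6`.
#'
#' @param counts non-negative feature x sample count matrix (>= 2 samples).
#' @return An object of class `tmm_norm`: a list with `factors`,
#'   `lib_sizes`, `cpm` (matrix) and `reference` (sample name).
#' @export
tmm_normalize <- function(counts) {
  if (is.data.frame(counts)) counts <- as.matrix(counts)
  if (ncol(counts) < 2L) stop("TMM needs at least 2 samples")
  if (any(counts < 0)) stop("counts must be non-negative")
  lib <- colSums(counts)
  if (any(lib == 0)) {
    stop("all-zero sample(s): ",
         paste(colnames(counts)[lib == 0], collapse = ", "))
  }
  f75 <- apply(counts, 2L, stats::quantile, probs = 0.75) / lib
  ref <- which.min(abs(f75 - mean(f75)))
  f <- vapply(seq_len(ncol(counts)), function(j) {
    if (j == ref) return(1)
    tmm_pair_factor(counts[, j], counts[, ref], lib[j], lib[ref])
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  names(f) <- colnames(counts)
  cpm <- sweep(counts, 2L, lib * f, "/") * 1e6
  structure(
    list(factors = f, lib_sizes = lib, cpm = cpm,
         reference = colnames(counts)[ref] %||% ref),
    class = "tmm_norm"
  )
}

#' @export
print.tmm_norm <- function(x, ...) {
  cat("<tmm_norm> ", nrow(x$cpm), " features x ", ncol(x$cpm),
      " samples; reference: ", x$reference, "\n", sep = "")
  print(round(x$factors, 4))
  invisible(x)
}

#' Tidiers for TMM normalization results
#'
#' @param x a [tmm_normalize()] result.
#' @param ... unused.
#' @return `tidy()` one row per sample (scaling factor, library size);
#'   `glance()` a one-row summary.
#' @method tidy tmm_norm
#' @export
tidy.tmm_norm <- function(x, ...) {
  tibble::tibble(
    sample = names(x$factors) %||% as.character(seq_along(x$factors)),
    factor = unname(x$factors),
    lib_size = unname(x$lib_sizes)
  )
}

#' @rdname tidy.tmm_norm
#' @method glance tmm_norm
#' @export
glance.tmm_norm <- function(x, ...) {
  tibble::tibble(
    n_features = nrow(x$cpm),
    n_samples = ncol(x$cpm),
    reference = as.character(x$reference),
    factor_geo_mean = exp(mean(log(x$factors)))
  )
}

#' Coefficient of variation per feature
#'
#' CV = sample standard deviation (n - 1 denominator) / mean. Zero-mean rows
#' are undefined (`NA`).
#'
#' @param m feature x sample matrix.
#' @return Named numeric vector.
#' @export
feature_cv <- function(m) {
  if (!is.matrix(m)) m <- matrix(m, nrow = 1L)
  mu <- rowMeans(m)
  s <- apply(m, 1L, stats::sd)
  cv <- ifelse(mu == 0, NA_real_, s / mu)
  stats::setNames(cv, rownames(m))
}

#' Constitutively expressed feature set
#'
#' Features whose minimum expression across samples falls below `min_cpm`
#' (or whose CV is undefined) are removed; the remainder are ranked by
#' ascending coefficient of variation and the `top_n` most stable kept.
#'
#' @param cpm CPM matrix with feature rownames.
#' @param min_cpm minimum per-sample expression to be eligible.
#' @param top_n number of features to keep (all, with a warning, if fewer
#'   are eligible).
#' @return Character vector of feature ids, most stable first.
#' @export
constitutive_features <- function(cpm, min_cpm = 50, top_n = 500L) {
  eligible <- apply(cpm, 1L, min) >= min_cpm
  cv <- feature_cv(cpm[eligible, , drop = FALSE])
  cv <- cv[!is.na(cv)]
  if (length(cv) < top_n) {
    warning("only ", length(cv), " eligible features (requested ", top_n, ")")
  }
  names(sort(cv))[seq_len(min(top_n, length(cv)))]
}

#' Strand-subtracted heatmap matrix around anchors
#'
#' For each anchored window the per-strand signal is trimmed at the window's
#' `trim_pct` percentile, min-max rescaled to [0, 1] (all-equal windows map
#' to 0), and the rescaled antisense values are subtracted from the rescaled
#' sense values, giving rows in [-1, 1]. Windows of minus-strand anchors are
#' reversed so downstream is always rightward; windows running off a
#' chromosome end are zero-padded and flagged.
#'
#' @param anchors tibble with `chrom`, `strand` and `anchor` (0-based
#'   position, e.g. a peak summit or pair midpoint).
#' @param track a [signal_track()].
#' @param flank half-window size in bp; each row covers
#'   `[anchor - flank, anchor + flank]`.
#' @param trim_pct percentile (0-100) at which to cap values.
#' @return A numeric matrix of class `signal_heatmap` (rows = anchors,
#'   `2 * flank + 1` columns) with attribute `clipped` marking padded rows.
#' @export
heatmap_matrix <- function(anchors, track, flank = 1000L, trim_pct = 90) {
  assert_cols(anchors, c("chrom", "strand", "anchor"))
  width <- 2L * flank + 1L
  lens <- track$chrom_lengths
  clipped <- logical(nrow(anchors))
  rescale_row <- function(v, pct) {
    cap <- stats::quantile(v, pct / 100, names = FALSE)
    v <- pmin(v, cap)
    rng <- range(v)
    if (rng[1] == rng[2]) return(numeric(length(v)))
    (v - rng[1]) / (rng[2] - rng[1])
  }
  rows <- purrr::pmap(
    list(anchors$chrom, anchors$strand, anchors$anchor, seq_len(nrow(anchors))),
    function(chrom, strand, anchor, i) {
      lo <- anchor - flank
      hi <- anchor + flank + 1L
      pad_l <- max(0L, -lo)
      len <- if (!is.null(lens)) unname(lens[chrom]) else NA_integer_
      pad_r <- if (!is.na(len)) max(0L, hi - len) else 0L
      if (pad_l > 0L || pad_r > 0L) clipped[i] <<- TRUE
      qlo <- lo + pad_l
      qhi <- hi - pad_r
      anti <- if (strand == "+") "-" else "+"
      sense <- c(numeric(pad_l), track_window(track, chrom, strand, qlo, qhi),
                 numeric(pad_r))
      asense <- c(numeric(pad_l), track_window(track, chrom, anti, qlo, qhi),
                  numeric(pad_r))
      if (strand == "-") {
        sense <- rev(sense)
        asense <- rev(asense)
      }
      rescale_row(sense, trim_pct) - rescale_row(asense, trim_pct)
    }
  )
  m <- do.call(rbind, rows)
  colnames(m) <- as.character(seq(-flank, flank))
  structure(m, class = c("signal_heatmap", class(m)), clipped = clipped)
}

#' Plot a signal heatmap
#'
#' @param object a [heatmap_matrix()] result.
#' @param ... unused.
#' @return A ggplot object (rows in input order, position on the x axis).
#' @method autoplot signal_heatmap
#' @export
autoplot.signal_heatmap <- function(object, ...) {
  df <- tibble::tibble(
    row = rep(seq_len(nrow(object)), times = ncol(object)),
    pos = rep(as.integer(colnames(object)), each = nrow(object)),
    value = as.vector(object)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pos, y = .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", limits = c(-1, 1)) +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "position relative to anchor (bp)", y = NULL,
                  fill = "sense - antisense")
}
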