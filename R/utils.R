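# Internal helpers. All coordinates are 0-based half-open; conversion to/from
# the 1-based closed GFF3 convention happens only in read_gff3().

# 0-based TSS of an interval given its strand (+: start, -: end - 1)
tss_pos <- function(start, end, strand) {
  ifelse(strand == "+", start, end - 1L)
}

# 0-based TTS (the opposite terminus)
tts_pos <- function(start, end, strand) {
  ifelse(strand == "+", end - 1L, start)
}

# signed offset of position `pos` from `origin` in transcription orientation:
# positive downstream of a feature on `strand`
oriented_offset <- function(pos, origin, strand) {
  ifelse(strand == "+", pos - origin, origin - pos)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

assert_cols <- function(df, cols, what = deparse(substitute(df))) {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    stop(what, " is missing required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  invisible(df)
}

# Pearson correlation that returns NA (the undefined flag) instead of erroring
# or warning when either vector is constant.
safe_cor <- function(x, y) {
  if (length(x) < 3L) stop("need at least 3 samples for a correlation")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)
}

# rowwise Pearson correlation of each row of `m` against vector `y`
# (constant rows or constant y -> NA)
row_cor <- function(m, y) {
  if (!is.matrix(m)) m <- matrix(m, nrow = 1L)
  n <- ncol(m)
  if (n < 3L) stop("need at least 3 samples for a correlation")
  ym <- y - mean(y)
  ys <- sqrt(sum(ym^2))
  xm <- m - rowMeans(m)
  xs <- sqrt(rowSums(xm^2))
  r <- as.vector(xm %*% ym) / (xs * ys)
  r[xs == 0 | ys == 0] <- NA_real_
  unname(r)
}
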