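#' Strand-specific per-base signal tracks
#'
#' A `signal_track` stores, per chromosome and strand, a sparse mapping from
#' 0-based position to a non-negative value: raw csRNA-seq 5' read-start
#' counts or normalized (CPM-scaled) signal. The minus strand is stored as
#' magnitudes; strandedness is carried by the query, mirroring the
#' one-file-per-strand bedGraph convention.
#'
#' @param tbl a data frame with columns `chrom`, `strand` (`"+"`/`"-"`),
#'   `pos` (0-based integer) and `value` (non-negative). Duplicate positions
#'   are summed.
#' @param chrom_lengths optional named vector of chromosome lengths (bp);
#'   when supplied, positions are validated against it.
#'
#' @return An object of class `signal_track`.
#' @examples
#' tr <- signal_track(tibble::tibble(
#'   chrom = "chr1", strand = "+", pos = c(10L, 10L, 12L), value = c(1, 2, 5)
#' ))
#' track_window(tr, "chr1", "+", 10, 13) # 3 0 5
#' @export
signal_track <- function(tbl, chrom_lengths = NULL) {
  assert_cols(tbl, c("chrom", "strand", "pos", "value"), "signal track table")
  if (any(tbl$value < 0)) stop("signal values must be non-negative")
  if (!all(tbl$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  if (!is.null(chrom_lengths)) {
    len <- chrom_lengths[tbl$chrom]
    if (anyNA(len)) {
      stop("positions on undeclared chromosome(s): ",
           paste(unique(tbl$chrom[is.na(len)]), collapse = ", "))
    }
    if (any(tbl$pos < 0 | tbl$pos >= len)) {
      stop("positions outside declared chromosome bounds")
    }
  } else if (any(tbl$pos < 0)) {
    stop("positions must be >= 0")
  }
  key <- paste(tbl$chrom, tbl$strand, sep = "\t")
  index <- lapply(split(seq_len(nrow(tbl)), key), function(i) {
    v <- rowsum(tbl$value[i], tbl$pos[i], reorder = TRUE)
    list(pos = as.integer(rownames(v)), val = as.numeric(v))
  })
  structure(list(index = index, chrom_lengths = chrom_lengths),
            class = "signal_track")
}

empty_track <- function(chrom_lengths = NULL) {
  structure(list(index = list(), chrom_lengths = chrom_lengths),
            class = "signal_track")
}

track_slot <- function(track, chrom, strand) {
  track$index[[paste(chrom, strand, sep = "\t")]]
}

#' @export
print.signal_track <- function(x, ...) {
  n <- sum(vapply(x$index, function(s) length(s$pos), integer(1)))
  cat("<signal_track> ", length(x$index), " chrom/strand slot(s), ",
      n, " positions\n", sep = "")
  invisible(x)
}

#' @rdname signal_track
#' @param x a `signal_track`.
#' @param ... unused.
#' @method as_tibble signal_track
#' @export
as_tibble.signal_track <- function(x, ...) {
  if (!length(x$index)) {
    return(tibble::tibble(chrom = character(), strand = character(),
                          pos = integer(), value = numeric()))
  }
  keys <- strsplit(names(x$index), "\t", fixed = TRUE)
  purrr::map2_dfr(x$index, keys, function(slot, k) {
    tibble::tibble(chrom = k[1], strand = k[2], pos = slot$pos, val = slot$val)
  }) |>
    dplyr::rename(value = "val") |>
    dplyr::arrange(.data$chrom, .data$strand, .data$pos)
}

#' Query a signal track
#'
#' `track_window()` returns the dense value vector over `[start, end)` (zeros
#' where no signal); `track_sparse()` the non-zero positions within the
#' interval; `track_sum()` their sum.
#'
#' @param track a [signal_track()].
#' @param chrom,strand slot to query.
#' @param start,end 0-based half-open interval.
#' @return `track_window()` a numeric vector of length `end - start`;
#'   `track_sparse()` a list with `pos` and `val`; `track_sum()` a number.
#' @export
track_window <- function(track, chrom, strand, start, end) {
  out <- numeric(end - start)
  s <- track_sparse(track, chrom, strand, start, end)
  if (length(s$pos)) out[s$pos - start + 1L] <- s$val
  out
}

#' @rdname track_window
#' @export
track_sparse <- function(track, chrom, strand, start, end) {
  slot <- track_slot(track, chrom, strand)
  if (is.null(slot)) return(list(pos = integer(), val = numeric()))
  lo <- findInterval(start - 0.5, slot$pos) + 1L
  hi <- findInterval(end - 0.5, slot$pos)
  if (lo > hi) return(list(pos = integer(), val = numeric()))
  list(pos = slot$pos[lo:hi], val = slot$val[lo:hi])
}

#' @rdname track_window
#' @export
track_sum <- function(track, chrom, strand, start, end) {
  sum(track_sparse(track, chrom, strand, start, end)$val)
}

#' Combine or rescale signal tracks
#'
#' `merge_tracks()` sums a list of tracks position-wise (e.g. to pool all
#' samples before summit calling); `scale_track()` multiplies all values by a
#' constant (e.g. `1e6 / (library size x TMM factor)` to obtain CPM-scaled
#' tracks).
#'
#' @param tracks a list of `signal_track` objects.
#' @param track a `signal_track`.
#' @param factor positive scaling constant.
#' @return A `signal_track`.
#' @export
merge_tracks <- function(tracks) {
  stopifnot(length(tracks) >= 1L)
  keys <- unique(unlist(lapply(tracks, function(t) names(t$index))))
  index <- lapply(keys, function(k) {
    slots <- purrr::compact(lapply(tracks, function(t) t$index[[k]]))
    pos <- unlist(lapply(slots, `[[`, "pos"))
    val <- unlist(lapply(slots, `[[`, "val"))
    v <- rowsum(val, pos, reorder = TRUE)
    list(pos = as.integer(rownames(v)), val = as.numeric(v))
  })
  names(index) <- keys
  structure(list(index = index, chrom_lengths = tracks[[1]]$chrom_lengths),
            class = "signal_track")
}

#' @rdname merge_tracks
#' @export
scale_track <- function(track, factor) {
  stopifnot(is.numeric(factor), length(factor) == 1L, factor > 0)
  track$index <- lapply(track$index, function(s) {
    s$val <- s$val * factor
    s
  })
  track
}

#' Read and write a strand pair of bedGraph files
#'
#' csRNA-seq coverage is exchanged as one bedGraph per strand. Intervals are
#' 0-based half-open; every covered base receives the record's value, and
#' overlapping records within a file are summed. The minus-strand file holds
#' magnitudes (values are stored as absolute values).
#'
#' @param plus_path,minus_path bedGraph file paths.
#' @param chrom_lengths optional named chromosome lengths for validation.
#' @return A [signal_track()].
#' @export
read_bedgraph_pair <- function(plus_path, minus_path, chrom_lengths = NULL) {
  read_one <- function(path, strand) {
    bg <- utils::read.table(path, sep = "\t", header = FALSE,
                            col.names = c("chrom", "start", "end", "value"),
                            colClasses = c("character", "integer", "integer",
                                           "numeric"))
    if (strand == "+" && any(bg$value < 0)) {
      stop("negative value in plus-strand bedGraph ", path)
    }
    bg$value <- abs(bg$value)
    if (!nrow(bg)) {
      return(tibble::tibble(chrom = character(), strand = character(),
                            pos = integer(), value = numeric()))
    }
    w <- bg$end - bg$start
    if (any(w <= 0)) stop("bedGraph interval with non-positive width in ", path)
    tibble::tibble(
      chrom = rep(bg$chrom, w),
      strand = strand,
      pos = unlist(purrr::map2(bg$start, bg$end - 1L, seq.int)),
      value = rep(bg$value, w)
    )
  }
  tbl <- dplyr::bind_rows(read_one(plus_path, "+"), read_one(minus_path, "-"))
  signal_track(tbl, chrom_lengths = chrom_lengths)
}

#' @rdname read_bedgraph_pair
#' @param track a `signal_track` to serialize.
#' @export
write_bedgraph_pair <- function(track, plus_path, minus_path) {
  tbl <- as_tibble.signal_track(track)
  write_one <- function(sub, path) {
    out <- data.frame(chrom = sub$chrom, start = sub$pos, end = sub$pos + 1L,
                      value = sub$value)
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  write_one(tbl[tbl$strand == "+", ], plus_path)
  write_one(tbl[tbl$strand == "-", ], minus_path)
  invisible(c(plus_path, minus_path))
}
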