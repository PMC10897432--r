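#' Genome annotation container
#'
#' Bundles chromosomes, gene models and transcripts. All coordinates are
#' 0-based half-open; the TSS of a feature is `start` on the plus strand and
#' `end - 1` on the minus strand.
#'
#' @param chromosomes tibble with `chrom`, `length`.
#' @param genes tibble with `gene_id`, `chrom`, `start`, `end`, `strand`,
#'   `biotype`.
#' @param transcripts tibble with `tx_id`, `gene_id`, `chrom`, `start`, `end`,
#'   `strand`, and optional `utr5_start`/`utr5_end` (0-based half-open 5' UTR,
#'   `NA` when not annotated).
#'
#' @return An object of class `genome_annotation`.
#' @export
genome_annotation <- function(chromosomes, genes, transcripts = NULL) {
  assert_cols(chromosomes, c("chrom", "length"), "chromosomes")
  assert_cols(genes, c("gene_id", "chrom", "start", "end", "strand", "biotype"),
              "genes")
  if (anyDuplicated(genes$gene_id)) stop("gene identifiers must be unique")
  if (any(genes$start >= genes$end)) stop("gene start must be < end")
  len <- stats::setNames(chromosomes$length, chromosomes$chrom)[genes$chrom]
  if (anyNA(len)) stop("gene on undeclared chromosome")
  if (any(genes$start < 0 | genes$end > len)) {
    stop("gene interval outside chromosome bounds")
  }
  if (is.null(transcripts)) {
    transcripts <- dplyr::transmute(
      genes,
      tx_id = paste0(.data$gene_id, ".1"), gene_id = .data$gene_id,
      chrom = .data$chrom, start = .data$start, end = .data$end,
      strand = .data$strand, utr5_start = NA_integer_, utr5_end = NA_integer_
    )
  }
  assert_cols(transcripts,
              c("tx_id", "gene_id", "chrom", "start", "end", "strand"),
              "transcripts")
  if (!"utr5_start" %in% names(transcripts)) transcripts$utr5_start <- NA_integer_
  if (!"utr5_end" %in% names(transcripts)) transcripts$utr5_end <- NA_integer_
  if (!all(transcripts$gene_id %in% genes$gene_id)) {
    stop("transcript with unknown parent gene")
  }
  structure(
    list(chromosomes = tibble::as_tibble(chromosomes),
         genes = tibble::as_tibble(genes),
         transcripts = tibble::as_tibble(transcripts)),
    class = "genome_annotation"
  )
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat("<genome_annotation> ", nrow(x$chromosomes), " chromosome(s), ",
      nrow(x$genes), " gene(s), ", nrow(x$transcripts), " transcript(s)\n",
      sep = "")
  invisible(x)
}

gff3_attr <- function(attrs, key) {
  m <- regmatches(attrs, regexpr(paste0("(^|;)", key, "=[^;]*"), attrs))
  out <- rep(NA_character_, length(attrs))
  hit <- lengths(regmatches(attrs, gregexpr(paste0("(^|;)", key, "="), attrs))) > 0
  out[hit] <- sub(paste0("^;?", key, "="), "", m)
  out
}

#' Read a GFF3 gene annotation
#'
#' Parses `gene`, `mRNA`/`transcript` (any type carrying a `Parent` that is a
#' gene) and `five_prime_UTR` records. GFF3 coordinates (1-based, closed) are
#' converted to the internal 0-based half-open convention at this boundary
#' and nowhere else. Chromosome lengths are taken from `##sequence-region`
#' directives; chromosomes seen only in records get the maximum end seen.
#' Gene biotype is read from a `biotype` or `locus_type` attribute and kept
#' verbatim.
#'
#' @param path GFF3 file path.
#' @return A [genome_annotation()].
#' @export
read_gff3 <- function(path) {
  lines <- readLines(path)
  seqreg <- grep("^##sequence-region", lines, value = TRUE)
  chroms <- tibble::tibble(chrom = character(), length = integer())
  if (length(seqreg)) {
    parts <- strsplit(trimws(seqreg), "\\s+")
    chroms <- tibble::tibble(
      chrom = vapply(parts, `[[`, "", 2L),
      length = vapply(parts, function(p) as.integer(p[[4]]), integer(1))
    )
  }
  body_idx <- which(!startsWith(lines, "#") & nzchar(trimws(lines)))
  if (!length(body_idx)) {
    return(genome_annotation(
      chroms,
      tibble::tibble(gene_id = character(), chrom = character(),
                     start = integer(), end = integer(), strand = character(),
                     biotype = character())
    ))
  }
  fields <- strsplit(lines[body_idx], "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 9L)
  if (length(bad)) {
    stop("malformed GFF3 record at line ", body_idx[bad[1]], " of ", path,
         " (expected 9 tab-separated columns)")
  }
  rec <- tibble::tibble(
    chrom = vapply(fields, `[[`, "", 1L),
    type  = vapply(fields, `[[`, "", 3L),
    start = as.integer(vapply(fields, `[[`, "", 4L)) - 1L,  # to 0-based
    end   = as.integer(vapply(fields, `[[`, "", 5L)),       # half-open
    strand = vapply(fields, `[[`, "", 7L),
    attrs = vapply(fields, `[[`, "", 9L),
    line = body_idx
  )
  if (anyNA(rec$start) || anyNA(rec$end)) {
    i <- which(is.na(rec$start) | is.na(rec$end))[1]
    stop("malformed coordinate at line ", rec$line[i], " of ", path)
  }
  rec$id <- gff3_attr(rec$attrs, "ID")
  rec$parent <- gff3_attr(rec$attrs, "Parent")

  genes <- rec[rec$type == "gene", ]
  biotype <- gff3_attr(genes$attrs, "biotype")
  lt <- gff3_attr(genes$attrs, "locus_type")
  biotype[is.na(biotype)] <- lt[is.na(biotype)]
  biotype[is.na(biotype)] <- "protein_coding"
  genes_tbl <- tibble::tibble(
    gene_id = genes$id, chrom = genes$chrom, start = genes$start,
    end = genes$end, strand = genes$strand, biotype = biotype
  )
  if (anyNA(genes_tbl$gene_id)) stop("gene record without ID attribute")

  tx <- rec[!rec$type %in% c("gene", "five_prime_UTR") & !is.na(rec$parent), ]
  tx <- tx[tx$parent %in% genes_tbl$gene_id, ]
  orphan <- rec[!rec$type %in% c("gene") & !is.na(rec$parent) &
                  !(rec$parent %in% c(genes_tbl$gene_id, tx$id)), ]
  if (nrow(orphan)) {
    stop("record at line ", orphan$line[1], " references unknown Parent '",
         orphan$parent[1], "'")
  }
  tx_tbl <- tibble::tibble(
    tx_id = tx$id, gene_id = tx$parent, chrom = tx$chrom, start = tx$start,
    end = tx$end, strand = tx$strand,
    utr5_start = NA_integer_, utr5_end = NA_integer_
  )
  utr <- rec[rec$type == "five_prime_UTR", ]
  if (nrow(utr) && nrow(tx_tbl)) {
    for (i in seq_len(nrow(utr))) {
      j <- match(utr$parent[i], tx_tbl$tx_id)
      if (is.na(j)) next
      tx_tbl$utr5_start[j] <- min(tx_tbl$utr5_start[j], utr$start[i], na.rm = TRUE)
      tx_tbl$utr5_end[j] <- max(tx_tbl$utr5_end[j], utr$end[i], na.rm = TRUE)
    }
  }
  if (!nrow(chroms)) {
    chroms <- rec |>
      dplyr::group_by(chrom = .data$chrom) |>
      dplyr::summarise(length = max(.data$end), .groups = "drop")
  }
  genome_annotation(chroms, genes_tbl,
                    if (nrow(tx_tbl)) tx_tbl else NULL)
}

#' Write a genome annotation as GFF3
#'
#' Inverse of [read_gff3()]: internal 0-based half-open coordinates are
#' converted back to the 1-based closed GFF3 convention.
#'
#' @param annotation a [genome_annotation()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(annotation, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  writeLines(sprintf("##sequence-region %s 1 %d",
                     annotation$chromosomes$chrom,
                     annotation$chromosomes$length), con)
  g <- annotation$genes
  writeLines(sprintf("%s\tnascentarch\tgene\t%d\t%d\t.\t%s\t.\tID=%s;biotype=%s",
                     g$chrom, g$start + 1L, g$end, g$strand, g$gene_id,
                     g$biotype), con)
  tx <- annotation$transcripts
  writeLines(sprintf("%s\tnascentarch\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
                     tx$chrom, tx$start + 1L, tx$end, tx$strand, tx$tx_id,
                     tx$gene_id), con)
  has_utr <- !is.na(tx$utr5_start) & !is.na(tx$utr5_end)
  if (any(has_utr)) {
    u <- tx[has_utr, ]
    writeLines(sprintf(
      "%s\tnascentarch\tfive_prime_UTR\t%d\t%d\t.\t%s\t.\tParent=%s",
      u$chrom, u$utr5_start + 1L, u$utr5_end, u$strand, u$tx_id), con)
  }
  invisible(path)
}

#' Read and write BED6 interval files
#'
#' BED is 0-based half-open, matching the internal convention, so no
#' coordinate shift is applied. A missing score column defaults to 0.
#'
#' @param path file path.
#' @return `read_bed()` returns a tibble with `chrom`, `start`, `end`,
#'   `name`, `score`, `strand`.
#' @export
read_bed <- function(path) {
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           colClasses = "character")
  if (ncol(raw) < 3L) stop("BED file needs at least 3 columns: ", path)
  out <- tibble::tibble(
    chrom = raw[[1]],
    start = as.integer(raw[[2]]),
    end = as.integer(raw[[3]]),
    name = if (ncol(raw) >= 4L) raw[[4]] else paste0("feature_", seq_len(nrow(raw))),
    score = if (ncol(raw) >= 5L) as.numeric(raw[[5]]) else 0,
    strand = if (ncol(raw) >= 6L) raw[[6]] else "+"
  )
  if (anyNA(out$start) || anyNA(out$end)) stop("non-numeric BED coordinate in ", path)
  out
}

#' @rdname read_bed
#' @param intervals tibble with `chrom`, `start`, `end`, `name`, `score`,
#'   `strand` (missing `score` written as 0).
#' @export
write_bed <- function(intervals, path) {
  assert_cols(intervals, c("chrom", "start", "end", "name", "strand"))
  if (!"score" %in% names(intervals)) intervals$score <- 0
  out <- data.frame(intervals$chrom, intervals$start, intervals$end,
                    intervals$name, intervals$score, intervals$strand)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read and write feature-by-sample matrices as TSV
#'
#' The first column holds feature identifiers, the header row sample
#' identifiers. Duplicated feature identifiers and non-numeric cells are
#' errors (named by row and column).
#'
#' @param path file path.
#' @return `read_matrix()` returns a numeric matrix with feature rownames.
#' @export
read_matrix <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          colClasses = "character")
  ids <- df[[1]]
  if (anyDuplicated(ids)) {
    stop("duplicated feature id(s) in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  vals <- df[, -1, drop = FALSE]
  m <- suppressWarnings(vapply(vals, as.numeric, numeric(nrow(df))))
  if (nrow(df) == 1L) m <- matrix(m, nrow = 1L, dimnames = list(NULL, names(vals)))
  if (anyNA(m) ) {
    idx <- which(is.na(m), arr.ind = TRUE)[1, ]
    stop("non-numeric value in ", path, " at row '", ids[idx[1]],
         "', column '", colnames(m)[idx[2]], "'")
  }
  rownames(m) <- ids
  m
}

#' @rdname read_matrix
#' @param m numeric matrix with feature rownames and sample colnames.
#' @param id_col name used for the feature-id header cell.
#' @export
write_matrix <- function(m, path, id_col = "feature_id") {
  df <- data.frame(rownames(m), m, check.names = FALSE)
  names(df)[1] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a differential-expression table
#'
#' Expects tab-separated columns `feature_id`, `log2fc`, `qvalue` and
#' optionally `max_expr` (maximum CPM/TPM across samples, used by the
#' exosome-insensitive gate). Positive `log2fc` means higher in the mutant.
#'
#' @param path file path.
#' @return A tibble.
#' @export
read_de_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  assert_cols(df, c("feature_id", "log2fc", "qvalue"), "DE table")
  if (anyDuplicated(df$feature_id)) stop("duplicated feature id in DE table ", path)
  if (!is.numeric(df$log2fc) || !is.numeric(df$qvalue)) {
    stop("log2fc and qvalue must be numeric in ", path)
  }
  tibble::as_tibble(df)
}

#' Read and write TSS/ACR peak tables as TSV
#'
#' Plain-text round trip of the full peak table (all columns preserved;
#' coordinates bit-exact).
#'
#' @param path file path.
#' @return `read_peaks()` returns a tibble.
#' @export
read_peaks <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  assert_cols(df, c("peak_id", "chrom", "start", "end"), "peak table")
  if (anyDuplicated(df$peak_id)) stop("duplicated peak id in ", path)
  tibble::as_tibble(df)
}

#' @rdname read_peaks
#' @param peaks tibble of peaks.
#' @export
write_peaks <- function(peaks, path) {
  utils::write.table(peaks, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
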