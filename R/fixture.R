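#' Write a simulated dataset as an on-disk fixture
#'
#' Serializes every component of a [simulate_dataset()] result in the plain
#' -text formats the pipeline consumes: GFF3 annotation, TSV peak/ACR/
#' transcript tables, one bedGraph pair per sample, TSV DE tables, the ACR
#' value matrix, the sample sheet, the YAML config and the truth tables.
#'
#' @param sim a `sim_dataset`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(sim, dir) {
  stopifnot(inherits(sim, "sim_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "tracks"), showWarnings = FALSE)
  dir.create(file.path(dir, "truth"), showWarnings = FALSE)
  write_gff3(sim$annotation, file.path(dir, "annotation.gff3"))
  write_peaks(sim$peaks, file.path(dir, "peaks.tsv"))
  write_peaks(sim$acrs, file.path(dir, "acrs.tsv"))
  utils::write.table(sim$transcripts, file.path(dir, "transcripts.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  te <- sim$te
  if (nrow(te)) {
    te$score <- 0
    te$strand <- "+"
    write_bed(te, file.path(dir, "te.bed"))
  } else {
    file.create(file.path(dir, "te.bed"))
  }
  write_matrix(sim$acr_values, file.path(dir, "acr_values.tsv"),
               id_col = "peak_id")
  utils::write.table(sim$samples, file.path(dir, "samples.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  for (s in names(sim$tracks)) {
    write_bedgraph_pair(sim$tracks[[s]],
                        file.path(dir, "tracks", paste0(s, ".plus.bedGraph")),
                        file.path(dir, "tracks", paste0(s, ".minus.bedGraph")))
  }
  for (assay in names(sim$de)) {
    for (m in names(sim$de[[assay]])) {
      utils::write.table(sim$de[[assay]][[m]],
                         file.path(dir, sprintf("de_%s_%s.tsv", assay, m)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  write_sim_config(sim$config, file.path(dir, "config.yaml"))
  for (nm in names(sim$truth)) {
    utils::write.table(sim$truth[[nm]],
                       file.path(dir, "truth", paste0(nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}

#' Read a fixture back from disk
#'
#' Inverse of [write_fixture()], using the package readers, so a round trip
#' exercises every parser.
#'
#' @param dir fixture directory.
#' @return A list with `annotation`, `peaks`, `acrs`, `transcripts`, `te`,
#'   `acr_values`, `samples`, `tracks`, `de` and `config`.
#' @export
read_fixture <- function(dir) {
  req <- c("annotation.gff3", "peaks.tsv", "acrs.tsv", "samples.tsv")
  miss <- req[!file.exists(file.path(dir, req))]
  if (length(miss)) {
    stop("fixture at ", dir, " is missing required file(s): ",
         paste(miss, collapse = ", "))
  }
  annotation <- read_gff3(file.path(dir, "annotation.gff3"))
  lens <- stats::setNames(annotation$chromosomes$length,
                          annotation$chromosomes$chrom)
  samples <- tibble::as_tibble(
    utils::read.table(file.path(dir, "samples.tsv"), sep = "\t",
                      header = TRUE, stringsAsFactors = FALSE)
  )
  tracks <- lapply(stats::setNames(samples$sample, samples$sample),
                   function(s) {
    read_bedgraph_pair(
      file.path(dir, "tracks", paste0(s, ".plus.bedGraph")),
      file.path(dir, "tracks", paste0(s, ".minus.bedGraph")),
      chrom_lengths = lens
    )
  })
  te_path <- file.path(dir, "te.bed")
  te <- if (file.exists(te_path) && file.size(te_path) > 0) {
    read_bed(te_path)
  } else {
    tibble::tibble(chrom = character(), start = integer(), end = integer(),
                   name = character(), score = numeric(), strand = character())
  }
  de <- list()
  for (f in list.files(dir, pattern = "^de_.*\\.tsv$")) {
    parts <- strsplit(sub("\\.tsv$", "", f), "_")[[1]]
    de[[parts[2]]][[parts[3]]] <- read_de_table(file.path(dir, f))
  }
  list(
    annotation = annotation,
    peaks = read_peaks(file.path(dir, "peaks.tsv")),
    acrs = read_peaks(file.path(dir, "acrs.tsv")),
    transcripts = tibble::as_tibble(
      utils::read.table(file.path(dir, "transcripts.tsv"), sep = "\t",
                        header = TRUE, stringsAsFactors = FALSE)
    ),
    te = te,
    acr_values = read_matrix(file.path(dir, "acr_values.tsv")),
    samples = samples,
    tracks = tracks,
    de = de,
    config = if (file.exists(file.path(dir, "config.yaml"))) {
      read_sim_config(file.path(dir, "config.yaml"))
    }
  )
}
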