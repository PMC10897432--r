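#' Intergenic unidirectional non-coding peaks
#'
#' Non-coding peaks that are not a member of any accepted bidirectional pair
#' and whose summit lies outside every gene body: the unidirectional
#' enhancer source class.
#'
#' @param peaks categorized peak table with `summit`.
#' @param pairs accepted pairs from [find_bidirectional()].
#' @param annotation a [genome_annotation()].
#' @return Subset of `peaks`.
#' @export
intergenic_nc_peaks <- function(peaks, pairs, annotation) {
  nc <- peaks[peaks$category != "mRNA", , drop = FALSE]
  paired <- unique(c(pairs$peak_a_id, pairs$peak_b_id))
  nc <- nc[!(nc$peak_id %in% paired), , drop = FALSE]
  g <- annotation$genes
  inside <- vapply(seq_len(nrow(nc)), function(i) {
    any(g$chrom == nc$chrom[i] & nc$summit[i] >= g$start &
          nc$summit[i] < g$end)
  }, logical(1))
  nc[!inside, , drop = FALSE]
}

pipeline_stages <- c("simulate", "metrics", "annotate", "antisense",
                     "bidirectional", "enhancers", "exosome")

need_file <- function(path, stage) {
  if (!file.exists(path)) {
    stop("stage '", stage, "' is missing required input: ", path,
         call. = FALSE)
  }
  path
}

#' Run the analysis pipeline end to end
#'
#' Chains the analysis stages over a simulated fixture (or a pre-existing
#' fixture directory), writing every stage output as TSV/BED under
#' `out_dir` and a manifest of output files with MD5 digests. With the same
#' configuration and seed, two runs produce byte-identical outputs.
#'
#' Stages: `simulate` (write the fixture), `metrics` (merged-track summits
#' and 80% widths, TMM/CPM), `annotate` (gene assignment, TSS categories,
#' transcript filtering, ACR labels), `antisense`, `bidirectional`,
#' `enhancers`, `exosome`. `"all"` runs everything in order. Later stages
#' read the files earlier stages wrote and raise a usage error naming any
#' missing input.
#'
#' @param out_dir output directory.
#' @param config a [sim_config()] (needed by the `simulate` stage).
#' @param params an [analysis_params()].
#' @param stages character vector of stages, or `"all"`.
#' @param null_draws inter-chromosomal null size for the enhancer stage.
#' @return Invisibly, a tibble manifest (file, md5).
#' @export
run_pipeline <- function(out_dir, config = NULL,
                         params = analysis_params(), stages = "all",
                         null_draws = 2000L) {
  if (identical(stages, "all")) stages <- pipeline_stages
  bad <- setdiff(stages, pipeline_stages)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fx_dir <- file.path(out_dir, "fixture")

  if ("simulate" %in% stages) {
    if (is.null(config)) stop("stage 'simulate' needs a sim_config")
    sim <- simulate_dataset(config)
    write_fixture(sim, fx_dir)
  }
  need_file(file.path(fx_dir, "peaks.tsv"), stages[1])
  fx <- read_fixture(fx_dir)
  seed <- fx$config$seed %||% config$seed %||% 1L
  mask <- fx$samples$sample[fx$samples$type == "wildtype"]

  out <- function(name) file.path(out_dir, name)
  tsv <- function(x, name) {
    utils::write.table(x, out(name), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }

  if ("metrics" %in% stages) {
    merged <- merge_tracks(fx$tracks)
    peaks <- annotate_summits(fx$peaks, merged, fraction = params$width_frac)
    counts <- quantify_peaks(peaks, fx$tracks)
    norm <- tmm_normalize(counts)
    write_peaks(peaks, out("peaks_metrics.tsv"))
    write_matrix(counts, out("counts.tsv"), id_col = "peak_id")
    write_matrix(norm$cpm, out("cpm.tsv"), id_col = "peak_id")
    tsv(tidy.tmm_norm(norm), "tmm_factors.tsv")
  }

  load_metrics <- function(stage) {
    list(
      peaks = read_peaks(need_file(out("peaks_metrics.tsv"), stage)),
      cpm = read_matrix(need_file(out("cpm.tsv"), stage))
    )
  }

  if ("annotate" %in% stages) {
    m <- load_metrics("annotate")
    peaks <- assign_tss(m$peaks, fx$annotation, params)
    kept_tx <- filter_transcripts(fx$transcripts, peaks, params)
    peaks <- categorize_tss(peaks, fx$annotation, kept_tx, params)
    acrs <- annotate_acr(fx$acrs, fx$annotation, fx$te, peaks, params)
    write_peaks(peaks, out("peaks_annotated.tsv"))
    tsv(kept_tx, "transcripts_kept.tsv")
    write_peaks(acrs, out("acrs_annotated.tsv"))
  }

  load_annotated <- function(stage) {
    list(
      peaks = read_peaks(need_file(out("peaks_annotated.tsv"), stage)),
      cpm = read_matrix(need_file(out("cpm.tsv"), stage))
    )
  }

  if ("antisense" %in% stages) {
    a <- load_annotated("antisense")
    pairs <- find_antisense(a$peaks, fx$annotation, a$cpm, mask, params) |>
      classify_antisense(params) |>
      sense_antisense_ratio(a$cpm, mask) |>
      pair_correlation(a$cpm, mask) |>
      partition_by_correlation(pos = 0.5, neg = -0.25)
    tsv(pairs, "antisense_pairs.tsv")
  }

  if ("bidirectional" %in% stages) {
    a <- load_annotated("bidirectional")
    pairs <- find_bidirectional(a$peaks, params) |>
      pair_correlation(a$cpm, mask, cols = c("peak_a_id", "peak_b_id")) |>
      max_cpm_ratio(a$cpm, mask)
    tsv(pairs, "bidirectional_pairs.tsv")
    tsv(correlation_distance_table(a$peaks, a$cpm, mask),
        "divergent_candidates.tsv")
  }

  if ("enhancers" %in% stages) {
    a <- load_annotated("enhancers")
    pairs <- tibble::as_tibble(utils::read.table(
      need_file(out("bidirectional_pairs.tsv"), "enhancers"),
      sep = "\t", header = TRUE, stringsAsFactors = FALSE))
    norm <- utils::read.table(need_file(out("tmm_factors.tsv"), "enhancers"),
                              sep = "\t", header = TRUE)
    scaled <- lapply(stats::setNames(norm$sample, norm$sample), function(s) {
      scale_track(fx$tracks[[s]],
                  1e6 / (norm$lib_size[norm$sample == s] *
                           norm$factor[norm$sample == s]))
    })
    ncnc <- pairs[pairs$pair_type == "ncTSS-ncTSS", , drop = FALSE]
    uni <- intergenic_nc_peaks(a$peaks, pairs, fx$annotation)
    enh <- compile_enhancers(ncnc, uni, a$peaks, fx$annotation, params)
    act <- enhancer_activity(enh, scaled)
    links <- enhancer_gene_correlations(enh, act, a$peaks, a$cpm, mask, params)
    targets <- select_target_genes(links, params$target_corr_min)
    null_r <- enhancer_null_correlations(enh, act, a$peaks, a$cpm, mask,
                                         n_draws = null_draws,
                                         seed = seed + 1L)
    tsv(enh, "enhancers.tsv")
    write_matrix(act, out("enhancer_activity.tsv"), id_col = "enhancer_id")
    tsv(links, "enhancer_links.tsv")
    tsv(tibble::tibble(gene_id = targets), "enhancer_targets.tsv")
    tsv(tibble::tibble(draw = seq_along(null_r), pearson_r = null_r),
        "enhancer_null.tsv")
  }

  if ("exosome" %in% stages) {
    if (!length(fx$de)) stop("stage 'exosome' is missing DE tables in the fixture")
    calls <- list()
    for (assay in names(fx$de)) {
      for (m in names(fx$de[[assay]])) {
        cl <- classify_exosome(fx$de[[assay]][[m]], assay = assay,
                               params = params)
        cl$assay <- assay
        cl$mutant <- m
        calls[[paste(assay, m)]] <- cl
      }
    }
    calls <- dplyr::bind_rows(calls)
    tsv(calls, "exosome_calls.tsv")
    cs <- calls[calls$assay == "csRNA", ]
    muts <- unique(cs$mutant)
    if (length(muts) == 2L) {
      sens <- split(cs$feature_id[cs$call == "sensitive"],
                    cs$mutant[cs$call == "sensitive"])
      ht <- exosome_overlap_test(sens[[muts[1]]] %||% character(),
                                 sens[[muts[2]]] %||% character(),
                                 universe = length(unique(cs$feature_id)))
      tsv(tibble::tibble(
        mutant_a = muts[1], mutant_b = muts[2],
        overlap = unname(ht$statistic), universe = unname(ht$parameter["N"]),
        size_a = unname(ht$parameter["size_a"]),
        size_b = unname(ht$parameter["size_b"]), p_value = ht$p.value
      ), "exosome_overlap.tsv")
    }
  }

  files <- sort(setdiff(list.files(out_dir, recursive = TRUE),
                        "manifest.tsv"))
  manifest <- tibble::tibble(
    file = files,
    md5 = unname(tools::md5sum(file.path(out_dir, files)))
  )
  utils::write.table(manifest, file.path(out_dir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(manifest)
}
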