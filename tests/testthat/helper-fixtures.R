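# Shared test fixtures, built in code.

# sparse track from position -> count pairs on one chrom/strand
toy_track <- function(pos, val, chrom = "chr1", strand = "+",
                      chrom_lengths = NULL) {
  signal_track(tibble::tibble(chrom = chrom, strand = strand,
                              pos = as.integer(pos), value = val),
               chrom_lengths = chrom_lengths)
}

# one-chromosome annotation with arbitrary genes
toy_annotation <- function(genes, chrom_length = 100000L,
                           transcripts = NULL) {
  genome_annotation(
    tibble::tibble(chrom = unique(genes$chrom), length = chrom_length),
    genes, transcripts
  )
}

toy_peaks <- function(summit, strand, category = "mRNA", chrom = "chr1",
                      assigned_gene = NA_character_) {
  n <- length(summit)
  tibble::tibble(
    peak_id = sprintf("p%03d", seq_len(n)),
    chrom = chrom,
    start = as.integer(summit) - 75L,
    end = as.integer(summit) + 76L,
    strand = strand,
    summit = as.integer(summit),
    category = rep_len(category, n),
    assigned_gene = rep_len(assigned_gene, n)
  )
}

# CPM-like matrix with named rows over 6 wild-type samples
toy_cpm <- function(rows) {
  m <- do.call(rbind, rows)
  colnames(m) <- WT_SAMPLES
  m
}
WT_SAMPLES <- c("DS", "L6", "L12", "L26", "L48", "L57")

# small simulation reused across tests (cached per session)
small_sim_config <- function(seed = 11L, ...) {
  defaults <- list(
    seed = seed, n_chromosomes = 3L, chrom_length = 150000L,
    n_genes = 30L, n_antisense_proximal = 6L, n_antisense_distal = 6L,
    n_divergent = 8L, n_bidirectional_nc = 4L,
    n_unidirectional_intergenic = 4L, n_enhancer_linked_genes = 4L,
    n_exosome_sensitive = 8L, n_te = 2L, n_decoy_acr = 3L
  )
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

cached_small_sim <- local({
  sim <- NULL
  function() {
    if (is.null(sim)) sim <<- simulate_dataset(small_sim_config())
    sim
  }
})

# O(N^2) all-windows brute force for the smallest window holding
# >= ceiling(frac * N) read starts
width80_bruteforce <- function(pos, val, fraction = 0.8) {
  target <- ceiling(fraction * sum(val))
  best <- Inf
  for (i in seq_along(pos)) {
    for (j in i:length(pos)) {
      if (sum(val[i:j]) >= target) {
        w <- pos[j] - pos[i] + 1L
        if (w < best) best <- w
        break
      }
    }
  }
  best
}

# textbook chi-square against expected counts
chisq_textbook <- function(observed, expected) {
  stat <- sum((observed - expected)^2 / expected)
  list(stat = stat,
       p = stats::pchisq(stat, length(observed) - 1L, lower.tail = FALSE))
}

# exhaustive hypergeometric upper tail from binomial coefficients
hyper_upper_enum <- function(N, K, B, ov) {
  js <- ov:min(K, B)
  sum(choose(K, js) * choose(N - K, B - js)) / choose(N, B)
}

# rule-order oracle for the ACR ladder: apply steps 1-4 in sequence
acr_ladder_oracle <- function(acrs, genes_detected, te, peaks, up = 400L,
                              down = 100L) {
  vapply(seq_len(nrow(acrs)), function(i) {
    s <- acrs$summit[i]
    ch <- acrs$chrom[i]
    lab <- "Intergenic"
    if (any(genes_detected$chrom == ch & s >= genes_detected$start &
              s < genes_detected$end)) {
      lab <- "Intragenic"
    }
    if (nrow(te) && any(te$chrom == ch & s >= te$start & s < te$end)) {
      lab <- "TE"
    }
    for (k in seq_len(nrow(peaks))) {
      if (peaks$chrom[k] != ch) next
      o <- if (peaks$strand[k] == "+") s - peaks$summit[k]
           else peaks$summit[k] - s
      if (o >= -up && o <= down) {
        lab <- "Promoter"
        break
      }
    }
    lab
  }, character(1))
}

# run the detection chain on a simulated dataset, returning everything the
# recovery checks need
run_detection <- function(sim, params = analysis_params(),
                          null_draws = 0L) {
  merged <- merge_tracks(sim$tracks)
  peaks <- annotate_summits(sim$peaks, merged, fraction = params$width_frac)
  counts <- quantify_peaks(peaks, sim$tracks)
  norm <- tmm_normalize(counts)
  peaks <- assign_tss(peaks, sim$annotation, params)
  kept_tx <- filter_transcripts(sim$transcripts, peaks, params)
  peaks <- categorize_tss(peaks, sim$annotation, kept_tx, params)
  mask <- sim$samples$sample[sim$samples$type == "wildtype"]
  antisense <- classify_antisense(
    find_antisense(peaks, sim$annotation, norm$cpm, mask, params), params)
  pairs <- find_bidirectional(peaks, params)
  uni <- intergenic_nc_peaks(peaks, pairs, sim$annotation)
  enh <- compile_enhancers(pairs[pairs$pair_type == "ncTSS-ncTSS", ], uni,
                           peaks, sim$annotation, params)
  scaled <- lapply(stats::setNames(names(sim$tracks), names(sim$tracks)),
                   function(s) {
    scale_track(sim$tracks[[s]],
                1e6 / (norm$lib_sizes[s] * norm$factors[s]))
  })
  act <- enhancer_activity(enh, scaled)
  links <- enhancer_gene_correlations(enh, act, peaks, norm$cpm, mask, params)
  list(peaks = peaks, norm = norm, mask = mask, antisense = antisense,
       pairs = pairs, uni = uni, enhancers = enh, activity = act,
       links = links)
}

# fraction of planted enhancer-gene links recovered at r >= r_min
link_recovery <- function(sim, det, r_min = 0.5) {
  te <- sim$truth$enhancers
  hits <- vapply(seq_len(nrow(te)), function(i) {
    mem <- strsplit(te$member_peaks[i], ",")[[1]]
    eids <- det$enhancers$enhancer_id[vapply(
      strsplit(det$enhancers$member_peaks, ","),
      function(mp) any(mp %in% mem), logical(1))]
    any(det$links$pearson_r[det$links$enhancer_id %in% eids &
                              det$links$gene_id == te$linked_gene[i]] >= r_min,
        na.rm = TRUE)
  }, logical(1))
  mean(hits)
}
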