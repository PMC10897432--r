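#' Simulation configuration
#'
#' Defines the toy genome and the planted feature classes. Defaults describe
#' the "mini" study layout: 3 chromosomes of 500 kb, 150 protein-coding
#' genes, 30 proximal + 30 distal antisense TSSs, 40 divergent (nc-pc)
#' promoters, 20 non-coding bidirectional (nc-nc) pairs, 20 intergenic
#' unidirectional non-coding TSSs, 20 enhancer-linked genes with target
#' Pearson r of 0.8, 20 exosome-sensitive features, and 6 time-point samples
#' plus 2 exosome-mutant samples. The sense:antisense amplitude ratio
#' defaults to 8 (the observed median sense:antisense expression ratio).
#'
#' @param seed mandatory RNG seed (integer).
#' @param n_chromosomes,chrom_length genome shape.
#' @param n_genes number of protein-coding genes (must cover all planted
#'   gene roles).
#' @param n_antisense_proximal,n_antisense_distal planted antisense TSSs.
#' @param n_divergent planted nc-pc divergent promoters.
#' @param n_bidirectional_nc planted nc-nc bidirectional pairs.
#' @param n_unidirectional_intergenic planted intergenic unidirectional
#'   non-coding TSSs.
#' @param n_enhancer_linked_genes genes linked to an enhancer with target
#'   correlation `corr_planted`.
#' @param n_exosome_sensitive features upregulated in the exosome mutants.
#' @param n_timepoints,n_mutants sample design (6 + 2).
#' @param summit_dispersion geometric decay parameter p of the two-sided
#'   read-start offset distribution, `P(offset d) ~ (1 - p) p^|d|`.
#' @param noise_rate background read starts per kb per strand per sample.
#' @param corr_planted,anticorr_planted target Pearson r for planted
#'   correlated / anti-correlated pairs.
#' @param expression_dispersion negative-binomial dispersion of per-sample
#'   feature counts.
#' @param sense_antisense_ratio sense/antisense amplitude ratio.
#' @param n_te,n_decoy_acr transposable-element cassettes and intergenic
#'   decoy ACRs.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed,
                       n_chromosomes = 3L,
                       chrom_length = 500000L,
                       n_genes = 150L,
                       n_antisense_proximal = 30L,
                       n_antisense_distal = 30L,
                       n_divergent = 40L,
                       n_bidirectional_nc = 20L,
                       n_unidirectional_intergenic = 20L,
                       n_enhancer_linked_genes = 20L,
                       n_exosome_sensitive = 20L,
                       n_timepoints = 6L,
                       n_mutants = 2L,
                       summit_dispersion = 0.7,
                       noise_rate = 0.5,
                       corr_planted = 0.8,
                       anticorr_planted = -0.6,
                       expression_dispersion = 0.1,
                       sense_antisense_ratio = 8,
                       n_te = 6L,
                       n_decoy_acr = 10L) {
  if (missing(seed) || is.null(seed) || is.na(seed)) {
    stop("seed is mandatory in sim_config()")
  }
  cfg <- as.list(environment())
  cfg$seed <- as.integer(seed)
  n_roles <- n_antisense_proximal + n_antisense_distal + n_divergent +
    n_enhancer_linked_genes
  if (n_genes < n_roles) {
    stop("n_genes (", n_genes, ") smaller than the planted gene roles (",
         n_roles, ")")
  }
  if (n_enhancer_linked_genes >
        n_bidirectional_nc + n_unidirectional_intergenic) {
    stop("more enhancer-linked genes than enhancer sources")
  }
  structure(cfg, class = c("sim_config", "list"))
}

#' @rdname sim_config
#' @param path YAML file path.
#' @export
read_sim_config <- function(path) {
  vals <- yaml::read_yaml(path)
  if (is.null(vals$seed)) stop("seed is mandatory in a simulation config")
  do.call(sim_config, vals)
}

#' @rdname sim_config
#' @param config a `sim_config`.
#' @export
write_sim_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

# standardize a vector to mean 0, sd 1
std01 <- function(v) (v - mean(v)) / stats::sd(v)

# latent stage profile: one of `n_tp` unimodal bumps plus feature noise;
# the bump share is kept small so unrelated features stay near-uncorrelated
latent_profile <- function(stage, n_tp, bump_weight = 0.15) {
  s <- seq_len(n_tp)
  bump <- std01(exp(-(s - stage)^2 / 2))
  eps <- std01(stats::rnorm(n_tp))
  std01(sqrt(bump_weight) * bump + sqrt(1 - bump_weight) * eps)
}

# mix a fresh profile against an anchor at target correlation
mix_profile <- function(anchor_g, r) {
  eta <- std01(stats::rnorm(length(anchor_g)))
  std01(r * anchor_g + sqrt(1 - r^2) * eta)
}

SG_AMPLITUDE <- 0.8  # log-scale amplitude of the stage profile

# expected counts over all samples for one feature
feature_lambda <- function(base, g, n_tp, n_mut, lfc_mut) {
  wt <- base * exp(SG_AMPLITUDE * g - SG_AMPLITUDE^2 / 2)
  mut <- base * exp(SG_AMPLITUDE * g[n_tp] - SG_AMPLITUDE^2 / 2) * 2^lfc_mut
  c(wt, mut)
}

draw_counts <- function(lambda, disp) {
  n <- if (disp > 0) {
    stats::rnbinom(length(lambda), mu = lambda, size = 1 / disp)
  } else {
    stats::rpois(length(lambda), lambda)
  }
  n + 1L  # one deterministic read at the summit per sample
}

#' Simulate a planted-truth dataset
#'
#' Builds a toy genome in which every feature class the pipeline detects is
#' planted with known ground truth: protein-coding genes with TSS peaks,
#' proximal/distal antisense TSSs, divergent nc-pc promoters, nc-nc
#' bidirectional pairs, intergenic unidirectional non-coding TSSs (the
#' latter two doubling as enhancer sources, a subset linked to genes at the
#' target correlation), reconstructed transcript candidates, ACRs over every
#' promoter and enhancer plus decoys, TE intervals, per-sample strand
#'-specific read-start tracks, and differential tables for two exosome
#' mutants. Read starts decay geometrically around each summit and
#' per-sample totals are negative-binomial around a stage-profile amplitude;
#' planted pair correlations are rejection-resampled (up to 10 draws) until
#' the realized count correlation is within 0.15 of target. Deterministic
#' given the config seed.
#'
#' @param config a [sim_config()].
#' @return A list of class `sim_dataset` with elements `config`, `samples`,
#'   `annotation`, `peaks`, `tracks`, `transcripts`, `te`, `acrs`,
#'   `acr_values`, `de` (per assay and mutant) and `truth` (per-class truth
#'   tables).
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)

  n_tp <- config$n_timepoints
  n_mut <- config$n_mutants
  stages <- c("DS", "L6", "L12", "L26", "L48", "L57")[seq_len(n_tp)]
  mutants <- c("hen2", "rrp4")[seq_len(n_mut)]
  samples <- tibble::tibble(
    sample = c(stages, mutants),
    stage = c(stages, rep(stages[n_tp], n_mut)),
    type = c(rep("wildtype", n_tp), rep("mutant", n_mut))
  )
  layout <- plant_layout(config)
  feats <- layout$feats

  # --- stage profiles, exosome fold changes -------------------------------
  feats$stage_k <- sample.int(n_tp, nrow(feats), replace = TRUE)
  nc_ids <- feats$peak_id[feats$class != "pc"]
  sens <- plant_sensitivity(nc_ids, config$n_exosome_sensitive)
  lfc_tbl <- matrix(0, nrow(feats), n_mut,
                    dimnames = list(feats$peak_id, mutants))
  for (m in mutants) {
    idx <- match(sens[[m]]$feature_id[sens[[m]]$intent == "sensitive"],
                 feats$peak_id)
    lfc_tbl[idx, m] <- sens[[m]]$log2fc[sens[[m]]$intent == "sensitive"]
  }

  # --- counts with planted correlations -----------------------------------
  disp <- config$expression_dispersion
  g_list <- vector("list", nrow(feats))
  counts <- matrix(0L, nrow(feats), n_tp + n_mut,
                   dimnames = list(feats$peak_id, samples$sample))
  feats$realized_r <- NA_real_
  row_of <- stats::setNames(seq_len(nrow(feats)), feats$peak_id)

  gen_one <- function(i, g) {
    lam <- feature_lambda(feats$base[i], g, n_tp, n_mut, lfc_tbl[i, ])
    draw_counts(lam, disp)
  }
  anchors <- which(is.na(feats$anchor_id))
  for (i in anchors) {
    g_list[[i]] <- latent_profile(feats$stage_k[i], n_tp)
    counts[i, ] <- gen_one(i, g_list[[i]])
  }
  # dependents: resample profile + counts until the realized WT-count
  # correlation is within 0.15 of target (<= 10 tries, keep the best)
  dep <- which(!is.na(feats$anchor_id) & is.na(feats$partner_id))
  for (i in dep) {
    a <- row_of[feats$anchor_id[i]]
    target <- feats$target_r[i]
    best <- NULL
    for (try in 1:10) {
      g <- mix_profile(g_list[[a]], target)
      cts <- gen_one(i, g)
      r <- stats::cor(cts[seq_len(n_tp)], counts[a, seq_len(n_tp)])
      cand <- list(g = g, cts = cts, r = r, err = abs(r - target))
      if (is.null(best) || cand$err < best$err) best <- cand
      if (best$err <= 0.15) break
    }
    g_list[[i]] <- best$g
    counts[i, ] <- best$cts
    feats$realized_r[i] <- best$r
  }
  # nc-nc pair members sharing one latent profile; linked pairs checked as
  # member-sum against the anchor gene
  pair_first <- which(!is.na(feats$partner_id) &
                        feats$peak_id < feats$partner_id)
  for (i in pair_first) {
    j <- row_of[feats$partner_id[i]]
    a_id <- feats$anchor_id[i]
    if (is.na(a_id)) {
      g <- latent_profile(feats$stage_k[i], n_tp)
      g_list[[i]] <- g
      g_list[[j]] <- mix_profile(g, 0.7)
      counts[i, ] <- gen_one(i, g_list[[i]])
      counts[j, ] <- gen_one(j, g_list[[j]])
      next
    }
    a <- row_of[a_id]
    target <- feats$target_r[i]
    best <- NULL
    for (try in 1:10) {
      g <- mix_profile(g_list[[a]], target)
      cts_i <- gen_one(i, g)
      cts_j <- gen_one(j, g)
      tot <- cts_i[seq_len(n_tp)] + cts_j[seq_len(n_tp)]
      r <- stats::cor(tot, counts[a, seq_len(n_tp)])
      cand <- list(g = g, ci = cts_i, cj = cts_j, r = r,
                   err = abs(r - target))
      if (is.null(best) || cand$err < best$err) best <- cand
      if (best$err <= 0.15) break
    }
    g_list[[i]] <- best$g
    g_list[[j]] <- best$g
    counts[i, ] <- best$ci
    counts[j, ] <- best$cj
    feats$realized_r[i] <- best$r
    feats$realized_r[j] <- best$r
  }

  # --- read-start tracks ---------------------------------------------------
  tracks <- build_tracks(feats, counts, samples$sample, config)

  # --- ACR accessibility, DE tables ---------------------------------------
  acr_values <- matrix(
    exp(stats::rnorm(nrow(layout$acrs) * nrow(samples), log(10), 0.4)),
    nrow(layout$acrs), nrow(samples),
    dimnames = list(layout$acrs$peak_id, samples$sample)
  )
  raw_cpm <- sweep(counts, 2L, colSums(counts), "/") * 1e6
  de <- build_de_tables(sens, raw_cpm, layout$transcripts, mutants)

  truth <- layout$truth
  truth$pairs_realized <- feats[!is.na(feats$target_r),
                                c("peak_id", "anchor_id", "target_r",
                                  "realized_r", "class")]
  truth$exosome <- dplyr::bind_rows(lapply(mutants, function(m) {
    dplyr::mutate(sens[[m]], mutant = m, .before = 1)
  }))

  structure(
    list(config = config, samples = samples, annotation = layout$annotation,
         peaks = layout$peaks, tracks = tracks,
         transcripts = layout$transcripts, te = layout$te,
         acrs = layout$acrs, acr_values = acr_values, de = de,
         truth = truth),
    class = "sim_dataset"
  )
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat("<sim_dataset> ", nrow(x$annotation$genes), " genes, ",
      nrow(x$peaks), " planted TSS peaks, ", length(x$tracks),
      " sample tracks, seed ", x$config$seed, "\n", sep = "")
  invisible(x)
}

# ---------------------------------------------------------------------------
# genome layout: cassettes placed left to right, round-robin over chromosomes

plant_layout <- function(config) {
  n_tp <- config$n_timepoints
  ratio <- config$sense_antisense_ratio
  roles <- c(rep("as_prox", config$n_antisense_proximal),
             rep("as_dist", config$n_antisense_distal),
             rep("divergent", config$n_divergent),
             rep("enh_linked", config$n_enhancer_linked_genes),
             rep("plain", config$n_genes - config$n_antisense_proximal -
                   config$n_antisense_distal - config$n_divergent -
                   config$n_enhancer_linked_genes))
  n_link <- config$n_enhancer_linked_genes
  n_link_ncnc <- min(ceiling(n_link / 2), config$n_bidirectional_nc)
  n_link_uni <- n_link - n_link_ncnc
  if (n_link_uni > config$n_unidirectional_intergenic) {
    stop("not enough unidirectional sources for the requested links")
  }

  cass <- list()
  add <- function(kind, ...) {
    cass[[length(cass) + 1L]] <<- c(list(kind = kind), list(...))
  }
  for (r in roles[roles != "enh_linked"]) add("gene", role = r)
  for (k in seq_len(n_link_ncnc)) add("enh_gene", src = "ncnc")
  for (k in seq_len(n_link_uni)) add("enh_gene", src = "uni")
  for (k in seq_len(config$n_bidirectional_nc - n_link_ncnc)) add("ncnc")
  for (k in seq_len(config$n_unidirectional_intergenic - n_link_uni)) add("uni")
  for (k in seq_len(config$n_te)) add("te")
  for (k in seq_len(config$n_decoy_acr)) add("decoy_acr")
  if (length(cass)) cass <- cass[sample.int(length(cass))]

  chroms <- tibble::tibble(
    chrom = paste0("chr", seq_len(config$n_chromosomes)),
    length = as.integer(config$chrom_length)
  )
  cursor <- stats::setNames(rep(2000L, nrow(chroms)), chroms$chrom)
  margin <- 2000L
  gap <- 800L

  genes <- list(); peaks <- list(); acrs <- list(); te <- list()
  transcripts <- list()
  truth_as <- list(); truth_div <- list(); truth_ncnc <- list()
  truth_uni <- list(); truth_enh <- list(); truth_acr <- list()
  feats <- list()
  ids <- new.env()
  next_id <- function(prefix) {
    n <- (get0(prefix, envir = ids, inherits = FALSE) %||% 0L) + 1L
    assign(prefix, n, envir = ids)
    sprintf("%s_%04d", prefix, n)
  }

  add_peak <- function(peak_id, chrom, strand, summit, class, base,
                       host_gene = NA_character_, anchor_id = NA_character_,
                       target_r = NA_real_, partner_id = NA_character_,
                       category_expected) {
    peaks[[length(peaks) + 1L]] <<- tibble::tibble(
      peak_id = peak_id, chrom = chrom, start = summit - 75L,
      end = summit + 76L, strand = strand
    )
    feats[[length(feats) + 1L]] <<- tibble::tibble(
      peak_id = peak_id, chrom = chrom, strand = strand, summit = summit,
      class = class, base = base, host_gene = host_gene,
      anchor_id = anchor_id, target_r = target_r, partner_id = partner_id,
      category_expected = category_expected
    )
  }
  add_promoter_acr <- function(chrom, tss, strand) {
    id <- next_id("acr")
    lo <- if (strand == "+") tss - 400L else tss - 100L
    hi <- if (strand == "+") tss + 101L else tss + 401L
    s <- if (strand == "+") tss - 150L else tss + 150L
    acrs[[length(acrs) + 1L]] <<- tibble::tibble(
      peak_id = id, chrom = chrom, start = lo, end = hi, summit = s
    )
    truth_acr[[length(truth_acr) + 1L]] <<- tibble::tibble(
      peak_id = id, label_expected = "Promoter"
    )
  }

  place_gene <- function(chrom, off, role, linked_enh = NA_character_,
                         forced_strand = NULL) {
    L <- sample(seq(3000L, 5000L, by = 100L), 1L)
    strand <- forced_strand %||% sample(c("+", "-"), 1L)
    gstart <- off + 1600L
    gend <- gstart + L
    gid <- next_id("gene")
    genes[[length(genes) + 1L]] <<- tibble::tibble(
      gene_id = gid, chrom = chrom, start = gstart, end = gend,
      strand = strand, biotype = "protein_coding", role = role
    )
    tss <- tss_pos(gstart, gend, strand)
    pc_peak <- next_id("tss_pc")
    base <- exp(stats::rnorm(1, log(180), 0.4))
    add_peak(pc_peak, chrom, strand, tss, "pc", base,
             host_gene = gid, category_expected = "mRNA")
    add_promoter_acr(chrom, tss, strand)

    if (role %in% c("as_prox", "as_dist")) {
      frac <- if (role == "as_prox") stats::runif(1, 0.18, 0.38)
              else stats::runif(1, 0.62, 0.90)
      o <- round(frac * L)
      s <- if (strand == "+") gstart + o else gend - 1L - o
      as_strand <- if (strand == "+") "-" else "+"
      as_id <- next_id("tss_as")
      corr_class <- sample(c("positive", "negative", "independent"), 1L,
                           prob = c(0.25, 0.25, 0.5))
      target <- switch(corr_class,
                       positive = config$corr_planted,
                       negative = config$anticorr_planted,
                       independent = NA_real_)
      as_class <- if (role == "as_prox") "proximal" else "distal"
      add_peak(as_id, chrom, as_strand, as.integer(s),
               paste0("antisense_", as_class), base / ratio, host_gene = gid,
               anchor_id = if (!is.na(target)) pc_peak else NA_character_,
               target_r = target, category_expected = "unstable")
      truth_as[[length(truth_as) + 1L]] <<- tibble::tibble(
        gene_id = gid, sense_peak_id = pc_peak, antisense_peak_id = as_id,
        class = as_class, corr_class = corr_class, target_r = target
      )
    }
    if (role == "divergent") {
      d <- sample(150:400, 1L)
      s <- if (strand == "+") tss - d else tss + d
      nc_strand <- if (strand == "+") "-" else "+"
      nc_id <- next_id("tss_div")
      target <- min(0.85, max(0.1, 0.9 - d / 600))
      add_peak(nc_id, chrom, nc_strand, as.integer(s), "divergent_nc",
               base / 4, host_gene = gid, anchor_id = pc_peak,
               target_r = target, category_expected = "unstable")
      truth_div[[length(truth_div) + 1L]] <<- tibble::tibble(
        gene_id = gid, pc_peak_id = pc_peak, nc_peak_id = nc_id,
        inter_tss_distance = d, target_r = target
      )
    }
    list(gene_id = gid, pc_peak = pc_peak, tss = tss, width = L + 3200L)
  }

  place_ncnc <- function(chrom, center, linked_gene_peak = NA_character_,
                         target = NA_real_) {
    d <- sample(150:400, 1L)
    m <- as.integer(center - d %/% 2L)
    p <- m + d
    id_a <- next_id("tss_bd")
    id_b <- next_id("tss_bd")
    base <- exp(stats::rnorm(1, log(60), 0.3))
    add_peak(id_a, chrom, "-", m, "ncnc", base,
             anchor_id = linked_gene_peak, target_r = target,
             partner_id = id_b, category_expected = "putativeLncRNA")
    add_peak(id_b, chrom, "+", p, "ncnc", base * exp(stats::rnorm(1, 0, 0.2)),
             anchor_id = linked_gene_peak, target_r = target,
             partner_id = id_a, category_expected = "putativeLncRNA")
    for (x in list(c(id_a, m, "-"), c(id_b, p, "+"))) {
      tl <- sample(300:800, 1L)
      s0 <- as.integer(x[2])
      transcripts[[length(transcripts) + 1L]] <<- tibble::tibble(
        tx_id = paste0("rtx_", x[1]), chrom = chrom,
        start = if (x[3] == "+") s0 else s0 - tl + 1L,
        end = if (x[3] == "+") s0 + tl else s0 + 1L,
        strand = x[3], source_peak = x[1]
      )
    }
    truth_ncnc[[length(truth_ncnc) + 1L]] <<- tibble::tibble(
      peak_a_id = id_a, peak_b_id = id_b, inter_tss_distance = d,
      linked_gene_peak = linked_gene_peak, target_r = target
    )
    # ACR over the element
    id <- next_id("acr")
    acrs[[length(acrs) + 1L]] <<- tibble::tibble(
      peak_id = id, chrom = chrom, start = m - 100L, end = p + 101L,
      summit = as.integer((m + p) %/% 2L)
    )
    truth_acr[[length(truth_acr) + 1L]] <<- tibble::tibble(
      peak_id = id, label_expected = "Promoter"
    )
    c(id_a, id_b)
  }

  place_uni <- function(chrom, center, linked_gene_peak = NA_character_,
                        target = NA_real_) {
    strand <- sample(c("+", "-"), 1L)
    id <- next_id("tss_uni")
    base <- exp(stats::rnorm(1, log(60), 0.3))
    add_peak(id, chrom, strand, as.integer(center), "unidirectional", base,
             anchor_id = linked_gene_peak, target_r = target,
             category_expected = "putativeLncRNA")
    tl <- sample(300:800, 1L)
    transcripts[[length(transcripts) + 1L]] <<- tibble::tibble(
      tx_id = paste0("rtx_", id), chrom = chrom,
      start = if (strand == "+") as.integer(center) else as.integer(center) - tl + 1L,
      end = if (strand == "+") as.integer(center) + tl else as.integer(center) + 1L,
      strand = strand, source_peak = id
    )
    truth_uni[[length(truth_uni) + 1L]] <<- tibble::tibble(
      peak_id = id, linked_gene_peak = linked_gene_peak, target_r = target
    )
    aid <- next_id("acr")
    acrs[[length(acrs) + 1L]] <<- tibble::tibble(
      peak_id = aid, chrom = chrom, start = as.integer(center) - 250L,
      end = as.integer(center) + 251L, summit = as.integer(center)
    )
    truth_acr[[length(truth_acr) + 1L]] <<- tibble::tibble(
      peak_id = aid, label_expected = "Promoter"
    )
    id
  }

  chrom_i <- 0L
  for (c_spec in cass) {
    chrom_i <- chrom_i %% nrow(chroms) + 1L
    ch <- chroms$chrom[chrom_i]
    off <- cursor[ch]
    used <- 0L
    if (c_spec$kind == "gene") {
      g <- place_gene(ch, off, c_spec$role)
      used <- g$width
    } else if (c_spec$kind == "enh_gene") {
      target <- config$corr_planted
      ggap <- sample(1000:2500, 1L)
      if (c_spec$src == "ncnc") {
        g <- place_gene(ch, off + 1600L + ggap, "enh_linked",
                        forced_strand = "+")
        members <- place_ncnc(ch, off + 800L, linked_gene_peak = g$pc_peak,
                              target = target)
        truth_enh[[length(truth_enh) + 1L]] <- tibble::tibble(
          source = "bidirectional_nc",
          member_peaks = paste(members, collapse = ","),
          linked_gene = g$gene_id, linked_gene_peak = g$pc_peak,
          target_r = target
        )
        used <- 1600L + ggap + g$width
      } else {
        g <- place_gene(ch, off + 1200L + ggap, "enh_linked",
                        forced_strand = "+")
        member <- place_uni(ch, off + 600L, linked_gene_peak = g$pc_peak,
                            target = target)
        truth_enh[[length(truth_enh) + 1L]] <- tibble::tibble(
          source = "unidirectional_intergenic", member_peaks = member,
          linked_gene = g$gene_id, linked_gene_peak = g$pc_peak,
          target_r = target
        )
        used <- 1200L + ggap + g$width
      }
    } else if (c_spec$kind == "ncnc") {
      place_ncnc(ch, off + 1200L)
      used <- 2400L
    } else if (c_spec$kind == "uni") {
      place_uni(ch, off + 1000L)
      used <- 2000L
    } else if (c_spec$kind == "te") {
      tid <- next_id("te")
      te[[length(te) + 1L]] <- tibble::tibble(
        chrom = ch, start = off + 400L, end = off + 1200L, name = tid
      )
      aid <- next_id("acr")
      acrs[[length(acrs) + 1L]] <- tibble::tibble(
        peak_id = aid, chrom = ch, start = off + 600L, end = off + 1001L,
        summit = off + 800L
      )
      truth_acr[[length(truth_acr) + 1L]] <- tibble::tibble(
        peak_id = aid, label_expected = "TE"
      )
      used <- 1600L
    } else if (c_spec$kind == "decoy_acr") {
      aid <- next_id("acr")
      acrs[[length(acrs) + 1L]] <- tibble::tibble(
        peak_id = aid, chrom = ch, start = off + 500L, end = off + 901L,
        summit = off + 700L
      )
      truth_acr[[length(truth_acr) + 1L]] <- tibble::tibble(
        peak_id = aid, label_expected = "Intergenic"
      )
      used <- 1400L
    }
    cursor[ch] <- off + used + gap
    if (cursor[ch] > config$chrom_length - margin) {
      stop("infeasible packing: planted features exceed chromosome ", ch,
           " (", cursor[ch], " > ", config$chrom_length - margin, " bp)")
    }
  }

  genes_tbl <- if (length(genes)) dplyr::bind_rows(genes) else
    tibble::tibble(gene_id = character(), chrom = character(),
                   start = integer(), end = integer(), strand = character(),
                   biotype = character(), role = character())
  # intragenic decoy ACRs in plain genes
  plain <- genes_tbl[genes_tbl$role == "plain", ]
  for (i in seq_len(min(10L, nrow(plain)))) {
    aid <- next_id("acr")
    mid <- as.integer((plain$start[i] + plain$end[i]) %/% 2L)
    acrs[[length(acrs) + 1L]] <- tibble::tibble(
      peak_id = aid, chrom = plain$chrom[i], start = mid - 200L,
      end = mid + 201L, summit = mid
    )
    truth_acr[[length(truth_acr) + 1L]] <- tibble::tibble(
      peak_id = aid, label_expected = "Intragenic"
    )
  }

  bind_or <- function(lst, proto) if (length(lst)) dplyr::bind_rows(lst) else proto
  feats_tbl <- bind_or(feats, tibble::tibble(
    peak_id = character(), chrom = character(), strand = character(),
    summit = integer(), class = character(), base = numeric(),
    host_gene = character(), anchor_id = character(), target_r = numeric(),
    partner_id = character(), category_expected = character()
  ))
  annotation <- genome_annotation(
    chroms, genes_tbl[, c("gene_id", "chrom", "start", "end", "strand",
                          "biotype")]
  )
  list(
    annotation = annotation,
    feats = feats_tbl,
    peaks = bind_or(peaks, tibble::tibble(
      peak_id = character(), chrom = character(), start = integer(),
      end = integer(), strand = character()
    )),
    transcripts = bind_or(transcripts, tibble::tibble(
      tx_id = character(), chrom = character(), start = integer(),
      end = integer(), strand = character(), source_peak = character()
    )),
    te = bind_or(te, tibble::tibble(chrom = character(), start = integer(),
                                    end = integer(), name = character())),
    acrs = bind_or(acrs, tibble::tibble(
      peak_id = character(), chrom = character(), start = integer(),
      end = integer(), summit = integer()
    )),
    truth = list(
      genes = genes_tbl,
      features = feats_tbl[, c("peak_id", "chrom", "strand", "summit",
                               "class", "host_gene", "category_expected")],
      antisense = bind_or(truth_as, tibble::tibble(
        gene_id = character(), sense_peak_id = character(),
        antisense_peak_id = character(), class = character(),
        corr_class = character(), target_r = numeric()
      )),
      divergent = bind_or(truth_div, tibble::tibble(
        gene_id = character(), pc_peak_id = character(),
        nc_peak_id = character(), inter_tss_distance = integer(),
        target_r = numeric()
      )),
      ncnc = bind_or(truth_ncnc, tibble::tibble(
        peak_a_id = character(), peak_b_id = character(),
        inter_tss_distance = integer(), linked_gene_peak = character(),
        target_r = numeric()
      )),
      unidirectional = bind_or(truth_uni, tibble::tibble(
        peak_id = character(), linked_gene_peak = character(),
        target_r = numeric()
      )),
      enhancers = bind_or(truth_enh, tibble::tibble(
        source = character(), member_peaks = character(),
        linked_gene = character(), linked_gene_peak = character(),
        target_r = numeric()
      )),
      acrs = bind_or(truth_acr, tibble::tibble(
        peak_id = character(), label_expected = character()
      ))
    )
  )
}

# distribute per-sample counts into read-start positions around summits and
# add uniform background noise
build_tracks <- function(feats, counts, sample_names, config) {
  p <- config$summit_dispersion
  lens <- stats::setNames(rep(as.integer(config$chrom_length),
                              config$n_chromosomes),
                          paste0("chr", seq_len(config$n_chromosomes)))
  lapply(stats::setNames(seq_along(sample_names), sample_names), function(si) {
    pos_l <- list(); chrom_l <- list(); strand_l <- list()
    for (i in seq_len(nrow(feats))) {
      n <- counts[i, si]
      if (n == 0L) next
      extra <- n - 1L
      d <- integer(0)
      if (extra > 0L) {
        mag <- stats::rgeom(extra, prob = 1 - p)
        mag <- pmin(mag, 74L)
        sgn <- sample(c(-1L, 1L), extra, replace = TRUE)
        d <- mag * sgn
      }
      pp <- feats$summit[i] + c(0L, d)
      k <- length(pos_l) + 1L
      pos_l[[k]] <- pp
      chrom_l[[k]] <- rep(feats$chrom[i], length(pp))
      strand_l[[k]] <- rep(feats$strand[i], length(pp))
    }
    if (config$noise_rate > 0) {
      for (ch in names(lens)) {
        for (st in c("+", "-")) {
          n_bg <- stats::rpois(1, config$noise_rate * lens[ch] / 1000)
          if (n_bg == 0L) next
          k <- length(pos_l) + 1L
          pos_l[[k]] <- sample.int(lens[ch], n_bg, replace = TRUE) - 1L
          chrom_l[[k]] <- rep(ch, n_bg)
          strand_l[[k]] <- rep(st, n_bg)
        }
      }
    }
    if (!length(pos_l)) return(empty_track(lens))
    signal_track(tibble::tibble(
      chrom = unlist(chrom_l), strand = unlist(strand_l),
      pos = as.integer(unlist(pos_l)), value = 1
    ), chrom_lengths = lens)
  })
}

# planted sensitivity intents and DE rows per mutant over nc features
plant_sensitivity <- function(nc_ids, n_sensitive) {
  n_sensitive <- min(n_sensitive, length(nc_ids))
  shared_n <- round(0.75 * n_sensitive)
  pool <- sample(nc_ids)
  shared <- pool[seq_len(shared_n)]
  own <- list(
    hen2 = pool[shared_n + seq_len(n_sensitive - shared_n)],
    rrp4 = pool[2 * n_sensitive - shared_n + seq_len(n_sensitive - shared_n)]
  )
  out <- list()
  for (m in c("hen2", "rrp4")) {
    sens_ids <- c(shared, own[[m]])
    intent <- ifelse(nc_ids %in% sens_ids, "sensitive",
                     sample(c("insensitive", "unclassified"),
                            length(nc_ids), replace = TRUE,
                            prob = c(0.7, 0.3)))
    lfc <- numeric(length(nc_ids))
    q <- numeric(length(nc_ids))
    for (k in seq_along(nc_ids)) {
      if (intent[k] == "sensitive") {
        lfc[k] <- stats::runif(1, 2, 4)
        q[k] <- stats::runif(1, 0.0005, 0.04)
      } else if (intent[k] == "insensitive") {
        lfc[k] <- stats::runif(1, -0.9, 0.9)
        q[k] <- stats::runif(1, 0.06, 0.95)
      } else if (stats::runif(1) < 0.5) {
        lfc[k] <- stats::runif(1, 1.2, 1.9)
        q[k] <- stats::runif(1, 0, 1)
      } else {
        lfc[k] <- stats::runif(1, -0.9, 0.9)
        q[k] <- stats::runif(1, 0.0005, 0.04)
      }
    }
    out[[m]] <- tibble::tibble(feature_id = nc_ids, intent = intent,
                               log2fc = lfc, qvalue = q)
  }
  out
}

build_de_tables <- function(sens, raw_cpm, transcripts, mutants) {
  de <- list(csRNA = list(), totalRNA = list())
  for (m in mutants) {
    tab <- sens[[m]]
    max_expr <- apply(raw_cpm[tab$feature_id, , drop = FALSE], 1L, max)
    de$csRNA[[m]] <- tibble::tibble(
      feature_id = tab$feature_id, log2fc = tab$log2fc, qvalue = tab$qvalue,
      max_expr = unname(max_expr)
    )
    tx <- transcripts
    if (nrow(tx)) {
      idx <- match(tx$source_peak, tab$feature_id)
      intent <- tab$intent[idx]
      de$totalRNA[[m]] <- tibble::tibble(
        feature_id = tx$tx_id,
        log2fc = tab$log2fc[idx],
        qvalue = tab$qvalue[idx],
        max_expr = ifelse(intent == "insensitive",
                          stats::runif(nrow(tx), 0.2, 50),
                          stats::runif(nrow(tx), 0.05, 50))
      )
    }
  }
  de
}
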