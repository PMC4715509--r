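#' Synthetic study generator with recorded ground truth
#'
#' Generates every input the pipeline consumes — genome, peaks, variants,
#' haplotype panel, differential-expression tables, motif instances and a
#' patient tissue cohort — with planted structure recorded as ground truth,
#' so every stage can be tested end to end without external data. All
#' generators are bit-reproducible from an integer seed.
#'
#' @name synthetic_data
NULL

#' Simulation configuration
#'
#' Defaults describe a desk-scale study: a 10 Mb genome in four
#' chromosomes; ~300 peaks with log-normal lengths (median 300 bp, about 1%
#' genome coverage); 200 variants of which a fraction
#' `planted_in_peak_fraction` is placed inside peaks; block-copy LD with
#' per-column mutation; two-timepoint DE tables with planted same-direction
#' target genes and decoys; and a 100-patient cohort with Hardy-Weinberg
#' genotypes at minor allele frequency 0.13 and a genotype effect of
#' `tissue_beta` noise-standard-deviations on expression.
#'
#' @param ... Named overrides of any default listed below.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(...) {
  cfg <- list(
    n_chromosomes = 4L,
    chrom_length_bp = 2.5e6,
    n_peaks = 300L,
    peak_meanlog = log(300),
    peak_sdlog = 0.5,
    peak_min_length = 50L,
    peak_max_length = 5000L,
    n_index_snps = 10L,
    n_background_snps = 190L,
    planted_in_peak_fraction = 0.3,
    ld_block_size = 6L,
    ld_mutation_rate = 0.05,
    n_haplotypes = 120L,
    n_genes = 300L,
    gene_min_length = 2000L,
    gene_max_length = 50000L,
    de_n_primary = 120L,
    de_n_opposite = 30L,
    de_n_single = 30L,
    de_n_nonarbs_same = 20L,
    de_effect_size = 1.5,
    de_alpha = 0.05,
    motif_n_a = 60L,
    motif_n_b = 30L,
    motif_n_planted = 20L,
    motif_max_dist_bp = 100L,
    motif_window_width = 100L,
    tissue_n_patients = 100L,
    tissue_maf = 0.13,
    tissue_beta = -1,
    tissue_noise_sd = 1,
    qpcr_e_target = 1.9,
    qpcr_e_ref = 1.85,
    qpcr_ct_noise_sd = 0.05,
    ihc_intensity_base = 10,
    ihc_pct_base = 60,
    ihc_pct_sd = 8)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown) > 0) {
    abort(sprintf("unknown sim_config field(s): %s",
                  paste(unknown, collapse = ", ")))
  }
  cfg[names(over)] <- over
  if (cfg$planted_in_peak_fraction < 0 || cfg$planted_in_peak_fraction > 1) {
    abort("planted_in_peak_fraction must lie in [0, 1]")
  }
  if (cfg$n_haplotypes < 20) abort("n_haplotypes must be >= 20")
  structure(cfg, class = "sim_config")
}

#' Generate chromosome sizes and gene models
#'
#' @param cfg A [sim_config()].
#' @param seed Integer seed.
#' @return List with `chrom_sizes` and `genes` tibbles.
#' @export
generate_genome <- function(cfg, seed) {
  if (cfg$gene_max_length >= cfg$chrom_length_bp) {
    abort("gene_max_length must be smaller than chrom_length_bp")
  }
  with_seed(seed, {
    chrom_sizes <- tibble(chrom = sprintf("chr%d", seq_len(cfg$n_chromosomes)),
                          size = as.integer(cfg$chrom_length_bp))
    n <- cfg$n_genes
    chrom <- sample(chrom_sizes$chrom, n, replace = TRUE)
    len <- as.integer(floor(runif(n, cfg$gene_min_length,
                                  cfg$gene_max_length + 1)))
    size <- chrom_sizes$size[match(chrom, chrom_sizes$chrom)]
    start <- as.integer(floor(runif(n) * (size - len)))
    genes <- tibble(chrom = chrom, strand = sample(c("+", "-"), n,
                                                   replace = TRUE),
                    start = start, end = start + len) %>%
      dplyr::arrange(.data$chrom, .data$start) %>%
      dplyr::mutate(id = sprintf("gene_%04d", dplyr::row_number())) %>%
      dplyr::select("id", "chrom", "strand", "start", "end")
    list(chrom_sizes = chrom_sizes, genes = validate_genes(genes))
  })
}

#' Generate peaks and variants with a planted in-peak fraction
#'
#' Exactly `round(f * n_variants)` variants are placed uniformly inside
#' randomly chosen peaks; the rest are placed uniformly in non-peak space.
#' All variant positions are distinct (rejection sampling). Ground truth
#' records which variants were planted inside peaks.
#'
#' @param cfg A [sim_config()].
#' @param chrom_sizes Tibble with `chrom`, `size`.
#' @param seed Integer seed.
#' @return List with `peaks`, `variants` and `ground_truth` (field
#'   `planted_in_peak`: character vector of variant ids).
#' @export
generate_peaks_and_variants <- function(cfg, chrom_sizes, seed) {
  f <- cfg$planted_in_peak_fraction
  n_var <- cfg$n_index_snps + cfg$n_background_snps
  n_in <- round(f * n_var)
  if (n_in > 0 && cfg$n_peaks == 0) {
    abort("cannot plant variants inside peaks when n_peaks is 0")
  }
  with_seed(seed, {
    np <- cfg$n_peaks
    chrom <- sample(chrom_sizes$chrom, np, replace = TRUE,
                    prob = chrom_sizes$size)
    len <- as.integer(pmin(pmax(round(rlnorm(np, cfg$peak_meanlog,
                                             cfg$peak_sdlog)),
                                cfg$peak_min_length),
                           cfg$peak_max_length))
    size <- chrom_sizes$size[match(chrom, chrom_sizes$chrom)]
    len <- pmin(len, size)
    start <- as.integer(floor(runif(np) * (size - len + 1)))
    peaks <- tibble(chrom = chrom, start = start, end = start + len,
                    score = round(30 + stats::rexp(np, 1 / 70), 1)) %>%
      dplyr::arrange(.data$chrom, .data$start) %>%
      dplyr::mutate(name = sprintf("peak_%05d", dplyr::row_number())) %>%
      dplyr::select("chrom", "start", "end", "name", "score")

    taken <- character(0)
    draw_in_peak <- function(k) {
      out <- tibble(chrom = character(), pos = integer())
      while (nrow(out) < k) {
        need <- k - nrow(out)
        pi <- sample.int(nrow(peaks), need, replace = TRUE)
        pos <- peaks$start[pi] +
          as.integer(floor(runif(need) * (peaks$end[pi] - peaks$start[pi]))) + 1L
        cand <- tibble(chrom = peaks$chrom[pi], pos = pos)
        key <- paste(cand$chrom, cand$pos)
        ok <- !(key %in% taken) & !duplicated(key)
        taken <<- c(taken, key[ok])
        out <- dplyr::bind_rows(out, cand[ok, ])
      }
      out
    }
    draw_out_peak <- function(k) {
      out <- tibble(chrom = character(), pos = integer())
      guard <- 0L
      while (nrow(out) < k) {
        guard <- guard + 1L
        if (guard > 1000L) abort("could not place variants outside peaks")
        need <- (k - nrow(out)) * 3L
        ci <- sample.int(nrow(chrom_sizes), need, replace = TRUE,
                         prob = chrom_sizes$size)
        cand <- tibble(chrom = chrom_sizes$chrom[ci],
                       pos = as.integer(floor(runif(need) *
                                              chrom_sizes$size[ci])) + 1L)
        cand <- dplyr::mutate(cand, id = sprintf("tmp_%d", dplyr::row_number()))
        inside <- count_overlaps(cand, peaks)$hits$variant_id
        cand <- cand[!(cand$id %in% inside), c("chrom", "pos")]
        key <- paste(cand$chrom, cand$pos)
        ok <- !(key %in% taken) & !duplicated(key)
        taken <<- c(taken, key[ok])
        out <- dplyr::bind_rows(out, utils::head(cand[ok, ], k - nrow(out)))
      }
      out
    }
    vin <- draw_in_peak(n_in)
    vout <- draw_out_peak(n_var - n_in)
    variants <- dplyr::bind_rows(
      dplyr::mutate(vin, planted = TRUE),
      dplyr::mutate(vout, planted = FALSE)) %>%
      dplyr::arrange(.data$chrom, .data$pos) %>%
      dplyr::mutate(id = sprintf("rs_sim_%04d", dplyr::row_number()))
    idx <- sample.int(n_var, min(cfg$n_index_snps, n_var))
    variants$role <- "plain"
    variants$role[idx] <- "index"
    planted_ids <- variants$id[variants$planted]
    variants <- dplyr::select(variants, "id", "chrom", "pos", "role")
    list(peaks = peaks, variants = validate_variants(variants),
         ground_truth = list(planted_in_peak = planted_ids))
  })
}

# flip a 0/1 vector at `rate`, retrying until polymorphic
flip_polymorphic <- function(col, rate, max_tries = 50L) {
  for (i in seq_len(max_tries)) {
    flips <- rbinom(length(col), 1, rate)
    out <- as.integer(xor(col, flips))
    if (!(mean(out) %in% c(0, 1))) return(out)
  }
  abort("could not generate a polymorphic haplotype column")
}

#' Draw variants uniformly over the genome
#'
#' The null condition for calibration studies: variant positions uniform
#' over the whole genome (peaks included), with distinct positions.
#'
#' @param n Number of variants.
#' @param chrom_sizes Tibble with `chrom`, `size`.
#' @param seed Integer seed.
#' @return Variant tibble (`id`, `chrom`, `pos`).
#' @export
uniform_variants <- function(n, chrom_sizes, seed) {
  with_seed(seed, {
    out <- tibble(chrom = character(), pos = integer())
    while (nrow(out) < n) {
      need <- n - nrow(out)
      ci <- sample.int(nrow(chrom_sizes), need, replace = TRUE,
                       prob = chrom_sizes$size)
      cand <- tibble(chrom = chrom_sizes$chrom[ci],
                     pos = as.integer(floor(runif(need) *
                                            chrom_sizes$size[ci])) + 1L)
      out <- dplyr::distinct(dplyr::bind_rows(out, cand))
    }
    dplyr::mutate(dplyr::arrange(out, .data$chrom, .data$pos),
                  id = sprintf("rs_unif_%04d", dplyr::row_number())) %>%
      dplyr::select("id", "chrom", "pos")
  })
}

#' Generate a block-structured haplotype panel
#'
#' Variants are grouped, within each chromosome, into consecutive blocks of
#' `ld_block_size`. The first column of a block is a founder draw; each
#' subsequent column is the previous column with independent per-haplotype
#' allele flips at `ld_mutation_rate`, so r-squared decays with the number
#' of copying steps between two columns. Blocks are mutually independent.
#' Ground truth records the realized r-squared of every within-block pair.
#'
#' @param cfg A [sim_config()].
#' @param variants Variant tibble (defines panel variants and order).
#' @param seed Integer seed.
#' @return List with `panel` (a [haplotype_panel()]) and `ground_truth`
#'   (field `ld_pairs`: tibble `id_a`, `id_b`, `r2`).
#' @export
generate_haplotype_panel <- function(cfg, variants, seed) {
  variants <- dplyr::arrange(validate_variants(variants), .data$chrom,
                             .data$pos)
  nh <- cfg$n_haplotypes
  with_seed(seed, {
    alleles <- matrix(0L, nrow = nh, ncol = nrow(variants))
    blocks <- list()
    for (cc in unique(variants$chrom)) {
      vi <- which(variants$chrom == cc)
      starts <- seq(1, length(vi), by = cfg$ld_block_size)
      for (s in starts) {
        block <- vi[s:min(s + cfg$ld_block_size - 1, length(vi))]
        blocks[[length(blocks) + 1]] <- block
        p <- runif(1, 0.15, 0.5)
        col <- rbinom(nh, 1, p)
        tries <- 0L
        while (mean(col) %in% c(0, 1) && tries < 50L) {
          col <- rbinom(nh, 1, p)
          tries <- tries + 1L
        }
        if (mean(col) %in% c(0, 1)) {
          abort("could not generate a polymorphic founder column")
        }
        alleles[, block[1]] <- as.integer(col)
        if (length(block) > 1) {
          for (j in block[-1]) {
            col <- flip_polymorphic(col, cfg$ld_mutation_rate)
            alleles[, j] <- col
          }
        }
      }
    }
    panel <- haplotype_panel(variants, alleles)
    ld_pairs <- purrr::map_dfr(blocks, function(block) {
      if (length(block) < 2) return(NULL)
      combs <- utils::combn(block, 2)
      tibble(id_a = variants$id[combs[1, ]],
             id_b = variants$id[combs[2, ]],
             r2 = vapply(seq_len(ncol(combs)), function(k) {
               compute_r2(alleles[, combs[1, k]], alleles[, combs[2, k]])
             }, double(1)))
    })
    list(panel = panel, ground_truth = list(ld_pairs = ld_pairs))
  })
}

#' Generate two-timepoint differential-expression tables
#'
#' Planted primary genes (sampled among genes that carry assigned peaks) are
#' significant at both timepoints with the same direction. Decoys include
#' opposite-direction genes, single-timepoint genes, and same-direction
#' genes without peaks; all remaining genes are null. Ground truth lists the
#' planted primary gene ids.
#'
#' @param cfg A [sim_config()].
#' @param genes Gene tibble.
#' @param gene_peak_map Assignment tibble from [assign_peaks_to_genes()].
#' @param seed Integer seed.
#' @return List with `de_t1`, `de_t2` tibbles (`gene_id`, `log_fc`, `p_adj`)
#'   and `ground_truth` (field `planted_primary`).
#' @export
generate_de_tables <- function(cfg, genes, gene_peak_map, seed) {
  arbs_genes <- intersect(genes$id, unique(gene_peak_map$gene_id))
  non_arbs <- setdiff(genes$id, arbs_genes)
  n_primary <- min(cfg$de_n_primary, length(arbs_genes))
  with_seed(seed, {
    planted <- sample(arbs_genes, n_primary)
    pool <- setdiff(arbs_genes, planted)
    opp <- sample(pool, min(cfg$de_n_opposite, length(pool)))
    pool <- setdiff(pool, opp)
    single <- sample(pool, min(cfg$de_n_single, length(pool)))
    nonarbs_same <- sample(non_arbs,
                           min(cfg$de_n_nonarbs_same, length(non_arbs)))
    sig_p <- function(k) runif(k, 1e-6, cfg$de_alpha * 0.8)
    null_p <- function(k) runif(k, cfg$de_alpha * 4, 1)
    eff <- function(k) pmax(0.2, abs(rnorm(k, cfg$de_effect_size, 0.3)))
    small <- function(k) {
      x <- rnorm(k, 0, 0.15)
      ifelse(x == 0, 0.01, x)
    }
    all_ids <- genes$id
    de <- tibble(gene_id = all_ids,
                 log_fc_t1 = small(length(all_ids)),
                 log_fc_t2 = small(length(all_ids)),
                 p_t1 = null_p(length(all_ids)),
                 p_t2 = null_p(length(all_ids)))
    set_rows <- function(de, ids, fun) {
      i <- match(ids, de$gene_id)
      fun(de, i)
    }
    de <- set_rows(de, planted, function(de, i) {
      dir <- sample(c(-1, 1), length(i), replace = TRUE)
      de$log_fc_t1[i] <- dir * eff(length(i))
      de$log_fc_t2[i] <- dir * eff(length(i))
      de$p_t1[i] <- sig_p(length(i))
      de$p_t2[i] <- sig_p(length(i))
      de
    })
    de <- set_rows(de, opp, function(de, i) {
      dir <- sample(c(-1, 1), length(i), replace = TRUE)
      de$log_fc_t1[i] <- dir * eff(length(i))
      de$log_fc_t2[i] <- -dir * eff(length(i))
      de$p_t1[i] <- sig_p(length(i))
      de$p_t2[i] <- sig_p(length(i))
      de
    })
    de <- set_rows(de, single, function(de, i) {
      dir <- sample(c(-1, 1), length(i), replace = TRUE)
      de$log_fc_t1[i] <- dir * eff(length(i))
      de$p_t1[i] <- sig_p(length(i))
      de
    })
    de <- set_rows(de, nonarbs_same, function(de, i) {
      dir <- sample(c(-1, 1), length(i), replace = TRUE)
      de$log_fc_t1[i] <- dir * eff(length(i))
      de$log_fc_t2[i] <- dir * eff(length(i))
      de$p_t1[i] <- sig_p(length(i))
      de$p_t2[i] <- sig_p(length(i))
      de
    })
    list(de_t1 = tibble(gene_id = de$gene_id, log_fc = de$log_fc_t1,
                        p_adj = de$p_t1),
         de_t2 = tibble(gene_id = de$gene_id, log_fc = de$log_fc_t2,
                        p_adj = de$p_t2),
         ground_truth = list(planted_primary = sort(planted)))
  })
}

#' Fixed-width windows centred on peaks
#'
#' @param peaks Peak tibble.
#' @param width Window width in bp (default 100).
#' @param chrom_sizes Optional tibble with `chrom`, `size` used to clamp
#'   windows at chromosome ends.
#' @return Peak tibble of windows, names carried over.
#' @export
peak_windows <- function(peaks, width = 100, chrom_sizes = NULL) {
  peaks <- ensure_peak_names(validate_peaks(peaks))
  mid <- floor((peaks$start + peaks$end) / 2)
  start <- pmax(0, mid - floor(width / 2))
  end <- start + width
  if (!is.null(chrom_sizes)) {
    sz <- chrom_sizes$size[match(peaks$chrom, chrom_sizes$chrom)]
    end <- pmin(end, sz)
    start <- pmax(0, end - width)
  }
  tibble(chrom = peaks$chrom, start = as.integer(start),
         end = as.integer(end), name = peaks$name)
}

#' Generate motif instances with planted co-occurring pairs
#'
#' `n_planted` A-instances are placed at the position of a B-instance (a
#' planted within-distance pair); the remaining A-instances are placed in
#' windows whose interval, expanded by `max_dist_bp`, does not touch any
#' B-bearing window, so the planted count is exactly the co-occurring count.
#'
#' @param windows Window tibble (for example from [peak_windows()]).
#' @param n_a,n_b Instance counts for motif types A and B.
#' @param n_planted Number of planted co-occurring A-instances
#'   (`<= n_a`).
#' @param max_dist_bp Co-occurrence distance (default 100).
#' @param seed Integer seed.
#' @return List with `a`, `b` instance tibbles and `ground_truth` (field
#'   `n_cooccurring`).
#' @export
generate_motif_instances <- function(windows, n_a, n_b, n_planted,
                                     max_dist_bp = 100, seed) {
  windows <- ensure_peak_names(validate_peaks(windows))
  if (n_planted > n_a) abort("n_planted must be <= n_a")
  if (n_b < 1) abort("need at least one B instance")
  with_seed(seed, {
    nw <- nrow(windows)
    widths <- windows$end - windows$start
    wb <- sample.int(nw, n_b, replace = TRUE)
    off_b <- as.integer(floor(runif(n_b) * widths[wb]))
    b <- tibble(motif_id = "motif_b", arbs_id = windows$name[wb],
                offset = off_b,
                strand = sample(c("+", "-"), n_b, replace = TRUE))
    host <- sample.int(n_b, n_planted, replace = n_planted > n_b)
    a_planted <- tibble(motif_id = "motif_a", arbs_id = b$arbs_id[host],
                        offset = b$offset[host],
                        strand = sample(c("+", "-"), n_planted,
                                        replace = TRUE))
    # windows safely away from any B-bearing window
    off <- chrom_offsets(windows %>% group_by(.data$chrom) %>%
                           summarise(size = max(.data$end) + 1,
                                     .groups = "drop"))
    abs_s <- off[windows$chrom] + windows$start
    abs_e <- off[windows$chrom] + windows$end
    b_wins <- unique(wb)
    clear <- vapply(seq_len(nw), function(i) {
      all(abs_s[i] - max_dist_bp >= abs_e[b_wins] |
            abs_e[i] + max_dist_bp <= abs_s[b_wins])
    }, logical(1))
    clear_wins <- which(clear)
    n_clean <- n_a - n_planted
    if (n_clean > 0 && length(clear_wins) == 0) {
      abort("no window is far enough from B instances to place clean A instances")
    }
    wa <- if (n_clean > 0) sample(clear_wins, n_clean, replace = TRUE)
          else integer(0)
    a_clean <- tibble(motif_id = "motif_a", arbs_id = windows$name[wa],
                      offset = as.integer(floor(runif(n_clean) * widths[wa])),
                      strand = sample(c("+", "-"), n_clean, replace = TRUE))
    list(a = dplyr::bind_rows(a_planted, a_clean), b = b,
         ground_truth = list(n_cooccurring = as.integer(n_planted)))
  })
}

#' Generate a genotyped tissue cohort with qPCR and IHC measurements
#'
#' Genotypes are drawn from Hardy-Weinberg proportions at the configured
#' minor allele frequency. Per patient and tissue, a latent log2 expression
#' equals `tissue_beta * tissue_noise_sd` for risk-allele carriers (dominant
#' model) plus Gaussian noise; qPCR Ct values are back-computed from it via
#' the Pfaffl relation at the configured assay efficiencies (with Ct-space
#' measurement noise), and IHC core intensities carry the same effect.
#'
#' @param cfg A [sim_config()].
#' @param seed Integer seed.
#' @return List with `patients`, `qpcr`, `ihc_cores`, `calibrator` (the
#'   calibrator Ct values) and `ground_truth` (fields `carriers`, `beta`,
#'   `expression`).
#' @export
generate_tissue_cohort <- function(cfg, seed) {
  if (cfg$tissue_n_patients < 4) abort("need at least 4 patients")
  q <- cfg$tissue_maf
  with_seed(seed, {
    n <- cfg$tissue_n_patients
    ids <- sprintf("P%03d", seq_len(n))
    geno <- sample(c("T/T", "T/G", "G/G"), n, replace = TRUE,
                   prob = c((1 - q)^2, 2 * q * (1 - q), q^2))
    carrier <- geno != "T/T"
    effect <- cfg$tissue_beta * cfg$tissue_noise_sd
    patients <- tibble(patient_id = ids, rs11891426 = geno,
                       age = round(runif(n, 48, 75)))
    tissues <- c("benign", "cancer")
    samp <- tidyr::expand_grid(patient_id = ids, tissue = tissues)
    samp$carrier <- carrier[match(samp$patient_id, ids)]
    samp$expression <- effect * samp$carrier +
      rnorm(nrow(samp), 0, cfg$tissue_noise_sd)
    samp$sample_id <- paste(samp$patient_id, samp$tissue, sep = "_")

    ct_t_cal <- 27
    ct_r_cal <- 25
    e_t <- cfg$qpcr_e_target
    e_r <- cfg$qpcr_e_ref
    ct_ref <- ct_r_cal + rnorm(nrow(samp), 0, cfg$qpcr_ct_noise_sd)
    dct_ref <- ct_r_cal - ct_ref
    dct_t <- (samp$expression * log(2) + dct_ref * log(e_r)) / log(e_t)
    ct_target <- ct_t_cal - dct_t +
      rnorm(nrow(samp), 0, cfg$qpcr_ct_noise_sd)
    qpcr <- dplyr::bind_rows(
      tibble(sample_id = samp$sample_id, patient_id = samp$patient_id,
             tissue = samp$tissue, gene = "target", ct = ct_target,
             efficiency = e_t),
      tibble(sample_id = samp$sample_id, patient_id = samp$patient_id,
             tissue = samp$tissue, gene = "reference", ct = ct_ref,
             efficiency = e_r))

    cores <- tidyr::expand_grid(patient_id = ids, tissue = tissues,
                                core_index = 1:3)
    cc <- carrier[match(cores$patient_id, ids)]
    cores$mean_intensity <- pmax(0.1, cfg$ihc_intensity_base + effect * cc +
                                   rnorm(nrow(cores), 0,
                                         cfg$tissue_noise_sd))
    cores$pct_positive <- pmin(100, pmax(
      0, cfg$ihc_pct_base + rnorm(nrow(cores), 0, cfg$ihc_pct_sd)))

    list(patients = patients, qpcr = qpcr, ihc_cores = cores,
         calibrator = tibble(gene = c("target", "reference"),
                             ct = c(ct_t_cal, ct_r_cal),
                             efficiency = c(e_t, e_r)),
         ground_truth = list(carriers = ids[carrier], beta = effect,
                             expression = samp[, c("sample_id",
                                                   "expression")]))
  })
}

#' Recover per-sample relative expression from a simulated qPCR table
#'
#' Applies the Pfaffl ratio to each sample against the calibrator and
#' returns log2 relative expression, ready for genotype stratification.
#'
#' @param qpcr qPCR tibble from [generate_tissue_cohort()] (long format:
#'   `sample_id`, `patient_id`, `tissue`, `gene`, `ct`, `efficiency`).
#' @param calibrator Calibrator tibble (`gene`, `ct`, `efficiency`).
#' @return Tibble with `patient_id`, `tissue`, `score` (log2 Pfaffl ratio).
#' @export
qpcr_expression_scores <- function(qpcr, calibrator) {
  stop_if_missing_cols(qpcr, c("sample_id", "patient_id", "tissue", "gene",
                               "ct", "efficiency"), "`qpcr`")
  cal <- setNames(calibrator$ct, calibrator$gene)
  wide <- qpcr %>%
    tidyr::pivot_wider(id_cols = c("sample_id", "patient_id", "tissue"),
                       names_from = "gene",
                       values_from = c("ct", "efficiency"))
  r <- pfaffl_ratio(e_target = wide$efficiency_target,
                    dct_target = cal[["target"]] - wide$ct_target,
                    e_ref = wide$efficiency_reference,
                    dct_ref = cal[["reference"]] - wide$ct_reference)
  tibble(patient_id = wide$patient_id, tissue = wide$tissue,
         score = log2(r))
}

#' Generate a complete synthetic study
#'
#' Chains every generator with seeds derived from one master seed and
#' returns all inputs plus the combined ground truth.
#'
#' @param cfg A [sim_config()].
#' @param seed Master integer seed.
#' @return List with `chrom_sizes`, `genes`, `peaks`, `variants`, `panel`,
#'   `gene_peak_map`, `de_t1`, `de_t2`, `motif` (windows + instances),
#'   `tissue` and `ground_truth`.
#' @export
simulate_study <- function(cfg = sim_config(), seed) {
  genome <- generate_genome(cfg, derive_seed(seed, 1))
  pv <- generate_peaks_and_variants(cfg, genome$chrom_sizes,
                                    derive_seed(seed, 2))
  hp <- generate_haplotype_panel(cfg, pv$variants, derive_seed(seed, 3))
  gpm <- assign_peaks_to_genes(pv$peaks, genome$genes)
  de <- generate_de_tables(cfg, genome$genes, gpm, derive_seed(seed, 4))
  windows <- peak_windows(pv$peaks, cfg$motif_window_width,
                          genome$chrom_sizes)
  mot <- generate_motif_instances(windows, cfg$motif_n_a, cfg$motif_n_b,
                                  cfg$motif_n_planted,
                                  cfg$motif_max_dist_bp,
                                  derive_seed(seed, 5))
  tis <- generate_tissue_cohort(cfg, derive_seed(seed, 6))
  list(chrom_sizes = genome$chrom_sizes, genes = genome$genes,
       peaks = pv$peaks, variants = pv$variants, panel = hp$panel,
       gene_peak_map = gpm, de_t1 = de$de_t1, de_t2 = de$de_t2,
       motif = list(windows = windows, a = mot$a, b = mot$b),
       tissue = tis[c("patients", "qpcr", "ihc_cores", "calibrator")],
       ground_truth = c(pv$ground_truth, hp$ground_truth,
                        de$ground_truth, mot$ground_truth,
                        tis$ground_truth),
       seed = seed)
}
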