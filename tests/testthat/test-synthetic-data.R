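test_that("generators are bit-reproducible from their seed", {
  cfg <- sim_config(n_genes = 50L, n_peaks = 60L,
                    n_background_snps = 40L, n_index_snps = 5L)
  g1 <- generate_genome(cfg, 7)
  g2 <- generate_genome(cfg, 7)
  expect_identical(g1, g2)
  pv1 <- generate_peaks_and_variants(cfg, g1$chrom_sizes, 8)
  pv2 <- generate_peaks_and_variants(cfg, g1$chrom_sizes, 8)
  expect_identical(pv1, pv2)
  s1 <- simulate_study(cfg, 9)
  s2 <- simulate_study(cfg, 9)
  expect_identical(s1, s2)
  expect_false(identical(generate_genome(cfg, 7), generate_genome(cfg, 8)))
})

test_that("genome generator respects sizes and represents both strands", {
  cfg <- sim_config(n_chromosomes = 2L, chrom_length_bp = 1e6,
                    n_genes = 100L, gene_max_length = 40000L)
  g <- generate_genome(cfg, 11)
  expect_equal(nrow(g$genes), 100)
  expect_true(all(g$genes$end <=
                    g$chrom_sizes$size[match(g$genes$chrom,
                                             g$chrom_sizes$chrom)]))
  expect_setequal(unique(g$genes$strand), c("+", "-"))
  # strand assignment is unbiased
  big <- generate_genome(sim_config(n_genes = 10000L), 12)
  frac <- mean(big$genes$strand == "+")
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / 10000))
})

test_that("planted in-peak fraction is honoured exactly", {
  sizes <- generate_genome(sim_config(), 21)$chrom_sizes
  for (f in c(0, 0.3, 1)) {
    cfg <- sim_config(planted_in_peak_fraction = f)
    pv <- generate_peaks_and_variants(cfg, sizes, 22)
    n_var <- cfg$n_index_snps + cfg$n_background_snps
    expect_equal(count_overlaps(pv$variants, pv$peaks)$count,
                 round(f * n_var))
    expect_equal(length(pv$ground_truth$planted_in_peak),
                 round(f * n_var))
  }
  expect_error(generate_peaks_and_variants(
    sim_config(n_peaks = 0L, planted_in_peak_fraction = 0.5), sizes, 23),
    "zero peaks|n_peaks is 0")
})

test_that("variant positions are globally distinct", {
  sizes <- generate_genome(sim_config(), 24)$chrom_sizes
  pv <- generate_peaks_and_variants(sim_config(), sizes, 25)
  expect_false(any(duplicated(paste(pv$variants$chrom, pv$variants$pos))))
})

test_that("haplotype blocks give perfect LD at zero mutation rate", {
  cfg <- sim_config(ld_mutation_rate = 0, ld_block_size = 4L,
                    n_background_snps = 20L, n_index_snps = 4L)
  sizes <- generate_genome(cfg, 31)$chrom_sizes
  pv <- generate_peaks_and_variants(cfg, sizes, 32)
  hp <- generate_haplotype_panel(cfg, pv$variants, 33)
  expect_equal(hp$ground_truth$ld_pairs$r2,
               rep(1, nrow(hp$ground_truth$ld_pairs)), tolerance = 1e-12)
})

test_that("recorded LD pairs are self-consistent and blocks are independent", {
  cfg <- sim_config()
  sizes <- generate_genome(cfg, 41)$chrom_sizes
  pv <- generate_peaks_and_variants(cfg, sizes, 42)
  hp <- generate_haplotype_panel(cfg, pv$variants, 43)
  lp <- hp$ground_truth$ld_pairs
  idx <- function(id) match(id, hp$panel$variants$id)
  for (k in sample.int(nrow(lp), 25)) {
    expect_equal(lp$r2[k],
                 compute_r2(hp$panel$alleles[, idx(lp$id_a[k])],
                            hp$panel$alleles[, idx(lp$id_b[k])]),
                 tolerance = 1e-12)
  }
  # across-block pairs: mean r2 near the 1/n_haplotypes independence scale
  set.seed(44)
  v <- hp$panel$variants
  cross <- replicate(300, {
    k <- sample.int(nrow(v), 2)
    key <- paste(sort(v$id[k]), collapse = "|")
    if (key %in% paste(lp$id_a, lp$id_b, sep = "|") ||
        key %in% paste(lp$id_b, lp$id_a, sep = "|")) NA_real_
    else compute_r2(hp$panel$alleles[, k[1]], hp$panel$alleles[, k[2]])
  })
  expect_lt(mean(cross, na.rm = TRUE), 5 / cfg$n_haplotypes)
})

test_that("DE decoys are never called and zero planting yields zero calls", {
  cfg <- sim_config(n_genes = 100L, de_n_primary = 30L)
  g <- generate_genome(cfg, 51)
  pv <- generate_peaks_and_variants(cfg, g$chrom_sizes, 52)
  map <- assign_peaks_to_genes(pv$peaks, g$genes)
  de <- generate_de_tables(cfg, g$genes, map, 53)
  calls <- suppressMessages(call_primary_targets(de$de_t1, de$de_t2, map))
  expect_setequal(primary_targets(calls), de$ground_truth$planted_primary)

  none <- generate_de_tables(sim_config(n_genes = 100L, de_n_primary = 0L),
                             g$genes, map, 54)
  calls0 <- suppressMessages(call_primary_targets(none$de_t1, none$de_t2,
                                                  map))
  expect_equal(calls0$n_primary, 0)
})

test_that("Hardy-Weinberg carrier fraction matches the closed form", {
  cfg <- sim_config(tissue_n_patients = 10000L, tissue_maf = 0.13)
  coh <- generate_tissue_cohort(cfg, 61)
  carrier_frac <- length(coh$ground_truth$carriers) / 10000
  expected <- 1 - 0.87^2  # 0.2431
  expect_lt(abs(carrier_frac - expected),
            4 * sqrt(expected * (1 - expected) / 10000))
})

test_that("noise-free cohorts separate carriers perfectly", {
  cfg <- sim_config(tissue_n_patients = 50L, tissue_beta = -100,
                    tissue_noise_sd = 1, qpcr_ct_noise_sd = 0)
  coh <- generate_tissue_cohort(cfg, 62)
  sc <- qpcr_expression_scores(coh$qpcr, coh$calibrator)
  sc$carrier <- sc$patient_id %in% coh$ground_truth$carriers
  expect_lt(max(sc$score[sc$carrier]), min(sc$score[!sc$carrier]))
})

test_that("qPCR back-computation recovers the latent expression", {
  cfg <- sim_config(tissue_n_patients = 30L, qpcr_ct_noise_sd = 0)
  coh <- generate_tissue_cohort(cfg, 63)
  sc <- qpcr_expression_scores(coh$qpcr, coh$calibrator)
  truth <- coh$ground_truth$expression
  sc$sample_id <- paste(sc$patient_id, sc$tissue, sep = "_")
  m <- dplyr::inner_join(sc, truth, by = "sample_id")
  expect_equal(m$score, m$expression, tolerance = 1e-10)
})

test_that("study inputs round-trip through the package readers", {
  cfg <- sim_config(n_genes = 40L, n_peaks = 50L, n_background_snps = 30L,
                    n_index_snps = 5L, de_n_primary = 10L,
                    tissue_n_patients = 10L, motif_n_a = 10L,
                    motif_n_b = 15L, motif_n_planted = 3L)
  s <- simulate_study(cfg, 71)
  dir <- withr::local_tempdir()
  write_study_inputs(s, dir)
  expect_identical(read_bed(file.path(dir, "peaks.bed"))$start,
                   s$peaks$start)
  v <- read_variants(file.path(dir, "variants.tsv"))
  expect_equal(v$id, s$variants$id)
  expect_equal(read_genes(file.path(dir, "genes.tsv"))$end, s$genes$end)
  expect_equal(read_chrom_sizes(file.path(dir, "chrom_sizes.tsv"))$size,
               s$chrom_sizes$size)
  panel <- read_haplotype_panel(file.path(dir, "panel.tsv"))
  expect_identical(unname(panel$alleles), unname(s$panel$alleles))
  gt <- jsonlite::read_json(file.path(dir, "ground_truth.json"),
                            simplifyVector = TRUE)
  expect_setequal(gt$planted_primary, s$ground_truth$planted_primary)
})
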