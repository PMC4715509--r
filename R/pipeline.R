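#' End-to-end study orchestration
#'
#' `write_study_inputs()` materialises a simulated study as the package's
#' standard plain-text formats; `run_study()` chains every analysis stage —
#' LD proxy expansion, peak-score filtering, overlap enrichment, target
#' calling, motif co-occurrence and the tissue report — over a simulated
#' study and writes machine-readable JSON/TSV reports plus a run manifest
#' (configuration echo, seed, package version, input checksums).
#'
#' @name pipeline
NULL

#' Write all study inputs to a directory
#'
#' @param study Output of [simulate_study()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study_inputs <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  write_bed(study$peaks, p("peaks.bed"))
  readr::write_tsv(study$variants, p("variants.tsv"))
  readr::write_tsv(study$genes, p("genes.tsv"))
  readr::write_tsv(study$chrom_sizes, p("chrom_sizes.tsv"))
  write_haplotype_panel(study$panel, p("panel.tsv"))
  readr::write_tsv(study$de_t1, p("de_t1.tsv"))
  readr::write_tsv(study$de_t2, p("de_t2.tsv"))
  write_bed(study$motif$windows, p("motif_windows.bed"))
  readr::write_tsv(study$motif$a, p("motif_a.tsv"))
  readr::write_tsv(study$motif$b, p("motif_b.tsv"))
  readr::write_tsv(study$tissue$patients, p("patients.tsv"))
  readr::write_tsv(study$tissue$qpcr, p("qpcr.tsv"))
  readr::write_tsv(study$tissue$ihc_cores, p("ihc_cores.tsv"))
  readr::write_tsv(study$tissue$calibrator, p("calibrator.tsv"))
  jsonlite::write_json(study$ground_truth, p("ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Run the full pipeline on a simulated study
#'
#' @param cfg A [sim_config()].
#' @param out_dir Directory for inputs, reports and the manifest.
#' @param seed Master integer seed (drives simulation and every stochastic
#'   stage).
#' @param n_sets Null sets for the enrichment test (default 1000 at desk
#'   scale; 10000 reproduces the full-scale setting).
#' @param r2_min LD threshold for proxy expansion (default 0.5).
#' @param min_score Peak-score threshold defining the binding-site universe
#'   (strict `>`, default 50).
#' @param alpha Adjusted-p cutoff for regulated genes (default 0.05).
#' @param max_dist_bp Motif co-occurrence distance (default 100).
#' @param window_bp Peak-to-gene window (default 50000).
#' @param n_perm Motif permutations (default 500).
#' @param conf_level Wilson interval confidence level (default 0.95).
#' @return A list with every stage result, invisibly; reports are written
#'   under `out_dir/reports`.
#' @export
run_study <- function(cfg = sim_config(), out_dir, seed, n_sets = 1000,
                      r2_min = 0.5, min_score = 50, alpha = 0.05,
                      max_dist_bp = 100, window_bp = 50000, n_perm = 500,
                      conf_level = 0.95) {
  if (n_sets < 1) abort("`n_sets` must be >= 1")
  study <- simulate_study(cfg, seed)
  in_dir <- file.path(out_dir, "inputs")
  write_study_inputs(study, in_dir)
  rep_dir <- file.path(out_dir, "reports")
  dir.create(rep_dir, showWarnings = FALSE, recursive = TRUE)

  arbs <- filter_peaks_by_score(study$peaks, min_score)
  index <- study$variants[study$variants$role == "index", ]
  ld <- expand_index_snps(index, study$panel, r2_min = r2_min)
  snp_set <- ld_variant_set(ld, study$panel)
  readr::write_tsv(ld, file.path(rep_dir, "ld_pairs.tsv"))

  enr <- enrichment_test(study$variants, arbs, study$chrom_sizes,
                         n_sets = n_sets, conf_level = conf_level,
                         seed = derive_seed(seed, 10))
  jsonlite::write_json(as.list(glance(enr)),
                       file.path(rep_dir, "enrichment.json"),
                       auto_unbox = TRUE, digits = NA)
  readr::write_tsv(tidy(enr), file.path(rep_dir, "null_counts.tsv"))

  gpm <- assign_peaks_to_genes(arbs, study$genes, window_bp = window_bp)
  calls <- call_primary_targets(study$de_t1, study$de_t2, gpm,
                                alpha = alpha)
  jsonlite::write_json(as.list(glance(calls)),
                       file.path(rep_dir, "target_calls.json"),
                       auto_unbox = TRUE, digits = NA)
  readr::write_tsv(tidy(calls), file.path(rep_dir, "target_calls.tsv"))

  mot <- coincidence_null(study$motif$a, study$motif$b,
                          study$motif$windows, n_perm = n_perm,
                          max_dist_bp = max_dist_bp,
                          seed = derive_seed(seed, 11))
  jsonlite::write_json(as.list(glance(mot)),
                       file.path(rep_dir, "motif_cooccurrence.json"),
                       auto_unbox = TRUE, digits = NA)

  scores <- qpcr_expression_scores(study$tissue$qpcr,
                                   study$tissue$calibrator)
  tissue_report <- suppressWarnings(
    stratified_expression_report(scores, study$tissue$patients,
                                 snp = "rs11891426", risk_allele = "G"))
  readr::write_tsv(tissue_report, file.path(rep_dir, "tissue_report.tsv"))

  manifest <- list(
    package = "peakrisk",
    version = as.character(utils::packageVersion("peakrisk")),
    seed = seed,
    parameters = list(n_sets = n_sets, r2_min = r2_min,
                      min_score = min_score, alpha = alpha,
                      max_dist_bp = max_dist_bp, window_bp = window_bp,
                      n_perm = n_perm, conf_level = conf_level),
    sim_config = unclass(cfg),
    input_checksums = as.list(tools::md5sum(list.files(in_dir,
                                                       full.names = TRUE))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)

  invisible(list(study = study, arbs = arbs, ld = ld,
                 snp_set = snp_set, enrichment = enr,
                 gene_peak_map = gpm, target_calls = calls,
                 motif = mot, tissue_report = tissue_report))
}
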