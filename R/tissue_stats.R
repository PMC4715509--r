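#' Tissue-level quantification and genotype-stratified statistics
#'
#' Efficiency-corrected relative qPCR expression (the Pfaffl ratio),
#' immunohistochemistry immunoreactivity scores, and the group comparisons
#' used on patient cohorts: Welch's unpaired t-test, Pearson correlation,
#' and chi-square tests on genotype contingency tables.
#'
#' @name tissue_stats
NULL

#' Pfaffl efficiency-corrected relative expression ratio
#'
#' R = E_target^dCt_target / E_reference^dCt_reference, where each dCt is
#' Ct(calibrator) - Ct(sample) and E is the per-assay amplification
#' efficiency (2 = perfect doubling per cycle). With both efficiencies equal
#' to 2 this reduces to the classic 2^-ddCt quantity.
#'
#' @param e_target,e_ref Amplification efficiencies (> 1; nominally <= 2).
#' @param dct_target,dct_ref Ct(calibrator) - Ct(sample) for the target and
#'   reference assays.
#' @return The relative expression ratio (> 0). Vectorized.
#' @export
#' @examples
#' pfaffl_ratio(2, 1, 2, 0)  # one extra target doubling: 2
pfaffl_ratio <- function(e_target, dct_target, e_ref, dct_ref) {
  if (any(e_target <= 1) || any(e_ref <= 1)) {
    abort("amplification efficiencies must be > 1")
  }
  if (any(e_target > 2.1) || any(e_ref > 2.1)) {
    warn("efficiency above 2.1: more than doubling per cycle is implausible")
  }
  e_target^dct_target / e_ref^dct_ref
}

#' Amplification efficiency from a standard-curve slope
#'
#' Convenience for dilution-series standard curves: E = 10^(-1/slope); a
#' slope of -3.3219 gives E = 2.
#'
#' @param slope Slope of Ct versus log10 input amount (negative).
#' @return Efficiency per cycle.
#' @export
efficiency_from_slope <- function(slope) {
  if (any(slope >= 0)) abort("standard-curve slopes must be negative")
  10^(-1 / slope)
}

#' Immunoreactivity score for one patient and tissue
#'
#' Per tissue core the score is mean staining intensity times the percentage
#' of positively stained cells; the patient score is the arithmetic mean
#' over the available cores (up to three per tissue type).
#'
#' @param cores Tibble with columns `patient_id`, `tissue`, `mean_intensity`
#'   (>= 0) and `pct_positive` (0-100), all rows from one patient and one
#'   tissue type.
#' @return The mean immunoreactivity score (scalar).
#' @export
#' @examples
#' cores <- tibble::tibble(patient_id = "P1", tissue = "cancer",
#'                         mean_intensity = c(8, 12, 10),
#'                         pct_positive = c(25, 50, 40))
#' ihc_patient_score(cores)  # mean of 200, 600, 400 = 400
ihc_patient_score <- function(cores) {
  stop_if_missing_cols(cores, c("patient_id", "tissue", "mean_intensity",
                                "pct_positive"), "`cores`")
  if (nrow(cores) < 1 || nrow(cores) > 3) {
    abort("a patient/tissue score uses 1 to 3 cores")
  }
  if (length(unique(cores$patient_id)) > 1) {
    abort("`cores` mixes patients")
  }
  if (length(unique(cores$tissue)) > 1) {
    abort("`cores` mixes tissue types; score benign and cancer separately")
  }
  if (any(cores$pct_positive < 0 | cores$pct_positive > 100)) {
    abort("pct_positive must lie in [0, 100]")
  }
  if (any(cores$mean_intensity < 0)) abort("mean_intensity must be >= 0")
  mean(cores$mean_intensity * cores$pct_positive)
}

#' Immunoreactivity scores for a whole cohort
#'
#' Applies [ihc_patient_score()] per patient and tissue type.
#'
#' @param cores Core tibble for many patients (same columns as
#'   [ihc_patient_score()]).
#' @return Tibble with `patient_id`, `tissue`, `score`, `n_cores`.
#' @export
ihc_cohort_scores <- function(cores) {
  stop_if_missing_cols(cores, c("patient_id", "tissue", "mean_intensity",
                                "pct_positive"), "`cores`")
  cores %>%
    group_by(.data$patient_id, .data$tissue) %>%
    summarise(score = mean(.data$mean_intensity * .data$pct_positive),
              n_cores = dplyr::n(), .groups = "drop")
}

#' Welch's unpaired two-sample comparison
#'
#' Welch-Satterthwaite t statistic, degrees of freedom and two-sided
#' p-value (unequal variances assumed).
#'
#' @param group_a,group_b Numeric vectors, each of length >= 2.
#' @return One-row tibble with `t`, `df`, `p`, `mean_a`, `mean_b`, `n_a`,
#'   `n_b`.
#' @export
welch_compare <- function(group_a, group_b) {
  if (length(group_a) < 2 || length(group_b) < 2) {
    abort("each group needs at least 2 observations")
  }
  if (any(!is.finite(group_a)) || any(!is.finite(group_b))) {
    abort("groups must be finite")
  }
  if (sd(group_a) == 0 && sd(group_b) == 0) {
    abort("both groups are constant: Welch comparison is degenerate")
  }
  tt <- t.test(group_a, group_b, var.equal = FALSE)
  tibble(t = unname(tt$statistic), df = unname(tt$parameter),
         p = tt$p.value, mean_a = mean(group_a), mean_b = mean(group_b),
         n_a = length(group_a), n_b = length(group_b))
}

#' Pearson correlation with a t-based p-value
#'
#' @param x,y Equal-length numeric vectors (n >= 3).
#' @return One-row tibble with `r`, `df`, `p`, `n`.
#' @export
pearson_corr <- function(x, y) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length")
  if (length(x) < 3) abort("need at least 3 paired observations")
  if (sd(x) == 0 || sd(y) == 0) {
    abort("correlation is undefined for a zero-variance input")
  }
  ct <- cor.test(x, y, method = "pearson")
  tibble(r = unname(ct$estimate), df = unname(ct$parameter),
         p = ct$p.value, n = length(x))
}

#' Pearson chi-square test on a genotype contingency table
#'
#' No continuity correction; df = (rows - 1) * (cols - 1).
#'
#' @param counts Matrix (or data frame) of non-negative integer counts; all
#'   row and column sums must be positive.
#' @return One-row tibble with `chi2`, `df`, `p`.
#' @export
genotype_table_test <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts))) {
    abort("counts must be non-negative integers")
  }
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    abort("a zero row or column marginal makes the test undefined")
  }
  ct <- suppressWarnings(chisq.test(counts, correct = FALSE))
  tibble(chi2 = unname(ct$statistic), df = unname(ct$parameter),
         p = ct$p.value)
}

#' Genotype-stratified expression comparison
#'
#' Compares a per-patient score between risk-allele carriers and
#' non-carriers under a dominant model (heterozygotes pooled with minor
#' homozygotes), per stratum: all samples, then each tissue type present.
#' Strata with fewer than 2 patients in either group are reported with a
#' warning and NA statistics.
#'
#' @param scores Tibble with `patient_id`, `tissue`, `score` (for example
#'   from [ihc_cohort_scores()]).
#' @param patients Tibble with `patient_id` and one genotype column per SNP
#'   (strings like `"T/T"`, `"T/G"`).
#' @param snp Name of the genotype column to stratify on.
#' @param risk_allele Single-letter allele whose carriers form the risk
#'   group.
#' @return Tibble, one row per stratum, with group sizes, means, Welch `t`,
#'   `df` and `p`.
#' @export
stratified_expression_report <- function(scores, patients, snp,
                                         risk_allele) {
  stop_if_missing_cols(scores, c("patient_id", "tissue", "score"),
                       "`scores`")
  stop_if_missing_cols(patients, c("patient_id", snp), "`patients`")
  dat <- dplyr::inner_join(scores,
                           patients[, c("patient_id", snp)],
                           by = "patient_id")
  alleles <- strsplit(dat[[snp]], "/", fixed = TRUE)
  dat$carrier <- vapply(alleles, function(a) risk_allele %in% a, logical(1))
  strata <- c("all", sort(unique(dat$tissue)))
  purrr::map_dfr(strata, function(s) {
    d <- if (s == "all") dat else dat[dat$tissue == s, ]
    ca <- d$score[d$carrier]
    nc <- d$score[!d$carrier]
    base <- tibble(stratum = s, snp = snp, risk_allele = risk_allele,
                   n_carrier = length(ca), n_noncarrier = length(nc),
                   mean_carrier = if (length(ca)) mean(ca) else NA_real_,
                   mean_noncarrier = if (length(nc)) mean(nc) else NA_real_)
    if (length(ca) < 2 || length(nc) < 2) {
      warn(sprintf(
        "stratum '%s': fewer than 2 patients in a genotype group; comparison skipped",
        s))
      return(dplyr::mutate(base, t = NA_real_, df = NA_real_, p = NA_real_))
    }
    w <- welch_compare(ca, nc)
    dplyr::mutate(base, t = w$t, df = w$df, p = w$p)
  })
}

#' Per-genotype score summary
#'
#' Companion to the dominant-model comparison: group sizes and means for
#' each individual genotype, per stratum.
#'
#' @inheritParams stratified_expression_report
#' @return Tibble with one row per stratum and genotype.
#' @export
genotype_score_summary <- function(scores, patients, snp) {
  stop_if_missing_cols(scores, c("patient_id", "tissue", "score"),
                       "`scores`")
  dat <- dplyr::inner_join(scores, patients[, c("patient_id", snp)],
                           by = "patient_id")
  dat$genotype <- dat[[snp]]
  dplyr::bind_rows(
    dat %>% dplyr::mutate(stratum = "all"),
    dat %>% dplyr::mutate(stratum = .data$tissue)) %>%
    group_by(.data$stratum, .data$genotype) %>%
    summarise(n = dplyr::n(), mean_score = mean(.data$score),
              sd_score = sd(.data$score), .groups = "drop")
}
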