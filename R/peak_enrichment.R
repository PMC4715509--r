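#' Matched random-peak permutation enrichment test
#'
#' Tests whether a variant set overlaps a peak set more often than expected
#' by chance. The null model draws random peak sets that match the observed
#' peaks exactly in chromosome and length, placing each peak uniformly on its
#' chromosome. The empirical p-value is the fraction of null sets whose
#' distinct-variant overlap count reaches the observed count, and its
#' uncertainty is summarised by a Wilson score confidence interval — the
#' score interval remains informative even when no null set reaches the
#' observed count.
#'
#' @name peak_enrichment
NULL

#' Wilson score confidence interval for a binomial proportion
#'
#' For x successes in n trials at confidence level `conf_level`, the interval
#' is centred at (p + z^2/2n) / (1 + z^2/n) with half-width
#' z * sqrt(p(1-p)/n + z^2/4n^2) / (1 + z^2/n), where p = x/n and z is the
#' standard-normal quantile. At x = 0 the lower bound is exactly 0 and the
#' upper bound is z^2 / (n + z^2).
#'
#' @param x Number of successes (0 <= x <= n).
#' @param n Number of trials (>= 1).
#' @param conf_level Confidence level in (0, 1); default 0.95.
#' @return One-row tibble with columns `estimate` (x/n), `low`, `high`.
#' @export
#' @examples
#' wilson_interval(0, 10000, 0.95)  # upper bound ~ 3.84e-4
wilson_interval <- function(x, n, conf_level = 0.95) {
  if (length(x) != 1 || length(n) != 1) abort("`x` and `n` must be scalars")
  if (n < 1) abort("`n` must be >= 1")
  if (x < 0 || x > n) abort("`x` must satisfy 0 <= x <= n")
  if (!(conf_level > 0 && conf_level < 1)) {
    abort("`conf_level` must be in (0, 1)")
  }
  z <- qnorm(1 - (1 - conf_level) / 2)
  p <- x / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  tibble(estimate = p,
         low = if (x == 0) 0 else max(0, centre - half),
         high = if (x == n) 1 else min(1, centre + half))
}

# shared placement engine: draw `n_sets` uniform starts for each peak on its
# own chromosome, on a concatenated coordinate axis. Returns a list with
# absolute starts (0-based), widths and set ids, peak-major order.
place_matched <- function(peaks, chrom_sizes, n_sets) {
  sz <- setNames(as.double(chrom_sizes$size), chrom_sizes$chrom)
  off <- chrom_offsets(chrom_sizes)
  missing <- setdiff(unique(peaks$chrom), names(sz))
  if (length(missing) > 0) {
    abort(sprintf("peak chromosome(s) absent from chrom_sizes: %s",
                  paste(missing, collapse = ", ")))
  }
  len <- as.double(peaks$end - peaks$start)
  max_start <- sz[peaks$chrom] - len
  if (any(max_start < 0)) {
    abort("a peak is longer than its chromosome; cannot place matched peaks")
  }
  n_peaks <- nrow(peaks)
  u <- runif(n_sets * n_peaks)
  span <- rep(max_start + 1, each = n_sets)
  start_local <- pmin(floor(u * span), rep(max_start, each = n_sets))
  list(abs_start = rep(off[peaks$chrom], each = n_sets) + start_local,
       width = rep(len, each = n_sets),
       set_id = rep.int(seq_len(n_sets), n_peaks),
       peak_idx = rep(seq_len(n_peaks), each = n_sets),
       start_local = start_local)
}

#' Simulate one chromosome- and size-matched random peak set
#'
#' Returns one random peak per input peak with identical chromosome and
#' length; the start is drawn uniformly from the placements that keep the
#' peak on its chromosome. Deterministic given `seed`.
#'
#' @param peaks Peak tibble.
#' @param chrom_sizes Tibble with `chrom`, `size`.
#' @param seed Integer RNG seed.
#' @return Peak tibble with the input's `name` and `score` carried over.
#' @export
simulate_matched_peaks <- function(peaks, chrom_sizes, seed) {
  peaks <- ensure_peak_names(validate_peaks(peaks))
  pl <- with_seed(seed, place_matched(peaks, chrom_sizes, n_sets = 1L))
  out <- peaks
  out$start <- as.integer(pl$start_local[order(pl$peak_idx)])
  out$end <- out$start + (peaks$end - peaks$start)
  out
}

#' Permutation enrichment of variants in peaks
#'
#' Computes the observed distinct-variant overlap count, then `n_sets` null
#' counts on chromosome/size-matched random peak sets, and summarises:
#' the empirical p-value `exceedances / n_sets` (an exceedance is a null
#' count at least — or, with `exceedance = "gt"`, strictly above — the
#' observed count), the add-one estimate `(exceedances + 1) / (n_sets + 1)`,
#' and the Wilson score interval for the exceedance proportion.
#'
#' @param variants Variant tibble (`id`, `chrom`, `pos`), unique ids.
#' @param peaks Peak tibble.
#' @param chrom_sizes Tibble with `chrom`, `size`; must cover every peak
#'   chromosome.
#' @param n_sets Number of null sets (default 10000).
#' @param conf_level Confidence level for the Wilson interval (default 0.95).
#' @param seed Integer RNG seed; the whole test is reproducible from it.
#' @param exceedance `"geq"` (default, conservative) or `"gt"`.
#' @return An object of class `enrichment_result`; see [tidy.enrichment_result()]
#'   and [glance.enrichment_result()].
#' @export
enrichment_test <- function(variants, peaks, chrom_sizes, n_sets = 10000,
                            conf_level = 0.95, seed,
                            exceedance = c("geq", "gt")) {
  exceedance <- match.arg(exceedance)
  variants <- validate_variants(variants)
  peaks <- ensure_peak_names(validate_peaks(peaks))
  if (nrow(variants) == 0) abort("`variants` must be non-empty")
  if (nrow(peaks) == 0) abort("`peaks` must be non-empty")
  if (n_sets < 1) abort("`n_sets` must be >= 1")
  observed <- count_overlaps(variants, peaks)$count

  off <- chrom_offsets(chrom_sizes)
  v_in <- variants[variants$chrom %in% names(off), , drop = FALSE]
  v_query <- IRanges::IRanges(
    start = as.integer(off[v_in$chrom] + v_in$pos), width = 1L)
  n_var <- nrow(v_in)

  null_counts <- integer(n_sets)
  n_peaks <- nrow(peaks)
  chunk <- max(1L, as.integer(2e6 %/% max(1L, n_peaks)))
  with_seed(seed, {
    done <- 0L
    while (done < n_sets) {
      n_c <- min(chunk, n_sets - done)
      pl <- place_matched(peaks, chrom_sizes, n_c)
      if (n_var > 0) {
        subj <- IRanges::IRanges(start = as.integer(pl$abs_start + 1),
                                 width = as.integer(pl$width))
        h <- IRanges::findOverlaps(v_query, subj)
        if (length(h) > 0) {
          set_of_hit <- pl$set_id[S4Vectors::subjectHits(h)]
          key <- (as.double(set_of_hit) - 1) * n_var +
            S4Vectors::queryHits(h)
          uniq <- !duplicated(key)
          null_counts[done + seq_len(n_c)] <-
            tabulate(set_of_hit[uniq], nbins = n_c)
        }
      }
      done <- done + n_c
    }
  })

  exceed <- if (exceedance == "geq") sum(null_counts >= observed)
            else sum(null_counts > observed)
  wi <- wilson_interval(exceed, n_sets, conf_level)
  structure(list(observed = observed,
                 null_counts = null_counts,
                 exceedances = as.integer(exceed),
                 p_empirical = exceed / n_sets,
                 p_addone = (exceed + 1) / (n_sets + 1),
                 wilson_low = wi$low,
                 wilson_high = wi$high,
                 n_sets = as.integer(n_sets),
                 conf_level = conf_level,
                 seed = seed,
                 exceedance = exceedance,
                 n_variants = nrow(variants),
                 n_peaks = n_peaks),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat("<enrichment_result>\n")
  cat(sprintf("  observed overlap: %d of %d variants in %d peaks\n",
              x$observed, x$n_variants, x$n_peaks))
  cat(sprintf("  null sets: %d (matched chromosome & size), seed %s\n",
              x$n_sets, format(x$seed)))
  cat(sprintf("  exceedances: %d  p_empirical = %.3g  (add-one %.3g)\n",
              x$exceedances, x$p_empirical, x$p_addone))
  cat(sprintf("  Wilson %d%% CI for exceedance proportion: [%.3g, %.3g]\n",
              round(100 * x$conf_level), x$wilson_low, x$wilson_high))
  invisible(x)
}

#' Tidy and one-row summaries of an enrichment result
#'
#' `tidy()` returns the null distribution (one row per null set);
#' `glance()` returns the one-row test summary.
#'
#' @param x An `enrichment_result`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy enrichment_result
#' @export
tidy.enrichment_result <- function(x, ...) {
  tibble(set = seq_len(x$n_sets), null_count = x$null_counts)
}

#' @rdname tidy.enrichment_result
#' @method glance enrichment_result
#' @export
glance.enrichment_result <- function(x, ...) {
  tibble(observed = x$observed, n_variants = x$n_variants,
         n_peaks = x$n_peaks, n_sets = x$n_sets,
         exceedances = x$exceedances, p_empirical = x$p_empirical,
         p_addone = x$p_addone, wilson_low = x$wilson_low,
         wilson_high = x$wilson_high, conf_level = x$conf_level,
         seed = x$seed)
}

#' Plot the null overlap distribution with the observed count
#'
#' @param object An `enrichment_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot enrichment_result
#' @export
autoplot.enrichment_result <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$null_count)) +
    ggplot2::geom_histogram(binwidth = 1, fill = "grey70",
                            colour = "grey40") +
    ggplot2::geom_vline(xintercept = object$observed, colour = "firebrick",
                        linewidth = 0.8) +
    ggplot2::labs(
      x = "variants overlapping matched random peaks",
      y = "null sets",
      title = sprintf("observed = %d; p_empirical = %.3g",
                      object$observed, object$p_empirical)) +
    ggplot2::theme_minimal()
}
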