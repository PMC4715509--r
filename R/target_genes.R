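#' Peak-to-gene assignment and primary target calling
#'
#' A gene is a potential target if a peak overlaps a window of `window_bp`
#' around its transcription start site (TSS, strand-aware) or lies anywhere
#' within the gene body. Primary targets are genes regulated in the same
#' direction at two post-stimulation timepoints (Benjamini-Hochberg adjusted
#' p at or below alpha at both) that also carry at least one assigned peak.
#'
#' @name target_genes
NULL

gene_tss <- function(genes, ignore_strand = FALSE) {
  if (ignore_strand) genes$start
  else ifelse(genes$strand == "+", genes$start, genes$end - 1L)
}

#' Assign peaks to genes by the TSS-window + gene-body rule
#'
#' Gene g receives peak p iff p overlaps the half-open window
#' `[TSS - window_bp, TSS + window_bp)` or overlaps the gene body
#' `[start, end)` (>= 1 shared bp either way). A peak may map to several
#' genes and a gene may receive several peaks.
#'
#' @param peaks Peak tibble.
#' @param genes Gene tibble (`id`, `chrom`, `strand`, `start`, `end`).
#' @param window_bp Window half-width around the TSS in bp (default 50000).
#'   `window_bp = 0` reduces the rule to gene-body overlap only.
#' @param ignore_strand If `TRUE`, the plain `start` coordinate is used as
#'   the TSS for both strands.
#' @return Tibble with columns `gene_id`, `peak_name` (one row per
#'   assignment), sorted by gene then peak.
#' @export
assign_peaks_to_genes <- function(peaks, genes, window_bp = 50000,
                                  ignore_strand = FALSE) {
  peaks <- ensure_peak_names(validate_peaks(peaks))
  genes <- validate_genes(genes)
  if (window_bp < 0) abort("`window_bp` must be >= 0")
  if (nrow(peaks) == 0 || nrow(genes) == 0) {
    return(tibble(gene_id = character(), peak_name = character()))
  }
  tss <- gene_tss(genes, ignore_strand)
  # per gene, the union of the two clause intervals, kept as two subject
  # ranges tagged with the gene row
  win_start <- pmax(0, tss - window_bp)
  win_end <- tss + window_bp
  out <- purrr::map_dfr(intersect(unique(peaks$chrom), unique(genes$chrom)),
    function(cc) {
      p <- peaks[peaks$chrom == cc, , drop = FALSE]
      gi <- which(genes$chrom == cc)
      subj_start <- c(win_start[gi], genes$start[gi])
      subj_end <- c(win_end[gi], genes$end[gi])
      gene_of <- c(gi, gi)
      keep <- subj_start < subj_end
      q <- IRanges::IRanges(start = p$start + 1L, end = p$end)
      s <- IRanges::IRanges(start = subj_start[keep] + 1L,
                            end = subj_end[keep])
      h <- IRanges::findOverlaps(q, s)
      tibble(gene_id = genes$id[gene_of[keep][S4Vectors::subjectHits(h)]],
             peak_name = p$name[S4Vectors::queryHits(h)])
    })
  if (nrow(out) == 0) {
    return(tibble(gene_id = character(), peak_name = character()))
  }
  dplyr::arrange(dplyr::distinct(out), .data$gene_id, .data$peak_name)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Standard BH adjusted p-values (clipped to 1), as used to define
#' regulated genes at an adjusted-p cutoff.
#'
#' @param p_values Numeric vector of raw p-values in \[0, 1\].
#' @return Adjusted p-values, same order as the input.
#' @export
bh_adjust <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0) || any(p_values > 1)) {
    abort("p-values must lie in [0, 1]")
  }
  p.adjust(p_values, method = "BH")
}

validate_de <- function(de, what) {
  stop_if_missing_cols(de, c("gene_id", "log_fc", "p_adj"), what)
  de <- as_tibble(de)
  if (nrow(de) > 0) {
    if (any(de$p_adj < 0 | de$p_adj > 1, na.rm = TRUE)) {
      abort(sprintf("%s: p_adj must lie in [0, 1]", what))
    }
    if (any(!is.finite(de$log_fc))) {
      abort(sprintf("%s: log_fc must be finite", what))
    }
    if (anyDuplicated(de$gene_id)) {
      abort(sprintf("%s: duplicate gene_id", what))
    }
  }
  de
}

#' Call primary target genes from two-timepoint differential expression
#'
#' A gene is regulated at a timepoint iff its adjusted p-value is at or
#' below `alpha`; regulated in the same direction iff regulated at both
#' timepoints with equal (nonzero) sign of log fold-change; primary iff
#' additionally it has at least one assigned peak. A gene present in only
#' one table is treated as not regulated at the missing timepoint.
#'
#' @param de_t1,de_t2 Tibbles with `gene_id`, `log_fc`, `p_adj` (one row per
#'   gene, BH-adjusted p-values).
#' @param gene_peak_map Assignment tibble from [assign_peaks_to_genes()].
#' @param alpha Adjusted-p cutoff (default 0.05, boundary included).
#' @return An object of class `target_calls` with a per-gene tibble and
#'   summary counts; see [tidy.target_calls()] and [glance.target_calls()].
#' @export
call_primary_targets <- function(de_t1, de_t2, gene_peak_map, alpha = 0.05) {
  de_t1 <- validate_de(de_t1, "de_t1")
  de_t2 <- validate_de(de_t2, "de_t2")
  stop_if_missing_cols(gene_peak_map, c("gene_id", "peak_name"),
                       "gene_peak_map")
  one_sided <- setdiff(union(de_t1$gene_id, de_t2$gene_id),
                       intersect(de_t1$gene_id, de_t2$gene_id))
  if (length(one_sided) > 0) {
    inform(sprintf(
      "%d gene(s) present at only one timepoint; treated as not regulated at the other",
      length(one_sided)))
  }
  genes <- dplyr::full_join(
    dplyr::rename(de_t1, log_fc_t1 = "log_fc", p_adj_t1 = "p_adj"),
    dplyr::rename(de_t2, log_fc_t2 = "log_fc", p_adj_t2 = "p_adj"),
    by = "gene_id")
  genes <- dplyr::mutate(
    genes,
    regulated_t1 = !is.na(.data$p_adj_t1) & .data$p_adj_t1 <= alpha,
    regulated_t2 = !is.na(.data$p_adj_t2) & .data$p_adj_t2 <= alpha,
    same_direction = .data$regulated_t1 & .data$regulated_t2 &
      sign(.data$log_fc_t1) == sign(.data$log_fc_t2) &
      sign(.data$log_fc_t1) != 0,
    has_arbs = .data$gene_id %in% unique(gene_peak_map$gene_id),
    primary = .data$same_direction & .data$has_arbs)
  genes <- dplyr::arrange(genes, .data$gene_id)
  structure(list(genes = genes, alpha = alpha,
                 n_regulated_t1 = sum(genes$regulated_t1),
                 n_regulated_t2 = sum(genes$regulated_t2),
                 n_same_direction = sum(genes$same_direction),
                 n_with_arbs = sum(genes$has_arbs),
                 n_primary = sum(genes$primary)),
            class = "target_calls")
}

#' @export
print.target_calls <- function(x, ...) {
  cat("<target_calls>\n")
  cat(sprintf("  regulated (p_adj <= %g): t1 %d, t2 %d\n",
              x$alpha, x$n_regulated_t1, x$n_regulated_t2))
  cat(sprintf("  same direction at both timepoints: %d\n",
              x$n_same_direction))
  cat(sprintf("  with >= 1 assigned peak: %d\n", x$n_with_arbs))
  cat(sprintf("  primary targets: %d\n", x$n_primary))
  invisible(x)
}

#' Tidy and one-row summaries of target calls
#'
#' `tidy()` returns the per-gene call table; `glance()` the category counts.
#'
#' @param x A `target_calls` object.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy target_calls
#' @export
tidy.target_calls <- function(x, ...) as_tibble(x$genes)

#' @rdname tidy.target_calls
#' @method glance target_calls
#' @export
glance.target_calls <- function(x, ...) {
  tibble(n_regulated_t1 = x$n_regulated_t1,
         n_regulated_t2 = x$n_regulated_t2,
         n_same_direction = x$n_same_direction,
         n_with_arbs = x$n_with_arbs,
         n_primary = x$n_primary,
         alpha = x$alpha)
}

#' Extract the gene ids called primary
#'
#' @param x A `target_calls` object.
#' @return Character vector of primary target gene ids.
#' @export
primary_targets <- function(x) {
  stopifnot(inherits(x, "target_calls"))
  x$genes$gene_id[x$genes$primary]
}

#' Signed distances from peak centres to the nearest TSS
#'
#' For every peak, the signed distance from its midpoint to the nearest TSS
#' among genes on the same chromosome. Distances are negated for minus-strand
#' genes so that positive always means downstream of the TSS in the gene's
#' reading direction. Ties in distance are broken by the lexicographically
#' smaller gene id.
#'
#' @param peaks Peak tibble.
#' @param genes Gene tibble.
#' @param ignore_strand Use the plain start coordinate as the TSS.
#' @return Tibble with `peak_name`, `gene_id`, `distance` (bp); peaks with no
#'   same-chromosome gene are dropped.
#' @export
tss_distances <- function(peaks, genes, ignore_strand = FALSE) {
  peaks <- ensure_peak_names(validate_peaks(peaks))
  genes <- validate_genes(genes)
  tss <- gene_tss(genes, ignore_strand)
  purrr::map_dfr(seq_len(nrow(peaks)), function(i) {
    gi <- which(genes$chrom == peaks$chrom[i])
    if (length(gi) == 0) return(NULL)
    mid <- (peaks$start[i] + peaks$end[i]) / 2
    d_raw <- mid - tss[gi]
    d <- ifelse(genes$strand[gi] == "-" & !ignore_strand, -d_raw, d_raw)
    ord <- order(abs(d), genes$id[gi])
    j <- ord[1]
    tibble(peak_name = peaks$name[i], gene_id = genes$id[gi[j]],
           distance = d[j])
  })
}

#' Histogram of peak-to-TSS distances
#'
#' Bins the signed nearest-TSS distances from [tss_distances()]. Counts sum
#' to the number of peaks that have a gene on their chromosome.
#'
#' @inheritParams tss_distances
#' @param bins Numeric vector of bin edges in bp (left-closed,
#'   right-open; distances outside the edges are dropped).
#' @return Tibble with `bin_start`, `bin_end`, `count`.
#' @export
tss_distance_profile <- function(peaks, genes,
                                 bins = seq(-50000, 50000, by = 5000),
                                 ignore_strand = FALSE) {
  d <- tss_distances(peaks, genes, ignore_strand)
  idx <- findInterval(d$distance, bins, rightmost.closed = FALSE)
  idx[d$distance >= bins[length(bins)]] <- NA
  idx[idx == 0] <- NA
  counts <- tabulate(idx[!is.na(idx)], nbins = length(bins) - 1)
  tibble(bin_start = bins[-length(bins)], bin_end = bins[-1],
         count = counts)
}

#' Plot a TSS distance profile
#'
#' @param profile Output of [tss_distance_profile()].
#' @return A ggplot.
#' @export
plot_tss_profile <- function(profile) {
  ggplot2::ggplot(profile,
                  ggplot2::aes(x = (.data$bin_start + .data$bin_end) / 2,
                               y = .data$count)) +
    ggplot2::geom_col(fill = "steelblue", width = NULL) +
    ggplot2::labs(x = "peak centre - TSS distance (bp, + = downstream)",
                  y = "peaks") +
    ggplot2::theme_minimal()
}
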