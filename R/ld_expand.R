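#' Haplotype panels and linkage-disequilibrium proxy expansion
#'
#' A haplotype panel holds phased biallelic alleles (0 = major/reference,
#' 1 = minor/alternate) for a set of variants across haplotypes. Pairwise
#' r-squared is computed by direct haplotype counting, and GWAS index
#' variants are expanded to linked proxies at a configurable r-squared
#' threshold within a genomic window.
#'
#' @name ld_expand
NULL

#' Construct a haplotype panel
#'
#' @param variants Variant tibble (`id`, `chrom`, `pos`), one row per column
#'   of `alleles`, in the same order.
#' @param alleles Integer/numeric matrix, haplotypes x variants, entries 0/1.
#'   Column names, if absent, are set to the variant ids.
#' @return An object of class `haplotype_panel`.
#' @export
haplotype_panel <- function(variants, alleles) {
  variants <- validate_variants(variants)
  alleles <- as.matrix(alleles)
  if (ncol(alleles) != nrow(variants)) {
    abort("`alleles` must have one column per variant row")
  }
  if (nrow(alleles) < 2) abort("a panel needs at least 2 haplotypes")
  if (!all(alleles %in% c(0, 1))) {
    abort("panel alleles must be coded 0/1 (biallelic, phased)")
  }
  storage.mode(alleles) <- "integer"
  colnames(alleles) <- variants$id
  structure(list(variants = variants, alleles = alleles,
                 n_haplotypes = nrow(alleles)),
            class = "haplotype_panel")
}

#' @export
print.haplotype_panel <- function(x, ...) {
  cat(sprintf("<haplotype_panel> %d haplotypes x %d variants on %d chromosome(s)\n",
              x$n_haplotypes, nrow(x$variants),
              length(unique(x$variants$chrom))))
  invisible(x)
}

#' Read/write a haplotype panel as TSV
#'
#' Wide format: columns `id`, `chrom`, `pos`, then one 0/1 column per
#' haplotype (`hap_1`, `hap_2`, ...). One row per variant.
#'
#' @param path Path to the TSV file.
#' @return For the reader, a `haplotype_panel`; the writer returns `path`
#'   invisibly.
#' @export
read_haplotype_panel <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  meta_cols <- c("id", "chrom", "pos")
  stop_if_missing_cols(df, meta_cols, "haplotype panel")
  hap_cols <- setdiff(names(df), meta_cols)
  if (length(hap_cols) < 2) abort("panel must contain >= 2 haplotype columns")
  alleles <- t(as.matrix(df[hap_cols]))
  haplotype_panel(df[meta_cols], alleles)
}

#' @rdname read_haplotype_panel
#' @param panel A `haplotype_panel`.
#' @export
write_haplotype_panel <- function(panel, path) {
  stopifnot(inherits(panel, "haplotype_panel"))
  hap <- as.data.frame(t(panel$alleles))
  names(hap) <- sprintf("hap_%d", seq_len(panel$n_haplotypes))
  readr::write_tsv(dplyr::bind_cols(panel$variants[c("id", "chrom", "pos")],
                                    hap), path)
  invisible(path)
}

#' Linkage-disequilibrium r-squared between two variants
#'
#' Computed by direct counting on phased 0/1 haplotype vectors:
#' r^2 = D^2 / (pA (1-pA) pB (1-pB)) with D = pAB - pA pB, where pA and pB
#' are the allele-1 frequencies and pAB the frequency of the 1/1 haplotype.
#' Equals the squared Pearson correlation of the two indicator vectors and is
#' invariant under relabelling 0 and 1 in either column.
#'
#' @param col_a,col_b Equal-length 0/1 vectors (one entry per haplotype).
#' @return r-squared in \[0, 1\].
#' @export
#' @examples
#' compute_r2(c(0, 0, 1, 1), c(0, 0, 1, 1))  # perfect LD: 1
#' compute_r2(c(0, 0, 1, 1), c(0, 1, 0, 1))  # independent: 0
compute_r2 <- function(col_a, col_b) {
  if (length(col_a) != length(col_b)) {
    abort("haplotype columns must have equal length")
  }
  if (length(col_a) < 2) abort("need at least 2 haplotypes")
  if (!all(col_a %in% c(0, 1)) || !all(col_b %in% c(0, 1))) {
    abort("alleles must be coded 0/1")
  }
  pa <- mean(col_a)
  pb <- mean(col_b)
  if (pa %in% c(0, 1) || pb %in% c(0, 1)) {
    abort("r-squared is undefined for a monomorphic column")
  }
  pab <- mean(col_a == 1 & col_b == 1)
  d <- pab - pa * pb
  r2 <- d^2 / (pa * (1 - pa) * pb * (1 - pb))
  min(max(r2, 0), 1)
}

#' Expand index variants to LD proxies
#'
#' For every index variant, all panel variants on the same chromosome within
#' `window_bp` whose r-squared with the index is at least `r2_min` are
#' reported as proxies. Each index variant is also its own proxy with
#' r-squared 1. Ties at exactly `r2_min` are included.
#'
#' @param index Variant tibble of index SNPs; every `id` must be present in
#'   the panel.
#' @param panel A [haplotype_panel()].
#' @param r2_min LD threshold in (0, 1\] (default 0.5).
#' @param window_bp Search window each side of the index position (default
#'   1 Mb, the conventional LD horizon).
#' @return Tibble with columns `index_id`, `proxy_id`, `chrom`, `pos`, `r2`,
#'   sorted by index then proxy position.
#' @export
expand_index_snps <- function(index, panel, r2_min = 0.5, window_bp = 1e6) {
  stopifnot(inherits(panel, "haplotype_panel"))
  index <- validate_variants(index)
  if (!(r2_min > 0 && r2_min <= 1)) abort("`r2_min` must be in (0, 1]")
  missing_ids <- setdiff(index$id, panel$variants$id)
  if (length(missing_ids) > 0) {
    abort(sprintf("index variant(s) absent from panel: %s",
                  paste(missing_ids, collapse = ", ")))
  }
  pv <- panel$variants
  out <- purrr::map_dfr(seq_len(nrow(index)), function(i) {
    id_i <- index$id[i]
    row_i <- which(pv$id == id_i)[1]
    chrom_i <- pv$chrom[row_i]
    pos_i <- pv$pos[row_i]
    cand <- which(pv$chrom == chrom_i & abs(pv$pos - pos_i) <= window_bp)
    col_i <- panel$alleles[, row_i]
    r2 <- vapply(cand, function(j) {
      if (j == row_i) return(1)
      col_j <- panel$alleles[, j]
      if (mean(col_j) %in% c(0, 1) || mean(col_i) %in% c(0, 1)) return(NA_real_)
      compute_r2(col_i, col_j)
    }, double(1))
    keep <- !is.na(r2) & r2 >= r2_min
    tibble(index_id = id_i, proxy_id = pv$id[cand[keep]],
           chrom = chrom_i, pos = pv$pos[cand[keep]], r2 = r2[keep])
  })
  dplyr::arrange(out, .data$index_id, .data$pos)
}

#' Merge index variants and their proxies into one variant set
#'
#' Convenience for the enrichment stage: the union of index and proxy
#' variants (distinct ids) as a variant tibble, with `role` marking index
#' versus proxy.
#'
#' @param ld_pairs Output of [expand_index_snps()].
#' @param panel The panel the pairs came from (supplies positions).
#' @return Variant tibble (`id`, `chrom`, `pos`, `role`).
#' @export
ld_variant_set <- function(ld_pairs, panel) {
  stopifnot(inherits(panel, "haplotype_panel"))
  ids <- unique(c(ld_pairs$index_id, ld_pairs$proxy_id))
  v <- panel$variants[panel$variants$id %in% ids, c("id", "chrom", "pos")]
  v$role <- ifelse(v$id %in% ld_pairs$index_id, "index", "proxy")
  dplyr::arrange(as_tibble(v), .data$chrom, .data$pos)
}
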