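# Brute-force oracles and small fixture builders shared across tests.
# Oracles are deliberately naive (double loops, direct counting) and
# independent of the package's interval/LD engines.

make_peaks <- function(chrom, start, end, name = NULL, score = NULL) {
  n <- length(start)
  tibble::tibble(chrom = rep_len(chrom, n), start = as.integer(start),
                 end = as.integer(end),
                 name = name %||% sprintf("p%d", seq_len(n)),
                 score = score %||% rep(NA_real_, n))
}

make_variants <- function(chrom, pos, id = NULL) {
  n <- length(pos)
  tibble::tibble(id = id %||% sprintf("rs%d", seq_len(n)),
                 chrom = rep_len(chrom, n), pos = as.integer(pos))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# O(n*m) double loop: distinct variants in >= 1 peak and all hit pairs
brute_overlap <- function(variants, peaks) {
  hits <- list()
  for (i in seq_len(nrow(variants))) {
    for (j in seq_len(nrow(peaks))) {
      if (variants$chrom[i] == peaks$chrom[j] &&
          variants$pos[i] - 1 >= peaks$start[j] &&
          variants$pos[i] - 1 < peaks$end[j]) {
        hits[[length(hits) + 1]] <- c(variants$id[i], peaks$name[j])
      }
    }
  }
  if (length(hits) == 0) {
    return(list(count = 0L,
                hits = tibble::tibble(variant_id = character(),
                                      peak_name = character())))
  }
  m <- do.call(rbind, hits)
  list(count = length(unique(m[, 1])),
       hits = tibble::tibble(variant_id = m[, 1], peak_name = m[, 2]))
}

# r-squared from the 2x2 haplotype count table
brute_r2 <- function(a, b) {
  n <- length(a)
  n11 <- sum(a == 1 & b == 1)
  n10 <- sum(a == 1 & b == 0)
  n01 <- sum(a == 0 & b == 1)
  pa <- (n11 + n10) / n
  pb <- (n11 + n01) / n
  d <- n11 / n - pa * pb
  d^2 / (pa * (1 - pa) * pb * (1 - pb))
}

# peak-to-gene rule, naive double loop; window half-open [tss-w, tss+w)
brute_assign <- function(peaks, genes, window_bp = 50000,
                         ignore_strand = FALSE) {
  out <- list()
  for (j in seq_len(nrow(genes))) {
    tss <- if (ignore_strand || genes$strand[j] == "+") genes$start[j]
           else genes$end[j] - 1L
    for (i in seq_len(nrow(peaks))) {
      if (peaks$chrom[i] != genes$chrom[j]) next
      in_win <- window_bp > 0 &&
        peaks$start[i] < tss + window_bp &&
        tss - window_bp < peaks$end[i]
      in_body <- peaks$start[i] < genes$end[j] &&
        genes$start[j] < peaks$end[i]
      if (in_win || in_body) {
        out[[length(out) + 1]] <- c(genes$id[j], peaks$name[i])
      }
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(gene_id = character(), peak_name = character()))
  }
  m <- unique(do.call(rbind, out))
  dplyr::arrange(tibble::tibble(gene_id = m[, 1], peak_name = m[, 2]),
                 gene_id, peak_name)
}

# Welch statistic from the closed form
brute_welch <- function(a, b) {
  va <- var(a) / length(a)
  vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  p <- 2 * pt(-abs(t), df)
  c(t = t, df = df, p = p)
}
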