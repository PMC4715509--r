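#' Motif co-occurrence within binding-site windows
#'
#' Quantifies clustering of two motif types found in fixed windows around
#' binding peaks: the fraction of A-instances with any B-instance within a
#' genomic distance, compared against a permutation null that re-places
#' every instance uniformly over the windows.
#'
#' @name motif_cooccur
NULL

# resolve instances (motif_id, arbs_id, offset, strand) to genomic positions
# using the owning window's coordinates
resolve_motif_positions <- function(instances, windows, what = "instances") {
  stop_if_missing_cols(instances, c("motif_id", "arbs_id", "offset"), what)
  windows <- ensure_peak_names(validate_peaks(windows))
  miss <- setdiff(unique(instances$arbs_id), windows$name)
  if (length(miss) > 0) {
    abort(sprintf("%s reference unknown window(s): %s", what,
                  paste(head(miss, 5), collapse = ", ")))
  }
  w <- windows[match(instances$arbs_id, windows$name), ]
  if (any(instances$offset < 0) ||
      any(instances$offset >= (w$end - w$start))) {
    abort(sprintf("%s: offset outside the owning window", what))
  }
  dplyr::mutate(as_tibble(instances), chrom = w$chrom,
                pos = w$start + .data$offset)
}

# for each query position, the distance to the nearest subject position on
# the same chromosome (Inf when none)
nearest_same_chrom <- function(q_chrom, q_pos, s_chrom, s_pos) {
  out <- rep(Inf, length(q_pos))
  for (cc in intersect(unique(q_chrom), unique(s_chrom))) {
    qi <- which(q_chrom == cc)
    sp <- sort(s_pos[s_chrom == cc])
    i <- findInterval(q_pos[qi], sp)
    d_left <- ifelse(i >= 1, q_pos[qi] - sp[pmax(i, 1)], Inf)
    d_right <- ifelse(i < length(sp), sp[pmin(i + 1, length(sp))] - q_pos[qi],
                      Inf)
    out[qi] <- pmin(d_left, d_right)
  }
  out
}

#' Fraction of A-motif instances near a B-motif instance
#'
#' An A-instance co-occurs if any B-instance's start lies within
#' `max_dist_bp` of its start (absolute genomic distance, start-to-start).
#'
#' @param a,b Motif instance tibbles with columns `motif_id`, `arbs_id`
#'   (owning window name), `offset` (0-based within the window), and
#'   optionally `strand`.
#' @param windows Peak tibble whose `name` column the `arbs_id` values
#'   reference.
#' @param max_dist_bp Maximum start-to-start distance in bp (default 100).
#' @return One-row tibble with `n_a`, `n_cooccurring`, `fraction`.
#' @export
cooccurrence_rate <- function(a, b, windows, max_dist_bp = 100) {
  if (nrow(a) == 0) abort("`a` must contain at least one instance")
  ra <- resolve_motif_positions(a, windows, "`a` instances")
  if (nrow(b) == 0) {
    return(tibble(n_a = nrow(ra), n_cooccurring = 0L, fraction = 0))
  }
  rb <- resolve_motif_positions(b, windows, "`b` instances")
  d <- nearest_same_chrom(ra$chrom, ra$pos, rb$chrom, rb$pos)
  n_co <- sum(d <= max_dist_bp)
  tibble(n_a = nrow(ra), n_cooccurring = as.integer(n_co),
         fraction = n_co / nrow(ra))
}

#' Random-coincidence null for motif co-occurrence
#'
#' Each permutation re-draws every A and B instance independently: the
#' owning window is chosen uniformly among `windows` and the offset
#' uniformly among the valid offsets `0 ... width - motif_length`. Instance
#' counts per motif type are preserved exactly. The expected coincidence
#' rate is the mean co-occurrence fraction over permutations, and the
#' empirical p-value is the fraction of permutations whose rate reaches the
#' observed rate.
#'
#' @inheritParams cooccurrence_rate
#' @param n_perm Number of permutations (default 1000).
#' @param motif_length Motif footprint in bp used to bound valid offsets
#'   (default 1, i.e. start positions).
#' @param seed Integer RNG seed.
#' @return An object of class `motif_cooccurrence` with fields `observed`
#'   (fraction), `n_cooccurring`, `expected_rate`, `perm_rates`, `p_perm`,
#'   `n_perm`, `max_dist_bp`, `seed`.
#' @export
coincidence_null <- function(a, b, windows, n_perm = 1000, max_dist_bp = 100,
                             motif_length = 1, seed) {
  if (n_perm < 1) abort("`n_perm` must be >= 1")
  windows <- ensure_peak_names(validate_peaks(windows))
  widths <- windows$end - windows$start
  if (any(widths < motif_length)) {
    abort("a window is shorter than `motif_length`")
  }
  obs <- cooccurrence_rate(a, b, windows, max_dist_bp)
  n_a <- nrow(a)
  n_b <- nrow(b)
  off <- chrom_offsets(dplyr::summarise(
    dplyr::group_by(windows, .data$chrom),
    size = max(.data$end) + 1, .groups = "drop"))
  perm_rates <- with_seed(seed, vapply(seq_len(n_perm), function(k) {
    wi_a <- sample.int(nrow(windows), n_a, replace = TRUE)
    wi_b <- sample.int(nrow(windows), n_b, replace = TRUE)
    off_a <- floor(runif(n_a) * (widths[wi_a] - motif_length + 1))
    off_b <- floor(runif(n_b) * (widths[wi_b] - motif_length + 1))
    pa <- off[windows$chrom[wi_a]] + windows$start[wi_a] + off_a
    pb <- off[windows$chrom[wi_b]] + windows$start[wi_b] + off_b
    ca <- windows$chrom[wi_a]
    cb <- windows$chrom[wi_b]
    d <- nearest_same_chrom(ca, pa, cb, pb)
    mean(d <= max_dist_bp)
  }, double(1)))
  structure(list(observed = obs$fraction,
                 n_cooccurring = obs$n_cooccurring,
                 n_a = n_a, n_b = n_b,
                 expected_rate = mean(perm_rates),
                 perm_rates = perm_rates,
                 p_perm = mean(perm_rates >= obs$fraction),
                 n_perm = as.integer(n_perm),
                 max_dist_bp = max_dist_bp,
                 seed = seed),
            class = "motif_cooccurrence")
}

#' @export
print.motif_cooccurrence <- function(x, ...) {
  cat("<motif_cooccurrence>\n")
  cat(sprintf("  observed: %d of %d A-instances within %d bp of a B (%.1f%%)\n",
              x$n_cooccurring, x$n_a, x$max_dist_bp, 100 * x$observed))
  cat(sprintf("  random coincidence rate: %.2f%% (over %d permutations)\n",
              100 * x$expected_rate, x$n_perm))
  cat(sprintf("  permutation p = %.3g\n", x$p_perm))
  invisible(x)
}

#' One-row summary of a motif co-occurrence test
#'
#' @param x A `motif_cooccurrence` object.
#' @param ... Unused.
#' @return A tibble.
#' @method glance motif_cooccurrence
#' @export
glance.motif_cooccurrence <- function(x, ...) {
  tibble(n_a = x$n_a, n_b = x$n_b, n_cooccurring = x$n_cooccurring,
         observed_rate = x$observed, expected_rate = x$expected_rate,
         p_perm = x$p_perm, n_perm = x$n_perm,
         max_dist_bp = x$max_dist_bp, seed = x$seed)
}
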