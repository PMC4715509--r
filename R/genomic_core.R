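#' Genomic core: peaks, variants, genes and their file formats
#'
#' Peaks and genes use 0-based half-open coordinates (the BED convention);
#' variants use 1-based positions (the VCF convention) and are converted
#' internally when intersected with intervals. All containers are plain
#' tibbles so results chain with the pipe.
#'
#' @name genomic_core
NULL

validate_peaks <- function(peaks, require_score = FALSE) {
  if (!is.data.frame(peaks)) abort("`peaks` must be a data frame")
  stop_if_missing_cols(peaks, c("chrom", "start", "end"), "`peaks`")
  peaks <- as_tibble(peaks)
  if (nrow(peaks) == 0) return(peaks)
  if (any(peaks$start < 0)) abort("peak start coordinates must be >= 0")
  bad <- which(peaks$start >= peaks$end)
  if (length(bad) > 0) {
    abort(sprintf("peak(s) with start >= end at row(s): %s",
                  paste(head(bad, 5), collapse = ", ")))
  }
  if ("score" %in% names(peaks)) {
    sc <- peaks$score[!is.na(peaks$score)]
    if (length(sc) > 0 && any(sc < 0)) abort("peak scores must be >= 0")
  }
  if (require_score &&
      (!"score" %in% names(peaks) || anyNA(peaks$score))) {
    abort("all peaks must carry a score for this operation")
  }
  peaks
}

validate_variants <- function(variants) {
  if (!is.data.frame(variants)) abort("`variants` must be a data frame")
  stop_if_missing_cols(variants, c("id", "chrom", "pos"), "`variants`")
  variants <- as_tibble(variants)
  if (nrow(variants) == 0) return(variants)
  if (any(variants$pos < 1)) abort("variant positions are 1-based: pos >= 1")
  if (any(is.na(variants$id)) || any(variants$id == "")) {
    abort("variant ids must be non-empty")
  }
  variants
}

validate_genes <- function(genes) {
  if (!is.data.frame(genes)) abort("`genes` must be a data frame")
  stop_if_missing_cols(genes, c("id", "chrom", "strand", "start", "end"),
                       "`genes`")
  genes <- as_tibble(genes)
  if (nrow(genes) == 0) return(genes)
  if (any(genes$start < 0) || any(genes$start >= genes$end)) {
    abort("gene models must satisfy 0 <= start < end")
  }
  if (!all(genes$strand %in% c("+", "-"))) {
    abort('gene strand must be "+" or "-"')
  }
  genes
}

# give unnamed peaks stable synthetic names so hits can reference them
ensure_peak_names <- function(peaks) {
  if (!"name" %in% names(peaks)) {
    peaks$name <- NA_character_
  }
  idx <- which(is.na(peaks$name) | peaks$name == "")
  if (length(idx) > 0) {
    peaks$name[idx] <- sprintf("peak_%05d", idx)
  }
  peaks
}

#' Read a BED3/BED5 peak file
#'
#' Columns: chrom, start (0-based), end (exclusive), optional name, optional
#' score (the peak caller's -10*log10 p-value). Lines starting with `#`,
#' `track` or `browser` are skipped.
#'
#' @param path Path to a tab-separated BED file.
#' @return A tibble with columns `chrom`, `start`, `end`, `name`, `score`.
#' @export
#' @examples
#' f <- tempfile(fileext = ".bed")
#' writeLines("chr1\t100\t200\tp1\t60", f)
#' read_bed(f)
read_bed <- function(path) {
  if (!file.exists(path)) abort(sprintf("BED file not found: %s", path))
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))
  lines <- lines[keep]
  line_no <- which(keep)
  if (length(lines) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  name = character(), score = double()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3)) {
    abort(sprintf("BED line %d has fewer than 3 columns",
                  line_no[which(nf < 3)[1]]))
  }
  chrom <- vapply(fields, `[[`, character(1), 1L)
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, character(1), 2L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[[`, character(1), 3L)))
  bad <- which(is.na(start) | is.na(end) | start < 0 | start >= end)
  if (length(bad) > 0) {
    abort(sprintf(
      "malformed BED coordinates at line %d (need integer 0 <= start < end)",
      line_no[bad[1]]))
  }
  name <- vapply(fields, function(f) if (length(f) >= 4) f[[4]] else NA_character_,
                 character(1))
  score <- vapply(fields, function(f) {
    if (length(f) >= 5) suppressWarnings(as.double(f[[5]])) else NA_real_
  }, double(1))
  validate_peaks(tibble(chrom = chrom, start = start, end = end,
                        name = name, score = score))
}

#' Write peaks to a BED file
#'
#' Inverse of [read_bed()]: coordinates and scores round-trip exactly.
#'
#' @param peaks A peak tibble (`chrom`, `start`, `end`, optional `name`,
#'   `score`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(peaks, path) {
  peaks <- validate_peaks(peaks)
  has_name <- "name" %in% names(peaks)
  has_score <- "score" %in% names(peaks)
  lines <- vapply(seq_len(nrow(peaks)), function(i) {
    out <- c(peaks$chrom[i], format(peaks$start[i], scientific = FALSE),
             format(peaks$end[i], scientific = FALSE))
    if (has_name || has_score) {
      out <- c(out, if (has_name && !is.na(peaks$name[i])) peaks$name[i] else ".")
    }
    if (has_score && !is.na(peaks$score[i])) {
      out <- c(out, format(peaks$score[i], scientific = FALSE))
    }
    paste(out, collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read tabular variant, gene and chromosome-size files
#'
#' Tab-separated files with a header line: variants need `id`, `chrom`, `pos`
#' (1-based); genes need `id`, `chrom`, `strand`, `start`, `end` (0-based
#' half-open); chromosome sizes need `chrom`, `size`.
#'
#' @param path Path to a TSV file.
#' @return A validated tibble.
#' @export
read_variants <- function(path) {
  validate_variants(readr::read_tsv(path, show_col_types = FALSE))
}

#' @rdname read_variants
#' @export
read_genes <- function(path) {
  validate_genes(readr::read_tsv(path, show_col_types = FALSE))
}

#' @rdname read_variants
#' @export
read_chrom_sizes <- function(path) {
  sizes <- readr::read_tsv(path, show_col_types = FALSE)
  stop_if_missing_cols(sizes, c("chrom", "size"), "chrom sizes")
  if (any(sizes$size <= 0)) abort("chromosome sizes must be positive")
  as_tibble(sizes)
}

#' Normalize chromosome naming
#'
#' Chromosome matching everywhere in the package is exact string equality;
#' this helper converts between "chr1" and "1" styles when two inputs
#' disagree. It is never applied implicitly.
#'
#' @param chrom Character vector of chromosome names.
#' @param style `"add"` to ensure a "chr" prefix, `"strip"` to remove it.
#' @return Character vector.
#' @export
normalize_chrom <- function(chrom, style = c("add", "strip")) {
  style <- match.arg(style)
  if (style == "strip") sub("^chr", "", chrom)
  else ifelse(grepl("^chr", chrom), chrom, paste0("chr", chrom))
}

#' Filter peaks by peak-caller score
#'
#' Retains peaks whose score is strictly greater than `min_score`, the
#' convention used to define the binding-site universe from MACS-style
#' -10*log10 p-value scores (default threshold 50).
#'
#' @param peaks Peak tibble with a `score` column.
#' @param min_score Strict lower bound on the score (default 50).
#' @return The retained peaks, input order preserved.
#' @export
filter_peaks_by_score <- function(peaks, min_score = 50) {
  peaks <- validate_peaks(peaks, require_score = TRUE)
  dplyr::filter(peaks, .data$score > min_score)
}

#' Is a variant inside a peak?
#'
#' A 1-based variant position `pos` lies in a half-open peak `[start, end)`
#' iff `start <= pos - 1 < end`. Vectorized elementwise with recycling.
#'
#' @param variants Variant tibble (`id`, `chrom`, `pos`).
#' @param peaks Peak tibble, same length or length 1.
#' @return Logical vector.
#' @export
variant_in_peak <- function(variants, peaks) {
  variants <- validate_variants(variants)
  peaks <- validate_peaks(peaks)
  pos0 <- variants$pos - 1L
  variants$chrom == peaks$chrom & pos0 >= peaks$start & pos0 < peaks$end
}

#' Count variants overlapping a peak set
#'
#' The headline counting operation: the number of DISTINCT variants lying in
#' at least one peak (a variant covered by two overlapping peaks counts
#' once), plus the full list of (variant, peak) hit pairs.
#'
#' @param variants Variant tibble (`id`, `chrom`, `pos`); ids must be unique.
#' @param peaks Peak tibble.
#' @return A list with `count` (integer) and `hits`, a tibble with columns
#'   `variant_id` and `peak_name` (one row per overlapping pair).
#' @export
#' @examples
#' peaks <- tibble::tibble(chrom = "chr1", start = 100L, end = 200L,
#'                         name = "p1")
#' snps <- tibble::tibble(id = c("rs1", "rs2"), chrom = "chr1",
#'                        pos = c(150L, 500L))
#' count_overlaps(snps, peaks)$count
count_overlaps <- function(variants, peaks) {
  variants <- validate_variants(variants)
  peaks <- ensure_peak_names(validate_peaks(peaks))
  if (anyDuplicated(variants$id)) {
    abort("duplicate variant ids are not allowed in count_overlaps()")
  }
  if (nrow(variants) == 0 || nrow(peaks) == 0) {
    return(list(count = 0L,
                hits = tibble(variant_id = character(),
                              peak_name = character())))
  }
  hits_list <- lapply(intersect(unique(variants$chrom), unique(peaks$chrom)),
    function(cc) {
      v <- variants[variants$chrom == cc, , drop = FALSE]
      p <- peaks[peaks$chrom == cc, , drop = FALSE]
      q <- IRanges::IRanges(start = v$pos, width = 1L)
      s <- IRanges::IRanges(start = p$start + 1L, end = p$end)
      h <- IRanges::findOverlaps(q, s)
      tibble(variant_id = v$id[S4Vectors::queryHits(h)],
             peak_name = p$name[S4Vectors::subjectHits(h)])
    })
  hits <- dplyr::bind_rows(hits_list)
  if (nrow(hits) == 0) {
    hits <- tibble(variant_id = character(), peak_name = character())
  }
  list(count = length(unique(hits$variant_id)), hits = hits)
}
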