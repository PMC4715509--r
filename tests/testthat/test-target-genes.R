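test_that("TSS-window boundary arithmetic under the half-open convention", {
  genes <- tibble::tibble(id = "g1", chrom = "chr1", strand = "+",
                          start = 50100L, end = 80000L)
  # window is [100, 100100): peak [0,100) shares no bp, [0,101) does
  expect_equal(nrow(assign_peaks_to_genes(make_peaks("chr1", 0, 100),
                                          genes)), 0)
  got <- assign_peaks_to_genes(make_peaks("chr1", 0, 101), genes)
  expect_equal(got$gene_id, "g1")
})

test_that("gene-body clause assigns peaks far from the TSS", {
  genes <- tibble::tibble(id = "g1", chrom = "chr1", strand = "+",
                          start = 0L, end = 300000L)
  pk <- make_peaks("chr1", 200000, 200500)  # 200 kb from TSS, inside body
  expect_equal(assign_peaks_to_genes(pk, genes)$gene_id, "g1")
  # window_bp = 0 reduces to gene-body overlap only
  pk2 <- make_peaks("chr1", 300100, 300200)
  expect_equal(nrow(assign_peaks_to_genes(pk2, genes, window_bp = 0)), 0)
})

test_that("strand-aware TSS flips the window for minus-strand genes", {
  genes <- tibble::tibble(id = "g1", chrom = "chr1", strand = "-",
                          start = 100000L, end = 200000L)
  pk <- make_peaks("chr1", 240000, 240100)  # 40 kb past the - strand TSS
  expect_equal(assign_peaks_to_genes(pk, genes)$gene_id, "g1")
  pk2 <- make_peaks("chr1", 60000, 60100)   # 40 kb before gene start
  expect_equal(nrow(assign_peaks_to_genes(pk2, genes)), 0)
  expect_equal(assign_peaks_to_genes(pk2, genes,
                                     ignore_strand = TRUE)$gene_id, "g1")
})

test_that("assignment equals the brute-force rule oracle on random instances", {
  set.seed(61)
  for (rep in 1:20) {
    genes <- tibble::tibble(
      id = sprintf("g%02d", 1:15),
      chrom = sample(c("chr1", "chr2"), 15, TRUE),
      strand = sample(c("+", "-"), 15, TRUE),
      start = st <- sample.int(900000, 15),
      end = st + sample.int(80000, 15))
    pk <- make_peaks(sample(c("chr1", "chr2"), 40, TRUE),
                     ps <- sample.int(950000, 40),
                     ps + sample.int(2000, 40))
    w <- sample(c(0, 10000, 50000), 1)
    got <- assign_peaks_to_genes(pk, genes, window_bp = w)
    want <- brute_assign(pk, genes, window_bp = w)
    expect_equal(got, want)
  }
})

test_that("bh_adjust reproduces hand-computed step-up values", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  # step-up with distinct ranks, computed by hand:
  # sorted p (.004,.02,.03): .004*3/1=.012; .02*3/2=.03; .03*3/3=.03
  expect_equal(bh_adjust(c(0.03, 0.004, 0.02)), c(0.03, 0.012, 0.03))
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
})

make_calls <- function(t1, t2, map, alpha = 0.05) {
  suppressMessages(call_primary_targets(t1, t2, map, alpha))
}

test_that("direction and peak clauses gate primary calls", {
  map <- tibble::tibble(gene_id = "gA", peak_name = "p1")
  up_down <- make_calls(
    tibble::tibble(gene_id = "gA", log_fc = 1.2, p_adj = 0.01),
    tibble::tibble(gene_id = "gA", log_fc = -0.8, p_adj = 0.01), map)
  expect_equal(up_down$n_primary, 0)
  expect_equal(up_down$n_same_direction, 0)

  # same direction, boundary p_adj = alpha included, but no peak
  no_peak <- make_calls(
    tibble::tibble(gene_id = "gB", log_fc = 1, p_adj = 0.04),
    tibble::tibble(gene_id = "gB", log_fc = 2, p_adj = 0.05),
    tibble::tibble(gene_id = character(), peak_name = character()))
  expect_equal(no_peak$n_same_direction, 1)
  expect_equal(no_peak$n_primary, 0)

  both <- make_calls(
    tibble::tibble(gene_id = "gA", log_fc = -1, p_adj = 0.05),
    tibble::tibble(gene_id = "gA", log_fc = -2, p_adj = 0.05), map)
  expect_equal(both$n_primary, 1)
  expect_equal(primary_targets(both), "gA")
})

test_that("a gene present at one timepoint only is not regulated there", {
  map <- tibble::tibble(gene_id = "gA", peak_name = "p1")
  expect_message(
    calls <- call_primary_targets(
      tibble::tibble(gene_id = c("gA", "gB"), log_fc = c(1, 1),
                     p_adj = c(0.01, 0.01)),
      tibble::tibble(gene_id = "gA", log_fc = 1, p_adj = 0.01),
      map),
    "one timepoint")
  expect_equal(calls$n_primary, 1)
  expect_false("gB" %in% primary_targets(calls))
})

test_that("calls are row-order invariant and monotone in alpha", {
  cfg <- sim_config(n_genes = 80L, de_n_primary = 25L)
  g <- generate_genome(cfg, 71)
  pv <- generate_peaks_and_variants(cfg, g$chrom_sizes, 72)
  map <- assign_peaks_to_genes(pv$peaks, g$genes)
  de <- generate_de_tables(cfg, g$genes, map, 73)
  base <- make_calls(de$de_t1, de$de_t2, map)
  shuf <- make_calls(de$de_t1[sample.int(nrow(de$de_t1)), ],
                     de$de_t2[sample.int(nrow(de$de_t2)), ], map)
  expect_setequal(primary_targets(base), primary_targets(shuf))
  wider <- make_calls(de$de_t1, de$de_t2, map, alpha = 0.2)
  expect_true(all(primary_targets(base) %in% primary_targets(wider)))
})

test_that("planted primary targets are recovered exactly", {
  cfg <- sim_config(n_genes = 120L, de_n_primary = 40L)
  g <- generate_genome(cfg, 81)
  pv <- generate_peaks_and_variants(cfg, g$chrom_sizes, 82)
  map <- assign_peaks_to_genes(pv$peaks, g$genes)
  de <- generate_de_tables(cfg, g$genes, map, 83)
  calls <- make_calls(de$de_t1, de$de_t2, map)
  expect_setequal(primary_targets(calls), de$ground_truth$planted_primary)
  gl <- glance(calls)
  expect_equal(gl$n_primary, length(de$ground_truth$planted_primary))
  expect_lte(gl$n_primary, gl$n_same_direction)
  expect_lte(gl$n_primary, gl$n_with_arbs)
})

test_that("TSS distances are signed, strand-flipped and tie-broken", {
  genes <- tibble::tibble(id = c("gA", "gB"),
                          chrom = "chr1", strand = c("+", "-"),
                          start = c(1000L, 5000L), end = c(2000L, 7000L))
  # peak centred exactly on gA's TSS
  d0 <- tss_distances(make_peaks("chr1", 950, 1050), genes)
  expect_equal(d0$distance, 0)
  expect_equal(d0$gene_id, "gA")
  # - strand gene gB has TSS 6999; peak centred 1 kb toward the gene body
  d1 <- tss_distances(make_peaks("chr1", 5949, 6049), genes)
  expect_equal(d1$distance, 1000)
  # equidistant genes tie-break by smaller id
  genes2 <- tibble::tibble(id = c("gB", "gA"), chrom = "chr1",
                           strand = "+", start = c(2000L, 4000L),
                           end = c(2500L, 4500L))
  dt <- tss_distances(make_peaks("chr1", 2950, 3050), genes2)
  expect_equal(dt$gene_id, "gA")
})

test_that("distance profile equals a brute-force nearest-TSS scan", {
  set.seed(91)
  genes <- tibble::tibble(id = sprintf("g%d", 1:20), chrom = "chr1",
                          strand = sample(c("+", "-"), 20, TRUE),
                          start = st <- sample.int(500000, 20),
                          end = st + sample.int(30000, 20))
  pk <- make_peaks("chr1", ps <- sample.int(520000, 50), ps + 200)
  d <- tss_distances(pk, genes)
  tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1)
  for (i in seq_len(nrow(pk))) {
    mid <- (pk$start[i] + pk$end[i]) / 2
    dd <- ifelse(genes$strand == "-", -(mid - tss), mid - tss)
    j <- order(abs(dd), genes$id)[1]
    expect_equal(d$distance[d$peak_name == pk$name[i]], dd[j])
  }
  prof <- tss_distance_profile(pk, genes,
                               bins = seq(-600000, 600000, 50000))
  expect_equal(sum(prof$count), nrow(pk))
})
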