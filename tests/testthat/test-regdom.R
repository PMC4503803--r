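chrlen <- c(chrT = 100000L)

ann <- function(tss, strand, gene = sprintf("gene%02d", seq_along(tss))) {
  data.frame(gene_id = gene, chrom = "chrT", tss = tss, strand = strand,
             stringsAsFactors = FALSE)
}

test_that("basal regulatory domains follow the 5 kb up / 1 kb down rule", {
  d <- basal_regulatory_domains(ann(10000, "+"), chrom_lengths = chrlen)
  expect_equal(GenomicRanges::start(d) - 1L, 5000)   # 0-based start
  expect_equal(GenomicRanges::end(d), 11000)         # half-open end

  d2 <- basal_regulatory_domains(ann(10000, "-"), chrom_lengths = chrlen)
  expect_equal(GenomicRanges::start(d2) - 1L, 9000)
  expect_equal(GenomicRanges::end(d2), 15000)

  # clipping at the chromosome start
  d3 <- basal_regulatory_domains(ann(2000, "+"), chrom_lengths = chrlen)
  expect_equal(GenomicRanges::start(d3) - 1L, 0)
  expect_equal(GenomicRanges::end(d3), 3000)

  # strand reflection: mirroring coordinates reproduces the mirrored domain
  L <- chrlen[["chrT"]]
  fw <- basal_regulatory_domains(ann(30000, "+"), chrom_lengths = chrlen)
  rv <- basal_regulatory_domains(ann(L - 30000, "-"), chrom_lengths = chrlen)
  expect_equal(GenomicRanges::start(rv) - 1L, L - GenomicRanges::end(fw))
  expect_equal(GenomicRanges::end(rv), L - (GenomicRanges::start(fw) - 1L))

  expect_error(basal_regulatory_domains(
    data.frame(gene_id = "g", chrom = "chrX", tss = 10, strand = "+"),
    chrom_lengths = chrlen), "unknown chromosome")
})

test_that("observed overlap equals brute-force per-base counting on a toy chromosome", {
  set.seed(30)
  len <- 10000L
  mk_gr <- function(iv) GenomicRanges::GRanges("chrT",
    IRanges::IRanges(start = iv[, 1] + 1L, end = iv[, 2]))
  for (rep in 1:5) {
    st <- sort(sample(0:(len - 200), 8))
    peaks_iv <- cbind(st, st + sample(20:150, 8, replace = TRUE))
    st2 <- sort(sample(0:(len - 400), 5))
    targets_iv <- cbind(st2, st2 + sample(50:300, 5, replace = TRUE))
    ws <- GenomicRanges::GRanges("chrT", IRanges::IRanges(1, len))
    res <- interval_overlap_test(mk_gr(peaks_iv), mk_gr(targets_iv), ws,
                                 n_sim = 100, seed = 1)
    # brute force on merged inputs (the test merges before measuring)
    merge_iv <- function(gr) {
      red <- GenomicRanges::reduce(gr)
      cbind(GenomicRanges::start(red) - 1L, GenomicRanges::end(red))
    }
    expect_equal(res$observed,
                 overlap_bp_brute(merge_iv(mk_gr(peaks_iv)),
                                  merge_iv(mk_gr(targets_iv)), len))
  }
})

test_that("randomization null conserves peak mass inside the workspace", {
  set.seed(31)
  # workspace of two segments with a gap; all null overlap of a
  # targets==workspace test equals total peak bp, every time
  ws <- GenomicRanges::GRanges("chrT",
    IRanges::IRanges(start = c(1, 6001), end = c(4000, 9000)))
  peaks <- GenomicRanges::GRanges("chrT",
    IRanges::IRanges(start = c(101, 1001, 6501), width = c(200, 300, 150)))
  res <- interval_overlap_test(peaks, ws, ws, n_sim = 200, seed = 2)
  expect_true(all(res$null == sum(GenomicRanges::width(peaks))))
  expect_equal(res$p_empirical, 1)   # observed cannot exceed the saturated null

  # a peak wider than one segment can never be placed there: with targets
  # covering only the narrow segment, null overlap is identically zero
  wide <- GenomicRanges::GRanges("chrT", IRanges::IRanges(101, 3600))
  seg2 <- GenomicRanges::GRanges("chrT", IRanges::IRanges(6001, 9000))
  res2 <- interval_overlap_test(wide, seg2, ws, n_sim = 150, seed = 4)
  expect_true(all(res2$null == 0))
  expect_equal(res2$p_empirical, 1)
})

test_that("enriched peaks reach the empirical-p floor", {
  cfg <- synth_config(n_genes = 150, n_samples = 60, n_module_genes = 30,
                      n_tfs = 5, n_driver_tfs = 2, regulon_size = 6,
                      driver_module_overlap = 3, seed = 32)
  gen <- generate_expression(cfg)
  gp <- generate_genome_and_peaks(cfg, gen$truth, n_peaks = 60,
                                  enrichment_fraction = 1)
  domains <- basal_regulatory_domains(
    gp$annotation[gp$annotation$gene_id %in% gp$truth$peak_target_genes, ],
    chrom_lengths = gp$chrom_lengths)
  res <- interval_overlap_test(gp$peaks, domains, gp$workspace,
                               n_sim = 200, seed = 3)
  expect_equal(res$p_empirical, 1 / 201)
  expect_gt(res$fold, 1)
})

test_that("BH adjustment matches the hand-computed step-up", {
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(adjust_pvalues(0.2), 0.2)
  expect_equal(adjust_pvalues(rep(1, 4)), rep(1, 4))
  # q-values are monotone non-decreasing in the sorted order
  set.seed(33)
  p <- runif(20)
  q <- adjust_pvalues(p)
  expect_true(all(diff(q[order(p)]) >= -1e-12))
  expect_error(adjust_pvalues(c(0.5, 1.2)), "\\[0, 1\\]")
})
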