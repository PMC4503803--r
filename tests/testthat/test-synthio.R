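test_that("synth_config validates its invariants", {
  expect_error(synth_config(module_age_corr = -1.2), "infeasible")
  expect_error(synth_config(n_module_genes = 3000), "exceeds n_genes")
  expect_error(synth_config(n_driver_tfs = 30), "exceeds n_tfs")
  expect_error(synth_config(driver_module_overlap = 50), "exceeds regulon_size")
  expect_error(synth_config(n_genes = 150), "too small")
  expect_s3_class(synth_config(seed = 3), "synth_config")
})

test_that("noiseless limit gives perfect anticorrelation of module genes with age", {
  cfg <- synth_config(n_genes = 400, n_samples = 60, module_age_corr = -1,
                      within_module_corr = 1, noise_sd = 0.5, seed = 4)
  gen <- generate_expression(cfg)
  rs <- apply(gen$study$values[gen$truth$module_genes, ], 1,
              cor, y = gen$study$traits$age)
  mixed <- unlist(gen$truth$mix_map, use.names = FALSE)
  plain <- setdiff(gen$truth$module_genes, mixed)
  expect_true(all(abs(rs[plain] + 1) < 1e-10))
})

test_that("realized eigengene-age correlation hits the target within 0.05", {
  for (sd in c(1, 2)) {
    gen <- generate_expression(synth_config(seed = sd))
    eig <- module_eigengene(gen$study, gen$truth$module_genes)
    expect_lt(abs(cor(eig, gen$study$traits$age) - (-0.4)), 0.05)
  }
})

test_that("generation is byte-deterministic under a fixed seed", {
  cfg <- synth_config(n_genes = 500, n_samples = 80, seed = 12)
  a <- generate_expression(cfg)
  b <- generate_expression(cfg)
  expect_identical(a$study$values, b$study$values)
  expect_identical(a$study$traits, b$study$traits)
  expect_identical(a$truth$regulons, b$truth$regulons)
})

test_that("confounders are independent of age and recorded at stated precision", {
  gen <- generate_expression(synth_config(seed = 21))
  tr <- gen$study$traits
  for (cf in c("RIN", "pH", "PMI"))
    expect_lte(abs(cor(tr[[cf]], tr$age)), 0.15)
  expect_true(all(abs(tr$RIN / 0.5 - round(tr$RIN / 0.5)) < 1e-9))
  expect_true(all(tr$PMI == round(tr$PMI)))
})

test_that("reusing ground truth redraws samples but keeps the structure", {
  cfg <- synth_config(n_genes = 500, n_samples = 80, seed = 31)
  a <- generate_expression(cfg)
  cfg2 <- cfg
  cfg2$seed <- 32L
  b <- generate_expression(cfg2, truth = a$truth)
  expect_identical(a$truth$module_genes, b$truth$module_genes)
  expect_identical(a$truth$regulons, b$truth$regulons)
  expect_false(identical(a$study$values, b$study$values))
})

test_that("marker panels honour the requested module overlap exactly", {
  gen <- generate_expression(synth_config(seed = 41))
  mk <- generate_marker_panels(synth_config(seed = 41), gen$truth,
                               panel_size = 162, overlap = 40)
  target <- mk$panels$target_cell
  expect_length(target, 162)
  expect_length(intersect(target, gen$truth$module_genes), 40)
  expect_length(intersect(mk$panels$off_cell_1, gen$truth$module_genes), 0)

  # zero overlap and full-module panel limits
  mk0 <- generate_marker_panels(synth_config(seed = 41), gen$truth,
                                panel_size = 30, overlap = 0)
  expect_length(intersect(mk0$panels$target_cell, gen$truth$module_genes), 0)
  mk_full <- generate_marker_panels(synth_config(seed = 41), gen$truth,
                                    panel_size = 100, overlap = 100)
  expect_setequal(mk_full$panels$target_cell, gen$truth$module_genes)

  expect_error(generate_marker_panels(synth_config(seed = 41), gen$truth,
                                      panel_size = 300, overlap = 200),
               "exceeds module size")
})

test_that("peaks fall inside target basal domains at enrichment 1 and BED output is reproducible", {
  cfg <- synth_config(n_genes = 300, n_samples = 60, n_module_genes = 40,
                      regulon_size = 12, driver_module_overlap = 6, seed = 51)
  gen <- generate_expression(cfg)
  gp <- generate_genome_and_peaks(cfg, gen$truth, n_peaks = 80,
                                  enrichment_fraction = 1)
  domains <- basal_regulatory_domains(
    gp$annotation[gp$annotation$gene_id %in% gp$truth$peak_target_genes, ],
    chrom_lengths = gp$chrom_lengths)
  hits <- GenomicRanges::countOverlaps(gp$peaks, domains)
  expect_true(all(hits >= 1))

  # byte-identical BED under a fixed seed
  f1 <- tempfile(fileext = ".bed"); f2 <- tempfile(fileext = ".bed")
  write_bed(gp$peaks, f1)
  gp2 <- generate_genome_and_peaks(cfg, gen$truth, n_peaks = 80,
                                   enrichment_fraction = 1)
  write_bed(gp2$peaks, f2)
  expect_identical(readLines(f1), readLines(f2))

  expect_error(generate_genome_and_peaks(cfg, gen$truth, chrom_length = 1000),
               "do not fit")
})

test_that("synthetic PPI wires the seed clique into a heavy-tailed background", {
  cfg <- synth_config(seed = 61)
  gen <- generate_expression(cfg)
  pp <- generate_ppi(cfg, gen$truth, n_proteins = 1000, clique_size = 12)
  gr <- pp$network$graph
  clique <- pp$truth$ppi_seed_clique
  sub <- igraph::induced_subgraph(gr, clique)
  expect_true(all(igraph::degree(sub) >= length(clique) - 1))

  # heavy tail: max degree at least 5x the median, over several seeds
  ratios <- vapply(1:10, function(s) {
    p <- generate_ppi(cfg, gen$truth, n_proteins = 1000, seed = s)
    d <- igraph::degree(p$network$graph)
    max(d) / median(d)
  }, numeric(1))
  expect_true(all(ratios >= 5))

  p1 <- generate_ppi(cfg, gen$truth, seed = 71)
  p2 <- generate_ppi(cfg, gen$truth, seed = 71)
  expect_identical(igraph::as_edgelist(p1$network$graph),
                   igraph::as_edgelist(p2$network$graph))

  expect_error(generate_ppi(cfg, gen$truth, n_proteins = 5, clique_size = 10),
               "clique size")
})
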