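#' Configuration for a synthetic cortex expression study
#'
#' Bundles all parameters of the synthetic-study generator. The defaults
#' emulate the statistical structure the downstream analysis assumes: one
#' planted co-expression module of 100 genes whose latent summary profile
#' (eigengene) declines with age at r = -0.4 over a 13-78 year span, a panel
#' of 20 transcription factors of which 5 "driver" TFs regulate targets
#' inside the module, and three tissue-quality confounders (RIN, pH, PMI)
#' drawn independently of age.
#'
#' @param n_genes total number of genes.
#' @param n_samples number of subjects.
#' @param age_range min and max subject age in years.
#' @param n_module_genes size of the planted age-dependent module.
#' @param module_age_corr target Pearson correlation between the module's
#'   latent eigengene and age (negative: expression declines with age).
#'   The generator resamples the eigengene noise until the realized
#'   correlation is within 0.02 of this target.
#' @param n_tfs number of transcription-factor genes.
#' @param n_driver_tfs number of TFs whose regulons intersect the module.
#' @param regulon_size number of target genes per TF regulon.
#' @param driver_module_overlap per-driver count of regulon targets that are
#'   also module members.
#' @param within_module_corr target pairwise Pearson correlation between
#'   plain module genes; sets the module gene noise level.
#' @param noise_sd multiplier on the idiosyncratic noise of background genes
#'   and regulon targets (expression units).
#' @param confounder_spec named list describing per-sample confounders; each
#'   entry is a list with `mean`, `sd`, optional `round` (recording
#'   precision), optional `tie = "eigengene"` with `tie_strength` to plant a
#'   confounder that tracks the module eigengene (used to probe suppression
#'   of the age-selection rule).
#' @param seed mandatory RNG seed; a fixed seed gives byte-identical output.
#' @return an object of class `synth_config`.
#' @export
synth_config <- function(n_genes = 2000,
                         n_samples = 150,
                         age_range = c(13, 78),
                         n_module_genes = 100,
                         module_age_corr = -0.4,
                         n_tfs = 20,
                         n_driver_tfs = 5,
                         regulon_size = 12,
                         driver_module_overlap = 8,
                         within_module_corr = 0.5,
                         noise_sd = 1,
                         confounder_spec = default_confounders(),
                         seed = 1L) {
  cfg <- list(n_genes = n_genes, n_samples = n_samples,
              age_range = as.numeric(age_range),
              n_module_genes = n_module_genes,
              module_age_corr = module_age_corr,
              n_tfs = n_tfs, n_driver_tfs = n_driver_tfs,
              regulon_size = regulon_size,
              driver_module_overlap = driver_module_overlap,
              within_module_corr = within_module_corr,
              noise_sd = noise_sd,
              confounder_spec = confounder_spec,
              seed = as.integer(seed))
  class(cfg) <- "synth_config"
  validate_synth_config(cfg)
  cfg
}

#' @export
print.synth_config <- function(x, ...) {
  cat(sprintf("synth_config: %d genes x %d samples, module %d genes (age r %.2f), %d TFs (%d drivers), seed %d\n",
              x$n_genes, x$n_samples, x$n_module_genes, x$module_age_corr,
              x$n_tfs, x$n_driver_tfs, x$seed))
  invisible(x)
}

#' Default tissue-quality confounder specification
#'
#' RIN (RNA integrity number, recorded to 0.5), pH (recorded to 0.1) and
#' PMI (postmortem interval in hours, integer) sampled independently of age.
#'
#' @return named list of confounder specifications for [synth_config()].
#' @export
default_confounders <- function() {
  list(RIN = list(mean = 7.5, sd = 1.0, round = 0.5),
       pH  = list(mean = 6.6, sd = 0.25, round = 0.1),
       PMI = list(mean = 30, sd = 10, round = 1))
}

validate_synth_config <- function(cfg) {
  stopifnot(cfg$n_genes >= 1, cfg$n_samples >= 3,
            length(cfg$age_range) == 2, cfg$age_range[1] < cfg$age_range[2])
  if (abs(cfg$module_age_corr) > 1)
    stop("infeasible module_age_corr: |r| must be <= 1")
  if (cfg$within_module_corr <= 0 || cfg$within_module_corr > 1)
    stop("within_module_corr must be in (0, 1]")
  if (cfg$noise_sd < 0) stop("noise_sd must be >= 0")
  if (cfg$n_module_genes > cfg$n_genes)
    stop("n_module_genes exceeds n_genes")
  if (cfg$n_driver_tfs > cfg$n_tfs)
    stop("n_driver_tfs exceeds n_tfs")
  if (cfg$driver_module_overlap > cfg$regulon_size)
    stop("driver_module_overlap exceeds regulon_size")
  if (cfg$n_driver_tfs * cfg$driver_module_overlap > cfg$n_module_genes)
    stop("driver regulon overlaps exceed module size")
  n_regulon_outside <- cfg$n_driver_tfs * (cfg$regulon_size - cfg$driver_module_overlap) +
    (cfg$n_tfs - cfg$n_driver_tfs) * cfg$regulon_size
  if (cfg$n_module_genes + cfg$n_tfs + n_regulon_outside > cfg$n_genes)
    stop("n_genes too small for module + TFs + regulon targets")
  if (is.null(cfg$seed) || is.na(cfg$seed)) stop("seed is mandatory")
  invisible(cfg)
}

# Role assignment: which genes are module members, TFs, regulon targets.
assign_roles <- function(cfg) {
  width <- max(4L, nchar(as.character(cfg$n_genes)))
  ids <- sprintf(paste0("G%0", width, "d"), seq_len(cfg$n_genes))
  tf_ids <- sort(sample(ids, cfg$n_tfs))
  driver_tfs <- sort(sample(tf_ids, cfg$n_driver_tfs))
  pool <- setdiff(ids, tf_ids)
  module_genes <- sort(sample(pool, cfg$n_module_genes))
  pool <- setdiff(pool, module_genes)

  regulons <- list()
  mix_map <- list()   # driver -> module genes it also drives
  module_avail <- module_genes
  for (tf in driver_tfs) {
    inside <- sort(sample(module_avail, cfg$driver_module_overlap))
    module_avail <- setdiff(module_avail, inside)
    outside <- sort(sample(pool, cfg$regulon_size - cfg$driver_module_overlap))
    pool <- setdiff(pool, outside)
    regulons[[tf]] <- c(inside, outside)
    mix_map[[tf]] <- inside
  }
  for (tf in setdiff(tf_ids, driver_tfs)) {
    targets <- sort(sample(pool, cfg$regulon_size))
    pool <- setdiff(pool, targets)
    regulons[[tf]] <- targets
  }
  truth <- list(gene_ids = ids, tf_ids = tf_ids, driver_tfs = driver_tfs,
                module_genes = module_genes, regulons = regulons,
                mix_map = mix_map, background = pool,
                marker_overlap = NULL, peak_target_genes = NULL,
                ppi_seed_clique = NULL)
  class(truth) <- "ground_truth"
  truth
}

#' Generate a synthetic expression study with known ground truth
#'
#' Samples ages uniformly over the configured range, builds a latent module
#' eigengene as a linear function of age plus noise (resampled until the
#' realized eigengene-age correlation is within 0.02 of the target), and
#' generates: plain module genes as loading x eigengene plus noise, driver
#' TFs sharing variance with the eigengene and a private regulatory factor,
#' regulon targets driven by their TF, and i.i.d. background genes.
#' Confounders are sampled independently of age and rejected/resampled until
#' their recorded values correlate with age at |r| <= 0.15.
#'
#' @param config a [synth_config()].
#' @param truth optionally, a `ground_truth` from a previous call: the gene
#'   role assignment (module membership, TFs, regulons) is reused and only
#'   the sample-level randomness is redrawn, emulating an independent cohort
#'   profiling the same regulatory structure.
#' @return list with `study` (an `expression_study`) and `truth`
#'   (a `ground_truth`).
#' @export
generate_expression <- function(config, truth = NULL) {
  validate_synth_config(config)
  with_rng(config$seed, {
    if (is.null(truth)) truth <- assign_roles(config)
    n <- config$n_samples
    sample_ids <- sprintf("S%03d", seq_len(n))

    age <- round(runif(n, config$age_range[1], config$age_range[2]), 1)
    z_age <- as.numeric(scale(age))
    r <- config$module_age_corr
    e <- NULL
    if (abs(abs(r) - 1) < .Machine$double.eps^0.5) {
      e <- r * z_age
    } else {
      for (try in seq_len(500)) {
        u <- rnorm(n)
        cand <- r * z_age + sqrt(1 - r^2) * u
        if (abs(cor(cand, age) - r) <= 0.02) { e <- cand; break }
      }
      if (is.null(e))
        stop("infeasible module_age_corr: could not realize target within 0.02")
      u_resid <- u
    }

    traits <- data.frame(age = age, row.names = sample_ids)
    for (nm in names(config$confounder_spec)) {
      sp <- config$confounder_spec[[nm]]
      val <- NULL
      for (try in seq_len(500)) {
        if (identical(sp$tie, "eigengene")) {
          ts <- sp$tie_strength %||% 0.9
          base <- if (exists("u_resid", inherits = FALSE)) u_resid else rnorm(n)
          raw <- ts * as.numeric(scale(base)) + sqrt(1 - ts^2) * rnorm(n)
        } else {
          raw <- rnorm(n)
        }
        cand <- sp$mean + sp$sd * raw
        if (!is.null(sp$round)) cand <- round(cand / sp$round) * sp$round
        if (abs(cor(cand, age)) <= 0.15) { val <- cand; break }
      }
      if (is.null(val))
        stop(sprintf("could not sample confounder '%s' independent of age", nm))
      traits[[nm]] <- val
    }

    g <- config$n_genes
    values <- matrix(NA_real_, nrow = g, ncol = n,
                     dimnames = list(truth$gene_ids, sample_ids))
    sigma_p <- sqrt(1 / config$within_module_corr - 1)

    mixed <- unlist(truth$mix_map, use.names = FALSE)
    plain_module <- setdiff(truth$module_genes, mixed)
    for (gene in plain_module) {
      lam <- runif(1, 0.8, 1.2)
      values[gene, ] <- lam * (e + sigma_p * rnorm(n))
    }

    # Driver TFs share variance with the module eigengene through a private
    # regulatory factor eta; their in-module targets mix the eigengene with
    # eta, and their out-of-module targets are children of the TF's non-
    # eigengene component (so the TF, not a sibling, is the best DPI
    # mediator, and regulon targets outside the module stay uncorrelated
    # with the module). Regulated genes carry more variance than background
    # genes, as regulated genes do in real data.
    eta <- list()
    for (tf in truth$driver_tfs) {
      eta[[tf]] <- rnorm(n)
      tf_priv <- 0.8 * eta[[tf]] + 0.33 * rnorm(n)
      values[tf, ] <- 0.5 * e + tf_priv
      for (gene in truth$mix_map[[tf]]) {
        lam <- runif(1, 0.8, 1.2)
        values[gene, ] <- lam * (e + 0.8 * eta[[tf]] + 0.8 * rnorm(n))
      }
      outside <- setdiff(truth$regulons[[tf]], truth$mix_map[[tf]])
      for (gene in outside) {
        values[gene, ] <- 0.92 * tf_priv / sqrt(0.7489) +
          0.6 * config$noise_sd * rnorm(n)
      }
    }

    for (tf in setdiff(truth$tf_ids, truth$driver_tfs)) {
      values[tf, ] <- 0.95 * rnorm(n) + 0.31 * rnorm(n)
      for (gene in truth$regulons[[tf]]) {
        values[gene, ] <- 0.92 * values[tf, ] + 0.6 * config$noise_sd * rnorm(n)
      }
    }

    bg <- truth$background
    if (length(bg) > 0) {
      values[bg, ] <- matrix(config$noise_sd * rnorm(length(bg) * n),
                             nrow = length(bg))
    }

    study <- expression_study(values, traits)
    list(study = study, truth = truth)
  })
}

#' Generate cell-type marker panels overlapping the planted module
#'
#' Emits one "target-cell" panel whose overlap with the planted module is
#' exactly `overlap` genes, plus off-cell panels disjoint from the module,
#' emulating curated marker lists for the module's cell type versus other
#' cell types. Default sizes follow the scale of published microglia marker
#' panels (162 markers, 40 inside the module).
#'
#' @param config a [synth_config()].
#' @param truth the `ground_truth` of the study.
#' @param panel_size size of the target panel.
#' @param overlap number of target-panel genes drawn from the module.
#' @param off_panel_sizes integer vector of sizes for off-cell panels
#'   (disjoint from the module).
#' @param seed RNG seed (defaults to a stage seed derived from the config).
#' @return list with `panels` (named list of gene-id vectors, first the
#'   target panel) and the updated `truth` (field `marker_overlap`).
#' @export
generate_marker_panels <- function(config, truth, panel_size = 162,
                                   overlap = 40, off_panel_sizes = 29,
                                   seed = stage_seed(config$seed, "markers")) {
  module <- truth$module_genes
  if (overlap > panel_size) stop("overlap exceeds panel_size")
  if (overlap > length(module)) stop("requested overlap exceeds module size")
  nonmodule <- setdiff(truth$gene_ids, module)
  if (panel_size - overlap > length(nonmodule))
    stop("not enough non-module genes for the panel")
  with_rng(seed, {
    in_mod <- sort(sample(module, overlap))
    out_mod <- sort(sample(nonmodule, panel_size - overlap))
    target <- c(in_mod, out_mod)
    panels <- list(target_cell = target)
    pool <- setdiff(nonmodule, out_mod)
    for (k in seq_along(off_panel_sizes)) {
      sz <- off_panel_sizes[k]
      if (sz > length(pool)) stop("not enough genes for off-cell panel")
      off <- sort(sample(pool, sz))
      pool <- setdiff(pool, off)
      panels[[paste0("off_cell_", k)]] <- off
    }
    truth$marker_overlap <- in_mod
    list(panels = panels, truth = truth)
  })
}

#' Generate a synthetic genome annotation, ChIP peaks and workspace
#'
#' Lays all genes on one synthetic chromosome at a fixed spacing with
#' jittered TSS positions and random strands, then places peaks with
#' log-normal lengths: a stated fraction inside the basal regulatory domains
#' (5 kb upstream / 1 kb downstream of the TSS) of the peak target genes
#' (the planted module), the remainder uniformly in the workspace.
#'
#' @param config a [synth_config()].
#' @param truth the `ground_truth` of the study.
#' @param n_peaks number of peaks.
#' @param peak_median_length median peak length in bp (log-normal).
#' @param peak_sdlog log-scale sd of peak lengths.
#' @param enrichment_fraction fraction of peaks placed inside target basal
#'   domains (0 = uniform placement everywhere).
#' @param gene_spacing bp between consecutive gene slots.
#' @param up,down basal domain extent upstream/downstream of the TSS (bp).
#' @param chrom_length optional chromosome length; must fit all genes at the
#'   stated spacing.
#' @param seed RNG seed.
#' @return list with `annotation` (data.frame gene_id, chrom, tss, strand),
#'   `peaks` (GRanges), `workspace` (GRanges covering the chromosome),
#'   `chrom_lengths` (named vector) and the updated `truth` (field
#'   `peak_target_genes`).
#' @export
generate_genome_and_peaks <- function(config, truth, n_peaks = 200,
                                      peak_median_length = 400,
                                      peak_sdlog = 0.5,
                                      enrichment_fraction = 0.6,
                                      gene_spacing = 20000,
                                      up = 5000, down = 1000,
                                      chrom_length = NULL,
                                      seed = stage_seed(config$seed, "genome")) {
  g <- config$n_genes
  needed <- gene_spacing * (g + 1)
  if (is.null(chrom_length)) chrom_length <- needed
  if (chrom_length < needed)
    stop(sprintf("genes do not fit: need %d bp at spacing %d, have %d",
                 needed, gene_spacing, chrom_length))
  if (gene_spacing < 2 * (up + down))
    warning("gene spacing smaller than twice the basal domain; domains will overlap")
  with_rng(seed, {
    jitter <- floor(runif(g, -gene_spacing / 8, gene_spacing / 8))
    tss <- as.integer(gene_spacing * seq_len(g) - gene_spacing / 2 + jitter)
    strand <- sample(c("+", "-"), g, replace = TRUE)
    annotation <- data.frame(gene_id = truth$gene_ids, chrom = "chrS",
                             tss = tss, strand = strand,
                             stringsAsFactors = FALSE)
    chrom_lengths <- c(chrS = as.integer(chrom_length))

    truth$peak_target_genes <- truth$module_genes
    domains <- basal_regulatory_domains(
      annotation[annotation$gene_id %in% truth$peak_target_genes, ],
      up = up, down = down, chrom_lengths = chrom_lengths)

    lens <- pmax(50L, pmin(5000L, as.integer(round(
      stats::rlnorm(n_peaks, log(peak_median_length), peak_sdlog)))))
    n_in <- round(enrichment_fraction * n_peaks)
    starts <- integer(n_peaks)
    dstart <- GenomicRanges::start(domains) - 1L  # back to 0-based
    dend <- GenomicRanges::end(domains)           # half-open end
    if (n_in > 0) {
      idx <- sample(length(domains), n_in, replace = TRUE)
      for (k in seq_len(n_in)) {
        d0 <- dstart[idx[k]]; d1 <- dend[idx[k]]
        L <- lens[k]
        if (L >= d1 - d0) {          # longer than the domain: center on it
          starts[k] <- max(0L, as.integer((d0 + d1 - L) %/% 2))
        } else {
          starts[k] <- d0 + as.integer(floor(runif(1, 0, d1 - d0 - L + 1)))
        }
      }
    }
    if (n_in < n_peaks) {
      k <- (n_in + 1):n_peaks
      starts[k] <- as.integer(floor(runif(length(k), 0, chrom_length - lens[k])))
    }
    peaks <- GenomicRanges::GRanges("chrS",
      IRanges::IRanges(start = starts + 1L, width = lens))
    workspace <- GenomicRanges::GRanges("chrS",
      IRanges::IRanges(start = 1L, end = as.integer(chrom_length)))
    GenomeInfoDb::seqlengths(peaks) <- chrom_lengths
    GenomeInfoDb::seqlengths(workspace) <- chrom_lengths
    list(annotation = annotation, peaks = peaks, workspace = workspace,
         chrom_lengths = chrom_lengths, truth = truth)
  })
}

#' Generate a synthetic protein-protein interaction network
#'
#' Builds a preferential-attachment (heavy-tailed degree) background graph
#' over a subset of the study's genes and additionally wires a seed clique:
#' the driver TFs plus module genes from their regulons, emulating the dense
#' physical interactions expected among a module's master regulators.
#'
#' @param config a [synth_config()].
#' @param truth the `ground_truth` of the study.
#' @param n_proteins number of nodes.
#' @param pa_m edges added per node in the preferential-attachment model.
#' @param pa_power preferential-attachment exponent.
#' @param clique_size size of the planted clique (driver TFs first, then
#'   their module-overlap targets).
#' @param seed RNG seed.
#' @return list with `network` (a `ppi_network`) and the updated `truth`
#'   (field `ppi_seed_clique`).
#' @export
generate_ppi <- function(config, truth, n_proteins = min(1000, config$n_genes),
                         pa_m = 2,
                         pa_power = 1, clique_size = 12,
                         seed = stage_seed(config$seed, "ppi")) {
  if (clique_size > n_proteins) stop("clique size exceeds node count")
  with_rng(seed, {
    mixed <- unlist(truth$mix_map, use.names = FALSE)
    clique <- truth$driver_tfs
    extra_needed <- clique_size - length(clique)
    if (extra_needed < 0) clique <- clique[seq_len(clique_size)]
    if (extra_needed > 0) {
      pool <- if (length(mixed) >= extra_needed) mixed else truth$module_genes
      if (length(pool) < extra_needed) stop("clique size exceeds available seed genes")
      clique <- c(clique, sort(sample(pool, extra_needed)))
    }
    others <- setdiff(truth$gene_ids, clique)
    if (n_proteins - length(clique) > length(others))
      stop("n_proteins exceeds available genes")
    nodes <- c(clique, sample(others, n_proteins - length(clique)))
    gr <- igraph::sample_pa(n_proteins, power = pa_power, m = pa_m,
                            directed = FALSE)
    igraph::V(gr)$name <- sample(nodes)  # decouple roles from attachment order
    cq <- t(utils::combn(clique, 2))
    gr <- igraph::add_edges(gr, as.vector(t(cq)))
    gr <- igraph::simplify(gr)
    truth$ppi_seed_clique <- clique
    list(network = ppi_network(gr), truth = truth)
  })
}

#' Generate a complete synthetic study bundle
#'
#' Runs all four generators (expression, marker panels, genome/peaks, PPI)
#' with per-stage seeds derived from the config seed and returns everything
#' the pipeline consumes.
#'
#' @param config a [synth_config()].
#' @param truth optional `ground_truth` to reuse (see [generate_expression()]).
#' @param ... passed on to the individual generators.
#' @return list with `study`, `truth`, `panels`, `annotation`, `peaks`,
#'   `workspace`, `chrom_lengths`, `ppi`.
#' @export
synth_study <- function(config, truth = NULL, ...) {
  ex <- generate_expression(config, truth = truth)
  mk <- generate_marker_panels(config, ex$truth)
  gp <- generate_genome_and_peaks(config, mk$truth, ...)
  pp <- generate_ppi(config, gp$truth)
  list(study = ex$study, truth = pp$truth, panels = mk$panels,
       annotation = gp$annotation, peaks = gp$peaks,
       workspace = gp$workspace, chrom_lengths = gp$chrom_lengths,
       ppi = pp$network)
}
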