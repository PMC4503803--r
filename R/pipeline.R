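#' Collapse probe-level expression to gene level
#'
#' Multiple probes mapping to the same gene are averaged per sample;
#' probes without a mapping are dropped (with a reported count).
#'
#' @param probe_matrix probe x sample numeric matrix (probe rownames).
#' @param probe_to_gene data.frame with columns `probe_id`, `gene_id`, or a
#'   named character vector (names = probe ids, values = gene ids).
#' @param traits optional per-sample trait data.frame.
#' @return an [expression_study()] at gene level.
#' @export
collapse_probes <- function(probe_matrix, probe_to_gene, traits = NULL) {
  if (is.data.frame(probe_to_gene)) {
    stopifnot(all(c("probe_id", "gene_id") %in% colnames(probe_to_gene)))
    map <- setNames(probe_to_gene$gene_id, probe_to_gene$probe_id)
  } else {
    map <- probe_to_gene
  }
  if (length(map) == 0) stop("empty probe-to-gene mapping")
  if (anyDuplicated(names(map)))
    stop("a probe maps to more than one gene")
  probes <- rownames(probe_matrix)
  mapped <- probes[probes %in% names(map)]
  dropped <- length(probes) - length(mapped)
  if (dropped > 0)
    message(sprintf("%d unmapped probe(s) dropped", dropped))
  if (length(mapped) == 0) stop("no probes map to genes")
  genes <- map[mapped]
  collapsed <- rowsum(probe_matrix[mapped, , drop = FALSE], group = genes) /
    as.vector(table(genes)[sort(unique(genes))])
  expression_study(as.matrix(collapsed), traits)
}

#' Pipeline configuration
#'
#' Bundles the per-stage parameters of the full analysis with the defaults
#' used throughout: minimum module size 10, eigengene merge height 0.25,
#' MI threshold p = 1e-7, DPI tolerance 0.1, 100 bootstrap rounds, 1000
#' random gene sets for marker enrichment, 1000 overlap randomizations,
#' 1000 PPI permutations, alpha = 0.05.
#'
#' @param synth a [synth_config()] describing the synthetic study to
#'   generate (the study source for this pipeline).
#' @param seed global pipeline seed; per-stage seeds are derived from it.
#' @param n_datasets number of replicate cohorts sharing the same ground
#'   truth (>= 2 enables the cross-dataset replication summary).
#' @param min_size,merge_height,cut_height module detection parameters.
#' @param powers,fit_target soft-power scan parameters.
#' @param alpha significance level used by the selection rule, the MR scan
#'   and the consensus retention.
#' @param mi_pvalue,dpi_tolerance,mi_n_null MI network parameters.
#' @param bootstrap_rounds bootstrap consensus rounds (0 = single network).
#' @param max_genes_minet cap on genes entering the MI network (all TFs and
#'   module genes, then highest-variance genes up to the cap).
#' @param B_enrich random gene sets for marker enrichment.
#' @param nsim_overlap randomizations for the peak overlap test.
#' @param perms_ppi within-degree permutations.
#' @param ppi_degree_bins degree binning for the PPI permutation test.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(synth = synth_config(),
                            seed = synth$seed,
                            n_datasets = 1,
                            min_size = 10, merge_height = 0.25,
                            cut_height = NULL,
                            powers = 1:20, fit_target = 0.90,
                            alpha = 0.05,
                            mi_pvalue = 1e-7, dpi_tolerance = 0.1,
                            mi_n_null = 1000,
                            bootstrap_rounds = 100,
                            max_genes_minet = 340,
                            B_enrich = 1000, nsim_overlap = 1000,
                            perms_ppi = 1000,
                            ppi_degree_bins = "log2") {
  cfg <- as.list(environment())
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full analysis pipeline on a synthetic study
#'
#' Executes, in order: study generation, co-expression module discovery and
#' age-dependent module selection, MI network reverse engineering and
#' regulon extraction (per dataset when `n_datasets >= 2`), master-regulator
#' identification with optional cross-dataset replication, marker
#' enrichment and marker age trend, ChIP-peak overlap with the module's
#' basal regulatory domains, and PPI connectivity of the identified
#' regulators. All intermediate artifacts are written under `outdir`
#' together with a JSON report (no timestamps: reruns with one seed are
#' byte-identical).
#'
#' @param config a [pipeline_config()].
#' @param outdir output directory (created if missing).
#' @return the report, invisibly (also written to `outdir/report.json`).
#' @export
run_pipeline <- function(config, outdir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  report <- list(parameters = config_as_report(config))

  ## stage 1: synthesize the study bundle
  bundle <- synth_study(config$synth)
  study <- bundle$study
  truth <- bundle$truth
  write_study_tsv(study, file.path(outdir, "expression.tsv"),
                  file.path(outdir, "traits.tsv"))
  write_panels_tsv(bundle$panels, file.path(outdir, "marker_panels.tsv"))
  write.table(bundle$annotation, file.path(outdir, "gene_annotation.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write_bed(bundle$peaks, file.path(outdir, "peaks.bed"))
  write_bed(bundle$workspace, file.path(outdir, "workspace.bed"))
  write_ppi_tsv(bundle$ppi, file.path(outdir, "ppi_edges.tsv"))
  write_truth_json(truth, file.path(outdir, "ground_truth.json"))

  ## stage 2: co-expression modules and age selection
  sim <- correlation_matrix(study)
  sp <- pick_soft_power(sim, powers = config$powers,
                        fit_target = config$fit_target)
  adj <- abs(sim)^sp$power
  tom <- adjacency_to_tom(adj)
  modules <- detect_modules(tom, study, min_size = config$min_size,
                            merge_height = config$merge_height,
                            cut_height = config$cut_height)
  age_report <- select_age_modules(modules, study$traits,
                                   alpha = config$alpha)
  memb <- data.frame(gene_id = names(modules$labels),
                     module_id = unname(modules$labels),
                     module_membership = module_membership_r(modules, study))
  write.table(memb, file.path(outdir, "module_membership.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(age_report$table, file.path(outdir, "age_module_report.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  sel <- age_report$table[age_report$table$selected, , drop = FALSE]
  selected_flag <- nrow(sel) > 0
  if (selected_flag) {
    best <- sel$module[which.min(sel$p_age)]
  } else {
    best <- age_report$table$module[which.min(age_report$table$p_age)]
    warning("no module passed the age-selection rule; proceeding with the most age-associated module")
  }
  module_id <- as.integer(sub("M", "", best))
  module_genes <- names(modules$labels)[modules$labels == module_id]
  eig <- modules$eigengenes[, best]
  slope <- regression_slope(eig, study$traits$age)
  report$coexpr <- list(
    soft_power = sp$power,
    n_modules = sum(age_report$table$n_genes > 0),
    selected_module = best,
    module_selected_by_rule = selected_flag,
    module_size = length(module_genes),
    eigengene_age_r = unname(cor(eig, study$traits$age)),
    eigengene_age_p = age_report$table$p_age[age_report$table$module == best],
    eigengene_age_slope = slope$slope,
    jaccard_vs_truth = jaccard(module_genes, truth$module_genes))

  ## stage 3-4: MI network(s), regulons, master regulators, replication
  run_one_network <- function(st, sd) {
    genes_net <- minet_gene_subset(st, truth$tf_ids, module_genes,
                                   config$max_genes_minet)
    sub <- expression_study(st$values[genes_net, , drop = FALSE], st$traits)
    net <- if (config$bootstrap_rounds >= 2) {
      bootstrap_consensus(sub, truth$tf_ids,
                          rounds = config$bootstrap_rounds,
                          p_value = config$mi_pvalue,
                          dpi_tolerance = config$dpi_tolerance,
                          n_null = config$mi_n_null,
                          alpha = config$alpha, seed = sd)
    } else {
      build_mi_network(sub, truth$tf_ids, p_value = config$mi_pvalue,
                       dpi_tolerance = config$dpi_tolerance,
                       n_null = config$mi_n_null, seed = sd)
    }
    regs <- extract_regulons(net)
    # FET universe: all expressed genes. The MI network is restricted to a
    # gene subset only for tractability; module and regulons are defined at
    # the expressed-gene scale, as in the source studies.
    mr <- identify_master_regulators(regs, module_genes, st$genes,
                                     alpha = config$alpha)
    list(net = net, regulons = regs, mr = mr)
  }
  first <- run_one_network(study, stage_seed(config$seed, "minet"))
  write.table(as_edge_list(first$net), file.path(outdir, "mi_edges.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(as.data.frame(first$mr), file.path(outdir, "mr_table.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  mr_results <- list(dataset_1 = first$mr)
  if (config$n_datasets >= 2) {
    for (d in 2:config$n_datasets) {
      cfg_d <- config$synth
      cfg_d$seed <- stage_seed(config$seed, paste0("dataset", d))
      rep_study <- generate_expression(cfg_d, truth = truth)$study
      mr_results[[paste0("dataset_", d)]] <-
        run_one_network(rep_study, stage_seed(config$seed, paste0("minet", d)))$mr
    }
    repl <- combine_across_datasets(mr_results)
    report$replication <- list(
      per_dataset = as.list(repl$per_dataset),
      replicated_in_all = repl$intersection,
      union_size = length(repl$union))
  }
  flagged <- first$mr$tf[first$mr$is_mr]
  report$mrscan <- list(
    n_tfs_tested = attr(first$mr, "n_tested"),
    n_mrs = length(flagged),
    mrs = flagged,
    driver_sensitivity = if (length(truth$driver_tfs) > 0)
      length(intersect(flagged, truth$driver_tfs)) / length(truth$driver_tfs)
      else NA,
    false_positives = length(setdiff(flagged, truth$driver_tfs)))

  ## stage 5: marker enrichment + age trend
  enr <- marker_enrichment(module_genes, bundle$panels$target_cell,
                           study$genes, B = config$B_enrich,
                           seed = stage_seed(config$seed, "markers_enrich"))
  trend <- marker_age_trend(study, bundle$panels$target_cell)
  report$markers <- list(
    observed = enr$observed, null_median = enr$null_median,
    fold = enr$fold, p_empirical = enr$p_empirical,
    panel_mean_age_r = trend$mean_r, panel_age_p = trend$p)

  ## stage 6: peak overlap with the module's basal regulatory domains
  domains <- basal_regulatory_domains(
    bundle$annotation[bundle$annotation$gene_id %in% module_genes, ],
    chrom_lengths = bundle$chrom_lengths)
  ov <- interval_overlap_test(bundle$peaks, domains, bundle$workspace,
                              n_sim = config$nsim_overlap,
                              seed = stage_seed(config$seed, "regdom"))
  ov$q_value <- adjust_pvalues(ov$p_empirical)
  report$regdom <- list(observed_bp = ov$observed, expected_bp = ov$expected,
                        fold = ov$fold, p_empirical = ov$p_empirical,
                        q_value = ov$q_value)

  ## stage 7: PPI connectivity of the identified regulators
  mr_module_targets <- intersect(
    unlist(first$regulons[intersect(flagged, names(first$regulons))]),
    module_genes)
  ppi_seeds <- utils::head(unique(c(flagged, mr_module_targets)), 50)
  if (length(ppi_seeds) > 0 &&
      length(intersect(ppi_seeds, igraph::V(bundle$ppi$graph)$name)) > 0) {
    conn <- within_degree_permutation_test(
      bundle$ppi, ppi_seeds, B = config$perms_ppi,
      degree_bins = config$ppi_degree_bins,
      seed = stage_seed(config$seed, "ppinet"))
    report$ppinet <- list(
      n_seeds = length(ppi_seeds),
      n_direct_edges = conn$observed$n_direct_edges,
      n_connected_seeds = conn$observed$n_connected_seeds,
      mean_direct_degree = conn$observed$mean_direct_degree,
      mean_indirect_connectivity = conn$observed$mean_indirect_connectivity,
      network_p_direct = unname(conn$network_p["n_direct_edges"]))
  } else {
    report$ppinet <- list(n_seeds = length(ppi_seeds),
                          note = "no seeds present in the PPI network")
  }

  jsonlite::write_json(report, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  write_report_md(report, file.path(outdir, "report.md"))
  invisible(report)
}

jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))

minet_gene_subset <- function(study, tf_ids, module_genes, max_genes) {
  core <- intersect(c(tf_ids, module_genes), study$genes)
  extra <- setdiff(study$genes, core)
  room <- max(0, max_genes - length(core))
  if (room > 0 && length(extra) > 0) {
    v <- apply(study$values[extra, , drop = FALSE], 1, var)
    extra <- extra[order(-v)][seq_len(min(room, length(extra)))]
  } else extra <- character(0)
  sort(c(core, extra))
}

config_as_report <- function(config) {
  out <- config[setdiff(names(config), "synth")]
  out$synth <- config$synth[setdiff(names(config$synth), "confounder_spec")]
  out$synth$confounders <- names(config$synth$confounder_spec)
  out$powers <- paste(range(config$powers), collapse = "-")
  out
}

write_report_md <- function(report, path) {
  f <- function(x, d = 3) formatC(x, digits = d, format = "g")
  lines <- c(
    "# Age-dependent module and master-regulator report", "",
    sprintf("- Soft power: %s; modules detected: %s", report$coexpr$soft_power,
            report$coexpr$n_modules),
    sprintf("- Selected module: %s (%d genes; selected by rule: %s)",
            report$coexpr$selected_module, report$coexpr$module_size,
            report$coexpr$module_selected_by_rule),
    sprintf("- Eigengene vs age: r = %s (p = %s), slope %s / year",
            f(report$coexpr$eigengene_age_r), f(report$coexpr$eigengene_age_p),
            f(report$coexpr$eigengene_age_slope)),
    sprintf("- Module recovery (Jaccard vs planted): %s",
            f(report$coexpr$jaccard_vs_truth)),
    "",
    sprintf("- Master regulators: %d of %d TFs tested (%s)",
            report$mrscan$n_mrs, report$mrscan$n_tfs_tested,
            paste(report$mrscan$mrs, collapse = ", ")),
    sprintf("- Driver sensitivity %s; false positives %d",
            f(report$mrscan$driver_sensitivity), report$mrscan$false_positives),
    "",
    sprintf("- Marker enrichment: %d observed vs null median %s (fold %s, p = %s)",
            report$markers$observed, f(report$markers$null_median),
            f(report$markers$fold), f(report$markers$p_empirical)),
    sprintf("- Marker panel mean age r: %s (p = %s)",
            f(report$markers$panel_mean_age_r), f(report$markers$panel_age_p)),
    "",
    sprintf("- Peak overlap: %s bp observed vs %s expected (fold %s, p = %s, q = %s)",
            f(report$regdom$observed_bp), f(report$regdom$expected_bp),
            f(report$regdom$fold), f(report$regdom$p_empirical),
            f(report$regdom$q_value)))
  if (!is.null(report$ppinet$n_direct_edges)) {
    lines <- c(lines, "",
      sprintf("- PPI: %s direct edges among %s connected seeds (mean degree %s), network p = %s",
              f(report$ppinet$n_direct_edges), f(report$ppinet$n_connected_seeds),
              f(report$ppinet$mean_direct_degree), f(report$ppinet$network_p_direct)))
  }
  if (!is.null(report$replication)) {
    lines <- c(lines, "",
      sprintf("- Replication: %s MRs in all %d datasets (%s)",
              length(report$replication$replicated_in_all),
              length(report$replication$per_dataset),
              paste(report$replication$replicated_in_all, collapse = ", ")))
  }
  writeLines(lines, path)
  invisible(report)
}
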