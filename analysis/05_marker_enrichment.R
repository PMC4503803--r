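#!/usr/bin/env Rscript
# Ask which cell population explains the selected module: count target-cell
# marker genes inside the module against 1000 random gene sets of the same
# size (fold over the null median, empirical p), check the off-cell panel,
# and measure the marker panel's mean expression-age correlation.

library(agemodnet)
study <- read_study_tsv("results/data/expression.tsv", "results/data/traits.tsv")
panels <- read_panels_tsv("results/data/marker_panels.tsv")
module_genes <- readLines("results/coexpr/selected_module_genes.txt")

dir.create("results/markers", showWarnings = FALSE)
out <- list()
for (nm in names(panels)) {
  enr <- marker_enrichment(module_genes, panels[[nm]], study$genes,
                           B = 1000, seed = 21L)
  cat(nm, ": "); print(enr)
  out[[nm]] <- list(observed = enr$observed, null_median = enr$null_median,
                    fold = enr$fold, p_empirical = enr$p_empirical)
}
jsonlite::write_json(out, "results/markers/enrichment.json",
                     auto_unbox = TRUE, digits = NA)

trend <- marker_age_trend(study, panels$target_cell)
print(trend)
trend_late <- marker_age_trend(study, panels$target_cell, min_age = 50)
cat("restricted to subjects 50+:\n"); print(trend_late)
write.table(trend$per_gene, "results/markers/target_panel_age_r.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
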