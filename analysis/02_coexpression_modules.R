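#!/usr/bin/env Rscript
# Build the weighted co-expression network, detect and merge modules, and
# apply the age-dependence selection rule: a module is kept when its
# eigengene's age correlation is significant (Bonferroni across modules) and
# more significant than its correlation with every tissue-quality confounder.

library(agemodnet)
study <- read_study_tsv("results/data/expression.tsv", "results/data/traits.tsv")
truth <- jsonlite::read_json("results/data/ground_truth.json",
                             simplifyVector = TRUE)

sim <- correlation_matrix(study)
sp <- pick_soft_power(sim, fit_target = 0.90)
cat(sprintf("soft power %d (scale-free fit %.2f)\n", sp$power,
            sp$fit_table$fit[sp$fit_table$power == sp$power]))

tom <- adjacency_to_tom(abs(sim)^sp$power)
modules <- detect_modules(tom, study, min_size = 10, merge_height = 0.25)
print(modules)

report <- select_age_modules(modules, study$traits, alpha = 0.05)
print(report)
sel <- report$table[report$table$selected, ]
stopifnot(nrow(sel) >= 1)
best <- sel$module[which.min(sel$p_age)]
module_genes <- names(modules$labels)[modules$labels == as.integer(sub("M", "", best))]
jac <- length(intersect(module_genes, truth$module_genes)) /
  length(union(module_genes, truth$module_genes))
cat(sprintf("selected %s: %d genes, Jaccard vs planted module %.2f\n",
            best, length(module_genes), jac))

eig <- modules$eigengenes[, best]
fit <- regression_slope(eig, study$traits$age)
cat(sprintf("eigengene vs age: r = %.3f, slope = %.4f per year (p = %.2g)\n",
            fit$r, fit$slope, fit$p))

dir.create("results/coexpr", showWarnings = FALSE)
write.table(data.frame(gene_id = names(modules$labels),
                       module_id = unname(modules$labels),
                       module_membership = agemodnet:::module_membership_r(modules, study)),
            "results/coexpr/module_membership.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(report$table, "results/coexpr/age_module_report.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
writeLines(module_genes, "results/coexpr/selected_module_genes.txt")
write.table(data.frame(sample_id = names(eig), eigengene = unname(eig)),
            "results/coexpr/selected_eigengene.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
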