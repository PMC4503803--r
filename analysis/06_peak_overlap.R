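#!/usr/bin/env Rscript
# Corroborate the master regulators at the genomic level: do ChIP peaks
# land in the basal regulatory domains (5 kb upstream / 1 kb downstream of
# the TSS) of the selected module's genes more than expected when peaks are
# re-placed uniformly within the workspace?

library(agemodnet)
annotation <- read.delim("results/data/gene_annotation.tsv")
chrom <- read.delim("results/data/chrom_lengths.tsv")
chrom_lengths <- setNames(as.integer(chrom$length), chrom$chrom)
peaks <- read_bed("results/data/peaks.bed")
workspace <- read_bed("results/data/workspace.bed")
module_genes <- readLines("results/coexpr/selected_module_genes.txt")

domains <- basal_regulatory_domains(
  annotation[annotation$gene_id %in% module_genes, ],
  up = 5000, down = 1000, chrom_lengths = chrom_lengths)
cat(sprintf("%d basal regulatory domains for the selected module\n",
            length(domains)))

res <- interval_overlap_test(peaks, domains, workspace,
                             n_sim = 1000, seed = 31L)
res$q_value <- adjust_pvalues(res$p_empirical)
print(res)

dir.create("results/regdom", showWarnings = FALSE)
write.table(data.frame(observed_bp = res$observed,
                       expected_bp = res$expected,
                       fold = res$fold, p_empirical = res$p_empirical,
                       n_sim = res$n_sim, q_value = res$q_value),
            "results/regdom/overlap_test.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
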