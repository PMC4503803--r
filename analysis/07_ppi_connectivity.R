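#!/usr/bin/env Rscript
# Do the identified master regulators interact at the protein level? Take
# the flagged TFs plus their in-module targets as seeds in the PPI network
# and test direct/indirect connectivity against 1000 within-degree
# node-label permutations.

library(agemodnet)
ppi <- read_ppi_tsv("results/data/ppi_edges.tsv")
mr <- read.delim("results/mrscan/mr_table.tsv")
regs <- jsonlite::read_json("results/minet/regulons.json",
                            simplifyVector = TRUE)
module_genes <- readLines("results/coexpr/selected_module_genes.txt")

flagged <- mr$tf[mr$is_mr]
targets <- intersect(unlist(regs[intersect(flagged, names(regs))]),
                     module_genes)
seeds <- head(unique(c(flagged, targets)), 50)
cat(sprintf("%d seed proteins (%d MRs + in-module targets)\n",
            length(seeds), length(flagged)))

direct <- seed_subnetwork(ppi, seeds)
cat(sprintf("direct network: %g interactions among %g connected seeds (mean degree %.2f)\n",
            direct$stats$n_direct_edges, direct$stats$n_connected_seeds,
            direct$stats$mean_direct_degree))

res <- within_degree_permutation_test(ppi, seeds, B = 1000,
                                      degree_bins = "log2", seed = 41L)
print(res)

dir.create("results/ppinet", showWarnings = FALSE)
jsonlite::write_json(list(observed = res$observed,
                          network_p = as.list(res$network_p),
                          n_fixed_seeds = res$n_fixed_seeds),
                     "results/ppinet/connectivity.json",
                     auto_unbox = TRUE, digits = NA)
write.table(data.frame(seed = names(res$per_node_p),
                       p = unname(res$per_node_p)),
            "results/ppinet/per_node_p.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
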