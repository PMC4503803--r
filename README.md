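# agemodnet

Aging reshapes the cortical transcriptome, and a disproportionate share of
that change is carried by microglia, the brain's resident immune cells.
`agemodnet` implements the full analysis chain for finding an age-dependent
co-expression module in cortex expression data and identifying the
transcription factors (TFs) that act as its **master regulators (MRs)** —
TFs whose predicted target set (*regulon*) overlaps the module far more than
chance — together with the three corroboration stages used to support such a
claim: cell-type marker enrichment, ChIP-peak overlap with basal regulatory
domains, and protein–protein interaction (PPI) connectivity.

Because the original cohort data are external, the package ships a
synthetic-study generator with known ground truth (planted module, planted
regulons, enriched peaks, wired-in PPI clique), so every stage is exercised
end-to-end by parameter recovery.

## The method

1. **Co-expression module discovery.** Pairwise Pearson correlations
   $r_{ij}$ become a soft-thresholded adjacency $a_{ij} = |r_{ij}|^\beta$,
   with $\beta$ the smallest power giving approximate scale-free topology.
   The adjacency is transformed to the topological overlap matrix

   $\mathrm{TOM}_{ij} = \dfrac{\ell_{ij} + a_{ij}}{\min(k_i,k_j) + 1 - a_{ij}},
   \qquad \ell_{ij} = \sum_u a_{iu}a_{uj},\; k_i = \sum_u a_{iu},$

   and modules are branches of the average-linkage tree on
   $1-\mathrm{TOM}$ (minimum size 10), merged while their eigengene
   dissimilarity is below 0.25. A module's **eigengene** is the first
   principal component of its gene-standardized submatrix. A module is
   **age-dependent** when its eigengene correlates with age more
   significantly than with every tissue-quality confounder (RIN, pH, PMI),
   confirmed by re-testing within confounder-matched sample strata.
2. **Regulon inference.** An undirected mutual-information network is
   reverse-engineered: Gaussian-kernel MI on copula-transformed pairs,
   edges kept above the MI threshold mapped from p = 1e-7 via a
   permutation-null tail fit, pruning by the data processing inequality
   (tolerance 0.1) with TF-target protection, and a bootstrap consensus
   over resampled cohorts. A TF's regulon is its neighbourhood in the
   final network.
3. **Master regulators.** For each TF, a one-sided Fisher's exact test on
   module membership × regulon membership, Bonferroni-corrected for the
   number of TFs tested; MRs can be intersected across replicate cohorts.
4. **Corroboration.** (a) Marker enrichment: observed marker count in the
   module versus 1000 random gene sets of the same size (fold over the
   null median, empirical p). (b) ChIP peaks versus the module's basal
   regulatory domains (5 kb upstream / 1 kb downstream of each TSS),
   randomizing peak placement within a workspace. (c) Seed connectivity in
   a PPI network against 1000 within-degree node-label permutations.

## Worked example

The numbered scripts under `analysis/` run the whole study; each is a thin
driver over package functions and writes its tables under `results/`.

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_coexpression_modules.R
# ... through analysis/07_ppi_connectivity.R
```

With the default configuration (2000 genes × 150 subjects, seed 1) this
prints, stage by stage:

```
planted module: 100 genes; drivers: G0471, G1017, G1533, G1860, G1974
planted eigengene vs age: r = -0.416 (target -0.40)

soft power 5 (scale-free fit 0.95)
selected M1: 121 genes, Jaccard vs planted module 0.83
eigengene vs age: r = -0.413, slope = -0.0017 per year (p = 1.5e-07)

5 of 18 tested TFs flagged as master regulators: G1017, G1860, G1974, G1533, G0471
driver sensitivity 1.00, false positives 0
replicated in all 3 cohorts: G0471, G1017, G1533, G1860, G1974

target_cell : enrichment_result: observed 41 vs null median 10 -> fold 4.1,
              empirical p = 0.000999 (B = 1000)
overlap_test_result: observed bp 51580 vs expected 1562.1 -> fold 33,
              empirical p = 0.000999 (n_sim = 1000)
connectivity_test (B = 1000, log2 bins): 29 direct edges among 9 connected
              seeds (mean degree 6.44), network p = 0.000999
```

Reading: the selection rule recovers the planted module (Jaccard 0.83) and
its eigengene declines with age at the planted strength; all five planted
driver TFs — and no others — are flagged as MRs and replicate across three
cohorts sharing the same regulatory ground truth; the module is enriched
for target-cell markers (41 observed vs 10 expected, empirical p at the
1/(B+1) floor); ChIP peaks pile into the module's basal regulatory domains
33-fold above the randomization null; and the MR proteins are densely
connected in the PPI network relative to degree-matched permutations.

`run_pipeline(pipeline_config(...), outdir)` performs the same chain in one
call and writes a JSON + Markdown report; rerunning with the same seed
reproduces every output byte for byte.

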