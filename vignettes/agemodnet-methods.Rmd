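---
title: "Methods: age-dependent modules and their master regulators"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: age-dependent modules and their master regulators}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's own account of the statistical machinery it
implements: the models and their assumptions, the tunable parameters and
why their defaults are what they are, what the synthetic-data generator
does and does not emulate, and the numerical choices made where the design
was genuinely open. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## 1. The scientific question

Postmortem cortex cohorts profile gene expression across the adult life
span together with tissue-quality covariates (RNA integrity number, pH,
postmortem interval). The analysis asks three nested questions: (i) is
there a coherent co-expression module whose summary expression tracks age
rather than tissue quality, (ii) which transcription factors regulate that
module ("master regulators", MRs) as judged by overlap between the module
and each TF's inferred regulon, and (iii) do independent data modalities —
cell-type marker panels, ChIP-seq binding, protein-protein interactions —
corroborate the claim.

## 2. Synthetic studies with known ground truth

Real cohorts cannot ship with the package, so every stage is validated by
parameter recovery on synthetic studies (`synth_config()`,
`generate_expression()` and friends). The generator plants exactly the
structure the analysis is built to find; recovering it is a necessary,
not a sufficient, condition for correctness on real data.

**The model.** Ages are uniform on 13–78 years, matching the span of adult
postmortem cohorts; a uniform design maximizes trend detectability. A
latent module eigengene is linear in standardized age plus Gaussian noise,
$e = r\,z_{\text{age}} + \sqrt{1-r^2}\,u$, with $r=-0.4$ by default; the
noise is resampled until the realized correlation is within 0.02 of the
target, leaving headroom so that the *sample* eigengene computed downstream
stays within 0.05. Plain module genes are $\lambda_i(e + \sigma_p
\varepsilon)$ with $\lambda_i \sim U(0.8, 1.2)$ and $\sigma_p$ set from the
target within-module correlation $w$ via $\sigma_p = \sqrt{1/w - 1}$
(default $w = 0.5$, i.e. moderately tight modules).

Driver TFs read a private regulatory factor $\eta$ and share variance with
the eigengene: $\mathrm{TF} = 0.5\,e + 0.8\,\eta + 0.33\,\zeta$. Their
in-module targets mix both factors, $\lambda_i(e + 0.8\eta + 0.8\zeta)$,
and their out-of-module targets are children of the TF's non-eigengene
component. Non-driver TFs and their targets form independent stars
($x = 0.92\,\mathrm{TF} + 0.6\,\zeta$). Two consequences are intentional:
the TF is always its targets' best observed proxy, so the data processing
inequality keeps the TF-target star rather than sibling-sibling edges;
and regulated genes carry more variance (~1.2–2.4) than background genes
(~1.0), as regulated genes do in real data, so variance-ranked gene
subsets retain them.

Confounders are sampled independently of age (rejection resampling until
the recorded values satisfy $|r| \le 0.15$; rejection rather than
orthogonalization keeps the marginals natural) and recorded at realistic
precision — RIN to 0.5, pH to 0.1, PMI to the hour — which is what makes
exact-value matched stratification meaningful. A confounder can instead be
tied to the eigengene's non-age component (`tie = "eigengene"`) to emulate
a quality artifact that mimics the module; this is the scenario in which
the selection rule must refuse the module.

**What is not emulated:** probe-level microarray noise, batch effects,
nonlinear age trajectories, correlated confounders, and cell-type
composition shifts. Passing recovery tests therefore demonstrates the
statistical machinery, not robustness to those artifacts.

Marker panels take the published scale of microglia marker lists as a size
template (162 markers, 40 inside the module) purely as a default. The
synthetic genome puts all genes on one chromosome at 20 kb spacing with
jittered TSSs and random strands; peak lengths are log-normal (median
400 bp) because ChIP peak lengths are right-skewed, and any positive
length distribution serves the test. The PPI background is
preferential-attachment (heavy-tailed degrees, as in curated interactomes)
with the seed clique wired in explicitly.

## 3. Co-expression modules

`pick_soft_power()` scans integer powers and returns the smallest $\beta$
whose scale-free fit index reaches the target. The fit index is the $R^2$
of log-density on log-connectivity over 10 equal-count connectivity bins;
with equal-count bins the meaningful response is the *density* (bin count
divided by bin width), which is what the implementation regresses. The
function's default target is 0.85. The pipeline passes 0.90: at 150
samples the 0.85 rule can stop at $\beta = 3$, where background noise
correlations ($|r| \approx 0.1$–$0.3$ between unrelated genes) survive the
power transform strongly enough to attach ~90 background genes to the
module branch; one step higher in $\beta$ suppresses them. This is an
analysis choice of the package, exposed as `fit_target`.

`detect_modules()` clusters $1-\mathrm{TOM}$ by average linkage and cuts
the tree statically at `cut_height`, defaulting to 0.995 × the maximum
merge height. The rationale: genes without partners join the tree in a
dense band just below the top; cutting just under that band isolates real
branches while everything in the band falls to module 0 and the minimum
size filter (10 genes) removes debris. This static cut approximates
dynamic branch cutting and is the one deliberately simplified component of
the stage; `cut_height` is exposed for tuning. Modules whose eigengenes
correlate above 0.75 (dissimilarity < 0.25) are merged iteratively, with
eigengenes recomputed after every merge.

Eigengenes are the first right-singular vector of the gene-standardized
submatrix, unit norm, sign-oriented so the mean correlation with member
genes is non-negative (the conventional disambiguation; the sign of a
principal component is otherwise arbitrary).

`select_age_modules()` correlates each eigengene with age and with every
confounder (Pearson; Spearman available via `spearman = TRUE`, two-sided
p from the t transform). The selection rule is: age association
significant at `alpha` *and* more significant than every confounder
association. Because a study yields ~15–20 modules and the rule is applied
to each, the default applies a Bonferroni correction across tested modules
to the age p-value before the `alpha` comparison; without it, at
$\alpha = 0.05$ with three confounders, the expected number of falsely
selected noise modules per study is close to one. `adjust = "none"` gives
the literal per-module rule. Matched validation recomputes the
eigengene-age correlation within strata of samples sharing an exact
recorded confounder value (minimum stratum size 5).

## 4. The mutual-information network

**Estimator.** `mutual_information()` rank-transforms each vector to
normal scores (a copula transform: MI is invariant under monotone maps,
and the transform removes marginal effects), then computes the plug-in
average of the log ratio of the joint Gaussian-kernel density to the
product of marginal kernel densities at the sample points, with
leave-one-out sums and Silverman's bandwidth $1.06\,\hat\sigma\,n^{-1/5}$
per axis. Evaluating the log-ratio at sample points makes the kernel
smoothing bias largely cancel between numerator and denominator, which a
grid-integrated KDE estimate of MI does not achieve. The estimate is
clamped at zero (the plug-in ratio can go slightly negative under
independence); ties are broken at random. A faster equal-frequency binned
plug-in estimator (`estimator = "bins"`) is available for exploratory
sweeps; the network builder always uses the kernel estimator. Because all genes of a study
share the same normal-score values, one kernel matrix serves every gene
pair; the all-pairs and permutation-null paths exploit this in compiled
code.

**Threshold.** The p = 1e-7 edge criterion cannot be reached by direct
permutation. `mi_threshold()` builds a null from ≥1000 random gene pairs
with one member's samples permuted, fits an exponential to the right tail
above the upper decile (null MI tails decay near-exponentially), and
inverts the fitted survival function; for p ≥ 0.1 the empirical quantile
is used directly. The extrapolation family is the documented choice; the
procedure is a replacement for, not a replica of, the cited tool's
internal mapping.

**DPI.** For every triangle, the weakest edge is marked when its MI falls
below $(1-\varepsilon)\min(\text{other two})$, with multiplicative slack
$\varepsilon = 0.1$ (the tolerance semantics used by published
implementations of the rule). TF protection is implemented literally: a
marked edge incident to a TF is exempt when the min-defining alternative
edge of that triangle joins two non-TFs, so a TF-target edge is never
discarded in favour of an edge between two non-TFs. Where two of the three
nodes are TFs the quoted rule is ambiguous; we protect if *any*
min-achieving alternative edge joins two non-TFs. All removals are applied
simultaneously after scanning every triangle, making the output
independent of edge enumeration order and a second application a no-op.

**Bootstrap consensus.** The network is rebuilt on sample-bootstrap
resamples; an edge is retained when its support count is significantly
above the mean per-round edge rate under a binomial null, BH-corrected at
0.05 (the consensus statistic of the cited tool is not described in
detail; a binomial exceedance test is the package's choice). Consensus
edge MI is the mean over supporting rounds.

## 5. Master regulators

`fisher_overlap()` is the one-sided ("greater") hypergeometric tail — the
direction follows from asking whether the intersection is *larger* than
chance. `identify_master_regulators()` Bonferroni-corrects over the TFs
actually tested (those with nonempty regulons after intersection with the
universe; empty regulons cannot be tested and are excluded from the
correction, with a message).

The universe is an explicit argument. The pipeline passes the full
expressed-gene universe rather than the MI-network gene set: the package
restricts the network to a few hundred genes (all TFs, the selected
module, then highest-variance fill) purely for tractability, and a
universe one-third of which is the module itself would cripple both the
sensitivity and the specificity of the overlap test relative to the
genome-wide networks the method is designed for. Callers who build
genome-wide networks should pass the network universe.

## 6. Marker enrichment and trends

The empirical p uses the +1 correction, $(\#\{null \ge obs\}+1)/(B+1)$,
so its floor is $1/(B+1)$ — with $B = 1000$, "p < 0.001" is exactly the
floor. Fold enrichment is defined against the null *median* (with 0/0
defined as 1 and $x/0$ as infinity). "Expressed" markers are those present
in the study's gene universe; no abundance cutoff is applied. The random
gene sets are drawn with the same *set size* as the module. Age trends
report per-gene Pearson correlations, the panel mean, and a two-sided
one-sample t-test of the correlations against zero, optionally restricted
to subjects at or above a minimum age.

## 7. Interval overlap

Basal regulatory domains span 5 kb upstream to 1 kb downstream of the TSS,
strand-aware, clipped to the chromosome; coordinates are 0-based half-open
internally and BED-native at the boundaries (GRanges carries the 1-based
closed representation in R). The test statistic is total nucleotide
overlap (peak-count overlap available via `statistic = "count"`). The
null re-places every peak uniformly among all positions within workspace
segments that can hold it — placements crossing workspace gaps are
impossible by construction, and per-simulation peak mass is conserved.
Composition-conditioned sampling (e.g. G+C isochores) would need external
genome annotation and is deliberately out of scope; the workspace
restriction is retained. Distal domain extensions are not applied: the
overlap test uses basal domains only. Multiple peak sets are corrected by
Benjamini-Hochberg (`adjust_pvalues()`).

## 8. PPI connectivity

The direct network is the induced subgraph on the seeds; indirect
connectivity counts, per seed, non-seed neighbours shared with at least
one other seed (length-2 paths through non-seeds — a stated surrogate for
the cited tool's associated-protein notion). The null permutes node labels
only within degree bins: exact-degree bins by default, which preserves the
seed-image degree multiset exactly; `log2` bins for hub-heavy networks
where exact bins are singletons and would pin seed labels (seeds in
singleton bins cannot move and are reported). Empirical p-values carry the
+1 correction — the quoted formula without it permits p = 0, which an
empirical test cannot assert.

## 9. Pipeline, determinism and problem sizes

`run_pipeline()` chains the stages, persists every intermediate artifact
as TSV/BED/JSON, and writes a report without timestamps so that a rerun
with the same seed is byte-identical. Per-stage seeds are derived from the
global seed by hashing the stage name, so any stage can be rerun
independently. Defaults follow the method's canonical settings: minimum
module size 10, merge height 0.25, MI p 1e-7, DPI tolerance 0.1, 100
bootstrap rounds, 1000 draws/simulations/permutations for the empirical
tests, $\alpha = 0.05$.

The validation suite runs at deliberately chosen sizes: studies of
600–2000 genes × 100–150 samples, MI networks of ≤340 genes, 10-seed
recovery runs, 100-seed null calibrations, and 200–500-replicate
calibration loops. These sizes are the package's choices for routine
validation; all of them scale up through configuration.

## 10. Known limitations

The static tree cut is a simplification of dynamic branch cutting and can
split diffuse modules at non-default powers. The MI threshold depends on
an exponential tail extrapolation five orders of magnitude beyond the
permutation support. The FET treats regulons as random draws from the
universe, which is optimistic when the network is restricted to a biased
gene subset (hence the expressed-gene universe default in the pipeline).
The generator's linear age model cannot probe nonlinear trajectories, and
none of the corroboration stages model assay-specific artifacts (ChIP
input bias, PPI literature ascertainment). Conclusions about real cohorts
require the real data.
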