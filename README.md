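# wpcna — weighted protein co-expression network analysis

`wpcna` is an R package for systems-level analysis of label-free proteomic
cohorts sampled across clinical groups — built around the study design of
control / asymptomatic Alzheimer's disease (AsymAD) / symptomatic AD brain
proteomes, and generic over any three-group design. It covers the full
path from a peptide-level table to trait-associated co-expression modules:

1. **Quantification** — protein-group filtering (≥ 1 unique peptide,
   ≥ 2 spectral matches) and top-3 peptide ion-intensity abundance
   estimation, plus membrane-vs-soluble enrichment decile profiling.
2. **Covariate regression** — per-protein bootstrap OLS
   (`abundance ~ group + age + sex + PMI`, group-stratified resampling,
   median coefficients) subtracting covariate effects while protecting the
   diagnosis signal.
3. **Differential abundance** — one-way ANOVA with Tukey HSD post-hoc
   pairwise comparisons (Tukey–Kramer standard errors, studentized-range
   p-values) and Venn summaries of the altered-protein sets.
4. **Network construction** — the core engine: biweight midcorrelation,
   signed soft-thresholded adjacency (`((1+s)/2)^β`, β = 11.5),
   mean-denominator topological overlap, dynamic hybrid tree cut with a
   medoid (PAM-like) assignment stage, module eigenproteins (first
   principal component of the standardized module submatrix), kME module
   membership, eigenprotein-correlation merging (cut height 0.07), kME
   reassignment (p = 0.05) and pruning.
5. **Enrichment** — one-tailed Fisher/hypergeometric over-representation of
   modules against GMT gene-set collections (cell-type markers,
   ontologies) with Benjamini–Hochberg FDR, and cross-network module
   overlap between two partitions with signed −log10(FDR) matrices.
6. **Trait correlation** — biweight midcorrelation of eigenproteins with
   diagnosis, CASI, CERAD and Braak, plus Kruskal–Wallis tests of
   eigenprotein differences across groups.
7. **Synthetic cohorts** — a generator that plants co-expression modules
   with disease-archetype expression profiles (transient AsymAD increase,
   preclinical decrease, progressive change, …), covariate effects and
   module–trait couplings, providing ground truth for every stage.

The WGCNA-style network machinery (bicor, TOM, tree cut, eigenproteins) is
implemented in this package; standard statistics go through base R and
established packages (`ptukey`, `phyper`, `p.adjust`, `kruskal.test`,
`fgsea` for GMT parsing, `ape` for Newick export).

## Worked example

Simulate the default cohort (18 samples, 8 planted modules spanning the
disease archetypes + 300 noise proteins), regress covariates, build the
network and relate modules to traits:

```r
library(wpcna)
spec <- synthetic_spec(seed = 42)
sim  <- generate_abundance(spec)
pm   <- regress_covariates(sim$matrix, sim$traits, n_bootstrap = 1000, seed = 42)
net  <- build_network(pm)
print(net)
#> module_partition (reassigned): 8 modules over 805 proteins, 235 unassigned
module_sizes(net$partition)
#>  M1  M2  M3  M4  M5  M6  M7  M8
#> 127 109  93  64  58  56  32  31
module_trait_bicor(net$eigenproteins, sim$traits)
#> module-trait bicor (n = 18; * p<0.05, ** p<0.01)
#>    diagnosis casi    cerad   braak
#> M1 -0.68**   +0.88** -0.46   -0.45
#> M2 +0.01     +0.12   +0.33   -0.01
#> M3 -0.59*    +0.56*  -0.19   -0.31
#> M4 +0.81**   -0.30   +0.79** +0.79**
#> M5 +0.62**   -0.56*  +0.36   +0.41
#> M6 -0.66**   +0.42   -0.51*  -0.68**
#> M7 +0.23     +0.09   +0.09   +0.38
#> M8 +0.74**   -0.42   +0.38   +0.48*
```

Eight modules are recovered, ranked by size. M4 — the planted
progressive-increase module coupled to amyloid burden — correlates with
diagnosis (r = +0.81) and CERAD (r = +0.79, the planted coupling was 0.7);
M1, the large progressive-decrease module coupled to cognition, tracks
CASI at r = +0.88 (higher expression with better cognition). Differential
abundance on the same matrix:

```r
sig <- significant_sets(anova_tukey(pm, sim$traits))
sig$union_count
#> [1] 345
sig$per_comparison
#> AsymAD_vs_control     AD_vs_control      AD_vs_AsymAD
#>               127               246               160
```

The whole pipeline can also be driven from one configuration
(`run_pipeline()` / `default_config()` / a YAML file, stage subcommands via
`inst/cli/wpcna.R`), writing per-stage TSV outputs, a Newick dendrogram and
a JSON run manifest; re-running an unchanged configuration reproduces
byte-identical outputs.

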