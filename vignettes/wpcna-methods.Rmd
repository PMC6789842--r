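---
title: "Weighted protein co-expression networks from label-free proteomics: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weighted protein co-expression networks from label-free proteomics: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical model behind `wpcna`, the
assumptions each stage makes, the parameters that matter, and the design
choices taken where the methodology leaves room. The package analyses
label-free proteomic cohorts sampled across three clinical groups —
pathology-free controls, asymptomatic Alzheimer's disease (AsymAD: AD
neuropathology with preserved cognition), and symptomatic AD — but every
stage is generic over any three-group design.

## From peptides to protein abundances

Label-free quantification rests on extracted ion-current (XIC) intensities
of identified peptides. `filter_protein_groups()` keeps protein groups
supported by at least one *unique* peptide (a peptide mapping to exactly one
group) and at least two peptide-spectrum matches, the matches summed over
the group's peptides across all samples. The cohort-wide reading of the
two-spectra rule is a deliberate choice (a per-sample reading would
discard sporadically sampled proteins that the unique-peptide rule admits);
it is recorded in the configuration.

`top3_protein_abundance()` estimates a protein's abundance in a sample as
the arithmetic mean of its three most intense peptides, the standard "top-3"
estimator whose precision is roughly constant across the dynamic range.
Proteins seen with only one or two peptides use the mean of what is
available, with the count recorded per cell: dropping them would contradict
the one-unique-peptide inclusion rule, and a partial mean is still an
unbiased (if noisier) abundance estimate under the multiplicative
ionization-efficiency model. Zero intensities are treated as missing, not as
zeros, because XIC absence reflects censoring at the detection limit rather
than true absence.

`membrane_enrichment_profile()` summarizes fractionation quality: per
protein the log2 ratio of membrane to soluble spectral counts, with a
pseudocount of 0.5 on both sides so membrane-only or soluble-only proteins
keep a finite, sign-preserving ratio. Proteins with fewer than three total
counts are excluded (counts that small cannot order a ratio meaningfully).
Ranked ratios are cut into ten near-equal deciles — sizes differ by at most
one, ties broken by (ratio, identifier) for reproducibility — and per-decile
compartment-class occupancy is reported.

## Covariate regression

Age, sex and post-mortem interval all influence measured protein levels.
`regress_covariates()` fits, per protein, the linear model
`abundance ~ group + age + sex + pmi` on bootstrap resamples drawn with
replacement *within* each diagnosis group (so group counts are preserved
exactly in every draw), and summarizes each covariate coefficient by its
median across resamples. The returned matrix subtracts
`b_cov * (x_cov - mean(x_cov))` for the covariates only: the group term is
protected, covariates are mean-centered so the grand mean survives, and the
removed component is by construction an exact linear function of the
covariate columns. The bootstrap-median aggregation is a robustness device
against influential cases in small cohorts; a default of 1000 resamples
makes the median stable to three decimals at n = 18. The number of
resamples, the median aggregation, and the OLS base learner are this
package's choices — the upstream literature describes the step only as
"bootstrap non-parametric regression" — and all three are configurable.
Proteins with fewer complete observations than model parameters plus two are
returned untouched, with a warning.

## Differential abundance

`anova_tukey()` performs a fixed-effects one-way ANOVA per protein on its
complete cases, followed by Tukey HSD pairwise comparisons with
Tukey–Kramer standard errors so unbalanced complete-case patterns are
handled correctly. Pairwise p-values come from the studentized range
distribution (`stats::ptukey`, a numeric-integration implementation of the
non-elementary CDF; the test suite pins it against published critical-value
tables, an independent double-integration oracle, and a one-million-draw
permutation oracle). Degenerate proteins are flagged rather than silently
tested: identical values give F = 0 and p = 1; separated groups with zero
within-group variance are reported with F = Inf, p = 0 and a reason code.
Following the source methodology, the pairwise p-values are thresholded at
0.05 without multiple-testing correction across proteins; the package
reports raw Tukey p-values and leaves the family-wise question to the
caller. The ANOVA runs on the covariate-regressed matrix by default.

## The network stage

The network engine implements the weighted signed co-expression methodology
for proteins:

* **Biweight midcorrelation.** For a profile `x`,
  `u_i = (x_i - med(x)) / (9 mad(x))` with the unscaled mad,
  `w_i = (1 - u_i^2)^2` for `|u_i| < 1` and 0 beyond, and the correlation is
  computed on `(x_i - med(x)) w_i`. One aberrant sample therefore cannot
  manufacture or destroy an edge, which matters at n = 18. Profiles with
  zero mad (majority-constant) cannot be robustly scaled and fall back to
  Pearson centering with a warning; dichotomous trait codings use the same
  fallback by construction.
* **Signed adjacency.** `a_ij = ((1 + s_ij)/2)^beta` maps correlation -1 to
  adjacency 0, so anti-correlated proteins are unconnected, and the soft
  power `beta = 11.5` suppresses weak edges smoothly.
  `pick_soft_threshold()` reports the scale-free fit index and connectivity
  spectrum across candidate powers for users choosing `beta` afresh.
* **Topological overlap.** `TOM_ij = (l_ij + a_ij) / (D_ij + 1 - a_ij)`
  with `l_ij` the shared-neighbor sum and, per the mean-denominator
  variant, `D_ij = (k_i + k_j)/2`; the min variant is available. TOM
  rewards proteins embedded in the same neighborhood, not merely correlated
  pairs.
* **Module detection.** Average-linkage hierarchical clustering of
  `1 - TOM`, cut by a dynamic hybrid procedure implemented bottom-up over
  the merge list: branches grow merge by merge, and when two branches that
  each satisfy the cluster criteria meet, both are finalized. The criteria
  are a minimum size (20), a ceiling on *core scatter* (the mean attachment
  height of the module's most tightly attached `min_module_size` members)
  and a floor on the *gap* between the merge height and the core's
  completion height. `deep_split` in 0..4 interpolates the scatter ceiling
  over c(0.64, 0.73, 0.82, 0.91, 0.95) of the height range between the 5th
  height percentile and the cut height (0.99 of the tallest merge), with
  the gap floor at three quarters of the complement. Measuring the gap from
  the core completion height, not the branch's running top, is deliberate:
  stragglers that join a branch just below a genuine boundary would
  otherwise erase the gap and block every split. A PAM-like stage then
  assigns leftover proteins to the nearest module *medoid*, by default only
  within the protein's own static branch (`pam_respects_dendro`), with ties
  broken toward the larger module.
* **Eigenproteins, kME, merging, reassignment, pruning.** A module's
  eigenprotein is the leading right singular vector of its standardized
  submatrix, sign-oriented to correlate positively with the module mean so
  "up in disease" reads directly off the profile; `variance_explained` is
  the leading singular value's share. kME is the Pearson correlation of
  each protein with each eigenprotein, with t-based p-values. Modules whose
  eigenproteins are nearly interchangeable (dissimilarity `1 - cor` below
  0.07) are merged iteratively, recomputing eigenproteins until no pair
  remains below the threshold — iteration matters, because a freshly merged
  pair's joint eigenprotein can capture a third module that neither parent
  did alone. A one-pass reassignment then moves any protein whose
  own-module kME is not significant (p > 0.05) but which has a
  significantly better home elsewhere; finally, members with insignificant
  kME and no significant alternative are returned to the unassigned pool.
  That pruning step mirrors the minimum-membership cleanup of the reference
  co-expression tooling; without it, chance passengers picked up during
  branch growth dilute the eigenproteins. Unassigned proteins never enter
  enrichment or trait statistics.

The merge threshold 0.07 is strict relative to common practice (0.15–0.25);
it is exposed as `merge_cut_height` and kept as the default deliberately,
matching the parameterization this pipeline reproduces. Trait statistics
use the final post-reassignment eigenprotein set. Proteins with any missing
abundance are excluded from network construction (TOM has no principled
missing-data extension) and listed in the log. At the ~1,800-protein scale
the network is built in a single block; no block-wise pre-clustering is
needed below roughly 10^4 proteins.

## Enrichment and cross-network overlap

`fisher_enrichment()` tests each (module, gene set) pair by the one-tailed
hypergeometric upper tail, with Benjamini–Hochberg FDR across all pairs of
a collection — the most conservative defensible family. The background
universe is the quantified proteome, not the genome: testing against the
genome would reward mere detectability. Symbols are uppercased and
deduplicated; set members absent from the background are dropped with a
logged count. `cross_network_overlap()` applies the same machinery to two
module partitions on their shared symbol universe and reports
positive-signed `-log10(FDR)` values plus Fisher confidence intervals per
cell.

## Module–trait relations

`module_trait_bicor()` correlates eigenproteins with diagnosis (coded
ordinally control = 0, AsymAD = 1, AD = 2 by default; a binary AD-vs-rest
coding is available), CASI (as measured, higher = better cognition, so
negative correlations mean higher expression with worse cognition), CERAD
and Braak, using the same biweight midcorrelation as the network with
t-based p-values at n - 2 degrees of freedom. Dichotomous columns fall back
to Pearson (median/mad are degenerate for binary codings). Stars mark raw
p < 0.05 and p < 0.01; an FDR column over the module-by-trait grid is
emitted alongside, leaving the multiplicity policy explicit but unimposed.
`eigenprotein_group_test()` provides the complementary Kruskal–Wallis test
of eigenprotein differences across the three groups, with tie correction.

## The synthetic cohort generator

`synthetic_spec()` defines the simulated study the tests and the acceptance
script run on. Defaults emulate the target study's structure at desk scale:
three groups of six samples; eight planted modules of sizes
120, 100, 80, 60, 50, 40, 30, 25 spanning six disease archetypes (stable,
progressive increase/decrease, early decrease then stable, transient
up/down in AsymAD); 300 unstructured noise proteins; a median within-module
correlation target of 0.6 (typical of strong co-expression modules at this
scale); covariate effects of 0.05 log2-units/year (age), 0.4 log2-units
(sex) and 0.1 log2-units/hour (PMI) on a random 30% of proteins with random
signs; and clinical traits coupled to module latents at r = 0.7 (CERAD to
the progressive-increase module, mirroring an amyloid-tracking module; CASI
to the large progressive-decrease module). Each module's proteins are
`loading * latent + noise` with loadings near 1 and the noise sd solved
from the correlation target; latents are the archetype's group-mean pattern
plus per-sample noise, standardized. Ages use a shared sorted backbone plus
small jitter so group means are matched within ~2 years, as in an
age-matched case selection. PMI is uniform on 2.5–8.5 h. Coupled pathology
scores are kept continuous (not rounded to the ordinal scale) so the
planted correlation is recoverable without discretization attenuation; this
is the one place the simulation is deliberately cleaner than real data.

What the generator does *not* emulate: peptide-level missingness structure,
batch effects beyond the three covariates, heavy-tailed abundance noise,
correlated noise proteins, or any cell-type composition signal. Passing
tests on this design therefore demonstrate that the machinery recovers the
structure it models — not that every real membrane proteome will resolve as
cleanly.

A note on what "recovery" can mean at n = 18: with 300 independent noise
proteins and 18 samples, sample correlations of |r| ~ 0.5–0.7 arise by
chance, and such proteins are genuinely module-like *in the realized data*.
Module recovery is therefore scored on the planted proteins (adjusted Rand
index against the design), with the noise pool held to a separate
majority-unassigned standard.

## Numerical and degenerate-input conventions

* mad is unscaled (constant = 1) inside the biweight, per the standard
  9-mad radius definition.
* Correlations are clamped to [-1, 1] and TOM to [0, 1] against floating
  point spill; symmetry is enforced by averaging with the transpose.
* Modules are labeled M1, M2, ... by decreasing size, ties broken by the
  alphabetically first member identifier, so labels are invariant to input
  order.
* Degenerate inputs warn and return a defined value rather than crash:
  all-equal TOM (single module or all-unassigned), constant traits (NA),
  zero-mad profiles (Pearson fallback); constant proteins and zero-variance
  modules are errors naming the offenders.
* All randomness flows from explicit seeds; bootstrap regression requires
  one, and the generator derives per-stage seeds by fixed offsets.

## Problem sizes used by the test suite

The suite exercises the full pipeline on the default 805-protein, 18-sample
design (ten seeds), the trait-coupling recovery on fifty seeds, a
one-million-draw permutation oracle for the Tukey stage, and oracle sweeps
of ~200 random correlation pairs, ~100 random TOM instances and ~90,000
hypergeometric tables. These sizes keep the whole suite within a few
minutes while leaving each statistical check enough resolution to fail
loudly if an implementation detail drifts.

## Known limitations

* Pairwise-complete bicor on matrices with missing values takes the slow
  per-pair path; the network stage itself is complete-case.
* The reassignment and pruning semantics (one pass, dual condition) are a
  documented interpretation; the reference tooling's internal behavior is
  not published in detail.
* No consensus networks, module preservation statistics, or partial
  correlations; ontology-graph-aware enrichment is out of scope — gene sets
  are flat GMT collections.
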