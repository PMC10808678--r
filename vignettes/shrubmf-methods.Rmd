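---
title: "Methods: assembly null models, multifunctionality and trade-offs in shrubmf"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: assembly null models, multifunctionality and trade-offs in shrubmf}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shrubmf)
```

`shrubmf` chains five analyses that soil ecologists usually run separately:
abundant/rare partitioning, phylogenetic null-model inference of community
assembly, multifunctionality indices, a per-sample functional trade-off
statistic, and driver attribution. This vignette explains each model, its
assumptions and tunable parameters, the numerical conventions, and what the
synthetic-data generator does and does not emulate.

## Study design and data model

The design is 3 successional stages (grass, mosaic, shrub) × 5 spatially
independent replicates = 15 samples. Each sample carries OTU count tables for
up to five taxonomic groups (archaea, bacteria, fungi, nematodes, protists),
one rooted phylogeny per group, and a 208-variable ecosystem-function matrix.
Tables are oriented samples × taxa/functions throughout, matching ordination
conventions. Counts must be non-negative integers; missing function values
are an ingestion error rather than being imputed, because both the
reflection and the unit scaling below depend on observed column maxima.

## Abundant and rare taxa

A taxon is *locally* abundant in a sample when its within-sample relative
abundance reaches the group's cutoff, and *regionally* abundant when its
across-sample mean does; the complements are rare, and taxa absent from a
sample belong to neither local set (a presence-conditional partition keeps
subcommunity dissimilarities well defined). The shipped per-group cutoffs —
0.1 % (archaea), 0.05 % (bacteria), 0.1 % (fungi), 0.1 % (nematodes), 0.2 %
(protists) — can be re-derived with `multicola_scan()`: for each candidate
cutoff the table is truncated, and the Spearman correlation between the
Bray–Curtis structures of the truncated and full tables is computed; the
chosen cutoff is the largest whose correlation still meets the retention
threshold (default 0.95, the conventional MultiCoLA criterion). Whether
truncation should use mean or per-sample relative abundance is genuinely
open; both are exposed (`truncate_by`), with the across-sample mean as the
default since the cutoff is a property of the whole table. The Procrustes
variant of MultiCoLA is not implemented.

## Assembly null models

`beta_mntd()` computes the between-community mean nearest taxon distance,
abundance-weighted by default (the convention of the null-model framework
this implements; unweighted is a switch). `beta_nti()` z-scores the observed
value against `n_null = 999` randomisations that shuffle taxon labels across
the tips of the phylogeny — topology and branch lengths fixed, the standard
"taxa labels" null. Alternative nulls are deliberately excluded. Pairs whose
null distribution has zero standard deviation (identical communities; star
trees, where every relabelling is isometric) are flagged undefined and
excluded from process fractions, with the count reported.

`raup_crick_bray()` builds null communities that preserve each observed
sample's richness and total abundance: taxa are drawn without replacement
with probability proportional to regional occupancy, and the remaining
individuals are filled multinomially proportional to regional mean relative
abundance. The observed Bray–Curtis dissimilarity is located in the null
distribution, ties counted with weight 0.5, and rescaled to [−1, +1]. Null
replicates are generated per sample within each randomisation round and
pairs are compared within a round; this preserves exactly the per-community
constraints while costing ~7× less than per-pair regeneration at 15 samples.
Ties are detected with an absolute tolerance of 1e−10 on the Bray scale.

The five-way classification follows the strict printed inequalities:
βNTI > +2 variable selection, βNTI < −2 homogeneous selection; otherwise
RC > +0.95 dispersal limitation, RC < −0.95 homogenizing dispersal, and
|RC| ≤ 0.95 drift. Boundary values (exactly ±2 or ±0.95) therefore fall to
the stochastic/drift side. (The source description of stochastic dominance
contains an evident typo — ">2" printed for both regimes — resolved here as
|βNTI| < 2 → stochastic, as the underlying framework defines.) For each
group the pipeline analyses the entire community plus the four
abundant/rare subcommunities, pruning the tree to each subcommunity's taxa.

`phylo_correlogram()` (a thin wrapper over `vegan::mantel.correlog`) checks
the premise that niche traits are phylogenetically conserved at short
distances. The one-tailed direction-adaptive permutation probabilities are
doubled and capped at 1, so reported p-values are two-sided and uniform
under a signal-free null; zero-variance traits are flagged undefined.

The βMNTD inner loop is implemented in C++ (`src/bmntd.cpp`) because a
999-randomisation null over all 105 sample pairs is evaluated thousands of
times in the calibration experiments; the implementation is cross-checked
against `picante::comdistnt` and against exhaustive tip-relabelling
enumeration on small trees in the test suite.

## Multifunctionality

Variables whose raw direction is "high = bad" — the three stoichiometric
ratios (OC:TN, OC:TP, TN:TP), unprotected organic carbon and its ratio, the
two fungal pathogen loads, and the 22 antibiotic-resistance-gene abundances,
29 variables in total — are reflected with r(f) = −f + max(f), then every
column is scaled to [0, 1] by its maximum (`f / max(f)`); `unit_scale()` is
the package's own implementation of that standard unit-scale standardisation.
Columns with no information after reflection (maximum ≤ 0) are dropped and
logged. Five indices are computed per sample and scope (aboveground,
underground, entire):

1. **Averaging**: mean of the standardized functions.
2. **Entropy-based at the maximum number of functions**: with shares
   $p_i = f_i / \sum_j f_j$ and Hill number $^qD$ (default $q = 1$,
   $\exp(-\sum p_i \ln p_i)$), the index is $A \cdot {}^qD / N$. The source
   cites but does not print the formula; this effective-number form was
   chosen because it collapses to the averaging index $A$ under perfect
   evenness, is bounded above by it, and penalises samples that deliver a
   few functions well and the rest poorly — exactly the "entropy" intuition.
   $q$ is a config knob.
3. **Averaging vs number of functions** and 4. **entropy vs number of
   functions**: Monte-Carlo means ± sd over random k-subsets of functions
   (exhaustive whenever $\binom{N}{k} \le 10{,}000$; N reaches 208, so
   exhaustive enumeration is generally infeasible), ending exactly at the
   full-scope value with sd 0 at k = N.
5. **Threshold counts**: number of functions with
   $f_{s,i} \ge t \cdot M_i$ over t = 0.1 … 0.9, where $M_i$ is the
   across-sample observed maximum by default (mean of the top-k values is a
   config alternative; observed max is the smallest-assumption choice).

## Functional trade-off intensity

For a pair of standardized functions $(x, y)$, the perpendicular distance to
the 1:1 line is $|x - y| / \sqrt 2$; a sample's trade-off intensity is the
mean over all $\binom{N}{2}$ pairs (computed via the sorted-order identity
for mean absolute pairwise differences, so the 208-function case costs
$O(N \log N)$ per sample). Intensity at a given number of paired functions
is the subset-mean over random k-subsets — how a cumulative variant would
differ is noted as open in the source; the subset mean was implemented
because it makes curves comparable across k.

## Driver analysis

Stage contrasts use the Kruskal–Wallis test plus pairwise Wilcoxon tests
(raw and Holm-adjusted p-values are both reported, since no adjustment is
prescribed at the source). Trajectories over grass → mosaic → shrub are
classified V / inverted-V when the mosaic median is the strict extremum with
at least one significant mosaic contrast, increase/decrease when medians are
monotone with a significant end-to-end contrast, flat otherwise; median ties
fall to flat unless a significant contrast resolves the direction.

Attribution chains: (i) iterative VIF screening — drop the worst predictor
while any VIF ≥ 10; (ii) redundancy analysis, implemented as least-squares
projection of the centred response matrix on the predictors followed by an
SVD of the fitted values (explained fraction = constrained / total inertia;
verified against `vegan::rda` in the tests); (iii) permutation forward
selection — the admission test permutes residuals of the current model
(row permutation is a config switch) and compares the candidate's added
variance against the *maximum* added variance over all remaining candidates
in each permutation, which corrects for best-of-candidates selection and
keeps the null admission rate at the nominal α (0.05 default); ties break
lexicographically so the path is column-order invariant; (iv) hierarchical
partitioning by exhaustive subset enumeration, capped at 12 predictors
(2^p cost; real workflows enter ≤ ~6 predictors after the previous two
steps), whose individual effects provably sum to the joint R².
Random-forest importance and PLS path modelling are out of scope; the
tables they would summarise are reproducible from the implemented steps.

## The synthetic-data generator

`simulate_dataset()` emulates the statistical structure the analysis
assumes, not amplicon data per se:

- **Phylogenies**: random coalescent trees (`ape::rcoal`). Coalescent trees
  concentrate depth on basal branches, so Brownian traits evolved on them
  carry deep phylogenetic signal — the regime in which nearest-taxon null
  models are informative. Tree shape is therefore a modelling choice, not an
  estimate of any real clade.
- **Niche traits**: Brownian motion on the tree, standardised to mean 0,
  sd 1 across tips (preserving the tree-structured covariance), so the
  selection strength has interpretable units.
- **Communities**: per-taxon lognormal baseline abundances (meanlog 0,
  sdlog 2 — a strongly skewed abundance distribution so per-sample occupancy
  is realistically incomplete) filtered by
  $\exp(-s\,(\mathrm{niche} - e_{\mathrm{stage}})^2)$ with stage optima
  (−1, 0, 1) and selection strength $s$ (default 0 = neutral), then
  multinomial draws at fixed depth 1000. Uniform depth removes rarefaction
  as a confounder; depth variation is available via the config.
- **Functions**: per-variable stage means follow monotone, V, inverted-V or
  flat profiles (baseline 10, effect 2, Gaussian noise sd 1). Under the
  default monotone profile the good direction improves toward shrub: raw
  values rise for ordinary variables and fall for reflect-flagged ones.
  The three shapes make the trajectory classifier testable.

For calibration experiments, "strong selection" means $s = 12$ with the
default stage optima: the Gaussian filter width ($\approx 0.2$ trait sd) is
then well below the between-stage optimum spacing (1 sd), so different
stages select phylogenetically distinct taxon sets, while per-sample
richness stays high enough for the null models to have power. Much larger
$s$ actually *weakens* the signal by collapsing richness. Even under this
scenario a minority of trait realisations carry little deep phylogenetic
signal (Brownian variance happens to fall within shallow clades); selection
then assembles phylogenetically mixed stage communities and βNTI stays
small. This mirrors real data — it is precisely why the correlogram check
precedes the null models — and it makes the selection-recovery statistic a
distribution over generator seeds (roughly 70 % of realisations exceed the
0.5 between-stage fraction) rather than a constant.

What the generator does **not** emulate: sequencing error, chimeras,
compositional artefacts of varying depth, taxon co-occurrence networks,
spatial autocorrelation among replicates, or realistic covariance among the
208 functions (they are conditionally independent given stage). Passing
tests therefore demonstrate that the inferential machinery is correct and
calibrated under the assumed generative model — not that any particular
field result would replicate.

## Registry accounting

The shipped registry enumerates 208 variables: 7 aboveground (species
richness; stand biomass, litter, total aboveground biomass; plant, shrub and
non-shrub cover) and 201 underground (8 nutrient provisioning, 144 element
cycling — including 20 soil carbon indicators, the separately counted
unprotected-organic-carbon ratio, 3 stoichiometric ratios, 2 elemental
limitations, 8 mineral phases, 2 root exudation variables, 40 plant-residue,
48 enzyme and 20 microbial-residue indicators —, 20 plant health, 4 water
regulation, 2 physical context, root biomass, and 22 antibiotic resistance
genes). The underground block lists admit more than one accounting that
totals 201; the one adopted (the unprotected-organic-carbon *ratio* counted
outside the twenty carbon indicators) is recorded here so the bookkeeping is
explicit. Generic placeholder names (`enzyme_activity_01` …) stand in for
assay-specific names that do not affect any computation; a custom registry
TSV can replace them.

## Numerical conventions and problem sizes

- All randomness is seed-driven; the pipeline derives module seeds
  deterministically from one global seed, so reports are bit-reproducible.
- Undefined quantities are explicit flags (`NA` + counts), never silent
  zeros: degenerate βNTI nulls, all-zero function columns, empty
  subcommunities, zero-variance traits.
- Equality tolerances: 1e−10 for Bray ties, 1e−12 for zero null sd, 1e−9
  for fraction sums.
- The test-suite and acceptance experiments run at 40 taxa per group, 15
  samples, 999 null randomisations, and 20 generator seeds for the
  calibration and direction-recovery checks — sizes at which the
  Monte-Carlo properties being asserted are stable from seed to seed while
  the whole suite completes in well under a minute of null-model time.

## Known limitations

- The βNTI null shuffles taxa across all tips of the (sub)tree; no
  within-bin (iCAMP-style) decomposition is offered.
- RC_bray's null is the abundance-based variant only; the presence-only
  variant is a knob on the same machinery but shares its occupancy model.
- Hierarchical partitioning is exact but exponential; it refuses more than
  12 predictors rather than approximating.
- The entropy-based index is one defensible reading of "entropy-based
  multifunctionality"; results at $q \ne 1$ or with other normalisations
  are not comparable across studies without stating the formula.
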