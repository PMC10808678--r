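# shrubmf

Shrub encroachment into grassland replaces a grass-dominated ecosystem with a
mosaic and finally a shrub-dominated one, and the soil community underneath it
reorganises along the way. `shrubmf` implements the analysis chain used to ask
what that succession does to ecosystem functioning: it links the **assembly
processes** of soil multitrophic communities (archaea, bacteria, fungi,
nematodes and protists, each split into abundant and rare fractions) to
**ecosystem multifunctionality** and the **trade-offs among functions**, across
a grass → mosaic → shrub gradient sampled as 3 stages × 5 replicates.

It is aimed at soil and microbial ecologists who have OTU tables, phylogenies
and a panel of measured ecosystem functions, and want the full inferential
chain in one tested toolbox rather than scattered scripts.

## What it computes

- **Abundant/rare partitioning** (`multicola_scan`, `partition_rarity`):
  multivariate cutoff level analysis chooses a relative-abundance cutoff
  (default per-group cutoffs 0.1/0.05/0.1/0.1/0.2 % for
  archaea/bacteria/fungi/nematodes/protists); each community is then split
  into *entire*, locally/regionally abundant and locally/regionally rare
  subcommunities.
- **Assembly null models** (`beta_nti`, `raup_crick_bray`,
  `classify_process`): the β-nearest-taxon index
  βNTI = (βMNTD_obs − mean βMNTD_null) / sd βMNTD_null, with the null built by
  shuffling taxon labels across phylogeny tips, and the abundance-based
  Raup–Crick metric RC_bray ∈ [−1, 1]. Pairs are classified as
  variable selection (βNTI > +2), homogeneous selection (βNTI < −2),
  dispersal limitation (|βNTI| < 2, RC > +0.95), homogenizing dispersal
  (|βNTI| < 2, RC < −0.95) or drift (|βNTI| < 2, |RC| ≤ 0.95).
  `phylo_correlogram` checks the phylogenetic-signal premise first.
- **Multifunctionality** (`multifunctionality` and friends): a 208-variable
  function registry (7 aboveground, 201 underground; "high = bad" variables
  are reflected with r(f) = −f + max(f)), unit scaling f / max(f), and five
  complementary indices per sample — averaging, entropy-based (Hill-number
  effective multifunctionality A·ᵠD/N at the maximum number of functions),
  both as curves over the number of functions, and threshold counts.
- **Functional trade-off intensity** (`tradeoff_intensity`): mean
  perpendicular distance |x − y|/√2 of standardized function pairs from the
  1:1 line, per sample, with curves over the number of paired functions.
- **Driver attribution** (`driver_analysis`): Kruskal–Wallis/Wilcoxon stage
  contrasts with V / inverted-V / monotone trajectory classification, VIF ≥ 10
  screening, redundancy analysis, permutation forward selection and
  exhaustive hierarchical partitioning of explained variance.
- **Synthetic data** (`simulate_dataset`): a generator reproducing the
  design's statistical structure — coalescent phylogenies, Brownian niche
  traits, lognormal abundances filtered by stage-specific environmental
  optima, multinomial sequencing, and a stage-structured function matrix —
  so the entire chain is testable end to end.

## Worked example

```r
library(shrubmf)

cfg <- run_config(
  synth      = synth_config(groups = c("bacteria", "protists"),
                            taxa_per_group = 40, selection_strength = 12),
  classifier = classifier_config(n_null = 199),
  mf         = mf_config(n_subset_draws = 50),
  drivers    = driver_config(n_perm = 199),
  seed       = 42)
rep <- run_pipeline(cfg)
print(rep)
#> shrubmf pipeline report
#>   samples: 15 (grass -> mosaic -> shrub)
#>   groups: bacteria, protists
#>   subcommunities analysed: 7
#>   aboveground MF: medians 0.810/0.858/0.927 | KW p = 0.0122 | trajectory: increase
#>   underground MF: medians 0.695/0.791/0.882 | KW p = 0.00193 | trajectory: increase
#>   entire MF: medians 0.701/0.793/0.883 | KW p = 0.00193 | trajectory: increase

head(process_fraction_table(rep), 5)
#>      group subcommunity                process   fraction
#> 1 bacteria       entire     variable selection 0.50961538
#> 2 bacteria       entire  homogeneous selection 0.00000000
#> 3 bacteria       entire   dispersal limitation 0.20192308
#> 4 bacteria       entire homogenizing dispersal 0.25000000
#> 5 bacteria       entire                  drift 0.03846154
```

The report says: under strong stage-specific selection the simulated
communities show selection-dominated between-stage turnover (half the sample
pairs classified as variable selection), and because the generator elevates
the "good" direction of every function toward the shrub stage, all three
multifunctionality scopes rise monotonically from grass to shrub with
significant Kruskal–Wallis contrasts.

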