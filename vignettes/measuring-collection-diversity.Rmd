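---
title: "Measuring the diversity of a collection of populations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring the diversity of a collection of populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(popdiv)
```

## The model

Each individual is a haplotype of 0/1 allele states over `L` biallelic SNP
loci. A population is summarised, per locus, by the fraction `p` of
individuals carrying allele 1; a collection of `m` populations by the vector
`p_1, ..., p_m`. Two base measures describe one population at one locus:

* expected heterozygosity `Het(p) = 2p(1 − p)`: the probability that two
  individuals drawn uniformly *with replacement* differ in allele. This is
  the haploid, frequency-based definition — not observed diploid
  heterozygosity — and it equals twice the Bernoulli variance `p(1 − p)`.
* split system diversity `SSD(p) = 1{0 < p < 1}`: whether the locus splits
  the population, i.e. both states are present. Summed over loci this counts
  the bipartitions represented in the set.

Four approaches lift a base measure to the collection (see the README table
for the formulas): pooling applies the base measure to `p̄ = mean(p_i)`;
averaging averages it within populations; pairwise differencing measures the
spread of the `p_i` (for Het, `(1/m²) Σ_{i,j}(p_i − p_j)²`, which equals
twice the population variance of the `p_i`; for SSD, the squared range);
fixing takes the expectation, under independent drift of each isolated
population to fixation (allele 1 with probability `p_i`), of the base
measure applied to one individual per population. The fixing expectation is
computable in closed form because each base measure has a formulation that
is linear in each individual state separately, so states can be replaced by
their expectations `p_i`.

Multi-locus scores are the per-locus scores summed over loci. All eight
measures are invariant to relabelling the two alleles (`p → 1 − p`) and to
reordering populations; per-locus Het-type scores lie in `[0, 0.5]`
(differencing in `[0, 1]`), SSD-type scores in `[0, 1]`.

Three identities tie the Het family together and are enforced at `1e-12` in
the tests:

* decomposition: `Het_pooling = Het_averaging + Het_differencing`
  (total = within + between gene diversity, `GD_T = GD_WS + GD_BS`);
* fixing: `Het_fixing = Het_pooling − Het_averaging / m`;
* variance: `Het_differencing = 2 · Var_pop(p_i)` with the divide-by-`m`
  (population) variance — the `1/m²` pairwise sum forces this convention,
  not the sample variance.

For subsets of size 2 and 3, `Het_fixing` is an exact positive multiple of
`SSD_fixing` (`1/2` and `4/9` respectively — the third elementary symmetric
polynomial cancels from `SSD_fixing` at `m = 3`), so their Pearson
correlation over any subset collection is exactly 1; from `m = 4` the
proportionality breaks and the correlation merely stays high.

## From VCF to frequency matrix

`read_vcf()` keeps biallelic SNP records only and recodes genotypes as
minority-allele presence/absence: the majority allele at a locus is the one
with more pooled allele copies over **all** mapped individuals (a single
global polarity per locus — a per-population majority would make frequencies
incomparable across populations); an individual scores 1 when it carries at
least one minority copy. Ties in allele counts are broken toward REF as
majority, with a warning. Half calls (`./1`) and missing genotypes are
treated as missing and excluded per locus from both numerator and
denominator of the population frequency; loci in which some population has
no called individual at all have an undefined frequency there and are
dropped from the whole matrix with a warning. Locus identifiers are
`CHROM:POS` (1-based). These missing-data conventions are this package's
own; QC beyond biallelic-SNP selection is out of scope and should happen
upstream.

## Subset search and correlation analysis

`max_diversity_exhaustive()` enumerates all `choose(m, k)` subsets in
lexicographic index order and returns *every* subset within `1e-9` of the
maximal total. The tolerance exists because totals are sums of thousands of
doubles; distinct subsets can attain the same optimum exactly, and tie
reporting is part of the contract. No pruning is attempted: averaging-type
optima are not monotone in `k` (adding a population can dilute the average),
so heuristics that assume monotonicity are unsound; `evaluated_count` makes
the brute-force cost visible.

`correlation_matrix()` computes each measure's total once per subset and
correlates measure pairs across the shared subset list. For large `k`,
`sample_subsets()` draws `N` subsets uniformly — with replacement at the
subset level by default (a documented convention; the draw count, not the
distinctness, is what the standard error formula uses), switchable to
without-replacement. Sampled correlations carry the standard error
`(1 − r²)/√(N − 3)`; Fisher-z intervals are deliberately not provided.
Pairs whose score vector is constant across subsets (easy for the
integer-valued pooled SSD, and automatic for the pooled/averaged SSD on
continuous synthetic matrices, where every locus is polymorphic in every
subset) are reported as flagged `NA` rows rather than numbers or silent
omissions.

`locus_sum_correlation_check()` exposes the single-locus versus
locus-summed comparison: when columns are independent replicates, the
correlation of summed totals matches the per-locus correlation up to
sampling error, which is why single-locus reasoning about measure agreement
transfers to whole panels.

## Synthetic data: what it emulates, and what it does not

The generators are pure functions of their parameters and a mandatory seed:

* `permute_matrix()` shuffles all `m × L` entries, preserving the marginal
  frequency distribution exactly while destroying population and locus
  structure;
* `uniform_matrix()` draws `p_ij ~ U[0, 1]`;
* `salmon_like_matrix()` draws `p_ij ~ Beta(0.3, 2.7)` (mean 0.1), a
  zero-skewed stand-in for SNP panels in which most minor-allele frequencies
  are near 0 in every population. The shape parameters are arguments, not
  constants;
* `bernoulli_populations()` adds finite-sample noise by drawing `n_i`
  individuals per population with state probabilities `p_ij`, exercising the
  encode-then-estimate pipeline.

All of these produce i.i.d. entries: no linkage between loci, no shared
drift history between populations, no exact zeros in the continuous
generators. That last point matters for interpretation. On any i.i.d.
zero-skewed matrix, a population that deviates from the near-zero bulk
deviates *toward* 0.5, so between-population spread and mean heterozygosity
rise together and `Het_differencing` correlates **positively** with
`Het_averaging`; on a uniform matrix deviant frequencies are extreme and
low-het, and the correlation is strongly negative. Empirical SNP panels,
where the negative sign co-occurs with a zero-skewed marginal, combine that
marginal with population structure that none of the i.i.d. generators
carry. The acceptance checks therefore assert the mutually positive
pooling/averaging/fixing block on the zero-skewed matrix and the
differencing signs on the uniform matrix, and passing them demonstrates
properties of the measures — not that any particular real data set will
show the same magnitudes. Near-zero correlations (averaging–fixing on
uniform data sits around 0 at 50 × 500) are asserted on neither.

## Numerical and design choices

* Per-locus scalar measures are the reference implementation;
  `subset_scores()` is an algebraically rearranged vectorised path (column
  sums and squared column sums per subset) used by search and correlation,
  and the suite asserts agreement to `1e-12`.
* Identity tolerances are `1e-12` (single-locus algebra in doubles); search
  tie tolerance is `1e-9` (sums over thousands of loci); the exact
  fixing-pair correlation is asserted to `1e-9`.
* Size weighting (`weights` arguments, `weighted = TRUE` in
  `collection_diversity()`) replaces the unweighted means in pooling and
  averaging with size-weighted means and reduces to the unweighted forms
  under equal weights. The differencing and fixing measures are left
  unweighted: their pairwise/product forms have no canonical weighted
  counterpart in this framework, and inventing one silently would change
  rankings. `m = 1` gives 0 for differencing and fixing and makes pooling
  equal averaging.
* Problem sizes in the checks — 1000 random frequency vectors for the
  identities, a 20 × 200 matrix for the exact fixing correlation
  (190 + 1140 subsets), 50 × 500 matrices at `k = 3` (19 600 subsets) for
  the sign structure, 6 × 4 matrices for the search-versus-brute-force
  equivalence — are chosen so each property is exercised well past its
  degenerate cases while the whole suite runs in well under a minute per
  block.

## Limitations

* Frequencies are treated as known; sampling uncertainty in `p_i` from 8–25
  genotyped individuals per population is not propagated.
* Exhaustive search is `O(choose(m, k) · k · L)`; it is meant for small `k`
  (for 50 populations, `k ≤ 4` is comfortable). No ILP or submodular
  machinery is provided.
* Only biallelic SNPs are supported; phasing, imputation and filtering are
  upstream concerns.
* Phylogenetic diversity, entropy/Hill numbers, and observed (diploid)
  heterozygosity are out of scope.
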