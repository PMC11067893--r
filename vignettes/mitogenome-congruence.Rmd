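---
title: "Methods: measuring gene-tree congruence with a mitogenome reference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: measuring gene-tree congruence with a mitogenome reference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The question the package answers

A mitochondrial genome is a single non-recombining locus: all of its genes
share one genealogy. A tree estimated from the complete mitogenome is
therefore the best available estimate of that genealogy, and a tree
estimated from any single gene is a noisier estimate of the *same* tree.
`mitoconcord` quantifies how much worse the single-gene estimates are, and
which alignment properties explain the loss. It does not infer the trees
themselves from real data (any external tool may be used for that); it
measures, compares, and explains.

## Metrics

**Robinson–Foulds (RF) distance.** Both trees are unrooted and reduced to
their sets of nontrivial bipartitions (splits with at least two taxa on
each side), each encoded by a canonical key: the sorted side that does not
contain the alphabetically first taxon. The RF distance is the size of the
symmetric difference of the two key sets. No normalization is applied, so
values are even for pairs of binary trees and bounded by `2(n-3)`.

**Polytomy branches and bifurcating nodes.** For a rooted tree, a node
with more than two children contributes all of its child branches to the
polytomy-branch count; a node with exactly two children is fully
bifurcating. A fully resolved rooted tree on `n` leaves has `n - 1`
bifurcating nodes (including the root) and 0 polytomy branches.

**Parsimony-informative (PI) sites and SIC.** A column is
parsimony-informative when at least two states each occur in at least two
sequences; gaps and IUPAC ambiguities are treated as missing. The
standardized information content is PI sites per kilobase,

```
sic = round(1000 * pi_sites / alignment_length_bp, 2)
```

so alignments of different lengths are comparable.

**Saturation slope.** Uncorrected p-distances (pairwise deletion) are
regressed by OLS, with a free intercept, on model-corrected distances
(JC69 by default; K80 and TN93 available, all with closed forms matching
`ape::dist.dna`). Because a proper correction satisfies `d >= p`, the
slope is at most ~1; the further below 1, the more multiple substitutions
the observed distances hide. Pairs whose corrected distance is undefined
(p at or beyond the model bound, or no comparable sites) are excluded;
when more than 25% of pairs are excluded (`max_excluded_frac`) the
regression is refused as unreliable rather than reported from a biased
subsample, and table builders record the slope as `NA`.

**Concordance factors.** The gene concordance factor of a reference
branch is the percentage of *decisive* gene trees containing that branch:
a gene tree missing taxa is restricted to its own leaf set, and counts
only when both restricted sides keep at least two taxa. It is reported to
one decimal, with the exact supporting/decisive counts alongside. The site
concordance factor samples `n_quartets` (default 100) quartets around each
internal branch — one leaf from each of two distinct subtrees at either
end — and averages, over quartets with at least one decisive site, the
percentage of clean two-state 2+2 site patterns that support the reference
pairing. The default of 100 quartets keeps the Monte Carlo error of a
percentage below a few points at negligible cost; the sampling seed is a
required argument, never an ambient default.

**SH test with RELL.** Site log-likelihoods are computed once per
candidate topology under GTR+I+G by Felsenstein pruning (branch lengths
optimized coordinate-wise unless supplied), then `n_replicates = 1000`
multinomial site-weight resamples (RELL — no re-optimization) build the
null distribution of the likelihood deficit. Each tree's p-value is the
fraction of replicates whose centered deficit is at least the observed
one; the maximum-likelihood tree has p = 1 by construction. Fewer than 100
replicates are refused by default because the p-value granularity becomes
meaningless. 1000 replicates bound the Monte Carlo standard error of a
p-value near 0.05 by about 0.007.

**Explaining RF.** `explain_rf_anova()` fits a sequential (Type-I) ANOVA
of RF distance on, by default, saturation slope, then alignment length,
then the length-by-PI-sites interaction. Type-I sums of squares depend on
term order, so the order is part of the model specification and is
configurable. Topology-derived columns (polytomies, support) are not
offered as default predictors because they are intrinsically coupled to
the response.

## The substitution model and likelihood engine

The model is GTR+I+G: six exchangeabilities in the order AC, AG, AT, CG,
CT, GT; four base frequencies; a proportion `p_invariant` of invariant
sites; and a discrete gamma with `n_categories` (default 4) classes whose
rates are the means of equal-probability sections of the gamma(α, α)
density, computed with the `pgamma(α + 1)` identity. Gamma rates are
scaled by `1/(1 - p_invariant)` so the mean rate over all classes
(including the zero-rate invariant class) is exactly 1, keeping branch
lengths in expected substitutions per site. The rate matrix is
eigendecomposed in its symmetrized similarity transform, which is
numerically stable and guarantees real eigenvalues for any reversible
model. Tiny negative transition probabilities from roundoff are clamped
and rows renormalized. Alignment columns are compressed to unique
patterns before pruning; IUPAC ambiguity codes enter as partial states
(all compatible bases equiprobable).

`p_invariant = 1` is accepted as a boundary case so the simulator can
generate all-constant alignments; likelihoods remain defined (non-constant
patterns get probability zero) but the mean-rate normalization is
necessarily vacuous there.

## What the simulator emulates — and what it does not

`simulation_config()` defaults mirror the shape of a mitogenome study:
51 taxa, 15 partitions with the published gene lengths (from `ND1` at
966 bp down to `ATP8` at 168 bp, plus the two rRNAs), a Yule tree rescaled
to a root-to-tip height of 0.3 expected substitutions (a typical
within-genus mitochondrial depth; heights well above ~1 saturate the
fast-evolving sites, heights well below ~0.05 leave short genes nearly
uninformative), and a GTR+I+G model with transition-biased
exchangeabilities `(1, 6, 1, 1, 6, 1)`, AT-rich frequencies
`(0.33, 0.28, 0.12, 0.27)`, `p_invariant = 0.3` and `gamma_shape = 0.5`.
These are round, typical vertebrate-mitochondrial values chosen once,
up front — not fitted to any dataset. The generator evolves states
edge-wise by exact transition probabilities with per-site rate classes
and per-partition rate multipliers.

It deliberately does **not** emulate: codon structure or selection,
alignment error, base-composition heterogeneity across lineages
(non-stationarity), or rate drift along the tree. Conclusions from
simulations are therefore about sampling noise and saturation, not about
systematic error.

Every stochastic function takes an explicit seed; orchestrators derive
component seeds deterministically (the tree uses `seed`, the alignment
`seed + 1`) and restore the caller's RNG state afterwards, so identical
configs give byte-identical studies.

## Numerical and algorithmic choices

- **NJ**: Saitou–Nei with the Studier–Keppler Q-criterion; ties broken at
  the lowest (row, column) index, so dendrograms are platform-stable;
  negative branch estimates clamped to zero with the total deficit
  recorded in an attribute. Exact on additive matrices.
- **Branch-length optimization**: coordinate-wise Brent search
  (`stats::optimize`) with accept-if-better sweeps, tolerance `1e-4`,
  30-sweep cap, branches bounded by 10 expected substitutions. This is
  robust and sufficient for RELL input; it is not a general ML tree
  searcher.
- **Distances**: closed-form JC69/K80/TN93 with pairwise deletion; TN93
  uses alignment-wide pooled base frequencies. Undefined pairs are `NA`
  with a count attribute, never silently zero.
- **ANOVA**: delegated to `stats::aov` on the assembled table; the
  package owns the table, not the linear algebra.

## Test problem sizes

The test suite's fixed scales (e.g. 8–12 taxa, 600–10,000 sites, 20–100
seeded replicates) were chosen to make each property decisive in seconds
on one CPU while staying inside the regime where the tested method is
statistically identifiable; recovery experiments hold the topology fixed
because random Yule trees routinely contain internal branches expecting
fewer than one substitution across the whole alignment, which no
estimator can resolve.

## Limitations

- Pruning works in probability space with pattern compression; for
  hundreds of taxa with extreme rates a log-space/scaling implementation
  would be needed.
- The SH implementation optimizes branch lengths per topology under one
  shared substitution model; it does not re-estimate model parameters per
  topology.
- The NJ estimator used in recovery experiments is a stand-in for the
  study pipeline's external ML/Bayesian inference, chosen for speed and
  exact reproducibility; its absolute recovery rates should not be read
  as statements about ML methods.
- Near-zero internal branches are reported as estimated (possibly
  clamped) values; the package does not collapse them into polytomies
  automatically.
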