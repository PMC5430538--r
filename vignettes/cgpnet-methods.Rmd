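---
title: "Network-assisted GWAS analysis: models, parameters and design choices"
author: "cgpnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Network-assisted GWAS analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cgpnet)
```

# The problem

Genome-wide association studies report one P-value per SNP. Two
obstacles stand between those P-values and gene-set biology: a gene's
natural statistic — its best SNP P-value — is biased by gene length
(more SNPs, more chances of a small minimum), and genes acting jointly
through protein interactions can be individually sub-significant.
`cgpnet` addresses both: an exact length-bias correction by circular
genomic permutation, followed by a search for interaction-network
modules whose association signal is dense and reproducible across two
parallel GWAS datasets.

# Exact gene-level P-values

## Model

All L autosomal SNP P-values are ordered chromosome 1 to 22 and placed
on a circle. A permutation sample rotates the values by an offset and
reassigns them to the fixed SNP positions; because neighbouring
statistics move together, the local correlation induced by linkage
disequilibrium is preserved, which an i.i.d. permutation would destroy.
With P_g the observed best P-value among the m_g SNPs of gene g, and
considering *all* L non-repeating rotations, the corrected P-value is

$$P_{corrected} = 1 - \frac{l}{L+1}, \qquad
  l = \#\{\text{rotations with } P_{\pi,g} > P_g\}.$$

The test is exact: no rotation is ever simulated. A rotation qualifies
for l if and only if the corresponding circular window of width m_g
contains no value at or below P_g, so l is the number of length-m_g
circular windows whose minimum exceeds P_g — computable from the
maximal circular runs of values above the threshold (each run of length
r contributes max(0, r − m_g + 1) windows).

Two semantic decisions are applied literally and covered by tests:

* the rotation set includes the identity (it can never increment l,
  because the comparison is strict), giving the L + 1 denominator;
* ties count against the gene (strict `>`), the conservative reading.

`corrected_p` therefore lies in [1/(L+1), 1]: the resolution floor of
the exact test is set by the number of SNPs, and the smallest value a
gene of m SNPs can attain is (m+1)/(L+1) (the m rotations that place
the global minimum inside its window always fail, plus the identity).
This floor matters for interpretation: with 20,000 SNPs a 20-SNP gene
can never fall below ~1.05 × 10⁻³ however strong its best SNP.

## Batch algorithm

Scoring all genes naively costs O(G·L). `computeGenePvalues()` instead
processes genes in decreasing order of P_g while deleting "blocker"
positions (values above the current threshold) from a circular doubly
linked list; the runs above threshold are then exactly the gaps between
surviving blockers, and a Fenwick tree keyed by gap length yields

$$l = \sum_{\text{gaps } \ge m} \text{len} - (m-1) \cdot
      \#\{\text{gaps} \ge m\}$$

in O(log L) per query, O((L+G) log L) overall. Correctness is defined
by the brute-force rotation enumeration oracle, against which the
batch path is tested exactly on hundreds of random circles, with and
without ties.

Gene windows mapped from interval annotations are always consecutive
index runs (the circle is genome-sorted and a gene sits on one
chromosome). For non-contiguous SNP sets (e.g. exon-only annotations)
`countValidRotationsGeneric()` intersects per-interval qualifying
masks computed from circular sliding-window minima; it is
oracle-tested but slower, O(L × #intervals).

# Scored networks

Gene P-values are transformed to z-scores, z = Φ⁻¹(1 − p), clamped to
[10⁻¹², 1 − 10⁻¹²] so z stays finite (the clamp is configurable and
recorded). The transform is evaluated in whichever normal tail is
small, keeping extreme z accurate. The scored network is the
intersection of the score table and the PPI: unscored proteins are
dropped rather than imputed (a module score is undefined for scoreless
genes), and scored genes with no surviving interaction are dropped too.
The network is deliberately not restricted to its largest connected
component — seeds in small components simply grow small modules.

# Dense module search

The module score is $Z_m = \sum_i z_i / \sqrt{k}$. Growth from a seed
adds the adjacent gene maximizing the new score (equivalently, the
highest-z neighbour; ties go to the lexicographically smallest id) iff

$$Z_{new} - Z_{old} \ge r \cdot Z_{old}, \qquad r = 0.1 .$$

The rule is applied literally also when Z_old ≤ 0, where the bar is
non-positive and score *decreases* can be accepted; this lets growth
escape negative-scored seeds and is documented behaviour under test
(an all-negative star stops immediately; a negative seed between two
strong genes climbs out). Candidate neighbourhoods are distance-1.
Growth from homogeneous strong cores stalls near k ≈ 5–7 regardless of
score magnitude, because √(k+1)/√k − 1 < r from k = 5 on — modules are
intrinsically small and overlapping, which is why redundancy reduction
and cross-dataset aggregation follow.

Within a dataset, modules are merged greedily: the pair with maximal
Dice similarity is replaced by its union (score recomputed) until all
pairs are below 0.5. "Hierarchical" linkage is not further specified by
the procedure's origin, so the package uses max-similarity-first with
deterministic tie-breaking (larger union, then lexicographic gene
list). Termination is guaranteed (each merge removes one module) and
the all-pairs postcondition is asserted in tests. Unions of overlapping
connected modules remain connected; tests assert this rather than the
type system.

# Cross-dataset selection

Every (dataset-1, dataset-2) module pair is scored with the same Dice
coefficient ("proportion of shared genes" is read as Dice, keeping a
single similarity notion everywhere; the overlap coefficient
|A∩B|/min(|A|,|B|) is available as `crossPairs(method = "overlap")`
for users who prefer the other reading). The 10 highest pairs are
selected, members are unioned within dataset, and the final module is
the intersection of the two unions, with its induced PPI edges. The
final module may be disconnected; components are reported, never
pruned. Nominal significance (corrected P < 0.05, configurable) is
flagged per dataset in the gene table.

Merged modules smaller than `minModuleSize` (default 4) do not enter
the pairing. This guard exists because stalled growths leave 1–3-gene
remnants, and whenever the same remnant arises in both datasets —
which is common, since stalling is largely a structural property of
the shared network — its cross-dataset Dice is exactly 1, crowding
every genuine pair out of the top-10. Pair similarity is informative
only when perfect overlap is non-trivial; with the guard, the selected
similarities on synthetic data (~0.42–0.64) match the regime the
method is known to operate in on real data.

# The significance battery

All permutation P-values use (x+1)/(n+1), bounded in [1/(n+1), 1].

* **P_assoc** (per dataset): the CGP null applied to the module score.
  Offsets are drawn without replacement from the L−1 non-identity
  rotations; at n ≥ L−1 the computation is exhaustive — with the
  default n = 100,000 and the synthetic L ≈ 20,000 it always is. Per
  offset, only the module genes' windows are re-scored (exactly
  equivalent for the module score and far cheaper); each gene's
  corrected P under a rotated threshold is obtained from the sorted
  circular sliding-window minima of its window width.
* **P_zm** (per dataset): n = 100,000 topology-free size-k gene sets.
* **P_zm^mhrw** (per dataset): connected random modules from a
  degree-corrected Metropolis–Hastings random walk — propose a uniform
  neighbour v of u, accept with min(1, deg(u)/deg(v)) — one walk
  started from every network gene, so N equals the network size. The
  published variant's exact modification is not specified in available
  text; this reconstruction is validated against its own
  analytically-computed absorption distribution on a small graph
  (3σ at 20,000 draws), not against the original.
* **P_sig^hyper**: inclusive upper hypergeometric tail P[X ≥ k] that a
  K-gene module holds at least k of the network's n nominally
  significant genes ("at least k" resolves the printed CDF notation in
  favour of the inclusive tail). Computed via `stats::phyper`,
  enumeration-oracle-tested.
* **P_sig^mhrw**: the significant-gene count compared against the MHRW
  modules.
* **P_con**: e = edges among significant module genes; each of n
  samples draws the same number of genes from the *unselected*
  (outside-module) significant genes — following the stated sampling
  population — and counts induced edges. When too few significant
  genes lie outside the module the statistic is undefined; the
  pipeline reports NA and says so, while the operation itself errors.

Nominal significance for enrichment and connectivity means corrected
P < α in **at least one** dataset (α = 0.05 default).

# The synthetic study

`simulationConfig()` defaults define the standard conditions:
10 chromosomes × 2,000 SNPs (L = 20,000), 500 genes tiling the SNPs in
consecutive non-overlapping intervals of 10–30 SNPs with 0–5-SNP gaps,
a 1,000-node preferential-attachment PPI with 10 edges per added node
(full-graph mean degree ≈ 20, the density regime of curated
experimental PPI networks; the 500 unannotated proteins drop out at
scoring, halving the scored network), LD as block-equicorrelated
latent normals (blocks of 20 SNPs, ρ = 0.8, typical of within-block
GWAS correlation), a planted connected module of 12 genes whose causal
SNP gets a +4 latent mean shift, and 20% of planted genes carrying
signal in only one dataset. P-values are upper-tail probabilities of
the latent scores. Everything is deterministic per seed; the PPI stage
derives its seed as seed + 1 so it can be regenerated independently.

What the generator emulates: the gene-length bias that CGP corrects
(longer genes get smaller best-P by chance, via more draws and shared
block effects); LD as exchangeable-block correlation; scale-free hub
structure; partial cross-dataset reproducibility of true signal. What
it does not: realistic haplotype structure, population stratification,
overlapping genes (an option exists for window-mapping tests but
defaults off), annotation/identifier mismatches, or evidence-quality
heterogeneity in the PPI. Passing tests therefore demonstrate the
pipeline's statistical machinery, not robustness to those real-data
complications.

A known property of the default conditions worth stating: with
L = 20,000 and ~20-SNP genes the corrected-P floor is ≈ 10⁻³, so a
planted gene's z saturates near 3.1 while the best of 500 background
genes reaches ≈ 2.9 by chance. Signal and background extremes are
close at this scale — exactly why the method aggregates over connected
modules and two datasets instead of ranking single genes. The final
module consequently carries connector genes beyond the planted truth
(typically 15–30 at these sizes, against 10–12 recovered planted
genes), mirroring the method's behaviour on real data, where roughly
half the union genes survive the cross-dataset intersection.

# Numerical and engineering choices

* Circle indices are 1-based; all contracts (l, corrected P) are
  index-origin-free.
* Dice values are compared exactly; IEEE division makes equal
  rationals identical doubles, so tie-breaking is well-defined.
* `searchAllModules()` output is invariant to node enumeration order
  (all tie rules are order-free); duplicate gene sets keep the
  lexicographically smallest seed as representative.
* Every sampler takes an explicit seed; the pipeline derives stage
  seeds from the master seed, and a provenance record (package
  version, configuration, input sizes, selected similarities) is
  written alongside results.
* Problem sizes in the test suite are scaled-down versions of the
  default study (e.g. 2,000 SNPs / 120 genes / 250-node PPI for
  end-to-end checks, 200 random circles of L ≤ 500 for the
  rotation-count oracle), chosen so the full suite exercises every
  contract in about a minute while the acceptance script runs the
  full-size study.

# Limitations

* The CGP correction is genome-average: genes in regions of unusually
  strong LD are under-corrected, weak-LD regions over-corrected; using
  only the best SNP per gene softens but does not remove this.
* The corrected-P floor 1/(L+1) (and (m+1)/(L+1) per gene) bounds
  attainable significance by SNP count.
* Greedy growth with r = 0.1 has no optimality guarantee and stalls on
  homogeneous cores near 5–7 genes by construction.
* The top-10 pair cut-off is a convention, not an optimum; no
  automatic selection of the pair count is attempted.
* The six assessment statistics are reported raw, with no
  multiple-testing adjustment across them.
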