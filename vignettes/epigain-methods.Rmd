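---
title: "Methods: epistasis networks, gene aggregation, and permutation thresholds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: epistasis networks, gene aggregation, and permutation thresholds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epigain)
```

This vignette documents the statistical machinery of `epigain`, the
assumptions behind it, the parameters that matter, and the places where
the design was genuinely open and a choice had to be made.

## The model

The data are a case–control genotype matrix: `n` samples by `m` biallelic
SNPs coded as minor-allele counts 0/1/2, and a binary disease label `Y`.
All association measures are plug-in (maximum-likelihood) information
quantities in bits over the empirical contingency tables:

* `H(X) = -Σ p log2 p` with the `0 log 0 = 0` convention;
* `I(X; Y) = H(X) + H(Y) − H(X, Y)`;
* `I(X1, X2; Y) = H(X1, X2) + H(Y) − H(X1, X2, Y)`, where the genotype
  pair is treated as a single categorical variable over its observed
  cells (at most 9);
* `IG(X1; X2; Y) = I(X1, X2; Y) − I(X1; Y) − I(X2; Y)`.

Genotypes are treated as *unordered categories*, so every measure is
invariant to relabelling the codes; in particular the orientation of the
minor-allele coding is irrelevant, which is why the PLINK reader's
minor-allele convention never changes a network.

`I(X1, X2; Y)` is bounded below by each marginal MI and is therefore
dominated by strong single-SNP effects. `IG` removes both marginal terms:
it is near zero for additive pairs, negative when the SNPs are redundant
(duplicated or strongly linked SNPs: `IG(X; X; Y) = −I(X; Y)` exactly),
and maximal for pure epistasis — the XOR pattern
`x1 = (0,0,1,1)`, `x2 = (0,1,0,1)`, `y = (0,1,1,0)` has
`I(X1;Y) = I(X2;Y) = 0` and `IG = I(X1,X2;Y) = 1` bit. The package builds
one complete SNP-pair network per measure and carries both to gene level,
because the two catch different interaction mechanisms.

Assumptions worth stating: the phenotype is strictly binary with both
classes present; missing genotypes must be resolved before any
information measure is computed (the functions refuse rather than
pairwise-delete, because pairwise deletion would make edge weights
incomparable across pairs); and no bias correction (e.g. Miller–Madow) is
applied — the estimator is the plain plug-in, so all weights share the
same small positive bias under the null, which the permutation threshold
absorbs by construction.

### Numerical choices

* **Log base 2.** Entropies in bits. The base rescales every weight and
  every threshold jointly, so rankings and thresholded networks do not
  depend on it; bits are the convention of the information-gain
  literature.
* **Empty cells** contribute nothing; the joint support is whatever is
  observed.
* **All-pairs computation.** The `m × m` weight matrix is assembled from
  cross-products of per-genotype indicator matrices split by phenotype
  class (18 BLAS multiplications per column block) rather than per-pair
  contingency tables, and is chunked over column blocks of 512 SNPs so
  memory stays bounded into the tens of thousands of SNPs. Exhaustive
  all-pairs at biobank scale (hundreds of thousands of SNPs) is outside
  desk scope; `run_pipeline(prescreen_top = k)` offers a marginal-MI
  prescreen as an explicitly flagged engineering shortcut that is *not*
  part of the method.

## Quality control and imputation

`filter_missingness()` removes SNPs missing in more than one third of
samples (a SNP at exactly one third stays). `filter_maf()` removes SNPs
with minor allele frequency strictly below 0.05, with
`MAF = min(p, 1−p)`, `p = (2·n2 + n1)/(2n)` over non-missing samples; a
SNP at exactly 0.05 stays. Both filters are idempotent and order-
preserving.

"Linkage-based" imputation is implemented as single-partner
conditional-mode filling: for SNP `s`, the partner is the SNP with the
largest squared Pearson correlation of genotype codes over samples
complete in both; a missing value takes the modal genotype of `s` within
the stratum of samples sharing the partner genotype, falling back to the
unconditional mode when the stratum is empty or the partner is itself
missing there. Modal ties break toward the smaller code; equal-correlation
partner ties are ordered by a seeded shuffle, so the result is
deterministic given the seed. Imputation always conditions on originally
observed values (never on fills made earlier in the pass) and never
touches a non-missing genotype. This is a deliberately simple stand-in
for haplotype-based imputation: it captures the one-strong-partner LD
structure that drives such methods without phasing, and it is exactly
testable against a by-hand conditional-mode oracle.

## Gene aggregation

A SNP→gene map assigns each SNP to exactly one gene (conflicting
multi-gene annotations keep the first mapping, with a warning). For an
unordered gene pair the edge weight aggregates all *inter-gene* SNP-pair
weights; intra-gene pairs are discarded since they would form self-loops.
Five aggregators are available:

* `max` (default): the single strongest inter-gene SNP pair, recorded in
  the edge's `snp_a`/`snp_b` provenance columns. A gene with many SNPs
  gains only the slow extreme-value growth of a maximum, not a linear
  accumulation, so hub status reflects signal strength rather than gene
  length.
* `sum`, `mean`, `min`: provided for comparison; sums inflate long genes,
  means and minima are dragged down by the weakest pairs of long genes.
* `count_above`: the number of SNP-pair edges above a supplied SNP-level
  cutoff — the older two-threshold counting scheme, kept so that the
  size-bias diagnostic can be run against it.

`degree_size_correlation()` makes the bias measurable: the Pearson
correlation between a network gene's degree and its SNP count. The test
suite and the acceptance script run this on null data (no planted
effects) and check that `max` yields a strictly smaller absolute
correlation than `count_above` in at least 9 of 10 seeds.

Two auxiliary constants of that diagnostic are not dictated by the method
and were fixed as follows: the `count_above` SNP-level cutoff is the 95th
percentile of SNP edge weights (the counting scheme needs a permissive
SNP threshold to have counts worth counting; at the 99th percentile the
counts degenerate to 0/1 and the scheme collapses into `max`), and both
gene networks are reduced to their top 5% of edges by weight before
degrees are measured, so the two schemes are compared at equal sparsity.
A sensitivity grid over SNP cutoffs (90th–95th percentile) and retention
quantiles (90–95%) showed the direction of the comparison is stable
throughout that regime.

## The permutation threshold and the sparsity scan

Significance is assessed once, at gene level (the single-threshold design
is the point of the max conversion; the SNP network itself is never
thresholded). The disease labels are permuted `n_permutations = 30`
times; under each permutation the *entire* construction is re-run — all
SNP-pair weights recomputed, then aggregated — and each gene edge's
permuted weights are averaged. The base threshold θ is the maximum of
these per-edge averages; edges of the observed network with weight
strictly greater than `θ·(1+α)` are retained, isolated genes dropped.
Choices inside this procedure:

* **One permuted label vector per replicate, shared across edges.**
  Independent permutations per edge would be equivalent in distribution
  and vastly more expensive; sharing keeps the null exchangeable and the
  run reproducible. The permutations are stored in the returned
  `threshold_spec`, so a test (or a sceptical user) can re-materialise
  every permuted network explicitly and re-derive θ.
* **Full recomputation under permutation** (rather than permuting some
  cached intermediate) is the conservative reading of
  permutation-then-average.
* **Strict inequality** at the cutoff: "above θ" is implemented as `>`;
  any fixed convention works, strictness matches the wording.
* **Negative IG edges** survive into the unthresholded gene network and
  are removed naturally by any θ ≥ 0.

α controls sparsity. `alpha_scan()` (default grid 0–5 in steps of 0.1)
tabulates per α: nodes, edges, connected components, scale-free R², and —
given a disease-gene list — node AUC and hypergeometric enrichment. Node
and edge counts are non-increasing in α by construction, which the tests
assert on every fixture. Network selection is deliberately left to the
user: rows whose R² is a local maximum along the grid are flagged
(`r2_local_max`), and `run_pipeline()` falls back to the best flagged row
*with a message and a manifest entry* when no α is supplied, but nothing
is chosen silently.

## Topology metrics

* **Scale-free R²**: ordinary least squares of `log10 P(k)` on `log10 k`
  over observed degrees `k ≥ 1` with positive frequency, among
  non-isolated nodes. No logarithmic binning, no maximum-likelihood
  power-law fit — this is the common "R² of the log-log plot" reading.
  Consequences worth knowing: a degree distribution with only two
  distinct degrees (a star, or a near-regular graph plus one hub) fits a
  line perfectly and scores R² = 1, and fewer than two distinct degrees
  is not assessable (a classed error, reported as `NA` in scan tables).
  Small networks therefore show R² = 1 rows more often than intuition
  suggests; the flag is a selection *aid*, not a verdict.
* **Components**: connected components among non-isolated nodes; 0 for an
  edgeless network.
* **Enrichment p**: upper-tail hypergeometric probability `P(K ≥ k)` of
  the observed overlap `k` between network genes (draws `n`) and the
  disease-gene list restricted to the universe (successes `M`, universe
  `N`). The universe is all genes represented in the post-QC map. Note
  that a network containing every universe gene scores p = 1 — an
  uninformative network, not a bug.
* **Node AUC**: every universe gene is scored by its degree (0 when
  absent from the network) and ranked against list membership with the
  mid-rank Mann–Whitney formula; an edgeless network scores 0.5. Degree
  is the minimal score consistent with "AUC of the network nodes"; the
  choice is a convention of this package, and any strictly monotone
  transform of the score leaves the AUC unchanged.
* **Gene size** means mapped-SNP count throughout (base-pair length may
  exist in annotations but SNP count is the direct driver of the bias
  mechanism).

## The synthetic-data generator

`simulate_dataset()` emulates a moderately sized case–control GWAS at
desk scale. Defaults: 188 cases and 247 controls; 300 SNPs at
Hardy–Weinberg proportions with MAFs uniform on (0.05, 0.5); 1% missing
genotypes; genes as contiguous SNP blocks with geometric (long-tailed)
sizes of mean 6 capped at 50; two planted marginal SNPs and two planted
XOR pairs. The phenotype follows a logistic penetrance model: baseline
prevalence 0.3 at the covariate mean, additive log-odds of 2.0 per minor
allele at marginal SNPs (a major-locus effect, chosen to be clearly
detectable at these sample sizes), and a log-odds contrast of 1.5 between
discordant and concordant dominant-coded genotypes of each planted pair —
the canonical XOR model of pure epistasis, whose marginal effects vanish
at balanced dominant frequencies. Cases and controls are sampled
retrospectively (batches are drawn until both quotas are met; a bounded
number of attempts guards against infeasible configurations), mirroring
the case–control design.

Planted SNPs draw their MAFs from a separate `planted_maf_range`,
defaulting to 0.2–0.4. This is deliberate: a purely epistatic XOR signal
at a rare allele is undetectable at *any* effect size, because discordant
dominant genotypes essentially never occur, so tying functional-SNP
frequency to the null range would make the generator's own contract
(planted pairs produce top-ranked IG edges) unsatisfiable on unlucky
draws. Epistasis simulators conventionally parameterise functional-SNP
MAF separately for the same reason.

What the generator does *not* emulate: LD structure beyond what sampling
noise induces (so imputation in simulated data leans on weak partners),
population stratification, relatedness, genotyping batch effects,
haplotype-scale correlation, and realistic gene annotations. Passing
tests on this generator therefore demonstrate correctness of the
computations and the claimed qualitative behaviours (complementarity of
MI and IG, size-neutrality of max aggregation, monotone sparsity), not
performance on real GWAS data.

## Problem sizes used in the simulation studies

The bias diagnostic runs 10 seeds of 300 samples × 600 SNPs (null);
the complementarity study runs 10 seeds of 600 samples × 100 SNPs with
one planted XOR pair and one planted marginal SNP; oracle agreement for
the information measures is checked on 100 random fixtures and for the
permutation threshold on explicit materialisations with 5 permutations.
These sizes were chosen so each study finishes in minutes on one core
while keeping the effects it probes comfortably inside its power range.

## Known limitations

* Threshold selection remains heuristic: the scan table and the local-R²
  flags inform a human choice; there is no automatic model-selection
  criterion.
* The plug-in estimator's positive bias grows with the number of observed
  cells; comparing MI and IG *values* across pairs with very different
  marginal distributions inherits that bias, even though the permutation
  threshold is calibrated for it under the null.
* Exhaustive all-pairs scales quadratically in SNPs; the marginal-MI
  prescreen changes the method and is flagged whenever used.
* One SNP maps to one gene; overlapping genes and intergenic SNPs are out
  of scope (unmapped SNPs are simply excluded from gene networks).
* AUC-by-degree and unbinned log-log R² are conventions of this package;
  other reasonable conventions exist and would give different numbers on
  the same network.
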