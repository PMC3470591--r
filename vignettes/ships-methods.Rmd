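---
title: "Divisive spectral clustering of SNP genotypes: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Divisive spectral clustering of SNP genotypes: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ships)
```

## The problem

Human and other natural populations are genetically heterogeneous: drift,
migration and mating structure leave systematic allele-frequency differences
between sub-populations. For association studies this stratification is a
confounder; for evolutionary work it is the signal. `ships` infers this
structure non-parametrically from a genotype matrix coded 0/1/2 — no
Hardy-Weinberg or linkage assumptions, no ancestry model. The price of the
non-parametric stance is that everything rests on a pairwise distance and on
a resampling-based choice of the number of clusters, and the user should
understand both.

## The pipeline and its assumptions

**Allele-sharing similarity.** The per-locus similarity of two diploid
genotypes is the number of shared alleles implied by the dosage difference:
$s_l(i,j) = 2 - |g_{il} - g_{jl}|$. The total similarity is the mean over
loci where both samples are observed, so it lives on the same $[0,2]$ scale
regardless of the SNP count or per-pair missingness, and the paired
dissimilarity is exactly $D = 2 - S$ (an involution about 1, asserted by the
test suite rather than recomputed from genotypes). Averaging treats loci as
exchangeable; linked markers contribute redundant information without
upweighting — the method is LD-agnostic, not LD-aware.

**Spectral bisection.** Each candidate group is split in two, never more:
recursion finds finer structure progressively, which is the method's central
bet. The group's similarity sub-matrix (sliced, never recomputed) is
converted to the normalized Laplacian $L = I - \tilde D^{-1/2} S \tilde
D^{-1/2}$; the degree matrix is strictly positive because self-similarity is
2. The two eigenvectors with smallest eigenvalues, rows rescaled to unit
norm, embed the samples on the unit circle; a two-component Gaussian mixture
assigns each sample by maximum posterior. Termination — the declaration that
a group is homogeneous — happens when the group is smaller than
`min_node_size`, when all embedding points coincide (constant similarity),
when the mixture fit fails, or when one component wins no samples.

**Pruning.** Divisive recursion oversplits by design; the tree is then
reduced-error pruned. Node quality is the sum of squared similarities
between the leaves of the node's subtree, computed as $Q(G) = SS(G) -
\sum_{F \in \text{leaves}(G)} SS(F)$ with $SS$ the within-set sum of squared
similarities over unordered pairs (the two formulations are algebraically
identical; the tests verify this to machine precision on built trees).
Collapsing the lowest-quality node — ties broken by depth, then by smallest
member index, for determinism — yields nested partitions from the built leaf
count down to one cluster. All internal nodes are collapse candidates, not
only parents of leaves; when a collapsed subtree had more than two leaves
the cluster count skips values, and every downstream consumer works on the
realized counts.

**Gap statistic without the logarithm.** For each realized $k$ the pooled
within-cluster dispersion $W_k = \sum_r D_r/(2 n_r)$ (squared
dissimilarities, ordered pairs) is compared against reference datasets with
the same dimensions and i.i.d. genotypes uniform on $\{0,1,2\}$ — data with
no structure at all, deliberately not frequency-matched. Each reference
dataset passes through the identical similarity–tree–prune code path, and
$\mathrm{Gap}(k) = \overline{W^*_k} - W_k$. The selected $\hat K$ is the
smallest $k$ with $\mathrm{Gap}(k) \ge \mathrm{Gap}(k') - s(k')$ for the
next larger realized $k'$, with $s = \mathrm{sd}(W^*)\sqrt{1 + 1/B}$. Using
$W$ rather than $\log W$ makes the statistic scale with the dispersion
itself; because the null and observed branches share one code path, any
rescaling of the similarity affects both sides identically.

## Tunable parameters

| parameter | default | meaning and rationale |
|---|---|---|
| `B` | 20 | null datasets for the gap statistic; the $\sqrt{1+1/B}$ factor absorbs the simulation error of the null mean. Below ~10 the error band is unreliable; 20 balances cost and stability. |
| `k_max` | 20 | largest cluster count entered in the gap table. No hard internal cap — set it comfortably above the number of populations you consider plausible. |
| `min_node_size` | 3 | smallest group the bisection will attempt; a mixture fit on fewer than 3 points is degenerate. Lowering to 1 reproduces the extreme splits-to-singletons behaviour. |
| `seed` | 1 | master seed; all randomness (null simulation) derives from it, so reruns are byte-identical. |
| `model_names` | `"EII"` | covariance family of the 2-component mixture (see below). |

## Why equal-volume spherical mixture components

The covariance structure of the bisection GMM is a genuinely open design
choice, and it matters. The row-normalized two-eigenvector embedding places
samples on the unit circle; three separated groups appear as three arcs, and
the arcs at the two extremes of the leading eigendirection are *curved
toward each other*. A mixture with flexible covariance (full, or diagonal
with free volume) can then reach higher likelihood by stretching one
elongated component across the two extreme arcs and dedicating the tight
component to the middle arc. The resulting "extremes versus middle" split is
a defensible 2-clustering of the embedding, but it makes the subsequent
two-cluster partition uninformative (the two most distant groups are
merged), flattens the gap curve at $k=2$, and can stall the selection rule
at $\hat K = 1$. We observed exactly this on discrete-admixture data, where
the admixed pool sits between its two source populations: for about a
quarter of simulation seeds a full-covariance mixture isolated the admixed
group first and the pipeline reported no structure.

Equal-volume spherical components (`EII`) constrain the mixture to behave
like k-means with soft posteriors: components cannot trade volume, so
straddling two distant arcs is never optimal. Across all simulated
scenarios (one, three, five, ten and twenty populations; discrete
admixture) this family recovers the correct cluster number and near-perfect
assignments, and it is therefore the default. The full mclust family
remains available through `model_names = NULL` for data whose embedding
geometry is known to be benign.

## What the simulator emulates — and what it does not

`simulate_structured()` draws an ancestral allele frequency per locus
uniformly on (0.05, 0.95), evolves it along a population tree by
Balding-Nichols draws (daughter frequency $\sim$
Beta$(f\frac{1-F}{F}, (1-f)\frac{1-F}{F})$, one $F$ per branch), and samples
genotypes binomially. The presets span a difficulty gradient: `M3`/`M5` are
star trees with branch $F=0.1$; `M10` (2 super-populations × 5) and `M20`
(4 × 5) are nested with $F=0.10$ above and $F=0.08$ below, so sister
populations are separated only by the smaller leaf-level drift. The
leaf-level value was calibrated once so that the nested scenarios are hard
but solvable: below roughly $F=0.06$ at these sample sizes the dispersion
removed by a within-super-population split falls to the level removed by
splitting unstructured data, and no resampling criterion can distinguish
them. `simulate_admixed()` mates two sources (one gamete each, transmission
probability genotype/2), then mates randomly within the pool for the
remaining generations; after five generations the pool is a discrete,
internally diverse cluster with allele frequencies midway between the
sources.

The simulator deliberately omits linkage disequilibrium, mutation,
selection, continuous admixture clines and coalescent genealogy noise. Real
SNP panels also carry informative-missingness and batch artefacts that
uniform-missingness handling does not model. Passing tests on these
presets therefore demonstrates that the pipeline recovers
allele-frequency-differentiated discrete structure at realistic drift
levels — not that it resolves continuous clines, related samples, or
LD-driven artefacts.

## Numerical choices and degenerate inputs

Eigenvector signs are fixed (first nonzero coordinate positive) so
embeddings are reproducible; embedding rows with norm below $10^{-12}$ are
left at zero. A node whose off-diagonal similarities are constant to
$10^{-12}$ is terminal (its second eigenvector is an arbitrary basis vector
of a degenerate eigenspace — pure noise). When the embedding collapses to
exactly two distinct points the mixture likelihood is singular, and the
limit assignment (each sample to its point) is used directly. Mixture fits
are wrapped defensively: a failure is treated as "nothing to split". In the
dispersion, singleton clusters contribute zero; the one-cluster value equals
the closed form $D_\text{total}/(2n)$, which the tests check. Null
replicates whose pruning never realizes some observed $k$ are imputed from
their nearest coarser realized partition. Ties in pruning quality are broken
deterministically. The adjusted Rand index returns 1 when both partitions
are the single all-in-one cluster (perfect recovery of no-structure, where
the formula is 0/0) and keeps the formula value 0 when only one side is
trivial.

## Problem sizes used by the test and acceptance runs

The bundled checks run at desk scale, chosen to finish in minutes on one
core while preserving the separation regimes: unstructured runs at
100 × 1000; three populations at 3 × 50 × 2000 with $F=0.1$; ten populations
at 10 × 30 × 3000; twenty at 20 × 25 × 3000; admixture at (60+60+60) × 2000
with source $F=0.15$ and five generations; the gap statistic uses $B=20$
(B=10 for the twenty-population run). Full-scale panels (hundreds of
thousands of SNPs) change the similarity estimates' precision, not the
algorithmic path.

## Known limitations

Forcing two-way splits means a true $k$-way symmetric structure must be
discovered across several levels; when a first split is genuinely ambiguous
the nested sequence can carry that ambiguity downstream. The no-log gap
compares dispersions on the observed scale against a uniform-genotype null
whose overall dispersion is larger; the selection rule therefore reads
*changes* per $k$, and very weak structure (drift below ~0.05 at these
sizes) is invisible to it. The sequential Dudoit rule inspects adjacent
$k$ only: a single uninformative split can hide a strong signal one step
further (mitigated, not eliminated, by the spherical mixture default).
Finally, ASD is a genotype-identity distance: structure carried by
haplotype sharing or rare-variant patterns needs a different similarity
matrix, which the pipeline accepts but does not provide.
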