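---
title: "Comparative transcriptomics of suppressor lines and parsimonious subnetwork inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative transcriptomics of suppressor lines and parsimonious subnetwork inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(suppnet)
library(dplyr)
```

## The experimental design suppnet models

suppnet analyses a classic suppressor-screen expression design: a
wild-type reference line, a primary mutant with a defective signaling
receptor, and several *suppressor* lines in which a second,
activation-tagged mutation partially reverts the mutant phenotype.  All
lines are profiled on expression arrays with a few biological replicates
each (the emulated study: 5 genotypes x 3 replicates of log2
intensities).  Two questions drive the analysis:

1. **Which genes does each suppressor restore, and which compensatory
   programs does it switch on instead?**  This is pure set logic over
   per-line differential-expression calls.
2. **Which pathways do the affected genes form?**  Differentially
   expressed genes are mapped onto a typed molecular interaction network
   and connected parsimoniously; the connected components are proxies of
   the restored, compensatory and non-restored pathways.

## Differential expression

Each non-reference line is compared against the reference with a
moderated two-sample statistic.  Per gene the log fold change is the
difference of line means on the log2 scale.  The pooled within-group
variance $s_g^2$ (with $d = n_1+n_2-2$ degrees of freedom) is shrunk
towards a common prior $s_0^2$ with prior degrees of freedom $d_0$:

$$\tilde s_g^2 = \frac{d_0 s_0^2 + d\, s_g^2}{d_0 + d},\qquad
  t_g = \frac{\overline{x}_{g1}-\overline{x}_{g0}}
             {\tilde s_g \sqrt{1/n_1 + 1/n_2}},$$

with $d_0 + d$ degrees of freedom.  $(d_0, s_0^2)$ are estimated from
the ensemble of gene variances by the method of moments on
$\log s_g^2$ under the scaled-F model
($\mathrm{var}(\log s^2) = \psi_1(d/2) + \psi_1(d_0/2)$, inverted with
Newton's method on the trigamma function).  The test suite cross-checks
the whole chain against limma on shared data; agreement is to numerical
precision for the fold changes and to ~1e-4 relative for the moderated
statistics.

P-values are adjusted per contrast with Benjamini-Hochberg, and a gene
is flagged differentially expressed (DE) when its adjusted p is at most
`fdr_threshold` (default 0.05) **and** $|logFC| \ge \log_2(\mathrm{fc})$
with fc = 1.5 by default.  The fold-change bound is interpreted on the
log2 scale, the standard microarray convention, and flags are two-sided.
Adjustment is per line: each line-vs-reference contrast is corrected
over all genes, matching the default behaviour of per-contrast
moderated analyses.

Upstream of testing, `quantile_normalize()` forces every sample onto the
mean order-statistic distribution (ties receive the mean of the quantile
values they span) and `collapse_probes()` removes probes mapping to more
than one gene and averages the remaining probes per gene.
`pca_qc()` summarizes replicate consistency as the ratio of within-line
to between-line dispersion of sample scores.

## Group logic

With a mutant `m` and exactly three suppressors, per-gene DE flags
define the groups:

| label | definition | core |
|---|---|---|
| A (restored) | DE in m, not DE in >= 2 suppressors | not DE in all 3 |
| B (compensatory) | not DE in m, DE in >= 2 suppressors | DE in all 3 |
| C (non-restored) | DE in m and in >= 2 suppressors | DE in all 3 |
| D/E/F (line-specific) | not DE in m, DE in exactly one suppressor | — |

Membership is purely flag-based: the sign or size of the change plays no
role, and a gene DE in the mutant with exactly one DE suppressor belongs
to A because two suppressors are *not* DE.  D, E and F track the
identity of the first, second and third entry of
`suppressor_lines` in the configuration.  `classify_groups()` is tested
against an exhaustively enumerated 16-pattern truth table and under
permutations of the suppressor order.

Two companion statistics quantify suppression strength: marker
concordance (literature-direction markers retained if DE in the mutant;
per suppressor the count restored to not-DE) and the squared Pearson
correlation of per-line logFC measured *relative to the mutant*, which
isolates the signal of restoration from the shared mutant background.

## Empirical-null gene scores and edge weights

For the network stage each gene receives a relevance score derived from
an empirical null.  Per gene the logFC of largest absolute value across
the assessed lines is selected (sign retained — a signed maximum would
systematically deflate consistently down-regulated genes, which the
two-tailed score below would then miss).  Because most genes do not
change, the distribution of this quantity is dominated by the null; its
mean and standard deviation are the Gaussian maximum-likelihood
estimates (mean, 1/n-denominator sd), and

$$\mathrm{score}(x) = \left|1 - 2\,\Phi\!\left(\frac{x-\mu}{\sigma}\right)\right| \in [0,1].$$

The score is 0 at the null mean, symmetric, monotone in $|x-\mu|$ and
approximately uniform for null genes.  Edge weights are the product of
the endpoint scores; genes present in the network but absent from the
expression data score 0, so their edges are maximally expensive yet
traversable — such genes can still be recovered as *connector genes*
when they lie on cheap paths between seeds.  At a sweep penalty $c$ the
edge cost is $c\,(1-w) + \varepsilon$ with a fixed
$\varepsilon = 10^{-3}$ floor that rules out zero-cost cycles in path
search.

## Subnetwork inference

Seed genes (by default the union of groups A, B and C) are connected on
the weighted network:

* **Bounded k-best path search, downstream mode.**  For every ordered
  seed pair, up to `k_paths` (50) lowest-cost simple paths with at most
  `path_length` (4) edges, following regulatory and metabolic edges only
  in their stated direction and protein-protein edges both ways.  Ties
  break by fewer edges, then the lexicographic node sequence.  The
  enumeration is exhaustive (a depth-bounded DFS in compiled code) and is
  verified against a brute-force oracle on 200 random small graphs.
* **Greedy parsimonious selection.**  Pooled candidates are added
  greedily by the ratio of newly connected seeds to the cost of the
  path's not-yet-selected edges, until no path connects a new seed.  The
  selection score is the number of connected seeds minus the total
  selected edge cost.  On small instances the greedy's total cost is
  within a small factor (empirically < 2, typically ~1.05) of the
  exhaustive-optimum cost for the same seed coverage.
* **Stability and size filters.**  At each of `cost_steps` (28)
  log-spaced penalties between `cost_min` (0.1) and `cost_max` (5), the
  selection is repeated on 10 jackknife draws of 80% of the seeds and
  the mean pairwise Jaccard index of the resulting undirected edge sets
  is the penalty's stability.  A penalty is rejected if stability falls
  below `jaccard_min` (0.5) or its subnetwork exceeds `max_edges` (500)
  unique undirected edges.  Edge identity throughout is the undirected
  (min endpoint, max endpoint, type) triple.
* **Finalization.**  Accepted edge sets are united and decomposed
  (direction-blind) into connected components, reported as separate
  subnetworks; non-seed members are flagged as connector genes.

Two properties of this construction are worth spelling out.  First,
selections supported by *shared* structure — many seed pairs routed
through the same hub — survive jackknifing, while selections composed of
seed-pair-exclusive paths dilute: under 80% resampling an edge used by a
single pair survives a pairwise comparison with Jaccard ceiling
$p^2/(2p-p^2) \approx 0.47 < 0.5$ (p = 0.64 the probability both
endpoints are kept).  The stability bound therefore acts as a structural
filter, not merely a noise filter: large heterogeneous seed sets whose
members connect through idiosyncratic shortest paths are rejected
wholesale and yield an empty result with a warning.  This mirrors the
motivating observation that scattered, line-specific stress-response
genes cannot be recovered as delineated subnetworks, and it is why the
planted-module analyses below seed the engine with module members rather
than every DE gene.  Second, because the greedy only ever adds paths
that cover new seeds, penalties mainly rescale costs without changing
the cover, so subnetwork size is non-increasing along the sweep.

## The synthetic-data generator

`simulate_expression()` draws, per gene, a baseline intensity
(Normal(7.5, 1.5), an array-like log2 scale), a residual variance from a
scaled inverse chi-square prior ($d_0 = 4$, $s_0^2 = 0.04$, i.e. a
typical replicate sd of ~0.2 with gene-to-gene spread, making variance
moderation testable), and planted effects realizing requested group
labels: a core-A gene is shifted only in the mutant, a core-B gene in
all three suppressors, a non-core C gene in the mutant and exactly two
suppressors, and so on.  Effect magnitudes are uniform on
`effect_range` (default 1-3 log2 units; the lower bound must exceed
$\log_2 1.5 \approx 0.585$ or the planted truth would be undetectable)
with equal proportions up- and down-regulated, since the gene score is
two-tailed.  Default label counts are the emulated study's group sizes
scaled to a quarter (5,000 genes, ATH1-like at 1/4 size, which runs in
seconds).  The generator also reports the true null parameters of the
background max-logFC selection, obtained by Monte Carlo under the noise
model including the correlation induced by the shared reference-line
mean.  An optional per-line effect multiplier plants a negative-feedback
gradient (better suppressors, smaller perturbations of the
biosynthesis-proxy genes), which `feedback_trend()` recovers as a
Spearman rank correlation with an exact permutation p over line
relabelings.

`simulate_network()` embeds the genes in a preferential-attachment
background graph (~4 edges per node, 5,000 nodes -> ~20,000 edges, a
1/4-scale stand-in for a compiled plant interactome) and wires each
planted module as a *regulon*: the module's first seed acts as a master
regulator connected to every member, 1-2 members are reached through a
non-DE connector gene instead of directly, and optional extra
member-member edges are controlled by `module_bias`.  Directed module
edges are oriented downstream from the regulator, matching the
downstream path-search mode.  Edge types follow the source proportions
of the emulated interactome (~33% regulatory, ~50% ppi, ~17% metabolic).
Two design choices deserve justification:

* Background edges directly linking two module seed genes are removed.
  A coincidental interaction between seeds of different planted modules
  is a true connection the method *should* use — which makes the planted
  truth unidentifiable.  Removing them is the planted-partition
  convention: inter-block structure is controlled, everything else free.
* `module_bias` defaults to 0.  Dense within-module wiring creates many
  alternative minimal covers; the parsimonious selection then picks
  an arbitrary one, which both lowers the jackknife stability and can
  split the recovered component.  The clean regulon makes the planted
  truth the unique parsimonious solution.

What the generator does *not* emulate: probe-level structure, array
batch effects, correlated co-expression beyond the planted effects,
scale-free degree exponents matched to a real interactome, or
biologically structured annotation.  Passing the planted-recovery tests
therefore demonstrates the machinery is correct and well-calibrated on
clean planted structure; it does not guarantee comparable precision and
recall on real networks, where modules overlap and edge evidence is
noisy.

## Enrichment and group-comparison utilities

`hypergeom_enrich()` computes the upper-tail hypergeometric p per term
(query of size n, term of size K in a universe of N), BH-adjusted across
terms with the same adjustment implementation as the DE stage.  The
universe defaults to the genes on the expression matrix — the only
self-consistent choice for synthetic runs, and standard practice when
the array defines the measurable space.  Annotations are used flat; no
propagation up an ontology graph is performed (a documented limitation).
`anova_tukey_cld()` runs one-way ANOVA with Tukey HSD and assigns
compact letters as the maximal cliques of the non-significance graph,
ordered so that "a" always marks the highest mean; with two groups the
Tukey p provably equals the equal-variance t-test p, which the suite
asserts.

## Numerical and determinism choices

* All tie-breaks are lexicographic on gene identifiers (opaque,
  case-sensitive strings); candidate paths carry a canonical order
  (cost, fewer edges, lexicographic node sequence), so greedy selection
  is deterministic.
* Every stochastic step takes an explicit integer seed; the same seed
  reproduces matrices and networks bit-identically.  Derived seeds are
  small fixed offsets of the user seed.
* The trigamma inversion uses Newton iterations to 1e-10 relative
  tolerance; degenerate inputs (zero gene variances) are excluded from
  the moment fit; a zero-variance null is an error rather than a
  division by zero.
* Empty selections are valid: two empty edge sets have Jaccard 1, an
  empty final union warns and returns an empty `subnetwork_set`.
* Problem sizes in the shipped tests: the planted-recovery scenario uses
  5,000 genes, ~20,000 edges and 3 modules of 15-25 seeds; property
  suites use 200 random graphs of at most 7 nodes and exhaustive
  enumeration up to $2^{12}$ path subsets.  These sizes keep the whole
  suite under a minute while leaving the oracles exact.

## Known limitations

* The published tool's exact objective function is not restated in its
  paper; the greedy ratio selection here is this package's definition of
  "most parsimonious", validated against exhaustive oracles at toy
  scale.  Bit-compatibility with the original implementation is not a
  goal, and the original study's eight specific subnetworks depend on an
  unpublished compiled interactome.
* The stability ensemble (10 jackknife draws at 80%) is this package's
  construction; ensembles built from solution pools or repeated
  stochastic runs would give different absolute stability values.
* With `module_bias` well above 0, or with via-connector members whose
  connector happens to score low, one or two module members can be
  "stolen" by cheap background routes into a neighbouring component;
  the recovery metrics expose this honestly rather than masking it.
* Group logic is hard-wired to exactly three suppressors (the >= 2-of-3
  rule); other designs need a config-level generalization.
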