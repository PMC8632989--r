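---
title: "Quantifying the network diversity of symptom phenotypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying the network diversity of symptom phenotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(symdiv)
```

## The scientific problem

Symptoms are non-specific: a single complaint such as fever or insomnia can
arise in many unrelated disease conditions, which limits its diagnostic
value. `symdiv` treats this non-specificity as a measurable network
property. On the clinical side, symptoms that co-occur within the same
differential-diagnosis record form a weighted **symptom co-occurrence
network (SCN)**; a symptom's *phenotypic diversity* (PD) is its node
diversity in that network and its *phenotype degree* (PE) its degree. On
the molecular side, each symptom carries a curated set of associated
genes; its *molecular diversity* is summarized by the **maximum node
diversity (MGD)** and **maximum degree (MGE)** of those genes inside a
score-filtered protein–protein interaction (PPI) network. The package then
asks, with explicit statistics, whether clinical diversity tracks
molecular diversity, whether co-occurring symptom pairs share genes more
often than a degree-preserving null allows, whether pairs are more
molecularly specific than single symptoms, and whether diverse symptoms
attract more drug targets.

## The node-diversity statistic

For a focal node $j$ with neighborhood $N(j)$, the diversity is

$$\phi(j) \;=\; \sum_{i \in N(j),\; k(i) \ge 2} \frac{\delta_j(i)}{k(i) - 1},$$

where $k(i)$ is the degree of neighbor $i$ and $\delta_j(i)$ is the number
of edges from $i$ to nodes **outside the closed neighborhood**
$N(j) \cup \{j\}$, equivalently $\delta_j(i) = k(i) - 1 - |N(i) \cap N(j)|$.
Every term lies in $[0, 1]$, so $0 \le \phi(j) \le k(j)$: $\phi$ counts,
neighbor by neighbor, the fraction of each neighbor's other links that
escape $j$'s immediate horizon. A node is diverse when its neighbors reach
far beyond it — a bridging-coefficient reading of non-specificity.

Two points about this definition deserve emphasis.

* **Which neighborhood $\delta$ leaves.** Published statements of this
  statistic are ambiguous about whether "links leaving that neighborhood"
  counts from the neighbor's own neighborhood or from the focal node's.
  We use the focal node's closed neighborhood. This is the only reading
  that bounds each term by 1 and hence $\phi \le$ degree, which is the
  pattern every reported diversity/degree pair in this literature obeys
  (including values like a diversity of 0.95 at degree 2, impossible
  under the per-neighbor reading on dense graphs).
* **Degree-1 neighbors contribute 0**; the $k(i) - 1$ denominator is
  otherwise undefined, and a leaf has no "other" links to leave with.

Closed forms used as test anchors: $\phi \equiv 0$ on complete graphs
(no link leaves a clique), $\phi(\text{leaf}) = 1$ and
$\phi(\text{center}) = 0$ on stars, and $\phi = (1, 0, 1)$ on a
three-node path. The implementation ships two independent routes — an
adjacency-list traversal for igraph objects and a linear-algebra form
($\phi = $ column sums of $A \odot (k - 1 - A^2)/(k - 1)$ restricted to
$k \ge 2$ rows) for adjacency matrices — and the test suite checks both
against a literal edge-enumeration oracle on every labeled graph with up
to 6 nodes and on random graphs up to 60 nodes.

$\phi$ is computed on unweighted topology throughout: SCN edge weights
(co-occurrence counts) are kept for thresholds and reporting only, which
matches the statistic's definition in terms of degree and adjacency
alone.

## From gene sets to molecular diversity

`molecular_diversity()` maps each phenotype's gene set into the PPI and
takes the maximum $\phi$ (MGD) and maximum degree (MGE) over the mapped
genes; genes absent from the network are excluded and counted, phenotypes
with no mapped gene are flagged rather than silently dropped, and MGD
ties are broken by lexicographic gene order so the attaining gene is
deterministic. Because a pair's MGD is a maximum over the *shared* genes —
a subset of either member's gene set — pair MGD can never exceed the
smaller single-symptom MGD. That subset-max monotonicity is the
structural skeleton of the pair-versus-single comparison and is asserted
for every enumerated pair in the tests. The *aggregate* median contrast
between the pair population and the single-symptom population is a
weaker, composition-dependent statement: shared-gene pairs over-sample
well-connected symptoms, and shared genes tend to be popular genes, so
the population medians can order either way even though each pair is
bounded by its own members. The package reports both the per-pair bound
and the population contrast and keeps them distinct.

## The randomization null for shared-gene pairs

Co-occurring symptom pairs sharing at least one gene are counted on the
real association table, then on permuted tables in which the bipartite
phenotype–gene graph is rewired by double-edge swaps (default $10 \times$
the edge count of attempted swaps per permutation, each permutation
restarting from the observed table). Swaps preserve every phenotype's
gene count and every gene's phenotype count exactly — the heavy-tailed
degree structure that drives sharing by chance — so the null isolates the
*alignment* of sharing with co-occurrence edges. The empirical p-value
uses the $(1 + \#\{\text{null} \ge \text{obs}\})/(n_{\text{perm}} + 1)$
convention and can never be zero; a normal-approximation z p-value is
reported alongside and clearly labeled, because analytic approximations
are the only way extremely small significance levels (far below
$1/(n_{\text{perm}}+1)$) can legitimately be quoted. The calibration test
uses a tie-randomized (continuity-corrected) transform of the null counts,
which is exactly uniform under exchangeability; the reported empirical p
keeps the conservative convention above.

The swap kernel is implemented in C++ driven by R's RNG, so every run is
reproducible from `set.seed()`; degree preservation is asserted
per-permutation in the tests rather than trusted.

## Comparative statistics

* **Correlations** are plain Pearson coefficients with two-sided t-based
  p-values (`pearson_correlation()`); the package applies no
  multiple-testing correction across its handful of reported
  correlations, and the tests verify agreement with the from-scratch
  covariance formula to 1e-12.
* **Median contrasts** use the Mann–Whitney/Wilcoxon rank-sum test with
  normal approximation and tie correction. The published analyses this
  package operationalizes report median contrasts without naming a test;
  the rank-sum test is the conventional choice for skewed diversity
  distributions. Two-sided by default; one-sided options exist because
  directional claims ("pairs have lower MGD") are sometimes the stated
  hypothesis, and the choice is surfaced, never silent.
* **Threshold proportions** (`proportion_ge()`) use an inclusive
  boundary, reported as half-up 2-decimal percentages with full precision
  retained.
* **Enrichment** is an upper-tail hypergeometric test per gene set, with
  the universe defaulting to the union of collection genes (external
  enrichment services use curated backgrounds that are not reproducible
  offline; the default is stated rather than imitated). Raw p < 0.05
  flags enrichment by default, mirroring common service conventions;
  Benjamini–Hochberg adjustment is available behind a flag for users who
  prefer controlled error rates over comparability.
* **Clustering** of the binary pair × pathway matrix uses average-linkage
  agglomerative clustering on Jaccard (binary) distances for both
  margins, deterministic given the matrix; all-zero profiles are treated
  as mutually identical rather than undefined.

## Drug-target proximity

The thresholded interactome is unweighted, so shortest paths reduce to
breadth-first search (the unit-weight specialization of Dijkstra's
algorithm). A drug target counts toward a symptom's DTN when it lies at
distance 0 (it *is* a symptom gene) or 1 (a direct neighbor of one);
targets shared by several drugs are deduplicated, and `n_drugs` counts
distinct drugs owning at least one counted target.

A limitation worth stating plainly: DTN is not a diversity-independent
readout. Because it counts targets inside a gene set's first-order
neighborhood, its expectation under *uniformly* placed targets is
proportional to that neighborhood's size, and neighborhood size
correlates with MGD in any heavy-tailed interactome (both are driven by
the set's best-connected genes). A positive DTN–MGD correlation therefore
has a mechanical component; only its magnitude beyond the uniform
baseline is evidence of targeted placement. The synthetic experiments in
the test suite expose exactly this: the correlation stays well above zero
even when targets are placed uniformly at random.

## The synthetic-data generator

No public deposit of the curated inputs exists, so the generator
(`synthetic_config()` and friends) emulates all six: a scored interactome
edge list, CUI-level symptom–gene associations with a semantic-type
column and a review drop list, a many-to-one term mapping, symptom-cluster
records with chief symptoms, drug–target pairs, and a GMT pathway
collection, plus a category annotation. Design choices:

* **Interactome:** preferential attachment by default ($m = 8$ on 2,000
  nodes, ~16,000 edges) — degree heterogeneity is what makes max-$\phi$
  statistics non-trivial; a configuration-model alternative provides
  degree-matched nulls, and an Erdős–Rényi option a homogeneous baseline.
  The emitted file adds ~30% decoy edges scored below 700 so that
  score-filtering at the standard threshold is actually exercised and
  recovers exactly the true graph.
* **Associations:** gene-set sizes follow a discrete power law (exponent
  2, range 3–200). Symptoms carry one of 14 body-system categories with
  overlapping category gene pools; records sample symptoms mostly within
  a category, so co-occurring symptoms share pool genes — the planted
  sharing signal. A `broad` label (30% of symptoms, record-inclusion
  weight 6) elevates SCN occurrence, degree and PD; with probability
  `diversity_coupling` a broad symptom draws genes weighted by
  $(\phi + 1)^2$, planting the PD–MGD association causally in the
  sampling rather than by post-hoc relabeling. Coupling defaults to 1
  (the generator's reference condition is the observed strong positive
  association); setting it to 0 yields a clean null, and both ends are
  exercised in the acceptance tests.
* **Records:** sizes are `min + Poisson(mean − min)` (default 2 + 4),
  chosen so the per-record pair counts at 2,000 records land near the
  link-to-record ratio of the clinical network the generator emulates.
* **Drugs:** 120 drugs with 1 + Poisson targets each (~170 distinct
  targets, ~8% of proteins, the ratio of the curated drug-target set to
  its interactome); with probability `drug_proximity_bias` a target is
  placed on or adjacent to a symptom gene.
* **Scales:** desk scale (300 symptoms, 2,000 genes, 2,000 records)
  generates in seconds and keeps the whole test suite in minutes while
  leaving every distributional feature (heavy tails, planted couplings)
  intact.

What the generator does **not** emulate: linguistic content and
terminology granularity of real clinical records, cross-language mapping
difficulty (the term mapping is consumed as a table either way),
correlated curation biases in association databases (e.g.,
disease-area-specific gene discovery), and any real pathway biology (the
GMT sets are interactome neighborhoods plus noise). Passing tests
therefore demonstrate that the *method* recovers planted structure and
respects its invariants — not that real curated data would show the same
effect sizes.

## Numerical and reporting conventions

* Reported means and percentages are rounded **half-up** to 2 decimals
  (base R's `round()` rounds half to even); full precision is always kept
  alongside, and the rounding helper is exported.
* Diversity values are written to TSV at 2 decimals; all comparisons and
  correlations use full precision.
* Very small p-values are reported in scientific notation without
  flooring.
* Empty inputs degrade explicitly: empty filtered tables warn rather than
  fail, unmapped phenotypes and skipped stages are counted and logged,
  and zero-variance correlations raise errors that the pipeline records
  as failed stages while later independent stages still run.
* Every pipeline output carries an FNV-1a hash of the canonical JSON form
  of its configuration, the seed, package version and a UTC timestamp.

## Known limitations

* The $\phi$ reading documented above is a considered resolution of an
  ambiguous printed formula; the package states it prominently rather
  than presenting it as the only possible interpretation.
* MGD is a maximum statistic and thus sensitive to single
  well-characterized hub genes; a symptom's MGD can be carried entirely
  by one gene.
* DTN's mechanical dependence on neighborhood size (above) means
  drug-target correlations should be read against an explicit uniform
  baseline, which the package can generate.
* $\phi$ degrades on near-saturated graphs: as a co-occurrence network
  approaches a clique, every neighbor's links stay inside every closed
  neighborhood and $\phi$ compresses toward zero — in dense regimes it can
  even *invert* against degree. Record-to-symptom ratios that saturate the
  SCN (e.g., many records over few symptoms) therefore produce
  uninterpretable PD; the generator's desk-scale defaults keep SCN density
  near 0.27 for this reason.
* The enrichment module makes no attempt to reproduce any specific web
  service's modified statistics or curated backgrounds; numeric agreement
  with service output is out of scope.
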