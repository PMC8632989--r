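# symdiv — network diversity of symptom phenotypes

`symdiv` quantifies how *non-specific* a symptom is, in two coupled
senses, and tests whether the two agree. Clinically, symptoms that appear
together in the same differential-diagnosis record form a weighted
**symptom co-occurrence network (SCN)**; a symptom's **phenotypic
diversity (PD)** is its node diversity there and **PE** its degree.
Molecularly, each symptom carries a set of associated genes; its
**molecular diversity** is the maximum node diversity (**MGD**) and
maximum degree (**MGE**) of those genes inside a score-filtered
protein–protein interaction network. The package is aimed at
symptom-science and network-medicine analyses: it implements the
diversity statistic, the two network builders, the comparative statistics
around them (correlations, rank-sum median contrasts, a
degree-preserving randomization test for shared-gene symptom pairs,
drug-target proximity counts, hypergeometric enrichment with
agglomerative clustering), a synthetic-data generator that emulates every
input with planted effects, and a config-driven end-to-end pipeline.

## The statistic

For a node $j$ with neighborhood $N(j)$,

$$\phi(j) = \sum_{i \in N(j),\, k(i) \ge 2} \frac{k(i) - 1 - |N(i) \cap N(j)|}{k(i) - 1},$$

the sum over $j$'s neighbors of the fraction of each neighbor's other
links that leave $j$'s closed neighborhood. Each term lies in $[0,1]$, so
$0 \le \phi \le \text{degree}$; $\phi = 0$ on cliques, $\phi = 1$ for the
leaf of a star. A symptom is diverse when its clinical (or a gene when
its molecular) neighborhood reaches far beyond itself. The vignette
(`vignettes/network-diversity.Rmd`) documents the reading of the
ambiguous published formula, the randomization null, and every numerical
convention.

## Worked example

The synthetic generator's defaults emulate the study conditions the
package targets (300 symptoms, 2,000 genes, ~16,000
preferential-attachment interactome edges, 2,000 cluster records, full
planted coupling between clinical breadth and gene diversity):

```r
library(symdiv)
bundle <- run_pipeline(list(synthetic = TRUE, seed = 7, n_perm = 199))
print(bundle)
```

```
Symptom network-diversity results bundle
  SCN: 300 nodes, 12144 links
  PPI: 2000 nodes, 15964 edges
  PD-MGD: PCC = 0.581 (n = 300, p = 2.01e-28)
  PE-MGE: PCC = 0.691 (n = 300, p = 7.61e-44)
  shared-gene pairs: 1522 observed vs null mean 986.1 (empirical p = 0.005)
  stages:
    association_summary      ok
    phenotypic_diversity     ok
    molecular_diversity      ok
    diversity_correlations   ok
    randomization            ok
    pair_vs_single           ok
    disease_comparison       skipped: no input
    drug_proximity           ok
    case_study               ok
```

Reading the numbers: the SCN built from 2,000 records has 300 symptoms
and 12,144 co-occurrence links. Phenotypic and molecular diversity
correlate strongly (PCC = 0.58) because the generator plants that
coupling; 1,522 co-occurring symptom pairs share at least one gene,
against a mean of 986 under 199 degree-preserving rewirings of the
symptom–gene graph (empirical p = 0.005, the floor at 199 permutations),
so sharing aligns with co-occurrence far beyond what the degree
sequences explain. Per-symptom tables are in the bundle:

```r
head(bundle$phenotypic_diversity, 3)
#>   phenotype  PE       PD rank
#> 1    sym178 143 57.63059    1
#> 2    sym119 138 56.86220    2
#> 3    sym176 147 56.17892    3
```

Every stage is also exposed directly (`node_diversity()`,
`build_cooccurrence_network()`, `molecular_diversity()`,
`shared_pair_randomization()`, `first_order_targets()`, `enrich()`, ...),
and `inst/cli/symdiv` wraps the pipeline for shell use
(`generate` / `run` / `diversity` / `report` subcommands).

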