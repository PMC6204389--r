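# coexminer

Signed weighted gene co-expression network analysis for RNA-seq count
data, with the downstream mining steps that turn a network into biology:
dense-subgraph decomposition, hub identification, functional term
enrichment, and promoter motif scanning. The package grew out of the
analysis style used for fungal lignocellulose-degradation transcriptomes
(*Trichoderma reesei* grown on plant biomass versus a soluble sugar), where
the questions are: which genes co-express into modules, which modules carry
the induced cellulases and transporters, which genes sit at the centre of
those modules, and which carry the regulator's DNA binding site in their
promoter.

## The model

From a filtered, TMM-normalised expression matrix the package computes
pairwise Pearson correlations and maps them to a **signed adjacency**

```
adj = (0.5 * (1 + cor))^beta
```

so that anti-correlated genes are weakly connected (cor = −1 → adj = 0) and
the soft power β, chosen as the smallest value whose connectivity
distribution fits a scale-free topology (signed R² ≥ 0.85), sharpens the
contrast. At β = 26, a correlation of 0.8 corresponds to adjacency 0.064 —
the conventional edge threshold for exported module graphs. Genes are
clustered on the **topological overlap matrix**

```
TOM_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 − a_ij),   l_ij = Σ_u a_iu a_uj
```

by average linkage; modules (≥ 30 genes) come from a static tree cut with a
data-driven height, near-collinear modules merge when their eigengene
dissimilarity falls below 0.15, and membership is polished by gene–eigengene
correlation (kME). On the exported |cor| > 0.8 edge lists, MCODE (degree
cutoff 2, node score cutoff 0.2, K-core 2, haircut) extracts dense
subclusters, hubs are nodes above the module's nearest-rank 90th degree
percentile, term enrichment uses the hypergeometric tail with
Benjamini–Hochberg correction, and promoters (1.5 kb upstream of the ATG,
strand-aware) are scanned with a position weight matrix under an exact
score null (p ≤ 1e-4).

A synthetic-data module generates count matrices with planted modules and
fold changes, genomes with planted motif instances, and annotation tables
with planted enrichments — with exported ground truth, so the whole pipeline
is testable without any external data.

## Worked example

```r
library(coexminer)

cfg <- sim_config(seed = 1)                      # 1200 genes, 6 planted modules,
sim <- simulate_expression(cfg)                  # 4 conditions x 3 replicates
ds  <- filter_low_expression(sim$dataset)        # cpm >= 1 in >= 3 samples
ex  <- rpkm(ds)                                  # TMM-normalised RPKM
de  <- call_de(ex, control = "fructose_24h")     # two-fold rule vs control

fit <- coexpression_network(log2(ex$values + 1)) # the central S3 fit
summary(fit)
#> Signed co-expression network (1200 genes, 12 samples)
#>   soft power beta = 29 (best available fit)
#>   6 module(s), 612 background gene(s)
#>  module genes edges
#>      M2   112  3817
#>      M1   109  3999
#>      M4   102  4440
#>      ...
```

Six modules are recovered, matching the six planted ones (adjusted Rand
index ≥ 0.8 against the ground truth in `sim$truth`). Downstream layers:

```r
hubs <- find_hubs(fit$edges)                     # degree > 90th percentile
#> hub_set (module scope, 90th percentile): 51 hub(s) in 6 module(s)

module_summary(fit$partition, fit$edges, de)[1:4, ]
#>   module nodes edges  up down up_pct down_pct
#> 1     M2   112  3817   0  110    0.0     38.5
#> 2     M1   109  3999   0  106    0.0     37.1
#> 3     M4   102  4440 101    0   41.1      0.0
#> 4     M3   101  4311 100    0   40.7      0.0

pwm  <- build_pwm(synthetic_xbs_sites())         # Xyr1-like 10-bp motif
#> pwm: width 10, consensus ATGGCAAATC, information content 10.6 bits
gen  <- simulate_genome(rownames(ex$values), cfg, pwm = pwm)
hits <- scan_promoters(pwm, extract_promoters(gen$genome, gen$models))
hub_crosstab(hubs, de, genes_with_xbs(hits, rownames(ex$values)))[1:2, ]
#>   module n_hubs n_de pct_de n_de_xbs pct_de_xbs
#> 1     M4     10   10    100        3       30.0
#> 2     M1      7    7    100        3       42.9
```

The summary table reads: module M4 holds 102 genes and 4440 high-correlation
edges; its 101 upregulated genes are 41.1% of all upregulated genes in the
dataset. The cross-tab reads: all 10 of M4's hubs are differentially
expressed, and 3 of those (30.0%) carry at least one predicted binding site
in their 1.5-kb promoter.

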