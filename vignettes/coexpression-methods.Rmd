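---
title: "Methods: signed co-expression networks, module mining and motif scanning"
author: "coexminer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: signed co-expression networks, module mining and motif scanning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the methods it implements:
the statistical model behind each stage, the parameters that matter and why
their defaults are what they are, what the synthetic-data generator does and
does not emulate, and the numerical and design decisions taken where the
procedure was genuinely open.

## 1. The pipeline at a glance

Counts → filter (CPM ≥ 1 in ≥ 3 samples) → TMM → RPKM → fold-change DE
calls; in parallel, log2(RPKM+1) → Pearson correlation → signed adjacency
`(0.5(1+cor))^β` → topological overlap (TOM) → average-linkage clustering →
static cut → eigengene merging → kME refinement → |cor| > 0.8 edge export →
MCODE subclusters, degree-percentile hubs, hypergeometric enrichment, PWM
promoter scanning → integrated module/hub/neighbourhood reports.

Everything downstream of the count matrix is deterministic: identical
inputs give identical partitions and reports.

## 2. Preprocessing

*Filtering* keeps genes with CPM ≥ `min_cpm` (default 1) in at least
`min_samples` (default 3) samples, computed on raw library sizes because
the filter precedes normalisation. *TMM* is implemented in full (weighted
trimmed mean of M-values; 30% two-sided trim on M, 5% on A; inverse
asymptotic binomial variance weights; rank-based trimming; reference =
sample whose upper-quartile count fraction is closest to the mean) and is
verified in the test suite to agree with edgeR's `calcNormFactors` to
1e-10 on random count matrices. *RPKM* divides by effective library size
(library × TMM factor) and gene length.

*Differential expression* is a pure fold-change rule: log2 of the ratio of
group means of RPKM, with a pseudocount (default 0.25 RPKM) guarding empty
denominators; `up` at log2FC ≥ 1, `down` at ≤ −1, per treatment group
against the control group, with an overall per-gene status (`mixed` when
directions disagree across time points). No dispersion estimation or
significance testing is attempted: the two-fold criterion is the contract.

*Scale for networking.* Correlations are computed on `log2(RPKM + 1)`. On
the linear scale, Pearson correlation is dominated by the few
highest-expression samples and module structure that is plainly present in
log space becomes unrecoverable; log2(x+1) is the standard variance
compression for this purpose. This is a package choice, stated here because
RPKM could equally be fed in untransformed.

## 3. The network fit

`coexpression_network()` is the package's central estimator and returns a
classed S3 object with `print`, `summary` and `plot` methods.

**Soft power.** For each candidate β (grid 1..30) the connectivity
`k_i = Σ_j adj_ij` is binned (10 equal-width bins) and log10(frequency) is
regressed on log10(mean k); the signed R² is `−sign(slope)·R²`. The chosen
β is the smallest reaching 0.85, else the maximiser with a warning. The
0.85 target and the signed formulation follow standard scale-free topology
practice for signed networks.

**TOM.** `TOM_ij = (l_ij + a_ij)/(min(k_i,k_j) + 1 − a_ij)` with
`l_ij = Σ_u a_iu a_uj`, self-adjacency excluded, computed by matrix
multiplication and verified against a brute-force triple loop to 1e-12.

**Module detection.** Average-linkage clustering of `1 − TOM`, a *static*
height cut, minimum module size 30, then two polish stages:

1. *Eigengene merging*: modules whose eigengenes (first principal component
   of the gene-standardised submatrix, sign-oriented to positive mean
   gene correlation) have dissimilarity `1 − cor` strictly below 0.15 are
   merged iteratively, closest pair first, eigengenes recomputed after
   each merge; the merged module keeps the larger constituent's label.
   "Strictly below" is enforced with a 1e-9 guard so a dissimilarity at
   exactly the threshold never merges.
2. *kME refinement*: every gene is reassigned to the module whose eigengene
   it correlates with best, provided that correlation reaches 0.7; genes
   below 0.7 for every module become background; modules falling under the
   minimum size dissolve; iterate to a fixed point (cap 5 rounds).

**Why this cut procedure.** The cut height is the genuinely open design
point: the tree-cut method and height are not derivable from the analysis
convention this package follows, and dynamic tree cutting is deliberately
out of scope. Two simple rules were evaluated on the generator's default
conditions and rejected for cause: a fixed absolute height (any value)
fails because the useful height scales with β, and a fixed quantile of the
merge heights fails because with 12 samples chance correlations make
background genes attach to module clusters *continuously* below the top
merges — there is no gap for a single rule to find. The implemented default
(`cut_height = "auto"`) therefore searches a small quantile grid of
candidate heights and keeps the cut that retains the most genes after
merging and kME refinement. The rationale: when the cut is too low, module
cores fragment below the minimum size and refinement cannot rescue their
genes; when it is too high, clusters are mixtures whose eigengenes
correlate well with nobody, and refinement strips their members; retained
gene count therefore peaks at the correct granularity. The search is
deterministic, and an explicit numeric `cut_height` bypasses it.
`cluster_and_cut()` alone (without expression values) uses a largest-gap
heuristic instead, documented on the function.

**Edge export** keeps within-module pairs with |cor| strictly > 0.8 —
at β = 26 this is adjacency 0.064 — because downstream graph analyses
(MCODE, hubs, Table-style summaries) operate per module graph. The
signed adjacency and the absolute-correlation threshold coexist by
convention: the network is signed, the exported graphs threshold
|cor|; with `anticor_fraction > 0` the generator plants anti-correlated
members specifically to exercise that distinction.

## 4. Graph mining

**MCODE** is re-implemented from its published definition: vertex weight =
(highest core number k of the closed neighbourhood) × (density `2E/V(V−1)`
of that k-core); complexes grow from unvisited seeds in decreasing weight
order (ties broken lexicographically by node id for determinism), admitting
unvisited neighbours with weight > (1 − 0.2) × seed weight, up to depth
100; complexes lacking a 2-core are discarded; the haircut iterates
degree-1 removal, so no singly connected member survives. Defaults (degree
cutoff 2, node score cutoff 0.2, K-core 2, max depth 100, haircut on, no
fluff) are the conventional ones. One consequence of the published
admission rule is worth stating: two equally dense cliques joined by a
single bridge form *one* complex, because the bridge endpoints carry the
full clique weight; the test suite freezes this traced behaviour.

**Hubs** are nodes whose degree strictly exceeds the nearest-rank 90th
percentile of the degree distribution. The distribution is taken per module
by default — hub counts are conventionally reported per module set — with a
`scope = "global"` alternative. The degree–betweenness Pearson correlation
(betweenness: unweighted Brandes, via igraph) is reported as a centrality
diagnostic and warned about when non-positive, but never filters hubs:
the percentile rule is the definition, the correlation a confirmation.
Modules under 10 nodes yield no hubs.

## 5. Enrichment

Hypergeometric upper tail (`stats::phyper`, exact in log space) per term
with at least one query hit; Benjamini–Hochberg across the tested terms
(m = number of tested terms). GO mode: significant at q ≤ 0.05. KOG mode:
raw p ≤ 1e-3 *and* q ≤ 0.05. Subcluster queries under 10 genes return an
empty, flagged result. The background is the set of all genes retained
after expression filtering, and annotations are assumed pre-propagated to
ancestor terms — the package does not parse ontology files or traverse the
DAG; supplying unpropagated annotations changes the meaning of K and the
resulting p-values.

## 6. Promoters and motif scanning

Promoters are the 1.5 kb immediately upstream of the start codon on the
gene's sense strand: window `[s−1500, s−1]` for a plus-strand ATG at `s`,
reverse complement of `[e+1, e+1500]` for a minus-strand ATG at `e`;
contig-edge truncation is flagged. When models come from GFF3 the `gene`
feature span is taken as the CDS span; annotations with UTRs should supply
explicit CDS coordinates instead.

PWMs are built from aligned sites or a count matrix with a
background-weighted pseudocount: cell b receives `pseudocount·4·bg_b`
(so a uniform background adds `pseudocount` per cell, and one site
"GGCAAA" at pseudocount 1 gives consensus frequency 0.4). Log-odds are in
bits. The null score distribution is exact: full enumeration of 4^w words
for w ≤ 8, positionwise convolution over a discretised score grid beyond.
Scores are discretised at 0.001 bits throughout — scanning and the null use
the same grid, so p-values are self-consistent; `pwm_pvalue` snaps within
the accumulated rounding error of one word. Windows containing N are
skipped entirely rather than scored against the background. Hits are
reported at p ≤ 1e-4 on both strands; the offset convention is the
position of the match's 5′-most base on the gene's sense orientation, −1
being the base adjacent to the ATG, so positions read like "two sites at
−733 and −320". By default the scan rebuilds the log-odds against the
0-order composition of the scanned promoter set (`background =
"promoters"`); `"pwm"` keeps the build-time background.

The bundled `synthetic_xbs_sites()` are 22 constructed 10-bp sequences
around the fungal Xyr1 consensus GGC(A/T)₃ — a synthetic stand-in with the
width and information content (10.6 bits) of a real transcription-factor
motif, not experimentally derived binding data.

## 7. The synthetic-data generator

The generator emulates a 4-condition induction design: a control sugar at
one time point and an inducing substrate at three time points (defaults:
fructose 24 h; bagasse 6, 12, 24 h), 3 replicates each — 12 libraries.
Replicate count is an assumption of the generator, not a literature value.

*Expression.* Each module has one latent per-sample profile, drawn
standard normal and rescaled to sd 0.7 (log2 units) exactly — calibrating
the realised, not just expected, within-module correlation — plus a
log2(de_fold) shift on substrate samples for responsive modules (directions
cycle up/down/none by default). Genes load positively on their module's
profile (loadings U(0.8, 1.2); a configurable fraction can load
negatively), with gene-level Gaussian noise scaled so the within-module
correlation of the latent log expression equals `within_module_cor`
(default 0.8). Background genes get independent noise at the same noise sd
as module genes — stable transcripts, as in real data; correlation is
scale-invariant, so their null correlation structure does not depend on
this sd. Counts are gamma-Poisson: intensities `2^x · length/1e3`,
multiplied by gamma noise with dispersion 0.05, then one multinomial draw
per library with totals uniform in 5–15 million, so column sums land in
the configured range *by construction*.

*Genome.* Genes are laid out ten per contig on alternating strands, each
with a 1500-bp promoter slot drawn from a 0-order background (default
uniform) and a short coding stub. A configurable fraction of genes
(default 0.3) receives one planted motif instance — the PWM consensus, or a
PWM-sampled word — at a uniformly drawn offset in [−1500, −width], recorded
in the ground truth. The 0-order background makes the scan's null
analytically checkable: the expected hit count is windows × strands ×
the realised size of the p ≤ 1e-4 threshold.

*Annotations.* Terms are assigned independently per gene at term-specific
background frequencies (U(0.02, 0.10)); each module's designated term is
`enrichment_fold` times more frequent inside that module (capped at 1).
Fold 1 produces a pure null table.

All randomness flows from one master seed through deterministic
per-component substreams, so regenerating any one layer leaves the others
unchanged.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: no read-level sampling (counts are drawn
directly); no GC/length biases beyond the linear length effect; no
batch structure; latent profiles are i.i.d. across samples rather than
temporally smooth; annotations are independent across terms (no ontology
structure); promoters are 0-order (real promoters have composition and
repeat structure that inflate motif false positives); and no attempt is
made to mimic a real gene catalogue. Two measured caveats worth knowing:
with 12 samples, chance correlations of background genes with a module
profile are large (sd ≈ 0.3), so some absorption/leakage is intrinsic and
module recovery is scored by adjusted Rand index rather than exactness;
and per-library normalisation removes any signal common to the whole
transcriptome, so a "module" spanning most of the library is structurally
unrecoverable — modules must be a minority of the transcriptome, as they
are in real data. Relatedly, trimmed-mean normalisation (ours and edgeR's
alike, which agree numerically) under-corrects when a quarter of the
transcriptome moves strongly in one direction with no counterweight; the
default design plants balanced up and down modules.

## 8. Numerical choices

- Score discretisation 0.001 bits; enumeration for width ≤ 8, convolution
  beyond; consensus score equals the column-max sum.
- Merge and threshold comparisons that the contracts state as strict are
  strict, with 1e-9 guards where floating point could tip an exact boundary
  (eigengene merging); edge export compares `abs(cor) > 0.8` directly.
- Zero-variance genes get correlation 0 (with a warning) rather than
  removal, so the gene index is stable across stages.
- hclust merge heights are rounded (1e-10) and made non-decreasing before
  cutting, guarding tie-induced inversions in average linkage.
- Percentages print half-up (1 decimal in module tables; nearest integer
  for hub DE shares); totals rows recompute percentages from summed counts
  rather than summing rounded percentages.
- MCODE seed ties break lexicographically; all stages are
  permutation-stable up to that rule.

## 9. Problem sizes used by the test suite

The suite's simulation scale is chosen to exercise every stage at desk
scale: the default recovery dataset is 1200 genes × 12 samples with six
100-gene modules; the scan null uses > 2 Mb of background promoter
sequence; enrichment null calibration uses 50 seeds, pipeline null
calibration 10 seeds at 300 genes; oracle comparisons run on ≤ 12-node
graphs, N ≤ 12 urns and width ≤ 6 motifs where exhaustive enumeration is
exact. The full suite runs in well under five minutes on one CPU.

## 10. Known limitations

Single-block implementation (dense matrices; intended for ≤ ~10,000
genes). No dynamic tree cut. No GO DAG handling. No higher-order background
models for scanning. DE calling is a fold-change rule, not an inference
procedure. The hub definition's "entire degree distribution" is read
per-module (with a global option) — an acknowledged ambiguity. Module
counts and memberships on real datasets depend on the cut procedure, whose
exact original form is not recoverable; the worked-example quantities the
package reproduces are therefore arithmetic identities and planted-truth
recoveries, not a re-derivation of any particular dataset's module list.
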