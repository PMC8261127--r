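---
title: "Methods: trait-linked co-expression modules, ceRNA networks, and multiplex random-walk prioritization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trait-linked co-expression modules, ceRNA networks, and multiplex random-walk prioritization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The analysis

`afcerna` implements, end to end, an analysis strategy for atrial-tissue
expression cohorts with three rhythm phenotypes: patients with no history of
atrial fibrillation in sinus rhythm (SR/SR), patients with an AF history in
sinus rhythm at sampling (AF/SR), and patients in AF at sampling (AF/AF).
Two clinical contrasts structure everything downstream: **AF
susceptibility** (AF/SR = 1 vs SR/SR = 0) and **AF persistence** (AF/AF = 1
vs AF/SR = 0).

The pipeline is: preprocess the count matrix; build a signed weighted gene
co-expression network and detect modules; correlate module eigengenes with
the two contrasts and keep the top modules; predict module-specific
lncRNA–mRNA ceRNA pairs by a shared-miRNA hypergeometric test; prioritize
lncRNAs by random walk with restart on a two-layer multiplex network seeded
with known disease genes; relate pathway activity to the key lncRNAs; and
classify rhythm status from the key ceRNA-pair expression with
batch-harmonized random forests validated on an independent cohort. A
synthetic-data generator with planted ground truth stands in for the
original cohorts, so every stage is testable offline.

# Preprocessing

Genes with counts below 10 in **more than** 80% of samples are removed (the
boundary is strict: low in exactly 80% is retained). Counts are
variance-stabilized as `log2(count / size_factor + 1)` with median-of-ratios
size factors. This is a deliberate stand-in for a model-based variance
stabilizing transform: it is deterministic, monotone within a sample, and
equivariant under per-sample scaling, which is all the module detection
downstream relies on; it does not flatten the mean–variance trend as well as
a fitted dispersion model would.

Surrogate variables are the top principal components of the residuals after
regressing every gene on the rhythm design (protected) plus sex
(adjustment). The number of SVs is user-fixed (default 2); the
permutation-based dimension estimate of the full surrogate-variable
machinery is intentionally not reimplemented. Sex and the SVs are then
regressed out per gene while the fitted rhythm component is retained, so
trait-linked variance survives cleaning, and the top 5,000 variance genes
(ties broken lexicographically by gene ID, for determinism) enter the
network.

A practical caution that shaped the synthetic design: residual PCA grabs
the largest residual variance directions *whatever they are*. If no genuine
technical structure dominates, the SVs latch onto biological co-expression
factors and removing them collapses within-group variance, which inflates
every module–trait correlation. The generator therefore plants a dominant
batch contrast and a continuous quality factor across all genes — the
situation surrogate-variable analysis assumes — and the SV stage recovers
exactly those.

# Signed network, modules, eigengenes

The signed adjacency is `a_ij = ((1 + cor(x_i, x_j)) / 2)^beta`, so only
positive co-expression forms strong edges. `pick_beta()` scans integer
powers and returns the smallest one whose connectivity distribution reaches
a scale-free fit of 0.9, measured as `-sign(slope) * R^2` of the log10
frequency vs log10 mean-connectivity regression over 10 equal-width bins
(empty bins dropped, diagonal excluded from connectivity). Planted-block
synthetic data is *not* scale-free — its fit plateaus near 0.4 — so the
pipeline configuration accepts `beta = "auto"` with a fallback to the
conventional power 12 for such data; `pick_beta()` itself errors when no
candidate qualifies, reporting the best fit achieved.

Topological overlap is
`TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with unit
diagonal. Modules come from average-linkage clustering of `1 - TOM` with a
**static** height cut; the full dynamic-hybrid tree cut is not
reimplemented, and the `deep_split` parameter is accepted for interface
compatibility only. The default cut height is 0.99 of the maximum merge
height: on data with a large unstructured background, the background genes
merge in a narrow band just below the dendrogram top (their pairwise
dissimilarities concentrate near 1), so quantiles of the merge-height
distribution are dominated by that band and make unreliable cut points,
while a cut just below the top separates the tight module subtrees and
leaves the background in sub-threshold fragments. Clusters below 30 genes
are unassigned (label 0) and surviving modules are renumbered by size.

The module eigengene is the first right-singular vector of the
gene-standardized member submatrix, sign-aligned to correlate nonnegatively
with the mean member profile (a convention; the sign is otherwise
arbitrary) and unit-norm. Modules whose eigengenes are closer than the
merge cut (dissimilarity `1 - cor < 0.25`) are merged iteratively, closest
pair first, recomputing eigengenes after each merge. Eigengene–trait
association uses Pearson correlation on the contrast's sample subset with
the two-sided p-value from `t = r * sqrt((n - 2) / (1 - r^2))`; the top two
modules per contrast (by p) continue to the ceRNA stage.

# Module-specific ceRNA networks

Within each selected module, every lncRNA–mRNA pair sharing at least one
miRNA is tested. With a database universe of `N` miRNAs, a lncRNA targeted
by `n` of them, an mRNA targeted by `M`, and `t` shared, the p-value is the
upper hypergeometric tail `P(X >= t)`, evaluated in log space with
`lchoose` for stability; it equals the complement of the partial sum over
`k < t` exactly, and is symmetric in `n` and `M`, so the choice of which
partner supplies the "draws" does not affect the result. `N` is always
computed from the loaded database, never assumed. Pairs with `t = 0` are
not tested — their p-value would be 1 and they would only dilute the
multiple-testing family.

Pairs with `p < 0.05` form the module network; Benjamini–Hochberg adjusted
p-values are computed within each module's family of tested pairs (the
module-specific construction implies module-level families; a global family
is available via configuration) and support a sensitivity network at
adjusted `p < 0.05`. Module networks are disjoint by construction and are
aggregated into one bipartite network whose nodes carry biotype, module and
a known-disease-gene flag. Intermodule pairs are never formed. A generic
over-representation test (`enrich_ora()`) applies the same tail probability
to gene-list/gene-set overlaps with BH across sets.

# Multiplex random walk with restart

The aggregated ceRNA network is layer 1; layer 2 keeps the functional
gene–gene edges whose two endpoints both occur in layer 1 (0/1 by default,
weighted optionally). The supra-transition matrix places
`(1 - delta) A^[alpha]` on diagonal blocks and `delta / (L - 1) I`
off-diagonal, then column-normalizes; for `L = 2` the off-diagonal factor
is just `delta`. With one layer, `delta` degenerates to 0 — the printed
block structure has no other layer to receive jump mass. A node isolated in
every layer would produce a zero column; its column is replaced by the
uniform distribution (teleportation) to keep the matrix column-stochastic.

The walk iterates `p_{t+1} = (1 - r) M p_t + r p_RS` (defaults:
`delta = 0.5`, `r = 0.7`, L1 tolerance 1e-10, at most 10^4 iterations).
The initial distribution gives each of `k` seeds probability `1/k` within
each layer, and the restart distribution reweights layer `alpha` by
`tau_alpha / L`, keeping total mass 1. The two-layer weights follow
`tau = [2/(1+R), 2R/(1+R)]` with `R` the layer-1 to layer-2 edge-count
ratio (the weights sum to `L = 2`). Seeds are the known disease genes
present in the network. A node's global score sums its stationary
probabilities across layers (a geometric-mean alternative is exposed); the
top two non-seed lncRNAs, ties broken by node ID, are the key lncRNAs.

Two structural facts worth recording. First, because the restart vector is
normalized to unit mass, duplicating a graph into two identical decoupled
layers (`delta = 0`) reproduces the single-layer probabilities exactly
(each layer carries half the mass; the layer-summed global score equals the
single-layer result) — it does not double them. Second, with coupling on,
column normalization turns the collapsed two-identical-layer chain into a
lazy walk with renormalized degrees, so no exact relation to the
single-layer walk holds at `delta > 0`; the solver is instead validated
against the direct linear solve `p = r (I - (1 - r) M)^{-1} p_RS`, with
which the iteration agrees to 1e-8 on networks up to 200 nodes.

# Pathway association

Gene sets come from GMT files, are intersected with the expression universe
first, and are kept when their remaining size lies in [10, 500]. The
single-sample activity score of a set is the per-sample mean of the member
genes' z-standardized expression — a transparent stand-in for
density/rank-based single-sample enrichment: deterministic, invariant to
gene-wise affine rescaling, and directionally interpretable, though less
robust to single outlier genes than a rank statistic. For each key lncRNA,
`score ~ rhythm + lnc_expr` is fit by ordinary least squares and the lncRNA
coefficient with its two-sided t p-value is reported. Rhythm enters as an
ordinal covariate (SR/SR = 0, AF/SR = 1, AF/AF = 2) by default because the
three groups are ordered stages of disease progression; passing a factor
dummy-codes it instead. By the adjustment property of least squares the
lncRNA coefficient is invariant to adding any multiple of the rhythm column
to the score.

# Classification

Features are a key lncRNA plus its partner mRNAs. The AF/AF and SR/SR
training samples (variance-stabilized counts) are merged with the
continuous test cohort on the feature genes and harmonized by per-gene
location–scale adjustment: each batch is standardized and mapped to the
pooled per-gene mean and variance, with no covariate protected. This
replaces empirical-Bayes shrinkage with direct moments, which is adequate
at the simulated scale and deterministic; the flag is recorded in every
report. A 500-tree random forest (default feature subsampling) is evaluated
by stratified six-fold cross-validation — out-of-fold class probabilities
are pooled into a single AUC, with per-fold AUCs also reported — and on the
held-out cohort. AUC is computed by the midrank Mann–Whitney formula, which
equals trapezoidal integration of the tie-aware ROC staircase exactly.

One mechanism deserves a note because it governs the batch-sensitivity
behaviour: a batch effect is constant per gene within a cohort, so it is an
affine map of each feature and cannot change the within-cohort ranking that
any per-feature monotone classifier induces. Held-out discrimination
degrades only when the shifted test samples saturate into the same terminal
nodes of the forest (prediction ties). The synthetic test cohort therefore
carries, besides random per-gene location/scale perturbations, a platform
shift aligned *against* the trait signal; at the default magnitude the
batch-retained test AUC drops noticeably, and at twice the signal magnitude
(the classifier stress test) it collapses toward chance while harmonization
restores it.

# The synthetic cohort

The generator mirrors the study design it replaces: 235 training samples
(SR/SR 43, AF/SR 74, AF/AF 118), 5,000 genes of which 460 are lncRNAs, six
planted modules of 300 genes each (the rest background), and a 38-sample
continuous-valued test cohort (32 AF, 6 SR) from a different platform. Per
sample and module a latent factor is drawn; module genes load on it as
`sqrt(rho) f + sqrt(1 - rho) e` with `rho = 0.6`. Module 1's factor shifts
by 2.5 SD in all AF-history samples (susceptibility); module 2's shifts in
AF/AF only (persistence). Factors are drawn with their group means fixed
exactly at the planted values (each group's empirical mean is centred
away): contrast specificity — trait-significant in the designated contrast,
null in the other — is then a property of the construction rather than of a
lucky draw. Counts are negative-binomial with a 1/mean dispersion trend,
per-sample log-normal depth factors, a sex effect on 30% of genes, and the
dominant batch/quality nuisance described above.

The miRNA universe holds 923 miRNAs. Planted ceRNA pairs (30 per trait
module) share exactly 8 miRNAs, with lncRNA target sets of 10 (the hub 12)
and mRNA target sets of 15; planted lncRNA sets within a module are
disjoint and mRNA filler miRNAs avoid them, so planted cross-pairs share
nothing. Decoy genes (4 lncRNAs, 20 mRNAs per module) draw small random
target sets whose chance overlaps sit below the significance boundary
except for rare two-miRNA coincidences. One hub lncRNA in the
susceptibility module pairs with all ten of its module's seed genes and has
functional (layer-2) edges to the other trait module's ten seeds, so it is
connected to every seed gene across the two layers and should rank first.
The 20 seed genes are planted mRNAs, ten per trait module.

What the generator does *not* emulate: read-level sequencing noise, isoform
structure, genuine miRNA seed-match biology, gene-length or GC biases,
correlated phenotype confounding, or the scale-free topology of real
co-expression networks (modules are homogeneous blocks). Passing tests
therefore demonstrate that the machinery recovers structure of the kind the
analysis assumes, at the planted effect sizes — not that the original
biological conclusions replicate on real data.

# Problem sizes and numerical choices

The validation suite runs the full default cohort (5,000 genes, 235 + 38
samples) for module recovery, ceRNA recovery, hub prioritization and
byte-level reproducibility; classifier sanity checks use a dedicated
800-gene two-module cohort with a clearly separable planted signal (effect
3.5 SD, 16 seed genes) and the saturation-level platform confound; solver
equivalence uses random 2-layer multiplexes up to 200 nodes; the
hypergeometric tail is checked against exhaustive enumeration for every
valid configuration with `N <= 30`. These sizes keep the whole suite within
a few minutes on a single core while exercising every code path at the
cohort dimensions the defaults describe.

Other numerical decisions: all randomness flows from explicit integer
seeds, and every pipeline stage consumes a stage-specific child of the
master seed, so outputs are byte-reproducible; variance ties in gene
selection and score ties in rankings break lexicographically; merge heights
made non-monotone by floating-point ties in average linkage are repaired by
a cumulative maximum (and a genuine decrease beyond rounding error is an
error); zero-variance genes are an error where they would corrupt a
statistic (correlation, eigengenes) and a warning where they can be safely
skipped (set scoring); hypergeometric p-values are clamped to at most 1
after summation.

# Known limitations

The stand-ins (log2 median-of-ratios for variance stabilization,
residual-PCA surrogate variables with fixed dimension, static tree cut,
moment-based batch harmonization, mean-z set scores) are deliberately
simpler than the reference methods they replace; each preserves the
property the downstream stage needs, and each is the first thing to revisit
when moving from synthetic to real cohorts. The ceRNA test conditions on
the target database and ignores miRNA expression; lncRNA–lncRNA and
mRNA–mRNA competition is out of scope. Random-forest hyperparameters are
the package defaults (500 trees); no tuning or calibration is attempted.
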