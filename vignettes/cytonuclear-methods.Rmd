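---
title: "Models and methods behind cytonuclear"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind cytonuclear}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cytonuclear)
```

## The scientific question

Allopolyploid species carry two parental subgenomes in one nucleus, but
their mitochondria and plastids are inherited from the maternal parent
only. Nuclear genes whose products are targeted to (or form complexes
with) the organelles therefore face a potential "mismatch" on the paternal
side: if cytonuclear incompatibilities matter, the paternal homoeologs of
organelle-targeted genes should evolve faster (higher dN/dS) and/or be
lost preferentially after polyploidization. `cytonuclear` implements a
genome-wide test of that prediction built on orthologous *quintets*: gene
groups containing one sequence from an outgroup, one from each of the two
diploid models of the progenitors, and the two homoeologous copies from
the allotetraploid. The fixed quintet species topology is

```
((polyploid_paternal, diploid_paternal),
 (polyploid_maternal, diploid_maternal), outgroup)
```

so each subgenome's terminal branch can carry its own evolutionary rate.

## The codon substitution model

All rate estimation uses an MG94-style codon model crossed with HKY
mutation ("MG94xHKY") on the 61 sense codons of the universal code. The
instantaneous rate from codon *i* to codon *j* is nonzero only for
single-nucleotide changes and equals the product of

* the F3x4 equilibrium frequency of the target nucleotide at the changed
  codon position,
* kappa, if the change is a transition,
* omega, if the change is nonsynonymous.

Each branch has its own omega (the *free-ratio* branch model) and its own
length *t* in expected substitutions per codon; kappa and the F3x4
frequencies are shared across branches. There is no among-site rate
variation: the analyses this package reproduces fix the gamma shape to
zero, and the package follows that choice. Codons containing gaps or `N`
are treated as missing data; terminal stop codons are converted to
missing data at load time and internal stop codons are rejected. MG94 was
preferred over the Goldman–Yang parameterization because its generator
separates synonymous and nonsynonymous flow exactly, which makes the
reported per-branch dN and dS closed-form functions of (t, omega, kappa):

* dS = t * rhoS / (3 fS) and dN = t * rhoN / (3 fN), where rho are the
  flow proportions at the branch's omega and f the site fractions at
  omega = 1, so that dN/dS equals the branch omega whenever dS > 0.

When a 61-codon frequency vector is supplied (e.g. to the simulator), it
is projected onto the F3x4 family via its positional marginals, and the
generator's stationary distribution — the renormalized positional
product — is what the object reports as `codon_freqs`. This keeps
simulation and inference inside one model family, so parameter recovery
is well-posed.

## Likelihood engine and optimization

The likelihood is computed by Felsenstein pruning over the 61-state chain,
specialized to the five-taxon quintet: partial likelihoods at the two
cherries depend only on the observed codon pair, so the engine evaluates
unique (tip, tip) pairs once and recombines per site pattern. Transition
matrices come from the eigendecomposition of the pi-symmetrized
generator, which also yields an analytic gradient of the log-likelihood
in all 15 parameters (7 branch lengths, 7 omegas, kappa) via
divided-difference (Fréchet) identities.

Optimization is box-constrained quasi-Newton (`L-BFGS-B`) on
log-transformed parameters, started from the conventional initial values
kappa = 2, omega = 0.4, with optional additional seeded jittered starts;
the best log-likelihood wins and ties (< 1e-6) go to the first start.
Bounds are t in [1e-8, 20], omega in [1e-6, 50], kappa in [0.05, 100]; a
branch omega at the upper cap is flagged `at_cap`, and a branch with
dS < 1e-8 has its omega reported as undefined (`NA`, flag `undefined`)
because the ratio is numerically meaningless there. Bootstrap replicate
refits are warm-started at the point estimate and polished by damped
Newton steps preconditioned with the point-fit Hessian (gradient
tolerance 0.02 on the log scale), falling back to the quasi-Newton path
when that fails; on matched replicates this reproduces cold quasi-Newton
refits to ~1e-3 in the omega ratio at a fraction of the cost.

Marginal ancestral codon states at the three internal nodes are computed
from the same fitted model (maximum posterior per site, ties broken
toward the lexicographically smallest codon). An NG86-style counting
estimator (`count_pairwise_dnds`, equal-path averaging, Jukes–Cantor
correction, stop-blocked pathways excluded) is included purely as an
independent oracle for the ML engine and is cross-checked against it in
the test suite at low divergence.

## Quintet inference

Gene trees are preprocessed by collapsing splits with bootstrap support
at or below 50 into polytomies; missing support values are never
collapsed, since only measured low support is evidence against a split.
From each (rooted, as read) gene tree the package extracts every
monophyletic, minimally inclusive, species-complete subtree — clades
containing all four species with no smaller such clade inside — and trims
lineage-specific duplicates by keeping, within each maximal single-species
(single-subgenome, for the polyploid) clade, the longest sequence, with
ties broken by a seeded uniform draw so reruns are reproducible.

Phylogenetic and syntenic quintet sets are merged by unordered member-set
identity: the *intersection* holds quintets identical in both, the
*union* adds quintets from either set sharing no member with the other
set, and quintets overlapping (but not identical to) a quintet of the
other set are conflicts, excluded from both.

Each surviving five-tip tree is rooted on the outgroup and scored
concordant when both species-tree cherries are present as resolved
splits, discordant when any resolved split conflicts with them, and
unresolved when polytomies prevent both verdicts. Unresolved quintets are
excluded along with discordant ones — the analysis retains only histories
consistent with the species tree, which is also what filters out gene
conversion and homoeologous exchange. Finally, quintets whose tree-wide
synonymous branch length exceeds a per-dataset cutoff are dropped as
poorly aligned; the boundary is kept (a *maximum* cutoff read as
inclusive).

## Rate tests

Per-category concatenations append genes in sorted gene-id order and
remember block boundaries. The headline statistic is the ratio of the
polyploid paternal to maternal terminal-branch omegas,
omega_PAT/omega_MAT. Uncertainty comes from a gene-block bootstrap:
B resamples of whole genes with replacement (each a reweighting of site
patterns, which is what makes B = 1000 feasible), each refitted with
`optimizer_replicates` runs whose per-branch lower medians are used.
Codon-column bootstrap (`codon_bootstrap`) is reserved for small
categories where the gene bootstrap would be degenerate. Two-tailed
p-values are read directly off the bootstrap distribution,
p = 2 min(Pr(<= ref), Pr(>= ref)), with resolution 2/B.

Category ratios are normalized by the *point* omega ratio of the
non-organelle-targeted (NOT) background — not by paired NOT resamples,
which the source workflow does not describe. This choice makes the test
slightly anticonservative when the background is small, because the
background's own sampling noise is ignored; in the intended use the NOT
set is roughly an order of magnitude larger than any organelle category,
which keeps the effect minor. The calibration experiment in the test
suite therefore pairs a 100-gene category with a six-fold larger NOT set,
mirroring the category-to-background proportions of real annotations.

Gene-level analyses use a sign test: for each quintet, which subgenome
branch has the higher omega (or dN); ties and undefined values are
excluded and the two-sided exact binomial test against 0.5 is applied.
Divergence binning splits genes at the lower median of the
diploid–diploid dN (median gene in the low bin) to ask whether
high-divergence genes show stronger paternal acceleration.
Polyploid-versus-diploid contrasts reuse the per-replicate branch omegas:
the ratio of each polyploid terminal branch to its sister diploid branch,
significant when the 95% percentile CI excludes 1. All medians are lower
medians, and every resampling routine is reproducible bit-for-bit from
its seed.

## Classification

Genes are classified by propagating a reference (model-species)
annotation through orthogroups: members of an orthogroup containing a
reference gene that interacts with the organelle genomes inherit the
interacting tier chain (and fine category); otherwise a gene is
organelle-targeted only if at least one targeting predictor votes for
that organelle *and* at least half the reference genes in the orthogroup
are organelle-targeted (dual-targeted reference genes counted once);
otherwise it is NOT. Dual-targeted genes belong to both organelle
partitions. The tier chains are nested by construction: enzyme-complex
genes are interacting, interacting genes are targeted. Quintets are
labeled via their maternal-diploid member by default; designs whose
maternal diploid model has no usable annotation (e.g. a
transcriptome-only assembly) can use the paternal diploid instead. The
four named targeting predictors are abstracted to vote counts; the tools
themselves are never run.

## Autapomorphies

Derived amino acid changes are counted on terminal branches at sites
conserved in the rest of the quintet: a site counts iff the focal tip's
amino acid differs from its reconstructed parent's, the other four tips
share one amino acid, the parent equals that shared state (derived
polarity — the stricter reading, using the model-based marginal
reconstruction rather than outgroup parsimony), and the site has no gaps
or ambiguity anywhere. A replacement is *radical* when its score in a
20x20 exchange matrix strictly exceeds 0.5. The matrix of record is an
external input (`read_exchange_matrix`); the built-in default
(`default_exchange_matrix`) is a binary polarity/charge-class partition
used by the tests. Category-versus-background subgenome bias in these
counts is tested with Fisher's exact test; a zero margin yields an
undefined marker rather than a p-value.

## Gene content

Subgenome bias in gene counts is delta = (n_pat − n_mat)/(n_pat + n_mat),
with a Clopper–Pearson exact 95% CI on the paternal proportion mapped to
the delta scale (2p − 1) and a two-sided exact binomial p-value against
0.5. This computation, applied to the two polyploid subgenome counts
alone, reproduces the published per-species deltas and CI endpoints
exactly, which is why the diploid-model columns enter only through the
background-corrected comparison (`normalized_bias`, an exact
two-proportion test of the category against the NOT background) — the
table footnote describing a ratio to the diploid models does not match
the printed numbers, and both readings are provided. Duplicate-retention
contrasts use Pearson's chi-square without continuity correction (the
intended sample sizes are thousands of genes), flagged when expected
counts fall below 1.

## The synthetic-data generator

The generator produces every input the pipeline consumes, with the
statistical structure the analysis assumes — and its defaults are the
package's study conditions:

* **Quintet alignments** evolve root codons drawn from the stationary
  distribution along the fixed topology by exact `exp(Qt)` transition
  probabilities, with per-branch omegas. Defaults: 400 codons (a typical
  plant CDS), terminal branches t = 0.05, ancestral ingroup branches
  0.02, outgroup 0.30 substitutions/codon (tree lengths comparable to
  published quintet estimates), kappa = 2, omega = 0.2 (moderate
  purifying selection), and mildly AT-rich positional base composition
  (A 0.28, C 0.20, G 0.23, T 0.29). The realized internal-node sequences
  are returned so reconstruction can be validated against truth.
* **Gene-tree sets** start from the species topology and, per gene,
  swap one diploid with the opposite-subgenome polyploid tip (the
  signature of gene conversion / homoeologous exchange) with the given
  discordance rate, duplicate a random tip into a paralog cherry with
  the duplication rate, and plant one low-support (<= 50) split with the
  low-support rate.
* **Gene-content tables** lose each homoeolog independently with
  per-subgenome probabilities.
* **Classification tables** are generated jointly consistent, so the
  classifier recovers every true tier exactly when the predictor error
  rate is zero.

What the generator deliberately does *not* emulate: indels and alignment
error (inputs are assumed aligned; the dS filter exists precisely because
real alignments fail), among-site rate variation, linkage and selection
heterogeneity along genes, synteny-block structure (syntenic quintet
lists are generated directly as tables), and assembly or annotation
artifacts. Passing tests on simulated data therefore demonstrate
correctness of the machinery under the model's assumptions, not
robustness to every pathology of real genome data.

## Numerical and scale choices

Likelihood evaluations use exact eigendecomposition (no scaling
approximations); site likelihoods are floored at 1e-300 to avoid log
underflow on pathological patterns. The test suite sizes its simulation
experiments to what a single CPU handles comfortably while keeping the
statistics meaningful: parameter recovery uses 100 replicate quintets of
2,000 codons; the null calibration of the normalized-ratio test uses 100
datasets of a 100-gene x 300-codon category against a 600-gene NOT
background with B = 100; the directional-power experiment uses 25
datasets of a 100-gene x 500-codon category with omega_PAT = 0.6 versus
omega_MAT = 0.2 (B = 100); oracle equivalence for the subtree extractor
uses 1,000 random trees of up to 12 tips, and the exact-test oracles
enumerate all 2x2 tables with cells up to 15 plus random tables with
margins up to 60, and all binomial configurations up to n = 60.
`scripts/acceptance.R` re-runs smaller versions of the same experiments
end to end and writes the resulting quantities as JSON.

## Known limitations

* Only the five-taxon quintet topology is supported; the engine is
  specialized to it by design.
* No curvature-based standard errors are reported; uncertainty comes from
  the bootstrap machinery only.
* No site or branch-site models and no model selection.
* The NOT-point normalization is slightly anticonservative for small
  backgrounds (see above); with paired background resampling the test
  would be exact but would no longer match the described workflow.
* Multiple testing across categories is deliberately not corrected,
  matching the per-category reporting convention of the analyses this
  package reproduces.
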