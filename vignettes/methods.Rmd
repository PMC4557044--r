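---
title: "Models and methods behind radphy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind radphy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

radphy links gene family radiations to the origin of a novel binary trait —
the motivating system is betalain pigmentation, which replaces anthocyanins
in a single flowering-plant clade and depends on a small set of enzyme
families (a 4,5-dioxygenase and a cytochrome P450) that duplicated into
trait-specific ("alpha") and ancestral ("beta") paralog clades. The package
implements the whole inference chain — homolog recovery, iterative gene-tree
refinement, duplication mapping, ancestral state reconstruction, codon-model
selection tests, diagnostic residues and physical gene clusters — together
with a synthetic-data generator that plants a known truth for every one of
those signals. This vignette explains the models, the tunable parameters,
the numerical choices, and what the synthetic experiments do and do not
demonstrate.

## Homolog search

`find_homologs()` runs optimal local alignment (Smith–Waterman with affine
gaps, BLOSUM62 by default) of the query against every database sequence and
converts raw scores to E-values with the Karlin–Altschul formula
`E = K m n exp(-lambda S)` using published gapped parameters for BLOSUM62
with gap open 11 / extend 1 (`lambda = 0.267`, `K = 0.041`). Two gates are
applied: `E <= 10` — deliberately permissive, so short or partial sequences
are not lost — and percent identity `>= 40%` (a `20%` alternative suits
distant single-genome searches). Identity is computed over aligned columns
excluding gaps, the common BLAST semantics; the choice is configurable
because the denominator convention materially changes the gate for partial
hits. One best alignment is kept per query–target pair; sub-optimal HSPs
are out of scope.

## Alignment and filtering

`progressive_align()` builds a deterministic guide tree by neighbor joining
on k-mer (k = 3) cosine distances and merges blocks by profile–profile
alignment under BLOSUM62 with affine gap costs (open 11, extend 1). The
aligner trades accuracy for determinism and zero external dependencies: it
never permutes residues within a row, which is the property the downstream
filters rely on. Column trimming keeps exactly the columns whose non-gap
occupancy is `>=` the threshold — the inclusive comparison matters at the
workflow's boundary settings 0.01, 0.05 and 0.1, and the tests pin it.
"Poorly aligned" has no single accepted definition; the
package operationalizes it as sequences with residues in fewer than half
of the well-occupied (>= 50% non-gap) core columns, logged for audit, with
the threshold configurable. Codon alignments are produced only by threading
CDS through a protein alignment (`backtranslate()`), so every codon column
corresponds to one amino-acid column; the clean-data rule then removes any
codon column containing a gap or an ambiguity code in any row, and the
completeness-window filter keeps sequences gapless across a reference codon
interval (codons 39–436 and 65–275 are the conventional windows for the
two pigment enzymes).

## Gene trees

Trees are estimated by ML pairwise distances under WAG (capped at 10
substitutions/site), neighbor joining (negative branches clamped to zero
with the deficit moved to the sibling branch), and likelihood refinement
with branch-length optimization and NNI hill-climbing under the same model;
bootstrap support resamples columns with replacement and maps bipartition
frequencies onto the base tree. This replaces a full ML tree search: at the
scale the pipeline targets (tens of sequences) NJ + NNI under WAG reaches
the same topological decisions the downstream stages need, and externally
estimated trees can be injected as newick at any stage. Gamma rate
heterogeneity is available through the underlying engine but off by
default.

The tree-surgery rules are applied exactly as stated: edges
strictly longer than 1.5 are cut and the component containing the anchor
(the reference sequence of known function) is kept, repeating until no
offending edge remains; tips on pendant branches strictly longer than 1.0
are removed with unary nodes suppressed and lengths summed; the anchored
clade can be extracted either around a target tip set or by expanding the
anchor by n sister lineages (default 1 — how many "closest outgroup
sequences" to retain is a free choice); rooting places the
root at the midpoint of the edge subtending the outgroup clade, a display
convention with no effect on reversible-model likelihoods.

## Duplication mapping

`lca_reconcile()` maps each gene-tree node to the species-tree MRCA of its
descendant species; a node is a duplication when it maps to the same
species node as at least one child. This is the parsimony (minimum) count:
losses are deliberately not enumerated — presence/absence matrices carry
that signal instead, with an optional Fisher exact test for loss asymmetry
between paralog clades that is clearly an add-on summary. Placements are
reported as the mapped species node plus its parent edge, i.e. the latest
interval in which the duplication can have occurred ("just before the
divergence of" that clade). Weakly supported nodes are not collapsed before
counting; the duplication counts therefore refer to the resolved topology
as estimated.

When the pipeline must split the gene tree into the anchor's paralog clade
and its sister, it considers the duplication nodes on the anchor's
root path and picks the one duplicating the largest species set (ties to
the most basal). A genuine whole-clade duplication duplicates many species,
whereas spurious duplications induced by tree-estimation noise typically
duplicate one or two; the maximum-overlap rule makes the alpha/beta split
robust to exactly the reconstruction errors the refinement loop cannot
remove. The alpha partition is the anchor-side child of that duplication;
the beta partition used for presence/absence, loss asymmetry and
diagnostics is the complement of alpha within the ingroup family, because
species that diverged before the duplication carry the ancestral
(beta-like) copy, and it is their single copy that the empirical
presence patterns count as "beta". The strict post-duplication sister
clade is reported separately. When sequence information is limited (short
codon windows), tree-estimation error can still attach a stray
pre-duplication tip inside the alpha clade and a single such intruder
voids strict invariance at diagnostic columns — a real sensitivity of
diagnostic-residue analysis, visible in the synthetic experiments at some
seeds and worth bearing in mind with real data.

## Trait ancestral states (Mk1)

The binary pigment trait evolves under a one-parameter symmetric CTMC with
closed-form transitions `P_same = (1 + e^(-2rt))/2`. The root prior is the
stationary (1/2, 1/2) — the symmetric stationary distribution is the only
prior consistent with the one-rate model. OTUs coded "missing" enter the pruning recursion with
partial likelihood (1, 1) rather than being dropped, which keeps the tree
shape (and therefore branch-length information) in the likelihood. The rate
is fitted by Brent-style 1-D optimization of the log rate on
[1e-8, 1e3] (tolerance 1e-8), with boundary optima flagged — an
all-one-state trait table has its MLE at the lower bound and is reported as
such, not hidden. Marginal posteriors use the standard two-pass re-rooting
computation and are verified against exhaustive enumeration over all
internal-node state assignments on small trees to 1e-10. Minus log
likelihood is reported alongside the log likelihood to match the reporting
convention of desktop ASR tools.

## Codon models and selection

Codon evolution follows a GY94-style model on the 61 sense codons of the
standard code: single-nucleotide changes only, target-frequency
proportional, multiplied by `kappa` for transitions and `omega` for
nonsynonymous changes; the generator is reversible and normalized to one
expected substitution per codon site. Site models M0, M1a (classes
`omega0 < 1` and `omega1 = 1`) and M2a (adding `omega2 >= 1`) and
branch-site model A (classes 0, 1, 2a, 2b with `omega2` on an a priori
foreground branch set only, and `p2a = p2 p0/(p0+p1)`,
`p2b = p2 p1/(p0+p1)`) are implemented with per-site mixture likelihoods
over pruning passes that share eigendecompositions across site classes and
compress identical site patterns. Codon frequencies default to F3x4
computed from the alignment (the common CodeML default; an equal-frequency
option exists). Foreground specification by clade resolves to all branches
within the clade, including its stem by default, since the hypothesis is
episodic selection starting at the clade's origin.

Two numerical conventions are worth stating. Branch lengths of the input
tree are held fixed during model fitting (the external reference
implementation co-optimizes them); the simulator and the fitter share one
scaling convention — the mixture-average substitution rate, computed with
background omegas, equals one — so parameter-recovery experiments are
internally consistent. Optimization is multi-start BFGS on unconstrained
transforms (log kappa, logit omega0, log(omega2 - 1), softmax
proportions), with transforms clamped to +-30 to keep the
eigendecomposition in floating-point range, and a nested-start helper that
launches the alternative model from the null's optimum so the fitted
log-likelihood of the alternative can never fall below the null's.

LRTs use chi-square with df = 2 for M1a vs M2a and df = 1 for model A vs
its null (`omega2 = 1`); the 50:50 mixture of a point mass at zero and
chi-square(1) is available for the boundary case and is what the pipeline
reports. Site identification offers naive empirical Bayes (posteriors at
the MLEs) and a Bayes empirical Bayes grid: 10 points per dimension over
(p0, p1) in the simplex, omega0 in (0,1) and omega2 in (1,11), weighting
each grid point by its data likelihood with the remaining parameters at
their MLEs. Both the 0.95 and 0.99 posterior thresholds are reported
because analyses conventionally report either; neither is hard-coded
as the answer.

## Diagnostic residues and gene clusters

A column is strictly diagnostic when clade A carries exactly one residue
and clade B exactly one different residue; the tolerant mode ("almost
invariant") requires A invariant, A's residue absent from B, and B's
majority residue at frequency `>= 1 - tau` with `tau = 0.1` by default —
the tolerance behind "almost invariantly" is unquantified in the source, so
it is a declared, configurable choice. Rows with gaps are excluded from the
invariance check, but a clade more than half gapped at a column is
ineligible there. Positions are reported in the numbering of an ungapped
reference row. Gene clustering measures the gap between nearest gene ends
(not midpoints), counts strictly intervening annotated genes, and tests the
gap against an inclusive 50 kb threshold.

## The synthetic scenario

`simulate_scenario()` is the package's study design, fixed once: 32 ingroup
species plus a 4-species outgrade on a pure-birth tree (ingroup scaled to
height 1, joined at depth 1.3); one forced gain of the derived state on the
stem of a clade holding ~55% of the ingroup and three forced reversals on
small nested clades, with no additional stochastic flips (rate 0), so that
presence/absence truth is exact; a gene family whose alpha copy arises on
the gain-clade stem and is absent from every reversal lineage, an extra
duplication inside alpha (the radiation) and one inside beta; codon
sequences of 210 codons (the scale of a typical single-enzyme codon window)
under branch-site model A with kappa 2, omega0 0.1, omega2 5 and 10% of
sites in the selected classes on the alpha foreground; two diagnostic
residues overwritten post hoc (imposed as observed invariants, not
generated by a selection coefficient, matching how such residues are
treated empirically); and a chromosome-2-style annotation with the two
focal loci 30 kb apart separated by exactly one intervening gene, plus
decoy loci on other chromosomes. Gene-tree branch lengths are species-tree
times scaled by 0.4 substitutions/site, keeping pairwise divergences well
inside the long-branch thresholds so the pruning rules fire only on planted
artifacts. A pure-birth (not birth–death) species tree is used because
gene-level losses, where the biological signal lives, are modelled
explicitly in the gene-family simulator. Every sub-simulator draws from its
own stream derived from the master seed, so adding a stage never perturbs
earlier outputs, and a fixed seed fixes every emitted byte.

What passing these experiments shows — and what it does not. The simulator
emulates clean orthology, no incomplete lineage sorting or horizontal
transfer, no alignment-length variation beyond planted artifacts, no
among-branch rate heterogeneity outside the branch-site classes, and
indel-free codon sequences. Recovery of the planted truth therefore
demonstrates the correctness of the inference chain, not its robustness to
the many ways real transcriptomes are messier; the filtering stages exist
precisely because real data violate these assumptions, and they are tested
on planted violations (scrambled sequences, long branches, low-occupancy
columns) rather than on a full generative model of assembly error.

## Problem sizes and design choices

The oracle-equivalence experiments run on trees of up to 6 tips (trait
model, exhaustive enumeration), 2–3 taxa and a few codons (codon models,
series-expansion matrix exponential) and 200 random gene/species tree
pairs of up to 8 tips (reconciliation); parameter-recovery and calibration
experiments use 100 replicates of 300-tip trees for the trait rate, 20
seeds of 6–10-taxon alignments of 300–500 codons for the codon models, and
100 replicates for the M2a-vs-M1a type-I error — sizes at which the
experiments are informative while the whole suite stays comfortably
runnable on a laptop. The command-line surface described alongside the
module designs is provided by the exported R functions and the
`run_pipeline()` driver rather than a shell wrapper: the intended users
drive the analysis from R, and every stage is a plain function call.
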