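# radphy

Lineage-specific gene family radiations are a recurring route to
evolutionary novelty: a gene duplicates on the stem of a clade, one copy
neofunctionalizes, and the derived trait appears in exactly the lineages
that keep that copy. Establishing such a link takes a chain of inferences —
recover homologs, build and clean a gene tree, map duplications onto the
species tree, reconstruct where the trait arose, test the candidate clade
for positive selection, find the residues that distinguish it, and check
whether the loci cluster physically in a genome. radphy implements that
entire chain as composable R functions, and ships a synthetic-data
generator that plants a known truth for every signal, so the pipeline can
be validated end to end without any external data or programs.

The motivating system is betalain pigmentation in Caryophyllales, where
trait-specific "alpha" paralog clades of two enzyme families arose by
duplication near the trait's origin, were lost in lineages that reverted to
anthocyanins, show positively selected and clade-diagnostic residues, and
sit within ~50 kb of each other on one chromosome.

## Core models and statistics

- **Homolog search**: Smith–Waterman local alignment (BLOSUM62, affine
  gaps), Karlin–Altschul E-values `E = K m n e^{-λS}`, gates `E ≤ 10` and
  identity ≥ 40%.
- **Gene trees**: ML distances and NNI likelihood refinement under WAG;
  occupancy trimming (0.01/0.05/0.1), pruning of branches > 1.5 and tips
  > 1.0, anchored clade extraction, outgroup rooting, bootstrap support.
- **Duplication mapping**: LCA reconciliation — a gene node is a
  duplication iff it maps to the same species node as one of its children;
  presence/absence matrices and loss-asymmetry summaries.
- **Trait history**: one-rate Mk model (`P_same = (1+e^{-2rt})/2`), root
  prior (1/2, 1/2), ML rate and marginal ancestral posteriors by the
  re-rooting method; "missing" OTUs contribute partial likelihood (1, 1).
- **Selection**: GY94 codon models — M0, M1a, M2a and branch-site model A
  (ω2 on a priori foreground branches only) — with likelihood-ratio tests
  (M1a vs M2a, df 2; model A vs null, df 1 or the 50:50 χ² mixture) and
  naive / Bayes empirical Bayes site posteriors at thresholds 0.95 and
  0.99.
- **Diagnostics**: clade-invariant residues (strict and "almost invariant"
  tolerant modes) in reference numbering; gene clusters by nearest-end
  distance with intervening-gene counts.

## Worked example

```r
library(radphy)

sc <- simulate_scenario(seed = 1)      # planted truth: sc$truth
report <- run_pipeline(sc, pipeline_config(n_bootstrap = 100))
report
#> radphy pipeline report
#>   search: 52 hits
#>   duplications: 5 (alpha clade: 1)
#>   Mk1 rate: 0.35673, -log L: 17.81094
#>   M1a-vs-M2a LRT p = 1.64e-07; model A LRT p = 5.98e-27; 12 sites BEB > 0.95
#>   diagnostic sites: 50, 120
#>   cluster: 30000 bp apart, 1 intervening
```

Reading that output: the homolog search recovered all 52 members of the
simulated family (decoys are excluded by the 40% identity gate); LCA
reconciliation on the estimated gene tree counts 5 duplications, one of
them inside the alpha clade (the planted radiation); the Mk1 fit estimates
the trait's transition rate and −log L on the species tree; both selection
tests reject their nulls — the data were simulated with ω2 = 5 on 10% of
sites in the alpha clade — and 12 sites exceed BEB posterior 0.95, all of
them truly selected (the planted truth lists 13); the two planted
diagnostic residues (positions 50 and 120 in the anchor's numbering) are
recovered exactly; and the two focal loci lie 30 kb apart with one
intervening gene, within the 50 kb clustering threshold.

Individual stages are plain functions — `find_homologs()`,
`progressive_align()`, `trim_columns()`, `ml_refine()`,
`prune_long_branches()`, `lca_reconcile()`, `fit_mk1()`,
`fit_codon_model()`, `eb_site_posteriors()`, `diagnostic_sites()`,
`gene_clusters()` — so any slice of the pipeline can be run, or external
alignments and trees injected, without the driver.

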