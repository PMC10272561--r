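# coexscreen

Trait-associated co-expression module discovery and network-proximity drug
screening, as one tested R pipeline.

## The problem

A recurring analysis pattern in disease transcriptomics: given case/control
bulk expression, find the gene co-expression module most associated with the
trait, characterize it (hub genes, per-sample and per-cell activity,
functional enrichment, cell-subtype association), and then screen approved
drugs against that module on a protein–protein interaction (PPI) network to
nominate repurposing candidates. `coexscreen` implements that whole chain
for analysts who want each step to be a small, testable function rather than
a stack of loosely coupled tools — plus a synthetic-data layer that plants
known modules, networks, drugs and cell populations so the chain's claims
can be verified against ground truth.

## The method at its core

- **Modules.** Biweight midcorrelation `bicor(x, y)`; soft power chosen
  against a scale-free fit target of 0.9; topological overlap
  `TOM_ij = (L_ij + a_ij) / (min(k_i, k_j) + 1 − a_ij)`; average-linkage
  clustering of `1 − TOM` with a static cut; eigengene merging at
  dissimilarity 0.1; grey and >1,000-gene modules excluded; module–trait
  Pearson correlation on eigengenes; hubs = top-10 genes by kME.
- **Scores.** Rank-weighted single-sample enrichment (exponent 0.25) for
  bulk samples; bin-controlled additive score (24 bins, 100 controls per
  set gene) on `ln(1 + count/lib × 10⁴)` values for cells; pseudo-bulk by
  per-sample summation.
- **Discrimination.** Hub-gene logistic regression scored by the median
  AUPRC (step-wise average precision) of 3 × stratified 5-fold CV.
- **Drug screen.** `D(X, Y) = Σ_{x∈X} Σ_{y∈Y} d(x, y) / (|X||Y|)` on the
  score-≥600 PPI graph (largest connected component); null from 1,000
  size-matched uniform pseudo-target draws; `Z = (D − μ)/σ`; one-sided
  lower-tail p, BH-adjusted across drugs (effective targets = pChEMBL > 6).

## Worked example: the synthetic study

The `analysis/` directory is a numbered workflow over the package; run it
end to end with

```sh
Rscript analysis/00_run_all.R
```

(about 10 s). Stage 1 simulates the study inputs: a 400-gene × 200-sample
bulk matrix with four planted modules (the first carrying the trait
effect), a 500-node scale-free PPI edge list, 20 drugs planted within one
hop of the trait module's high-loading genes among 180 null drugs, and
2,000 cells in four subtypes with `Mic1` over-expressing the module. The
later stages then print, among other things:

```
soft power 2 (scale-free target not reached; max fit used)
4 retained modules: module_1, module_2, module_3, module_4
planted trait module recovered as module_1; ranked 1 by |trait r|
Trait-leading module: module_1 (r = 0.396, p = 6.7e-09)
Best module by 3x5-fold CV median AUPRC: module_1 (0.683)
Top enriched pathway: planted_module_1 (p_adj = 1.78e-52)
Highest-scoring cell subtype: Mic1 (mean additive score 1.223)
planted drugs in the top 20: 85%
```

Reading those numbers: the chain re-finds every planted module exactly and
ranks the trait module first; the module's point-biserial trait correlation
(0.396) matches what a 0.8-SD latent shift at n = 200 can produce; the CV
AUPRC of 0.683 sits at the analytic ceiling for that effect size (the trait
reaches a classifier only through the shared factor, capping AUC at
Φ(0.8/√2) ≈ 0.71); enrichment and subtype scoring point at the planted
pathway and the planted subtype; and 17 of the top-20 drugs by BH-adjusted
proximity are planted ones. The per-stage tables (assignments, eigengenes,
kME, scores, markers, the ranked drug screen with its
`targets|mean|SD` background column) land under `results/study/`.

`run_pipeline(pipeline_config(...))` runs the same stages as one call with
a hash-recorded manifest, if you prefer a single entry point.

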