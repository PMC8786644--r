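# pansurvnet

Pan-cancer survival prediction from gene expression with gradient-boosted
Cox models, and extraction of a survival-associated network module from a
protein–protein interaction (PPI) network.

The package is aimed at computational biologists who want to (i) train
censored-survival models on one tumor cohort or on patients pooled across
cohorts, (ii) ask which genes carry the predictive signal and whether that
signal generalizes across cancer types, and (iii) project the gene-level
importance onto a PPI to obtain connected survival modules. Because the
motivating use case (TCGA-scale expression and clinical data) is large and
access-controlled, the package ships a synthetic-data generator that
emulates the statistical structure of the problem — multiple censored
cohorts with a partly shared prognostic signature and a PPI with a planted
module — so every stage can be validated against known ground truth.

## The method

**Boosted Cox models.** Risk scores are additive regression-tree ensembles
φ(x) = Σₖ fₖ(x) fit by gradient boosting on the negative partial
log-likelihood of the Cox proportional-hazards model

  ℓ(s) = − Σ_{i : Eᵢ=1} [ sᵢ − log Σ_{j : Tⱼ ≥ Tᵢ} exp(sⱼ) ],

where Tᵢ is the observed time and Eᵢ the event flag (1 = death observed).
The risk set uses Tⱼ ≥ Tᵢ (Breslow-style ties). The package owns this loss,
its gradient/curvature, and the concordance index (C-index: fraction of
comparable patient pairs ranked concordantly by predicted risk; 0.5 =
chance); tree fitting is delegated to xgboost (`objective = survival:cox`).

**Embedded feature selection.** Within each training replication, a
stratified 4-fold CV trains 20 size-limited models per fold (5–20 trees,
depth 1–3, varying column subsampling) after removing zero-MAD (constant)
genes; per-gene split gain is averaged over all 80 models and the top 500
genes are kept. Hyperparameters of the final model are then tuned by
random search (500 candidates, 4-fold CV, mean C-index).

**Cross-cohort entropy.** Per-cohort importance weights (gain summed over
replications) are normalized per gene into a probability vector over
cohorts and scored with base-2 Shannon entropy H = −Σ P log₂ P: H = 0 for a
cohort-specific gene, H = log₂(#cohorts) (4.64 bits for 25 cohorts) for a
gene equally important everywhere.

**Network propagation.** The heaviest in-network genes seed a random walk
with restart, p ← (1−r)·W·p + r·p₀ with r = 0.8, where W is
column-stochastic with transitions proportional to neighbor *coreness*
(k-core number) rather than degree, countering the hub bias of PPIs.
Per-node significance comes from permuting the initial weight multiset
(empirical p, BH FDR ≤ 0.05), and modules are the connected components of
the subgraph induced by seeds plus significant genes that contain at least
one seed and two genes.

## Worked example

The `analysis/` scripts run the whole pipeline at reduced scale on synthetic
data (sizes chosen for a desk run; full-scale defaults live in
`pipeline_config()`):

```sh
Rscript analysis/01_simulate.R       # cohorts + PPI with planted truth
Rscript analysis/02_single_cohort.R  # per-cohort replications
Rscript analysis/03_pan_cancer.R     # pooled training + held-out transfer
Rscript analysis/04_entropy.R        # cross-cohort entropy
Rscript analysis/05_network.R        # propagation + modules
Rscript analysis/06_enrichment.R     # Fisher ORA of module genes
```

Output from a run (seed 2026, 5 cohorts × 80 patients, 300 genes, 10
planted prognostic genes of which 6 shared):

```
overall single-cohort mean: 0.586
pan-cancer mean test C-index over 5 replications: 0.775
held-out heldout_shared (n=30): C-index 0.750
held-out heldout_null (n=30): C-index 0.645
mean entropy, top-20 pan-cancer genes:    0.956 bits
mean entropy, top-20 single-cohort genes: 0.794 bits
planted module recovery: 8/10 planted genes among seeds, 8/10 in modules
top set: planted_signature (overlap 8/10, p = 5.03e-08, FDR = 3.02e-07)
```

Pooling cohorts lifts the mean test C-index from 0.586 to 0.775 because
per-cohort sample sizes (64 training patients) are too small to learn the
signature alone; the pooled model also transfers to a held-out cohort that
shares the signature (0.750). The null held-out cohort has no signal — its
0.645 is sampling noise at n = 30 (≈15 events). Top pan-cancer genes carry
higher cross-cohort entropy than top single-cohort genes, i.e. they
generalize, and the network stage concentrates 8 of the 10 planted genes
into one seed-anchored module whose gene set is strongly enriched for the
planted signature.

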