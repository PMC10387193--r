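# netrank

Network-based gene prioritisation for biomarker discovery, in R.

## The problem

Classical differential-expression tools score genes one at a time, ignoring
the fact that disease genes act through shared pathways and interactions. A
gene with a moderate phenotype association that sits among strongly
associated neighbours in an interaction or co-expression network is often a
better biomarker candidate than an isolated gene with the same marginal
association — it is more interpretable, and signatures built from such genes
tend to share function.

`netrank` implements the NetRank algorithm, a damped random-surfer model (in
the PageRank family) that fuses the two sources of evidence. Each gene *j*
receives a score *r<sub>j</sub>* solving the fixed-point system

```
r_j = (1 - d) s_j  +  d * Σ_i  m_ij r_i / deg_i
```

where *s<sub>j</sub>* is the gene's phenotype association (the absolute
point-biserial Pearson correlation with the binary case/control label),
*m<sub>ij</sub>* is the symmetric edge weight between genes *i* and *j*,
*deg<sub>i</sub>* = Σ<sub>j</sub> *m<sub>ij</sub>* is the weighted degree,
and *d* ∈ [0, 1] is the damping factor: *d* = 0 is pure correlation ranking,
larger *d* leans on connectivity. The fixed point is computed by Jacobi
(power) iteration from *r* = *s*, a supremum-norm contraction for *d* < 1,
and can be cross-checked against the dense closed form
*r* = (1 − *d*)(I − *d* Pᵀ)⁻¹ *s* with P = D⁻¹M.

Around the core sit the pieces of a working pipeline: expression cleaning
and per-gene min-max normalisation, stratified 70/30 development/test
splitting, correlation priors with t-test p-values, STRING-style edge-list
import (0–1000 combined scores), soft-thresholded co-expression networks
(|cor|^β adjacency with a scale-free-topology fit to choose β), top-K
signature selection under a p-value cutoff, and held-out evaluation by
first-principal-component AUC and an SVM. A seeded synthetic-data generator
plants biomarker modules with known truth so the whole path is testable
offline.

## Worked example

```r
library(netrank)

sim <- simulate_netrank_data(n_genes = 200, n_samples = 150, n_cases = 50,
                             n_biomarkers = 10, effect_size = 1.5, seed = 7)
run <- netrank_pipeline(sim$expression, sim$labels, network = sim$network,
                        k = 15, split_seed = 7)
print(run)
```

```
NetRank pipeline run
  200 genes x 150 samples (105 dev / 45 test), network: supplied
  d = 0.5; signature: 15 gene(s) (k = 15, p < 0.05)
  held-out PCA first-component AUC 0.9911
Held-out SVM evaluation (radial kernel, 15 gene(s), n = 45)
  Precision  Recall     F1_score   Accuracy   AUC
  1.000      0.800      0.889      0.933      0.993
  confusion: tp 12 fp 0 fn 3 tn 30
```

The pipeline cleaned and normalised the 200 × 150 matrix, split it 70/30
stratified by label, computed the correlation prior on the 105 development
samples, propagated it over the supplied network with *d* = 0.5, and kept
the 15 top-scoring genes with association p < 0.05. On the 45 unseen test
samples the first principal component of the signature separates cases from
controls with AUC 0.99, and an RBF SVM trained on the development split
classifies them with accuracy 0.93. All 10 planted biomarkers are in the
signature:

```r
print(run$fit, n = 5)
#> NetRank gene ranking (d = 0.5, power solve)
#>   converged after 23 iteration(s), residual 6.24e-10 (tol 1e-09)
#>   200 genes; top of the ranking:
#>  gene_id netrank_score rank prior_s   prior_p prior_r
#>    G0008        0.6189    1  0.5577 6.406e-10  0.5577
#>    G0006        0.6101    2  0.6156 2.783e-12  0.6156
#>    G0001        0.5501    3  0.5541 8.679e-10  0.5541
#>    G0009        0.5389    4  0.5893 3.757e-11  0.5893
#>    G0004        0.5105    5  0.6582 2.363e-14  0.6582

length(intersect(run$signature$gene_id, sim$truth$biomarkers))
#> [1] 10
```

The fit is an ordinary S3 model object: `coef()` returns the score vector,
`residuals()` the per-gene fixed-point defect, `plot()` a score-vs-prior
scatter, and `as.data.frame()` the full ranking table. Real data enter
through `read_expression()`, `read_labels()` and `read_string_network()` /
`read_network()`; a thin command-line wrapper lives in
`inst/scripts/netrank-pipeline.R`.

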