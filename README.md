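# lionessRT

Individualized replication-timing and RNA coexpression networks for
basal-like vs classical subtyping of pancreatic ductal adenocarcinoma
(PDAC).

PDAC splits into two transcriptomic subtypes — basal-like (poorly
differentiated, worse prognosis) and classical — defined by two largely
anticorrelated gene programs. Cohort-level coexpression networks average
that structure away. `lionessRT` builds networks at **single-patient
resolution** and integrates a **replication-timing (RT) proxy** derived
from promoter DNA methylation: late-replicating heterochromatin is
hypermethylated, so an inverted, smoothed, z-scored methylation track
approximates replication timing without Repli-seq.

The core quantities, in the field's standard notation:

* **RT proxy** per genomic window: `RT_w = -zscore(median-binned, smoothed
  beta)`, aggregated to domains by length-weighted means
  `RT_D = sum(l(w) RT_w) / sum(l(w))`, plus per-sample `RT_mean` and
  `frac_late` (length-weighted fraction of windows with `RT_w < 0`).
* **Integrated edge weight** for genes i, j:
  `w_int = a*w_rna + b*(2*s_rt - 1) + gamma*norm(w_rna)`, where `w_rna` is
  Pearson (or precision-matrix partial) correlation, `s_rt` the normalized
  RT-domain similarity, and `norm(.)` a z-score over surviving pairs;
  pairs with `|w_rna| < 0.5` are dropped, then `w_int >= tau` and the
  global top-K edges are kept.
* **LIONESS individualization** over the frozen edge set:
  `e(q) = N*e(all) - (N-1)*e(-q)`.
* **Module scores** `m_k(q) = mean of e_ij(q) over intra-module edges`,
  read out by a penalized logistic model
  `p_basal(q) = sigma(beta0 + sum_k beta_k m_k(q))`, optionally gated by a
  morphology embedding model `m'_k(q) = m_k(q) * sigma(theta' f(q))`.
* **Validation**: permutation nulls
  (`Z = (x_real - mu_shuffle)/sigma_shuffle`,
  `p_emp = (1 + #{x_s >= x_real})/(1 + S)`), bootstrap top-K edge Jaccard
  stability, and a 5x5x5 grid sweep over `(a, b, gamma)`.

A built-in synthetic-cohort generator plants subtype structure
(anticorrelated programs, subtype-specific program coherence, early/late
replication domains, subtype-separated embeddings) so the whole pipeline
is testable without any external data. See the vignette
(`vignettes/rt-lioness-networks.Rmd`) for the model, calibration and
design decisions.

## Worked example

```r
library(lionessRT)

cfg <- syntheticConfig(nSamples = 60, nGenes = 30, nModules = 3,
                       genesPerModule = 8, embeddingDim = 50, seed = 2024)
generateCohort(cfg, file.path(tempdir(), "demo-cohort"))
cohort <- readCohort(file.path(tempdir(), "demo-cohort"))

report <- runCondition(cohort, "RT_RNA", runConfig())
print(report)
#> RunReport [ RT_RNA ] status: ok
#>  n_nodes n_edges   density mean_degree transitivity components subtype_auc
#>       24      74 0.2681159    6.166667    0.9172932           3   0.9537037

perModuleAUC(report$scores, cohort$labels, report$modules)
#>    module n_genes       auc
#>  module_0       8 0.9502315
#>  module_2       8 0.5856481
#>  module_1       8 0.1041667

head(sampleSummary(report$rt$tracks), 3)
#>   sample_id       rt_mean frac_late
#> 1      S001  8.258212e-17      0.32
#> 2      S002 -1.957687e-17      0.31
#> 3      S003 -3.640253e-17      0.32
```

Reading the output: the integrated network keeps 74 edges over the 24
genes that belong to coherent programs; the cross-validated subtype AUC is
0.954. `module_0` recovers the planted basal program — its raw
per-patient score separates subtypes at AUC 0.95 in the basal direction,
while `module_1` (the classical program) discriminates in the opposite
direction (0.10 basal-positive = 0.90 classical-positive; the midrank
identity `AUC_basal = 1 - AUC_classical` is exact). `rt_mean` is ~0 by
construction (the RT proxy is a genome-wide z-score) and `frac_late`
recovers the planted 30% late-replicating genome within boundary-window
tolerance.

Named conditions `RNA`, `RT`, `RT_RNA`, `RT_RNA_PCORR` and `MORPH_RNA`
run the corresponding stage graphs; `runCondition(..., outDir = )` writes
edge lists, module tables, scores, per-module AUCs, a JSON report and an
md5 output manifest.

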