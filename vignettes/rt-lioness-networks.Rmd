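---
title: "Individualized replication-timing and RNA coexpression networks"
author: "lionessRT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Individualized replication-timing and RNA coexpression networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lionessRT)
```

# Scope and model

Pancreatic ductal adenocarcinoma has two major transcriptomic subtypes,
basal-like and classical, defined by two largely anticorrelated gene
programs. `lionessRT` asks how much of the coexpression structure that
separates these subtypes is visible at single-patient resolution, and
whether a replication-timing (RT) proxy derived from promoter DNA
methylation — late-replicating chromatin is hypermethylated, so an
inverted, smoothed, z-scored methylation track approximates replication
timing — stabilizes that structure.

The pipeline has five stages.

**1. Methylation to RT proxy.** Per sample, promoter beta values are parsed
from heterogeneous vendor files (automatic probe/beta column detection,
clipping to $[0,1]$), binned into uniform genomic windows of length
$L$ (default 200{,}000 bp), summarized by the within-window median
$\tilde M_w$, smoothed by a centered rolling mean along each chromosome,
and converted by

$$ RT_w = -\,z\!\left(M^{smooth}_w\right), $$

with the z-score taken genome-wide over the sample's non-missing windows.
Contiguous windows are grouped into domains of span 300{,}000 bp with the
length-weighted mean
$RT_D = \sum_{w \subset D} \ell(w) RT_w \big/ \sum_{w \subset D} \ell(w)$,
and per-sample summaries are the length-weighted genome mean
$\overline{RT}$ and the late fraction
$frac_{late} = \sum_w \ell(w)\,\mathbb{1}[RT_w < 0] / \sum_w \ell(w)$.

**2. Global network.** Gene associations are Pearson correlations
$r_{ij}$ (optionally partial correlations
$\rho_{ij} = -\Omega_{ij}/\sqrt{\Omega_{ii}\Omega_{jj}}$,
$\Omega = \Sigma^{-1}$). RT similarity between genes is the normalized
spread $s^{RT}_{ij} = 1 - |RT_{D(i)} - RT_{D(j)}| / \max_{u,v}|RT_{D(u)} -
RT_{D(v)}|$, signed as $\tilde s = 2s - 1$. Pairs with
$|w^{RNA}| < 0.5$ are dropped, the surviving associations are z-scored
(population denominator), and the integrated weight is

$$ w^{INT}_{ij} = a\,w^{RNA}_{ij} + b\,\tilde s^{RT}_{ij} +
   \gamma\,\mathrm{norm}(w^{RNA}_{ij}), $$

defaulting to $(a, b, \gamma) = (1.0, 0.5, 0.5)$. Edges with
$w^{INT} \ge \tau = 0.5$ are kept up to the global top-$K = 5000$, with
boundary ties broken lexicographically so selection is deterministic.

**3. Individualization (LIONESS).** For any edge function evaluated on the
frozen retained pair set, the patient-specific network is
$e_{ij}(q) = N\,e_{ij}(all) - (N-1)\,e_{ij}(-q)$. The pair set is *not*
re-selected per leave-one-out subset: freezing it keeps $e(q)$ comparable
across patients and matches module scoring over a fixed edge set. The
identity is exact for linear (per-sample-mean) statistics, which the test
suite exploits as an oracle.

**4. Modules and subtype readout.** Communities of the retained weighted
graph (greedy modularity; negative weights floored at zero for clustering
only) are ordered by size and labeled `module_0, module_1, ...`. Module
scores are plain means of individualized intra-module edges,
$m_k(q) = |E_k|^{-1} \sum_{(i,j)\in E_k} e_{ij}(q)$, and the subtype
readout is the penalized logistic model
$\hat p_{basal}(q) = \sigma(\beta_0 + \sum_k \beta_k m_k(q))$ with
stratified cross-validated out-of-fold probabilities pooled into one AUC.
Raw per-module discrimination is the midrank AUC of $m_k$ itself; the
direction identity $AUC_{basal} = 1 - AUC_{classical}$ is exact under
midranks. Optionally, a morphology gate $g(q) = \sigma(\theta^\top
\tilde f(q))$ — an L2-penalized logistic fit of the subtype on
standardized patient-level image embeddings, trained only on the other CV
folds of the sample being gated — multiplies the module score,
$m_k'(q) = m_k(q)\,g(q)$. Morphology never becomes a node.

**5. Validation.** Subtype labels are permuted $S = 100$ times for
$Z_{metric} = (x_{real} - \mu_{shuffle})/\sigma_{shuffle}$ and the
empirical p-value $p_{emp} = (1 + \#\{x_{shuffle} \ge x_{real}\})/(1+S)$;
edge stability is the pairwise Jaccard overlap of top-$K$ edge sets over
50 seeded 80% subsamples; and the mixing coefficients are swept over the
$5 \times 5 \times 5$ grid $a \in 0.5{:}1.5$, $b, \gamma \in 0{:}1$
(step 0.25).

# Key parameters

| parameter | default | meaning |
|---|---|---|
| `minAbsCorr` | 0.5 | floor on the RNA association before mixing |
| `tau` | 0.5 | threshold on $w^{INT}$ |
| `topKGlobal` / `topKPlot` | 5000 / 500 | retained / plotted edges |
| `minSamples` | 5 | non-missing samples required per gene |
| mix $(a, b, \gamma)$ | (1.0, 0.5, 0.5) | RT/RNA mixing coefficients |
| `windowSize` / `domainSpan` | 200 kb / 300 kb | RT window and domain scales |
| `smoothWidth` | 3 | rolling-mean width (odd), truncated at chromosome ends |
| `shuffles` / `nBoot` / `bootFrac` / `stabilityTopK` | 100 / 50 / 0.8 / 10000 | validation settings |
| `cvFolds` / `penalty` | 5 / 0.01 | subtype readout settings |
| `seed` | 1337 | global seed |

# The synthetic cohort and what it plants

`syntheticConfig()` defines the package's reference study conditions: 120
patients at the 60/40 basal/classical balance observed in the cohort the
pipeline is modeled on, 50 genes — the size of the standard subtyping
signature — organized as three 15-gene modules plus background genes, a
two-chromosome toy genome of 100 windows with a planted late-replicating
fraction of 0.3 placed as terminal blocks (late windows draw beta around
0.80, early around 0.30), and 1300-dimensional morphology embeddings whose
first direction separates subtypes.

**Why a mean shift alone is not the planted signal.** Individualized
Pearson edges behave like products of pooled-standardized expression
values. Under a pure between-subtype mean shift both classes deviate from
the pooled mean (by $(1-p)\Delta$ and $-p\Delta$), so both produce
*positive* products and the mean intra-module edge barely discriminates —
simulation puts its AUC near 0.55. The discriminative quantity for a
single-sample network is *co-activation*: how coherently a sample expresses
the program. `subtypeEffectSize` therefore drives two planted features at
once: the mean shift of each program ($\pm e/2$ by subtype) and a
subtype-specific program coherence. Each program gene loads on its program
factor with correlation $\rho_{own}$ in the program's own subtype and
$\rho_{other}$ in the opposite subtype, with own/other ratio
$(1 + \kappa e)/(1 - \kappa e)$, $\kappa = 0.8$. At $e = 1$ the basal
program is coherent in basal tumours ($\rho_{own} \approx 0.96$) and
largely decohered in classical ones ($\rho_{other} \approx 0.11$); at
$e = 0$ both collapse to the same value and no signal remains.

**Calibration.** The pooled within-module covariance decomposes as
$c_1 + w_{own}\rho_{own} + (1 - w_{own})\rho_{other} + B$ with
$B = p(1-p)e^2$ the between-subtype component, $c_1$ a shared program-axis
loading, and $w_{own}$ the prevalence of the program's own subtype ($p$
for the basal program, $1-p$ for the classical one). The generator solves
this per program so the pooled Pearson equals `withinModuleCorr` exactly
(preserving the pooled value when the own-side correlation hits its 0.97
cap). The between-program correlation (`betweenProgramCorr`, default
−0.2) arises mostly from the reciprocal shifts themselves; a stronger
explicit cross-loading would dilute the subtype-specific factors, which is
why the default is modest. Latent values are mapped to positive
expression as $\exp(\log 100 + 0.05\,Z)$ — near-linear, so planted Pearson
structure survives to within a few thousandths.

**What the generator does not emulate:** probe-level heteroscedasticity
and array batch structure, copy-number or purity effects on methylation,
genome-scale chromosome counts, biologically realistic module size
diversity, and any coupling between methylation and *expression* beyond
gene placement in early/late domains. Passing the planted-recovery tests
therefore demonstrates that the machinery recovers the structure it is
pointed at — not that real cohorts carry signals this clean.

# Numerical conventions and degenerate inputs

* **Population denominators** everywhere a z-score or a shuffle sd is
  taken; deterministic and exact on small fixed examples (a two-point
  z-score is $\pm 1$).
* **Lateness sign:** high methylation ⇒ late replication ⇒ *low* RT proxy;
  the late indicator is $RT_w < 0$ by default, with `lateSign` exposing the
  opposite convention, which some formulations print.
* **Zero-variance cases:** constant promoter rows get z = 0 and state
  `baseline`; a zero-variance smoothed track yields a degenerate RT of 0
  with a warning; constant RT profiles correlate as 0 with a warning; an
  all-equal RT vector makes every similarity 1; missing $RT_D$ pairs take
  the neutral similarity 0.5 ($\tilde s = 0$).
* **Smoothing edges** are truncated (shorter windows at chromosome ends);
  chromosomes are never mixed; a missing window median stays missing and is
  excluded from every length-weighted sum.
* **Partial correlations** add a ridge $10^{-4}\,\mathrm{tr}(\Sigma)/p$
  before inversion whenever genes reach or exceed samples (or plain
  inversion fails); the error message reports the reciprocal condition
  estimate when even that is singular.
* **Tie-breaks:** edge selection orders by decreasing $w^{INT}$, then
  lexicographically by gene pair; module labels order by size then first
  gene id. All selection is reproducible under a fixed seed and input
  order.
* **Empty networks** (nothing passes the floor or $\tau$, e.g. a
  timing-only run on a cohort with no usable timing variation) are
  reported as a structured `empty_network` run with `NA` metrics rather
  than an error.

# Design choices where the design was open

* **Module detection.** No specific community algorithm is canonical for
  this readout; greedy modularity (`igraph::cluster_fast_greedy`) was
  chosen for determinism and zero extra hyperparameters, with Louvain
  behind a switch. Singleton communities are pooled and excluded from
  scoring.
* **Morphology gating.** "Weighting module activation" is implemented as
  the smallest mechanism that does so without creating morphology nodes: a
  multiplicative sigmoid gate from a single shared embedding model,
  applied out-of-fold to avoid leakage. `morphGate = "off"` restores the
  identity gate.
* **Normalization order.** The z-scoring of RNA associations is computed
  *after* the $|w^{RNA}|$ floor, on the surviving pairs.
* **Window z-scoring scope** is genome-wide per sample (all chromosomes
  pooled), keeping RT comparable across chromosomes.
* **Window vs domain scale.** Both a 200 kb window grid and a 300 kb
  domain span are retained as two distinct scales.
* **Readout fit.** The module-score logistic readout is a compact IRLS
  ridge fit (an unpenalized intercept, a weak penalty so separation stays
  finite); the high-dimensional morphology gate uses `glmnet` ridge.

# Problem sizes used by the tests and acceptance script

The bundled checks run the full pipeline at the reference conditions
(n = 120, 50 genes, 100 windows) for planted recovery, and a reduced
cohort (n = 40–60, 24 genes) for the permutation-null calibration (20
repeats at S = 50) and the 125-cell grid sweep; exact identities (the
LIONESS linear-statistic inversion, the residual-regression partial
correlation oracle) use 20–100 random micro-instances. These sizes are the
package's reference experiment sizes; all scale linearly if enlarged.

# Limitations

Partial-correlation networks are built at the cohort level only (the
individualized stage uses the same machinery but a per-patient precision
matrix is not separately validated); the RT proxy is a methylation
surrogate, not measured replication timing, and inherits promoter-array
coverage; module discovery happens once on the global network, so patient
networks share a module definition; and the morphology gate weights
existing RNA modules rather than discovering morphology-specific ones.
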