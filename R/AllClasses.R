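#' @import methods
#' @importFrom S4Vectors DataFrame metadata
#' @importFrom GenomicRanges GRanges seqnames start end width
#' @importFrom IRanges IRanges
#' @importClassesFrom GenomicRanges GRanges
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay
#' @importFrom stats cor cov median rnorm setNames predict sd complete.cases
#' @importFrom utils head combn read.csv write.csv write.table
NULL

# ---------------------------------------------------------------------------
# Configuration objects
# ---------------------------------------------------------------------------

#' Mixing and edge-selection configuration
#'
#' Holds every parameter of the global-network stage: the mixing coefficients
#' of the integrated edge weight `w_int = a * w_rna + b * s_rt_signed +
#' gamma * norm(w_rna)`, the edge threshold `tau`, the top-K budgets, and the
#' correlation floor applied to the RNA association before mixing.
#'
#' @slot alpha weight `a` on the RNA association.
#' @slot betaMix weight `b` on the signed replication-timing similarity.
#' @slot gamma weight on the z-scored RNA association.
#' @slot tau edge threshold applied to `w_int`.
#' @slot topKGlobal number of edges retained in the global network.
#' @slot topKPlot size of the plotting subset (top of the retained set).
#' @slot minSamples minimum non-missing samples per gene.
#' @slot minAbsCorr absolute floor on the RNA association before mixing.
#' @slot usePartial use partial correlations (precision-matrix based) as the
#'   RNA association instead of Pearson.
#' @slot seed integer seed threaded through stochastic downstream stages.
#' @export
setClass("MixConfig", representation(
  alpha = "numeric", betaMix = "numeric", gamma = "numeric", tau = "numeric",
  topKGlobal = "integer", topKPlot = "integer", minSamples = "integer",
  minAbsCorr = "numeric", usePartial = "logical", seed = "integer"
))

setValidity("MixConfig", function(object) {
  msg <- character()
  if (object@topKPlot > object@topKGlobal) msg <- c(msg, "topKPlot must be <= topKGlobal")
  if (object@minSamples < 3L) msg <- c(msg, "minSamples must be >= 3")
  if (object@minAbsCorr < 0) msg <- c(msg, "minAbsCorr must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct a MixConfig
#'
#' Defaults follow the study's parameter table: correlation floor 0.5,
#' global top-K 5000, plot top-K 500, minimum of 5 non-missing samples,
#' seed 1337 and replication-timing/RNA mix (1.0, 0.5, 0.5).
#'
#' @param alpha,betaMix,gamma mixing coefficients `a`, `b`, `gamma`.
#' @param tau threshold on the integrated weight.
#' @param topKGlobal,topKPlot edge budgets for the network and its plot subset.
#' @param minSamples minimum non-missing samples per gene.
#' @param minAbsCorr absolute correlation floor on the RNA association.
#' @param usePartial logical; use partial instead of Pearson correlation.
#' @param seed integer seed.
#' @return a [MixConfig-class] object.
#' @examples
#' mixConfig(alpha = 1, betaMix = 0, gamma = 0)
#' @export
mixConfig <- function(alpha = 1.0, betaMix = 0.5, gamma = 0.5, tau = 0.5,
                      topKGlobal = 5000L, topKPlot = 500L, minSamples = 5L,
                      minAbsCorr = 0.5, usePartial = FALSE, seed = 1337L) {
  new("MixConfig", alpha = alpha, betaMix = betaMix, gamma = gamma, tau = tau,
      topKGlobal = as.integer(topKGlobal), topKPlot = as.integer(topKPlot),
      minSamples = as.integer(minSamples), minAbsCorr = minAbsCorr,
      usePartial = usePartial, seed = as.integer(seed))
}

#' Synthetic-cohort configuration
#'
#' Parameters of the built-in cohort generator. The defaults define the
#' package's reference study conditions: 120 patients at the cohort's 60/40
#' basal/classical balance, 50 genes in three 15-gene programs (the basal and
#' classical programs mutually anticorrelated), a planted late-replicating
#' fraction of 0.3, and 1300-dimensional morphology embeddings.
#'
#' @slot nSamples,nGenes,nModules,genesPerModule cohort dimensions.
#' @slot withinModuleCorr target pooled Pearson correlation within a module.
#' @slot betweenProgramCorr target correlation between the basal and classical
#'   programs (negative).
#' @slot basalFraction proportion of basal samples in (0, 1).
#' @slot subtypeEffectSize standardized subtype signal: the mean shift of
#'   program expression between subtypes, and equally the strength of the
#'   subtype-specific co-activation of each program (see the vignette).
#' @slot probesPerPromoter promoter probes emitted per gene.
#' @slot betaNoiseSD standard deviation of per-probe beta noise.
#' @slot lateFractionPlanted fraction of genome windows assigned late replication.
#' @slot embeddingDim,embeddingEffectSize morphology embedding dimension and
#'   the standardized subtype separation along its first direction.
#' @slot seed integer seed; equal seeds give byte-identical cohorts.
#' @export
setClass("SyntheticConfig", representation(
  nSamples = "integer", nGenes = "integer", nModules = "integer",
  genesPerModule = "integer", withinModuleCorr = "numeric",
  betweenProgramCorr = "numeric", basalFraction = "numeric",
  subtypeEffectSize = "numeric", probesPerPromoter = "integer",
  betaNoiseSD = "numeric", lateFractionPlanted = "numeric",
  embeddingDim = "integer", embeddingEffectSize = "numeric", seed = "integer"
))

setValidity("SyntheticConfig", function(object) {
  msg <- character()
  nb <- object@nSamples - floor((1 - object@basalFraction) * object@nSamples)
  if (object@basalFraction <= 0 || object@basalFraction >= 1)
    msg <- c(msg, "basalFraction must lie in (0, 1)")
  else if (nb < 2L || (object@nSamples - nb) < 2L)
    msg <- c(msg, "each subtype needs at least 2 samples")
  if (object@withinModuleCorr < 0 || object@withinModuleCorr > 1)
    msg <- c(msg, "withinModuleCorr must lie in [0, 1]")
  if (object@betweenProgramCorr > 0 || object@betweenProgramCorr < -1)
    msg <- c(msg, "betweenProgramCorr must lie in [-1, 0]")
  if (object@lateFractionPlanted < 0 || object@lateFractionPlanted > 1)
    msg <- c(msg, "lateFractionPlanted must lie in [0, 1]")
  if (object@nModules * object@genesPerModule > object@nGenes)
    msg <- c(msg, "nModules * genesPerModule must be <= nGenes")
  if (object@nModules < 2L) msg <- c(msg, "need at least 2 modules (the two programs)")
  if (length(msg)) msg else TRUE
})

#' Construct a SyntheticConfig
#'
#' @param nSamples,nGenes,nModules,genesPerModule cohort dimensions.
#' @param withinModuleCorr,betweenProgramCorr planted correlation structure.
#' @param basalFraction proportion of basal samples.
#' @param subtypeEffectSize standardized subtype signal (see
#'   [SyntheticConfig-class]).
#' @param probesPerPromoter,betaNoiseSD,lateFractionPlanted methylation layer.
#' @param embeddingDim,embeddingEffectSize morphology layer.
#' @param seed integer seed.
#' @return a [SyntheticConfig-class] object.
#' @export
syntheticConfig <- function(nSamples = 120L, nGenes = 50L, nModules = 3L,
                            genesPerModule = 15L, withinModuleCorr = 0.7,
                            betweenProgramCorr = -0.2, basalFraction = 0.6,
                            subtypeEffectSize = 1.0, probesPerPromoter = 3L,
                            betaNoiseSD = 0.05, lateFractionPlanted = 0.3,
                            embeddingDim = 1300L, embeddingEffectSize = 1.0,
                            seed = 1337L) {
  new("SyntheticConfig", nSamples = as.integer(nSamples),
      nGenes = as.integer(nGenes), nModules = as.integer(nModules),
      genesPerModule = as.integer(genesPerModule),
      withinModuleCorr = withinModuleCorr,
      betweenProgramCorr = betweenProgramCorr, basalFraction = basalFraction,
      subtypeEffectSize = subtypeEffectSize,
      probesPerPromoter = as.integer(probesPerPromoter),
      betaNoiseSD = betaNoiseSD, lateFractionPlanted = lateFractionPlanted,
      embeddingDim = as.integer(embeddingDim),
      embeddingEffectSize = embeddingEffectSize, seed = as.integer(seed))
}

#' Grid-search specification
#'
#' Inclusive ranges with step for the mixing coefficients `a`, `b`, `gamma`.
#' The defaults (`0.5:1.5` by 0.25, `0:1` by 0.25, `0:1` by 0.25) span
#' 5 x 5 x 5 = 125 cells.
#'
#' @slot aRange,bRange,gRange numeric triplets `c(from, to, by)`.
#' @export
setClass("GridSpec", representation(
  aRange = "numeric", bRange = "numeric", gRange = "numeric"
))

setValidity("GridSpec", function(object) {
  ok <- function(r) length(r) == 3L && r[3] > 0 && r[2] >= r[1]
  if (!ok(object@aRange) || !ok(object@bRange) || !ok(object@gRange))
    "each range must be c(from, to, by) with by > 0 and to >= from" else TRUE
})

#' @rdname GridSpec-class
#' @param aRange,bRange,gRange numeric `c(from, to, by)` triplets.
#' @return a [GridSpec-class] object.
#' @export
gridSpec <- function(aRange = c(0.5, 1.5, 0.25), bRange = c(0, 1, 0.25),
                     gRange = c(0, 1, 0.25)) {
  new("GridSpec", aRange = aRange, bRange = bRange, gRange = gRange)
}

# Expand a GridSpec into its Cartesian table (a fastest-varying last).
gridCells <- function(grid) {
  a <- seq(grid@aRange[1], grid@aRange[2], by = grid@aRange[3])
  b <- seq(grid@bRange[1], grid@bRange[2], by = grid@bRange[3])
  g <- seq(grid@gRange[1], grid@gRange[2], by = grid@gRange[3])
  expand.grid(gamma = g, b = b, a = a)[, c("a", "b", "gamma")]
}

#' Run configuration for the end-to-end pipeline
#'
#' Bundles the network mix, the grid spec, the replication-timing settings
#' and the validation/model settings. Every default equals the study's
#' parameter table where that table specifies it.
#'
#' @slot mix a [MixConfig-class].
#' @slot grid a [GridSpec-class].
#' @slot windowSize uniform genomic window length L in bp (default 200000).
#' @slot domainSpan replication-timing domain span in bp (default 300000).
#' @slot smoothWidth odd width of the rolling-mean smoother (default 3).
#' @slot lateSign `"negative"` (late = rt < 0, the package default) or
#'   `"positive"` (the printed-formula convention).
#' @slot hypoThresh,hyperThresh z-score thresholds for methylation states.
#' @slot shuffles number of label permutations S (default 100).
#' @slot nBoot,bootFrac,stabilityTopK bootstrap stability settings
#'   (50, 0.8, 10000).
#' @slot cvFolds,penalty subtype model settings (stratified 5-fold CV, weak
#'   L2 penalty).
#' @slot morphGate `"sigmoid_mult"` or `"off"`.
#' @slot seed integer seed (default 1337).
#' @export
setClass("RunConfig", representation(
  mix = "MixConfig", grid = "GridSpec", windowSize = "integer",
  domainSpan = "integer", smoothWidth = "integer", lateSign = "character",
  hypoThresh = "numeric", hyperThresh = "numeric", shuffles = "integer",
  nBoot = "integer", bootFrac = "numeric", stabilityTopK = "integer",
  cvFolds = "integer", penalty = "numeric", morphGate = "character",
  seed = "integer"
))

setValidity("RunConfig", function(object) {
  msg <- character()
  if (!object@lateSign %in% c("negative", "positive"))
    msg <- c(msg, "lateSign must be 'negative' or 'positive'")
  if (!object@morphGate %in% c("sigmoid_mult", "off"))
    msg <- c(msg, "morphGate must be 'sigmoid_mult' or 'off'")
  if (object@hypoThresh >= object@hyperThresh)
    msg <- c(msg, "hypoThresh must be < hyperThresh")
  if (object@smoothWidth < 1L || object@smoothWidth %% 2L == 0L)
    msg <- c(msg, "smoothWidth must be odd and >= 1")
  if (object@domainSpan < object@windowSize)
    msg <- c(msg, "domainSpan must be >= windowSize")
  if (object@bootFrac <= 0 || object@bootFrac > 1)
    msg <- c(msg, "bootFrac must lie in (0, 1]")
  if (length(msg)) msg else TRUE
})

#' @rdname RunConfig-class
#' @param mix,grid,windowSize,domainSpan,smoothWidth,lateSign see slots.
#' @param hypoThresh,hyperThresh,shuffles,nBoot,bootFrac,stabilityTopK see slots.
#' @param cvFolds,penalty,morphGate,seed see slots.
#' @return a [RunConfig-class] object.
#' @export
runConfig <- function(mix = mixConfig(), grid = gridSpec(),
                      windowSize = 200000L, domainSpan = 300000L,
                      smoothWidth = 3L, lateSign = "negative",
                      hypoThresh = -1, hyperThresh = 1, shuffles = 100L,
                      nBoot = 50L, bootFrac = 0.8, stabilityTopK = 10000L,
                      cvFolds = 5L, penalty = 0.01, morphGate = "sigmoid_mult",
                      seed = 1337L) {
  new("RunConfig", mix = mix, grid = grid, windowSize = as.integer(windowSize),
      domainSpan = as.integer(domainSpan), smoothWidth = as.integer(smoothWidth),
      lateSign = lateSign, hypoThresh = hypoThresh, hyperThresh = hyperThresh,
      shuffles = as.integer(shuffles), nBoot = as.integer(nBoot),
      bootFrac = bootFrac, stabilityTopK = as.integer(stabilityTopK),
      cvFolds = as.integer(cvFolds), penalty = penalty, morphGate = morphGate,
      seed = as.integer(seed))
}

# ---------------------------------------------------------------------------
# Data containers
# ---------------------------------------------------------------------------

#' Promoter-level methylation container
#'
#' A [SummarizedExperiment::SummarizedExperiment] (genes x samples) with
#' assays `meanBeta` (mean promoter beta per gene), `zscore` (gene-wise
#' population z-scores across samples) and `state` (hypo/baseline/hyper).
#'
#' @export
setClass("PromoterMethylation", contains = "SummarizedExperiment")

#' Replication-timing window tracks for a cohort
#'
#' Per-sample genomic window tracks: median beta per window, the smoothed
#' track, and the replication-timing proxy `rt = -zscore(smoothed)`.
#' Coordinates are 0-based half-open (stored 1-based closed in the GRanges).
#'
#' @slot windows `GRanges` of the window grid.
#' @slot medianBeta,smoothed,rt matrices (windows x samples).
#' @slot sampleIds character vector of sample names.
#' @export
setClass("RTTrackSet", representation(
  windows = "GRanges", medianBeta = "matrix", smoothed = "matrix",
  rt = "matrix", sampleIds = "character"
))

setValidity("RTTrackSet", function(object) {
  n <- length(object@windows)
  m <- length(object@sampleIds)
  dims <- vapply(list(object@medianBeta, object@smoothed, object@rt),
                 function(x) all(dim(x) == c(n, m)), logical(1))
  if (!all(dims)) "matrix dimensions must be windows x samples" else TRUE
})

#' Replication-timing domains for a cohort
#'
#' Fixed-span groupings of contiguous windows with the length-weighted mean
#' replication-timing proxy `RT_D` per sample.
#'
#' @slot domains `GRanges` of domain spans.
#' @slot rt matrix (domains x samples) of `RT_D`; `NA` where every member
#'   window is missing.
#' @slot sampleIds character sample names.
#' @export
setClass("RTDomainSet", representation(
  domains = "GRanges", rt = "matrix", sampleIds = "character"
))

#' Gene-gene correlation container
#'
#' Pairwise Pearson correlations, the covariance, and (optionally) the
#' precision-matrix partial correlations `rho_ij = -Omega_ij /
#' sqrt(Omega_ii Omega_jj)` with `Omega = Sigma^-1`.
#'
#' @slot genes character gene ids (sorted).
#' @slot r Pearson correlation matrix.
#' @slot sigma covariance matrix.
#' @slot rho partial-correlation matrix (0 x 0 until computed).
#' @slot nSamples number of samples used.
#' @export
setClass("CorrelationSet", representation(
  genes = "character", r = "matrix", sigma = "matrix", rho = "matrix",
  nSamples = "integer"
))

setValidity("CorrelationSet", function(object) {
  p <- length(object@genes)
  msg <- character()
  if (!all(dim(object@r) == c(p, p))) msg <- c(msg, "r must be genes x genes")
  else {
    if (max(abs(object@r - t(object@r))) > 1e-8) msg <- c(msg, "r must be symmetric")
    if (p > 0 && max(abs(diag(object@r) - 1)) > 1e-8) msg <- c(msg, "diag(r) must be 1")
    if (p > 0 && (min(object@r) < -1 - 1e-8 || max(object@r) > 1 + 1e-8))
      msg <- c(msg, "r entries must lie in [-1, 1]")
  }
  if (length(msg)) msg else TRUE
})

#' Global integrated gene network
#'
#' The retained edge set after thresholding at `tau` and top-K selection,
#' with all edge ingredients kept per pair.
#'
#' @slot nodes character gene ids appearing in retained edges.
#' @slot edges data.frame with columns `gene_i`, `gene_j` (i < j
#'   lexicographically), `w_rna`, `s_rt`, `s_rt_signed`, `w_rna_norm`,
#'   `w_int`, ordered by decreasing `w_int`.
#' @slot mix the [MixConfig-class] used.
#' @slot plotEdges integer indices (into `edges`) of the plotting subset.
#' @export
setClass("GlobalNetwork", representation(
  nodes = "character", edges = "data.frame", mix = "MixConfig",
  plotEdges = "integer"
))

setValidity("GlobalNetwork", function(object) {
  e <- object@edges
  msg <- character()
  need <- c("gene_i", "gene_j", "w_rna", "s_rt", "s_rt_signed", "w_rna_norm", "w_int")
  if (!all(need %in% names(e))) msg <- c(msg, "edges missing required columns")
  else {
    if (nrow(e) > object@mix@topKGlobal) msg <- c(msg, "more edges than topKGlobal")
    if (nrow(e) && min(e$w_int) < object@mix@tau - 1e-12)
      msg <- c(msg, "all retained edges must satisfy w_int >= tau")
    if (nrow(e) && any(e$gene_i >= e$gene_j)) msg <- c(msg, "edges must have gene_i < gene_j")
  }
  if (length(msg)) msg else TRUE
})

#' Patient-specific (LIONESS) networks
#'
#' Per-sample edge vectors derived from a population edge function via
#' `e(q) = N * e(all) - (N - 1) * e(-q)` over a frozen pair set.
#'
#' @slot sampleIds character sample names (length N).
#' @slot edgeIndex data.frame with columns `gene_i`, `gene_j` shared by all
#'   vectors.
#' @slot eAll numeric vector: the edge function on all N samples.
#' @slot eMinus matrix (edges x samples) of leave-one-out values.
#' @slot eQ matrix (edges x samples) of individualized values.
#' @export
setClass("LionessSet", representation(
  sampleIds = "character", edgeIndex = "data.frame", eAll = "numeric",
  eMinus = "matrix", eQ = "matrix"
))

setValidity("LionessSet", function(object) {
  n <- length(object@sampleIds); m <- nrow(object@edgeIndex)
  msg <- character()
  if (length(object@eAll) != m) msg <- c(msg, "eAll length must match edgeIndex")
  if (!all(dim(object@eMinus) == c(m, n))) msg <- c(msg, "eMinus must be edges x samples")
  if (!all(dim(object@eQ) == c(m, n))) msg <- c(msg, "eQ must be edges x samples")
  ok <- is.finite(object@eQ) & is.finite(object@eMinus)
  if (any(ok)) {
    recon <- n * object@eAll - (n - 1) * object@eMinus
    if (max(abs(object@eQ - recon)[ok]) > 1e-9)
      msg <- c(msg, "eQ must equal N*eAll - (N-1)*eMinus to 1e-9")
  }
  if (length(msg)) msg else TRUE
})

#' Gene modules of a global network
#'
#' Disjoint gene communities with their intra-module edge sets.
#'
#' @slot modules named list (`module_0`, `module_1`, ...) of gene id vectors,
#'   ordered by decreasing size.
#' @slot edgeSets named list of data.frames (`gene_i`, `gene_j`) of
#'   intra-module edges of the source network.
#' @slot unassigned genes from singleton communities, excluded from scoring.
#' @export
setClass("ModuleSet", representation(
  modules = "list", edgeSets = "list", unassigned = "character"
))

setValidity("ModuleSet", function(object) {
  g <- unlist(object@modules, use.names = FALSE)
  msg <- character()
  if (anyDuplicated(g)) msg <- c(msg, "modules must be disjoint on genes")
  if (!identical(names(object@modules), names(object@edgeSets)))
    msg <- c(msg, "modules and edgeSets must share names")
  if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# show() methods
# ---------------------------------------------------------------------------

setMethod("show", "MixConfig", function(object) {
  cat("MixConfig: a =", object@alpha, " b =", object@betaMix,
      " gamma =", object@gamma, " tau =", object@tau, "\n",
      " topK =", object@topKGlobal, "(plot", object@topKPlot, ")",
      " |w_rna| >=", object@minAbsCorr,
      if (object@usePartial) " [partial corr]" else " [Pearson]", "\n")
})

setMethod("show", "SyntheticConfig", function(object) {
  cat("SyntheticConfig:", object@nSamples, "samples,", object@nGenes, "genes,",
      object@nModules, "modules x", object@genesPerModule, "genes\n",
      " basal fraction", object@basalFraction, "| effect size",
      object@subtypeEffectSize, "| planted late fraction",
      object@lateFractionPlanted, "| seed", object@seed, "\n")
})

setMethod("show", "RTTrackSet", function(object) {
  cat("RTTrackSet:", length(object@windows), "windows x",
      length(object@sampleIds), "samples on",
      length(unique(as.character(GenomicRanges::seqnames(object@windows)))),
      "chromosomes\n")
})

setMethod("show", "RTDomainSet", function(object) {
  cat("RTDomainSet:", length(object@domains), "domains x",
      length(object@sampleIds), "samples;",
      sum(!is.finite(object@rt)), "missing RT_D values\n")
})

setMethod("show", "CorrelationSet", function(object) {
  cat("CorrelationSet:", length(object@genes), "genes,",
      object@nSamples, "samples;",
      if (nrow(object@rho)) "partial correlations computed\n" else
        "partial correlations not computed\n")
})

setMethod("show", "GlobalNetwork", function(object) {
  cat("GlobalNetwork:", length(object@nodes), "nodes,", nrow(object@edges),
      "edges (tau =", object@mix@tau, ", K =", object@mix@topKGlobal, ")\n")
})

setMethod("show", "LionessSet", function(object) {
  cat("LionessSet:", nrow(object@edgeIndex), "edges x",
      length(object@sampleIds), "samples;",
      sum(!is.finite(object@eQ)), "missing individualized values\n")
})

setMethod("show", "ModuleSet", function(object) {
  sizes <- vapply(object@modules, length, integer(1))
  cat("ModuleSet:", length(sizes), "modules (sizes:",
      paste(sizes, collapse = ", "), ");", length(object@unassigned),
      "unassigned genes\n")
})
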