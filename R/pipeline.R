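# End-to-end orchestration: cohort I/O, named run conditions, artifact
# export and the evaluators used by the permutation null and grid search.

#' Read an expression matrix TSV
#'
#' Gene ids in the first column, sample ids in the header.
#'
#' @param path TSV path.
#' @return a genes x samples numeric matrix.
#' @export
readExpression <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  genes <- as.character(dt[[1L]])
  dup <- unique(genes[duplicated(genes)])
  if (length(dup)) stop("duplicate gene id(s): ", paste(dup, collapse = ", "))
  m <- as.matrix(dt[, -1L, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(!vapply(dt[-1L], is.numeric, logical(1)))[1L] + 1L
    stop("non-numeric expression values in column ", names(dt)[bad])
  }
  rownames(m) <- genes
  m
}

#' Read subtype labels
#'
#' CSV with columns `sample_id` and `subtype` (basal/classical, any case).
#'
#' @param path CSV path.
#' @return a named character vector (sample id -> "basal"/"classical").
#' @export
readLabels <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "subtype") %in% names(df)))
    stop("labels file needs columns sample_id, subtype")
  lab <- tolower(trimws(df$subtype))
  bad <- setdiff(unique(lab), c("basal", "classical"))
  if (length(bad)) stop("unknown subtype token(s): ", paste(bad, collapse = ", "))
  counts <- table(lab)
  message("labels: ", paste(names(counts), counts, sep = "=", collapse = ", "))
  stats::setNames(lab, df$sample_id)
}

#' Read morphology embeddings
#'
#' TSV with `sample_id` followed by the embedding dimensions.
#'
#' @param path TSV path.
#' @return a samples x dimensions numeric matrix with sample-id rownames.
#' @export
readEmbeddings <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  m <- as.matrix(dt[, -1L, drop = FALSE])
  rownames(m) <- as.character(dt[[1L]])
  m
}

#' Load a cohort directory
#'
#' Reads the layout written by [generateCohort()]: `manifest.csv`,
#' `expression.tsv`, `labels.csv`, optionally `embeddings.tsv`, and
#' per-sample methylation files under `methylation/` (parsed with automatic
#' column detection and aligned on the manifest).
#'
#' @param dir cohort directory.
#' @return a list with `expression`, `labels`, `manifest`, `beta`,
#'   `embeddings` (NULL when absent), `sampleIds`.
#' @export
readCohort <- function(dir) {
  need <- file.path(dir, c("manifest.csv", "expression.tsv", "labels.csv"))
  missing <- need[!file.exists(need)]
  if (length(missing))
    stop("cohort input(s) not found: ", paste(missing, collapse = ", "))
  manifest <- readManifest(need[1L])
  expression <- readExpression(need[2L])
  labels <- suppressMessages(readLabels(need[3L]))
  methDir <- file.path(dir, "methylation")
  beta <- NULL
  if (dir.exists(methDir)) {
    files <- sort(list.files(methDir, full.names = TRUE))
    names(files) <- sub("\\.[^.]*$", "", basename(files))
    beta <- betaMatrix(files, manifest)
  }
  embPath <- file.path(dir, "embeddings.tsv")
  emb <- if (file.exists(embPath)) readEmbeddings(embPath) else NULL
  list(expression = expression, labels = labels, manifest = manifest,
       beta = beta, embeddings = emb, sampleIds = colnames(expression))
}

#' In-memory cohort from a simulated data set
#'
#' Shapes the output of [simulateCohortData()] like [readCohort()], skipping
#' the file round-trip. Useful for simulation studies where the on-disk
#' dialects are not under test.
#'
#' @param dat a list from [simulateCohortData()].
#' @return a cohort list accepted by [runCondition()].
#' @export
asCohort <- function(dat) {
  list(expression = dat$expression, labels = dat$subtype,
       manifest = dat$manifest, beta = dat$beta, embeddings = dat$embeddings,
       sampleIds = dat$sampleIds, moduleTruth = dat$moduleTruth,
       genome = dat$genome)
}

# Condition-specific mix: RNA and MORPH_RNA force the pure-correlation mix;
# RT uses the same machinery over rank-based RT profile correlations;
# RT_RNA_PCORR switches the association to partial correlations.
.conditionMix <- function(condition, mix) {
  switch(condition,
    RNA = , MORPH_RNA = methods::initialize(mix, alpha = 1, betaMix = 0,
                                            gamma = 0, usePartial = FALSE),
    RT = methods::initialize(mix, alpha = 1, betaMix = 0, gamma = 0,
                             usePartial = FALSE),
    RT_RNA = methods::initialize(mix, usePartial = FALSE),
    RT_RNA_PCORR = methods::initialize(mix, usePartial = TRUE),
    stop("unknown condition: ", condition))
}

# Global-network construction for a condition; returns list(net, rtPart)
# with net = NULL when the network is empty. Shared by runCondition() and
# the bootstrap network builder.
.buildGlobalNetwork <- function(cohort, condition, config) {
  mix <- .conditionMix(condition, config@mix)
  rtPart <- if (condition %in% c("RT", "RT_RNA", "RT_RNA_PCORR")) {
    if (!is.null(cohort$rtCache)) {
      # per-sample RT tracks are independent, so column-subsetting the
      # cached gene x sample profile is exact for any sample subset
      rp <- cohort$rtCache
      rp$geneRT <- rp$geneRT[, cohort$sampleIds, drop = FALSE]
      rp
    } else .cohortGeneRT(cohort, config)
  } else NULL
  edges <- tryCatch({
    if (condition == "RT") {
      prof <- rtPart$geneRT
      keep <- apply(prof, 1L, function(v) {
        s <- popSD(v); sum(!is.na(v)) >= mix@minSamples && !is.na(s) && s > 0
      })
      if (sum(keep) < 2L) stop("empty network: no variable RT profiles")
      prof <- prof[keep, , drop = FALSE]
      prof <- prof[order(rownames(prof)), , drop = FALSE]
      rho <- rtProfileCorrelation(prof)
      cs <- new("CorrelationSet", genes = rownames(prof), r = rho,
                sigma = rho, rho = matrix(numeric(0), 0, 0),
                nSamples = ncol(prof))
      integrateEdges(cs, NULL, mix)
    } else {
      cs <- expressionCorrelations(cohort$expression, mix@minSamples)
      if (mix@usePartial) cs <- partialCorrelations(cs)
      sRT <- NULL
      if (!is.null(rtPart) && mix@betaMix != 0) {
        rtMean <- rowMeans(rtPart$geneRT, na.rm = TRUE)
        rtMean[is.nan(rtMean)] <- NA_real_
        full <- stats::setNames(rep(NA_real_, length(cs@genes)), cs@genes)
        full[intersect(names(rtMean), cs@genes)] <-
          rtMean[intersect(names(rtMean), cs@genes)]
        sRT <- rtSimilarity(full)
      }
      integrateEdges(cs, sRT, mix)
    }
  }, error = function(e) {
    if (grepl("empty network", conditionMessage(e))) NULL else stop(e)
  })
  net <- if (is.null(edges)) NULL else
    tryCatch(selectEdges(edges, mix), error = function(e) {
      if (grepl("empty network", conditionMessage(e))) NULL else stop(e)
    })
  list(net = net, rtPart = rtPart, mix = mix)
}

# Gene-level RT ingredients from a cohort (requires beta + manifest).
.cohortGeneRT <- function(cohort, config) {
  if (is.null(cohort$beta))
    stop("condition requires methylation input: no 'methylation/' directory ",
         "or beta matrix in the cohort")
  grid <- makeWindowGrid(cohort$manifest, config@windowSize)
  tracks <- rtTrackSet(cohort$beta, cohort$manifest, grid, config@smoothWidth)
  domains <- aggregateDomains(tracks, config@domainSpan)
  list(tracks = tracks, domains = domains,
       geneRT = geneRTProfile(domains, cohort$manifest,
                              rownames(cohort$expression)))
}

#' Run one named pipeline condition end to end
#'
#' Conditions: `RNA` (pure Pearson coexpression), `RT` (rank-based
#' correlation of replication-timing profiles), `RT_RNA` (integrated
#' weights), `RT_RNA_PCORR` (integrated, partial correlations), `MORPH_RNA`
#' (RNA plus morphology-gated module scores). Every condition runs:
#' association -> edge integration -> threshold/top-K -> LIONESS ->
#' modules -> module scores -> logistic subtype readout. An empty network
#' (nothing passes the correlation floor or `tau`) yields a structured
#' report with `status = "empty_network"` and `NA` metrics rather than an
#' error, mirroring timing-only runs on cohorts without usable timing
#' variation.
#'
#' @param cohort a cohort list from [readCohort()] (or the in-memory
#'   equivalent).
#' @param condition one of `"RNA"`, `"RT"`, `"RT_RNA"`, `"RT_RNA_PCORR"`,
#'   `"MORPH_RNA"`.
#' @param config a [RunConfig-class].
#' @param outDir optional directory; when given, every artifact table plus a
#'   JSON report and an md5 output manifest are written.
#' @return a `RunReport` list: `condition`, `status`, `network`, `lioness`,
#'   `modules`, `scores`, `fit`, `moduleAUC`, `metrics`, `rt` (tracks and
#'   domains when computed), `mix`.
#' @export
runCondition <- function(cohort, condition = c("RNA", "RT", "RT_RNA",
                                               "RT_RNA_PCORR", "MORPH_RNA"),
                         config = runConfig(), outDir = NULL) {
  condition <- match.arg(condition)
  mix <- .conditionMix(condition, config@mix)
  expr <- cohort$expression
  report <- list(condition = condition, status = "ok", mix = mix)
  class(report) <- "RunReport"

  if (condition == "MORPH_RNA" && is.null(cohort$embeddings))
    stop("condition MORPH_RNA requires embeddings (embeddings.tsv)")
  built <- .buildGlobalNetwork(cohort, condition, config)
  rtPart <- built$rtPart
  report$rt <- rtPart
  net <- built$net
  if (is.null(net)) {
    report$status <- "empty_network"
    report$metrics <- data.frame(n_nodes = NA, n_edges = 0L, density = NA,
                                 mean_degree = NA, transitivity = NA,
                                 components = NA, subtype_auc = NA)
    if (!is.null(outDir)) .writeRunArtifacts(report, outDir)
    return(report)
  }
  report$network <- net

  idx <- net@edges[, c("gene_i", "gene_j")]
  edgeFn <- if (condition == "RT")
    spearmanEdgeFunction(rtPart$geneRT, idx, mix@minSamples)
  else
    integratedEdgeFunction(expr, if (is.null(rtPart)) NULL else rtPart$geneRT,
                           mix, idx)
  lion <- lionessNetworks(edgeFn, cohort$sampleIds, idx)
  report$lioness <- lion

  mods <- detectModules(net, seed = config@seed)
  report$modules <- mods
  scores <- moduleScores(lion, mods)
  if (condition == "MORPH_RNA")
    scores <- morphModulate(scores, cohort$embeddings, cohort$labels,
                            cvFolds = config@cvFolds, seed = config@seed,
                            gate = config@morphGate)
  report$scores <- scores

  report$fit <- tryCatch(
    fitSubtype(scores, cohort$labels, cvFolds = config@cvFolds,
               seed = config@seed, penalty = config@penalty),
    error = function(e) { warning("subtype fit failed: ", conditionMessage(e)); NULL })
  report$moduleAUC <- perModuleAUC(scores, cohort$labels, mods)
  report$metrics <- cbind(topologyMetrics(net),
                          subtype_auc = if (is.null(report$fit)) NA_real_
                                        else report$fit$auc)
  if (!is.null(outDir)) .writeRunArtifacts(report, outDir)
  report
}

#' @export
print.RunReport <- function(x, ...) {
  cat("RunReport [", x$condition, "] status:", x$status, "\n")
  if (!is.null(x$metrics)) print(x$metrics, row.names = FALSE)
  invisible(x)
}

.writeRunArtifacts <- function(report, outDir) {
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  paths <- character(0)
  if (!is.null(report$network)) {
    paths["edges"] <- writeEdgeList(report$network, file.path(outDir, "edges.tsv"))
    paths["plot"] <- exportPlotSubgraph(report$network,
                                        file.path(outDir, "plot_subgraph.json"))
  }
  if (!is.null(report$modules)) {
    mm <- report$modules@modules
    df <- data.frame(module_id = rep(names(mm), lengths(mm)),
                     gene = unlist(mm, use.names = FALSE))
    p <- file.path(outDir, "modules.tsv")
    utils::write.table(df, p, sep = "\t", row.names = FALSE, quote = FALSE)
    paths["modules"] <- p
  }
  if (!is.null(report$scores)) {
    p <- file.path(outDir, "module_scores.tsv")
    utils::write.table(data.frame(sample_id = rownames(report$scores),
                                  report$scores, check.names = FALSE),
                       p, sep = "\t", row.names = FALSE, quote = FALSE)
    paths["scores"] <- p
  }
  if (!is.null(report$moduleAUC)) {
    p <- file.path(outDir, "module_auc.csv")
    utils::write.csv(report$moduleAUC, p, row.names = FALSE, quote = FALSE)
    paths["module_auc"] <- p
  }
  if (!is.null(report$lioness))
    paths <- c(paths, writeLioness(report$lioness, outDir))
  p <- file.path(outDir, "topology.csv")
  utils::write.csv(report$metrics, p, row.names = FALSE, quote = FALSE)
  paths["topology"] <- p
  if (!is.null(report$fit)) {
    p <- file.path(outDir, "model_coefficients.json")
    jsonlite::write_json(list(beta0 = report$fit$beta0,
                              betas = as.list(report$fit$betas),
                              positive = report$fit$positive),
                         p, auto_unbox = TRUE, digits = NA)
    paths["coefficients"] <- p
  }
  p <- file.path(outDir, "report.json")
  jsonlite::write_json(list(condition = report$condition,
                            status = report$status,
                            metrics = report$metrics,
                            mix = list(a = report$mix@alpha,
                                       b = report$mix@betaMix,
                                       gamma = report$mix@gamma,
                                       tau = report$mix@tau,
                                       top_k = report$mix@topKGlobal)),
                       p, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  paths["report"] <- p
  hashes <- tools::md5sum(unname(paths))
  utils::write.csv(data.frame(artifact = names(paths), path = basename(unname(paths)),
                              md5 = unname(hashes)),
                   file.path(outDir, "output_manifest.csv"), row.names = FALSE,
                   quote = FALSE)
  invisible(paths)
}

#' Precompute replication-timing ingredients for repeated runs
#'
#' Computes the RT tracks, domains and gene-level RT profiles once and
#' attaches them to the cohort, so that grid sweeps, bootstrap resampling
#' and repeated conditions reuse them (exact under sample subsetting, since
#' every per-sample track is computed independently).
#'
#' @param cohort a cohort list with methylation (`beta`) present.
#' @param config a [RunConfig-class].
#' @return the cohort with an `rtCache` element.
#' @export
precomputeRT <- function(cohort, config = runConfig()) {
  cohort$rtCache <- .cohortGeneRT(cohort, config)
  cohort
}

#' Metric evaluator for the grid search
#'
#' Returns a closure `function(a, b, gamma)` that reruns the integrated
#' condition with those mixing coefficients and reports the topology
#' metrics plus the cross-validated subtype AUC — the cell `(1, 0, 0)`
#' reproduces the RNA-only condition exactly.
#'
#' @param cohort a cohort list.
#' @param config a [RunConfig-class].
#' @return a function usable as the [gridSearch()] evaluator.
#' @export
gridEvaluator <- function(cohort, config = runConfig()) {
  if (is.null(cohort$rtCache) && !is.null(cohort$beta))
    cohort <- precomputeRT(cohort, config)
  force(config)
  function(a, b, gamma) {
    mix <- methods::initialize(config@mix, alpha = a, betaMix = b,
                               gamma = gamma, usePartial = FALSE)
    cfg <- methods::initialize(config, mix = mix)
    rep <- runCondition(cohort, "RT_RNA", cfg)
    m <- rep$metrics
    c(density = m$density, mean_degree = m$mean_degree,
      transitivity = m$transitivity, components = m$components,
      auc = m$subtype_auc)
  }
}

#' Label-permutation metric function for a fixed cohort
#'
#' Builds the network, LIONESS set and module scores once (they do not
#' depend on the labels) and returns a function mapping a label vector to
#' the tracked metrics: the cross-validated subtype AUC, the top raw module
#' AUC, and the (label-invariant) density and transitivity. Suitable as the
#' `pipelineFn` of [permutationNull()].
#'
#' @param cohort a cohort list.
#' @param condition pipeline condition (default `"RNA"`).
#' @param config a [RunConfig-class].
#' @return `function(labels) -> named numeric`.
#' @export
nullMetricsFunction <- function(cohort, condition = "RNA", config = runConfig()) {
  rep <- runCondition(cohort, condition, config)
  if (rep$status != "ok") stop("cannot build null metrics: ", rep$status)
  scores <- rep$scores
  topo <- rep$metrics
  function(labels) {
    fit <- fitSubtype(scores, labels, cvFolds = config@cvFolds,
                      seed = config@seed, penalty = config@penalty)
    pm <- perModuleAUC(scores, labels)
    c(auc = fit$auc, top_module_auc = max(pm$auc),
      density = topo$density, transitivity = topo$transitivity)
  }
}

#' Network builder for bootstrap stability
#'
#' Returns a closure mapping a sample subset to the ordered retained edge
#' keys of the condition's global network, for use with
#' [bootstrapStability()].
#'
#' @param cohort a cohort list.
#' @param condition pipeline condition (default `"RT_RNA"`).
#' @param config a [RunConfig-class].
#' @return `function(sampleIds) -> character` of edge keys.
#' @export
networkBuilder <- function(cohort, condition = "RT_RNA", config = runConfig()) {
  if (condition %in% c("RT", "RT_RNA", "RT_RNA_PCORR") &&
      is.null(cohort$rtCache) && !is.null(cohort$beta))
    cohort <- precomputeRT(cohort, config)
  force(config); force(condition)
  function(ids) {
    sub <- cohort
    sub$expression <- cohort$expression[, ids, drop = FALSE]
    if (!is.null(cohort$beta)) sub$beta <- cohort$beta[, ids, drop = FALSE]
    sub$labels <- cohort$labels[ids]
    sub$sampleIds <- ids
    built <- .buildGlobalNetwork(sub, condition, config)
    if (is.null(built$net)) return(character(0))
    e <- built$net@edges
    edgeKey(e$gene_i, e$gene_j)
  }
}
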