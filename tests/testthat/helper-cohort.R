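# Shared fixtures, all generated in code. The small cohort keeps the planted
# structure of the defaults at a size where a full pipeline run takes well
# under a second.

smallConfig <- function(...) {
  args <- list(nSamples = 40L, nGenes = 24L, nModules = 3L,
               genesPerModule = 6L, embeddingDim = 25L, seed = 11L)
  args[names(list(...))] <- list(...)
  do.call(syntheticConfig, args)
}

# memoised cohorts so independent tests do not regenerate them
.fixtures <- new.env()

smallCohort <- function() {
  if (is.null(.fixtures$small))
    .fixtures$small <- asCohort(simulateCohortData(smallConfig()))
  .fixtures$small
}

smallCohortRT <- function() {
  if (is.null(.fixtures$smallRT))
    .fixtures$smallRT <- precomputeRT(smallCohort(), runConfig())
  .fixtures$smallRT
}

# a tiny manifest for parser tests: 4 promoter probes over 2 genes
tinyManifest <- function() {
  data.frame(
    probe_id = c("cg1", "cg2", "cg3", "cg4"),
    gene = c("geneA", "geneA", "geneB", "geneA;geneB"),
    region_class = c("TSS200", "5UTR", "TSS1500", "First Exon"),
    chrom = "chr1",
    pos = c(100L, 300L, 500L, 700L),
    stringsAsFactors = FALSE)
}

writeLinesTo <- function(lines, name = "f.txt") {
  path <- file.path(withr::local_tempdir(.local_envir = parent.frame()), name)
  writeLines(lines, path)
  path
}

# independent brute-force oracle for partial correlations: correlation of
# residuals after regressing out every other variable
residualPartialCor <- function(X) {
  p <- ncol(X)
  rho <- diag(p)
  for (i in seq_len(p - 1)) for (j in (i + 1):p) {
    others <- setdiff(seq_len(p), c(i, j))
    ri <- if (length(others)) stats::resid(stats::lm(X[, i] ~ X[, others])) else X[, i]
    rj <- if (length(others)) stats::resid(stats::lm(X[, j] ~ X[, others])) else X[, j]
    rho[i, j] <- rho[j, i] <- stats::cor(ri, rj)
  }
  dimnames(rho) <- list(colnames(X), colnames(X))
  rho
}

# best Jaccard overlap of each detected module against planted truth
# (moduleTruth: named character vector gene -> module/background)
moduleRecoveryJaccard <- function(mods, moduleTruth) {
  truth <- split(names(moduleTruth), moduleTruth)
  truth <- truth[grepl("^module_", names(truth))]
  vapply(moduleList(mods), function(det) {
    max(vapply(truth, function(tg)
      length(intersect(det, tg)) / length(union(det, tg)), numeric(1)))
  }, numeric(1))
}
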