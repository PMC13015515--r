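# Methylation ingestion: heterogeneous beta-value files, probe manifest,
# promoter aggregation and methylation-state calls.

.PROMOTER_CLASSES <- c("TSS200", "TSS1500", "5UTR", "FIRSTEXON")

# Normalize probe-id strings: trim whitespace, strip quotes, keep case.
.normProbe <- function(x) gsub('^["\']+|["\']+$', "", trimws(as.character(x)))

# Canonical form of a region class: "First Exon" / "1stExon" / "5'UTR" ->
# FIRSTEXON / 5UTR etc.
.normRegion <- function(x) {
  x <- toupper(gsub("[ '_-]", "", as.character(x)))
  x[x == "1STEXON"] <- "FIRSTEXON"
  x
}

#' Read a probe manifest
#'
#' Expects columns `probe_id`, `gene` (possibly `;`-separated for probes
#' mapping to several genes), `region_class`, `chrom`, `pos` (0-based).
#'
#' @param path CSV file path.
#' @return a data.frame with normalized probe ids.
#' @export
readManifest <- function(path) {
  mf <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("probe_id", "gene", "region_class", "chrom", "pos")
  if (!all(need %in% names(mf)))
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  mf$probe_id <- .normProbe(mf$probe_id)
  mf$gene[is.na(mf$gene)] <- ""
  if (anyDuplicated(mf$probe_id)) stop("manifest probe ids must be unique")
  if (any(mf$pos < 0)) stop("manifest positions must be >= 0")
  mf
}

#' Parse a single beta-value file with automatic column detection
#'
#' Vendor methylation exports differ in separator, header presence and
#' column order; this parser identifies the probe-id column as the one whose
#' normalized values best match the manifest (requiring at least a 50% match
#' rate) and the beta column as the remaining column with the highest
#' fraction of numeric values. Non-numeric betas are dropped and values are
#' clipped to \[0, 1\].
#'
#' @param path file path.
#' @param manifest manifest data.frame from [readManifest()].
#' @return a named numeric vector (probe id -> beta).
#' @export
parseBetaFile <- function(path, manifest) {
  if (!file.exists(path)) stop("cannot read file: ", path)
  if (file.size(path) == 0L) stop("empty methylation file: ", path)
  dt <- data.table::fread(path, header = "auto", colClasses = "character",
                          data.table = FALSE, showProgress = FALSE)
  if (nrow(dt) == 0L || ncol(dt) < 2L)
    stop("need at least 2 detectable columns in ", path)
  probeSet <- manifest$probe_id
  matchRate <- vapply(dt, function(col)
    mean(.normProbe(col) %in% probeSet), numeric(1))
  if (max(matchRate) < 0.5)
    stop("format error: no column with >= 50% manifest-probe matches in ", path)
  probeCol <- which.max(matchRate)
  numRate <- vapply(seq_along(dt), function(j) {
    if (j == probeCol) return(-1)
    mean(!is.na(suppressWarnings(as.numeric(dt[[j]]))))
  }, numeric(1))
  betaCol <- which.max(numRate)
  probes <- .normProbe(dt[[probeCol]])
  betas <- suppressWarnings(as.numeric(dt[[betaCol]]))
  keep <- !is.na(betas) & nzchar(probes)
  betas <- pmin(pmax(betas[keep], 0), 1)
  stats::setNames(betas, probes[keep])
}

#' Assemble a beta matrix for a cohort
#'
#' Parses each file with [parseBetaFile()] and aligns values on the manifest
#' probe universe (probes absent from a file are `NA`).
#'
#' @param paths named character vector of file paths; names become sample
#'   ids (file basenames are used when unnamed).
#' @param manifest manifest data.frame.
#' @return a matrix (probes x samples) of betas in \[0, 1\].
#' @export
betaMatrix <- function(paths, manifest) {
  ids <- names(paths)
  if (is.null(ids)) ids <- sub("\\.[^.]*$", "", basename(paths))
  beta <- matrix(NA_real_, nrow(manifest), length(paths),
                 dimnames = list(manifest$probe_id, ids))
  for (i in seq_along(paths)) {
    v <- parseBetaFile(paths[i], manifest)
    hit <- intersect(names(v), manifest$probe_id)
    beta[hit, i] <- v[hit]
  }
  beta
}

# Expand the manifest to one row per (probe, gene) pair, promoter probes only.
.promoterMap <- function(manifest) {
  cls <- .normRegion(manifest$region_class)
  keep <- cls %in% .PROMOTER_CLASSES & nzchar(manifest$gene)
  mf <- manifest[keep, , drop = FALSE]
  if (nrow(mf) == 0L) return(data.frame(probe_id = character(), gene = character()))
  genes <- strsplit(mf$gene, ";", fixed = TRUE)
  data.frame(probe_id = rep(mf$probe_id, lengths(genes)),
             gene = trimws(unlist(genes)), stringsAsFactors = FALSE)
}

#' Aggregate promoter methylation per gene
#'
#' Averages beta values over each gene's promoter-class probes (TSS200,
#' TSS1500, 5'UTR, First Exon); probes annotated to several genes contribute
#' to every mapped gene. Gene-wise z-scores are then computed across samples
#' (population denominator; zero-variance genes get z = 0 and state
#' `baseline`) and summarized as hypo/baseline/hyper at fixed z thresholds.
#'
#' @param beta probes x samples matrix from [betaMatrix()].
#' @param manifest manifest data.frame.
#' @param hypoThresh,hyperThresh z-score thresholds (defaults -1, +1).
#' @return a [PromoterMethylation-class] with assays `meanBeta`, `zscore`,
#'   `state`.
#' @export
promoterAggregate <- function(beta, manifest, hypoThresh = -1, hyperThresh = 1) {
  map <- .promoterMap(manifest)
  map <- map[map$probe_id %in% rownames(beta), , drop = FALSE]
  if (nrow(map) == 0L) stop("no usable promoter probes found")
  vals <- beta[map$probe_id, , drop = FALSE]
  grp <- factor(map$gene)
  meanBeta <- rowsum(ifelse(is.na(vals), 0, vals), grp) /
    rowsum((!is.na(vals)) * 1, grp)
  meanBeta <- as.matrix(meanBeta)
  meanBeta[!is.finite(meanBeta)] <- NA_real_
  z <- t(apply(meanBeta, 1L, popZ))
  dimnames(z) <- dimnames(meanBeta)
  state <- callStates(z, hypoThresh, hyperThresh)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(meanBeta = meanBeta, zscore = z, state = state),
    rowData = S4Vectors::DataFrame(gene = rownames(meanBeta)))
  new("PromoterMethylation", se)
}

#' Call methylation states from z-scores
#'
#' `z <= hypoThresh` is `hypo`, `z >= hyperThresh` is `hyper`, anything else
#' (including `NA`-free zero-variance rows, which have z = 0) is `baseline`.
#'
#' @param z numeric matrix of gene-wise z-scores.
#' @param hypoThresh,hyperThresh thresholds with `hypoThresh < hyperThresh`.
#' @return a character matrix of the same shape.
#' @export
callStates <- function(z, hypoThresh = -1, hyperThresh = 1) {
  if (hypoThresh >= hyperThresh) stop("hypoThresh must be < hyperThresh")
  state <- matrix("baseline", nrow(z), ncol(z), dimnames = dimnames(z))
  state[z <= hypoThresh] <- "hypo"
  state[z >= hyperThresh] <- "hyper"
  state[is.na(z)] <- NA_character_
  state
}

#' Write long and wide promoter methylation tables
#'
#' @param pm a [PromoterMethylation-class].
#' @param dir output directory.
#' @return invisibly, the two file paths.
#' @export
writePromoterMatrices <- function(pm, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  mb <- SummarizedExperiment::assay(pm, "meanBeta")
  widePath <- file.path(dir, "promoter_methylation_wide.tsv")
  utils::write.table(data.frame(gene = rownames(mb), mb, check.names = FALSE),
                     widePath, sep = "\t", row.names = FALSE, quote = FALSE)
  long <- data.frame(sample_id = rep(colnames(mb), each = nrow(mb)),
                     gene = rep(rownames(mb), ncol(mb)),
                     mean_beta = as.vector(mb))
  longPath <- file.path(dir, "promoter_methylation_long.tsv")
  utils::write.table(long, longPath, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(c(wide = widePath, long = longPath))
}
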