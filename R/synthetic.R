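# Synthetic cohort with planted subtype structure.
#
# The generator emulates the four inputs of the pipeline (per-sample
# methylation files, a 450K-style probe manifest, an expression matrix,
# subtype labels, morphology embeddings) on a toy two-chromosome genome.
# Planted truth: module membership, per-sample subtype, late windows.

.TOY_CHROMS <- c("chr1", "chr2")
.TOY_WINDOWS_PER_CHROM <- 50L
.EARLY_BETA <- 0.30
.LATE_BETA <- 0.80
.EXPR_LOG_SCALE <- 0.05    # exp(log(100) + scale * Z): near-linear, positive
.COACTIVATION_KAPPA <- 0.8 # co-activation differential per unit effect size

#' Toy genome window grid
#'
#' Two chromosomes of 50 uniform windows each (window length `windowSize`,
#' 0-based half-open coordinates).
#'
#' @param windowSize window length L in bp.
#' @return a `GRanges` of windows.
#' @export
toyGenomeWindows <- function(windowSize = 200000L) {
  n <- .TOY_WINDOWS_PER_CHROM
  starts <- (seq_len(n) - 1L) * windowSize
  GenomicRanges::GRanges(
    rep(.TOY_CHROMS, each = n),
    IRanges::IRanges(start = rep(starts, length(.TOY_CHROMS)) + 1L,
                     width = windowSize))
}

#' Plant early/late replication structure on a window grid
#'
#' Assigns each window an early/late state so that late windows carry
#' systematically higher beta values (hypermethylation marks late
#' replication). Per chromosome, the number of late windows is
#' `round(lateFractionPlanted * n)` — exact on grids where the product is an
#' integer and within one window otherwise — placed as a contiguous terminal
#' block, mimicking a late-replicating domain.
#'
#' @param config a [SyntheticConfig-class].
#' @param genome a `GRanges` window grid with >= 10 windows per chromosome.
#' @return the `GRanges` with metadata columns `late` (logical) and
#'   `base_beta`.
#' @export
plantRTStructure <- function(config, genome) {
  stopifnot(is(config, "SyntheticConfig"), is(genome, "GRanges"))
  chrom <- as.character(GenomicRanges::seqnames(genome))
  counts <- table(chrom)
  if (any(counts < 10L)) stop("genome must have >= 10 windows per chromosome")
  late <- logical(length(genome))
  for (ch in names(counts)) {
    idx <- which(chrom == ch)
    idx <- idx[order(GenomicRanges::start(genome)[idx])]
    nLate <- round(config@lateFractionPlanted * length(idx))
    if (nLate > 0L) late[idx[(length(idx) - nLate + 1L):length(idx)]] <- TRUE
  }
  S4Vectors::mcols(genome)$late <- late
  S4Vectors::mcols(genome)$base_beta <- ifelse(late, .LATE_BETA, .EARLY_BETA)
  genome
}

# Latent expression model. subtype_effect_size e drives (i) the mean shift
# of the two programs (+/- e/2 by subtype) and (ii) a subtype-specific
# co-activation: the program factor correlation is rho0*(1 + kappa*e) in the
# program's own subtype and rho0*(1 - kappa*e) in the other. rho0 is
# calibrated analytically so the pooled within-module Pearson equals
# within_module_corr (see the vignette for the derivation).
.exprModelParams <- function(config) {
  p <- config@basalFraction
  e <- config@subtypeEffectSize
  rw <- config@withinModuleCorr
  kap <- .COACTIVATION_KAPPA
  B <- p * (1 - p) * e^2
  c1 <- max(0, abs(config@betweenProgramCorr) * (1 + B) - B)
  # pooled within-program covariance is c1 + wOwn*rho_own + (1-wOwn)*rho_other
  # + B; the own/other co-activation ratio is (1+kappa*e)/(1-kappa*e). Solve
  # per program (own-subtype weight p for the basal program, 1-p for the
  # classical one) so the pooled Pearson equals within_module_corr, keeping
  # the pooled value exact when the own-side correlation hits its cap.
  Fstar <- max(rw * (1 + B) - B - c1, 0)
  solveRho <- function(wOwn) {
    ke <- kap * e
    if (ke <= 0) {
      own <- other <- min(Fstar, 0.97)
    } else if (ke < 1) {
      R <- (1 + ke) / (1 - ke)
      other <- Fstar / (wOwn * R + (1 - wOwn))
      own <- R * other
    } else {
      own <- Inf; other <- 0
    }
    if (own > 0.97) {
      own <- 0.97
      other <- (Fstar - wOwn * own) / (1 - wOwn)
    }
    c(own = min(max(own, 0.005), 0.97), other = min(max(other, 0.005), 0.97))
  }
  r1 <- solveRho(p); r2 <- solveRho(1 - p)
  list(B = B, c1 = c1, kappa = kap,
       rhoOwn1 = r1[["own"]], rhoOther1 = r1[["other"]],
       rhoOwn2 = r2[["own"]], rhoOther2 = r2[["other"]])
}

#' Simulate a cohort in memory
#'
#' The in-memory core of the generator: expression with block-correlated
#' modules (module 1 the basal program, module 2 the anticorrelated classical
#' program), promoter-probe methylation over a planted early/late genome,
#' subtype labels, and subtype-correlated morphology embeddings.
#' [generateCohort()] serializes this object to the on-disk input formats.
#'
#' @param config a [SyntheticConfig-class].
#' @return a list with elements `sampleIds`, `subtype` (named character),
#'   `expression` (genes x samples), `manifest` (probe annotation
#'   data.frame), `beta` (probes x samples), `embeddings` (samples x dim),
#'   `genome` (window `GRanges` with planted `late`), `moduleTruth` (named
#'   character: `module_1`/`module_2`/... or `background`).
#' @export
simulateCohortData <- function(config) {
  stopifnot(is(config, "SyntheticConfig"))
  validObject(config)
  set.seed(config@seed)

  n <- config@nSamples
  nG <- config@nGenes
  gpm <- config@genesPerModule
  nMod <- config@nModules
  sampleIds <- sprintf("S%03d", seq_len(n))
  genes <- sprintf("gene%03d", seq_len(nG))

  ## --- subtype labels: floor the classical count, remainder to basal -----
  nBasal <- n - floor((1 - config@basalFraction) * n)
  basal <- logical(n)
  basal[sample.int(n, nBasal)] <- TRUE
  subtype <- ifelse(basal, "basal", "classical")
  names(subtype) <- sampleIds

  ## --- module truth ------------------------------------------------------
  moduleTruth <- rep("background", nG)
  for (m in seq_len(nMod))
    moduleTruth[((m - 1L) * gpm + 1L):(m * gpm)] <- sprintf("module_%d", m)
  names(moduleTruth) <- genes

  ## --- latent expression -------------------------------------------------
  par <- .exprModelParams(config)
  e <- config@subtypeEffectSize
  shift <- ifelse(basal, e / 2, -e / 2)
  P <- stats::rnorm(n)                       # shared program axis
  Fm <- matrix(stats::rnorm(n * nMod), n, nMod)
  Z <- matrix(stats::rnorm(n * nG), n, nG)   # residuals, overwritten below
  for (g in seq_len(nG)) {
    mt <- moduleTruth[g]
    if (mt == "module_1") {
      rho_s <- ifelse(basal, par$rhoOwn1, par$rhoOther1)
      resid <- sqrt(pmax(0.02, 1 - rho_s - par$c1))
      Z[, g] <- shift + sqrt(par$c1) * P + sqrt(rho_s) * Fm[, 1L] + resid * Z[, g]
    } else if (mt == "module_2") {
      rho_s <- ifelse(basal, par$rhoOther2, par$rhoOwn2)
      resid <- sqrt(pmax(0.02, 1 - rho_s - par$c1))
      Z[, g] <- -shift - sqrt(par$c1) * P + sqrt(rho_s) * Fm[, 2L] + resid * Z[, g]
    } else if (mt != "background") {
      m <- as.integer(sub("module_", "", mt))
      rho_s <- config@withinModuleCorr
      Z[, g] <- sqrt(rho_s) * Fm[, m] + sqrt(1 - rho_s) * Z[, g]
    }
  }
  expression <- t(exp(log(100) + .EXPR_LOG_SCALE * Z))
  dimnames(expression) <- list(genes, sampleIds)

  ## --- genome and methylation -------------------------------------------
  genome <- plantRTStructure(config, toyGenomeWindows())
  chrom <- as.character(GenomicRanges::seqnames(genome))
  wStart0 <- GenomicRanges::start(genome) - 1L
  late <- S4Vectors::mcols(genome)$late

  # gene placement: basal program in early chr1 windows, classical program in
  # late chr1+chr2 windows, remaining modules early chr2, background cycles
  # everywhere. Promoters sit mid-window.
  early1 <- which(chrom == "chr1" & !late)
  lateAll <- which(late)
  early2 <- which(chrom == "chr2" & !late)
  allWin <- seq_along(genome)
  geneWindow <- integer(nG)
  for (g in seq_len(nG)) {
    mt <- moduleTruth[g]
    k <- ((g - 1L) %% gpm) + 1L
    geneWindow[g] <- if (mt == "module_1") early1[(k - 1L) %% length(early1) + 1L]
      else if (mt == "module_2") lateAll[(k - 1L) %% length(lateAll) + 1L]
      else if (mt == "background") allWin[(g - 1L) %% length(allWin) + 1L]
      else early2[((g - 1L) %% length(early2)) + 1L]
  }
  tss <- wStart0[geneWindow] + 100000L

  promoterClasses <- c("TSS200", "TSS1500", "5UTR", "First Exon")
  promoterOffsets <- c(-150L, -900L, 300L, 80L, -1400L, 500L)
  nPP <- config@probesPerPromoter
  probeGene <- character(0); probeClass <- character(0)
  probeChrom <- character(0); probePos <- integer(0)
  for (g in seq_len(nG)) {
    off <- promoterOffsets[((seq_len(nPP) - 1L) %% length(promoterOffsets)) + 1L]
    cls <- promoterClasses[((g + seq_len(nPP) - 2L) %% 4L) + 1L]
    probeGene <- c(probeGene, rep(genes[g], nPP), genes[g])
    probeClass <- c(probeClass, cls, "Body")
    probeChrom <- c(probeChrom, rep(chrom[geneWindow[g]], nPP + 1L))
    probePos <- c(probePos, tss[g] + off, tss[g] + 5000L)
  }
  # 5% of promoter probes map to two genes of the same module (probe
  # expansion downstream assigns the value to both).
  isProm <- probeClass != "Body"
  promIdx <- which(isProm)
  multi <- promIdx[seq_along(promIdx) %% 20L == 0L]
  for (i in multi) {
    g <- probeGene[i]
    mt <- moduleTruth[g]
    mates <- setdiff(names(moduleTruth)[moduleTruth == mt], g)
    if (length(mates)) probeGene[i] <- paste(g, mates[1L], sep = ";")
  }
  # background probes: 3 per window so every window is covered
  bgOff <- c(50000L, 100000L, 150000L)
  bgChrom <- rep(chrom, each = length(bgOff))
  bgPos <- as.integer(rep(wStart0, each = length(bgOff)) + rep(bgOff, length(genome)))
  probeGene <- c(probeGene, rep("", length(bgPos)))
  probeClass <- c(probeClass, rep("Body", length(bgPos)))
  probeChrom <- c(probeChrom, bgChrom)
  probePos <- c(probePos, bgPos)

  manifest <- data.frame(
    probe_id = sprintf("cg%06d", seq_along(probeGene)),
    gene = probeGene, region_class = probeClass,
    chrom = probeChrom, pos = probePos, stringsAsFactors = FALSE)

  # betas: window base level + probe noise, clipped away from {0, 1}
  probeWindow <- integer(nrow(manifest))
  for (i in seq_len(nrow(manifest)))
    probeWindow[i] <- which(chrom == manifest$chrom[i] &
                              wStart0 <= manifest$pos[i] &
                              manifest$pos[i] < wStart0 + GenomicRanges::width(genome))[1L]
  base <- S4Vectors::mcols(genome)$base_beta[probeWindow]
  beta <- matrix(stats::rnorm(nrow(manifest) * n, mean = base,
                              sd = config@betaNoiseSD),
                 nrow(manifest), n)
  beta <- pmin(pmax(beta, 0.01), 0.99)
  dimnames(beta) <- list(manifest$probe_id, sampleIds)

  ## --- morphology embeddings --------------------------------------------
  emb <- matrix(stats::rnorm(n * config@embeddingDim), n, config@embeddingDim)
  emb[, 1L] <- emb[, 1L] + ifelse(basal, 1, -1) * config@embeddingEffectSize / 2
  dimnames(emb) <- list(sampleIds, sprintf("e%d", seq_len(config@embeddingDim)))

  list(sampleIds = sampleIds, subtype = subtype, expression = expression,
       manifest = manifest, beta = beta, embeddings = emb, genome = genome,
       moduleTruth = moduleTruth)
}

#' Generate a synthetic cohort on disk
#'
#' Writes the full input set the pipeline consumes: per-sample methylation
#' TXT files in two alternating dialects (comma-separated with a
#' `probe,beta` header for odd samples; tab-separated headerless for even
#' samples, exercising the automatic column detection), a probe manifest
#' CSV, an expression TSV, a labels CSV, an embeddings TSV, and a
#' `truth.json` with the planted ground truth. Generation is byte-identical
#' for equal configurations.
#'
#' @param config a [SyntheticConfig-class].
#' @param outDir output directory (created if missing).
#' @return invisibly, a `CohortManifest` list with elements `dir`, `files`
#'   (named paths) and `truth` (module membership, subtype labels, late
#'   windows).
#' @examples
#' cfg <- syntheticConfig(nSamples = 8, nGenes = 12, nModules = 2,
#'                        genesPerModule = 4, embeddingDim = 10)
#' cm <- generateCohort(cfg, file.path(tempdir(), "toy-cohort"))
#' names(cm$files)
#' @export
generateCohort <- function(config, outDir) {
  dat <- simulateCohortData(config)
  methDir <- file.path(outDir, "methylation")
  if (!dir.exists(methDir) && !dir.create(methDir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", outDir)

  fmt <- function(x) sprintf("%.6f", x)
  methFiles <- character(length(dat$sampleIds))
  for (i in seq_along(dat$sampleIds)) {
    sid <- dat$sampleIds[i]
    path <- file.path(methDir, paste0(sid, ".txt"))
    b <- dat$beta[, i]
    lines <- if (i %% 2L == 1L)
      c("probe,beta", paste(names(b), fmt(b), sep = ","))
    else
      paste(names(b), fmt(b), sep = "\t")
    writeLines(lines, path)
    methFiles[i] <- path
  }
  names(methFiles) <- dat$sampleIds

  manifestPath <- file.path(outDir, "manifest.csv")
  utils::write.csv(dat$manifest, manifestPath, row.names = FALSE, quote = FALSE)

  exprPath <- file.path(outDir, "expression.tsv")
  exprOut <- data.frame(gene = rownames(dat$expression),
                        apply(dat$expression, 2, fmt),
                        check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(exprOut, exprPath, sep = "\t", row.names = FALSE,
                     quote = FALSE)

  labelsPath <- file.path(outDir, "labels.csv")
  utils::write.csv(data.frame(sample_id = dat$sampleIds,
                              subtype = unname(dat$subtype)),
                   labelsPath, row.names = FALSE, quote = FALSE)

  embPath <- file.path(outDir, "embeddings.tsv")
  embOut <- data.frame(sample_id = dat$sampleIds,
                       apply(dat$embeddings, 2, function(x) sprintf("%.5f", x)),
                       check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(embOut, embPath, sep = "\t", row.names = FALSE,
                     quote = FALSE)

  lateDf <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(dat$genome)),
    start = GenomicRanges::start(dat$genome) - 1L,
    end = GenomicRanges::end(dat$genome),
    late = S4Vectors::mcols(dat$genome)$late)
  truth <- list(
    modules = split(names(dat$moduleTruth), dat$moduleTruth),
    subtype = as.list(dat$subtype),
    late_windows = lateDf,
    seed = config@seed)
  truthPath <- file.path(outDir, "truth.json")
  jsonlite::write_json(truth, truthPath, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)

  out <- list(dir = outDir,
              files = list(methylation = methFiles, manifest = manifestPath,
                           expression = exprPath, labels = labelsPath,
                           embeddings = embPath, truth = truthPath),
              truth = truth)
  class(out) <- "CohortManifest"
  invisible(out)
}
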