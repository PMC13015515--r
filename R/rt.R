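# Replication-timing proxy: windowed medians, smoothing, inversion/z-scoring,
# domain aggregation, per-sample summaries and gene-level RT profiles.

#' Build a uniform window grid covering the manifest coordinates
#'
#' One set of uniform windows of length `windowSize` per chromosome, from 0
#' to the smallest multiple of `windowSize` covering the largest probe
#' position (0-based half-open).
#'
#' @param manifest manifest data.frame with `chrom` and `pos`.
#' @param windowSize window length L in bp (default 200000).
#' @return a `GRanges` of windows.
#' @export
makeWindowGrid <- function(manifest, windowSize = 200000L) {
  windowSize <- as.integer(windowSize)
  chroms <- sort(unique(manifest$chrom))
  grl <- lapply(chroms, function(ch) {
    maxPos <- max(manifest$pos[manifest$chrom == ch])
    nWin <- ceiling((maxPos + 1) / windowSize)
    GenomicRanges::GRanges(ch, IRanges::IRanges(
      start = (seq_len(nWin) - 1L) * windowSize + 1L, width = windowSize))
  })
  suppressWarnings(do.call(c, grl))  # chromosomes have disjoint seqinfo
}

# Map probe coordinates onto windows; returns an integer window index per
# probe (NA when off-grid). Computed once per manifest+grid.
.probeToWindow <- function(manifest, grid) {
  pr <- GenomicRanges::GRanges(manifest$chrom,
                               IRanges::IRanges(start = manifest$pos + 1L, width = 1L))
  hit <- GenomicRanges::findOverlaps(pr, grid, select = "first")
  as.integer(hit)
}

#' Window medians and smoothing for one sample
#'
#' Per window, the median beta of contained probes (`NA` for empty windows,
#' which are excluded from all downstream sums); then a centered rolling
#' mean of the window medians within each chromosome (odd width, truncated
#' at chromosome ends, never mixing chromosomes).
#'
#' @param betaVec named numeric vector (probe id -> beta) for one sample.
#' @param manifest manifest data.frame with probe coordinates.
#' @param grid window `GRanges` from [makeWindowGrid()].
#' @param smoothWidth odd smoothing width (default 3).
#' @return the `GRanges` grid with metadata columns `median_beta` and
#'   `smoothed`.
#' @export
binAndSmooth <- function(betaVec, manifest, grid, smoothWidth = 3L) {
  idx <- match(.normProbe(names(betaVec)), manifest$probe_id)
  keep <- !is.na(idx)
  win <- .probeToWindow(manifest[idx[keep], , drop = FALSE], grid)
  med <- rep(NA_real_, length(grid))
  byWin <- split(betaVec[keep], win)
  med[as.integer(names(byWin))] <- vapply(byWin, stats::median, numeric(1),
                                          na.rm = TRUE)
  sm <- .smoothByChrom(med, as.character(GenomicRanges::seqnames(grid)),
                       smoothWidth)
  out <- grid
  S4Vectors::mcols(out)$median_beta <- med
  S4Vectors::mcols(out)$smoothed <- sm
  out
}

.smoothByChrom <- function(x, chrom, width) {
  out <- rep(NA_real_, length(x))
  for (ch in unique(chrom)) {
    i <- which(chrom == ch)
    if (all(is.na(x[i]))) {
      warning("all windows empty on ", ch, "; chromosome skipped")
      next
    }
    out[i] <- rollMeanTrunc(x[i], width)
  }
  out
}

#' Convert smoothed methylation to a replication-timing proxy
#'
#' `rt = -zscore(smoothed)` with the z-score taken genome-wide over all
#' non-missing windows of the sample (population denominator): higher
#' methylation maps to a lower RT proxy, i.e. later replication. If the
#' smoothed track has zero variance the RT proxy is degenerate and set to 0
#' everywhere with a warning.
#'
#' @param windows `GRanges` from [binAndSmooth()] with a `smoothed` column.
#' @return the `GRanges` with an added `rt` metadata column.
#' @export
methylationToRT <- function(windows) {
  sm <- S4Vectors::mcols(windows)$smoothed
  if (sum(!is.na(sm)) < 2L) stop("need >= 2 non-missing windows for z-scoring")
  s <- popSD(sm)
  if (is.na(s) || s == 0) {
    warning("zero variance across windows; degenerate RT set to 0")
    rt <- ifelse(is.na(sm), NA_real_, 0)
  } else {
    rt <- -(sm - mean(sm, na.rm = TRUE)) / s
  }
  S4Vectors::mcols(windows)$rt <- rt
  windows
}

#' Cohort-level replication-timing tracks
#'
#' Runs [binAndSmooth()] and [methylationToRT()] for every sample of a beta
#' matrix over a shared window grid.
#'
#' @param beta probes x samples matrix from [betaMatrix()].
#' @param manifest manifest data.frame.
#' @param grid window `GRanges`; defaults to [makeWindowGrid()] on the
#'   manifest.
#' @param smoothWidth odd smoothing width (default 3).
#' @return an [RTTrackSet-class].
#' @export
rtTrackSet <- function(beta, manifest, grid = NULL, smoothWidth = 3L) {
  if (is.null(grid)) grid <- makeWindowGrid(manifest)
  nW <- length(grid); nS <- ncol(beta)
  med <- sm <- rt <- matrix(NA_real_, nW, nS,
                            dimnames = list(NULL, colnames(beta)))
  chrom <- as.character(GenomicRanges::seqnames(grid))
  win <- .probeToWindow(manifest, grid)[match(rownames(beta), manifest$probe_id)]
  byWin <- split(seq_len(nrow(beta)), win)
  winIdx <- as.integer(names(byWin))
  for (s in seq_len(nS)) {
    v <- beta[, s]
    med[winIdx, s] <- vapply(byWin, function(ii) stats::median(v[ii], na.rm = TRUE),
                             numeric(1))
    sm[, s] <- .smoothByChrom(med[, s], chrom, smoothWidth)
    x <- sm[, s]
    sd_s <- popSD(x)
    rt[, s] <- if (is.na(sd_s) || sd_s == 0) {
      warning("zero variance for sample ", colnames(beta)[s], "; RT set to 0")
      ifelse(is.na(x), NA_real_, 0)
    } else -(x - mean(x, na.rm = TRUE)) / sd_s
  }
  med[is.nan(med)] <- NA_real_
  new("RTTrackSet", windows = grid, medianBeta = med, smoothed = sm, rt = rt,
      sampleIds = colnames(beta))
}

# Shared domain grouping: windows -> domain id by floor(start0 / span), per
# chromosome; returns list(domains = GRanges, member = list of window index
# vectors).
.domainGroups <- function(grid, domainSpan) {
  chrom <- as.character(GenomicRanges::seqnames(grid))
  start0 <- GenomicRanges::start(grid) - 1L
  bin <- floor(start0 / domainSpan)
  key <- paste(chrom, bin, sep = ":")
  member <- split(seq_along(grid), factor(key, levels = unique(key)))
  dchrom <- vapply(member, function(i) chrom[i[1L]], character(1))
  dstart <- vapply(member, function(i) min(start0[i]), numeric(1))
  dend <- vapply(member, function(i) max(GenomicRanges::end(grid)[i]), numeric(1))
  domains <- GenomicRanges::GRanges(dchrom,
                                    IRanges::IRanges(start = dstart + 1L, end = dend))
  list(domains = domains, member = member)
}

#' @rdname aggregateDomains
#' @export
setMethod("aggregateDomains", "RTTrackSet", function(x, domainSpan = 300000L, ...) {
  if (domainSpan < min(GenomicRanges::width(x@windows)))
    stop("domainSpan must be >= the window size")
  grp <- .domainGroups(x@windows, domainSpan)
  len <- GenomicRanges::width(x@windows)
  rtD <- matrix(NA_real_, length(grp$member), length(x@sampleIds),
                dimnames = list(NULL, x@sampleIds))
  for (d in seq_along(grp$member)) {
    i <- grp$member[[d]]
    w <- len[i]
    for (s in seq_along(x@sampleIds)) {
      v <- x@rt[i, s]
      ok <- !is.na(v)
      if (any(ok)) rtD[d, s] <- sum(w[ok] * v[ok]) / sum(w[ok])
    }
  }
  new("RTDomainSet", domains = grp$domains, rt = rtD, sampleIds = x@sampleIds)
})

#' @rdname aggregateDomains
#' @export
setMethod("aggregateDomains", "GRanges", function(x, domainSpan = 300000L, ...) {
  if (!"rt" %in% names(S4Vectors::mcols(x)))
    stop("windows need an 'rt' metadata column; run methylationToRT() first")
  if (domainSpan < min(GenomicRanges::width(x)))
    stop("domainSpan must be >= the window size")
  grp <- .domainGroups(x, domainSpan)
  len <- GenomicRanges::width(x)
  rt <- S4Vectors::mcols(x)$rt
  rtD <- vapply(grp$member, function(i) {
    v <- rt[i]; w <- len[i]; ok <- !is.na(v)
    if (!any(ok)) return(NA_real_)
    sum(w[ok] * v[ok]) / sum(w[ok])
  }, numeric(1))
  out <- grp$domains
  S4Vectors::mcols(out)$rt_domain <- unname(rtD)
  out
})

.summarizeRT <- function(rt, len, lateSign) {
  ok <- !is.na(rt)
  if (!any(ok)) return(c(rt_mean = NA_real_, frac_late = NA_real_))
  w <- len[ok]; v <- rt[ok]
  lateHit <- if (lateSign == "negative") v < 0 else v > 0
  c(rt_mean = sum(w * v) / sum(w), frac_late = sum(w * lateHit) / sum(w))
}

#' @rdname sampleSummary
#' @export
setMethod("sampleSummary", "RTTrackSet", function(x, lateSign = c("negative", "positive"), ...) {
  lateSign <- match.arg(lateSign)
  len <- GenomicRanges::width(x@windows)
  out <- t(vapply(seq_along(x@sampleIds),
                  function(s) .summarizeRT(x@rt[, s], len, lateSign),
                  numeric(2)))
  data.frame(sample_id = x@sampleIds, rt_mean = out[, 1], frac_late = out[, 2],
             stringsAsFactors = FALSE)
})

#' @rdname sampleSummary
#' @export
setMethod("sampleSummary", "GRanges", function(x, lateSign = c("negative", "positive"), ...) {
  lateSign <- match.arg(lateSign)
  if (!"rt" %in% names(S4Vectors::mcols(x)))
    stop("windows need an 'rt' metadata column")
  v <- .summarizeRT(S4Vectors::mcols(x)$rt, GenomicRanges::width(x), lateSign)
  data.frame(sample_id = NA_character_, rt_mean = v[1], frac_late = v[2],
             stringsAsFactors = FALSE)
})

#' Gene-level replication-timing profiles
#'
#' Assigns each gene, per sample, the `RT_D` of the domain containing the
#' gene's most 5' promoter-probe position. Genes without annotated promoter
#' coordinates are excluded with a warning; genes landing in all-missing
#' domains carry `NA`.
#'
#' @param domains an [RTDomainSet-class].
#' @param manifest manifest data.frame.
#' @param genes character vector of gene ids to profile.
#' @return a matrix (genes x samples) of `RT_D` values.
#' @export
geneRTProfile <- function(domains, manifest, genes) {
  map <- .promoterMap(manifest)
  map <- merge(map, manifest[, c("probe_id", "chrom", "pos")], by = "probe_id")
  anchors <- do.call(rbind, lapply(genes, function(g) {
    rows <- map[map$gene == g, , drop = FALSE]
    if (nrow(rows) == 0L) return(NULL)
    i <- which.min(rows$pos)
    data.frame(gene = g, chrom = rows$chrom[i], pos = rows$pos[i])
  }))
  missing <- setdiff(genes, anchors$gene)
  if (length(missing))
    warning("genes without promoter coordinates excluded: ",
            paste(missing, collapse = ", "))
  gr <- GenomicRanges::GRanges(anchors$chrom,
                               IRanges::IRanges(start = anchors$pos + 1L, width = 1L))
  hit <- GenomicRanges::findOverlaps(gr, domains@domains, select = "first")
  prof <- matrix(NA_real_, nrow(anchors), length(domains@sampleIds),
                 dimnames = list(anchors$gene, domains@sampleIds))
  ok <- !is.na(hit)
  prof[ok, ] <- domains@rt[hit[ok], , drop = FALSE]
  prof
}

#' Export one sample's RT track as bedGraph
#'
#' @param tracks an [RTTrackSet-class].
#' @param sample sample id.
#' @param path output path (`.bedGraph`).
#' @return invisibly, the path.
#' @export
exportRTTrack <- function(tracks, sample, path) {
  s <- match(sample, tracks@sampleIds)
  if (is.na(s)) stop("unknown sample: ", sample)
  gr <- tracks@windows
  S4Vectors::mcols(gr) <- NULL
  score <- tracks@rt[, s]
  keep <- !is.na(score)
  gr <- gr[keep]
  S4Vectors::mcols(gr)$score <- score[keep]
  GenomeInfoDb::seqlengths(gr) <- vapply(
    split(GenomicRanges::end(gr), as.character(GenomicRanges::seqnames(gr))),
    max, numeric(1))[GenomeInfoDb::seqlevels(gr)]
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}
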