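# Patient-specific networks via the LIONESS leave-one-out identity
#   e_ij(q) = N * e_ij(all) - (N - 1) * e_ij(-q)
# over a pair set frozen from the global network.

#' Individualized networks from any edge function
#'
#' Evaluates `edgeFn` once on all N samples and once per leave-one-out
#' subset, then forms the individualized vectors by the LIONESS identity.
#' The pair set (`edgeIndex`) is frozen: `edgeFn` is evaluated on that pair
#' set without per-subset re-selection, keeping `e(q)` comparable across
#' patients. A failure of `edgeFn` on a subset (e.g. zero variance after
#' removal) flags that sample's vector as missing and the run continues.
#'
#' @param edgeFn `function(sampleIds) -> numeric` returning one value per
#'   row of `edgeIndex`; must be deterministic for fixed input.
#' @param sampleIds character vector of N >= 3 sample ids.
#' @param edgeIndex data.frame with columns `gene_i`, `gene_j`.
#' @return a [LionessSet-class].
#' @examples
#' # the identity inverts a linear statistic exactly:
#' x <- matrix(rnorm(20), 2, 10, dimnames = list(c("a", "b"), paste0("s", 1:10)))
#' fn <- function(ids) mean(x["a", ids] * x["b", ids])
#' ls <- lionessNetworks(fn, colnames(x), data.frame(gene_i = "a", gene_j = "b"))
#' all.equal(drop(lionessMatrix(ls)), x["a", ] * x["b", ])
#' @export
lionessNetworks <- function(edgeFn, sampleIds, edgeIndex) {
  n <- length(sampleIds)
  if (n < 3L) stop("need N >= 3 samples")
  m <- nrow(edgeIndex)
  eAll <- edgeFn(sampleIds)
  if (length(eAll) != m) stop("edgeFn must return one value per edge")
  eMinus <- matrix(NA_real_, m, n, dimnames = list(NULL, sampleIds))
  for (q in seq_len(n)) {
    v <- tryCatch(edgeFn(sampleIds[-q]), error = function(e) {
      warning("edge function failed for leave-out of ", sampleIds[q], ": ",
              conditionMessage(e))
      rep(NA_real_, m)
    })
    eMinus[, q] <- v
  }
  eQ <- n * eAll - (n - 1) * eMinus
  new("LionessSet", sampleIds = sampleIds, edgeIndex = edgeIndex,
      eAll = as.numeric(eAll), eMinus = eMinus, eQ = eQ)
}

# --- edge-function factories ------------------------------------------------

# Pairwise Pearson on the frozen pair set; genes falling below minSamples
# non-missing values or zero variance yield NA edges.
.pairCor <- function(expr, gi, gj, minSamples, method = "pearson") {
  if (method == "pearson" && !anyNA(expr)) {
    # fast path: complete data, vectorized variance screen
    v <- rowMeans(expr * expr) - rowMeans(expr)^2
    ok <- ncol(expr) >= minSamples & v > 0
    cm <- suppressWarnings(stats::cor(t(expr)))
  } else {
    ok <- rowSums(!is.na(expr)) >= minSamples &
      apply(expr, 1L, function(v) { s <- popSD(v); !is.na(s) && s > 0 })
    cm <- suppressWarnings(stats::cor(t(expr), method = method,
                                      use = "pairwise.complete.obs"))
  }
  cm[!ok, ] <- NA_real_; cm[, !ok] <- NA_real_
  cm[cbind(match(gi, rownames(expr)), match(gj, rownames(expr)))]
}

#' Pearson edge function over a frozen pair set
#'
#' @param expr genes x samples expression matrix.
#' @param edgeIndex data.frame with `gene_i`, `gene_j`.
#' @param minSamples minimum non-missing samples per gene within a subset.
#' @return a `function(sampleIds)` usable with [lionessNetworks()].
#' @export
pearsonEdgeFunction <- function(expr, edgeIndex, minSamples = 5L) {
  gi <- edgeIndex$gene_i; gj <- edgeIndex$gene_j
  function(ids) .pairCor(expr[, ids, drop = FALSE], gi, gj, minSamples)
}

#' Spearman edge function over RT profiles
#'
#' Rank-transforms the per-sample RT values within the subset before the
#' Pearson step, matching the rank-based RT profile correlation of the
#' global stage.
#'
#' @param rtProfiles genes x samples RT matrix.
#' @param edgeIndex data.frame with `gene_i`, `gene_j`.
#' @param minSamples minimum non-missing samples per gene within a subset.
#' @return a `function(sampleIds)` usable with [lionessNetworks()].
#' @export
spearmanEdgeFunction <- function(rtProfiles, edgeIndex, minSamples = 5L) {
  gi <- edgeIndex$gene_i; gj <- edgeIndex$gene_j
  function(ids) .pairCor(rtProfiles[, ids, drop = FALSE], gi, gj, minSamples,
                         method = "spearman")
}

#' Integrated edge function over a frozen pair set
#'
#' Recomputes every ingredient of the integrated weight on the sample
#' subset: the RNA association (Pearson, or partial correlation when
#' `mix@usePartial`), the replication-timing similarity from the
#' subset-mean gene RT values, and the z-scored association over the frozen
#' pair set; then mixes them with the configured `(a, b, gamma)`. With
#' `b = gamma = 0` this reduces exactly to the Pearson edge function.
#'
#' @param expr genes x samples expression matrix.
#' @param geneRT genes x samples RT profile matrix, or `NULL` for neutral
#'   timing (similarity 0.5 everywhere).
#' @param mix a [MixConfig-class].
#' @param edgeIndex data.frame with `gene_i`, `gene_j`.
#' @return a `function(sampleIds)` usable with [lionessNetworks()].
#' @export
integratedEdgeFunction <- function(expr, geneRT, mix, edgeIndex) {
  gi <- edgeIndex$gene_i; gj <- edgeIndex$gene_j
  function(ids) {
    sub <- expr[, ids, drop = FALSE]
    wrna <- if (mix@usePartial) {
      cs <- expressionCorrelations(sub, minSamples = min(mix@minSamples, length(ids)))
      cs <- partialCorrelations(cs)
      cs@rho[cbind(match(gi, cs@genes), match(gj, cs@genes))]
    } else .pairCor(sub, gi, gj, mix@minSamples)
    s <- rep(0.5, length(wrna))
    if (!is.null(geneRT)) {
      rtMean <- rowMeans(geneRT[, ids, drop = FALSE], na.rm = TRUE)
      rtMean[is.nan(rtMean)] <- NA_real_
      if (sum(!is.na(rtMean)) >= 2L) {
        sm <- rtSimilarity(rtMean)
        s <- sm[cbind(match(gi, rownames(sm)), match(gj, colnames(sm)))]
        s[is.na(s)] <- 0.5
      }
    }
    norm <- if (mix@gamma != 0) popZ(wrna) else rep(0, length(wrna))
    norm[is.na(norm)] <- 0
    mix@alpha * wrna + mix@betaMix * (2 * s - 1) + mix@gamma * norm
  }
}

#' Write LIONESS edge vectors
#'
#' Wide (edges x samples) and long (edge, sample, value) TSVs plus a
#' per-sample missing-edge count CSV.
#'
#' @param lion a [LionessSet-class].
#' @param dir output directory.
#' @return invisibly, the three file paths.
#' @export
writeLioness <- function(lion, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  key <- edgeKey(lion@edgeIndex$gene_i, lion@edgeIndex$gene_j)
  widePath <- file.path(dir, "lioness_wide.tsv")
  utils::write.table(data.frame(edge = key, lion@eQ, check.names = FALSE),
                     widePath, sep = "\t", row.names = FALSE, quote = FALSE)
  long <- data.frame(edge = rep(key, length(lion@sampleIds)),
                     sample_id = rep(lion@sampleIds, each = length(key)),
                     e_q = as.vector(lion@eQ))
  longPath <- file.path(dir, "lioness_long.tsv")
  utils::write.table(long, longPath, sep = "\t", row.names = FALSE, quote = FALSE)
  missPath <- file.path(dir, "lioness_missing.csv")
  utils::write.csv(data.frame(sample_id = lion@sampleIds,
                              n_missing = colSums(!is.finite(lion@eQ))),
                   missPath, row.names = FALSE, quote = FALSE)
  invisible(c(wide = widePath, long = longPath, missing = missPath))
}
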