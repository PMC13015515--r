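# Gene modules, per-patient module scores, the logistic subtype readout and
# morphology-gated scoring.

#' Detect gene modules in the global network
#'
#' Greedy modularity (fast-greedy) community detection on the retained
#' weighted graph; negative integrated weights are floored at zero for the
#' clustering step only. Communities are ordered by decreasing size (ties
#' by first gene id) and labeled `module_0`, `module_1`, ... Singleton
#' communities are pooled into an unassigned set excluded from scoring.
#' Deterministic for a fixed network and seed.
#'
#' @param net a [GlobalNetwork-class].
#' @param seed integer seed (clustering is deterministic; the seed is set
#'   for reproducibility of any downstream randomized method).
#' @param method `"greedy"` (default) or `"louvain"`.
#' @return a [ModuleSet-class].
#' @export
detectModules <- function(net, seed = 1337L, method = c("greedy", "louvain")) {
  method <- match.arg(method)
  e <- net@edges
  if (nrow(e) == 0L) stop("network has no edges")
  g <- igraph::graph_from_data_frame(
    data.frame(from = e$gene_i, to = e$gene_j,
               weight = pmax(e$w_int, 0) + 1e-9),
    directed = FALSE, vertices = sort(net@nodes))
  set.seed(seed)
  comm <- if (method == "greedy") igraph::cluster_fast_greedy(g)
          else igraph::cluster_louvain(g)
  member <- split(igraph::V(g)$name, igraph::membership(comm))
  member <- lapply(member, sort)
  sizes <- vapply(member, length, integer(1))
  first <- vapply(member, `[`, character(1), 1L)
  member <- member[order(-sizes, first)]
  keep <- vapply(member, length, integer(1)) >= 2L
  unassigned <- as.character(sort(unlist(member[!keep], use.names = FALSE)))
  member <- member[keep]
  names(member) <- sprintf("module_%d", seq_along(member) - 1L)
  edgeSets <- lapply(member, function(genes) {
    sel <- e$gene_i %in% genes & e$gene_j %in% genes
    out <- e[sel, c("gene_i", "gene_j"), drop = FALSE]
    rownames(out) <- NULL
    out
  })
  hasEdges <- vapply(edgeSets, nrow, integer(1)) > 0L
  unassigned <- as.character(sort(c(unassigned,
                       unlist(member[!hasEdges], use.names = FALSE))))
  new("ModuleSet", modules = member[hasEdges], edgeSets = edgeSets[hasEdges],
      unassigned = unassigned)
}

#' Per-patient module scores
#'
#' `m_k(q)` is the plain mean of the individualized edge weights `e_ij(q)`
#' over the intra-module edges `E_k`; missing edges are excluded from both
#' numerator and denominator, and per-module coverage (fraction of
#' non-missing intra-module edges, averaged over samples) is attached as the
#' `"coverage"` attribute.
#'
#' @param lion a [LionessSet-class].
#' @param mods a [ModuleSet-class].
#' @return a samples x modules numeric matrix; `NA` where every
#'   intra-module edge is missing for a sample.
#' @export
moduleScores <- function(lion, mods) {
  key <- edgeKey(lion@edgeIndex$gene_i, lion@edgeIndex$gene_j)
  out <- matrix(NA_real_, length(lion@sampleIds), length(mods@modules),
                dimnames = list(lion@sampleIds, names(mods@modules)))
  coverage <- stats::setNames(numeric(length(mods@modules)), names(mods@modules))
  for (k in names(mods@modules)) {
    ek <- mods@edgeSets[[k]]
    if (nrow(ek) == 0L) stop("module ", k, " has no intra-module edges")
    rows <- match(edgeKey(ek$gene_i, ek$gene_j), key)
    rows <- rows[!is.na(rows)]
    if (length(rows) == 0L) stop("module ", k, " edges absent from LIONESS set")
    vals <- lion@eQ[rows, , drop = FALSE]
    out[, k] <- colMeans(vals, na.rm = TRUE)
    coverage[k] <- mean(colMeans(!is.na(vals)))
  }
  out[is.nan(out)] <- NA_real_
  attr(out, "coverage") <- coverage
  out
}

#' Fit the logistic subtype readout
#'
#' Maximum-likelihood logistic regression of the subtype on the module
#' scores, `p_basal(q) = sigma(beta0 + sum_k beta_k m_k(q))`, with a weak L2
#' penalty so complete separation stays finite. Stratified k-fold
#' cross-validation (seeded) produces pooled out-of-fold probabilities; the
#' reported AUC is the midrank AUC of those probabilities, and the decision
#' rule is `p >= 0.5`.
#'
#' @param scores samples x modules matrix from [moduleScores()].
#' @param labels character vector/factor of `basal`/`classical`, named by
#'   sample or aligned with the score rows.
#' @param cvFolds number of CV folds (default 5).
#' @param seed integer seed for fold assignment.
#' @param penalty L2 penalty strength (default 0.01).
#' @param positive positive class, `"basal"` (default) or `"classical"`.
#' @return a list with `beta0`, `betas`, `pHat`, `yHat`, `auc`, `folds`,
#'   `positive`, `nDropped`.
#' @export
fitSubtype <- function(scores, labels, cvFolds = 5L, seed = 1337L,
                       penalty = 0.01, positive = c("basal", "classical")) {
  positive <- match.arg(positive)
  labels <- .alignLabels(labels, rownames(scores))
  keep <- stats::complete.cases(scores) & !is.na(labels)
  nDropped <- sum(!keep)
  if (nDropped) message(nDropped, " sample(s) with missing scores dropped")
  x <- scores[keep, , drop = FALSE]
  y <- as.numeric(labels[keep] == positive)
  if (min(table(y)) < 2L) stop("need >= 2 samples per class")
  folds <- stratifiedFolds(y, cvFolds, seed)
  if (any(vapply(split(y, folds), function(v) length(unique(v)), integer(1)) < 2L))
    stop("a CV fold contains a single class; use fewer, larger folds")
  pHat <- rep(NA_real_, length(y))
  for (f in sort(unique(folds))) {
    test <- folds == f
    fit <- ridgeLogistic(x[!test, , drop = FALSE], y[!test], lambda = penalty)
    pHat[test] <- predictLogistic(fit, x[test, , drop = FALSE])
  }
  final <- ridgeLogistic(x, y, lambda = penalty)
  list(beta0 = final$beta0, betas = final$betas,
       pHat = stats::setNames(pHat, rownames(x)),
       yHat = stats::setNames(as.integer(pHat >= 0.5), rownames(x)),
       auc = midrankAUC(pHat, y == 1), folds = stats::setNames(folds, rownames(x)),
       positive = positive, nDropped = nDropped)
}

.alignLabels <- function(labels, ids) {
  labels <- stats::setNames(tolower(as.character(labels)), names(labels))
  bad <- setdiff(unique(labels[!is.na(labels)]), c("basal", "classical"))
  if (length(bad)) stop("unknown subtype token(s): ", paste(bad, collapse = ", "))
  if (!is.null(names(labels)) && !is.null(ids)) {
    if (!all(ids %in% names(labels))) stop("labels missing for some samples")
    labels <- labels[ids]
  }
  labels
}

#' Rank-based AUC of raw module scores
#'
#' Per module, the midrank AUC of the raw score against the subtype labels
#' — no model fitting. The direction identity
#' `AUC(basal positive) = 1 - AUC(classical positive)` holds exactly.
#'
#' @param scores samples x modules matrix.
#' @param labels subtype labels (see [fitSubtype()]).
#' @param modules optional [ModuleSet-class] to report gene counts.
#' @param positive positive class (default `"basal"`).
#' @return a data.frame with columns `module`, `n_genes`, `auc`.
#' @export
perModuleAUC <- function(scores, labels, modules = NULL,
                         positive = c("basal", "classical")) {
  positive <- match.arg(positive)
  labels <- .alignLabels(labels, rownames(scores))
  pos <- labels == positive
  auc <- vapply(colnames(scores), function(k) midrankAUC(scores[, k], pos),
                numeric(1))
  nGenes <- if (is.null(modules)) NA_integer_ else
    vapply(colnames(scores), function(k)
      length(modules@modules[[k]]), integer(1))
  out <- data.frame(module = colnames(scores), n_genes = nGenes, auc = auc,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[order(-out$auc), , drop = FALSE]
}

#' Standardize morphology embeddings
#'
#' Centers and scales each embedding dimension to cohort mean 0 and
#' (population) sd 1; constant dimensions become 0.
#'
#' @param emb samples x dimensions matrix.
#' @return the standardized matrix.
#' @export
standardizeEmbeddings <- function(emb) {
  emb <- as.matrix(emb)
  mu <- colMeans(emb)
  sd <- apply(emb, 2L, popSD)
  sd[sd == 0] <- 1
  sweep(sweep(emb, 2L, mu), 2L, sd, "/")
}

#' Morphology-gated module scores
#'
#' Weights each patient's module activation by a morphology gate
#' `g(q) = sigma(theta' f(q))` where `theta` is an L2-penalized logistic
#' regression of the subtype label on the standardized patient-level
#' embeddings (one shared `theta` across modules). To avoid leakage, the
#' gate applied to a sample is always produced by a model trained on the
#' other CV folds. Morphology never becomes a network node; it only
#' modulates the scoring of RNA-derived modules:
#' `m'_k(q) = m_k(q) * g(q)`.
#'
#' @param scores samples x modules matrix from [moduleScores()].
#' @param emb samples x dimensions embedding matrix (rows named by sample).
#' @param labels subtype labels.
#' @param cvFolds,seed cross-validation settings.
#' @param penalty ridge penalty for the gate fit (glmnet lambda, default 1).
#' @param gate `"sigmoid_mult"` (default) or `"off"` (identity gate, scores
#'   returned unchanged).
#' @return the modulated score matrix with the per-sample gates attached as
#'   attribute `"gate"`.
#' @export
morphModulate <- function(scores, emb, labels, cvFolds = 5L, seed = 1337L,
                          penalty = 1, gate = c("sigmoid_mult", "off")) {
  gate <- match.arg(gate)
  if (gate == "off") {
    attr(scores, "gate") <- stats::setNames(rep(1, nrow(scores)), rownames(scores))
    return(scores)
  }
  emb <- as.matrix(emb)
  if (!all(rownames(scores) %in% rownames(emb)))
    stop("every scored sample needs an embedding")
  emb <- emb[rownames(scores), , drop = FALSE]
  labels <- .alignLabels(labels, rownames(scores))
  f <- standardizeEmbeddings(emb)
  y <- as.numeric(labels == "basal")
  folds <- stratifiedFolds(y, cvFolds, seed)
  g <- rep(NA_real_, nrow(f))
  for (k in sort(unique(folds))) {
    test <- folds == k
    fit <- glmnet::glmnet(f[!test, , drop = FALSE], y[!test],
                          family = "binomial", alpha = 0, lambda = penalty,
                          standardize = FALSE)
    g[test] <- as.numeric(stats::predict(fit, f[test, , drop = FALSE],
                                         type = "response"))
  }
  out <- scores * g
  attr(out, "coverage") <- attr(scores, "coverage")
  attr(out, "gate") <- stats::setNames(g, rownames(scores))
  out
}
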