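# Global network construction: expression correlations, partial
# correlations, replication-timing similarity, integrated edge weights,
# thresholding/top-K selection and topology metrics.

#' Pairwise expression correlations
#'
#' Pearson correlation `r_ij = corr(X_i, X_j)` over complete pairs. Genes
#' with fewer than `minSamples` non-missing values or zero variance are
#' dropped with a warning.
#'
#' @param expr genes x samples numeric matrix.
#' @param minSamples minimum non-missing samples per retained gene.
#' @return a [CorrelationSet-class] (genes sorted lexicographically).
#' @export
expressionCorrelations <- function(expr, minSamples = 5L) {
  expr <- as.matrix(expr)
  nOk <- rowSums(!is.na(expr))
  sds <- apply(expr, 1L, popSD)
  keep <- nOk >= minSamples & !is.na(sds) & sds > 0
  if (any(!keep))
    warning(sum(!keep), " gene(s) dropped (insufficient samples or zero variance)")
  expr <- expr[keep, , drop = FALSE]
  if (nrow(expr) < 2L) stop("fewer than 2 genes survive filtering")
  expr <- expr[order(rownames(expr)), , drop = FALSE]
  r <- stats::cor(t(expr), use = "pairwise.complete.obs")
  r <- (r + t(r)) / 2
  diag(r) <- 1
  r[r > 1] <- 1; r[r < -1] <- -1
  sigma <- stats::cov(t(expr), use = "pairwise.complete.obs")
  sigma <- (sigma + t(sigma)) / 2
  new("CorrelationSet", genes = rownames(expr), r = r, sigma = sigma,
      rho = matrix(numeric(0), 0, 0), nSamples = ncol(expr))
}

#' Partial correlations from the precision matrix
#'
#' `rho_ij = -Omega_ij / sqrt(Omega_ii Omega_jj)` with `Omega = Sigma^-1`.
#' When the covariance is ill-conditioned (as when genes approach or exceed
#' samples) a ridge `lambda * I` is added before inversion; the default
#' ridge is `1e-4 * trace(Sigma) / p` whenever `p >= n` or the plain
#' inversion fails.
#'
#' @param cs a [CorrelationSet-class].
#' @param ridge non-negative ridge; `NULL` selects the default policy.
#' @return the [CorrelationSet-class] with the `rho` slot filled (diagonal
#'   set to 1 by convention, entries clipped to \[-1, 1\]).
#' @export
partialCorrelations <- function(cs, ridge = NULL) {
  sigma <- cs@sigma
  p <- nrow(sigma)
  autoRidge <- 1e-4 * mean(diag(sigma))
  if (is.null(ridge)) ridge <- if (p >= cs@nSamples) autoRidge else 0
  omega <- tryCatch(solve(sigma + ridge * diag(p)), error = function(e) NULL)
  if (is.null(omega) && ridge == 0)
    omega <- tryCatch(solve(sigma + autoRidge * diag(p)), error = function(e) NULL)
  if (is.null(omega))
    stop("covariance singular even after ridge; reciprocal condition estimate ",
         format(rcond(sigma), digits = 3))
  d <- sqrt(diag(omega))
  rho <- -omega / tcrossprod(d)
  rho <- (rho + t(rho)) / 2
  diag(rho) <- 1
  rho[rho > 1] <- 1; rho[rho < -1] <- -1
  dimnames(rho) <- dimnames(sigma)
  methods::initialize(cs, rho = rho)
}

#' Replication-timing similarity between genes
#'
#' `s_ij = 1 - |RT_D(i) - RT_D(j)| / max_uv |RT_D(u) - RT_D(v)|`, in
#' \[0, 1\]: the pair attaining the maximal spread has similarity 0, equal
#' timing has similarity 1. If all values are equal the similarity is 1
#' everywhere; pairs involving a missing `RT_D` get the neutral value 0.5
#' (signed similarity 0), so timing neither boosts nor penalizes
#' un-locatable genes.
#'
#' @param rtValues named numeric vector of gene-level `RT_D` values.
#' @return a symmetric similarity matrix with unit diagonal.
#' @export
rtSimilarity <- function(rtValues) {
  g <- names(rtValues)
  ok <- !is.na(rtValues)
  if (sum(ok) < 2L) stop("need >= 2 genes with non-missing RT_D")
  spread <- max(rtValues[ok]) - min(rtValues[ok])
  s <- matrix(0.5, length(rtValues), length(rtValues), dimnames = list(g, g))
  if (spread == 0) {
    s[ok, ok] <- 1
  } else {
    d <- abs(outer(rtValues[ok], rtValues[ok], "-"))
    s[ok, ok] <- 1 - d / spread
  }
  diag(s) <- 1
  s
}

#' Rank-based correlation of gene RT profiles
#'
#' Pearson correlation of rank-transformed per-sample RT values (Spearman,
#' average ranks for ties). Pairs involving a constant profile are undefined
#' and emitted as 0 with a warning.
#'
#' @param rtProfiles genes x samples matrix of per-sample RT values.
#' @return a symmetric correlation matrix with unit diagonal.
#' @export
rtProfileCorrelation <- function(rtProfiles) {
  if (ncol(rtProfiles) < 3L) stop("need >= 3 samples")
  sds <- apply(rtProfiles, 1L, popSD)
  const <- !is.na(sds) & sds == 0
  rho <- suppressWarnings(
    stats::cor(t(rtProfiles), method = "spearman",
               use = "pairwise.complete.obs"))
  if (any(const) || anyNA(rho)) {
    warning("constant or incomplete RT profiles; undefined correlations set to 0")
    rho[is.na(rho)] <- 0
  }
  rho <- (rho + t(rho)) / 2
  diag(rho) <- 1
  rho
}

#' Integrated edge table
#'
#' Builds the per-pair edge table. The RNA association `w_rna` is the
#' partial correlation when `mix@usePartial`, otherwise Pearson. Pairs with
#' `|w_rna| < minAbsCorr` are dropped before mixing; `w_rna_norm` is the
#' population z-score of the surviving associations; and
#' `w_int = a * w_rna + b * (2 s_rt - 1) + gamma * w_rna_norm`.
#' Output pairs are ordered lexicographically by gene id with
#' `gene_i < gene_j`.
#'
#' @param cs a [CorrelationSet-class].
#' @param sRT optional similarity matrix from [rtSimilarity()]; `NULL` means
#'   no timing information (neutral similarity 0.5 for every pair).
#' @param mix a [MixConfig-class].
#' @return a data.frame with columns `gene_i`, `gene_j`, `w_rna`, `s_rt`,
#'   `s_rt_signed`, `w_rna_norm`, `w_int`.
#' @export
integrateEdges <- function(cs, sRT = NULL, mix = mixConfig()) {
  genes <- cs@genes
  W <- if (mix@usePartial) {
    if (!nrow(cs@rho)) stop("usePartial = TRUE but partial correlations not computed")
    cs@rho
  } else cs@r
  ut <- which(upper.tri(W), arr.ind = TRUE)
  gi <- genes[ut[, 1L]]; gj <- genes[ut[, 2L]]
  wrna <- W[ut]
  s <- if (is.null(sRT)) rep(0.5, length(wrna)) else {
    if (!all(genes %in% rownames(sRT)))
      stop("sRT must cover every gene of the correlation set")
    sRT[cbind(match(gi, rownames(sRT)), match(gj, colnames(sRT)))]
  }
  keep <- !is.na(wrna) & abs(wrna) >= mix@minAbsCorr
  if (!any(keep)) stop("empty network: no pair passes the |w_rna| floor")
  gi <- gi[keep]; gj <- gj[keep]; wrna <- wrna[keep]; s <- s[keep]
  s[is.na(s)] <- 0.5
  norm <- popZ(wrna)
  edges <- data.frame(
    gene_i = pmin(gi, gj), gene_j = pmax(gi, gj), w_rna = wrna, s_rt = s,
    s_rt_signed = 2 * s - 1, w_rna_norm = norm,
    stringsAsFactors = FALSE)
  edges$w_int <- mix@alpha * edges$w_rna + mix@betaMix * edges$s_rt_signed +
    mix@gamma * edges$w_rna_norm
  edges <- edges[order(edges$gene_i, edges$gene_j), , drop = FALSE]
  rownames(edges) <- NULL
  edges
}

#' Threshold and top-K edge selection
#'
#' Keeps edges with `w_int >= tau`, then the top `topKGlobal` by `w_int`
#' (ties at the boundary broken lexicographically by gene pair, so selection
#' is deterministic); the plotting subset is the top `topKPlot` of the
#' retained set.
#'
#' @param edges edge table from [integrateEdges()].
#' @param mix a [MixConfig-class].
#' @return a [GlobalNetwork-class].
#' @export
selectEdges <- function(edges, mix = mixConfig()) {
  if (nrow(edges) == 0L) stop("empty network: no edges supplied")
  pass <- edges[!is.na(edges$w_int) & edges$w_int >= mix@tau, , drop = FALSE]
  if (nrow(pass) == 0L) stop("empty network: no edge passes tau = ", mix@tau)
  ord <- order(-pass$w_int, pass$gene_i, pass$gene_j)
  pass <- pass[ord, , drop = FALSE]
  pass <- utils::head(pass, mix@topKGlobal)
  rownames(pass) <- NULL
  nodes <- sort(unique(c(pass$gene_i, pass$gene_j)))
  new("GlobalNetwork", nodes = nodes, edges = pass, mix = mix,
      plotEdges = seq_len(min(nrow(pass), mix@topKPlot)))
}

#' Network topology metrics
#'
#' Density `2|E| / (n(n-1))`, mean degree, global transitivity
#' (3 triangles / connected triples) and the number of connected components,
#' all on the node set of genes appearing in retained edges.
#'
#' @param x a [GlobalNetwork-class] or an edge data.frame with `gene_i`,
#'   `gene_j`.
#' @return a one-row data.frame with `n_nodes`, `n_edges`, `density`,
#'   `mean_degree`, `transitivity`, `components`.
#' @export
topologyMetrics <- function(x) {
  e <- if (is(x, "GlobalNetwork")) x@edges else x
  if (nrow(e) == 0L) stop("network has no edges")
  key <- edgeKey(e$gene_i, e$gene_j)
  e <- e[!duplicated(key), , drop = FALSE]
  nodes <- sort(unique(c(e$gene_i, e$gene_j)))
  n <- length(nodes); m <- nrow(e)
  A <- matrix(0L, n, n, dimnames = list(nodes, nodes))
  ii <- match(e$gene_i, nodes); jj <- match(e$gene_j, nodes)
  A[cbind(ii, jj)] <- 1L; A[cbind(jj, ii)] <- 1L
  deg <- rowSums(A)
  triangles <- sum(diag(A %*% A %*% A)) / 6
  triples <- sum(deg * (deg - 1) / 2)
  trans <- if (triples > 0) 3 * triangles / triples else 0
  # components by union-find
  parent <- seq_len(n)
  find <- function(a) { while (parent[a] != a) { parent[a] <<- parent[parent[a]]; a <- parent[a] }; a }
  for (k in seq_len(m)) {
    ra <- find(ii[k]); rb <- find(jj[k])
    if (ra != rb) parent[ra] <- rb
  }
  comps <- length(unique(vapply(seq_len(n), find, integer(1))))
  data.frame(n_nodes = n, n_edges = m,
             density = 2 * m / (n * (n - 1)),
             mean_degree = 2 * m / n,
             transitivity = trans, components = comps)
}

#' Write an edge list TSV
#'
#' @param net a [GlobalNetwork-class].
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeEdgeList <- function(net, path) {
  utils::write.table(net@edges, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Export the plotting subgraph as node-link JSON
#'
#' The top `topKPlot` retained edges in a node-link structure usable by
#' standard graph viewers.
#'
#' @param net a [GlobalNetwork-class].
#' @param path output `.json` path.
#' @return invisibly, the path.
#' @export
exportPlotSubgraph <- function(net, path) {
  e <- net@edges[net@plotEdges, , drop = FALSE]
  nodes <- sort(unique(c(e$gene_i, e$gene_j)))
  jsonlite::write_json(
    list(nodes = data.frame(id = nodes),
         links = data.frame(source = e$gene_i, target = e$gene_j,
                            weight = e$w_int)),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
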