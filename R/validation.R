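# Statistical validation: permutation nulls, bootstrap edge stability and
# the mixing-coefficient grid search.

#' Permutation null for pipeline metrics
#'
#' Permutes the subtype labels uniformly S times (seeded), recomputes the
#' tracked metrics per shuffle via `pipelineFn`, and reports per metric
#' `Z = (x_real - mu_shuffle) / sigma_shuffle` (population sd; `NA` with a
#' note when the shuffle spread is zero) and the empirical p-value
#' `p_emp = (1 + #\{x_shuffle >= x_real\}) / (1 + S)`, bounded below by
#' `1/(S+1)`. Shuffles where `pipelineFn` fails are dropped, S decremented
#' and a warning emitted.
#'
#' @param pipelineFn `function(labels) -> named numeric` of metrics; must be
#'   deterministic given the permuted labels.
#' @param labels the observed labels (any vector; permuted as a whole).
#' @param S number of shuffles (default 100).
#' @param seed integer seed.
#' @return a data.frame with columns `metric`, `x_real`, `mu_shuffle`,
#'   `sigma_shuffle`, `z`, `p_emp`, `S`; the shuffle draws are attached as
#'   attribute `"shuffles"`.
#' @export
permutationNull <- function(pipelineFn, labels, S = 100L, seed = 1337L) {
  if (S < 1L) stop("S must be >= 1")
  xReal <- pipelineFn(labels)
  if (is.null(names(xReal))) stop("pipelineFn must return a named vector")
  rng <- localRNG(seed)
  draws <- matrix(NA_real_, S, length(xReal),
                  dimnames = list(NULL, names(xReal)))
  ok <- logical(S)
  for (s in seq_len(S)) {
    perm <- labels[rng$permute(length(labels))]
    names(perm) <- names(labels)
    v <- tryCatch(pipelineFn(perm), error = function(e) NULL)
    if (is.null(v)) next
    draws[s, ] <- v[names(xReal)]
    ok[s] <- TRUE
  }
  if (any(!ok)) warning(sum(!ok), " shuffle(s) failed and were dropped")
  draws <- draws[ok, , drop = FALSE]
  Seff <- nrow(draws)
  res <- do.call(rbind, lapply(names(xReal), function(mname) {
    xs <- draws[, mname]
    xs <- xs[!is.na(xs)]
    mu <- mean(xs); sg <- popSD(xs)
    z <- if (is.na(sg) || sg == 0) NA_real_ else (xReal[[mname]] - mu) / sg
    data.frame(metric = mname, x_real = xReal[[mname]], mu_shuffle = mu,
               sigma_shuffle = sg, z = z,
               p_emp = (1 + sum(xs >= xReal[[mname]])) / (1 + length(xs)),
               S = length(xs), stringsAsFactors = FALSE)
  }))
  rownames(res) <- NULL
  if (any(is.na(res$z)))
    message("zero shuffle spread for: ",
            paste(res$metric[is.na(res$z)], collapse = ", "))
  attr(res, "shuffles") <- draws
  res
}

#' Bootstrap edge stability (Jaccard)
#'
#' Draws `nBoot` seeded subsamples (without replacement, size
#' `ceiling(frac * N)`), rebuilds the network on each via `builder`, and
#' compares every pair of bootstrap top-K edge sets by Jaccard similarity
#' `|A intersect B| / |A union B|` on unordered gene-pair keys (weights
#' ignored).
#'
#' @param builder `function(sampleIds) -> character` of edge keys ordered by
#'   decreasing weight (use [edgeKey()]), or a data.frame with `gene_i`,
#'   `gene_j` ordered by decreasing weight.
#' @param sampleIds character vector of sample ids.
#' @param nBoot bootstrap iterations (default 50).
#' @param frac resample fraction (default 0.8).
#' @param topK edges compared per bootstrap (default 10000).
#' @param seed integer seed.
#' @param replace resample with replacement (default FALSE).
#' @return a list with `jaccard` (data.frame `pair_a`, `pair_b`, `jaccard`),
#'   `summary` (mean/sd), `nBoot`, `frac`, `topK`.
#' @export
bootstrapStability <- function(builder, sampleIds, nBoot = 50L, frac = 0.8,
                               topK = 10000L, seed = 1337L, replace = FALSE) {
  n <- length(sampleIds)
  size <- ceiling(frac * n)
  rng <- localRNG(seed)
  sets <- vector("list", nBoot)
  for (b in seq_len(nBoot)) {
    ids <- sampleIds[rng$sampleInt(n, size, replace = replace)]
    res <- builder(ids)
    if (is.data.frame(res)) res <- edgeKey(res$gene_i, res$gene_j)
    if (length(res) < topK && b == 1L)
      message("builder yields ", length(res), " edges (< topK = ", topK,
              "); comparing over available edges")
    sets[[b]] <- utils::head(res, topK)
  }
  pairs <- utils::combn(nBoot, 2L)
  jac <- apply(pairs, 2L, function(p) {
    a <- sets[[p[1L]]]; b <- sets[[p[2L]]]
    u <- length(union(a, b))
    if (u == 0L) return(1)
    length(intersect(a, b)) / u
  })
  jdf <- data.frame(pair_a = pairs[1L, ], pair_b = pairs[2L, ], jaccard = jac)
  list(jaccard = jdf,
       summary = c(mean = mean(jac), sd = stats::sd(jac)),
       nBoot = nBoot, frac = frac, topK = topK)
}

#' Mixing-coefficient grid search
#'
#' Full Cartesian sweep over the `(a, b, gamma)` grid (125 cells at the
#' default ranges); each cell records whatever named metrics the evaluator
#' returns (typically topology metrics plus the subtype AUC). Failed cells
#' are marked and the sweep continues. Ordering is deterministic: `a`
#' slowest, `gamma` fastest.
#'
#' @param grid a [GridSpec-class].
#' @param evaluator `function(a, b, gamma) -> named numeric`.
#' @return a data.frame with columns `a`, `b`, `gamma`, `status`, and one
#'   column per metric.
#' @export
gridSearch <- function(grid, evaluator) {
  cells <- gridCells(grid)
  rows <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    v <- tryCatch(evaluator(cells$a[i], cells$b[i], cells$gamma[i]),
                  error = function(e) NULL)
    rows[[i]] <- if (is.null(v))
      data.frame(cells[i, ], status = "failed", stringsAsFactors = FALSE)
    else
      data.frame(cells[i, ], status = "ok", as.list(v), stringsAsFactors = FALSE)
  }
  out <- data.table::rbindlist(rows, fill = TRUE)
  as.data.frame(out)
}
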