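# Correlations, RT similarity, integrated weights, edge selection, topology.

test_that("Pearson correlations: affine invariance and a hand-computed 3-gene case", {
  set.seed(1)
  x <- rnorm(30)
  expr <- rbind(g1 = x, g2 = 2 * x + 1, g3 = rnorm(30))
  colnames(expr) <- paste0("s", 1:30)
  cs <- expressionCorrelations(expr)
  expect_equal(corMatrix(cs)["g1", "g2"], 1, tolerance = 1e-12)
  # hand-computed covariance/correlation oracle
  X <- matrix(c(1, 2, 3, 4,
                2, 1, 4, 3,
                1, 1, 2, 5), nrow = 3, byrow = TRUE,
              dimnames = list(c("a", "b", "c"), paste0("s", 1:4)))
  csX <- expressionCorrelations(X, minSamples = 3L)
  manual <- function(u, v) {
    cu <- u - mean(u); cv <- v - mean(v)
    sum(cu * cv) / sqrt(sum(cu^2) * sum(cv^2))
  }
  expect_equal(corMatrix(csX)["a", "b"], manual(X["a", ], X["b", ]), tolerance = 1e-12)
  expect_equal(corMatrix(csX)["a", "c"], manual(X["a", ], X["c", ]), tolerance = 1e-12)
})

test_that("independent genes stay near zero correlation at n = 1000", {
  set.seed(2)
  expr <- matrix(rnorm(5000), 5, 1000,
                 dimnames = list(paste0("g", 1:5), paste0("s", 1:1000)))
  cs <- expressionCorrelations(expr)
  off <- corMatrix(cs)[upper.tri(diag(5))]
  expect_true(all(abs(off) < 0.12))
})

test_that("gene filtering drops low-coverage and constant genes", {
  expr <- rbind(g1 = c(1, 2, 3, NA, NA, NA), g2 = rnorm(6), g3 = rep(1, 6),
                g4 = rnorm(6))
  colnames(expr) <- paste0("s", 1:6)
  expect_warning(cs <- expressionCorrelations(expr, minSamples = 5L), "dropped")
  expect_setequal(cs@genes, c("g2", "g4"))
  expect_error(suppressWarnings(expressionCorrelations(expr[c(1, 3), ], 5L)),
               "fewer than 2 genes")
})

test_that("partial correlations match the residual-regression oracle", {
  # diagonal covariance: independence
  set.seed(3)
  exprD <- matrix(rnorm(4 * 200), 4, 200,
                  dimnames = list(paste0("g", 1:4), paste0("s", 1:200)))
  csD <- partialCorrelations(expressionCorrelations(exprD))
  offD <- partialMatrix(csD)[upper.tri(diag(4))]
  expect_true(all(abs(offD) < 0.2))
  # chain X -> Y -> Z: rho_XZ ~ 0 while r_XZ clearly > 0
  n <- 2000
  X <- rnorm(n); Y <- X + rnorm(n, sd = 0.5); Z <- Y + rnorm(n, sd = 0.5)
  expr <- rbind(X = X, Y = Y, Z = Z); colnames(expr) <- paste0("s", 1:n)
  cs <- partialCorrelations(expressionCorrelations(expr))
  expect_gt(corMatrix(cs)["X", "Z"], 0.5)
  expect_lt(abs(partialMatrix(cs)["X", "Z"]), 0.1)
  expect_lt(abs(partialMatrix(cs)["X", "Z"] -
                  residualPartialCor(t(expr))["X", "Z"]), 1e-8)
})

test_that("RT similarity follows the normalized-spread formula", {
  s <- rtSimilarity(c(a = 0, b = 1, c = 0.5))
  expect_equal(s["a", "b"], 0)
  expect_equal(s["a", "c"], 0.5)
  expect_equal(diag(s), c(a = 1, b = 1, c = 1))
  # degenerate equal-RT convention
  expect_true(all(rtSimilarity(c(a = 2, b = 2, c = 2)) == 1))
  # missing values get the neutral similarity
  sm <- rtSimilarity(c(a = 0, b = 1, c = NA))
  expect_equal(sm["a", "c"], 0.5)
  expect_equal(sm["c", "c"], 1)
  # brute-force double loop oracle
  set.seed(4)
  v <- setNames(rnorm(10), paste0("g", 1:10))
  s10 <- rtSimilarity(v)
  spread <- max(v) - min(v)
  for (i in 1:9) for (j in (i + 1):10)
    expect_equal(s10[i, j], 1 - abs(v[[i]] - v[[j]]) / spread, tolerance = 1e-12)
})

test_that("RT profile correlation is Spearman with midrank ties", {
  set.seed(5)
  base <- rnorm(20)
  prof <- rbind(p1 = base, p2 = exp(base), p3 = -base, p4 = rnorm(20))
  colnames(prof) <- paste0("s", 1:20)
  rho <- rtProfileCorrelation(prof)
  expect_equal(rho["p1", "p2"], 1)
  expect_equal(rho["p1", "p3"], -1)
  expect_equal(rho["p1", "p4"], cor(base, prof["p4", ], method = "spearman"),
               tolerance = 1e-12)
  # constant profile -> 0 with warning
  prof2 <- rbind(prof, p5 = rep(1, 20))
  expect_warning(rho2 <- rtProfileCorrelation(prof2), "constant")
  expect_true(all(rho2["p5", c("p1", "p2", "p3", "p4")] == 0))
})

test_that("integrated weights follow the mixing formula exactly", {
  set.seed(6)
  expr <- matrix(rnorm(5 * 40), 5, 40,
                 dimnames = list(paste0("g", 1:5), paste0("s", 1:40)))
  expr[2, ] <- expr[1, ] + rnorm(40, sd = 0.3)
  expr[4, ] <- expr[3, ] + rnorm(40, sd = 0.3)
  cs <- expressionCorrelations(expr)
  rt <- setNames(c(0.2, 0.25, -1, -0.9, 0.8), paste0("g", 1:5))
  sRT <- rtSimilarity(rt)
  mixA <- mixConfig(alpha = 1, betaMix = 0, gamma = 0, minAbsCorr = 0.5)
  eA <- integrateEdges(cs, sRT, mixA)
  expect_equal(eA$w_int, eA$w_rna)                  # RNA-only equivalence
  mixB <- mixConfig(alpha = 0, betaMix = 1, gamma = 0, minAbsCorr = 0)
  sOne <- sRT; sOne[] <- 1
  eB <- integrateEdges(cs, sOne, mixB)
  expect_true(all(eB$w_int == 1))
  # default mix against a hand-computed spreadsheet oracle
  mixD <- mixConfig()                               # (1, 0.5, 0.5), floor 0.5
  eD <- integrateEdges(cs, sRT, mixD)
  r <- corMatrix(cs)
  wAll <- r[upper.tri(r)]
  keep <- abs(wAll) >= 0.5
  wKeep <- wAll[keep]
  normOracle <- (wKeep - mean(wKeep)) / popSD(wKeep)
  for (k in seq_len(nrow(eD))) {
    i <- eD$gene_i[k]; j <- eD$gene_j[k]
    expect_equal(eD$w_rna[k], r[i, j], tolerance = 1e-12)
    expect_equal(eD$w_int[k],
                 1 * r[i, j] + 0.5 * (2 * sRT[i, j] - 1) +
                   0.5 * normOracle[match(eD$w_rna[k], wKeep)],
                 tolerance = 1e-12)
  }
  # monotonicity in b: raising b raises w_int where s_signed > 0, lowers where < 0
  mixHi <- mixConfig(alpha = 1, betaMix = 0.9, gamma = 0.5)
  eHi <- integrateEdges(cs, sRT, mixHi)
  dlt <- eHi$w_int - eD$w_int
  expect_true(all(dlt[eD$s_rt_signed > 0] > 0))
  expect_true(all(dlt[eD$s_rt_signed < 0] < 0))
  # everything filtered -> empty-network error
  expect_error(integrateEdges(cs, sRT, mixConfig(minAbsCorr = 0.9999)),
               "empty network")
})

test_that("edge selection thresholds, takes top-K deterministically and is idempotent", {
  mkEdges <- function(w) data.frame(
    gene_i = sprintf("a%02d", seq_along(w)), gene_j = sprintf("b%02d", seq_along(w)),
    w_rna = w, s_rt = 0.5, s_rt_signed = 0, w_rna_norm = 0, w_int = w)
  mix <- mixConfig(tau = 0.5, topKGlobal = 10L, topKPlot = 2L, minAbsCorr = 0)
  net <- selectEdges(mkEdges(c(0.6, 0.4)), mix)
  expect_equal(nrow(edgeTable(net)), 1L)
  mix2 <- mixConfig(tau = 0, topKGlobal = 2L, topKPlot = 1L, minAbsCorr = 0)
  net2 <- selectEdges(mkEdges(c(0.9, 0.8, 0.7)), mix2)
  expect_equal(edgeTable(net2)$w_int, c(0.9, 0.8))
  expect_error(selectEdges(mkEdges(c(0.1, 0.2)), mix), "passes tau")
  # sort-and-slice oracle on 100 random edges, with ties
  set.seed(7)
  w <- round(runif(100), 2)
  mix3 <- mixConfig(tau = 0.3, topKGlobal = 40L, topKPlot = 5L, minAbsCorr = 0)
  net3 <- selectEdges(mkEdges(w), mix3)
  df <- mkEdges(w)
  df <- df[df$w_int >= 0.3, ]
  df <- df[order(-df$w_int, df$gene_i, df$gene_j), ][1:40, ]
  expect_equal(edgeTable(net3)$w_int, df$w_int)
  expect_equal(edgeTable(net3)$gene_i, df$gene_i)
  # idempotence: reselecting the retained set returns it unchanged
  net4 <- selectEdges(edgeTable(net3), mix3)
  expect_equal(edgeTable(net4), edgeTable(net3))
})

test_that("topology metrics match igraph on canonical and random graphs", {
  mkNet <- function(e) {
    df <- data.frame(gene_i = pmin(e[, 1], e[, 2]), gene_j = pmax(e[, 1], e[, 2]),
                     w_rna = 1, s_rt = 0.5, s_rt_signed = 0, w_rna_norm = 0,
                     w_int = 1)
    df
  }
  tri <- mkNet(cbind(c("a", "b", "a"), c("b", "c", "c")))
  mTri <- topologyMetrics(tri)
  expect_equal(mTri$density, 1)
  expect_equal(mTri$transitivity, 1)
  expect_equal(mTri$components, 1L)
  path <- mkNet(cbind(c("a", "b"), c("b", "c")))
  expect_equal(topologyMetrics(path)$transitivity, 0)
  # independent library oracle on a random graph
  set.seed(8)
  n <- 30
  pairs <- t(combn(sprintf("v%02d", 1:n), 2))
  sel <- pairs[runif(nrow(pairs)) < 0.12, ]
  m <- topologyMetrics(mkNet(sel))
  g <- igraph::graph_from_edgelist(sel, directed = FALSE)
  expect_equal(m$density, igraph::edge_density(g))
  expect_equal(m$mean_degree, mean(igraph::degree(g)))
  expect_equal(m$transitivity, igraph::transitivity(g, type = "global"))
  expect_equal(m$components, igraph::components(g)$no)
})
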