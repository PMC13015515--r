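# Module detection, scoring, the logistic readout and morphology gating.

mkNetFromEdges <- function(e, tau = 0, topK = 1000L) {
  df <- data.frame(gene_i = pmin(e$from, e$to), gene_j = pmax(e$from, e$to),
                   w_rna = e$w, s_rt = 0.5, s_rt_signed = 0, w_rna_norm = 0,
                   w_int = e$w)
  selectEdges(df, mixConfig(tau = tau, topKGlobal = topK, topKPlot = 10L,
                            minAbsCorr = 0))
}

test_that("disconnected cliques are recovered as exactly those modules", {
  cl <- function(genes) {
    p <- t(combn(genes, 2))
    data.frame(from = p[, 1], to = p[, 2], w = 1)
  }
  net <- mkNetFromEdges(rbind(cl(c("a1", "a2", "a3")), cl(c("b1", "b2", "b3", "b4"))))
  mods <- detectModules(net, seed = 1L)
  expect_equal(moduleList(mods),
               list(module_0 = c("b1", "b2", "b3", "b4"),
                    module_1 = c("a1", "a2", "a3")))
  # intra-module edge sets are complete
  expect_equal(nrow(moduleEdges(mods)$module_0), 6L)
  expect_equal(nrow(moduleEdges(mods)$module_1), 3L)
  # determinism across repeated runs
  expect_identical(moduleList(detectModules(net, seed = 1L)), moduleList(mods))
  expect_identical(moduleList(detectModules(net, seed = 99L)), moduleList(mods))
})

test_that("planted blocks are recovered on the synthetic cohort", {
  co <- smallCohort()
  rep <- runCondition(co, "RNA", runConfig())
  jac <- moduleRecoveryJaccard(rep$modules, co$moduleTruth)
  expect_true(all(jac >= 0.8))
})

test_that("module scores are plain means of intra-module individualized edges", {
  idx <- data.frame(gene_i = c("a", "a", "b", "d"),
                    gene_j = c("b", "c", "c", "e"))
  eQ <- matrix(c(0.7, 0.2, 0.3, 9,
                 0.7, 0.4, 0.1, 9), ncol = 2,
               dimnames = list(NULL, c("s1", "s2")))
  # construct a LionessSet satisfying the identity for N = 2
  lion <- new("LionessSet", sampleIds = c("s1", "s2"), edgeIndex = idx,
              eAll = rep(0, 4), eMinus = -eQ, eQ = eQ)
  mods <- new("ModuleSet",
              modules = list(module_0 = c("a", "b", "c"), module_1 = c("d", "e")),
              edgeSets = list(module_0 = idx[1:3, ], module_1 = idx[4, ]),
              unassigned = character(0))
  sc <- moduleScores(lion, mods)
  expect_equal(sc["s1", "module_0"], mean(c(0.7, 0.2, 0.3)))
  expect_equal(sc["s1", "module_1"], 9)
  # single-edge module returns that edge; constant edges return the constant
  expect_equal(sc["s2", "module_1"], 9)
  # explicit double-loop oracle
  for (s in 1:2) {
    acc <- 0
    for (k in 1:3) acc <- acc + eQ[k, s]
    expect_equal(unname(sc[s, "module_0"]), unname(acc / 3), tolerance = 1e-12)
  }
  # linearity: scaling every edge scales every score
  lion2 <- lion; lion2@eQ <- 3 * eQ
  expect_equal(moduleScores(lion2, mods), 3 * sc, ignore_attr = TRUE)
  # missing edges drop out of numerator and denominator
  lion3 <- lion; lion3@eQ[1, 1] <- NA
  sc3 <- moduleScores(lion3, mods)
  expect_equal(sc3["s1", "module_0"], mean(c(0.2, 0.3)))
})

test_that("the logistic readout behaves at the no-signal and separation extremes", {
  set.seed(30)
  n <- 60
  labels <- setNames(rep(c("basal", "classical"), each = n / 2), sprintf("s%02d", 1:n))
  noise <- matrix(rnorm(n * 2), n, 2,
                  dimnames = list(names(labels), c("module_0", "module_1")))
  fit0 <- fitSubtype(noise, labels, seed = 7L)
  expect_lt(abs(fit0$auc - 0.5), 0.25)
  sep <- noise
  sep[, 1] <- ifelse(labels == "basal", 1, -1)
  fit1 <- fitSubtype(sep, labels, seed = 7L)
  expect_equal(fit1$auc, 1.0)
  expect_true(all(fit1$yHat[labels == "basal"] == 1L))
  # the fitted model discriminates perfectly whichever class is positive
  fitC <- fitSubtype(sep, labels, seed = 7L, positive = "classical")
  expect_equal(fitC$auc, 1.0)
  # imbalanced labels with too many folds leave single-class folds
  labImb <- setNames(rep(c("basal", "classical"), c(3, 57)), names(labels))
  expect_error(fitSubtype(noise, labImb, cvFolds = 5L, seed = 1L),
               "single class|larger folds")
})

test_that("per-module AUC is rank-based, direction-symmetric and monotone-invariant", {
  labels <- rep(c("basal", "classical"), each = 10)
  sc <- cbind(module_0 = as.numeric(labels == "basal"),
              module_1 = rnorm(20))
  rownames(sc) <- sprintf("s%02d", 1:20)
  names(labels) <- rownames(sc)
  pm <- perModuleAUC(sc, labels)
  expect_equal(pm$auc[pm$module == "module_0"], 1)
  pmC <- perModuleAUC(sc, labels, positive = "classical")
  expect_equal(pmC$auc[pmC$module == "module_0"], 0)
  # exact direction identity with midrank ties
  expect_equal(pm$auc, 1 - pmC$auc[match(pm$module, pmC$module)], tolerance = 1e-15)
  # invariance under strictly monotone transforms
  sc2 <- sc; sc2[, "module_1"] <- exp(3 * sc[, "module_1"])
  expect_equal(perModuleAUC(sc2, labels)$auc, pm$auc)
  # agreement with an independent AUC implementation
  roc <- pROC::roc(labels == "basal", sc[, "module_1"],
                   levels = c(FALSE, TRUE), direction = "<", quiet = TRUE)
  expect_equal(pm$auc[pm$module == "module_1"], as.numeric(pROC::auc(roc)))
})

test_that("random module scores give chance-level AUC at n = 200", {
  set.seed(31)
  labels <- setNames(rep(c("basal", "classical"), 100), sprintf("s%03d", 1:200))
  sc <- matrix(rnorm(200), 200, 1, dimnames = list(names(labels), "module_0"))
  expect_lt(abs(perModuleAUC(sc, labels)$auc - 0.5), 0.1)
})

test_that("morphology gating is identity when off and harmless when uninformative", {
  co <- smallCohort()
  rep <- runCondition(co, "RNA", runConfig())
  sc <- rep$scores
  off <- morphModulate(sc, co$embeddings, co$labels, gate = "off")
  expect_equal(unclass(off)[, ], unclass(sc)[, ])
  expect_true(all(attr(off, "gate") == 1))
  # subtype-uninformative embeddings barely move the per-module AUC
  set.seed(32)
  embNull <- matrix(rnorm(length(co$sampleIds) * 25), length(co$sampleIds), 25,
                    dimnames = list(co$sampleIds, paste0("e", 1:25)))
  modNull <- morphModulate(sc, embNull, co$labels, seed = 5L)
  a0 <- perModuleAUC(sc, co$labels)$auc
  a1 <- perModuleAUC(modNull, co$labels)$auc
  expect_true(all(abs(sort(a0) - sort(a1)) < 0.12))
})

test_that("informative embeddings do not degrade the basal-module AUC", {
  co <- smallCohort()  # embeddingEffectSize 1 separates dim 1 by subtype
  rep <- runCondition(co, "RNA", runConfig())
  sc <- rep$scores
  pm0 <- perModuleAUC(sc, co$labels)
  top <- pm0$module[which.max(pm0$auc)]
  mod <- morphModulate(sc, co$embeddings, co$labels, seed = 5L)
  pm1 <- perModuleAUC(mod, co$labels)
  expect_gte(pm1$auc[pm1$module == top] + 0.03, pm0$auc[pm0$module == top])
  # embeddings must be standardized per dimension
  std <- standardizeEmbeddings(co$embeddings)
  expect_equal(colMeans(std), rep(0, ncol(std)), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(apply(std, 2, popSD), rep(1, ncol(std)), tolerance = 1e-12,
               ignore_attr = TRUE)
  # dimension mismatch is a schema error
  expect_error(morphModulate(sc, co$embeddings[1:5, ], co$labels),
               "embedding")
})
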