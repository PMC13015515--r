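# Beta-file parsing, promoter aggregation and state calls.

test_that("parseBetaFile clips values and handles both dialects identically", {
  mf <- tinyManifest()
  pComma <- writeLinesTo(c("probe,beta", "cg1,0.2", "cg2,1.3"), "comma.txt")
  v <- parseBetaFile(pComma, mf)
  expect_equal(v, c(cg1 = 0.2, cg2 = 1.0))
  pTab <- writeLinesTo(c("cg1\t0.2", "cg2\t1.3"), "tab.txt")
  expect_equal(parseBetaFile(pTab, mf), v)
})

test_that("column detection finds probe and beta columns regardless of order", {
  mf <- tinyManifest()
  swapped <- writeLinesTo(c("beta,probe", "0.2,cg1", "1.3,cg2"), "sw.txt")
  expect_equal(parseBetaFile(swapped, mf), c(cg1 = 0.2, cg2 = 1.0))
  # quoted, padded probe ids are normalized
  quoted <- writeLinesTo(c('probe,beta', '"cg1" ,0.4', ' cg2,0.6'), "q.txt")
  expect_equal(parseBetaFile(quoted, mf), c(cg1 = 0.4, cg2 = 0.6))
  # non-numeric betas are dropped
  nn <- writeLinesTo(c("probe,beta", "cg1,NA_bad", "cg2,0.5"), "nn.txt")
  expect_equal(parseBetaFile(nn, mf), c(cg2 = 0.5))
})

test_that("parseBetaFile errors on unusable files", {
  mf <- tinyManifest()
  alien <- writeLinesTo(c("x,y", "foo,0.2", "bar,0.3", "baz,0.4"), "alien.txt")
  expect_error(parseBetaFile(alien, mf), "format error")
  empty <- writeLinesTo(character(0), "empty.txt")
  expect_error(parseBetaFile(empty, mf), "empty")
  expect_error(parseBetaFile(file.path(tempdir(), "nope.txt"), mf), "cannot read")
})

test_that("promoter aggregation averages promoter probes and expands multi-gene probes", {
  mf <- tinyManifest()
  beta <- matrix(c(0.2, 0.4, 0.6, 0.8,
                   0.3, 0.5, 0.7, 0.9), ncol = 2,
                 dimnames = list(mf$probe_id, c("s1", "s2")))
  pm <- promoterAggregate(beta, mf)
  mb <- SummarizedExperiment::assay(pm, "meanBeta")
  # geneA: cg1, cg2 and the shared cg4; geneB: cg3 and cg4
  expect_equal(mb["geneA", "s1"], mean(c(0.2, 0.4, 0.8)))
  expect_equal(mb["geneB", "s1"], mean(c(0.6, 0.8)))
  expect_equal(mb["geneB", "s2"], mean(c(0.7, 0.9)))
})

test_that("aggregation is invariant to probe order and body probes are excluded", {
  mf <- rbind(tinyManifest(),
              data.frame(probe_id = "cg9", gene = "geneA", region_class = "Body",
                         chrom = "chr1", pos = 9000L))
  beta <- matrix(runif(10), 5, 2, dimnames = list(mf$probe_id, c("s1", "s2")))
  pm1 <- promoterAggregate(beta, mf)
  perm <- c(4, 2, 5, 1, 3)
  pm2 <- promoterAggregate(beta[perm, ], mf[perm, ])
  expect_equal(SummarizedExperiment::assay(pm1, "meanBeta"),
               SummarizedExperiment::assay(pm2, "meanBeta"))
  # body probe value does not enter geneA's mean
  expect_equal(SummarizedExperiment::assay(pm1, "meanBeta")["geneA", "s1"],
               mean(beta[c("cg1", "cg2", "cg4"), "s1"]))
})

test_that("gene-wise z-scores have population mean 0 / sd 1 and constants stay baseline", {
  mf <- tinyManifest()
  set.seed(5)
  beta <- matrix(runif(4 * 6, 0.2, 0.8), 4, 6,
                 dimnames = list(mf$probe_id, paste0("s", 1:6)))
  beta["cg3", ] <- 0.5  # geneB gets cg3 (constant) + cg4 (varying)
  pm <- promoterAggregate(beta, mf)
  z <- SummarizedExperiment::assay(pm, "zscore")
  for (g in rownames(z)) {
    expect_equal(mean(z[g, ]), 0, tolerance = 1e-12)
    expect_equal(popSD(z[g, ]), 1, tolerance = 1e-12)
  }
  # fully constant gene: z = 0 everywhere, state baseline
  betaC <- beta
  betaC[c("cg3", "cg4"), ] <- 0.5
  mfB <- mf; mfB$gene[4] <- "geneB"  # make geneB fully constant
  pmC <- promoterAggregate(betaC, mfB)
  expect_true(all(SummarizedExperiment::assay(pmC, "zscore")["geneB", ] == 0))
  expect_true(all(SummarizedExperiment::assay(pmC, "state")["geneB", ] == "baseline"))
})

test_that("state calls follow the thresholds and match the normal tail rate", {
  expect_equal(callStates(matrix(-2), -1, 1)[1], "hypo")
  expect_equal(callStates(matrix(0), -1, 1)[1], "baseline")
  expect_equal(callStates(matrix(1), -1, 1)[1], "hyper")
  expect_error(callStates(matrix(0), 1, -1), "hypoThresh")
  set.seed(42)
  z <- matrix(rnorm(1e5), 1)
  fracHyper <- mean(callStates(z, -1, 1) == "hyper")
  expect_lt(abs(fracHyper - pnorm(-1)), 0.01)  # P(Z >= 1) = 0.1587
})

test_that("promoter matrices round-trip in long and wide form", {
  mf <- tinyManifest()
  beta <- matrix(runif(8), 4, 2, dimnames = list(mf$probe_id, c("s1", "s2")))
  pm <- promoterAggregate(beta, mf)
  dir <- withr::local_tempdir()
  paths <- writePromoterMatrices(pm, dir)
  wide <- read.delim(paths["wide"], check.names = FALSE)
  expect_equal(as.matrix(wide[, -1]),
               SummarizedExperiment::assay(pm, "meanBeta"),
               ignore_attr = TRUE)
  long <- read.delim(paths["long"])
  expect_equal(nrow(long), 2 * nrow(wide))
})
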