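# Windowed medians, smoothing, RT inversion, domains and summaries.

# manifest with one probe per kb over two chromosomes, window size 1000
gridManifest <- function(nWin = 10L, perWin = 3L, chroms = c("chr1", "chr2")) {
  pos <- unlist(lapply(seq_len(nWin) - 1L, function(w)
    w * 1000L + seq(100L, 900L, length.out = perWin)))
  df <- do.call(rbind, lapply(chroms, function(ch)
    data.frame(gene = "", region_class = "Body", chrom = ch, pos = as.integer(pos))))
  df$probe_id <- sprintf("cg%04d", seq_len(nrow(df)))
  df[, c("probe_id", "gene", "region_class", "chrom", "pos")]
}

test_that("window medians and the rolling-mean smoother behave as stated", {
  mf <- gridManifest(nWin = 3L, perWin = 3L, chroms = "chr1")
  grid <- makeWindowGrid(mf, 1000L)
  b <- setNames(c(0.1, 0.2, 0.9, rep(0.5, 6)), mf$probe_id)
  w <- binAndSmooth(b, mf, grid, smoothWidth = 3L)
  expect_equal(S4Vectors::mcols(w)$median_beta[1], 0.2)
  # constant track is a smoothing fixed point
  bc <- setNames(rep(0.5, 9), mf$probe_id)
  wc <- binAndSmooth(bc, mf, grid, smoothWidth = 3L)
  expect_equal(S4Vectors::mcols(wc)$smoothed, rep(0.5, 3))
  # single spike among flat neighbours attenuates to the triplet mean
  mf5 <- gridManifest(nWin = 5L, perWin = 1L, chroms = "chr1")
  g5 <- makeWindowGrid(mf5, 1000L)
  bs <- setNames(c(0.2, 0.2, 0.8, 0.2, 0.2), mf5$probe_id)
  ws <- binAndSmooth(bs, mf5, g5, smoothWidth = 3L)
  expect_equal(S4Vectors::mcols(ws)$smoothed[3], mean(c(0.2, 0.8, 0.2)))
  # truncated edges: first window averages the first two
  expect_equal(S4Vectors::mcols(ws)$smoothed[1], mean(c(0.2, 0.2)))
})

test_that("smoothing never mixes chromosomes and empty windows stay missing", {
  mf <- gridManifest(nWin = 3L, perWin = 1L)
  grid <- makeWindowGrid(mf, 1000L)
  b <- setNames(c(0.1, 0.1, 0.1, 0.9, 0.9, 0.9), mf$probe_id)
  w <- binAndSmooth(b, mf, grid, smoothWidth = 3L)
  sm <- S4Vectors::mcols(w)$smoothed
  expect_equal(sm, c(0.1, 0.1, 0.1, 0.9, 0.9, 0.9))  # no bleed across chr1/chr2
  # drop the middle chr1 probe -> that window is NA, neighbours unaffected
  w2 <- binAndSmooth(b[-2], mf, grid, smoothWidth = 3L)
  expect_true(is.na(S4Vectors::mcols(w2)$median_beta[2]))
  expect_true(is.na(S4Vectors::mcols(w2)$smoothed[2]))
})

test_that("RT proxy is the negated population z-score of the smoothed track", {
  mf <- gridManifest(nWin = 2L, perWin = 1L, chroms = "chr1")
  grid <- makeWindowGrid(mf, 1000L)
  w <- binAndSmooth(setNames(c(0.2, 0.8), mf$probe_id), mf, grid, smoothWidth = 1L)
  w <- methylationToRT(w)
  # population z of a two-point set is +/- 1; inversion flips the sign
  expect_equal(S4Vectors::mcols(w)$rt, c(1, -1))

  mf10 <- gridManifest(nWin = 10L, perWin = 1L, chroms = "chr1")
  g10 <- makeWindowGrid(mf10, 1000L)
  set.seed(7)
  w10 <- methylationToRT(binAndSmooth(setNames(runif(10), mf10$probe_id),
                                      mf10, g10))
  rt <- S4Vectors::mcols(w10)$rt
  expect_equal(mean(rt), 0, tolerance = 1e-12)
  expect_equal(popSD(rt), 1, tolerance = 1e-12)
  # monotone methylation -> strictly decreasing rt (antitone inversion)
  wm <- methylationToRT(binAndSmooth(
    setNames(seq(0.1, 0.9, length.out = 10), mf10$probe_id), mf10, g10,
    smoothWidth = 1L))
  expect_true(all(diff(S4Vectors::mcols(wm)$rt) < 0))
  # degenerate: constant track warns and returns all-zero rt
  expect_warning(
    wz <- methylationToRT(binAndSmooth(setNames(rep(0.4, 10), mf10$probe_id),
                                       mf10, g10)), "zero variance")
  expect_true(all(S4Vectors::mcols(wz)$rt == 0))
})

test_that("domain RT is the length-weighted mean of member windows", {
  mf <- gridManifest(nWin = 6L, perWin = 1L, chroms = "chr1")
  grid <- makeWindowGrid(mf, 1000L)
  w <- binAndSmooth(setNames(runif(6), mf$probe_id), mf, grid, smoothWidth = 1L)
  # uniform windows, rt {1, -1} in one domain -> RT_D = 0
  S4Vectors::mcols(w)$rt <- c(1, -1, 1, -1, 1, -1)
  d <- aggregateDomains(w, domainSpan = 6000L)
  expect_equal(S4Vectors::mcols(d)$rt_domain, 0)

  # non-uniform windows: l = {100k, 200k}, rt = {0.9, 0} -> 0.3
  gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(
    start = c(1L, 100001L), end = c(100000L, 300000L)))
  S4Vectors::mcols(gr)$rt <- c(0.9, 0)
  d2 <- aggregateDomains(gr, domainSpan = 300000L)
  expect_equal(S4Vectors::mcols(d2)$rt_domain, 0.3)

  # random windows equal the brute-force weighted mean to 1e-9
  set.seed(13)
  S4Vectors::mcols(w)$rt <- rnorm(6)
  d3 <- aggregateDomains(w, domainSpan = 3000L)
  len <- GenomicRanges::width(w)
  grpIdx <- list(1:3, 4:6)
  for (k in 1:2) {
    i <- grpIdx[[k]]
    expect_equal(S4Vectors::mcols(d3)$rt_domain[k],
                 sum(len[i] * S4Vectors::mcols(w)$rt[i]) / sum(len[i]),
                 tolerance = 1e-9)
  }
  # all-missing domain carries NA
  S4Vectors::mcols(w)$rt[4:6] <- NA
  d4 <- aggregateDomains(w, domainSpan = 3000L)
  expect_true(is.na(S4Vectors::mcols(d4)$rt_domain[2]))
})

test_that("RT_D and summaries are invariant to splitting a window in half", {
  gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(
    start = c(1L, 1001L, 2001L), width = 1000L))
  S4Vectors::mcols(gr)$rt <- c(0.5, -0.2, 0.8)
  split <- GenomicRanges::GRanges("chr1", IRanges::IRanges(
    start = c(1L, 501L, 1001L, 2001L), width = c(500L, 500L, 1000L, 1000L)))
  S4Vectors::mcols(split)$rt <- c(0.5, 0.5, -0.2, 0.8)
  expect_equal(S4Vectors::mcols(aggregateDomains(gr, 3000L))$rt_domain,
               S4Vectors::mcols(aggregateDomains(split, 3000L))$rt_domain)
  expect_equal(sampleSummary(gr)[, c("rt_mean", "frac_late")],
               sampleSummary(split)[, c("rt_mean", "frac_late")])
})

test_that("frac_late counts the configured lateness sign, length-weighted", {
  gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(
    start = c(1L, 1001L, 2001L, 3001L), width = 1000L))
  S4Vectors::mcols(gr)$rt <- c(1, 2, 0.1, 0.5)
  expect_equal(sampleSummary(gr)$frac_late, 0)           # no rt < 0
  S4Vectors::mcols(gr)$rt <- c(-1, -2, 0.1, 0.5)
  expect_equal(sampleSummary(gr)$frac_late, 0.5)         # uniform, half late
  expect_equal(sampleSummary(gr, lateSign = "positive")$frac_late, 0.5)
  S4Vectors::mcols(gr)$rt <- c(-1, 1, 1, 1)
  expect_equal(sampleSummary(gr, lateSign = "positive")$frac_late, 0.75)
})

test_that("gene RT profiles inherit the domain of the most 5' promoter probe", {
  co <- smallCohortRT()
  tracks <- co$rtCache$tracks
  domains <- co$rtCache$domains
  prof <- co$rtCache$geneRT
  # two genes anchored in the same domain have identical profiles
  mf <- co$manifest
  pm <- lionessRT:::.promoterMap(mf)
  pm <- merge(pm, mf[, c("probe_id", "chrom", "pos")])
  anchor <- vapply(rownames(prof), function(g) {
    rows <- pm[pm$gene == g, ]
    i <- which.min(rows$pos)
    hit <- GenomicRanges::findOverlaps(
      GenomicRanges::GRanges(rows$chrom[i], IRanges::IRanges(rows$pos[i] + 1L, width = 1L)),
      windowRanges(domains), select = "first")
    as.integer(hit)
  }, integer(1))
  shared <- names(anchor)[duplicated(anchor) | duplicated(anchor, fromLast = TRUE)]
  if (length(shared) >= 2) {
    pair <- names(anchor)[anchor == anchor[shared[1]]][1:2]
    expect_equal(prof[pair[1], ], prof[pair[2], ])
  }
  # profiles equal a direct per-sample recomputation
  expect_equal(prof, rtMatrix(domains)[anchor, , drop = FALSE],
               ignore_attr = TRUE)
})

test_that("cohort tracks match single-sample computation and export to bedGraph", {
  co <- smallCohort()
  grid <- makeWindowGrid(co$manifest, 200000L)
  tracks <- rtTrackSet(co$beta[, 1:3], co$manifest, grid)
  one <- methylationToRT(binAndSmooth(co$beta[, 2], co$manifest, grid))
  expect_equal(rtMatrix(tracks)[, 2], S4Vectors::mcols(one)$rt)
  path <- file.path(withr::local_tempdir(), "s.bedGraph")
  exportRTTrack(tracks, sampleIds(tracks)[1], path)
  bg <- rtracklayer::import(path, format = "bedGraph")
  expect_equal(length(bg), sum(!is.na(rtMatrix(tracks)[, 1])))
  expect_equal(bg$score, unname(rtMatrix(tracks)[!is.na(rtMatrix(tracks)[, 1]), 1]),
               tolerance = 1e-6)
})
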