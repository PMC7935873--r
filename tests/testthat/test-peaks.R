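flatPileup <- function(v, name = "x", contig = "c")
  TagPileup(name, setNames(list(v), contig),
            setNames(list(numeric(length(v))), contig))

test_that("the enrichment track is zero for equal and for depth-shifted libraries", {
  withr::with_seed(31, v <- rpois(300, 20) + 1)
  expect_equal(trackValues(enrichmentTrack(flatPileup(v), flatPileup(v)), "c"),
               numeric(300))
  # a uniform 2x depth difference is normalised away
  expect_equal(trackValues(enrichmentTrack(flatPileup(2 * v), flatPileup(v)),
                           "c"),
               numeric(300))
})

test_that("per-position log-likelihood ratios match a numeric-maximisation oracle", {
  ip <- c(rep(5, 50), 50, rep(5, 49))
  input <- rep(5, 100)
  pp <- peakParams()
  tr <- enrichmentTrack(flatPileup(ip, "ip"), flatPileup(input, "in"), pp)
  s <- sum(input) / sum(ip)  # deeper (IP) library scaled down
  x <- 50 * s + pp$pseudocount
  y <- 5 + pp$pseudocount
  expect_equal(trackValues(tr, "c")[51], bruteForceLlr(x, y),
               tolerance = 1e-6)
  # positions where scaled IP is below input score zero (one-sided)
  expect_true(all(trackValues(tr, "c")[-51] == 0))
})

test_that("region calling merges small gaps and discards short regions", {
  pp <- peakParams(g = 20L, l = 120L, llr_cutoff = 2)
  v <- numeric(600)
  v[101:200] <- 5     # 100-nt run
  v[216:350] <- 5     # 15-nt gap (<= g): merged; total 250 nt
  v[500:590] <- 5     # isolated 91-nt run (< l): discarded
  reg <- callRegions(SignalTrack(list(c = v)), pp)
  expect_equal(nrow(reg), 1L)
  expect_equal(c(reg$start, reg$end), c(100L, 350L))

  # an isolated run of exactly 100 nt is discarded at l = 120
  v2 <- numeric(400); v2[101:200] <- 9
  expect_equal(nrow(callRegions(SignalTrack(list(c = v2)), pp)), 0L)
})

test_that("region calling equals the threshold/merge/filter oracle on random tracks", {
  pp <- peakParams(g = 5L, l = 12L, llr_cutoff = 2)
  for (rep in 1:100) {
    withr::with_seed(7000 + rep,
      v <- pmax(rnorm(400, mean = 1.2, sd = 1.5), 0))
    reg <- callRegions(SignalTrack(list(c = v)), pp)
    oracle <- bruteForceRegions(v, pp$llr_cutoff, pp$g, pp$l)
    expect_equal(reg$start, oracle$start)
    expect_equal(reg$end, oracle$end)
  }
})

test_that("dependence labels follow the mutant-overlap rule and partition regions", {
  pp <- peakParams()
  wt <- numeric(1000); wt[101:300] <- 5; wt[501:700] <- 5
  mut <- numeric(1000); mut[101:300] <- 5   # first region persists in mutant
  mut[801:950] <- 5                         # mutant-only region
  wt_tr <- SignalTrack(list(c = wt)); mut_tr <- SignalTrack(list(c = mut))
  peaks <- classifyDependence(callRegions(wt_tr, pp), wt_tr, mut_tr, pp)
  expect_equal(peaks$label, c("independent", "dependent", "mutant_only"))
  expect_equal(peaks$start, c(100L, 500L, 800L))
  # WT regions carry exactly one dependent/independent label
  wtl <- peaks$label[peaks$label != "mutant_only"]
  expect_equal(length(wtl), 2L)
})

test_that("synthetic dependent and independent sites are labelled accordingly", {
  fix <- pipelineFixture()
  dep <- fix$sites[fix$sites$dependence == "dependent", ]
  ind <- fix$sites[fix$sites$dependence == "independent", ]
  expect_gt(siteFractionInLabel(dep, fix$peaks, "dependent"), 0.9)
  expect_gt(siteFractionInLabel(ind, fix$peaks, "independent"), 0.8)
})

test_that("peak splitting cuts deep valleys only and conserves coverage", {
  pp <- peakParams(smooth_window = 1L, min_child_len = 5L)
  # twin summits 100 and 80 with a valley of 30 (< 0.5 * 80): split
  v <- c(seq(10, 100, length.out = 30), seq(99, 30, length.out = 30),
         seq(31, 80, length.out = 30), seq(79, 20, length.out = 30))
  tr <- SignalTrack(list(c = c(numeric(10), v, numeric(10))))
  peaks <- data.frame(name = "p", contig = "c", start = 10L,
                      end = 10L + length(v), score = 3, summit = 40L,
                      label = "dependent", stringsAsFactors = FALSE)
  sp <- splitPeaks(peaks, tr, pp)
  expect_equal(nrow(sp), 2L)
  expect_equal(sp$start[1], peaks$start)
  expect_equal(sp$end[2], peaks$end)
  expect_equal(sp$start[2], sp$end[1])           # children tile the parent
  expect_true(all(sp$label == "dependent"))      # label inherited

  # valley of 50 (>= 0.5 * 80): not split
  v2 <- c(seq(10, 100, length.out = 30), seq(99, 50, length.out = 30),
          seq(51, 80, length.out = 30), seq(79, 20, length.out = 30))
  tr2 <- SignalTrack(list(c = c(numeric(10), v2, numeric(10))))
  expect_equal(nrow(splitPeaks(peaks, tr2, pp)), 1L)

  # monotone signal: returned unchanged
  v3 <- seq_len(length(v))
  tr3 <- SignalTrack(list(c = c(numeric(10), v3, numeric(10))))
  sp3 <- splitPeaks(peaks, tr3, pp)
  expect_equal(nrow(sp3), 1L)
  expect_equal(c(sp3$start, sp3$end), c(peaks$start, peaks$end))
})

test_that("splitting the synthetic peaks conserves intervals and labels", {
  fix <- pipelineFixture()
  sp <- splitPeaks(fix$peaks, pileupCoverage(fix$libs$wt_ip), fix$pp)
  expect_gte(nrow(sp), nrow(fix$peaks))
  for (pn in unique(sp$parent)) {
    ch <- sp[sp$parent == pn, ]
    pa <- fix$peaks[fix$peaks$name == pn, ]
    expect_equal(min(ch$start), pa$start)
    expect_equal(max(ch$end), pa$end)
    # children tile the parent without overlap
    o <- order(ch$start)
    expect_true(all(ch$end[o][-nrow(ch)] == ch$start[o][-1]))
    expect_true(all(ch$label == pa$label))
  }
})

test_that("peak ranking is score-descending with stable coordinate ties", {
  peaks <- data.frame(name = c("a", "b", "c", "d"), contig = "c",
                      start = c(40L, 10L, 90L, 5L), end = c(60L, 30L, 110L, 25L),
                      score = c(2, 7, 2, 1), summit = 1L, label = "dependent",
                      stringsAsFactors = FALSE)
  r <- rankPeaks(peaks)
  expect_equal(r$name, c("b", "a", "c", "d"))
  # permuted input gives the identical order
  r2 <- rankPeaks(peaks[c(3, 1, 4, 2), ])
  expect_equal(r2$name, r$name)
})

test_that("the top-ranked synthetic peak covers a planted site", {
  fix <- pipelineFixture()
  top <- rankPeaks(fix$peaks)[1, ]
  expect_true(any(fix$sites$m6a_pos >= top$start &
                  fix$sites$m6a_pos < top$end))
})

test_that("peak matrices show body enrichment, edge NA padding and genotype contrast", {
  # uniform 4x enrichment across the body, 1x flanks
  n <- 2000L
  ip <- rep(10, n); input <- rep(10, n)
  ip[801:1200] <- 40
  peaks <- data.frame(name = "p", contig = "c", start = 800L, end = 1200L,
                      score = 1, summit = 900L, label = "dependent",
                      stringsAsFactors = FALSE)
  pp <- peakParams(pseudocount = 0)
  m <- peakMatrix(peaks, flatPileup(ip, "ip"), flatPileup(input, "in"), pp)
  s <- sum(input) / sum(ip)
  expect_equal(unname(m[1, 51:250]), rep(4 * s, 200))
  expect_equal(unname(m[1, 1:50]), rep(1 * s, 50))
  expect_equal(unname(m[1, 251:300]), rep(1 * s, 50))

  # peak at the contig start: left flank is NA
  peaks0 <- transform(peaks, start = 0L, end = 400L)
  m0 <- peakMatrix(peaks0, flatPileup(ip, "ip"), flatPileup(input, "in"), pp)
  expect_true(all(is.na(m0[1, 1:50])))
  expect_true(all(!is.na(m0[1, 51:300])))

  # dependent peaks: WT rows brighter than the same intervals in the mutant
  fix <- pipelineFixture()
  dep <- fix$peaks[fix$peaks$label == "dependent", ]
  mw <- peakMatrix(dep, fix$libs$wt_ip, fix$libs$wt_input, fix$pp)
  mm <- peakMatrix(dep, fix$libs$mut_ip, fix$libs$mut_input, fix$pp)
  expect_gt(mean(rowMeans(mw, na.rm = TRUE)),
            mean(rowMeans(mm, na.rm = TRUE)))
})
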