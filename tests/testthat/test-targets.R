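test_that("peak annotation applies the fixed precedence order", {
  # gene on [100, 400): 5'UTR 100-160, CDS 160-340, 3'UTR 340-400
  models <- simpleModel(contig = "c", start = 100L, u5 = 60L, cds = 180L,
                        u3 = 60L)
  pk <- function(s, e) data.frame(contig = "c", start = s, end = e,
                                  stringsAsFactors = FALSE)
  expect_equal(annotatePeaks(pk(0L, 50L), models)$category, "other")
  # overlapping both start codon (160-163) and 5'UTR: start codon wins
  expect_equal(annotatePeaks(pk(150L, 162L), models)$category, "start_codon")
  expect_equal(annotatePeaks(pk(120L, 150L), models)$category, "utr5")
  # overlapping 3'UTR and CDS: 3'UTR earlier in the order
  expect_equal(annotatePeaks(pk(300L, 360L), models)$category, "utr3")
  expect_equal(annotatePeaks(pk(200L, 300L), models)$category, "cds")

  # introns outrank every exonic category
  two <- makeModels(data.frame(
    contig = "c", start = c(100L, 300L, 150L), end = c(200L, 400L, 350L),
    strand = "+", type = c("exon", "exon", "CDS"), gene_id = "g2",
    transcript_id = "g2.t", stringsAsFactors = FALSE))
  expect_equal(annotatePeaks(pk(190L, 310L), two)$category, "intron")

  # minus-strand start codon sits at the CDS high-coordinate end
  mm <- simpleModel(contig = "c", start = 100L, u5 = 60L, cds = 180L,
                    u3 = 60L, strand = "-")
  expect_equal(annotatePeaks(pk(338L, 342L), mm)$category, "start_codon")
})

test_that("category fractions sum to one and reject empty inputs", {
  peaks <- data.frame(contig = "c", start = c(0L, 10L, 20L, 30L),
                      end = c(5L, 15L, 25L, 35L),
                      category = c("utr5", "utr5", "cds", "other"),
                      stringsAsFactors = FALSE)
  fr <- categoryFractions(peaks)
  expect_equal(sum(fr$fraction), 1)
  expect_equal(fr$fraction[fr$category == "utr5"], 0.5)
  expect_equal(fr$fraction[fr$category == "cds"], 0.25)
  expect_error(categoryFractions(peaks[0, ]), "empty")
})

test_that("planted-site annotation recovers the configured 5'UTR bias", {
  fix <- pipelineFixture()
  s <- fix$sites
  site_iv <- data.frame(contig = s$contig, start = s$m6a_pos,
                        end = s$m6a_pos + 1L, stringsAsFactors = FALSE)
  ann <- annotatePeaks(site_iv, fix$models)
  expect_equal(unname(ann$category == "utr5"), unname(s$segment == "utr5"))
  frac <- mean(ann$category == "utr5")
  se <- sqrt(0.8 * 0.2 / nrow(s))
  expect_lt(abs(frac - 0.8), 3 * se)
})

test_that("gene binning counts dependent peaks only and partitions the universe", {
  models <- makeModels(data.frame(
    contig = "c", start = c(0L, 1000L, 2000L), end = c(500L, 1500L, 2500L),
    strand = "+", type = "exon", gene_id = c("g1", "g2", "g3"),
    transcript_id = c("g1.t", "g2.t", "g3.t"), stringsAsFactors = FALSE))
  peaks <- data.frame(
    contig = "c",
    start = c(10L, 60L, 110L, 160L, 210L, 1010L, 1100L),
    end = c(50L, 100L, 150L, 200L, 250L, 1050L, 1140L),
    label = c(rep("dependent", 5), "independent", "independent"),
    stringsAsFactors = FALSE)
  bins <- binGenesByPeakCount(peaks, models)
  expect_equal(bins$bin[bins$gene_id == "g1"], "3+")  # 5 dependent peaks
  expect_equal(bins$bin[bins$gene_id == "g2"], "none")  # independent only
  expect_equal(bins$bin[bins$gene_id == "g3"], "none")
  expect_equal(nrow(bins), 3L)
  expect_equal(sum(table(bins$bin)), 3L)
})

test_that("bootstrap backgrounds are seeded, degenerate-safe and consistent", {
  expect_equal(bootstrapBackground(5.0, n_draws = 10L, draw_size = 3L),
               rep(5, 30))
  withr::with_seed(2, pool <- rnorm(200))
  a <- bootstrapBackground(pool, 1000L, 50L, seed = 9L)
  b <- bootstrapBackground(pool, 1000L, 50L, seed = 9L)
  expect_identical(a, b)
  se <- sd(pool) / sqrt(length(pool))
  expect_lt(abs(mean(a) - mean(pool)), 3 * se)
  expect_error(bootstrapBackground(numeric(0), 10L, 5L), "empty")
})

test_that("the KS statistic matches hand values and the exhaustive oracle", {
  r <- ksTwoSample(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r$D, 0)
  expect_equal(r$p, 1)
  expect_equal(ksTwoSample(c(1, 2, 3), c(4, 5, 6))$D, 1)
  expect_equal(ksTwoSample(c(1, 3), c(2, 4))$D, 0.5)

  # exact equality with the brute-force sup over a grid of small samples
  withr::with_seed(13, {
    for (i in 1:50) {
      n <- sample(1:8, 1); m <- sample(1:8, 1)
      x <- sample(seq(0, 2, by = 0.25), n, replace = TRUE)
      y <- sample(seq(0, 2, by = 0.25), m, replace = TRUE)
      expect_equal(ksTwoSample(x, y)$D, bruteForceKsD(x, y))
    }
  })
  # cross-check D against the stats implementation on continuous data
  withr::with_seed(14, {
    x <- rnorm(40); y <- rnorm(60, 0.4)
  })
  expect_equal(ksTwoSample(x, y)$D, unname(stats::ks.test(x, y)$statistic))
})

test_that("bin comparisons recover a planted TE effect with ordered medians", {
  cfg <- simConfig(n_genes = 900L, frac_methylated = 0.35, te_effect = 0.5,
                   property_na_rate = 0, seed = 17L)
  sim <- simulateTranscriptome(cfg)
  pl <- plantM6ASites(sim$genome, sim$models, cfg)
  props <- simulatePropertyTables(sim$models, pl$sites, cfg)
  dep <- pl$sites[pl$sites$dependence == "dependent", ]
  peaks <- data.frame(contig = dep$contig, start = dep$m6a_pos,
                      end = dep$m6a_pos + 1L, label = "dependent",
                      stringsAsFactors = FALSE)
  bins <- binGenesByPeakCount(peaks, sim$models)
  res <- compareBins(props, bins, n_draws = 300L, seed = 5L)
  te <- res[res$property == "translational_efficiency", ]
  expect_lt(te$p[te$bin == "3+"], 0.05)
  m <- setNames(te$median_bin, te$bin)
  expect_true(m[["3+"]] < m[["2"]] && m[["2"]] < m[["1"]] &&
              m[["1"]] < te$median_bg[te$bin == "1"])

  # output is invariant to the row order of the inputs
  res2 <- compareBins(props[sample(nrow(props)), ],
                      bins[rev(seq_len(nrow(bins))), ],
                      n_draws = 300L, seed = 5L)
  expect_equal(res, res2)

  # ECDF export covers every bin and stays within (0, 1]
  ec <- binEcdfTable(props, bins)
  expect_setequal(unique(ec$bin), unique(bins$bin))
  expect_true(all(ec$ecdf > 0 & ec$ecdf <= 1))
})
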