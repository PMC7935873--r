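test_that("transcriptome simulation is byte-deterministic under a seed", {
  cfg <- simConfig(n_genes = 10L, seed = 42L)
  a <- simulateTranscriptome(cfg)
  b <- simulateTranscriptome(cfg)
  fa <- withr::local_tempfile(fileext = ".fa")
  fb <- withr::local_tempfile(fileext = ".fa")
  writeGenome(a$genome, fa); writeGenome(b$genome, fb)
  expect_identical(readLines(fa), readLines(fb))
  ga <- withr::local_tempfile(fileext = ".gtf")
  gb <- withr::local_tempfile(fileext = ".gtf")
  writeTranscriptModels(a$models, ga); writeTranscriptModels(b$models, gb)
  expect_identical(readLines(ga), readLines(gb))
})

test_that("simulated transcripts conserve segment lengths and hit the configured mean", {
  cfg <- simConfig(n_genes = 500L, cds_len = 900, seed = 3L)
  sim <- simulateTranscriptome(cfg)
  tx <- transcriptTable(sim$models)
  expect_true(all(tx$utr5_len + tx$cds_len + tx$utr3_len == tx$mature_length))
  se <- sd(tx$cds_len) / sqrt(nrow(tx))
  expect_lt(abs(mean(tx$cds_len) - 900), 3 * se + 1.5)  # +1.5: codon rounding
})

test_that("planted sites carry the A/C dinucleotide and honour segment bias", {
  fix <- pipelineFixture()
  sites <- fix$sites
  ctx <- c(extractContexts(sites, fix$genome, flank = 2))
  expect_true(all(substr(ctx, 3, 4) == "AC"))  # centre A then the mutated C
  # cim_pos is the transcript-adjacent base 3' of m6a_pos
  expect_true(all(ifelse(sites$strand == "+",
                         sites$cim_pos == sites$m6a_pos + 1L,
                         sites$cim_pos == sites$m6a_pos - 1L)))
})

test_that("segment bias of (1,0,0) forces every site into the 5'UTR", {
  cfg <- simConfig(n_genes = 40L, segment_bias = c(utr5 = 1, cds = 0, utr3 = 0),
                   seed = 11L)
  sim <- simulateTranscriptome(cfg)
  pl <- plantM6ASites(sim$genome, sim$models, cfg)
  expect_true(all(pl$sites$segment == "utr5"))
})

test_that("default segment bias lands ~80% of many sites in 5'UTRs", {
  cfg <- simConfig(n_genes = 700L, frac_methylated = 0.9, seed = 5L)
  sim <- simulateTranscriptome(cfg)
  pl <- plantM6ASites(sim$genome, sim$models, cfg)
  n <- nrow(pl$sites)
  expect_gt(n, 800)
  frac <- mean(pl$sites$segment == "utr5")
  se <- sqrt(0.8 * 0.2 / n)
  expect_lt(abs(frac - 0.8), 3 * se + 0.01)  # +0.01: collision resampling
})

test_that("planted-context registry matches a rescan of the emitted genome", {
  fix <- pipelineFixture()
  ctx <- extractContexts(fix$sites, fix$genome,
                         flank = fix$cfg$context_offset)
  # planted context AAACT with the A at offset 2: flank-2 window reads AAACT
  expect_true(all(substr(ctx, 1, 5) == fix$cfg$context))
})

test_that("miCLIP libraries show the designed genotype-specific enrichment", {
  fix <- pipelineFixture()
  covmean <- function(lib, pos)
    mean(trackValues(pileupCoverage(fix$libs[[lib]]), "chrS")[(pos - 20):(pos + 20) + 1L])
  dep <- fix$sites[fix$sites$dependence == "dependent", ]
  ind <- fix$sites[fix$sites$dependence == "independent", ]
  depth <- fix$cfg$depth
  # dependent sites: mutant IP stays at input level, wild-type IP enriched
  mut_at_dep <- mean(vapply(dep$m6a_pos, function(p) covmean("mut_ip", p),
                            numeric(1)))
  wt_at_dep <- mean(vapply(dep$m6a_pos, function(p) covmean("wt_ip", p),
                           numeric(1)))
  expect_lt(abs(mut_at_dep / depth - 1), 0.15)
  expect_gt(wt_at_dep / depth, 0.8 * fix$cfg$ip_enrichment)
  # independent sites: both genotypes enriched
  mut_at_ind <- mean(vapply(ind$m6a_pos, function(p) covmean("mut_ip", p),
                            numeric(1)))
  expect_gt(mut_at_ind / depth, 0.8 * fix$cfg$ip_enrichment)
})

test_that("observed m/k at planted CIMs lies inside the filter bounds for >=95% of sites", {
  fix <- pipelineFixture()
  k <- trackValues(pileupCoverage(fix$libs$wt_ip), "chrS")
  m <- trackValues(pileupMismatches(fix$libs$wt_ip), "chrS")
  r <- m[fix$sites$cim_pos + 1L] / k[fix$sites$cim_pos + 1L]
  expect_gte(mean(r > 0.01 & r < 0.5), 0.95)
})

test_that("property tables plant a monotone TE deficit and leave other properties null", {
  cfg <- simConfig(n_genes = 900L, frac_methylated = 0.5, te_effect = 0.5,
                   property_na_rate = 0, seed = 21L)
  sim <- simulateTranscriptome(cfg)
  pl <- plantM6ASites(sim$genome, sim$models, cfg)
  props <- simulatePropertyTables(sim$models, pl$sites, cfg)
  ndep <- table(pl$sites$gene_id[pl$sites$dependence == "dependent"])
  nd <- as.integer(ndep[props$gene_id]); nd[is.na(nd)] <- 0L
  te_mean <- vapply(0:3, function(k)
    mean(props$translational_efficiency[if (k < 3) nd == k else nd >= 3]),
    numeric(1))
  expect_true(all(diff(te_mean) < 0))  # background > 1 site > 2 > 3+
  # half-life of methylated vs background genes: same distribution, so the
  # KS distance shrinks as the simulation grows (averaged over seeds)
  hlD <- function(n_genes, seed) {
    cfg <- simConfig(n_genes = n_genes, frac_methylated = 0.5,
                     property_na_rate = 0, seed = seed)
    sim <- simulateTranscriptome(cfg)
    pl <- plantM6ASites(sim$genome, sim$models, cfg)
    pr <- simulatePropertyTables(sim$models, pl$sites, cfg)
    meth <- pr$gene_id %in% pl$sites$gene_id
    ksTwoSample(pr$half_life_hours[meth], pr$half_life_hours[!meth])$D
  }
  d_small <- mean(vapply(21:23, function(s) hlD(150L, s), numeric(1)))
  d_large <- mean(vapply(21:23, function(s) hlD(900L, s), numeric(1)))
  expect_lt(d_large, d_small)
  expect_lt(d_large, 0.1)
})

test_that("behaviour traces hit the extremes and the null expectation", {
  cfg1 <- behaviorSimConfig(n_units = 3L, seed = 2L)
  pis <- performanceIndices(simulateBehavior(1, cfg1), fps = cfg1$fps)
  expect_equal(pis$half_pi_oct, rep(0.5, 3))
  expect_equal(pis$full_pi, rep(1.0, 3))

  # same seed, byte-identical TSV
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  writeTsvTable(simulateBehavior(0.7, cfg1), f1)
  writeTsvTable(simulateBehavior(0.7, cfg1), f2)
  expect_identical(readLines(f1), readLines(f2))

  cfg2 <- behaviorSimConfig(n_units = 1000L, fps = 2L, test_seconds = 60L,
                            seed = 6L)
  pis2 <- performanceIndices(simulateBehavior(0.5, cfg2), fps = 2)
  se <- sd(pis2$full_pi) / sqrt(nrow(pis2))
  expect_lt(abs(mean(pis2$full_pi)), 3 * se)
})

test_that("spectral counts plant recoverable readers and flag absences", {
  sc <- simulateSpectralCounts(n_background = 300L, n_readers = 2L,
                               n_repelled = 1L, n_absent = 30L,
                               fold = 8, seed = 9L)
  readers <- sc$truth$protein[sc$truth$role == "reader"]
  rat <- enrichmentRatios(sc$counts)
  rr <- rat[rat$protein %in% readers, ]
  expect_lt(abs(mean(c(rr$ratio_rep1, rr$ratio_rep2)) - 3), 0.6)
  bg <- rat[rat$protein %in% sc$truth$protein[sc$truth$role == "background"], ]
  expect_lt(abs(mean(c(bg$ratio_rep1, bg$ratio_rep2))), 0.2)
  # absences are emitted with present = FALSE in exactly one replicate
  ab <- sc$counts[!sc$counts$present, ]
  expect_equal(length(unique(ab$protein)), 30L)
  per <- table(ab$protein, ab$replicate)
  expect_true(all(rowSums(per > 0) == 1))
})
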