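# Shared fixtures and independent brute-force oracles.

makeGenome <- function(...) {
  seqs <- c(...)
  g <- Biostrings::DNAStringSet(unname(seqs))
  names(g) <- names(seqs)
  g
}

# build TranscriptModels straight from a feature table (0-based half-open)
makeModels <- function(df) flym6A:::buildTranscriptModels(df)

# single-exon coding transcript helper
simpleModel <- function(gene = "g1", contig = "chr1", start = 0L,
                        u5 = 30L, cds = 60L, u3 = 30L, strand = "+") {
  len <- u5 + cds + u3
  cdsg <- if (strand == "+") c(start + u5, start + u5 + cds)
          else c(start + u3, start + u3 + cds)
  makeModels(data.frame(
    contig = contig, start = c(start, cdsg[1]), end = c(start + len, cdsg[2]),
    strand = strand, type = c("exon", "CDS"), gene_id = gene,
    transcript_id = paste0(gene, ".t1"), stringsAsFactors = FALSE))
}

# --- independent oracles -------------------------------------------------

# position-by-position CIM filter, written without the vectorised path
bruteForceCims <- function(k, m, bases, m_min = 1, lo = 0.01, hi = 0.5) {
  out <- list()
  for (i in seq_along(k)) {
    if (k[i] == 0) next
    r <- m[i] / k[i]
    if (!(m[i] > m_min && r > lo && r < hi)) next
    if (bases[i] == "C" && i > 1 && bases[i - 1] == "A")
      out[[length(out) + 1L]] <- c(pos = i - 1L, strand = 1L)
    if (bases[i] == "G" && i < length(bases) && bases[i + 1] == "T")
      out[[length(out) + 1L]] <- c(pos = i - 1L, strand = 2L)
  }
  if (length(out) == 0L)
    return(data.frame(pos = integer(0), strand = character(0)))
  d <- as.data.frame(do.call(rbind, out))
  d$strand <- c("+", "-")[d$strand]
  d[order(d$pos, d$strand), ]
}

# threshold -> merge -> length-filter scan, one position at a time
bruteForceRegions <- function(v, cutoff, g, l) {
  qual <- which(v >= cutoff)
  if (length(qual) == 0L)
    return(data.frame(start = integer(0), end = integer(0)))
  regions <- list()
  cur_start <- qual[1]; cur_end <- qual[1]
  for (i in qual[-1]) {
    if (i - cur_end - 1 <= g) cur_end <- i
    else {
      regions[[length(regions) + 1L]] <- c(cur_start, cur_end)
      cur_start <- i; cur_end <- i
    }
  }
  regions[[length(regions) + 1L]] <- c(cur_start, cur_end)
  d <- as.data.frame(do.call(rbind, regions))
  names(d) <- c("from", "to")
  d <- d[d$to - d$from + 1 >= l, , drop = FALSE]
  data.frame(start = d$from - 1L, end = d$to)
}

# exhaustive sup over all real thresholds of |ECDF_x - ECDF_y|
bruteForceKsD <- function(x, y) {
  ts <- sort(unique(c(x, y)))
  max(vapply(ts, function(t) abs(mean(x <= t) - mean(y <= t)), numeric(1)))
}

# two-hypothesis Poisson log10 LR by numeric maximisation (independent of
# the closed form in the implementation)
bruteForceLlr <- function(x, y) {
  loglik <- function(lam, obs) obs * log(lam) - lam
  l1 <- loglik(x, x) + loglik(y, y)
  opt <- optimize(function(l) loglik(l, x) + loglik(l, y),
                  interval = c(1e-6, x + y + 10), maximum = TRUE)
  max((l1 - opt$objective) / log(10), 0)
}

# exact two-tailed Mann-Whitney p by enumerating all group assignments
enumerateMwP <- function(x, y) {
  pooled <- c(x, y)
  n <- length(x)
  idx <- combn(length(pooled), n)
  ustat <- function(a, b) sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  u_obs <- ustat(x, y)
  us <- apply(idx, 2, function(j) ustat(pooled[j], pooled[-j]))
  mu <- n * length(y) / 2
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-12)
}

# --- shared end-to-end pipeline fixture (computed once) ------------------

pipelineFixture <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    cfg <- simConfig(seed = 7L)
    sim <- simulateTranscriptome(cfg)
    pl <- plantM6ASites(sim$genome, sim$models, cfg)
    libs <- simulateMiclipLibraries(pl$genome, sim$models, pl$sites, cfg)
    pp <- peakParams()
    wt <- enrichmentTrack(libs$wt_ip, libs$wt_input, pp)
    mut <- enrichmentTrack(libs$mut_ip, libs$mut_input, pp)
    peaks <- classifyDependence(callRegions(wt, pp), wt, mut, pp)
    cache <<- list(cfg = cfg, genome = pl$genome, models = sim$models,
                   sites = pl$sites, libs = libs, pp = pp, wt = wt,
                   mut = mut, peaks = peaks)
    cache
  }
})

# fraction of sites lying inside peaks of a given label
siteFractionInLabel <- function(sites, peaks, label) {
  p <- peaks[peaks$label == label, , drop = FALSE]
  if (nrow(sites) == 0L) return(NA_real_)
  mean(vapply(seq_len(nrow(sites)), function(i)
    any(p$contig == sites$contig[i] & p$start <= sites$m6a_pos[i] &
        p$end > sites$m6a_pos[i]), logical(1)))
}
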