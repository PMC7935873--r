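# Synthetic-data generation: every input the analysis consumes can be
# simulated with the statistical structure the downstream methods assume
# (5'UTR-biased methylation in an AAACT context, writer-dependent vs
# -independent IP enrichment, planted translational-efficiency deficits,
# biased occupancy traces, spectral counts with planted readers).

derivedSeed <- function(seed, k) (as.integer(seed) + 104729L * k) %% 2147483647L

#' Configuration for the miCLIP simulator
#'
#' Defaults describe the simulated study conditions: mean input depth 30
#' tags per transcript position, 8-fold IP enrichment in a +/-50 nt window
#' around each methylated site (linear decay over a further 60 nt), a
#' C-to-T crosslink-induced transition rate of 0.15 at the site (sequencing
#' error 0.001 elsewhere), 80% of sites in 5'UTRs, 80% of sites dependent
#' on the writer, and the planted context `AAACT` with the methylated A at
#' string offset 2 (0-based) followed by the mutated C.
#'
#' @param n_genes number of genes.
#' @param utr5_len,cds_len,utr3_len mean segment lengths (nt).
#' @param len_cv coefficient of variation of segment lengths.
#' @param frac_methylated fraction of genes carrying at least one site.
#' @param sites_per_gene_dist named probability vector over site counts.
#' @param frac_dependent fraction of sites dependent on the writer.
#' @param segment_bias probability a site lands in 5'UTR/CDS/3'UTR.
#' @param context planted motif; `context_offset` (0-based) marks the
#'   methylated A, which must be followed by a C.
#' @param context_offset 0-based offset of the methylated A in `context`.
#' @param ip_enrichment fold IP-over-input coverage at sites.
#' @param depth mean input coverage per transcript position.
#' @param cim_rate per-tag C-to-T probability at the crosslinked C; must lie
#'   strictly inside (0.01, 0.5) so planted sites pass the CIM filter.
#' @param error_rate off-site C-to-T sequencing-error rate.
#' @param te_effect per-dependent-site decrement of log2 translational
#'   efficiency.
#' @param site_window half-width (nt) of the full-enrichment window.
#' @param flank_decay nt over which enrichment decays linearly to 1.
#' @param intergenic intergenic spacer length (nt).
#' @param n_exons exons per transcript (introns of `intron_len` nt).
#' @param intron_len intron length when `n_exons > 1`.
#' @param minus_strand_frac fraction of genes on the minus strand.
#' @param background_depth_frac intergenic coverage as a fraction of depth.
#' @param property_na_rate fraction of missing values per property table
#'   column.
#' @param seed integer master seed; all `simulate*` functions derive their
#'   streams from it deterministically.
#' @return validated configuration list (class `SimConfig`).
#' @export
simConfig <- function(n_genes = 200L, utr5_len = 300, cds_len = 900,
                      utr3_len = 400, len_cv = 0.15,
                      frac_methylated = 0.3,
                      sites_per_gene_dist = c("1" = 0.6, "2" = 0.3, "3" = 0.1),
                      frac_dependent = 0.8,
                      segment_bias = c(utr5 = 0.8, cds = 0.1, utr3 = 0.1),
                      context = "AAACT", context_offset = 2L,
                      ip_enrichment = 8, depth = 30, cim_rate = 0.15,
                      error_rate = 0.001, te_effect = 0.5,
                      site_window = 50L, flank_decay = 60L,
                      intergenic = 400L, n_exons = 1L, intron_len = 80L,
                      minus_strand_frac = 0.5,
                      background_depth_frac = 0.02,
                      property_na_rate = 0.02, seed = 1L) {
  cfg <- as.list(environment())
  fr <- c(frac_methylated, frac_dependent, minus_strand_frac,
          property_na_rate)
  if (any(fr < 0 | fr > 1)) stop("fractions must lie in [0, 1]")
  if (abs(sum(sites_per_gene_dist) - 1) > 1e-9 ||
      abs(sum(segment_bias) - 1) > 1e-9)
    stop("sites_per_gene_dist and segment_bias must sum to 1")
  if (!(cim_rate > 0.01 && cim_rate < 0.5))
    stop("cim_rate must lie strictly inside (0.01, 0.5)")
  if (depth <= 0) stop("depth must be positive")
  bases <- strsplit(context, "")[[1]]
  if (context_offset + 2L > length(bases) ||
      bases[context_offset + 1L] != "A")
    stop("context_offset must index an A within the context")
  class(cfg) <- "SimConfig"
  cfg
}

revcompBase <- function(b) c(A = "T", C = "G", G = "C", T = "A", N = "N")[b]

#' Simulate a transcriptome (genome FASTA + transcript models)
#'
#' One transcript per gene laid out sequentially on a single contig
#' (`chrS`) with random uniform background sequence, intergenic spacers,
#' and segment lengths drawn around the configured means (truncated
#' normal).  Deterministic under `cfg$seed`.
#'
#' @param cfg a [simConfig()] list.
#' @return list with elements `genome` (`DNAStringSet`) and `models`
#'   ([TranscriptModels-class]).
#' @export
simulateTranscriptome <- function(cfg) {
  stopifnot(inherits(cfg, "SimConfig"))
  withr::with_seed(derivedSeed(cfg$seed, 0L), {
    n <- cfg$n_genes
    drawLen <- function(mu, floor_) {
      l <- round(rnorm(n, mu, cfg$len_cv * mu))
      pmax(l, floor_)
    }
    minseg <- nchar(cfg$context) + 14L
    u5 <- drawLen(cfg$utr5_len, minseg)
    cd <- drawLen(cfg$cds_len, max(minseg, 90L))
    cd <- cd - cd %% 3L  # keep CDS a codon multiple
    u3 <- drawLen(cfg$utr3_len, minseg)
    mat <- u5 + cd + u3
    strand <- ifelse(runif(n) < cfg$minus_strand_frac, "-", "+")
    glen <- mat + (cfg$n_exons - 1L) * cfg$intron_len
    starts <- cfg$intergenic + cumsum(c(0L, (glen + cfg$intergenic)[-n]))
    total <- starts[n] + glen[n] + cfg$intergenic
    seq <- sample(c("A", "C", "G", "T"), total, replace = TRUE)
    ids <- sprintf("g%04d", seq_len(n))
    exons <- vector("list", n)
    rows <- vector("list", n)
    for (i in seq_len(n)) {
      # split the mature length into n_exons roughly equal exons
      ne <- cfg$n_exons
      cuts <- round(seq(0L, mat[i], length.out = ne + 1L))
      w <- diff(cuts)
      es <- starts[i] + cumsum(c(0L, (w + cfg$intron_len)[-ne]))
      exm <- cbind(es, es + w)
      storage.mode(exm) <- "integer"
      tid <- paste0(ids[i], ".t1")
      cdst <- c(u5[i], u5[i] + cd[i])  # transcript coords
      cdsg <- segmentGenomicIntervals(exm, strand[i], cdst[1], cdst[2])
      rows[[i]] <- data.frame(
        gene_id = ids[i], transcript_id = tid, contig = "chrS",
        strand = strand[i], cds_start = min(cdsg[, 1]),
        cds_end = max(cdsg[, 2]), mature_length = mat[i],
        utr5_len = u5[i], cds_len = cd[i], utr3_len = u3[i],
        stringsAsFactors = FALSE)
      exons[[i]] <- exm
    }
    tx <- do.call(rbind, rows)
    names(exons) <- tx$transcript_id
    genome <- Biostrings::DNAStringSet(paste0(seq, collapse = ""))
    names(genome) <- "chrS"
    list(genome = genome,
         models = new("TranscriptModels", transcripts = tx, exons = exons))
  })
}

#' Plant m6A sites into a simulated transcriptome
#'
#' Writes the configured context into the genome at each site
#' (strand-aware: the transcript reads the context 5'->3') and records a
#' registry of planted sites with their genomic m6A (methylated A) and CIM
#' (following C) positions, transcript segment and writer dependence.
#'
#' @param genome `DNAStringSet` from [simulateTranscriptome()].
#' @param models matching [TranscriptModels-class].
#' @param cfg a [simConfig()] list.
#' @return list with elements `genome` (modified) and `sites` (data.frame:
#'   gene_id, transcript_id, contig, strand, t_pos, m6a_pos, cim_pos,
#'   segment, dependence).
#' @export
plantM6ASites <- function(genome, models, cfg) {
  stopifnot(inherits(cfg, "SimConfig"))
  tx <- models@transcripts
  ctx <- strsplit(cfg$context, "")[[1]]
  L <- length(ctx)
  off <- cfg$context_offset
  pad <- 6L  # keep motif-extraction flanks inside the transcript
  withr::with_seed(derivedSeed(cfg$seed, 1L), {
    nmeth <- round(cfg$frac_methylated * nrow(tx))
    meth <- sort(sample(seq_len(nrow(tx)), nmeth))
    out <- list()
    for (i in meth) {
      nsites <- as.integer(sample(names(cfg$sites_per_gene_dist), 1L,
                                  prob = cfg$sites_per_gene_dist))
      segs <- sample(c("utr5", "cds", "utr3"), nsites, replace = TRUE,
                     prob = cfg$segment_bias)
      bounds <- segmentTranscriptBounds(tx[i, ])
      chosen <- integer(0)
      keptseg <- character(0)
      for (s in segs) {
        lo <- bounds[[s]][1] + off + pad
        hi <- bounds[[s]][2] - (L - off) - pad
        if (hi <= lo) next
        ok <- FALSE
        for (try in 1:100) {
          t <- as.integer(floor(runif(1, lo, hi)))
          if (all(abs(t - chosen) >= L + 1L)) { ok <- TRUE; break }
        }
        if (!ok) next  # drop colliding site
        chosen <- c(chosen, t)
        keptseg <- c(keptseg, s)
      }
      if (length(chosen) == 0L) next
      dep <- ifelse(runif(length(chosen)) < cfg$frac_dependent,
                    "dependent", "independent")
      ex <- models@exons[[tx$transcript_id[i]]]
      for (j in seq_along(chosen)) {
        t <- chosen[j]
        tspan <- (t - off):(t - off + L - 1L)
        gpos <- transcriptToGenomic(ex, tx$strand[i], tspan)
        letters <- if (tx$strand[i] == "+") ctx else revcompBase(ctx)
        out[[length(out) + 1L]] <- data.frame(
          gene_id = tx$gene_id[i], transcript_id = tx$transcript_id[i],
          contig = tx$contig[i], strand = tx$strand[i], t_pos = t,
          m6a_pos = transcriptToGenomic(ex, tx$strand[i], t),
          cim_pos = transcriptToGenomic(ex, tx$strand[i], t + 1L),
          segment = keptseg[j], dependence = dep[j],
          plant_gpos = I(list(gpos)), plant_letters = I(list(letters)),
          stringsAsFactors = FALSE)
      }
    }
    if (length(out) == 0L)
      stop("no sites could be planted; transcripts too short?")
    sites <- do.call(rbind, out)
    # apply all edits per contig in one replaceLetterAt call
    for (nm in unique(sites$contig)) {
      rows <- sites$contig == nm
      at <- unlist(sites$plant_gpos[rows]) + 1L  # to 1-based
      lt <- unlist(sites$plant_letters[rows])
      keep <- !duplicated(at, fromLast = TRUE)
      genome[[nm]] <- Biostrings::replaceLetterAt(
        genome[[nm]], at[keep], lt[keep])
    }
    sites$plant_gpos <- NULL
    sites$plant_letters <- NULL
    rownames(sites) <- NULL
    list(genome = genome, sites = sites)
  })
}

# enrichment-factor profile: 1 everywhere, rising to `fold` within
# +/-site_window of each site with linear shoulders over flank_decay nt
enrichmentProfile <- function(len, site_pos, cfg) {
  f <- rep(1, len)
  W <- cfg$site_window; D <- cfg$flank_decay; E <- cfg$ip_enrichment
  for (p in site_pos) {
    lo <- max(0L, p - W - D); hi <- min(len - 1L, p + W + D)
    d <- abs(seq(lo, hi) - p)
    w <- ifelse(d <= W, 1, pmax(0, 1 - (d - W) / D))
    idx <- (lo:hi) + 1L
    f[idx] <- pmax(f[idx], 1 + (E - 1) * w)
  }
  f
}

#' Simulate the four miCLIP tag pileups
#'
#' Input coverage is Poisson(`depth`) over exonic positions (a small
#' `background_depth_frac` of that elsewhere); IP coverage is multiplied by
#' the enrichment profile around sites active in that library (all planted
#' sites for wild-type IP, only writer-independent sites for mutant IP).
#' C-to-T mismatch counts are Binomial(k, `cim_rate`) at the CIM position
#' of active sites in IP libraries and Binomial(k, `error_rate`) elsewhere.
#'
#' @param genome planted `DNAStringSet`.
#' @param models [TranscriptModels-class].
#' @param sites planted-site registry from [plantM6ASites()].
#' @param cfg a [simConfig()] list.
#' @return named list of four [TagPileup-class] objects: `wt_ip`,
#'   `wt_input`, `mut_ip`, `mut_input`.
#' @export
simulateMiclipLibraries <- function(genome, models, sites, cfg) {
  stopifnot(inherits(cfg, "SimConfig"))
  lens <- contigLengths(genome)
  # exonic mask per contig
  exonic <- lapply(setNames(names(lens), names(lens)),
                   function(nm) logical(lens[[nm]]))
  tx <- models@transcripts
  for (i in seq_len(nrow(tx))) {
    ex <- models@exons[[tx$transcript_id[i]]]
    for (j in seq_len(nrow(ex)))
      exonic[[tx$contig[i]]][(ex[j, 1] + 1L):ex[j, 2]] <- TRUE
  }
  active <- list(
    wt_ip = sites, wt_input = sites[0, ],
    mut_ip = sites[sites$dependence == "independent", , drop = FALSE],
    mut_input = sites[0, ])
  enriched <- c(wt_ip = TRUE, wt_input = FALSE, mut_ip = TRUE,
                mut_input = FALSE)
  libs <- list()
  for (lib in names(active)) {
    seed <- derivedSeed(cfg$seed, 2L + match(lib, names(active)))
    libs[[lib]] <- withr::with_seed(seed, {
      cov <- list(); mm <- list()
      for (nm in names(lens)) {
        len <- lens[[nm]]
        lambda <- cfg$depth *
          ifelse(exonic[[nm]], 1, cfg$background_depth_frac)
        sub <- active[[lib]][active[[lib]]$contig == nm, , drop = FALSE]
        if (enriched[[lib]] && nrow(sub) > 0L)
          lambda <- lambda * enrichmentProfile(len, sub$m6a_pos, cfg)
        k <- rpois(len, lambda)
        p <- rep(cfg$error_rate, len)
        if (nrow(sub) > 0L) p[sub$cim_pos + 1L] <- cfg$cim_rate
        m <- rbinom(len, k, p)
        cov[[nm]] <- k; mm[[nm]] <- m
      }
      TagPileup(lib, SignalTrack(cov), SignalTrack(mm))
    })
  }
  libs
}

#' Simulate gene-level property tables
#'
#' log2 fold change and mRNA half-life are independent of methylation;
#' log2 translational efficiency is decremented by `te_effect` per planted
#' writer-dependent site.
#'
#' @param models [TranscriptModels-class].
#' @param sites planted-site registry.
#' @param cfg a [simConfig()] list.
#' @param seed optional seed overriding the one derived from `cfg$seed`
#'   (useful for replicate tables over one transcriptome).
#' @return data.frame: gene_id, log2fc, half_life_hours,
#'   translational_efficiency (with `NA`s at `property_na_rate`).
#' @export
simulatePropertyTables <- function(models, sites, cfg, seed = NULL) {
  stopifnot(inherits(cfg, "SimConfig"))
  genes <- unique(models@transcripts$gene_id)
  ndep <- table(sites$gene_id[sites$dependence == "dependent"])
  nd <- as.integer(ndep[genes])
  nd[is.na(nd)] <- 0L
  if (is.null(seed)) seed <- derivedSeed(cfg$seed, 10L)
  withr::with_seed(seed, {
    n <- length(genes)
    df <- data.frame(
      gene_id = genes,
      log2fc = rnorm(n, 0, 0.5),
      half_life_hours = rlnorm(n, log(3), 0.6),
      translational_efficiency = 2^(rnorm(n, 0, 1) - cfg$te_effect * nd),
      stringsAsFactors = FALSE)
    if (cfg$property_na_rate > 0) {
      for (col in c("log2fc", "half_life_hours", "translational_efficiency")) {
        na <- runif(n) < cfg$property_na_rate
        df[[col]][na] <- NA_real_
      }
    }
    df
  })
}

#' Configuration for the behaviour simulator
#'
#' @param n_units conditioning units (each a cohort of `flies_per_unit`
#'   flies run through reciprocal OCT/MCH trials).
#' @param flies_per_unit flies per unit (the assay averages 12).
#' @param fps video frames per second.
#' @param test_seconds length of the testing phase (s).
#' @param window_seconds scored window at the end of the test (s).
#' @param persistence per-frame probability a fly keeps its current side
#'   rather than redrawing from the stationary bias.
#' @param seed integer seed.
#' @return validated configuration list (class `BehaviorSimConfig`).
#' @export
behaviorSimConfig <- function(n_units = 14L, flies_per_unit = 12L, fps = 5L,
                              test_seconds = 120L, window_seconds = 30L,
                              persistence = 0.9, seed = 1L) {
  cfg <- as.list(environment())
  if (window_seconds > test_seconds)
    stop("window_seconds must not exceed test_seconds")
  if (persistence < 0 || persistence >= 1)
    stop("persistence must lie in [0, 1)")
  class(cfg) <- "BehaviorSimConfig"
  cfg
}

#' Simulate occupancy traces for one experimental group
#'
#' Each fly follows a two-state Markov chain whose stationary probability
#' of sitting on the unconditioned side is `bias`; reciprocal OCT and MCH
#' trials are generated per unit.  `bias = 0.5` is no avoidance
#' (expected full PI 0); `bias = 1` is complete avoidance (full PI +1).
#'
#' @param bias probability a fly occupies the unconditioned side.
#' @param cfg a [behaviorSimConfig()] list.
#' @return data.frame: unit, trial_odor, frame (0-based),
#'   n_conditioned_side, n_unconditioned_side.
#' @export
simulateBehavior <- function(bias, cfg) {
  stopifnot(inherits(cfg, "BehaviorSimConfig"))
  if (bias < 0 || bias > 1) stop("bias must lie in [0, 1]")
  withr::with_seed(cfg$seed, {
    nf <- cfg$fps * cfg$test_seconds
    units <- sprintf("u%03d", seq_len(cfg$n_units))
    out <- vector("list", cfg$n_units * 2L)
    idx <- 1L
    for (u in units) for (odor in c("OCT", "MCH")) {
      nfly <- cfg$flies_per_unit
      s <- matrix(0L, nrow = nfly, ncol = nf)
      s[, 1] <- rbinom(nfly, 1L, bias)
      for (f in 2:nf) {
        keep <- rbinom(nfly, 1L, cfg$persistence)
        fresh <- rbinom(nfly, 1L, bias)
        s[, f] <- ifelse(keep == 1L, s[, f - 1L], fresh)
      }
      nu <- colSums(s)
      out[[idx]] <- data.frame(
        unit = u, trial_odor = odor, frame = seq_len(nf) - 1L,
        n_conditioned_side = nfly - nu, n_unconditioned_side = nu,
        stringsAsFactors = FALSE)
      idx <- idx + 1L
    }
    do.call(rbind, out)
  })
}

#' Simulate replicate spectral-count tables
#'
#' Background proteins draw m6A- and A-probe counts from the same
#' per-protein Poisson mean in each replicate; planted readers have their
#' m6A mean multiplied by `fold` (repelled proteins: the A mean).
#' `n_absent` background proteins are marked absent (`present = FALSE`,
#' count 0) from one randomly chosen replicate to exercise the
#' replicate-consistency filter.
#'
#' @param n_background number of background proteins.
#' @param n_readers planted m6A readers.
#' @param n_repelled planted repelled proteins.
#' @param n_absent background proteins absent from exactly one replicate.
#' @param base_mean mean spectral count scale.
#' @param fold planted enrichment fold.
#' @param seed integer seed.
#' @return list with `counts` (data.frame: protein, probe, replicate,
#'   count, present) and `truth` (data.frame: protein, role).
#' @export
simulateSpectralCounts <- function(n_background = 350L, n_readers = 2L,
                                   n_repelled = 0L, n_absent = 35L,
                                   base_mean = 20, fold = 8, seed = 1L) {
  n <- n_background + n_readers + n_repelled
  if (n_absent > n_background)
    stop("n_absent cannot exceed n_background")
  withr::with_seed(seed, {
    proteins <- sprintf("P%04d", seq_len(n))
    role <- c(rep("reader", n_readers), rep("repelled", n_repelled),
              rep("background", n_background))
    mu <- rlnorm(n, log(base_mean), 0.5)
    absent_idx <- sample(which(role == "background"), n_absent)
    absent_rep <- sample(1:2, n_absent, replace = TRUE)
    rows <- list()
    for (rep_i in 1:2) for (probe in c("m6A", "A")) {
      lam <- mu
      lam[role == "reader" & probe == "m6A"] <-
        mu[role == "reader"] * fold
      lam[role == "repelled" & probe == "A"] <-
        mu[role == "repelled"] * fold
      count <- rpois(n, lam)
      present <- rep(TRUE, n)
      gone <- absent_idx[absent_rep == rep_i]
      present[gone] <- FALSE
      count[gone] <- 0L
      rows[[length(rows) + 1L]] <- data.frame(
        protein = proteins, probe = probe, replicate = rep_i,
        count = count, present = present, stringsAsFactors = FALSE)
    }
    counts <- do.call(rbind, rows)
    counts <- counts[order(counts$protein, counts$probe, counts$replicate), ]
    rownames(counts) <- NULL
    list(counts = counts,
         truth = data.frame(protein = proteins, role = role,
                            stringsAsFactors = FALSE))
  })
}

#' Write / read a TagPileup as paired bedGraphs
#'
#' @param pileup [TagPileup-class].
#' @param coveragePath,mismatchPath bedGraph files for k and m tracks.
#' @return `coveragePath`, invisibly.
#' @export
writePileup <- function(pileup, coveragePath, mismatchPath) {
  writeBedGraph(pileupCoverage(pileup), coveragePath)
  writeBedGraph(pileupMismatches(pileup), mismatchPath)
  invisible(coveragePath)
}

#' @rdname writePileup
#' @param name library name.
#' @param contigLengths named integer vector of contig lengths.
#' @export
readPileup <- function(name, coveragePath, mismatchPath, contigLengths) {
  TagPileup(name, readBedGraph(coveragePath, contigLengths),
            readBedGraph(mismatchPath, contigLengths))
}
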