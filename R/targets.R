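# Target-gene analyses: transcript-segment annotation of peaks with the
# fixed precedence order, gene binning by dependent-peak count, bootstrap
# background distributions from non-methylated genes and two-sample
# Kolmogorov-Smirnov comparisons of gene-level properties.

#' Annotate peaks to transcript segments
#'
#' Categories are assigned with a fixed precedence, first overlap wins:
#' `other` (no overlap with any transcript model), `intron`,
#' `start_codon` (the 3-nt window at the CDS 5' end), `utr5`, `utr3`,
#' `cds`.  Annotation uses the per-gene longest transcript.
#'
#' @param peaks peak table (contig, start, end).
#' @param models [TranscriptModels-class].
#' @return `peaks` with a `category` column.
#' @export
annotatePeaks <- function(peaks, models) {
  sel <- longestTranscripts(models)
  tx <- sel@transcripts
  cats <- list(intron = list(), start_codon = list(), utr5 = list(),
               utr3 = list(), cds = list(), span = list())
  add <- function(cat, contig, iv) {
    if (is.null(iv) || nrow(iv) == 0L) return()
    cats[[cat]][[length(cats[[cat]]) + 1L]] <<- data.frame(
      contig = contig, start = iv[, 1], end = iv[, 2],
      stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(tx))) {
    ex <- sel@exons[[tx$transcript_id[i]]]
    add("span", tx$contig[i], cbind(min(ex[, 1]), max(ex[, 2])))
    if (nrow(ex) > 1L)
      add("intron", tx$contig[i],
          cbind(ex[-nrow(ex), 2], ex[-1L, 1]))
    if (!is.na(tx$cds_start[i])) {
      sc <- if (tx$strand[i] == "+")
        cbind(tx$cds_start[i], tx$cds_start[i] + 3L)
      else cbind(tx$cds_end[i] - 3L, tx$cds_end[i])
      add("start_codon", tx$contig[i], sc)
      u5 <- tx$utr5_len[i]; cd <- tx$cds_len[i]
      mat <- tx$mature_length[i]
      add("utr5", tx$contig[i],
          segmentGenomicIntervals(ex, tx$strand[i], 0L, u5))
      add("cds", tx$contig[i],
          segmentGenomicIntervals(ex, tx$strand[i], u5, u5 + cd))
      add("utr3", tx$contig[i],
          segmentGenomicIntervals(ex, tx$strand[i], u5 + cd, mat))
    }
  }
  tabs <- lapply(cats, function(l)
    if (length(l)) do.call(rbind, l)
    else data.frame(contig = character(0), start = integer(0),
                    end = integer(0)))
  hits <- function(tab, p)
    any(tab$contig == p$contig & tab$start < p$end & tab$end > p$start)
  category <- character(nrow(peaks))
  for (i in seq_len(nrow(peaks))) {
    p <- peaks[i, ]
    category[i] <- if (!hits(tabs$span, p)) "other"
      else if (hits(tabs$intron, p)) "intron"
      else if (hits(tabs$start_codon, p)) "start_codon"
      else if (hits(tabs$utr5, p)) "utr5"
      else if (hits(tabs$utr3, p)) "utr3"
      else if (hits(tabs$cds, p)) "cds"
      else "other"  # exonic overlap of a transcript with no CDS model
  }
  peaks$category <- category
  peaks
}

#' Fractions of peaks per transcript-segment category
#'
#' @param peaks annotated peak table (needs `category`).
#' @return data.frame category, n, fraction (fractions sum to 1).
#' @export
categoryFractions <- function(peaks) {
  if (nrow(peaks) == 0L) stop("empty peak table")
  if (!"category" %in% names(peaks))
    stop("peaks must be annotated first (see annotatePeaks)")
  tab <- table(peaks$category)
  data.frame(category = names(tab), n = as.integer(tab),
             fraction = as.numeric(tab) / nrow(peaks),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Assign overlapping genes to peaks
#'
#' Genes whose longest-transcript span overlaps the peak, comma-joined in
#' lexicographic order ('' when intergenic).
#'
#' @param peaks peak table.
#' @param models [TranscriptModels-class].
#' @return `peaks` with a `gene_ids` column.
#' @export
assignPeakGenes <- function(peaks, models) {
  sel <- longestTranscripts(models)
  tx <- sel@transcripts
  spans <- data.frame(
    gene_id = tx$gene_id, contig = tx$contig,
    start = vapply(sel@exons[tx$transcript_id],
                   function(e) min(e[, 1]), integer(1)),
    end = vapply(sel@exons[tx$transcript_id],
                 function(e) max(e[, 2]), integer(1)),
    stringsAsFactors = FALSE)
  peaks$gene_ids <- vapply(seq_len(nrow(peaks)), function(i) {
    p <- peaks[i, ]
    g <- spans$gene_id[spans$contig == p$contig &
                       spans$start < p$end & spans$end > p$start]
    paste(sort(unique(g)), collapse = ",")
  }, character(1))
  peaks
}

#' Bin genes by their number of writer-dependent peaks
#'
#' Only `dependent`-labelled peaks count.  With the default edges
#' `c(1, 2, 3)` the bins are `none` (0 dependent peaks), `1`, `2`, `3+`.
#'
#' @param peaks peak table with `label` (and `gene_ids`, added here when
#'   missing).
#' @param models [TranscriptModels-class] defining the gene universe.
#' @param edges increasing lower bin edges; the last is open-ended.
#' @return data.frame: gene_id, n_dependent_peaks, bin.
#' @export
binGenesByPeakCount <- function(peaks, models, edges = c(1L, 2L, 3L)) {
  if (is.unsorted(edges, strictly = TRUE) || edges[1] < 1L)
    stop("edges must be strictly increasing and >= 1")
  if (!"gene_ids" %in% names(peaks))
    peaks <- assignPeakGenes(peaks, models)
  genes <- sort(unique(models@transcripts$gene_id))
  dep <- peaks[peaks$label == "dependent", , drop = FALSE]
  glist <- unlist(strsplit(dep$gene_ids[dep$gene_ids != ""], ","))
  cnt <- table(glist)
  n <- as.integer(cnt[genes]); n[is.na(n)] <- 0L
  labels <- c(as.character(edges[-length(edges)]),
              paste0(edges[length(edges)], "+"))
  bin <- rep("none", length(genes))
  pos <- findInterval(n, edges)
  bin[pos > 0L] <- labels[pos[pos > 0L]]
  data.frame(gene_id = genes, n_dependent_peaks = n, bin = bin,
             stringsAsFactors = FALSE)
}

#' Bootstrap background sample from non-methylated genes
#'
#' Concatenates `n_draws` with-replacement resamples of `draw_size`
#' values; deterministic under `seed`.
#'
#' @param values property values of the background ("none") gene pool
#'   (missing values must already be removed).
#' @param n_draws number of resamples.
#' @param draw_size size of each resample.
#' @param seed integer seed.
#' @return numeric vector of length `n_draws * draw_size`.
#' @export
bootstrapBackground <- function(values, n_draws = 1000L, draw_size, seed = 1L) {
  if (length(values) == 0L) stop("empty background pool")
  if (n_draws < 1L || draw_size < 1L) stop("need n_draws, draw_size >= 1")
  withr::with_seed(seed,
    values[sample.int(length(values), n_draws * draw_size, replace = TRUE)])
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' D is the supremum distance between the two empirical CDFs (evaluated as
#' right-continuous step functions, ties handled at distinct values); the
#' two-sided p-value comes from the asymptotic Kolmogorov distribution at
#' effective sample size `n_x * n_y / (n_x + n_y)`.
#'
#' @param x,y numeric samples.
#' @return list: D, p, n_x, n_y.
#' @export
ksTwoSample <- function(x, y) {
  n <- length(x); m <- length(y)
  if (n < 1L || m < 1L) stop("both samples must be non-empty")
  w <- c(x, y)
  o <- order(w)
  steps <- cumsum(ifelse(o <= n, 1 / n, -1 / m))
  ws <- w[o]
  at <- c(diff(ws) != 0, TRUE)  # evaluate only at distinct values
  D <- max(abs(steps[at]))
  ne <- n * m / (n + m)
  lambda <- sqrt(ne) * D
  if (lambda == 0) p <- 1
  else {
    j <- 1:100
    p <- 2 * sum((-1)^(j - 1) * exp(-2 * j^2 * lambda^2))
    p <- min(max(p, 0), 1)
  }
  if (p == 0) p <- .Machine$double.xmin
  list(D = D, p = p, n_x = n, n_y = m)
}

#' Compare property distributions of target bins against a bootstrap
#' background
#'
#' For every property column and every bin other than `none`, the bin's
#' values are tested against a bootstrap background built from the `none`
#' genes (draw size defaulting to the bin size so the ECDFs are
#' comparable).  Missing values are dropped per analysis.  The result is
#' invariant to the row order of the inputs.
#'
#' @param properties data.frame with `gene_id` plus numeric property
#'   columns.
#' @param bins data.frame from [binGenesByPeakCount()].
#' @param n_draws bootstrap resamples.
#' @param draw_size per-resample size (default: the bin size).
#' @param seed integer seed; each comparison derives its own stream.
#' @return data.frame: bin, property, n, D, p, median_bin, median_bg.
#' @export
compareBins <- function(properties, bins, n_draws = 1000L,
                        draw_size = NULL, seed = 1L) {
  properties <- properties[order(properties$gene_id), , drop = FALSE]
  bins <- bins[order(bins$gene_id), , drop = FALSE]
  props <- setdiff(names(properties), "gene_id")
  none_genes <- bins$gene_id[bins$bin == "none"]
  lv <- setdiff(unique(bins$bin), "none")
  lv <- lv[order(suppressWarnings(as.numeric(sub("\\+$", "", lv))))]
  rows <- list()
  ci <- 0L
  for (pr in sort(props)) for (b in lv) {
    ci <- ci + 1L
    gx <- bins$gene_id[bins$bin == b]
    x <- properties[[pr]][match(gx, properties$gene_id)]
    x <- x[!is.na(x)]
    pool <- properties[[pr]][match(none_genes, properties$gene_id)]
    pool <- pool[!is.na(pool)]
    if (length(x) == 0L || length(pool) == 0L) next
    ds <- if (is.null(draw_size)) length(x) else draw_size
    bg <- bootstrapBackground(pool, n_draws, ds,
                              seed = derivedSeed(seed, ci))
    ks <- ksTwoSample(x, bg)
    rows[[length(rows) + 1L]] <- data.frame(
      bin = b, property = pr, n = length(x), D = ks$D, p = ks$p,
      median_bin = median(x), median_bg = median(bg),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Per-bin empirical CDF table for plotting
#'
#' @param properties,bins as in [compareBins()].
#' @return long data.frame: property, bin, value, ecdf.
#' @export
binEcdfTable <- function(properties, bins) {
  props <- setdiff(names(properties), "gene_id")
  rows <- list()
  for (pr in sort(props)) for (b in sort(unique(bins$bin))) {
    g <- bins$gene_id[bins$bin == b]
    v <- properties[[pr]][match(g, properties$gene_id)]
    v <- sort(v[!is.na(v)])
    if (length(v) == 0L) next
    rows[[length(rows) + 1L]] <- data.frame(
      property = pr, bin = b, value = v,
      ecdf = seq_along(v) / length(v), stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
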