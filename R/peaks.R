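# IP-over-input differential region calling with a genetic control:
# per-position Poisson log10 likelihood-ratio track, threshold/merge/filter
# region calling (g = 20, l = 120), dependence classification against the
# writer-null libraries, local-minimum splitting, ranking and heatmap
# matrices.

#' Peak-calling parameters
#'
#' `g` and `l` default to the differential caller's published settings
#' (max merge gap 20 nt, min region length 120 nt).  The per-position
#' statistic is a one-sided Poisson log10 likelihood ratio comparing a
#' common-rate hypothesis against an IP-elevated one after scaling the
#' deeper library down to the shallower; `llr_cutoff = 2` is the package
#' default.
#'
#' @param g maximum merge gap (nt) between qualifying runs.
#' @param l minimum merged region length (nt).
#' @param llr_cutoff log10 likelihood-ratio threshold.
#' @param pseudocount added to scaled counts before the ratio.
#' @param valley_ratio split a peak when the valley between two summits is
#'   below this fraction of the smaller summit.
#' @param flank heatmap flank width (nt).
#' @param dependence_overlap fraction of a wild-type region that must also
#'   pass `llr_cutoff` in the mutant track for the region to be called
#'   writer-independent.
#' @param min_child_len children shorter than this are re-merged with
#'   their taller neighbour after splitting.
#' @param smooth_window moving-average window (nt) used when locating
#'   summits and valleys.
#' @return parameter list (class `PeakParams`).
#' @export
peakParams <- function(g = 20L, l = 120L, llr_cutoff = 2.0,
                       pseudocount = 1.0, valley_ratio = 0.5,
                       flank = 500L, dependence_overlap = 0.5,
                       min_child_len = 30L, smooth_window = 25L) {
  if (g < 0 || l <= 0 || llr_cutoff <= 0) stop("need g >= 0, l > 0, llr_cutoff > 0")
  if (valley_ratio <= 0 || valley_ratio >= 1)
    stop("valley_ratio must lie in (0, 1)")
  p <- as.list(environment())
  class(p) <- "PeakParams"
  p
}

# depth scale factors: deeper library scaled down to the shallower
depthScale <- function(ip, input) {
  t_ip <- sum(vapply(ip@coverage@values, sum, numeric(1)))
  t_in <- sum(vapply(input@coverage@values, sum, numeric(1)))
  if (t_ip <= 0 || t_in <= 0) stop("zero-depth library")
  if (t_ip >= t_in) c(ip = t_in / t_ip, input = 1)
  else c(ip = 1, input = t_ip / t_in)
}

#' Per-position IP-over-input enrichment track
#'
#' For scaled counts `x` (IP) and `y` (input), each incremented by the
#' pseudocount, the statistic is the log10 likelihood ratio between the
#' maximum-likelihood Poisson model (rates x and y) and the common-rate
#' model (rate (x+y)/2), set to 0 wherever `x <= y` (one-sided:
#' depletion is not scored).  Equal libraries give an identically-zero
#' track; a pure depth difference is normalised away.
#'
#' @param ip,input [TagPileup-class] objects on the same contigs.
#' @param params a [peakParams()] list.
#' @return [SignalTrack-class] of log10 likelihood ratios.
#' @export
enrichmentTrack <- function(ip, input, params = peakParams()) {
  if (!identical(sort(contigNames(ip)), sort(contigNames(input))))
    stop("IP and input pileups must cover the same contigs")
  s <- depthScale(ip, input)
  pc <- params$pseudocount
  vals <- list()
  for (nm in contigNames(ip)) {
    x <- trackValues(pileupCoverage(ip), nm) * s[["ip"]] + pc
    y <- trackValues(pileupCoverage(input), nm) * s[["input"]] + pc
    mid <- (x + y) / 2
    llr <- (x * log(x) + y * log(y) - (x + y) * log(mid)) / log(10)
    llr[x <= y] <- 0
    vals[[nm]] <- llr
  }
  SignalTrack(vals)
}

#' Call enriched regions from an enrichment track
#'
#' Positions at or above `llr_cutoff` are taken; qualifying runs separated
#' by at most `g` nt are merged; merged regions shorter than `l` nt are
#' discarded.
#'
#' @param track [SignalTrack-class] of log10 likelihood ratios.
#' @param params a [peakParams()] list.
#' @return data.frame: contig, start, end (0-based half-open), sorted and
#'   disjoint.
#' @export
callRegions <- function(track, params = peakParams()) {
  out <- list()
  for (nm in contigNames(track)) {
    v <- trackValues(track, nm)
    idx <- which(v >= params$llr_cutoff)       # 1-based indices
    if (length(idx) == 0L) next
    brk <- which(diff(idx) > params$g + 1L)
    from <- idx[c(1L, brk + 1L)]
    to <- idx[c(brk, length(idx))]
    w <- to - from + 1L
    keep <- w >= params$l
    if (!any(keep)) next
    out[[nm]] <- data.frame(contig = nm, start = from[keep] - 1L,
                            end = to[keep], stringsAsFactors = FALSE)
  }
  if (length(out) == 0L)
    return(data.frame(contig = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res <- res[order(res$contig, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

regionStats <- function(region, track) {
  v <- trackValues(track, region$contig)[(region$start + 1L):region$end]
  list(score = mean(v), summit = region$start + which.max(v) - 1L)
}

#' Classify wild-type regions by writer dependence
#'
#' A wild-type region is labelled `independent` when at least
#' `dependence_overlap` of its length also passes `llr_cutoff` in the
#' mutant enrichment track, else `dependent`.  Regions enriched only in
#' the mutant are appended with label `mutant_only`.
#'
#' @param wt_regions regions from [callRegions()] on the wild-type track.
#' @param wt_track,mut_track enrichment [SignalTrack-class] objects
#'   computed with the same parameters.
#' @param params a [peakParams()] list.
#' @return peak data.frame: name, contig, start, end, score (mean log10 LR
#'   over the interval), summit, label.
#' @export
classifyDependence <- function(wt_regions, wt_track, mut_track,
                               params = peakParams()) {
  rows <- list()
  for (i in seq_len(nrow(wt_regions))) {
    r <- wt_regions[i, ]
    mut <- trackValues(mut_track, r$contig)[(r$start + 1L):r$end]
    frac <- mean(mut >= params$llr_cutoff)
    st <- regionStats(r, wt_track)
    rows[[length(rows) + 1L]] <- data.frame(
      contig = r$contig, start = r$start, end = r$end, score = st$score,
      summit = st$summit,
      label = if (frac >= params$dependence_overlap) "independent"
              else "dependent",
      stringsAsFactors = FALSE)
  }
  mut_regions <- callRegions(mut_track, params)
  for (i in seq_len(nrow(mut_regions))) {
    r <- mut_regions[i, ]
    overlaps <- any(wt_regions$contig == r$contig &
                    wt_regions$start < r$end & wt_regions$end > r$start)
    if (overlaps) next
    st <- regionStats(r, mut_track)
    rows[[length(rows) + 1L]] <- data.frame(
      contig = r$contig, start = r$start, end = r$end, score = st$score,
      summit = st$summit, label = "mutant_only", stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L)
    return(data.frame(name = character(0), contig = character(0),
                      start = integer(0), end = integer(0),
                      score = numeric(0), summit = integer(0),
                      label = character(0), stringsAsFactors = FALSE))
  res <- do.call(rbind, rows)
  res <- res[order(res$contig, res$start), , drop = FALSE]
  res <- cbind(name = sprintf("peak_%05d", seq_len(nrow(res))), res,
               stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

movingAverage <- function(v, w) {
  if (w <= 1L || length(v) <= 2L) return(v)
  h <- w %/% 2L
  n <- length(v)
  cs <- c(0, cumsum(v))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# local maxima of a numeric vector, plateau-safe: run-length encode, keep
# runs higher than both neighbouring runs (edge runs compare one side
# only); summit index = centre of the run (1-based)
localSummits <- function(s) {
  r <- rle(s)
  nv <- length(r$values)
  if (nv == 1L) return(integer(0))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  is_max <- logical(nv)
  for (j in seq_len(nv)) {
    left_ok <- j == 1L || r$values[j] > r$values[j - 1L]
    right_ok <- j == nv || r$values[j] > r$values[j + 1L]
    is_max[j] <- left_ok && right_ok
  }
  as.integer(floor((starts[is_max] + ends[is_max]) / 2))
}

#' Split compound peaks at local minima
#'
#' Within each peak, summits of the (moving-average smoothed) raw IP
#' signal are located; the peak is cut at the minimum between two adjacent
#' summits whenever the valley value is below
#' `valley_ratio * min(summit values)`.  Children shorter than
#' `min_child_len` are re-merged with their taller neighbour; children
#' inherit the parent's label and score, and the union of children tiles
#' the parent exactly.
#'
#' @param peaks peak table from [classifyDependence()].
#' @param ip_track raw IP coverage [SignalTrack-class].
#' @param params a [peakParams()] list.
#' @return peak data.frame in the same shape, with a `parent` column.
#' @export
splitPeaks <- function(peaks, ip_track, params = peakParams()) {
  rows <- list()
  for (i in seq_len(nrow(peaks))) {
    p <- peaks[i, ]
    v <- trackValues(ip_track, p$contig)[(p$start + 1L):p$end]
    s <- movingAverage(v, params$smooth_window)
    summits <- localSummits(s)
    cuts <- integer(0)
    if (length(summits) >= 2L) {
      for (j in seq_len(length(summits) - 1L)) {
        a <- summits[j]; b <- summits[j + 1L]
        valley_rel <- which.min(s[a:b]) + a - 1L
        if (s[valley_rel] < params$valley_ratio * min(s[a], s[b]))
          cuts <- c(cuts, valley_rel)
      }
    }
    bnd <- c(0L, sort(unique(cuts)) - 1L, length(v))  # 0-based offsets
    # re-merge short children with the taller neighbour
    repeat {
      w <- diff(bnd)
      if (length(w) <= 1L || all(w >= params$min_child_len)) break
      j <- which(w < params$min_child_len)[1]
      hgt <- function(kk) max(s[(bnd[kk] + 1L):bnd[kk + 1L]])
      drop_left <- if (j == 1L) FALSE
        else if (j == length(w)) TRUE
        else hgt(j - 1L) >= hgt(j + 1L)
      bnd <- if (drop_left) bnd[-j] else bnd[-(j + 1L)]
    }
    nch <- length(bnd) - 1L
    for (j in seq_len(nch)) {
      cs <- p$start + bnd[j]; ce <- p$start + bnd[j + 1L]
      seg <- v[(bnd[j] + 1L):bnd[j + 1L]]
      rows[[length(rows) + 1L]] <- data.frame(
        name = if (nch == 1L) p$name else sprintf("%s.%d", p$name, j),
        contig = p$contig, start = cs, end = ce, score = p$score,
        summit = cs + which.max(seg) - 1L, label = p$label,
        parent = p$name, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Rank peaks by score
#'
#' Descending by score with deterministic (contig, start) tie-breaking.
#'
#' @param peaks peak table.
#' @return the table reordered, with a `rank` column.
#' @export
rankPeaks <- function(peaks) {
  o <- order(-peaks$score, peaks$contig, peaks$start)
  res <- peaks[o, , drop = FALSE]
  res$rank <- seq_len(nrow(res))
  rownames(res) <- NULL
  res
}

# area-preserving resampling of a piecewise-constant signal to nbins
resampleMean <- function(v, nbins) {
  L <- length(v)
  cs <- c(0, cumsum(v))
  cumAt <- function(t) {
    f <- floor(t)
    val <- cs[pmin(f, L) + 1L] + (t - f) * c(v, 0)[pmin(f, L - 1L) + 1L]
    val[t >= L] <- cs[L + 1L]
    val
  }
  e <- seq(0, L, length.out = nbins + 1L)
  (cumAt(e[-1L]) - cumAt(e[-(nbins + 1L)])) / (L / nbins)
}

#' Input-normalised signal matrix over peaks
#'
#' One row per peak: the depth-scaled, pseudocounted IP/input ratio with
#' the peak body rescaled to 200 bins flanked by `flank` nt of unscaled
#' sequence binned at 10 nt.  Positions beyond the contig are `NA`.  Rows
#' are sorted by decreasing row mean.
#'
#' @param peaks peak table.
#' @param ip,input [TagPileup-class] objects.
#' @param params a [peakParams()] list.
#' @param body_bins number of bins for the rescaled peak body.
#' @return numeric matrix with peak names as rownames.
#' @export
peakMatrix <- function(peaks, ip, input, params = peakParams(),
                       body_bins = 200L) {
  s <- depthScale(ip, input)
  pc <- params$pseudocount
  fb <- params$flank %/% 10L
  mat <- matrix(NA_real_, nrow = nrow(peaks), ncol = fb + body_bins + fb)
  rownames(mat) <- if ("name" %in% names(peaks)) peaks$name
                   else sprintf("peak_%05d", seq_len(nrow(peaks)))
  for (i in seq_len(nrow(peaks))) {
    p <- peaks[i, ]
    len <- length(trackValues(pileupCoverage(ip), p$contig))
    posn <- (p$start - params$flank):(p$end + params$flank - 1L)
    ratio <- rep(NA_real_, length(posn))
    ok <- posn >= 0L & posn < len
    kip <- trackValues(pileupCoverage(ip), p$contig)[posn[ok] + 1L]
    kin <- trackValues(pileupCoverage(input), p$contig)[posn[ok] + 1L]
    ratio[ok] <- (kip * s[["ip"]] + pc) / (kin * s[["input"]] + pc)
    nf <- params$flank
    left <- ratio[seq_len(nf)]
    body <- ratio[(nf + 1L):(length(ratio) - nf)]
    right <- ratio[(length(ratio) - nf + 1L):length(ratio)]
    bin10 <- function(x) {
      m <- matrix(x[seq_len(fb * 10L)], nrow = 10L)
      colMeans(m)  # NA-propagating: edge bins stay NA
    }
    mat[i, ] <- c(bin10(left), resampleMean(body, body_bins), bin10(right))
  }
  mat[order(-rowMeans(mat, na.rm = TRUE)), , drop = FALSE]
}
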