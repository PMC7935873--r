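# Transcript <-> genome coordinate arithmetic.  All coordinates 0-based
# half-open; transcript position 0 is the mature 5' end (highest genomic
# coordinate for minus-strand transcripts).

exonWidths <- function(ex) ex[, 2L] - ex[, 1L]

# 0-based transcript positions -> 0-based genomic positions
transcriptToGenomic <- function(ex, strand, tpos) {
  mat <- sum(exonWidths(ex))
  if (any(tpos < 0L | tpos >= mat)) stop("transcript position out of range")
  p <- if (strand == "+") tpos else mat - 1L - tpos
  w <- exonWidths(ex)
  cw <- cumsum(w)
  idx <- findInterval(p, c(0L, cw), rightmost.closed = FALSE)
  off <- p - c(0L, cw)[idx]
  as.integer(ex[idx, 1L] + off)
}

# 0-based genomic positions (must be exonic) -> 0-based transcript positions
genomicToTranscript <- function(ex, strand, gpos) {
  w <- exonWidths(ex)
  cw0 <- c(0L, cumsum(w))
  idx <- rep(NA_integer_, length(gpos))
  for (j in seq_len(nrow(ex))) {
    hit <- gpos >= ex[j, 1L] & gpos < ex[j, 2L]
    idx[hit] <- j
  }
  if (anyNA(idx)) stop("genomic position not exonic")
  p <- cw0[idx] + (gpos - ex[idx, 1L])
  mat <- sum(w)
  if (strand == "+") as.integer(p) else as.integer(mat - 1L - p)
}

# Genomic intervals (2-col matrix, 0-based half-open) covering transcript
# range [tfrom, tto).
segmentGenomicIntervals <- function(ex, strand, tfrom, tto) {
  mat <- sum(exonWidths(ex))
  if (tfrom >= tto) return(matrix(integer(0), ncol = 2L))
  # convert to plus-order (genomic-increasing) mature coordinates
  if (strand == "+") { a <- tfrom; b <- tto } else {
    a <- mat - tto; b <- mat - tfrom
  }
  w <- exonWidths(ex)
  cw0 <- c(0L, cumsum(w))
  out <- matrix(integer(0), ncol = 2L)
  for (j in seq_len(nrow(ex))) {
    lo <- max(a, cw0[j]); hi <- min(b, cw0[j + 1L])
    if (lo < hi) {
      gs <- ex[j, 1L] + (lo - cw0[j])
      out <- rbind(out, c(gs, gs + (hi - lo)))
    }
  }
  out
}

# Mature-transcript segment bounds of one transcripts-table row:
# list(utr5 = c(from, to), cds = ..., utr3 = ...), 0-based half-open in
# transcript coordinates; NULL when the transcript has no annotated CDS.
segmentTranscriptBounds <- function(txrow) {
  if (is.na(txrow$cds_start)) return(NULL)
  u5 <- txrow$utr5_len; cd <- txrow$cds_len
  list(utr5 = c(0L, u5), cds = c(u5, u5 + cd),
       utr3 = c(u5 + cd, txrow$mature_length))
}
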