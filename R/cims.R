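# Crosslink-induced-mutation (CIM) calling: C-to-T transitions with a
# preceding A, filtered with m > 1 and 0.01 < m/k < 0.5 (both strict).

#' CIM filter parameters
#'
#' The canonical miCLIP filter: keep a position when the mutated-tag count
#' m exceeds `m_min_exclusive` (strictly) and the ratio m/k lies strictly
#' between `ratio_lo` and `ratio_hi`, the reference base is C and the
#' transcript-5' neighbouring base is A.
#'
#' @param m_min_exclusive retain sites with `m > m_min_exclusive`.
#' @param ratio_lo,ratio_hi strict bounds on m/k.
#' @param require_ref_c require the reference base at the site to be C (on
#'   the site's strand).
#' @param require_preceding_a require the transcript-preceding base to be A.
#' @return parameter list (class `CimFilterParams`).
#' @export
cimFilterParams <- function(m_min_exclusive = 1L, ratio_lo = 0.01,
                            ratio_hi = 0.5, require_ref_c = TRUE,
                            require_preceding_a = TRUE) {
  if (!(ratio_lo >= 0 && ratio_lo < ratio_hi && ratio_hi <= 1))
    stop("need 0 <= ratio_lo < ratio_hi <= 1")
  p <- as.list(environment())
  class(p) <- "CimFilterParams"
  p
}

#' Call putative m6A sites as CIMs
#'
#' Scans a pileup for positions whose C-to-T evidence passes the filter.
#' "Preceding" is defined in transcript 5'->3' orientation: on the plus
#' strand the A sits at `cim_pos - 1`; a minus-strand site appears in
#' genome space as a G at `cim_pos` with a T at `cim_pos + 1` (the
#' complemented A).  A position yields at most one site per strand.
#'
#' @param pileup [TagPileup-class] (conventionally the wild-type IP).
#' @param genome `DNAStringSet` matching the pileup contigs.
#' @param params a [cimFilterParams()] list.
#' @return data.frame sorted by (contig, cim_pos): contig, cim_pos,
#'   m6a_pos, strand, m, k, ratio (coordinates 0-based).
#' @export
callCims <- function(pileup, genome, params = cimFilterParams()) {
  if (!all(contigNames(pileup) %in% contigNames(genome)))
    stop("pileup contig missing from genome")
  plens <- contigLengths(pileup)
  glens <- contigLengths(genome)[names(plens)]
  if (!all(plens == glens))
    stop("pileup and genome contig lengths differ")
  out <- list()
  for (nm in contigNames(pileup)) {
    k <- trackValues(pileupCoverage(pileup), nm)
    m <- trackValues(pileupMismatches(pileup), nm)
    if (any(m > 0 & k == 0))
      stop("mismatch count with zero coverage on contig ", nm)
    ratio <- ifelse(k > 0, m / k, 0)
    cand <- which(m > params$m_min_exclusive &
                  ratio > params$ratio_lo & ratio < params$ratio_hi)
    if (length(cand) == 0L) next
    bases <- strsplit(as.character(genome[[nm]]), "")[[1]]
    len <- length(bases)
    for (i in cand) {            # i is a 1-based index; 0-based pos = i - 1
      pos <- i - 1L
      plus_ok <- TRUE; minus_ok <- FALSE
      if (params$require_ref_c) {
        plus_ok <- bases[i] == "C"
        minus_ok <- bases[i] == "G"
      }
      if (params$require_preceding_a) {
        plus_ok <- plus_ok && i > 1L && bases[i - 1L] == "A"
        minus_ok <- minus_ok && i < len && bases[i + 1L] == "T"
      } else if (!params$require_ref_c) {
        minus_ok <- FALSE        # no base evidence: report as plus strand
      }
      if (plus_ok)
        out[[length(out) + 1L]] <- data.frame(
          contig = nm, cim_pos = pos, m6a_pos = pos - 1L, strand = "+",
          m = m[i], k = k[i], ratio = ratio[i], stringsAsFactors = FALSE)
      if (minus_ok)
        out[[length(out) + 1L]] <- data.frame(
          contig = nm, cim_pos = pos, m6a_pos = pos + 1L, strand = "-",
          m = m[i], k = k[i], ratio = ratio[i], stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L)
    return(data.frame(contig = character(0), cim_pos = integer(0),
                      m6a_pos = integer(0), strand = character(0),
                      m = numeric(0), k = numeric(0), ratio = numeric(0),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res <- res[order(res$contig, res$cim_pos, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' CIMs inside the top-ranked dependent peaks
#'
#' Restricts a CIM table to sites whose `cim_pos` falls inside (half-open)
#' one of the `n_top` highest-ranked writer-dependent peaks.
#'
#' @param cims CIM table from [callCims()].
#' @param peaks peak table carrying `label` and `score` columns.
#' @param n_top number of top dependent peaks to keep.
#' @return the filtered CIM table.
#' @export
cimsInTopPeaks <- function(cims, peaks, n_top = 1000L) {
  if (n_top <= 0L) stop("n_top must be positive")
  dep <- peaks[peaks$label == "dependent", , drop = FALSE]
  dep <- rankPeaks(dep)
  dep <- head(dep, n_top)
  if (nrow(dep) == 0L || nrow(cims) == 0L) return(cims[0, , drop = FALSE])
  keep <- logical(nrow(cims))
  for (i in seq_len(nrow(dep))) {
    keep <- keep | (cims$contig == dep$contig[i] &
                    cims$cim_pos >= dep$start[i] &
                    cims$cim_pos < dep$end[i])
  }
  res <- cims[keep, , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Assign CIMs to the annotated transcript strand
#'
#' The tag pileups are unstranded, so a mismatch position admits both a
#' plus-strand (A-then-C) and a minus-strand (G-then-T) reading.  Sites
#' are assigned to the strand of the transcript(s) they fall in: a CIM is
#' kept when at least one overlapping transcript (per-gene longest model)
#' matches its strand.  Unannotated sites cannot be oriented and are
#' dropped unless `keep_unannotated`.
#'
#' @param cims CIM table from [callCims()].
#' @param models [TranscriptModels-class].
#' @param keep_unannotated keep sites outside every transcript span.
#' @return the filtered CIM table.
#' @export
filterCimsByTranscriptStrand <- function(cims, models,
                                         keep_unannotated = FALSE) {
  sel <- longestTranscripts(models)
  tx <- sel@transcripts
  spans <- data.frame(
    contig = tx$contig, strand = tx$strand,
    start = vapply(sel@exons[tx$transcript_id],
                   function(e) min(e[, 1]), integer(1)),
    end = vapply(sel@exons[tx$transcript_id],
                 function(e) max(e[, 2]), integer(1)),
    stringsAsFactors = FALSE)
  keep <- vapply(seq_len(nrow(cims)), function(i) {
    ov <- spans$contig == cims$contig[i] &
      spans$start <= cims$cim_pos[i] & spans$end > cims$cim_pos[i]
    if (!any(ov)) return(keep_unannotated)
    any(spans$strand[ov] == cims$strand[i])
  }, logical(1))
  res <- cims[keep, , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Write CIMs as BED6 plus full TSV
#'
#' BED name is `m{m}_k{k}`, score is `round(1000 * ratio)`.
#'
#' @param cims CIM table.
#' @param bedPath,tsvPath output files (either may be `NULL` to skip).
#' @return `cims`, invisibly.
#' @export
writeCims <- function(cims, bedPath = NULL, tsvPath = NULL) {
  if (!is.null(bedPath)) {
    writeBed(data.frame(
      contig = cims$contig, start = cims$cim_pos,
      end = cims$cim_pos + 1L,
      name = sprintf("m%d_k%d", as.integer(cims$m), as.integer(cims$k)),
      score = round(1000 * cims$ratio), strand = cims$strand,
      stringsAsFactors = FALSE), bedPath)
  }
  if (!is.null(tsvPath)) writeTsvTable(cims, tsvPath)
  invisible(cims)
}
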