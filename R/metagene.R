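# Metagene profiles: per-transcript signal lifted to mature-transcript
# coordinates, segments rescaled to a fixed 200/1000/300-bin
# 5'UTR/CDS/3'UTR axis, per-gene normalised to unit mass and averaged.

#' Lift a genomic signal to mature-transcript coordinates
#'
#' Concatenates per-exon values in transcript 5'->3' order (reversed for
#' minus-strand transcripts); intronic signal is absent from the output.
#'
#' @param track [SignalTrack-class].
#' @param models [TranscriptModels-class].
#' @param transcript_id transcript to lift.
#' @return numeric vector of length equal to the mature transcript.
#' @export
transcriptSignal <- function(track, models, transcript_id) {
  tx <- models@transcripts
  i <- match(transcript_id, tx$transcript_id)
  if (is.na(i)) stop("unknown transcript: ", transcript_id)
  ex <- models@exons[[transcript_id]]
  v <- trackValues(track, tx$contig[i])
  out <- unlist(lapply(seq_len(nrow(ex)),
                       function(j) v[(ex[j, 1] + 1L):ex[j, 2]]),
                use.names = FALSE)
  if (tx$strand[i] == "-") rev(out) else out
}

#' Scale a transcript signal onto the fixed metagene axis
#'
#' Each of the 5'UTR, CDS and 3'UTR segments is independently resampled to
#' its bin count (default 200/1000/300) by area-preserving per-bin means of
#' the piecewise-constant signal, then the whole vector is divided by its
#' sum so every transcript contributes unit mass.
#'
#' @param signal mature-transcript signal from [transcriptSignal()].
#' @param models [TranscriptModels-class].
#' @param transcript_id transcript the signal belongs to.
#' @param seg_bins bin counts for 5'UTR, CDS, 3'UTR.
#' @param min_total transcripts whose total raw signal is not greater than
#'   this are skipped (returns `NULL`).
#' @return normalised numeric vector of `sum(seg_bins)` bins, or `NULL`
#'   when the transcript lacks an annotated UTR/CDS segment or carries no
#'   signal.
#' @export
scaleToMetagene <- function(signal, models, transcript_id,
                            seg_bins = c(200L, 1000L, 300L),
                            min_total = 0) {
  tx <- models@transcripts
  i <- match(transcript_id, tx$transcript_id)
  if (is.na(i)) stop("unknown transcript: ", transcript_id)
  b <- segmentTranscriptBounds(tx[i, ])
  if (is.null(b)) return(NULL)
  lens <- c(tx$utr5_len[i], tx$cds_len[i], tx$utr3_len[i])
  if (any(lens == 0L)) return(NULL)
  if (length(signal) != tx$mature_length[i])
    stop("signal length does not match mature transcript")
  if (sum(signal) <= min_total) return(NULL)
  segs <- list(signal[(b$utr5[1] + 1L):b$utr5[2]],
               signal[(b$cds[1] + 1L):b$cds[2]],
               signal[(b$utr3[1] + 1L):b$utr3[2]])
  v <- c(resampleMean(segs[[1]], seg_bins[1]),
         resampleMean(segs[[2]], seg_bins[2]),
         resampleMean(segs[[3]], seg_bins[3]))
  v / sum(v)
}

#' Aggregate metagene profiles for a gene set
#'
#' Selects the per-gene longest transcript, computes each library's
#' normalised per-gene metagene vector and averages them.  Genes lacking
#' an annotated UTR or carrying no signal are excluded (counted).  An
#' IP/input ratio profile over the aggregated bin means is also returned;
#' the two libraries are additionally reported separately so either
#' normalisation order can be inspected.
#'
#' @param track_ip,track_input [SignalTrack-class] objects.
#' @param models [TranscriptModels-class] (all transcripts; the longest
#'   per gene is selected internally).
#' @param gene_set gene identifiers to aggregate (default: all genes).
#' @param seg_bins bin counts for 5'UTR, CDS, 3'UTR.
#' @param min_total see [scaleToMetagene()].
#' @param keep_per_gene keep the per-gene matrices in the profiles.
#' @return list with `ip` and `input` ([MetageneProfile-class]), `ratio`
#'   (numeric vector of aggregated IP mean / input mean per bin) and
#'   `n_excluded`.
#' @export
aggregateMetagene <- function(track_ip, track_input, models,
                              gene_set = NULL,
                              seg_bins = c(200L, 1000L, 300L),
                              min_total = 0, keep_per_gene = FALSE) {
  sel <- longestTranscripts(models)
  tx <- sel@transcripts
  if (!is.null(gene_set)) tx <- tx[tx$gene_id %in% gene_set, , drop = FALSE]
  nb <- sum(seg_bins)
  per_ip <- list(); per_in <- list()
  excluded <- 0L
  for (i in seq_len(nrow(tx))) {
    tid <- tx$transcript_id[i]
    vi <- scaleToMetagene(transcriptSignal(track_ip, sel, tid), sel, tid,
                          seg_bins, min_total)
    vn <- scaleToMetagene(transcriptSignal(track_input, sel, tid), sel, tid,
                          seg_bins, min_total)
    if (is.null(vi) || is.null(vn)) { excluded <- excluded + 1L; next }
    per_ip[[tx$gene_id[i]]] <- vi
    per_in[[tx$gene_id[i]]] <- vn
  }
  if (length(per_ip) == 0L) stop("no usable transcripts for metagene")
  mk <- function(lst) {
    m <- do.call(rbind, lst)
    new("MetageneProfile", values = colMeans(m),
        nGenes = length(lst),
        perGene = if (keep_per_gene) m else matrix(numeric(0), 0, 0),
        segBins = as.integer(seg_bins))
  }
  ip <- mk(per_ip); input <- mk(per_in)
  list(ip = ip, input = input,
       ratio = ip@values / pmax(input@values, .Machine$double.eps),
       n_excluded = excluded)
}

#' Metagene profile as a tidy table
#'
#' @param profile [MetageneProfile-class].
#' @return data.frame: bin (0-based), segment label, value.
#' @export
metageneTable <- function(profile) {
  segs <- rep(c("utr5", "cds", "utr3"), profile@segBins)
  data.frame(bin = seq_along(profile@values) - 1L, segment = segs,
             value = profile@values, stringsAsFactors = FALSE)
}
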