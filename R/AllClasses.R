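#' @import methods
#' @importFrom stats rbinom rnorm rpois rlnorm runif quantile median sd
#'   var pnorm qnorm qt setNames wilcox.test complete.cases
#' @importFrom utils head read.delim write.table combn
#' @importClassesFrom Biostrings DNAStringSet
NULL

#' SignalTrack: dense per-position genomic signal
#'
#' Holds one non-negative value per genomic position for each contig.
#' This is the common carrier for tag coverage, C-to-T mismatch counts and
#' enrichment (log10 likelihood-ratio) tracks.  Coordinates are 0-based
#' half-open throughout the package; element `i` of a contig vector is the
#' value at genomic position `i - 1` in 1-based terms, i.e. R index `i`
#' corresponds to 0-based position `i - 1`.
#'
#' @slot values named list, one numeric vector per contig.
#' @export
setClass("SignalTrack", slots = c(values = "list"))

setValidity("SignalTrack", function(object) {
  v <- object@values
  if (is.null(names(v)) || any(names(v) == "") || anyDuplicated(names(v)))
    return("contig names must be unique and non-empty")
  for (nm in names(v)) {
    x <- v[[nm]]
    if (!is.numeric(x) || length(x) == 0L)
      return(sprintf("contig '%s': values must be a non-empty numeric vector", nm))
    if (anyNA(x) || any(!is.finite(x)))
      return(sprintf("contig '%s': values must be finite", nm))
    if (any(x < 0))
      return(sprintf("contig '%s': values must be non-negative", nm))
  }
  TRUE
})

#' Construct a SignalTrack
#'
#' @param values named list of non-negative numeric vectors, one per contig.
#' @return A [SignalTrack-class] object.
#' @export
SignalTrack <- function(values) {
  new("SignalTrack", values = lapply(values, as.numeric))
}

#' All-zero SignalTrack for given contig sizes
#'
#' @param contigLengths named integer vector of contig lengths.
#' @return A [SignalTrack-class] of zeros.
#' @export
zeroTrack <- function(contigLengths) {
  SignalTrack(lapply(as.list(contigLengths), function(n) numeric(n)))
}

#' TagPileup: per-position tag coverage and C-to-T mismatch counts
#'
#' For a single miCLIP (or input) library: `k[i]`, the number of unique tags
#' spanning position `i`, and `m[i]`, the number of those tags carrying a
#' C-to-T transition at `i`.
#'
#' @slot name library name.
#' @slot coverage [SignalTrack-class] of spanning-tag counts (k).
#' @slot mismatches [SignalTrack-class] of C-to-T transition counts (m).
#' @export
setClass("TagPileup",
  slots = c(name = "character", coverage = "SignalTrack",
            mismatches = "SignalTrack"))

setValidity("TagPileup", function(object) {
  k <- object@coverage@values
  m <- object@mismatches@values
  if (!identical(sort(names(k)), sort(names(m))))
    return("coverage and mismatch tracks must share contigs")
  for (nm in names(k)) {
    if (length(k[[nm]]) != length(m[[nm]]))
      return(sprintf("contig '%s': coverage and mismatch lengths differ", nm))
    if (any(m[[nm]] > k[[nm]]))
      return(sprintf("contig '%s': mismatch count exceeds coverage", nm))
  }
  TRUE
})

#' Construct a TagPileup
#'
#' @param name library name.
#' @param coverage,mismatches [SignalTrack-class] objects (or named lists)
#'   with identical contigs; mismatches must satisfy `0 <= m <= k`.
#' @return A [TagPileup-class] object.
#' @export
TagPileup <- function(name, coverage, mismatches) {
  if (!is(coverage, "SignalTrack")) coverage <- SignalTrack(coverage)
  if (!is(mismatches, "SignalTrack")) mismatches <- SignalTrack(mismatches)
  new("TagPileup", name = name, coverage = coverage, mismatches = mismatches)
}

#' TranscriptModels: exon/CDS structures grouped by gene
#'
#' Internal coordinates are 0-based half-open; GTF input (1-based inclusive)
#' is converted on read.  The `transcripts` table carries one row per
#' transcript with derived mature-transcript segment lengths; `exons` is a
#' list (named by transcript_id) of two-column matrices (start, end) sorted
#' by genomic start.
#'
#' @slot transcripts data.frame with columns gene_id, transcript_id, contig,
#'   strand, cds_start, cds_end, mature_length, utr5_len, cds_len, utr3_len.
#' @slot exons named list of integer matrices.
#' @export
setClass("TranscriptModels",
  slots = c(transcripts = "data.frame", exons = "list"))

setValidity("TranscriptModels", function(object) {
  tx <- object@transcripts
  need <- c("gene_id", "transcript_id", "contig", "strand", "cds_start",
            "cds_end", "mature_length", "utr5_len", "cds_len", "utr3_len")
  if (!all(need %in% names(tx)))
    return(paste("transcripts table missing columns:",
                 paste(setdiff(need, names(tx)), collapse = ", ")))
  if (anyDuplicated(tx$transcript_id))
    return("duplicate transcript_id")
  if (!all(tx$strand %in% c("+", "-")))
    return("strand must be '+' or '-'")
  if (!identical(sort(names(object@exons)), sort(tx$transcript_id)))
    return("exon list names must match transcript_id")
  for (i in seq_len(nrow(tx))) {
    ex <- object@exons[[tx$transcript_id[i]]]
    if (!is.matrix(ex) || ncol(ex) != 2L)
      return("each exon entry must be a 2-column matrix")
    if (any(ex[, 2] <= ex[, 1]))
      return("exon end must exceed start")
    if (nrow(ex) > 1L && any(ex[-1L, 1] < ex[-nrow(ex), 2]))
      return(sprintf("transcript '%s': exons must be sorted and non-overlapping",
                     tx$transcript_id[i]))
    mat <- sum(ex[, 2] - ex[, 1])
    if (mat != tx$mature_length[i])
      return(sprintf("transcript '%s': mature_length does not match exons",
                     tx$transcript_id[i]))
    if (!is.na(tx$cds_start[i])) {
      segs <- c(tx$utr5_len[i], tx$cds_len[i], tx$utr3_len[i])
      if (any(segs < 0) || sum(segs) != mat)
        return(sprintf("transcript '%s': segment lengths must be >= 0 and sum to mature length",
                       tx$transcript_id[i]))
    }
  }
  TRUE
})

#' MetageneProfile: 1500-bin normalized transcript-coordinate signal
#'
#' @slot values numeric vector (one value per metagene bin).
#' @slot nGenes number of genes averaged.
#' @slot perGene optional per-gene matrix (genes x bins); 0-row when absent.
#' @slot segBins bin counts of the 5'UTR/CDS/3'UTR segments.
#' @export
setClass("MetageneProfile",
  slots = c(values = "numeric", nGenes = "integer", perGene = "matrix",
            segBins = "integer"))

setValidity("MetageneProfile", function(object) {
  if (length(object@values) != sum(object@segBins))
    return("values length must equal sum of segment bins")
  if (nrow(object@perGene) > 0L &&
      ncol(object@perGene) != length(object@values))
    return("perGene matrix width must match values")
  TRUE
})

#' ContextMatrix: nucleotide frequencies around CIM sites
#'
#' Column 0 (the centre) is the methylated A, i.e. the base immediately 5'
#' (transcript orientation) of the mutated C; the C sits at position +1.
#'
#' @slot freq 4 x (2*flank + 1) matrix of relative frequencies (rows
#'   A, C, G, T); every column sums to 1.
#' @slot nSites number of contexts counted.
#' @slot flank flank width in nt on each side of the centre.
#' @slot nDropped sites dropped for falling off a contig edge.
#' @export
setClass("ContextMatrix",
  slots = c(freq = "matrix", nSites = "integer", flank = "integer",
            nDropped = "integer"))

setValidity("ContextMatrix", function(object) {
  f <- object@freq
  if (!identical(rownames(f), c("A", "C", "G", "T")))
    return("freq rows must be A, C, G, T")
  if (ncol(f) != 2L * object@flank + 1L)
    return("freq must have 2*flank + 1 columns")
  if (any(f < 0)) return("frequencies must be non-negative")
  if (object@nSites > 0L && any(abs(colSums(f) - 1) > 1e-9))
    return("columns must sum to 1")
  TRUE
})
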