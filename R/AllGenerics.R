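#' Contig names of a genomic object
#' @param x a SignalTrack, TagPileup or DNAStringSet-based genome.
#' @return character vector of contig names.
#' @export
setGeneric("contigNames", function(x) standardGeneric("contigNames"))

#' Contig lengths of a genomic object
#' @param x a SignalTrack, TagPileup or DNAStringSet-based genome.
#' @return named integer vector of contig lengths.
#' @export
setGeneric("contigLengths", function(x) standardGeneric("contigLengths"))

#' Per-contig values of a track
#' @param x a SignalTrack or TagPileup.
#' @param contig optional contig name; when missing the full named list is
#'   returned.
#' @return numeric vector (one contig) or named list (all contigs).
#' @export
setGeneric("trackValues", function(x, contig) standardGeneric("trackValues"))

#' @rdname SignalTrack-class
#' @param x,contig see generic.
#' @export
setMethod("contigNames", "SignalTrack", function(x) names(x@values))

#' @rdname SignalTrack-class
#' @export
setMethod("contigLengths", "SignalTrack", function(x)
  vapply(x@values, length, integer(1)))

#' @rdname SignalTrack-class
#' @export
setMethod("trackValues", "SignalTrack", function(x, contig) {
  if (missing(contig)) return(x@values)
  if (!contig %in% names(x@values))
    stop("unknown contig: ", contig)
  x@values[[contig]]
})

setMethod("show", "SignalTrack", function(object) {
  len <- contigLengths(object)
  cat("SignalTrack with", length(len), "contig(s):",
      paste0(names(len), " (", len, " nt)", collapse = ", "), "\n")
})

#' Coverage track of a pileup
#' @param x a TagPileup.
#' @return a SignalTrack.
#' @export
setGeneric("pileupCoverage", function(x) standardGeneric("pileupCoverage"))

#' C-to-T mismatch track of a pileup
#' @param x a TagPileup.
#' @return a SignalTrack.
#' @export
setGeneric("pileupMismatches", function(x) standardGeneric("pileupMismatches"))

#' @rdname TagPileup-class
#' @param x see generic.
#' @export
setMethod("pileupCoverage", "TagPileup", function(x) x@coverage)

#' @rdname TagPileup-class
#' @export
setMethod("pileupMismatches", "TagPileup", function(x) x@mismatches)

#' @rdname TagPileup-class
#' @export
setMethod("contigNames", "TagPileup", function(x) contigNames(x@coverage))

#' @rdname TagPileup-class
#' @export
setMethod("contigLengths", "TagPileup", function(x) contigLengths(x@coverage))

setMethod("show", "TagPileup", function(object) {
  cat("TagPileup '", object@name, "': total tags ",
      format(sum(vapply(object@coverage@values, sum, numeric(1)))),
      ", total C-to-T ",
      format(sum(vapply(object@mismatches@values, sum, numeric(1)))),
      "\n", sep = "")
})

#' Transcript annotation table
#' @param x a TranscriptModels object.
#' @return data.frame of per-transcript fields.
#' @export
setGeneric("transcriptTable", function(x) standardGeneric("transcriptTable"))

#' Exon intervals of one transcript
#' @param x a TranscriptModels object.
#' @param transcript_id transcript identifier.
#' @return 2-column matrix of 0-based half-open exon intervals.
#' @export
setGeneric("transcriptExons",
           function(x, transcript_id) standardGeneric("transcriptExons"))

#' @rdname TranscriptModels-class
#' @param x,transcript_id see generics.
#' @export
setMethod("transcriptTable", "TranscriptModels", function(x) x@transcripts)

#' @rdname TranscriptModels-class
#' @export
setMethod("transcriptExons", "TranscriptModels", function(x, transcript_id) {
  ex <- x@exons[[transcript_id]]
  if (is.null(ex)) stop("unknown transcript: ", transcript_id)
  ex
})

setMethod("show", "TranscriptModels", function(object) {
  tx <- object@transcripts
  cat("TranscriptModels:", nrow(tx), "transcript(s) from",
      length(unique(tx$gene_id)), "gene(s)\n")
})

setMethod("show", "MetageneProfile", function(object) {
  cat("MetageneProfile:", length(object@values), "bins (",
      paste(object@segBins, collapse = "/"), ") over",
      object@nGenes, "gene(s); sum =",
      format(sum(object@values)), "\n")
})

setMethod("show", "ContextMatrix", function(object) {
  cat("ContextMatrix:", object@nSites, "site(s), flank",
      object@flank, "nt,", object@nDropped, "edge site(s) dropped\n")
})

#' Values of a metagene profile
#' @param x a MetageneProfile.
#' @return numeric vector of bin values.
#' @export
setGeneric("profileValues", function(x) standardGeneric("profileValues"))

#' @rdname MetageneProfile-class
#' @param x see generic.
#' @export
setMethod("profileValues", "MetageneProfile", function(x) x@values)

#' Frequencies of a context matrix
#' @param x a ContextMatrix.
#' @return 4 x (2*flank+1) numeric matrix.
#' @export
setGeneric("contextFrequencies",
           function(x) standardGeneric("contextFrequencies"))

#' @rdname ContextMatrix-class
#' @param x see generic.
#' @export
setMethod("contextFrequencies", "ContextMatrix", function(x) x@freq)
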