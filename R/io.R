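#' Read a genome FASTA
#'
#' Sequences are uppercased on read; letters outside A/C/G/T/N are
#' rejected.  The returned object is a [Biostrings::DNAStringSet] named by
#' contig (FASTA header up to the first whitespace).
#'
#' @param path FASTA file.
#' @return named `DNAStringSet`.
#' @export
readGenome <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- Biostrings::readBStringSet(path)
  if (length(raw) == 0L) stop("FASTA contains no records")
  nms <- sub("\\s.*$", "", names(raw))
  if (any(nms == "")) stop("FASTA record with empty name")
  if (anyDuplicated(nms)) stop("duplicate contig name in FASTA")
  seqs <- toupper(as.character(raw))
  if (any(nchar(seqs) == 0L)) stop("empty FASTA record")
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad))
    stop("contig '", nms[which(bad)[1]],
         "' contains characters outside {A,C,G,T,N}")
  genome <- Biostrings::DNAStringSet(seqs)
  names(genome) <- nms
  genome
}

#' Write a genome FASTA
#'
#' @param genome named `DNAStringSet`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeGenome <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path)
  invisible(path)
}

#' @rdname readGenome
#' @param x a `DNAStringSet` genome.
#' @export
setMethod("contigNames", "DNAStringSet", function(x) names(x))

#' @rdname readGenome
#' @export
setMethod("contigLengths", "DNAStringSet", function(x)
  setNames(Biostrings::width(x), names(x)))

#' Read transcript models from GTF
#'
#' Parses `exon` and `CDS` features (grouped by `transcript_id`) and
#' converts the 1-based inclusive GTF coordinates to the package's 0-based
#' half-open convention.  Per-transcript 5'UTR/CDS/3'UTR mature-segment
#' lengths are derived strand-aware.
#'
#' @param path GTF file.
#' @return A [TranscriptModels-class] object.
#' @export
readTranscriptModels <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type %in% c("exon", "CDS")]
  if (length(gr) == 0L) stop("GTF contains no exon/CDS features")
  if (is.null(gr$gene_id) || is.null(gr$transcript_id) ||
      anyNA(gr$gene_id) || anyNA(gr$transcript_id))
    stop("GTF features must carry gene_id and transcript_id attributes")
  df <- data.frame(
    contig = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,  # to 0-based half-open
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    type = as.character(gr$type),
    gene_id = gr$gene_id,
    transcript_id = gr$transcript_id,
    stringsAsFactors = FALSE)
  buildTranscriptModels(df)
}

# df: contig,start,end,strand,type,gene_id,transcript_id (0-based half-open)
buildTranscriptModels <- function(df) {
  txids <- unique(df$transcript_id)
  exons <- vector("list", length(txids))
  names(exons) <- txids
  rows <- vector("list", length(txids))
  for (i in seq_along(txids)) {
    sub <- df[df$transcript_id == txids[i], , drop = FALSE]
    ex <- sub[sub$type == "exon", , drop = FALSE]
    if (nrow(ex) == 0L) stop("transcript without exons: ", txids[i])
    if (length(unique(ex$strand)) != 1L || length(unique(ex$contig)) != 1L)
      stop("transcript on mixed strand/contig: ", txids[i])
    strand <- ex$strand[1]
    if (!strand %in% c("+", "-"))
      stop("transcript without strand: ", txids[i])
    o <- order(ex$start)
    exm <- cbind(ex$start[o], ex$end[o])
    storage.mode(exm) <- "integer"
    cds <- sub[sub$type == "CDS", , drop = FALSE]
    mat <- sum(exm[, 2] - exm[, 1])
    if (nrow(cds) > 0L) {
      cs <- min(cds$start); ce <- max(cds$end)
      # CDS must lie inside the exon union
      covered <- function(a, b)
        any(exm[, 1] <= a & exm[, 2] >= b)
      if (!covered(cs, cs + 1L) || !covered(ce - 1L, ce))
        stop("CDS outside exons for transcript ", txids[i])
      t1 <- genomicToTranscript(exm, strand,
                                if (strand == "+") cs else ce - 1L)
      t2 <- genomicToTranscript(exm, strand,
                                if (strand == "+") ce - 1L else cs)
      utr5 <- t1
      cdsl <- t2 - t1 + 1L
      utr3 <- mat - utr5 - cdsl
      if (utr3 < 0L) stop("CDS exceeds transcript for ", txids[i])
      rows[[i]] <- data.frame(
        gene_id = ex$gene_id[1], transcript_id = txids[i],
        contig = ex$contig[1], strand = strand,
        cds_start = cs, cds_end = ce, mature_length = mat,
        utr5_len = utr5, cds_len = cdsl, utr3_len = utr3,
        stringsAsFactors = FALSE)
    } else {
      rows[[i]] <- data.frame(
        gene_id = ex$gene_id[1], transcript_id = txids[i],
        contig = ex$contig[1], strand = strand,
        cds_start = NA_integer_, cds_end = NA_integer_, mature_length = mat,
        utr5_len = NA_integer_, cds_len = NA_integer_,
        utr3_len = NA_integer_, stringsAsFactors = FALSE)
    }
    exons[[i]] <- exm
  }
  new("TranscriptModels", transcripts = do.call(rbind, rows), exons = exons)
}

#' Write transcript models to GTF
#'
#' Emits exon and CDS features, converting back to the 1-based inclusive
#' GTF convention.
#'
#' @param models [TranscriptModels-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeTranscriptModels <- function(models, path) {
  tx <- models@transcripts
  feats <- list()
  for (i in seq_len(nrow(tx))) {
    ex <- models@exons[[tx$transcript_id[i]]]
    feats[[length(feats) + 1L]] <- data.frame(
      contig = tx$contig[i], start = ex[, 1], end = ex[, 2],
      strand = tx$strand[i], type = "exon", gene_id = tx$gene_id[i],
      transcript_id = tx$transcript_id[i], stringsAsFactors = FALSE)
    if (!is.na(tx$cds_start[i])) {
      cdsg <- segmentGenomicIntervals(
        ex, tx$strand[i], tx$utr5_len[i], tx$utr5_len[i] + tx$cds_len[i])
      # phase: codon offset at the start of each CDS piece, transcript order
      w <- cdsg[, 2] - cdsg[, 1]
      if (tx$strand[i] == "-") w <- rev(w)
      ph <- (3L - (cumsum(c(0L, w[-length(w)])) %% 3L)) %% 3L
      if (tx$strand[i] == "-") ph <- rev(ph)
      feats[[length(feats) + 1L]] <- data.frame(
        contig = tx$contig[i], start = cdsg[, 1], end = cdsg[, 2],
        strand = tx$strand[i], type = "CDS", gene_id = tx$gene_id[i],
        transcript_id = tx$transcript_id[i], phase = ph,
        stringsAsFactors = FALSE)
    }
  }
  for (j in seq_along(feats))
    if (is.null(feats[[j]]$phase)) feats[[j]]$phase <- NA_integer_
  all <- do.call(rbind, feats)
  gr <- GenomicRanges::GRanges(
    seqnames = all$contig,
    ranges = IRanges::IRanges(start = all$start + 1L, end = all$end),
    strand = all$strand, type = all$type, gene_id = all$gene_id,
    transcript_id = all$transcript_id, phase = all$phase)
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

#' Per-gene longest mature transcript
#'
#' Selects, for each gene, the transcript with the greatest mature (exonic)
#' length; ties broken by lexicographic transcript_id.
#'
#' @param models [TranscriptModels-class].
#' @return A [TranscriptModels-class] restricted to one transcript per gene.
#' @export
longestTranscripts <- function(models) {
  tx <- models@transcripts
  o <- order(tx$gene_id, -tx$mature_length, tx$transcript_id)
  tx <- tx[o, , drop = FALSE]
  keep <- tx[!duplicated(tx$gene_id), , drop = FALSE]
  rownames(keep) <- NULL
  new("TranscriptModels", transcripts = keep,
      exons = models@exons[keep$transcript_id])
}

#' Read a bedGraph file into a dense SignalTrack
#'
#' Positions not covered by any interval are zero.  Overlapping intervals
#' and negative values are rejected.
#'
#' @param path bedGraph file (4 columns, 0-based half-open).
#' @param contigLengths named integer vector giving the dense array sizes.
#' @return A [SignalTrack-class].
#' @export
readBedGraph <- function(path, contigLengths) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^(track|#)", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0L) return(zeroTrack(contigLengths))
  gr <- rtracklayer::import(path, format = "bedGraph")
  if (any(gr$score < 0)) stop("bedGraph contains negative values")
  if (!GenomicRanges::isDisjoint(gr))
    stop("bedGraph contains overlapping intervals")
  cn <- as.character(GenomicRanges::seqnames(gr))
  if (!all(cn %in% names(contigLengths)))
    stop("bedGraph contig not in contigLengths: ",
         setdiff(unique(cn), names(contigLengths))[1])
  if (any(GenomicRanges::end(gr) > contigLengths[cn]))
    stop("bedGraph interval beyond contig end")
  gr <- GenomicRanges::GRanges(
    seqnames = factor(cn, levels = names(contigLengths)),
    ranges = IRanges::ranges(gr), score = gr$score,
    seqlengths = contigLengths)
  cov <- GenomicRanges::coverage(gr, weight = gr$score)
  SignalTrack(lapply(setNames(names(contigLengths), names(contigLengths)),
                     function(nm) as.numeric(cov[[nm]])))
}

#' Write a SignalTrack as bedGraph
#'
#' Adjacent equal-value runs are merged; zero runs are omitted (bedGraph
#' semantics: unreported positions read back as zero).
#'
#' @param track [SignalTrack-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeBedGraph <- function(track, path) {
  parts <- list()
  for (nm in contigNames(track)) {
    v <- track@values[[nm]]
    r <- rle(v)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths  # 0-based
    keep <- r$values != 0
    if (any(keep))
      parts[[nm]] <- data.frame(contig = nm, start = starts[keep],
                                end = ends[keep], score = r$values[keep])
  }
  if (length(parts) == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  all <- do.call(rbind, parts)
  gr <- GenomicRanges::GRanges(
    seqnames = all$contig,
    ranges = IRanges::IRanges(start = all$start + 1L, end = all$end),
    score = all$score)
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Write intervals as BED6
#'
#' Records are sorted by (contig, start) before writing.
#'
#' @param records data.frame with columns contig, start, end, name, score,
#'   strand (0-based half-open; strand in `+`, `-`, `.`).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeBed <- function(records, path) {
  need <- c("contig", "start", "end", "name", "score", "strand")
  if (!all(need %in% names(records)))
    stop("records must have columns: ", paste(need, collapse = ", "))
  if (any(records$start >= records$end)) stop("BED record with start >= end")
  if (!all(records$strand %in% c("+", "-", ".")))
    stop("strand must be one of '+', '-', '.'")
  records <- records[order(records$contig, records$start), , drop = FALSE]
  st <- records$strand
  st[st == "."] <- "*"
  gr <- GenomicRanges::GRanges(
    seqnames = records$contig,
    ranges = IRanges::IRanges(start = records$start + 1L,
                              end = records$end),
    strand = st, name = records$name, score = records$score)
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' Read a BED6 file
#'
#' @param path BED file.
#' @return data.frame with columns contig, start, end, name, score, strand
#'   (0-based half-open).
#' @export
readBed <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  gr <- rtracklayer::import(path, format = "bed")
  st <- as.character(GenomicRanges::strand(gr))
  st[st == "*"] <- "."
  data.frame(
    contig = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    name = if (is.null(gr$name)) "." else gr$name,
    score = if (is.null(gr$score)) 0 else gr$score,
    strand = st, stringsAsFactors = FALSE)
}

#' Read a typed TSV table
#'
#' The header must match the schema names exactly (same order); `NA` is the
#' missing-value token.
#'
#' @param path TSV file with header.
#' @param schema named character vector mapping column name to one of
#'   `"character"`, `"numeric"`, `"integer"`, `"logical"`.
#' @return data.frame typed per schema.
#' @export
readTsvTable <- function(path, schema) {
  if (!file.exists(path)) stop("no such file: ", path)
  header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  if (!identical(header, names(schema)))
    stop("TSV header does not match schema: expected [",
         paste(names(schema), collapse = ", "), "], found [",
         paste(header, collapse = ", "), "]")
  read.delim(path, colClasses = unname(schema), na.strings = "NA",
             check.names = FALSE, stringsAsFactors = FALSE)
}

#' Write a TSV table
#'
#' @param df data.frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeTsvTable <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}
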