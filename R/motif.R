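# Sequence context around CIMs: strand-aware flanking k-mers centred on
# the methylated A, position frequency matrix, IUPAC consensus.

IUPAC_CODES <- c(A = "A", C = "C", G = "G", T = "T",
                 AC = "M", AG = "R", AT = "W", CG = "S", CT = "Y",
                 GT = "K", ACG = "V", ACT = "H", AGT = "D", CGT = "B",
                 ACGT = "N")

#' Extract sequence contexts around CIM sites
#'
#' Returns the `2*flank + 1`-mer centred on the methylated A of each site,
#' in transcript orientation: minus-strand contexts are
#' reverse-complemented, so the mutated C always sits at centre + 1.
#' Sites too close to a contig edge are dropped (counted in the
#' `"n_dropped"` attribute).
#'
#' @param cims CIM table from [callCims()] (needs contig, m6a_pos, strand).
#' @param genome `DNAStringSet`.
#' @param flank nt on each side of the centre.
#' @return character vector of contexts with attribute `n_dropped`.
#' @export
extractContexts <- function(cims, genome, flank = 5L) {
  lens <- contigLengths(genome)
  out <- character(0)
  dropped <- 0L
  for (i in seq_len(nrow(cims))) {
    nm <- cims$contig[i]; c0 <- cims$m6a_pos[i]
    if (c0 - flank < 0L || c0 + flank >= lens[[nm]]) {
      dropped <- dropped + 1L
      next
    }
    s <- Biostrings::subseq(genome[[nm]], start = c0 - flank + 1L,
                            width = 2L * flank + 1L)
    if (cims$strand[i] == "-") s <- Biostrings::reverseComplement(s)
    out <- c(out, as.character(s))
  }
  attr(out, "n_dropped") <- dropped
  out
}

#' Position frequency matrix of contexts
#'
#' @param contexts equal-length context strings from [extractContexts()].
#' @param flank flank width used (recovered from string length when
#'   missing).
#' @return A [ContextMatrix-class]; columns sum to 1.
#' @export
contextFrequencyMatrix <- function(contexts, flank = NULL) {
  n_dropped <- attr(contexts, "n_dropped")
  if (is.null(n_dropped)) n_dropped <- 0L
  if (length(contexts) == 0L) stop("no contexts")
  w <- unique(nchar(contexts))
  if (length(w) != 1L) stop("contexts must have equal length")
  if (is.null(flank)) flank <- (w - 1L) %/% 2L
  cm <- Biostrings::consensusMatrix(Biostrings::DNAStringSet(contexts),
                                    as.prob = TRUE)
  f <- matrix(0, 4L, w, dimnames = list(c("A", "C", "G", "T"), NULL))
  for (b in c("A", "C", "G", "T"))
    if (b %in% rownames(cm)) f[b, ] <- cm[b, ]
  colnames(f) <- as.character(seq_len(w) - 1L - flank)
  new("ContextMatrix", freq = f, nSites = length(contexts),
      flank = as.integer(flank), nDropped = as.integer(n_dropped))
}

#' IUPAC consensus of a context matrix
#'
#' Per column, the IUPAC code covering every base with relative frequency
#' at or above `min_freq`.
#'
#' @param matrix a [ContextMatrix-class].
#' @param min_freq inclusion threshold.
#' @return single consensus string (centre = methylated A at position
#'   `flank + 1` of the string).
#' @export
iupacConsensus <- function(matrix, min_freq = 0.2) {
  f <- matrix@freq
  codes <- vapply(seq_len(ncol(f)), function(j) {
    bases <- rownames(f)[f[, j] >= min_freq]
    if (length(bases) == 0L)
      bases <- rownames(f)[which.max(f[, j])]
    IUPAC_CODES[[paste(sort(bases), collapse = "")]]
  }, character(1))
  paste(codes, collapse = "")
}

#' Write a context matrix as TSV
#'
#' Rows A/C/G/T, columns -flank..+flank.
#'
#' @param matrix a [ContextMatrix-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeContextMatrix <- function(matrix, path) {
  df <- data.frame(base = rownames(matrix@freq), matrix@freq,
                   check.names = FALSE, stringsAsFactors = FALSE)
  writeTsvTable(df, path)
}
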