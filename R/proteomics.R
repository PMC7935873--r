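# m6A-probe proteomics scoring: replicate-consistency filter,
# pseudocounted log2 enrichment ratios and interquartile-fence
# classification of bound / repelled / background proteins.

#' Remove proteins not recovered in both replicates
#'
#' A protein is retained when it is present (any probe) in replicate 1 and
#' in replicate 2.
#'
#' @param counts spectral-count table (protein, probe, replicate, count,
#'   present).
#' @return list: `counts` (retained rows), `n_removed` (proteins dropped),
#'   `n_retained`.
#' @export
filterConsistent <- function(counts) {
  if (nrow(counts) == 0L) stop("empty spectral-count table")
  pres <- counts[counts$present, c("protein", "replicate")]
  in1 <- unique(pres$protein[pres$replicate == 1])
  in2 <- unique(pres$protein[pres$replicate == 2])
  keep <- intersect(in1, in2)
  all_prot <- unique(counts$protein)
  list(counts = counts[counts$protein %in% keep, , drop = FALSE],
       n_removed = length(setdiff(all_prot, keep)),
       n_retained = length(keep))
}

#' Per-replicate log2 enrichment ratios
#'
#' `log2((count_m6A + pseudocount) / (count_A + pseudocount))`; the
#' pseudocount is applied to every count so proteins seen with only one
#' probe still get a defined ratio.
#'
#' @param counts spectral-count table (typically the retained output of
#'   [filterConsistent()]).
#' @param pseudocount added to all counts.
#' @return data.frame: protein, ratio_rep1, ratio_rep2.
#' @export
enrichmentRatios <- function(counts, pseudocount = 1) {
  prot <- sort(unique(counts$protein))
  getc <- function(probe, rep_i) {
    idx <- counts$probe == probe & counts$replicate == rep_i
    v <- setNames(counts$count[idx], counts$protein[idx])
    out <- v[prot]
    out[is.na(out)] <- 0
    out
  }
  r1 <- log2((getc("m6A", 1) + pseudocount) / (getc("A", 1) + pseudocount))
  r2 <- log2((getc("m6A", 2) + pseudocount) / (getc("A", 2) + pseudocount))
  data.frame(protein = prot, ratio_rep1 = unname(r1),
             ratio_rep2 = unname(r2), stringsAsFactors = FALSE)
}

#' Classify proteins by interquartile-range fences
#'
#' Per replicate, a protein is beyond the upper fence when its log2 ratio
#' strictly exceeds `Q3 + iqr_mult * IQR` (below `Q1 - iqr_mult * IQR` for
#' the lower fence).  `bound` requires the upper fence in both replicates;
#' `repelled` the lower fence in both; everything else is `background`.
#'
#' @param ratios data.frame from [enrichmentRatios()].
#' @param iqr_mult fence multiplier.
#' @return `ratios` with a `class` column.
#' @export
classifyBinders <- function(ratios, iqr_mult = 2.0) {
  if (nrow(ratios) < 4L)
    stop("need at least 4 proteins for stable quartiles")
  fence <- function(v) {
    q <- quantile(v, c(0.25, 0.75), names = FALSE, type = 7)
    iqr <- q[2] - q[1]
    c(lo = q[1] - iqr_mult * iqr, hi = q[2] + iqr_mult * iqr)
  }
  f1 <- fence(ratios$ratio_rep1)
  f2 <- fence(ratios$ratio_rep2)
  up <- ratios$ratio_rep1 > f1[["hi"]] & ratios$ratio_rep2 > f2[["hi"]]
  dn <- ratios$ratio_rep1 < f1[["lo"]] & ratios$ratio_rep2 < f2[["lo"]]
  ratios$class <- ifelse(up, "bound", ifelse(dn, "repelled", "background"))
  ratios
}
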