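---
title: "Methods: genetically controlled m6A miCLIP analysis"
author: "flym6A"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genetically controlled m6A miCLIP analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models behind each analysis stage, the
defaults and why they were chosen, the numerical conventions, and what the
synthetic-data generator does and does not emulate.

## Coordinates and containers

Everything internal is 0-based half-open, matching BED/bedGraph; GTF
(1-based inclusive) is converted at the boundary and never stored.
Genomes are Biostrings `DNAStringSet`s; per-position signal lives in the
`SignalTrack` S4 class (a dense numeric vector per contig); a miCLIP
library is a `TagPileup` holding a coverage track *k* and a C→T mismatch
track *m* with the validity-enforced invariant 0 ≤ m ≤ k. Tag pileups are
treated as unstranded; strand is recovered from the reference base
configuration and, where ambiguity remains, from the annotated transcript
(`filterCimsByTranscriptStrand()`), since crosslink chemistry is a
transcript-space phenomenon but bedGraph carries no strand.

## CIM calling

A crosslink-induced mutation is a C→T transition supported by `m > 1`
mutated tags at a ratio strictly inside `0.01 < m/k < 0.5`, at a reference
C whose transcript-5′ neighbour is A. Both bounds and the count threshold
are strict, and the package treats "preceding" in transcript orientation:
a minus-strand site appears in genome space as G at the site with T one
base 3′ (genomic +1). A position yields at most one site per strand. No
FDR machinery is attached — the hard filter is the method. The
strict-ratio upper bound excludes homozygous variants (m/k ≈ 1) and the
lower bound suppresses sequencing error; note that at high coverage
(k ≈ 200) genuine error-rate mismatches occasionally clear both bounds, so
a small residue of non-crosslink calls is expected and quantified in the
test-suite against the planted registry.

## Differential peak calling and genetic classification

The external differential caller is reimplemented as a documented
two-hypothesis model rather than ported byte-for-byte. Let x and y be the
IP and input counts at a position after scaling the deeper library down to
the shallower's total and adding a pseudocount (default 1). The statistic
is the log₁₀ likelihood ratio between independent Poisson rates (x, y) and
a common rate (x+y)/2, set to zero when x ≤ y: enrichment is one-sided, so
the track is non-negative and exportable as bedGraph. Equal libraries and
pure depth shifts score identically zero.

Region calling thresholds the track at `llr_cutoff` (default 2.0 — the
original tool's cutoff is unpublished, so this is the package's documented
default), merges qualifying runs separated by ≤ `g` = 20 nt and discards
merged regions shorter than `l` = 120 nt, the published parameter pair.

A wild-type region is labelled **independent** when ≥ 50 % of its length
also clears the cutoff in the writer-null enrichment track, else
**dependent**; mutant-only regions are reported as a third class. The
50 % persistence rule is one defensible operationalisation of "signal
persisted in the mutant" and is exposed as `dependence_overlap`.

**Known limitation.** Whole-region labels cannot resolve *compound*
regions that contain both a dependent and an independent site. At
realistic site densities (several sites per gene 5′UTR) such regions are
common, and any persistence threshold trades missed dependent sites
against mislabelled independent ones; the end-to-end recovery test
measures exactly this trade-off against the planted registry, and peak
splitting does not rescue it because two sites closer than ~170 nt under
the default enrichment geometry do not produce a valley deeper than half
the smaller summit.

Splitting itself follows the classical sub-peak rule: summits of the
moving-average-smoothed (window 25 nt) IP coverage; a cut at the minimum
between adjacent summits when the valley is below `valley_ratio` = 0.5 of
the smaller summit; children shorter than 30 nt re-merge with the taller
neighbour; children tile the parent exactly and inherit its label.

Heatmap matrices report the depth-scaled, pseudocounted IP/input ratio
with the peak body area-resampled to 200 bins and 500 nt flanks binned at
10 nt; flanks beyond the contig are NA.

## Metagene

Per gene the longest mature transcript is selected (ties by transcript
id). Signal is lifted exon-wise to mature-transcript coordinates, the
5′UTR/CDS/3′UTR segments are independently resampled to 200/1000/300 bins
by area-preserving per-bin means of the piecewise-constant signal (this
preserves uniformity and segment means; nearest-neighbour sampling does
not), and the 1500-bin vector is divided by its sum. The aggregate is the
arithmetic mean of per-gene unit-mass vectors. Transcripts lacking an
annotated UTR or carrying no signal are skipped and counted. Because the
question of whether IP should be input-normalised before or after scaling
is genuinely open, both library profiles are returned separately together
with a bin-wise IP/input ratio of the aggregates.

## Motif context

Contexts are (2·flank+1)-mers centred on the methylated A (position +1 is
the mutated C), reverse-complemented for minus-strand sites so all
contexts read in transcript orientation; edge sites are dropped and
counted. Frequencies come from `Biostrings::consensusMatrix`; the IUPAC
consensus includes every base with column frequency ≥ 0.2 (a logo is a
thresholdless visualisation, so the 0.2 inclusion level is the package's
documented choice; flank = 5 likewise).

## Transcript-segment annotation and target properties

Peak categories follow a fixed precedence, first overlap wins: other (no
transcript model), intron, start codon (the 3-nt window at the CDS 5′
end, strand-aware), 5′UTR, 3′UTR, CDS. The listed order is interpreted as
assignment priority. Genes are binned by their count of
*dependent*-labelled peaks with edges {1, 2, 3+} (the published figure
does not print its edges; they are an argument).

Property comparisons build a background by concatenating `n_draws`
with-replacement resamples (default 1000) of the non-methylated gene
pool, each resample sized to the compared bin so the ECDFs are
comparable, then apply a two-sided two-sample Kolmogorov–Smirnov test: D
is the exact sup-distance of the step ECDFs; the p-value uses the
asymptotic Kolmogorov distribution at effective size n·m/(n+m), with no
ties correction (properties are continuous). Raw p-values are reported,
matching the presentation style of estimation-era figures. Pooling the
resamples (rather than testing against a single resample) was chosen
because it approximates the pool ECDF while keeping the stated bootstrap
structure. One calibration subtlety follows from this choice: the
concatenated background behaves like an infinite sample, so the test is
approximately a one-sample test against the pool ECDF and is calibrated
only when the pool is much larger than the bin (pool/bin ≳ 10). The
type-I calibration test therefore simulates a small methylated fraction
(12 % of 800 genes), where every bin satisfies that ratio; with
comparable pool and bin sizes the reported p-values would be
anti-conservative, which users should keep in mind for tiny backgrounds.

## Behavioural statistics

Half PI is the mean over the final 30 s (at the trace's fps) of
0.5·(n_uncond − n_cond)/(n_uncond + n_cond), skipping frames with no flies
in either zone; the 0.5 factor makes the reciprocal-trial sum (full PI)
span [−1, 1]. Effect sizes are mean differences with a seeded
bias-corrected-and-accelerated bootstrap CI (default 5000 resamples;
acceleration from a leave-one-out jackknife over all observations;
percentile CIs by flag). Mann–Whitney p-values are exact (enumeration via
the exact U distribution) when both groups have ≤ 8 untied values, else
the tie- and continuity-corrected normal approximation. Precision
planning uses the large-sample margin of error z₁₋α/₂·√(2/n) — 0.33 SD
units at n = 72 — and two-group power is available analytically (both
rejection tails, so power at d = 0 equals the level exactly) or by seeded
Monte-Carlo simulation.

## Probe proteomics

Proteins absent from either replicate are removed first and counted.
Enrichment is log₂((m⁶A + 1)/(A + 1)) per replicate — the pseudocount is
applied to *all* counts for continuity, not only to proteins seen with
one probe. Classification uses per-replicate quartile fences: bound means
strictly above Q3 + 2·IQR in both replicates, repelled strictly below
Q1 − 2·IQR in both. Per-axis fences (rather than a pooled statistic) are
the default reading of a two-replicate scatter threshold. With fewer than
4 proteins quartiles are refused.

## The synthetic-data generator

Defaults define the simulated study conditions: 200 genes on one contig,
single-exon transcripts (multi-exon by flag, used to exercise intron
precedence), mean segment lengths 300/900/400 nt (CV 0.15), 30 % of genes
methylated with 1–3 sites (60/30/10 %), 80 % of sites in the 5′UTR, 80 %
writer-dependent, context `AAACT` with the methylated A at offset 2, mean
input depth 30, IP enrichment 8× within ±50 nt of a site decaying
linearly over a further 60 nt (so single-site regions clear the 120-nt
length filter), crosslink C→T rate 0.15 (inside the filter's open
interval), off-site error 0.001 (so the 0.01 lower ratio bound is
actually exercised), and a planted translational-efficiency deficit of
0.5 log₂ units per dependent site. Behaviour traces are two-state Markov
chains per fly (per-frame persistence 0.9) whose stationary probability
of the unconditioned side is the group bias; 12 flies per unit, 5 fps,
120 s tests scored on the last 30 s. Spectral counts are Poisson around
lognormal per-protein means with planted 8× readers.

What it does **not** emulate: read-level artefacts (PCR duplicates,
mapping bias, fragment-length structure), overlapping genes, alternative
isoforms, crosslinking sequence preference beyond the planted context,
and correlated replicate structure in proteomics. Passing tests therefore
demonstrate algorithmic correctness and statistical calibration under the
stated generative model, not robustness to alignment-level artefacts.

All `simulate*` functions are byte-deterministic given the configuration
seed; sub-streams are derived per stage so regenerated pieces are stable.

## Test problem sizes and other scope choices

Test and acceptance runs use deliberately modest sizes — 200-gene
pipelines (pooled over ten seeds for rate estimates), 800–900-gene
property tables, 200 null calibration replicates, 1000 coverage
simulations at 5000 bootstrap resamples, 10,000 power replicates — chosen
to give stable estimates at interactive runtimes. The binomial check of
the 5′UTR bias is asserted on 1-nt intervals at planted sites: whole
peaks spanning a 5′UTR usually also touch the start codon, which then
wins by precedence (the field groups "5′UTR/start codon" for the same
reason), so site-level annotation is the direct read-out of the planted
segment. The package's interface is its exported functions and this
vignette; no shell entry points are provided beyond the acceptance
script, as the intended users work in R.
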