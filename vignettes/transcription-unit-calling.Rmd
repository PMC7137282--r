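---
title: "Calling transcription units from histone-modification ChIP-seq"
author: "chromTU"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling transcription units from histone-modification ChIP-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromTU)
```

## The problem and the model

Transcript catalogues built from RNA-seq reflect RNA abundance, not
transcriptional activity: unstable or rapidly degraded transcripts leave
little steady-state RNA, and assembly breaks down in low-coverage regions.
Chromatin records transcription more directly — promoter-proximal
H3K4me3/H3K27ac, co-transcriptionally deposited H3K36me3 over gene bodies,
and repressive H3K27me3/H3K9me3 elsewhere. chromTU infers *active
transcription units* (TUs) — contiguous regions transcribed by RNA
polymerase II, from TSS to TTS — from the binarized enrichment of the six
IHEC class 1 marks alone.

The genome is tiled with non-overlapping 200-bp bins (about a nucleosome
plus linker; the last bin of a contig may be shorter). The observation for
bin $i$ is the row $C_{i\cdot}$ of the binary class matrix ($m$ bins
$\times$ $n$ marks). A hidden Markov model with $k = 17$ states generates
these rows as products of independent Bernoullis,
$P(C_{i\cdot}\mid s) = \prod_j e_{sj}^{C_{ij}}(1-e_{sj})^{1-C_{ij}}$.

The state space encodes gene anatomy on both strands:

* a single **TSS** state and a single **TTS** state, shared by the two
  strand chains;
* six gene-body states (first, internal, last exon and intron) per strand,
  twelve in all. In genome order a forward gene reads
  `TSS, exon1+, …, TTS`; a reverse gene reads `TTS, exonL−, …, exon1−,
  TSS`. Because TSS and TTS are shared, two adjacent opposite-strand TUs
  can legitimately meet in a single boundary bin;
* three **background** states. Three (rather than one) let the model
  separate quiescent chromatin from H3K27me3- and H3K9me3-dominated
  repressed domains, which otherwise bleed into gene-body states.

All other transitions — between body states of opposite strands, from
background directly into a gene body, TSS→TSS, and so on — are *structural
zeros*: exactly 0, never updated.

## Semi-supervised estimation

Parameters split into a supervised (clamped) part and a free part.

**Supervised.** Transcripts from an annotation are mapped to bins: the bin
holding the 5′ end is the TSS bin, the bin holding the 3′ end the TTS bin,
and bins strictly between are labelled by the exon/intron component
covering the majority of the bin (TSS/TTS take precedence in their own
bins; a bin shared by several transcripts is counted once per transcript).
Bin-to-bin label transitions, counted in transcript orientation and
restricted to the grammar above, give maximum-likelihood estimates of the
body-internal transitions; reverse-chain entries are the transposed
(incoming) counts row-normalised, which is the ML estimate on the reversed
sequences. Emission rows per component role are the fraction of labelled
bins in which each mark is enriched, clipped into $[\varepsilon,
1-\varepsilon]$ with $\varepsilon = 10^{-6}$; forward and reverse body
states share emission rows by default (`tie_strands`), since histone marks
do not distinguish strand. Before emission estimation, training
transcripts are filtered by 2-means clustering of their mean binarized Pol
II enrichment over TSS and TTS bins, keeping the high-mean cluster; if all
features are identical the filter degenerates and every transcript is
kept, with a warning.

**Free.** Background emission rows, every transition whose source or
target is TSS, TTS or a background state, and the initial distribution are
fitted by Baum–Welch under constraints: clamped entries are bit-identical
before and after training, and within each transition row the free entries
share exactly the row mass not held by clamped entries, in proportion to
their expected transition counts — the constrained M-step maximiser, so
the total log-likelihood is non-decreasing at every iteration (asserted at
tolerance $10^{-8}$). Background emissions are initialised from
genome-wide mark frequencies scaled by 0.5/1.0/1.5; exactly identical
background rows would be a fixed point of EM, so the scaling breaks the
symmetry deterministically. Where the annotation leaves a free chain exit
with no observed mass (e.g. `exon1+ → TTS` when no single-exon transcript
was seen), clamped entries in that row are rescaled so the free entries
keep at least `free_floor = 1e-3` of trainable mass.

Each contig is an independent observation sequence; sufficient statistics
are pooled across contigs. The defaults `max_iter = 300`, `tol = 1e-4`
run EM essentially to convergence — important in practice, because an
under-trained model leaves the three background states nearly
interchangeable, and a Viterbi path through interchangeable states pays a
$\log(1/3)$ split penalty per bin that makes it cheaper to bridge short
intergenic gaps inside a gene-body state, inflating false-positive TU
bins.

## Binarization

Enrichment calling treats the per-bin ChIP count $s_i$ as binomial in
$t_i = \mathrm{chip}_i + \mathrm{control}_i$ trials with a two-component
mixture over success probabilities, fitted by EM (background initialised
at the median per-bin ChIP fraction, enriched at the 90th percentile;
deterministic, no random restarts). Bins with $t_i = 0$ are excluded from
the fit and never called. The q-value of a bin is the running mean of
$1 - P(\text{enriched})$ along decreasing posterior order, with tied
posteriors sharing the value at the end of their tie group (this makes
calls invariant under bin permutation); bins with $q \le$ FDR (default
0.2) are called. When the two components collapse (ChIP
indistinguishable from control) the enriched label goes to the
minority-initialised component, so its posterior equals a small mixing
proportion and nothing is called.

## Decoding and refinement

Viterbi (log-space, ties toward the lowest state index) gives the state
path per contig; forward–backward (scaled, safe for $T \sim 10^6$)
gives a per-bin TU posterior — the summed posterior over the 14 TU states
— used as the ranking score in evaluation. Refinement extracts each
maximal same-strand gene-body run and emits a TU iff its flanking bins are
the correct boundaries (TSS before / TTS after for "+", TTS before / TSS
after for "−"), spanning the boundary bins inclusive; body runs truncated
by a contig end, and isolated TSS/TTS bins, are dropped. No merging across
background gaps and no length filter beyond the structural 3-bin minimum
is applied: the topology already enforces TU structure, and anything more
would be an undocumented heuristic.

## Evaluation

The gold standard marks a bin actively transcribed iff binarized Pol II
ChIP **and** nascent-RNA evidence agree: $AT = E_{\text{PolII}} \wedge
E_{\text{nascent}}$, with optional exclusion intervals (assembly gaps)
removed from all tallies. Contingency counts, precision/recall/
specificity, and ROC/PRC curves (descending-score thresholds, ties
grouped, trapezoidal AUC) are standard. Because transcribed bins are rare,
full-genome AUCs are dominated by negatives; the subsampled estimator
keeps all positive bins plus an equal number of sampled negatives per
iteration and reports $\mathrm{mean}(L_{AUC}) -
\mathrm{sd}(L_{AUC})/\sqrt{n}$ over $n$ iterations (sample standard
deviation; a mean shrunk by its standard error, i.e. deliberately
conservative). The sampling scheme is the package's choice; the combining
formula is fixed. Masks at other resolutions (50/100/500 bp) are
re-derived from intervals, never resampled from coarser vectors.

## The synthetic-data generator

`sim_config()` defines the study conditions: a 700-kb two-contig genome,
30 non-overlapping multi-exon transcripts (exon count $1 + \mathrm{Pois}(2)$,
exponential exon/intron lengths with 200-bp floors, mean intergenic gap
6 kb + 1 kb floor, mixed strands), per-role mark probabilities chosen to
mimic the canonical promoter/body/background signatures, and a count
model: per-bin trials uniform on [20, 100], ChIP fraction 0.5 in
background vs 0.9 in enriched bins — so binarization at FDR 0.2 recovers
marks imperfectly (per-mark F1 ≈ 0.89), which is intended: the HMM must
integrate across marks and neighbours. Pol II evidence covers TU bins with
probability 0.9, and 10% of TUs are withheld from the nascent-RNA
evidence, emulating Pol II-positive transcripts without RNA support.

What the generator does *not* emulate: overlapping genes and isoforms,
copy-number and mappability artefacts, fragment-level read placement,
mark-specific antibody efficiencies, and long-range dependence of real
chromatin domains. Passing tests therefore demonstrate correctness of the
algorithms under the stated generative assumptions, not real-data
performance.

## Numerical choices and problem sizes

* Forward–backward uses per-position scaling; Viterbi log-space. Emission
  probabilities are clipped to $[10^{-12}, 1-10^{-12}]$ inside likelihood
  computation so values stay finite even for user-supplied 0/1 rows.
* EM stops on log-likelihood improvement `< tol` or `max_iter`;
  monotonicity is asserted (tolerance $10^{-8}$) rather than assumed.
* Tie-breaks are deterministic everywhere (Viterbi: lowest state index;
  q-values: tie groups; k-means: fixed seed, default 17).
* Degenerate inputs fail loudly: all-zero count tracks, all-excluded
  evaluation grids, all-positive/negative gold standards for ROC,
  transcripts shorter than 3 bins (skipped with a warning).
* Test and acceptance problem sizes were chosen to exercise asymptotics
  while staying desk-sized: path enumeration up to $k^T = 4^8$, parameter
  recovery on 50,000–100,000 bins, the full pipeline on 3,500 bins.

## Known limitations

* Functional and non-functional transcription are not distinguished; the
  model reports chromatin-defined activity.
* Isoforms and nested/overlapping TUs on the same strand cannot be
  separated; the Viterbi path is a single segmentation.
* Very short TUs (< 3 bins, i.e. < 600 bp at default resolution) are
  structurally invisible.
* With closely spaced same-signature genes the decoder can merge TUs
  across short gaps (see the EM-convergence note above); the boundary rule
  guarantees well-formed output but not perfect segmentation.
* The binarization is a self-contained binomial-mixture caller; externally
  binarized tracks can be supplied as TSV when a specific caller is
  preferred.
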