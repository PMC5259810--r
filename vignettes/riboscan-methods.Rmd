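---
title: "Tag-based SSU profiling from shotgun reads: models and design"
author: "riboscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tag-based SSU profiling from shotgun reads: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riboscan)
```

## The problem

Amplicon (16S/18S) sequencing profiles microbial communities through PCR
primers that are known to amplify taxa unevenly. Whole-community shotgun
surveys avoid primers entirely, and because the SSU rRNA gene is
universal and heavily expressed, a useful fraction of shotgun (and
especially total-RNA) reads covers it. `riboscan` recovers those reads
directly: it detects the conserved boundary of a chosen hypervariable
region on each raw read and extracts the adjacent variable sequence as a
fixed-length taxonomic *tag*. No assembly, alignment to references, or
OTU clustering is involved, which keeps the procedure fast and makes tag
identity exact and reproducible across studies.

## Detection model

A recognition profile describes the 23-nt conserved *recognition
sequence* (RS) immediately flanking the target V-region:

* **PSSM.** Per position $i$ and base $b$, the weight is the smoothed
  log-odds $w_{ib} = \log_2\!\big(\tfrac{(c_{ib}+\alpha)/(N_i+4\alpha)}
  {\pi_b}\big)$ with pseudocount $\alpha = 0.5$ and uniform background
  $\pi$. A 23-nt window scores as the sum of its per-position weights;
  `N` scores the column minimum (worst case). All-gap training columns
  get zero rows. Exponentiating the matrix against the background and
  renormalising recovers the smoothed training frequencies exactly,
  which the test suite checks as a round-trip property.
* **Probe pattern.** The lowest-entropy run of 8 columns inside the RS
  window, written as an IUPAC degenerate string (bases at frequency
  ≥ 0.05 enter the code; a fully degenerate position collapses to `N`).
  The probe is a prefilter only: candidate sites matching it with at
  most one mismatch (configurable) are handed to the PSSM. With an
  unlimited mismatch budget the prefilter is inert and results are
  identical to exhaustive scanning; at the default budget the measured
  loss on synthetic reads is below 1%.
* **Window placement.** The nominal RS window abuts the V-region
  boundary given by the reference's region map; a ±5-column shift
  search keeps the placement with minimal mean column entropy, since
  annotated boundaries are approximate.
* **Threshold.** The largest score at which at least 95% of training
  sequences still pass at their true site (the order statistic of the
  training score distribution). Because training scores are discrete,
  the realised training sensitivity typically exceeds the target.

Supplementary taxon-specific profiles are trained with the same
machinery on any phylum whose members miss the universal threshold at a
rate above 5%; scanning keeps only the best-scoring hit per read and
region, with ties broken deterministically (profile id, strand, offset).

## Tag extraction and quality

Both strands of every read are scanned, and tags are always reported in
gene-sense orientation so mate pairs and antisense reads aggregate
together. A hit yields an observation only when the full 33-nt tag fits
on the read (shorter context is discarded rather than truncated, so all
tags are directly comparable) and — when qualities are present — every
tag base reaches Q30. The per-base gate, rather than a mean-quality
gate, is what makes the downstream error model sharp: at Q30 each
surviving base has error probability at most $10^{-3}$. Tags containing
ambiguity codes are dropped. A 60-nt *long* variant is extracted under
the same per-base gate when enough read remains; for an upstream-flank
profile the long variant begins with the tag, for a downstream-flank
profile it ends with it (the tag always sits at the RS-adjacent end).

## Sequencing-error model

For a focal tag, each observed tag at Hamming distance 1 contributes
$E = n\,e/3$ expected reads, where $n$ is the neighbor's read count and
$e$ the mean observed error probability at the differing position
(averaged over observations from the Phred qualities; FASTA input falls
back to a constant, default $10^{-3}$). The per-sample `fp` field is the
sum over all $3L$ neighbors; unobserved neighbors contribute zero and
multi-error paths are neglected, which the per-base Q30 gate justifies.
The expectation is reported, never subtracted: the package does not
denoise or merge tags. The generative direction is tested at depth: on
$10^6$ simulated reads from one taxon at $e = 10^{-3}$, each specific
1-nt variant is observed $n_{\text{true}}\,e/3$ times within 3σ binomial
bounds, and `expectedFp` applied to the resulting table recovers each
variant's count within the same bounds. Note the $n$ in the bound is the
*observed* neighbor count — the quantity the model itself uses — not the
raw number of simulated reads, since detection sensitivity is below 1.

## Annotation and concordance

A reference index maps every tag (and long variant) detected in a
reference collection to the sequences and 7-rank lineages containing
it. Annotation walks kingdom → species, emitting the modal label while
its fraction among non-empty labels stays at or above the vote
threshold (default 0.5; exact modal ties stop the walk, and empty or
placeholder labels leave the denominator). `confidence` is the modal
fraction at the emitted rank and equals, by construction, the tag's
*concordance* at that rank — the modal-label fraction among reference
sequences containing the tag, 1 when they all agree. Long-variant
lookups take precedence over tag lookups because the longer context is
more specific; the `use` field records which was used.

## Synthetic data: what it emulates, what it does not

The generator mirrors the SSU architecture the method relies on: 10
conserved blocks (40 nt) alternating with 9 variable blocks (70 nt,
named V1–V9), a nested taxonomy whose variable-block similarity tracks
lineage depth (one substitution round of rate 0.15 per rank step), and
conserved blocks mutated per taxon at 2% per base — the flank-noise
level at which a 95% training-sensitivity sweep is meaningfully
exercised. Reads are drawn by taxon abundance with uniform positions
(or anchored over one region's RS + tag for error-model experiments),
substitution errors only, and constant Phred strings that encode the
simulated error rate ($Q = -10\log_{10} e$, capped at Q40), so the
quality gate behaves as it would on real data. Real rRNA features it
does *not* emulate: secondary-structure covariation, indels,
platform-specific error and quality profiles, chimeras, and variable
16S copy number. Passing tests therefore demonstrate internal
correctness of the detection, counting, error and annotation models at
realistic signal/noise — not database-scale sensitivity on real
organisms.

## Problem sizes and numerical choices

The validation experiments use 600 synthetic taxa (400 training / 200
held out) for sensitivity, $10^7$ random 80-nt fragments for the
false-positive rate, $10^6$ anchored reads for the error model and
$10^5$ error-free reads for abundance recovery — sizes at which the
binomial error bars are tight relative to the thresholds being checked
while a full run stays in the tens of minutes on one CPU. Alignment
columns are 0-based half-open throughout; ranks are ordered k, p, c, o,
f, g, s with missing ranks as explicit empty strings; long-variant ties
break lexicographically; profile JSON stores doubles at 17 significant
digits so profiles reload bit-identically; `fp` prints at 4 decimals in
the tag table. All generators are seeded, and identical configuration
plus seed reproduces outputs byte for byte.

## Open design points and limitations

Where the underlying scheme leaves room, the package fixes one choice
and documents it: the RS may sit on either flank (`side`), with
upstream the default; hits from universal and supplementary profiles on
the same read are deduplicated to the single best score; paired-end
mates count as independent observations unless collapsed by read name
(`collapseByReadName`); and tag- versus long-based annotation conflicts
are resolved in favour of the long sequence. The error model considers
substitutions only, and `fp` is reported rather than used for
filtering — deciding whether a low-count tag is credible is left to the
analyst, who has `n`, `npos` and `fp` side by side.
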