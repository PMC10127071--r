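---
title: "Methods: finding and quantifying protein-coding circular RNAs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: finding and quantifying protein-coding circular RNAs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circpep)
```

## The problem

Circular RNAs (circRNAs) arise by back-splicing: a downstream splice donor
is joined to an upstream acceptor, producing a covalently closed loop. A
subset of circRNAs is translated, and the resulting proteins can be
invisible to conventional proteomics because standard search databases
contain only linear gene models. Demonstrating that a circRNA is
*translatable* requires a chain of evidence:

1. the back-splice junction (BSJ) itself must be called reliably —
   individual callers disagree, so circles supported by at least *k* of *n*
   tools are retained;
2. the circle's spliced sequence must be assembled from the genome and
   annotation;
3. open reading frames must be predicted **on the circle**, where
   translation can read through the junction — repeatedly, if no stop codon
   intervenes (rolling-circle translation);
4. a custom search database of circRNA-derived proteins must be digested in
   silico and stripped of every peptide that also occurs in the reference
   proteome, because only circRNA-unique (in practice, junction-spanning)
   peptides are admissible evidence;
5. peptide-spectrum matches (PSMs) from a search engine are mapped back to
   circles; and
6. candidate proteins are quantified by parallel reaction monitoring (PRM)
   against spiked heavy-isotope-labelled peptides.

`circpep` implements this chain end to end, downstream of the external
read aligners, circRNA callers and search engines whose outputs it
consumes.

## Translation on a circle

Let the circle have sequence $S$ of length $L$ (nt), written from the
acceptor-side base after the BSJ (offset 0). Translation is defined on the
infinite repetition $SSS\dots$: from a start codon at circle offset $s$,
codons are read until the first in-frame stop.

The key observation is frame periodicity. After one pass the reading frame
shifts by $L \bmod 3$, so the frame at the start offset recurs after

$$P = \begin{cases} 1 & L \equiv 0 \pmod 3\\ 3 & \text{otherwise}\end{cases}$$

passes. A scan of $P \cdot L$ nt from the start therefore decides every
ORF: either a stop occurs in that window, or the ORF is periodic and never
terminates. This is what makes rolling-circle translation representable —
when $3 \nmid L$, a single ORF can be longer than one pass of the circle.
The canonical example built into the synthetic generator is a 322-nt circle
encoding a 161-aa protein: $3 \times 161 + 3 = 486 > 322$, so the ribosome
crosses the junction and terminates in the second pass.

Consequences used as test invariants:

* a stop-terminated ORF satisfies $|{\rm protein}| \le L - 1$ when
  $3 \nmid L$ and $|{\rm protein}| \le L/3 - 1$ when $3 \mid L$;
* the multiset of predicted proteins is invariant under rotation of the
  circle representation (offsets shift by $-r \bmod L$);
* every stop-terminated ORF coincides with an ORF found by a conventional
  linear scanner run on the $(P{+}1)$-fold linearization, compared as
  $({\rm start} \bmod L, {\rm protein})$ pairs.

ORFs with no stop in the $P \cdot L$ window are reported with
`termination = "none"` and their protein truncated at $P \cdot L$ nt; they
are excluded from the peptide database by default because a truncation of a
periodic product is not a defined proteoform. Note the length bound above
applies to terminating ORFs only — a stop-free circle with $3 \nmid L$
yields a truncated product of exactly $L$ residues.

Every ATG occurrence (including ATGs spanning the junction) is a candidate
start, and nested in-frame ORFs are all reported with a shared `stop_id`;
selecting e.g. the single longest junction-spanning ORF per circle is a
reporting policy (`select_orfs()`), deliberately separated from the finder.
Codons containing `N` translate to `X` and never count as stop, so
ambiguous genome positions cannot fabricate a termination.

## Coordinates and consensus

All junctions are normalized to 0-based half-open coordinates at parse
time: CIRI2 output is treated as 1-based inclusive, CIRCexplorer2 and
find_circ as BED-style 0-based half-open. Off-by-one errors here silently
corrupt any downstream intersection, which is why the parsers are
dialect-explicit, the converters round-trip, and the synthetic generator
emits each caller file in its *native* dialect to exercise the conversion.

`build_consensus()` groups calls by exact `(chrom, start, end, strand)` by
default (`slack = 0`) and keeps groups supported by `min_callers >= 2`
distinct tools. Whether published screens intersected exactly or with
tolerance is typically unstated; exact matching is the stricter choice and
the default, with `slack > 0` available (clusters require all pairwise
boundary differences within the slack; canonical coordinates come from the
highest-read call, ties broken by smallest coordinates, so output is
deterministic). Strand is part of the identity because sense and antisense
circles are distinct molecules. Duplicate calls by one caller collapse to
one vote with their read counts collapsed to the maximum, so a noisy caller
cannot vote twice. Mismatched chromosome naming (`chr1` vs `1`) is
reported, never silently rewritten.

## Circle assembly

A junction is assembled from the transcript whose exon boundaries match
both junction ends exactly; exons inside `[start, end)` are concatenated in
transcript order and minus-strand circles reverse-complemented. When
several transcripts match, the one with most exons inside the span wins,
then the lexicographically smallest `transcript_id` — an arbitrary but
reproducible rule for a genuinely underdetermined choice. Offset 0 of the
circle is fixed at the acceptor-side base: any rotation is biologically
equivalent, but one must be chosen for ORF coordinates to be reproducible.
Junctions matching no annotated transcript fall back to the unspliced
genomic span with a warning (or an error with `fallback_genomic = FALSE`);
alternative internal splicing within a circle is out of scope — a known
isoform with a different exon chain is handled as its own annotated
transcript, not predicted de novo.

## Peptide database and uniqueness

Tryptic digestion cleaves C-terminal of K/R except before P, with up to
`max_missed = 2` missed cleavages. Uniqueness filtering removes any peptide
occurring as a **substring** of any reference protein — stricter than
comparing tryptic peptide sets, because it also rejects semi-tryptic
fragments of reference proteins that could otherwise masquerade as
circRNA-unique. Isoleucine and leucine are isobaric and indistinguishable
by standard MS, so matching collapses I/L by default
(`il_equivalence = TRUE`) — the conservative choice when claiming novel
evidence. Peptide lengths are bounded to 7–52 aa, a conventional
MS-observable range; all bounds are configurable. An N-terminal-Met-removed
variant of each protein is not generated (a documented toggle candidate,
off because it multiplies the database without evidence it is needed).

PSMs passing `q <= 0.01` (standard 1% FDR; PSMs without a reported q-value
are taken at face value) that match a unique peptide nominate the parent
circle. Every nomination is emitted `flagged_for_review = TRUE` with a
per-PSM detail table: the manual-curation step of published screens is
represented as a machine-readable report, never replicated or silently
auto-accepted.

## PRM quantification

Relative abundance is the ratio of summed transition peak areas,
endogenous over heavy:
$r = \sum_i a^{\rm light}_i / \sum_i a^{\rm heavy}_i$, the ratio-of-sums
convention of targeted-proteomics software, robust to one weak transition.
At least 3 transitions per precursor are required — fewer is a refusal, not
a silent pass — and a zero total heavy area is an error. Group comparisons
use the two-tailed unpaired t-test (Welch by default; the pooled variant is
available where equal variances are defensible), with degenerate cases
(singleton groups, zero denominators) reported as `NA` and flagged.

## What the synthetic generator emulates — and what it does not

`simulate_circ_study()` plants, under one seed: a two-chromosome genome
with multi-exon genes (30–60 nt flanking exons, 50–150 nt introns, some
minus-strand); circles whose single designed ORF is single-pass,
rolling-circle, or non-terminating; three callers with sensitivities
0.85/0.80/0.75 emitting native-dialect files; a reference proteome with
deliberately embedded collision peptides; a PSM table mixing true
circRNA-unique hits (q < 0.01), reference-only peptides, shuffled decoys,
above-threshold rows and a hit for a circle outside the consensus set; and
PRM transitions at a known light/heavy ratio (default 0.5) with
multiplicative lognormal noise (CV 10%, mean-corrected so the expected
noise factor is 1) — the standard error model for chromatographic peak
areas. One planted circle always reproduces the 322-nt/161-aa
rolling-circle structure.

Circle design fixes ATG at offset 0 and the stop at coding offset
$3 \cdot {\rm target}$, draws all other bases from {A,C,G} (no T, so no
spurious start or stop can assemble away from the planted ones, including
across the junction), and verifies the result by an independent scan,
rejecting and redrawing on wrapped-frame collisions. For a handful of
(L, target) combinations the wrapped stop codon would overlap the fixed
start ATG incompatibly; these are detected and refused as infeasible.

The generator does **not** emulate: read-level RNA-seq (FASTQ) or
spectrum-level MS data; caller-specific false-positive structure
(mis-mapped junction artifacts); incomplete or wrong annotation; sequence
compositional bias (planted coding regions are T-free by construction);
PTMs or charge states. Passing the end-to-end test therefore demonstrates
that the pipeline's logic is exact on well-formed inputs with known truth —
it does not certify performance on real tissue data, where caller error
modes and search-engine FDR behaviour dominate.

## Problem sizes and numerical choices

The test suite and acceptance script use: 500 random circles with
$L \in [3, 600]$ for oracle equivalence, rotation invariance and the
length bound; a 30-circle synthetic study for end-to-end recovery (expected
result: the planted `>= 2`-caller, PSM-supported circle set with zero false
positives and zero false negatives); 500 replicates for PRM ratio recovery
(true ratio 0.5, CV 10%, median within 2%). These sizes give the
properties broad coverage while keeping a full run in the order of a
minute.

Other numerical choices: `min_aa = 20` as a floor for MS-detectable
products (no universal standard exists; it is configurable); stop codons
are excluded from junction-crossing counts (coding residues only — either
convention is defensible, this one is documented and tested); all
tie-breaks (transcript choice, slack-cluster canonicalization, ORF
ordering) are deterministic so reruns are byte-identical; empty
intermediate results short-circuit downstream stages cleanly rather than
erroring.

## Known limitations

* Near-cognate starts (CUG/GUG) and IRES/m6A-driven initiation evidence are
  not modelled; `start_codons` is configurable but defaults to ATG.
* Coding-potential scoring, ribosome profiling support and decoy-database
  generation are out of scope (the last is a search-engine concern).
* The uniqueness filter guarantees absence from the *given* reference
  proteome only; an incomplete reference overstates uniqueness.
* FDR is taken from the upstream search engine's q-values; no rescoring is
  attempted.
* Quantification assumes the spiked heavy peptide co-elutes and ionizes
  identically to the endogenous form, as PRM practice does.
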