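---
title: "Detecting tissue-selective miRNA precursors by local coverage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting tissue-selective miRNA precursors by local coverage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phloemir)
library(dplyr)
```

## The problem

Plant miRNA precursors (pri-miRNAs) can be detected in phloem sap, raising
the question of which precursors are selectively recruited into the phloem
translocation stream rather than merely reflecting expression in
surrounding leaf tissue. Given two assembled tissue transcriptomes (e.g.
phloem exudate and leaf mesophyll) plus their raw reads, phloemir answers:
which contigs contain pre-miRNA hairpins, how abundant is each precursor
*specifically at the precursor* (not averaged over a possibly chimeric
contig), and which precursors are phloem-specific, leaf-specific, or
shared.

The pipeline has five stages:

1. **Homology screen.** Every pre-miRNA query is locally aligned
   (Smith–Waterman, affine gaps, both strands) against every contig, and a
   hit is retained only when its Karlin–Altschul E-value satisfies the
   strict filter $E < 10^{-15}$. The mature-miRNA window annotated on the
   query is projected through the alignment column map onto contig
   coordinates.
2. **Coverage.** Reads are mapped back to contigs (k-mer seeded, ungapped,
   mismatch-limited) and per-position depth profiles are built. Two
   statistics summarise abundance: **average coverage** (AC), the mean
   depth over the whole contig, and **local coverage** (LC), the depth at
   the central nucleotide of the mature miRNA.
3. **Selection.** Candidates pass when LC exceeds a strict threshold
   (default LC > 30). The LC distribution per tissue is characterised
   descriptively — 10-unit histogram and Shapiro–Wilk test — but never
   gates the pipeline: the test simply documents that LC is right-skewed,
   which motivates a threshold rather than a parametric cut.
4. **Comparison.** Tissues are joined per query; each query gets a
   mobility class — `phloem_specific`, `leaf_specific`, `shared`, or
   `neither`.
5. **Diagnosis.** Every candidate contig is checked for AC/LC discordance:
   if the dominant coverage peak misses the precursor and
   $\mathrm{AC}/(\mathrm{LC}+1)$ is large, AC is flagged as misleading,
   with six-frame ORF calls explaining the peak (the typical cause being a
   chimeric contig fusing a highly expressed mRNA with a low-abundance
   precursor, sometimes on the opposite strand).

## Why LC and not AC

AC is the conventional abundance measure for a contig, but de novo
assemblies contain chimeras. A contig that fuses a strongly expressed
protein-coding transcript to a weakly expressed precursor inherits a large
AC from the coding half while the precursor itself is nearly uncovered. LC
reads the depth exactly where the mature miRNA lies, so it is immune to
this artifact. The discordance report makes the failure mode explicit
instead of silently trusting AC.

The "central nucleotide" of a mature interval $[s, s+L)$ is defined as
$s + \lfloor (L-1)/2 \rfloor$ — for even $L$ the left-of-middle position.
The convention is fixed, documented, and configurable in effect through the
interval itself; mature miRNAs are usually 21–22 nt, so the two candidate
centres differ by one position of an interval whose depth is locally flat.

## E-value statistics

For an alignment score $S$ between a query of length $m$ and a database of
total length $n$ (the summed length of all searched contigs), the expected
number of chance hits is $E = K m n e^{-\lambda S}$. $\lambda$ is the
unique positive root of $\sum_{ij} p_i p_j e^{\lambda s_{ij}} = 1$, solved
by bracketed root finding to a residual below $10^{-9}$; for match +1 /
mismatch −1 on a uniform background the closed form is $\lambda = \ln 3$.
$K$ is kept at 0.41 (a typical ungapped nucleotide value) rather than
derived analytically: the pipeline only uses E-values through one strict
threshold, so mutual consistency — not absolute calibration — is what
matters, and both $K$ and the threshold are configuration values.

Scoring defaults are common nucleotide-BLAST practice: match +2,
mismatch −3, gap open −5, gap extend −2 (a gap of length $g$ costs
`gap_open + g * gap_extend`). A 92-nt precursor embedded verbatim scores
184, giving $E$ around $10^{-45}$ for realistic database sizes, while the
best chance alignment between a 92-nt query and megabase-scale noise stays
tens of orders of magnitude above the $10^{-15}$ cutoff — the filter is
sharp, which is why a strict inequality is safe.

## The synthetic-data generator

Because the original tissue libraries are external archive accessions, the
package ships a generator that emulates their structure with exact ground
truth. Its defaults are the study conditions used throughout the tests:

| parameter | default | meaning |
|---|---|---|
| `n_queries` | 20 | hairpin precursor queries |
| stem / loop / mature | 40 / 12 / 21 nt | hairpin geometry (92-nt query) |
| `stem_mismatches` | 3 | imperfect reverse-complement 3' arm |
| specific / shared | 6 + 6 / 2 | tissue-specific and shared precursors |
| `n_background` | 6 per tissue | precursor-free contigs |
| `n_chimeric` | 1 | leaf contig fusing ORF + precursor segments |
| abundance high : low | 50 : 1 | relative transcript weights |
| reads | 50,000 × 100 nt per tissue | single-end, error-free by default |
| contig length | 400–2000 nt | uniform |

Reads are drawn by sampling a source region with probability proportional
to `weight × (region_len − read_len + 1)` and then a start uniformly, so
interior depth at any position is Binomial(R, ℓ/(G−ℓ+1)). The chimeric
contig is generated from two regions with separate weights (ORF segment
high, precursor segment low), which is what makes its whole-contig AC
misleading; its fused ORF is placed on the strand opposite the precursor.
The 50:1 abundance ratio is a free choice — no abundance distribution for
phloem RNAs is established — picked so that selected precursors sit far
above the LC threshold (expected LC in the hundreds) while the chimeric
precursor segment stays well below it (expected LC ≈ 10).

What the generator does *not* emulate: realistic error profiles (errors
are i.i.d. substitutions; default rate 0), paired ends, strand-specific
library artifacts, expression noise beyond multinomial sampling, splice
junctions, or RNA secondary-structure thermodynamics (hairpins are
sequence-level constructions, not folded structures). Passing end-to-end
tests therefore demonstrate the correctness of the statistics and the
pipeline logic under clean conditions, not robustness to every real-data
pathology — though the mapper tolerates substitutions and accepts external
SAM, so real alignments can be substituted.

## Numerical and design choices

* **Coordinates** are 0-based half-open everywhere internally, matching
  BED; SAM POS is converted on read/write.
* **Read mapper.** Seeds are the read's first and last k-mer (k = 21,
  both strands), verified by full-length ungapped mismatch counting
  (max 3). Ambiguous reads (best placement tied across contigs) are
  discarded rather than randomly placed so LC is deterministic. The
  mapper is ungapped by design; gapped alignments can be supplied as SAM.
* **Best-hit reduction.** When several contigs in one tissue match one
  query above threshold, the lowest E-value represents the query (ties:
  highest LC) — the comparison's decision unit is one contig per
  (tissue, query).
* **Coverage peak** is the longest run of positions with depth ≥ 50% of
  the contig maximum (ties: leftmost). The 0.5 fraction and the
  discordance ratio (default 5) are configurable; the ratio uses
  AC/(LC+1) so zero-LC contigs are well-defined.
* **ORF calls** require an ATG start and span to the next in-frame stop
  (or the last complete codon), first ATG per stop-delimited segment, all
  six frames, minimum 150 nt by default.
* **In-silico PCR** requires total primer mismatches ≤ 2 with the
  3'-terminal 3 bases exact — the 3' rule is what makes
  species-discriminating primers work. Both primer-role orientations are
  scanned; product length spans both primer footprints.
* **Shapiro–Wilk** uses the standard Royston implementation
  (`stats::shapiro.test`); degenerate inputs (n < 3, zero variance) are
  reported as errors or NA rather than fabricated statistics.
* **Determinism.** Every stochastic stage takes an explicit seed;
  identical config + seed reproduces FASTA/FASTQ byte-for-byte, and
  `run_all()` twice on the same inputs writes byte-identical reports.

## Problem sizes in the test-suite

Unit and property tests run on reduced scenarios (8 queries, ~8000 reads)
chosen to exercise every code path in seconds; the end-to-end acceptance
checks use the full default conditions above (20 queries, 50,000 reads per
tissue). The aligner is validated against an exhaustive
dynamic-programming oracle on 100 random pairs of up to 25 nt, and depth
profiles against brute-force membership counting on 1000 random
placements.

## A worked fixture

The packaged paired-tissue abundance table demonstrates the selection
logic on published-scale values:

```{r}
cmp <- compare_from_table(threshold = 30)
glance(cmp)
filter(tidy(cmp), class != "neither") |>
  select(query_id, leaf_lc, phloem_lc, class)
```

Strict LC > 30 keeps 11 contigs per tissue with exactly two pre-miRNAs in
the intersection; one precursor is phloem-only, one leaf-only — the
pattern that motivates the species-discriminating PCR validation
implemented in `find_primer_sites()` / `in_silico_pcr()`.

## Known limitations

* E-values use the ungapped statistics with a fixed K; gapped-alignment
  Karlin–Altschul fitting by simulation is out of scope.
* The homology screen is exhaustive Smith–Waterman, not seeded — fine for
  tens of queries × thousands of contigs, not for genome-scale databases.
* One best alignment per (query, contig); sub-optimal HSPs are not
  reported.
* The discordance verdict depends on a single dominant peak; multimodal
  coverage with a genuine precursor peak plus a larger unrelated peak is
  still flagged, which is the intended conservative behaviour.
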