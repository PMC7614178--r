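---
title: "The repeatkit two-step repeat annotation protocol: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The repeatkit two-step repeat annotation protocol}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(repeatkit)
```

## The problem

Plant genomes are dominated by transposable elements (TEs), and masking
them is a prerequisite for gene annotation. The two common strategies
fail in opposite directions: de novo k-mer detectors are fast and
library-free but report anonymous intervals, while homology masking with
a community repeat library is interpretable but inherits the library's
contamination — entries derived from host genes will mask real genes,
and disease-resistance NLR loci, which are young, repetitive-looking
multigene families, are the classic victims. `repeatkit` implements a
protocol that combines the two: call repeats by k-mer counting, then
classify only the called intervals against a curated, nonredundant TE
library. This vignette documents the models, the tunable parameters and
the design decisions behind each module.

## Repeat detection by canonical k-mer counting

The detector scores position $i$ of a genome with $c(w_i)$, the
genome-wide occurrence count of the canonical form of the $k$-mer $w_i$
starting there. The canonical form is the lexicographic minimum of a word
and its reverse complement, so the two strands of an inverted TE copy
contribute to one shared count. Maximal runs of positions with
$c(w_i) \ge t$ become intervals $[a, b + k)$ (the last word's full
extent, clipped to the sequence end); intervals separated by at most
`merge_dist` bp are merged; intervals shorter than `min_repeat_len` are
dropped. The interval score is the mean position count over the word
starts it covers, and windows containing `N` score 0.

Tunable parameters, with defaults and rationale:

* **`k` (word size), default AUTO** = $\lfloor \log_4 L \rfloor$ clamped
  to $[13, 16]$ for total genome length $L$ in bp. The clamp matches the
  word sizes observed in practice on plant genomes of increasing size;
  explicit small `k` is allowed for small test genomes, where the AUTO
  choice would make every word unique.
* **`count_threshold` $t$, default 3** (occurrences). With
  $k = \lfloor \log_4 L \rfloor$, a random unique $k$-mer is expected
  $L/4^k \in [1, 4)$ times by chance, counting both strands; $t = 3$
  therefore sits just above the background expectation while a family
  with $\ge 3$ aligned copies still clears it. The detector is a
  transparent count-threshold caller by design — no smoothing or hidden
  state — so that every call is auditable against the count table; the
  acceptance surface for this simplification is planted-repeat recovery
  on synthetic genomes, not bitwise equivalence with any specific
  external masker.
* **`merge_dist`, default $k$** bp. An isolated substitution inside a
  repeat copy breaks the run of high-count words for exactly $k$
  positions; merging across gaps of up to $k$ bp heals those breaks
  without bridging unrelated repeats.
* **`min_repeat_len`, default $\max(2k, 30)$** bp: drops calls supported
  by a single spurious high-count word.

Two invariants are tested rather than assumed: total count mass equals
the number of N-free windows (mass conservation against a naive
per-position oracle), and lowering $t$ never decreases the masked bp
(monotonicity). Soft-masking lowercases exactly the called intervals and
never changes sequence length.

## Classification against a classified library

Only repeats **longer than 90 bp** are processed (strict inequality; a
90 bp call is skipped, a 91 bp call is annotated). Each annotatable
repeat is aligned to the library; the best hit — maximal alignment
score, ties broken by larger aligned span, then by lexicographically
smallest library id — supplies the classification, which is parsed from
the library FASTA header after the *first* `#`
(`RLG_43695:mipsREdat_9.3p_ALL#LTR/Gypsy` gives class `LTR/Gypsy`; the
class text may itself contain `/` or further `#`). Repeats with no
qualifying hit stay `UNANNOTATED`; satellite and simple repeats are
expected to remain in this bin, since the protocol deliberately does not
annotate them.

The default aligner is internal: exact shared 11-mers seed gapless
blocks per diagonal, blocks are X-drop extended (score +1/−1, drop 10)
and chained collinearly with a penalty of one column per bp of diagonal
shift; chaining tolerates up to 60 bp of block overlap (an artifact of
extension past an indel), and overlapping columns are trimmed from both
the match and column totals so identity is never inflated. Alignments
with identity ≥ 0.70 and span ≥ 90 bp are reported. This keeps the
toolkit dependency-free and lets the identity be checked against a full
Smith–Waterman oracle (agreement within 0.03 on 300 bp pairs up to 15%
divergence, enforced in the test suite). For production use with a
long-read mapper, `annotate_repeats(..., paf = read_paf(path))` consumes
external PAF alignments instead, with query names `seq_id:start-end`.

A best-hit-per-repeat contract (rather than a per-base mosaic) is used
because it is the simplest contract consistent with per-repeat
classification output; a repeat genuinely spanning two families receives
the single best class, which users should be aware of.

## Library curation

Sources (TE libraries and transcript sets) are merged with ids prefixed
by a source tag; sequences outside **90–55,000 bp (inclusive)** are
dropped — the bounds are admissible limits, so a 90 bp or a 55,000 bp
sequence is kept. Pairs are connected when local alignment (both
strands) reaches **95% identity** over the combined aligned blocks and
**75% coverage of the shorter sequence**; clusters are the connected
components of this graph. At this stringency the components are the
natural closure of the pairwise criterion; an inflation-based partition
(MCL) is a plug point, not implemented, because no inflation parameter
is part of the protocol. The **longest member** of each cluster is its
representative (ties to the lexicographically smallest id, making the
partition and representatives invariant under input order — both
properties are tested).

Cluster filtering: TE-only clusters are kept; transcript-only clusters
are dropped; mixed TE/transcript clusters — the dangerous ones — are
kept only when (a) they contain sequences from at least **six** distinct
TE libraries and (b) their fraction of members flagged as potential host
genes is **exactly zero**. The zero threshold is deliberate: a fraction
"below 0.00" is read as "0.00 after rounding", i.e. no flagged member at
all. Raising the library threshold computes an intersection-like
library; lowering it a union-like one.

Library quality is audited with control Pfam-domain lists: positives
found in TEs, negatives found in NLR disease-resistance genes. The
domain search itself (hmmscan) is consumed as a `--domtblout`-style
table, not recomputed; version suffixes are stripped from accessions
(`PF02892.12` → `PF02892`). The confusion matrix counts
TP/FN/FP/TN by set intersection and reports sensitivity and specificity
rounded to two decimals. Control lists are not assumed disjoint — some
domains (e.g. the zf-BED zinc finger) occur in both transposases and R
genes — so any overlap between the lists is reported explicitly rather
than silently resolved.

## Masking benchmark statistics

All interval arithmetic is 0-based half-open (BED convention);
conversion to and from 1-based closed coordinates happens only at the
GFF boundary, and exon sets are taken from the transcript flagged
canonical (else the one with most exonic bp). Per-feature overlap is the
union of intersections with the merged repeat set, bedtools-intersect
style, and is verified against a per-base set oracle.

Proximal flanks are strand-oriented windows of 500 bp (default) next to
each gene, clipped at chromosome ends. Base pairs intersecting *any*
gene are subtracted; when a neighbor gene cuts a window in two, only the
fragment contiguous with the focal gene's edge is kept — the window is
meant to be *proximal* regulatory space, and a fragment beyond an
intervening gene is not. Unstranded features are treated as `+`.

The NLR masking odds ratio is

$$\mathrm{OR} = \frac{\mathrm{NLR}_{masked} / \mathrm{Gen}_{masked}}
                     {\mathrm{NLR} / \mathrm{Gen}}$$

with all four spaces measured in bp (the quantities are "spaces", and bp
is the resolution at which masking acts). Only loci with **more than
50 bp** of repeat overlap contribute to $\mathrm{NLR}_{masked}$; an
exactly-50 bp overlap contributes nothing. $\mathrm{OR} = 1$ means NLR
space is masked at the genome-average density, $\mathrm{OR} > 1$ that
NLR genes are preferentially masked. The statistic is undefined (an
error, not a silent 0) when nothing is masked or no NLR space is given.

Domain enrichment among repeat-overlapped genes uses gene-level
presence/absence 2×2 tables (a gene carrying a domain twice counts
once — the reproducible reading of proteome-level domain frequencies as
expected values): foreground = genes with **more than 50 bp** overlap,
background = the remaining gene universe. Two-sided Fisher exact
p-values (minimum-likelihood summation, the convention of R's
`fisher.test`, which is also the implementation) are adjusted by
Benjamini–Hochberg across all tested domains; only *enrichment*
(odds ratio > 1, FDR < 0.05) is flagged — depletion is visible in the
table but not flagged, since the protocol's question is whether masking
preferentially hits a domain class. Degenerate tables where foreground
and background rates are equal (e.g. a domain present in every gene)
report an odds ratio of 1.

The canonical k-mer census counts distinct canonical words with
occurrence ≥ 20 (the jellyfish `-C` / `dump -L 20` convention) at
k = 16, 21 or 31. Note that complementary rotations of a periodic
sequence share a canonical key: `ACGT` repeated 100 times has three
distinct canonical 16-mers, not four, because the `CGTA…` and `TACG…`
rotations are reverse complements of one another.

## The simulator: what it emulates and what it does not

`simulate_genome()` plants `n_families` random consensus sequences
(default 5, 300–3,000 bp) as `copies_per_family` copies (default 20),
each independently mutated (2% substitutions, 0.2% single-bp indels by
default) and inserted on a random strand at non-overlapping positions in
an i.i.d. background of 40% GC — numbers chosen to emulate a young,
moderately diverged TE complement at a repeat fraction (~20%) typical of
small plant genomes. Copies *replace* background residues, so the
planted fraction bookkeeping is exact, and truth BED, classified truth
library, gene models (GFF3 with a canonical transcript), NLR loci and a
gene-to-domain table are emitted alongside. Identical seeds give
byte-identical outputs.

What the simulator does **not** emulate — and hence what passing tests
do not show about real data: nested and fragmented insertions, solo-LTR
formation, target-site duplications, TE age structure, satellite arrays
and low-complexity sequence, GC heterogeneity, and assembly gaps beyond
literal `N`s. Detector performance on the synthetic genome (recall
≈ 0.98, precision ≈ 0.99) is therefore an upper bound; the protocol's
behaviour on real genomes must be judged with the benchmark statistics,
not the simulator.

## Numerical choices and degenerate inputs

* Ties are always broken deterministically (larger span, then smallest
  id for hits; smallest id for equal-length representatives), so every
  pipeline stage is reproducible and order-invariant.
* `N` is a legal residue: windows containing it score 0 in the detector
  and are skipped by seeding; intervals may span it.
* Lowercase input residues are uppercased for counting and alignment
  (prior masking is ignored — the protocol computes its own), but case
  is preserved through FASTA I/O so soft-masked output survives
  round-trips.
* Empty call sets report precision 1 with a warning (no false positives
  were made); empty truth sets are an error (recall is undefined).
* Zero repeat bp makes annotated fractions 0 with a warning; an all-zero
  Fisher table gives p = 1 with a warning.
* Interval containers validate $0 \le start < end \le L$ everywhere;
  overlap-sensitive statistics (masked fraction) refuse overlapping
  input rather than silently double-counting.

## Problem sizes used in the shipped checks

The test suite and the acceptance script run entirely on simulated data:
a 1 Mbp genome with 100 planted copies for detector recovery (the
standard study condition), 80–300 kb genomes for the module-level
properties, ≤ 50-sequence libraries for clustering-oracle equivalence,
and 200-interval random sets for the per-base overlap oracle. These
sizes keep the whole suite at desk scale while leaving every code path —
including the AUTO word-size clamp, which is exercised through the
closed form — covered.

## Known limitations

* The count-threshold detector has no trained background model; on
  genomes with strong compositional heterogeneity a single global
  threshold may over-mask GC-poor regions. The threshold is exposed.
* The internal aligner is a classifier, not a polisher: identities are
  accurate to a few percent (oracle-bounded at 0.03), but breakpoints
  are approximate. Use external PAF alignments when exact breakpoints
  matter.
* All-pairs clustering is quadratic in library size; it is meant for
  curation experiments and fixtures, not for re-clustering
  million-sequence collections.
* Per-repeat best-hit classification cannot represent chimeric repeats.
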