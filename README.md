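# repeatkit

Transposable elements (TEs) make up most of many plant genomes, and the
first step of almost every annotation pipeline is to find and soft-mask
them. Homology-based masking with a repeat library is sensitive but
inherits the library's defects: entries derived from cellular genes can
mask real genes — disease-resistance (NLR) loci are notorious casualties —
and redundant multi-source libraries make annotation slow and
inconsistent. `repeatkit` implements a two-step alternative protocol,
together with the machinery to build and audit the library it uses:

1. **De novo repeat detection by k-mer counting.** Every position of the
   genome is scored with the genome-wide count of the canonical k-mer
   starting there (canonical = lexicographic min of the word and its
   reverse complement, so both strands share one count). Maximal runs of
   positions with count ≥ *t* become repeat intervals, which are merged,
   length-filtered and soft-masked. The word size is chosen as
   `k = floor(log4 L)` clamped to 13–16 for a genome of length `L`.
2. **Classification against a nonredundant TE library.** Repeats longer
   than 90 bp are aligned to a classified library (internal
   seed–chain–extend aligner, or external PAF alignments); each repeat
   inherits the class of its best hit, parsed from the library FASTA
   header after the first `#` (e.g. `RLG_43695:...#LTR/Gypsy`).

The library-curation module builds such a library from multiple source
collections: sequences of 90–55,000 bp are clustered at ≥ 95% identity and
≥ 75% coverage of the shorter sequence, the longest member of each cluster
is kept as representative, and mixed TE/transcript clusters are retained
only with support from ≥ 6 distinct TE libraries and no members flagged as
potential host genes. Library quality is summarised as a confusion matrix
against control Pfam-domain lists (TE-associated positives, R-gene
negatives), reporting sensitivity `TP/(TP+FN)` and specificity
`TN/(TN+FP)`.

The benchmark module quantifies what a masking strategy does to
annotation: overlap fractions for genes, exons and proximal 500-bp flanks
(neighbor genes subtracted), the odds ratio of NLR masking

    OR = (NLRmasked / Genmasked) / (NLR / Gen)

over loci with > 50 bp of repeat overlap, Fisher exact tests (with
Benjamini–Hochberg FDR) for Pfam-domain enrichment among genes with
> 50 bp of repeat overlap, and canonical k-mer censuses (k = 16/21/31,
count ≥ 20). A simulator plants mutated TE-family copies in a random
background so every stage can be scored against a known truth.

## Worked example

```r
library(repeatkit)

# a 1 Mbp genome with 5 planted TE families x 20 copies at 2% divergence
sim <- simulate_genome(simulation_params(seed = 42))
sim$planted_fraction
#> [1] 0.224998

det <- detect_repeats(sim$genome)   # k chosen automatically (13 here)
det$masked_fraction
#> [1] 0.222245
evaluate_against_truth(det$intervals, sim$repeats)
#>    recall precision        f1
#> 0.9821910 0.9943576 0.9882368

ann <- annotate_repeats(det$intervals, sim$genome, sim$library)
annotated_fraction(ann, sim$genome)["repeat_fraction"]
#> repeat_fraction
#>       0.9905465
```

The detector recovers 98% of planted repeat bases at 99% precision and
masks 22.2% of the genome against 22.5% planted; annotation against the
truth library classifies 99% of the called repeat space.

The same pipeline is available from a shell via the thin dispatcher in
`exec/`:

```sh
repeatkit simulate --length 200000 --families 3 --copies 8 --seed 5 \
    --out-dir fx/
repeatkit mask fx/genome.fa --out-bed fx/called.bed --out-fasta fx/masked.fa
#> k = 13 | 170723 distinct k-mers | 72 repeats | masked 22.56%
repeatkit annotate fx/called.bed fx/genome.fa fx/library.fa --out fx/ann.bed
#> 72 repeats | 99.3% of repeat space annotated
repeatkit benchmark fx/called.bed --genome fx/genome.fa \
    --genes fx/genes.gff3 --nlr fx/nlr.bed --out fx/report.tsv
```

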