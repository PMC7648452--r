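# kmersurprisal

Alignment-free analysis of the information content of biological
sequences, for genomicists who want to ask "how much information does
this locus carry?" without building a multiple sequence alignment.

The core quantity is the **surprisal** of a k-mer *x*,

    S(x) = -log2 p(x),        p(x) = counts(x) / Σ counts(x)   [bits]

estimated from a genome-wide frequency table. From the same table the
package derives the Shannon entropy *H = E[S]*, the total information
*I = total · H*, and the redundancy *R = 1 − H_obs / H_max* with
*H_max = k·log2 A* (2k bits for DNA, k·log2 20 for peptides), together
with saturation diagnostics for choosing k. Because surprisal is
inversely related to occurrence, averaging it across many loci anchored
at a shared biological feature — splice junctions here — exposes common
motifs as low-surprisal stretches and constrained or depleted sequence
(e.g. CG-containing words in a CpG-suppressed genome) as high-surprisal
stretches. Profiles are computed in DNA, coding-mRNA and amino-acid
space, with coding k-mers deduplicated by genomic locus so transcripts
sharing exons are counted once, and amino-acid values expanded 3-fold
onto nucleotide offsets in their codon phase for cross-space comparison.

A seeded synthetic genome + GTF generator with planted splice features
(GT…AG introns, polypyrimidine tracts, branch points, exon-skipping
isoforms, tunable CG suppression) makes every stage testable fully
offline.

## Worked example

```r
library(kmersurprisal)

spec   <- synthetic_genome_spec(seed = 42, chrom_lengths = c(200000L, 100000L),
                                n_genes = 12L)
fx     <- write_fixture(spec, "demo")          # genome.fa, annotation.gtf, ...
genome <- read_genome_fasta(fx$fasta)
models <- parse_gtf(fx$gtf)

tab <- count_kmers(genome, 6, both_strands = TRUE)
entropy_summary(tab)
#> <entropy_summary> k=6 (nucleotide)
#>   H_obs=11.6405 bits  H_max=12.0000 bits  R=0.0300
#>   I=6.984e+06 bits over 599,980 windows; 4089 k-mers observed (fraction 0.998)
```

The 6-mer table realises almost all of its 12-bit capacity (R = 0.03);
the missing 0.36 bits come from compositional skew and CG suppression.
Segregating the table by CG content shows the suppression directly —
k-mers containing more copies of the depleted dinucleotide are rarer and
therefore more surprising:

```r
segregate_spectrum(tab, "CG")$surprisal[, c("class", "n_kmers", "mean")]
#>   class n_kmers  mean
#> 1     0    2911 11.69
#> 2     1    1091 14.42
#> 3     2      87 17.09
```

Profiling surprisal across donor splice sites (offset 0 = first intron
base; the junction lies between offsets −1 and 0):

```r
jx  <- derive_junctions(models, min_dist = 100)
don <- jx[jx$kind == "donor", ]
w   <- junction_windows(don, genome = genome, upstream = 8, downstream = 8)
prof <- profile_surprisal(w, surprisal_table(tab))
subset(prof$stats, offset >= -2 & offset <= 2)
#>    offset  n mean_surprisal     sd      cv n_excluded
#> 7      -2 82          12.12 1.2427 0.10254          0
#> 8      -1 82          12.10 1.1392 0.09417          0
#> 9       0 82          11.71 0.4341 0.03708          0
#> 10      1 82          11.19 0.3992 0.03567          0
#> 11      2 82          11.44 0.4366 0.03815          0
```

All 82 filtered donors begin `GT`, so the k-mers starting at offsets 0–1
are drawn from a constrained class: their across-junction sd collapses
(0.40–0.43 vs ≈1.2 bits in the exon) and their mean drops toward the
class-conditional expectation. The same machinery produces acceptor and
exon–exon profiles, coding-mRNA and amino-acid panels
(`coding_kmer_table()`, `aa_profile_expand()`), positional CG frequency,
phased dinucleotide usage and sequence-logo information content.

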