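---
title: "k-mer surprisal: model, conventions and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{k-mer surprisal: model, conventions and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kmersurprisal)
```

## The model

A sequence is read as an ensemble of overlapping words of length $k$
(k-mers) over a fixed alphabet: the four nucleotides for DNA and coding
mRNA, or the twenty standard amino-acid letters for peptides. Counting
every window that consists entirely of alphabet symbols gives a frequency
table, from which the probability of a k-mer $x$ is its maximum-likelihood
estimate

$$p(x) = \frac{\mathrm{counts}(x)}{\sum_x \mathrm{counts}(x)},$$

where the denominator is the number of accepted windows. The
self-information, or *surprisal*, of $x$ is

$$S(x) = -\log_2 p(x) \quad \text{(bits)},$$

so common words carry little information and rare words much. The Shannon
entropy of the table is the expected surprisal
$H = -\sum_x p(x)\log_2 p(x)$, the total information of the ensemble is
$I = \sum_x \mathrm{counts}(x)\,S(x) = \mathrm{total}\cdot H$, and the
*redundancy*

$$R = 1 - \frac{H^{\mathrm{obs}}}{H^{\mathrm{max}}}, \qquad
H^{\mathrm{max}} = k\log_2 A,$$

measures the fraction of encodable capacity left unrealised by nullomers
(unobserved k-mers) and by skew in the distribution. These four statistics
are implemented in `kmer_probability()`, `kmer_surprisal()`,
`kmer_entropy()` and `entropy_summary()`, always in bits.

## Choosing k

Because a finite sequence of $N$ windows cannot realise more than $N$
distinct k-mers, $H^{\mathrm{obs}}$ saturates while $H^{\mathrm{max}}$
grows linearly in $k$: redundancy rises and the fraction of possible
k-mers observed collapses once $A^k$ outgrows $N$. `k_selection_report()`
computes both diagnostics over a range of $k$ and flags rows where
$A^k > N$ as `truncated`; `saturation_k()` returns the smallest $k$ past
that point (17 for a both-strands human-scale genome of $6.2\times10^9$
positions). In practice this motivates 12-mers for genome-wide DNA work
and 9-mers (amino-acid 3-mers) when DNA, coding mRNA and peptide spaces
are compared, the coding sequence being a much smaller corpus.

## Junction profiles

Splice junctions give a fixed biological anchor at which surprisal can be
averaged across many loci. The package uses one convention everywhere:

* offset 0 is the first position downstream of the junction in transcript
  orientation, offset −1 the last position upstream, so the junction falls
  between −1 and 0;
* the value plotted at offset $i$ is the surprisal of the k-mer whose
  *first* symbol sits at offset $i$. The k-mer at offset −1 of an
  exon–exon junction therefore joins the last base of the upstream exon to
  the following $k-1$ bases across the splice, which is what makes
  junction-specific word usage visible as a spike or dip at −1.

Donor (5′ splice site) and acceptor (3′ splice site) profiles are read
from genomic sequence on the transcript strand; exon–exon profiles are
read from the spliced sequence — against the genomic k-mer table for the
DNA panel and against the CDS-restricted table for the coding-mRNA panel.
Junctions closer than `min_dist` (default 100 nt, configurable) to the
transcript ends (donor/acceptor) or to the translation start/end
(exon–exon) are removed before profiling. Windows that overrun a sequence
end are padded with `"."` and only the affected offsets are dropped, not
the junction. k-mers containing foreign symbols, and k-mers that are
nullomers in the scoring table, are likewise excluded per offset with the
exclusion count reported; surprisal of a nullomer is deliberately an
error, never an infinite sentinel, so means cannot silently absorb it.

### Amino-acid comparison

Amino-acid k-mers are a third the length of the nucleotide k-mers they
are compared with ($k_{aa} = k_{nt}/3$; `aa_profile_expand()` refuses
$k_{nt}$ not divisible by 3). To overlay the spaces, each junction's
residue-level surprisal values are repeated over the three nucleotide
offsets of their codon, shifted by that junction's codon phase (the CDS
offset of the junction mod 3): a residue at amino-acid offset $a$ of a
phase-$\phi$ junction covers nucleotide offsets $3a-\phi+\{0,1,2\}$.
Averaging then proceeds per nucleotide offset. The expansion is exactly
conservative: each residue value occupies three consecutive nucleotide
offsets per junction, which the tests assert literally.

### Coefficient of variation

The per-offset coefficient of variation is reported as the standard
sd/mean under the primary name `cv`; because some conventions print the
inverted ratio, `coefficient_of_variation()` also emits `mean_over_sd`.
Offsets with fewer than two junctions or zero mean are undefined.

## The multiple-transcript correction

Most genes express several transcripts sharing exons, so naive
per-transcript counting would multiply-count k-mers from shared exons.
`coding_kmer_table()` keys every coding k-mer occurrence by its genomic
locus — chromosome, strand, start and end of the occupied span, with
junction-spanning k-mers spanning the intervening intron — and retains
exactly one occurrence per distinct key, ordered by transcript id for
determinism. Duplicating every transcript in the annotation leaves the
resulting tables bit-identical, which is both a test and an acceptance
check. The locus key cannot distinguish two junction-spanning k-mers with
identical outer coordinates but different splice chains; following the
key as defined, such collisions are collapsed with a warning rather than
silently or fatally.

## Composition analyses

`segregate_spectrum()` partitions observed k-mers by the number of
occurrences of a dinucleotide (CG by default) they contain, attaching to
each class its occurrence spectrum and a surprisal summary (min,
quartiles, max, mean over distinct k-mers). Under CG suppression the
class means rise monotonically: k-mers containing the depleted
dinucleotide are systematically rarer, hence more surprising.
`dinucleotide_frequency()` normalises overlapping dinucleotide counts
over all 16 categories, optionally adding the reverse-complement strand —
both strands are counted and all 16 entries reported, rather than folding
complementary pairs. `phased_dinucleotide_usage()` assigns every
dinucleotide inside a CDS to a codon phase by its start offset mod 3
(phase 0 = codon positions 1–2, phase 1 = 2–3, phase 2 joins a codon to
the next); windows never cross CDS records or splice junctions.
`position_information()` computes the sequence-logo statistic $2-H$ per
alignment column, with no small-sample correction.

## The synthetic genome generator

`synthetic_genome_spec()` / `generate_synthetic_genome()` build a fully
offline test fixture: background chromosomes from a first-order Markov
chain, and planted protein-coding genes with the features the analysis
stages look for. Defaults define the study conditions used throughout the
tests and the acceptance script:

| parameter | default | why |
|---|---|---|
| `chrom_lengths` | 2 × 1 Mb | large enough for stable 6–9-mer tables, small enough for desk-scale runs |
| `base_frequencies` | 0.295/0.205/0.205/0.295 | tetrapod-like 41% GC |
| `cg_suppression` | 0.2 | strong CpG depletion, the regime the composition analyses target |
| `n_genes` | 40 | a few hundred junctions after filtering |
| `exons_per_gene` | 3–8, `exon_length` 90–300 nt | compact but multi-junction genes |
| `intron_length` | 200–1500 nt | room for branch point, tract and deep-intron flanks |
| `polypyrimidine_length` | 10–20 nt at `pyrimidine_prob` 0.85, ending 4–8 nt upstream of the acceptor | canonical tract geometry |
| `branch_consensus` | `CTAAC`, ending 15–55 nt upstream | canonical branch-point placement |

Every intron begins `GT` and ends `AG`; every CDS starts `ATG`, ends
`TAA`, has length divisible by 3 and no internal stop (internal stops are
repaired by a `T`→`C` first-base edit, which cannot create new stops).
Genes receive an exon-skipping second isoform whenever an internal exon
exists to skip — the skipped exon's length is forced to a multiple of 3,
and a bounded retry regenerates the gene if the novel junction would
create a stop — so shared exons exercise the locus correction everywhere.
The transcript count is treated as structure, not sequence randomness:
changing only the seed changes sequences but not gene/transcript counts.
A single RNG stream seeded once per generation run, with the caller's
stream restored afterwards, makes fixtures byte-reproducible;
`write_fixture()` round-trips through FASTA/GTF/peptide files exactly.

### What the fixture does and does not emulate

The generator plants terminal dinucleotides, tract, branch point, CDS
framing, exon sharing and CG suppression — enough to exercise every
analysis stage and to recover parameter directions (class-wise surprisal
ordering, tract-region deviation, phase uniformity). It does not emulate
repeats, isochores, CpG islands, extended splice-site consensus beyond
GT/AG, codon-usage bias or UTRs. One consequence worth stating plainly:
in real genomes the polypyrimidine tract appears as a surprisal *valley*,
because pyrimidine-rich k-mers are genuinely overrepresented genome-wide;
on the synthetic background tract k-mers are drawn from a lower-entropy,
composition-shifted distribution that is *not* globally enriched, so the
tract offsets deviate *upward* (by roughly 0.4–0.5 bits against
flank-to-flank noise an order of magnitude smaller). The recovery tests
therefore assert a significant deviation at the planted offsets rather
than a sign, and passing them shows signal localisation, not the sign
observed in real data.

## Numerical and representational choices

* Logarithms are base 2 throughout; every statistic is in bits.
* Nucleotide k-mers are encoded 2 bits per base into doubles (exact to
  $2^{53}$), supporting $k \le 16$; counting tabulates sorted codes, and
  lookup tables densify to an indexed array when $A^k \le 2^{24}$,
  falling back to sparse named vectors beyond that.
* Input is uppercased; soft-masked lowercase counts as its uppercase
  base; any window containing a symbol outside the alphabet is discarded
  whole, never truncated, and windows never span record boundaries.
* The probability denominator is the number of accepted windows, which is
  self-consistent under window skipping (the "length − k" reading is
  ambiguous once windows are discarded).
* Both-strands counting appends the reverse complement of every input as
  an independent sequence, double-counting palindromic k-mers.
* Serialization is deterministic: tables in lexicographic k-mer order,
  profiles in offset order, and CLI outputs carry a configuration digest
  in `# ` header comments.
* Ties and degenerate inputs: empty tables raise classed
  undefined-distribution errors; `p = 1` yields surprisal exactly 0;
  locus deduplication retains the first occurrence by transcript id.

## Problem sizes used by the test suite

The unit tests run on strings up to a few kb and an 80 + 50 kb synthetic
fixture; the oracle-equivalence suite uses 200 random sequences up to
10 kb at $k \le 8$; planted-signal recovery runs at the study conditions
(2 Mb, `cg_suppression` 0.2) with 6-mer and 9-mer tables. These sizes
give per-offset standard errors several-fold below the asserted effects
while keeping the whole suite under a minute of compute.

## Known limitations

* Canonical (strand-collapsed) k-mer counting, streaming/disk-backed
  counting for nucleotide $k > 16$, FASTQ input and GFF3 annotation are
  out of scope.
* The locus key's splice-chain ambiguity is surfaced as a warning, not
  resolved.
* `uniform_count_table()` materialises $A^k$ counts and refuses
  $A^k > 2^{24}$; beyond that the closed forms (`max_entropy()`) are the
  intended tool.
* Amino-acid profile windows are specified in residues internally; the
  CLI derives them from nucleotide extents by division.
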