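# primercall

Mapping-free variant calling for PCR-targeted amplicon sequencing with
fully overlapping read pairs.

## The problem

Highly multiplexed PCR target-enrichment protocols (Hi-Plex and similar
systems) produce libraries of uniform-size amplicons in which each
sequencing read begins with the gene-specific primer (GSP) that seeded
its amplicon, and the two reads of a pair each span the entire
primer-intervening insert. Two consequences follow:

1. **Reads do not need to be mapped.** The primer at the 5′ end of a read
   identifies its amplicon — and therefore its reference coordinates —
   exactly. A hash table keyed on the first *N* primer bases replaces the
   aligner.
2. **Every template is sequenced twice.** Because the mates overlap the
   insert completely, a genuine variant must appear *identically on both
   reads of the pair*, while sequencing-chemistry errors almost never do.
   Pair concordance is therefore a powerful artefact filter.

`primercall` implements this calling strategy for R: it bins read pairs
by primer prefix, compares each primer-trimmed insert against the
expected reference sequence (an index-by-index linear scan, falling back
to a Needleman–Wunsch-style global alignment with affine gaps when the
mismatch pattern suggests an indel), intersects the variants seen by the
two mates, and reports SNVs and small indels that satisfy frequency
thresholds, with optional G-test genotyping of SNVs. It is intended for
users of amplicon panels who want stringent, fast, reproducible variant
calls without a BAM in sight.

## The calling model

A pair bound to a tile contributes evidence only if both mates cover at
least a fraction *f* of the tile (default 0.9) and, optionally, at least
one mate exactly matches the reference over an anchor window just after
its primer (default 30 bp, off by default). For each tile the caller
reports every pair-concordant variant *v* with

- `NP` — the number of concordant pairs carrying *v*,
- `DP` — the number of pairs overlapping the tile after filters,
- `PP = NP / DP`,

and labels *v* with filter `at` if `NP < min_abs_pairs` (default 2) and
`pt` if `PP < min_prop_pairs` (default 0.05); both comparisons are
inclusive (`>=` passes). SNVs can be genotyped by comparing the observed
base pileup at the variant position against the expected distribution of
each candidate genotype *g* under a constant-error model (error rate
ε = 1/500 by default): for a diploid the candidates are ref/ref, ref/alt,
alt/alt, the expectation mixes the genotype's alleles uniformly with
errors spread over the other three bases, and the reported genotype
minimises the G statistic

```
G = 2 * Σ_b  O_b * ln( O_b / (n * E_b) )
```

over bases with observed count `O_b > 0` (`n` is the pileup size).

## A worked example

The package ships a simulator that generates a panel (reference FASTA +
primer TSVs) and paired FASTQ reads with planted variants, so the full
pipeline can be exercised without external data:

```r
library(primercall)

panel <- make_panel(5, insert_len = 100, primer_len = 20, seed = 3)
truth <- make_truth(panel, c("s1", "s2"), seed = 4)
sim   <- simulate_reads(panel, truth, c("s1", "s2"),
                        depth = 60, error_rate = 0.001, seed = 5)

dir   <- tempfile(); files <- write_panel(panel, dir)
fq    <- write_fastq(sim, dir)

run <- call_variants(files$coords, files$seqs, files$reference, fq,
                     prefix_len = 20, genotype = TRUE)
run$calls
```

```
  sample chrom pos ref  alt    vclass pair_count depth proportion filters   gt g_statistic
1     s1  chrT 276 TGA    T  deletion         56    56 1.00000000         <NA>          NA
2     s1  chrT 468   C    G       SNV          1    60 0.01666667   at;pt  0/0       4.69
3     s1  chrT 552   A    T       SNV         24    56 0.42857143          0/1       1.30
4     s2  chrT 130   A ATGC insertion         28    57 0.49122807         <NA>          NA
5     s2  chrT 737   G    A       SNV         30    58 0.51724138          0/1       0.22
```

All four planted variants PASS (empty `filters`), with heterozygous
genotypes at the VAF-0.5 sites; a single pair in sample s1 happened to
carry the same sequencing error on both mates and is reported but
labelled `at;pt` — below both frequency thresholds, exactly the class of
artefact the thresholds exist to suppress. `write_outputs()` writes the
multi-sample VCF, the per-amplicon coverage TSV, and the run log;
`autoplot(run, "coverage")` and `autoplot(run, "calls")` give quick
ggplot2 views.

A command-line front end over the same functions is installed at
`system.file("scripts", "primercall.R", package = "primercall")`:

```sh
Rscript primercall.R --primer-coords coords.tsv --primer-sequences seqs.tsv \
  --reference ref.fa --out calls.vcf --genotype sample1_R1.fastq sample1_R2.fastq
```

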