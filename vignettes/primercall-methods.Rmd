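---
title: "Mapping-free primer-directed variant calling: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping-free primer-directed variant calling: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(primercall)
```

## The method

`primercall` calls SNVs and small indels from PCR-targeted amplicon
sequencing without mapping reads. The library structure it assumes is
that of Hi-Plex-style panels: each amplicon ("tile") is a contiguous
reference span flanked by a gene-specific primer pair, every read starts
with its primer at the 5′ end, and the two reads of a pair each overlap
the whole insert (read length ≥ primer + insert; 3′ ends may run into
adapter). The pipeline has five stages.

**1. Indexing.** The panel's primers are hashed by their first `N` bases
(`prefix_len`). Each tile contributes two keys — forward primer
(plus-strand 5′ flank) and reverse primer (the oligo as synthesized,
i.e. the reverse complement of the 3′ flank) — pointing at the tile and
an orientation. `N` must not exceed the shortest primer; key collisions
abort index construction (binning correctness depends on key
uniqueness, so last-writer-wins would silently corrupt results), and a
primer with `N` among its first `prefix_len` bases is rejected because
exact-match hashing can never match it.

**2. Binning.** A pair is bound to a tile only when both mates hash to
the *same* tile in complementary orientations; mates hashing to
different tiles (cross-tile chimeras), the same orientation, or nothing
are counted and logged as unassigned. Matching is exact over the first
`N` bases — a single sequencing error in the prefix discards the pair,
which is the documented cost of hashing. The full primer (not just `N`
bases) is then trimmed, because a variant under a primer is overwritten
by the oligo and must never be called from primer bases; reads are
truncated at the tile's insert length (adapter read-through), and the
reverse mate is reverse-complemented so both inserts are plus-strand.

**3. Comparison.** Each insert is compared to the reference insert span
it is anchored to (forward mate: tile 5′ end; reverse mate: tile 3′
end). The linear scan compares index by index. In `thorough` mode up to
one mismatch is accepted as an SNV; in `fast` mode several are, provided
consecutive mismatches are separated by **more than** `fast_gap` bases.
Clustered mismatches are the downstream signature of an indel, so either
policy falls back to a global affine-gap alignment (Gotoh; match +2,
mismatch −1, gap open −5, gap extend −0.5 by default) of the read insert
against the full tile reference. Aligned columns become variants:
substitutions as SNVs, merged gap runs as VCF-anchored indels,
left-normalised within the tile.

**4. Pair concordance and thresholds.** Pairs failing the overlap
requirement (each mate must cover ≥ `min_overlap_frac` of the tile,
default 0.9, boundary inclusive) are discarded from both evidence and
depth; optionally pairs must also pass an anchor check (at least one
mate's first `anchor_len` post-primer bases exactly matching the
reference, default 30 bp, disabled by default — it is an
additional-stringency option, and requiring only one mate keeps variants
near one end of the tile detectable). The variants of a pair are the
set intersection of its two mates' variant lists; anything seen by one
mate only — sequencing artefacts, masked positions, or discordant
alleles at the same locus — contributes nothing. Per tile, each distinct
variant is tallied over pairs and labelled `at` when its pair count is
below `min_abs_pairs` (default 2) and `pt` when its proportion of the
tile's surviving pairs is below `min_prop_pairs` (default 0.05). Both
comparisons are inclusive (`>=` passes); labelled variants are written
with their FILTER status rather than suppressed.

**5. Genotyping (optional).** For each reported SNV a pileup is formed at
the variant position. Each pair contributes one base: the consensus of
its two mates (conflicting or masked mates contribute nothing; a single
covering mate counts alone) — consistent with the pair-concordance
philosophy and avoiding double-counting templates. Each candidate
genotype (hom-ref/het/hom-alt for diploid, ref/alt for haploid) defines
an expected base distribution: a read draws its base uniformly from the
genotype's alleles and is corrupted with probability ε (default 1/500)
into one of the other three bases uniformly. The genotype minimising the
G statistic `G = 2 Σ O_b ln(O_b / n E_b)` is reported, with `0·ln 0 = 0`
and infinite distance when observed mass falls where a candidate expects
none; ties prefer the candidate with more reference alleles.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `prefix_len` | 20 bases | primer prefix hashed for binning; ≤ shortest primer |
| `mode`, `fast_gap` | `thorough`, 5 bases | linear-scan acceptance policy before fallback |
| `min_overlap_frac` | 0.9 | tile fraction each mate must cover |
| `anchor`, `anchor_len` | off, 30 bases | post-primer exact-match window, ≥1 mate |
| `min_abs_pairs` | 2 pairs | absolute evidence threshold (`at`) |
| `min_prop_pairs` | 0.05 | proportional evidence threshold (`pt`) |
| `qual_threshold` | 0 (off) | Phred score below which bases are masked to `N` |
| `ploidy`, `error_rate` | 2, 1/500 | genotype model |

Masked (`N`) bases never mismatch the reference and never support a
variant, so masking can neither create evidence nor break concordance;
masked pairs still count toward depth. Masking is applied *after*
binning: the prefix rule is an exact raw-sequence match and makes no use
of qualities.

## Design decisions

Several choices were genuinely open and are recorded here as the
package's own decisions.

- **Coordinates are 1-based inclusive** in the primer-coordinates file,
  matching VCF. The file dialect itself carries no convention, so this
  is stated prominently: a panel prepared with 0-based/half-open (BED)
  coordinates must be shifted before use.
- **Fast-mode direction.** Fast mode accepts multiple linear-scan
  mismatches only when consecutive mismatches are separated by *more*
  than `fast_gap` bases. The inverse convention (accepting clustered
  mismatches) is expressible with the same machinery but would interpret
  indel signatures as SNV runs; the chosen direction treats clusters as
  indel evidence and falls back to alignment.
- **Pair-level binding.** Mates are paired positionally (record *i* of
  file 1 with record *i* of file 2, the FASTQ convention) and bound as a
  pair, rather than binning reads individually and re-matching mates
  within tiles; this removes any re-pairing ambiguity.
- **Alignment scoring and ties.** The affine-gap defaults penalise a
  1-base gap (−5.5) far more than a mismatch (−1), so an isolated
  substitution is never represented as a gap pair. Among equal-scoring
  alignments the traceback prefers diagonal moves and extends gap runs
  leftward, and indels are subsequently left-aligned within the tile, so
  the emitted variant is canonical and platform-independent. Alignment
  columns in terminal gap runs arise from read truncation at tile edges
  and yield no variants.
- **Inclusive thresholds.** Both frequency cut-offs pass at equality
  (`NP >= min_abs_pairs`, `PP >= min_prop_pairs`), verified by exact
  boundary fixtures in the tests.
- **Depth denominator.** `DP` counts only pairs surviving the overlap
  (and, when enabled, anchor) filters; discarded pairs appear in the
  coverage log's filter chain but not in proportions.
- **One multi-sample VCF.** Samples are called independently and merged
  at write time; the per-sample filter status is kept in the `FT`
  FORMAT field and the site FILTER is `PASS` when any sample passes.
  QUAL is left missing — the method defines no site quality. Genotyping
  emits the raw G statistic (`GS`) rather than a calibrated quality.
- **Candidate genotypes** are restricted to combinations of the called
  ref and alt alleles; indels are reported without genotype.

## The simulator

`make_panel()` / `make_truth()` / `simulate_reads()` generate the exact
statistical structure the caller assumes: non-overlapping tiles whose
primers are true reference flanks with unique prefixes; fragments built
as `fwd_primer + insert + revcomp(rev_primer) + adapter`; read 1 the 5′
prefix of the fragment and read 2 the 5′ prefix of its reverse
complement; per-pair Bernoulli allele sampling at the planted VAF (an
exact-count mode exists for threshold boundary tests); independent
per-base substitution errors; optional off-panel pairs and a low-quality
tail profile to exercise masking. Default conditions — 100 bp inserts,
20 bp primers, depth 100, per-base error 0.001, VAFs 0.5/1.0 —
correspond to typical short-read amplicon panels with the order of
100-nucleotide tiles.

The simulator deliberately does *not* model PCR duplicates/jackpotting,
indel sequencing errors, platform-specific quality profiles, or
primer-site polymorphisms. Passing tests therefore demonstrate the
correctness of the algorithm under its stated assumptions — exact primer
prefixes, independent substitution errors, complete mate overlap — not
robustness to every failure mode of real libraries. In particular,
per-pair concordance cannot suppress errors introduced *before*
sequencing (PCR jackpots appear on both mates), which is a known
limitation of the approach itself.

## Numerical and degenerate-input behaviour

- Comparisons are pure functions: identical inputs give identical
  variant lists across runs and platforms; the only non-deterministic
  output bytes are timestamp header lines (suppressable with
  `date = FALSE`).
- Overlap and proportion boundaries are evaluated with a small epsilon
  (1e−9 / 1e−12) so exact fractions such as 45/50 or 2/40 pass the
  inclusive rule despite floating-point representation.
- `G = 0` exactly when observed proportions equal the expectation;
  observed counts where a candidate expects zero mass give `Inf`
  without numeric fault; tiny negative rounding noise is clamped to 0.
- Zero-depth tiles produce no calls but are logged with zero counts;
  an empty panel yields an empty index and header-only outputs; an empty
  FASTQ pair yields empty results rather than errors.
- Indel left-normalisation is idempotent and never shifts an anchor left
  of the tile start (the available reference context).

## Problem sizes used in the checks

The bundled verification (`tests/testthat/test-acceptance.R`,
`scripts/acceptance.R`) runs at desk scale, chosen so the full suite
completes in minutes while keeping every estimate's sampling error far
from its pass margin: 1,000 substitution-only pairs against an
independent global-alignment oracle; 500 planted 1–5 bp indels against a
brute-force placement oracle; 10,000 single-mate artefact pairs; twenty
independent end-to-end simulations of 10 tiles × 3 samples × depth 100;
and 1,000 genotype-recovery replicates per genotype at depth 100.
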