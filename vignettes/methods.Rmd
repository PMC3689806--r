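---
title: "TEloci: methods, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{TEloci: methods, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

TEloci calls transposable element (TE) insertions that are present in a
resequenced individual but absent from the reference genome, and genotypes
each call, from unassembled short reads alone. This vignette documents the
model, every tunable parameter, the numerical choices, what the bundled
simulator does and does not emulate, and the limitations a user should
keep in mind.

## The split-read model

A TE insertion into a target site duplicates that site: if the reference
reads `L–TSD–R`, the insertion allele reads `L–TSD–TE–TSD–R`. Reads
sampled across either junction therefore consist of unique genomic
sequence ending (or starting) with the TSD, immediately followed (or
preceded) by a TE end. TEloci exploits three consequences:

1. junction reads contain TE sequence *anchored at a TE terminus* — a
   match that does not touch the first or last TE base carries no
   insertion-site information and is discarded;
2. after trimming the TE portion, the left flank's high-coordinate end
   and the right flank's low-coordinate end must map to the *identical*
   reference window of exactly one TSD width, whose sequence satisfies
   the TSD specification (either strand rendering is accepted, since the
   element inserts in either orientation);
3. reads from an allele *without* the insertion cross the site in one
   piece ("spanners"), so the flanker:spanner ratio at a site reflects
   the allele configuration: roughly 0 spanners for a homozygous
   insertion, ~2:1 flankers:spanners for a heterozygous one, and a few
   flankers against many spanners for a rare somatic insertion.

An insertion is called when at least one left and one right flanker (two
or more reads total) share a perfect TSD overlap. The reported position is
the 1-based inclusive target-site span (`chrom:start..end`); the
coordinate of the last target-site base is exposed alongside
(`last_base`) because single-coordinate reporting is common in TE
annotation. One cluster of overlapping flanks may contain several
disjoint satisfying TSD windows (tandem or nearby events); each distinct
window becomes a distinct call, since each carries independent two-sided
evidence.

## Parameters

| parameter | default | unit | where | rationale |
|---|---|---|---|---|
| `seed_len` | 7 | nt | TE scan | smallest practical exact seed; dense (every position) seeding makes it a superset of coarser tilings |
| `min_aligned` | 10 | nt | TE scan | minimum read–TE match worth trusting on 35–100-bp reads |
| `allowance` | 0 | fraction | TE scan | mismatches ÷ aligned bases; 0 keeps only perfect TE matches, raise to 0.02–0.1 for diverged element families |
| `min_trimmed_len` | 10 | nt | trimming | flanks must be strictly longer than this to be mappable evidence |
| `max_genome_mismatch` | 3 | count | flank mapping | tolerance for SNPs/errors in the flank while keeping placements specific |
| `flank_len` | 100 | nt | report | reference context per side for primer design |
| `band` | 12 | nt | whole-read aligner | widest indel representable; keep ≥ TSD width + 3 so footprints fit |
| `max_edit` | 5 | count | whole-read aligner | edit budget for a 100-bp read, mirroring conventional short-read aligner defaults; also bounds the largest detectable footprint |
| `kmer` | 16 | nt | whole-read aligner | seed length for candidate lookup |
| `pad` | TSD width + 5 | nt | spanner counting | exact-match margin around the target site (see below) |
| `min_footprint_support` | 2 | reads | footprints | minimum reads carrying the identical indel |
| trim `-t/-l`, filter `-q/-p` | 20/50, 20/80 | Phred/nt/% | preprocessing | standard stringent short-read quality thresholds |

The TSD specification accepts an exact sequence (`TSD=TAA`), an integer
width (`TSD=3`), or a fixed-width pattern over IUPAC codes and character
classes (`TSD=T[AT]A`, `TSD=TNA`). Variable-width constructs are rejected
rather than guessed: the TSD-overlap test needs a fixed window width, so a
`*`/`+`/`{}` pattern has no well-defined overlap semantics.

## Numerical and edge-case choices

**Coordinates.** All internal coordinates are 1-based inclusive — the
R/Bioconductor convention shared by IRanges, GenomicRanges and GFF3 — so
internal and reported coordinates coincide. Helpers
`interval_0h_to_1i()`/`interval_1i_to_0h()` convert to and from 0-based
half-open for BED-style interchange; the two are exact inverses.

**`N` bases** never match anything, including another `N` — in the TE
scan, in flank placement and in spanner verification. Ambiguous sequence
should only ever reduce evidence, not create it.

**Boundary senses** follow the tool conventions they mirror: the TE-scan
mismatch fraction is retained at *equality* with the allowance; trimmed
flanks are kept only when *strictly* longer than `min_trimmed_len`; the
quality filter keeps a read at exactly the threshold fraction.

**Mismatch-tolerant extension.** With `allowance > 0`, the TE-scan
extension absorbs a mismatch whenever the *final* mismatch fraction of the
committed window stays within the allowance (lookahead-and-commit in
alternating directions), not only when the running fraction does — a
mismatch early in a long perfect stretch should not truncate the match.

**Genotype arithmetic is exact.** The average flanker count F is a
half-integer and the cascade's thresholds are phrased over integers and
dyadic rationals (e.g. "S at most 20% of F" is evaluated as `5·S ≤ F`), so
no floating-point rounding can flip a boundary case. The cascade is
order-sensitive by construction — the first satisfied rule wins — and the
test suite asserts that permuting it changes at least one published
example, guarding against silent reordering.

**Uniqueness.** A trimmed flank is used only if it has exactly one
best-scoring (minimum-mismatch) placement across both strands of the whole
reference; ties are discarded, so insertions inside repeats are invisible
(see Limitations). For whole reads, ambiguous placements are kept in the
alignment output but flagged and excluded from spanner counts.

**Spanner verification.** A spanner must cover the target site padded by
`pad = TSD width + 5` bp per side, contiguously, with no indel opening in
the padded window or at the target-site boundaries, and — because the
internal aligner emits `=`/`X` CIGAR operations — with no mismatch in the
window either. The padding is load-bearing in two ways. First, a read
ending *inside* the target site matches the insertion allele equally well
(the TSD is duplicated at the junction), so bare coverage of the TSD is
not evidence for an empty site. Second, a junction read carrying a few
terminal TE bases can be force-aligned across the site with terminal
mismatches; since the TE ends and the reference flank are both fixed
sequences, a site where they happen to coincide for the first few bases
would leak *every* such junction read through a narrow margin. Five extra
exact bases push the chance of that systematic coincidence below ~0.1%
per site per side, at the cost of rejecting true spanners with a
sequencing error in a ~16-bp window (≈3% at an error rate of 0.002).
External BAM/SAM files whose CIGARs use plain `M` lose the mismatch part
of this check; the gap and coverage requirements still apply.

**Footprint evidence.** An excision footprint is reported as the
most-supported identical indel (type, position, length) within one TSD
width of the site, with at least `min_footprint_support = 2` reads. A read
lends support only if its alignment carries *exactly one* indel and no
mismatch operations in the window: junction reads of the insertion allele
can otherwise be squeezed into the reference as a recurring
indel-plus-mismatch pattern and masquerade as footprint evidence. Ties
between equally supported indels break to the smallest distance from the
target site, then leftmost position — deterministic output. Precise
excisions restore the reference and leave no footprint; they surface only
as homozygous-classified sites with unexpectedly few spanners (rules
ii/iii), and are undetectable at heterozygous sites because a perfect
excision spanner is indistinguishable from the insertion-free allele's
spanner.

**Degenerate inputs.** An empty call list produces a header-only report;
a TE-free read set produces zero calls and exit status 0; a site on a
chromosome unknown to the alignments is an error naming the site (a
mismatched reference is a user error worth failing loudly on, whereas a
covered chromosome with zero overlapping reads legitimately counts zero
spanners).

## Replacing the external aligners

The original style of pipeline delegates read–TE search, flank mapping and
whole-read alignment to BLAT, Bowtie and BWA. TEloci implements these
three contracts internally (in C++ via Rcpp) so that results are
self-contained and the trim bookkeeping (which read end was trimmed, which
TE end was touched) flows through mapping unchanged:

* *read–TE scan*: dense exact-seed, ungapped extension, both
  orientations; gapped read-vs-TE alignment is deliberately unsupported —
  junction reads are short and the default allowance is 0;
* *flank placement*: exhaustive ungapped scan of both strands, reporting
  the best mismatch count and the number of equally good placements — at
  the genome sizes of desk-scale analyses exhaustive search doubles as
  its own gold standard, and the suite cross-checks it against an
  independent brute-force oracle;
* *whole-read alignment*: seeded (16-mer) candidate lookup, ungapped
  evaluation first, then banded semi-global dynamic programming around
  each candidate, emitting `=`/`X`/`I`/`D` CIGARs; traceback prefers
  diagonal, then deletion, then insertion, so CIGARs are deterministic.
  In paired mode, a flank whose own placement is ambiguous can be rescued
  by a uniquely placed mate within 500 bp, and duplicate placements are
  collapsed.

The reference-copy scan (`scan_reference_for_te()`) is the one place an
established implementation does the matching: Biostrings'
`matchPattern()` with a mismatch ceiling of just under 10% of the element
length, on both strands, filtered to copies at least 90% of the element
long. Ungapped full-length matching means truncated copies fail either
the length or the identity filter, which is the intended behaviour.

## What the simulator emulates — and what it does not

`simulate_individual()`/`simulate_reads()` build a diploid individual as a
set of cell lineages: a germline lineage (homozygous events on both
haplotypes, heterozygous on one) plus one lineage per somatic event
carrying it at a specified cell fraction (fractions must sum below 1;
somatic excisions remove a homozygous insertion from one haplotype of
their lineage, precisely or leaving a footprint). Fragments are sampled
uniformly, weighted by lineage fraction, haplotypes 1:1; paired fragments
draw lengths from Normal(350, 50) (a typical paired-end library;
truncated below two read lengths); substitution errors occur at a flat
per-base rate (default 0.002) with a matching quality drop (Q37 → Q14).
Everything is deterministic under a seed.

Deliberately not modelled: indel sequencing errors, position- and
cycle-dependent quality profiles, GC-coverage bias, PCR duplicates,
chimeric fragments, and repeat-rich genome structure (the reference is
i.i.d. random sequence, so unique mapping is easy). Passing the recovery
suite therefore demonstrates the *logic* of calling and genotyping — TSD
geometry, filter boundaries, count ratios, coverage response — not
robustness to real-genome repeat content or library artefacts.

Test and acceptance runs use problem sizes chosen to exercise those
properties compactly: a 100-kb genome at 30× (20 planted germline events)
for the recovery check, 25-kb genomes at 30× over 20 replicates for the
somatic-attrition comparison, and sub-kilobase instances for the
brute-force oracle equivalences.

## Limitations

* Insertions inside sequence that is repeated in the reference are
  undetectable: multi-mapping flanks are discarded by design.
* Somatic sensitivity is coverage-bound: an event in a fraction f of
  cells yields junction reads at ~f/2 of the homozygous rate, and the
  suite's attrition test shows somatic calls are preferentially lost when
  reads are halved.
* The rule cascade can classify low-coverage heterozygous sites as
  homozygous-with-excision (e.g. F = 6, S = 3 fires rule ii). This is the
  cascade's defined behaviour and is preserved as such; interpose a
  coverage floor downstream if it matters for your data.
* Footprints larger than `max_edit` bases are not representable by the
  whole-read aligner and will be missed; raise `band`/`max_edit` for
  elements with long footprints.
* Genotypes are hard calls from count ratios; no likelihoods or quality
  scores are attached, and polyploids are out of scope.
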