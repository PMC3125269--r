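---
title: "BAC-end survey methods: masking, SSR mining, hit filtration and paired-end synteny"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{BAC-end survey methods: masking, SSR mining, hit filtration and paired-end synteny}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bescan)
```

## The survey problem

BAC-end sequences (BES) are single Sanger reads taken from both ends of
large-insert (roughly 100–200 kb) bacterial artificial chromosome clones.
For a species without a reference genome — the motivating case is a salmonid
with a recent whole-genome duplication and a repeat-rich genome — a few
hundred thousand BES are often the first genome-scale sample of sequence
content. Three analyses extract most of their value:

1. **Repeat characterization.** Masking the reads with a species-specific
   repeat library measures how much of the genome is repetitive, and an
   all-vs-all alignment of the *masked* reads exposes repeat families the
   library still misses.
2. **Microsatellite (SSR) mining.** Tandem repeats of 1–10 bp motifs with
   clean flanking sequence become PCR-genotypable markers that link genetic
   and physical maps.
3. **Comparative synteny.** Because the two reads of a clone face each other
   across a known insert length, a pair of uniquely mapped end-reads on a
   sequenced reference genome tests conserved gene order: same chromosome
   (macro-synteny), and the right span and relative orientation
   (microsynteny).

`bescan` implements this pipeline with tidy tabular interfaces, plus a fully
seeded synthetic-data generator that produces every input with recorded
ground truth, so each stage is testable end to end.

## Repeat masking

The masker is a seed-and-extend local aligner: exact `seed_k`-mer matches
(default 11) between a read and a library consensus (both strands) are
extended without gaps in both directions under an x-drop rule (+1 match,
−1 mismatch, stop when the score falls `xdrop = 20` below its running
maximum). Alignments of at least `min_hit_len = 30` bp at identity
≥ `min_identity = 0.80` contribute their read intervals to the mask;
intervals are merged, and the bases are never rewritten, so downstream
stages choose a soft- or hard-masked view. Extension is ungapped: the
masker's job is interval recovery, not optimal alignment, and at the
divergence levels a curated library is built for (≤ 20%), substitution-style
extension recovers implanted intervals at the ≥ 95% level the test-suite
property demands while keeping the implementation simple and fast.

Masking is idempotent, and lowering `min_identity` can only grow the masked
fraction — both are tested properties. `masked_fraction()` is the headline
statistic (percent of base pairs masked); `cross_mask_fraction(a, b)` masks
one library's consensi with another library and is asymmetric by
construction, which is how the redundancy between two species' repeat
libraries is measured.

**Self-alignment census.** After masking, `self_hit_census()` aligns each
read's unmasked runs against every other read's and counts, per read, the
other reads with a significant hit. Significance uses the ungapped
Karlin–Altschul e-value `K·m·n·exp(−λS)` with λ = ln 3 and K = 0.33, the
analytic values for +1/−1 scoring under a uniform base model, with `m` the
read's unmasked length and `n` the total unmasked database length; the
cutoff defaults to 1e−5, matching the homology searches. Counts are binned
LOW (≤ 10), MODERATE (11–50), HIGH (> 50); reads in the upper bins point at
repeat families missing from the library. The two boundary counts are
assigned to the lower bin — the bin edges are conventionally quoted as
"more than 10" and "more than 50", which leaves the boundary counts
unassigned, so the package fixes them downward and documents it. The census
is validated on synthetic families (a planted 30-copy family must come out
MODERATE for every member) rather than against any published percentages,
whose denominator (the read set actually aligned all-vs-all) is not
recoverable.

**Eligibility.** Reads enter homology searches only if they keep *more than*
`min_run = 100` bp of contiguous unmasked sequence (a strict bound;
a run of exactly 100 bp fails).

## SSR mining

`find_tandem_repeats()` scans each read at every period `p` in 1–10 by
comparing the sequence with itself at lag `p`. Maximal runs of agreement
become candidate arrays; when `max_mismatch_frac > 0` (default 0.2),
neighbouring runs are chained across mismatch gaps of at most `p` positions
while the running mismatch fraction stays within tolerance. Each candidate
is then re-scored exactly: the motif is the per-phase majority consensus
anchored at the array start (phase-preserving), purity is the fraction of
positions matching a perfect tiling of that motif, and the array must reach
`min_length = 12` bp, `min_copies` (4 for period ≤ 2, 3 otherwise) and
purity ≥ 1 − `max_mismatch_frac`. These thresholds are typical SSR-mining
practice for "default settings" of tandem-repeat detectors and are all
configurable. Overlapping candidates of different periods — e.g. a perfect
`(AC)n` array is also a perfect period-4 array — resolve to the
higher-purity, then longer, then shorter-period call, so each locus is
reported once. At `max_mismatch_frac = 0` the detector provably equals a
brute-force enumerator of maximal perfect arrays; the test suite fuzzes this
equivalence on hundreds of random strings.

**Canonical classes.** A motif and its reverse complement describe the same
locus read from opposite strands, so classes merge them: `GA` and `TC` are
one class `GA/TC`. Rotations are *not* merged — `TG` and `AC` stay distinct
classes, following the convention of SSR survey tables, which distinguish
rotated motifs because they imply different repeat phases at the locus.
`canonical_class()` orders the pair lexicographically so that the label is a
pure, involutive function of the motif; `summarize_ssrs()` instead labels
each class by the variant most often observed in the data (so a
TG-dominated class prints as `TG/CA`), which is how published tables order
their labels. Classes below a configurable count threshold roll into
"Other" within their period group, and the report carries both a raw locus
count and a deduplicated `(read, interval)` count, because survey totals are
quoted under both conventions.

**Flank eligibility.** A locus is a primer candidate when at least
`min_flank = 50` *clean* bases flank it on each side within the read —
clean meaning unmasked (masking runs first) and not part of any other SSR
locus. Primer thermodynamics are out of scope; the flank rule is the
eligibility gate a primer-design step would consume.

## Hit filtration

BLAST tabular hits (the 12-column comment-tolerant dialect) are filtered per
read in three steps, after a global e-value cutoff of 1e−5:

1. keep only hits at the read's minimal e-value;
2. among those, keep the highest HSP product, defined as percent identity ×
   alignment length (on the 0–100 identity scale as printed in tabular
   output);
3. accept the read only if exactly one subject remains.

In translated (protein) mode, peptide subjects are first renamed to their
genes — one gene may encode several peptides — so uniqueness is judged at
the gene level and two tied peptides of one gene still yield a unique
assignment. Residual ties after step 2 across different subjects make the
read *ambiguous*: resolving such ties any other way would invent
information. The pipeline is deterministic under permutation of the input
rows (a tied single-subject representative is chosen by a fixed sort), each
step returns a subset of its input, and the whole cascade equals an
exhaustive evaluation of the three rules on every fuzzed case in the test
suite. Whether the global cutoff applies before or after step 1 is
immaterial whenever the minimum passes the cutoff; the package applies the
cutoff first.

One parsing convention matters: query coordinates are normalised to
ascending order, and alignment strand is carried in an explicit `strand`
column, set to minus when exactly one coordinate pair in the file was
descending. This keeps nucleotide-hit strand (subject order) and
translated-hit frame sign (query order) through one invariant
representation.

## Paired-end synteny

`pair_ends()` joins unique assignments back to clones. Per clone and
reference species, `call_synteny()` classifies:

- `SINGLE_END` — only one end assigned;
- `DISCORDANT` — ends on different chromosomes (exact name comparison;
  unplaced scaffolds count as chromosomes);
- `MACRO_ONLY` — same chromosome (macro-synteny);
- `MICRO` — macro-synteny, plus span within `[10, 300]` kb *and*
  tail-to-tail orientation.

The **span** is the inner gap: the number of reference bases strictly
between the two aligned intervals, clamped at zero for overlapping or
abutting hits. "Space between the ends" could also be read as the
outer extent; the inner gap is the conservative reading and the difference
(the two read lengths, ~1 kb) is negligible against the 10–300 kb window.
Both window bounds are inclusive. **Tail-to-tail** means the hits lie on
opposite strands with 3′ ends pointing at each other — equivalently the
left-hand hit on the plus strand and the right-hand hit on the minus
strand. Because which end of a clone got labelled forward is arbitrary,
both mirror assignments pass; of the eight strand × order configurations,
exactly two are tail-to-tail (a tested enumeration).

In protein mode the reference placement of an assignment is its *gene*:
the hit interval becomes the gene extent and the genomic strand is the
product of the alignment frame sign and the gene strand. Spans are then
gene-to-gene distances, which is why translated-mode microsynteny is
systematically scarcer than nucleotide-mode — ORF boundaries blur the
span and orientation signal. Clones unique in different modes at the two
ends are not paired across modes; `intersect_modes()` reports clones with
same-chromosome support in both modes and is symmetric.

## Summary statistics

Every printed percentage is `percent(numerator, denominator, decimals)`:
100·n/d rounded **half away from zero** at the printed precision, and every
emitted summary table stores its derived percentages as (numerator row,
denominator row, decimals) triples so an audit can — and does, on every
construction — recompute them from the counts. GC content is G+C over
A+C+G+T with IUPAC ambiguity codes excluded from numerator and denominator
alike. Q20 length counts bases with phred quality ≥ 20. The marker
polymorphism summary classifies a marker as failed (no product in any
parent), monomorphic (one allele size observed) or polymorphic (otherwise),
a three-way partition of the tested loci; a locus is additionally
*duplicated* when any single diploid parent shows more than two alleles —
the operational genotyping signature of a duplicated locus in a
re-diploidising genome — and duplicated loci may still be polymorphic, so
that count sits outside the partition.

## The synthetic study

`sim_config()` fixes the study conditions; the defaults are the sequencing
regime of a large BES survey:

| parameter | default | meaning |
|---|---|---|
| `both_end_rate` | 0.92 | clones with both ends sequenced |
| `read_len_range`, `read_len_mean` | 101–832, 546 bp | read length distribution (scaled beta) |
| `insert_range` | 100–200 kb | clone insert size |
| `gc` | 0.42 | background GC |
| `repeat_target_fraction` | 0.595 | genome fraction covered by repeat copies |
| `ssr_rate` | 0.07 / kb | implanted SSR density, dinucleotide-dominated class mix |
| `rearrangement_rate` | 2 / Mb | breakpoints between source and reference |
| `hit_noise` | miss 0.1, paralog 0.1, tie 0.05 | emulated search noise |

The generator builds a source genome by alternating exponential background
gaps with diverged repeat-family copies until the target repeat fraction is
met (realised coverage lands within 1% of target), implants perfect SSR
arrays in background gaps — rewriting the few seam bases so that no
position pairs at the motif period across an implant boundary, which makes
implanted boundaries exactly recoverable — and annotates genes for the
translated searches. The reference genome is the source cut at Poisson
breakpoints into blocks dealt round-robin onto chromosomes (adjacent blocks
therefore never share a chromosome, so a clone straddling a breakpoint is
discordant by construction), each block inverted with probability ½.
Paired reads face inward from the insert boundaries, which is exactly what
makes tail-to-tail geometry recoverable; under a block inversion both hit
strands and their order flip together, so intact clones stay tail-to-tail.

Emulated searches stand in for running an aligner: each read inside a
conserved block gets a true tabular hit at its mapped location with an
e-value far below the cutoff, plus configurable noise — missed hits, weaker
paralog decoys (removed by filtration step 1), and equal-score ties on a
second chromosome (forcing ambiguity). Reads more than half covered by
implanted repeats get scattered multi-hits instead, emulating what
unmasked repetitive sequence does to a search. The registry records, per
clone, the expected placement, inner gap, orientation and classification,
so end-to-end tests compare pipeline output with geometric truth: on a
noiseless 2,000-clone study every intact conserved clone with a usable pair
of reads and an in-window gap must be called MICRO (sensitivity 1.0) and
every breakpoint-straddling clone with a usable pair DISCORDANT.

**What the generator does not emulate.** Background sequence is i.i.d.
random: real genomes carry low-complexity and diverged-repeat structure the
library does not describe, so real masked fractions and census tails will
differ. Mismatch-tolerant SSR scanning on i.i.d. background also produces
many chance loci at long periods, so the *class distribution* of detected
loci is validated against implanted truth and constructed locus sets, not
against the background-dominated totals. E-values are pass/fail tokens, not
Karlin–Altschul statistics of a real database search; Sanger error
profiles, chimeric clones and cloning bias are absent. Passing tests
therefore demonstrate correctness of the pipeline's rules and their
composition, not field performance on any particular genome.

## Problem sizes and determinism

The packaged study scale — 5 Mb source genome, 5 chromosomes, 2,000 clones,
~3,800 reads — was chosen once as a desk-scale stand-in that still yields
hundreds of paired, uniquely-mapped clones per mode; all counts scale with
the configuration. Every generator consumes an explicit seed (module
offsets keep the streams of the sub-generators independent), and identical
configurations are byte-identical in output, which the suite asserts.

## Known limitations

- The masker has no gapped extension stage; indel-diverged repeat copies
  fragment into several intervals (merged when within an x-drop bridge) and
  very high indel densities would under-mask. For library-vs-read masking at
  curated-library divergences this does not affect interval recovery.
- The census e-value is analytic for +1/−1 ungapped scores; it is not
  calibrated against a specific aligner's statistics.
- `canonical_class()` labels cannot reproduce abundance-ordered published
  labels for a single locus (only a data-aware summary can), which is why
  the class *key* and the display label are separate concepts.
- Protein-mode synteny requires an external gene-location table; the
  package does not parse annotation formats (GFF) itself.
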