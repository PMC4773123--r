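---
title: "Catalogue-building for plant small RNAs without a genome: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Catalogue-building for plant small RNAs without a genome: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seedmir)
library(dplyr)
```

## The problem

When a plant species has no genome assembly, miRNAs cannot be annotated by
mapping reads to hairpin loci. A genome-independent alternative treats known
mature miRNAs of *other* plant species as the reference: because plant miRNA
families are deeply conserved, a sequenced small RNA that is
character-identical to a known mature miRNA can be annotated as the
corresponding miRNA of the new species. seedmir implements that strategy as a
reusable, fully tested pipeline:

1. **Preprocess** — 3' adapter clipping, quality end trimming, inclusive
   15-nt length floor, artifact removal, collapsing reads to unique tags
   with copy numbers.
2. **Subtract** — removal of tags lying, at 100% identity over their full
   length, inside structural ncRNAs (rRNA, tRNA, snRNA, snoRNA); this also
   catches much degraded-mRNA contamination.
3. **Identify** — full-length exact equality against a mature plant miRNA
   library; matched tags with at least 10 copies become the conserved
   catalogue, with family aggregation and length profiling.
4. **Candidates** — unmatched tags of ≥ 18 nt are exported for external
   novel-miRNA predictors (prediction itself is out of scope here).
5. **Conservation** — a per-miRNA conservation rate across the reference
   species, and its correlation with abundance.
6. **Cross-kingdom screen** — an ungapped best-overlay score of every
   plant–animal miRNA pair with seed-region stringency.
7. **qPCR quantification** — relative expression by the comparative-Ct
   (2^-ddCt) method.

## Exact matching as the identity predicate

The historical pipelines ran megablast at 100% identity. At that threshold
the alignment problem degenerates into two string predicates, which seedmir
implements directly:

* **ncRNA subtraction**: the tag occurs as an exact contiguous substring of
  a reference sequence (the tag is fully covered; the reference is longer).
* **miRNA identification**: the tag equals the mature sequence — full
  length both ways, no overhangs, no mismatches.

Exact predicates are deterministic and have no E-value or word-size dialect,
and a brute-force all-pairs scan provides an independent oracle that the
test suite runs on every build. Reverse-complement matching is deliberately
off: small RNA reads are sense-stranded. A one-mismatch tag is *retained*
(not subtracted) and *unannotated* — both by design.

When several reference species carry an identical mature sequence the
assigned name follows the lexicographically smallest (species code, member
name) pair, and every source entry is recorded in a `sources` column. This
tie-break is a convention, not biology; it is configurable in the sense that
all sources remain available downstream.

## Family derivation

Family names are derived from member names by stripping, in order, the
species prefix, a trailing `-5p`/`-3p` arm suffix, a trailing `.N` variant
suffix, and trailing lowercase member letters: `mol-miR159b.1` → `miR159`,
`mol-miR156f-5p` → `miR156`. Duplicate member labels with different mature
sequences count as distinct members. Absent (`NA`) arm counts contribute
nothing to family totals and are never coerced to zero. Applied to the
packaged catalogue fixture this rule yields 40 families from 94 members,
with `miR156`, `miR166` and `miR167` at eight members each — the package's
own computation, re-run in the test suite.

## Thresholds that matter

| parameter | default | role |
|---|---|---|
| `min_length` | 15 nt | post-trim insert floor (inclusive) |
| `min_adapter_overlap` | 5 | smallest adapter prefix clipped at the 3' end |
| `quality_threshold` | Phred 20 | terminal-base trimming (a convention; end trimming is rarely decisive for 50-nt small RNA reads) |
| `min_count` | 10 copies | abundance floor for a conserved call |
| `novel_min_length` | 18 nt | candidate floor against degraded fragments |
| `r_min` | 0.55 | cross-kingdom screen r-value floor |
| `seed_min` | 5 | matched positions required in the seed window |
| `seed_window` | 2–8 | animal-frame seed coordinates |

Unclipped reads are kept by default (`keep_unclipped = TRUE`): an insert can
legitimately fill the whole read. Both choices are parameters because
published pipelines rarely state them.

## The cross-kingdom overlay score

Every plant–animal pair is scored by sliding the plant sequence ungapped
along the animal sequence and keeping the offset with the most matching
positions (ties prefer the smaller absolute offset, then the smaller
offset). The report pattern is written in the *animal frame*: one character
per animal position, holding the plant base where it matches and `-`
otherwise. The r-value is matches divided by the animal sequence length —
this denominator choice reproduces the printed r-values of all nine
published reference patterns bundled as a fixture, whose lengths track the
animal, not the plant, sequence. Alternative conventions (overlap length,
longer sequence) would change r-values for partially overlapping pairs;
only the animal-frame convention is consistent with the bundled table.

Seed matching counts matched positions inside animal positions 2–8. One
published pair passes the screen despite only 4 seed matches under this
window, so the seed coordinates are parameters rather than constants — the
original tool's convention is not recoverable. Reported r-values are
rounded half-up to two decimals (matching the published table); comparisons
against thresholds always use full precision.

## The conservation rate

The rate of a miRNA is the number of *other-species mature reference
entries* whose sequence matches — entries, not distinct species, because
mature libraries carry many identical records across species and a rate of
order 100–150 for a canonical family member is only consistent with entry
counting. Default matching is exact equality; a containment mode (either
sequence inside the other) is provided and is provably never smaller. The
conservation–abundance relationship is summarised as a Pearson correlation
of rate against log10 read count; base 10 only rescales the axis and leaves
the coefficient unchanged. On the packaged top-20 conservation fixture the
coefficient is ~0.07 — rank-truncated tables are a biased sample for this
statistic, which is why the full annotation table is the intended input.

## Relative quantification

`ddct()` averages replicate Ct values per (sample, assay), subtracts the
endogenous-control assay (e.g. `miR159`) within each sample, subtracts the
calibrator sample's dCt per assay, and reports `2^-ddCt`. The calibrator's
fold is exactly 1 and folds are invariant to any constant Ct shift applied
to a whole sample — both identities are asserted in the tests. Replicate
aggregation is the arithmetic mean with SD carried for reporting only;
amplification-efficiency correction and fold-change inference statistics
are out of scope. `normalize_to_assay()` re-expresses folds relative to a
chosen anchor miRNA within each sample, the presentation used when one
assay is declared the within-panel control. The calibrator sample is a
required explicit argument: leaving it implicit is the most common source
of irreproducible ddCt figures.

## What the simulator emulates — and what it does not

`simulation_config()` / `build_references()` / `simulate_library()` generate
libraries with a complete truth manifest. Defaults (chosen once, as the
package's standard study conditions):

* 10,000 reads of 50 nt; 20 miRNA families over 5 reference species with
  1–4 members each; 30% of members as miR/miR* duplexes; 40% of matures
  shared across species codes (the planted conservation truth).
* Log-normal per-miRNA abundance weights (`meanlog = log(300)`,
  `sdlog = 1.8`) spanning roughly four orders of magnitude, matching the
  12-to-65,243-copy spread of deeply skewed seed libraries. The largest
  draws are assigned to 21-nt and then 24-nt species: in real plant
  libraries the dominant reads are canonical 21-nt miRNAs and 24-nt
  siRNA-like RNAs, and an uncoupled draw would let any length class win a
  given library by chance.
* 15% structural-ncRNA fragments and 10% degraded-mRNA fragments; the
  former must disappear at subtraction, the latter must survive it and fall
  through to the candidate/unmatched bins.
* The Illumina small RNA 3' adapter (`TGGAATTCTCGGGTGCCAAGG`) after every
  insert, padded with random bases to the read length.

Two deliberate idealisations keep ground truth exact: all planted sequences
are distinct, and no insert ends in a ≥ 5-base adapter prefix (such inserts
would merge with the appended adapter and clip short). Consequently the
passing recovery test — annotated set equals planted miRNAs with ≥ 10
copies, with exact counts — demonstrates correctness of the bookkeeping,
*not* robustness to real-data phenomena: sequencing errors (available via
`error_rate`, default 0), adapter-homologous inserts, shared sub-sequences
between miRNAs and transcripts, or 5' contamination (not modelled, along
with indels and UMIs). Quality strings are constant-high except at
simulated error positions, so quality trimming has a signal without a full
error profile.

## Numerical and degenerate-input choices

* Length floors are inclusive everywhere (a 15-nt insert survives
  `min_length = 15`).
* Collapsed tags order by descending count then lexicographic sequence;
  screen results by descending r-value then plant name; conservation ranks
  break ties by read count then name. All outputs are deterministic and a
  rerun from one configuration is byte-identical (asserted on checksums).
* An empty FASTQ is an empty read set; an empty ncRNA reference is a
  configuration error (silent pass-through would look like a clean
  library); an empty other-species reference gives rate 0 with a warning.
* The correlation refuses fewer than 3 positive-count points or a
  zero-variance axis rather than returning `NA`.
* Printed-table count cells parse comma- and period-grouped thousands and
  treat `NA`/blank as absent, never zero; this leniency applies only to the
  packaged fixtures, not to user data files.

## Scale of the bundled checks

The test suite and the acceptance script run on simulated libraries of
1,000–20,000 reads, oracle scans capped at ~200 tags × ~100 reference
entries, and exhaustive overlay enumeration for sequences up to 30 nt —
sizes at which the brute-force oracles are exact and the whole suite
completes in well under a minute. Published-table anchors (the 94-member
catalogue, the top-20 conservation table, the nine overlay patterns) are
desk-scale and exact. Sequencing-run-scale figures (tens of millions of
reads against live miRBase/Rfam releases) depend on external deposits and
database versions and are intentionally not reproduced.

## Known limitations

* Exact identity cannot annotate single-nucleotide variants of known
  miRNAs; that is the method's defining stringency, not a bug.
* The conservation rate inherits reference redundancy; comparing rates
  across differently curated references is not meaningful.
* The overlay score is ungapped; an indel-containing homology will score
  poorly at every offset.
* 2^-ddCt assumes ~100% amplification efficiency for all assays.
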