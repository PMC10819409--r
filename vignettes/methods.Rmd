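---
title: "Methods: off-target prediction and WGS screening of edited clones"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: off-target prediction and WGS screening of edited clones}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crisproff)
```

`crisproff` screens CRISPR/Cas-edited clones for unintended genetic
variation using clone-versus-parent whole-genome sequencing. This vignette
documents the underlying models, the parameters that matter and their
defaults, the design decisions taken where convention rather than a single
published rule governs, and what the synthetic fixtures do and do not
demonstrate.

## The site-search model

A guide is a protospacer $P \in \{A,C,G,T\}^L$ ($18 \le L \le 24$) plus a
PAM pattern over the IUPAC alphabet and a PAM side (3' for Cas9-style
`NGG`, 5' for Cas12a-style `TTTV`). A genomic locus is reported as a
candidate cleavage site under a sensitivity profile $(m, b)$ when it
admits an alignment with:

* at most $m$ substitutions on aligned guide/genome positions;
* optionally **one** contiguous bulge when $b > 0$: a DNA bulge of $k \le b$
  extra unpaired genomic bases (genomic span $L + k$) **or** an RNA bulge of
  $k \le b$ unpaired guide bases (genomic span $L - k$), never both;
* the PAM matched exactly, positionwise under IUPAC semantics, immediately
  adjacent to the protospacer span on the PAM side, read in strand
  orientation.

This is the alignment model shared by the alignment-based off-target
predictors the ensemble emulates. Several choices deserve explicit
statement because published tool descriptions leave them implicit:

* **PAM mismatches are not permitted**, and PAM positions do not count
  toward the mismatch budget.
* **Bulges are strictly interior** to the alignment. A terminal bulge is
  equivalent to a shorter or shifted ungapped match, so admitting it would
  double-count loci.
* The bulge-size bound is applied **symmetrically to DNA and RNA bulges**;
  the emulated tools advertise a "DNA bulge size" but implement both bulge
  types under one bound.
* **A genomic `N` matches nothing** — no guide base and no IUPAC code,
  including the degenerate code `N` itself. Assembly gaps and masked
  regions therefore never produce predicted sites. Soft-masked (lowercase)
  bases, by contrast, are uppercased on load and fully searchable: masking
  must not hide real sites.
* **Canonicalisation.** For a fixed genomic span the bulge type and size
  are forced by the span length, so each (contig, start, end, strand) is
  reported once, with the placement minimising the mismatch count (ties
  resolved toward the leftmost genomic placement; the placement itself is
  not part of the output, so the tie-break only stabilises internal
  bookkeeping). A perfect ungapped site is typically accompanied in
  bulge-aware profiles by overlapping bulged alignments of the same locus
  at shifted spans; these are genuinely distinct admissible alignments and
  are deliberately *not* window-merged, so that provenance stays auditable.
  Downstream cross-referencing uses distance windows and is insensitive to
  this multiplicity.

The engine itself is a vectorised scan: per contig and strand it
accumulates positionwise mismatch indicators into suffix sums at genomic
shifts $-b \dots b$, from which the minimal mismatch count of every
(position, bulge configuration) follows in $O(bL)$ vector operations.
Correctness is pinned by an exhaustive brute-force oracle (every window,
every interior single-bulge placement, character-by-character) that the
test suite runs against the engine on dozens of seeded genomes; the two
must agree exactly.

### The ensemble

The default configuration runs four profiles — $(3,0)$, $(5,2)$, $(5,2)$,
$(5,0)$ — mirroring a four-tool ensemble in which two tools are
bulge-aware and two are not, and one tool stops at three mismatches. Tools
are emulated only through their $(m, b)$ bounds; per-tool PAM restrictions
or scoring schemes are out of scope. The ensemble output is the
deduplicated union of the per-profile site lists with a `sources` column
listing every admitting profile. Whether a multi-tool ensemble should
deduplicate or concatenate is genuinely open; union-with-provenance was
chosen because it keeps every tool's contribution auditable in one table.

## The unique-variant screen

From a two-sample VCF (the Mutect2 tumour/normal layout: clone and parent
as sample columns of one file), records are decomposed per ALT allele and
retained only when **all** of the following hold:

| rule | retained when | default |
|---|---|---|
| filter | caller FILTER is `PASS` | — |
| zygosity | both genotypes known | — |
| genotype pattern | clone het, parent hom-ref | — |
| depth | clone DP known and ≥ `min_depth` | 10 |
| allele fraction | clone AF known and ≥ `min_allele_fraction` | 0.2 |

"Below 10×" and "below 0.2" are read literally: strictly-less-than
excludes, so DP = 10 and AF = 0.2 are retained; both boundaries are
unit-tested. A hom-alt clone genotype is excluded under the
genotype-pattern rule (the screen demands a *heterozygous* alternative).
Excluded records are tallied under the **first** failing rule in the fixed
order above, so the exclusion summary is a partition. The allele fraction
comes from the clone's `AF` FORMAT field when present, else from
`AD`-derived `alt/(ref+alt)`, else it is unknown (and the record screened
out). The screen is stated for SNVs in the source methodology; it is
applied unchanged to MNVs and indels here, since curated variant lists in
this setting include both. Indels whose allele-length difference reaches
50 bp are flagged at structural-variant scale for summaries.

## Cross-referencing and the string search

A screened variant is linked to a predicted site when the variant's
±`window` flank (default 200 bp) intersects the site's
protospacer-plus-PAM span. Distance is measured between closed genomic
spans — coordinate difference between the nearest ends, 0 on overlap. A
linked variant is labelled `on_target` when it lies within
`on_target_radius` (default 2,000 bp) of the intended target interval;
the 2-kb default reflects the working rule that the few kilobases around
an edited locus deserve scrutiny, and it is configurable.

The parallel string search drops the PAM requirement entirely: each
variant's flank is scanned, ungapped, for the protospacer in both
orientations (gRNA+ and gRNA−) with up to 4 substitutions. Because it is
PAM-free, it is a strict superset detector for ungapped low-mismatch loci
— the property is tested — and it is what recovers intended silent edits
whose guides were designed against variant-bearing haplotypes absent from
the reference, a failure mode of PAM-anchored prediction that the test
suite reproduces. The genome-wide-search-then-lookup formulation and the
window-restricted formulation are equivalent for reporting; the
window-restricted form is implemented.

## CNV screening

Calls from two read-depth callers are intersected: a call is retained when
its length strictly exceeds `min_size` (default 1,000 bp) and a same-type
call from the other caller reciprocally overlaps it by at least
`min_reciprocal_overlap` (default 0.5; reciprocal overlap is
$\min(o/|A|, o/|B|)$). The 50% reciprocal-overlap concordance rule is the
field convention, adopted because the source methodology names the two
callers but not a merge rule; a `require_concordance = FALSE` mode keeps
size-filtered single-caller calls for workflows that inspect calls
manually. Retained calls are classified with a fixed precedence —
parental match (`not_de_novo`), then 3–10 Mb (`large_rare`), then coding
exon intersection (`exonic`), then `other_de_novo` — making the
categories mutually exclusive and total. Whole-chromosome abnormalities
are subsumed by the large-rare band (bounds configurable); karyotype-level
detection is out of scope.

## Cohort statistics

Per-clone unintended-event counts are compared between groups with the
classic pooled-variance (equal-variance) two-sample t-test:
$t = (\bar x - \bar y) / \sqrt{s_p^2 (1/n_1 + 1/n_2)}$,
$\mathrm{df} = n_1 + n_2 - 2$, two-sided p from the t distribution
(`stats::pt`; the tail is cross-checked in tests against numerical
integration of the t density to $10^{-6}$ over df 1–60, and the whole
statistic against `stats::t.test(var.equal = TRUE)`). The pooled form, not
Welch's, is used: on the packaged cohort only the pooled test reproduces
the reported p-values (0.003 for plasmid-vs-RNP on counts {2,8} vs
{0,3,1,1,1,1,3,1,1,0,1,0,0,1}; 0.2536 for Cas9-vs-Cas12a), which fixes
the convention. Degenerate inputs are total: zero pooled variance with
equal means gives $t=0, p=1$; with unequal means, $p=0$ plus a warning.

**Event counting.** One event per genome-wide validated variant row, plus
one event per unintended on-target modification; physically linked
on-target lesions in one clone (an insertion with its adjacent
mono-allelic deletion) count once. This is the only convention consistent
with all four packaged group means (5.0, 1.0, 1.83, 0.5 events/clone),
and it is recorded as an inference, not a quoted rule.

**Known numeric flags.** The packaged per-clone coverages average 41.38×,
while the figure usually quoted alongside this cohort is 41.3×; the
package reports its own computed mean and does not force the match.
Deletion lengths are reported inclusively (end − start + 1); one
mono-allelic deletion in the packaged tables (330 bp inclusive) is
elsewhere described as 329 bp, i.e. half-open — the inclusive convention
is applied uniformly and the discrepancy noted here rather than patched.

## Coordinates and formats

Internal coordinates are 1-based inclusive throughout (the VCF convention,
and the convention of the packaged hg19 tables); BED output converts to
0-based half-open at the boundary and back on re-read, and the conversion
is its own inverse. FASTA I/O goes through Biostrings, VCF parsing through
VariantAnnotation (per-allele genotypes re-derived from GT for decomposed
records), interval overlap through GenomicRanges. The BED6+ writer and the
fixture VCF writer are in-package: the former because the reports carry
arbitrary extra attribute columns plus a comment header, the latter
because the generator emits simple two-sample VCFv4.2 text that is read
back through the package's own reader in tests.

## What the synthetic fixtures show — and what they do not

The generator produces IID-base genomes at a configurable GC fraction
(default 0.41, human-like), then overwrites chosen loci with constructs
realising requested mismatch counts, bulge states and PAM validity;
planted loci are spaced at least $2(L + \mathrm{window})$ apart to prevent
cross-talk. Because substituted or inserted bases can accidentally create
a cheaper alignment of the same span, the generator re-scores each planted
span with an independent local scorer and records the *realised* minimum
in the truth table; truth assertions are subset assertions at planted loci
while full-output correctness rests on the oracle-equivalence property.
Variant fixtures plant four truth classes (linked-pass, linked-fail with
exactly one named failing rule, unlinked-pass, on-target), with expected
cross-reference labels computed from actual distances; CNV fixtures cover
every retention/classification outcome. All generators are pure functions
of their seed.

These fixtures demonstrate *mechanical* correctness: that each screen
implements its stated rule and the chain recovers planted truth with
precision and recall 1. They do not emulate sequencing error, mapping
artefacts, repeat structure, real linkage between lesions, or the base
composition of real genomes — so passing fixtures says nothing about
caller quality upstream, and real-data performance inherits whatever the
upstream caller got wrong. Read-level simulation is deliberately out of
scope, as are the external prediction tools themselves, cleavage-activity
scores (CFD/MIT), chromatin accessibility, and probabilistic attribution
of variants to editing versus culture.

## Problem sizes and determinism

The shipped tests run the oracle-equivalence property on 50 seeded 1-kb
genomes with three planted loci each (all four profiles, plus budget
monotonicity and strand-mirror symmetry per genome), end-to-end scenarios
on ~32-kb two-contig genomes with nine planted sites, and the statistical
oracle over df 1–60 — sizes chosen so the whole suite completes in a
couple of minutes on one CPU while still exercising every code path; the
engine itself handles megabase-scale contigs. Pipeline outputs are a pure
function of inputs and configuration: re-running a scenario writes
byte-identical reports, with the only timestamp confined to the run
manifest.
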