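---
title: "Methods: from assembled transcripts to survival-associated novel peptides"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from assembled transcripts to survival-associated novel peptides}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(novelpep)
```

## The problem

Reference-based peptide search can only identify peptides present in the
annotated proteome. Tumour transcriptomes, however, express unannotated
products: alternatively spliced junctions, translation upstream or
downstream of annotated coding sequence, intronic read-through, pseudogene
and lncRNA translation, and open reading frames in intergenic DNA. A
proteogenomic pipeline finds these by searching MS/MS spectra against a
sample-specific database built from de novo assembled transcripts, then
asking — for each confidently identified peptide that no reference protein
contains — *where in the genome it comes from* and *whether it matters
clinically*. `novelpep` implements exactly those bespoke stages; assembly,
spectral search, FDR estimation and PepQuery rescoring remain external
tools whose outputs are consumed through file interfaces.

## Database construction

Each assembled transcript is translated in six frames with the standard
genetic code. An open reading frame is a maximal stop-free segment
(stop-to-stop), with **no start-codon requirement**: six-frame search
databases conventionally drop the methionine requirement, and upstream
(5′) extensions in particular need not begin with Met. Codons containing
`N` translate to `X`, and `X` terminates a segment exactly like a stop —
no amino-acid sequence is fabricated across an ambiguous base.

Only the single longest ORF per transcript enters the database by default
(`extract_longest_orf()`); `build_custom_database(all_orfs = TRUE,
min_orf_aa = ...)` keeps every segment above a length floor for users who
want a denser database. The minimum length has no default floor beyond the
digestion filters, because any retained peptide must anyway survive the
7–30-residue window. Ties between equal-length ORFs are broken by frame
order `+1,+2,+3,-1,-2,-3`, then leftmost position — an arbitrary but fixed
rule that makes the database a pure function of its inputs.

Decoys are whole-sequence reversals of every target, id-prefixed with
`DECOY_`; a palindromic target whose decoy equals itself is reported. In
silico trypsin digestion cleaves after K or R, suppressed before P (the
Keil rule, toggleable), with defaults matching common search settings:

| parameter | default | meaning |
|---|---|---|
| `max_missed_cleavages` | 2 | uncut internal K/R sites allowed per peptide |
| `min_len`, `max_len` | 7, 30 | retained peptide length (residues) |
| `keil_rule` | TRUE | no cleavage when K/R is followed by P |

## Novelty

Reference matching is substring matching **anywhere** in any reference
protein, not only at tryptic boundaries: a peptide embedded in an annotated
protein is not novel regardless of cleavage context, so this is the
conservative choice that minimises false novelty. Isoleucine and leucine
are isobaric and indistinguishable by standard fragmentation, so I/L
folding is applied to both the index and every query by default
(`il_equivalent = TRUE`).

FDR is consumed, not re-estimated: the upstream post-processor already
combined engine scores into peptide confidence, so `filter_novel()` keeps
PSMs with `confidence >= 1 - fdr_threshold` and never re-scores spectra.
PepQuery validation keeps a peptide when at least one of its PSMs has
permutation p ≤ 0.01 with zero unrestricted modifications (`n_ptm = 0`);
peptides with no PepQuery result at all are dropped and reported rather
than silently passed. Multi-genomic-location removal happens later, in the
genome-mapping stage, because it needs coordinates; the novelty stage marks
but does not drop.

## Projection and classification

A peptide at amino-acid offset *a* of an ORF occupies transcript
nucleotides `tx_nt_start + 3a … + 3(a + len)` on the ORF's reading strand;
minus-frame ORFs are mirrored into transcript-forward coordinates, then
mapped through the alignment blocks (minus-strand alignments mirror once
more into genome-forward blocks). All internal coordinates are 0-based
half-open; GTF/GFF3 is converted from 1-based inclusive at the boundary and
BED12 written 0-based half-open, with round-trips tested bit-exactly.
Projection always conserves length: Σ genomic block lengths = 3 × peptide
length.

Peptides whose alignments resolve to more than one genomic locus (distinct
chromosome, strand, or merged block structure) are removed entirely;
identical placements reached through different isoforms of one gene
collapse to a single locus and survive.

Classification assigns exactly one category by a precedence ladder, because
the event taxonomy overlaps and a deterministic total function is required:

1. **Biotype partition** — overlap with a protein-coding gene beats overlap
   with a noncoding gene (pseudogene / lncRNA / TEC by biotype) beats
   intergenic (`NORF_INTERGENIC`). When genes on both strands overlap, the
   peptide's own coding strand (inherited from its source transcript) is
   preferred and the choice is deterministic.
2. **Within a coding gene**, junction evidence is the most specific signal:
   `EXON_SKIPPING` (the peptide's implied intron joins the annotated
   boundaries of non-consecutive exons) beats `JUNCTIONAL_VARIATION` (a
   junction inside the gene matching no annotated intron, both sides
   exonic) beats `EXON_EXTENSION_OVERLAP` (a block crossing an exon
   boundary) beats `UTR5`/`UTR3` placement beats `EXON_EXTENSION_INTRONIC`
   beats `FRAMESHIFT_NOVEL_FRAME`.
3. **Demotion to nORF** — a coding-gene peptide with no frame or
   source-transcript link to the annotation is evidence for a novel ORF,
   not for a variant of the annotated product: intronic peptides whose
   source transcript does not also align in-frame to an annotated exon of
   the same gene become `NORF_INTRONIC`; UTR peptides without a linked
   source become `NORF_UTR_REGION`; CDS-overlapping peptides without a
   link (or in-frame ones, which cannot arise from a genuinely novel
   sequence and indicate an annotation disagreement) become
   `NORF_ALTFRAME`.

The intronic split deserves its own note, since retained-intron peptides
can plausibly be filed either as exon extensions or as independent intronic
ORFs: here an intronic peptide counts as `EXON_EXTENSION_INTRONIC`
precisely when its source transcript also covers ≥ 1 annotated exon of the
same gene *and* the translated frame agrees with the annotated CDS frame at
a shared position — i.e. when the peptide is readable as in-frame
read-through — and as `NORF_INTRONIC` otherwise. Frame comparison uses the
CDS `phase` attribute of the translation-first block where present, else
phase 0, and compares codon offsets at one shared position per contiguous
overlap (the offset is constant along a gap-free overlap, so one position
suffices).

## Survival screen

Peptide-region expression is mean per-base read coverage over the peptide's
genomic blocks, converted to counts per million:
CPM = coverage / library size × 10⁶. Samples are split at the **mean**
expression; ties at the mean go to LOW (fixed for determinism). Constant
expression vectors cannot be stratified and the peptide is skipped with a
message.

The survival model is the Kaplan–Meier product-limit estimator, compared
between groups with the two-sample log-rank test,
χ² = (O − E)² / V on one degree of freedom — the standard companion test
for Kaplan–Meier comparisons, adopted here as a design choice since a
specific test is not dictated by the screen itself. Raw p-values are
reported by default (no multiple-testing correction), matching how such
screens are usually reported peptide-by-peptide; a Benjamini–Hochberg
option exists (`p_adjust_method = "BH"`) but is off. An optional
expression pre-filter hook (`expression_filter`) is provided but off by
default, because what such a pre-screen should test (detection vs
differential expression) is analysis-specific.

The **parent-gene control** is the screen's defining feature: a peptide is
`significant` only when its own p ≤ α (default 0.05) *and* its parent gene
shows no survival association. "No association" uses a deliberately strict
threshold of p > 0.1 — near-significant parent association already
disqualifies, since the goal is attribution of the signal to the novel
region. The `direction` field (`HIGH_EXPR_POOR` / `LOW_EXPR_POOR`) comes
from the sign of observed-minus-expected deaths in the high group.

Note one statistical consequence of the control: against an independent,
truly null parent gene, the parent p-value is uniform, so the control
falsely vetoes a true peptide hit with probability equal to the parent
threshold (0.1 by default). Power statements about the screen therefore
refer to *detection* of the planted effect (the peptide's own test at α
with the correct direction); the veto behaviour is validated separately by
planting a parent-gene effect and checking the peptide is excluded.

## What the synthetic fixtures emulate — and what they don't

`simulate_fixtures()` builds a two-chromosome toy genome (a few tens of
kilobases per chromosome; laid out to keep full-suite runtimes in seconds)
carrying, by default, five gene loci per event category. Every locus is
designed so that its planted peptide is **guaranteed**, for any seed, to
(a) lie in its transcript's longest six-frame ORF, (b) be fully tryptic
(flanked by K/R, no internal cleavage site, length 10), (c) be absent —
after I/L folding — from the annotated proteome, and (d) classify to
exactly one category. Guarantees hold because every random draw happens
inside a verification loop that re-draws (using synonymous-codon freedom
where sequence is doubly constrained, e.g. the out-of-frame peptide whose
in-frame reading must still be stop-free CDS) until the constraints are
met; generation is still a pure function of the seed.

Coding genes have three exons, CDS length ≡ 0 mod 3 with a single terminal
stop, and frame-aligned exon boundaries; clinical cohorts draw exponential
survival times with the hazard multiplied by the spec's `hazard_ratio`
(default 3) in the planted high-expression half, independent exponential
censoring calibrated to the requested `censoring_rate` (default 0.2), and
subtypes assigned round-robin. PSM tables plant known (reference-tryptic)
and novel peptides at confidence above the 1% FDR line plus sub-threshold
rows the filter must drop; PepQuery tables pass an exact, configurable
fraction of novel peptides.

Passing on these fixtures shows the machinery is correct, not that real
data are this clean: real assemblies contain chimeras and truncations,
real peptides hit repetitive loci (exercised here only by construction),
event classes overlap ambiguously, expression is not bimodal, and hazards
are not exponential with a clean two-group structure. The generator makes
no attempt at read-level or spectrum-level realism (no FASTQ, no mzML).

## Numerical and degenerate-input choices

* Empty or non-IUPAC nucleotide input, empty proteomes, zero library
  sizes, and p-value thresholds outside (0, 1] are hard errors; malformed
  PSM rows and annotation features are rejected row-by-row with a message.
* A transcript whose six frames are all empty or all-stop is skipped with
  a warning rather than failing the database build.
* Log-rank with no events is an error (undefined test); a zero variance
  yields χ² = 0.
* The Kaplan–Meier curve is right-continuous with S(0) = 1 and, with zero
  censoring, equals the empirical survival function exactly (tested to
  machine precision).
* Problem sizes used by the test suite and acceptance script — 100
  random 200-residue proteins for the digestion oracle, 50 random 400-nt
  transcripts for the ORF oracle, 1,000 projected peptides for the
  per-base oracle, 1,000 null replicates (n = 200) for log-rank
  calibration, 200 replicates for power — are the package's chosen
  precision/runtime trade-off and complete in well under a minute each.

## Known limitations

* Classification requires transcript-to-genome alignments; the package
  does not do spliced realignment of peptides de novo, fusion detection,
  or single-amino-acid-variant calling.
* Reference matching is exact substring matching (after I/L folding);
  near-isobaric substitutions other than I/L are not folded.
* The survival screen is nonparametric and two-group only — no Cox
  modelling, covariates, or continuous-expression tests.
* BAM-level coverage extraction is out of scope; the screen consumes
  precomputed coverage tables.
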