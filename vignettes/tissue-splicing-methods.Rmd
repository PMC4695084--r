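---
title: "Methods: junction filtering, normalization and tissue specificity in juncspect"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: junction filtering, normalization and tissue specificity in juncspect}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(juncspect)
```

# Overview

`juncspect` characterises tissue-restricted alternative splicing across a
multi-tissue RNA-seq panel. The pipeline consumes spliced alignments in
SAM format — it deliberately does *not* perform spliced alignment — and
proceeds in five stages: junction extraction, empirical filtering,
annotation classification, expression quantification with cross-tissue
normalization, and tissue-specificity analysis. A synthetic alignment
generator with planted ground truth validates each stage and the
composition of all of them.

All genomic coordinates inside the package are 0-based half-open. SAM
positions (1-based) and GTF intervals (1-based inclusive) are converted
at the boundary; BED input/output is already 0-based half-open. A
junction is identified with the intron interval it implies,
`chrom:intron_start-intron_end`.

# Junction extraction

Each `N` CIGAR operation of a mapped, primary alignment defines a
putative intron. A read with *k* skips contributes evidence to *k*
junctions. Per (read, junction) incidence the package records:

- the **offset**, the read's leftmost aligned reference position minus
  the intron start. Only relative multiplicity matters downstream, so
  whether offsets are read starts or flanking-segment lengths is
  immaterial — entropy is invariant under relabeling;
- the **mismatch count**, the whole-read edit distance (`NM` tag). The
  whole read is used rather than the flanking segments only, because the
  filter is defined on "reads spanning a junction", not on sub-alignments.

Secondary alignments are excluded by default (`include_secondary = TRUE`
admits them). Records with malformed CIGARs or truncated fields are
skipped and counted in a QC tally instead of aborting the run. Junctions
are keyed *without* strand, so evidence from both orientations of an
unstranded library merges; a consensus strand (or `*`) is reported. When
the splice-strand tag (`XS`) is present it is carried along, otherwise
the strand is unknown, and annotation lookups for unknown-strand
junctions are positional (strand-blind).

# Filtering

Three statistics per junction drive the filters:

- **offset entropy** `S = -Σ pᵢ log pᵢ`, `pᵢ = cᵢ / Σ cᵢ` over the offset
  histogram. The logarithm base defaults to 2 and is configurable
  (`log_base`). Base 2 is the package's choice: with natural logarithms a
  junction supported by two equally used offsets scores `ln 2 ≈ 0.693`,
  below the default 0.75 cut, which would reject the large class of
  modestly covered but well-dispersed junctions the filter is meant to
  keep; in base 2 the same configuration scores 1.0.
- **average mismatches** `m̄`, the arithmetic mean over spanning reads.
- **intron length** `L = intron_end − intron_start` in bp.

A junction is retained iff `S ≥ entropy_min` **and** `m̄ ≤ mismatch_max`
**and** `L ≥ intron_min`. Defaults: `entropy_min = 0.75` for both library
types, `mismatch_max = 1.5` (single-end) or `1.0` (paired-end), and
`intron_min = 50` bp — candidates shorter than the minimum length of
known introns are more plausibly small deletions. The boundary semantics
(≥, ≤, ≥) are taken literally from those operating points: a junction
exactly at every threshold passes.

The filter report attributes removals two ways: a partition by the first
failing rule (in the order entropy, mismatch, intron length) and a tally
of every failed rule per junction; both are reported because a junction
can fail several rules at once. When classifications are supplied the
report adds retention fractions for annotated and novel junctions
separately.

Filters are applied per tissue per library type; the pooled per-library
junction set is the union of the per-tissue retained sets. Pooling before
filtering is possible by merging evidence first (`merge_evidence()` —
extraction is additive), but per-tissue filtering is the default because
presence calls downstream are per tissue.

## Threshold calibration

The empirical calibration treats annotated junctions as the gold
standard: `calibration_profiles()` returns the annotated/novel
`(S, m̄)` point sets and intron-length histograms for inspection, and
`suggest_thresholds()` mechanises the choice with nearest-rank quantiles
of the annotated sample: `entropy_min` at the lower `(1 − retention)`
quantile (0-based rank `floor((1 − r)(n − 1))`) and `mismatch_max` at the
`retention` quantile with the rank rounded *up*
(`ceiling(r(n − 1))`). The asymmetry is deliberate: rounding the
mismatch rank down can retain fractionally fewer than `r·n` annotated
junctions, while rounding up guarantees each criterion alone keeps at
least `r·n` of them. Published default thresholds remain the defaults;
the chooser is for recalibration on new data.

# Annotation classification

`build_annotation_index()` holds the known intron set and the derived
donor (5′ with respect to strand) and acceptor (3′) site sets,
deduplicated across sources. Classification is a total function with four
exclusive outcomes:

1. `annotated` — the intron interval itself is known;
2. `novel_both_sites` — both boundary positions are annotated sites, in a
   combination not seen as a pair;
3. `novel_one_site` — exactly one boundary is an annotated site;
4. `novel_neither` — neither is.

"One site" is exclusive (exactly one) so that the three novel classes
partition the unannotated junctions. Site lookups respect strand for
stranded junctions and ignore it for unknown-strand junctions; boundary
membership is tested against the union of donor and acceptor sites,
without requiring the matched site type to be consistent between the two
boundaries (the data the design targets are unstranded, so a stricter
policy would be arbitrary).

# Expression and normalization

**Junctions:** raw expression in a tissue is the spanning-read count;
junctions without evidence in a tissue are 0.

**Genes:** raw expression is mean exonic depth — total aligned bases over
the gene's exon-union positions divided by the exon-union length. Skipped
(`N`) segments of spliced reads contribute no depth. Gene length is
defined as the exon-union length so that the ratio is exactly the mean
depth over the positions counted in the numerator. Genes default to a
protein-coding biotype filter (configurable).

**Normalization:** `c̃(e, t) = c(e, t) · N̄ / Nₜ`, with `Nₜ` the tissue's
total aligned primary reads (each paired-end mate counted separately) and
`N̄` the mean across tissues. The same linear map applies to junction and
gene matrices, which is what makes the two comparable at a common
threshold; it is RPKM-like but normalizes to the mean library instead of
per million reads and (for genes) on nucleotide coverage instead of read
count. The map is invertible given the sizes, and rescaling all library
sizes by a common factor leaves it unchanged. Single-end and paired-end
libraries are normalized and analysed separately end to end, meeting only
in the specificity comparisons.

# Tissue specificity

Presence is a strict inequality, `c̃ > τ` ("over the threshold");
`τ ∈ {5, 10, 50, 100, 500, 1000}` is surveyed for the distribution
profiles and `τ = 10` is used for the headline analyses. The
tissue-count distribution excludes entities present nowhere. As `τ`
grows, mass shifts toward the single-tissue bin; the ratio of detectable
junctions to detectable genes per threshold is provided as the
detection-bias control.

Junction-gene pairing assigns a junction to the unique gene owning an
annotated donor/acceptor site at either boundary. Junctions matching
sites of two or more genes (gene overlap, or a donor of one gene with an
acceptor of another) are excluded as multi-gene; junctions matching no
site stay unpaired. A junction matching two sites of the *same* gene in a
new combination pairs to that gene. The T×T specificity matrix tallies
pairs by (junction tissue count, gene tissue count), dropping pairs
absent everywhere; cells above the diagonal (junction broader than gene)
can only arise from threshold effects, since spanning reads are a subset
of the gene's reads.

Tissue-specific calls require agreement between the library types: an
entity is specific to tissue *t* iff it is present in exactly `{t}` in
the single-end data and exactly `{t}` in the paired-end data. The two
libraries act as technical replicates in a design without biological
replicates; a single-library mode exists for simulation tests. The
gene-level summary (genes containing at least one single-tissue junction,
for genes expressed at all / in >1 tissue / in every tissue) is
restricted to multi-exon genes, which are the only possible junction
hosts; the tissue-count distributions are not so restricted by default.

# The synthetic-data generator

The generator emulates the structure of a 16-tissue human body-map
design: one individual per tissue (no biological replicates), one 75 bp
single-end and one 2×50 bp paired-end library per tissue (insert ≈ 210
bp), intron lengths between 50 and 100,000 bp, and a mixture of
annotated and novel, ubiquitous and tissue-restricted genes and
junctions. Reads are emitted pre-aligned: sequence content, quality
strings, base-level errors and alignment itself are out of scope, and
mismatch counts exist only as `NM` tags.

Planted structure, all recorded in the `truth_set`:

- a fraction of genes (`frac_tissue_specific_genes`, default 0.2) is
  expressed in exactly one tissue; all other genes are ubiquitous. The
  two-class design keeps the planted tissue-count bins exact; real panels
  also populate intermediate breadths.
- a fraction of ubiquitous genes (default 0.25) receives one extra
  exon-skipping junction expressed in a single tissue — the
  specific-junction-in-ubiquitous-gene class at the centre of the
  analysis. These junctions are annotated (the skip interval is added to
  the annotation), so their recovery is independent of novelty.
- a target fraction of all junctions (`frac_novel_junctions`, default
  0.1, matching the ~10% novel rate seen in deeply annotated genomes) is
  withheld from the annotation index, planted in equal thirds as: a new
  combination of two annotated sites (an exon skip), one annotated site
  with the other boundary displaced 10–30 bp into exonic sequence, and
  both boundaries displaced. Construction guarantees the planted boundary
  status is exactly what classification recovers.
- novel junctions default to a quarter of the base depth
  (`novel_depth_factor = 0.25`): unannotated junctions in well-annotated
  genomes sit disproportionately near detection thresholds, and this is
  what drives their lower cross-library concordance.
- optional artifact junctions (`frac_artifact_junctions`, default 0)
  draw their offsets from a geometric distribution
  (`offset_geom_prob = 0.95`) so reads stack at one or two offsets and
  the expected empirical entropy falls well below 0.75. Sampling noise
  means an occasional artifact clears the threshold, which is also true
  of real artifacts; tests therefore compare retention *rates*, not
  individual junctions.

Read generation per tissue and library: spanning-read counts per
expressed junction are Poisson with mean `depth_per_tissue` (default 50)
times the junction's depth factor — the Poisson model is a modelling
choice, not data-derived. Offsets are uniform over all positions leaving
at least 1 aligned bp on each side of the junction within its flanking
exons. Unspliced gene-body reads top exonic coverage up to roughly
`gene_body_depth_factor` (default 0.5) times the junction depth, so gene
presence calls saturate at the same thresholds as junctions. Mismatch
counts are Poisson with mean `mismatch_rate` (default 0.5, comfortably
inside both mismatch cuts so that the cut removes artifacts rather than
ordinary reads). Paired-end fragments place the spliced mate first and
its mate in the downstream flanking exon at the configured insert size,
clamped to the exon. Genes are laid out without overlap on synthetic
chromosomes (`chrS1…`), with 3–6 exons of 120–260 bp (single-exon genes:
`frac_single_exon_genes`, default 0.1) and log-uniform intron lengths, so
that every exon can host a read and every junction has valid offsets.

Determinism: a fixed seed makes the reference and every SAM file
byte-identical across runs; each (tissue, library) pair derives its own
stream seed from the master seed, so files are independent but
reproducible, and the simulator returns its own per-junction read counts
for exact cross-checks against extraction.

What passing on synthetic data does *not* show: robustness to alignment
error, mappability structure, overlapping genes, intermediate expression
breadths, fragment GC bias, or real splice-site sequence context. The
generator validates the bookkeeping and the statistics, not the aligner
upstream of them.

# Numerical and degenerate-input choices

- Entropy of an empty histogram is an error (a junction requires ≥ 1
  read); a single offset gives exactly 0.
- `library_sizes()` rejects non-positive totals; the pipeline substitutes
  1 for a zero-read tissue (with a logged message) so that empty inputs
  yield empty but well-formed outputs.
- Zero-length genes are an error in `gene_expression()`; zero-length
  introns are rejected (and counted) when building the annotation index.
- BED junction records represent one exonic base on each side of the
  intron (`chromStart = intron_start − 1`, `chromEnd = intron_end + 1`,
  `blockSizes = "1,1"`); a junction starting at position 0 has no
  representable upstream base and is skipped with a warning. Scores cap
  at 1000 as BED requires. Track header lines are optional because strict
  BED consumers reject them.
- Concept-score normalization divides each set's sum scores by its set
  size, subtracts the equivalently normalized random-gene background per
  concept, and clips negatives to 0.

# Problem sizes used by the test-suite

The validation suite runs the full pipeline on a panel of 16 tissues and
200 genes (~750 junctions, ~3 million alignment records across 32 SAM
files) at saturating depth, which completes in about a minute on one CPU;
unit and property tests use panels of 2–4 tissues and 3–80 genes, and
oracle checks use 10³–10⁴ random cases. These sizes were chosen to make
every planted quantity exactly recoverable while keeping the suite quick
to run; the pipeline itself streams one tissue at a time and scales to
larger panels.

# Limitations

- The pipeline quantifies junction *presence*, not splicing ratios: no
  PSI, no differential-splicing statistics, no transcript assembly.
- Fusion and non-canonical splice-motif evidence is out of scope; the
  package trusts the aligner's skip operations.
- With one individual per tissue, "tissue-specific" cannot be
  distinguished from donor-specific; the SE/PE agreement requirement
  controls technical, not biological, variation.
- The multi-gene exclusion discards junctions in overlapping gene pairs
  rather than attempting assignment.
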