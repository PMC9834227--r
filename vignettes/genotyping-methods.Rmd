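---
title: "Genotyping known variants in droplet snRNA-seq: methods and design"
author: "dropGeno"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genotyping known variants in droplet snRNA-seq: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Droplet-based 3' and 5' gene-expression chemistries sequence roughly 91
and 90 nt from one end of each captured transcript. That makes them poor
variant-discovery instruments but, for an *a priori known*
single-nucleotide variant — say, a mosaic somatic variant previously
called from bulk exome sequencing — the expression BAM can be reused as a
genotyping assay at zero extra cost, provided the variant's position is
actually covered. Coverage depends on three things this package
quantifies:

1. **distance from the captured transcript end** in spliced (mRNA)
   coordinates;
2. **expression level** of the host gene in the assayed cell population;
3. **internal poly-A mispriming**, which creates alternative capture
   sites and hence coverage far from the annotated end.

Given per-cell genotype calls, the package also computes per-cell-type
variant allele fractions and a coarse developmental-origin
classification: a somatic variant carried by cell types from two or more
germ layers must have arisen before gastrulation.

## Per-cell allele counting

`countAlleles()` is a VarTrix-equivalent counter. For each (cell,
variant) pair, reads overlapping the variant position are grouped by the
corrected cell barcode (CB tag) and UMI (UB tag). Filters, all
configurable through `countingParams()`:

| parameter | default | why |
|---|---|---|
| `minMapq` | 30 | excludes multimappers in a spliced-alignment context |
| `minBaseq` | 20 | drops low-confidence base calls at the site |
| `primaryOnly` | TRUE | secondary/supplementary records are re-representations of the same molecule |
| `umiConsensus` | majority | one vote per molecule; ties are discarded |
| `callPolicy` | alt_dominant | see below |

Reads lacking CB or UB, reads whose alignment skips the position
(deletion or splice gap), and reads whose base is neither the ref nor
the alt allele contribute nothing. After per-UMI consensus, each UMI
adds one count to the cell's `refUmis` or `altUmis` entry. The
three-way call is `ALT` if the cell has at least one alt UMI, `REF` if
it has only ref UMIs, and `NO_CALL` without coverage. A cell observed
with both alleles is reported `ALT` — a genuine heterozygous or mosaic
carrier transcribes both alleles, and the three-way scheme has no
"both" category — but is retained in a `both` mask for audit. Under
this audit rule the two classic scoring intents ("alt-dominant" vs
"consensus") yield the same call matrix, so `callPolicy` is kept only
to document intent.

Coverage, used by every downstream detection statistic, is defined at
the UMI level (`refUmis + altUmis >= 1`), consistent with
UMI-deduplicated expression counting.

## Distance to the transcript end

Distances are computed in **spliced transcript coordinates** on one
canonical transcript per gene — the MANE transcript when a MANE list is
given to `loadAnnotation()`, otherwise the longest transcript (ties
broken lexicographically). Spliced rather than genomic distance is the
right metric because capture and read-off proceed along the mature
mRNA.

Coordinates are 0-based: a variant at the cap site has `dist_5p = 0`,
and `dist_5p + dist_3p = transcript length - 1` always. "Within the
first 105 nucleotides of the transcription start site" therefore means
`dist_5p <= 104`. The kit-relevant distance is `dist_3p` for 3'
chemistry and `dist_5p` for 5'; pooled analyses may take the minimum,
but `stratifyByDistance()` operates on the kit-matched distance.
Intronic variants are removed by `filterIntronic()` (exome calls often
include intronic positions that snRNA-seq cannot see in spliced reads;
nuclei do contain pre-mRNA, a caveat noted under limitations).

## Internal poly-A mispriming

During reverse transcription the poly-dT primer can anneal to A-rich
sequence inside the transcript body, initiating cDNA synthesis there
and producing coverage far from the annotated end. `scanPolyA()` flags
a site when it sees **a maximal A-run of at least 6 nt** or **a 10-nt
window at least 80% A**; overlapping hits are merged and the merged
site is anchored at the first base of its longest A-run. These
thresholds are package defaults — the phenomenon is qualitative in the
source data and no community-standard cutoff exists — and all three are
configurable. Sites overlapping the final window of the transcript are
excluded: that is the genuine poly-A context.

`nearestCaptureSite()` turns sites into an **effective distance**: in 3'
chemistry a site can rescue a variant strictly upstream of it within one
read length (reads extend upstream from the capture site); in 5'
chemistry, a variant at or downstream of the site within one read
length. The effective distance is the minimum over the annotated end
and all usable sites, and never exceeds the annotated distance.

## Evaluation statistics

- `detectionFraction()`: per variant, the proportion of cells with UMI
  coverage; computed per dataset (per patient, per kit) — pooling is
  always explicit.
- `stratifyByDistance()`: fraction of variants detected in at least 5%
  of cells, in cumulative strata within 100 bp and within 1,000 bp of
  the kit-relevant end plus the residual beyond-1,000 stratum. Empty
  strata are reported as undefined, never as zero.
- `stratifyByExpression()`: the same detection criterion in overlapping
  "mean log-normalized expression greater than t" strata (defaults
  t = 0.1 and t = 5).
- `falsePositiveRate()`: on null variants (positions genuinely absent
  from the assayed sample, e.g. another patient's private variants
  absent from population databases), the per-variant rate of having any
  ALT cell. The per-variant definition is primary; the total count of
  ALT cell-calls and a single-nucleus flag per offender are also
  reported.
- `perClusterVaf()`: VAF over genotyped cells
  (`n_alt / (n_alt + n_ref)`, NO_CALL excluded from the denominator),
  with the all-cells ALT fraction (`vaf_of_all`) reported alongside for
  comparison against bulk VAF. The choice of denominator is a design
  decision: genotyped-cells-only is the reading consistent with
  cluster-level VAFs being far higher than the bulk fraction, and both
  columns are emitted so either convention can be read off.
- `kitGenotypedFraction()`: fraction of cells with any call, per
  chemistry — the cross-kit comparison for a variant near one end.

## Lineage classification

`classifyOrigin()` sums ALT cells per germ layer using a cell-type map
(`defaultGermLayerMap()` ships the nine cortical types: microglia and
lymphocytes mesodermal, the neural/glial types ectodermal, the
mitochondrial technical cluster unknown). A layer counts as carrying
the variant when it reaches `minAltCellsPerLayer` ALT cells (default
2). Two or more layers: `pre_gastrulation`; exactly one:
`lineage_restricted`; none: `insufficient_evidence`. The minimum-
evidence threshold is this package's own guard against single-nucleus
false positives — the underlying biological inference is qualitative —
and it is surfaced as a parameter, never silently applied.

## Expression QC and marker scoring

`logNormalize()` is the standard
`ln(1 + 10^4 * count / cellTotal)`; `qcMetrics()`/`filterCells()`
implement the conventional per-nucleus UMI/gene/percent-mitochondrial
surface, removing cells with *more than* 5% mitochondrial counts
(the boundary is kept). `concordance()` correlates per-gene mean
log-normalized expression between two datasets over their shared gene
universe (reported both over all shared genes and over expressed genes,
since the choice is ambiguous), or produces a cluster-by-cluster
correlation matrix. `proportionExpressing()` uses a strict
greater-than-1-CPM rule. The marker efficacy score for gene g marking
cluster k is

$$ S = \frac{\sum_{j \ne k} (p_k - p_j)^2}{\sum_{j \ne k} (p_k - p_j)} $$

with S = 0 when the difference sum is zero (uniform or absent
expression) and S = 1 for perfectly binary expression. When a
non-marked cluster expresses the gene more than the marked one the raw
value leaves [0, 1]; it is clamped and the raw value kept as an
attribute, a case the original formulation does not cover.

## The synthetic data generator

`simConfig()` + `simulateDataset()` emulate the essential physics of
the assay so that every downstream stage can be tested offline with
known truth:

- **Reference**: a miniature genome, genes in tandem on alternating
  strands, random exon/intron structure, one canonical transcript per
  gene; selected genes receive an internal A-homopolymer at a chosen
  spliced position (written through the exon structure, so the run
  exists on the mRNA even across a junction).
- **Cells**: types drawn from configured proportions (defaults: nine
  cortical types at realistic snRNA-seq proportions), counts per (gene,
  cell) negative-binomial with per-(gene, type) means and a common
  dispersion (default size 2, a typical droplet overdispersion).
- **Capture**: one capture event per molecule. With probability
  `1 - (1 - misprimingRate)^nSites` the molecule primes at one of the
  internal poly-A sites found by the same scanner the analysis uses
  (uniformly chosen); otherwise at the annotated kit end. The read
  covers exactly `readLength` nt (91 for 3', 90 for 5') upstream (3')
  or downstream (5') of the capture site, spliced into genomic blocks.
- **Capture offset**: `captureDecay` adds an exponential offset of the
  capture site into the transcript body. The default is 0 — capture
  exactly at the annotated end — which makes the geometry sharp: a
  variant farther than one read length from the end receives exactly
  zero coverage, the property the distance analyses are tested against.
  A positive decay reproduces the graded end-bias of real libraries and
  is exercised by its own test.
- **Variants**: mutant cells are flagged Bernoulli(`mosaicFraction`),
  optionally restricted to a subset of cell types (used to emulate
  lineage-restricted mutations); every molecule from a mutant cell
  carries the alt base before per-base error is applied.
- **Reads**: per-base substitution errors at `errorRate` (default
  0.001, a typical raw short-read rate); UMI duplicates at
  `1 + Poisson(0.3)` reads per molecule, a shallow-sequencing
  duplication level; 10-nt UMIs drawn uniformly with collisions allowed,
  matching droplet chemistry scale. Reads are written directly as
  coordinate-sorted, indexed BAM records with CB/UB tags — the
  simulator stands in for the upstream aligner, keeping the pipeline
  offline. 5'-kit reads are written on the transcript strand and
  3'-kit reads on the opposite strand; the counter is strand-agnostic
  either way.

With the seed fixed, all outputs are byte-identical across runs and
across output directories.

### What the simulator does not model

No base-quality variation (all bases Q37), no indels, no ambient RNA,
no doublets, no intronic (pre-mRNA) reads, no barcode sequencing
errors, and mutant cells are effectively homozygous for the alt allele
on the transcript level (real heterozygous carriers transcribe both
alleles, which depresses per-cell ALT sensitivity but not the zero-error
specificity properties). Two consequences matter when reading test
results. First, passing tests demonstrate the *logic* of the pipeline —
geometry, counting, consensus, stratification — not calibrated
performance on real libraries. Second, because simulated base qualities
are uniform, the base-quality filter cannot remove sequencing errors;
at high coverage the per-variant null false-positive rate in synthetic
data is therefore driven entirely by `errorRate` times coverage and is
markedly higher than in real data, where miscalled bases carry low
quality scores and are filtered. The zero-specificity property is
instead established exactly at `errorRate = 0`.

## Numerical and policy choices

- Coordinates: exons are held as native 1-based Bioconductor ranges;
  all exposed transcript coordinates are 0-based spliced positions, and
  the two distance conventions above are asserted globally in tests.
- UMI consensus ties are discarded rather than assigned — the least
  surprising behaviour, and directly testable.
- Barcode suffixes (`-1` and similar) are normalized on both sides of
  every join; a join with zero overlapping barcodes is an error that
  names the likely suffix mismatch.
- A variant whose chromosome is missing from the BAM header yields a
  warning and an all-NO_CALL column rather than an error, so one bad
  contig name cannot kill a batch.
- Degenerate inputs are defined, not accidental: empty distance or
  expression strata are NA; a cluster with zero genotyped cells has
  undefined VAF; an empty null set, zero-cell matrix, or zero-overlap
  join is an explicit error.

## Problem sizes

The test suite and the acceptance script run entirely on synthetic
data sized for a desktop: unit fixtures of tens to hundreds of reads;
property checks on populations of 250-2,000 cells; one 5,000-cell,
single-gene run for mosaic-fraction recovery; and a 1,500-cell,
24-gene, two-chemistry experiment in the acceptance script. These sizes
were chosen so the binomial tolerances of the recovery checks are tight
(three binomial standard deviations at n = 5,000 is about one
percentage point) while the full suite stays in the minutes range.

## Known limitations

- Distances use annotated canonical-transcript ends; real libraries
  also capture at unannotated poly-A sites, so annotated `dist_3p` can
  overstate the true capture distance.
- The mispriming thresholds (run >= 6, 80% A in 10 nt) are declared,
  not inferred from data.
- Intronic reads from nuclear pre-mRNA are not modelled and intronic
  variants are filtered rather than exploited.
- The lineage call is a coarse two-of-three-layers rule on ALT counts;
  it does not model cell-type misassignment or CNV-driven allelic
  imbalance.
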