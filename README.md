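# dropGeno

Genotyping a priori known single-nucleotide variants in droplet-based
single-nucleus 3'/5' RNA-seq data, and quantifying when that is
feasible.

## The problem

Somatic variants are mosaic: present in only a fraction of a tissue's
cells. Bulk assays see an averaged allele fraction and say nothing
about *which* cell types carry the variant. Droplet snRNA-seq assigns
every transcript to a cell barcode, so for a variant already known
from exome sequencing, the expression BAM doubles as a per-nucleus
genotyping assay — but only when the variant position is covered, and
3'/5' chemistries sequence just ~91/90 nt from one transcript end.
dropGeno is for researchers who want to reuse their 10x-style
expression data to ask: *can this variant be genotyped at all, which
nuclei carry it, and what does that imply about its developmental
origin?*

## What it computes

For cells *c* and a variant with alleles (ref, alt), reads overlapping
the site are binned by (cell barcode, UMI); each UMI casts one
majority-consensus allele vote, giving UMI counts
$r_c$ (ref) and $a_c$ (alt) and the three-way call

    ALT if a_c >= 1,  REF if a_c = 0 and r_c >= 1,  NO_CALL otherwise.

Around that core:

- spliced **distance to transcript end** on the canonical (MANE or
  longest) transcript: `dist_5p = tx_coord`,
  `dist_5p + dist_3p = L - 1`, intronic variants filtered;
- **internal poly-A mispriming** scan (maximal A-run >= 6 nt, or 10-nt
  window >= 80% A) and the resulting *effective* capture distance;
- **detection statistics**: per-variant detection fraction
  (cells with >= 1 UMI at the site), stratified by kit-matched end
  distance (<= 100 bp, <= 1,000 bp, beyond) and by mean log-normalized
  expression (> 0.1, > 5), at a 5%-of-nuclei detection criterion;
- **null-variant false-positive rate**: per-variant rate of ALT calls
  at positions genuinely absent from the sample;
- **per-cell-type VAF** `n_alt / (n_alt + n_ref)` with NO_CALL excluded
  from the denominator, plus the all-cells ALT fraction for comparison
  with bulk VAF;
- **cross-kit genotyped fractions** (3' vs 5') for the same variant;
- **developmental-origin classification**: ALT evidence in >= 2 germ
  layers implies a pre-gastrulation origin;
- expression QC (`ln(1 + 10^4 x/total)` normalization, percent-mito
  filtering at 5%), cross-dataset concordance (r, r^2), and the marker
  efficacy score `sum(d^2)/sum(d)` over cluster proportion differences;
- a **synthetic read simulator** (genome, GTF, VCF, tagged BAM, MTX
  counts, truth tables) emulating end-biased capture at 91/90 nt,
  negative-binomial expression, mosaic variants, internal poly-A
  mispriming, sequencing error, and UMI duplication — so the entire
  pipeline is testable with known ground truth and no patient data.

## Worked example

Simulate a 500-nucleus 5'-chemistry experiment with a mosaic variant
50 nt from the 5' end, genotype it, and classify its origin:

```r
library(dropGeno)

cfg <- simConfig(nCells = 500, nGenes = 4, exprMean = 3,
                 kitEnd = "five_prime",
                 transcriptLengthRange = c(1500, 1500),
                 mosaicFraction = 0.05, seed = 42)
sim <- simulateDataset(
    cfg,
    variantSpec = data.frame(gene_id = "gene001", tx_coord = 50,
                             role = "somatic_candidate"),
    outdir = file.path(tempdir(), "demo"))

variants <- readVariantSites(sim$paths$vcf)
gm <- countAlleles(sim$paths$bam, variants,
                   countingParams(barcodes = sim$cellTable$barcode))
gm
#> GenotypeMatrices: 1 variants x 500 cells
#>   calls: REF 408  ALT 24  NO_CALL 68

ts <- loadAnnotation(sim$paths$gtf)
variantDistances(variants, ts)
#> DataFrame with 1 row and 6 columns
#>     variant_id transcript_id  tx_coord   dist_5p   dist_3p      status
#>    <character>   <character> <integer> <integer> <integer> <character>
#> 1 chrS:551_A>G         tx001        50        50      1449      exonic

detectionFraction(gm)
#> chrS:551_A>G
#>        0.864
```

86% of nuclei have UMI coverage of the site (it sits inside the 90-nt
5' read window of a well-expressed gene), and 24 of the 432 genotyped
nuclei are ALT — an overall ALT-cell fraction of 4.8%, recovering the
simulated 5% mosaic fraction. Per cell type:

```r
meta <- data.frame(barcode = sim$cellTable$barcode,
                   cluster = sim$cellTable$cell_type)
vaf <- perClusterVaf(annotateCalls(gm, meta, kit = "5p"))
head(vaf[order(-vaf$n_alt),
         c("cluster", "n_alt", "n_ref", "n_nocall", "vaf")], 6)
#>                     cluster n_alt n_ref n_nocall        vaf
#> 10                      ALL    24   408       68 0.05555556
#> 3        Excitatory Neurons     7   133       19 0.05000000
#> 8          Oligodendrocytes     5    91       16 0.05208333
#> 5  MGE-Derived Interneurons     4    23        3 0.14814815
#> 1                Astrocytes     3    46        8 0.06122449
#> 6                 Microglia     2    40        4 0.04761905

classifyOrigin(vaf)[c("classification", "layers_with_alt")]
#> $classification
#> [1] "pre_gastrulation"
#>
#> $layers_with_alt
#> [1] "ectoderm" "mesoderm"
```

ALT nuclei appear in both ectoderm-derived (neurons, glia) and
mesoderm-derived (microglia) cell types, so the variant is classified
as arising before gastrulation.

A YAML-driven end-to-end run (simulate → genotype → annotate →
mispriming → evaluate → lineage, with a checksummed JSON manifest) is
available as `runAll("config.yaml")`, and a thin command-line wrapper
ships in `inst/scripts/dropgeno.R`.

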