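# polyArray

Single-locus SNP assay design and genotype-cluster analysis for
allopolyploid genomes.

## The problem

Allopolyploid crops such as oilseed rape (*Brassica napus*, genomes
A + C) defeat naive SNP array design: the two resident subgenomes are so
similar that a 50-bp assay probe frequently hybridises to both
homoeologous loci, and the resulting two-colour intensity patterns are
compressed, shifted, or split into four-to-five clusters that routine
genotype-calling software cannot resolve. polyArray is for researchers
building or analysing Infinium-style genotyping arrays in polyploids: it
implements the complete desk side of the design — candidate filtering,
probe-uniqueness ranking, cluster-pattern classification and rescue, and
genetic/physical map reconciliation — plus simulators that generate every
input with known truth.

## What it computes

* **Aggregation** — per-genotype variant calls (VCF) and coverage (BED)
  become a sites x genotypes `SNPSummaryMatrix`. A cell is MISSING below
  the platform depth minimum (3x long-read, 8x short-read), REFERENCE
  when covered without a variant, and otherwise HET when the alternate
  read fraction lies in [0.2, 0.8], HOM_VARIANT above. Panel statistics
  per site: missing fraction, het fraction, and alternate allele
  frequency with HET counted as half an allele.
* **Filter cascade** — five independent predicates with first-failure
  attribution and a telescoping attrition report: variant-free 60-bp
  flank on at least one side; at most two alleles; missing <= 0.70, het
  <= 0.40, frequency in [0.2, 0.8]; external design score >= 0.6;
  transversion exclusion (default: only the two-bead A/T and C/G pairs).
* **Probes** — 50-bp probes abutting the SNP on each clean side; a probe
  matches a genomic locus when **35 consecutive bp align exactly** on
  either strand (overlapping hits merge into one locus). SNPs are ranked
  by match count, fewest first, capped at 2 by default.
* **Clusters** — polar normalisation theta = (2/pi)·atan2(Y, X),
  R = X + Y; per-SNP 1-D Gaussian mixtures over theta (BIC, K <= 5);
  six-way pattern taxonomy (genome-specific separation > 0.6 between
  extreme cluster means; shifted clusters confined to one half of theta
  space; multi-cluster heterozygote excess; presence/absence separation
  in R; monomorphic; failed). Shifted assays — a monomorphic homoeolog
  co-hybridising, true genotypes AAAA/AAAB/AABB — are rescued by
  relabelling, calls use a responsibility-margin confidence with a 0.05
  no-call threshold, and species-specific diploid cluster files are
  derived by refitting.
* **Mapping** — doubled-haploid recombinant fractions, Kosambi distances
  d = 25·ln((1+2r)/(1−2r)) cM, co-segregation bins, physical anchoring at
  >= 85 % identity, per-linkage-group density statistics (markers/cM,
  cM/marker, Kb/marker), homoeology-aware concordance classification
  (concordant / homoeologous / discordant) and translocated-segment
  detection.

## Worked example

Simulate an allotetraploid design study end to end and reproduce a
published-style map-density table:

```r
library(polyArray)

cfg   <- simConfig(seed = 2024, nSNP = 500, nGenotypes = 20)
sim   <- simulateAllotetraploid(cfg)             # A+C reference, 3 % divergence
panel <- simulateVariantPanel(sim$reference, cfg)
ssm   <- aggregatePanel(panel$variantSets, sim$reference)
ssm
#> SNPSummaryMatrix: 500 candidate sites x 20 genotypes
#>   median missingFrac 0.05 | median altFreq 0.474

cands <- addDesignScores(annotateFlanks(ssm, sim$reference),
                         panel$designScores)
runCascade(cands)$report
#>           step excluded remaining
#> 1         none        0       500
#> 2     flanking       10       490
#> 3 multiallelic       25       465
#> 4   confidence       75       390
#> 5 design_score       25       365
#> 6 transversion       25       340
```

Each exclusion count equals the simulator's planted truth exactly. The
340 survivors yield probes whose genome-wide match counts split into 227
unique and 113 twice-matching assays (`probeTable()`,
`snpMatchCounts()`, `rankAndSelect()`) — the two classes an array design
admits.

Density statistics recomputed from a published per-linkage-group count
table (shipped in `inst/extdata/`):

```r
counts <- read.table(system.file("extdata", "brassica_dh_map_counts.tsv",
                                 package = "polyArray"),
                     sep = "\t", header = TRUE)
st <- mapDensityStats(counts)
st[st$lg %in% c("A1", "C5", "Total"),
   c("lg", "mappedLoci", "mapCm", "markersPerCm", "cmPerMarker",
     "kbPerMarker")]
#>     lg mappedLoci  mapCm markersPerCm cmPerMarker kbPerMarker
#>     A1        913   75.9        12.03        0.08       10.14
#>     C5        651  124.4         5.23        0.19       30.45
#>  Total      21766 1814.9        11.99        0.08       14.59
```

21,766 genetically mapped loci over 1,814.9 cM give 11.99 markers per cM
(one marker every 0.08 cM); 49,744 physically positioned loci over
725,833 Kb give one marker every 14.59 Kb.

A command-line front end over the same functions is installed at
`inst/scripts/polyarray.R` (subcommands `aggregate`, `filter`, `probes`,
`select`, `cluster-fit`, `cluster-call`, `map-stats`, `concordance`,
`simulate`).

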