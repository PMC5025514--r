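---
title: "Designing single-locus SNP assays for allopolyploid genomes with polyArray"
author: "polyArray authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing single-locus SNP assays for allopolyploid genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

An allotetraploid such as oilseed rape carries two complete ancestral
genomes (A and C) in one nucleus. Hybridisation-based genotyping assays
interrogate a locus with a 50-bp probe, and at typical homoeologous
divergence a large fraction of candidate probes bind both subgenomes at
once. The consequences are visible in two-colour intensity space: instead
of three clean genotype clusters (AA, AB, BB) spanning the normalised
allele-signal axis, assays show compressed, shifted, or four-to-five
cluster patterns that routine software mis-calls. polyArray implements the
desk side of designing such an array and analysing its output: filtering
millions of candidate variants down to single-locus assays, quantifying
probe uniqueness, classifying and rescuing cluster patterns, and
reconciling genetic with physical marker positions.

## Panel aggregation and site calling

Per-genotype variant calls (VCF) and coverage intervals (BED) are merged
into a sites-by-genotypes `SNPSummaryMatrix` (a
`RangedSummarizedExperiment`). Each cell is classified by a total rule:

* MISSING if the position is uncovered, or a variant record falls below
  the platform depth minimum — 3x for long-read 454-type data, 8x for
  short-read Illumina-type data;
* REFERENCE if covered with no variant record;
* otherwise the alternate-read fraction decides: within the heterozygote
  band [0.2, 0.8] the call is HET, above it HOM_VARIANT, below it
  REFERENCE.

The within-genotype heterozygote band is a package decision (the
aggregation convention in the original pipelines is not fully specified);
it mirrors the panel-level allele-frequency band and is configurable via
`depthThresholds()`. Panel statistics per site are the missing fraction,
the heterozygote fraction among non-missing calls, and the alternate
allele frequency among non-missing calls with HET counted as half an
allele — the second unresolved convention, also configurable. Sites whose
reference allele disagrees with the reference sequence are flagged and
retained with a warning, because merged panels from mixed pipelines
commonly contain such rows.

Coordinates are 1-based closed internally (the IRanges idiom); BED
half-open and VCF 1-based conventions are converted at the I/O boundary
only.

## The five-step filter cascade

`runCascade()` applies five independent predicates in a configurable
order and attributes every exclusion to the first failing step, producing
a telescoping attrition report (`step, excluded, remaining`):

1. **Flanking sequence** — at least one side of the SNP must offer 60 bp
   with no other panel variant, no N, and no chromosome edge.
2. **Multi-allele** — more than two total alleles cannot be assayed by
   single-base extension chemistry.
3. **Confidence** — excluded when missing fraction > 0.70, heterozygote
   fraction > 0.40, or allele frequency outside [0.2, 0.8].
4. **Design score** — an externally supplied per-SNP designability score
   in [0, 1]; scores < 0.6 are excluded. The score is consumed as an
   opaque column; no attempt is made to re-create any vendor scorer.
5. **Transversions** — under the default `AT_CG_ONLY` mode only A/T and
   C/G pairs are excluded: these are the pairs that cannot be resolved by
   two-colour chemistry with one bead type and therefore consume two
   beads per assay. A literal `ALL_TRANSVERSIONS` mode is provided; the
   narrow default reflects how small this attrition step is in practice
   relative to the number of true transversions.

All inequalities are strict, so exact-boundary candidates (frequency
exactly 0.8, score exactly 0.6, missing exactly 0.70) pass. Because the
predicates are independent, the survivor set is invariant under
permutation of the step order — a property the tests exercise — while
the per-step attribution depends on the order, as in any published
attrition table.

## Probe extraction and uniqueness

Each surviving SNP yields up to two candidate probes: the 50 bp
immediately upstream on the forward strand and the 50 bp immediately
downstream as a reverse complement, so that the probe's 3' end always
abuts the SNP base (which the probe excludes — single-base extension
reads the SNP position itself). Only flank sides that passed the
flanking-sequence filter
are eligible. Allele pair A/T or C/G marks the assay `INFINIUM_I` (two
beads), all other pairs `INFINIUM_II`.

`countProbeMatches()` counts the distinct genomic loci sharing an exact
common substring of at least 35 consecutive bp with the probe, on either
strand. Matching is implemented by constant-width dictionary search
(Biostrings `PDict`) over every 35-bp window of the probe; hits are
projected to forward coordinates, and overlapping or abutting hit
intervals are merged so that one locus is counted once regardless of how
many windows or strands hit it. The count always includes the source
locus. Exactness (no mismatches within the run) is a deliberate
simplification relative to mismatch-tolerant aligners; the contract is
equivalence with a brute-force all-windows oracle, which the test suite
checks on planted-repeat genomes including the 34-vs-35 boundary.

A SNP's match count is the minimum over its candidate probes (the design
picks the best side; a `max` combiner is available for conservatism).
`rankAndSelect()` prefers the fewest matches, breaks ties by design score
then id, caps the admitted match count (default 2: unique plus
twice-matching loci), and supports per-class quotas and minimum genomic
spacing.

## Cluster fitting, the pattern taxonomy, and rescue

Raw two-colour signal is polar-normalised: theta = (2/pi)·atan2(Y, X) in
[0, 1] and R = X + Y. The per-SNP model is a one-dimensional Gaussian
mixture over theta, fitted for K = 1..5 with equal- and unequal-variance
models and selected by BIC (mclust). R is used only for the low-intensity
and presence/absence decisions; one-dimensional fitting keeps the model
identifiable on small panels, and two-dimensional fitting is a possible
extension. The fit is deterministic, so cluster files are reproducible.

Two numerical details matter:

* **Truncation coalescing.** Theta is bounded, so extreme clouds develop
  point masses at 0 and 1 that BIC happily fits as additional
  near-zero-variance components. Components whose means are closer than
  `mergeTol = 0.12` are therefore coalesced (moment-matched) after the
  fit. The bound comes from the geometry of the taxonomy: even the most
  compressed legitimate pattern places three genotype clouds within half
  the theta space, i.e. roughly 0.16 apart, so sub-components closer
  than 0.12 cannot be distinct genotype clouds.
* **No-signal cells.** Samples with R below `rLowThreshold = 0.2` (on a
  scale where a full-signal assay sits near R = 1) are excluded from the
  fit and carry assignment 0. The low-intensity criterion — fail the SNP
  outright when more than half the samples are dark — is a package
  decision; the source pipelines removed such assays by manual review
  without a stated threshold.

Classification follows a fixed precedence (the taxonomy in the field is
descriptive, not algorithmic, so an order had to be chosen):
low-intensity, presence/absence, multi-cluster, genome-specific, shifted,
monomorphic.

* `FAILED_LOW_INTENSITY`: more than 50 % dark samples.
* `PRESENCE_ABSENCE`: 10-50 % dark samples with the lit samples forming
  clusters within a 0.3 theta span — one allele yields no fluorescence,
  so genotypes separate in R at a single theta position; heterozygotes
  are undetectable and calls are made by signal versus no-signal.
* `MULTI_CLUSTER_UNRESOLVABLE`: four or more components, or three with a
  middle-component weight above 0.6 (both homoeologous loci segregating
  produces four-to-five clusters with a large apparent heterozygote
  excess). Two-to-three-component models that neither span theta nor fit
  one half also land here — the taxonomy must be total.
* `GENOME_SPECIFIC`: two or three components whose extreme means differ
  by more than 0.6. The rule is applied to the extreme components rather
  than requiring exactly three clusters so that doubled-haploid panels,
  which lack an AB cloud, still qualify — a documented divergence from a
  strictly three-cluster reading.
* `SHIFTED`: two or more components confined to one half of theta space.
  This is the signature of a monomorphic co-hybridising homoeolog: the
  true genotypes (effectively AAAA / AAAB / AABB) are compressed and
  mislabelled by routine analysis. `rescueShifted()` automates the manual
  curation that makes such assays scorable: extreme components are
  relabelled AA and BB, the middle one AB, and sample-to-component
  assignments are untouched (the tests assert bit-identity).
* `MONOMORPHIC`: a single cloud with signal; scorable but
  non-polymorphic.

Genotypes are called by maximum responsibility among labelled components.
The confidence score is the margin between the best and second-best
labelled responsibility, a transparent analog of proprietary calling
scores: a sample equidistant between two clouds scores zero. Calls below
the no-call threshold (default 0.05, the conventional production setting)
become NO_CALL, which makes the call rate monotone in the threshold.

Cluster files are JSON (components, labels, pattern, scorability,
assignments) and round-trip exactly; proprietary binary formats are
deliberately not produced. `deriveDiploidClusterFile()` refits every SNP
on the samples of one ancestral diploid species: assays specific to the
other subgenome lose their target and collapse to no-signal; assays that
were homoeolog-compressed in the tetraploid resolve to well-separated
clusters; residual shifted fits are relabelled. The per-species summary
reports scorable and polymorphic counts.

## Genetic maps and physical concordance

The mapping module measures a supplied marker order — it does not search
order space, since de novo ordering is a separate, well-served problem.
For doubled-haploid lines the recombinant fraction between two markers is
the fraction of discordant lines among jointly non-missing lines, and map
distances use the Kosambi function d = 25·ln((1+2r)/(1−2r)) cM with exact
inverse r = tanh(d/50)/2 (round-trip verified to 1e-12).

Bins: consecutive markers merge when their genotype vectors agree on
every jointly non-missing line *and* at least one line is jointly
informative. Missing data act as wildcards, but the joint-information
requirement prevents vacuous merges through all-missing markers — the
convention is a package decision where the field's practice is silent.

Physical anchoring keeps the best alignment hit per marker at >= 85 %
identity; co-optimal hits on different chromosomes are flagged ambiguous
(the marker could sit on either homoeolog), and markers below threshold
stay unanchored. `computeMapStats()` reports per-linkage-group bin
counts, locus counts, physical spans and the three density statistics
(markers/cM, cM/marker, Kb/marker), rounded half-up to two decimals as
printed map tables conventionally are, plus gap lists (genetic gaps >= 9
cM; physical intervals > 500 Kb by default). `mapDensityStats()` applies
the same arithmetic directly to a table of printed per-LG counts, which
is how the package reproduces published density statistics.

`classifyConcordance()` labels each mapped marker CONCORDANT (anchored to
the chromosome expected for its linkage group), HOMOEOLOGOUS (anchored to
that chromosome's homoeologous partner — the signature of homoeologous
exchange or cross-subgenome mis-anchoring), DISCORDANT, or UNANCHORED.
Homoeology is a user-supplied chromosome pairing table, defaulting to
numbered A-C pairs, because true homoeology in real genomes is
block-level; fractions are reported over classified markers and sum to 1.
`detectSegments()` then scans each linkage group in map order for runs of
at least three consecutive non-concordant markers sharing one alternate
chromosome — the signature of a translocated or mis-assembled segment —
and reports genetic and physical extents.

## What the simulators emulate — and what they do not

Every pipeline input can be generated with recorded truth
(`simulateAllotetraploid()`, `simulateVariantPanel()`,
`simulateIntensities()`, `simulateDiploidIntensities()`,
`simulateDH()`), and all generators are byte-deterministic under a fixed
seed.

* **Reference**: subgenome A is uniform-random; subgenome C is derived by
  per-bp substitution at the configured divergence (default 3 %, a
  realistic homoeologous divergence for recently merged subgenomes), so
  homoeologous coordinates align trivially. Desk-scale defaults: two
  chromosomes of 100 kb per subgenome.
* **Variant panel**: sites are planted on a spaced grid with
  deterministic per-class call compositions so that each planted failure
  mode fails exactly its intended filter step (flank-contaminated
  victims receive secondary variants in both flanks; the contaminating
  sites keep one clean side and survive). The default panel is 20
  genotypes, a quarter on the long-read platform, with 5 % missing and
  10 % heterozygous calls at clean sites.
* **Intensities**: each SNP draws one of the six pattern classes
  (defaults: 60 % genome-specific, 15 % shifted, 10 % unresolvable, 5 %
  each presence/absence, monomorphic and failed — the genome-specific
  share reflecting what a probe-uniqueness-optimised array achieves).
  Cloud geometries use extreme means 0.04/0.96, a central heterozygote
  cloud, shifted triplets compressed into one half of theta space, and
  five-component layouts with inflated middle weights for the
  unresolvable class. Genotype-cloud weights are 0.4/0.2/0.4,
  modelling the largely homozygous inbred-line diversity panels that
  cluster files are actually built from. Gaussian theta noise (default
  sd 0.03) is applied and values clamped to [0, 1], which is exactly the
  truncation the coalescing rule exists for.
* **DH population**: 124 lines by default (a typical doubled-haploid
  mapping population size), crossovers placed independently per interval
  with recombination fractions from the inverse Kosambi distance of the
  true map. No crossover interference is simulated — Kosambi is used
  only as the distance scale — so recovery tests tolerate the resulting
  small mismatch. Anchors follow the genetic order at 400 Kb/cM with a
  configurable fraction of homoeologous swaps and an optional
  translocated block.

The simulators do **not** emulate: linkage disequilibrium or population
structure; realistic repeat landscapes or GC composition (uniform base
draw); read-level sequencing error (variant calls are planted, not
called from reads); crossover interference; batch or laboratory effects
in intensity data; or block-level homoeologous exchange within
chromosomes. Passing recovery tests therefore demonstrates correctness
of the algorithms under the stated generative model, not performance on
any particular real data set.

## Problem sizes and numerical conventions

The test and acceptance runs use desk-scale sizes chosen to exercise
every code path with comfortable statistical resolution: 400-kb
simulated tetraploid genomes, 1,000-site variant fixtures, intensity
panels of up to 600 SNPs by 200 samples at noise sd 0.05, and
doubled-haploid populations of 124 lines across four 90-cM linkage
groups. Reported density statistics are rounded half away from zero at
two decimals (`roundHalfUp()`); R's default half-to-even rounding would
disagree with printed tables on boundary values. All fits and
simulations are deterministic given the seed: mixture fitting uses
deterministic hierarchical initialisation, and every generator derives
its RNG stream from the mandatory `simConfig(seed = )`.

## Known limitations

* Probe matching is exact-substring; a mismatch-tolerant rule (as
  alignment tools implement) would count slightly more multi-locus
  probes at high divergence.
* The mixture is one-dimensional in theta; presence/absence detection
  uses simple R thresholds rather than a joint 2-D model.
* Confidence scores are responsibility margins, not calibrated
  probabilities; the 0.05 no-call threshold retains its conventional
  semantics but is not numerically comparable to proprietary scores.
* The bin rule treats missing data as wildcards; heavily missing markers
  can chain into one bin through sparse overlap.
* Marker ordering is validated, not estimated.
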