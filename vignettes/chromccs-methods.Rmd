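---
title: "Methods: comparative chromatin accessibility analysis of the cardiac conduction system"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative chromatin accessibility analysis of the cardiac conduction system}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromccs)
```

# The analytical problem

The cardiac conduction system (CCS) — sinoatrial node (SAN), atrioventricular
node (AVN) and ventricular conduction system (VCS) — makes up a tiny fraction
of the heart's cells, so its cis-regulatory elements are diluted out of
whole-heart accessibility maps. Given per-component ATAC-Seq peak sets plus a
working-cardiomyocyte (CM) background set, `chromccs` implements the
downstream comparative analysis: which regions are open or closed where,
which transcription-factor (TF) motifs and networks distinguish each
component, which distal elements behave like component-enriched enhancers and
which genes they plausibly regulate, and whether cardiac-rhythm GWAS variants
concentrate in those elements.

All coordinates are 0-based, half-open (BED convention) everywhere inside the
package; 1-based inputs (SNP tables) are converted on read and re-emitted
1-based. A single internal convention eliminates off-by-one drift between
stages. Strand is carried through interval sets but ignored in overlap
computations, because chromatin accessibility is unstranded.

# Interval algebra

Interval sets are normalized (sorted, overlapping and bookended records
fused) on construction; the algebra itself — merging with a gap tolerance,
element-level intersection, n-way membership partitioning of the
nonredundant union, set difference against a universe — is delegated to
`GenomicRanges`/`IRanges` behind the package's own surface, and the test
suite checks every operation against an independent per-basepair
boolean-array implementation on 10^5-bp chromosomes.

Decisions worth making explicit:

* **Overlap means >= 1 shared basepair** by default. No reciprocal-overlap
  requirement is imposed; the minimum shared-bp count is a parameter
  (`min_overlap_bp`) wherever presence is called.
* **Intersection is element-level and asymmetric**: `intersect_intervals(a, b)`
  returns the regions of `a` that touch `b`, with `a`'s coordinates intact.
  This matches how peak-set overlap percentages are reported in the field.
* **Partition counting is region-level on the union** (the convention behind
  proportional multi-set overlap diagrams); basepair totals per class are
  also reported because figure conventions vary. The all-zero signature
  cannot occur by construction and is asserted against.
* **Proximal vs distal** uses a +/-2 kb window around each TSS by default.
  Published analyses of this kind cite established cutoffs without always
  printing them; 2 kb is the common promoter-window choice, and the cutoff
  is a parameter (`cutoff_bp`) rather than a constant.

# Occupancy classification

The master region list is the merged union of the four sample peak sets; each
master region gets one presence bit per sample in the fixed order
(CM, SAN, AVN, VCS). "Open in a sample" means the sample's reproducible peak
set overlaps the region — presence/absence of a called peak, not a
signal-level criterion; replicate reconciliation (`reconcile_replicates`,
region kept iff present in both replicates) is available as a pre-step.

The category of a region is a pure function of its bit pattern. Nine named
patterns cover full sharing, CCS-wide opening/closing and single-component
opening/closing; the six remaining attainable patterns are `Mixed`:

| pattern (CM,SAN,AVN,VCS) | category |
|---|---|
| 1111 | Shared |
| 0111 | CCS Open |
| 1000 | CCS Closed |
| 0100 / 1011 | SAN Open / SAN Closed |
| 0010 / 1101 | AVN Open / AVN Closed |
| 0001 / 1110 | VCS Open / VCS Closed |
| other (6 patterns) | Mixed |

Component "Open" categories take the strictest reading of uniqueness: the
component is open while CM *and* the other two CCS components are closed. A
`lenient` flag relaxes this: patterns with CM closed and two (but not all
three) CCS components open are assigned `CCS Open`, and the mirrored CM-open
patterns `CCS Closed`, instead of `Mixed`. The strict table is the default
and the tested path. A property test enumerates all 15 attainable patterns
and asserts the classification is exhaustive and mutually exclusive.

# Motif scanning and networks

A position weight matrix is a 4 x W column-stochastic matrix over
(A, C, G, T); a hit's score is the summed per-column log2 odds against the
background (bits). Scanning covers both strands (a minus-strand hit scores
the window's reverse complement, implemented by scanning with the
row-complemented, column-reversed matrix) and skips windows containing N.
Numerical choices:

* When any PWM column contains a zero, 0.25 is added to every cell before
  renormalization, so every log-odds entry is finite. Background defaults to
  uniform 0.25 per base.
* The default hit threshold is 0.8 x the PWM's maximum achievable score. No
  published threshold exists for this kind of analysis; 0.8 of maximum is a
  common stringent default, and the threshold is a parameter everywhere.
* Overlapping hits of one PWM are all retained (no greedy masking).

Motif fold-enrichment of a target region set over a background is the ratio
of the fractions of regions containing >= 1 hit, with a one-sided
hypergeometric p-value on region counts; PWMs are reported sorted by fold.
GGAA microsatellites — candidate ETS-family binding substrates — are found
as maximal non-overlapping tandem runs of GGAA (and TTCC on the reverse
strand) with a minimum unit count.

Networks are built from gene-proximal accessible chromatin: for each gene,
the component's peaks within `cutoff_bp` of the TSS are scanned with each
PWM, and the TF-gene interaction score is the sum of hit bit-scores over
those regions (hit count is available behind `metric = "count"`; the exact
aggregate used in published network constructions is not printed, and the
sum of scores is the natural additive choice). TF connectivity is the number
of distinct target genes — not summed scores — and components are ranked
against the CM network by the connectivity difference, ties broken by
component connectivity then TF name, so the ranking is fully deterministic.

De novo motif discovery is out of scope by design: the package scans a known
panel. The bundled `default_pwm_panel()` consists of eight synthetic
consensus-built matrices named for the motif families prominent in
conduction-system chromatin (ETS, MEF2, homeobox, bHLH, T-box, GATA, SCRT,
SP); they are constructed in code and are not database matrices.

# Enhancer prioritization

Candidate enhancers per component are distal accessible regions overlapping
the union of the supplied H3K27ac catalogs ("across development" is modeled
as the pooled union). Assignment against a validated-enhancer (VISTA-like)
catalog is a 4-way overlap: each element gets the subset of candidate sets
touching it, and an element is **CCS-enriched** iff it overlaps at least one
CCS component and *not* CM — absence of CM overlap is required, matching the
published sharing arithmetic.

Hit-rate comparisons use a two-sided Fisher exact test computed by
hypergeometric point-mass summation (all tables with fixed margins whose
probability does not exceed the observed table's); the test suite checks the
p-value against both an independent log-choose enumeration and
`stats::fisher.test` to 1e-12. Percentages in reports are rounded half away
from zero to match printed formatting.

Target nomination for an enhancer considers genes whose TSS lies within
`window_bp` (default 500 kb each side; 1 Mb is the documented alternative
used in some text descriptions) of the enhancer span, keeps those with a
component-vs-CM expression-enrichment ratio >= `enrichment_threshold`
(default 1.5; no published threshold exists, so it is a flagged parameter),
and ranks contact-supported genes (a promoter-capture contact linking the
gene's promoter to an interval overlapping the enhancer) above the rest,
then by enrichment. Genes absent from the expression table count as
enrichment 0 with a warning.

# Variant annotation

Liftover is block-based: a position maps iff it falls inside exactly one
alignment block; plus-strand blocks map by offset, minus-strand blocks
reverse the offset. UCSC chain files are parsed into the simplified
six-column block table that is the package's canonical map format; the map
is invertible and round-trips positions exactly.

The landing frequency of a SNP set in a region set is the count of mapped
single-basepair positions inside the set divided by the set's total
basepairs (merged; the published denominator convention is not stated, and
merged totals are the well-defined choice). Fold enrichment divides by a
baseline rate, by default the whole-genome rate n/G with G = 2.7e9 bp — a
configuration constant rather than a value derived from any FASTA, so the
worked example (607 SNPs / 2.7e9 bp = 2.2e-7 at two significant figures)
is reproducible bit-for-bit. Nested reporting follows the convention of
fold vs genome for the background set and additionally fold vs that
background for the enriched set. No linkage-disequilibrium expansion is
applied: the single mapped basepair either lands in a set or does not.

The trend statistic across ordered (hits, set_bp) pairs is the
Cochran-Armitage chi-square test for trend with equally spaced scores
(`stats::prop.trend.test`); pairwise comparisons use the 1-df chi-square
without continuity correction by default (correction behind a flag — the
test family is standard, the correction choice is not dictated). For two
sets the trend statistic algebraically equals the 2x2 chi-square, which the
suite asserts. Trait subsets pair heart rate with SAN, PR interval with AVN,
QRS interval with the AVN and VCS sets combined (pathology anywhere from the
AVN to the proximal bundle branches prolongs QRS), and QT interval with VCS.

Allele-effect scoring extracts the sequence around a mapped variant, scores
every window covering the variant on both strands with the reference base
and again with the alternate base, and reports the best score per allele and
their difference in bits; a negative delta means the alternate allele
weakens the best motif match. A reference-allele mismatch against the genome
is a hard error naming the position.

# The synthetic study generator

`simulate_study()` generates every input the pipeline consumes, with the
planted structure recorded as ground truth. It emulates the *downstream
summaries* of a multi-component accessibility study — peak BEDs, catalogs,
expression-enrichment and contact tables, SNP tables — not raw reads, and
its defaults are fixed once as the desk-scale study conditions:

* 3 chromosomes x 1 Mb, 600 master regions (widths ~N(400, 80) bp,
  non-overlapping), 60 genes, 600 SNPs, an 8-motif panel.
* Category mixture anchored at 39% fully shared regions — the approximate
  shared fraction reported for this kind of four-way comparison — with the
  remaining mass spread over the named categories and a 15% `Mixed` class
  drawn from the six unnamed patterns so that branch is always exercised.
* Planted motif: the ETS-family consensus embedded with probability 0.8
  into each gene-proximal SAN-open region and nowhere else (chance
  consensus matches in uniform background remain possible and are part of
  what the recovery tests tolerate).
* Planted SNP enrichment: each SNP lands in planted set k with probability
  fold_k x set_bp_k / G (uniform within the set), the rest uniformly over
  the complement, so the measured fold estimates fold_k directly; default
  folds are 5, 16 and 100 over the three disjoint component-open region
  sets. The coordinate map is identity-valued over 10-kb blocks with a
  configurable unmappable fraction (default 0, so all 600 SNPs map and fold
  recovery is assessed at n = 600; the ~50%-unmappable scenario typical of
  cross-species mapping is exercised in the test suite).
* Catalogs: H3K27ac-like regions cover 70% of distal peaks plus decoys in
  inter-region gaps; validated-enhancer elements sit on covered distal
  regions with known component subsets; every CCS-enriched element gets a
  true target gene (nearest gene) with expression enrichment above
  threshold and a supporting contact, while decoy genes stay strictly below
  threshold and decoy contacts link random gene-element pairs at rate 0.05.

One RNG stream per artifact class (regions, categories, genes, genome,
planting, SNPs, map, catalogs) is derived from the master seed, so changing
e.g. the SNP count does not perturb the peak layout; identical
configurations produce byte-identical files. An internal audit validates
every ground-truth entry against the generated artifacts before a fixture is
handed out.

What the generator does *not* emulate — realistic nucleotide composition,
signal-level accessibility, correlated peak structure, LD between variants —
bounds what passing recovery tests show about real data: they demonstrate
that the implementation measures what was planted, not that real studies
have this structure.

# Calibration and recovery checks

The test suite measures, among others:

* exact recovery of planted occupancy categories (the construction is
  deterministic);
* planted SNP folds {5, 16, 100} recovered within 3 binomial standard
  errors at 600 SNPs;
* the planted TF ranked first in >= 95% of 100 seeded replicates of the
  network construction (replicates use a reduced scale — one 150-kb
  chromosome, 60 regions, 15 genes, a 4-motif panel, with extra mass on the
  planted component's open category so every replicate contains plantable
  regions — chosen so the whole loop runs in seconds);
* the planted enhancer target ranked first for every planted pair under the
  deterministic construction (decoy contact rate 0); with decoy contacts at
  the default rate, occasional decoy-supported competitors are expected and
  the recovery percentage is reported rather than asserted;
* type-I error of the trend test within 3 standard errors of 0.05 over
  2,000 replicates of uniform SNP placement across three *disjoint* sets.
  Disjoint (not nested) sets are used because the Cochran-Armitage statistic
  assumes independent binomial strata; nested sets share counts and are not
  expected to be calibrated in the strict sense, which is worth remembering
  when reading nested trend p-values from real data.

Dataset-level counts from full-scale studies (tens of thousands of peaks,
genome-scale catalogs) are not reproducible at desk scale; the pipeline
emits the corresponding counts when full-scale inputs are supplied.

# Known limitations

* Binary presence/absence stands in for quantitative differential
  accessibility; no count-based DAR statistics are computed.
* Network edges rest on proximal motif presence only — distal regulation is
  deliberately underestimated, and interaction scores are not comparable
  across PWMs of different widths.
* The enhancer cascade inherits the coverage biases of the supplied
  H3K27ac catalogs; components with divergent regulatory repertoires (the
  SAN, notably) will be under-called.
* Liftover handles single-basepair variants only; no multi-bp or
  split-block mapping.
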