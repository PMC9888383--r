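# chromccs

Comparative chromatin-accessibility analysis for the cardiac conduction
system (CCS) — the sinoatrial node (SAN), atrioventricular node (AVN) and
ventricular conduction system (VCS) — against working cardiomyocytes (CM).

The CCS is a tiny fraction of the heart's cells, so its cis-regulatory
elements vanish into whole-heart maps. Given one ATAC-Seq peak BED per
component plus a CM background set, `chromccs` runs the downstream
comparative analysis end to end:

* **Interval algebra** — BED I/O, merging, element-level intersection,
  n-way membership partitioning of the nonredundant peak union,
  proximal/distal splitting around TSSs (0-based half-open coordinates
  throughout, built on GenomicRanges/IRanges).
* **Occupancy classification** — one presence bit per sample per union
  region and a truth-table category: `Shared`, `CCS/SAN/AVN/VCS Open` or
  `Closed`, or `Mixed`. For example, a region open in CM, SAN and AVN but
  closed in VCS is `VCS Closed`; open in CM only is `CCS Closed`.
* **Motifs and networks** — position-weight-matrix scanning on both strands
  (log2-odds bit scores), motif fold-enrichment ranking, GGAA-microsatellite
  detection, and TF→gene network construction from gene-proximal accessible
  motif hits, with TFs ranked by connectivity gain over the CM network.
* **Enhancer prioritization** — distal regions ∩ H3K27ac catalogs, 4-way
  assignment against a validated-enhancer (VISTA-like) catalog with
  CCS-enrichment calls, Fisher exact hit-rate comparisons (hypergeometric
  enumeration), and target-gene nomination with window, expression and
  promoter-contact filters.
* **Variant annotation** — block-based liftover (UCSC chain or simplified
  block table), per-basepair SNP landing frequency and fold enrichment
  (landing frequency = SNPs in set / set bp; fold = ratio to the n/G genome
  baseline), Cochran-Armitage trend and pairwise χ² tests, trait-component
  subsets (HR→SAN, PR→AVN, QRS→AVN∪VCS, QT→VCS), and allele-effect PWM
  scoring of single variants.
* **Synthetic study generator** — a fully deterministic, seeded generator of
  every input above with planted ground truth (categories, motif
  embeddings, SNP enrichment folds, enhancer targets) for
  parameter-recovery testing.

## Worked example

Generate a synthetic study, classify occupancy, and annotate SNPs:

```r
library(chromccs)

cfg <- synth_config(seed = 42)   # 3 x 1 Mb chromosomes, 600 regions, 600 SNPs
sim <- simulate_study(cfg)

occ <- build_occupancy(sim$master, sim$samples)
summarize_categories(occ)$counts
#>     Shared   CCS Open CCS Closed   SAN Open SAN Closed   AVN Open AVN Closed
#>        227         44         54         23         28         28         25
#>   VCS Open VCS Closed      Mixed
#>         46         27         98
```

227/600 ≈ 38% of union regions are open in all four samples; the planted
mixture put 39% of its mass on `Shared`, and recovery of the drawn
categories is exact (`identical(occ$category, sim$truth$regions$category)`).

The enhancer hit-rate comparison, with the counts of a published validation
experiment (18 of 22 tested elements active vs 14 of 53 historical
controls):

```r
hit_rate_comparison(18, 22, 14, 53)
#> hit rate: 18 of 22 (82%) vs control 14 of 53 (26%); Fisher exact p = 1.89e-05
```

SNP enrichment in a planted region set (planted fold 100):

```r
snps <- liftover_snps(sim$snps, sim$cmap)
landing_frequency(snps, sim$fold_sets[["VCS Open"]],
                  genome_bp = sum(cfg$chrom_sizes))
#>   set_label set_bp n_snps_total n_snps_in_set landing_frequency
#> 1  VCS Open  19102          600           385        0.02015496
#>   baseline_frequency fold_vs_baseline
#> 1              2e-04         100.7748
```

385 of 600 SNPs land in 19.1 kb of planted VCS-open chromatin: 0.020 SNPs/bp
against a genome baseline of 2×10⁻⁴, i.e. ~101-fold enrichment, recovering
the planted fold of 100.

A thin command-line wrapper over the pipeline stages
(`classify`, `grn`, `enhancers`, `snps`, `simulate`) is installed at
`inst/scripts/ccs_pipeline.R`.

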