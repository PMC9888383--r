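# small, fast configuration used throughout the generator tests
small_cfg <- function(seed = 1, ...) {
  args <- list(seed = seed,
               chrom_sizes = c(chr1 = 2e5, chr2 = 2e5),
               n_regions = 120, n_genes = 24, n_snps = 200,
               snp_fold = c("SAN Open" = 4, "AVN Open" = 8, "VCS Open" = 20),
               pwm_panel = default_pwm_panel()[c("ETS1", "MEF2A", "GATA4", "SP1")],
               n_vista = 12, n_h3k27ac_decoys = 10)
  over <- list(...)
  args[names(over)] <- over
  do.call(synth_config, args)
}

test_that("generation is fully deterministic given the seed", {
  a <- generate_peaksets(small_cfg(3))
  b <- generate_peaksets(small_cfg(3))
  expect_identical(a$truth, b$truth)
  genes <- generate_genes(small_cfg(3), a)
  g1 <- generate_genome_and_motifs(small_cfg(3), a, genes)
  g2 <- generate_genome_and_motifs(small_cfg(3), a, genes)
  expect_identical(g1$genome, g2$genome)
  cfg0 <- small_cfg(3, snp_fold = numeric())
  s1 <- generate_snps(cfg0, list(), genome = g1$genome)
  s2 <- generate_snps(cfg0, list(), genome = g1$genome)
  expect_identical(s1$snps, s2$snps)
})

test_that("degenerate mixtures produce the expected peak-set layouts", {
  shared_only <- c("Shared" = 1, stats::setNames(rep(0, 9),
                   setdiff(CCS_CATEGORIES, "Shared")))
  cfg <- small_cfg(2, category_mixture = shared_only)
  ps <- generate_peaksets(cfg)
  for (s in CCS_SAMPLES)
    expect_equal(as.data.frame(ps$samples[[s]])[1:3], as.data.frame(ps$master)[1:3],
                 ignore_attr = TRUE)

  closed_only <- c("CCS Closed" = 1, stats::setNames(rep(0, 9),
                   setdiff(CCS_CATEGORIES, "CCS Closed")))
  ps2 <- generate_peaksets(small_cfg(2, category_mixture = closed_only))
  expect_equal(nrow(ps2$samples$CM), nrow(ps2$master))
  expect_equal(nrow(ps2$samples$SAN), 0)
})

test_that("occupancy classification recovers every planted category exactly", {
  for (seed in 1:3) {
    ps <- generate_peaksets(small_cfg(seed))
    occ <- build_occupancy(ps$master, ps$samples)
    expect_identical(occ$category, ps$truth$category)
    s <- summarize_categories(occ)
    expect_equal(s$counts, stats::setNames(
      as.numeric(table(factor(ps$truth$category, levels = CCS_CATEGORIES))),
      CCS_CATEGORIES))
  }
})

test_that("planted motif embeddings are present verbatim; plant_prob 0 plants nothing", {
  cfg <- small_cfg(5)
  ps <- generate_peaksets(cfg)
  genes <- generate_genes(cfg, ps)
  gm <- generate_genome_and_motifs(cfg, ps, genes)
  expect_gt(nrow(gm$embeddings), 0)
  cons <- pwm_consensus(cfg$pwm_panel[["ETS1"]])
  for (i in seq_len(nrow(gm$embeddings)))
    expect_equal(get_sequence(gm$genome, gm$embeddings$chrom[i],
                              gm$embeddings$start[i], gm$embeddings$end[i]), cons)
  cfg0 <- small_cfg(5, plant_prob = 0)
  gm0 <- generate_genome_and_motifs(cfg0, ps, genes)
  expect_equal(nrow(gm0$embeddings), 0)
})

test_that("null SNP placement gives in-set frequencies near set_bp/genome_bp", {
  cfg <- small_cfg(7, n_snps = 2000,
                   snp_fold = c("Shared" = 1))
  ps <- generate_peaksets(cfg)
  occ <- build_occupancy(ps$master, ps$samples)
  shared <- category_regions(occ, "Shared")
  sn <- generate_snps(cfg, list("Shared" = shared))
  G <- sum(cfg$chrom_sizes)
  p0 <- total_bp(shared) / G
  n_in <- sum(sn$truth$planted_set == "Shared")
  se <- sqrt(2000 * p0 * (1 - p0))
  expect_lt(abs(n_in - 2000 * p0), 3 * se)
})

test_that("unmappable blocks reduce mapped SNPs binomially and liftover is identity elsewhere", {
  cfg <- small_cfg(9, n_snps = 1278, unmappable_frac = 0.5, snp_fold = numeric())
  ps <- generate_peaksets(cfg)
  sn <- generate_snps(cfg, list())
  out <- liftover_snps(sn$snps, sn$cmap)
  n_mapped <- sum(out$mapped)
  # conditional on the realized map, mapped counts are binomial with
  # p = covered fraction of the genome (block dropout is the dominant noise)
  p_cov <- sum(sn$cmap$src_end - sn$cmap$src_start) / sum(cfg$chrom_sizes)
  expect_lt(abs(p_cov - 0.5), 3 * 0.5 / sqrt(40))  # 40 blocks at 10 kb
  expect_lt(abs(n_mapped - 1278 * p_cov), 3 * sqrt(1278 * p_cov * (1 - p_cov)))
  # where mapped, the identity map preserves the drawn destination position
  expect_equal(out$mapped_pos[out$mapped],
               sn$truth$dst_pos[out$mapped])
  expect_equal(out$mapped, sn$truth$mappable)
})

test_that("catalog generation: full coverage retains every distal peak; truths validate", {
  cfg <- small_cfg(4, h3k27ac_cover = 1, n_h3k27ac_decoys = 0)
  ps <- generate_peaksets(cfg)
  genes <- generate_genes(cfg, ps)
  cats <- generate_catalogs_and_tables(cfg, ps, genes)
  for (s in c("SAN", "AVN", "VCS")) {
    res <- select_candidate_enhancers(ps$samples[[s]], genes,
                                      cutoff_bp = cfg$cutoff_bp,
                                      h3k27ac_catalogs = list(cats$h3k27ac))
    expect_equal(res$percent_overlap, 100)
  }
  # planted VISTA component subsets are recovered by assign_vista
  cand <- stats::setNames(lapply(CCS_SAMPLES, function(s)
    select_candidate_enhancers(ps$samples[[s]], genes, cfg$cutoff_bp,
                               list(cats$h3k27ac))$candidates), CCS_SAMPLES)
  asg <- assign_vista(cand, cats$vista)
  truth <- cats$truth[match(asg$vista_id, cats$truth$vista_id), ]
  expect_equal(asg$ccs_enriched, truth$ccs_enriched)
  recovered_frac <- mean(truth$ccs_enriched == asg$ccs_enriched)
  expect_equal(recovered_frac, 1)
})

test_that("simulate_study writes a complete, readable fixture directory", {
  dir <- withr::local_tempdir()
  sim <- simulate_study(small_cfg(6), dir = dir)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  back <- read_bed(file.path(dir, "peaks_SAN.bed"))
  expect_equal(nrow(back), nrow(sim$samples$SAN))
  genome <- read_genome_fasta(file.path(dir, "genome.fa"))
  expect_identical(genome, sim$genome)
  pwms <- read_jaspar(file.path(dir, "pwms.txt"))
  expect_equal(names(pwms), names(sim$config$pwm_panel))
  snps <- read_snp_table(file.path(dir, "snps.tsv"))
  expect_equal(snps$pos, sim$snps$pos)
  cmap <- read_block_map(file.path(dir, "blockmap.tsv"))
  expect_equal(nrow(cmap), nrow(sim$cmap))
  # rerunning with the same seed reproduces byte-identical key files
  dir2 <- withr::local_tempdir()
  simulate_study(small_cfg(6), dir = dir2)
  for (f in c("peaks_CM.bed", "genome.fa", "snps.tsv", "expression.tsv"))
    expect_identical(readLines(file.path(dir, f)), readLines(file.path(dir2, f)))
})
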