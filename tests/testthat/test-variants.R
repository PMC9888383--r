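make_map <- function(...) coordinate_map(data.frame(...))

test_that("liftover: identity map, misses, and minus-strand offset reversal", {
  cmap <- make_map(src_chrom = "hs1", src_start = 0, src_end = 1000,
                   dst_chrom = "chr1", dst_start = 0, dst_strand = "+")
  snps <- data.frame(snp_id = c("a", "b"), chrom = c("hs1", "hs2"),
                     pos = c(500, 10), ref = "A", alt = "C", trait = "HR")
  out <- liftover_snps(snps, cmap)
  expect_equal(out$mapped, c(TRUE, FALSE))
  expect_equal(out$mapped_pos[1], 500)
  expect_equal(out$reason[2], "no_block")

  neg <- make_map(src_chrom = "hs1", src_start = 100, src_end = 110,
                  dst_chrom = "chr1", dst_start = 50, dst_strand = "-")
  # exhaustive per-position check of the reversal
  for (k in 0:9) {
    s <- data.frame(snp_id = "x", chrom = "hs1", pos = 100 + k,
                    ref = "A", alt = "C", trait = "HR")
    expect_equal(liftover_snps(s, neg)$mapped_pos, 50 + (10 - 1 - k))
  }
})

test_that("liftover is injective within a block and round-trips via the inverse", {
  cmap <- make_map(src_chrom = c("hs1", "hs1"), src_start = c(0, 300),
                   src_end = c(200, 400), dst_chrom = "chr1",
                   dst_start = c(1000, 40), dst_strand = c("+", "-"))
  pos <- c(0:19, 300:399)
  snps <- data.frame(snp_id = paste0("s", seq_along(pos)), chrom = "hs1",
                     pos = pos, ref = "A", alt = "C", trait = "other")
  fwd <- liftover_snps(snps, cmap)
  expect_true(all(fwd$mapped))
  expect_false(any(duplicated(fwd$mapped_pos)))
  back <- liftover_snps(data.frame(snp_id = fwd$snp_id, chrom = fwd$mapped_chrom,
                                   pos = fwd$mapped_pos, ref = "A", alt = "C",
                                   trait = "other"),
                        invert_map(cmap))
  expect_equal(back$mapped_pos, snps$pos)
})

test_that("malformed maps are rejected", {
  expect_error(make_map(src_chrom = "hs1", src_start = 10, src_end = 10,
                        dst_chrom = "c", dst_start = 0, dst_strand = "+"),
               "src_start >= src_end")
  expect_error(make_map(src_chrom = c("hs1", "hs1"), src_start = c(0, 50),
                        src_end = c(100, 150), dst_chrom = "c",
                        dst_start = c(0, 0), dst_strand = "+"),
               "overlap")
})

test_that("chain parsing reproduces block arithmetic on both strands", {
  f <- withr::local_tempfile(fileext = ".chain")
  writeLines(c(
    "chain 1000 hs1 5000 + 100 400 chr1 6000 + 200 500 1",
    "150 50 50",
    "100",
    "",
    "chain 900 hs2 5000 + 0 100 chr2 1000 - 0 100 2",
    "100",
    ""), f)
  cmap <- read_chain(f)
  expect_equal(nrow(cmap), 3)
  b1 <- cmap[cmap$src_chrom == "hs1" & cmap$src_start == 100, ]
  expect_equal(c(b1$src_end, b1$dst_start), c(250, 200))
  b2 <- cmap[cmap$src_chrom == "hs1" & cmap$src_start == 300, ]
  expect_equal(c(b2$src_end, b2$dst_start), c(400, 400))
  # negative query strand: forward dst_start = q_size - (q_pos + size)
  b3 <- cmap[cmap$src_chrom == "hs2", ]
  expect_equal(b3$dst_start, 900)
  expect_equal(b3$dst_strand, "-")
})

test_that("SNP table round-trips with 1-based/0-based conversion", {
  f <- withr::local_tempfile(fileext = ".tsv")
  snps <- data.frame(snp_id = "rs1", chrom = "hs1", pos = 99, ref = "G",
                     alt = "T", trait = "QT")
  write_snp_table(snps, f)
  on_disk <- utils::read.table(f, header = TRUE, sep = "\t")
  expect_equal(on_disk$pos, 100)
  expect_equal(read_snp_table(f)$pos, 99)
})

test_that("landing frequency: closed forms and scale invariance", {
  # the worked baseline: 607 SNPs over 2.7e9 bp
  expect_equal(signif(607 / 2.7e9, 2), 2.2e-7)
  snps <- data.frame(chrom = "chr1", pos = c(5, 900), ref = "A", alt = "C")
  set10 <- interval_set("chr1", 0, 10)
  lf <- landing_frequency(snps, set10, genome_bp = 1000)
  expect_equal(lf$n_snps_in_set, 1)
  expect_equal(lf$landing_frequency, 0.1)
  expect_equal(lf$fold_vs_baseline, 0.1 / (2 / 1000))
  # genome against itself: fold exactly 1
  genome_set <- interval_set("chr1", 0, 1000)
  expect_equal(landing_frequency(snps, genome_set, genome_bp = 1000)$fold_vs_baseline, 1)
  # scale invariance: doubling set and genome leaves the fold unchanged
  snps2 <- data.frame(chrom = rep(c("chr1", "chr2"), each = 2),
                      pos = c(5, 900, 5, 900), ref = "A", alt = "C")
  set2 <- interval_set(c("chr1", "chr2"), c(0, 0), c(10, 10), normalize = FALSE)
  lf2 <- landing_frequency(snps2, set2, genome_bp = 2000)
  expect_equal(lf2$fold_vs_baseline, lf$fold_vs_baseline)
  expect_error(landing_frequency(snps, subtract_universe(set10, set10),
                                 genome_bp = 1000), "zero total basepairs")
})

test_that("trend test: degenerate flag, two-set identity with 2x2 chi-square", {
  res_flat <- data.frame(set_label = c("a", "b"), n_snps_in_set = c(0, 0),
                         set_bp = c(1000, 1000))
  flat <- enrichment_trend_test(res_flat)
  expect_true(flat$degenerate)
  expect_equal(flat$p_trend, 1)

  res2 <- data.frame(set_label = c("a", "b"), n_snps_in_set = c(30, 70),
                     set_bp = c(10000, 10000))
  tt <- enrichment_trend_test(res2)
  chi <- suppressWarnings(stats::prop.test(c(30, 70), c(10000, 10000),
                                           correct = FALSE))
  expect_equal(tt$statistic, unname(chi$statistic), tolerance = 1e-12)
  expect_equal(tt$p_trend, chi$p.value, tolerance = 1e-12)
  # identical frequencies: statistic 0, p ~ 1
  res_eq <- data.frame(set_label = c("a", "b", "c"), n_snps_in_set = c(10, 100, 1000),
                       set_bp = c(1e4, 1e5, 1e6))
  expect_equal(enrichment_trend_test(res_eq)$statistic, 0, tolerance = 1e-12)
})

test_that("trait-component analysis pairs traits with their component sets", {
  avn <- interval_set("chr1", 0, 100, label = "AVN")
  vcs <- interval_set("chr1", 200, 300, label = "VCS")
  san <- interval_set("chr1", 400, 500, label = "SAN")
  cm <- interval_set("chr1", 900, 1000, label = "CM")
  snps <- data.frame(chrom = "chr1",
                     pos = c(10, 20, 250, 450, 950),
                     ref = "A", alt = "C",
                     trait = c("PR", "PR", "QRS", "HR", "QT"))
  tab <- trait_component_analysis(snps, list(SAN = san, AVN = avn, VCS = vcs), cm)
  pr <- tab[tab$trait == "PR", ]
  expect_equal(c(pr$paired_pct, pr$cm_pct), c(100, 0))
  qrs <- tab[tab$trait == "QRS", ]
  expect_equal(qrs$paired_set, "AVN+VCS")
  expect_equal(qrs$paired_pct, 100)
  qt <- tab[tab$trait == "QT", ]
  expect_equal(c(qt$paired_pct, qt$cm_pct), c(0, 100))
  expect_error(trait_component_analysis(snps, list(SAN = san), cm), "missing")
  expect_warning(
    trait_component_analysis(snps[snps$trait != "HR", , drop = FALSE],
                             list(SAN = san, AVN = avn, VCS = vcs), cm),
    "HR")
})

test_that("allele effect matches window-by-window brute force for both alleles", {
  set.seed(12)
  p <- pwm(matrix(stats::runif(16, 0.05, 1), nrow = 4), "toy")  # W = 4
  s <- random_seq(20)
  genome <- c(chr1 = s)
  pos <- 10
  snp <- data.frame(snp_id = "v", chrom = "chr1", pos = pos,
                    ref = substr(s, pos + 1, pos + 1), alt = "G")
  if (snp$ref == "G") snp$alt <- "C"
  eff <- allele_effect(p, genome, snp, flank_bp = 6)
  brute <- function(seqmod) {
    oracle <- oracle_scan(seqmod, p$mat, p$background, -Inf)
    cover <- oracle[oracle$start <= pos & oracle$start + 4 > pos, ]
    max(cover$score)
  }
  s_alt <- s
  substr(s_alt, pos + 1, pos + 1) <- snp$alt
  expect_equal(eff$best_ref_score, brute(s), tolerance = 1e-9)
  expect_equal(eff$best_alt_score, brute(s_alt), tolerance = 1e-9)
  expect_equal(eff$delta_bits, eff$best_alt_score - eff$best_ref_score)

  # consensus-breaking substitution has negative delta
  pc <- default_pwm_panel()[["SCRT1"]]
  cons <- pwm_consensus(pc)
  g2 <- c(chr1 = paste0("TTTTT", cons, "TTTTT"))
  snp2 <- data.frame(snp_id = "v2", chrom = "chr1", pos = 9,
                     ref = substr(cons, 5, 5), alt = "T")
  eff2 <- allele_effect(pc, g2, snp2, flank_bp = pc$width)
  expect_lt(eff2$delta_bits, 0)
  # degenerate ref == alt gives delta 0
  snp3 <- snp2
  snp3$alt <- snp3$ref
  expect_equal(allele_effect(pc, g2, snp3, flank_bp = pc$width)$delta_bits, 0)
  # reference mismatch is a hard error naming the position
  snp4 <- snp2
  snp4$ref <- setdiff(c("A", "C", "G", "T"), substr(cons, 5, 5))[1]
  expect_error(allele_effect(pc, g2, snp4, flank_bp = pc$width), "mismatch at chr1:9")
})
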