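test_that("perfect-match scoring on both strands gives the closed-form score", {
  # p(A,i) = 1 for W = 2, uniform background: score 2 * log2(4) = 4 bits
  m <- matrix(c(1, 0, 0, 0, 1, 0, 0, 0), nrow = 4)
  p <- pwm(m, "polyA")
  # pseudocounting keeps probabilities finite but near 1
  hitsA <- scan_pwm("AA", p, min_score_bits = 2.0)
  expect_equal(nrow(hitsA), 1)
  expect_equal(hitsA$strand, "+")
  expect_equal(hitsA$score, 2 * log2((1.25 / 2) / 0.25), tolerance = 1e-12)
  hitsT <- scan_pwm("TT", p, min_score_bits = 2.0)
  expect_equal(nrow(hitsT), 1)
  expect_equal(hitsT$strand, "-")
  expect_equal(hitsT$score, hitsA$score)
})

test_that("windows containing N are skipped and wide PWMs return empty", {
  p <- default_pwm_panel()[["ETS1"]]
  expect_equal(nrow(scan_pwm("ACGT", p)), 0)  # sequence shorter than motif
  seqN <- paste0(substr(pwm_consensus(p), 1, 5), "N",
                 substr(pwm_consensus(p), 7, 10))
  expect_equal(nrow(scan_pwm(seqN, p, min_score_bits = -Inf)), 0)
})

test_that("scanning matches exhaustive per-window scoring on random sequence", {
  set.seed(21)
  for (rep in 1:3) {
    s <- random_seq(2000)
    m <- matrix(stats::runif(4 * 6, 0.05, 1), nrow = 4)
    p <- pwm(m, "rand")
    thr <- 0.5 * pwm_max_score(p)
    hits <- scan_pwm(s, p, min_score_bits = thr, offset = 0)
    oracle <- oracle_scan(s, p$mat, p$background, thr)
    o <- order(oracle$start, oracle$strand)
    expect_equal(nrow(hits), nrow(oracle))
    expect_equal(hits$start, oracle$start[o])
    expect_equal(hits$strand, oracle$strand[o])
    expect_equal(hits$score, oracle$score[o], tolerance = 1e-9)
  }
})

test_that("strand symmetry: scanning the reverse complement swaps strands", {
  set.seed(5)
  s <- random_seq(500)
  p <- default_pwm_panel()[["MEF2A"]]
  fwd <- scan_pwm(s, p, min_score_bits = 5)
  rc <- scan_pwm(revcomp(s), p, min_score_bits = 5)
  expect_equal(sort(fwd$score), sort(rc$score), tolerance = 1e-9)
  expect_equal(sum(fwd$strand == "+"), sum(rc$strand == "-"))
  # coordinates mirror: start' = L - end
  expect_equal(sort(500 - fwd$end), sort(rc$start))
})

test_that("JASPAR-style PWM text round-trips", {
  panel <- default_pwm_panel()
  f <- withr::local_tempfile(fileext = ".txt")
  write_jaspar(panel, f)
  back <- read_jaspar(f)
  expect_equal(names(back), names(panel))
  expect_equal(back[["GATA4"]]$mat, panel[["GATA4"]]$mat, tolerance = 1e-6)
})

test_that("GGAA microsatellite runs match brute-force enumeration", {
  expect_equal(find_ggaa_repeats("GGAAGGAAGGAA")$n_units, 3)
  expect_equal(nrow(find_ggaa_repeats("GGAACGGAA")), 0)
  ttcc <- find_ggaa_repeats("TTCCTTCC")
  expect_equal(ttcc$motif, "TTCC")
  set.seed(31)
  for (rep in 1:5) {
    s <- paste(sample(c("G", "A", "T", "C", "GGAA", "TTCC"), 400,
                      replace = TRUE, prob = c(.2, .2, .2, .2, .1, .1)),
               collapse = "")
    got <- find_ggaa_repeats(s, min_units = 2)
    for (unit in c("GGAA", "TTCC")) {
      oracle <- oracle_runs(s, unit, 2)
      sub <- got[got$motif == unit, ]
      expect_equal(sub$start, oracle$start)
      expect_equal(sub$n_units, oracle$n_units)
    }
  }
})

test_that("motif enrichment: identity gives fold 1, absent motif fold 0 / p 1", {
  set.seed(8)
  genome <- c(chr1 = random_seq(20000))
  regions <- interval_set("chr1", seq(0, 19000, by = 1000), seq(400, 19400, by = 1000),
                          normalize = FALSE)
  panel <- default_pwm_panel()[c("ETS1", "SP1")]
  res <- motif_enrichment(regions, regions, panel, genome, min_score_bits = 5)
  expect_true(all(res$fold[res$target_frac > 0] == 1))
  # a motif with no hits anywhere: fold 0, p = 1
  res2 <- motif_enrichment(regions, regions, default_pwm_panel()["MEF2A"], genome,
                           min_score_bits = Inf)
  expect_equal(res2$fold, 0)
  expect_equal(res2$p_value, 1)
})

test_that("planted motif enrichment is recovered near the planted fold", {
  set.seed(17)
  p <- default_pwm_panel()[["ETS1"]]
  cons <- pwm_consensus(p)
  n_t <- 120; n_b <- 400
  mk_region <- function(planted) {
    s <- random_seq(200)
    if (planted) substr(s, 90, 99) <- cons
    s
  }
  target_seq <- vapply(seq_len(n_t), function(i) mk_region(i <= 0.5 * n_t), "")
  bg_seq <- vapply(seq_len(n_b), function(i) mk_region(i <= 0.05 * n_b), "")
  genome <- stats::setNames(c(target_seq, bg_seq),
                            paste0("c", seq_len(n_t + n_b)))
  target <- interval_set(paste0("c", 1:n_t), rep(0, n_t), rep(200, n_t),
                         normalize = FALSE)
  background <- interval_set(paste0("c", n_t + 1:n_b), rep(0, n_b), rep(200, n_b),
                             normalize = FALSE)
  res <- motif_enrichment(target, background, list(ETS1 = p), genome)
  # planted fold 10; binomial SE dominated by the background fraction
  se <- sqrt(0.05 * 0.95 / n_b) / 0.05 * 10
  expect_lt(abs(res$fold - 10), 3 * se)
  expect_lt(res$p_value, 1e-6)
})

test_that("GRN edges: single perfect proximal hit yields a single scored edge", {
  p <- pwm(matrix(c(1, 0, 0, 0, 1, 0, 0, 0), nrow = 4), "polyA")
  genome <- c(chr1 = paste0(strrep("C", 100), "AA", strrep("C", 100)))
  genes <- data.frame(gene = "g1", chrom = "chr1", tss = 90, strand = "+")
  peaks <- interval_set("chr1", 95, 110)
  edges <- build_grn(peaks, genes, list(polyA = p), genome, cutoff_bp = 50,
                     min_score_bits = 2.0, component = "SAN")
  expect_equal(nrow(edges), 1)
  expect_equal(edges$target_gene, "g1")
  expect_equal(edges$interaction_score, 2 * log2((1.25 / 2) / 0.25), tolerance = 1e-12)

  # region outside the cutoff window contributes no edge
  far_peaks <- interval_set("chr1", 150, 170)
  expect_warning(
    edges2 <- build_grn(far_peaks, genes, list(polyA = p), genome, cutoff_bp = 50,
                        min_score_bits = 2.0),
    "no accessible region")
  expect_equal(nrow(edges2), 0)
})

test_that("TF ranking orders by connectivity delta with deterministic ties", {
  comp <- data.frame(tf_name = c(rep("tfA", 10), rep("tfB", 3)),
                     target_gene = c(sprintf("g%02d", 1:10), sprintf("g%02d", 1:3)),
                     component = "SAN", interaction_score = 1, n_hits = 1)
  cm <- data.frame(tf_name = c(rep("tfA", 2), rep("tfB", 3)),
                   target_gene = c("g01", "g02", "g01", "g02", "g03"),
                   component = "CM", interaction_score = 1, n_hits = 1)
  r <- rank_tfs(comp, cm)
  expect_equal(r$tf_name[1], "tfA")
  expect_equal(r$delta[1], 8)
  expect_equal(r$rank, 1:2)
  # identical lists with equal connectivity: all deltas zero, lexicographic order
  cm_eq <- cm[cm$target_gene %in% c("g01", "g02"), ]
  r2 <- rank_tfs(cm_eq, cm_eq)
  expect_equal(r2$delta, c(0, 0))
  expect_equal(r2$tf_name, c("tfA", "tfB"))
  # unequal connectivity at delta 0: higher component connectivity first
  r2b <- rank_tfs(cm, cm)
  expect_equal(r2b$tf_name, c("tfB", "tfA"))
  # invariance to edge order
  r3 <- rank_tfs(comp[sample(nrow(comp)), ], cm[sample(nrow(cm)), ])
  expect_equal(r3, r)
})

test_that("subnetwork extraction sorts by score and truncates", {
  edges <- data.frame(tf_name = "tfA", target_gene = c("g1", "g2", "g3"),
                      component = "SAN", interaction_score = c(1, 5, 3), n_hits = 1)
  top2 <- extract_subnetwork(edges, "tfA", 2)
  expect_equal(top2$target_gene, c("g2", "g3"))
  expect_equal(nrow(extract_subnetwork(edges, "tfA", 10)), 3)
  expect_error(extract_subnetwork(edges, "tfZ"), "not present")
})
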