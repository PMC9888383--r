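## GWAS-variant annotation: block-based coordinate liftover, per-basepair
## landing-frequency / fold-enrichment statistics, trend and pairwise
## chi-square tests, trait-component subsets and allele-effect PWM scoring.

#' Read a SNP table
#'
#' TSV with header columns `snp_id`, `chrom`, `pos` (1-based, converted to
#' 0-based internally), `ref`, `alt`, `trait`. Trait values are expected in
#' `{HR, PR, QRS, QT, other}`.
#' @param path TSV path.
#' @return data.frame with `pos` 0-based.
#' @export
read_snp_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("snp_id", "chrom", "pos", "ref", "alt", "trait")
  if (!all(need %in% names(df)))
    stop("SNP table must have columns: ", paste(need, collapse = ", "))
  df$pos <- as.numeric(df$pos)
  if (any(!df$ref %in% .DNA_BASES) || any(!df$alt %in% .DNA_BASES))
    stop("SNP alleles must be single bases A/C/G/T")
  df$pos <- df$pos - 1  # 1-based on disk -> 0-based internal
  df[need]
}

#' Write a SNP table (positions re-emitted 1-based)
#' @param snps data.frame with 0-based `pos`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_snp_table <- function(snps, path) {
  out <- snps
  out$pos <- out$pos + 1
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a coordinate map from alignment blocks
#'
#' Blocks are `(src_chrom, src_start, src_end, dst_chrom, dst_start,
#' dst_strand)` with 0-based half-open source coordinates; `dst_start` is the
#' forward-strand start of the equal-length destination interval. For a `+`
#' block, source offset `k` maps to `dst_start + k`; for a `-` block, to
#' `dst_start + (len - 1 - k)`. Blocks must not overlap on the source.
#'
#' @param blocks data.frame with the six columns above.
#' @return data.frame of class `coordinate_map`, sorted by source position.
#' @export
coordinate_map <- function(blocks) {
  need <- c("src_chrom", "src_start", "src_end", "dst_chrom", "dst_start", "dst_strand")
  if (!all(need %in% names(blocks)))
    stop("coordinate map needs columns: ", paste(need, collapse = ", "))
  if (any(blocks$src_start >= blocks$src_end))
    stop("malformed block: src_start >= src_end")
  if (any(!blocks$dst_strand %in% c("+", "-")))
    stop("dst_strand must be '+' or '-'")
  blocks <- blocks[order(blocks$src_chrom, blocks$src_start), need, drop = FALSE]
  by_chr <- split(blocks, blocks$src_chrom)
  for (b in by_chr) {
    if (nrow(b) > 1 && any(b$src_start[-1] < b$src_end[-nrow(b)]))
      stop("malformed map: blocks overlap on source chromosome ", b$src_chrom[1])
  }
  rownames(blocks) <- NULL
  class(blocks) <- c("coordinate_map", "data.frame")
  blocks
}

#' Read a simplified 6-column block table
#' @param path TSV with header matching [coordinate_map()] columns.
#' @return a `coordinate_map`.
#' @export
read_block_map <- function(path) {
  coordinate_map(utils::read.table(path, header = TRUE, sep = "\t",
                                   stringsAsFactors = FALSE))
}

#' Write a block table
#' @param cmap a `coordinate_map`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_block_map <- function(cmap, path) {
  utils::write.table(as.data.frame(cmap), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Parse a UCSC chain file into a coordinate map
#'
#' Reads `chain` headers and their `size dt dq` block lines, emitting one
#' 6-column block per ungapped aligned segment. Negative-strand query
#' coordinates are converted to forward-strand `dst_start` positions.
#' @param path chain file path.
#' @return a `coordinate_map`.
#' @export
read_chain <- function(path) {
  lines <- readLines(path)
  rows <- list()
  i <- 1
  while (i <= length(lines)) {
    ln <- trimws(lines[i])
    if (!nzchar(ln)) { i <- i + 1; next }
    f <- strsplit(ln, "\\s+")[[1]]
    if (f[1] != "chain")
      stop("chain parse error at line ", i, ": expected 'chain' header")
    if (length(f) < 12)
      stop("chain parse error at line ", i, ": truncated header")
    t_name <- f[3]; t_strand <- f[5]; t_pos <- as.numeric(f[6])
    q_name <- f[8]; q_size <- as.numeric(f[9]); q_strand <- f[10]
    q_pos <- as.numeric(f[11])
    if (t_strand != "+")
      stop("chain parse error at line ", i, ": target strand must be '+'")
    i <- i + 1
    repeat {
      if (i > length(lines)) stop("chain parse error: unexpected end of file")
      bl <- trimws(lines[i])
      i <- i + 1
      if (!nzchar(bl)) break
      g <- as.numeric(strsplit(bl, "\\s+")[[1]])
      size <- g[1]
      dst_start <- if (q_strand == "+") q_pos else q_size - (q_pos + size)
      rows[[length(rows) + 1L]] <- data.frame(
        src_chrom = t_name, src_start = t_pos, src_end = t_pos + size,
        dst_chrom = q_name, dst_start = dst_start, dst_strand = q_strand,
        stringsAsFactors = FALSE)
      if (length(g) == 1) break
      t_pos <- t_pos + size + g[2]
      q_pos <- q_pos + size + g[3]
    }
  }
  if (!length(rows)) stop("no chains found in ", path)
  coordinate_map(do.call(rbind, rows))
}

#' Invert a coordinate map
#'
#' Swaps source and destination; block orientation is preserved. Lifting a
#' position through a map and then through its inverse returns the original
#' position.
#' @param cmap a `coordinate_map`.
#' @return a `coordinate_map`.
#' @export
invert_map <- function(cmap) {
  len <- cmap$src_end - cmap$src_start
  coordinate_map(data.frame(
    src_chrom = cmap$dst_chrom, src_start = cmap$dst_start,
    src_end = cmap$dst_start + len,
    dst_chrom = cmap$src_chrom, dst_start = cmap$src_start,
    dst_strand = cmap$dst_strand, stringsAsFactors = FALSE))
}

#' Lift single-basepair variants through a coordinate map
#'
#' A position maps iff it falls inside exactly one block; unmapped records
#' are retained with a reason code (`"no_block"`).
#'
#' @param snps SNP data.frame with 0-based `pos`.
#' @param cmap a `coordinate_map`.
#' @return the input with added columns `mapped` (logical), `mapped_chrom`,
#'   `mapped_pos`, `reason`.
#' @export
liftover_snps <- function(snps, cmap) {
  n <- nrow(snps)
  mapped_chrom <- rep(NA_character_, n)
  mapped_pos <- rep(NA_real_, n)
  reason <- rep(NA_character_, n)
  by_chr <- split(seq_len(nrow(cmap)), cmap$src_chrom)
  for (i in seq_len(n)) {
    idx <- by_chr[[snps$chrom[i]]]
    if (is.null(idx)) { reason[i] <- "no_block"; next }
    b <- cmap[idx, ]
    j <- which(snps$pos[i] >= b$src_start & snps$pos[i] < b$src_end)
    if (length(j) != 1) { reason[i] <- "no_block"; next }
    k <- snps$pos[i] - b$src_start[j]
    len <- b$src_end[j] - b$src_start[j]
    mapped_chrom[i] <- b$dst_chrom[j]
    mapped_pos[i] <- if (b$dst_strand[j] == "+") b$dst_start[j] + k
                     else b$dst_start[j] + (len - 1 - k)
  }
  snps$mapped <- is.na(reason)
  snps$mapped_chrom <- mapped_chrom
  snps$mapped_pos <- mapped_pos
  snps$reason <- reason
  snps
}

#' Per-basepair SNP landing frequency and fold enrichment of a region set
#'
#' Counts mapped SNPs whose single mapped basepair lies inside the set; the
#' landing frequency is that count over the set's total basepairs, and fold
#' enrichment is the ratio to a baseline per-bp rate (default: the
#' whole-genome rate `n_snps_total / genome_bp`).
#'
#' @param snps SNP data.frame; rows with `mapped == FALSE` are ignored. A
#'   plain data.frame with `mapped_chrom`/`mapped_pos` (or `chrom`/`pos`)
#'   also works.
#' @param region_set a nonempty `interval_set`.
#' @param genome_bp genome size used for the default baseline (default
#'   2.7e9, the conventional mappable mouse genome size).
#' @param baseline optional explicit baseline per-bp frequency (e.g. the CM
#'   enhancer rate when reporting nested fold gains).
#' @param label label stored on the result (defaults to the set's label).
#' @return one-row data.frame of class `enrichment_result` with columns
#'   `set_label`, `set_bp`, `n_snps_total`, `n_snps_in_set`,
#'   `landing_frequency`, `baseline_frequency`, `fold_vs_baseline`.
#' @export
landing_frequency <- function(snps, region_set, genome_bp = 2.7e9,
                              baseline = NULL, label = NULL) {
  bp <- total_bp(region_set)
  if (bp <= 0) stop("region set has zero total basepairs")
  if ("mapped" %in% names(snps)) snps <- snps[snps$mapped, , drop = FALSE]
  ch <- if ("mapped_chrom" %in% names(snps)) snps$mapped_chrom else snps$chrom
  pos <- if ("mapped_pos" %in% names(snps)) snps$mapped_pos else snps$pos
  n_total <- length(pos)
  in_set <- 0L
  if (n_total > 0) {
    gr <- GenomicRanges::GRanges(ch, IRanges::IRanges(pos + 1, pos + 1))
    in_set <- sum(.count_ov(gr, .as_gr(region_set)) > 0)
  }
  freq <- in_set / bp
  base <- if (is.null(baseline)) n_total / genome_bp else baseline
  out <- data.frame(set_label = if (is.null(label)) set_label(region_set) else label,
                    set_bp = bp, n_snps_total = n_total, n_snps_in_set = in_set,
                    landing_frequency = freq, baseline_frequency = base,
                    fold_vs_baseline = freq / base, stringsAsFactors = FALSE)
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' Trend test across nested or ordered enrichment results
#'
#' Cochran-Armitage-style chi-square test for trend on the (hits, set_bp)
#' pairs with equally spaced scores, plus pairwise 2x2 chi-square tests
#' (1 df, no continuity correction by default). Results are expected in
#' nesting order, e.g. genome, then CM enhancers, then CCS enhancers.
#'
#' @param results list of `enrichment_result` rows (or a data.frame with
#'   `set_label`, `n_snps_in_set`, `set_bp`).
#' @param correct apply continuity correction in the pairwise tests.
#' @return list with `p_trend`, `statistic`, `degenerate` (flag, all-zero
#'   hits give p = 1), and `pairwise` (data.frame `set_a`, `set_b`,
#'   `chisq`, `p`).
#' @export
enrichment_trend_test <- function(results, correct = FALSE) {
  if (is.list(results) && !is.data.frame(results))
    results <- do.call(rbind, lapply(results, as.data.frame))
  if (nrow(results) < 2) stop("trend test requires >= 2 region sets")
  hits <- results$n_snps_in_set
  bp <- results$set_bp
  if (all(hits == 0))
    return(list(p_trend = 1, statistic = 0, degenerate = TRUE, pairwise = NULL))
  tt <- suppressWarnings(stats::prop.trend.test(hits, bp, score = seq_along(hits)))
  pairs <- utils::combn(seq_along(hits), 2)
  pw <- apply(pairs, 2, function(ij) {
    i <- ij[1]; j <- ij[2]
    ct <- suppressWarnings(stats::prop.test(c(hits[i], hits[j]), c(bp[i], bp[j]),
                                            correct = correct))
    c(chisq = unname(ct$statistic), p = ct$p.value)
  })
  pairwise <- data.frame(set_a = results$set_label[pairs[1, ]],
                         set_b = results$set_label[pairs[2, ]],
                         chisq = pw["chisq", ], p = pw["p", ],
                         stringsAsFactors = FALSE)
  list(p_trend = tt$p.value, statistic = unname(tt$statistic),
       degenerate = FALSE, pairwise = pairwise)
}

## trait -> functionally paired component set(s)
.TRAIT_PAIRING <- list(HR = "SAN", PR = "AVN", QRS = c("AVN", "VCS"), QT = "VCS")

#' Trait-by-component SNP landing analysis
#'
#' For each EKG trait, the percent of that trait's mapped SNPs landing in the
#' functionally paired component enhancer set (heart rate with SAN, PR
#' interval with AVN, QRS interval with the AVN and VCS sets combined, QT
#' interval with VCS) and in the CM enhancer set, with a pairwise chi-square
#' p-value on the two proportions. Traits with zero mapped SNPs are omitted
#' with a warning.
#'
#' @param snps mapped SNP data.frame with a `trait` column.
#' @param component_enhancers named list of `interval_set`s including `SAN`,
#'   `AVN`, `VCS`.
#' @param cm_enhancers `interval_set` of CM enhancers.
#' @param correct continuity correction for the pairwise test.
#' @return data.frame with columns `trait`, `n_snps`, `paired_set`,
#'   `paired_hits`, `paired_pct`, `cm_hits`, `cm_pct`, `chisq_p`.
#' @export
trait_component_analysis <- function(snps, component_enhancers, cm_enhancers,
                                     correct = FALSE) {
  if ("mapped" %in% names(snps)) snps <- snps[snps$mapped, , drop = FALSE]
  rows <- list()
  for (trait in names(.TRAIT_PAIRING)) {
    comps <- .TRAIT_PAIRING[[trait]]
    if (any(!comps %in% names(component_enhancers)))
      stop("component enhancer set(s) missing for trait ", trait, ": ",
           paste(setdiff(comps, names(component_enhancers)), collapse = ", "))
    sub <- snps[snps$trait == trait, , drop = FALSE]
    if (nrow(sub) == 0) {
      warning("no mapped SNPs for trait ", trait, "; row omitted")
      next
    }
    paired_df <- do.call(rbind, lapply(component_enhancers[comps], function(s)
      as.data.frame(s)[c("chrom", "start", "end")]))
    paired <- merge_intervals(interval_set(paired_df, label = paste(comps, collapse = "+"),
                                           normalize = FALSE))
    ch <- if ("mapped_chrom" %in% names(sub)) sub$mapped_chrom else sub$chrom
    pos <- if ("mapped_pos" %in% names(sub)) sub$mapped_pos else sub$pos
    gr <- GenomicRanges::GRanges(ch, IRanges::IRanges(pos + 1, pos + 1))
    ph <- sum(.count_ov(gr, .as_gr(paired)) > 0)
    cmh <- sum(.count_ov(gr, .as_gr(cm_enhancers)) > 0)
    p <- if (ph == 0 && cmh == 0) 1
    else suppressWarnings(stats::prop.test(c(ph, cmh), c(nrow(sub), nrow(sub)),
                                           correct = correct))$p.value
    rows[[trait]] <- data.frame(
      trait = trait, n_snps = nrow(sub), paired_set = paste(comps, collapse = "+"),
      paired_hits = ph, paired_pct = percent_of(ph, nrow(sub)),
      cm_hits = cmh, cm_pct = percent_of(cmh, nrow(sub)),
      chisq_p = p, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Allele effect of a variant on a PWM match
#'
#' Extracts the sequence `flank_bp` either side of the mapped variant, scores
#' every window (both strands) covering the variant position with the
#' reference base and again with the substituted alternate base, and reports
#' the best score for each allele and their difference in bits. A negative
#' delta means the alternate allele weakens the best motif match.
#'
#' @param x a `pwm`.
#' @param genome named character vector of chromosome sequences.
#' @param snp one-row mapped SNP (uses `mapped_chrom`/`mapped_pos` when
#'   present, else `chrom`/`pos`), with `ref` and `alt` alleles.
#' @param flank_bp flank length (`>= pwm width`).
#' @return list with `best_ref_score`, `best_alt_score`, `delta_bits`.
#' @export
allele_effect <- function(x, genome, snp, flank_bp = NULL) {
  W <- x$width
  if (is.null(flank_bp)) flank_bp <- W
  stopifnot(flank_bp >= W)
  ch <- if ("mapped_chrom" %in% names(snp) && !is.na(snp$mapped_chrom[1]))
    snp$mapped_chrom[1] else snp$chrom[1]
  pos <- if ("mapped_pos" %in% names(snp) && !is.na(snp$mapped_pos[1]))
    snp$mapped_pos[1] else snp$pos[1]
  L <- nchar(genome[[ch]])
  lo <- max(0, pos - flank_bp)
  hi <- min(L, pos + flank_bp + 1)
  seq_ref <- get_sequence(genome, ch, lo, hi)
  at <- pos - lo + 1  # 1-based position of the variant within the flank
  if (substr(seq_ref, at, at) != snp$ref[1])
    stop(sprintf("reference allele mismatch at %s:%s: genome has %s, SNP table says %s",
                 ch, format(pos, scientific = FALSE), substr(seq_ref, at, at), snp$ref[1]))
  seq_alt <- seq_ref
  substr(seq_alt, at, at) <- snp$alt[1]
  best_cover <- function(s) {
    hits <- scan_pwm(s, x, min_score_bits = -Inf, chrom = ch, offset = lo)
    cover <- hits[hits$start <= pos & hits$end > pos, , drop = FALSE]
    if (nrow(cover) == 0) -Inf else max(cover$score)
  }
  ref_s <- best_cover(seq_ref)
  alt_s <- best_cover(seq_alt)
  list(best_ref_score = ref_s, best_alt_score = alt_s, delta_bits = alt_s - ref_s)
}
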