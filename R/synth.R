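## Deterministic, seeded generator of every input the pipeline consumes, with
## planted structure recorded as ground truth for parameter-recovery tests.
##
## One RNG stream per generated artifact class (regions, categories, genes,
## genome, planting, SNPs, map, catalogs), derived once from the master seed,
## so e.g. changing the number of SNPs does not perturb the peak layout.

.MIXED_PATTERNS <- c("1100", "1010", "1001", "0110", "0101", "0011")

.synth_streams <- function(seed) {
  set.seed(seed)
  stats::setNames(sample.int(2^31 - 2, 8),
                  c("regions", "categories", "genes", "genome",
                    "plant", "snps", "map", "catalogs"))
}

.consensus_pwm <- function(name, consensus, strength = 0.85) {
  b <- strsplit(consensus, "")[[1]]
  W <- length(b)
  mat <- matrix((1 - strength) / 3, nrow = 4, ncol = W,
                dimnames = list(.DNA_BASES, NULL))
  mat[cbind(match(b, .DNA_BASES), seq_len(W))] <- strength
  pwm(mat, tf_name = name)
}

#' Bundled panel of synthetic TF motifs
#'
#' Eight JASPAR-style matrices constructed in code with consensus cores
#' representative of the motif families prominent in conduction-system
#' chromatin (ETS, MEF2, homeobox, bHLH, T-box, GATA, SCRT, SP). These are
#' synthetic stand-ins, not database matrices.
#' @param strength consensus base probability per column.
#' @return named list of `pwm` objects.
#' @export
default_pwm_panel <- function(strength = 0.85) {
  cons <- c(ETS1 = "ACCGGAAGTG", MEF2A = "CTAAAAATAG", NKX25 = "CACTTGAAGT",
            HAND2 = "GGCCATCTGG", TBX5 = "AGGTGTGAAG", GATA4 = "AAGATAAGGC",
            SCRT1 = "AAACAGGTGC", SP1 = "GGGGCGGGGC")
  stats::setNames(lapply(names(cons), function(n) .consensus_pwm(n, cons[[n]], strength)),
                  names(cons))
}

#' Synthetic-study configuration
#'
#' Defaults define the desk-scale study: 3 chromosomes of 1 Mb, 600 master
#' regions, 60 genes, an 8-motif panel and 600 SNPs, with the category
#' mixture anchored at ~39% fully shared regions.
#'
#' @param seed master seed; all randomness derives from it.
#' @param chrom_sizes named numeric vector of chromosome lengths (bp).
#' @param n_regions number of master (union) regions.
#' @param peak_width `c(mean, sd)` of region widths in bp (minimum 60).
#' @param category_mixture named probabilities over [CCS_CATEGORIES]
#'   (must sum to 1).
#' @param n_genes number of genes (TSS placed inside master regions,
#'   component-open regions first).
#' @param cutoff_bp proximal/distal TSS cutoff.
#' @param pwm_panel named list of `pwm` objects.
#' @param planted_tf name of the planted motif (must be in the panel).
#' @param plant_component occupancy category component whose open proximal
#'   regions receive the planted motif.
#' @param plant_prob probability an eligible region carries the motif.
#' @param n_snps number of SNPs.
#' @param snp_fold named per-bp enrichment factor per planted region set.
#' @param trait_mixture named probabilities over traits.
#' @param unmappable_frac fraction of alignment blocks dropped from the
#'   coordinate map.
#' @param block_bp alignment-block size.
#' @param h3k27ac_cover fraction of distal peaks covered by the active-mark
#'   catalog.
#' @param n_h3k27ac_decoys,n_vista decoy catalog regions / validated-enhancer
#'   elements.
#' @param contact_rate decoy contact probability per (gene, element) pair.
#' @param enrichment_threshold expression-enrichment threshold the planted
#'   targets exceed.
#' @return list of class `synth_config`.
#' @export
synth_config <- function(seed = 1,
                         chrom_sizes = c(chr1 = 1e6, chr2 = 1e6, chr3 = 1e6),
                         n_regions = 600,
                         peak_width = c(mean = 400, sd = 80),
                         category_mixture = c(
                           "Shared" = 0.39, "CCS Open" = 0.06, "CCS Closed" = 0.10,
                           "SAN Open" = 0.05, "SAN Closed" = 0.05,
                           "AVN Open" = 0.05, "AVN Closed" = 0.05,
                           "VCS Open" = 0.05, "VCS Closed" = 0.05,
                           "Mixed" = 0.15),
                         n_genes = 60, cutoff_bp = 2000,
                         pwm_panel = default_pwm_panel(),
                         planted_tf = "ETS1", plant_component = "SAN",
                         plant_prob = 0.8,
                         n_snps = 600,
                         snp_fold = c("SAN Open" = 5, "AVN Open" = 16, "VCS Open" = 100),
                         trait_mixture = c(HR = 0.2, PR = 0.2, QRS = 0.2,
                                           QT = 0.2, other = 0.2),
                         unmappable_frac = 0, block_bp = 10000,
                         h3k27ac_cover = 0.7, n_h3k27ac_decoys = 50,
                         n_vista = 40, contact_rate = 0.05,
                         enrichment_threshold = 1.5) {
  stopifnot(abs(sum(category_mixture) - 1) < 1e-9,
            all(names(category_mixture) %in% CCS_CATEGORIES),
            abs(sum(trait_mixture) - 1) < 1e-9,
            plant_prob >= 0, plant_prob <= 1,
            unmappable_frac >= 0, unmappable_frac < 1,
            h3k27ac_cover >= 0, h3k27ac_cover <= 1,
            contact_rate >= 0, contact_rate <= 1,
            planted_tf %in% names(pwm_panel),
            all(snp_fold >= 1))
  structure(list(seed = seed, chrom_sizes = chrom_sizes, n_regions = n_regions,
                 peak_width = peak_width, category_mixture = category_mixture,
                 n_genes = n_genes, cutoff_bp = cutoff_bp, pwm_panel = pwm_panel,
                 planted_tf = planted_tf, plant_component = plant_component,
                 plant_prob = plant_prob, n_snps = n_snps, snp_fold = snp_fold,
                 trait_mixture = trait_mixture, unmappable_frac = unmappable_frac,
                 block_bp = block_bp, h3k27ac_cover = h3k27ac_cover,
                 n_h3k27ac_decoys = n_h3k27ac_decoys, n_vista = n_vista,
                 contact_rate = contact_rate,
                 enrichment_threshold = enrichment_threshold),
            class = "synth_config")
}

#' Generate the four sample peak sets with planted occupancy categories
#'
#' Draws non-overlapping master regions, assigns each a category from the
#' configured mixture (Mixed regions get one of the six unnamed attainable
#' bit patterns), and materializes per-sample peak sets from the category's
#' bit pattern. The construction is deterministic given the seed, and
#' categorization of the output recovers the drawn categories exactly.
#'
#' @param cfg a `synth_config`.
#' @return list with `master` (`interval_set`), `samples` (named list of 4
#'   `interval_set`s in CM, SAN, AVN, VCS order) and `truth` (data.frame with
#'   per-region `category` and bit `pattern`).
#' @export
generate_peaksets <- function(cfg) {
  streams <- .synth_streams(cfg$seed)
  sizes <- cfg$chrom_sizes
  n_chr <- round(cfg$n_regions * sizes / sum(sizes))
  n_chr[1] <- cfg$n_regions - sum(n_chr[-1])

  set.seed(streams[["regions"]])
  rows <- list()
  for (ci in seq_along(sizes)) {
    n <- n_chr[ci]
    if (n == 0) next
    w <- pmax(60, round(stats::rnorm(n, cfg$peak_width[["mean"]], cfg$peak_width[["sd"]])))
    slack <- sizes[ci] - sum(w) - (n + 1)
    if (slack < 0)
      stop("infeasible packing on ", names(sizes)[ci],
           ": increase chromosome size or reduce regions")
    extra <- as.vector(stats::rmultinom(1, slack, rep(1, n + 1)))
    gaps <- 1 + extra
    starts <- cumsum(gaps)[seq_len(n)] + c(0, cumsum(w))[seq_len(n)]
    rows[[ci]] <- data.frame(chrom = names(sizes)[ci], start = starts,
                             end = starts + w, stringsAsFactors = FALSE)
  }
  master_df <- do.call(rbind, rows)

  set.seed(streams[["categories"]])
  category <- sample(names(cfg$category_mixture), nrow(master_df), replace = TRUE,
                     prob = cfg$category_mixture)
  pattern <- unname(stats::setNames(names(.CATEGORY_TABLE), .CATEGORY_TABLE)[category])
  is_mixed <- category == "Mixed"
  if (any(is_mixed))
    pattern[is_mixed] <- sample(.MIXED_PATTERNS, sum(is_mixed), replace = TRUE)

  bits <- do.call(rbind, lapply(strsplit(pattern, ""), function(b) as.integer(b) == 1L))
  colnames(bits) <- CCS_SAMPLES
  samples <- stats::setNames(lapply(CCS_SAMPLES, function(s) {
    sel <- master_df[bits[, s], , drop = FALSE]
    if (nrow(sel) == 0) return(.empty_set(s))
    interval_set(sel, label = s, normalize = FALSE)
  }), CCS_SAMPLES)
  master <- interval_set(master_df, label = "master", normalize = FALSE)
  truth <- cbind(master_df, data.frame(category = category, pattern = pattern,
                                       stringsAsFactors = FALSE))
  list(master = master, samples = samples, truth = truth)
}

#' Generate gene annotations anchored inside master regions
#'
#' TSSs are placed inside master regions (so the hosting region is always
#' TSS-proximal); regions of the planted component's Open category are
#' assigned genes first, guaranteeing the planted motif sits in gene-proximal
#' accessible chromatin.
#'
#' @param cfg a `synth_config`.
#' @param ps output of [generate_peaksets()].
#' @return gene annotation data.frame (`gene`, `chrom`, `tss`, `strand`) with
#'   an extra `host_region` index column.
#' @export
generate_genes <- function(cfg, ps) {
  streams <- .synth_streams(cfg$seed)
  set.seed(streams[["genes"]])
  tr <- ps$truth
  planted_cat <- paste(cfg$plant_component, "Open")
  pri <- which(tr$category == planted_cat)
  rest <- setdiff(seq_len(nrow(tr)), pri)
  host <- c(sample(pri), sample(rest))[seq_len(min(cfg$n_genes, nrow(tr)))]
  tss <- tr$start[host] + vapply(host, function(i)
    sample.int(tr$end[i] - tr$start[i], 1) - 1L, 0L)
  data.frame(gene = sprintf("gene%03d", seq_along(host)),
             chrom = tr$chrom[host], tss = tss,
             strand = sample(c("+", "-"), length(host), replace = TRUE),
             host_region = host, stringsAsFactors = FALSE)
}

#' Generate a genome with the planted motif embedded
#'
#' Background sequence is i.i.d. uniform over ACGT. The planted TF's
#' consensus is embedded with probability `plant_prob` into each
#' gene-proximal region of the planted component's Open category (and never
#' elsewhere); embedding positions are recorded, as are the implied planted
#' TF-to-gene edges.
#'
#' @param cfg a `synth_config`.
#' @param ps output of [generate_peaksets()].
#' @param genes output of [generate_genes()].
#' @return list with `genome` (named character vector), `embeddings`
#'   (data.frame `chrom`, `start`, `end`, `region`) and `planted_edges`
#'   (data.frame `tf_name`, `target_gene`).
#' @export
generate_genome_and_motifs <- function(cfg, ps, genes) {
  streams <- .synth_streams(cfg$seed)
  set.seed(streams[["genome"]])
  genome <- vapply(cfg$chrom_sizes, function(L)
    paste(sample(.DNA_BASES, L, replace = TRUE), collapse = ""), "")
  names(genome) <- names(cfg$chrom_sizes)

  set.seed(streams[["plant"]])
  consensus <- pwm_consensus(cfg$pwm_panel[[cfg$planted_tf]])
  W <- nchar(consensus)
  tr <- ps$truth
  planted_cat <- paste(cfg$plant_component, "Open")
  ## eligible: planted-category regions within cutoff_bp of a TSS
  win_lo <- pmax(0, genes$tss - cfg$cutoff_bp)
  win_hi <- genes$tss + cfg$cutoff_bp
  eligible <- which(tr$category == planted_cat &
                      vapply(seq_len(nrow(tr)), function(i)
                        any(genes$chrom == tr$chrom[i] &
                              win_lo < tr$end[i] & win_hi > tr$start[i]), TRUE))
  emb <- list()
  for (i in eligible) {
    width <- tr$end[i] - tr$start[i]
    if (width < W) next
    if (stats::runif(1) > cfg$plant_prob) next
    off <- sample.int(width - W + 1, 1) - 1L
    s <- tr$start[i] + off
    substr(genome[[tr$chrom[i]]], s + 1, s + W) <- consensus
    emb[[length(emb) + 1L]] <- data.frame(chrom = tr$chrom[i], start = s,
                                          end = s + W, region = i,
                                          stringsAsFactors = FALSE)
  }
  embeddings <- if (length(emb)) do.call(rbind, emb)
  else data.frame(chrom = character(), start = numeric(), end = numeric(),
                  region = integer(), stringsAsFactors = FALSE)
  edges <- list()
  for (r in embeddings$region) {
    gi <- which(genes$chrom == tr$chrom[r] &
                  win_lo < tr$end[r] & win_hi > tr$start[r])
    for (g in gi)
      edges[[length(edges) + 1L]] <- data.frame(tf_name = cfg$planted_tf,
                                                target_gene = genes$gene[g],
                                                stringsAsFactors = FALSE)
  }
  planted_edges <- if (length(edges)) unique(do.call(rbind, edges))
  else data.frame(tf_name = character(), target_gene = character(),
                  stringsAsFactors = FALSE)
  list(genome = genome, embeddings = embeddings, planted_edges = planted_edges)
}

#' Generate SNPs with planted per-bp fold enrichment, plus a coordinate map
#'
#' Each SNP lands inside planted region set `k` with probability
#' `fold_k * set_bp_k / genome_bp` (uniformly within the set), the remaining
#' mass uniformly over the complement, so the measured fold enrichment
#' estimates `fold_k` directly. Region sets must be pairwise disjoint. The
#' coordinate map is identity-valued over alignment blocks tiling the genome,
#' with a configurable fraction of blocks dropped (SNPs there stay
#' unmapped); source chromosome names are prefixed `src_`.
#'
#' @param cfg a `synth_config`.
#' @param region_sets named list of disjoint `interval_set`s; names must
#'   cover `names(cfg$snp_fold)`.
#' @param genome optional genome to draw reference alleles from.
#' @return list with `snps` (source-coordinate table: `snp_id`, `chrom`,
#'   `pos` 0-based, `ref`, `alt`, `trait`), `cmap` (a `coordinate_map`) and
#'   `truth` (per-SNP drawn set, destination position, mappable flag).
#' @export
generate_snps <- function(cfg, region_sets, genome = NULL) {
  streams <- .synth_streams(cfg$seed)
  G <- sum(cfg$chrom_sizes)
  folds <- cfg$snp_fold
  if (any(!names(folds) %in% names(region_sets)))
    stop("region_sets missing entries for: ",
         paste(setdiff(names(folds), names(region_sets)), collapse = ", "))
  sets <- region_sets[names(folds)]
  set_bp <- vapply(sets, total_bp, 0)
  mass <- folds * set_bp / G
  if (sum(mass) > 1)
    stop("requested in-set probability mass exceeds 1; reduce folds or set sizes")

  set.seed(streams[["snps"]])
  n <- cfg$n_snps
  cls <- sample(c(names(folds), ".bg"), n, replace = TRUE,
                prob = c(mass, 1 - sum(mass)))
  chrom <- character(n)
  pos <- numeric(n)
  cum <- cumsum(as.numeric(cfg$chrom_sizes))
  draw_genome_pos <- function() {
    u <- stats::runif(1) * G
    ci <- findInterval(u, c(0, cum), rightmost.closed = TRUE)
    c(ci, floor(u - c(0, cum)[ci]))
  }
  in_any_set <- function(ch, p) {
    any(vapply(sets, function(s)
      any(s$chrom == ch & s$start <= p & s$end > p), TRUE))
  }
  for (i in seq_len(n)) {
    if (cls[i] == ".bg") {
      repeat {
        d <- draw_genome_pos()
        ch <- names(cfg$chrom_sizes)[d[1]]
        if (!in_any_set(ch, d[2])) break
      }
      chrom[i] <- ch
      pos[i] <- d[2]
    } else {
      s <- sets[[cls[i]]]
      w <- s$end - s$start
      j <- sample.int(nrow(s), 1, prob = w)
      chrom[i] <- s$chrom[j]
      pos[i] <- s$start[j] + sample.int(w[j], 1) - 1
    }
  }
  ref <- if (!is.null(genome))
    vapply(seq_len(n), function(i) substr(genome[[chrom[i]]], pos[i] + 1, pos[i] + 1), "")
  else sample(.DNA_BASES, n, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(.DNA_BASES, b), 1), "")
  trait <- sample(names(cfg$trait_mixture), n, replace = TRUE,
                  prob = cfg$trait_mixture)

  set.seed(streams[["map"]])
  blocks <- list()
  for (ci in seq_along(cfg$chrom_sizes)) {
    L <- cfg$chrom_sizes[[ci]]
    starts <- seq(0, L - 1, by = cfg$block_bp)
    ends <- pmin(starts + cfg$block_bp, L)
    keep <- stats::runif(length(starts)) >= cfg$unmappable_frac
    if (!any(keep)) next
    blocks[[ci]] <- data.frame(
      src_chrom = paste0("src_", names(cfg$chrom_sizes)[ci]),
      src_start = starts[keep], src_end = ends[keep],
      dst_chrom = names(cfg$chrom_sizes)[ci], dst_start = starts[keep],
      dst_strand = "+", stringsAsFactors = FALSE)
  }
  cmap <- coordinate_map(do.call(rbind, blocks))
  mappable <- vapply(seq_len(n), function(i) {
    b <- cmap[cmap$src_chrom == paste0("src_", chrom[i]), ]
    any(pos[i] >= b$src_start & pos[i] < b$src_end)
  }, TRUE)

  snps <- data.frame(snp_id = sprintf("rs%06d", seq_len(n)),
                     chrom = paste0("src_", chrom), pos = pos,
                     ref = ref, alt = unname(alt), trait = trait,
                     stringsAsFactors = FALSE)
  truth <- data.frame(snp_id = snps$snp_id, planted_set = cls,
                      dst_chrom = chrom, dst_pos = pos, mappable = mappable,
                      stringsAsFactors = FALSE)
  list(snps = snps, cmap = cmap, truth = truth)
}

#' Generate active-mark and validated-enhancer catalogs plus consumed tables
#'
#' The H3K27ac-like catalog covers a configurable fraction of distal master
#' regions plus decoy regions placed in inter-region gaps. Validated
#' (VISTA-like) elements are placed on a subset of covered distal regions
#' with known component subsets; for every CCS-enriched element, the nearest
#' gene is recorded as its true target, given an expression-enrichment ratio
#' above threshold and a supporting promoter contact. Decoy contacts link
#' random gene-element pairs at `contact_rate`.
#'
#' @param cfg a `synth_config`.
#' @param ps output of [generate_peaksets()].
#' @param genes output of [generate_genes()].
#' @return list with `h3k27ac` (`interval_set`), `vista` (`interval_set`
#'   with ids), `expression` (data.frame gene x component ratios), `contacts`
#'   (data.frame in the contact-table schema) and `truth` (data.frame
#'   `vista_id`, `pattern`, `ccs_enriched`, `target_gene`).
#' @export
generate_catalogs_and_tables <- function(cfg, ps, genes) {
  streams <- .synth_streams(cfg$seed)
  set.seed(streams[["catalogs"]])
  tr <- ps$truth
  ## distal master regions: not within cutoff of any TSS
  pd <- split_proximal_distal(ps$master, genes, cutoff = cfg$cutoff_bp)
  distal_idx <- which(paste(tr$chrom, tr$start) %in% paste(pd$distal$chrom, pd$distal$start))
  covered <- distal_idx[stats::runif(length(distal_idx)) < cfg$h3k27ac_cover]
  h3k_rows <- tr[covered, c("chrom", "start", "end")]
  ## decoys in gaps: midpoints between consecutive regions
  if (cfg$n_h3k27ac_decoys > 0) {
    gaps <- list()
    for (ch in unique(tr$chrom)) {
      sub <- tr[tr$chrom == ch, ]
      if (nrow(sub) < 2) next
      mid <- floor((sub$end[-nrow(sub)] + sub$start[-1]) / 2)
      ok <- sub$start[-1] - sub$end[-nrow(sub)] > 700
      gaps[[ch]] <- data.frame(chrom = ch, start = mid[ok] - 150,
                               end = mid[ok] + 150, stringsAsFactors = FALSE)
    }
    gaps <- do.call(rbind, gaps)
    if (!is.null(gaps) && nrow(gaps) > 0) {
      pick <- sample.int(nrow(gaps), min(cfg$n_h3k27ac_decoys, nrow(gaps)))
      h3k_rows <- rbind(h3k_rows, gaps[pick, ])
    }
  }
  h3k27ac <- interval_set(h3k_rows, label = "H3K27ac", normalize = FALSE)

  vista_idx <- sample(covered, min(cfg$n_vista, length(covered)))
  vista_idx <- sort(vista_idx)
  vista_df <- tr[vista_idx, c("chrom", "start", "end")]
  vista_ids <- sprintf("syn%04d", seq_along(vista_idx))
  vista <- interval_set(vista_df$chrom, vista_df$start, vista_df$end,
                        name = vista_ids, label = "VISTA", normalize = FALSE)
  bits <- do.call(rbind, lapply(strsplit(tr$pattern[vista_idx], ""),
                                function(b) as.integer(b) == 1L))
  colnames(bits) <- CCS_SAMPLES
  ccs_enriched <- rowSums(bits[, c("SAN", "AVN", "VCS"), drop = FALSE]) > 0 & !bits[, "CM"]

  ## expression: decoys strictly below threshold, planted targets above
  comps <- c("SAN", "AVN", "VCS")
  expr <- data.frame(gene = genes$gene, stringsAsFactors = FALSE)
  for (cc in comps)
    expr[[cc]] <- stats::runif(nrow(genes), 0.5,
                               min(1.25, cfg$enrichment_threshold - 0.05))
  target_gene <- rep(NA_character_, length(vista_idx))
  contacts <- list()
  for (k in seq_along(vista_idx)) {
    if (!ccs_enriched[k]) next
    i <- vista_idx[k]
    same <- which(genes$chrom == tr$chrom[i])
    if (!length(same)) next
    g <- same[which.min(abs(genes$tss[same] - (tr$start[i] + tr$end[i]) / 2))]
    target_gene[k] <- genes$gene[g]
    for (cc in comps[bits[k, comps]])
      expr[[cc]][g] <- stats::runif(1, cfg$enrichment_threshold + 1, cfg$enrichment_threshold + 2.5)
    contacts[[length(contacts) + 1L]] <- data.frame(
      bait_chrom = genes$chrom[g], bait_start = max(0, genes$tss[g] - 1000),
      bait_end = genes$tss[g] + 1000, gene = genes$gene[g],
      other_chrom = tr$chrom[i], other_start = tr$start[i], other_end = tr$end[i],
      stringsAsFactors = FALSE)
  }
  ## decoy contacts
  if (cfg$contact_rate > 0) {
    n_decoy <- stats::rbinom(1, nrow(genes) * length(vista_idx), cfg$contact_rate)
    for (d in seq_len(n_decoy)) {
      g <- sample.int(nrow(genes), 1)
      i <- vista_idx[sample.int(length(vista_idx), 1)]
      contacts[[length(contacts) + 1L]] <- data.frame(
        bait_chrom = genes$chrom[g], bait_start = max(0, genes$tss[g] - 1000),
        bait_end = genes$tss[g] + 1000, gene = genes$gene[g],
        other_chrom = tr$chrom[i], other_start = tr$start[i], other_end = tr$end[i],
        stringsAsFactors = FALSE)
    }
  }
  contacts <- if (length(contacts)) do.call(rbind, contacts)
  else data.frame(bait_chrom = character(), bait_start = numeric(),
                  bait_end = numeric(), gene = character(),
                  other_chrom = character(), other_start = numeric(),
                  other_end = numeric(), stringsAsFactors = FALSE)
  truth <- data.frame(vista_id = vista_ids, pattern = tr$pattern[vista_idx],
                      ccs_enriched = ccs_enriched, target_gene = target_gene,
                      region = vista_idx, stringsAsFactors = FALSE)
  list(h3k27ac = h3k27ac, vista = vista, expression = expr, contacts = contacts,
       truth = truth)
}

## internal audit: every ground-truth entry must be consistent with the
## generated artifacts before a fixture is handed out
.audit_truth <- function(sim) {
  cfg <- sim$config
  occ <- build_occupancy(sim$master, sim$samples)
  stopifnot(identical(occ$category, sim$truth$regions$category))
  consensus <- pwm_consensus(cfg$pwm_panel[[cfg$planted_tf]])
  emb <- sim$truth$embeddings
  if (nrow(emb))
    stopifnot(all(vapply(seq_len(nrow(emb)), function(i)
      get_sequence(sim$genome, emb$chrom[i], emb$start[i], emb$end[i]) == consensus,
      TRUE)))
  stopifnot(all(sim$truth$vista$target_gene[!is.na(sim$truth$vista$target_gene)]
                %in% sim$genes$gene))
  invisible(TRUE)
}

#' Run the full synthetic-study generator
#'
#' Generates peak sets, genes, genome with planted motifs, catalogs and
#' tables, and SNPs with coordinate map; validates every ground-truth entry
#' against the generated artifacts; optionally writes all files in exactly
#' the formats the analysis modules read, with a manifest JSON.
#'
#' @param cfg a `synth_config`.
#' @param dir optional output directory; created if missing.
#' @return list with `master`, `samples`, `genes`, `genome`, `h3k27ac`,
#'   `vista`, `expression`, `contacts`, `snps`, `cmap`, `truth` (list of
#'   ground-truth tables), `config`, and `paths` when `dir` was given.
#' @export
simulate_study <- function(cfg = synth_config(), dir = NULL) {
  ps <- generate_peaksets(cfg)
  genes <- generate_genes(cfg, ps)
  gm <- generate_genome_and_motifs(cfg, ps, genes)
  cats <- generate_catalogs_and_tables(cfg, ps, genes)
  occ <- build_occupancy(ps$master, ps$samples)
  fold_sets <- stats::setNames(
    lapply(names(cfg$snp_fold), function(cat) category_regions(occ, cat)),
    names(cfg$snp_fold))
  snps <- generate_snps(cfg, fold_sets, genome = gm$genome)
  sim <- list(master = ps$master, samples = ps$samples, genes = genes,
              genome = gm$genome, h3k27ac = cats$h3k27ac, vista = cats$vista,
              expression = cats$expression, contacts = cats$contacts,
              snps = snps$snps, cmap = snps$cmap,
              fold_sets = fold_sets,
              truth = list(regions = ps$truth, embeddings = gm$embeddings,
                           planted_edges = gm$planted_edges,
                           vista = cats$truth, snps = snps$truth),
              config = cfg)
  .audit_truth(sim)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    p <- function(f) file.path(dir, f)
    paths <- list(master = p("master.bed"), genome = p("genome.fa"),
                  pwms = p("pwms.txt"), genes = p("genes.tsv"),
                  h3k27ac = p("h3k27ac.bed"), vista = p("vista.bed"),
                  expression = p("expression.tsv"), contacts = p("contacts.tsv"),
                  snps = p("snps.tsv"), blockmap = p("blockmap.tsv"))
    for (s in CCS_SAMPLES) {
      paths[[paste0("peaks_", s)]] <- p(paste0("peaks_", s, ".bed"))
      write_bed(sim$samples[[s]], paths[[paste0("peaks_", s)]])
    }
    write_bed(sim$master, paths$master)
    write_genome_fasta(sim$genome, paths$genome)
    write_jaspar(cfg$pwm_panel, paths$pwms)
    write_gene_annotation(genes[c("gene", "chrom", "tss", "strand")], paths$genes)
    write_bed(sim$h3k27ac, paths$h3k27ac)
    write_bed(sim$vista, paths$vista)
    utils::write.table(sim$expression, paths$expression, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(sim$contacts, paths$contacts, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    write_snp_table(sim$snps, paths$snps)
    write_block_map(sim$cmap, paths$blockmap)
    manifest <- list(seed = cfg$seed,
                     chrom_sizes = as.list(cfg$chrom_sizes),
                     n_regions = cfg$n_regions, n_genes = cfg$n_genes,
                     n_snps = cfg$n_snps, planted_tf = cfg$planted_tf,
                     plant_component = cfg$plant_component,
                     snp_fold = as.list(cfg$snp_fold),
                     files = lapply(paths, basename))
    jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE, pretty = TRUE)
    sim$paths <- paths
  }
  sim
}
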